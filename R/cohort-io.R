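#' @include AllClasses.R constructors.R
NULL

#' Write a cohort to tab-separated files
#'
#' Writes \code{cn.tsv} (header = gene ids, first column \code{sample_id}),
#' \code{variants.tsv} (long format: sample_id, gene_id, tumor_type, effect)
#' and \code{labels.tsv} (sample_id, tumor_type) into \code{directory}.
#'
#' @param cohort list with elements cn, variants, labels as returned by
#'   \code{\link{generateCohort}}
#' @param directory output directory (created if missing)
#' @return invisibly, the three file paths
#' @export
writeCohort <- function(cohort, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  cnPath <- file.path(directory, "cn.tsv")
  varPath <- file.path(directory, "variants.tsv")
  labPath <- file.path(directory, "labels.tsv")

  cn <- cohort$cn
  cnDf <- data.frame(sample_id = cn@sampleIds, cn@values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  names(cnDf) <- c("sample_id", cn@geneIds)
  utils::write.table(cnDf, cnPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$variants@records, varPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  labDf <- data.frame(sample_id = names(cohort$labels),
                      tumor_type = as.integer(cohort$labels),
                      stringsAsFactors = FALSE)
  utils::write.table(labDf, labPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(cn = cnPath, variants = varPath, labels = labPath))
}

#' Read a cohort written by \code{writeCohort}
#'
#' Malformed entries are rejected with an error naming the offending line and
#' column. An empty variants file yields an empty table.
#'
#' @param directory directory holding cn.tsv, variants.tsv and labels.tsv
#' @return a cohort list (cn, variants, labels)
#' @export
readCohort <- function(directory) {
  cnPath <- file.path(directory, "cn.tsv")
  varPath <- file.path(directory, "variants.tsv")
  labPath <- file.path(directory, "labels.tsv")
  for (p in c(cnPath, varPath, labPath))
    if (!file.exists(p)) stop("missing cohort file: ", p)

  cnDf <- utils::read.table(cnPath, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (names(cnDf)[1L] != "sample_id")
    stop("cn.tsv line 1, column 1: expected header 'sample_id'")
  vals <- as.matrix(cnDf[, -1L, drop = FALSE])
  bad <- which(!(vals %in% CN_LEVELS) | is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("cn.tsv line %d, column %d: value '%s' is not a copy-number level in {-2..2}",
                 bad[1L, 1L] + 1L, bad[1L, 2L] + 1L,
                 as.character(vals[bad[1L, 1L], bad[1L, 2L]])))
  cn <- cnMatrix(vals, cnDf$sample_id, colnames(cnDf)[-1L])

  labDf <- utils::read.table(labPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tumor_type") %in% names(labDf)))
    stop("labels.tsv line 1: expected columns sample_id, tumor_type")
  labels <- as.integer(labDf$tumor_type)
  names(labels) <- labDf$sample_id
  if (any(is.na(labels)) || any(labels < 1L))
    stop(sprintf("labels.tsv line %d, column 2: invalid tumor type",
                 which(is.na(labels) | labels < 1L)[1L] + 1L))

  recDf <- utils::read.table(varPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "character",
                                            "integer", "character"))
  if (nrow(recDf) > 0) {
    badEff <- which(!(recDf$effect %in% names(EFFECT_VALUES)))
    if (length(badEff) > 0)
      stop(sprintf("variants.tsv line %d, column 4: unknown effect level '%s'",
                   badEff[1L] + 1L, recDf$effect[badEff[1L]]))
    badSmp <- which(!(recDf$sample_id %in% cn@sampleIds))
    if (length(badSmp) > 0)
      stop(sprintf("variants.tsv line %d, column 1: unknown sample id '%s'",
                   badSmp[1L] + 1L, recDf$sample_id[badSmp[1L]]))
    badGene <- which(!(recDf$gene_id %in% cn@geneIds))
    if (length(badGene) > 0)
      stop(sprintf("variants.tsv line %d, column 2: unknown gene id '%s'",
                   badGene[1L] + 1L, recDf$gene_id[badGene[1L]]))
  }
  nTypes <- max(labels, if (nrow(recDf)) recDf$tumor_type else 1L)
  variants <- variantsTable(recDf, cn@sampleIds, cn@geneIds, nTypes)
  list(cn = cn, variants = variants, labels = labels)
}
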