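#' @include AllClasses.R constructors.R
NULL

#' Hamming distance between two gene columns
#'
#' Counts positions where the two vectors disagree; the normalized value is
#' the count divided by the vector length (the fraction of samples that
#' disagree).
#'
#' @param p,q equal-length vectors
#' @return list with elements \code{count} and \code{normalized}
#' @examples
#' hammingDist(c(0, 1, 2, -1), c(0, 2, 2, 1))  # count 2, normalized 0.5
#' @export
hammingDist <- function(p, q) {
  if (length(p) != length(q)) stop("hammingDist: length mismatch")
  cnt <- sum(p != q)
  list(count = cnt, normalized = cnt / length(p))
}

#' Copy-number gene filtering by greedy Hamming clustering
#'
#' Genes (columns, assumed sorted by chromosomal position) are grouped left to
#' right: the current representative absorbs each following gene while the
#' normalized Hamming distance between the representative's column and the
#' gene's column stays below \code{dCN}; the first gene at distance >= dCN
#' starts a new group. One representative (the first gene) is kept per group.
#'
#' @param cn a \linkS4class{CNMatrix} (or plain matrix)
#' @param dCN normalized distance threshold in [0,1). \code{dCN = 0} keeps
#'   every gene (no distance is below 0).
#' @return list with \code{values} (filtered matrix, original column order),
#'   \code{genes} (representative gene ids)
#' @export
cnFilter <- function(cn, dCN) {
  if (is(cn, "CNMatrix")) {
    vals <- cn@values; genes <- cn@geneIds
  } else {
    vals <- cn; genes <- colnames(cn)
    if (is.null(genes)) genes <- paste0("G", seq_len(ncol(vals)))
  }
  if (length(vals) == 0L || ncol(vals) == 0L) stop("cnFilter: empty matrix")
  if (dCN < 0 || dCN >= 1) stop("cnFilter: dCN must lie in [0,1)")
  s <- nrow(vals)
  reps <- 1L
  repCol <- vals[, 1L]
  if (ncol(vals) > 1L) {
    for (j in 2:ncol(vals)) {
      d <- sum(repCol != vals[, j]) / s
      if (d < dCN) next           # absorbed into the current group
      reps <- c(reps, j)          # distance reached the threshold: new group
      repCol <- vals[, j]
    }
  }
  list(values = vals[, reps, drop = FALSE], genes = genes[reps])
}

#' Encode mutation-effect levels to fixed real values
#'
#' LOW = 0.2, MODERATE = 0.5, MODIFIER = 0.9, HIGH = 1.0; \code{NA} (no
#' record) encodes to 0. Unknown strings are rejected.
#'
#' @param level character vector of effect levels (or NA for absent)
#' @return numeric vector of encoded values
#' @export
encodeEffect <- function(level) {
  out <- rep(0, length(level))
  present <- !is.na(level)
  bad <- present & !(level %in% names(EFFECT_VALUES))
  if (any(bad))
    stop("encodeEffect: unknown effect level '", level[which(bad)[1L]], "'")
  out[present] <- EFFECT_VALUES[level[present]]
  out
}

# dense encoded matrix over (samples x genes) from long records;
# multiple records for one cell are combined by sum (default) or max
encodeVariantsMatrix <- function(records, sampleIds, geneIds,
                                 aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  V <- matrix(0, length(sampleIds), length(geneIds),
              dimnames = list(sampleIds, geneIds))
  if (nrow(records) == 0L) return(V)
  i <- match(records$sample_id, sampleIds)
  j <- match(records$gene_id, geneIds)
  keep <- !is.na(i) & !is.na(j)
  i <- i[keep]; j <- j[keep]
  v <- encodeEffect(records$effect[keep])
  if (aggregate == "sum") {
    for (k in seq_along(v)) V[i[k], j[k]] <- V[i[k], j[k]] + v[k]
  } else {
    for (k in seq_along(v)) V[i[k], j[k]] <- max(V[i[k], j[k]], v[k])
  }
  V
}

#' Variants gene filtering by per-class effect mass
#'
#' For each tumor type t the records of type-t samples are encoded into a
#' dense matrix V_t; gene j is selected when the column sum of V_t strictly
#' exceeds \code{kVar}. The final gene set is the union over tumor types; the
#' returned matrix is the whole-cohort encoded matrix restricted to the
#' selected genes (absent entries are 0).
#'
#' @param variants a \linkS4class{VariantsTable}
#' @param labels named integer vector of tumor types per sample (training
#'   labels; used to split the records by type)
#' @param kVar effect-mass threshold; selection uses strict \code{>}
#' @param aggregate how multiple records in one (sample, gene) cell combine
#' @return list with \code{values} (samples x selected genes matrix, sample
#'   order = variants sample universe) and \code{genes} (selected ids, in
#'   gene-universe order)
#' @export
variantsFilter <- function(variants, labels, kVar,
                           aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is(variants, "VariantsTable"))
  if (variants@nTypes < 1L) stop("variantsFilter: no tumor types")
  if (kVar < 0) stop("variantsFilter: kVar must be >= 0")
  rec <- variants@records
  genes <- variants@geneIds
  selected <- logical(length(genes))
  for (t in seq_len(variants@nTypes)) {
    typeSamples <- names(labels)[labels == t]
    if (length(typeSamples) == 0L) next
    recT <- rec[rec$sample_id %in% typeSamples, , drop = FALSE]
    if (nrow(recT) == 0L) next
    Vt <- encodeVariantsMatrix(recT, typeSamples, genes, aggregate)
    selected <- selected | (colSums(Vt) > kVar)
  }
  sel <- genes[selected]
  V <- encodeVariantsMatrix(rec, variants@sampleIds, sel, aggregate)
  list(values = V, genes = sel)
}

#' Assemble the model-input feature matrix
#'
#' Concatenates the filtered copy-number and variants matrices column-wise,
#' optionally appends a constant-one bias column, and zero-pads both
#' dimensions to the next power of two.
#'
#' @param cnFiltered output of \code{\link{cnFilter}} (or a plain matrix with
#'   gene ids as colnames)
#' @param varFiltered output of \code{\link{variantsFilter}} (or a matrix);
#'   may be NULL when no variants features are used
#' @param addBias append a constant-one column (matched by the bias row of a
#'   composed weight matrix)
#' @return a \linkS4class{FeatureMatrix}
#' @export
assembleFeatures <- function(cnFiltered, varFiltered = NULL, addBias = FALSE) {
  asPart <- function(x, prefix) {
    if (is.null(x)) return(list(values = NULL, genes = character()))
    if (is.list(x) && !is.null(x$values)) return(x)
    list(values = x, genes = colnames(x) %||% paste0(prefix, seq_len(ncol(x))))
  }
  cnP <- asPart(cnFiltered, "CN")
  vaP <- asPart(varFiltered, "VAR")
  if (!is.null(cnP$values) && !is.null(vaP$values)) {
    if (nrow(cnP$values) != nrow(vaP$values))
      stop("assembleFeatures: sample mismatch between CN and variants parts")
    cnRn <- rownames(cnP$values); vaRn <- rownames(vaP$values)
    if (!is.null(cnRn) && !is.null(vaRn) && !identical(cnRn, vaRn))
      stop("assembleFeatures: sample order differs between CN and variants parts")
  }
  X <- cbind(cnP$values, vaP$values)
  if (is.null(X)) stop("assembleFeatures: no input features")
  s <- nrow(X); g0 <- ncol(X)
  if (addBias) X <- cbind(X, 1)
  g <- ncol(X)
  Xp <- zeroPadMatrix(X, nextPow2(s), nextPow2(g))
  new("FeatureMatrix", X = unname(Xp), nSamples = as.integer(s),
      nFeatures = as.integer(g), cnGenes = as.character(cnP$genes),
      varGenes = as.character(vaP$genes), hasBias = addBias)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
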