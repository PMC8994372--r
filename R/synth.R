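#' @include AllClasses.R constructors.R
NULL

# run expr under a fixed seed without clobbering the caller's RNG stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# replace values[idx] by a different copy-number level, uniformly at random
resampleAway <- function(values, idx) {
  if (!any(idx)) return(values)
  k <- sum(idx)
  # offset 1..4 from the current level, cyclic over the 5 levels
  cur <- match(values[idx], CN_LEVELS)
  off <- sample.int(4L, k, replace = TRUE)
  values[idx] <- CN_LEVELS[((cur - 1L + off) %% 5L) + 1L]
  values
}

#' Generate a synthetic cohort
#'
#' Emulates the statistical structure the classification method assumes:
#' \itemize{
#'   \item 5-level copy numbers with positional similarity: contiguous blocks
#'     of \code{blockSize} genes share a per-sample base profile; each entry
#'     disagrees with its block with probability \code{flipProb}. Adjacent
#'     blocks are forced to differ in every sample, so with
#'     \code{flipProb = 0} the copy-number filter recovers exactly one
#'     representative per block at any threshold in (0, 1).
#'   \item class signal: each block carries a per-class prototype level that a
#'     sample's base value follows with probability \code{signalStrength}.
#'   \item sparse per-class mutation-effect records: every (sample, gene) pair
#'     mutates at the baseline \code{mutationRate}; genes informative for the
#'     sample's class mutate at a rate boosted by up to 10x with
#'     \code{signalStrength}. Effect levels are drawn from
#'     \code{effectWeights}.
#' }
#' Identical configurations (including the seed) reproduce identical cohorts.
#'
#' @param cfg a \linkS4class{SynthConfig}
#' @return a list with elements \code{cn} (\linkS4class{CNMatrix}),
#'   \code{variants} (\linkS4class{VariantsTable}) and \code{labels}
#'   (named integer vector of tumor types in 1..nTumorTypes)
#' @examples
#' coh <- generateCohort(synthConfig(nSamples = 16, nGenes = 64, seed = 1))
#' dim(cnValues(coh$cn))
#' @export
generateCohort <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  withSeed(cfg@seed, {
    n <- cfg@nSamples; G <- cfg@nGenes; T <- cfg@nTumorTypes
    b <- cfg@blockSize
    sampleIds <- sprintf("S%04d", seq_len(n))
    geneIds <- sprintf("G%05d", seq_len(G))

    labels <- sample(rep_len(seq_len(T), n))
    names(labels) <- sampleIds

    nBlocks <- ceiling(G / b)
    blockOf <- rep(seq_len(nBlocks), each = b)[seq_len(G)]

    # per-block class prototypes and per-sample base profiles
    proto <- matrix(sample(CN_LEVELS, nBlocks * T, replace = TRUE),
                    nBlocks, T)
    base <- matrix(0L, n, nBlocks)
    for (blk in seq_len(nBlocks)) {
      useProto <- stats::runif(n) < cfg@signalStrength
      v <- ifelse(useProto, proto[blk, labels],
                  sample(CN_LEVELS, n, replace = TRUE))
      if (blk > 1L) v <- resampleAway(v, v == base[, blk - 1L])
      base[, blk] <- v
    }

    cn <- base[, blockOf, drop = FALSE]
    if (cfg@flipProb > 0) {
      flip <- matrix(stats::runif(n * G) < cfg@flipProb, n, G)
      cn <- matrix(resampleAway(as.vector(cn), as.vector(flip)), n, G)
    }
    cnObj <- cnMatrix(cn, sampleIds, geneIds)

    # class-informative genes for the variants channel
    nInf <- max(1L, round(0.02 * G))
    infGenes <- matrix(0L, nInf, T)
    for (t in seq_len(T)) infGenes[, t] <- sample.int(G, nInf)
    boost <- 1 + 9 * cfg@signalStrength

    rate <- matrix(cfg@mutationRate, n, G)
    for (t in seq_len(T)) {
      rows <- which(labels == t)
      rate[rows, infGenes[, t]] <- pmin(1, cfg@mutationRate * boost)
    }
    hit <- which(matrix(stats::runif(n * G), n, G) < rate, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      eff <- sample(names(EFFECT_VALUES), nrow(hit), replace = TRUE,
                    prob = cfg@effectWeights)
      records <- data.frame(sample_id = sampleIds[hit[, 1L]],
                            gene_id = geneIds[hit[, 2L]],
                            tumor_type = labels[hit[, 1L]],
                            effect = eff, stringsAsFactors = FALSE)
      records <- records[order(records$sample_id, records$gene_id), ]
      rownames(records) <- NULL
    } else {
      records <- data.frame(sample_id = character(), gene_id = character(),
                            tumor_type = integer(), effect = character(),
                            stringsAsFactors = FALSE)
    }
    variants <- variantsTable(records, sampleIds, geneIds, T)
    list(cn = cnObj, variants = variants, labels = labels)
  })
}

subsetCohort <- function(cohort, ids) {
  cn <- cohort$cn
  keep <- match(ids, cn@sampleIds)
  cnSub <- cnMatrix(cn@values[keep, , drop = FALSE], ids, cn@geneIds)
  rec <- cohort$variants@records
  recSub <- rec[rec$sample_id %in% ids, , drop = FALSE]
  rownames(recSub) <- NULL
  vaSub <- variantsTable(recSub, ids, cn@geneIds, cohort$variants@nTypes)
  list(cn = cnSub, variants = vaSub, labels = cohort$labels[ids])
}

#' Split a cohort into training and test parts
#'
#' Stratified by tumor type so both parts contain every class.
#'
#' @param cohort a cohort list from \code{\link{generateCohort}}
#' @param trainFraction fraction of each class assigned to training
#' @param seed RNG seed for the split
#' @return list with elements \code{train} and \code{test}, each a cohort list
#' @export
splitCohort <- function(cohort, trainFraction = 0.75, seed = 1L) {
  labels <- cohort$labels
  withSeed(seed, {
    trainIds <- unlist(lapply(unique(labels), function(t) {
      ids <- sample(names(labels)[labels == t])
      ids[seq_len(max(1L, round(trainFraction * length(ids))))]
    }))
    testIds <- setdiff(names(labels), trainIds)
    list(train = subsetCohort(cohort, sort(trainIds)),
         test = subsetCohort(cohort, sort(testIds)))
  })
}
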