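#' @include AllClasses.R
NULL

#' Construct a copy-number matrix
#'
#' @param values integer matrix (samples x genes) with entries in \{0,+/-1,+/-2\}
#' @param sampleIds,geneIds identifier vectors; taken from dimnames when NULL.
#'   Column order defines the positional (chromosomal) gene order used by
#'   \code{\link{cnFilter}}.
#' @return a \linkS4class{CNMatrix}
#' @export
cnMatrix <- function(values, sampleIds = rownames(values),
                     geneIds = colnames(values)) {
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nrow(values)))
  if (is.null(geneIds)) geneIds <- paste0("G", seq_len(ncol(values)))
  storage.mode(values) <- "integer"
  dimnames(values) <- NULL
  new("CNMatrix", values = values, sampleIds = as.character(sampleIds),
      geneIds = as.character(geneIds))
}

#' Construct a variants-record table
#'
#' @param records data.frame with columns sample_id, gene_id, tumor_type,
#'   effect
#' @param sampleIds,geneIds the sample and gene universe the records live in
#' @param nTypes number of tumor types
#' @return a \linkS4class{VariantsTable}
#' @export
variantsTable <- function(records, sampleIds, geneIds, nTypes) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    records <- data.frame(sample_id = character(), gene_id = character(),
                          tumor_type = integer(), effect = character(),
                          stringsAsFactors = FALSE)
  records$sample_id <- as.character(records$sample_id)
  records$gene_id <- as.character(records$gene_id)
  records$tumor_type <- as.integer(records$tumor_type)
  records$effect <- as.character(records$effect)
  new("VariantsTable", records = records,
      sampleIds = as.character(sampleIds), geneIds = as.character(geneIds),
      nTypes = as.integer(nTypes))
}

#' Synthetic-cohort configuration
#'
#' Defaults emulate the study conditions the downstream stages assume: an
#' 11-class cohort with block-correlated 5-level copy numbers and sparse
#' per-class mutation-effect records carrying a learnable linear signal.
#' The default effect-level weights follow the marginal level frequencies of
#' the competition dataset (LOW/MODERATE/MODIFIER/HIGH roughly
#' 22/53/16/9 percent).
#'
#' @param nSamples,nGenes,nTumorTypes cohort dimensions
#' @param blockSize genes per correlated copy-number block
#' @param flipProb within-block disagreement probability
#' @param mutationRate baseline mutation-record rate per (sample, gene)
#' @param effectWeights probability vector over LOW/MODERATE/MODIFIER/HIGH
#' @param signalStrength class-signal probability in [0,1]
#' @param seed RNG seed (required)
#' @return a \linkS4class{SynthConfig}
#' @export
synthConfig <- function(nSamples = 512L, nGenes = 2048L, nTumorTypes = 11L,
                        blockSize = 8L, flipProb = 0.05,
                        mutationRate = 0.01,
                        effectWeights = c(0.2215, 0.5302, 0.1576, 0.0907),
                        signalStrength = 0.9, seed) {
  if (missing(seed)) stop("seed is a required SynthConfig field")
  new("SynthConfig", nSamples = as.integer(nSamples),
      nGenes = as.integer(nGenes), nTumorTypes = as.integer(nTumorTypes),
      blockSize = as.integer(blockSize), flipProb = flipProb,
      mutationRate = mutationRate,
      effectWeights = effectWeights / sum(effectWeights),
      signalStrength = signalStrength, seed = as.integer(seed))
}

#' Gene-filter parameters
#' @param dCN normalized Hamming threshold in [0,1)
#' @param kVar effect-mass threshold (>= 0)
#' @param B model-size exponent (filtered feature count capped at 2^B)
#' @return a \linkS4class{FilterParams}
#' @export
filterParams <- function(dCN, kVar, B = 10L) {
  new("FilterParams", dCN = dCN, kVar = kVar, B = as.integer(B))
}

#' Training configuration
#' @param batchSize minibatch size
#' @param epochs training epochs
#' @param dropoutRate dropout rate on the hidden layer
#' @param nHidden hidden-layer width
#' @param folds cross-validation folds
#' @param learningRate Adam learning rate
#' @param useBias train with bias terms (folded into the composed matrix)
#' @param seed RNG seed for initialization, shuffling and dropout
#' @return a \linkS4class{TrainConfig}
#' @export
trainConfig <- function(batchSize = 32L, epochs = 50L, dropoutRate = 0.9,
                        nHidden = 64L, folds = 10L, learningRate = 0.01,
                        useBias = TRUE, seed = 1L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), dropoutRate = dropoutRate,
      nHidden = as.integer(nHidden), folds = as.integer(folds),
      learningRate = learningRate, useBias = useBias, seed = as.integer(seed))
}

#' Approximate-softmax configuration
#' @param r squaring-count exponent
#' @param L exponential scaling constant
#' @param M Goldschmidt input scale
#' @param d Goldschmidt factor count
#' @return a \linkS4class{SoftmaxConfig}
#' @export
softmaxConfig <- function(r = 4L, L = 64, M = 80, d = 30L) {
  new("SoftmaxConfig", r = as.integer(r), L = L, M = M, d = as.integer(d))
}

#' Derived normalizer Lr = (L/2^r)^(2^r)
#'
#' Satisfies Lr * aeExp(x, r, L) ~ exp(x).
#' @param cfg a \linkS4class{SoftmaxConfig}
#' @return the normalizing constant
#' @export
softmaxLr <- function(cfg) (cfg@L / 2^cfg@r)^(2^cfg@r)
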