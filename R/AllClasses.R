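#' @import methods
NULL

CN_LEVELS <- c(-2L, -1L, 0L, 1L, 2L)

#' Effect-level encoding values
#'
#' Mutation-effect levels are encoded to fixed real values: LOW = 0.2,
#' MODERATE = 0.5, MODIFIER = 0.9, HIGH = 1.0; absence of a record encodes
#' to 0.
#' @keywords internal
EFFECT_VALUES <- c(LOW = 0.2, MODERATE = 0.5, MODIFIER = 0.9, HIGH = 1.0)

# ---------------------------------------------------------------------------
# Cohort containers
# ---------------------------------------------------------------------------

#' Copy-number matrix
#'
#' Samples x genes integer matrix of gene-level copy-number calls in
#' \{0, +/-1, +/-2\}, with genes stored in chromosomal-position order (column
#' order is the positional order the copy-number filter relies on).
#'
#' @slot values integer matrix, samples in rows, genes in columns
#' @slot sampleIds character vector of sample identifiers (row names)
#' @slot geneIds character vector of gene identifiers in positional order
#' @exportClass CNMatrix
setClass("CNMatrix",
  representation(values = "matrix", sampleIds = "character",
                 geneIds = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != length(object@sampleIds))
      return("number of rows must equal length(sampleIds)")
    if (ncol(v) != length(object@geneIds))
      return("number of columns must equal length(geneIds)")
    if (anyDuplicated(object@geneIds)) return("duplicated gene ids")
    if (anyDuplicated(object@sampleIds)) return("duplicated sample ids")
    if (!all(v %in% CN_LEVELS))
      return("copy-number values must lie in {-2,-1,0,1,2}")
    TRUE
  })

#' Sparse mutation-effect records
#'
#' Long-format records (sample, gene, tumor type, effect level) of predicted
#' somatic-mutation effects, together with the sample and gene universe needed
#' to build the dense encoded per-tumor-type matrices.
#'
#' @slot records data.frame with columns sample_id, gene_id, tumor_type,
#'   effect (effect in LOW/MODERATE/MODIFIER/HIGH)
#' @slot sampleIds sample universe
#' @slot geneIds gene universe (shared with the copy-number matrix)
#' @slot nTypes number of tumor types
#' @exportClass VariantsTable
setClass("VariantsTable",
  representation(records = "data.frame", sampleIds = "character",
                 geneIds = "character", nTypes = "integer"),
  validity = function(object) {
    r <- object@records
    need <- c("sample_id", "gene_id", "tumor_type", "effect")
    if (!all(need %in% names(r)))
      return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (nrow(r) > 0) {
      if (!all(r$effect %in% names(EFFECT_VALUES)))
        return("unknown effect level(s): effects must be LOW, MODERATE, MODIFIER or HIGH")
      if (!all(r$sample_id %in% object@sampleIds))
        return("records reference unknown sample ids")
      if (!all(r$gene_id %in% object@geneIds))
        return("records reference unknown gene ids")
      if (!all(r$tumor_type %in% seq_len(object@nTypes)))
        return("records reference tumor types outside 1..nTypes")
    }
    if (object@nTypes < 1L) return("nTypes must be >= 1")
    TRUE
  })

#' Assembled model-input matrix
#'
#' Concatenation X = [C_filtered | V_filtered] (plus an optional constant-one
#' bias column), zero-padded so both dimensions are powers of two. True
#' (unpadded) dimensions are retained so padding can be stripped after
#' inference.
#'
#' @slot X numeric matrix with power-of-two dimensions
#' @slot nSamples true sample count before row padding
#' @slot nFeatures true feature count before column padding
#' @slot cnGenes ids of the copy-number feature columns
#' @slot varGenes ids of the variants feature columns
#' @slot hasBias TRUE when a constant-one column was appended before padding
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(X = "matrix", nSamples = "integer", nFeatures = "integer",
                 cnGenes = "character", varGenes = "character",
                 hasBias = "logical"),
  validity = function(object) {
    if (!isPow2(nrow(object@X)) || !isPow2(ncol(object@X)))
      return("padded dimensions must be powers of two")
    if (object@nSamples > nrow(object@X) || object@nFeatures > ncol(object@X))
      return("true dims exceed padded dims")
    s <- object@nSamples; g <- object@nFeatures
    if (s < nrow(object@X) &&
        any(object@X[(s + 1):nrow(object@X), ] != 0))
      return("padding rows must be all-zero")
    if (g < ncol(object@X) &&
        any(object@X[, (g + 1):ncol(object@X)] != 0))
      return("padding columns must be all-zero")
    TRUE
  })

# ---------------------------------------------------------------------------
# Configuration objects
# ---------------------------------------------------------------------------

#' Synthetic-cohort configuration
#'
#' @slot nSamples,nGenes,nTumorTypes cohort dimensions
#' @slot blockSize genes per correlated copy-number block
#' @slot flipProb probability a copy-number entry disagrees with its block
#' @slot mutationRate expected fraction of (sample, gene) pairs carrying a
#'   mutation record at baseline
#' @slot effectWeights probability vector over LOW/MODERATE/MODIFIER/HIGH
#' @slot signalStrength probability in [0,1] that a block's base copy number
#'   follows the class prototype (0 = no class signal); also scales the
#'   mutation-rate boost of class-informative genes
#' @slot seed RNG seed (required; one stream per cohort)
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(nSamples = "integer", nGenes = "integer",
                 nTumorTypes = "integer", blockSize = "integer",
                 flipProb = "numeric", mutationRate = "numeric",
                 effectWeights = "numeric", signalStrength = "numeric",
                 seed = "integer"),
  validity = function(object) {
    for (f in c("nSamples", "nGenes", "nTumorTypes", "blockSize")) {
      if (slot(object, f) < 1L) return(paste0(f, " must be >= 1"))
    }
    for (f in c("flipProb", "mutationRate", "signalStrength")) {
      v <- slot(object, f)
      if (v < 0 || v > 1) return(paste0(f, " must be a probability in [0,1]"))
    }
    w <- object@effectWeights
    if (length(w) != 4L) return("effectWeights must have length 4")
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
      return("effectWeights must be nonnegative and sum to 1")
    if (length(object@seed) != 1L || is.na(object@seed))
      return("seed must be a single integer")
    TRUE
  })

#' Gene-filter parameters
#'
#' @slot dCN normalized Hamming-distance threshold in [0,1) for copy-number
#'   clustering
#' @slot kVar effect-mass threshold (>= 0) for variants selection
#' @slot B model-size exponent; the filtered feature count must not exceed 2^B
#' @exportClass FilterParams
setClass("FilterParams",
  representation(dCN = "numeric", kVar = "numeric", B = "integer"),
  validity = function(object) {
    if (object@dCN < 0 || object@dCN >= 1) return("dCN must lie in [0,1)")
    if (object@kVar < 0) return("kVar must be >= 0")
    if (object@B < 1L) return("B must be a positive integer")
    TRUE
  })

#' Shallow-network training configuration
#'
#' Defaults follow the protocol's training recipe: batch size 32, 50 epochs,
#' dropout rate 0.9 on the 64-node linear hidden layer, 10 cross-validation
#' folds. The optimizer (Adam) and learning rate are implementation defaults.
#'
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(batchSize = "integer", epochs = "integer",
                 dropoutRate = "numeric", nHidden = "integer",
                 folds = "integer", learningRate = "numeric",
                 useBias = "logical", seed = "integer"),
  validity = function(object) {
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      return("dropoutRate must lie in [0,1)")
    if (object@folds < 2L) return("folds must be >= 2")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@epochs < 0L) return("epochs must be >= 0")
    if (object@nHidden < 1L) return("nHidden must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be > 0")
    TRUE
  })

#' Approximate-softmax configuration
#'
#' Parameters of the polynomial softmax: the scaled-limit exponential
#' AE_{r,L}(x) = ((2^r + x)/L)^(2^r) and Goldschmidt inversion of the class
#' sum on (0, 2M) with d product factors. Lr = (L/2^r)^(2^r) is the derived
#' normalizer satisfying Lr * AE(x) ~ exp(x).
#'
#' @slot r squaring count exponent (>= 1)
#' @slot L exponential scaling constant (> 0)
#' @slot M Goldschmidt input scale (> 0)
#' @slot d Goldschmidt factor count (>= 1)
#' @exportClass SoftmaxConfig
setClass("SoftmaxConfig",
  representation(r = "integer", L = "numeric", M = "numeric", d = "integer"),
  validity = function(object) {
    if (object@r < 1L) return("r must be >= 1")
    if (object@L <= 0) return("L must be > 0")
    if (object@M <= 0) return("M must be > 0")
    if (object@d < 1L) return("d must be >= 1")
    TRUE
  })

# ---------------------------------------------------------------------------
# HE-side objects
# ---------------------------------------------------------------------------

#' Simulated CKKS ciphertext
#'
#' A length-n complex slot vector with a remaining-level counter. Stands in
#' for a CKKS ciphertext: every slotwise operation acts on all n slots in
#' parallel, and each (constant) multiplication consumes one level.
#'
#' @slot slots complex vector of length n
#' @slot level remaining multiplicative levels (nonnegative)
#' @slot n slot count (power of two)
#' @slot ctx the simulator context holding operation counters
#' @exportClass SimCipher
setClass("SimCipher",
  representation(slots = "complex", level = "integer", n = "integer",
                 ctx = "environment"),
  validity = function(object) {
    if (!isPow2(object@n)) return("slot count n must be a power of two")
    if (length(object@slots) != object@n)
      return("slot vector length must equal n")
    if (object@level < 0L) return("level must be nonnegative")
    TRUE
  })

#' Packing plan for the encrypted matrix-vector product
#'
#' Describes how a padded s x g input matrix is packed into ciphertexts with
#' n slots using duplication factor m. With complex pairing two diagonals
#' share one slot vector (real + imaginary part), so each ciphertext carries
#' ell = 2n/(ms) diagonals and g/ell ciphertexts are needed; real-only
#' packing carries ell = n/(ms) and needs twice as many.
#'
#' @slot s padded sample count (power of two)
#' @slot g padded feature count (power of two)
#' @slot T number of output classes
#' @slot n slot count (power of two)
#' @slot m duplication factor (power of two)
#' @slot complexPack TRUE for complex-pair (imaginary-part) packing
#' @exportClass PackingPlan
setClass("PackingPlan",
  representation(s = "integer", g = "integer", T = "integer", n = "integer",
                 m = "integer", complexPack = "logical"),
  validity = function(object) {
    for (f in c("s", "g", "n", "m"))
      if (!isPow2(slot(object, f)))
        return(paste0(f, " must be a power of two"))
    if (object@T < 1L) return("T must be >= 1")
    if (object@m * object@s > object@n)
      return("m*s exceeds the slot count n")
    ell <- if (object@complexPack) 2L * object@n %/% (object@m * object@s)
           else object@n %/% (object@m * object@s)
    if (object@complexPack && ell < 2L)
      return("complex packing needs ell = 2n/(ms) >= 2")
    if (object@g %% ell != 0L && object@g > ell)
      return("g must be a multiple of the per-ciphertext diagonal count ell")
    if (object@g < ell)
      return(paste0("slot count too large: one ciphertext would hold ", ell,
                    " diagonals but only g = ", object@g, " exist"))
    TRUE
  })

#' Trained shallow-network weights
#'
#' The plain-side two-layer parameterization (W1, b1, W2, b2) together with
#' the composed inference matrix W. When biases are used the net bias
#' b1 %*% W2 + b2 is folded into W as an extra row matched by a constant-one
#' feature column, so encrypted inference is a single matrix product.
#'
#' @exportClass ModelWeights
setClass("ModelWeights",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 W = "matrix", useBias = "logical"))

#' Trained model bundle
#'
#' Everything encrypted inference needs: composed weights, the selected gene
#' lists (the only thing the client needs to prepare its data), the filter
#' parameters and the calibrated softmax configuration.
#'
#' @exportClass SNNModel
setClass("SNNModel",
  representation(weights = "ModelWeights", cnGenes = "character",
                 varGenes = "character", filterParams = "FilterParams",
                 softmaxCfg = "SoftmaxConfig", nClasses = "integer",
                 varAggregate = "character"))

#' Result of an encrypted inference run
#'
#' @slot scores samples x classes matrix of approximate-softmax outputs
#' @slot predicted argmax class per sample
#' @slot metrics named list (microAUC, accuracy) when labels were supplied
#' @slot costs named list of simulator operation counts
#' @exportClass InferenceResult
setClass("InferenceResult",
  representation(scores = "matrix", predicted = "integer",
                 metrics = "list", costs = "list"),
  validity = function(object) {
    if (length(object@predicted) != nrow(object@scores))
      return("one predicted label per score row required")
    if (length(object@predicted) &&
        (min(object@predicted) < 1L || max(object@predicted) > ncol(object@scores)))
      return("predicted labels must lie in 1..T")
    TRUE
  })
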