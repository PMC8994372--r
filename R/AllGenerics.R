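#' @include AllClasses.R
NULL

#' Accessors for cohort and HE containers
#'
#' @param x an object
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cnValues", function(x) standardGeneric("cnValues"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("slotValues", function(x) standardGeneric("slotValues"))
#' @rdname accessors
#' @export
setGeneric("ctLevel", function(x) standardGeneric("ctLevel"))
#' @rdname accessors
#' @export
setGeneric("composedWeights", function(x) standardGeneric("composedWeights"))
#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))
#' @rdname accessors
#' @export
setGeneric("inferenceScores", function(x) standardGeneric("inferenceScores"))

setMethod("cnValues", "CNMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@sampleIds, x@geneIds)
  v
})
setMethod("geneIds", "CNMatrix", function(x) x@geneIds)
setMethod("sampleIds", "CNMatrix", function(x) x@sampleIds)
setMethod("geneIds", "VariantsTable", function(x) x@geneIds)
setMethod("sampleIds", "VariantsTable", function(x) x@sampleIds)
setMethod("variantRecords", "VariantsTable", function(x) x@records)
setMethod("featureValues", "FeatureMatrix", function(x) x@X)
setMethod("slotValues", "SimCipher", function(x) x@slots)
setMethod("ctLevel", "SimCipher", function(x) x@level)
setMethod("composedWeights", "SNNModel", function(x) x@weights@W)
setMethod("selectedGenes", "SNNModel",
  function(x) list(cn = x@cnGenes, var = x@varGenes))
setMethod("inferenceScores", "InferenceResult", function(x) x@scores)

setMethod("show", "CNMatrix", function(object) {
  cat("CNMatrix:", length(object@sampleIds), "samples x",
      length(object@geneIds), "genes; levels in {-2..2}\n")
})
setMethod("show", "VariantsTable", function(object) {
  cat("VariantsTable:", nrow(object@records), "records over",
      length(object@sampleIds), "samples,", length(object@geneIds),
      "genes,", object@nTypes, "tumor types\n")
})
setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", object@nSamples, "x", object@nFeatures,
      "(padded to", nrow(object@X), "x", ncol(object@X), ");",
      length(object@cnGenes), "CN +", length(object@varGenes),
      "variant genes", if (object@hasBias) "+ bias column" else "", "\n")
})
setMethod("show", "SimCipher", function(object) {
  cat("SimCipher:", object@n, "slots, level", object@level, "\n")
})
setMethod("show", "PackingPlan", function(object) {
  cat("PackingPlan: s =", object@s, "g =", object@g, "T =", object@T,
      "n =", object@n, "m =", object@m,
      if (object@complexPack) "(complex-pair packing)" else "(real-only)",
      "\n  ", planDiagsPerCt(object), "diagonals/ciphertext,",
      planCipherCount(object), "ciphertext(s)\n")
})
setMethod("show", "SoftmaxConfig", function(object) {
  cat(sprintf("SoftmaxConfig: r = %d, L = %g, M = %g, d = %d (Lr = %g)\n",
              object@r, object@L, object@M, object@d,
              (object@L / 2^object@r)^(2^object@r)))
})
setMethod("show", "SNNModel", function(object) {
  cat("SNNModel:", nrow(object@weights@W), "x", ncol(object@weights@W),
      "composed weight matrix;", length(object@cnGenes), "CN genes,",
      length(object@varGenes), "variant genes,", object@nClasses, "classes\n")
})
setMethod("show", "InferenceResult", function(object) {
  cat("InferenceResult:", nrow(object@scores), "samples x",
      ncol(object@scores), "classes\n")
  if (length(object@metrics))
    cat("  metrics:", paste(names(object@metrics),
        sprintf("%.4f", unlist(object@metrics)), collapse = ", "), "\n")
})
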