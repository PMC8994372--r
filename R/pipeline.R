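#' @include AllClasses.R train.R packing.R softmax.R metrics.R preprocess.R
NULL

# feature matrix of a cohort restricted to a model's selected genes
modelFeatures <- function(model, cohort) {
  cn <- cohort$cn
  missingCN <- setdiff(model@cnGenes, cn@geneIds)
  if (length(missingCN) > 0)
    stop("cohort is missing selected CN genes: ",
         paste(missingCN, collapse = ", "))
  missingVar <- setdiff(model@varGenes, cohort$variants@geneIds)
  if (length(missingVar) > 0)
    stop("cohort is missing selected variant genes: ",
         paste(missingVar, collapse = ", "))
  Ct <- cnValues(cn)[, model@cnGenes, drop = FALSE]
  Vt <- encodeVariantsMatrix(cohort$variants@records, cn@sampleIds,
                             model@varGenes, model@varAggregate)
  assembleFeatures(list(values = Ct, genes = model@cnGenes),
                   list(values = Vt, genes = model@varGenes),
                   addBias = model@weights@useBias)
}

#' Run encrypted inference on a test cohort
#'
#' Client side: the test cohort is restricted to the model's selected genes
#' (the only preprocessing the data owner must perform), assembled, padded and
#' encrypted under the duplicated diagonal packing. Server side: the encrypted
#' matrix-vector product with the composed weight matrix is followed by the
#' polynomial softmax, all on simulated ciphertexts. The decrypted scores are
#' stripped of padding and, when labels are supplied, scored by micro-averaged
#' AUC and accuracy.
#'
#' @param model a trained \linkS4class{SNNModel}
#' @param cohort test cohort (list with cn, variants and optionally labels)
#' @param m duplication factor
#' @param n slot count; chosen automatically when NULL
#' @param complexPack use complex-pair packing
#' @param mode simulator arithmetic mode ("exact" or "fixed")
#' @param labels optional named integer labels for metric computation
#'   (defaults to \code{cohort$labels})
#' @return an \linkS4class{InferenceResult}
#' @export
runInference <- function(model, cohort, m = 2L, n = NULL,
                         complexPack = TRUE, mode = "exact",
                         labels = cohort$labels) {
  fm <- modelFeatures(model, cohort)
  if (fm@nSamples == 0L) stop("runInference: empty test cohort")
  sPad <- nrow(fm@X); gPad <- ncol(fm@X)
  W <- model@weights@W
  if (nrow(W) > gPad)
    stop("runInference: weight rows exceed the padded feature count")
  Wpad <- zeroPadMatrix(W, gPad, ncol(W))
  T <- model@nClasses

  plan <- if (is.null(n)) autoPlan(sPad, gPad, T, m, complexPack)
          else packingPlan(sPad, gPad, T, n, m, complexPack)
  ctx <- heContext(n = plan@n, mode = mode)

  cts <- encodeInputs(fm@X, plan, ctx)
  masks <- encodeWeights(Wpad, plan)
  ctY <- encryptedMatvec(cts, masks, plan)
  matvecCounts <- opCounts(ctx)

  ctP <- approxSoftmax(ctY, model@softmaxCfg, plan)
  scoresPad <- decodeScores(ctP, plan)
  scores <- scoresPad[seq_len(fm@nSamples), , drop = FALSE]
  rownames(scores) <- sampleIds(cohort$cn)
  predicted <- max.col(scores, ties.method = "first")

  metrics <- list()
  if (!is.null(labels)) {
    labels <- as.integer(labels[sampleIds(cohort$cn)])
    metrics <- list(microAUC = microAUC(scores, oneHot(labels, T)),
                    accuracy = classificationAccuracy(scores, labels))
  }
  total <- opCounts(ctx)
  costs <- list(n_ciphertexts = length(cts),
                matvec = as.list(matvecCounts),
                total = as.list(total),
                plan = list(s = plan@s, g = plan@g, T = plan@T, n = plan@n,
                            m = plan@m, complexPack = plan@complexPack))
  new("InferenceResult", scores = scores, predicted = as.integer(predicted),
      metrics = metrics, costs = costs)
}

#' Plain-pipeline reference scores
#'
#' The unencrypted counterpart of \code{\link{runInference}}: same gene
#' restriction and weights, exact arithmetic.
#'
#' @param model a trained \linkS4class{SNNModel}
#' @param cohort test cohort
#' @param softmax "exact" for the true softmax, "approx" for the plain-side
#'   polynomial softmax (same math the encrypted circuit evaluates)
#' @return samples x classes probability matrix
#' @export
plainInference <- function(model, cohort, softmax = c("exact", "approx")) {
  softmax <- match.arg(softmax)
  fm <- modelFeatures(model, cohort)
  X <- fm@X[seq_len(fm@nSamples), seq_len(fm@nFeatures), drop = FALSE]
  if (model@weights@useBias) X <- X[, -ncol(X), drop = FALSE]  # plainScores re-adds it
  sc <- plainScores(model@weights, X)
  out <- if (softmax == "exact") exactSoftmax(sc)
         else approxSoftmax(sc, model@softmaxCfg)
  rownames(out) <- sampleIds(cohort$cn)
  out
}

#' Write a cost report as JSON
#' @param result an \linkS4class{InferenceResult}
#' @param path output file
#' @return the path, invisibly
#' @export
writeCostReport <- function(result, path) {
  jsonlite::write_json(result@costs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
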