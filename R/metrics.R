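#' @include AllClasses.R
NULL

#' Micro-averaged AUC
#'
#' Pools all (sample, class) score/indicator pairs into one ROC curve and
#' returns its AUC, computed by the rank (Mann-Whitney) statistic with ties
#' credited one half.
#'
#' @param scores numeric matrix (samples x classes) or vector of pooled scores
#' @param labels one-hot indicator matrix of the same shape (or binary vector)
#' @return AUC in [0, 1]
#' @export
microAUC <- function(scores, labels) {
  sc <- as.numeric(scores)
  y <- as.numeric(labels)
  if (length(sc) != length(y)) stop("microAUC: shape mismatch")
  if (!all(y %in% c(0, 1))) stop("microAUC: labels must be a 0/1 indicator")
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0)
    stop("microAUC: need at least one positive and one negative entry")
  rk <- rank(sc)  # average ranks give the half-credit tie convention
  (sum(rk[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Classification accuracy of argmax predictions
#'
#' @param scores samples x classes score matrix (or integer predictions)
#' @param labels integer class labels in 1..T
#' @return fraction of samples whose argmax matches the label
#' @export
classificationAccuracy <- function(scores, labels) {
  pred <- if (is.matrix(scores)) max.col(scores, ties.method = "first")
          else as.integer(scores)
  if (length(pred) != length(labels)) stop("shape mismatch")
  mean(pred == as.integer(labels))
}
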