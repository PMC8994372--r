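#' @include AllClasses.R constructors.R preprocess.R softmax.R
NULL

oneHot <- function(labels, T) {
  Y <- matrix(0, length(labels), T)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

#' Compose the two-layer weights into a single inference matrix
#'
#' The shallow network has a linear hidden layer, so its pre-softmax output is
#' the linear map \code{X W1 W2 + (b1 W2 + b2)}. The product \code{W1 W2} has
#' rank at most the hidden width; the net bias is folded in as an extra row of
#' the composed matrix, matched by a constant-one feature column appended to
#' X, so encrypted inference is a single matrix product \code{Y = X_aug W}.
#'
#' @param W1 g x h hidden weights
#' @param W2 h x T output weights
#' @param b1 length-h hidden bias (or zeros)
#' @param b2 length-T output bias (or zeros)
#' @param useBias append the folded bias row (if FALSE, biases must be zero)
#' @return composed matrix: g x T, or (g+1) x T with the bias row last
#' @export
composeWeights <- function(W1, W2, b1 = rep(0, ncol(W1)),
                           b2 = rep(0, ncol(W2)), useBias = TRUE) {
  if (ncol(W1) != nrow(W2)) stop("composeWeights: shape mismatch")
  W <- unname(W1 %*% W2)
  if (!useBias) {
    if (any(b1 != 0) || any(b2 != 0))
      stop("composeWeights: nonzero biases with useBias = FALSE")
    return(W)
  }
  rbind(W, as.numeric(b1 %*% W2) + b2)
}

#' Train the shallow network
#'
#' One linear hidden layer (default 64 nodes) with dropout, a T-node output
#' layer and softmax cross-entropy loss, optimized by minibatch Adam. The
#' linear hidden activation makes the composed model a rank-limited linear
#' map; the two-layer parameterization is kept during training so dropout
#' regularizes as in the original recipe.
#'
#' @param X numeric matrix (samples x features; unpadded) or a
#'   \linkS4class{FeatureMatrix} (the true block is used)
#' @param labels integer class labels in 1..T
#' @param cfg a \linkS4class{TrainConfig}
#' @param T number of classes (default \code{max(labels)})
#' @return a \linkS4class{ModelWeights} with the composed matrix in slot W
#' @export
trainModel <- function(X, labels, cfg = trainConfig(), T = max(labels)) {
  if (is(X, "FeatureMatrix"))
    X <- X@X[seq_len(X@nSamples), seq_len(X@nFeatures), drop = FALSE]
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (T < 2L) stop("trainModel: need at least 2 classes")
  s <- nrow(X); g <- ncol(X); h <- cfg@nHidden
  Y <- oneHot(labels, T)

  withSeed(cfg@seed, {
    sdW <- sqrt(2 / (g + h))
    W1 <- matrix(stats::rnorm(g * h, sd = sdW), g, h)
    W2 <- matrix(stats::rnorm(h * T, sd = sqrt(2 / (h + T))), h, T)
    b1 <- rep(0, h); b2 <- rep(0, T)

    lr <- cfg@learningRate; beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    ms <- list(W1 = W1 * 0, W2 = W2 * 0, b1 = b1 * 0, b2 = b2 * 0)
    vs <- ms
    tstep <- 0
    keep <- 1 - cfg@dropoutRate

    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample.int(s)
      for (start in seq(1L, s, by = cfg@batchSize)) {
        idx <- ord[start:min(start + cfg@batchSize - 1L, s)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        nb <- length(idx)

        H <- Xb %*% W1
        if (cfg@useBias) H <- sweep(H, 2L, b1, "+")
        if (keep < 1) {
          mask <- matrix(stats::runif(nb * h) < keep, nb, h) / keep
          Hd <- H * mask
        } else {
          mask <- NULL
          Hd <- H
        }
        Z <- Hd %*% W2
        if (cfg@useBias) Z <- sweep(Z, 2L, b2, "+")
        P <- exactSoftmax(Z)
        if (any(!is.finite(P)))
          stop("trainModel: non-finite loss (diverged); lower the learning rate")

        dZ <- (P - Yb) / nb
        gW2 <- crossprod(Hd, dZ)
        gb2 <- colSums(dZ)
        dH <- dZ %*% t(W2)
        if (!is.null(mask)) dH <- dH * mask
        gW1 <- crossprod(Xb, dH)
        gb1 <- colSums(dH)

        tstep <- tstep + 1
        adam <- function(param, gname, grad) {
          ms[[gname]] <<- beta1 * ms[[gname]] + (1 - beta1) * grad
          vs[[gname]] <<- beta2 * vs[[gname]] + (1 - beta2) * grad^2
          mhat <- ms[[gname]] / (1 - beta1^tstep)
          vhat <- vs[[gname]] / (1 - beta2^tstep)
          param - lr * mhat / (sqrt(vhat) + eps)
        }
        W1 <- adam(W1, "W1", gW1)
        W2 <- adam(W2, "W2", gW2)
        if (cfg@useBias) {
          b1 <- adam(b1, "b1", gb1)
          b2 <- adam(b2, "b2", gb2)
        }
      }
    }
    W <- composeWeights(W1, W2, b1, b2, useBias = cfg@useBias)
    new("ModelWeights", W1 = W1, b1 = b1, W2 = W2, b2 = b2, W = W,
        useBias = cfg@useBias)
  })
}

#' Pre-softmax scores of the composed model
#'
#' @param weights a \linkS4class{ModelWeights}
#' @param X feature matrix without the bias column (samples x g)
#' @return samples x T score matrix, identical to the plain network's output
#' @export
plainScores <- function(weights, X) {
  X <- as.matrix(X)
  if (weights@useBias) X <- cbind(X, 1)
  X %*% weights@W
}

# stratified fold assignment: every sample lands in exactly one fold and each
# class is spread as evenly as possible across folds
stratifiedFolds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (t in unique(labels)) {
    idx <- sample(which(labels == t))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated grid search over the filter parameters
#'
#' For every pair (dCN, kVar) whose filtered feature count is at most 2^B,
#' evaluates the mean per-fold micro-averaged AUC of the shallow network under
#' stratified k-fold cross-validation, picks the maximizing pair (ties broken
#' toward fewer filtered genes, then smaller dCN), retrains on the full
#' training set and calibrates the softmax approximation on the training
#' scores.
#'
#' @param cohort training cohort (list with cn, variants, labels)
#' @param cnGrid candidate dCN values
#' @param varGrid candidate kVar values
#' @param B model-size exponent (filtered feature bound 2^B)
#' @param cfg a \linkS4class{TrainConfig}
#' @param varAggregate aggregation for repeated variant records
#' @param softmaxR,softmaxD fixed softmax-approximation parameters passed to
#'   calibration
#' @return a \linkS4class{SNNModel}; the CV table is attached as attribute
#'   \code{"cvTable"}
#' @export
gridSearch <- function(cohort, cnGrid, varGrid, B = 10L, cfg = trainConfig(),
                       varAggregate = "sum", softmaxR = 4L, softmaxD = 30L) {
  if (length(cnGrid) == 0L || length(varGrid) == 0L)
    stop("gridSearch: empty parameter grid")
  labels <- cohort$labels
  T <- max(labels)
  results <- NULL
  best <- NULL

  for (dCN in cnGrid) {
    cnF <- cnFilter(cohort$cn, dCN)
    for (kVar in varGrid) {
      vaF <- variantsFilter(cohort$variants, labels, kVar, varAggregate)
      gTot <- length(cnF$genes) + length(vaF$genes)
      if (gTot > 2^B) {
        results <- rbind(results,
          data.frame(dCN = dCN, kVar = kVar, g = gTot, microAUC = NA))
        next
      }
      X <- cbind(cnF$values, vaF$values)
      auc <- withSeed(cfg@seed, {
        fold <- stratifiedFolds(labels, cfg@folds)
        perFold <- vapply(seq_len(cfg@folds), function(f) {
          tr <- fold != f
          w <- trainModel(X[tr, , drop = FALSE], labels[tr], cfg, T = T)
          sc <- plainScores(w, X[!tr, , drop = FALSE])
          microAUC(sc, oneHot(labels[!tr], T))
        }, numeric(1))
        mean(perFold)
      })
      results <- rbind(results,
        data.frame(dCN = dCN, kVar = kVar, g = gTot, microAUC = auc))
      cand <- list(dCN = dCN, kVar = kVar, g = gTot, auc = auc)
      if (is.null(best) || auc > best$auc ||
          (auc == best$auc && (gTot < best$g ||
                               (gTot == best$g && dCN < best$dCN))))
        best <- cand
    }
  }
  if (is.null(best))
    stop("gridSearch: no (dCN, kVar) pair satisfies the size bound 2^", B)

  model <- fitModel(cohort, filterParams(best$dCN, best$kVar, B), cfg,
                    varAggregate, softmaxR, softmaxD)
  attr(model, "cvTable") <- results
  model
}

#' Fit the model at fixed filter parameters
#'
#' Filters the training cohort, trains the shallow network on all training
#' samples, composes the inference matrix and calibrates the softmax
#' approximation on the training scores.
#'
#' @param cohort training cohort (list with cn, variants, labels)
#' @param params a \linkS4class{FilterParams}
#' @param cfg a \linkS4class{TrainConfig}
#' @param varAggregate aggregation for repeated variant records
#' @param softmaxR,softmaxD softmax-approximation parameters for calibration
#' @return a \linkS4class{SNNModel}
#' @export
fitModel <- function(cohort, params, cfg = trainConfig(),
                     varAggregate = "sum", softmaxR = 4L, softmaxD = 30L) {
  labels <- cohort$labels
  T <- max(labels)
  cnF <- cnFilter(cohort$cn, params@dCN)
  vaF <- variantsFilter(cohort$variants, labels, params@kVar, varAggregate)
  g <- length(cnF$genes) + length(vaF$genes)
  if (g > 2^params@B)
    stop("fitModel: ", g, " filtered features exceed the bound 2^", params@B)
  X <- cbind(cnF$values, vaF$values)
  weights <- trainModel(X, labels, cfg, T = T)
  scores <- plainScores(weights, X)
  cfgSm <- calibrateSoftmax(scores, r = softmaxR, d = softmaxD)
  new("SNNModel", weights = weights, cnGenes = cnF$genes,
      varGenes = vaF$genes, filterParams = params, softmaxCfg = cfgSm,
      nClasses = as.integer(T), varAggregate = varAggregate)
}
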