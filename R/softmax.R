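#' @include AllClasses.R he-sim.R packing.R constructors.R
NULL

#' Scaled-limit exponential approximation
#'
#' \code{aeExp(x, r, L) = ((2^r + x)/L)^(2^r)}, evaluated with one addition,
#' one constant multiplication and r squarings. It satisfies
#' \code{Lr * aeExp(x) ~ exp(x)} with \code{Lr = (L/2^r)^(2^r)} and, unlike
#' minimax fits, is strictly increasing on (-2^r, Inf) - the property that
#' preserves score rankings (and hence micro-averaged AUC) under the
#' approximation. Stability requires \code{|2^r + x| < L} over the input
#' range; out-of-range inputs produce valid but inaccurate values and raise a
#' warning in the plain path.
#'
#' @param x numeric vector or a \linkS4class{SimCipher} (slotwise)
#' @param r squaring-count exponent
#' @param L scaling constant
#' @param warn warn when plain inputs leave the stable range
#' @return same type as \code{x}
#' @export
aeExp <- function(x, r, L, warn = TRUE) {
  if (is(x, "SimCipher")) {
    t <- heCMult(x, 1 / L)              # x/L
    t <- heAddPlain(t, 2^r / L)         # (2^r + x)/L
    for (i in seq_len(r)) t <- heMult(t, t)
    return(t)
  }
  if (warn && any(abs(2^r + x) >= L))
    warning("aeExp: input outside the stable range |2^r + x| < L")
  ((2^r + x) / L)^(2^r)
}

#' Goldschmidt approximate inversion on (0, 2)
#'
#' Evaluates \code{prod_{i=0}^{d-1} (1 + (1-x)^(2^i))}, the degree 2^d - 1
#' truncation of the geometric series for 1/x, using 2d - 2 multiplications
#' (d - 1 squarings of the error term plus d - 1 accumulator products). The
#' signed relative error is \code{-(1-x)^(2^d)}: the result underestimates
#' 1/x, severely so as x approaches 0.
#'
#' @param x numeric vector in (0, 2) or a \linkS4class{SimCipher}
#' @param d number of product factors (>= 1)
#' @return same type as \code{x}
#' @export
goldschmidt <- function(x, d) {
  if (d < 1L) stop("goldschmidt: d must be >= 1")
  if (is(x, "SimCipher")) {
    e <- hePlainSub(1, x)               # 1 - x, level-free
    a <- heAddPlain(e, 1)               # 1 + (1-x)
    if (d >= 2L) {
      for (i in 2:d) {
        e <- heMult(e, e)
        a <- heMult(a, heAddPlain(e, 1))
      }
    }
    return(a)
  }
  e <- 1 - x
  a <- 1 + e
  if (d >= 2L) {
    for (i in 2:d) {
      e <- e * e
      a <- a * (1 + e)
    }
  }
  a
}

#' Scaled approximate inversion on (0, 2M)
#'
#' \code{1/x ~ (1/M) * goldschmidt(x/M, d)}; the relative error equals that of
#' \code{\link{goldschmidt}} at x/M.
#'
#' @param x numeric vector in (0, 2M) or a \linkS4class{SimCipher}
#' @param M input scale
#' @param d Goldschmidt factor count
#' @return same type as \code{x}
#' @export
scaledInverse <- function(x, M, d) {
  if (is(x, "SimCipher")) {
    z <- heCMult(x, 1 / M)
    g <- goldschmidt(z, d)
    return(heCMult(g, 1 / M))
  }
  goldschmidt(x / M, d) / M
}

#' Calibrate softmax-approximation parameters from training scores
#'
#' Chooses the smallest L from \code{candidatesL} such that
#' \code{max |2^r + score| <= L * (1 - margin)} over the training score matrix
#' (pre-softmax X W over the training set), then chooses M so that the
#' per-sample sums of AE values are admissible for the Goldschmidt inversion:
#' the maximal sum must not exceed \code{2 M (1 - margin)} and the minimal sum
#' S_min must satisfy \code{(1 - S_min/M)^(2^d) <= invTol} (the inversion
#' error explodes as its input nears 0). The default M = 80 is kept whenever
#' it is admissible.
#'
#' @param trainScores numeric matrix of pre-softmax scores (samples x classes)
#' @param r squaring-count exponent
#' @param d Goldschmidt factor count
#' @param candidatesL ladder of candidate scaling constants
#' @param margin safety margin on both bounds (default 10 percent)
#' @param defaultM preferred Goldschmidt scale
#' @param invTol admissible relative error of the inversion at the smallest
#'   observed AE sum
#' @return a \linkS4class{SoftmaxConfig}
#' @export
calibrateSoftmax <- function(trainScores, r = 4L, d = 30L,
                             candidatesL = 2^(5:12), margin = 0.1,
                             defaultM = 80, invTol = 1e-3) {
  trainScores <- as.matrix(trainScores)
  mx <- max(abs(2^r + trainScores))
  ok <- candidatesL * (1 - margin) >= mx
  if (!any(ok))
    stop("calibrateSoftmax: no admissible L in the candidate list for score range")
  L <- candidatesL[which(ok)[1L]]

  sums <- rowSums(aeExp(trainScores, r, L, warn = FALSE))
  sMax <- max(sums); sMin <- min(sums)
  admissibleM <- function(M) {
    sMax <= 2 * M * (1 - margin) &&
      (1 - sMin / M)^(2^d) <= invTol
  }
  if (admissibleM(defaultM)) {
    M <- defaultM
  } else {
    # center the observed sums in the inversion's sweet spot
    M <- sMax / (2 * (1 - margin))
    if (!admissibleM(M))
      M <- sqrt(sMax * sMin)  # large spread: balance both ends
    if (!admissibleM(M))
      stop("calibrateSoftmax: no admissible M; AE sums span too wide a range (",
           format(sMin), " .. ", format(sMax), ")")
  }
  softmaxConfig(r = r, L = L, M = M, d = d)
}

#' Exact softmax (plain reference)
#' @param v numeric vector or matrix (rows = samples)
#' @return softmax probabilities, same shape
#' @export
exactSoftmax <- function(v) {
  if (is.matrix(v)) {
    e <- exp(v - apply(v, 1L, max))
    return(e / rowSums(e))
  }
  e <- exp(v - max(v))
  e / sum(e)
}

#' Approximate softmax
#'
#' Polynomial softmax per the identity
#' \code{softmax(v) ~ Gol(sum_i AE(v_i)) * (AE(v_1), ..., AE(v_t))} with the
#' inversion evaluated through \code{\link{scaledInverse}}. The plain method
#' takes a score matrix; the encrypted method takes the class-group
#' ciphertexts produced by \code{\link{encryptedMatvec}} and reuses the
#' packing layout: the m class blocks inside each ciphertext are summed by
#' log2(m) rotated additions, group ciphertexts are combined by plain
#' additions, the contribution of zero-padded classes (a known constant,
#' AE(0) each) is subtracted, and the inverted sum multiplies each AE
#' ciphertext back.
#'
#' @param x numeric score matrix (samples x classes) or a list of
#'   \linkS4class{SimCipher} from \code{\link{encryptedMatvec}}
#' @param cfg a \linkS4class{SoftmaxConfig}
#' @param plan required for the encrypted method: the shared packing plan
#' @return probabilities in the same form as the input (matrix, or list of
#'   ciphertexts decodable with \code{\link{decodeScores}})
#' @export
approxSoftmax <- function(x, cfg, plan = NULL) {
  stopifnot(is(cfg, "SoftmaxConfig"))
  r <- cfg@r; L <- cfg@L; M <- cfg@M; d <- cfg@d
  if (!is.list(x)) {
    x <- as.matrix(x)
    A <- aeExp(x, r, L, warn = FALSE)
    S <- rowSums(A)
    inv <- scaledInverse(S, M, d)
    return(A * inv)
  }
  if (is.null(plan)) stop("approxSoftmax: encrypted path needs the packing plan")
  if (length(x) != ceiling(plan@T / plan@m))
    stop("approxSoftmax: ciphertext layout does not match the plan")
  m <- plan@m; s <- plan@s
  aes <- lapply(x, aeExp, r = r, L = L)
  # class sum: m in-ciphertext blocks, then across class groups
  groupSums <- lapply(aes, function(ct) rotSum(ct, s, 2L, log2i(m)))
  S <- Reduce(heAdd, groupSums)
  nPad <- m * ceiling(plan@T / m) - plan@T
  if (nPad > 0)
    S <- heAddPlain(S, -nPad * aeExp(0, r, L, warn = FALSE))
  inv <- scaledInverse(S, M, d)
  lapply(aes, heMult, ct2 = inv)
}
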