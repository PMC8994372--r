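#' @include AllClasses.R he-sim.R
NULL

#' Build a packing plan
#'
#' @param s padded sample count (power of two)
#' @param g padded feature count (power of two)
#' @param T number of output classes
#' @param n ciphertext slot count (power of two, >= m*s)
#' @param m duplication factor: each diagonal is placed in the ciphertext m
#'   times, trading m-fold more ciphertexts for log-factor fewer rotations
#' @param complexPack pack two diagonals per slot vector (real + imaginary
#'   part), halving both the ciphertext count and the constant multiplications
#' @return a \linkS4class{PackingPlan}
#' @export
packingPlan <- function(s, g, T, n, m = 1L, complexPack = TRUE) {
  new("PackingPlan", s = as.integer(s), g = as.integer(g), T = as.integer(T),
      n = as.integer(n), m = as.integer(m), complexPack = complexPack)
}

#' Choose a slot count and build a plan automatically
#'
#' Picks the largest slot count not exceeding \code{nMax} that still fills
#' every ciphertext (n <= m*s*g / 2 for complex packing, m*s*g for real-only),
#' bounded below by m*s.
#'
#' @inheritParams packingPlan
#' @param nMax slot-count cap (default 2^16, half the ring dimension 2^17)
#' @return a \linkS4class{PackingPlan}
#' @export
autoPlan <- function(s, g, T, m = 1L, complexPack = TRUE, nMax = 2^16) {
  full <- if (complexPack) m * s * g / 2 else m * s * g
  n <- max(m * s, min(nMax, full))
  if (complexPack) n <- max(n, 2 * m * s / 2)  # ell >= 2
  packingPlan(s, g, T, n, m, complexPack)
}

# diagonals per ciphertext (ell) and ciphertext count for a plan
planDiagsPerCt <- function(plan) {
  base <- plan@n %/% (plan@m * plan@s)
  if (plan@complexPack) 2L * base else base
}
planCipherCount <- function(plan) plan@g %/% planDiagsPerCt(plan)

#' Extract the cyclic diagonals of a matrix
#'
#' Diagonal j (j = 0, ..., g-1) of an s x g matrix X is the length-s vector
#' with entry k equal to \code{X[k, [j+k-1]_g]}, where \code{[.]_g} is the
#' 1-based cyclic index in \{1, ..., g\}. The matrix-vector product X w equals
#' \code{sum_j x_j * w^(j)} slotwise (see \code{\link{rotateWeight}}).
#'
#' @param X numeric matrix (s x g)
#' @return s x g matrix whose column j+1 is diagonal x_j
#' @export
extractDiagonals <- function(X) {
  s <- nrow(X); g <- ncol(X)
  out <- matrix(0, s, g)
  k <- seq_len(s)
  for (j in 0:(g - 1L)) {
    out[, j + 1L] <- X[cbind(k, cyc1(j + k - 1L, g))]
  }
  out
}

#' Cyclically indexed weight vector
#'
#' Entry k (k = 1, ..., s) of \code{w^(j)} is \code{w[[j+k-1]_g]}: the weight
#' column re-indexed along diagonal j so that Hadamard products with the
#' matrix diagonals reassemble the matrix-vector product.
#'
#' @param w weight column of length g
#' @param j diagonal index (0-based)
#' @param s output length (sample count)
#' @return numeric vector of length s
#' @export
rotateWeight <- function(w, j, s) {
  g <- length(w)
  w[cyc1(j + seq_len(s) - 1L, g)]
}

#' Encode an input matrix into simulated ciphertexts
#'
#' With complex packing, ciphertext i (i = 0, ..., n_ct - 1) holds, for
#' q = 0, ..., ell/2 - 1, m contiguous copies of the complex vector
#' \code{x_(i*ell+2q) + 1i * x_(i*ell+2q+1)}; real-only packing stores m
#' copies of each single diagonal.
#'
#' @param X padded input matrix (dims must match the plan)
#' @param plan a \linkS4class{PackingPlan}
#' @param ctx a simulator context with \code{ctx$n == plan@n}
#' @return list of \linkS4class{SimCipher} of length \code{g/ell}
#' @export
encodeInputs <- function(X, plan, ctx) {
  stopifnot(nrow(X) == plan@s, ncol(X) == plan@g)
  if (ctx$n != plan@n) stop("encodeInputs: context slot count differs from plan")
  if (plan@m * plan@s > plan@n) stop("encodeInputs: m*s exceeds slot count")
  D <- extractDiagonals(X)
  ell <- planDiagsPerCt(plan)
  nCt <- planCipherCount(plan)
  m <- plan@m
  cts <- vector("list", nCt)
  for (i in 0:(nCt - 1L)) {
    if (plan@complexPack) {
      pieces <- lapply(0:(ell %/% 2L - 1L), function(q) {
        v <- complex(real = D[, i * ell + 2L * q + 1L],
                     imaginary = D[, i * ell + 2L * q + 2L])
        rep(v, m)
      })
    } else {
      pieces <- lapply(0:(ell - 1L), function(q) {
        rep(as.complex(D[, i * ell + q + 1L]), m)
      })
    }
    cts[[i + 1L]] <- encryptVec(unlist(pieces), ctx)
  }
  cts
}

#' Encode the weight matrix into plain mask vectors
#'
#' For class group j (j = 0, ..., ceil(T/m) - 1) and ciphertext i, the mask
#' interleaves the cyclically indexed weight vectors of classes jm, ..., jm+m-1
#' against the diagonals held by ciphertext i. Classes at or beyond T are
#' zero-padded. In complex mode the masks carry \code{w - 1i*w'} pairs and are
#' pre-scaled by 1/2 so that the conjugate-add step directly yields the real
#' part (saving one level).
#'
#' @param W weight matrix (g x T, rows padded to the plan's g)
#' @param plan a \linkS4class{PackingPlan}
#' @return list (over class groups) of lists (over ciphertexts) of complex
#'   mask vectors of length n
#' @export
encodeWeights <- function(W, plan) {
  stopifnot(nrow(W) == plan@g)
  g <- plan@g; s <- plan@s; m <- plan@m; T <- plan@T
  ell <- planDiagsPerCt(plan)
  nCt <- planCipherCount(plan)
  nGroups <- ceiling(T / m)
  wcol <- function(cls) {           # 0-based class index, zero beyond T
    if (cls >= T) rep(0, g) else W[, cls + 1L]
  }
  masks <- vector("list", nGroups)
  for (j in 0:(nGroups - 1L)) {
    masks[[j + 1L]] <- vector("list", nCt)
    for (i in 0:(nCt - 1L)) {
      if (plan@complexPack) {
        pieces <- lapply(0:(ell %/% 2L - 1L), function(q) {
          unlist(lapply(0:(m - 1L), function(r) {
            wre <- rotateWeight(wcol(j * m + r), i * ell + 2L * q, s)
            wim <- rotateWeight(wcol(j * m + r), i * ell + 2L * q + 1L, s)
            0.5 * complex(real = wre, imaginary = -wim)
          }))
        })
      } else {
        pieces <- lapply(0:(ell - 1L), function(q) {
          unlist(lapply(0:(m - 1L), function(r) {
            as.complex(rotateWeight(wcol(j * m + r), i * ell + q, s))
          }))
        })
      }
      masks[[j + 1L]][[i + 1L]] <- unlist(pieces)
    }
  }
  masks
}

#' Encrypted matrix-vector multiplication
#'
#' For each class group j: multiply every input ciphertext by its mask, (in
#' complex mode) add the conjugate to extract the real part, sum over
#' ciphertexts, and rotate-and-sum with stride m*s to collapse the diagonal
#' blocks. The decrypted first m*s slots of output j hold the score vectors
#' y_(jm), ..., y_(jm+m-1) concatenated (repeated over the remaining slots).
#'
#' @param cts ciphertext list from \code{\link{encodeInputs}}
#' @param masks mask list from \code{\link{encodeWeights}}
#' @param plan the shared \linkS4class{PackingPlan}
#' @return list of \linkS4class{SimCipher}, one per class group
#' @export
encryptedMatvec <- function(cts, masks, plan) {
  if (length(cts) != planCipherCount(plan))
    stop("encryptedMatvec: ciphertext count does not match the plan")
  if (length(masks) != ceiling(plan@T / plan@m))
    stop("encryptedMatvec: mask group count does not match the plan")
  ell <- planDiagsPerCt(plan)
  sumDepth <- if (plan@complexPack) log2i(ell / 2L) else log2i(ell)
  out <- vector("list", length(masks))
  for (j in seq_along(masks)) {
    acc <- NULL
    for (i in seq_along(cts)) {
      p <- heCMult(cts[[i]], masks[[j]][[i]])
      if (plan@complexPack) p <- heAdd(p, heConj(p))
      acc <- if (is.null(acc)) p else heAdd(acc, p)
    }
    out[[j]] <- rotSum(acc, plan@m * plan@s, 2L, sumDepth)
  }
  out
}

#' Decode class scores from matrix-vector output ciphertexts
#'
#' @param ctY list returned by \code{\link{encryptedMatvec}}
#' @param plan the packing plan
#' @return s x T numeric score matrix (padded dims; real parts of the first
#'   m*s slots of each group)
#' @export
decodeScores <- function(ctY, plan) {
  s <- plan@s; m <- plan@m; T <- plan@T
  Y <- matrix(0, s, T)
  for (j in seq_along(ctY)) {
    slots <- decryptVec(ctY[[j]])
    for (r in 0:(m - 1L)) {
      cls <- (j - 1L) * m + r + 1L
      if (cls > T) break
      Y[, cls] <- Re(slots[(r * s + 1L):((r + 1L) * s)])
    }
  }
  Y
}

#' Closed-form operation counts of a plan
#'
#' Rotations: \code{log2(n/(m*s)) * ceiling(T/m)}; constant multiplications:
#' one per ciphertext per class group, i.e. \code{(s*g/(2n)) * m * ceiling(T/m)}
#' with complex packing and twice that real-only; ciphertexts:
#' \code{m*s*g/(2n)} (complex) or \code{m*s*g/n} (real-only). These must equal
#' the simulator's counters for any valid plan.
#'
#' @param plan a \linkS4class{PackingPlan}
#' @return named numeric vector (n_rot, n_cmult, n_ct)
#' @export
predictCosts <- function(plan) {
  groups <- ceiling(plan@T / plan@m)
  nCt <- planCipherCount(plan)
  c(n_rot = log2i(plan@n / (plan@m * plan@s)) * groups,
    n_cmult = nCt * groups,
    n_ct = nCt)
}
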