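#' @include AllClasses.R
NULL

#' Create a simulator context
#'
#' The context holds the global operation tallies (rotations, constant
#' multiplications, ciphertext multiplications, additions, conjugations) and
#' the arithmetic mode. Default arithmetic is exact double-precision complex;
#' fixed-point mode quantizes ciphertext slots to \code{2^-ctScale} and plain
#' masks to \code{2^-ptScale} after each operation, mirroring the scaling
#' factors a leveled fixed-point implementation would use (2^60 for
#' ciphertexts, 2^40 for plain vectors).
#'
#' @param n default slot count for \code{\link{encryptVec}} (power of two)
#' @param levelBudget fresh-ciphertext level (multiplicative depth budget)
#' @param mode \code{"exact"} or \code{"fixed"}
#' @param ctScale,ptScale fixed-point scale exponents
#' @return an environment with counters (see \code{\link{opCounts}})
#' @export
heContext <- function(n = 2^16, levelBudget = 44L, mode = c("exact", "fixed"),
                      ctScale = 60, ptScale = 40) {
  mode <- match.arg(mode)
  if (!isPow2(n)) stop("heContext: n must be a power of two")
  ctx <- new.env(parent = emptyenv())
  ctx$n <- as.integer(n)
  ctx$levelBudget <- as.integer(levelBudget)
  ctx$mode <- mode
  ctx$ctScale <- ctScale
  ctx$ptScale <- ptScale
  resetCounts(ctx)
  ctx
}

#' Operation tallies of a simulator context
#' @param ctx a context from \code{\link{heContext}}
#' @return named numeric vector: n_rot, n_cmult, n_mult, n_add, n_conj,
#'   max_depth_used
#' @export
opCounts <- function(ctx) {
  c(n_rot = ctx$n_rot, n_cmult = ctx$n_cmult, n_mult = ctx$n_mult,
    n_add = ctx$n_add, n_conj = ctx$n_conj,
    max_depth_used = ctx$max_depth_used)
}

#' Reset the operation tallies of a context
#' @param ctx a simulator context
#' @return the context, invisibly
#' @export
resetCounts <- function(ctx) {
  ctx$n_rot <- 0L; ctx$n_cmult <- 0L; ctx$n_mult <- 0L
  ctx$n_add <- 0L; ctx$n_conj <- 0L; ctx$max_depth_used <- 0L
  invisible(ctx)
}

quantizeSlots <- function(z, scale) {
  f <- 2^scale
  complex(real = round(Re(z) * f) / f, imaginary = round(Im(z) * f) / f)
}

maybeQuantizeCt <- function(ctx, z) {
  if (ctx$mode == "fixed") quantizeSlots(z, ctx$ctScale) else z
}

newCipher <- function(slots, level, ctx) {
  new("SimCipher", slots = as.complex(slots), level = as.integer(level),
      n = as.integer(length(slots)), ctx = ctx)
}

noteDepth <- function(ctx, level) {
  used <- ctx$levelBudget - level
  if (used > ctx$max_depth_used) ctx$max_depth_used <- as.integer(used)
}

#' Encrypt a vector into a simulated ciphertext
#'
#' Short vectors are zero-extended to the context's n slots.
#' @param v numeric or complex vector, length <= n
#' @param ctx a simulator context
#' @param level starting level (defaults to the context budget)
#' @return a \linkS4class{SimCipher}
#' @export
encryptVec <- function(v, ctx, level = ctx$levelBudget) {
  if (length(v) > ctx$n)
    stop("encryptVec: vector longer than the slot count (", ctx$n, ")")
  slots <- c(as.complex(v), rep(0+0i, ctx$n - length(v)))
  newCipher(maybeQuantizeCt(ctx, slots), level, ctx)
}

#' Decrypt a simulated ciphertext
#' @param ct a \linkS4class{SimCipher}
#' @return the complex slot vector
#' @export
decryptVec <- function(ct) ct@slots

checkPair <- function(a, b) {
  if (a@n != b@n)
    stop("operands have different slot counts (", a@n, " vs ", b@n, ")")
}

#' Simulated SIMD ciphertext operations
#'
#' Slotwise addition, subtraction, Hadamard multiplication, constant (plain
#' mask) multiplication, conjugation and cyclic left rotation. \code{heMult}
#' and \code{heCMult} consume one level and increment their counters;
#' addition, subtraction, conjugation and rotation are level-free. Plain-side
#' variants (\code{heAddPlain}, \code{hePlainSub}) model additions of
#' unencrypted constants, which cost neither a level nor a key-switch.
#'
#' @param ct,ct2 \linkS4class{SimCipher} operands with equal slot counts
#' @param v plain numeric/complex vector (recycled to n slots) or scalar
#' @param r rotation amount (reduced mod n)
#' @return a \linkS4class{SimCipher}
#' @name heOps
NULL

#' @rdname heOps
#' @export
heAdd <- function(ct, ct2) {
  checkPair(ct, ct2)
  ctx <- ct@ctx
  ctx$n_add <- ctx$n_add + 1L
  newCipher(maybeQuantizeCt(ctx, ct@slots + ct2@slots),
            min(ct@level, ct2@level), ctx)
}

#' @rdname heOps
#' @export
heSub <- function(ct, ct2) {
  checkPair(ct, ct2)
  ctx <- ct@ctx
  ctx$n_add <- ctx$n_add + 1L
  newCipher(maybeQuantizeCt(ctx, ct@slots - ct2@slots),
            min(ct@level, ct2@level), ctx)
}

#' @rdname heOps
#' @export
heMult <- function(ct, ct2) {
  checkPair(ct, ct2)
  lvl <- min(ct@level, ct2@level)
  if (lvl < 1L) stop("heMult: level exhausted (depth budget used up)")
  ctx <- ct@ctx
  ctx$n_mult <- ctx$n_mult + 1L
  out <- newCipher(maybeQuantizeCt(ctx, ct@slots * ct2@slots), lvl - 1L, ctx)
  noteDepth(ctx, out@level)
  out
}

#' @rdname heOps
#' @export
heCMult <- function(ct, v) {
  if (ct@level < 1L) stop("heCMult: level exhausted (depth budget used up)")
  ctx <- ct@ctx
  mask <- rep_len(as.complex(v), ct@n)
  if (ctx$mode == "fixed") mask <- quantizeSlots(mask, ctx$ptScale)
  ctx$n_cmult <- ctx$n_cmult + 1L
  out <- newCipher(maybeQuantizeCt(ctx, ct@slots * mask), ct@level - 1L, ctx)
  noteDepth(ctx, out@level)
  out
}

#' @rdname heOps
#' @export
heAddPlain <- function(ct, v) {
  ctx <- ct@ctx
  mask <- rep_len(as.complex(v), ct@n)
  if (ctx$mode == "fixed") mask <- quantizeSlots(mask, ctx$ptScale)
  newCipher(maybeQuantizeCt(ctx, ct@slots + mask), ct@level, ctx)
}

#' @rdname heOps
#' @export
hePlainSub <- function(v, ct) {
  ctx <- ct@ctx
  mask <- rep_len(as.complex(v), ct@n)
  if (ctx$mode == "fixed") mask <- quantizeSlots(mask, ctx$ptScale)
  newCipher(maybeQuantizeCt(ctx, mask - ct@slots), ct@level, ctx)
}

#' @rdname heOps
#' @export
heConj <- function(ct) {
  ctx <- ct@ctx
  ctx$n_conj <- ctx$n_conj + 1L
  newCipher(Conj(ct@slots), ct@level, ctx)
}

#' @rdname heOps
#' @export
heRotate <- function(ct, r) {
  ctx <- ct@ctx
  n <- ct@n
  r <- ((as.integer(r) %% n) + n) %% n
  ctx$n_rot <- ctx$n_rot + 1L
  slots <- if (r == 0L) ct@slots else c(ct@slots[(r + 1L):n], ct@slots[1:r])
  newCipher(slots, ct@level, ctx)
}

#' Rotate-and-sum circuit
#'
#' Iteratively computes \code{ct <- ct + Rot(ct, stride * base^j)} for
#' \code{j = 0, ..., depth-1}. Output slot i holds the cyclic sum
#' \code{sum_{j=0}^{base^depth - 1} m[(i + j*stride) mod n]}; exactly
#' \code{depth} rotations are used.
#'
#' @param ct a \linkS4class{SimCipher}
#' @param stride slot stride of the summation
#' @param base rotation-growth base (2 for the log-depth circuit)
#' @param depth number of rotate-add iterations (0 = identity)
#' @return a \linkS4class{SimCipher}
#' @export
rotSum <- function(ct, stride, base = 2L, depth) {
  if (depth < 0L) stop("rotSum: depth must be >= 0")
  for (j in seq_len(depth)) {
    ct <- heAdd(ct, heRotate(ct, stride * base^(j - 1L)))
  }
  ct
}
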