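# internal helpers shared across modules

isPow2 <- function(x) {
  x == round(x) && x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

nextPow2 <- function(x) {
  stopifnot(x >= 1)
  2^ceiling(log2(x))
}

log2i <- function(x) {
  l <- log2(x)
  if (abs(l - round(l)) > 1e-9) stop("not a power of two: ", x)
  as.integer(round(l))
}

# 1-based cyclic index [x]_g in {1, ..., g}
cyc1 <- function(x, g) ((x - 1L) %% g) + 1L

zeroPadMatrix <- function(X, nr, nc) {
  out <- matrix(0, nr, nc)
  out[seq_len(nrow(X)), seq_len(ncol(X))] <- X
  out
}
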