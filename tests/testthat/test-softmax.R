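test_that("aeExp evaluates the scaled-limit exponential", {
  expect_equal(aeExp(0, 4, 32), 2^-16)
  expect_equal(aeExp(-16, 4, 32), 0)                    # zero base at x = -2^r
  # Lr * AE(1) is exactly (1 + 1/16)^16, the classic limit term
  Lr <- (32 / 16)^16
  expect_equal(Lr * aeExp(1, 4, 32), (1 + 1 / 16)^16, tolerance = 1e-12)
  expect_equal(Lr * aeExp(1, 4, 32), 2.63792849, tolerance = 1e-7)
  expect_lt(abs(Lr * aeExp(1, 4, 32) - exp(1)), 0.1)
  expect_warning(aeExp(100, 4, 32), "stable range")
})

test_that("aeExp is strictly increasing above -2^r", {
  for (r in 4:8) {
    x <- seq(-2^r + 0.01, 50, length.out = 500)
    y <- aeExp(x, r, 2^(r + 2), warn = FALSE)
    expect_true(all(diff(y) >= 0))
    # strictly increasing wherever the value is above double underflow
    rep <- y > 1e-12
    expect_true(all(diff(y[rep]) > 0))
  }
})

test_that("the exponential approximation converges as r grows", {
  x <- seq(-5, 5, length.out = 201)
  supErr <- vapply(4:8, function(r) {
    L <- 2^(r + 2)                 # keep |2^r + x| < L at every r
    Lr <- (L / 2^r)^(2^r)
    max(abs(Lr * aeExp(x, r, L) - exp(x)))
  }, numeric(1))
  expect_true(all(diff(supErr) < 0))
})

test_that("goldschmidt equals the truncated geometric series", {
  expect_equal(goldschmidt(1, 5), 1)                    # exact at x = 1
  expect_equal(goldschmidt(0.5, 2), 1.875)              # 1.5 * 1.25
  expect_equal((1 / 0.5 - goldschmidt(0.5, 2)) / (1 / 0.5), 0.0625)  # 0.5^4

  series <- function(x, d) sum((1 - x)^(0:(2^d - 1)))
  expect_equal(goldschmidt(0.5, 5), series(0.5, 5), tolerance = 1e-13)

  set.seed(1)
  for (x in runif(20, 0.05, 1.95)) {
    for (d in c(1, 2, 3, 5, 8, 10)) {
      expect_equal(goldschmidt(x, d), series(x, d), tolerance = 1e-10)
      relErr <- (1 / x - goldschmidt(x, d)) * x
      # absolute comparison: for large d the error underflows past the
      # resolution of the subtraction above
      expect_lt(abs(relErr - (1 - x)^(2^d)), 1e-10)
    }
  }
})

test_that("ciphertext goldschmidt uses 2d - 2 multiplications", {
  for (d in c(1, 2, 5, 10)) {
    ctx <- heContext(4, levelBudget = 25)
    ct <- encryptVec(c(0.5, 1.2, 0.8, 1), ctx)
    out <- goldschmidt(ct, d)
    expect_equal(opCounts(ctx)[["n_mult"]], max(0, 2 * d - 2))
    expect_equal(Re(decryptVec(out)), goldschmidt(c(0.5, 1.2, 0.8, 1), d),
                 tolerance = 1e-10)
  }
})

test_that("scaledInverse extends the inversion to (0, 2M)", {
  expect_equal(scaledInverse(80, 80, 5), 1 / 80)        # x = M is exact
  expect_equal(scaledInverse(40, 80, 30), 0.025, tolerance = 1e-11)
  # near zero the error follows the closed form and is negligible at d = 30
  x <- 0.01 * 80
  relErr <- (1 / x - scaledInverse(x, 80, 30)) * x
  expect_equal(relErr, (1 - 0.01)^(2^30))
  expect_lt(abs(relErr), 1e-6)
})

test_that("calibration picks the smallest admissible L with a 10% margin", {
  sc <- matrix(seq(-10, 10, length.out = 22), 2)
  cfg <- calibrateSoftmax(sc, r = 4)
  expect_equal(cfg@L, 32)   # max|16 + x| = 26 <= 32 * 0.9 = 28.8
  cfg2 <- calibrateSoftmax(matrix(c(-20, 20), 1), r = 4)
  expect_equal(cfg2@L, 64)  # max|16 + x| = 36 > 28.8 -> next rung

  cfg0 <- calibrateSoftmax(matrix(0, 3, 4), r = 4)
  expect_equal(cfg0@L, 32)  # 16 <= 32 * 0.9 already admissible

  # invariant to sample order
  perm <- sc[sample(nrow(sc)), ]
  expect_equal(calibrateSoftmax(perm, r = 4)@L, cfg@L)

  expect_error(calibrateSoftmax(matrix(1e6, 2, 2), r = 4,
                                candidatesL = 2^(5:8)),
               "no admissible L")
})

test_that("calibration keeps M admissible for the inversion", {
  # confident scores: default M = 80 is admissible
  sc <- cbind(runif(50, 25, 40), matrix(runif(50 * 10, -10, 10), 50))
  cfg <- calibrateSoftmax(sc, r = 4)
  expect_equal(cfg@M, 80)
  # a wide score spread forces L = 64; rows with low maxima then have tiny AE
  # sums and M = 80 would blow up the inversion error, so M falls back
  scLow <- rbind(c(35, 0, 0, 0), c(6, 0, 0, 0))
  cfgLow <- calibrateSoftmax(scLow, r = 4)
  expect_equal(cfgLow@L, 64)
  expect_lt(cfgLow@M, 80)
  sums <- rowSums(aeExp(scLow, 4, cfgLow@L, warn = FALSE))
  expect_lte(max(sums), 2 * cfgLow@M)
  expect_lt((1 - min(sums) / cfgLow@M)^(2^30), 1e-3)
})

test_that("approximate softmax is symmetric, normalized and rank-preserving", {
  cfg <- softmaxConfig(4, 64, 80, 30)
  # constant in-range scores: every class gets ~1/T
  out <- approxSoftmax(matrix(20, 1, 11), cfg)
  expect_equal(as.numeric(out), rep(1 / 11, 11), tolerance = 1e-6)

  set.seed(2)
  V <- cbind(runif(200, 25, 40), matrix(runif(200 * 10, -10, 10), 200))
  V <- t(apply(V, 1, sample))      # shuffle the dominant position
  A <- approxSoftmax(V, cfg)
  E <- exactSoftmax(V)
  expect_lt(max(abs(A - E)), 1e-2)
  expect_equal(rowSums(A), rep(1, 200), tolerance = 1e-3)
  for (i in 1:20)
    expect_identical(order(A[i, ]), order(E[i, ]))   # full rank preservation
})

test_that("the encrypted softmax circuit matches its plain counterpart", {
  set.seed(3)
  s <- 8; T <- 3   # T not a multiple of m exercises the padded-class path
  sc <- matrix(runif(s * T, -5, 5), s, T)
  sc[cbind(1:s, sample(T, s, TRUE))] <- runif(s, 25, 35)  # confident rows
  cfg <- calibrateSoftmax(sc, r = 4)
  expect_equal(cfg@M, 80)

  for (m in c(1L, 2L)) {
    plan <- packingPlan(s, 8, T, 32, m, complexPack = TRUE)
    ctx <- heContext(32)
    # feed the scores through the encrypted pipeline via an identity product:
    # X = [sc | 0] against the first T columns of the identity
    Xs <- cbind(sc, matrix(0, s, 8 - T))
    Wid <- diag(1, 8)[, 1:T]
    cts <- encodeInputs(Xs, plan, ctx)
    masks <- encodeWeights(Wid, plan)
    ctY <- encryptedMatvec(cts, masks, plan)
    ctP <- approxSoftmax(ctY, cfg, plan)
    enc <- decodeScores(ctP, plan)
    plain <- approxSoftmax(sc, cfg)
    expect_equal(enc, unname(plain), tolerance = 1e-9)
    expect_lt(max(abs(enc - exactSoftmax(sc))), 1e-2)
  }
})
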