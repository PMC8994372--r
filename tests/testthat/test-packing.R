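test_that("extractDiagonals follows the cyclic index rule", {
  X <- matrix(c(1, 3, 2, 4), 2, 2)      # [[1,2],[3,4]]
  D <- extractDiagonals(X)
  expect_equal(D[, 1], c(2, 3))         # x_0
  expect_equal(D[, 2], c(1, 4))         # x_1

  X1 <- matrix(c(5, 6, 7), 3, 1)
  expect_equal(extractDiagonals(X1)[, 1], c(5, 6, 7))   # g = 1: lone column
})

test_that("diagonal decomposition reassembles the matrix-vector product", {
  set.seed(2)
  for (rep in 1:5) {
    X <- matrix(rnorm(64), 8, 8)
    w <- rnorm(8)
    D <- extractDiagonals(X)
    acc <- rowSums(vapply(0:7, function(j) D[, j + 1] * rotateWeight(w, j, 8),
                          numeric(8)))
    expect_equal(acc, as.numeric(X %*% w), tolerance = 1e-12)
  }
})

test_that("rotateWeight re-indexes cyclically", {
  w <- c(10, 20, 30, 40)
  expect_equal(rotateWeight(w, 1, 4), w)          # j=1, s=g: identity layout
  expect_equal(rotateWeight(rep(7, 4), 3, 6), rep(7, 6))  # constant vector
  s <- 5; g <- 4; j <- 2
  wj <- rotateWeight(w, j, s)
  for (k in 1:s) expect_equal(wj[k], w[((j + k - 2) %% g) + 1])
})

test_that("encodeInputs produces the planned ciphertext count and inverts", {
  X <- matrix(sample(-2:2, 32, TRUE), 8, 4)

  # toy real-only duplicated plan: 2 ciphertexts
  plan <- packingPlan(8, 4, 4, 32, 2, complexPack = FALSE)
  ctx <- heContext(32)
  cts <- encodeInputs(X, plan, ctx)
  expect_length(cts, 2)

  # complex pairing on the same dims: 1 ciphertext
  planC <- packingPlan(8, 4, 4, 32, 2, complexPack = TRUE)
  ctsC <- encodeInputs(X, planC, heContext(32))
  expect_length(ctsC, 1)

  # decrypt-and-unpack recovers the diagonals (first copy of each)
  D <- extractDiagonals(X)
  slots <- decryptVec(ctsC[[1]])
  for (q in 0:1) {
    block <- slots[(q * 2 * 8 + 1):(q * 2 * 8 + 8)]
    expect_equal(Re(block), D[, 2 * q + 1])
    expect_equal(Im(block), D[, 2 * q + 2])
    # the m = 2 duplicate
    dup <- slots[(q * 2 * 8 + 9):(q * 2 * 8 + 16)]
    expect_equal(dup, block)
  }

  # minimal m = 1 complex case: one ciphertext, x_0 + i x_1, no duplication
  X2 <- matrix(rnorm(8), 4, 2)
  plan2 <- packingPlan(4, 2, 2, 4, 1, complexPack = TRUE)
  cts2 <- encodeInputs(X2, plan2, heContext(4))
  expect_length(cts2, 1)
  D2 <- extractDiagonals(X2)
  expect_equal(decryptVec(cts2[[1]]),
               complex(real = D2[, 1], imaginary = D2[, 2]))
})

test_that("encodeWeights reproduces the interleaved warm-up layout", {
  set.seed(4)
  W <- matrix(rnorm(16), 4, 4)
  plan <- packingPlan(8, 4, 4, 32, 2, complexPack = FALSE)
  masks <- encodeWeights(W, plan)
  expect_length(masks, 2)            # ceil(T/m) class groups
  expect_length(masks[[1]], 2)       # one mask per ciphertext
  # group k, ciphertext l holds (w_2k^(2l) || w_2k+1^(2l) || w_2k^(2l+1) || w_2k+1^(2l+1))
  for (k in 0:1) for (l in 0:1) {
    expected <- c(rotateWeight(W[, 2 * k + 1], 2 * l, 8),
                  rotateWeight(W[, 2 * k + 2], 2 * l, 8),
                  rotateWeight(W[, 2 * k + 1], 2 * l + 1, 8),
                  rotateWeight(W[, 2 * k + 2], 2 * l + 1, 8))
    expect_equal(Re(masks[[k + 1]][[l + 1]]), expected)
    expect_true(all(Im(masks[[k + 1]][[l + 1]]) == 0))
  }
})

test_that("classes beyond T are zero-masked when T is not a multiple of m", {
  W <- matrix(1, 4, 3)              # T = 3, m = 2 -> second group half zero
  plan <- packingPlan(8, 4, 3, 32, 2, complexPack = FALSE)
  masks <- encodeWeights(W, plan)
  expect_length(masks, 2)
  m2 <- Re(masks[[2]][[1]])
  # blocks of 8 slots alternate class 2 (jm+0 = 2 < T) and padded class 3
  expect_true(all(m2[9:16] == 0))    # r = 1 block of q = 0
  expect_true(all(m2[25:32] == 0))   # r = 1 block of q = 1
  expect_true(all(m2[1:8] == 1))
})

test_that("encrypted matrix-vector product matches the dense oracle", {
  set.seed(6)
  X <- matrix(rnorm(64), 8, 8)
  W <- matrix(rnorm(32), 8, 4)
  res <- runToyMatvec(X, W, 8, 8, 4, 64, 2, TRUE)
  expect_equal(res$Y, X %*% W, tolerance = 1e-10)
})

test_that("all duplication factors give identical decrypted scores", {
  set.seed(8)
  X <- matrix(rnorm(16 * 8), 16, 8)
  W <- matrix(rnorm(8 * 4), 8, 4)
  exact <- X %*% W
  ys <- lapply(c(1, 2, 4), function(m) {
    plan <- autoPlan(16, 8, 4, m = m)
    runToyMatvec(X, W, 16, 8, 4, plan@n, m, TRUE)$Y
  })
  for (Y in ys) expect_equal(Y, exact, tolerance = 1e-10)
  expect_equal(ys[[1]], ys[[3]], tolerance = 1e-12)
})

test_that("fixed-point arithmetic stays within 1e-6 relative error", {
  set.seed(9)
  X <- matrix(sample(-2:2, 64, TRUE), 8, 8)
  W <- matrix(rnorm(32), 8, 4)
  res <- runToyMatvec(X, W, 8, 8, 4, 64, 2, TRUE, mode = "fixed")
  expect_lt(max(abs(res$Y - X %*% W)) / max(abs(X %*% W)), 1e-6)
})

test_that("predicted costs match the worked toy example", {
  planNaive <- packingPlan(8, 4, 4, 32, 1, complexPack = FALSE)
  expect_equal(predictCosts(planNaive)[["n_rot"]], 8)
  planDup <- packingPlan(8, 4, 4, 32, 2, complexPack = FALSE)
  expect_equal(predictCosts(planDup)[["n_rot"]], 2)
  expect_equal(predictCosts(planDup)[["n_cmult"]], 4)
  expect_equal(predictCosts(planDup)[["n_ct"]], 2)
  planIm <- packingPlan(8, 4, 4, 32, 2, complexPack = TRUE)
  expect_equal(predictCosts(planIm)[["n_cmult"]], 2)
  expect_equal(predictCosts(planIm)[["n_rot"]], 2)
})

test_that("doubling m trades rotations for ciphertexts", {
  s <- 16; g <- 32; T <- 8; n <- 256
  costs <- lapply(c(1, 2, 4, 8), function(m)
    predictCosts(packingPlan(s, g, T, n, m, TRUE)))
  rots <- vapply(costs, `[[`, numeric(1), "n_rot")
  cts <- vapply(costs, `[[`, numeric(1), "n_ct")
  expect_true(all(diff(rots) < 0))            # strictly fewer rotations
  expect_equal(cts, cts[1] * c(1, 2, 4, 8))   # linear ciphertext growth
})

test_that("invalid plans are rejected", {
  expect_error(packingPlan(8, 4, 4, 32, 3), "power of two")
  expect_error(packingPlan(8, 4, 4, 4, 1), "m\\*s exceeds")
  expect_error(packingPlan(2, 2, 2, 64, 1), "slot count too large")
})
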