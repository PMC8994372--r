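test_that("hammingDist counts disagreeing positions", {
  expect_identical(hammingDist(c(0, 1, 2), c(0, 1, 2))$count, 0L)
  d <- hammingDist(c(0, 1, 2, -1), c(0, 2, 2, 1))
  expect_identical(d$count, 2L)
  expect_equal(d$normalized, 0.5)
  expect_identical(hammingDist(c(1, 1), c(-1, -1))$count, 2L)
  expect_error(hammingDist(1:3, 1:4), "length mismatch")
})

test_that("cnFilter groups greedily from the left and keeps representatives", {
  # all columns identical: a single group led by the first gene
  C <- matrix(1L, 4, 5, dimnames = list(NULL, paste0("g", 1:5)))
  f <- cnFilter(C, 0.5)
  expect_identical(f$genes, "g1")

  # dCN = 0: no distance is below 0, every gene leads its own group
  C2 <- matrix(sample(-2:2, 20, TRUE), 4, 5,
               dimnames = list(NULL, paste0("g", 1:5)))
  expect_length(cnFilter(C2, 0)$genes, 5)

  # hand-simulated greedy pass: g2 joins g1 (dist 1/4), g3 starts a group
  # (dist 4/4), g4 joins g3 (dist 1/4)
  C3 <- cbind(g1 = c(0, 0, 0, 0), g2 = c(0, 0, 0, 1),
              g3 = c(2, 2, 2, 2), g4 = c(2, 2, 2, 1))
  expect_identical(cnFilter(C3, 0.5)$genes, c("g1", "g3"))

  expect_error(cnFilter(matrix(nrow = 4, ncol = 0), 0.1), "empty")
})

test_that("cnFilter output is a subsequence with pairwise-separated representatives", {
  set.seed(42)
  for (i in 1:20) {
    C <- matrix(sample(-2:2, 12 * 30, TRUE), 12, 30,
                dimnames = list(NULL, sprintf("g%02d", 1:30)))
    d <- runif(1, 0.05, 0.9)
    f <- cnFilter(C, d)
    idx <- match(f$genes, colnames(C))
    expect_false(is.unsorted(idx))               # subsequence, order kept
    expect_identical(idx[1], 1L)                 # first gene always kept
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        sep <- mean(C[, idx[k - 1]] != C[, idx[k]])
        expect_gte(sep, d)                       # consecutive reps separated
      }
    }
  }
})

test_that("cnFilter representative count is monotone nonincreasing in dCN", {
  set.seed(7)
  C <- matrix(sample(-2:2, 16 * 40, TRUE), 16, 40)
  counts <- vapply(c(0, 0.1, 0.2, 0.4, 0.6, 0.9),
                   function(d) length(cnFilter(C, d)$genes), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("effect levels encode to the fixed value set", {
  expect_equal(encodeEffect("HIGH"), 1.0)
  expect_equal(encodeEffect("LOW"), 0.2)
  expect_equal(encodeEffect("MODERATE"), 0.5)
  expect_equal(encodeEffect("MODIFIER"), 0.9)
  expect_equal(encodeEffect(NA_character_), 0)
  expect_error(encodeEffect("SEVERE"), "unknown effect")
})

makeVariants <- function(records, samples, genes, nTypes) {
  variantsTable(records, samples, genes, nTypes)
}

test_that("variantsFilter selects genes whose per-type effect mass exceeds the threshold", {
  samples <- paste0("s", 1:3); genes <- paste0("g", 1:3)
  # column sums for type 1: g1 = 0.4, g2 = 1.5, g3 = 0
  rec <- data.frame(
    sample_id = c("s1", "s2", "s1", "s2"),
    gene_id = c("g1", "g1", "g2", "g2"),
    tumor_type = 1L,
    effect = c("LOW", "LOW", "MODERATE", "HIGH"))
  vt <- makeVariants(rec, samples, genes, 1L)
  labels <- c(s1 = 1L, s2 = 1L, s3 = 1L)
  expect_identical(variantsFilter(vt, labels, 1)$genes, "g2")
  # kVar = 0: every gene with at least one record
  expect_identical(variantsFilter(vt, labels, 0)$genes, c("g1", "g2"))
  # tie at exactly kVar is excluded (strict >)
  expect_identical(variantsFilter(vt, labels, 1.5)$genes, character(0))
})

test_that("variantsFilter takes the union of per-type selections", {
  samples <- paste0("s", 1:2); genes <- paste0("g", 1:3)
  rec <- data.frame(
    sample_id = c("s1", "s2"),
    gene_id = c("g1", "g3"),
    tumor_type = c(1L, 2L),
    effect = c("HIGH", "HIGH"))
  vt <- makeVariants(rec, samples, genes, 2L)
  labels <- c(s1 = 1L, s2 = 2L)
  expect_identical(variantsFilter(vt, labels, 0.5)$genes, c("g1", "g3"))
})

test_that("variantsFilter selection is antitone in kVar", {
  coh <- tinyCohort(seed = 11, mutationRate = 0.05)
  sizes <- vapply(c(0, 0.5, 1, 2, 4, 8), function(k)
    length(variantsFilter(coh$variants, coh$labels, k)$genes), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("repeated records for one cell aggregate by sum (or max on request)", {
  samples <- "s1"; genes <- "g1"
  rec <- data.frame(sample_id = "s1", gene_id = "g1", tumor_type = 1L,
                    effect = c("LOW", "HIGH"))
  vt <- makeVariants(rec, samples, genes, 1L)
  labels <- c(s1 = 1L)
  expect_equal(variantsFilter(vt, labels, 0)$values[1, 1], 1.2)
  expect_equal(variantsFilter(vt, labels, 0, aggregate = "max")$values[1, 1], 1)
})

test_that("assembleFeatures concatenates, pads to powers of two and keeps padding zero", {
  Xc <- matrix(1, 5, 3); Xv <- matrix(2, 5, 5)
  fm <- assembleFeatures(Xc, Xv)
  expect_identical(dim(featureValues(fm)), c(8L, 8L))   # 5 -> 8 rows, 8 cols
  expect_identical(fm@nFeatures, 8L)                    # already a power of 2
  expect_true(all(featureValues(fm)[6:8, ] == 0))

  fm6 <- assembleFeatures(matrix(1, 4, 2), matrix(1, 4, 4))
  expect_identical(ncol(featureValues(fm6)), 8L)        # 6 -> 8 with zero cols
  expect_true(all(featureValues(fm6)[, 7:8] == 0))

  expect_error(assembleFeatures(matrix(1, 4, 2), matrix(1, 5, 2)),
               "sample mismatch")
})

test_that("padded product equals the unpadded product on the true block", {
  set.seed(3)
  X <- matrix(rnorm(6 * 6), 6, 6)
  W <- matrix(rnorm(6 * 3), 6, 3)
  fm <- assembleFeatures(X[, 1:3], X[, 4:6])
  Wp <- heSNN:::zeroPadMatrix(W, ncol(featureValues(fm)), 3)
  full <- featureValues(fm) %*% Wp
  expect_equal(full[1:6, ], X %*% W, tolerance = 1e-12)
  expect_true(all(full[7:8, ] == 0))
})

test_that("a cohort restricted to the selected genes reproduces the feature matrix", {
  coh <- tinyCohort(seed = 13)
  cnF <- cnFilter(coh$cn, 0.3)
  vaF <- variantsFilter(coh$variants, coh$labels, 0.5)
  full <- assembleFeatures(cnF, vaF)

  # client-side view: only the selected genes are shared/encrypted
  keep <- geneIds(coh$cn) %in% c(cnF$genes, vaF$genes)
  cnSub <- cnMatrix(cnValues(coh$cn)[, geneIds(coh$cn)[keep], drop = FALSE])
  rec <- variantRecords(coh$variants)
  vtSub <- variantsTable(rec[rec$gene_id %in% vaF$genes, ],
                         sampleIds(coh$cn), geneIds(coh$cn)[keep],
                         coh$variants@nTypes)
  CtSub <- cnValues(cnSub)[, cnF$genes, drop = FALSE]
  VtSub <- heSNN:::encodeVariantsMatrix(variantRecords(vtSub),
                                        sampleIds(coh$cn), vaF$genes)
  again <- assembleFeatures(list(values = CtSub, genes = cnF$genes),
                            list(values = VtSub, genes = vaF$genes))
  expect_equal(featureValues(again), featureValues(full))
})
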