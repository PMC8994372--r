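# small cohorts shared across test files

tinyCohort <- function(seed = 1L, nSamples = 60L, nGenes = 64L,
                       nTumorTypes = 4L, blockSize = 4L, flipProb = 0.05,
                       mutationRate = 0.02, signalStrength = 0.9) {
  generateCohort(synthConfig(nSamples = nSamples, nGenes = nGenes,
                             nTumorTypes = nTumorTypes, blockSize = blockSize,
                             flipProb = flipProb, mutationRate = mutationRate,
                             signalStrength = signalStrength, seed = seed))
}

quickTrainConfig <- function(epochs = 10L, seed = 1L, folds = 3L) {
  trainConfig(epochs = epochs, seed = seed, folds = folds,
              learningRate = 0.001)
}

# random valid packing plan dims for fuzz tests
randomPlanDims <- function() {
  s <- 2^sample(1:4, 1)          # 2..16 samples
  g <- 2^sample(1:4, 1)          # 2..16 features
  T <- sample(1:6, 1)
  m <- 2^sample(0:2, 1)
  complexPack <- sample(c(TRUE, FALSE), 1)
  # n must satisfy m*s <= n and ell <= g (so every ciphertext is filled)
  full <- if (complexPack) m * s * g / 2 else m * s * g
  nMin <- if (complexPack) m * s else m * s
  if (full < nMin) return(NULL)
  nOpts <- 2^(log2(nMin):log2(full))
  n <- sample(nOpts, 1)
  if (complexPack && 2 * n / (m * s) < 2) return(NULL)
  list(s = s, g = g, T = T, n = n, m = m, complexPack = complexPack)
}

runToyMatvec <- function(X, W, s, g, T, n, m, complexPack,
                         mode = "exact") {
  plan <- packingPlan(s, g, T, n, m, complexPack)
  ctx <- heContext(n, mode = mode)
  cts <- encodeInputs(X, plan, ctx)
  masks <- encodeWeights(W, plan)
  ctY <- encryptedMatvec(cts, masks, plan)
  list(Y = decodeScores(ctY, plan), counts = opCounts(ctx), plan = plan,
       nCt = length(cts), ctx = ctx, ctY = ctY)
}
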