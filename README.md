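# heSNN

Privacy-preserving multi-label tumor-type classification with a shallow
neural network evaluated over (simulated) homomorphic encryption.

## The problem

A server owns a classifier that predicts a tumor type from a patient's
genomic profile — gene-level copy-number calls in {0, ±1, ±2} and predicted
somatic-mutation effects (LOW / MODERATE / MODIFIER / HIGH). A client wants
the prediction without revealing the profile. Under the CKKS approximate
homomorphic-encryption scheme the server can evaluate its model directly on
the encrypted profile, but only additions, multiplications, slot rotations
and conjugations are available, multiplications consume a finite level
budget, and rotations dominate the running time. This package implements,
end to end and fully testable without any external data, the ingredients
that make such an inference protocol practical:

1. **HE-friendly gene filtering.** Copy-number columns (in chromosomal
   order) are clustered greedily by normalized Hamming distance
   `dist_H(p, q)/s`; one representative gene is kept per cluster
   (threshold `d_cn`). Variant records are encoded to fixed values
   (LOW = 0.2, MODERATE = 0.5, MODIFIER = 0.9, HIGH = 1.0, absent = 0) and,
   per tumor type *t*, gene *j* is kept when the column mass
   `Σ_i V_t(i,j) > k_var`; the final set is the union over types. The
   filtered feature count is capped at `2^B`. The client only ever needs
   the selected gene lists.
2. **A shallow network trained in plaintext.** One 64-node *linear* hidden
   layer with dropout 0.9 and an 11-node softmax output (batch size 32,
   50 epochs). Because the hidden activation is linear the trained network
   composes into a single rank-≤64 matrix `W` (biases folded in via a
   constant-one feature column), so encrypted inference is one matrix
   product `Y = X·W`.
3. **Duplicated diagonal packing.** `X·w` is decomposed into Hadamard
   products of the cyclic diagonals `x_j(k) = X(k, [j+k-1]_g)` with
   re-indexed weight vectors. Each diagonal is placed in the ciphertext
   `m` times and two diagonals share one complex slot vector
   (real + imaginary part), giving `log2(n/(ms))·⌈T/m⌉` rotations and
   `(sg/2n)·m·⌈T/m⌉` constant multiplications from `m·sg/(2n)` ciphertexts —
   a tunable trade-off of memory against rotations. A rotate-and-sum circuit
   collapses the partial products.
4. **Polynomial softmax.** The exponential is approximated by the
   scaled-limit form `AE_{r,L}(x) = ((2^r + x)/L)^(2^r)` (one constant
   multiplication plus `r` squarings; strictly increasing above `-2^r`, so
   score rankings — and micro-averaged AUC — survive the approximation), and
   the normalizing division by Goldschmidt's algorithm
   `1/x ≈ Π_{i<d} (1 + (1-x)^(2^i))` on `(0, 2M)`, with `(r, L, M, d)`
   calibrated from the training scores.

Everything runs on a plaintext simulator of CKKS slot semantics
(`SimCipher`) that enforces level consumption and counts every rotation,
multiplication, constant multiplication, addition and conjugation, so the
cost formulas above are audited by the test suite rather than assumed.
Real cryptography (key generation, encryption noise, bootstrapping) is out
of scope by design.

## Worked example

```r
library(heSNN)

coh   <- generateCohort(synthConfig(nSamples = 256, nGenes = 512,
                                    nTumorTypes = 11, seed = 42))
sp    <- splitCohort(coh, 0.75, seed = 42)
model <- fitModel(sp$train, filterParams(dCN = 0.2, kVar = 2, B = 10),
                  trainConfig(epochs = 50, learningRate = 0.001, seed = 42))
model
#> SNNModel: 79 x 11 composed weight matrix; 64 CN genes, 14 variant genes, 11 classes
model@softmaxCfg
#> SoftmaxConfig: r = 4, L = 32, M = 80, d = 30 (Lr = 65536)

res <- runInference(model, sp$test, m = 2)   # encrypted inference, m = 2 duplication
res
#> InferenceResult: 66 samples x 11 classes
#>   metrics: microAUC 1.0000, accuracy 0.9848
res@costs$matvec[c("n_rot", "n_cmult")]      # audited operation counts
#> $n_rot   [1] 36
#> $n_cmult [1] 6
round(inferenceScores(res)[1:3, 1:5], 4)
#>        [,1]  [,2]   [,3]  [,4]  [,5]
#> S0007 8e-04 4e-04 0.9761 1e-04 4e-04
#> S0009 0e+00 7e-04 0.9926 0e+00 2e-04
#> S0011 4e-04 8e-04 0.9951 1e-04 8e-04
```

The 79 = 64 CN representatives + 14 selected variant genes + 1 folded bias
row. The per-sample rows are approximate-softmax probabilities; the third
class dominates for these samples and the micro-averaged AUC pools all
(sample, class) score/indicator pairs into one ROC curve. The filter
clusters the 512 synthetic genes (blocks of 8 positionally correlated
genes) down to 64 representatives, exactly one per block.

A thin CLI wraps the same functions
(`inst/cli/hesnn.R synth | train | infer | cost`):

```sh
Rscript inst/cli/hesnn.R synth --out cohort --samples 96 --genes 256 --classes 4 --seed 3
Rscript inst/cli/hesnn.R train --data cohort --model model --dcn 0.3 --kvar 0.5 -B 8
Rscript inst/cli/hesnn.R infer --data cohort --model model --out out --dup 2
Rscript inst/cli/hesnn.R cost  --samples 128 --genes 1024 --classes 11 --dup 2
```

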