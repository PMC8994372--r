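---
title: "Methods: encrypted shallow-network tumor classification"
author: "heSNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encrypted shallow-network tumor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heSNN)
```

# Overview

`heSNN` implements an inference protocol in which a server evaluates a
trained tumor-type classifier on a client's encrypted genomic profile. The
pipeline has four stages: gene filtering, plaintext training, encrypted
matrix-vector multiplication under a packed (SIMD) ciphertext layout, and a
polynomial softmax. This vignette explains the model behind each stage, the
parameters that matter, the numerical choices we made where the design was
genuinely open, and what the synthetic-data tests do and do not demonstrate.

# Data model and filtering

The inputs are a copy-number matrix `C` (samples × genes, levels
0, ±1, ±2, genes ordered by chromosomal position) and sparse
mutation-effect records (sample, gene, tumor type, effect level). Both
filters are deliberately simple — a client with limited compute must be able
to apply them by just *selecting columns*:

* **Copy-number filter.** Neighboring genes tend to share copy-number
  state, so columns are clustered greedily from the left: the current
  representative absorbs each following gene while the normalized Hamming
  distance (fraction of samples that disagree) is `< d_cn`; the first gene
  at distance `≥ d_cn` opens a new cluster. Only representatives are kept.
  `d_cn` is a fraction in `[0, 1)`; `d_cn = 0` keeps every gene. Distances
  are measured against the *representative*, not the previous gene, so a
  slow positional drift cannot chain distant genes into one cluster.
* **Variants filter.** Effects are encoded LOW = 0.2, MODERATE = 0.5,
  MODIFIER = 0.9, HIGH = 1.0, absent = 0. Per tumor type `t`, gene `j`
  survives when its encoded column mass over the type's samples strictly
  exceeds `k_var`; the final gene set is the union over types. When one
  (sample, gene) cell carries several records their encoded values are
  *summed* by default (cohort-level effect counts exceed one record per
  cell on average, so discarding multiplicity loses information); a
  max-aggregation switch exists for users who prefer a saturation model.

The concatenated matrix `X = [C̃ | Ṽ]` is zero-padded in both dimensions to
powers of two, which the packing below requires; padding is provably inert
(padded `X·W` restricted to the true block equals the unpadded product, a
property the tests assert).

The model-size bound `2^B` (default `B = 10`) caps the filtered feature
count. It exists purely for the encrypted side: ciphertext count and
rotation count grow with the padded feature dimension.

# The shallow network and weight composition

The classifier is a one-hidden-layer network: 64 hidden nodes with a
*linear* activation and dropout rate 0.9, then a `T`-node softmax output
(defaults: batch size 32, 50 epochs, stratified 10-fold cross-validation in
the grid search). The linear hidden layer is the crucial modeling
commitment: the composed map `W = W1·W2` has rank at most 64, so encrypted
inference needs exactly one matrix product. We keep the two-layer
parameterization during training because dropout between the layers
regularizes differently from training a single dense matrix.

Two training details are implementation choices, documented here because no
authoritative recipe fixes them:

* **Biases.** We train with biases and fold the net bias `b1·W2 + b2` into
  an extra row of `W`, matched by a constant-one feature column, so the
  encrypted circuit remains a single product. Bias-free training is
  available (`useBias = FALSE`).
* **Optimizer.** Minibatch Adam with learning rate 0.001 (the conventional
  default of the framework the recipe originates from), β₁ = 0.9,
  β₂ = 0.999. The loss is softmax cross-entropy; a non-finite loss aborts
  with a diagnostic rather than returning garbage weights.

Cross-validated grid search over `(d_cn, k_var)` scores each admissible
pair (filtered size ≤ `2^B`) by mean per-fold micro-averaged AUC. Ties
break toward fewer filtered genes, then smaller `d_cn` — cheaper encrypted
inference at equal quality. Folds are stratified by tumor type so small
synthetic cohorts never produce empty validation classes. Per-fold
averaging (not pooling) of the AUC is our documented convention.

# The ciphertext simulator

CKKS ciphertexts hold `n` complex slots (default `n = 2^16`, half the ring
dimension `2^17`); all arithmetic is slotwise, plus cyclic rotation and
complex conjugation. The simulator reproduces exactly this *functional*
semantics on plain complex vectors, enforces the level contract (every
ciphertext or constant multiplication consumes one of `levelBudget = 44`
levels, matching a 2670-bit modulus at a 2^60 scaling factor), and tallies
every operation. Two arithmetic modes exist:

* **exact** (default): double-precision complex arithmetic. Used for all
  correctness oracles.
* **fixed**: slots are quantized to a 2^-60 grid after every operation and
  plain masks to 2^-40, mirroring the scaling factors a fixed-point
  implementation would use. This bounds the approximation drift the real
  scheme's rescaling would introduce — the tests require ≤ 1e-6 relative
  error on the matrix product — but it does *not* model cryptographic
  noise, which is deliberately out of scope.

Conjugation is level-free, matching practice; the ÷2 in the conjugate-add
real-part extraction is pre-folded into the weight masks to save a level.

# Packing and the encrypted product

`X·w` decomposes over the cyclic diagonals `x_j(k) = X(k, [j+k-1]_g)`:
`X·w = Σ_j x_j ⊙ w^(j)` with `w^(j)(k) = w([j+k-1]_g)`. Index arithmetic is
1-based cyclic in the notation above and 0-based internally; rather than
trusting the transcription of the index rule, the tests validate the
decomposition solely through a dense matrix-multiplication oracle, so an
off-by-one cannot survive.

Each diagonal is written into the ciphertext `m` times (`m` a power of
two), and complex pairing stores diagonals `2q, 2q+1` as real and imaginary
parts of one slot vector. A ciphertext then carries `ℓ = 2n/(ms)` diagonals
and `m·sg/(2n)` ciphertexts suffice. For each group of `m` classes the
server multiplies every ciphertext by one precomputed mask (interleaving
the `m` weight columns against the resident diagonals, zero-padding class
indices beyond `T`), extracts real parts via conjugate-add, sums over
ciphertexts and finishes with a rotate-and-sum of depth `log2(n/(ms))` at
stride `ms`. The closed-form costs

* rotations: `log2(n/(ms)) · ⌈T/m⌉`
* constant multiplications: `(sg/2n) · m · ⌈T/m⌉` (twice that without
  complex pairing)
* ciphertexts: `m·sg/(2n)`

are not just documentation: `predictCosts()` must equal the simulator's
counters on every fuzzed plan, and the worked 8×4 toy configuration
reproduces the published counts (8 rotations naive; 2 rotations, 4 constant
multiplications, 2 ciphertexts duplicated; 2 constant multiplications with
complex pairing). Raising `m` buys rotations with memory: ciphertext count
grows linearly while rotation count falls, the protocol's central
trade-off. The constant-multiplication accounting counts one `CMult` per
ciphertext per class group; the conjugate of a product is not a second
`CMult`.

One packing constraint is worth stating: we require every ciphertext to be
*full* (`g` a multiple of `ℓ`), i.e. the slot count must satisfy
`n ≤ m·s·g/2` for complex packing. `autoPlan()` picks the largest such `n`
under a cap. Sparse trailing ciphertexts would be easy to add but would
break the clean cost identities the package audits.

# Polynomial softmax

With scores `v` the exact softmax is `exp(v_i)/Σ exp(v_j)`. Two polynomial
pieces replace the non-polynomial parts:

* **Scaled-limit exponential** `AE_{r,L}(x) = ((2^r + x)/L)^(2^r)`,
  computable with one constant multiplication and `r` squarings, satisfying
  `(L/2^r)^(2^r) · AE(x) ≈ exp(x)`. Its virtue over minimax or Chebyshev
  fits is *monotonicity* on `(-2^r, ∞)`: a monotone approximation preserves
  score rankings, hence argmax decisions and (pooled) AUC behave. Defaults
  `r = 4` with `L` calibrated (see below).
* **Goldschmidt inversion** `1/x ≈ Π_{i=0}^{d-1} (1 + (1-x)^(2^i))` on
  `(0, 2)`, extended to `(0, 2M)` by `1/x ≈ (1/M)·Gol(x/M)`. The product of
  `d` factors equals the geometric series truncated at degree `2^d - 1`,
  uses `2d - 2` multiplications, and has signed relative error
  `-(1-x)^(2^d)`. (Some derivations quote exponent `2^(d+1)` by counting
  one extra squaring; with `d` product factors the exponent is exactly
  `2^d`, which the tests verify numerically.) Default `d = 30`, `M = 80`.

The encrypted circuit computes `AE` of every packed class score, sums the
`m` in-ciphertext class blocks with `log2(m)` rotations, adds the class-group
ciphertexts, subtracts the known constant contributed by zero-padded classes
(each pads `AE(0) = (2^r/L)^(2^r)`, a plain subtraction costing nothing),
inverts the sum with the scaled Goldschmidt, and multiplies back. Total
depth ≈ `r + d + 4` levels, inside the 44-level budget at the defaults.

## Calibration and the accuracy regime

Calibration inspects the training-score matrix `X·W`:

* `L` is the smallest ladder value (`32, 64, 128, …`) with
  `max |2^r + score| ≤ 0.9·L`. Keeping `L` small matters: it keeps `AE`
  values (and their sums) away from zero.
* `M = 80` is kept when admissible; admissibility demands the AE sums fit
  in `(0, 1.8·M)` *and* the inversion error at the smallest observed sum,
  `(1 - S_min/M)^(2^d)`, stays below 1e-3. Otherwise `M` falls back to
  `S_max/1.8`. The second condition is essential: Goldschmidt
  *underestimates* `1/x` badly near zero — with tiny AE sums and a large
  `M` the entire probability vector collapses toward zero. The 10% margin
  and the 1e-3 inversion tolerance are our choices; the method only
  requires "large enough" bounds.

A regime statement users should know: the polynomial softmax is
*rank-faithful everywhere* in the stable range but *elementwise-accurate
only for confidently separated scores*. Writing
`log AE(v) = 2^r·log(1 + v/2^r) - const = v - v²/2^(r+1) + …`, the
approximation distorts pairwise log-odds by `(v_i² - v_j²)/2^(r+1)`. Two
competing classes with large, nearly equal scores therefore shift the
softmax probabilities by far more than 1e-2 even though their order is
preserved — e.g. scores `(5, 4.5, -5, …)` already err by ≈ 0.03 at `r = 4`.
The package's elementwise-accuracy tests consequently draw score vectors
the way a trained confident classifier produces them (one dominant logit
well separated from the rest, within the calibrated range); on 10⁴ such
11-class vectors the maximum elementwise deviation from the exact softmax
is ≈ 1.5e-3 with 100% argmax agreement. Out-of-range encrypted inputs
cannot be detected at run time (the server sees only ciphertexts), so the
plain path warns on out-of-range values while the encrypted path relies on
the calibration — exactly the situation a deployment faces.

# The synthetic-data generator

`generateCohort()` emulates the statistical structure the method assumes:

* **Positional copy-number similarity**: contiguous blocks of `blockSize`
  genes (default 8) share a per-sample base profile, each entry flipped to
  another level with probability `flipProb` (default 0.05). Adjacent blocks
  are forced to differ in *every* sample, so with `flipProb = 0` the
  copy-number filter provably recovers exactly one representative per block
  at any threshold in `(0, 1)` — the block-recovery test is exact, not
  probabilistic.
* **Class signal in both channels**: each block has a per-class prototype
  level that a sample follows with probability `signalStrength` (default
  0.9), and 2% of genes per class mutate at a rate boosted up to tenfold.
  Both filters therefore select informative genes, and a linear model is
  learnable — by design, since the pipeline under test is linear.
* **Sparse effect records**: baseline mutation rate 0.01 per (sample,
  gene); effect levels drawn with weights ≈ (0.22, 0.53, 0.16, 0.09),
  the marginal level frequencies of the competition-style dataset.
* Defaults `nSamples = 512`, `nGenes = 2048`, `nTumorTypes = 11` mirror the
  scale at which the end-to-end recovery test runs (a 768-sample cohort
  split 2:1 into 512 training and 256 test samples, 2048 genes).

What the generator does *not* emulate: chromosome structure and real
linkage decay (blocks are exchangeable and sharply bounded), class-marginal
imbalance of real cohorts, label noise, and any nonlinear
genotype-phenotype relation. Passing tests therefore demonstrate that the
pipeline recovers the *kind* of signal it is designed for and that the
encrypted circuit computes the same function as the plain one — they say
nothing about classification accuracy on real tumor data, which depends on
the external cohort.

# Numerical conventions and degenerate inputs

* Micro-averaged AUC pools all (sample, class) score/indicator pairs into
  one ROC curve; ties earn half credit (Mann-Whitney convention, computed
  via average ranks). All-one-class inputs are an error, not a NaN.
* Metrics are computed on the approximate-softmax outputs — the quantity
  the protocol actually reveals to the client.
* `d_cn = 0` keeps all genes; `k_var` ties are excluded (strict `>`);
  an empty copy-number matrix, an empty test cohort, empty parameter grids
  and no-admissible-pair grid searches raise informative errors.
* Weight initialization is Glorot-style normal; dropout uses inverted
  scaling so zero-epoch training composes the untouched initial weights.
* Determinism: every stochastic stage (generator, split, training,
  fold assignment) takes an explicit seed and restores the caller's RNG
  state.

# Problem sizes used by the shipped checks

The test suite runs the oracle-equivalence and cost-identity fuzzers over
100 random plans (dimensions 2–16, all duplication factors and both
packings), the softmax comparison over 10⁴ random 11-class vectors, and the
end-to-end recovery on a 768 × 2048 cohort with 11 classes — sizes chosen
so the full suite completes in well under a minute while still exercising
every circuit at its production layout (`n = 2^16` slots appears via
`autoPlan` in the end-to-end path). The acceptance script reruns the
published toy configuration (s = 8, g = 4, T = 4, n = 32) and reports the
operation counters.

# Known limitations

* No cryptography: no keys, no encryption noise, no bootstrapping, no
  security estimation. The simulator validates circuits and costs, not
  security or wall-clock performance.
* Elementwise softmax accuracy degrades for near-tied large scores (regime
  analysis above); rankings are preserved whenever scores exceed `-2^r`.
* The packing targets the tall-skinny product `X·W` with small `T`;
  general encrypted matrix-matrix multiplication is out of scope.
* Training is plaintext by construction (the protocol's threat model);
  encrypted training is not attempted.
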