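---
title: "Methods: mayfly-optimized segmentation, texture features and fused classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mayfly-optimized segmentation, texture features and fused classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sczscreen)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, the numerical choices, and what
the synthetic tests do and do not demonstrate.

## The screening problem

The task is binary classification of individual 2D axial brain MRI
slices into controlled (CON) and schizophrenia (SCZ) classes. The
pipeline combines a *deep* feature block from a pluggable backbone with
a *handcrafted* block built from tissue texture, selects compact subsets
of both, fuses them serially, and evaluates standard binary classifiers
under cross-validation. Everything except the pretrained backbone is
computed by this package; the backbone is a contract
(224×224 image → 1024 finite floats) with a deterministic fixture
implementation for testing.

## Skull stripping

MRI head slices carry a bright cranial rim that would dominate any
intensity-based tissue analysis. The stripping filter is deliberately
classical: binarize at Otsu's single threshold; find bright connected
components; call a component an *annulus* when its filled hull is much
larger than itself (hollowness ratio > 1.5); if an annulus is present,
fill the head, erode with a disc (default radius 6 px at 224×224 — a
little wider than a typical rim) and keep the largest remaining
component; otherwise keep the filled largest bright component. One
subtlety: an input that was *already* stripped has dark tissue touching
an exact-zero background, and an Otsu re-threshold would shed that rim.
Such inputs (recognized by a large exactly-zero background fraction)
keep their nonzero support instead, which makes the operation idempotent
rather than progressively shrinking the mask.

Degenerate inputs (constant images, empty foreground) raise
`"no head found"` rather than returning an empty mask.

## Tissue separation

**Tri-level Otsu.** Two cut points `(t1, t2)` partition the in-mask
histogram (256 bins; the histogram is computed over the brain mask only,
because background zeros would otherwise dominate the criterion) into
three classes, scored by the between-class variance
`sum_k w_k (mu_k - mu_T)^2`, empty classes contributing zero. The
search space is tiny (254 choose 2), so an exhaustive scan is feasible
and serves as the oracle; the shipped search instead runs the mayfly
optimizer over continuous `[1, 254]^2` with rounding and sorting at
evaluation (rounded ties nudged apart by one level), which matches the
exhaustive optimum on phantom histograms in 20/20 seeded runs at the
default budget of 30 flies × 60 iterations — a deliberately small budget
for a 2-D problem.

**MRF refinement.** Threshold labels are refined by iterated conditional
modes (ICM) on the energy

> per-pixel `(I_p - mu_l)^2 / (2 sigma_l^2) + log(sigma_l)` +
> `smoothness` × (number of unlike in-mask neighbor pairs),

i.e. a Gaussian negative log-likelihood plus a Potts prior
(`smoothness = 1`, 4-neighborhood by default). Including the
`log sigma` normalization term is a deliberate choice: it makes the
per-sweep re-estimation of class means *and* variances an exact
coordinate-descent step, so the energy trace is provably non-increasing
even with parameter updates. Two safeguards: a re-estimate is accepted
only if it does not raise the energy (the variance floor of 0.5 gray
levels, needed for noiseless classes, could otherwise break exact
descent), and a class that loses all pixels keeps its last non-empty
parameters instead of dividing by zero. Sweeps use a 2×2 chromatic
decomposition — pixels of one (row parity, column parity) color class
have no neighbors of the same color under either 4- or 8-connectivity —
so each vectorized sub-sweep is an exact ICM step. Convergence is
declared when fewer than `tol = 1e-3` of in-mask labels change in a
sweep, up to `max_sweeps = 50`.

GM and WM are then identified by ordering the estimated class means
(T1-weighted convention: CSF/background darkest, WM brightest); fewer
than three non-empty classes is an error, not a silent guess.

## Handcrafted features (286 = 25 + 25 + 4×59)

**GLCM (25 descriptors × WM, GM).** Co-occurrence is accumulated over
pixel pairs with both ends in the tissue mask, at distance 1 for angles
0°, 45°, 90° and 135°, after min–max quantization to 8 gray levels;
each angle's matrix is symmetrized and normalized, descriptors are
computed per angle and averaged. The fixed 25-name list (contrast,
correlation, energy, homogeneity, entropy, dissimilarity, maximum
probability, sum average/variance/entropy, difference variance/entropy,
autocorrelation, cluster shade/prominence, inverse difference, IDMN,
IDN, the two information measures of correlation, variance, mean,
max-row-mean, trace, marginal uniformity) fixes the feature order and
makes it testable; degenerate cases are pinned (constant tissue gives
energy 1 / contrast 0 / entropy 0; zero marginal deviations give
correlation 0 rather than NaN).

**Weighted LBP (59 bins × W = 1..4).** Each interior in-mask pixel is
coded against an effective threshold blending a local and a global
reference:

> `thr = (ALGL + W * (mu + sigma)) / 2`

where ALGL is the mean of the 3×3 neighborhood, `mu` and `sigma` are
taken over the brain mask and W is the weight. Bit *q* of the 8-bit code
is set when neighbor *q* (circular order E, NE, N, NW, W, SW, S, SE) is
≥ `thr`; ties count as 1 so the convention is bit-exact testable. Two
readings of the published formulas had to be fixed here, and both are
package decisions: (i) ALGL is the nine-pixel mean
`(sum of 8 neighbors + center)/9` — the printed formula sums the center
eight times yet divides by nine, which contradicts both the name
"average local gray level" and the constant-image identity ALGL = center
that the rest of the design relies on; (ii) the blend of local and
global references is the arithmetic mean, which uses every published
quantity, reduces toward plain LBP for small W, and makes the per-pixel
bit count monotonically non-increasing in W (codes grow sparser as the
weight rises, matching the published weight sweep qualitatively).
Histograms use the standard 59-bin uniform-pattern scheme (58 uniform
codes in ascending order, all codes with more than two circular 0/1
transitions pooled), L1-normalized by default; raw counts always sum to
the number of coded pixels.

## The mayfly optimizer

Both the threshold search and the feature selection ride on one
box-bounded maximizer with sexed swarms. Males update velocity with
distance-damped attraction toward personal and global bests
(`C1 = 1`, `C2 = 1.5`, visibility exponent `beta = 2`); the current best
male instead jitters by a nuptial dance `d·R`, `d = 5`, R uniform in
[−1, 1]. Females are attracted toward their rank-paired male when he is
strictly better and otherwise random-walk; rank-paired uniform crossover
produces offspring that replace worse same-sex individuals, so the
best-so-far trace never decreases. Design points that the published
equations leave open, fixed here: the inertia weight on the previous
velocity is 1 (the printed update shows a bare `V_t`); the dance and the
female walk share a geometric decay (0.99 per iteration — undamped
jitter of size 5 never converges on unit-scale problems); the female
condition is "male strictly better → attraction" (the printed inequality
reads backwards relative to the original mayfly algorithm, and ties take
the walk branch either way); bounds are enforced by clamping with
velocity zeroing on the clamped dimension; pairing is by fitness rank
and crossover is uniform per dimension. Zero values of `C1`, `C2`, the
dance and the walk scale are permitted: they are meaningful limiting
configurations (pure ballistic motion) used by the property tests. The
published swarm settings (30 flies, 3000 iterations) are the
constructor defaults; the package's own calls use much smaller budgets
because their search spaces are tiny (see below).

## Feature selection (286 → 103)

Positions live in `[0, 1]^286` and decode to masks by `x > 0.5`. The
fitness is the Cartesian distance between class centroids of z-scored
training features restricted to the mask, normalized by `sqrt(k)` —
without the normalization, adding any nonzero-gap feature would always
help and the optimizer would simply select everything. Zero-variance
features get scale 1 and are flagged. The published subset size (103) is
enforced deterministically after optimization by |gap| ranking: oversized
masks drop the smallest-gap selected features, undersized masks add the
largest-gap unselected ones, ties toward the lower index. An empty
decode scores a large negative constant so it can never win. Selection
is always fit on training folds only; the mask records its fit fold and
the evaluation harness asserts fold identity before applying it.

## Deep block and fusion

The fixture backbone projects 400 multi-scale block statistics (block
means of the scaled image at 4×4/8×8/16×16 grids plus gradient-magnitude
block means) through a fixed Gaussian random matrix with a fixed bias;
it is deterministic, linear in the pooled statistics (hence Lipschitz in
the pixels), and maps the all-zero image exactly to its bias vector —
properties chosen so downstream tests are bit-reproducible. It is a
testing instrument, not an approximation of any pretrained network. The
supervised reduction keeps the 512 of 1024 dimensions with the largest
absolute pooled t-statistics (zero-variance dimensions rank first when
their class means differ, last otherwise; ties toward lower index).
Fusion is plain ordered concatenation, 512 + 103 = 615, width-checked.

## Evaluation

Eleven registered classifiers: softmax (multinomial logistic), decision
trees pruned to at most 4/20/100 leaves (coarse/medium/fine), logistic
regression, Gaussian naive Bayes, linear SVM, depth-3 gradient-boosted
trees with 30 rounds, and k-NN with k = 100/10/1. The tiers are fixed in
a registry because the published roster names variants without
parameters. Cross-validation is stratified at slice level by default;
subject-level grouping is provided because slices of one subject are
strongly correlated and slice-level folds are optimistically biased — no
claim is made about which convention the published numbers used. Metrics
are the six standard confusion-matrix ratios, ×100, rounded half-up to
four decimals (matching the published table formatting; R's default
banker's rounding would differ in the last digit). Zero denominators
yield NaN with a warning, never a silent 0. The "best" fold is the
highest-accuracy fold with ties broken by F1, the best-trial reporting
convention of the published tables.

## The phantom generator

The phantom is a two-ellipse cartoon, not an anatomical model: skull
annulus (intensity 240), a CSF gap (50), a GM ribbon (120), a WM core
(200) with two CSF ventricles, Gaussian noise (default sd 6), all on a
224×224 grid. Defaults were chosen once as plausible 8-bit T1-weighted
tissue contrasts with the correct ordering CSF < GM < WM < skull. The
SCZ effect is controllable and selectable: `"texture"` adds spatially
correlated noise (Gaussian-blurred white noise, kernel sd 2.5 px, scaled
to `class_effect` gray levels) to the GM/WM compartments; the
alternative `"gm_fraction"` mode shrinks the WM core. The texture mode
is the default because no published characterization of the
discriminative image property exists, and correlated texture is the
kind of signal GLCM/LBP features are built to detect. Per-slice RNG
streams are derived from (seed, index, class) through a splitmix32-type
hash — linear seed offsets are *not* sufficient: Mersenne–Twister
streams with arithmetically related seeds are correlated enough for
texture statistics to classify a zero-effect cohort well above chance,
which the hash eliminates.

What passing phantom tests show: the pipeline detects controllable
texture differences and stays at chance when none exist, with all
transformers fit per fold. What they do not show: performance on real
MRI, where anatomy varies across subjects, noise is Rician, intensity is
not standardized, and the discriminative signal is unknown — none of
which the phantom emulates.

## Problem sizes and budgets

Test and acceptance runs use reduced, fixed sizes chosen once: phantoms
at 96×96 (geometry scales with the grid) with 10 slices per class for
end-to-end studies; threshold searches at 15–30 flies × 25–60
iterations; selection at 15–20 flies × 15–150 iterations; planted-signal
tables at 100 samples per class with 10 informative of 286 features at
standardized effect 2. End-to-end separability is averaged over 5 seeds;
the null condition is compared against the central 95% binomial interval
at the pooled prediction count.

## Known limitations

- The weighted-LBP thresholds at W ≥ 2 usually exceed the 8-bit range on
  bright tissue, so those histograms degenerate toward a single spike;
  they are kept for contract fidelity but carry little signal.
- ICM is a local minimizer; no graph-cut or annealing alternative is
  provided.
- The fixture backbone is linear in pooled statistics and cannot stand
  in for a convolutional network's representational power; conclusions
  about DF+HF fusion quality on real data require a real backbone via
  the adapter.
- Slice-level cross-validation is the default for fidelity to the
  published protocol even though subject-level grouping is statistically
  sounder when slices share subjects.
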