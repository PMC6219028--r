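---
title: "Windowed texture features and intensity-routed tissue classification for IVUS plaque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed texture features and intensity-routed tissue classification for IVUS plaque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the model and its
assumptions, the parameters that matter and their defaults, what the
phantom generator does and does not emulate, the numerical conventions,
and the design choices made where more than one reasonable option existed.

```{r setup, message = FALSE}
library(ivustex)
library(dplyr)
```

## The classification model

Plaque pixels are classified into fibrous tissue (FT), fibro-fatty tissue
(FFT), necrotic core (NC) and dense calcium (DC). The central modeling
assumption is about *intensity*: on gray-scale IVUS, NC and DC are
brighter than FT and FFT, and DC is brightest of all (calcium is strongly
echogenic). This ordering is exploited twice:

1. **Routing.** The brightest gray value observed over *training FT
   pixels* becomes a threshold. At prediction time a pixel strictly
   brighter than that threshold cannot plausibly be fibrous, so it skips
   the first two classifiers and goes straight to the NC-vs-DC net. The
   comparison is strict (`intensity > threshold` routes high): the
   threshold is itself an FT pixel's value, so FT's own maximum must stay
   on the low side. An `intensity_threshold(percentile =)` option allows a
   sub-maximum percentile as a guard against single outlier FT pixels; the
   default (100, the maximum) is the reference behavior.
2. **Hierarchy.** Low-intensity pixels are classified in two binary
   stages — net 1 (FT/FFT group vs NC/DC group), then net 2 (FT vs FFT)
   or net 3 (NC vs DC) — rather than one four-way decision. The
   easiest distinction (fibrous vs bright) is made first with the most
   data; the hardest (FT vs FFT, which are both medium-echogenic) gets a
   dedicated classifier and its own feature subset.

Each net is a random forest of 100 trees with depth capped at 10, seeded
for reproducibility and trained single-threaded (`ranger`). Scores are
*tree-vote fractions* (so they have granularity 0.01 with 100 trees), and
a pixel is assigned a net's positive class when more than half the trees
vote for it. The positive classes are net 1 = NC/DC group, net 2 = FFT,
net 3 = DC.

Two training-pool choices deserve note:

- Nets 2 and 3 train on *all* pixels of their tissue pair (every FT/FFT
  pixel for net 2, every NC/DC pixel for net 3), by tissue identity —
  not only on the pixels the cascade would route to them. Training by
  identity keeps each net's task well defined independently of the other
  nets' errors.
- Net 1 trains on all low-intensity pixels, labeled by group. If the
  training data's NC/DC pixels all sit above the threshold, net 1 has a
  single-class pool and training aborts with a class-coverage error
  rather than silently fitting a degenerate model. In practice speckle
  ensures overlap: some NC pixels always fall below the FT maximum.

One structural failure mode is worth knowing: an FFT pixel brighter than
every training FT pixel is *forced* into NC or DC by the architecture.
With the intensity ordering above this is rare, but it is a property of
the routing rule, not of the forests.

## The 54 features

Every plaque pixel gets 54 features from windows centered on it (the mask
constrains window *centers* only; windows near the frame border are
completed by reflect padding, see below):

| family | count | window | notes |
|---|---|---|---|
| intensity | 1 | 1×1 | the raw center-pixel gray value, never quantized |
| first-order statistics | 5 | 5×5 | population mean, variance, SD, excess kurtosis, skewness |
| GLCM (Haralick) | 17 | 5×5 | distance 1, angle 135°, 16 gray bins |
| Laws' energy measures | 18 | 5×5 | 9 masks × (mean squared, mean absolute) response |
| extended GLRLM | 11 | 5×5 | horizontal runs, 16 gray bins |
| LBP | 2 | 3×3 | basic code and rotation-invariant uniform code |

Numerical conventions, chosen once and oracle-tested:

- **Moments** are population moments over all 25 window pixels
  (normalizer 1/25), kurtosis is excess kurtosis, and a zero-variance
  window defines skewness = kurtosis = 0.
- **Quantization** for GLCM/GLRLM is uniform over [0, 255] into 16 bins
  (256 raw levels over 25 pixels would give degenerate matrices; 16 is
  the common radiomics default). The gray level entering the weighted
  run-length and co-occurrence formulas is the 1-based bin index.
- **GLCM offset**: 135° pairs (r, c) with (r−1, c−1), single direction,
  counts normalized over accumulated pairs; a `glcm_symmetric` flag adds
  the reversed pairs. Entropies use the natural log with 0·log 0 := 0.
  The information measure of correlation is the first variant
  (IMC1 = (H − HXY1)/max(HX, HY)); the normalized inverse difference
  moment divides the squared level difference by Ng². GLCM variance uses
  the row-marginal mean. Shifting all gray values by one bin width leaves
  contrast and dissimilarity unchanged (level differences are preserved);
  arbitrary shifts are *not* invariant because quantization boundaries
  move — the zero-sum Laws masks, by contrast, are exactly shift
  invariant.
- **Laws masks**: the nine 5×5 masks are outer products of
  L5 = (1,4,6,4,1), E5 = (−1,−2,0,2,1), S5 = (−1,0,2,0,−1),
  R5 = (1,−4,6,−4,1): E5L5, S5L5, R5L5, E5E5, S5E5, R5E5, S5S5, R5S5,
  R5R5, with each asymmetric product averaged with its transpose. The
  wave vector W5 appears in the classical Laws family but not in this
  package's nine-mask set. Each mask is correlated with the
  reflect-padded 5×5 window to give a same-size texture image whose mean
  squared (MSS) and mean absolute (MAS) responses are the features; every
  mask is zero-sum, so constant windows give exactly 0.
- **GLRLM** runs are maximal same-bin runs along the configured direction
  (default horizontal; the direction is configurable since different
  conventions exist in the literature). The 11 features are the five
  conventional (SRE, LRE, GLN, RLN, RP) plus six gray-level-weighted
  extensions (LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE).
- **LBP** neighbors are read clockwise from the top-left pixel, bit *n*
  weighted 2ⁿ; the comparison is `s(x) = 1 iff x ≥ 0`, so a flat
  neighborhood codes as 255. The riu2 code is the number of set bits when
  the circular transition count U ≤ 2 and N + 1 = 9 otherwise (U is even
  for circular patterns, so the U ≤ 2 / U > 2 dichotomy is exhaustive).
- **Reflect padding** is edge-excluding (index −1 mirrors to +1), the
  common image-processing default. Padding rather than discarding border
  pixels keeps every labeled pixel in the dataset.

The per-window functions are thin wrappers over one compiled kernel; the
test suite checks all 54 values against independent brute-force oracles
(literal formula evaluation, exhaustive pair enumeration, nested-loop
convolution, scan-line run extraction, bitwise code assembly) to 1e-9 on
randomized windows.

## Feature selection

Plain PCA produces linear combinations, but the per-net classifiers
consume *named original features*. The selector therefore standardizes
the 54 columns, retains the fewest principal components reaching the
variance target (default 0.95), scores each original feature by its
maximum absolute loading over the retained components, and keeps either
the top `k` features or — by default — those above the 0.6 quantile of
the scores, which yields subsets of roughly 20 features, the scale
typical for this problem. Determinism is enforced by a sign convention
(each component's largest-magnitude loading is made positive) and a
canonical-order tie-break. Zero-variance columns are excluded from
standardization rather than divided by zero, and can never be selected.

After z-scoring, no single high-variance feature can dominate the
components — dominance is about correlation structure, not raw variance.
This is intentional: raw-variance ranking would simply pick the features
with the largest units.

## Evaluation

Per net: confusion counts, sensitivity/specificity/accuracy in percent,
the ROC curve swept at every distinct observed score (with 100 trees,
scores live on a 0.01 grid, so ties are collapsed into single operating
points), and the trapezoid AUC — which equals the tie-adjusted pairwise
concordance probability, a property the tests verify exactly.

By default each net is evaluated on its *ground-truth pool*, mirroring
the training-pool choice: net 1 on all low-intensity pixels against group
truth, net 2 on all FT/FFT-truth pixels, net 3 on all NC/DC-truth pixels.
The NC/DC-truth pool already contains every high-intensity pixel that has
a defined NC-vs-DC truth; high-intensity pixels whose truth is FT/FFT
have no binary truth for net 3 and are necessarily counted only in the
overall 4-class confusion. A `pool = "routed"` flag evaluates nets 2-3 on
the pixels the cascade actually sent them instead, for sensitivity
analysis. The overall 4-class confusion and accuracy always come from the
routed predictions. Because the reference train/test protocol is a choice
(per-frame holdout here), every report records the pool it used.

## The phantom generator

Real annotated IVUS pullbacks cannot ship with the package, so the study
conditions are defined by a seeded generator:

- **Geometry**: a 400×400 frame with an annular plaque between radii 60
  and 150 px (the "intima" and "media-adventitia"); background (lumen
  and adventitia) at mean gray 25.
- **Tissue blobs**: 32 uniform random seed points partition the annulus
  into Voronoi cells; whole cells are greedily assigned to classes,
  largest first, each to the class with the largest remaining area
  deficit. This keeps empirical class proportions within about one cell
  (~3%) of the targets FT 0.35, FFT 0.25, NC 0.22, DC 0.18 — plain
  per-seed class sampling would let proportions drift by the (large)
  variance of Voronoi cell areas.
- **Intensity**: class means 60 (FFT), 90 (FT), 150 (NC), 210 (DC) —
  the assumed ordering — times multiplicative unit-mean gamma speckle
  with scale σ = 0.1, clipped to [0, 255] and rounded. Multiplicative
  speckle is the standard first-order model of ultrasound texture, and it
  makes the *absolute* noise level scale with the class mean, so windowed
  statistics carry class information beyond the raw intensity.
- **Hard regime** (`hard_phantom_spec()`): FFT and FT means narrowed to
  82 vs 95 with per-class speckle scales 0.18 vs 0.05. Raw intensity then
  separates the two fibrous classes poorly, while their local texture
  differs strongly — this regime exists to demonstrate that the texture
  features, not just the intensity column, drive net 2. With a single
  global σ, narrowing the means would make FT and FFT nearly identical in
  distribution and the comparison meaningless, which is why the spec
  carries an optional per-class σ.

What the phantom does *not* emulate: beamforming and point-spread
anisotropy, attenuation with depth, acoustic shadowing behind calcium,
catheter ring-down and guidewire artifacts, speckle spatial correlation,
and the irregular blob geometry of real plaque. Passing the phantom study
therefore shows that the pipeline is implemented correctly and that its
architecture can exploit intensity ordering and texture — it does not
certify clinical accuracy on patient data, where the published experience
with this family of methods reports per-net accuracies in the 70-85%
range rather than the near-perfect numbers a separable phantom yields.

## Reference study and problem sizes

The reference study (also what `scripts/acceptance.R` reruns) uses 5
training and 2 test frames of 400×400 — about 300k labeled training
pixels and 120k test pixels — in both regimes, a size chosen so the full
study completes in a few minutes on one CPU while keeping per-class pixel
counts in the tens of thousands. The held-out separable-regime study
achieves ≥ 95% 4-class accuracy and per-net AUC ≥ 0.95; in the hard
regime, net 2 beats the intensity-only baseline by a wide margin
(roughly 99% vs 85% accuracy). The test suite reruns the same study; unit
tests use 96×96 phantoms for speed.

```{r example, eval = FALSE}
report <- run_pipeline(run_config(seed = 1))
tidy(report)
glance(report)
autoplot(report)   # per-net ROC curves
```

## Known limitations

- The FT-maximum threshold is brittle to label noise in FT (one
  mislabeled bright pixel raises it); the percentile option mitigates
  but the reference behavior keeps the maximum.
- Feature extraction is single-scale (5×5) and single-orientation
  (one GLCM angle, one run direction); multi-orientation averaging is
  out of scope.
- PCA selection is unsupervised; it optimizes variance coverage, not
  class separation.
- The train/test protocol on real data (per-patient vs per-frame vs
  per-pixel splits) materially affects reported accuracy; the package
  only fixes the phantom protocol and records the split in its reports.
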