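# ivustex

Pixel-wise plaque tissue characterization for grayscale intravascular
ultrasound (IVUS).

## The problem

IVUS produces cross-sectional gray-scale images of coronary arteries.
Clinicians want to know what an atherosclerotic plaque is made of:
fibrous tissue (FT), fibro-fatty tissue (FFT), necrotic core (NC), or
dense calcium (DC) — the standard four-class plaque taxonomy. The
RF-signal-based "virtual histology" that usually answers this needs
special hardware and is limited to one frame per cardiac cycle, so there
is long-standing interest in reading tissue composition directly from the
gray-scale image.

`ivustex` implements an intensity-based multi-level approach to this task:

1. **Features.** For every pixel inside the plaque mask (the region between
   the intima and the media-adventitia), 54 windowed texture features are
   computed from 5×5 neighborhoods (3×3 for LBP): 5 first-order statistics,
   17 grey level co-occurrence matrix (GLCM, Haralick) features at
   distance 1 / 135°, 18 Laws' energy measures (9 masks × {mean squared,
   mean absolute} response), 11 extended grey level run length matrix
   (GLRLM) features, the raw pixel intensity, and 2 local binary pattern
   codes (basic and rotation-invariant uniform LBP^riu2).
2. **Selection.** Per classifier, PCA on the standardized features ranks
   each original feature by its maximum absolute loading over the
   components that explain 95% of the variance, and keeps the top-scoring
   subset.
3. **Classification.** A cascade of three seeded binary random forests
   (100 trees, depth ≤ 10). The maximum intensity observed over training
   FT pixels is a routing threshold: pixels brighter than any FT pixel can
   only be NC or DC and go straight to net 3. Net 1 splits the remaining
   low-intensity pixels into the FT/FFT vs NC/DC groups, net 2 resolves
   FT vs FFT, net 3 resolves NC vs DC.
4. **Evaluation.** Per-net sensitivity/specificity/accuracy
   (`Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/N`, in percent),
   ROC curves swept over the tree-vote fractions, trapezoid AUC, and the
   overall 4-class confusion matrix.

Because clinical IVUS pullbacks cannot be redistributed, the package ships
a seeded speckle **phantom generator**: an annular "plaque" partitioned
into contiguous tissue blobs whose mean intensities are ordered
FFT < FT < NC < DC, rendered with multiplicative unit-mean gamma speckle.
The whole pipeline runs, and is tested, on these phantoms.

## A worked example

```r
library(ivustex)

# a small phantom: 96x96 frame, annulus radii 14/40 px
ph <- generate_phantom(phantom_spec(size = 96, r1 = 14, r2 = 40, seed = 3))
train <- extract_features(ph$frame, ph$mask, ph$labels)
dim(train)
#> [1] 4408   57        # 4408 plaque pixels: row, col, label + 54 features

model <- train_multilevel(train, seed = 7)
model
#> <multilevel_model>
#>   intensity threshold: 122 (percentile 100 of FT pixels)
#>   forests: 100 trees, depth <= 10, seed 7
#>   net1 (FT/FFT vs NC/DC): 22 features
#>   net2 (FT vs FFT): 22 features
#>   net3 (NC vs DC): 22 features

# held-out phantom from a different seed
held <- generate_phantom(phantom_spec(size = 96, r1 = 14, r2 = 40, seed = 12))
test <- extract_features(held$frame, held$mask, held$labels)
report <- evaluate_model(model, test)
tidy(report)[, c("net", "sensitivity", "specificity", "accuracy", "auc")]
#> # A tibble: 3 × 5
#>   net   sensitivity specificity accuracy   auc
#>   <chr>       <dbl>       <dbl>    <dbl> <dbl>
#> 1 net1         68.2       100       99.7 0.999
#> 2 net2         99.5        99.6     99.5 1.000
#> 3 net3         98.0        98.0     98.0 0.998
glance(report)$overall_accuracy
#> [1] 98.77495
```

The intensity threshold (122 here) is the brightest gray value any
training FT pixel reached; the per-net rows report each binary task on its
ground-truth pixel pool, and `overall_accuracy` is the held-out 4-class
per-pixel accuracy of the full cascade. (Net 1's sensitivity is computed
over the few NC/DC pixels that fall below the threshold on this small
phantom — 22 pixels here — hence its coarse value; the 400×400 reference
study rests on tens of thousands.) `autoplot(report)` draws the three
ROC curves; `plot_phantom(ph, "labels")` shows the simulated tissue map.

A thin command-line front end over the same functions is installed as
`exec/ivustex` (`ivustex {simulate,extract,select,train,predict,evaluate,run-all}`).

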