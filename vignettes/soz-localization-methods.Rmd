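---
title: "Methods: hybrid CNN + expert-knowledge sorting of rs-fMRI independent components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid CNN + expert-knowledge sorting of rs-fMRI independent components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Independent component analysis of resting-state fMRI decomposes a scan into
spatial maps with associated BOLD time courses. In pre-surgical screening of
refractory epilepsy, experts sort these independent components (ICs) into
three categories: measurement **NOISE** (motion, vascular and scanner
artifact), normal resting-state networks (**RSN**), and components whose
activation pattern marks the seizure onset zone (**SOZ**). Roughly half of
all ICs are noise, ~43% are RSN, and only ~5% are SOZ — a class imbalance
that defeats purely supervised classifiers, because the rare SOZ class is
exactly the one that matters. `sozloc` implements a hybrid: a CNN learns the
(data-rich) noise-vs-non-noise distinction from rendered IC montages, while
a small expert-knowledge model separates RSN from SOZ using four features
that encode what experts actually look for. A fusion rule combines the two
arms and the SOZ is localized as the largest activation cluster of each IC
finally labeled SOZ.

## The two model arms

### CNN noise screen

The binary CNN consumes montages resized to 270 x 470 x 3 and uses, as
defaults, three 3 x 3 convolution layers with 64, 64 and 256 filters, each
followed by 2 x 2 max pooling, a 704-unit ReLU dense layer with dropout
0.33, a sigmoid output, binary cross-entropy loss and Adam at learning rate
1e-4. RSN and SOZ ICs are relabeled to a single non-noise class
("NOISE-bar", encoded 1) before training; inputs are scaled to [0, 1] by
division by 255; early stopping monitors a 20% validation split with
patience 5 and the best weights are restored. The implementation is a
compact, fully vectorized conv-net written for this package (R driver, C++
kernels for convolution and pooling); its backward pass is verified against
numerical gradients in the test suite. Because a net this wide is not
trainable in reasonable time on a laptop-scale synthetic study, the package
also ships a `small` configuration — inputs downscaled to 44 x 76, filters
(4, 4, 8), dense width 16, learning rate 3e-3, at most 10 epochs with
patience 3 — that keeps the exact topology (three conv + pool stages,
dense + dropout, sigmoid). All cohort-scale experiments in the tests and
the acceptance script use the small configuration; the full-size defaults
remain available for real-data work.

The sigmoid threshold is 0.5 with ties going to the non-noise class; the
class encoding (NOISE-bar = 1) is a documented package choice.

### Expert-knowledge model

Four features per IC form the expert vector F = (f_clusters,
f_wm_ventricle, activelet_gini, sine_gini):

1. **Cluster count / asymmetry** (`f_clusters`). Activation pixels are
   recovered from the montage by a color-dominance rule (R >= 166,
   R - G >= 30, G >= B on the 0-255 scale), clustered per slice with
   DBSCAN (defaults epsilon = 2 px, v_min = 4; a pixel needs more than
   v_min neighbors within epsilon to be a core point), and only clusters
   strictly larger than 135 px are retained. With `c` the median per-slice
   count of retained clusters and `asym` the dominant-side fraction of
   clustered pixels relative to the slice midline, the score is
   `(2*asym - 1)/c`: 1 for a single fully lateralized cluster (the SOZ
   ideal), ~0 for mirrored symmetric RSN patterns. The midline is taken at
   the brain-mask centroid column, making the score translation invariant.
2. **Gray matter -> white matter -> ventricle extension**
   (`f_wm_ventricle`). A two-pass protocol: each slice is first inpainted
   to remove the activation overlay (onion-peel averaging; gradients
   inside the inpainted corridor are treated as fill artifacts), then
   Sobel edge detection extracts contours. Contour components adjacent to
   non-brain area (background or interior holes) are brain-boundary
   contours; the longest remaining interior component (ties by enclosed
   area) is the white-matter contour. On base slices — the first third of
   the tile order, where ventricles are prominent — the ventricle region
   is the interior area that interrupts the brain silhouette, minus pixels
   adjacent to any boundary contour. The feature is the fraction of
   retained clusters that both intersect the white-matter contour (dilated
   by 2 px, absorbing rasterization gaps plus the 1-px artifact margin
   around inpainted pixels) and reach the ventricle region.
3. **Wavelet-domain sparsity** (`activelet_gini`). Each 256-sample window
   of the BOLD series is decomposed with a 4-level undecimated a-trous
   spline-wavelet transform; the Gini index of the pooled detail-coefficient
   magnitudes (all four levels together) measures sparsity. True
   activelets (exponential-spline wavelets tuned to the hemodynamic
   response) are not fully specified by their common citations; the
   package uses the B3-spline a-trous scheme behind the same interface so
   a faithful activelet basis can be swapped in. The decomposition is
   exactly invertible, which the tests verify.
4. **Sine-dictionary sparsity** (`sine_gini`). The Gini index of the DFT
   magnitudes restricted to 0.01-0.1 Hz (46 bins for a 256-sample window
   at TR 2 s). SOZ series concentrate their in-band energy in a few
   dominant components; RSN series spread it densely.

A note on dominant frequencies: a criterion sometimes quoted for SOZ time
courses ("dominant frequencies above 6 Hz") cannot be evaluated at TR 2 s,
where the spectrum ends at 0.25 Hz. The package therefore reports the
dominant in-band frequency as a diagnostic only and carries the two Gini
features in the expert vector; the ablation machinery treats exactly these
two as the temporal knowledge components.

Windows are non-overlapping and mean-centered (DC removal before spectral
analysis); a 600-sample series yields 2 windows with the 88-sample
remainder dropped.

**Training.** For ICs labeled RSN (y = -1) or SOZ (y = +1), feature vectors
are L2-normalized and the weight vector omega minimizes
`sum_i (1 - y_i * omega . Fhat_i)^2` subject to `sum(omega) = 1`, solved as
an equality-constrained least-squares problem (SVD pseudo-inverse in the
constraint null space; the minimum-norm minimizer breaks ties, which makes
duplicated features split their weight evenly). Weights are not constrained
non-negative — only the sum constraint is imposed. Class balance is restored
before the fit by SMOTE in feature space: synthetic SOZ samples are linear
interpolations between a real SOZ sample and one of its k = 5 (clipped to
minority size - 1) nearest SOZ neighbors. SMOTE applies only to the
expert-model fit; the binary CNN sees the near-balanced noise/non-noise
data unaltered.

**Scoring.** An IC's confidence of being SOZ is
`rho = omega . F / ||F||` — scale invariant in F. The standalone
expert-model decision is `sign(rho)` (SOZ iff rho > 0), the natural
consequence of the +/-1 target coding; a zero feature vector is assigned
rho = 0 with a warning.

### Fusion and localization

If the CNN calls the montage non-noise, the expert label (RSN or SOZ)
stands. If the CNN calls it NOISE, the IC remains NOISE unless the expert
arm says SOZ with rho strictly greater than 0.9, in which case the expert
call overrides the screen. The threshold comparison is strict. For each IC
finally labeled SOZ, the reported SOZ is its largest retained activation
cluster across slices (argmax of pixel count; ties go to the lowest tile
index, then the lowest centroid row). The expert feature with the largest
contribution `omega_j * F_j` is reported as the explanation for each SOZ
call. SOZ ICs with no retained cluster are flagged unlocalizable rather
than silently reclassified.

## The synthetic cohort generator

Real pediatric rs-fMRI IC data of this kind is restricted, so the package
ships a seeded generator that emulates the rendered ICs after ICA — not raw
4-D fMRI, not the ICA unmixing itself. Each synthetic patient contributes
ICs at the study's class mix (51% NOISE, 43% RSN, 6% SOZ by default; SOZ is
floored at one IC per patient so patient-level sensitivity is defined).
Montages are 709 x 1006 x 3 renders of 46 axial slice tiles in a 5 x 10
grid, base to apex; each tile holds an elliptical pseudo-brain with a
bright gray-matter ring, a prominent interior white-matter contour band
and, on base slices, two dark ventricle holes. The activation overlay
follows the class rules: SOZ ICs carry one thick capsule per involved base
slice, confined to one hemisphere, running from the gray-matter ring across
the white-matter contour into a ventricle; RSN ICs carry 2-3 disc pairs
mirrored across the slice midline that never touch the ventricles; NOISE
ICs carry rim arcs on the brain boundary, scattered background speckles and
small sub-threshold white-matter speckles. Time courses (600 samples, TR
2 s) are sparse in-band sinusoid mixtures (SOZ, 2-4 components), dense
in-band mixtures (RSN, ~25 components), or broadband noise with drift and
spikes (NOISE), all with a noise floor so no series is constant.

The `separation` parameter (1 by default) is an extension with no real-data
counterpart: below 1, a corresponding fraction of ICs violates its class
rules (truncated or mirrored SOZ capsules, one-sided RSN patterns,
parenchymal NOISE blobs, blended spectra), which makes graded
parameter-recovery experiments possible. At separation 1 the designed
feature values are textbook — SOZ ICs score 1 on both spatial features,
RSN ICs score ~0 — and the tests assert precisely this construction.

Montage demographics (age group, sex) are tags drawn from the study's
marginal frequencies purely to exercise subgroup reporting; they have no
biological meaning. Cohorts store time courses and per-IC seeds; montages
are re-rendered deterministically on demand, keeping a 1,000-IC cohort of
native-resolution images memory-bounded. Identical configuration and seed
reproduce cohorts bit for bit.

What passing on this generator shows — and what it does not: it validates
the mechanics end to end (feature extraction recovers designed geometry,
the constrained fit recovers discriminative weights, fusion and
cross-validation are wired correctly) under conditions where the expert
rules hold cleanly. It does not show that the features transfer to real IC
renders, where anatomy, registration error and expert disagreement blur
every one of these rules.

## Slice extraction and anatomy, in detail

Tiles are located by template matching: the montage's per-pixel channel
minimum (which suppresses the warm overlay) is cross-correlated with a
packaged synthetic single-slice template via FFT; because tiles repeat on a
regular grid with the template's period, the grid phase is voted globally
over the folded correlation surface and each cell is accepted if its local
correlation exceeds 10% of the best cell's. This rejects blank grid cells
and montages that contain no brain-like structure at all. A template built
from a standard brain atlas can be supplied in place of the packaged one.
Template matching runs on the native image; the resized image feeds only
the CNN. Coordinates are 0-based (row, col) with half-open tile extents;
base slices are the first third of the tile order.

## Evaluation harness

`loocv()` implements leave-one-patient-out cross-validation: for each fold
the CNN and the expert model are trained on all other patients and every IC
of the held-out patient is labeled once. Metrics are per-IC SOZ-vs-rest
(accuracy, precision, sensitivity, F1), with a per-patient "any true SOZ IC
found" sensitivity alongside, since clinical reading is patient-level; both
are reported because the natural granularity is genuinely ambiguous.
Subgroup breakdowns by the generator's age and sex tags exercise the
reporting shape. The 3-class cost-sensitive CNN baseline (`mode = "cnn3"`)
runs on identical folds with inverse-frequency class weights.
`ablation_suite()` refits the expert arm with each feature masked in turn;
the CNN outputs are reused across variants because the noise screen does
not depend on the feature mask — results are identical to retraining it,
at a tenth of the cost. Significance helpers provide the KS normality check
and the one-sided two-sample t-test over subgroup metric samples, with
explicit handling of degenerate zero-variance samples.

## Numerical choices and problem sizes

* DBSCAN: epsilon = 2 px, v_min = 4 (the neighborhood scale of 8-connected
  pixel raster data); retention strictly greater than 135 px. Cluster
  merging is exact (connected components over the epsilon-adjacency), and
  equivalence with a brute-force O(n^2) expansion is tested on hundreds of
  random masks.
* Sobel threshold 0.5 on [0, 1] intensities; the tile anatomy is rendered
  with a smooth interior falloff so that the white-matter band is the only
  sharp interior contour.
* The constrained fit tolerates rank deficiency (SVD cutoff at machine
  precision scaled by the problem size) and warns when features carry no
  class signal.
* Cohort-scale experiments use 10 patients x 100 ICs at separation 1 with
  a fixed seed, the small CNN configuration, and one feature-extraction
  pass shared by all experiments; a full run (extraction, two
  cross-validated models, four ablation variants) completes in roughly a
  quarter hour on one CPU.
* All randomness flows through per-component seeds derived from the
  configuration seed; the package never touches the caller's RNG state.

## Known limitations

* "White matter" and "ventricle" are contour-defined proxies on rendered
  2-D montages, not anatomical segmentations; no mapping to scanner or
  atlas space exists for the synthetic substrate.
* Clustering is per-slice 2-D; no 3-D continuity across slices is imposed.
* The activelet basis is approximated by a B3-spline a-trous scheme (see
  above).
* Whether ventricle extension should be required in at least one slice or
  as a fraction of slices is not settled by the source material; the
  package uses the fraction form, which degrades more gracefully on noisy
  masks.
* The per-IC explanation is the single largest weighted feature
  contribution; it is a pointer for review, not a causal attribution.
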