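---
title: "Photon event centroiding for EBCCD photon counting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon event centroiding for EBCCD photon counting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebcentroid)
```

## The problem

Photon counting imaging assembles an image from individually detected
photons.  On an electron-bombarded CCD (EBCCD), each photoelectron is
accelerated from the photocathode directly into the sensor and deposits its
charge in a small cluster of pixels — a *photon event*.  The true photon
position can be recovered with sub-pixel accuracy by fitting the event — the
same centroiding problem that single-molecule localisation microscopy
solves, so this package applies the SMLM machinery (wavelet detection,
iterative Gaussian PSF fitting, multi-emitter model selection) to EBCCD
frame stacks.  The pipeline is:

1. per-stack (or per-chunk) base-level estimation — the camera dark offset
   is the average of per-frame minimum grey values;
2. *ion-event clipping* — pixels brighter than the photon-event maximum are
   set just above it (default +5 %), so rare ultra-bright ion events cannot
   inflate the per-frame detection threshold;
3. *detection* — first B-spline à-trous wavelet plane `F1`, peak-intensity
   threshold `PIT = k · sd(F1)` per frame (k = 2 for sparse data, 1.5 for
   dense data), 8-connected components with watershed splitting, one
   candidate per region;
4. *sub-pixel localisation* — Poisson maximum-likelihood or least-squares
   Gaussian fits, weighted least-squares integrated-Gaussian fit, local
   centroid, or radial symmetry, on a square fitting region (radius 2 px
   for speed, 7 px for multi-emitter work);
5. *multi-emitter fitting* (optional) — one- vs two-emitter Poisson MLE
   with a likelihood-ratio test at p = 10⁻⁶ (χ², 3 degrees of freedom);
   then duplicate removal at 160 nm and a strict intensity filter
   (> 4000 pe sparse preset / > 3000 pe dense preset), in that order;
6. *accumulation* — photon images at 1-pixel and 1/5-pixel resolution, the
   folded 5×5 sub-pixel occupancy, and the fixed-pattern-noise metric
   `FPN = (Nmax − Nmin) / Nmean × 100 %`.

All coordinates are zero-based and continuous: pixel `(ix, iy)` spans
`[ix, ix+1) × [iy, iy+1)` with its centre at `(ix + 0.5, iy + 0.5)`.  The
fractional-part convention makes the boundary value `frac = 1` unreachable,
so occupancy bins are half-open and counts are conserved exactly.

## The synthetic camera

No public EBCCD raw stacks exist, so every stage is validated against a
simulator whose *stated world* is fixed once and used everywhere.  A frame
is built as

```
ADU = round( base + N(0, σ_read) + Poisson(rendered pe) / gain ),
```

with defaults: 512×512 or smaller test geometries, 80 nm image pixel size,
gain 36 pe/ADU, base level 120 ADU (the camera's 100–140 ADU range drifts
with temperature, which is why the pipeline re-estimates it per chunk), and
events with a mean amplitude of 6000 photoelectrons at a 10 % coefficient
of variation — a narrow pulse-height distribution, consistent with an
intensity filter at 4000 pe keeping essentially all true events.

Three modelling choices deserve explanation, because the published
phenomenology cannot be reproduced without them:

**Read noise σ_read = 0.5 ADU.**  A global threshold at `2 · sd(F1)` over a
512² frame only works if the filtered-frame variance is *event-dominated*:
if read noise contributed even 1 ADU, the threshold would sit ~3 filtered
noise σ above zero and hundreds of single-pixel noise crossings per frame
would be inevitable.  The reference acquisition demonstrably operated a
2·sd threshold successfully at super-high analog gain, so sub-ADU effective
read noise is the regime consistent with that evidence.

**A peaked event profile.**  The default event is a mixture of two
concentric Gaussians — 80 % of the charge in a core of `0.35 σ`, 20 % in
wings, marginal SD `σ_y = 0.8 px` — matching the described "high central
peak with small wings" of electron-bombarded events.  A *pure* Gaussian
event fitted by a Gaussian PSF is a model-matched estimator: its position
wobble vs sub-pixel phase vanishes, the 5×5 occupancy is uniform up to
multinomial noise, and fixed pattern noise collapses to the sampling floor.
Real EBCCD data show strong FPN structure, which can only come from a
mismatch between event shape and centroiding function; the peaked profile
supplies exactly that.  `profile = "gauss"` retains the idealised shape for
analytic tests where estimator and data-generating model must coincide.

**Horizontal widening as discrete charge deferral.**  Events are widened in
the CCD read-out direction.  For any mirror-symmetric widening the mean
fractional-x of any reflection-equivariant estimator is exactly 0.5 —
symmetric shapes cannot explain centroids piling at the right pixel edge.
The simulator therefore defers a geometric fraction of each pixel column's
charge toward +x (weights `(1−α)α^k` at k pixel shifts, the
charge-transfer-inefficiency mechanism), with α solved so the marginal x SD
equals `σ_x` (default asymmetry 1.15, i.e. α ≈ 0.15 — "small wings").  A
continuous one-sided smear was tried and rejected: it shifts the detection
anchor together with the charge, and the bias cancels through the pipeline.
Magnitudes were frozen from deterministic phase-map studies before the
acceptance tests were written, and not revisited.

Ion events (an accelerated residual-gas ion striking the photocathode) are
simulated as rare (default 1 per 3 frames), large (3× σ) and ~1400× brighter
than photon events, putting their peaks in the few-thousand-ADU range the
clipping stage exists for.  Clipped ion remnants are deliberately *not*
removed downstream: they get localised as spurious photon events, and their
rarity makes this harmless — the package reproduces that design.

What a green test does **not** establish: the simulator's wings and
pulse-height distribution are second-moment models, not measured profiles;
absolute photon counts, processing times, and the absolute FPN percentages
of real acquisitions depend on the true event shape and are out of scope.
Rank properties (ML-Gaussian ≤ local centroid on FPN), mechanisms (ion
threshold failure, MFA separation) and calibrated statistics are what the
tests pin down.

## Numerical choices

* **Fitting.**  All iterative fits run L-BFGS-B with analytic gradients,
  at most 1000 iterations, on the parameters `(x₀, y₀, I, σ, b)`; position
  is bounded to the fitting region, `σ` to `[0.3, 3]` px, intensity and
  background to non-negative values.  Fits that do not converge or return
  less than one photoelectron are dropped and counted, never imputed.
* **σ is fitted, not frozen.**  The published "SD set to 1.0 pixels" is
  treated as the *initial* value (the originating tool fits σ); freezing it
  would erase the differences between the compared methods.
  `fix_sigma = TRUE` restores a frozen σ.
* **Poisson likelihood on converted data.**  Grey values are converted to
  photoelectrons with clamping at zero before ML fitting (negative photon
  counts are unphysical).  ADU quantisation and read noise make the
  background slightly overdispersed relative to Poisson; consequently the
  MFA likelihood-ratio test is calibrated under the one-emitter Poisson
  model (where its false-split rate is < 1 % at p = 10⁻⁶) but splits
  liberally on real frames.  The pipeline absorbs those ghost splits with
  duplicate removal and the intensity filter — the same post-processing
  order prescribed for MFA use, and the reason the duplicate threshold of
  160 nm equals 2 px at 80 nm/px.
* **Model selection df = 3.**  The two-emitter model adds `x₂, y₂, I₂`
  (shared σ and background), so the LRT uses `χ²₃`; an F-test variant would
  be the natural alternative for least-squares objectives.
* **Watershed.**  Components containing several regional maxima (plateaus
  merged) are split by growing seed labels in order of decreasing filtered
  intensity.  Component centroids round to the containing pixel, ties
  toward the smaller index — deterministic and testable.
* **à-trous cascade.**  `F1 = V0 − k2 ∗ V0` with `V0 = k1 ∗ input`;
  applying the zero-padded dilated kernel directly to the raw input rings
  around events narrower than its tap spacing and was rejected (the band
  pass would dip at the true centre of a sharp core).
* **Detection scoring.**  Recall is hit-based (a truth event is detected if
  any candidate lies within 2 px): a merged overlapping pair *is* detected
  by its common region, and separating it is the multi-emitter fitter's
  job.  One-to-one matching is used for localisation accuracy, where
  double-counting would flatter the result.

## Design decisions that were genuinely open

* Base level "average minimum grey value" is read as per-frame minima
  averaged over frames (not the minimum of per-frame averages); the
  alternative reading would be dominated by bright-event flux.
* The photon-event maximum for clipping is estimated per stack as the
  0.999 quantile of per-frame maxima after excluding frames whose maximum
  exceeds 3× the median per-frame maximum; "slightly above" is +5 %.
* Duplicate removal keeps the brighter member (greedy, descending
  intensity).  A consequence proved in the test suite: with this rule a
  sub-threshold localisation can never shield a brighter one, so applying
  the intensity filter before or after duplicate removal yields identical
  survivors — the pipeline still runs duplicates first, matching the
  documented tool order.
* Intensity filters operate in photoelectrons (the calibration converts at
  36 pe/ADU); the filter is strict (`>`).
* MFA-on vs MFA-off comparisons use identical post-processing on both
  sides; comparing a filtered MFA run against an unfiltered plain run
  measures the filters, not the multi-emitter model.

## Known limitations

* True EBCCD event wings may deviate from the two-Gaussian model beyond
  second moments; simulator realism past those moments is unvalidated.
* The wavelet kernel normalisation is pinned by this package's own oracle;
  bit-level equivalence with any external plugin is not claimed.
* The Poisson MLE ignores read-noise variance; a noise-corrected likelihood
  (adding the read variance in pe² to data and model) would calibrate MFA
  on raw frames and is a natural extension.
* No drift correction, frame linking, or astigmatic 3D PSFs.
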