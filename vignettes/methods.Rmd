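---
title: "Methods: whole-brain tracing quantification with ictrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain tracing quantification with ictrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictrace)
```

# The quantification problem

Monosynaptic rabies tracing labels the brain-wide *presynaptic inputs* of a
genetically restricted starter population; anterograde AAV tracing labels
the *axonal outputs* of the same region. Turning stacks of coronal section
images into comparable connectivity measures requires a chain of steps,
each of which this package implements as a separately testable module:

1. **Detection** — find labeled somata (retrograde tracings),
   eGFP+/mCherry+ double-positive starter cells, and axon-positive pixels
   (anterograde tracings) in fluorescence section images.
2. **Atlas assignment** — relate every detection to a named region of
   interest (ROI) on the coronal atlas plane nearest its bregma
   coordinate, honouring exclusion zones (fiber bundles, the injection
   site).
3. **Normalization** — convert raw counts to percent of the brain-wide
   total per animal, plus cell densities (cells/mm²) and percent
   innervation densities (axon pixels / ROI pixel capacity), with a
   background threshold.
4. **Profiles** — cell/innervation density along the anterior–posterior
   (A–P) axis per region, interpolated and smoothed.
5. **Network analysis** — input–output reciprocity, fold-difference maps,
   pairwise Pearson correlation across tracings and complete-linkage
   clustering.
6. **Statistics** — relative-percent-difference (RPD) count validation and
   per-region one-way ANOVA with Tukey HSD.

A synthetic-data module generates section images and cohort count tables
with known ground truth, so the whole chain can be exercised and
benchmarked without microscopy data.

# Conventions

* Images are matrices indexed `[x, y]`; pixel coordinates are 0-based.
* Bregma coordinates are in mm; positive is rostral. Atlas sections are
  ordered rostro-caudally (decreasing bregma). A bregma query resolves to
  the nearest section; an exact midpoint resolves rostrally.
* Polygons treat boundary points as inside. When nested or overlapping
  ROIs both contain a point, the smallest-area (most specific) ROI wins —
  the behaviour expected of nested anatomical annotations.
* All quantification is single-hemisphere (ipsilateral to the injection).

# Detection

## Somata

The pipeline is deliberately deterministic:
difference-of-Gaussians (DoG) enhancement → threshold → hole filling →
watershed splitting of touching cells → connected components → particle
filters. A trainable pixel classifier could substitute for the first two
steps, but cannot be reproduced from a parameter file; with clean
fluorescence the *particle filters* — area within **70–1000 px²** and
circularity within **0.30–1.0** — do the real selection work, and those
are applied verbatim.

Parameter notes (`detection_params()`):

* `rolling_ball_radius` (default 20 px): background is estimated by a
  grayscale morphological opening with a disc element and subtracted; a
  flat background is removed exactly and the result is clipped at zero.
* `blob_sigma_range` (default 2–15 px): DoG scales bracketing the soma
  radius range.
* the default threshold is `median + 5·mad` of the enhanced image — robust
  to the object fraction, and exactly zero response on a blank image.
* Object size is measured on the *half-max support* of each component
  (pixels above half the component's peak enhancement). The detection
  threshold must sit low to catch dim cells, so the raw component includes
  a blur skirt; the half-max contour tracks the true object boundary and
  keeps the px² area filter meaningful.
* Circularity is `4π·area/perimeter²` with a two-direction Crofton
  perimeter estimate (unbiased for discs, the shape class the filter is
  calibrated on), clipped at 1.

The area filter is interpreted in px² on uncalibrated images, the
particle-analyzer default; no spatial calibration is assumed.

## Starter cells

Rabies-competent starter cells are double positive: detected in eGFP and
confirmed in mCherry (the TVA marker). Detection runs per z-plane on the
eGFP stack; a detection is accepted when the *median* mCherry intensity
inside its mask exceeds a global Otsu-derived threshold of the
background-subtracted mCherry stack, guarded by a `median + 4·mad` noise
floor so that a channel containing only noise (no TVA expression at all)
cannot pass an Otsu split of its background. Detections in adjacent planes
within `z_link_radius` (default 10 px) merge transitively into one cell;
the merged centroid is the area-weighted mean. This matches the intended
semantics — each cell counted once however many planes it spans.

## Axon pixels

Axons are thin bright ridges. The detector computes the Hessian at scale
`ridge_sigma` and scores each pixel with the *anisotropy of its negative
curvature*: `|λ₂| − |λ₁|` where λ₂ ≤ λ₁ are the Hessian eigenvalues and
λ₂ < 0. For a ridge, λ₁ ≈ 0 and the score approaches the full curvature
magnitude; for an isotropic blob (a labeled soma, a bleed-through cell
body) λ₁ ≈ λ₂ and the score collapses toward zero. The simpler score
`|λ₂|` alone cannot distinguish a blob from a ridge of equal width and
contrast — both have the same most-negative eigenvalue — so the
eigenvalue-difference form is used; it is the standard resort of ridge
filters that must suppress blobs.

# Quantification

Counts are tabulated per (mouse, region, bregma), with the anatomical grid
completed by zero records wherever the atlas defines an ROI; densities and
profiles therefore see true anatomical zeros rather than missing rows.
Exclusions never silently delete signal: records carry `excluded` plus a
reason (`injection_site`, `fiber_bundle`), and out-of-atlas detections are
tallied.

* `percent_total` = 100 × raw / (brain-wide non-excluded total of that
  mouse). Before thresholding these sum to exactly 100 per mouse.
* RV `density` = Σ counts / Σ ROI areas over the sections where the region
  exists. Summing numerators and denominators (instead of averaging
  per-section densities) avoids zero-inflation from anatomical absence.
* AAV `innervation_density` = 100 × positive pixels / ROI pixel capacity,
  at (region, bregma) level and as a region aggregate of summed
  components.

**Background threshold.** Regions carrying less than 0.03% of the total
are considered background and set to zero (percentages and densities),
flagged, and *not* renormalized — percent of total is defined against the
brain-wide total, and renormalizing would silently redefine it. The
comparison is strict (`< 0.03%`), applied per mouse at the subregion
granularity at which the rule is stated, before any aggregation to the 17
major regions. Applying the rule per section instead would zero locally sparse
tails of otherwise robust regions; per-region was chosen and is stated
here.

**Hierarchy aggregation.** Raw counts and percent-of-total sum over the
children of each major region; densities are recomputed from summed
numerators/denominators, never averaged percentages. Aggregation commutes
exactly with normalization (tested).

# Anterior–posterior profiles

`ap_profile()` emits one value per atlas level where the region exists
(cells/mm² or percent innervation), averaged over mice with SEM.
`fill_and_smooth()` linearly interpolates *interior* gaps only — no
extrapolation beyond the first/last observed level — then applies
Savitzky–Golay smoothing. The filter is implemented as explicit local
polynomial least squares; near the profile ends the window truncates to
the available points rather than padding, so no data is invented beyond
the anatomical range. Smoothing is exact for polynomials up to the
configured order (including at truncated edge windows). Window 7 and
order 2 are the defaults — wide enough to suppress Poisson jitter at
~140 µm level spacing without flattening region-scale peaks — and both
are exposed in configuration and recorded in output metadata, since no
canonical values exist for these profiles.

# Network analysis

Tracings are compared as percent-of-total vectors over the 17 major
regions. The correlation matrix is pairwise Pearson; clustering is
agglomerative complete linkage on the distance `1 − r`, with deterministic
lowest-index tie-breaking, returning a merge tree convertible to `hclust`.
`1 − r` (rather than `1 − |r|` or a correlation-of-correlations transform)
is the conventional reading when "correlation coefficients were
hierarchically clustered" is all that is specified; the choice is
config-visible in the result object. Excitatory and inhibitory rabies
tracings enter one pooled input-vs-input analysis (18 tracings); whether
the two cell classes separate is then a result, not an assumption.

Fold-difference maps use `(input + floor)/(output + floor)` with a default
pseudo-floor of 0.01 percentage points, keeping one-sided zeros finite;
regions silent on both sides are omitted. Reciprocity correlations exclude
regions lacking both input and output. Starter centers (count-weighted
mean bregma) are dense-ranked, most rostral first.

# Statistics

* `rpd(a, b)` = 100·|a−b| / ((a+b)/2): symmetric, scale-invariant; used to
  validate automated against human counts. The three-human-count panel is
  implemented as the three pairwise two-count RPDs plus the RPD of the
  human mean against the automated count. (A single combined
  `|h₁ − h₂ − h₃|`-over-mean statistic, sometimes seen in methods text,
  degenerates to ≈100% for three near-equal counts and cannot serve as a
  similarity measure; the pairwise form is the usable reading.)
* `oneway_anova()` is the classical fixed-effects decomposition
  (`F = MSB/MSW`, df `k−1`, `N−k`), delegated to the standard pooled-variance
  test and cross-checked in the test suite against explicit sums of
  squares. `tukey_hsd()` uses the studentized range with the Tukey–Kramer
  correction, so unbalanced synthetic cohorts do not error.

# The synthetic cohort generator

The generator's defaults encode the study conditions it emulates:

* 3 mice per condition; targets aIC/mIC/pIC; conditions RV-excitatory,
  RV-inhibitory, AAV-excitatory (18 input + 9 output tracings).
* Brain-wide rabies input totals uniform in **5,000–45,000** cells;
  convergence ratios within **6–15** (the ratio is drawn and the starter
  count derived, so the range holds by construction).
* Per-mouse connectivity `w ~ Dirichlet(c·archetype)` over the 75
  subregions. The archetype major-region shares encode cohort-level
  fractions characteristic of this system: sensory-cortex input shares of
  23/20/41% for aIC/mIC/pIC, motor-dominated aIC inputs, striatal output
  shares of 32/9/11%, amygdala output shares of 1.5/6/6%.
* The concentration default (250) was fixed once such that the documented
  cluster contract holds robustly — the aIC tracings separate from an
  mIC/pIC pool at the 2-cluster cut — while mouse-to-mouse variability
  keeps mean pairwise correlations in the range typical of real tracing
  cohorts (the generator yields ≈0.8 for inputs, ≈0.7 for outputs).
  Per-animal variability in real cohorts is larger than a Dirichlet at
  this concentration implies; reproducing that spread would make the
  cluster separation itself unreliable, and the separation is the
  structural property downstream analyses depend on.
* `effect_size` scales the total-variation distance between the aIC
  archetype and the mIC/pIC pool mean (default geometry ≈ 0.33); at 0 the
  aIC archetype collapses onto the pool and clustering carries no
  information about the aIC labels (negative control, tested).
* Counts per (region, bregma) are the total × connectivity weight × a
  normalized Gaussian A–P profile per region, observed through Poisson
  noise (negative binomial optional — with no empirical noise model
  available, the simplest count family is the default, with an
  overdispersion knob). Expected counts sum exactly to the drawn total.
* Starter centers sit at the stereotaxic A–P coordinates of the three
  injection targets (+1.9, +0.7, −0.5 mm) with 0.15 mm jitter; a
  configurable spillover fraction (default 0) plants starter cells in
  piriform-like and motor/sensory regions.

The canonical synthetic atlas reproduces the *structure* consumed
downstream — 75 subregion codes under 17 major regions, one polygon set
per level from +2.65 mm caudally, single hemisphere — with rectangular
ROIs of heterogeneous sizes. The anatomy itself (real region outlines,
manually warped per section) is deliberately not reproduced: no downstream
computation depends on it. Caudal-most levels beyond the last synthetic
region's extent carry no ROIs and are dropped, so the synthetic atlas ends
near −5.2 mm.

Section images contain a constant background, a smooth low-frequency bias
field, Gaussian noise (SNR = peak soma intensity / noise sd), uniform-disc
somata, shared-centroid starter discs in eGFP+mCherry, and smoothed
random-walk axon curves 1–3 px wide. They emulate none of: tissue
autofluorescence, anisotropic PSFs, staining gradients, overlapping cell
clumps beyond what the watershed handles, or z-optics (planes are
discrete). Passing the detection benchmark on these images therefore
demonstrates the correctness of the filter chain and its bookkeeping — not
detection parity on real tissue, which additionally depended on a
classifier trained per tracing.

# Problem sizes and numerical choices

The test suite and acceptance script use: a 100-image detection benchmark
(10–50 somata per 512×512 section, SNR 10) scored by mutual
nearest-centroid matching within 5 px; 1,000 random ANOVA instances and
200 random ≤6-leaf matrices against brute-force oracles; 10,000 null
simulations for type-I calibration at n = 3×3; 50 cohort replicates for
the zero-effect negative control; 500 replicates for the
law-of-large-numbers check on a 5-region toy. Degenerate inputs are
signalled, not silently absorbed: zero-total mice, all-missing profiles,
constant vectors in correlation, zero starter counts and absent regions
each raise a typed error; an all-equal-constant-groups ANOVA reports F = 0
with a `degenerate` flag rather than 0/0.

# Known limitations

* Detection parity with a per-tracing trained classifier is out of reach
  by design; the benchmark quantifies the deterministic chain on synthetic
  images only.
* ROIs are taken as given; there is no elastic registration to damaged or
  warped tissue.
* The 0.03% rule's granularity and the smoothing parameters are design
  choices documented above, not externally fixed constants.
* Pixel counts are not synapse counts; AAV innervation densities measure
  axon presence, not connection strength.
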