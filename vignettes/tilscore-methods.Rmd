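---
title: "Methods: TIL density estimation on H&E whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIL density estimation on H&E whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilscore)
```

## The problem

Tumor-infiltrating lymphocytes (TILs) are a prognostic biomarker in
non-small cell lung cancer and other solid tumors: patients whose tumor
and tumor-associated stroma carry a denser lymphocyte infiltrate tend to
survive longer. Counting lymphocytes by eye across a gigapixel
hematoxylin-and-eosin (H&E) whole-slide image (WSI) is slow and
subjective, and exhaustive computational analysis of every tile is
wasteful because most of a slide is glass, debris, or tissue without
prognostic content. `tilscore` implements a staged pipeline that spends
expensive computation only where it matters, and a synthetic-slide
generator that lets every stage be validated against exact ground truth.

## Pipeline model

**Stage 1 — patch extraction.** The slide is block-averaged by
`mask_downsample` (default 32), converted to grayscale with BT.601 luma
(0.299 R + 0.587 G + 0.114 B), and thresholded: a pixel is tissue iff
its luma is strictly below `gray_threshold = 170` (stained tissue is
darker than glass; the boundary value counts as background so the rule
has no ambiguity). Connected components below `min_object_area_px = 64`
mask pixels are dropped as debris. A non-overlapping grid of
`patch_size = 768` px squares anchored at the slide origin is laid over
the mask; partial edge patches are dropped, and a grid cell becomes a
candidate when at least `tissue_fraction_min = 10%` of its footprint is
tissue — deliberately permissive, because the content-based filter that
follows is the real gatekeeper. Each candidate is then read at full
resolution and deconvolved into hematoxylin–eosin–DAB densities with
the Ruifrok–Johnston stain matrix; optical density is normalized so an
intensity of 1e-6 maps to 1, the convention of the mainstream imaging
libraries, which fixes the numeric scale of the threshold. Patches with
mean hematoxylin below `h_threshold = 0.017` lack nuclear content and
are discarded; equality keeps the patch. Users of a different
deconvolution convention must recalibrate this threshold.

**Stage 2 — classification.** Each surviving patch receives one of four
labels: tumor, stroma, necrosis, or normal tissue. The classifier is a
*contract* (`til_classifier`), not a fixed model: a trained CNN can be
plugged in through a thin adapter without touching the pipeline. The
package ships (i) a ground-truth oracle for synthetic slides, which
labels a patch by the majority region class under its footprint with
ties broken by the fixed priority tumor > stroma > necrosis > normal,
mirroring the predominant-component rule used when pathologists label
mixed patches; and (ii) a heuristic reference classifier driven by
nuclear-blob density and eosin intensity with documented thresholds —
a label signal for fixtures, with no claim of CNN-level accuracy on
real tissue. Only tumor and stroma patches continue: necrosis and
normal lung carry little prognostic information and would dilute the
score.

**Stage 3 — quantification and scoring.** A pluggable quantifier
(`til_quantifier`) returns nucleus detections per patch. The classical
reference detector thresholds the hematoxylin channel at 0.05, labels
connected components, keeps areas in [20, 600] px, and calls a
component a lymphocyte when its area is ≤ 250 px and its circularity
4πA/P² is ≥ 0.7 (stand-in parameters for roughly 0.25–0.5 µm/px, not
claims about any trained model). The ground-truth oracle returns the
planted nuclei whose centers fall in the patch; centroid assignment
makes counts partition exactly across the grid. The lymphocyte count
\(c_i\) of patch \(i\) becomes a density
\[ d_i = \frac{c_i}{(\text{patch\_size} \times \text{mpp})^2} \times 10^6
\quad [\text{cells/mm}^2], \]
the slide score is the mean over its patches, and a patient with \(k\)
slides scores the mean of slide means — not the pooled patch mean, so a
slide with few patches is not out-voted. A slide with *no* retained
patches yields "no score" (`evaluable = FALSE`), never 0, because 0
would masquerade as "no TILs".

**Randomized sampling.** Between extraction and classification, the
candidate set can be thinned to `m = max(1, round(ratio × N))` patches
drawn uniformly without replacement (round-half-to-even; R's
Mersenne-Twister seeded locally per call). Under simple random sampling
the sampled mean density is an exactly unbiased estimator of the
full-set slide score, so the operating ratio trades only variance, not
bias, against compute. `monte_carlo_stability()` quantifies that trade:
for replicate *r* it samples every slide with seed `base_seed + r`,
rescores, and reports the mean and spread of scores and of the cohort
concordance index per ratio. Since every downstream stage is
deterministic per patch, the harness annotates the full candidate set
once and resamples annotated records — numerically identical to
rerunning the stages per replicate and far cheaper.

**Survival evaluation.** `concordance_index()` implements Harrell's c
with explicit conventions: a pair is comparable iff the strictly
shorter observed time is an event (ties in time, including two events
at the same time, are non-comparable), tied risk scores count 0.5, and
a direction flag negates scores for protective markers like the TIL
score. `quartile_groups()` pins the type-7 (linear interpolation)
percentile definition with right-closed intervals, and accepts frozen
cutoffs so new patients can be scored against a reference cohort —
both readings of "quantile cut-offs from a test subset" are therefore
supported. `km_estimator()` is the product-limit estimator;
`logrank_test()` accumulates observed-minus-expected event counts with
the hypergeometric covariance and supports more than two groups.
Multivariable Cox modelling is deliberately left to the established
survival tooling rather than reimplemented here.

## The synthetic-slide generator

`generate_slide()` emulates exactly the properties the pipeline
measures, not histology per se:

* background glass is a flat near-white gray (default 245);
* tissue fills are defined as mixtures in stain space, frozen so that
  every fill has BT.601 luma below 170 (it passes the tissue mask) but
  mean hematoxylin *below* 0.017 — bare tissue without nuclei is
  rejected by the H-filter, so that filter is genuinely exercised;
* nuclei are hematoxylin-dark disks (lymphocyte H ≈ 0.130, other
  ≈ 0.091) planted uniformly within their region; the planted count per
  region is the *deterministic* rounding of density × area, so
  density-recovery tests carry zero planting noise (a Poisson option
  exists behind a flag);
* necrosis gets a low-contrast sinusoidal texture and, by default,
  under 5% of tumor nuclear density, giving classifiers a real signal;
* identical spec + seed produces a byte-identical TIFF.

Because the `tiff` writer cannot store resolution tags, the generator
writes the microns-per-pixel value to a JSON sidecar
(`<slide>.mpp.json`), which `open_slide()` reads alongside genuine TIFF
resolution metadata; an explicit override always wins, and a slide
without any mpp source fails loudly rather than guessing.

What the generator does **not** emulate: stain variability, scanner
artifacts (folds, pen marks), overlapping nuclear textures, tertiary
lymphoid structures, or any photorealistic tissue appearance. Passing
tests on synthetic slides therefore validate the pipeline's *logic*
(geometry, thresholds, normalization, aggregation, sampling,
statistics) — they do not certify performance of any particular
classifier or detector on real H&E scans.

`generate_cohort()` builds one slide spec per patient (tumor and stroma
halves sharing a patient-specific lymphocyte density) and draws
disease-specific survival from an exponential model whose log-hazard is
linear in the true density: baseline hazard 0.4 events/unit time,
log-hazard slope −0.85 per 1000 cells/mm² (reproducing the roughly
0.28 hazard ratio between patients ~1500 cells/mm² apart that TIL
quartile analyses report in lung cancer), and independent uniform
censoring on [0, 15], which yields about half the cohort as events.

## Numerical and design choices

* **Coordinates** are 0-based level-0 pixels; a patch spans the
  half-open square \([x, x+P) \times [y, y+P)\), matching array
  slicing and removing off-by-one ambiguity. Flat images are 1-level
  pyramids; multi-page TIFFs are read as pyramids. Patches are read
  from level 1 (full resolution) by default, configurable via
  `read_level`.
* **mpp** is stored once per slide and assumed isotropic, since the
  density normalization uses a single mpp term.
* **Grayscale** is pinned to BT.601 luma so mask tests are bit-exact.
* **Grid** stride equals the patch size (no overlap), since overlap
  buys nothing for a mean-density estimate.
* The **H-filter comparison** is ≥ (keep on equality), and the tissue
  threshold is < (170 itself is background): both boundaries fixed for
  determinism.
* **Sampling seeds**: replicate `r` of the stability harness uses
  `base_seed + r`, making every draw auditable.
* **Degenerate inputs**: empty patch sets, slides without mpp,
  unlabeled records reaching the prognostic filter, single-group
  log-rank calls, and cohorts without comparable pairs all raise typed
  errors (`til_*_error`) instead of returning silent defaults.

## Problem sizes used in validation

The test-suite and acceptance-script experiments run at desk scale,
chosen so each one still has the statistical power its check needs:
slides of 512–1536 px per side at 0.25–1 µm/px, patch sizes 128–768 px,
a 200-patient cohort of 1024 px slides with 16 patches each, 200
Monte-Carlo replicates for sampling stability, and 1000-case
brute-force sweeps for the exact-arithmetic and concordance oracles.
At these sizes a density of 1500 cells/mm² plants 1500–3500 nuclei per
slide, and the end-to-end recovery error of the oracle pipeline is
well under 1%.

## Known limitations

* The in-memory slide model targets region exports and synthetic
  fixtures (up to a few hundred megapixels), not gigapixel clinical
  scans; plugging in a lazy tile reader behind `open_slide()` is the
  natural extension.
* The heuristic classifier's thresholds are calibrated to the synthetic
  palette; on real tissue a trained model should be plugged into the
  classifier contract.
* The reference detector undercounts when nuclei touch (connected
  components merge); the generator's `min_separation_px` exists
  precisely so detector tests can avoid that regime, and counts from
  the ground-truth oracle are unaffected.
* Scores from slides with very few retained patches are noisy; the
  stability harness makes that noise measurable rather than hiding it.
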