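---
title: "Quantifying tissue ammonia from Nessler-stained micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue ammonia from Nessler-stained micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nesslerquant)
```

## The measurement model

Nessler's reagent (alkaline potassium tetraiodomercurate) precipitates an
orange-brown product in proportion to local ammonia, over a pale
hematoxylin-counterstained tissue field. In a brightfield RGB capture the
precipitate is simply *dark*: its HSV value channel
`V = max(R, G, B)/255` is low, while unstained tissue and background are
high. The pipeline therefore

1. extracts the value channel (which is itself a grayscale rendering of
   the image, so no separate luminance conversion is applied),
2. inverts it (`1 - V`), so precipitate becomes bright,
3. applies one fixed global threshold `t = 0.7` — a pixel is stained iff
   `1 - V >= t`, equivalently `V <= 1 - t = 0.3`, and
4. reports the fraction of *all* image pixels classified stained.

The assumptions this encodes are worth stating. Staining intensity is
treated as binary: a pixel is precipitate or it is not, and darkness
beyond the threshold carries no extra weight. The denominator is the whole
field of view, not a tissue-segmented region, so acquisition should fill
the frame with tissue consistently across samples. No hue gating is
applied: very dark counterstained nuclei can in principle cross the value
threshold, and the method relies on that contribution being small and
comparable across groups. These choices reproduce the measurement as
published; an analysis wanting hue windows or tissue masks is a different
(and no longer comparable) measurement.

Two small conventions are fixed so results are bit-reproducible: the
threshold comparison is inclusive (`>=`, so a uniform image exactly at the
threshold is fully stained), and it is applied on the continuous
`[0, 1]` scale after 8-bit intensities are divided by 255.

## Normalization and the Ammonia Score

Absolute area fractions depend on section thickness, development time and
illumination, so cohorts are normalized internally: each sample's mean
fraction (over its replicate fields, 5 by convention) is divided by the
mean fraction of healthy-control samples. At least three controls are
required — fewer is a hard error, not a warning — and a cohort whose
controls show zero stained area is rejected as degenerate rather than
scored. Normalization uses the mean of per-sample means (not pooled
replicates, not a median): with balanced replicate counts the two means
coincide, and the per-sample mean keeps each specimen's weight equal when
counts are unbalanced.

The area ratio is then binned into the integer Ammonia Score:
`[0,2) -> 1`, `[2,10) -> 2`, `[10,20) -> 3`, `[20,30) -> 4`,
`[30,40) -> 5`, `[40,Inf) -> 6`. The published ranges share endpoints and
leave the value 40 formally unassigned ("30-40" vs ">40"); the
left-closed, right-open reading used here is the unique total,
non-overlapping cover of the half-line, and every shared endpoint maps to
the higher bin. This convention is pinned by tests so it cannot drift.

```{r rubric}
assign_score(c(1, 5, 15, 25, 35, 50))
assign_score(c(2, 10, 20, 30, 40))   # boundaries take the higher bin
```

## Parameters that matter

* `threshold` (unitless, on the inverted value channel; default 0.7):
  the single tuning constant of the measurement. It is a *fixed* global
  setting — per-image adaptation (Otsu and friends) would break
  between-sample comparability, which is the entire point of the score.
* `replicate_policy` (default 5 fields per sample): below 3 replicates
  the per-sample CV is too unstable to mean much; the package warns but
  still computes.
* Minimum controls (fixed at 3): the floor for a meaningful control
  average.
* `test_choice` (`mann_whitney` default, `welch` optional): the score is
  ordinal and cohorts are small (3–8 samples), so a rank test is the
  defensible default. The exact U null is used when the smaller group has
  at most 8 samples, both have at most 25, and no value is shared
  *across* groups; within-group duplicates leave U and its classical
  exact distribution unchanged, so they do not force the normal
  approximation. Otherwise the tie-corrected normal approximation with
  continuity correction is used, and the report always records which path
  was taken. No multiple-testing correction is applied by default,
  matching how the raw p < 0.05 criterion is reported.

## Validation statistics

Replicate precision is the coefficient of variation across the repeated
field measurements of one section (sample SD with the n − 1 denominator,
as a percent of the mean; defined as 0 for identical or single
replicates). When a manifest carries a `section_id` column, the report
also gives the CV across section means of the same specimen — in real
tissue the between-section spread is several-fold larger than the
within-section spread, and the report keeps the two tiers separate for
that reason. Method comparison against a paired colorimetric kit value is
the standard product-moment correlation with a two-sided p from the t
transform on n − 2 degrees of freedom (an exact permutation p is
available for n ≤ 8).

## What the synthetic generator emulates — and what it does not

`generate_section()` builds what the pipeline actually measures: a pale
tissue field (value channel in (0.3, 1]) carrying dark blob-shaped
precipitate (value in [0, 0.3)), at a requested stained-area fraction
with a pixel-exact ground-truth mask. Blobs are disks of random radius
(3–12 px by default) that may overlap; the union mask defines the truth,
and the last blob is trimmed pixel-wise so the achieved stained count
equals the rounded target exactly. Precipitate is rendered in warm
orange-brown hues and tissue in pale pink purely for visual plausibility
— the hue is cosmetic, because the pipeline ignores it; only the value
separation is load-bearing, and tests deliberately do not depend on hue.

Gaussian pixel noise (SD 0.02 by default) is added on the value channel
and *truncated* so no pixel enters a guard band of half-width 0.02 around
the 0.3 decision boundary; the margin is at least 1/255 so 8-bit
quantization cannot flip a pixel either. Under these defaults measurement
error against ground truth is exactly zero, which is what makes the
generator usable as an oracle for the composed pipeline.

Real micrographs are of course not like this: illumination gradients,
partial-intensity precipitate at the threshold boundary, dark nuclei,
JPEG artifacts and out-of-focus fields all put pixels *near* 0.3, where
the fixed threshold genuinely decides. Passing the synthetic suites
therefore demonstrates that the arithmetic of the pipeline, the
normalization and the rubric is correct — not that the 0.7 threshold is
optimal for any particular stain batch. The published real-data anchors
(within-image CVs of a few percent, between-section CVs several-fold
larger, a strong positive kit correlation) depend on stained tissue and
are treated as design templates, not as numbers the synthetic data could
meaningfully reproduce.

Cohort generation (`generate_cohort()`) uses a control stained fraction
of 0.015 by default — a realistic low-stain healthy baseline that leaves
headroom for a 50-fold ratio within a feasible canvas — with 3%
multiplicative replicate jitter, matching the low end of observed
replicate CVs. Targets whose fraction would exceed 0.9 are capped with a
warning. A synthetic paired kit value (proportional to the true fraction,
2% noise) rides along so method-comparison runs work end to end.

## Numerical choices and degenerate inputs

* 16-bit sources are rescaled by max-value division before the pipeline;
  everything downstream is scale-normalized anyway.
* Fixture output is restricted to lossless formats (PNG/TIFF); JPEG is
  accepted as *input* but refused for generated ground truth.
* A replicate mean of zero with zero spread gives CV 0; zero mean with
  nonzero spread is an error rather than an infinity.
* Exactly boundary-valued ratios (2, 10, 20, 30, 40) take the higher
  score; callers relying on a different endpoint convention will see a
  one-bin difference at those exact values only.
* All generator randomness flows from a single integer seed, and
  generation restores the caller's RNG stream.

## Problem sizes used by the test and acceptance suites

The suites run entirely on generated data: sections of 32–128 px a side,
cohorts of up to 19 samples with 5 replicate images each, 100 random
64×64 images for the pipeline-versus-reference equivalence sweep, and
5,000 simulated null cohorts at n = 10 per group for the type-I
calibration of the default test. These sizes make every property
checkable in seconds while leaving the code paths identical to full-size
runs.

## Known limitations

The package measures what the published pipeline measures — no color
deconvolution, no tissue segmentation, no illumination correction, no
adaptive thresholding. Whole-slide pyramidal formats are out of scope;
inputs are ordinary TIFF/PNG/JPEG captures. The score's six bins are
coarse by design (they are a communication device between laboratories),
so downstream statistics on the underlying area ratios are usually more
informative than statistics on the integer scores.
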