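---
title: "Positive-pixel counting and H-score quantification of IHC images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positive-pixel counting and H-score quantification of IHC images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcscore)
```

## The measurement problem

Chromogenic immunohistochemistry renders a protein of interest as a brown
DAB precipitate over a blue hematoxylin counterstain. Manual grading of such
slides ("weak/moderate/strong staining in x% of cells") is subjective;
positive-pixel counting replaces it with a deterministic rule applied to
every pixel of the imaged tissue. `ihcscore` implements that rule, the
downstream H-score, and the two-group statistics used to relate the score to
a clinical covariate such as lymph-node status (N0 vs N1), together with a
synthetic image generator that makes every stage testable against exact
ground truth.

## The pixel model

Each 8-bit RGB pixel is re-expressed in hue/saturation/intensity:

* intensity \(I = (R+G+B)/3\), on the 0–255 scale — darker stain means more
  chromogen;
* saturation \(S = 1 - \min(R,G,B)/I\) (0 for black), separating colored
  stain from gray background;
* hue, the hexagonal hue angle normalized to \([0,1)\) with 0 at pure red,
  wrapping circularly; achromatic pixels get hue 0.

A pixel inside the region of interest is **positive** when all three gates
pass: circular hue distance to `hue_center` at most `hue_width/2`,
\(S \ge\) `saturation_threshold`, and \(I <\) `iwp_high`. Positive pixels
are binned by intensity into strong `[isp_low, ip_low)`, medium
`[ip_low, iwp_low)` and weak `[iwp_low, iwp_high)`. All bins are half-open
and closed at the darker edge, so a pixel sitting exactly on a boundary is
assigned once, to the darker bin. Pixels at or above `iwp_high` are treated
as too faint to be stained and are negative even when their hue and
saturation match — that is what an upper weak-intensity bound means.

### Default thresholds

The defaults are the publicly documented DAB defaults of the vendor-style
positive-pixel-counting algorithm this reproduces: `hue_center = 0.1`
(brown), `hue_width = 0.5`, `saturation_threshold = 0.04`, and intensity
cuts 220 / 175 / 100 / 0. Studies that use the vendor tool rarely report
deviations from these defaults, so they are the sensible reference
configuration; every threshold is overridable through
`pixel_class_params()`, and file-based runs echo the resolved parameters
into the output directory so any reported number can be regenerated.

The ROI is an input, not an inference: masks emulate the pathologist's
manual delineation of tumor parenchyma (stroma and dermis excluded). An
absent mask means "count everything"; an all-excluded mask is a defined
degenerate case that yields zero counts and a scoring error downstream,
because no score is defined on an empty ROI.

## From counts to the H-score

With \(N_{wp}, N_p, N_{sp}\) the weak/medium/strong counts and
\(N_{Total}\) the number of counted (included) pixels, per-bin positivity
fractions are \(N_{wp}/N_{Total}\) and so on, and

\[ H = 1\cdot\%\text{weak} + 2\cdot\%\text{medium} + 3\cdot\%\text{strong} \]

with the percentages as fractions in \([0,1]\), giving \(H \in [0,3]\). The
0–3 scale is deliberate: reported group means like 1.05 and 0.11 live on it,
and the conventional pathology 0–300 scale is exactly this value times 100.
Scores are kept at full precision internally; CSV output rounds to four
decimals.

## Group comparison

`compare_groups()` reports per-group mean, SEM (sample standard deviation
over \(\sqrt n\)), a two-sided unpaired two-sample t-test and the
fold-change of the means. "Unpaired t-test" with no variance qualifier
conventionally denotes the pooled Student test, so that is the default;
Welch's form is one argument away. The fold-change is
reference-group-over-comparison-group (N0/N1 in the demo) and its direction
is always printed alongside the ratio; a zero denominator is reported as
undefined rather than infinity. When both groups are exactly constant the t
statistic is taken at its limit (0 with p = 1 for equal means, signed
infinity with p = 0 otherwise) — this only arises in synthetic data with
zero between-sample spread. Text reports round means/SEM to 2 decimals,
fold-change to 1 decimal and p to 4 significant figures; CSVs keep full
precision. No multiple-testing correction is applied for a single
comparison.

## The synthetic generator

Real slides bring nuisance the thresholds must survive; the generator
isolates the arithmetic by planting known truth:

* Geometry: a full-frame ROI or a centered disc (radius 0.45 of the short
  side) emulating a tissue-microarray core on white background.
* Class allocation: the planted weak/medium/strong/negative fractions are
  rounded to whole pixels by largest remainder, then single pixels are moved
  between adjacent classes until the realized weighted score equals the
  nearest grid point to the planted target. Realized scores live on a grid
  of spacing \(1/n\) (n = ROI pixels), so the realized H-score is always
  within \(0.5/n\) of the target — plain largest remainder alone can land up
  to several \(1/n\) steps away when rounding errors align across classes.
* Rendering: positives are DAB-brown (hue at the window center, saturation
  shrinking near white so no channel clips) with intensity drawn uniformly
  from strictly inside the target bin, at least \(\max(2, 3\sigma)\) away
  from each bin edge for channel-noise sd \(\sigma\); negatives are
  hematoxylin-blue (hue 2/3, far outside the brown window). Gaussian channel
  noise is added to ROI pixels, then channels are clamped and rounded.
  The margins mean zero-noise images are recovered *exactly* and noisy ones
  nearly so, which separates classifier correctness from generator
  ambiguity.
* Cohorts: per-sample target H-scores are drawn from a normal around the
  group mean (truncated to \([0,3]\)) and inverted to fractions. The
  inversion is underdetermined (one equation, three unknowns), so the
  mixture shape is fixed — fractions proportional to (0.5, 0.3, 0.2) —
  and scaled to the target; that shape saturates at \(H = 1.7\), beyond
  which the generator falls back to strong-only staining. Sub-seeds are
  derived per image as `seed + sample index`, so cohorts are reproducible
  image by image, and the generator restores the caller's RNG state.

What the generator does **not** emulate: nuclear texture, stain
colocalization, uneven illumination, scanner compression, or tissue
morphology. Passing tests therefore demonstrate that the arithmetic —
classification, counting, scoring, statistics — is correct, not that the
default thresholds are optimal for any particular scanner or stain batch;
on real material the ROI masks and possibly the thresholds need
pathologist review.

## Numerical and design choices

* Ties at equal channel maxima resolve hue in R, G, B branch order; this
  only matters on exactly balanced pixels and matches the per-pixel oracle
  used in the tests.
* 16-bit input is rescaled to 8-bit on read with a warning; alpha is
  dropped; masks are any-nonzero-includes.
* The demonstration cohort (`run_demo()`) uses 8 samples per group, target
  means 1.05 (N0) and 0.11 (N1), zero between-sample spread, noise-free
  96×96 disc images (5860-pixel ROI). These sizes make the full
  simulate→quantify→compare loop run in seconds while keeping pixel
  quantization (\(\le 0.5/n\) per sample) far below reporting precision;
  the recovered fold-change prints as 9.5 at one decimal.
* Statistical validation uses 2,000-replicate null simulations at n = 8 per
  group, where the pooled test's rejection rate at \(\alpha = 0.05\) must
  sit within 0.05 ± 0.01 (binomial tolerance).

## Known limitations

* No color deconvolution into optical-density stain channels: thresholds
  act in HSI space, as in the source algorithm, so heavily overlapping
  stains (strong hematoxylin over DAB) can shift hue out of the window.
* No whole-slide pyramid formats (SVS/NDPI) and no automatic tumor/stroma
  segmentation; images are unitless rasters and ROIs are supplied.
* The pixel-based H-score is not the pathologist's ordinal 0/1+/2+/3+
  cell-category score; the two correlate but are not interchangeable.
* One record per input image: if a patient contributed several cores,
  aggregation to patient level is left to the manifest.
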