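---
title: "Radial gene positioning analysis: model, calibration and design notes"
author: "radialFISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial gene positioning analysis: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialFISH)
```

## The measurement model

Interphase nuclei keep most gene loci at preferred radial positions, and
several pathologies — prostate cancer among them — shift individual loci
toward the nuclear interior or periphery. `radialFISH` quantifies such
shifts from 2D FISH images of segmented tissue nuclei.

For a segmented nucleus the Euclidean distance transform (EDT) assigns every
pixel its distance to the nearest background pixel. A FISH signal detected
at sub-pixel position $s$ gets the **relative radial position**

$$\mathrm{RRP}(s) \;=\; \frac{\mathrm{EDT}(s)}{\max_{p \in \text{nucleus}}
\mathrm{EDT}(p)} \in [0, 1],$$

with 0 the nuclear periphery and 1 the nuclear center. Dividing by the
per-nucleus EDT maximum normalizes out nuclear size and shape, which vary
strongly between FFPE specimens; this is what makes RRPs poolable across
nuclei and tissues. All detected alleles of a nucleus contribute,
regardless of copy number; the pooled values of one gene in one tissue form
its **relative radial distribution (RRD)**, and the concatenated RRDs of a
gene over all normal tissues form the **pooled normal distribution (PND)**,
the reference for repositioning calls.

A tissue is called *repositioned* for a gene when the two-sample
Kolmogorov–Smirnov test between its RRD and the reference yields
$p < \alpha$ with $\alpha = 0.01$ (strict inequality). Significant calls are
labeled **I** (more internal) when the RRD median RRP exceeds the reference
median and **P** (more peripheral) otherwise.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `alpha` | 0.01 | probability | strict threshold for significance |
| `tophatRadius` | 5 | px | disc radius of the white top-hat; of the order of a diffraction-limited spot |
| `minArea` | 4 | px | smallest accepted spot component |
| `noiseFloorSigmas` | 3 | — | detection threshold floor in background-noise SDs |
| `minNuclei` | 88 | nuclei | warning threshold for sparse RRDs |
| `nNuclei` (simulator) | 120 | nuclei | per-tissue analysis count typical of FFPE epithelial panels (roughly 90–170 in practice) |
| `psfSigma` | 1.5 | px | Gaussian width of the emulated projected PSF |
| spot peak | 10 × noise SD | intensity | emulates a well-labeled probe |

No multiple-testing correction is applied across tissues or genes: the
cohort convention this package reproduces works with raw $p < 0.01$ calls,
and the worked-example statistics depend on that convention. Treat the
per-comparison significance level accordingly when many comparisons are
made.

## Direction statistic and other open choices

The direction of a significant shift is decided by the **median difference**
of RRPs, with a mean-difference fallback on exact median ties. The median is
robust to the pixelated tails of RRDs and matches the visual ordering of
cumulative RRD curves; mean, trimmed mean or a quantile band would order the
clear-cut cases identically.

KS $p$-values use the asymptotic two-sample distribution with effective
sample size $n_a n_b/(n_a+n_b)$; allele counts in realistic cohorts
(roughly 180–340 per RRD) are comfortably in its regime. Below a combined
$n$ of 50 the implementation switches to the exact Smirnov distribution
(`exact = "auto"`).

When a normal tissue is compared against a PND that contains it, the tissue
is *not* removed from the reference — the pooled-reference convention this
package mirrors. `compareToPND(..., leaveOneOut = TRUE)` provides the
alternative; with 6–8 pooled normals the two differ little, but leaving the
tissue in is slightly conservative.

Marker evaluation treats direction explicitly. Two conventions appear in
subgroup-biomarker work and both are expressible: a directional rule (e.g.
`c(SP100 = "P")`) counts only the required direction as a detection, while
`"any"` counts any significant repositioning. The bundled cohort's
intermediate/high-Gleason false-negative rates follow the `"any"`
convention (their printed values equal one minus the repositioning rate),
whereas the corresponding false-positive rates are directional; the
acceptance script encodes each marker the way its reference statistic was
defined.

## The bundled prostate cohort

`loadProstateCohort()` ships a curated worked example: 32 prostate cancers
and 25 benign tissues (16 normal, 9 benign disease) with per-gene
repositioning calls for *SP100*, *TGFB3*, *SATB1* and *LMNA* and
Gleason/TNM/risk metadata. Because published summary matrices leave blank
cells ambiguous (not significant vs not assayed), the encoding makes the
assay matrix explicit: a missing (tissue, gene) row means *not assayed*.
The assay matrix was reconciled from the per-subgroup denominators of the
source summary tables; the file headers document the handful of
interchangeable choices and the three reconciled grade entries.

```{r cohort}
cohort <- loadProstateCohort()
subgroupSummary(cohort$calls, cohort$clinical, "SP100", "gleason_group")
```

The composite risk rule (high: Gleason 8–10 and/or T3/T4 and/or N1 and/or
M1, evaluated first so partial records can still be high; low/intermediate:
Gleason 2–6 / 7 with T1–T2 and N0M0) reproduces the recorded risk label of
all 32 cancers. An N0 record without a distant-metastasis entry is counted
N0M0 — required for the non-metastatic counts to balance — while a record
with neither N nor M stays unknown. Grade groups derive from the *reported*
predominant grade rather than the first grade of the score decomposition:
the two disagree in this cohort (e.g. a 6 (2+4) tumor reported as grade 4),
and the reported grade is what the subgroup denominators are built from.

## What the simulator emulates — and what it does not

`simulateTissue()` exists so every downstream stage is testable without
external image data. It emulates: convex-ish epithelial nucleus outlines
(random-harmonic "wobble" on an ellipse, star-shaped hence simply
connected), non-overlapping placement, 1–4 FISH alleles per nucleus placed
at *known* target RRPs, an isotropic Gaussian PSF, and additive Gaussian
background noise clipped at zero. Spot placement matches a target
normalized-EDT value (not a radius) because the analysis is defined on
normalized EDT; targets outside the attainable pixel grid snap to the
nearest attainable EDT level, so `point_mass(0)` and `point_mass(1)` land
on boundary and EDT-maximum pixels exactly.

It deliberately does **not** emulate 3D stacks (inputs are taken to be
maximum-intensity projections), deconvolution artifacts, chromatin texture,
touching or border-truncated nuclei, or segmentation error. Passing
round-trip tests therefore validate the *measurement pipeline* — detection,
EDT normalization, pooling, testing — not robustness to segmentation
quality or optical artifacts in real tissue.

## Numerical choices

* **EDT**: exact Euclidean distances via `EBImage::distmap`, verified in the
  test suite against a brute-force nearest-background-pixel oracle (exact
  equality on random masks). Distances are measured to background pixels
  present in the image; nuclei touching the image border are excluded from
  `mapTissue()` because their EDT would be truncated and bias the
  normalization.
* **Sub-pixel EDT lookup**: bilinear interpolation at the spot centroid
  (nearest-pixel lookup differs by at most half a pixel of EDT); RRPs are
  clamped to $[0,1]$.
* **Spot detection**: white top-hat (disc radius 5) → Otsu threshold on the
  in-nucleus enhanced intensities → components of ≥ 4 px, reported by their
  unweighted pixel centroid ("geometric gravity center" read as unweighted;
  intensity weighting would move centroids by well under a pixel for
  near-isotropic blobs). Otsu alone always splits a unimodal noise
  histogram, so the threshold is floored at `noiseFloorSigmas` (default 3)
  robust background SDs — quartile-based so the zero-clipped background is
  estimated correctly; signal-free nuclei then yield no detections (< 5%
  false-positive rate by simulation).
* **Pixels are isotropic**: physical X–Y calibration cancels under the
  per-nucleus normalization and is not modeled.
* **Coordinates** are 1-based (col, row) pixel centers throughout, the R
  matrix convention.
* **Determinism**: all simulator randomness flows from one integer seed
  (`rngSeed` / the pipeline `seed`); identical seeds give byte-identical
  outputs.

## Validation problem sizes

The test suite checks, among others: exact EDT–oracle agreement on 100
random masks up to 30×30; the analytic $(R-r)/R$ profile on a radius-50
disc within ±0.03; simulator-to-mapper recovery of realized RRPs within
±0.05 for ≥95% of matched alleles on a noise-free 120-nucleus tissue; KS
null-call rate 0.01 ± 0.006 over 2,000 replicates at 240 alleles against a
960-allele reference; >95% power with the correct direction label for a
beta(2,2) → beta(2,5) peripheral shift at 240 alleles; exact pooling
conservation and KS symmetry. Scale (2×) and rotation invariance of RRPs
hold up to pixelation (±0.02 / ±0.03) on radius-25 nuclei. The full
synthetic pipeline runs at 25 nuclei per tissue in the tests — large enough
for unambiguous calls with the strong simulated shifts — and at 120 in the
acceptance script's round-trip metric.

## Known limitations

* Calls are per-tissue, not per-nucleus; heterogeneous subclones within a
  tissue blur into one RRD.
* The KS test is sensitive to any distributional difference, not only
  location shifts; the I/P label summarizes the median direction and can
  understate shape-only changes.
* With ~100–250 alleles per RRD, subtle shifts (median differences well
  under 0.05) are below power at $\alpha = 0.01$; reported false-negative
  rates of single-gene markers are correspondingly high.
* The interfaces are R functions and tables (plus `runFullPipeline()`); a
  shell-level CLI is not provided.
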