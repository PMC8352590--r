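---
title: "CortexQuant: methods and design notes"
author: "CortexQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CortexQuant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

CortexQuant quantifies, per cell, how strongly a fluorescently tagged
protein is enriched in the cell cortex, how asymmetrically it is
distributed around the periphery, and how many filopodia the cell
extends; it additionally computes pixel-wise two-channel colocalization,
spline-averaged linescan profiles, and the group statistics used to
compare genotypes and drug treatments. All measurements run on
maximum-intensity projections of confocal z-stacks. The package is
validated end to end by parameter recovery on synthetic micrographs with
known ground truth; no real microscopy data are required for any test.

## Conventions

Images are row-major matrices with the origin at the top-left pixel
center and y (row index) increasing downward. Physical calibration goes
through a single pixel size in µm (default 0.212 µm, a typical EMCCD /
63x oil-immersion configuration); micron-to-pixel conversions are never
rounded to integer pixels. Angular position about a cell centroid is
measured from the +x axis (increasing column) toward +y, in (−π, π].
One fixed convention is shared by the renderer, the asymmetry binning
and the ray caster, so polarity angles and detected tip angles are
directly comparable.

## The synthetic scene generator

`SceneParams()` describes one cell; its defaults are the conditions under
which the package is validated:

| parameter | default | meaning |
|---|---|---|
| `pixelSizeUm` | 0.212 | µm per pixel |
| `cellRadiusUm` | 8 | mean radius of a vegetative amoeboid cell |
| `boundaryRoughness` | 0.04 | total amplitude of an order-2..5 cosine perturbation of the outline |
| `nucleusRadiusUm`, `nucleusOffsetUm` | 2, 1.5 | dark (signal-free) nucleus, strictly inside the body |
| `cytoplasmLevel`, `backgroundLevel` | 100, 10 | intensities, a.u. |
| `enrichment` | 1.2 | band mean = E × cytoplasm mean |
| `polarityAmplitude`, `polarityAngle` | 0, 0 | band modulated by 1 + A·cos(θ − θ₀) |
| `bandWidthUm` | 0.8 | cortical band width |
| `filopodiumLengthUm`, `filopodiumWidthUm`, `tipGain` | 3, 0.25, 3 | shaft at cytoplasm level; Gaussian tip punctum of σ = width and amplitude tipGain × shaft |
| `poissonScale`, `gaussianSd` | 1, 5 | per-pixel variance = poissonScale·mean + gaussianSd² |
| `nSlices` | 5 | z-sections (4–6 is typical for live imaging) |

The outline is a circle perturbed by a low-order cosine series — smooth
but non-circular, as amoeboid outlines are, while keeping the analytic
area and annulus computable at roughness 0. Filopodia are placed at
random angles with at least 15° pairwise separation (filopodia closer
than that are not resolvable as separate structures at this pixel size
and are also rare in vivo) and rendered as radial rays with a bright
terminal punctum, matching the tip-enriched localization of filopodial
myosins. Z-sections share one ideal image and differ only in the noise
realization: downstream analysis uses maximum projections, so 3-D optics
are deliberately out of scope. There is no point-spread function,
photobleaching, drift or motility; consequently the synthetic boundary
is one pixel sharp, which makes segmentation easier than on real data —
passing recovery tests demonstrates correctness of the measurement
chain, not segmentation robustness on low-contrast cells.

Noise is Poisson (scaled) plus Gaussian read noise, clipped at zero;
`seed` fully determines every render (verified bit-for-bit in the test
suite). Two-channel scenes construct channel B inside the mask as
ρ·z_A + √(1−ρ²)·ε with ε *exactly* orthogonalized against the
standardized channel-A fluctuation z_A and both standardized to unit
sample variance, then shifted (affinely, which Pearson r ignores) to
stay non-negative. The in-mask sample correlation therefore equals ρ
exactly, so colocalization recovery tests isolate the cytofluorogram
computation rather than sampling error.

Multi-cell fields place cells by rejection sampling with non-overlapping
bodies, a configurable minimum gap, and a margin that keeps the whole
structure — filopodia included — inside the frame; placement failure is
an explicit error, never a silent overlap.

## Segmentation and the cortical partition

Cells are thresholded with Otsu's method on the intensity range rescaled
to [0, 1] (parameter-free and invariant to global gain; a fixed
threshold can be configured). Thin protrusions are removed from the body
mask by a morphological opening of radius 0.5 µm; the opened mask is
then dilated by the same brush and intersected with the original mask,
which restores the jagged boundary pixels the opening shaved off the
body itself — without this reconstruction the band partition is biased
inward by up to a pixel, which measurably attenuates the asymmetry
statistic. The nucleus is detected photometrically (it is devoid of
signal): interior holes of the thresholded mask are merged with interior
regions darker than half the in-cell median, keeping regions of at least
2 µm². Cells touching the border are flagged and excluded by default
(their partition would be truncated), as are cells whose mean intensity
is below background mean + 3 SD — the operational form of "not
expressing the transgene".

The cortical band is defined on the *filled* body (nucleus filled in, so
it creates no internal boundary) as the pixels within `bandWidthUm` of
the cell boundary, using the exact Euclidean distance transform. One
numerical subtlety: the transform measures distances to the nearest
*background pixel center*, which overestimates the distance to the
continuous boundary by 0–0.5 px depending on sub-pixel boundary position
and direction; the mean offset for an isotropic boundary is close to a
quarter pixel. The band threshold therefore includes a +0.25 px
correction, calibrated against the analytic annulus of ideal disks
across radii and pixel sizes (unbiased to about 1%; without it the band
is ~7% too thin at 0.212 µm pixels). Band, cytoplasm and nucleus
partition the filled body exactly; cells thinner than twice the band are
flagged unmeasurable rather than returning an empty cytoplasm.

A known limitation of threshold segmentation: under strong polarity with
no net enrichment (A ≥ ~0.5 at E = 1) the dark limb of the band falls
below the Otsu threshold and is clipped from the mask. The closed-form
asymmetry validation therefore runs on generator-truth masks
(`truthCellRecord()` / `truthPartition()`), isolating the statistic from
the thresholding stage.

## Cortical metrics

The cortex:cytoplasm ratio is the mean band intensity divided by the
mean cytoplasm intensity — gain-invariant by construction. The asymmetry
statistic assigns band pixels to 360 angular bins about the centroid and
reports the SD across bin means. Binning (rather than an SD over raw
band pixels) matches plotting intensity versus peripheral position and
decouples the statistic from band thickness; the raw-pixel mode is
available as a config option since the original reduction is not
specified. By default the SD is reported on raw intensities, with a
normalized mode (÷ cytoplasm mean) for comparisons across cells of
different expression level. Empty bins (strongly concave outlines) are
excluded from the SD and flagged when they exceed 25% of bins. For a
band M (1 + A cos(θ − θ₀)) the statistic recovers M·A/√2 to well within
3% at 360 bins.

## Filopodium detection

Rays are cast from the centroid (or, for pathological concave shapes,
the pole of inaccessibility) every 1°, sampled bilinearly at 0.5 px
steps from the body boundary outward to 15 µm, truncating where the ray
enters a neighboring cell. Background statistics come from pixels at
least 3 µm outside every body. A ray's candidate tip is its outermost
local maximum above background mean + 4 SD that is *rooted*: at least
half of the samples between the boundary and the peak must exceed
background mean + 2 SD. Rootedness encodes the biology — a filopodium
tip is connected to the cell by its shaft — and rejects both isolated
noise spikes in the background and peaks reached by skipping over empty
space. Candidates then pass angular non-maximum suppression (a candidate
with a brighter candidate within the 5° merge angle is a flank of that
peak, not a separate tip), and survivors are chain-clustered when both
their angular gap is within the merge angle and their radial positions
agree within 1 µm; each cluster reports its brightest candidate, with
sub-pixel position from a quadratic fit around the 1-D ray peak. With
two filopodia 10° apart, a 5° merge angle reports two tips and a 15°
merge angle one — the merge angle is the resolution limit the user
chooses. Tips are registered to the cell with the nearest boundary
(ties to the smaller cell id, deterministically) and dropped when
farther than the search length from every cell. On 200 synthetic cells
with 0–6 filopodia at default geometry, detected counts match truth
exactly in ≥ 95% of cells (in practice ~100%).

## Colocalization and linescans

Cytofluorograms pair all in-mask pixels of two aligned channels —
typically the union of cell masks of a field — and report Pearson r;
thresholded Manders/Costes variants are intentionally not implemented.
Linescans sample bilinearly at 1 px spacing with optional perpendicular
averaging; axis-aligned width-1 scans return raster values exactly. The
longest-axis profile takes the principal axis of the mask's
pixel-coordinate covariance through the centroid, clipped to the mask
extent plus a margin; near-circular cells (axis ratio < 1.05) are
flagged, any diameter then being equivalent.

Profiles are normalized to [0, 1] and averaged by pooling all points and
fitting a restricted cubic spline: the natural cubic basis
(`splines::ns`), linear beyond the boundary knots, with 5 knots at the
{5, 27.5, 50, 72.5, 95} percentiles of pooled positions — a standard
placement; the knot count and grid are configurable since no canonical
rule exists. The mean curve is the fitted spline evaluated on a common
100-point grid; SD and SEM bands come from the individual profiles
interpolated to the grid (SEM = SD/√n pointwise, exactly), matching the
shaded-band semantics of averaged-extension plots. A least-squares
spline can overshoot near the boundary knots by a fraction of the noise
amplitude, so the mean curve is clamped to the pointwise envelope of the
input profiles. On 10 sigmoidal profiles with noise SD 0.05 the fitted
mean recovers the generating curve with RMSE < 0.03.

## Statistics

ROUT-style outlier exclusion is implemented as the published method
reduced to the constant-model case, the applicable special case for a
univariate metric: robust location = median; robust scale
RSDR = 68.27th percentile of absolute residuals × N/(N−1) (one fitted
parameter); per-point two-sided p-values from t(N−1); and a
Benjamini–Hochberg step-up at the user's maximum FDR Q (default 0.001 —
"definite outliers" only). The commercial implementation's small-sample
constants are unpublished, so validation is tolerance-based: on clean
normal samples of n = 1000 the filter flags ≤ 0.5% of points on average,
while a +50σ contaminant is caught in ≥ 99% of replicates. Samples of
fewer than 10 points are returned unfiltered with a warning.

Group comparisons run on cell-level values (the full dataset), not on
experiment means; per-experiment means are computed for superplot-style
reporting only, and both the unweighted grand mean of experiment means
and the pooled mean are reported because they differ under unequal
per-experiment n. One-way ANOVA uses `stats::aov` with Tukey HSD over
all pairs or Dunnett comparisons against a named control
(`multcomp::glht`); the two-group case reduces exactly to the pooled
t-test (F = t²). Significance codes use the conventional cutpoints
0.05/0.01/0.001/0.0001, config-exposed. Condition summary tables report
the percentage of cells with at least one filopodium, the mean count ±
SEM among positive cells only (0 with n_positive = 0 when no cell has
any), and the cortex:cytoplasm ratio ± SEM after ROUT filtering applied
to the ratio only.

## Problem sizes and determinism

The validation suite uses 30 cells per condition for noisy ratio
recovery, 200 cells for filopodium counting, 100 seeds × n = 1000 for
outlier-filter specificity, 2000 simulated datasets for the ANOVA null
calibration, and 50 random blob masks checked against an exhaustive
O(foreground × background) distance oracle — sizes at which the Monte
Carlo error is comfortably below every tolerance while the whole suite
runs in about a minute. Every stochastic step is seeded; the pipeline
derives per-cell seeds from one master seed, so reruns with the same
configuration reproduce identical output bytes.

## Known limitations

- Threshold segmentation assumes the tagged protein fills the cytoplasm;
  membrane-only markers or strongly polarized, unenriched signals break
  the mask (see above).
- Touching cells are not split (synthetic fields are generated
  non-overlapping; real touching cells should be excluded upstream).
- The maximum of several noisy z-sections is a biased estimator of the
  underlying intensity; with the default noise model this depresses the
  measured ratio of a 20%-enriched cell by about 0.015. Ratios are
  therefore compared between conditions measured identically, not read
  as absolute enrichment.
- Filopodium detection assumes roughly radial protrusions with a
  tip-enriched signal; strongly curved or tangential protrusions and
  tip-less markers are out of scope, as are lengths/curvature (only
  counts are summarized).
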