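---
title: "Quantifying choriocapillaris flow deficits from en-face OCTA slabs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choriocapillaris flow deficits from en-face OCTA slabs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfd)
```

## The measurement problem

The choriocapillaris (CC) is the dense capillary monolayer directly under
the retinal pigment epithelium (RPE). On swept-source OCT angiography
(OCTA), a thin en-face slab through the CC shows a granular decorrelation
texture; regions where the flow signal drops below its local surroundings
are read as *flow deficits* (FDs) — candidate areas of hypoperfusion.
Because CC capillaries are at or below the lateral resolution of the
instrument, FD analysis is performed on the binarized en-face image rather
than on individual vessels, and four biomarkers summarize each eye:

* **FD%** — deficit pixels as a percentage of the imaged field,
* **FD count** — number of connected deficit components,
* **mean FD size** (µm²),
* **total FD area** (mm²).

Two artifacts make this measurement fragile. First, anything that
attenuates the OCT beam above the CC — chiefly the RPE — darkens the flow
slab without any real perfusion change ("shadowing"). Second, a global
threshold cannot follow the slowly varying illumination of the slab, so a
*local* threshold is required. This package implements the processing
chain that has become standard for CC quantification: multiplicative
shadow compensation, followed by Phansalkar local adaptive thresholding
at window radii of 4 and 8 pixels, followed by connected-component
analysis on a calibrated physical geometry.

## Shadow compensation

Let $F$ be the flow slab and $S$ the co-registered structure slab, both
single-channel rasters on the same grid. The compensated image is

$$ C = F \times G_\sigma\!\big((2^{b}-1) - S\big), $$

i.e. the structure slab is inverted, smoothed with a Gaussian of standard
deviation $\sigma$ (default 2 px), and multiplied pixelwise into the flow
slab. Where an overlying opacity attenuates both slabs by a factor $a$,
the inverted structure is bright, and the product restores the flow
signal. The product is computed in floating precision; by default it is
then rescaled affinely so that its minimum maps to 0 and its maximum to
full scale (`output_rescale = "linear_to_full_range"`) before
quantization by round-half-up. The alternative `"none"` mode clips the
raw product at full scale, emulating a saturating integer multiply, and
is provided for comparisons with pipelines that work that way; the two
modes produce different absolute intensity scales but the local
threshold adapts to either. A constant product (e.g. a uniformly bright
structure slab whose inverse is zero) rescales to an all-zero image.

Smoothing uses a separable kernel truncated at $\lceil 3\sigma \rceil$
taps per side and renormalized, with borders handled by edge
replication; the same border rule is used by the thresholding stage so
the two stages see consistent boundary behaviour.

## Phansalkar thresholding

For each pixel, with $\mu$ and $\sigma$ the mean and *population*
standard deviation of the normalized intensities (divided by
$2^{b}-1$) in the window of radius $R$ centred there:

$$ t = \mu \left( 1 + p\,e^{-q\mu} + k\left(\frac{\sigma}{r} - 1\right) \right), $$

and the pixel is a deficit when its normalized intensity is *strictly*
below $t$. Defaults are the published constants $k = 0.25$, $r = 0.5$,
$p = 2$, $q = 10$. The exponential term raises the threshold in dark
regions, which is what distinguishes Phansalkar's rule from
Niblack/Sauvola and makes it usable on low-contrast capillary images.
Choices the formula leaves open are fixed as follows:

* **Window shape**: circular (centre distance $\le R$), matching
  rank-filter neighbourhoods; a square window is available and is what
  the brute-force oracle in the test suite uses for cross-checks.
* **Tie rule**: strict inequality, so an all-zero image yields *no*
  deficits ($0 < 0$ is false). Documented because printed descriptions
  of the method are silent on ties.
* **Borders**: edge replication; every window therefore has the same
  pixel count, and the local statistics at the border are those of the
  replicated contents.
* **Variance**: population (divisor $n$), not sample.

Both radii 4 and 8 px are computed by default — at the default 12 µm
pitch these are 48 µm and 96 µm neighbourhoods — because reported CC
metrics differ materially between the two and sensible practice is to
report both.

## Component metrics

Deficit pixels are grouped into maximal connected components, by default
under 8-connectivity (diagonally touching black pixels are "contiguous";
4-connectivity is available for sensitivity analysis). Components
touching the image border count like any other, and no minimum-size
filter is applied by default (`min_size_px = 0`); the knob exists
because some CC pipelines drop deficits smaller than the normal
intercapillary distance. Areas use the physical pixel area from the scan
geometry: a 6 × 6 mm field on a 500 × 500 grid gives 144 µm² per pixel,
so `fd_total_area_mm2 = fd_percent / 100 × 36` by construction — an
identity the test suite also checks against a published reference
summary table shipped in `inst/extdata/` (two of whose three arms
satisfy it to print precision; the third does not as printed and is not
used as an anchor).

The grid size deserves emphasis: devices export en-face slabs at
different resolutions, and a "radius 4 px" window is a different
physical neighbourhood on each. The geometry is therefore an explicit,
mandatory parameter (`scan_geometry()`), with the 500 × 500 / 6 mm
default documented rather than assumed.

## The synthetic generator

`generate_pair()` produces flow/structure pairs with a known ground-truth
deficit mask, so every stage is testable without patient data. It
emulates exactly the features the chain relies on, no more:

* **Background texture**: a Gaussian random field smoothed to a 3 px
  correlation length, mapped to mean 0.78 and SD 0.045 of full scale —
  a bright, granular background that the local threshold should classify
  as flow.
* **Deficits**: filled ellipses with lognormal areas (default mean
  150 px, SD 300 px — a heavy right tail, as real FD size distributions
  have), stamped at intensity 0.05 of full scale until the planted
  fraction is within 0.01 of target; the last blob is capped so the
  target is never overshot. An unreachable target marks the truth mask
  with a `target_unreached` attribute.
* **Shadows**: band-shaped multiplicative attenuation applied to *both*
  slabs, with an 8-row raised-cosine penumbra. The structure base level
  is $1/(1+a) = 2/3$ of full scale so that the default attenuation
  $a = 0.5$ is *exactly* cancelled by invert-and-multiply compensation:
  inverting $s$ and $as$ gives multipliers in ratio
  $(1 - as)/(1 - s) = 1/a$ precisely when $s = 1/(1+a)$. This makes the
  compensation benefit analytically expectable rather than an empirical
  accident of the generator.
* **Noise**: additive Gaussian, SD 2 intensity units (8-bit scale),
  applied after shadowing — so shadowed regions have proportionally
  worse signal-to-noise, as in real scans.

All randomness flows from the single `seed` through a private RNG stream
that neither reads nor perturbs the caller's RNG state; identical specs
give bit-identical triplets.

What the generator does *not* model: OCTA speckle statistics,
projection artifacts, motion, vessel-shaped (rather than elliptical)
deficits, and spatially varying texture. Passing recovery tests
therefore shows the chain is correct and self-consistent under the
stated image model — not that its absolute numbers transfer to any
particular instrument.

### A texture floor worth knowing about

On a deficit-free, noise-free synthetic field the pipeline still reports
a small nonzero FD%: about 1% at radius 4 but about 7% at radius 8.
The mechanism is instructive. With no dark blobs anywhere, the
full-range rescale stretches the pure background field across the whole
intensity range, roughly doubling the relative local standard deviation
and pulling the local mean toward mid-scale, where the $p\,e^{-q\mu}$
term is no longer negligible; the radius-8 window additionally sees
nearly the full texture variance. As soon as genuine deficits exist the
rescale is anchored by them and the floor disappears — recovery error
at planted fractions of 10–40% is under 1 percentage point. The test
suite records the floor at both radii rather than hiding it.

## Cohort statistics

`compare_groups()` reproduces the group-comparison layer: a
Kruskal–Wallis omnibus test per metric and radius when three arms are
present, plus Mann–Whitney and Welch *t* rows for every pair.
Conventions:

* All-tied data make the Kruskal–Wallis tie correction degenerate
  (0/0); the statistic is defined as $H = 0$, $p = 1$ there, which is
  the information-free answer.
* Mann–Whitney uses an exact two-sided p when the combined sample size
  is at most 12 with no ties (enumeration is cheap and exact), else the
  tie-corrected normal approximation with continuity correction.
* Welch's *t* with zero variance in both groups returns $p = 1$ for
  equal means and is an error for unequal means (the statistic is
  undefined); inside a batch comparison table such degenerate pairs
  become `NA` rows rather than aborting the run.
* Raw p-values are reported with no multiplicity correction, matching
  common reporting practice for these biomarkers.
* Both eyes of a subject are treated as independent observations. This
  mirrors how such cohorts are usually analyzed but understates the
  true standard errors (inter-eye correlation is substantial); a
  mixed-effects extension is deliberately out of scope.

`fd_regression()` is an ordinary least-squares screen of a metric on
age, treatment duration, daily dose (mg/kg) and cumulative dose (g),
with an explicit singularity error naming collinear columns.

## Problem sizes and determinism

The validation suite runs the full 500 × 500 default geometry for
single-eye recovery and compensation-benefit experiments (10 seeds per
condition) and a reduced 250 × 250 grid for the 18-eye three-arm cohort
reproduction, sizes chosen to exercise the default conditions while
keeping the suite quick to run routinely. Every pipeline stage is
deterministic; end-to-end runs on identical inputs produce byte-identical
report CSVs, and the optional `keep_intermediates` audit trail exposes
the compensated image and masks from which every reported number can be
re-derived by hand.

## Known limitations

* The pipeline consumes exported en-face slabs; slab segmentation,
  signal-strength screening and device-file parsing are out of scope.
* Compensation assumes shadowing is multiplicative and visible in the
  structure slab; it cannot correct signal loss the structure slab does
  not witness, and over-bright structure regions can overcorrect.
* FD metrics are sensitive to every parameter of the chain (σ, the
  Phansalkar constants, radius, connectivity, rescale mode); reports
  embed the full parameter set in their header for exactly this reason,
  and numbers should only be compared across runs that share it.
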