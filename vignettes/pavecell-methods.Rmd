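---
title: "Methods: outline morphometrics and phylogenetic signal for pavement cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outline morphometrics and phylogenetic signal for pavement cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pavecell` implements a comparative pipeline for leaf pavement-cell shape:
outline ingestion, traditional shape descriptors, elliptic Fourier
analysis, dataset-level statistics, and phylogenetic-signal testing. This
vignette records the models, the parameter choices that matter, and the
limits of what the shipped synthetic data can demonstrate.

## Outlines and their canonical form

An outline is an ordered closed polygon in micrometres. On construction it
is canonicalized — explicit closure removed, consecutive duplicates
dropped, orientation corrected to counter-clockwise by the signed-area
test — and rejected if self-crossing (a segment-intersection scan with a
bounding-box prefilter; polygons that merely *touch* at a vertex, as crack
contours of pinched pixel components legitimately do, are accepted).
Input orientation is auto-corrected rather than rejected because hand
tracings arrive in either direction.

Masks are traced along pixel *edges* (the crack contour), not through
pixel centres, so a k × k pixel square yields area exactly k² px². This
convention is unbiased for small objects, where centre-interpolating
contours (marching squares) shave corners. Components are 4-connected;
at corners where a component touches itself diagonally the trace prefers
the turn towards the interior, which keeps the outer boundary a single
loop. Components touching the image border are extracted but flagged, and
excluded from summaries by default: their shape is censored by the frame.
The default speckle threshold (`min_area = 50` px²) suppresses stray
foreground pixels that manual tracing never produces but automated
binarization does.

All measurement happens after resampling to 300 equally spaced (in arc
length) vertices. Hand-traced outlines have wildly uneven vertex density;
fixed density removes that nuisance from every descriptor and makes
Fourier coefficients comparable across cells. 300 points resolve the
deepest lobes the generator produces while keeping the O(n²) simplicity
scan cheap.

## Descriptors

* Area and perimeter: shoelace formula and summed chord lengths.
* Aspect ratio: extents along/across the principal axis of the vertex
  covariance of the *resampled* outline. The covariance definition (not
  the maximum Feret chord) is the default because a 2 × 1 rectangle must
  give AR = 0.5; the Feret chord measures the diagonal and violates that.
  The Feret variant remains available (`method = "feret"`). Eigenvalue
  ties (isotropic shapes) resolve deterministically to angle 0 and are
  flagged.
* Solidity: polygon area over convex-hull area. Note the known
  conflation: a curved, banana-shaped cell with a smooth margin also has
  low solidity. No correction is applied; the descriptor is reported as
  defined.
* Circularity: P²/(4πA), ≥ 1 with equality only for a circle at infinite
  sampling density.
* Quartile classes split a descriptor at its dataset quartiles (type-7
  linear-interpolation quantiles — the ubiquitous default). Intervals are
  right-closed so boundary ties fall in the lower class.

## Elliptic Fourier analysis

The forward transform uses the closed-form Kuhl–Giardina sums over the
chord-length parameterization of the resampled polygon. Outlines are
pre-aligned along their *longest radius* — the vertex farthest from the
centroid is rotated onto the positive x-axis — which is the literal
reading of radius-based alignment; the covariance-axis alternative is one
flag away. The default harmonic count is 20; `select_harmonics()` finds
the smallest count whose cumulative power passes a threshold (0.999 by
default) when a data-driven choice is wanted.

Normalization follows the first-harmonic ellipse: the starting point is
rotated to the end of its semi-major axis, the coefficient frame onto
that axis, and everything is divided by its magnitude (size by
first-harmonic magnitude; the a₁ = 1, b₁ = c₁ = 0 canonical form). Two
technical choices deserve note:

* The construction has a half-period ambiguity (either end of the major
  axis can start the ellipse); the two candidates differ by sign flips on
  even harmonics. A deterministic rule — take the candidate whose first
  coefficient differing beyond numerical noise is larger — makes
  normalization exactly invariant to input rotation, starting vertex and
  scale (tested to 1e-6). Reflection is deliberately *not* quotiented
  away.
* Under chord-length parameterization an ellipse is **not** a pure first
  harmonic: constant-speed traversal of a 2:1 ellipse puts ≈ 0.6% of its
  power into harmonic 3 (the package's transform matches an independent
  FFT oracle to machine precision on this). Consequently N-harmonic
  truncation error scales as the square root of the residual power
  fraction — about 1.7% of the mean radius for a 1.15:1 ellipse at N = 2 —
  and statements like "an ellipse is harmonic 1 alone" hold only
  asymptotically as the shape approaches a circle. Likewise a k-lobed
  radial perturbation concentrates power at harmonics k − 1 and k + 1
  (the sin(kθ)·cos(θ) products), not at k.

The pipeline still reports the descriptor-based morphospace as primary:
on a factorial grid varying lobe amplitude and aspect ratio
independently, normalized-coefficient distances rank-correlate strongly
with aspect-ratio differences (≈ 0.87) but weakly with solidity
differences (≈ 0.18). EFA is a good base-shape summary and a poor
undulation summary — which is exactly why solidity exists in this
pipeline.

## Dataset statistics

PCA standardizes each descriptor to unit variance by default: area is in
µm² while the other three are dimensionless, and an unstandardized PCA is
dominated by area variance (the unstandardized variant is kept behind a
flag, and both are reported by the acceptance script). Dataset-level
medians and ranges are computed over side-pooled *species means*, with an
all-cells variant available; species-level rows are the natural unit for
a comparative dataset in which sampling per species is standardized.

Spearman's ρ uses average ranks under ties, with the two-sided p-value
from the t-approximation (t = ρ√((n−2)/(1−ρ²)), n − 2 df). The
small-sample Edgeworth-series refinement of the classical algorithm is
not implemented; for the n ≥ 30 species subsets analysed here the two
agree to well within the decision threshold, and the t form is the one
stated alongside the statistic throughout.

Per-species aggregation caps each leaf side at 30 cells (the study
design's sampling depth) by a seeded subsample (default seed 20181003)
when more are supplied. The adaxial–abaxial solidity difference is
defined only for species measured on both sides; the dataset-level
summary reports the count and fraction of species whose abaxial surface
is the more undulate one.

## Phylogenetic signal

Trees are consumed, never inferred. Proximity weights are inverse
patristic distances, row-normalized — the common default of
phylogenetic-autocorrelation software; results are comparable only
within one weighting method, so the method is recorded in the result's
metadata. Local Moran's I is

I_i = (z_i / m₂) · Σ_j w_ij z_j,  z_i = x_i − x̄,  m₂ = Σ z²/n,

with conditional-permutation p-values: tip i's value is held fixed while
the others are shuffled, 999 permutations by default, and
p = (1 + #{perm ≥ obs}) / (1 + n_perm), which can never be exactly zero.
The hotspot test is one-sided for positive autocorrelation by default
(matching the hotspot question); a two-sided variant exists. Counting is
tie-tolerant (≥ obs − 1e-9): on ultrametric trees many permuted lags tie
with the observed statistic *exactly*, and naive floating-point
comparison silently drops ties, biasing p low — this was caught by an
exhaustive-enumeration oracle at n = 6 and is covered by a regression
test. Raw and Benjamini–Hochberg-adjusted p-values are both reported,
since hotspot counts are sensitive to that choice. Under row-normalized
weights the mean of the local statistics equals global I (checked
internally); global significance uses total randomization, with
E[I] = −1/(n − 1) as the calibration anchor.

Brownian trait simulation (root-to-tip accumulation of normal increments,
variance σ²·branch length) provides the positive control; iid traits the
negative one. On 50–60-tip Yule trees the hotspot type-I rate sits at the
nominal 0.05 and Brownian/clade-structured traits raise the hotspot
fraction by well over 0.15.

## The synthetic generator: what it emulates, and what it does not

`make_lobed_cell()` is a radial-perturbation model:
r(θ) = 1 + amp·sin(kθ + φ) on an ellipse, plus optional multiplicative
radial jitter. It spans solidity from 1 down to ≈ 0.58 (at amp = 0.4,
k = 12) with analytic control, which covers the bulk of real epidermides
but not the most extreme jigsaw cells; true interdigitation of
neighbouring cells, space-filling tessellation and mechanical models of
lobe formation are out of scope. Because the perturbation is radial, the
polygon is star-shaped and always simple.

The species dataset draws per-species solidity and aspect-ratio targets
from clade-level Beta distributions (the natural family on (0, 1)),
chooses a lobe count k ∈ 5:12 whose calibration range covers the solidity
target, and inverts a cached, numerically precomputed amp → solidity
curve (strictly decreasing per k; solidity is affine-invariant, so the
curve needs no aspect-ratio stratification). Cell-level variation enters
through 1% radial jitter and per-cell amplitude noise (sd 0.02); abaxial
cells get a +0.05 amplitude offset, reproducing the tendency of lower
leaf surfaces to be more undulate. Leaf aspect ratio follows the cell
target with log-normal noise in the fern and monocot clades and is drawn
independently for eudicots, mirroring the observation that cell and leaf
anisotropy are coupled in some lineages and not in others. The shipped
specification (`inst/extdata/default_clades.csv`) — 30 species each of
fern (S̄ 0.68, AR̄ 0.60), monocot (S̄ 0.88, AR̄ 0.35) and eudicot (S̄ 0.78,
AR̄ 0.65) — reproduces the qualitative ordering seen in real epidermides
(ferns most undulate, monocots least and most elongate). These are
synthetic choices, not estimates from any real dataset.

What passing tests on these data do and do not show: they validate the
measurement chain (tracing, resampling, descriptors, EFA), the statistics
and the signal tests against controlled ground truth; they cannot
validate robustness to segmentation artefacts, staining noise, curved
banana-shaped cells, or genuinely interdigitating margins, none of which
the generator produces.

Clade-mapped validation trees grow one unit-height Yule subtree per clade
(clade crowns at depth 0.5) on a pectinate backbone, so clade-structured
traits are phylogenetically clustered by construction.

## Numerical choices and problem sizes

All randomness flows from a single seed through named substreams
(simulation, subsampling, permutations); identical configuration and seed
reproduce byte-identical outputs. Degenerate inputs fail loudly and
early: zero-area or self-crossing polygons, constant traits, constant
descriptor columns under standardization, tips at zero patristic
distance, species missing from metadata. Per-outline measurement failures
inside a batch are logged and skipped without aborting the run.

The shipped study design used throughout the tests and the acceptance
script is 90 species × 2 sides × 30 cells of 300 vertices each
(≈ 5,400 outlines), Moran calibration on 50–60-tip trees with 999
permutations across 100–500 seed replicates, and raster round trips at
≥ 200 px cell diameter. On a single core the acceptance script completes
in a few minutes.

## Known limitations

* Solidity conflates margin undulation with global curvature of the cell
  body; no curvature correction is applied.
* The lobed-cell model cannot reach solidity below ≈ 0.58, so the most
  extreme jigsaw phenotypes are unrepresented in synthetic datasets.
* The Spearman p-value uses the t-approximation in all regimes.
* EFA reconstruction and power claims are tied to the chord-length
  parameterization; alternative parameterizations (e.g. equal-angle) give
  different harmonic decompositions of the same curve.
* Hotspot counts depend on the proximity method, permutation count and α;
  they are comparable only within one configuration, which is why the
  result objects carry their configuration as metadata.
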