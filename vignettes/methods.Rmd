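---
title: "Quantifying macular perfusion and lens opacity: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macular perfusion and lens opacity: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octalens)
```

## What the package computes

`octalens` implements a three-stage quantitative analysis of the effect of
cataract surgery on retinal blood flow:

1. **OCTA perfusion quantification.** En-face OCT-angiography images of the
   macula (bright vessels on a dark background, one image per retinal
   plexus — SVP, ICP, DCP) are reduced to nine scalar metrics.
2. **AS-OCT lens opacimetry.** Anterior-segment OCT B-scans of the
   crystalline lens are segmented and the mean pixel intensity (0–255,
   "pixel intensity units", PIU) of the lens and of its nucleus is
   measured, averaged over a radial series of 15 scans.
3. **Cohort statistics.** Per-eye longitudinal tables (four timepoints:
   preoperative T0, then T1–T3 after surgery) are analysed with one-way
   within-subject ANOVA (Mauchly sphericity check, Greenhouse–Geisser
   correction) and a Pearson correlation screen of metric changes against
   lens opacity, nuclear opacity, cumulative dissipated energy (CDE),
   intraocular-pressure change, phacoemulsification time and fluid volume.

Because no raw clinical images accompany this kind of study, the package
carries first-class synthetic-data generators with analytically known
ground truth; every stage is validated against them.

## The OCTA quantification model

The chain is: multiscale Hessian (Frangi-type) vesselness → Otsu threshold
on the vesselness response → strict binarization (`value > threshold`) →
small-hole filling → perimeter extraction and homotopic thinning → branch
decomposition → metrics.

With $A(x,y)$ the binary vessel map, $S(x,y)$ its skeleton, $P(x,y)$ the
perimeter map and $n$ the pixel count of the image:

* **VAD** $= \sum A / n$ — vessel area density;
* **VDI** $= \sum A / \sum S$ — vessel diameter index (area per unit
  skeleton length);
* **VPI** $= \sum P / \sum A$ — vessel perimeter index;
* **BVT** $= \frac1m \sum_{i=1}^m \mathrm{geodesic}_i /
  \mathrm{euclidean}_i$ over the $m$ non-loop skeleton branches — blood
  vessel tortuosity;
* **VCI** $= (\sum P)^2 / (4\pi \sum A)$ — vessel complexity index;
* **BP**, **EP** — branchpoint and endpoint counts of the skeleton
  (degree ≥ 3 with adjacent branchpoint pixels merged into one node;
  degree 1);
* **TVL** $= \sum S$ — total vessel length as a *pixel count*;
* **AVL** $=$ TVL / number of branches.

The first three and VCI are exact integer-count ratios; the package's test
suite asserts the identities $\mathrm{VAD}\cdot n = \sum A$,
$\mathrm{VDI}\cdot \mathrm{TVL} = \sum A$ and
$\mathrm{VPI}\cdot\sum A = \sum P$ to $10^{-9}$.

### Two length conventions, deliberately

TVL counts skeleton pixels, which keeps VDI's identity exact. Branch
*geodesic* lengths instead weight diagonal steps by $\sqrt2$, which is what
makes tortuosity hit closed forms (an L-shaped path of ten orthogonal steps
right and ten down has BVT $= 20/(10\sqrt2)$). Both definitions are exposed
side by side and never mixed.

A consequence worth knowing: the pixel count of an 8-connected digital line
of Euclidean length $L$ at angle $\theta$ is $\approx L\max(|\cos\theta|,
|\sin\theta|)$, which averages $\approx 0.90$ over uniformly distributed
orientations. TVL therefore systematically *underestimates* the true
centerline arc length by on the order of 10–14% for isotropic vascular
networks (we measure a mean ratio of about 0.88 on the default synthetic
trees). This is a property of the pixel-count definition, not an
implementation defect; comparisons of TVL across images of the same
geometry are unaffected. The corresponding recovery check in the acceptance
suite asserts a 10% band against the continuous arc length and is
accordingly expected to sit just outside it — we keep the check honest
rather than redefining TVL.

### Filter parameters

The vesselness filter uses Gaussian scales $\{1,2,3,4\}$ px, shape
sensitivity $\beta = 0.5$, and a contrast constant set adaptively per scale
to half the maximum Hessian norm; all are exposed in `quant_config()`.
These are conventional choices — the analysis they reproduce names the
filter but no constants. Two further cleaning steps address known artefacts
of this chain:

* **Junction hole filling** (`hole_fill_area`, default 10 px): Hessian
  vesselness is suppressed at the centre of bifurcations (the local
  structure is blob-like, not tubular), which can punch a 1–10 px hole into
  a junction after thresholding; the skeleton then forms a spurious loop
  and two extra branchpoints. Enclosed background pockets up to the
  configured size are therefore filled. Genuine intercapillary spaces are
  orders of magnitude larger and untouched.
* **Spur pruning** (`min_branch_length`, default 0 = off): homotopic
  thinning occasionally emits 1–3 px spurs near junctions and corners. The
  package default leaves pruning off (the reproduced pipeline is silent on
  it); the validation experiments in the test suite and acceptance script
  run with `min_branch_length = 6`, which removes thinning spurs without
  touching the shortest real branches (≥ 10 px by generator construction).

Thinning itself deletes only *simple points* (pixels whose removal provably
preserves the number of 8-connected foreground and 4-connected background
components, decided by a precomputed 256-entry lookup table) in four
directional sub-iterations, never removes branch tips, and runs to
convergence; single-pixel-wideness and component preservation are asserted
property-style in the tests.

## The synthetic OCTA scene

`generate_vascular_tree()` grows binary trees of tubular branches:
per-level length and width decay, a configurable bifurcation angle, and
sinusoidal normal-direction perturbation (zero at branch endpoints) for
tortuosity. The recorded truth — branch polylines, stroke widths, node
degrees, branchpoint/endpoint counts, total arc length — is exact by
construction. `render_octa_image()` rasterizes anti-aliased strokes whose
coverage thresholded at 0.5 is exactly the set of pixels within half a
stroke width of a centerline, so pixel-count ground truth is well defined;
speckle is multiplicative noise plus additive background noise, a
deliberately simple stand-in that mimics the grain of OCT angiograms
without claiming physical fidelity.

Scene-design constraints keep the scene *resolvable by the analysis*: trees
live in disjoint grid cells, non-incident branches keep a clearance of 8 px
beyond their half-widths, sibling branches may not fold back onto each
other (turn clamp 1.2 rad), and no branch shorter than `max(10, 3·width)`
px is placed. Under these conditions the full pipeline recovers BP and EP
*exactly* on the default trees — which is what makes the topology recovery
a meaningful end-to-end test. Default sizes (canvas 256 px, trunk 48 px,
depth 3, two trees, widths 3 → 2) give scenes whose vessel calibre relative
to the field of view resembles a 3 × 3 mm macular scan at this sampling.
What the generator does **not** emulate: the foveal avascular zone,
capillary meshes with real loops, projection artefacts, or
device-specific noise statistics — so passing these tests says the
*computation* is right, not that the metrics are clinically validated.

Controlled sweeps use two utilities rather than re-drawing scenes:
`merge_trees()` adds whole trees onto a shared canvas one cell at a time
(density can only add area, so VAD must rise), and
`scale_tree_tortuosity()` rescales every branch's normal displacement on a
fixed geometry (tortuosity rises with nothing else changing).

## Lens opacimetry

Each B-scan is thresholded (Otsu by default; a fixed threshold can be
configured), and per column the first and last foreground rows are taken as
the anterior and posterior lens surface samples. Both surfaces are fitted
with 4th-order polynomials; *substantially deviating* samples — absolute
residual above `deviation_k` (default 3) times the robust scale
$1.4826\cdot\mathrm{median}|r|$ — are **replaced by their fitted value**
(keeping full column coverage, matching a "correct the deviating points"
workflow rather than discarding them) and the curve refit, with the
deviating set re-judged against the original samples each round so a point
can be re-admitted; once the set stabilises the replacement fixed point
equals least squares on the undisturbed samples. With clean data the fit is
exact to numerical precision; with 10% gross outliers the curve is still
recovered to under half a pixel (asserted in the acceptance suite).

The lens mask is the strict between-surfaces region over the columns where
both surfaces were detected (no extrapolation of the quartic beyond data).
Whole-lens opacity is the arithmetic mean intensity under the mask; nuclear
opacity is the mean inside an ellipse centred at the mask centroid with
semi-axes 25% of the lens lateral extent and 30% of its central thickness
(the explicit stand-in for a manually adjusted clinical ROI; both fractions
configurable). A radial series (15 scans by default) is averaged
arithmetically with no inter-scan normalisation — intensity variation
between scans is handled purely by averaging, and per-scan values are kept
for audit. An unsegmentable scan fails the whole series with its index
named, mirroring a repeat-the-examination rule.

CDE is the product `average phaco power (%) × phaco time (s)`.

## Cohort statistics

`rm_anova()` implements the one-way within-subject decomposition directly
($F = MS_{time}/MS_{error}$ with $(k-1)$ and $(n-1)(k-1)$ df); the test
suite cross-checks it against `stats::aov` with an `Error(subject/time)`
stratum. Mauchly's $W$ comes from the eigenvalues of the orthonormal
contrast covariance with the standard first-order chi-square approximation
(the $W$ statistic matches `stats::mauchly.test` to machine precision; the
p-value differs in the third decimal because base R adds a higher-order
series term). When sphericity is rejected at the configured level, the
Greenhouse–Geisser $\hat\varepsilon = (\sum\lambda)^2 / ((k-1)\sum
\lambda^2)$, clamped to $[1/(k-1), 1]$, scales both degrees of freedom —
so corrected p-values are never smaller than uncorrected ones. If the
contrast covariance is singular (integer-valued metrics constant across
timepoints, or too few subjects) sphericity is unassessable and the
uncorrected test is reported with the sphericity field empty.

Shapiro–Wilk normality checks are emitted as diagnostics only and gate
nothing. The correlation screen reports raw Pearson p-values with the
significance flag at $\alpha = 0.05$ (matching how such tables are usually
reported) and a Holm-adjusted column alongside for transparency; the flag
deliberately ignores the adjustment. The change entering the screen is
configurable and defaults to T3 − T0; T1 − T0 is one argument away.

## The synthetic cohort

`generate_cohort()` draws one row per eye. Metric trajectories follow a
jump-then-plateau profile (largest change in the first follow-up week,
little after) whose per-series baselines, spreads and timepoint means are
taken from published magnitudes for the 27 metric × plexus series; IOP
declines over follow-up (16.1 → 13.0 mmHg), and CDE (2.9 ± 1.8 %s), phaco
time (213 ± 118 s), fluid volume (42 ± 13 ml), lens opacity (43.9 ± 6.3
PIU) and nuclear opacity (36.7 ± 13.7 PIU) are drawn from truncated
normals of these magnitudes.

The correlation between nuclear opacity and the metric change is induced by
a bivariate-normal construction,
$$\Delta_i = \delta + \sigma_\Delta\,(r\,z_i^{op} +
\sqrt{1-r^2}\,z_i^{eye}),$$
so the *population* correlation equals the target exactly. Two scale
parameters are kept distinct on purpose: `change_sd_frac` is
$\sigma_\Delta$ (zero makes every eye's change identical — the correlation
is then undefined and the table is flagged), while `noise_sd_frac` is
measurement noise added only to the *intermediate* timepoints, so the
configured follow-up difference carries the exact correlation. The
T0 column receives no separate measurement noise: at a single baseline
visit, measurement error and between-eye spread are statistically
indistinguishable, so the baseline SD absorbs both.

Under a zero-effect profile the empirical type-I error of the
GG-corrected ANOVA at $\alpha = 0.05$ over 1000 simulated 46-eye cohorts
falls within [0.02, 0.09] (asserted in the acceptance suite), and an
injected correlation of 0.5 at $n = 200$ is recovered inside its Fisher-z
95% interval by the full `correlation_screen()` path.

## Numerical choices and degenerate inputs

* Binarization is strictly `value > threshold`; for integer images Otsu
  candidates are the 256 native levels (verified against an exhaustive
  between-class-variance scan), for continuous grids 256 equal-width bins.
* The second-derivative Gaussian kernel is normalised to a zero sum so a
  constant image yields exactly zero vesselness.
* The lens-mask strict inequality uses a $10^{-6}$ px tolerance so fitted
  curves that pass exactly through integer rows behave set-theoretically.
* Branch decomposition resolves ties deterministically (lowest step cost,
  then lowest row, then column, for junction attachments); loops are
  excluded from BVT with their count reported.
* Constant grids (Otsu), empty masks and skeletons, underdetermined fits
  (< 5 samples), crossing surfaces, missing ANOVA cells and constant
  correlation inputs all raise classed errors rather than returning NaN.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script were sized to be thorough yet
quick on a single CPU: the oracle-equivalence sweep covers all 512 3×3
masks exhaustively plus 100,000 random masks up to 6×6; topology recovery
uses 8 default trees; lens recovery uses a 24-scene grid plus 100
(50 in the script) radial-series repeats; the type-I calibration uses 1000
(500 in the script) null cohorts of 46 eyes; the end-to-end study runs 4
eyes at 96 px. All sizes are parameters, and nothing in the package caps
them.

## Known limitations

* Pixel-count TVL underestimates continuous centerline length for oblique
  vessels (see above); AVL inherits this.
* The Frangi chain is tuned for bright-on-dark en-face angiograms; it does
  not handle projection artefacts or signal-strength gradients.
* The speckle models are statistical stand-ins, not physical OCT speckle.
* Mauchly's p uses the first-order chi-square approximation.
* The opacimetry assumes the lens is the dominant bright structure in the
  B-scan; cornea/iris remnants must have been cropped away upstream.
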