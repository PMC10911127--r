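---
title: "Quantifying axis elongation in blastoderm explants: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axis elongation in blastoderm explants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(explantr)
```

## The measurement problem

Zebrafish blastoderm explants are embryonic cell masses cultured without the
yolk cell. Upon local Nodal signaling activation they self-elongate in a way
that mimics embryonic axis extension: mesendodermal progenitors align
mediolaterally, intercalate between medial neighbours, and the tissue narrows
perpendicular to the extension while lengthening along it. BMP signaling,
read out as nuclear phosphorylated Smad5, forms a long-range gradient across
the explant and must stay low in the mesendoderm for elongation to proceed.

`explantr` implements the quantification layer for this system: given
silhouette masks, tracked nuclear point clouds, cell outlines and per-nucleus
intensity tables, it produces the morphometric, dispersal, alignment and
signaling-gradient statistics that characterize the elongation process. A
synthetic-data module generates every input class with known ground truth, so
each stage is testable without microscopy data.

## Clone dispersal

The dispersal statistic measures, per time frame, the mean absolute
separation of each tracked clone cell from all other clone cells, decomposed
along and perpendicular to the extension axis after projection along z
(the imaging axis):

$$D_\parallel(t) = \frac{1}{n}\sum_i \frac{1}{n-1}\sum_{j \ne i}
  \left|\,(\mathbf{x}_i - \mathbf{x}_j)\cdot \hat{\mathbf{u}}(t)\,\right|$$

and analogously for the perpendicular direction. Each series is normalized to
its value at the initial time point; the end value is the dispersal *fold
change*. Averaging per-cell means over cells equals averaging over unordered
pairs, so the wording ambiguity between the two is moot; we compute the
per-cell form and verify the equivalence against a brute-force double loop in
the tests.

The axis is annotated by a stable back anchor and tip anchors placed sparsely
in time (the field convention is every ten frames); the tip is linearly
interpolated between anchors and held constant beyond the last one —
linearity is the minimal assumption between sparse annotations. Single-frame
track gaps are linearly interpolated; tracks with longer gaps, or starting
after the analysis onset, are excluded, mirroring manual track curation.
Normalization "relative to the initial time point" is implemented as a ratio,
since fold changes are the reported quantity.

The generator's flow model is a time-interpolated affine map: offsets from
the clone centroid scale as $s_\parallel^{k/(K-1)}$ axially and
$s_\perp^{k/(K-1)}$ perpendicular at frame $k$ of $K$. Endpoint fold
changes are all the measurements constrain, and the exponential-in-time
interpolation is the simplest flow consistent with them. The wild-type
mesendoderm preset uses $s_\parallel = 2.02$, $s_\perp = 0.88$ over 260 min
(14 frames, 20 min apart); the ectoderm preset 1.12/0.83; early-phase presets
1.2 and 0.99 over 122 min. Because the statistic is translation-invariant and
the axis is exact in the noise-free construction, the pipeline recovers these
factors to machine precision — a construction-consistency check, not a
reproduction of the biological measurement.

The tip-distance correlation statistic ($R^2$ of normalized tip distances at
onset versus end) is exactly 1 only for isotropic flows; under anisotropic
scaling the 2D Euclidean tip distance is not an affine function of its
initial value, and the wild-type preset yields $R^2 \approx 0.995$. The tests
assert both behaviours explicitly.

## Explant morphometrics

**Circularity** is $4\pi A/P^2$ with the area from the pixel count and the
perimeter from a sub-pixel traced boundary polygon: marching squares at the
0.5 level followed by a 5-point circular moving average. The smoothing
removes the half-pixel staircase; a rasterized disk then scores 0.993 and a
400x100 rectangle 0.507 (closed form 0.5027), capping the error well inside
the 2% band the raster representation warrants. Values are clipped at 1.

**Extension classification** operationalizes the visual "clear indentation"
criterion: the boundary's convexity defects are extracted (deepest boundary
point per convex-hull gap), and the explant is called extended when two
defects on distinct hull gaps — the two flanks of a neck — each exceed a
depth threshold (default 15 um from the hull) and a turning threshold
(default 40 degrees, measured at the defect over ±10 um of arclength on the
unsmoothed boundary, so corner angles are not rounded off before
measurement). The indentation point is the midpoint of the two flank
defects. Borderline necks (at least half the depth threshold) are logged.
A user-supplied indentation point overrides detection and is logged as
manual.

**Extension length** is the within-mask geodesic distance from the tip to
the indentation point, normalized by the tip-to-back geodesic length. Tip
and back are the endpoints of the mask's geodesic diameter (two-sweep
farthest-point heuristic); the tip is the endpoint geodesically closer to
the indentation. We use geodesic path length rather than a skeleton-based
midline: for the tubular, mildly curved silhouettes in scope the two agree
within raster tolerance, and the geodesic formulation reuses the exact
machinery of the shape profile without skeleton-spur instabilities. Strongly
C-shaped explants would make the geodesic path hug the inner boundary and
underestimate a true midline; such shapes are outside the geometry this
package targets.

**Geodesic distances** use the 8-connected pixel graph with step weights 1
and sqrt(2), computed by repeated forward/backward chamfer sweeps to a fixed
point. Each sweep relaxes half of the neighbour edges, so iteration
converges to the exact shortest-path distances even in hooked masks; the
test suite proves exact agreement with an independently written Dijkstra
oracle, including a C-shaped mask where the geodesic must wrap around the
gap. The **shape profile** seeds the distance map with the pixels of a
central reference box (40 px wide by default) and reports, per axial
station (1 px spacing by default), the maximum geodesic distance among
foreground pixels on one side of the axis — the reconstructed half-width.
Which side is profiled is a configuration choice (left by default).

Domain morphology (length/width ratio along a stated axis, area fractions,
normalized expression-domain areas) and the embryo axis-length ratio
(polyline arc length over Euclidean height) are direct geometric
definitions; their tests are closed forms (axis-aligned rectangles, analytic
ellipses, a semicircle giving pi/2).

## Cell alignment and paired nuclear intensities

Cell orientation is the major-axis angle of the ellipse sharing the
polygon's second-order area moments (Green's-theorem forms) — the "best fit
ellipse" of standard raster toolchains, chosen over boundary least squares
for exactly that reason. Angles live in [-90, 90) and deviations from the
tissue axis fold into [0, 90]. Cells with aspect ratio below 1.05 are
flagged near-isotropic, kept in outputs, and excludable by configuration;
no handling rule is imposed because none is canonical.

The paired intensity readout measures the mean signal in a 6-px-wide circle
at the nucleus, subtracts the mean of five 4-px-wide circles placed in the
cytoplasm (inside the outline, outside the nuclear circle; positions drawn
with the run seed when not supplied, and returned for logging), and divides
by the nuclear DAPI mean. Pixel-specified diameters stay in pixels and are
converted through the calibration at use time, because that is how such
parameters are specified in practice. Depth gating keeps planes 45-60 um
from the explant top (or within 37.5 um of the mesendoderm top in embryos).

The orientation generator draws axial angles from a wrapped normal on the
doubled angle with standard deviation $1/\sqrt{\kappa}$; $\kappa = 0$ is
uniform (mean deviation 45 degrees), $\kappa = \infty$ degenerate at the
mean. This family is a modelling choice: only the uniform-to-aligned
progression matters for the tests, not the exact tail shape.

## Nuclear signaling-gradient profiles

The gradient pipeline, in order: QC filtering (flagged enveloping-layer,
yolk-syncytial-layer, inhomogeneous-DAPI and dividing nuclei removed; depth
window 180 um for explants, 60-120 um for embryos), projected minimum
distance to the reference contour (the operator-drawn line of nuclei on the
high-intensity side), cytoplasmic background subtraction (mean of 12 spot
means per channel; 12 per side for dual stainings), DAPI normalization, and
max-distance normalization per sample. Background subtraction precedes DAPI
division because backgrounds are measured on raw spot means. Raw (not
background-subtracted) DAPI is used as the normalizer, and distance to the
contour is the minimum over reference points rather than to an interpolated
curve; both choices are configuration-visible but are the defaults the
measurement definitions imply.

Binning uses half-open bins $[k w, (k+1) w)$ (last bin closed) of width
0.04 for explants and 0.02 for embryos — about two cell diameters. Bin 0 is
anchored at the reference (high-intensity) side; plotting from the low side
is presentation only. The first and last 4% of the axis are excluded from
the reported curve because sample curvature leaves those bins nearly empty:
one bin per edge at w = 0.04, two at w = 0.02. Reported values are divided
by the reference value — the mean ratio of the designated first reported
bin of the control group, computed per replicate and averaged — or
self-referenced with a logged notice for single-sample runs. Bin counts,
including excluded edges, always sum to the post-QC nucleus count.

The top-decile position takes the ceiling(0.1 n) nuclei of highest
DAPI-normalized corrected intensity (ties at the cutoff all included, and
logged) and averages their normalized distances. Being rank-based, it is
invariant to any monotone transformation of intensity: on a noise-free
fixture the intensity ranking equals the distance ranking whatever the
gradient range, so the statistic only separates gradient ranges in the
presence of intensity noise. Its monotonicity in decay length is therefore
tested at the generators' reference 10% intensity CV, where it holds in
every probed run.

Domain extent walks the normalized back-to-tip axis and reports the farthest
position at which the positivity rule holds (signaling domains anchored at
the back) or the first such position (reporter domains entered from the
tip). The default rule — ratio above the mean + 2 sd of the low-side
background nuclei (farthest 20% of the axis) — operationalizes "clearly
visible nuclear staining" and is exposed in the configuration, as is the
graded/radial call: graded requires the first-three over last-three reported
bin ratio to reach 2.0 *and* a Spearman trend of at most -0.5; both
statistics are returned with every call so the thresholds are auditable.

The gradient generator places nuclei uniformly in a box, applies an
exponential, logistic or flat spatial profile, and multiplies both channels
by the same depth-attenuation field $(1-a)^{z/100}$, which the DAPI ratio
cancels exactly (verified to 1e-6 and in practice to machine precision).
The {exponential, logistic, flat} family spans graded versus radial
phenotypes; real profiles are only known graphically, so no shape is
privileged beyond that.

## Statistical harness

Every group is gated through the D'Agostino-Pearson omnibus normality test
(implemented from the standard skewness and kurtosis transformations and
validated against frozen reference values from an independent
implementation); groups smaller than 8 use Shapiro-Wilk, where the
moment-based transformations are undefined. All groups normal selects
Student's t (two groups) or one-way ANOVA; otherwise Mann-Whitney or
Kruskal-Wallis. Omnibus designs run a pairwise post hoc with Holm
correction — the conventional default where no correction is named — and
report medians and quartiles per group. The end-to-end select-then-test
procedure holds its nominal type-I error (0.05 within [0.035, 0.065] over
2000 Gaussian-null replicates in the acceptance run).

## Fixture realism, problem sizes and limitations

The generators emulate the *statistical* structure the measurements assume:
affine advection with Gaussian positional noise, Poisson-Gaussian pixel
noise, multiplicative intensity noise at 10% CV, clone sizes of 40-60 cells,
800 nuclei per gradient sample, 100-500 cell outlines. They do not emulate
cell-cell exclusion, segmentation errors, anisotropic point-spread functions,
drift other than on axis anchors, or mechanistic signaling dynamics — so
green tests certify the estimators against their definitions and against
known ground truth, not robustness to every artifact of real microscopy.
No quantitative single-cell noise magnitudes are published for this system;
the defaults above are stated so they can be swept rather than trusted.

Test and acceptance problem sizes (200 oracle clones of up to 12 cells, a
4x3 recovery grid with 200 seeded runs, 102 gradient-recovery runs, 2000
null replicates, geodesic oracles up to 64x64) keep the full suite under a
minute while leaving each statistical check adequately powered; they are the
package's reference conditions and are fixed in the scripts.

Known limitations: 2D analyses throughout (projection along z is part of
the measurement definitions, not a simplification we can lift); the
extension midline assumption above; the minimal spot detector is a
difference-of-Gaussians blob finder adequate for rendered fixtures and
well-separated nuclei, not a replacement for a production segmentation
pipeline; and QC exclusions are represented as input flags on the nucleus
table — the package applies them but does not attempt to derive them from
the images, since those calls were made visually in the first place.
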