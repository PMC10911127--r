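# explantr

Quantitative analysis of axis elongation in zebrafish blastoderm explants
and embryos.

During gastrulation, zebrafish embryos elongate their body axis through
convergence-and-extension movements: mesendodermal cells align their long
axes with the mediolateral tissue axis and intercalate between medial
neighbours, narrowing the tissue while lengthening it. Blastoderm explants —
embryonic cell masses cultured without the yolk cell — reproduce this
elongation ex vivo, and its progress is read out through a set of
quantitative measurements that this package implements for researchers
analyzing such experiments:

- **Explant morphometrics** — circularity (4πA/P² on a sub-pixel traced
  boundary), automated extended/not-extended classification from boundary
  concavities, normalized extension length, geodesic half-width shape
  profiles (exact 8-connected chamfer distances from a central reference
  box), expression-domain length/width ratios, area fractions, and the
  embryo axis-length ratio.
- **Clone dispersal** — the mean within-clone pairwise distance per time
  point, decomposed parallel and perpendicular to a time-varying extension
  axis (tip + back anchors, z-projection), normalized to the initial time
  point; fold changes, tip-distance rank-preservation R², and clone
  categorization by reporter-domain overlap (<25% rules).
- **Cell alignment** — best-fit-ellipse orientation from polygon area
  moments, angular deviation from the tissue axis folded to [0, 90]°, and
  the paired nuclear signaling readout (6-px nuclear circle, five 4-px
  cytoplasmic background circles, DAPI normalization, 45–60 µm depth gate).
- **Signaling-gradient profiles** — nuclear pSmad5/pSmad2 pipelines: QC
  filtering, projected minimum distance to a reference nucleus contour,
  12-spot cytoplasmic background subtraction, DAPI normalization,
  fixed-width binning (0.04 explant / 0.02 embryo) with edge exclusion and
  control referencing, top-decile position, domain extent, and
  graded-vs-radial classification.
- **Statistics** — the normality-gated test harness (D'Agostino–Pearson,
  Shapiro–Wilk fallback for n < 8; t / Mann–Whitney / ANOVA /
  Kruskal–Wallis with Holm-corrected post hocs).
- **Synthetic data** — generators for every input class (silhouette masks,
  affine-advected clone point clouds, orientation fields, gradient-bearing
  nucleus tables, rendered multi-channel stacks) with ground-truth records,
  so the whole pipeline runs and is tested without any microscopy download.

## Worked example

The wild-type mesendoderm flow preset encodes the measured dispersal regime
(2.02-fold parallel, 0.88-fold perpendicular over 260 min). The pipeline
recovers it from the generated tracks:

```r
library(explantr)
sim    <- simulate_clone_flow(flow_preset("wildtype_mesendoderm"))
curves <- dispersal_curves(sim$table, sim$axis)
round(tail(curves, 3), 3)
#>      t parallel_um perpendicular_um n_cells parallel_norm perpendicular_norm
#> 12 220      50.976           27.490      60         1.813              0.897
#> 13 240      53.809           27.221      60         1.914              0.889
#> 14 260      56.800           26.955      60         2.020              0.880
fold_change(curves, t_end = 260)
#>      parallel perpendicular
#>          2.02          0.88
```

The normalized parallel distance doubles while the perpendicular one
shrinks — the signature of oriented intercalation. A synthetic nuclear
pSmad5 gradient (exponential, decay 0.2 of the axis, 10% intensity noise)
run through the full profile pipeline:

```r
g   <- simulate_gradient_nuclei(gradient_params(decay_length = 0.2, seed = 1))
tab <- qc_filter(g$table, run_config("explant"))
tab <- distance_to_reference(tab, g$contour)
tab <- background_subtract(tab, g$background_spots)
#> background_subtract: psmad5 background = 20.18 (12 spots)
prof <- build_profile(tab, run_config("explant"))
head(prof[!prof$excluded, c("bin_center", "intensity", "n")], 4)
#>   bin_center intensity  n
#> 1       0.06     1.000 35
#> 2       0.10     0.805 28
#> 3       0.14     0.631 36
#> 4       0.18     0.517 36
classify_profile(prof)$class
#> [1] "graded"
fit_exponential_profile(prof)
#> [1] 0.194
```

The recovered background (20.18 vs a true 20), the declining referenced bin
means, the "graded" call and the fitted decay length (0.194 vs a true 0.2)
are all read directly off the binned profile; `top_decile_position(tab)`
(0.068 here) summarizes how close the high-signal nuclei sit to the
reference side.

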