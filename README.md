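# octalens

Quantitative analysis of macular perfusion from en-face OCT angiography
(OCTA) and of crystalline-lens opacity from anterior-segment OCT (AS-OCT),
plus the longitudinal statistics that link the two — the computational
toolchain of studies asking how cataract surgery changes retinal blood
flow, and for whom preoperative lens density predicts that change.

## Who it is for

Researchers who have en-face OCTA exports (8-bit grayscale PNG, one image
per retinal plexus — superficial SVP, intermediate ICP, deep DCP) and
radial AS-OCT B-scan series of the lens, and want reproducible,
script-level versions of:

* the nine standard skeleton-based perfusion metrics,
* objective lens and nuclear densitometry in pixel intensity units (PIU),
* repeated-measures ANOVA across follow-up visits with sphericity handling,
  and a Pearson correlation screen against surgical parameters.

Because clinical images from such studies are rarely shared, the package
also ships first-class synthetic-data generators (vascular trees, lens
B-scans, longitudinal cohorts) with analytically known ground truth; the
entire pipeline is validated against them.

## The metrics

With `A` the binarized vessel map, `S` its skeleton, `P` its perimeter map
and `n` the image pixel count:

| metric | definition | meaning |
|---|---|---|
| VAD | ΣA / n | vessel area density |
| VDI | ΣA / ΣS | vessel diameter (dilation) index |
| VPI | ΣP / ΣA | perimeter per unit area (dropout marker) |
| BVT | mean geodesic/Euclidean branch length | tortuosity |
| VCI | (ΣP)² / (4π ΣA) | complexity (isoperimetric) index |
| BP, EP | node counts on the skeleton | branching / termination |
| TVL, AVL | ΣS, ΣS / #branches | total and average vessel length |

The chain behind them: multiscale Hessian (Frangi) vesselness → Otsu
threshold → strict binarization → junction-hole filling → homotopic
thinning → branch decomposition. Lens opacimetry: Otsu segmentation →
robust 4th-order polynomial surface fits with correction of deviating edge
points → strict between-surfaces mask → mean intensity, plus an elliptical
nuclear ROI; a radial series of 15 scans is averaged. CDE (cumulative
dissipated energy) = average phaco power (%) × phaco time (s).

## Worked example

```r
library(octalens)

# a synthetic macular scene with known ground truth
tr  <- generate_vascular_tree(depth = 3, density = 2, seed = 42)
img <- render_octa_image(tr, quality_index = 55, plexus_label = "SVP")
quantify(img, quant_config(min_branch_length = 6))
#> Perfusion metrics
#>   VAD 0.0193  VDI 5.3974  VPI 0.3785  BVT 1.1752  VCI 14.4
#>   BP 1  EP 5  TVL 234  AVL 58.50
tr$true_counts
#> $bp [1] 1      $ep [1] 5     # recovered exactly
```

The branchpoint/endpoint counts match the generator's truth exactly; TVL
(234 skeleton pixels) sits about 11% below the continuous centerline arc
length (263.6 px) — the expected digital-length bias of a pixel-count
definition, discussed in the methods vignette.

```r
# lens densitometry over a radial series of 15 speckled B-scans
scene <- default_lens_scene(speckle_sd = 0.2)      # cortex 40, nucleus 60
lens_opacity_from_series(generate_lens_series(scene, seed = 7))
#> Lens opacity 46.31 PIU, nuclear opacity 57.45 PIU (15 scans)

# longitudinal statistics on a simulated 46-eye cohort
co <- generate_cohort(cohort_sim_params(seed = 3))
rm_anova(as.matrix(co[paste0("vad_svp_t", 0:3)]))
#> Repeated-measures ANOVA: F(1.46, 65.5) = 70.79, p = 1.248e-14
#>   Mauchly W = 0.1352 (p = 2.257e-17); GG epsilon = 0.4853 [correction applied]
```

The lens value of 46.31 PIU is the area-weighted cortex/nucleus mixture of
the scene (analytically 46.2), and the ANOVA detects the built-in
jump-then-plateau perfusion increase, with the Greenhouse–Geisser
correction engaged because the jump concentrates the variance in one
contrast. `correlation_screen(co)` then reproduces the familiar table
layout (metric × plexus rows against lens opacity, nuclear opacity, CDE,
IOP change, phaco time, fluid volume).

A complete on-disk study can be simulated and analysed in one pass:

```r
simulate_study("study/", n_eyes = 8, seed = 1)
res <- run_study(study_config("study/", "study/out"))
```

which writes `metrics.csv`, `opacity.csv`, `cohort.csv`,
`timepoint_summary.csv`, `correlation_screen.csv` and a per-eye exclusion
log. A thin CLI over the same functions lives in
`inst/scripts/octalens-cli.R` (subcommands `simulate-study`,
`quantify-octa`, `lens-opacity`, `cohort-stats`, `run-study`).

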