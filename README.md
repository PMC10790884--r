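# petoccupancy

Receptor occupancy from baseline/blocking dynamic PET, with a
resting-state-fMRI-derived brain parcellation.

## What it does, and for whom

In a blocking study, a receptor-selective radioligand is scanned twice —
once at baseline and once after drug administration — and the drug's target
engagement in each brain region is read off as the fractional loss of
binding:

    Occ(%) = 100 * (BP_ND_baseline − BP_ND_blocking) / BP_ND_baseline

where BP_ND is the non-displaceable binding potential estimated with the
simplified reference tissue model (SRTM),

    C_T(t) = R1·C_R(t) + R1·(k2REF − k2a)·[C_R ⊗ exp(−k2a·t)](t),
    k2 = R1·k2REF,  k2a = k2 / (1 + BP_ND),

fitted simultaneously to all regional time-activity curves (TACs) with one
reference efflux rate k2REF *coupled* (shared) across regions per scan, the
cerebellum serving as reference input. The package is aimed at PET kinetic
modelers and imaging methodologists who need this chain as reusable,
testable components rather than study-specific scripts:

* `build_parcellation()` — normalized-cut spectral clustering of
  thresholded, Fisher-z-averaged voxel correlation graphs from
  resting-state fMRI (spatially constrained, 26-connectivity; K = 200 in
  the reference configuration);
* `extract_roi_tacs()` — regional and reference TACs from 4D dynamic PET
  plus a 3D label volume;
* `fit_srtm_coupled()` — deterministic profile-based simultaneous SRTM fit
  (per-region R1 and BP_ND, one k2REF per scan);
* `filter_refit_loop()` / `compute_occupancy()` — occupancy with the
  standard discard rules (baseline BP_ND < 0.2, DVR < 1.2, occupancy
  outside 0–100%) and refit of the surviving regions;
* `summarize_occupancy()` — study summaries (mean ± SD, range, top-k) over
  per-region means, including on the packaged 137-region reference table;
* `simulate_study()`, `simulate_rsfmri()`, `simulate_dynamic_phantom()` —
  synthetic inputs with known ground truth for every stage.

See the vignette in `vignettes/receptor-occupancy.Rmd` for the model,
numerical scheme and design decisions.

## Worked example

Simulate a 6-region baseline/blocking study at 3% peak noise, run the full
occupancy analysis, and compare with the planted truth:

```r
library(petoccupancy)
sim <- simulate_study(n_rois = 6, noise_cv = 0.03, seed = 42)
res <- filter_refit_loop(sim$baseline, sim$blocking)
res
#> <occupancy_result> 6/6 ROIs retained after 1 pass(es); k2REF 0.1499 (baseline) / 0.1535 (blocking) /min
cbind(round(res$table[, c("bp_baseline", "bp_blocking",
                          "occupancy_percent")], 3),
      true_occ = round(sim$truth$occupancy, 3))
#>   bp_baseline bp_blocking occupancy_percent true_occ
#> 1       3.004       0.861            71.332   71.407
#> 2       0.785       0.525            33.103   34.049
#> 3       2.762       1.509            45.355   45.426
#> 4       3.267       0.997            69.482   71.701
#> 5       2.010       0.508            74.721   73.802
#> 6       3.092       2.262            26.851   26.462
```

Every region is retained (none trips the low-binding or impossible-occupancy
rules), the coupled reference efflux rate lands near the generating value of
0.14/min, and the estimated occupancies track the planted field to within a
couple of percentage points at this noise level.

The packaged 137-region reference table summarizes to:

```r
summarize_occupancy(load_table1_fixture(), top_k = 3)
#> <occupancy_summary> 137 ROIs
#>   baseline BP_ND: 1.44 (+/- 0.33 SD)
#>   occupancy: 39.5% (+/- 10.9% SD), range 19.84-74.72%
#>   top 3 regions by occupancy:
#>     l angular gyrus               74.72%
#>     l intraparietal sulcus        70.97%
#>     r angular gyrus               70.47%
```

i.e. roughly 40% average occupancy across regions, with the angular gyri
and intraparietal sulci among the most occupied.

A thin command-line front end over the same functions lives at
`inst/cli/petoccupancy.R` (subcommands `parcellate`, `extract-tacs`,
`fit-srtm`, `occupancy`, `summarize`, `simulate`).

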