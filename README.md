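# fibrilquant

Quantification tools for ex vivo corneal ultrastructure experiments, for
researchers who image stromal collagen by transmission electron microscopy,
assay thermal stability by differential scanning calorimetry (DSC), and
compare treatment groups (e.g. enzyme-digested ectasia models with and
without riboflavin/UVA crosslinking).

The package covers the full measurement chain:

* **Segmentation** of fibril cross-sections ("spots") in calibrated
  grayscale micrographs: adaptive local-mean binarization
  (foreground iff intensity − local block mean > offset), morphological
  opening with a disk element, 8-connected component labeling, and
  exclusion of elongated artifacts by moment eccentricity
  (*e* = √(1 − λ₂/λ₁) of the inertia ellipse; disks ≈ 0, lines → 1).
* **Morphometry**: equivalent-circle diameters *d* = 2√(A/π)·c (nm),
  nearest-neighbour interfibrillar distances, and randomized-window spot
  density — the median count over 200 uniformly placed 300 × 300 px windows.
* **DSC**: linear baseline subtraction from the curve tails, then peak
  location with moving-average smoothing and parabolic sub-grid refinement,
  yielding the collagen denaturation transition temperature.
* **Group statistics**: mean ± SD summaries, planned pairwise pooled
  Student *t*-tests (enzyme vs control; crosslinked vs non-crosslinked
  within enzyme family), and derived swelling-reduction percentages
  100·(x̄_ref − x̄)/x̄_ref.
* **Synthetic data**: a ground-truth-annotated generator (hard-disk random
  sequential adsorption scenes, rendered micrographs, single-endotherm
  thermograms, per-eye group tables) so the whole chain is testable without
  experimental data.

## Worked example

```r
library(fibrilquant)

## simulate a calibrated micrograph: ~210 fibrils of mean diameter
## 40.67 nm at 200 fibrils/um^2 (18 per 300 px window), 5 artifacts
scene <- generate_scene(density_per_um2 = 200, diam_mean_nm = 40.67,
                        diam_sd_nm = 2, min_gap_nm = 4, n_artifacts = 5,
                        image_shape_px = c(1024, 1024), nm_per_px = 1,
                        seed = 7)
img <- render_micrograph(scene, noise_sd = 0.05, blur_sigma_px = 1)

seg <- segment_micrograph(img)          # binarize, open, label, filter
morph <- summarize_image(seg$components, img, seed = 8)
morph
#> <morphometry 'synthetic-seed7': 211 fibrils>
#>   diameter     41.37 +/- 1.80 nm (n = 186, border-censored excluded)
#>   NN distance  54.15 +/- 7.99 nm
#>   density      18.0 spots / 300 px window (200.0 per um^2; 200 windows)
```

The 211 recovered spots match the 210 generated fibrils (the 5 elongated
artifacts are excluded by the eccentricity filter; one noise cluster slips
in). The density median recovers the generated 18 per window exactly;
diameters run a fraction of a nanometre high under the 1 px blur (see the
vignette's limitations section).

```r
tg <- generate_thermogram(71.99, baseline_slope = 0.01, noise_sd = 0.02,
                          seed = 9)
transition_temperature(tg)
#> <transition: 72.12 degC (peak height 1)>

swl <- subset(load_reference_table("cct"), measure == "swelled_cct_um")
percent_swelling_reduction(swl, "ChaseABC-CXL+Col", "ChaseABC-CXL")
#> [1] 16.74208     # rounds to 17%
```

The bundled reference tables (`load_reference_table("cct")`,
`"morphometry"`, `"transition"`) hold the nine-group mean ± SD summaries of
central corneal thickness, TEM morphometry and transition temperature for
the chondroitinase/collagenase crosslinking design; the swelling-reduction
worked example above reproduces the published 17% (chondroitinase family),
6% (collagenase family) and <4% (control family) figures from those cells.

An end-to-end run (simulate → segment → measure → dsc → report) with
logging and a provenance record:

```r
cfg <- run_config(calibration_nm_per_px = 1, seed = 11)
run_pipeline(cfg, "run1")
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/fibrilquant.R run --config config.yaml --out run1
```

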