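# histodiff

Quantitative bridges between prostate histology and diffusion-weighted
MRI (DWI). In prostate cancer, the apparent diffusion coefficient (ADC)
of water measured by DWI falls as tumours become more cellular and lose
their glandular (luminal) architecture — but turning that qualitative
association into numbers requires models and measurements at the
histology scale. histodiff provides, for researchers working on
radiology–pathology correlation:

- **Cellularity maps** from RGB histology: CIELAB lightness
  thresholding of stained nuclei, area-based counting
  (count = stained area / mean nucleus area, default 41.29 µm²), and
  leave-two-out cross-validated threshold calibration against manual
  counts.
- **Luminal-fraction (λ) maps**: k-means colour clustering in the
  CIELAB chroma plane (k = 6), automatic selection of the near-white
  lumen cluster, morphological closing and component-size filtering.
- **Simulated ADC (sADC)**: a Monte-Carlo random walk of water
  molecules in the segmented diffusing space of each map subregion
  (defaults Np = 5000 walkers, Nt = 2630 steps, T = 8.67 ms,
  Df = 3.0×10⁻³ mm²/s, periodically tessellated field), with the
  diffusivity estimated from the mean-squared-displacement slope via
  the 2D Einstein relation D = slope/4.
- **The stereological model** linking ADC and cellularity C through
  the diffusing-space fraction ε = 1 − Ān·C and the tortuosity power
  law ADC = D₀·ε^τ, with multi-start nonlinear least-squares fitting,
  bootstrap confidence intervals, an errors-in-variables refinement,
  and leave-one-animal-out cross-validation.
- **Monoexponential ADC fitting** of multi-b-value, multi-direction
  signals (b = 0–800 s/mm²), and a **2-component mixture of linear
  regressions** (EM) that assigns map pixels to tissue vs lumen
  compartments with posterior-probability maps.
- A **synthetic-tissue generator** with exact ground truth (planted
  nucleus centres and lumen masks) used throughout the test suite.

## Worked example

Generate a synthetic slide, calibrate the segmentation threshold against
(ground-truth) manual counts, derive the three microstructure maps, and
fit the ADC–cellularity model to a synthetic ROI cohort:

```r
library(histodiff)

spec <- tissue_spec(image_size_px = c(1000, 1000),
                    target_cellularity = 4000,      # cells/mm^2
                    target_luminal_fraction = 30,   # percent
                    seed = 11)
tissue <- generate_tissue(spec)
L <- rgb_to_lightness(tissue$image)

truth_map <- true_cellularity_map(tissue$truth, 250)
counts <- round(truth_map$values * subregion_area_mm2(truth_map))
thr <- optimize_threshold(labeled_grid(L, counts, subregion_px = 250))
thr
#> <threshold_result> t_opt = 72.01 L (folds: 71.9, 72.0, 72.0, 72.0, 72.0, 72.1, 72.0, 72.0)
#>   CVS median = 4.99% (per fold: 2.8%, 2.0%, 12.1%, 4.1%, 6.7%, 1.8%, 7.4%, 5.9%)

cellularity_map(segment_nuclei(L, thr$t_opt), 250)
#> <quant_map> cellularity: 4 x 4 grid, 57.5 um/cell (250 px @ 0.23 um/px)
#>   values: min 1770 / median 4271 / max 7462 (0 missing)

clusters <- cluster_colors(tissue$image, k = 6, seed = 3)
luminal_fraction_map(extract_lumen_mask(clusters,
                                        lumen_config(grid_px = 250)), 250)
#> <quant_map> luminal_fraction: 4 x 4 grid, 57.5 um/cell (250 px @ 0.23 um/px)
#>   values: min 4.907 / median 26.73 / max 70.04 (0 missing)

sadc_map(L, thr$t_opt, 250,
         sim_config(n_particles = 1000, n_steps = 500, seed = 17))
#> <quant_map> sadc: 4 x 4 grid, 57.5 um/cell (250 px @ 0.23 um/px)
#>   values: min 0.002164 / median 0.002546 / max 0.002904 (0 missing)
```

The threshold lands between the nucleus and stroma lightness modes with
a median cross-validated count error of 5%; the cellularity map brackets
the planted 4000 cells/mm²; the λ map brackets the planted 30%; and
every sADC value sits below the free-water 3.0×10⁻³ mm²/s, more so where
the tissue is denser.

```r
params <- model_params(D0 = 2.18e-3, An_bar = 68.17, tau = 0.599)
rois <- generate_roi_dataset(params, n_rois = 50, noise_cv = 0.03, seed = 1)
fit_cellularity_model(rois, n_boot = 500, seed = 2)
#> <model_fit> n = 50, exponent = consistent
#>   D0     = 0.002176 mm^2/s
#>   An_bar = 69.81 um^2
#>   tau    = 0.5657
#>   95% CI D0: (0.002136, 0.002232)
#>   95% CI An_bar: (62.19, 76.66)
#>   95% CI tau: (0.4555, 0.719)
#>   r^2 = 0.983

loao_crossvalidate(rois, "cellularity")
#> <cv_result> model = cellularity: median |rel dev| = 4.3%, NRMSE = 0.038 (50 ROIs)
```

With 3% noise on both coordinates the fit recovers the generating
parameters (D₀ to 0.2%, τ to 6% here), and held-out animals' cellularity
is predicted from ADC alone to within a few percent.

A thin command-line interface over the same functions lives at
`inst/cli/histodiff.R` (subcommands `synth`, `cellularity`, `lumen`,
`sadc`, `adcfit`, `fit`, `lmm`, `sweep`, `pipeline`).

See `vignettes/histodiff-methods.Rmd` for the model derivation,
parameter conventions, numerical choices, and the limits of synthetic
validation.

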