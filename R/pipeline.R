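#' Read an RGB raster image (PNG or TIFF)
#' @param path image path; format chosen by extension.
#' @return numeric rows x cols x 3 array in \[0,1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext,
                     " (use PNG or TIFF)"))
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB array as PNG or TIFF
#' @param image rows x cols x 3 array in \[0,1\].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(image, path),
         tif = ,
         tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Top-level pipeline configuration
#'
#' Aggregates the stage configurations with defaults matching the
#' reference acquisition and analysis protocol throughout: 0.23 um
#' pixels, 500 px subregions, k = 6 colour clusters, Np = 5000 walkers,
#' Nt = 2630 steps, T = 8.67 ms, Df = 3.0e-3 mm^2/s, and the b-grid
#' 0, 100, 200, 400, 800 s/mm^2.
#'
#' @param image path to the RGB histology image, or the array itself.
#' @param pixel_size_um physical pixel size; must be supplied explicitly
#'   (raster formats carry no trustworthy physical size).
#' @param subregion_px map subregion side in pixels.
#' @param threshold numeric lightness threshold, or `"auto"` to optimize
#'   against `manual_counts`.
#' @param manual_counts per-subregion manual nucleus counts (matrix) for
#'   `threshold = "auto"`.
#' @param mean_nucleus_area_um2 mean nucleus cross-sectional area.
#' @param lumen a [lumen_config()]; by default one whose map grid matches
#'   `subregion_px`, so all maps share a geometry.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param simulate_sadc logical: run the (slow) sADC simulation stage.
#' @param dwi_csv optional path to a DWI signal CSV (b, direction, value).
#' @param b_values expected b-grid for DWI fitting.
#' @param output_dir directory for all outputs.
#' @param seed global seed; all stage seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(image,
                            pixel_size_um = 0.23,
                            subregion_px = 500L,
                            threshold = "auto",
                            manual_counts = NULL,
                            mean_nucleus_area_um2 = 41.29,
                            lumen = NULL,
                            sim = sim_config(),
                            simulate_sadc = FALSE,
                            dwi_csv = NULL,
                            b_values = c(0, 100, 200, 400, 800),
                            output_dir = tempfile("histodiff_out"),
                            seed = 1L) {
  if (is.null(pixel_size_um) || !is.finite(pixel_size_um) ||
      pixel_size_um <= 0) {
    stop("pixel_size_um must be supplied and positive; it is never guessed")
  }
  # lambda maps share the cellularity-map grid unless configured otherwise
  if (is.null(lumen)) lumen <- lumen_config(grid_px = subregion_px)
  structure(list(image = image, pixel_size_um = pixel_size_um,
                 subregion_px = as.integer(subregion_px),
                 threshold = threshold, manual_counts = manual_counts,
                 mean_nucleus_area_um2 = mean_nucleus_area_um2,
                 lumen = lumen, sim = sim,
                 simulate_sadc = isTRUE(simulate_sadc),
                 dwi_csv = dwi_csv, b_values = b_values,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full histology-to-maps pipeline
#'
#' Stages: lightness conversion; threshold selection (fixed or optimized
#' against manual counts); cellularity map; colour clustering and
#' luminal-fraction map; optional sADC simulation; optional DWI ADC fit.
#' All map CSVs (+ JSON sidecars) and a provenance manifest are written
#' to the configured output directory. Every stage seed derives from the
#' global seed, so re-running with the same config reproduces identical
#' outputs; failures abort with the stage name while earlier outputs are
#' preserved.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `threshold`, `cellularity`, `luminal_fraction`,
#'   `sadc` (or NULL), `adc_fit` (or NULL), `manifest_path`, `output_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  img <- stage("input", {
    if (is.character(cfg$image)) read_image(cfg$image) else cfg$image
  })
  L <- stage("lightness", rgb_to_lightness(img))

  thr_stage <- stage("threshold", {
    if (identical(cfg$threshold, "auto")) {
      if (is.null(cfg$manual_counts)) {
        stop("threshold = 'auto' needs manual_counts")
      }
      grid <- labeled_grid(L, cfg$manual_counts,
                           subregion_px = cfg$subregion_px,
                           pixel_size_um = cfg$pixel_size_um)
      res <- optimize_threshold(grid, cfg$mean_nucleus_area_um2)
      list(t = res$t_opt, result = res)
    } else {
      list(t = as.numeric(cfg$threshold), result = NULL)
    }
  })
  thr <- thr_stage$t
  thr_result <- thr_stage$result

  cell <- stage("cellularity", {
    mask <- segment_nuclei(L, thr)
    cellularity_map(mask, cfg$subregion_px, cfg$mean_nucleus_area_um2,
                    cfg$pixel_size_um)
  })
  write_quantmap(cell, file.path(cfg$output_dir, "cellularity.csv"))

  lf <- stage("lumen", {
    clusters <- cluster_colors(img, k = cfg$lumen$k,
                               seed = derive_seed(cfg$seed, 2L))
    mask <- extract_lumen_mask(clusters, cfg$lumen)
    luminal_fraction_map(mask, cfg$lumen$grid_px, cfg$pixel_size_um)
  })
  write_quantmap(lf, file.path(cfg$output_dir, "luminal_fraction.csv"))

  sadc <- NULL
  if (cfg$simulate_sadc) {
    sadc <- stage("sadc", {
      sim <- cfg$sim
      sim$seed <- derive_seed(cfg$seed, 3L)
      sadc_map(L, thr, cfg$subregion_px, sim, cfg$pixel_size_um)
    })
    write_quantmap(sadc, file.path(cfg$output_dir, "sadc.csv"))
  }

  adc_fit <- NULL
  if (!is.null(cfg$dwi_csv)) {
    adc_fit <- stage("adcfit", {
      sig <- read_dwi_csv(cfg$dwi_csv)
      S <- average_directions(sig)
      fit_monoexponential(sig$b_values, S)
    })
    jsonlite::write_json(adc_fit,
                         file.path(cfg$output_dir, "adc_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "histodiff",
    version = as.character(utils::packageVersion("histodiff")),
    seed = cfg$seed,
    threshold = thr,
    threshold_cvs_median = if (!is.null(thr_result)) thr_result$cvs_median,
    config = list(pixel_size_um = cfg$pixel_size_um,
                  subregion_px = cfg$subregion_px,
                  mean_nucleus_area_um2 = cfg$mean_nucleus_area_um2,
                  lumen = unclass(cfg$lumen),
                  sim = unclass(cfg$sim),
                  b_values = cfg$b_values,
                  simulate_sadc = cfg$simulate_sadc))
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")

  list(threshold = thr, threshold_result = thr_result,
       cellularity = cell, luminal_fraction = lf, sadc = sadc,
       adc_fit = adc_fit, manifest_path = manifest_path,
       output_dir = cfg$output_dir)
}
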