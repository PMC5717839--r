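#' Quantitative histology/MRI map
#'
#' A `quant_map` is a 2D grid of per-subregion scalar values derived from a
#' source image (or from MRI), together with the physical geometry needed to
#' interpret it: the subregion side length in source pixels, the source pixel
#' size in micrometres, and the quantity carried by each grid cell.
#'
#' Supported quantities and their units:
#' * `cellularity` — nuclei per square millimetre (cells/mm^2)
#' * `luminal_fraction` — percent of subregion area occupied by lumina
#' * `sadc`, `adc` — diffusion coefficients in mm^2/s
#'
#' Missing subregions (e.g. no diffusing space) are `NA`, never zero.
#'
#' @param values numeric matrix of grid values (rows = image rows).
#' @param subregion_px integer side length of one grid cell in source pixels.
#' @param pixel_size_um physical size of one source pixel (micrometres).
#' @param quantity one of `"cellularity"`, `"luminal_fraction"`, `"sadc"`,
#'   `"adc"`.
#' @param origin integer pair: source-image pixel offset of the grid's
#'   top-left corner.
#' @param seed optional integer recording the seed that produced the values.
#' @return An object of class `quant_map`.
#' @export
quant_map <- function(values, subregion_px, pixel_size_um,
                      quantity = c("cellularity", "luminal_fraction",
                                   "sadc", "adc"),
                      origin = c(0L, 0L), seed = NULL) {
  quantity <- match.arg(quantity)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(subregion_px >= 1, pixel_size_um > 0, length(origin) == 2)
  fin <- values[is.finite(values)]
  if (quantity %in% c("cellularity", "luminal_fraction") &&
      any(fin < -1e-9)) {
    stop(quantity, " map values must be non-negative")
  }
  if (quantity == "luminal_fraction" && any(fin > 100 + 1e-9)) {
    stop("luminal_fraction map values must not exceed 100%")
  }
  structure(
    list(values = values,
         subregion_px = as.integer(subregion_px),
         pixel_size_um = pixel_size_um,
         quantity = quantity,
         origin = as.integer(origin),
         seed = seed),
    class = "quant_map")
}

#' @export
print.quant_map <- function(x, ...) {
  side_um <- x$subregion_px * x$pixel_size_um
  cat(sprintf("<quant_map> %s: %d x %d grid, %.1f um/cell (%d px @ %.3g um/px)\n",
              x$quantity, nrow(x$values), ncol(x$values), side_um,
              x$subregion_px, x$pixel_size_um))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: min %.4g / median %.4g / max %.4g (%d missing)\n",
                min(v), stats::median(v), max(v), sum(!is.finite(x$values))))
  }
  invisible(x)
}

#' @export
as.matrix.quant_map <- function(x, ...) x$values

#' Physical area of one map subregion in mm^2
#' @param map a [quant_map()].
#' @return scalar area in mm^2.
#' @export
subregion_area_mm2 <- function(map) {
  (map$subregion_px * map$pixel_size_um * 1e-3)^2
}

map_units <- function(quantity) {
  switch(quantity,
         cellularity = "cells/mm^2",
         luminal_fraction = "%",
         sadc = "mm^2/s",
         adc = "mm^2/s",
         "unitless")
}

#' Write a quantitative map to CSV with a JSON geometry sidecar
#'
#' The CSV holds one row per grid cell (`row`, `col`, `value`); missing
#' values are written as empty cells. The sidecar records quantity, units,
#' grid geometry, origin and seed, so that [read_quantmap()] reconstructs
#' the object exactly (values at full double precision).
#'
#' @param map a [quant_map()].
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_quantmap <- function(map, path) {
  stopifnot(inherits(map, "quant_map"))
  idx <- expand.grid(row = seq_len(nrow(map$values)),
                     col = seq_len(ncol(map$values)))
  df <- data.frame(row = idx$row, col = idx$col,
                   value = map$values[cbind(idx$row, idx$col)])
  write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(quantity = map$quantity,
               units = map_units(map$quantity),
               n_rows = nrow(map$values), n_cols = ncol(map$values),
               subregion_px = map$subregion_px,
               pixel_size_um = map$pixel_size_um,
               origin = map$origin,
               seed = map$seed)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a quantitative map written by [write_quantmap()]
#' @param path CSV path (sidecar expected at `<path>.json`).
#' @return A [quant_map()].
#' @export
read_quantmap <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("geometry sidecar missing: ", sidecar,
         " (maps are never read without units/geometry metadata)")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- read.csv(path)
  vals <- matrix(NA_real_, meta$n_rows, meta$n_cols)
  vals[cbind(df$row, df$col)] <- df$value
  quant_map(vals, meta$subregion_px, meta$pixel_size_um,
            quantity = meta$quantity, origin = meta$origin,
            seed = meta$seed)
}

#' Export a map as a scaled 32-bit TIFF
#'
#' TIFF storage here is normalized: values are divided by a positive scale
#' (recorded in the sidecar `<path>.json`) so they fit the \[0,1\] range of
#' the TIFF writer; missing cells are stored as 0. Multiply the pixel values
#' by `tiff_scale` from the sidecar to recover physical units. Use the CSV
#' format ([write_quantmap()]) for lossless round trips including missing
#' cells; the TIFF export is intended for viewing maps in image software.
#'
#' @param map a [quant_map()].
#' @param path TIFF output path.
#' @return the scale used, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "quant_map"))
  v <- map$values
  fin <- v[is.finite(v)]
  scale <- if (length(fin) && max(fin) > 0) max(fin) else 1
  img <- v / scale
  img[!is.finite(img)] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  meta <- list(quantity = map$quantity, units = map_units(map$quantity),
               tiff_scale = scale, subregion_px = map$subregion_px,
               pixel_size_um = map$pixel_size_um, origin = map$origin)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(scale)
}
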