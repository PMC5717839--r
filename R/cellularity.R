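#' Convert an RGB image to the CIELAB lightness channel
#'
#' Uses the sRGB colour space with D65 white point (the package-wide
#' convention). Accepts an rows x cols x 3 array with values in \[0,1\] or
#' 8-bit \[0,255\]; a grayscale matrix or an RGBA array is converted with a
#' warning.
#'
#' @param image numeric array (rows x cols x 3), RGBA array, or matrix.
#' @return matrix of L values in \[0, 100\].
#' @export
rgb_to_lightness <- function(image) {
  if (is.matrix(image)) {
    warning("grayscale input: replicating channel to RGB for Lab conversion")
    image <- array(rep(image, 3), c(dim(image), 3))
  }
  if (length(dim(image)) != 3) {
    stop("image must be a rows x cols x 3 array (or a matrix)")
  }
  if (dim(image)[3] == 4) {
    warning("dropping alpha channel for Lab conversion")
    image <- image[, , 1:3, drop = FALSE]
  }
  if (dim(image)[3] != 3) stop("image must have 3 colour channels")
  if (max(image) > 1 + 1e-9) image <- image / 255
  nr <- dim(image)[1]; nc <- dim(image)[2]
  flat <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  matrix(lab[, 1], nr, nc)
}

# full Lab conversion, used by the lumen module (A/B chroma channels)
rgb_to_lab <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    stop("image must be a rows x cols x 3 array")
  }
  image <- image[, , 1:3, drop = FALSE]
  if (max(image) > 1 + 1e-9) image <- image / 255
  nr <- dim(image)[1]; nc <- dim(image)[2]
  flat <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], nr, nc),
       a = matrix(lab[, 2], nr, nc),
       b = matrix(lab[, 3], nr, nc))
}

#' Segment nuclei by lightness thresholding
#'
#' Pixels darker than the threshold (`L < t`) are classified as stained
#' nuclei.
#'
#' @param L lightness matrix from [rgb_to_lightness()].
#' @param t threshold in L units, \[0, 100\].
#' @return logical matrix (TRUE = nucleus).
#' @export
segment_nuclei <- function(L, t) {
  stopifnot(is.matrix(L), is.numeric(t), length(t) == 1, t >= 0, t <= 100)
  L < t
}

#' Cellularity map from a nucleus segmentation mask
#'
#' The image is tiled into square subregions; within each, the estimated
#' nucleus count is the segmented area divided by the mean nucleus
#' cross-sectional area, and the map value is that count divided by the
#' subregion's physical area (cells/mm^2). Partial subregions at the
#' image edges are dropped.
#'
#' @param mask logical matrix from [segment_nuclei()].
#' @param subregion_px subregion side length in pixels (default 500).
#' @param mean_nucleus_area_um2 mean nucleus cross-sectional area (um^2),
#'   default 41.29.
#' @param pixel_size_um physical pixel size (um), default 0.23.
#' @return a [quant_map()] of cellularity.
#' @export
cellularity_map <- function(mask, subregion_px = 500L,
                            mean_nucleus_area_um2 = 41.29,
                            pixel_size_um = 0.23) {
  stopifnot(is.matrix(mask), subregion_px >= 1, mean_nucleus_area_um2 > 0,
            pixel_size_um > 0)
  if (subregion_px > min(dim(mask))) stop("subregion larger than image")
  area_px <- block_reduce(mask * 1, subregion_px, stat = "sum")
  counts <- area_px * pixel_size_um^2 / mean_nucleus_area_um2
  sub_area_mm2 <- (subregion_px * pixel_size_um * 1e-3)^2
  quant_map(counts / sub_area_mm2, subregion_px, pixel_size_um,
            quantity = "cellularity")
}

#' Manually counted calibration grid for threshold optimization
#'
#' A square image region subdivided into a regular grid of subregions,
#' each with a gold-standard manual nucleus count, used to calibrate the
#' segmentation threshold. The reference layout is a 2000 x 2000 px region
#' in a 4 x 4 grid of 500 px subregions.
#'
#' @param image RGB array (or a precomputed lightness matrix).
#' @param manual_counts numeric matrix of per-subregion counts laid out as
#'   the grid (row i, column j of the matrix = subregion at grid row i,
#'   column j).
#' @param subregion_px subregion side length in pixels.
#' @param pixel_size_um physical pixel size (um).
#' @return object of class `labeled_grid`.
#' @export
labeled_grid <- function(image, manual_counts, subregion_px = 500L,
                         pixel_size_um = 0.23) {
  L <- if (is.matrix(image)) image else rgb_to_lightness(image)
  if (min(L) < 0 || max(L) > 100) {
    stop("lightness values must lie in [0, 100]")
  }
  stopifnot(is.matrix(manual_counts), all(manual_counts >= 0))
  nr <- nrow(L); nc <- ncol(L)
  if (nr %/% subregion_px != nrow(manual_counts) ||
      nc %/% subregion_px != ncol(manual_counts)) {
    stop("manual_counts layout does not match image/subregion geometry")
  }
  if (nr %% subregion_px != 0 || nc %% subregion_px != 0) {
    stop("region dimensions must be divisible by the subregion size")
  }
  structure(list(L = L, manual_counts = manual_counts,
                 subregion_px = as.integer(subregion_px),
                 pixel_size_um = pixel_size_um),
            class = "labeled_grid")
}

#' Optimize the nucleus-segmentation threshold by leave-two-out CV
#'
#' For each of the disjoint pairs of neighbouring subregions (paired
#' row-wise in raster order), the pair is held out and the threshold
#' minimizing the sum of absolute differences between estimated and manual
#' counts on the remaining subregions is found by a coarse grid search
#' (step 0.5 L) followed by golden-section refinement. The held-out pair
#' yields the fold's cross-validation score (CVS, mean relative count
#' error); the final threshold is the mean of the fold thresholds.
#'
#' @param grid a [labeled_grid()].
#' @param mean_nucleus_area_um2 mean nucleus area (um^2).
#' @param pixel_size_um physical pixel size (um); defaults to the grid's.
#' @return object of class `threshold_result`: `t_opt`,
#'   `fold_thresholds`, `cvs_values`, `cvs_median`.
#' @export
optimize_threshold <- function(grid, mean_nucleus_area_um2 = 41.29,
                               pixel_size_um = NULL) {
  stopifnot(inherits(grid, "labeled_grid"))
  px <- pixel_size_um %||% grid$pixel_size_um
  counts <- as.vector(t(grid$manual_counts)) # raster order
  n_sub <- length(counts)
  if (all(counts == 0)) {
    stop("all manual counts are zero: threshold objective is degenerate")
  }
  if (n_sub %% 2 != 0) stop("need an even number of subregions to pair")

  # per-subregion sorted lightness values, raster order
  sp <- grid$subregion_px
  gr <- nrow(grid$manual_counts); gc <- ncol(grid$manual_counts)
  sortedL <- vector("list", n_sub)
  k <- 0L
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      k <- k + 1L
      block <- grid$L[((i - 1) * sp + 1):(i * sp),
                      ((j - 1) * sp + 1):(j * sp)]
      sortedL[[k]] <- sort(as.vector(block))
    }
  }
  px2_over_area <- px^2 / mean_nucleus_area_um2
  est_counts <- function(t) {
    vapply(sortedL, function(s) findInterval(t, s), numeric(1)) *
      px2_over_area
  }
  objective <- function(t, train) sum(abs(est_counts(t)[train] - counts[train]))

  folds <- split(seq_len(n_sub), rep(seq_len(n_sub / 2), each = 2))
  t_grid <- seq(0, 100, by = 0.5)
  # precompute counts for the coarse grid: n_t x n_sub
  grid_counts <- t(vapply(t_grid, est_counts, numeric(n_sub)))

  fold_t <- numeric(length(folds))
  cvs <- numeric(length(folds))
  for (f in seq_along(folds)) {
    held <- folds[[f]]
    train <- setdiff(seq_len(n_sub), held)
    obj_grid <- rowSums(abs(sweep(grid_counts[, train, drop = FALSE], 2,
                                  counts[train])))
    t0 <- t_grid[which.min(obj_grid)]
    refined <- stats::optimize(objective, train = train,
                               interval = c(max(0, t0 - 0.5),
                                            min(100, t0 + 0.5)))
    # keep whichever of coarse/refined attains the lower objective
    fold_t[f] <- if (refined$objective <= min(obj_grid)) refined$minimum
                 else t0
    est_h <- est_counts(fold_t[f])[held]
    cvs[f] <- mean(abs(est_h - counts[held]) / pmax(counts[held], 1))
  }
  structure(list(t_opt = mean(fold_t), fold_thresholds = fold_t,
                 cvs_values = cvs, cvs_median = stats::median(cvs)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> t_opt = %.2f L (folds: %s)\n", x$t_opt,
              paste(sprintf("%.1f", x$fold_thresholds), collapse = ", ")))
  cat(sprintf("  CVS median = %.2f%% (per fold: %s)\n", 100 * x$cvs_median,
              paste(sprintf("%.1f%%", 100 * x$cvs_values), collapse = ", ")))
  invisible(x)
}
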