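#' Default HES-like colour palette
#'
#' Mean 8-bit RGB colours for the three tissue compartments of an
#' HES-stained (hematoxylin-erythrosine-saffron) section: dark blue-purple
#' nuclei, pale pink stroma, near-white gland lumina, plus a per-channel
#' Gaussian noise SD (8-bit units) applied to the rendered image.
#'
#' @param nucleus,stroma,lumen length-3 RGB means in \[0,255\].
#' @param noise_sd per-channel noise SD in 8-bit units.
#' @return named list used as the `color_model` of [tissue_spec()].
#' @export
hes_palette <- function(nucleus = c(64, 44, 118),
                        stroma = c(225, 170, 185),
                        lumen = c(250, 250, 250),
                        noise_sd = 5) {
  stopifnot(length(nucleus) == 3, length(stroma) == 3, length(lumen) == 3,
            noise_sd >= 0)
  list(nucleus = nucleus, stroma = stroma, lumen = lumen,
       noise_sd = noise_sd)
}

#' Specification of a synthetic tissue image
#'
#' Parameters controlling the synthetic HES-like tissue generator. Defaults
#' reflect the digitized-slide geometry the mapping pipeline assumes:
#' 0.23 um square pixels and a mean nucleus cross-sectional area of
#' 41.29 um^2. The nucleus-area SD defaults to 8 um^2 (roughly 20% CV,
#' a typical spread for epithelial nuclei); only the SE of the mean area is
#' known from manual contouring, so the SD is a modelling choice.
#'
#' @param image_size_px integer pair (rows, cols).
#' @param pixel_size_um physical pixel size, micrometres.
#' @param target_cellularity expected nucleus density, cells/mm^2. The
#'   planted count is Poisson with mean `target_cellularity * area_mm2`.
#' @param target_luminal_fraction percent of the image occupied by lumina,
#'   in \[0, 100\].
#' @param nucleus_area_mean_um2,nucleus_area_sd_um2 truncated-normal
#'   parameters of individual nucleus cross-sectional areas (um^2).
#' @param nucleus_eccentricity_range unitless pair in \[0, 1); nucleus
#'   ellipse eccentricities are drawn uniformly from this interval.
#' @param color_model palette from [hes_palette()].
#' @param seed integer seed; all randomness in [generate_tissue()] flows
#'   from it.
#' @return object of class `tissue_spec`.
#' @export
tissue_spec <- function(image_size_px = c(1000L, 1000L),
                        pixel_size_um = 0.23,
                        target_cellularity = 3000,
                        target_luminal_fraction = 20,
                        nucleus_area_mean_um2 = 41.29,
                        nucleus_area_sd_um2 = 8,
                        nucleus_eccentricity_range = c(0.3, 0.8),
                        color_model = hes_palette(),
                        seed = 1L) {
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 8),
            pixel_size_um > 0,
            target_cellularity >= 0,
            target_luminal_fraction >= 0, target_luminal_fraction <= 100,
            nucleus_area_mean_um2 > 0, nucleus_area_sd_um2 >= 0,
            length(nucleus_eccentricity_range) == 2,
            all(nucleus_eccentricity_range >= 0),
            all(nucleus_eccentricity_range < 1))
  structure(
    list(image_size_px = as.integer(image_size_px),
         pixel_size_um = pixel_size_um,
         target_cellularity = target_cellularity,
         target_luminal_fraction = target_luminal_fraction,
         nucleus_area_mean_um2 = nucleus_area_mean_um2,
         nucleus_area_sd_um2 = nucleus_area_sd_um2,
         nucleus_eccentricity_range = sort(nucleus_eccentricity_range),
         color_model = color_model,
         seed = as.integer(seed)),
    class = "tissue_spec")
}

# rasterize an ellipse: pixel (row, col) indices whose centres fall inside.
# center in um, semi-axes a >= b in um, orientation theta in radians.
ellipse_pixels <- function(cx, cy, a, b, theta, px, nr, nc) {
  half <- a + px
  r0 <- floor((cy - half) / px) + 1L; r1 <- ceiling((cy + half) / px)
  c0 <- floor((cx - half) / px) + 1L; c1 <- ceiling((cx + half) / px)
  if (r0 < 1L || c0 < 1L || r1 > nr || c1 > nc) return(NULL) # clipped
  rows <- r0:r1; cols <- c0:c1
  yy <- (rows - 0.5) * px - cy
  xx <- (cols - 0.5) * px - cx
  g <- expand.grid(y = yy, x = xx)
  u <- g$x * cos(theta) + g$y * sin(theta)
  v <- -g$x * sin(theta) + g$y * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(NULL)
  idx <- expand.grid(row = rows, col = cols)
  cbind(row = idx$row[inside], col = idx$col[inside])
}

#' Generate a synthetic HES-like tissue image with ground truth
#'
#' Renders an RGB image of dark elliptical nuclei on pale stroma with
#' near-white luminal blobs, plus exact ground truth (nucleus centres,
#' nucleus mask, lumen mask). Lumina are smoothed-random-field blobs grown
#' to the target area fraction; nuclei are non-overlapping ellipses placed
#' in the stroma by rejection sampling (areas from a truncated normal).
#' Nucleus and lumen masks are disjoint by construction.
#'
#' @param spec a [tissue_spec()].
#' @param max_tries_per_nucleus rejection-sampling retry cap per nucleus.
#' @return list with elements `image` (rows x cols x 3 array in \[0,1\]) and
#'   `truth` (class `tissue_truth`: `nucleus_centers_um` (n x 2, x/y),
#'   `nucleus_areas_um2`, `nucleus_mask`, `lumen_mask`, `spec`).
#' @export
generate_tissue <- function(spec, max_tries_per_nucleus = 200L) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
    px <- spec$pixel_size_um
    area_mm2 <- nr * nc * px^2 * 1e-6

    # luminal blobs: threshold a Gaussian-smoothed noise field at the
    # quantile giving the requested area fraction
    lf <- spec$target_luminal_fraction
    if (lf <= 0) {
      lumen_mask <- matrix(FALSE, nr, nc)
    } else if (lf >= 100) {
      lumen_mask <- matrix(TRUE, nr, nc)
    } else {
      field <- matrix(rnorm(nr * nc), nr, nc)
      sigma <- max(4, min(nr, nc) / 25)
      field <- EBImage::gblur(field, sigma = sigma)
      thr <- stats::quantile(field, 1 - lf / 100, names = FALSE)
      lumen_mask <- field > thr
    }

    n_target <- rpois(1, spec$target_cellularity * area_mm2)
    nucleus_mask <- matrix(FALSE, nr, nc)
    occupied <- lumen_mask
    stroma_idx <- which(!lumen_mask)
    centers <- matrix(numeric(0), 0, 2,
                      dimnames = list(NULL, c("x_um", "y_um")))
    areas <- numeric(0)
    ecc_rng <- spec$nucleus_eccentricity_range

    if (n_target > 0 && length(stroma_idx) == 0) {
      stop("no stromal space to place nuclei; achievable max cellularity ",
           "is 0 cells/mm^2 at luminal fraction ", lf, "%")
    }
    for (i in seq_len(n_target)) {
      placed <- FALSE
      for (try in seq_len(max_tries_per_nucleus)) {
        area <- rnorm(1, spec$nucleus_area_mean_um2, spec$nucleus_area_sd_um2)
        if (area < 1) next # truncate: nuclei below 1 um^2 are not drawn
        ecc <- runif(1, ecc_rng[1], ecc_rng[2])
        b_over_a <- sqrt(1 - ecc^2)
        a <- sqrt(area / (pi * b_over_a))
        b <- a * b_over_a
        theta <- runif(1, 0, pi)
        k <- stroma_idx[sample.int(length(stroma_idx), 1L)]
        row <- ((k - 1L) %% nr) + 1L
        col <- ((k - 1L) %/% nr) + 1L
        cx <- (col - 0.5 + runif(1, -0.5, 0.5)) * px
        cy <- (row - 0.5 + runif(1, -0.5, 0.5)) * px
        pix <- ellipse_pixels(cx, cy, a, b, theta, px, nr, nc)
        if (is.null(pix) || any(occupied[pix])) next
        nucleus_mask[pix] <- TRUE
        occupied[pix] <- TRUE
        centers <- rbind(centers, c(cx, cy))
        areas <- c(areas, area)
        placed <- TRUE
        break
      }
      if (!placed) {
        achieved <- nrow(centers) / area_mm2
        stop(sprintf(paste0("could not place nucleus %d of %d after %d ",
                            "tries; achievable max cellularity here is ",
                            "about %.0f cells/mm^2"),
                     i, n_target, max_tries_per_nucleus, achieved))
      }
    }

    cm <- spec$color_model
    img <- array(0, c(nr, nc, 3))
    for (ch in 1:3) {
      plane <- matrix(cm$stroma[ch], nr, nc)
      plane[lumen_mask] <- cm$lumen[ch]
      plane[nucleus_mask] <- cm$nucleus[ch]
      if (cm$noise_sd > 0) {
        plane <- plane + rnorm(nr * nc, 0, cm$noise_sd)
      }
      img[, , ch] <- pmin(pmax(plane / 255, 0), 1)
    }

    truth <- structure(
      list(nucleus_centers_um = centers,
           nucleus_areas_um2 = areas,
           nucleus_mask = nucleus_mask,
           lumen_mask = lumen_mask,
           spec = spec),
      class = "tissue_truth")
    list(image = img, truth = truth)
  })
}

#' Ground-truth cellularity map from planted nucleus centres
#'
#' Counts planted nuclei per subregion by the centroid rule (a nucleus
#' belongs to the subregion containing its centre) and divides by the
#' subregion physical area.
#'
#' @param truth `tissue_truth` from [generate_tissue()].
#' @param subregion_px subregion side length in pixels.
#' @return a [quant_map()] of cellularity (cells/mm^2).
#' @export
true_cellularity_map <- function(truth, subregion_px = 500L) {
  stopifnot(inherits(truth, "tissue_truth"))
  px <- truth$spec$pixel_size_um
  nr <- nrow(truth$nucleus_mask) %/% subregion_px
  nc <- ncol(truth$nucleus_mask) %/% subregion_px
  if (nr < 1 || nc < 1) stop("subregion larger than image")
  counts <- matrix(0, nr, nc)
  if (nrow(truth$nucleus_centers_um) > 0) {
    col_px <- floor(truth$nucleus_centers_um[, "x_um"] / px)
    row_px <- floor(truth$nucleus_centers_um[, "y_um"] / px)
    gi <- row_px %/% subregion_px + 1L
    gj <- col_px %/% subregion_px + 1L
    keep <- gi >= 1 & gi <= nr & gj >= 1 & gj <= nc
    for (k in which(keep)) counts[gi[k], gj[k]] <- counts[gi[k], gj[k]] + 1
  }
  area_mm2 <- (subregion_px * px * 1e-3)^2
  quant_map(counts / area_mm2, subregion_px, px, quantity = "cellularity",
            seed = truth$spec$seed)
}

#' Ground-truth luminal-fraction map from the planted lumen mask
#' @param truth `tissue_truth` from [generate_tissue()].
#' @param grid_px grid cell side length in pixels.
#' @return a [quant_map()] of luminal fraction (%).
#' @export
true_luminal_fraction_map <- function(truth, grid_px = 500L) {
  stopifnot(inherits(truth, "tissue_truth"))
  frac <- block_reduce(truth$lumen_mask * 1, grid_px, stat = "mean")
  quant_map(100 * frac, grid_px, truth$spec$pixel_size_um,
            quantity = "luminal_fraction", seed = truth$spec$seed)
}

#' Simulate a multi-direction diffusion-weighted signal
#'
#' Monoexponential decay `S(b) = s0 * exp(-b * adc)` per gradient
#' direction, with additive Gaussian noise. The default b-grid is the
#' acquisition grid used throughout the package: 0, 100, 200, 400,
#' 800 s/mm^2 along three orthogonal directions.
#'
#' @param adc diffusivity in mm^2/s (>= 0).
#' @param s0 signal intensity at b = 0.
#' @param b_values b-values in s/mm^2; must be non-negative and include 0.
#' @param n_directions number of gradient directions.
#' @param noise_sd additive noise SD in signal units.
#' @param seed integer seed or NULL.
#' @return object of class `dwi_signal`: list with `b_values`, `signals`
#'   (matrix, b-values x directions), `n_directions`.
#' @export
generate_dwi_signal <- function(adc, s0 = 1000,
                                b_values = c(0, 100, 200, 400, 800),
                                n_directions = 3L, noise_sd = 0,
                                seed = NULL) {
  if (length(b_values) == 0) stop("b_values must not be empty")
  stopifnot(adc >= 0, all(b_values >= 0), n_directions >= 1, noise_sd >= 0)
  if (!any(b_values == 0)) stop("b_values must include b = 0")
  with_seed(seed, {
    clean <- s0 * exp(-b_values * adc)
    signals <- matrix(rep(clean, n_directions),
                      nrow = length(b_values), ncol = n_directions)
    if (noise_sd > 0) {
      signals <- signals + rnorm(length(signals), 0, noise_sd)
    }
    dimnames(signals) <- list(paste0("b", b_values),
                              paste0("dir", seq_len(n_directions)))
    structure(list(b_values = b_values, signals = signals,
                   n_directions = as.integer(n_directions)),
              class = "dwi_signal")
  })
}

#' Simulate an ROI-level (ADC, cellularity) cohort from the tissue model
#'
#' Draws per-ROI cellularity uniformly in a range, computes the noiseless
#' ADC through the stereological power law (area fraction -> forward
#' model), then applies multiplicative Gaussian noise of a given
#' coefficient of variation to both coordinates. ROIs are assigned
#' round-robin to animals for grouped (leave-one-animal-out) validation,
#' and tissue classes are labelled by cellularity strata. Luminal fraction
#' and simulated-ADC columns are filled from the package's ROI-level linear
#' relations (luminal fraction 16.3 per 1e-3 mm^2/s of ADC, offset -3.33;
#' sADC = 0.77 * ADC + 1.29e-3 mm^2/s) with the same noise.
#'
#' @param params a [model_params()].
#' @param n_rois number of ROIs.
#' @param cellularity_range cells/mm^2 pair; must stay below the packing
#'   limit `1 / An_bar`.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed or NULL.
#' @param n_animals number of animal IDs to cycle over.
#' @return data.frame with columns `animal_id`, `roi_id`, `tissue_class`,
#'   `adc`, `cellularity`, `luminal_fraction`, `sadc`.
#' @export
generate_roi_dataset <- function(params, n_rois = 50,
                                 cellularity_range = c(1e3, 12e3),
                                 noise_cv = 0.03, seed = NULL,
                                 n_animals = 5L) {
  stopifnot(inherits(params, "model_params"), n_rois >= 1,
            length(cellularity_range) == 2, noise_cv >= 0, n_animals >= 1)
  packing <- 1 / (params$An_bar * 1e-6)
  if (max(cellularity_range) > packing) {
    stop(sprintf("cellularity range exceeds the packing limit 1/An_bar = %.0f cells/mm^2",
                 packing))
  }
  with_seed(seed, {
    C <- runif(n_rois, cellularity_range[1], cellularity_range[2])
    eps <- area_fraction(C, params$An_bar)
    adc <- adc_forward(eps, params)
    lf <- pmax(0, 16.3 * adc * 1e3 - 3.33)
    sadc <- 0.77 * adc + 1.29e-3
    mult <- function(x) x * (1 + noise_cv * rnorm(length(x)))
    adc_obs <- mult(adc); C_obs <- mult(C)
    lf_obs <- mult(lf); sadc_obs <- mult(sadc)
    cls <- cut(C, breaks = c(-Inf, 2500, 5000, 9000, Inf),
               labels = c("healthy", "benign", "PIN/adenocarcinoma",
                          "poorly_differentiated"))
    data.frame(animal_id = paste0("animal",
                                  rep_len(seq_len(n_animals), n_rois)),
               roi_id = paste0("roi", seq_len(n_rois)),
               tissue_class = as.character(cls),
               adc = adc_obs,
               cellularity = C_obs,
               luminal_fraction = lf_obs,
               sadc = sadc_obs,
               stringsAsFactors = FALSE)
  })
}
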