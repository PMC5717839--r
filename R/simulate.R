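#' Diffusion domain: free-space mask with physical geometry
#'
#' The arena for the random-walk simulator: a binary mask whose TRUE
#' pixels are freely diffusing space, the physical pixel size, and whether
#' the mask is periodically tessellated to approximate an infinite field.
#'
#' @param free_mask logical matrix (TRUE = diffusing space).
#' @param pixel_size_um physical pixel size (um).
#' @param periodic if TRUE (default), membership at proposed positions is
#'   evaluated on the periodically tiled mask; positions themselves keep
#'   accumulating true displacement.
#' @return object of class `diffusion_domain`.
#' @export
diffusion_domain <- function(free_mask, pixel_size_um = 0.23,
                             periodic = TRUE) {
  stopifnot(is.matrix(free_mask), pixel_size_um > 0)
  free_mask <- free_mask > 0
  if (!any(free_mask)) stop("domain has no free space: cannot start walkers")
  structure(list(free_mask = free_mask, pixel_size_um = pixel_size_um,
                 periodic = isTRUE(periodic)),
            class = "diffusion_domain")
}

#' Random-walk simulation configuration
#'
#' Defaults match the reference protocol: 5000 particles, 2630 time steps,
#' total diffusion time 8.67 ms, free diffusivity 3.0e-3 mm^2/s (free
#' water at 37 C). The per-component Gaussian step variance is
#' `sigma^2 = 2 * Df * T / Nt`.
#'
#' @param n_particles number of walkers (Np).
#' @param n_steps number of time increments (Nt).
#' @param total_time total diffusion time T in seconds.
#' @param free_diffusivity Df in mm^2/s.
#' @param seed integer seed or NULL.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_particles = 5000L, n_steps = 2630L,
                       total_time = 8.67e-3, free_diffusivity = 3.0e-3,
                       seed = NULL) {
  stopifnot(n_particles >= 1, n_steps >= 1, total_time > 0,
            free_diffusivity > 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_steps = as.integer(n_steps),
                 total_time = total_time,
                 free_diffusivity = free_diffusivity,
                 seed = seed),
            class = "sim_config")
}

#' Monte-Carlo random walk of water molecules in segmented free space
#'
#' Walkers start uniformly over free-pixel centres. Each step proposes an
#' isotropic Gaussian displacement with per-component variance
#' `2 * Df * T / Nt`; proposals landing on a non-free pixel are rejected
#' (the position is unchanged for that increment, no re-draw). When the
#' domain is periodic, membership of positions beyond the field of view is
#' evaluated on the tessellated mask while the true displacement keeps
#' accumulating. The mean squared displacement against the initial
#' positions is recorded after every step.
#'
#' @param domain a [diffusion_domain()].
#' @param cfg a [sim_config()].
#' @return object of class `msd_curve`: `times` (s, length Nt + 1 starting
#'   at 0), `msd` (mm^2, `msd[1] = 0`), `n_particles`, `seed`.
#' @export
random_walk <- function(domain, cfg = sim_config()) {
  stopifnot(inherits(domain, "diffusion_domain"), inherits(cfg, "sim_config"))
  mask <- domain$free_mask
  px <- domain$pixel_size_um
  nr <- nrow(mask); nc <- ncol(mask)
  H <- nr * px; W <- nc * px
  dt <- cfg$total_time / cfg$n_steps
  sigma_um <- sqrt(2 * cfg$free_diffusivity * 1e6 * dt) # Df in um^2/s
  if (sigma_um > max(H, W)) {
    warning("step SD (", signif(sigma_um, 3),
            " um) exceeds the mask extent; tessellation aliasing likely")
  }
  free_idx <- which(mask)
  np <- cfg$n_particles

  with_seed(cfg$seed, {
    start <- free_idx[sample.int(length(free_idx), np, replace = TRUE)]
    row0 <- ((start - 1L) %% nr) + 1L
    col0 <- ((start - 1L) %/% nr) + 1L
    x <- (col0 - 0.5) * px
    y <- (row0 - 0.5) * px
    x0 <- x; y0 <- y
    msd_um2 <- numeric(cfg$n_steps + 1L)
    for (t in seq_len(cfg$n_steps)) {
      nx <- x + rnorm(np, 0, sigma_um)
      ny <- y + rnorm(np, 0, sigma_um)
      if (domain$periodic) {
        cj <- pmin(nc, floor((nx %% W) / px) + 1L)
        ci <- pmin(nr, floor((ny %% H) / px) + 1L)
        ok <- mask[cbind(ci, cj)]
      } else {
        inside <- nx >= 0 & nx < W & ny >= 0 & ny < H
        ok <- inside
        if (any(inside)) {
          cj <- pmin(nc, floor(nx[inside] / px) + 1L)
          ci <- pmin(nr, floor(ny[inside] / px) + 1L)
          ok[inside] <- mask[cbind(ci, cj)]
        }
      }
      x[ok] <- nx[ok]
      y[ok] <- ny[ok]
      msd_um2[t + 1L] <- mean((x - x0)^2 + (y - y0)^2)
    }
    structure(list(times = seq(0, cfg$total_time, length.out =
                                 cfg$n_steps + 1L),
                   msd = msd_um2 * 1e-6, # um^2 -> mm^2
                   n_particles = np,
                   seed = cfg$seed),
              class = "msd_curve")
  })
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d particles, %d steps over %.3g ms; final MSD = %.3g mm^2\n",
              x$n_particles, length(x$times) - 1L, 1e3 * max(x$times),
              x$msd[length(x$msd)]))
  invisible(x)
}

#' Estimate the diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of MSD on time over all recorded points (free
#' intercept, robust to short-time boundary-layer curvature); the 2D
#' Einstein relation gives `D = slope / 4`.
#'
#' @param msd an `msd_curve` from [random_walk()], or a list with numeric
#'   `times` (s) and `msd` (mm^2).
#' @return diffusivity in mm^2/s.
#' @export
estimate_diffusivity <- function(msd) {
  stopifnot(!is.null(msd$times), !is.null(msd$msd),
            length(msd$times) == length(msd$msd))
  if (length(msd$times) < 2) stop("need at least 2 time points")
  if (diff(range(msd$times)) == 0) stop("zero time span")
  fit <- lm(msd$msd ~ msd$times)
  unname(coef(fit)[2]) / 4
}

#' Simulated-ADC map from an RGB histology image
#'
#' The image is tiled into subregions matching the cellularity-map
#' geometry. Within each subregion, nuclei are segmented by lightness
#' thresholding; the free space is the complement of the nucleus mask; a
#' random walk is simulated in that space (periodically tessellated) and
#' its estimated diffusivity becomes the subregion's sADC value.
#' Subregions with no free space are set to missing (NA). Each subregion
#' uses an independent seed derived from `cfg$seed`.
#'
#' @param image RGB array.
#' @param threshold lightness threshold for nucleus segmentation.
#' @param subregion_px subregion side in pixels (default 500).
#' @param cfg a [sim_config()].
#' @param pixel_size_um physical pixel size (um).
#' @return a [quant_map()] of sADC (mm^2/s).
#' @export
sadc_map <- function(image, threshold, subregion_px = 500L,
                     cfg = sim_config(), pixel_size_um = 0.23) {
  L <- if (is.matrix(image)) image else rgb_to_lightness(image)
  if (subregion_px > min(dim(L))) stop("subregion larger than image")
  nuc <- segment_nuclei(L, threshold)
  gr <- nrow(L) %/% subregion_px
  gc <- ncol(L) %/% subregion_px
  vals <- matrix(NA_real_, gr, gc)
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      block <- nuc[((i - 1) * subregion_px + 1):(i * subregion_px),
                   ((j - 1) * subregion_px + 1):(j * subregion_px)]
      free <- !block
      if (!any(free)) next # no diffusing space: leave missing
      sub_cfg <- cfg
      sub_cfg$seed <- derive_seed(cfg$seed, (i - 1L) * gc + j)
      dom <- diffusion_domain(free, pixel_size_um, periodic = TRUE)
      vals[i, j] <- estimate_diffusivity(random_walk(dom, sub_cfg))
    }
  }
  quant_map(vals, subregion_px, pixel_size_um, quantity = "sadc",
            seed = cfg$seed)
}

#' Random-disc obstacle domain at a target free-space fraction
#'
#' Places discs (overlap allowed) of a given radius at uniform random
#' centres until the free-space fraction drops to the target. Used by the
#' tortuosity power-law sweep.
#'
#' @param size_px domain side length in pixels (square).
#' @param free_fraction target fraction of free pixels, in (0, 1\].
#' @param radius_um disc radius (um).
#' @param pixel_size_um physical pixel size (um).
#' @param seed integer seed or NULL.
#' @return a [diffusion_domain()] (periodic).
#' @export
disc_domain <- function(size_px = 400L, free_fraction = 0.7,
                        radius_um = 4.66, pixel_size_um = 0.23,
                        seed = NULL) {
  stopifnot(free_fraction > 0, free_fraction <= 1, radius_um > 0)
  n <- as.integer(size_px)
  mask <- matrix(TRUE, n, n)
  if (free_fraction < 1) {
    r_px <- radius_um / pixel_size_um
    # precompute a disc stamp
    rr <- ceiling(r_px)
    off <- expand.grid(dr = -rr:rr, dc = -rr:rr)
    off <- off[off$dr^2 + off$dc^2 <= r_px^2, ]
    with_seed(seed, {
      max_discs <- ceiling(4 * n * n / nrow(off))
      for (d in seq_len(max_discs)) {
        if (mean(mask) <= free_fraction) break
        ci <- sample.int(n, 1L); cj <- sample.int(n, 1L)
        # periodic wrap of the stamp
        ri <- ((ci + off$dr - 1L) %% n) + 1L
        rj <- ((cj + off$dc - 1L) %% n) + 1L
        mask[cbind(ri, rj)] <- FALSE
      }
    })
  }
  diffusion_domain(mask, pixel_size_um, periodic = TRUE)
}

#' Tortuosity power-law validation sweep
#'
#' Simulates the random walk in random-disc domains across a series of
#' free-space fractions and fits the power law
#' `log(sADC) = log(D0) + tau * log(eps)` by least squares, where `eps`
#' is the realized free fraction of each domain. Levels whose realized
#' free space is empty are skipped with a warning.
#'
#' @param free_fractions numeric vector of target free-space fractions in
#'   (0, 1\]; at least 4 levels.
#' @param cfg a [sim_config()]; per-level seeds are derived from
#'   `cfg$seed`.
#' @param size_px domain side in pixels.
#' @param radius_um disc radius (um).
#' @param pixel_size_um physical pixel size (um).
#' @return object of class `tortuosity_sweep`: `table` (data.frame with
#'   `eps`, `sadc`), `tau`, `D0`, `r_squared`.
#' @export
tortuosity_sweep <- function(free_fractions, cfg = sim_config(),
                             size_px = 400L, radius_um = 4.66,
                             pixel_size_um = 0.23) {
  stopifnot(all(free_fractions > 0), all(free_fractions <= 1))
  if (length(free_fractions) < 4) stop("need at least 4 fraction levels")
  eps <- numeric(0); sadc <- numeric(0)
  for (i in seq_along(free_fractions)) {
    dom <- tryCatch(
      disc_domain(size_px, free_fractions[i], radius_um, pixel_size_um,
                  seed = derive_seed(cfg$seed, 1000L + i)),
      error = function(e) NULL)
    if (is.null(dom)) {
      warning("no free space at target fraction ", free_fractions[i],
              "; level skipped")
      next
    }
    sub_cfg <- cfg
    sub_cfg$seed <- derive_seed(cfg$seed, i)
    d_hat <- estimate_diffusivity(random_walk(dom, sub_cfg))
    eps <- c(eps, mean(dom$free_mask))
    sadc <- c(sadc, d_hat)
  }
  fit <- lm(log(sadc) ~ log(eps))
  r2 <- summary(fit)$r.squared
  structure(list(table = data.frame(eps = eps, sadc = sadc),
                 tau = unname(coef(fit)[2]),
                 D0 = exp(unname(coef(fit)[1])),
                 r_squared = r2),
            class = "tortuosity_sweep")
}

#' @export
print.tortuosity_sweep <- function(x, ...) {
  cat(sprintf("<tortuosity_sweep> %d levels: tau = %.3f, D0 = %.3g mm^2/s, r^2 = %.3f\n",
              nrow(x$table), x$tau, x$D0, x$r_squared))
  invisible(x)
}
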