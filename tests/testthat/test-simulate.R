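test_that("free Brownian motion reproduces the Einstein relation", {
  dom <- diffusion_domain(matrix(TRUE, 200, 200), 0.23)
  cfg <- sim_config(n_particles = 2000, n_steps = 600, seed = 42)
  msd <- random_walk(dom, cfg)
  expect_equal(msd$msd[1], 0)
  expect_true(all(diff(msd$times) > 0))
  # MSD after k steps = 4 Df t within Monte-Carlo error
  k <- length(msd$msd)
  expected <- 4 * cfg$free_diffusivity * msd$times[k]
  expect_lt(abs(msd$msd[k] - expected) / expected, 0.1)
  d <- estimate_diffusivity(msd)
  expect_lt(abs(d - 3.0e-3) / 3.0e-3, 0.05)
})

test_that("confinement suppresses displacement", {
  # single free pixel, non-periodic: every step leaving it is rejected,
  # so the MSD plateaus at the pixel scale (with the tessellated field a
  # lone free pixel becomes a lattice of free sites instead, and hops
  # between images keep the MSD growing)
  mask <- matrix(FALSE, 5, 5)
  mask[3, 3] <- TRUE
  dom <- diffusion_domain(mask, 0.23, periodic = FALSE)
  cfg <- sim_config(n_particles = 300, n_steps = 300, seed = 1)
  msd <- random_walk(dom, cfg)
  # displacement bounded by the pixel diagonal
  expect_lt(max(msd$msd), 2 * (0.23 * 1e-3)^2)
  d_free <- estimate_diffusivity(random_walk(
    diffusion_domain(matrix(TRUE, 5, 5), 0.23), cfg))
  expect_lt(estimate_diffusivity(msd), 0.05 * d_free)
})

test_that("obstacles reduce the MSD slope", {
  set.seed(5)
  free <- diffusion_domain(matrix(TRUE, 150, 150), 0.23)
  obst <- diffusion_domain(matrix(runif(150 * 150) > 0.5, 150, 150), 0.23)
  cfg <- sim_config(n_particles = 1200, n_steps = 400, seed = 9)
  d_free <- estimate_diffusivity(random_walk(free, cfg))
  d_obst <- estimate_diffusivity(random_walk(obst, cfg))
  expect_lt(d_obst, d_free)
})

test_that("diffusivity estimation inverts the 2D Einstein relation", {
  times <- seq(0, 8.67e-3, length.out = 100)
  exact <- list(times = times, msd = 4 * 3.0e-3 * times)
  expect_equal(estimate_diffusivity(exact), 3.0e-3, tolerance = 1e-12)
  half <- list(times = times, msd = 0.5 * exact$msd)
  expect_equal(estimate_diffusivity(half), 1.5e-3, tolerance = 1e-12)
  expect_error(estimate_diffusivity(list(times = 1, msd = 0)), "2 time")
  expect_error(estimate_diffusivity(list(times = c(1, 1), msd = c(0, 0))),
               "zero time span")
})

test_that("identical seeds reproduce walks bit-identically", {
  dom <- disc_domain(120, 0.7, seed = 3)
  cfg <- sim_config(n_particles = 500, n_steps = 200, seed = 17)
  a <- random_walk(dom, cfg)
  b <- random_walk(dom, cfg)
  expect_identical(a$msd, b$msd)
  cfg2 <- sim_config(n_particles = 500, n_steps = 200, seed = 18)
  expect_false(identical(random_walk(dom, cfg2)$msd, a$msd))
})

test_that("estimated D decreases over nested obstacle sets", {
  # same seed places discs in the same order, so lower free-fraction
  # targets yield supersets of the obstacle set
  cfg <- sim_config(n_particles = 800, n_steps = 300, seed = 4)
  fracs <- c(0.95, 0.8, 0.65, 0.5)
  masks <- lapply(fracs, function(f)
    disc_domain(150, f, seed = 12)$free_mask)
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]])) # nested
  }
  ds <- vapply(masks, function(m)
    estimate_diffusivity(random_walk(diffusion_domain(m, 0.23), cfg)),
    numeric(1))
  expect_true(all(diff(ds) < 0))
})

test_that("periodic slab geometry matches the free-axis prediction", {
  # horizontal free bands spanning the full width: x-motion stays free,
  # y-motion is confined, so the long-time MSD slope tends to 2 Df t
  # and the estimator returns Df / 2
  mask <- matrix(FALSE, 120, 120)
  band <- rep(c(TRUE, FALSE), each = 10, length.out = 120)
  mask[band, ] <- TRUE
  dom <- diffusion_domain(mask, 0.23)
  cfg <- sim_config(n_particles = 3000, n_steps = 1500, seed = 8)
  msd <- random_walk(dom, cfg)
  # fit the late-time slope where the confined axis has plateaued
  late <- seq(round(0.6 * length(msd$times)), length(msd$times))
  slope <- coef(lm(msd$msd[late] ~ msd$times[late]))[2]
  expect_lt(abs(slope / 4 - 0.5 * cfg$free_diffusivity) /
              (0.5 * cfg$free_diffusivity), 0.05)
})

test_that("sADC maps respect the free-diffusivity ceiling", {
  cfg <- sim_config(n_particles = 400, n_steps = 250, seed = 6)
  # blank white image: sADC ~ Df everywhere
  white <- matrix(99, 200, 200)
  m <- sadc_map(white, threshold = 50, subregion_px = 100, cfg = cfg)
  expect_true(all(abs(m$values - 3.0e-3) / 3.0e-3 < 0.1))
  # synthetic tissue: strictly below Df wherever nuclei are present
  tis <- shared_tissue()
  L <- rgb_to_lightness(tis$image[1:400, 1:400, ])
  sm <- sadc_map(L, 50, 200, cfg)
  nf <- histodiff:::block_reduce(segment_nuclei(L, 50) * 1, 200, "mean")
  expect_true(all(sm$values[nf > 0.01] < 3.0e-3))
})

test_that("mean sADC decreases with planted cellularity", {
  cfg <- sim_config(n_particles = 400, n_steps = 250, seed = 13)
  dens <- c(1000, 5000, 10000)
  mean_sadc <- vapply(dens, function(dn) {
    tis <- generate_tissue(tissue_spec(image_size_px = c(300, 300),
                                       target_cellularity = dn,
                                       target_luminal_fraction = 0,
                                       seed = 500 + dn))
    L <- rgb_to_lightness(tis$image)
    mean(sadc_map(L, 50, 150, cfg)$values)
  }, numeric(1))
  expect_true(all(diff(mean_sadc) < 0))
})

test_that("subregions with no free space become missing, not zero", {
  L <- matrix(10, 100, 100) # everything "nucleus" at t = 50
  L[1:50, 1:50] <- 95
  m <- sadc_map(L, 50, 50, sim_config(100, 50, seed = 2))
  expect_true(is.finite(m$values[1, 1]))
  expect_true(all(is.na(m$values[c(2, 3, 4)])))
})

test_that("tortuosity sweep recovers a power law with physical exponent", {
  cfg <- sim_config(n_particles = 1000, n_steps = 500, seed = 21)
  sw <- tortuosity_sweep(c(0.45, 0.55, 0.65, 0.75, 0.85, 1.0), cfg,
                         size_px = 250)
  expect_equal(nrow(sw$table), 6)
  expect_gt(sw$r_squared, 0.9)
  expect_gt(sw$tau, 0)
  expect_lt(sw$tau, 1)
  # the eps = 1 level sits at sADC ~ Df
  expect_lt(abs(sw$table$sadc[6] / cfg$free_diffusivity - 1), 0.1)
  expect_error(tortuosity_sweep(c(0.5, 0.7), cfg), "at least 4")
})

test_that("domains and configs validate their inputs", {
  expect_error(diffusion_domain(matrix(FALSE, 5, 5)), "no free space")
  expect_error(sim_config(n_particles = 0), "n_particles")
  expect_warning(
    random_walk(diffusion_domain(matrix(TRUE, 2, 2), 0.01),
                sim_config(10, 2, total_time = 10, seed = 1)),
    "tessellation")
})
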