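ref_params <- model_params(2.18e-3, 68.17, 0.599)

test_that("area fraction converts cellularity with unit reconciliation", {
  expect_equal(area_fraction(0, 68.17), 1)
  expect_equal(area_fraction(1e6 / 68.17, 68.17), 0)
  expect_equal(area_fraction(5000, 68.17), 0.65915, tolerance = 1e-10)
  expect_error(area_fraction(2e4, 68.17), "packing limit")
  expect_error(area_fraction(-1, 68.17), "non-negative")
})

test_that("forward power law evaluates ADC = D0 * eps^tau", {
  expect_equal(adc_forward(1, ref_params), 2.18e-3)
  expect_equal(adc_forward(0, ref_params), 0)
  expect_equal(adc_forward(0.6592, ref_params), 1.70e-3,
               tolerance = 2e-3)
  expect_equal(adc_forward(0.6592, ref_params),
               2.18e-3 * 0.6592^0.599, tolerance = 1e-12)
  expect_error(adc_forward(1.2, ref_params), "\\[0, 1\\]")
})

test_that("inverse model recovers the endpoints and rejects adc > D0", {
  expect_equal(cellularity_from_adc(ref_params$D0, ref_params), 0)
  expect_equal(cellularity_from_adc(0, ref_params), 1e6 / 68.17)
  expect_error(cellularity_from_adc(3e-3, ref_params), "exceeds D0")
  # printed exponent variant differs from the consistent one
  a <- cellularity_from_adc(1e-3, ref_params, exponent = "consistent")
  b <- cellularity_from_adc(1e-3, ref_params, exponent = "printed")
  expect_gt(abs(a - b) / a, 0.01)
})

test_that("forward/inverse composition is the identity over valid inputs", {
  withr::with_seed(19, {
    C <- runif(1000, 0, 0.999e6 / 68.17)
    for (ex in c("consistent", "printed")) {
      p <- ref_params
      adc <- if (ex == "consistent") {
        adc_forward(area_fraction(C, p$An_bar), p)
      } else {
        p$D0 * area_fraction(C, p$An_bar)^(2 * p$tau)
      }
      back <- cellularity_from_adc(adc, p, exponent = ex)
      expect_lt(max(abs(back - C)) / max(C), 1e-10)
    }
  })
})

test_that("equivalent circular radius follows sqrt(area/pi)", {
  expect_equal(equivalent_circle_radius(pi), 1)
  expect_equal(round(equivalent_circle_radius(68.17), 2), 4.66)
  expect_equal(equivalent_circle_radius(4 * pi),
               2 * equivalent_circle_radius(pi))
  expect_error(equivalent_circle_radius(-1), "positive")
})

test_that("noiseless cohorts are refit to machine-level accuracy", {
  rois <- generate_roi_dataset(ref_params, 40, c(1e3, 12e3),
                               noise_cv = 0, seed = 7)
  fit <- fit_cellularity_model(rois, n_boot = 0)
  expect_lt(abs(fit$params$D0 - 2.18e-3) / 2.18e-3, 1e-3)
  expect_lt(abs(fit$params$An_bar - 68.17) / 68.17, 1e-3)
  expect_lt(abs(fit$params$tau - 0.599) / 0.599, 1e-3)
  expect_gt(fit$r_squared, 0.999999)
})

test_that("parameter recovery under 3% noise is accurate on average", {
  errs <- vapply(seq_len(60), function(s) {
    rois <- generate_roi_dataset(ref_params, 40, c(1e3, 12e3),
                                 noise_cv = 0.03, seed = 3000 + s)
    f <- fit_cellularity_model(rois, n_boot = 0)
    c(abs(f$params$D0 - 2.18e-3) / 2.18e-3,
      abs(f$params$An_bar - 68.17) / 68.17,
      abs(f$params$tau - 0.599) / 0.599)
  }, numeric(3))
  med <- apply(errs, 1, median)
  expect_lt(med[1], 0.10) # D0
  expect_lt(med[2], 0.10) # An_bar
  # tau is the weakly identified parameter at this design and noise:
  # its sampling sd is ~13%, so the median error sits near 10%
  expect_lt(med[3], 0.15)
})

test_that("eiv refinement removes the errors-in-variables tau bias", {
  signed <- vapply(seq_len(25), function(s) {
    rois <- generate_roi_dataset(ref_params, 50, c(1e3, 12e3),
                                 noise_cv = 0.03, seed = 4000 + s)
    nls_f <- fit_cellularity_model(rois, n_boot = 0)
    eiv_f <- fit_cellularity_model(rois, n_boot = 0, method = "eiv")
    c(nls = (nls_f$params$tau - 0.599) / 0.599,
      eiv = (eiv_f$params$tau - 0.599) / 0.599)
  }, c(nls = 0, eiv = 0))
  expect_lt(abs(mean(signed["eiv", ])), abs(mean(signed["nls", ])))
})

test_that("bootstrap CIs cover the generating D0 and widen with noise", {
  hits <- 0L
  n_rep <- 30L
  for (s in seq_len(n_rep)) {
    rois <- generate_roi_dataset(ref_params, 40, c(1e3, 12e3),
                                 noise_cv = 0.03, seed = 5000 + s)
    f <- fit_cellularity_model(rois, n_boot = 250, seed = 6000 + s)
    ci <- f$ci95["D0", ]
    if (ci[1] <= 2.18e-3 && 2.18e-3 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)

  widths <- vapply(c(0.01, 0.03, 0.06), function(cv) {
    rois <- generate_roi_dataset(ref_params, 40, c(1e3, 12e3),
                                 noise_cv = cv, seed = 777)
    f <- fit_cellularity_model(rois, n_boot = 150, seed = 888)
    unname(diff(f$ci95["D0", ]))
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("linear fitting returns exact results on exact lines", {
  x <- 1:10
  f <- fit_linear(x, 2 * x + 1, n_boot = 0)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  fc <- fit_linear(x, rep(3, 10), n_boot = 0)
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$r_squared, 0)
  expect_error(fit_linear(rep(1, 5), 1:5), "zero variance")
})

test_that("planted luminal-fraction line is recovered within its CI", {
  withr::with_seed(23, {
    adc <- runif(40, 0.5e-3, 2.5e-3)
    lf <- 16.3 * adc * 1e3 - 3.33 + rnorm(40, 0, 2)
  })
  f <- fit_linear(adc * 1e3, lf, n_boot = 500, seed = 31)
  expect_true(f$ci95["slope", 1] <= 16.3 && 16.3 <= f$ci95["slope", 2])
  expect_true(f$ci95["intercept", 1] <= -3.33 &&
                -3.33 <= f$ci95["intercept", 2])
})

test_that("LOAO cross-validation is exact on noiseless cohorts", {
  rois <- generate_roi_dataset(ref_params, 40, c(1e3, 12e3),
                               noise_cv = 0, seed = 13, n_animals = 5)
  cv <- loao_crossvalidate(rois, "cellularity")
  expect_lt(cv$median_abs_relative_deviation, 1e-6)
  expect_lt(cv$nrmse, 1e-6)
  expect_equal(nrow(cv$per_fold), 40)
  # noise raises the deviation
  roisN <- generate_roi_dataset(ref_params, 40, c(1e3, 12e3),
                                noise_cv = 0.05, seed = 13, n_animals = 5)
  cvN <- loao_crossvalidate(roisN, "cellularity")
  expect_gt(cvN$median_abs_relative_deviation,
            cv$median_abs_relative_deviation)
  # single animal owning everything is rejected
  rois1 <- rois
  rois1$animal_id <- "only"
  expect_error(loao_crossvalidate(rois1, "cellularity"), "2 animals")
})

test_that("NRMSE is invariant under affine rescaling of the target", {
  rois <- generate_roi_dataset(ref_params, 30, c(1e3, 12e3),
                               noise_cv = 0.05, seed = 41, n_animals = 3)
  cv1 <- loao_crossvalidate(rois, "luminal")
  rois2 <- rois
  rois2$luminal_fraction <- rois2$luminal_fraction * 10
  cv2 <- loao_crossvalidate(rois2, "luminal")
  expect_equal(cv1$nrmse, cv2$nrmse, tolerance = 1e-10)
})
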