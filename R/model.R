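#' Parameters of the stereological ADC-cellularity model
#'
#' The biophysical model treats an imaging voxel as impermeable
#' non-diffusing volumes (cells/nuclei, mean cross-sectional area
#' `An_bar`) bathed in a fluid of diffusivity `D0`. The diffusing-space
#' fraction `eps = 1 - An_bar * C` (with C the cellularity) maps to the
#' measured ADC through the tortuosity power law `ADC = D0 * eps^tau`.
#'
#' @param D0 fluid-compartment diffusivity, mm^2/s.
#' @param An_bar mean non-diffusing cross-sectional area, um^2.
#' @param tau tortuosity exponent (unitless, > 0).
#' @return object of class `model_params`.
#' @export
model_params <- function(D0, An_bar, tau) {
  stopifnot(is.finite(D0), D0 > 0, is.finite(An_bar), An_bar > 0,
            is.finite(tau), tau > 0)
  structure(list(D0 = D0, An_bar = An_bar, tau = tau),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> D0 = %.4g mm^2/s, An_bar = %.4g um^2, tau = %.4g\n",
              x$D0, x$An_bar, x$tau))
  invisible(x)
}

#' Diffusing-space area fraction from cellularity
#'
#' `eps2 = 1 - An_bar * C`, with `An_bar` converted from um^2 to mm^2 so
#' the product with cellularity (cells/mm^2) is unitless. By the
#' stereological approximation, this cross-sectional area fraction also
#' estimates the voxel volume fraction of diffusing fluid.
#'
#' @param C cellularity, cells/mm^2 (vectorized).
#' @param An_bar mean non-diffusing cross-sectional area, um^2.
#' @return area fraction(s) in \[0, 1\].
#' @export
area_fraction <- function(C, An_bar) {
  stopifnot(An_bar > 0, all(is.finite(C)))
  if (any(C < 0)) stop("cellularity must be non-negative")
  eps <- 1 - An_bar * 1e-6 * C
  if (any(eps < -1e-12)) {
    stop(sprintf("cellularity exceeds packing limit 1/An_bar = %.0f cells/mm^2",
                 1 / (An_bar * 1e-6)))
  }
  pmax(eps, 0)
}

#' Forward model: ADC from diffusing-space fraction
#' @param eps area/volume fraction of diffusing space, in \[0, 1\].
#' @param params a [model_params()].
#' @return ADC in mm^2/s, `D0 * eps^tau`.
#' @export
adc_forward <- function(eps, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(eps < 0 | eps > 1)) stop("eps must lie in [0, 1]")
  params$D0 * eps^params$tau
}

#' Inverse model: cellularity from ADC
#'
#' Inverts the composed model `ADC = D0 * (1 - An_bar * C)^tau` to
#' `C = (1/An_bar) * (1 - (ADC/D0)^(1/tau))`. The algebraically
#' consistent exponent `1/tau` is the default; the historical printed
#' variant with exponent `1/(2*tau)` is available via
#' `exponent = "printed"` (the two differ and are never silently mixed).
#'
#' @param adc ADC in mm^2/s, in \[0, D0\] (vectorized).
#' @param params a [model_params()].
#' @param exponent `"consistent"` (1/tau, default) or `"printed"`
#'   (1/(2 tau)).
#' @return cellularity in cells/mm^2.
#' @export
cellularity_from_adc <- function(adc, params,
                                 exponent = c("consistent", "printed")) {
  stopifnot(inherits(params, "model_params"))
  exponent <- match.arg(exponent)
  if (any(adc < 0)) stop("adc must be non-negative")
  if (any(adc > params$D0 * (1 + 1e-12))) {
    stop("adc exceeds D0: diffusing fraction would be negative")
  }
  p <- if (exponent == "consistent") 1 / params$tau else 1 / (2 * params$tau)
  (1 / (params$An_bar * 1e-6)) * (1 - pmin(adc / params$D0, 1)^p)
}

#' Equivalent circular radius of the mean non-diffusing area
#' @param area cross-sectional area in um^2 (> 0).
#' @return radius in um, `sqrt(area / pi)`.
#' @export
equivalent_circle_radius <- function(area) {
  if (any(!is.finite(area) | area <= 0)) stop("area must be positive")
  sqrt(area / pi)
}

# model prediction of cellularity from ADC for given raw parameters
predict_cellularity <- function(adc, D0, An_bar, tau, p_exp) {
  (1 / (An_bar * 1e-6)) * (1 - pmin(pmax(adc / D0, 0), 1)^p_exp)
}

#' Fit the ADC-cellularity model to ROI data by nonlinear least squares
#'
#' Fits `C = (1/An_bar) * (1 - (ADC/D0)^(1/tau))` to per-ROI
#' (ADC, cellularity) pairs with a multi-start Levenberg-Marquardt
#' trust-region solver; 95% confidence intervals by nonparametric
#' bootstrap over ROIs (percentile method).
#'
#' Two estimators are available. `method = "nls"` (default) is ordinary
#' nonlinear least squares of cellularity on ADC. Because ADC enters as a
#' noisy predictor, NLS carries a small errors-in-variables bias
#' (tau tends to be overestimated when both coordinates are noisy);
#' `method = "eiv"` fits an orthogonal-distance (errors-in-variables)
#' criterion assuming equal relative noise on both coordinates, which
#' removes that bias at some computational cost.
#'
#' @param rois data.frame with numeric columns `adc` (mm^2/s) and
#'   `cellularity` (cells/mm^2); at least 4 rows.
#' @param exponent inverse-model exponent convention, see
#'   [cellularity_from_adc()].
#' @param n_boot bootstrap resamples for CIs (0 disables CIs).
#' @param seed seed for the bootstrap.
#' @param method `"nls"` (default) or `"eiv"`.
#' @return object of class `model_fit`: `params` ([model_params()]),
#'   `ci95` (3 x 2 matrix or NULL), `r_squared`, `residuals`, `rss`,
#'   `exponent`, `n`.
#' @export
fit_cellularity_model <- function(rois, exponent = c("consistent", "printed"),
                                  n_boot = 2000L, seed = NULL,
                                  method = c("nls", "eiv")) {
  exponent <- match.arg(exponent)
  method <- match.arg(method)
  stopifnot(is.data.frame(rois), all(c("adc", "cellularity") %in% names(rois)))
  adc <- rois$adc; C <- rois$cellularity
  ok <- is.finite(adc) & is.finite(C) & adc > 0 & C > 0
  adc <- adc[ok]; C <- C[ok]
  if (length(adc) < 4) stop("need at least 4 ROIs with positive adc and cellularity")

  point_est <- function(a, cc) {
    est <- fit_cellularity_nls(a, cc, exponent)
    if (method == "eiv") est <- fit_cellularity_eiv(a, cc, exponent, est)
    est
  }
  point <- point_est(adc, C)
  pred <- predict_cellularity(adc, point["D0"], point["An_bar"], point["tau"],
                              if (exponent == "consistent") 1 / point["tau"]
                              else 1 / (2 * point["tau"]))
  resid <- C - pred
  rss <- sum(resid^2)
  r2 <- 1 - rss / sum((C - mean(C))^2)

  ci95 <- NULL
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(length(adc), replace = TRUE)
        tryCatch(point_est(adc[idx], C[idx]),
                 error = function(e) c(D0 = NA_real_, An_bar = NA_real_,
                                       tau = NA_real_))
      }, numeric(3))
    })
    ci95 <- t(apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
                    na.rm = TRUE))
    colnames(ci95) <- c("lower", "upper")
  }

  structure(list(params = model_params(point["D0"], point["An_bar"],
                                       point["tau"]),
                 ci95 = ci95, r_squared = r2, residuals = resid,
                 rss = rss, exponent = exponent, n = length(adc)),
            class = "model_fit")
}

# multi-start LM fit; returns named c(D0, An_bar, tau)
fit_cellularity_nls <- function(adc, C, exponent) {
  form <- if (exponent == "consistent") {
    C ~ (1 / (An_bar * 1e-6)) *
      (1 - pmin(pmax(adc / D0, 1e-12), 1)^(1 / tau))
  } else {
    C ~ (1 / (An_bar * 1e-6)) *
      (1 - pmin(pmax(adc / D0, 1e-12), 1)^(1 / (2 * tau)))
  }
  a_max <- max(adc)
  # starts: log-spaced D0 above max(adc) crossed with a tau grid;
  # An_bar started from the packing implied by the largest cellularity
  d0_starts <- a_max * c(1.02, 1.15, 1.4, 2, 3)
  tau_starts <- c(0.3, 0.5, 0.6, 0.8, 1.2)
  an_start <- 0.8e6 / max(C)
  best <- NULL
  for (i in seq_along(d0_starts)) {
    st <- list(D0 = d0_starts[i], An_bar = an_start, tau = tau_starts[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form,
        data = data.frame(C = C, adc = adc),
        start = st,
        lower = c(D0 = a_max * 1.0001, An_bar = 1e-3, tau = 1e-3),
        upper = c(D0 = 1, An_bar = 1e4, tau = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(rss = rss, coef = coef(fit))
      }
    }
  }
  if (is.null(best)) {
    stop("nonlinear fit failed to converge from every start; ",
         "check that adc and cellularity are inversely related")
  }
  c(D0 = unname(best$coef["D0"]), An_bar = unname(best$coef["An_bar"]),
    tau = unname(best$coef["tau"]))
}

# orthogonal-distance refinement: minimize, over parameters and latent
# per-point cellularities, the sum of squared relative deviations in both
# coordinates (equal relative noise assumed). `start` is a named
# c(D0, An_bar, tau) from the NLS fit.
fit_cellularity_eiv <- function(adc, C, exponent, start) {
  tau_pow <- if (exponent == "consistent") 1 else 2
  nll <- function(par) {
    D0 <- exp(par[1]); An <- exp(par[2]); tau <- exp(par[3]) / tau_pow
    tot <- 0
    for (i in seq_along(adc)) {
      f <- function(Cs) {
        A <- D0 * max(1 - An * 1e-6 * Cs, 1e-12)^(tau * tau_pow)
        ((C[i] - Cs) / C[i])^2 + ((adc[i] - A) / adc[i])^2
      }
      hi <- min(C[i] * 1.5, 0.999e6 / An)
      tot <- tot + stats::optimize(f, c(C[i] * 0.5, hi))$objective
    }
    tot
  }
  o <- stats::optim(log(c(start["D0"], start["An_bar"],
                          start["tau"] * tau_pow)), nll,
                    control = list(maxit = 1000, reltol = 1e-10))
  est <- exp(o$par)
  c(D0 = unname(est[1]), An_bar = unname(est[2]),
    tau = unname(est[3]) / tau_pow)
}

#' @export
print.model_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<model_fit> n = %d, exponent = %s\n", x$n, x$exponent))
  cat(sprintf("  D0     = %.4g mm^2/s\n  An_bar = %.4g um^2\n  tau    = %.4g\n",
              p$D0, p$An_bar, p$tau))
  if (!is.null(x$ci95)) {
    for (nm in rownames(x$ci95)) {
      cat(sprintf("  95%% CI %s: (%.4g, %.4g)\n", nm,
                  x$ci95[nm, 1], x$ci95[nm, 2]))
    }
  }
  cat(sprintf("  r^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' Ordinary least-squares linear fit with bootstrap confidence intervals
#'
#' @param x,y numeric vectors (>= 3 points; x must vary).
#' @param n_boot bootstrap resamples for the 95% CIs (0 disables).
#' @param seed seed for the bootstrap.
#' @return object of class `linear_fit`: `slope`, `intercept`, `ci95`
#'   (2 x 2 matrix or NULL), `r_squared`, `residuals`, `n`.
#' @export
fit_linear <- function(x, y, n_boot = 2000L, seed = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite points")
  if (stats::sd(x) == 0) stop("x has zero variance; slope undefined")
  fit <- lm(y ~ x)
  co <- coef(fit)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(resid(fit)^2) / tss
  ci95 <- NULL
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(length(x), replace = TRUE)
        if (stats::sd(x[idx]) == 0) return(c(NA_real_, NA_real_))
        rev_ab <- coef(lm(y[idx] ~ x[idx]))
        c(rev_ab[2], rev_ab[1])
      }, numeric(2))
    })
    ci95 <- t(apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
                    na.rm = TRUE))
    dimnames(ci95) <- list(c("slope", "intercept"), c("lower", "upper"))
  }
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 ci95 = ci95, r_squared = r2,
                 residuals = unname(resid(fit)), n = length(x)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope = %.4g, intercept = %.4g, r^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  if (!is.null(x$ci95)) {
    cat(sprintf("  95%% CI slope: (%.4g, %.4g); intercept: (%.4g, %.4g)\n",
                x$ci95["slope", 1], x$ci95["slope", 2],
                x$ci95["intercept", 1], x$ci95["intercept", 2]))
  }
  invisible(x)
}

#' Leave-one-animal-out cross-validation of ADC-based prediction
#'
#' For each animal: fit the chosen model (`"cellularity"` = stereological
#' power law; `"luminal"` = linear luminal-fraction-on-ADC fit) to all
#' other animals' ROIs, predict the held-out animal's ROIs from their ADC,
#' and record the absolute relative deviation `|pred - obs| / obs`.
#' Reports the median deviation over all held-out ROIs and the NRMSE
#' (RMSE divided by the observed range).
#'
#' @param rois data.frame with columns `animal_id`, `adc`, and the target
#'   column (`cellularity` or `luminal_fraction`).
#' @param model `"cellularity"` or `"luminal"`.
#' @param exponent exponent convention for the cellularity model.
#' @return object of class `cv_result`: `median_abs_relative_deviation`,
#'   `nrmse`, `per_fold` (data.frame with animal, observed, predicted).
#' @export
loao_crossvalidate <- function(rois, model = c("cellularity", "luminal"),
                               exponent = c("consistent", "printed")) {
  model <- match.arg(model)
  exponent <- match.arg(exponent)
  target <- if (model == "cellularity") "cellularity" else "luminal_fraction"
  stopifnot(is.data.frame(rois),
            all(c("animal_id", "adc", target) %in% names(rois)))
  animals <- unique(rois$animal_id)
  if (length(animals) < 2) stop("need at least 2 animals for LOAO")
  per <- list()
  for (an in animals) {
    train <- rois[rois$animal_id != an, , drop = FALSE]
    test <- rois[rois$animal_id == an, , drop = FALSE]
    if (nrow(train) == 0) {
      stop("animal ", an, " owns all ROIs; cannot cross-validate")
    }
    pred <- if (model == "cellularity") {
      fit <- fit_cellularity_model(train, exponent = exponent, n_boot = 0)
      cellularity_from_adc(pmin(test$adc, fit$params$D0), fit$params,
                           exponent = exponent)
    } else {
      fit <- fit_linear(train$adc, train$luminal_fraction, n_boot = 0)
      fit$intercept + fit$slope * test$adc
    }
    per[[an]] <- data.frame(animal_id = an,
                            observed = test[[target]],
                            predicted = pred)
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  obs <- per$observed
  dev <- abs(per$predicted - obs) / abs(obs)
  rmse <- sqrt(mean((per$predicted - obs)^2))
  rng <- diff(range(obs))
  structure(list(median_abs_relative_deviation = stats::median(dev),
                 nrmse = if (rng > 0) rmse / rng else NA_real_,
                 per_fold = per, model = model),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> model = %s: median |rel dev| = %.1f%%, NRMSE = %.3f (%d ROIs)\n",
              x$model, 100 * x$median_abs_relative_deviation, x$nrmse,
              nrow(x$per_fold)))
  invisible(x)
}
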