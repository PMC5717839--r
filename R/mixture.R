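#' Assemble per-pixel microstructure triples from co-registered maps
#'
#' Joins cellularity, luminal-fraction and sADC maps that share the same
#' grid geometry into one table of per-pixel triples, dropping pixels that
#' are missing in any map.
#'
#' @param cell_map,lf_map,sadc_map_ [quant_map()]s on identical grids.
#' @return data.frame with columns `row`, `col`, `cellularity`,
#'   `luminal_fraction`, `sadc`.
#' @export
pixel_triples <- function(cell_map, lf_map, sadc_map_) {
  maps <- list(cell_map, lf_map, sadc_map_)
  dims <- lapply(maps, function(m) dim(m$values))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("maps do not share a common grid geometry")
  }
  idx <- expand.grid(row = seq_len(nrow(cell_map$values)),
                     col = seq_len(ncol(cell_map$values)))
  df <- data.frame(row = idx$row, col = idx$col,
                   cellularity = cell_map$values[cbind(idx$row, idx$col)],
                   luminal_fraction = lf_map$values[cbind(idx$row, idx$col)],
                   sadc = sadc_map_$values[cbind(idx$row, idx$col)])
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Two-component mixture of linear regressions by EM
#'
#' Models sADC as a mixture of linear regressions on cellularity and
#' luminal fraction with Gaussian residuals: each pixel belongs to one of
#' two linear "compartments". Fitted by expectation-maximization from
#' several random starts (best log-likelihood wins). Components are
#' ordered by the mean luminal fraction of their hard assignments, so
#' component 1 is the tissue compartment (low luminal fraction) and
#' component 2 the lumen compartment.
#'
#' @param triples data.frame with columns `cellularity`,
#'   `luminal_fraction`, `sadc` (e.g. from [pixel_triples()]).
#' @param n_components number of components (2).
#' @param n_restarts random EM restarts.
#' @param seed integer seed or NULL.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @return object of class `mixture_fit`: `coefficients` (3 x K matrix:
#'   intercept, cellularity, luminal_fraction), `residual_sd`, `weights`,
#'   `posteriors` (n x K), `log_likelihood`, `loglik_trace`, `n_iter`,
#'   `assignments` (hard labels), `triples`.
#' @export
fit_lmm <- function(triples, n_components = 2L, n_restarts = 10L,
                    seed = NULL, max_iter = 500L, tol = 1e-8) {
  stopifnot(all(c("cellularity", "luminal_fraction", "sadc") %in%
                  names(triples)))
  K <- as.integer(n_components)
  n <- nrow(triples)
  if (n < 10 * K) stop("need at least ", 10 * K, " pixels for ", K,
                       " components")
  y <- triples$sadc
  X <- cbind(1, triples$cellularity, triples$luminal_fraction)
  colnames(X) <- c("intercept", "cellularity", "luminal_fraction")

  best <- NULL
  seeds <- vapply(seq_len(n_restarts), function(r) {
    s <- derive_seed(seed, r)
    if (is.null(s)) NA_integer_ else s
  }, integer(1))
  for (r in seq_len(n_restarts)) {
    rs <- if (is.na(seeds[r])) NULL else seeds[r]
    run <- tryCatch(em_linear_mixture(y, X, K, rs, max_iter, tol),
                    error = function(e) NULL)
    if (!is.null(run) && !run$degenerate &&
        (is.null(best) || run$loglik > best$loglik)) {
      best <- run
    }
  }
  if (is.null(best)) {
    stop("every EM restart degenerated (a component captured fewer than ",
         "1/n of the weight); the data may not support ", K, " components")
  }

  # order components by mean luminal fraction of hard assignments
  hard <- max.col(best$post)
  mean_lf <- vapply(seq_len(K), function(k) {
    sel <- hard == k
    if (any(sel)) mean(triples$luminal_fraction[sel]) else Inf
  }, numeric(1))
  ord <- order(mean_lf)
  structure(list(coefficients = best$beta[, ord, drop = FALSE],
                 residual_sd = best$sigma[ord],
                 weights = best$pi[ord],
                 posteriors = best$post[, ord, drop = FALSE],
                 log_likelihood = best$loglik,
                 loglik_trace = best$trace,
                 n_iter = best$iter,
                 assignments = order(ord)[hard],
                 triples = triples),
            class = "mixture_fit")
}

# EM core for a K-component mixture of Gaussian linear regressions
em_linear_mixture <- function(y, X, K, seed, max_iter, tol) {
  n <- length(y); p <- ncol(X)
  with_seed(seed, {
    # random soft initialization
    post <- matrix(runif(n * K), n, K)
    post <- post / rowSums(post)
    pi_k <- rep(1 / K, K)
    beta <- matrix(0, p, K, dimnames = list(colnames(X), NULL))
    sigma <- rep(stats::sd(y), K)
    loglik <- -Inf
    trace <- numeric(0)
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      # M-step: weighted least squares per component
      for (k in seq_len(K)) {
        w <- post[, k]
        if (sum(w) < p + 1e-8) { degenerate <- TRUE; break }
        fit <- lm.wfit(X, y, w)
        beta[, k] <- fit$coefficients
        res <- y - X %*% beta[, k]
        sigma[k] <- sqrt(sum(w * res^2) / sum(w))
        if (!is.finite(sigma[k]) || sigma[k] < 1e-12 * stats::sd(y)) {
          degenerate <- TRUE; break
        }
      }
      pi_k <- colMeans(post)
      if (degenerate || any(pi_k < 1 / n)) { degenerate <- TRUE; break }
      # E-step in log space
      logd <- vapply(seq_len(K), function(k) {
        dnorm(y, mean = as.vector(X %*% beta[, k]), sd = sigma[k],
              log = TRUE) + log(pi_k[k])
      }, numeric(n))
      m <- apply(logd, 1, max)
      lse <- m + log(rowSums(exp(logd - m)))
      new_loglik <- sum(lse)
      post <- exp(logd - lse)
      trace <- c(trace, new_loglik)
      if (is.finite(loglik) &&
          abs(new_loglik - loglik) < tol * (abs(loglik) + 1e-12)) {
        loglik <- new_loglik
        break
      }
      loglik <- new_loglik
    }
    list(beta = beta, sigma = sigma, pi = pi_k, post = post,
         loglik = loglik, trace = trace, iter = length(trace),
         degenerate = degenerate)
  })
}

#' @export
print.mixture_fit <- function(x, ...) {
  K <- ncol(x$coefficients)
  cat(sprintf("<mixture_fit> %d components, logLik = %.2f (%d EM iterations)\n",
              K, x$log_likelihood, x$n_iter))
  for (k in seq_len(K)) {
    cat(sprintf("  C%d: weight %.2f, sADC = %.3g %+.3g*cellularity %+.3g*luminal_fraction, sd %.3g\n",
                k, x$weights[k], x$coefficients["intercept", k],
                x$coefficients["cellularity", k],
                x$coefficients["luminal_fraction", k], x$residual_sd[k]))
  }
  invisible(x)
}

#' Posterior class-probability maps from a mixture fit
#'
#' Places each pixel's posterior component probabilities back onto the
#' shared map grid; pixels absent from the fitted triples stay missing.
#'
#' @param fit a [fit_lmm()] result whose `triples` carry `row`/`col`
#'   map coordinates.
#' @param template a [quant_map()] providing the grid geometry.
#' @return list of `quant_map` objects, one per component, carrying
#'   unitless posterior probabilities in \[0, 1\] (quantity
#'   `"posterior_probability"`) on the template's grid geometry.
#' @export
posterior_maps <- function(fit, template) {
  stopifnot(inherits(fit, "mixture_fit"), inherits(template, "quant_map"))
  tri <- fit$triples
  if (is.null(tri$row) || is.null(tri$col)) {
    stop("fitted triples carry no map coordinates (row/col)")
  }
  if (max(tri$row) > nrow(template$values) ||
      max(tri$col) > ncol(template$values)) {
    stop("triples' coordinates exceed the template grid: geometry mismatch")
  }
  K <- ncol(fit$posteriors)
  lapply(seq_len(K), function(k) {
    vals <- matrix(NA_real_, nrow(template$values), ncol(template$values))
    vals[cbind(tri$row, tri$col)] <- fit$posteriors[, k]
    structure(list(values = vals,
                   subregion_px = template$subregion_px,
                   pixel_size_um = template$pixel_size_um,
                   quantity = "posterior_probability",
                   origin = template$origin, seed = NULL),
              class = "quant_map")
  })
}
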