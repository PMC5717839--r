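#' Average diffusion-weighted signals over gradient directions
#'
#' Arithmetic mean of the signal across directions at each b-value (the
#' trace-averaged decay curve). Averaging is done in the signal domain,
#' not the log domain.
#'
#' @param signal a `dwi_signal` from [generate_dwi_signal()], or a matrix
#'   with one row per b-value and one column per direction.
#' @return numeric vector of mean signal per b-value.
#' @export
average_directions <- function(signal) {
  m <- if (inherits(signal, "dwi_signal")) signal$signals else signal
  if (!is.matrix(m)) stop("expected a dwi_signal or a b x direction matrix")
  unname(rowMeans(m))
}

#' Fit the monoexponential diffusion model S(b) = S0 exp(-b ADC)
#'
#' Default is log-linear least squares (exact for noiseless
#' monoexponential data); `method = "nls"` refines the log-linear solution
#' by nonlinear least squares in the signal domain, which weights high-b
#' points differently under noise. A negative fitted ADC is clipped to 0
#' and flagged.
#'
#' @param b b-values (s/mm^2), at least 2 distinct.
#' @param S signals (same length, strictly positive).
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return list with `adc` (mm^2/s), `s0`, `clipped` (logical).
#' @export
fit_monoexponential <- function(b, S, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  stopifnot(length(b) == length(S))
  if (length(unique(b)) < 2) stop("need at least 2 distinct b-values")
  if (any(S <= 0)) {
    stop("non-positive signal at b = ",
         paste(b[S <= 0], collapse = ", "),
         "; log-domain fitting requires positive signals")
  }
  fit <- lm(log(S) ~ b)
  adc <- -unname(coef(fit)[2])
  s0 <- exp(unname(coef(fit)[1]))
  if (method == "nls") {
    nl <- tryCatch(
      minpack.lm::nlsLM(S ~ s0 * exp(-b * adc),
                        data = data.frame(S = S, b = b),
                        start = list(s0 = s0, adc = max(adc, 1e-6))),
      error = function(e) NULL)
    if (!is.null(nl)) {
      adc <- unname(coef(nl)["adc"])
      s0 <- unname(coef(nl)["s0"])
    }
  }
  clipped <- adc < 0
  list(adc = max(adc, 0), s0 = s0, clipped = clipped)
}

#' Mean of a quantitative map under an ROI mask
#'
#' Arithmetic mean of the non-missing map values where the mask is TRUE.
#'
#' @param map a [quant_map()].
#' @param roi_mask logical matrix with the map's grid dimensions.
#' @return scalar mean.
#' @export
roi_mean <- function(map, roi_mask) {
  stopifnot(inherits(map, "quant_map"), is.matrix(roi_mask))
  if (!all(dim(roi_mask) == dim(map$values))) {
    stop("ROI mask dimensions ", paste(dim(roi_mask), collapse = "x"),
         " do not match map grid ", paste(dim(map$values), collapse = "x"))
  }
  v <- map$values[roi_mask > 0]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("ROI mask selects no non-missing map values")
  mean(v)
}

#' Read a DWI signal table from CSV
#'
#' Expected columns: `b`, `direction`, `value`; all directions must share
#' the same b-grid.
#'
#' @param path CSV path.
#' @return a `dwi_signal`.
#' @export
read_dwi_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("b", "direction", "value") %in% names(df)))
  dirs <- sort(unique(df$direction))
  bs <- sort(unique(df$b))
  m <- matrix(NA_real_, length(bs), length(dirs),
              dimnames = list(paste0("b", bs), paste0("dir", dirs)))
  for (d in seq_along(dirs)) {
    sub <- df[df$direction == dirs[d], ]
    sub <- sub[order(sub$b), ]
    if (!identical(as.numeric(sub$b), as.numeric(bs))) {
      stop("direction ", dirs[d], " has a mismatched b-grid")
    }
    m[, d] <- sub$value
  }
  structure(list(b_values = bs, signals = m,
                 n_directions = length(dirs)),
            class = "dwi_signal")
}

#' Write a DWI signal to CSV (b, direction, value)
#' @param signal a `dwi_signal`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_dwi_csv <- function(signal, path) {
  stopifnot(inherits(signal, "dwi_signal"))
  df <- expand.grid(b = signal$b_values,
                    direction = seq_len(signal$n_directions))
  df$value <- as.vector(signal$signals)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
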