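#' Acquisition series container
#'
#' One modality's image stack (rows x cols x n_times) with its timing vector
#' for one sample, session and load level.
#'
#' @param stack 3-D numeric array of non-negative magnitudes.
#' @param times timing vector in ms, strictly increasing, length matching the
#'   third stack dimension, at least 3 points.
#' @param modality modality tag (see [qmri_modalities()]).
#' @param pixel_spacing mm per pixel edge.
#' @param meta named list of metadata (sample id, session, load level, arm,
#'   seed).
#' @return An object of class `acq_series`.
#' @export
acq_series <- function(stack, times, modality, pixel_spacing, meta = list()) {
  modality <- match.arg(modality, qmri_modalities())
  if (length(dim(stack)) != 3L) qc_format_error("stack must be a 3-D array")
  if (dim(stack)[3] != length(times)) {
    qc_format_error(sprintf("stack has %d frames but %d times",
                            dim(stack)[3], length(times)))
  }
  if (length(times) < 3L) qc_format_error("need at least 3 timing points")
  if (any(times < 0) || any(diff(times) <= 0)) {
    qc_format_error("times must be non-negative and strictly increasing")
  }
  if (any(stack < 0)) qc_format_error("magnitudes must be non-negative")
  structure(list(stack = stack, times = as.numeric(times), modality = modality,
                 pixel_spacing = pixel_spacing, meta = meta),
            class = "acq_series")
}

#' Forward signal models
#'
#' Mono-exponential magnitude models: spin-echo, gradient-echo and spin-lock
#' series decay as `s0 * exp(-t / tau)`; the inversion-recovery series is the
#' magnitude three-parameter model `|s0 * (1 - b * exp(-t / tau))|` with
#' inversion factor `b` in (0, 2].
#'
#' @param modality modality tag.
#' @param params named vector or list with `s0`, `tau` and (for `T1_IR`) `b`.
#' @param times timing vector (ms).
#' @return Numeric vector of signal magnitudes.
#' @examples
#' forward_signal("T2_SE", c(s0 = 100, tau = 50), c(0, 50)) # 100, 100 * exp(-1)
#' @export
forward_signal <- function(modality, params, times) {
  modality <- match.arg(modality, qmri_modalities())
  params <- as.list(params)
  s0 <- params$s0; tau <- params$tau
  if (!is_scalar_number(tau) || tau <= 0) qc_validation_error("tau must be positive")
  if (!is_scalar_number(s0) || s0 <= 0) qc_validation_error("s0 must be positive")
  if (modality == "T1_IR") {
    b <- params$b
    if (!is_scalar_number(b) || b <= 0 || b > 2) qc_validation_error("b must lie in (0, 2]")
    abs(s0 * (1 - b * exp(-times / tau)))
  } else {
    s0 * exp(-times / tau)
  }
}

#' Select timing points for fitting
#'
#' For T2 and T2* series only echoes strictly below the cutoff (default
#' 60 ms) are fitted, to limit noise-floor bias at long echo times; T1 and
#' T1rho series use all points.
#'
#' @param times timing vector (ms).
#' @param modality modality tag.
#' @param cutoff echo-time cutoff (ms).
#' @return Integer indices of the retained timing points.
#' @export
select_times <- function(times, modality, cutoff = 60) {
  modality <- match.arg(modality, qmri_modalities())
  idx <- if (modality %in% c("T2_SE", "T2star_GRE")) which(times < cutoff)
         else seq_along(times)
  if (length(idx) < 3L) {
    qc_degenerate_error(sprintf(
      "degenerate protocol: only %d timing points survive the %g ms cutoff",
      length(idx), cutoff))
  }
  idx
}

#' R-squared adjusted for degrees of freedom
#'
#' `1 - (1 - R^2) * (n - 1) / (n - n_params - 1)` with
#' `R^2 = 1 - SSres / SStot`.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param n_params number of fitted parameters.
#' @return The adjusted coefficient of determination (can be negative).
#' @export
adjusted_r2 <- function(observed, predicted, n_params) {
  n <- length(observed)
  if (length(predicted) != n) qc_validation_error("observed/predicted length mismatch")
  if (n <= n_params + 1) qc_validation_error("need n > n_params + 1 observations")
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) qc_degenerate_error("zero total variance: adjusted R2 undefined")
  ssres <- sum((observed - predicted)^2)
  r2 <- 1 - ssres / sstot
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

#' Fitting options
#'
#' @param modality modality tag (sets the time-constant bounds: T1 in
#'   `[1, 5000]` ms, others in `[1, 500]` ms).
#' @param cutoff echo-time cutoff in ms, applied to T2/T2* only.
#' @param r2_threshold adjusted-R-squared validity threshold in (0, 1).
#' @param tau_bounds length-2 vector overriding the default bounds (ms).
#' @param s0_factor upper bound of the amplitude as a multiple of the maximum
#'   observed signal.
#' @param n_starts number of log-spaced time-constant starts in the
#'   initialization grid.
#' @param max_iter,ftol Levenberg-Marquardt iteration cap and relative
#'   sum-of-squares convergence tolerance.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(modality = "T2_SE", cutoff = 60, r2_threshold = 0.95,
                        tau_bounds = NULL, s0_factor = 10,
                        n_starts = 5L, max_iter = 60L, ftol = 1e-12) {
  modality <- match.arg(modality, qmri_modalities())
  tau_bounds <- tau_bounds %||% if (modality == "T1_IR") c(1, 5000) else c(1, 500)
  if (any(!is.finite(tau_bounds)) || any(tau_bounds <= 0) || tau_bounds[1] >= tau_bounds[2]) {
    qc_config_error("tau_bounds must be finite, positive and increasing")
  }
  if (r2_threshold <= 0 || r2_threshold >= 1) {
    qc_config_error("r2_threshold must lie in (0, 1)")
  }
  structure(list(modality = modality, cutoff = cutoff,
                 r2_threshold = r2_threshold, tau_bounds = tau_bounds,
                 s0_factor = s0_factor, n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), ftol = ftol),
            class = "fit_options")
}

#' Fit a single pixel's relaxation curve
#'
#' Bounded multi-start Levenberg-Marquardt least squares on the modality's
#' forward model (see [forward_signal()]). Starts are a log-spaced
#' time-constant grid with the analytic conditional amplitude; the
#' best-residual start wins, ties broken towards the smaller time constant.
#' Non-convergence is flagged, not raised; constant signals are flagged
#' degenerate.
#'
#' @param modality modality tag.
#' @param times timing vector (already selected; ms).
#' @param signal magnitude vector, same length as `times`.
#' @param options a [fit_options()].
#' @return List with `params` (named: `s0`, `tau`, `b`), `adj_r2`,
#'   `converged` and `degenerate`.
#' @export
fit_pixel <- function(modality, times, signal, options = fit_options(modality)) {
  modality <- match.arg(modality, qmri_modalities())
  if (length(times) != length(signal)) qc_validation_error("times/signal length mismatch")
  Y <- matrix(signal, nrow = 1)
  fit <- fit_batch(modality, times, Y, options)
  if (fit$degenerate[1]) {
    return(list(params = c(s0 = NA_real_, tau = NA_real_, b = NA_real_),
                adj_r2 = NA_real_, converged = FALSE, degenerate = TRUE))
  }
  n_par <- if (modality == "T1_IR") 3L else 2L
  pred <- forward_signal(modality,
                         list(s0 = fit$s0[1], tau = fit$tau[1], b = fit$b[1]),
                         times)
  list(params = c(s0 = fit$s0[1], tau = fit$tau[1], b = fit$b[1]),
       adj_r2 = adjusted_r2(signal, pred, n_par),
       converged = fit$converged[1], degenerate = FALSE)
}

#' Fit a parameter map over a mask
#'
#' Applies [select_times()] then fits every in-mask pixel. A pixel is valid
#' iff its fit converged, its adjusted R-squared exceeds the threshold and
#' its time constant lies within bounds. Out-of-mask and degenerate pixels
#' carry `NA`.
#'
#' @param series an [acq_series()].
#' @param mask logical matrix matching the stack's in-plane dimensions.
#' @param options a [fit_options()] for the series' modality.
#' @return An object of class `parameter_map` with matrices `value` (ms),
#'   `s0`, `b` (inversion factor, T1 only), `adj_r2`, `valid`, plus modality
#'   and provenance.
#' @export
fit_map <- function(series, mask, options = fit_options(series$modality)) {
  if (!inherits(series, "acq_series")) qc_validation_error("series must be an acq_series")
  d <- dim(series$stack)
  if (!is.logical(mask) || nrow(mask) != d[1] || ncol(mask) != d[2]) {
    qc_validation_error("mask shape does not match the stack")
  }
  if (!any(mask)) qc_validation_error("empty mask")
  sel <- select_times(series$times, series$modality, options$cutoff)
  t_sel <- series$times[sel]
  flat <- matrix(series$stack, nrow = d[1] * d[2])
  idx <- which(as.vector(mask))
  Y <- flat[idx, sel, drop = FALSE]
  fit <- fit_batch(series$modality, t_sel, Y, options)

  n <- length(t_sel)
  p <- if (series$modality == "T1_IR") 3L else 2L
  sstot <- rowSums((Y - rowMeans(Y))^2)
  adj <- rep(NA_real_, length(idx))
  ok_var <- sstot > 0 & !fit$degenerate
  r2 <- 1 - fit$ssr[ok_var] / sstot[ok_var]
  adj[ok_var] <- 1 - (1 - r2) * (n - 1) / (n - p - 1)

  lb <- options$tau_bounds[1]; ub <- options$tau_bounds[2]
  valid_v <- !fit$degenerate & fit$converged & !is.na(adj) &
    adj > options$r2_threshold & fit$tau >= lb & fit$tau <= ub

  mk <- function(v) { m <- matrix(NA_real_, d[1], d[2]); m[idx] <- v; m }
  valid <- matrix(FALSE, d[1], d[2]); valid[idx] <- valid_v
  structure(list(value = mk(fit$tau), s0 = mk(fit$s0), b = mk(fit$b),
                 adj_r2 = mk(adj), valid = valid, mask = mask,
                 modality = series$modality, options = options,
                 meta = series$meta),
            class = "parameter_map")
}
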