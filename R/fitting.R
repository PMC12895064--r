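#' Fitting control options
#'
#' Collects the tunable options of the per-feature nonlinear
#' least-squares fits.
#'
#' @param period Expected period in hours (default 24, circadian).
#' @param period_tolerance Fractional half-width of the period search
#'   band: the angular frequency is bounded to
#'   `[2*pi/(period*(1+tol)), 2*pi/(period*(1-tol))]`. Default 0.25.
#' @param gamma_max Bound on `|gamma|`. The default `NULL` uses
#'   `6 / max(time)`, so the amplitude envelope can change by at most
#'   `exp(±3)` over the observed span; this keeps the exponential
#'   identifiable and finite.
#' @param n_phase Number of equispaced phase starting values in
#'   `[0, 2*pi)` for the multi-start grid. Default 8.
#' @param max_eval Maximum function evaluations per start. Default 5000.
#' @param tol Relative convergence tolerance on parameters and cost.
#'   Default 1e-8.
#' @return A list of class `rhythm_control`.
#' @export
rhythm_control <- function(period = 24, period_tolerance = 0.25,
                           gamma_max = NULL, n_phase = 8L,
                           max_eval = 5000L, tol = 1e-8) {
  stopifnot(period > 0, period_tolerance > 0, period_tolerance < 1,
            n_phase >= 1L, max_eval >= 1L, tol > 0)
  structure(list(period = period, period_tolerance = period_tolerance,
                 gamma_max = gamma_max, n_phase = as.integer(n_phase),
                 max_eval = as.integer(max_eval), tol = tol),
            class = "rhythm_control")
}

# Minimum time step between distinct sampling times.
sampling_interval <- function(t) {
  ut <- sort(unique(t))
  if (length(ut) < 2L) stop("need at least two distinct timepoints", call. = FALSE)
  min(diff(ut))
}

# Parameter bounds for one waveform family given the data and control.
fit_bounds <- function(kind, t, control) {
  tol <- control$period_tolerance
  om_lo <- 2 * pi / (control$period * (1 + tol))
  om_hi <- 2 * pi / (control$period * (1 - tol))
  gmax <- control$gamma_max %||% (6 / max(t))
  if (kind == "transient") {
    per_hi <- 2 * pi / om_lo
    dt <- sampling_interval(t)
    list(lower = c(A = 0, omega = om_lo, p_tau = 0, sigma = dt / 2, y = -Inf),
         upper = c(A = Inf, omega = om_hi, p_tau = per_hi, sigma = per_hi / 4,
                   y = Inf))
  } else {
    list(lower = c(A = 0, gamma = -gmax, omega = om_lo, phi = -Inf, y = -Inf),
         upper = c(A = Inf, gamma = gmax, omega = om_hi, phi = Inf, y = Inf))
  }
}

# Deterministic multi-start grid. Phase and impulse location are the
# multimodal axes, so those are gridded; everything else starts at a
# moment-based guess.
fit_starts <- function(kind, t, x, control) {
  A0 <- (max(x) - min(x)) / 2
  y0 <- mean(x)
  om0 <- 2 * pi / control$period
  if (kind == "transient") {
    dt <- sampling_interval(t)
    cycle <- floor(t / control$period)
    u <- t %% control$period
    # per-cycle argmax of the signal locates candidate impulse centres;
    # the gate makes the SSR surface multimodal between sampling points,
    # so each centre is expanded by sub-interval offsets and paired with
    # several width starts
    p0 <- unique(vapply(split(seq_along(t), cycle),
                        function(i) u[i][which.max(x[i])], numeric(1)))
    grid <- expand.grid(p = unique(as.vector(outer(p0, dt * c(-1, -0.5, 0, 0.5),
                                                   "+"))),
                        s = dt * c(0.5, 1, 2))
    grid$p <- grid$p %% control$period
    unname(Map(function(p, s) c(A = max(A0, 1e-3), omega = om0, p_tau = p,
                                sigma = s, y = y0),
               grid$p, grid$s))
  } else {
    phis <- 2 * pi * (seq_len(control$n_phase) - 1L) / control$n_phase
    lapply(phis, function(ph) c(A = max(A0, 1e-3), gamma = 0, omega = om0,
                                phi = ph, y = y0))
  }
}

model_predict <- function(kind, par, t) {
  wave_eval(kind, t, as.list(par))
}

new_waveform_fit <- function(kind, par, data, converged, flags = character()) {
  fitted <- model_predict(kind, par, data$time)
  resid <- data$value - fitted
  ssr <- sum(resid^2)
  structure(list(
    kind = kind,
    par = par,
    ssr = ssr,
    rmse = sqrt(ssr / nrow(data)),
    fitted = fitted,
    converged = converged,
    n_obs = nrow(data),
    n_params = length(par),
    flags = flags,
    data = data
  ), class = "waveform_fit")
}

# Constant-mean pseudo-fit used for degenerate inputs and non-convergence.
constant_fit <- function(kind, data, converged, flags) {
  par <- if (kind == "transient") {
    c(A = 0, omega = 2 * pi / 24, p_tau = 0, sigma = 1, y = mean(data$value))
  } else {
    c(A = 0, gamma = 0, omega = 2 * pi / 24, phi = 0, y = mean(data$value))
  }
  new_waveform_fit(kind, par, data, converged = converged, flags = flags)
}

prepare_series <- function(data, control) {
  stopifnot(is.data.frame(data))
  if (!all(c("time", "value") %in% names(data))) {
    stop("`data` must have columns `time` and `value`", call. = FALSE)
  }
  data <- dplyr::as_tibble(data)
  keep <- is.finite(data$time) & is.finite(data$value)
  if (!all(keep)) data <- data[keep, , drop = FALSE]
  # canonical observation order: makes the fit independent of input row
  # order (floating-point accumulation is order-sensitive)
  data <- dplyr::arrange(data, .data$time, .data$value)
  if (diff(range(data$time)) < control$period) {
    warning("time span is shorter than one expected period; ",
            "frequency and envelope estimates may be unstable", call. = FALSE)
  }
  data
}

#' Fit one waveform family to a single time series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, via
#' [minpack.lm::nls.lm()]) over a deterministic multi-start grid: eight
#' equispaced starting phases for the oscillatory families, and impulse
#' centres at the per-cycle maxima for the transient. Replicates are
#' fitted as individual observations, never averaged, preserving error
#' degrees of freedom for the downstream lack-of-fit test. The start with
#' the lowest converged sum of squared residuals wins.
#'
#' @param data Data frame with numeric columns `time` (hours) and `value`
#'   (signal units); a `replicate` column is carried through untouched.
#'   Rows with missing time or value are dropped.
#' @param kind One of [waveform_kinds()].
#' @param control A [rhythm_control()] list.
#' @return An object of class `waveform_fit`: a list with elements `kind`,
#'   `par` (named parameter vector), `ssr`, `rmse` (`sqrt(ssr / n_obs)`),
#'   `fitted`, `converged`, `n_obs`, `n_params`, `flags`, and the fitted
#'   `data`. Use [tidy()], [glance()], [augment()] or [autoplot()] on it.
#' @export
#' @examples
#' tt <- rep(seq(0, 46, by = 2), each = 2)
#' df <- data.frame(time = tt,
#'                  value = wave_harmonic(tt, A = 2, omega = 2 * pi / 24))
#' fit <- fit_waveform(df, "harmonic")
#' glance(fit)
fit_waveform <- function(data, kind, control = rhythm_control()) {
  kind <- check_kind(kind)
  data <- prepare_series(data, control)
  x <- data$value
  t <- data$time
  n_par <- length(param_names(kind))
  if (length(x) < n_par) {
    stop("series has ", length(x), " usable observations but the ", kind,
         " model needs at least ", n_par, call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    fit <- constant_fit(kind, data, converged = TRUE, flags = "constant_input")
    fit$par["y"] <- x[1]
    fit$fitted <- rep(x[1], length(x))
    fit$ssr <- 0
    fit$rmse <- 0
    return(fit)
  }
  b <- fit_bounds(kind, t, control)
  starts <- fit_starts(kind, t, x, control)
  clamp <- function(p) pmin(pmax(p, b$lower), b$upper)
  resid_fn <- function(par) x - model_predict(kind, par, t)
  ctl <- minpack.lm::nls.lm.control(ftol = control$tol, ptol = control$tol,
                                    maxfev = control$max_eval, maxiter = 1000L)
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = clamp(st), lower = b$lower, upper = b$upper,
                         fn = resid_fn, control = ctl),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% c(1L, 2L, 3L, 4L, 6L, 7L, 8L)
    if (!ok) next
    ssr <- sum(res$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = res$par, ssr = ssr)
  }
  if (is.null(best)) {
    return(constant_fit(kind, data, converged = FALSE, flags = "no_convergence"))
  }
  par <- unlist(best$par)
  period_hat <- 2 * pi / par[["omega"]]
  if (kind == "transient") {
    par[["p_tau"]] <- par[["p_tau"]] %% period_hat
  } else {
    par[["phi"]] <- par[["phi"]] %% (2 * pi)
  }
  new_waveform_fit(kind, par, data, converged = TRUE)
}

#' Fit all four waveform families to a single time series
#'
#' Runs [fit_waveform()] once per family and returns the four results in
#' the canonical order harmonic, square, cycloid, transient. A failure in
#' one family (for example too few observations for its parameter count)
#' is recorded as a non-converged constant-mean pseudo-fit and never
#' aborts the remaining families.
#'
#' @inheritParams fit_waveform
#' @return A tibble with one row per family: columns `kind`, `ssr`,
#'   `rmse`, `converged`, and the full `waveform_fit` in list-column
#'   `fit`.
#' @export
#' @examples
#' tt <- rep(seq(0, 46, by = 2), each = 2)
#' df <- data.frame(time = tt,
#'                  value = wave_cycloid(tt, A = 2, omega = 2 * pi / 24))
#' fits <- fit_waveforms(df)
#' select_best(fits)$kind
fit_waveforms <- function(data, control = rhythm_control()) {
  fits <- lapply(waveform_kinds(), function(kind) {
    tryCatch(fit_waveform(data, kind, control), error = function(e) {
      warning(kind, " fit failed: ", conditionMessage(e), call. = FALSE)
      d <- prepare_series(data, control)
      constant_fit(kind, d, converged = FALSE,
                   flags = paste0("error: ", conditionMessage(e)))
    })
  })
  tibble::tibble(
    kind = waveform_kinds(),
    ssr = vapply(fits, function(f) f$ssr, numeric(1)),
    rmse = vapply(fits, function(f) f$rmse, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    fit = fits
  )
}

#' Select the optimal model by sum of squared residuals
#'
#' The model with the lowest SSR among the converged fits is optimal.
#' Exact ties are broken by the fixed family order harmonic, square,
#' cycloid, transient (simplest interpretation first; all families carry
#' five parameters). If no fit converged, the harmonic constant-mean
#' pseudo-fit is returned and is flagged non-rhythmic downstream.
#'
#' @param fits Result of [fit_waveforms()], or a plain list of
#'   `waveform_fit` objects.
#' @return The winning `waveform_fit`.
#' @export
select_best <- function(fits) {
  if (is.data.frame(fits)) fits <- fits$fit
  stopifnot(length(fits) >= 1L)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  pool <- if (any(conv)) fits[conv] else fits
  ssr <- vapply(pool, function(f) f$ssr, numeric(1))
  pool[[which.min(ssr)]]
}

#' @export
print.waveform_fit <- function(x, ...) {
  cat("<waveform_fit> ", x$kind,
      if (!x$converged) " (not converged)" else "", "\n", sep = "")
  cat("  n_obs: ", x$n_obs, "   ssr: ", signif(x$ssr, 6),
      "   rmse: ", signif(x$rmse, 6), "\n", sep = "")
  cat("  parameters:\n")
  print(signif(x$par, 6))
  invisible(x)
}
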