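#' Detect rhythmic features in a time-course table
#'
#' The batch entry point: for every feature, fits all four waveform
#' families by bounded nonlinear least squares, selects the lowest-SSR
#' model, tests rhythmicity with the zero-amplitude lack-of-fit F-test,
#' confirms observed-vs-fitted agreement with Kendall's tau, adjusts
#' both p-value families across the whole batch with Benjamini-Hochberg,
#' and classifies regulatory behaviour from the amplitude-change
#' coefficient. A feature is called rhythmic when both adjusted p-values
#' fall below `alpha` — a conservative filter-then-confirm composite.
#'
#' Features are independent work units and the whole pipeline is
#' deterministic: identical input (in any row order) yields identical
#' per-feature results. Features with too few usable observations are
#' skipped, not fatal; the skip report is attached as
#' `attr(result, "skipped")`.
#'
#' @param data Long tibble with columns `feature`, `time` (hours),
#'   `value`, and optionally `replicate` (see [read_rhythm_table()]).
#'   A table without a `feature` column is treated as one single series.
#' @param period Expected period, hours (default 24).
#' @param period_tolerance Fractional period search half-width
#'   (default 0.25).
#' @param alpha Significance level applied to both BH-adjusted p-value
#'   families (default 0.05).
#' @param gamma_threshold Stability threshold for
#'   [classify_regulation()], per hour (default 0.01).
#' @param normalize Z-score each feature before fitting. The default
#'   `NULL` enables it for multi-feature tables and disables it for a
#'   single series (raw-unit fitting, e.g. behavioural counts).
#' @param min_obs Minimum usable observations per feature (default 6,
#'   one more than the parameter count of the largest model).
#' @param keep_fits Keep each feature's best `waveform_fit` in a `fit`
#'   list-column (default `TRUE`; needed for fitted-value output and
#'   plotting).
#' @param control A [rhythm_control()]; built from `period` and
#'   `period_tolerance` when not supplied.
#' @return A tibble with one row per analysed feature: identifier, best
#'   model, parameter estimates (`gamma`/`phi` are `NA` for the
#'   transient, `p_tau`/`sigma` for the other families),
#'   `period_hours = 2*pi/omega`, `rmse`, `regulation`, the F and tau
#'   statistics with raw and BH-adjusted p-values, the `rhythmic` flag,
#'   plus `converged`, `n_obs` and any per-feature `flags`.
#' @export
#' @examples
#' panel <- simulate_panel(n_per_class = 2, kinds = c("harmonic", "null"),
#'                         noise_sd = 0.05, seed = 7)
#' calls <- detect_rhythms(panel$data)
#' dplyr::count(calls, best_model, rhythmic)
detect_rhythms <- function(data, period = 24, period_tolerance = 0.25,
                           alpha = 0.05, gamma_threshold = 0.01,
                           normalize = NULL, min_obs = 6L,
                           keep_fits = TRUE, control = NULL) {
  stopifnot(is.data.frame(data), nrow(data) > 0,
            alpha > 0, alpha < 1, min_obs >= 6L)
  control <- control %||% rhythm_control(period = period,
                                         period_tolerance = period_tolerance)
  if (!"feature" %in% names(data)) data$feature <- "series_1"
  if (!"replicate" %in% names(data)) data$replicate <- "r1"
  if (!all(c("time", "value") %in% names(data))) {
    stop("`data` must have columns `time` and `value`", call. = FALSE)
  }
  normalize <- normalize %||% (dplyr::n_distinct(data$feature) > 1L)

  data <- data[is.finite(data$time), , drop = FALSE]
  usable <- data[is.finite(data$value), , drop = FALSE]
  counts <- dplyr::count(usable, .data$feature)
  all_feats <- unique(data$feature)
  low <- setdiff(all_feats, counts$feature[counts$n >= min_obs])
  skipped <- tibble::tibble(
    feature = low,
    reason = sprintf("fewer than %d usable observations", min_obs))
  if (length(low)) {
    warning("skipping ", length(low), " feature(s) with fewer than ",
            min_obs, " usable observations", call. = FALSE)
    usable <- usable[!usable$feature %in% low, , drop = FALSE]
  }
  if (nrow(usable) == 0L) {
    stop("no analysable features (",
         nrow(skipped), " skipped: too few observations)", call. = FALSE)
  }
  if (normalize) usable <- zscore_normalize(usable)

  per_feature <- function(df) {
    fits <- suppressWarnings(fit_waveforms(df, control))
    best <- select_best(fits)
    ft <- if (best$converged && best$n_obs > best$n_params) {
      zero_amplitude_test(best)
    } else {
      list(f_stat = NA_real_, f_p = NA_real_, perfect_fit = FALSE)
    }
    kd <- kendall_agreement(best$data$value, best$fitted)
    p <- best$par
    is_tr <- best$kind == "transient"
    tibble::tibble(
      feature_id = df$feature[1],
      best_model = best$kind,
      A = p[["A"]],
      gamma = if (is_tr) NA_real_ else p[["gamma"]],
      omega = p[["omega"]],
      period_hours = 2 * pi / p[["omega"]],
      phi = if (is_tr) NA_real_ else p[["phi"]],
      y = p[["y"]],
      p_tau = if (is_tr) p[["p_tau"]] else NA_real_,
      sigma = if (is_tr) p[["sigma"]] else NA_real_,
      rmse = best$rmse,
      regulation = classify_regulation(p["gamma"] %||% NA_real_, best$kind,
                                       gamma_threshold),
      f_stat = ft$f_stat,
      f_p = ft$f_p,
      tau = kd$tau,
      tau_p = kd$tau_p,
      perfect_fit = isTRUE(ft$perfect_fit),
      converged = best$converged,
      n_obs = best$n_obs,
      flags = paste(best$flags, collapse = ";"),
      fit = list(best)
    )
  }
  calls <- usable |>
    dplyr::group_split(.data$feature) |>
    purrr::map_dfr(per_feature)

  calls <- calls |>
    dplyr::mutate(
      f_q = bh_adjust(.data$f_p),
      tau_q = bh_adjust(.data$tau_p),
      rhythmic = !is.na(.data$f_q) & !is.na(.data$tau_q) &
        .data$f_q < alpha & .data$tau_q < alpha &
        .data$A > sqrt(.Machine$double.eps)
    ) |>
    dplyr::relocate("f_q", .after = "f_p") |>
    dplyr::relocate("tau_q", .after = "tau_p") |>
    dplyr::relocate("rhythmic", .after = "tau_q")
  if (!keep_fits) calls$fit <- NULL
  attr(calls, "skipped") <- skipped
  attr(calls, "alpha") <- alpha
  calls
}
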