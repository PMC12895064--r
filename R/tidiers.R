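#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a waveform fit
#'
#' @param x A `waveform_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`,
#'   `estimate`.
#' @method tidy waveform_fit
#' @export
tidy.waveform_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' One-row summary of a waveform fit
#'
#' @param x A `waveform_fit`.
#' @param ... Unused.
#' @return A tibble with `kind`, `n_obs`, `n_params`, `ssr`, `rmse`,
#'   `period_hours`, `converged`.
#' @method glance waveform_fit
#' @export
glance.waveform_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_obs = x$n_obs, n_params = x$n_params,
                 ssr = x$ssr, rmse = x$rmse,
                 period_hours = 2 * pi / x$par[["omega"]],
                 converged = x$converged)
}

#' Augment the fitted data with predictions and residuals
#'
#' @param x A `waveform_fit`.
#' @param ... Unused.
#' @return The fitted data with `.fitted` and `.resid` columns.
#' @method augment waveform_fit
#' @export
augment.waveform_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = .data$value - x$fitted)
}

#' Plot observed values and the fitted waveform
#'
#' Observations as points, the fitted model as a dense curve over the
#' observed time span.
#'
#' @param object A `waveform_fit`.
#' @param n Number of curve evaluation points (default 400).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot waveform_fit
#' @export
autoplot.waveform_fit <- function(object, n = 400, ...) {
  tt <- seq(min(object$data$time), max(object$data$time), length.out = n)
  curve <- tibble::tibble(time = tt,
                          value = model_predict(object$kind, object$par, tt))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "signal",
                  title = paste0(object$kind, " fit (rmse ",
                                 signif(object$rmse, 3), ")")) +
    ggplot2::theme_minimal()
}

#' Summary plot of a batch of rhythm calls
#'
#' Bar chart of best-model assignments among rhythmic features, split by
#' regulatory class — the at-a-glance composition view of an analysed
#' panel.
#'
#' @param calls Tibble from [detect_rhythms()].
#' @param rhythmic_only Show only features called rhythmic
#'   (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_rhythm_summary <- function(calls, rhythmic_only = TRUE) {
  stopifnot(is.data.frame(calls))
  df <- if (rhythmic_only) dplyr::filter(calls, .data$rhythmic) else calls
  ggplot2::ggplot(df, ggplot2::aes(x = .data$best_model,
                                   fill = .data$regulation)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "best model", y = "features", fill = "regulation") +
    ggplot2::theme_minimal()
}
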