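#' Zero-amplitude lack-of-fit F-statistic from residual sums
#'
#' Compares the best model against its zero-amplitude reduction (all
#' optimal parameters kept but `A = 0`, which collapses every family to
#' the constant baseline `y`). With `ssr0` the residual sum of the
#' zero-amplitude model, `ssr1` that of the full model, `n` observations
#' and `p` model parameters, the statistic is
#' `F = ((ssr0 - ssr1) / q) / (ssr1 / (n - p))` with `q = p - 1` (all
#' shape parameters become inert when the amplitude is zero; only the
#' baseline remains), referred to the F distribution with `(q, n - p)`
#' degrees of freedom. `ssr0 < ssr1` is clamped to `F = 0`. A perfect
#' full-model fit (`ssr1 = 0`) gives `p = 0` with a `perfect_fit` flag
#' instead of a division by zero.
#'
#' @param ssr0 Residual sum of squares of the zero-amplitude (constant)
#'   model.
#' @param ssr1 Residual sum of squares of the full model.
#' @param n_obs Number of observations; must exceed `n_params`.
#' @param n_params Number of parameters of the full model (5 for every
#'   family here).
#' @return A list with `f_stat`, `f_p`, and logical `perfect_fit`.
#' @export
#' @examples
#' ftest_zero_amplitude(ssr0 = 10, ssr1 = 2, n_obs = 8, n_params = 5)
ftest_zero_amplitude <- function(ssr0, ssr1, n_obs, n_params) {
  stopifnot(ssr0 >= 0, ssr1 >= 0, n_params >= 2)
  if (n_obs <= n_params) {
    stop("lack-of-fit test needs n_obs > n_params (", n_obs, " <= ",
         n_params, ")", call. = FALSE)
  }
  q <- n_params - 1
  df2 <- n_obs - n_params
  if (ssr1 <= .Machine$double.eps * max(1, ssr0)) {
    improved <- ssr0 > ssr1
    return(list(f_stat = if (improved) Inf else 0,
                f_p = if (improved) 0 else 1,
                perfect_fit = TRUE))
  }
  f <- max(0, ((ssr0 - ssr1) / q) / (ssr1 / df2))
  list(f_stat = f,
       f_p = stats::pf(f, q, df2, lower.tail = FALSE),
       perfect_fit = FALSE)
}

#' Zero-amplitude lack-of-fit test for a fitted waveform
#'
#' Computes the zero-amplitude residual sum (predictions collapse to the
#' fitted baseline `y`) from the fit's own data and applies
#' [ftest_zero_amplitude()].
#'
#' @param fit A `waveform_fit` from [fit_waveform()] or [select_best()].
#' @return A list with `f_stat`, `f_p`, `ssr0`, `ssr1`, `perfect_fit`.
#' @export
zero_amplitude_test <- function(fit) {
  stopifnot(inherits(fit, "waveform_fit"))
  ssr0 <- sum((fit$data$value - fit$par[["y"]])^2)
  out <- ftest_zero_amplitude(ssr0, fit$ssr, fit$n_obs, fit$n_params)
  out$ssr0 <- ssr0
  out$ssr1 <- fit$ssr
  out
}

#' Kendall's tau agreement between observed and fitted values
#'
#' Rank correlation (with tie correction) between the measurements and
#' the model's fitted values, confirming that the selected waveform
#' tracks the observed ordering and not just its variance. Wraps
#' [stats::cor.test()] with `method = "kendall"` (exact p-value for small
#' untied samples, asymptotic with tie correction otherwise). Degenerate
#' input in which either vector is entirely tied leaves tau undefined;
#' it is reported as `tau = 0`, `tau_p = 1` with `degenerate = TRUE`.
#'
#' @param observed Numeric vector of measurements.
#' @param fitted Numeric vector of model predictions, same length >= 3.
#' @return A list with `tau`, `tau_p`, and logical `degenerate`.
#' @export
#' @examples
#' kendall_agreement(c(1, 2, 3, 4), c(1, 3, 2, 4))
kendall_agreement <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 3)
  if (length(unique(observed)) < 2L || length(unique(fitted)) < 2L) {
    return(list(tau = 0, tau_p = 1, degenerate = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(observed, fitted, method = "kendall",
                    alternative = "two.sided", exact = NULL))
  list(tau = unname(ct$estimate), tau_p = ct$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard false-discovery-rate step-up adjustment across one family of
#' tests (here: one family per statistic across all features of a
#' batch), order-preserving with the input and clipped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA` allowed and
#'   propagated.
#' @return Adjusted p-values, same length and order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.5))
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify regulatory behaviour from the amplitude-change coefficient
#'
#' The sign and size of `gamma` describe whether a rhythm's amplitude is
#' actively changing over the sampled timeframe: `gamma < -threshold` is
#' `"damped"` (down-regulated), `gamma > threshold` is `"forced"`
#' (up-regulated), and `|gamma| <= threshold` is `"stable"` (not actively
#' up- or down-regulated). The transient family carries no envelope, so
#' its class is always `"not_applicable"`.
#'
#' @param gamma Amplitude-change coefficient(s), per hour (vectorised).
#' @param kind Waveform kind(s), recycled against `gamma`.
#' @param threshold Positive stability threshold, per hour. The default
#'   0.01 corresponds to roughly a 27% envelope change over 48 h, a
#'   visually flat bound.
#' @return Character vector of `"damped"`, `"forced"`, `"stable"`,
#'   `"not_applicable"`.
#' @export
#' @examples
#' classify_regulation(c(-0.05, 0.005, 0.05), "harmonic")
classify_regulation <- function(gamma, kind, threshold = 0.01) {
  stopifnot(threshold > 0)
  n <- max(length(gamma), length(kind))
  gamma <- rep_len(gamma, n)
  kind <- rep_len(kind, n)
  out <- character(n)
  out[kind == "transient"] <- "not_applicable"
  idx <- kind != "transient"
  g <- gamma[idx]
  out[idx] <- ifelse(abs(g) <= threshold, "stable",
                     ifelse(g < 0, "damped", "forced"))
  out
}
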