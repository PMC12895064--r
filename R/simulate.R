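#' Simulate one rhythmic (or flat) time series
#'
#' Generates a single feature on a regular sampling grid: the chosen
#' waveform evaluated at each timepoint plus i.i.d. Gaussian noise per
#' replicate observation. `kind = "null"` produces a flat feature (the
#' baseline `y` plus noise), the negative class for false-positive
#' checks.
#'
#' @param kind One of [waveform_kinds()] or `"null"`.
#' @param params Named list of waveform parameters (see [wave_eval()]);
#'   for `"null"` only `y` is used.
#' @param span Total sampling span, hours.
#' @param interval Sampling interval, hours.
#' @param replicates Replicates per timepoint.
#' @param noise_sd Gaussian noise standard deviation, signal units.
#' @param feature Feature identifier stored in the output.
#' @return A tibble with columns `feature`, `time`, `replicate`, `value`.
#' @export
#' @examples
#' simulate_rhythm("square", list(A = 2, gamma = 0, omega = 2 * pi / 24,
#'                                phi = 1, y = 0), noise_sd = 0.1)
simulate_rhythm <- function(kind, params, span = 48, interval = 2,
                            replicates = 2, noise_sd = 0.1,
                            feature = "feature_1") {
  stopifnot(span > 0, interval > 0, replicates >= 1, noise_sd >= 0)
  grid <- seq(0, span, by = interval)
  if (max(grid) == span && span %% interval == 0) grid <- grid[grid < span]
  tt <- rep(grid, each = replicates)
  rep_id <- rep(seq_len(replicates), times = length(grid))
  p <- as.list(params)
  mu <- if (identical(kind, "null")) {
    rep((p$y %||% 0), length(tt))
  } else {
    wave_eval(kind, tt, p)
  }
  tibble::tibble(
    feature = feature,
    time = tt,
    replicate = paste0("r", rep_id),
    value = mu + stats::rnorm(length(tt), 0, noise_sd)
  )
}

default_param_ranges <- function(period) {
  list(A = c(1, 3), gamma = c(-0.05, 0, 0.05), phi = c(0, 2 * pi),
       y = c(-1, 1), p_tau = c(0, period), sigma = c(1, 3))
}

draw_params <- function(kind, period, ranges) {
  r <- ranges
  unif <- function(b) stats::runif(1, b[1], b[2])
  if (kind == "null") return(list(y = unif(r$y)))
  base <- list(A = unif(r$A), omega = 2 * pi / period, y = unif(r$y))
  if (kind == "transient") {
    c(base, list(p_tau = unif(r$p_tau) %% period, sigma = unif(r$sigma)))
  } else {
    # gamma defaults to a small discrete set {damped, stable, forced}
    g <- if (length(r$gamma) > 2) sample(r$gamma, 1) else unif(r$gamma)
    c(base, list(gamma = g, phi = unif(r$phi) %% (2 * pi)))
  }
}

#' Simulate a ground-truth labelled feature panel
#'
#' Builds a seeded synthetic omics time course: `n_per_class` features
#' for each requested class (the four waveform families plus flat
#' `"null"` features), parameters drawn uniformly from `param_ranges`.
#' The default design mirrors a dense circadian experiment: 24 h period
#' sampled every 2 h over 48 h (two full cycles) with 2 replicates.
#' Identical arguments and seed reproduce the panel bit for bit.
#'
#' @param n_per_class Features per class.
#' @param kinds Character vector drawn from
#'   `c(waveform_kinds(), "null")`.
#' @param period Generating period, hours.
#' @inheritParams simulate_rhythm
#' @param noise_prop If not `NULL`, per-feature noise sd is
#'   `noise_prop * A` (amplitude-proportional noise; `"null"` features
#'   use `noise_prop * mean(param_ranges$A)` so they are not noiseless),
#'   overriding `noise_sd`.
#' @param param_ranges Named list of low/high bounds per parameter (a
#'   `gamma` entry with more than two values is treated as a discrete
#'   set). Defaults via `default_param_ranges(period)`: A in \[1, 3\],
#'   gamma in \{-0.05, 0, 0.05\}, phi in \[0, 2*pi), y in \[-1, 1\],
#'   p_tau in \[0, period), sigma in \[1, 3\] h.
#' @param seed Integer seed fixing the whole panel.
#' @return A list with `data` (long tibble: `feature`, `time`,
#'   `replicate`, `value`) and `truth` (tibble: `feature`, `kind`, and
#'   the generating parameters, `NA` where a parameter does not apply).
#' @export
#' @examples
#' panel <- simulate_panel(n_per_class = 2, seed = 1)
#' dplyr::count(panel$truth, kind)
simulate_panel <- function(n_per_class = 25,
                           kinds = c(waveform_kinds(), "null"),
                           period = 24, span = 48, interval = 2,
                           replicates = 2, noise_sd = 0.1,
                           noise_prop = NULL,
                           param_ranges = NULL, seed = 1L) {
  stopifnot(length(kinds) >= 1L, n_per_class >= 1L, span >= period)
  bad <- setdiff(kinds, c(waveform_kinds(), "null"))
  if (length(bad)) stop("unknown kind(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  ranges <- utils::modifyList(default_param_ranges(period),
                              as.list(param_ranges %||% list()))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    rows <- list(); truths <- list(); k <- 0L
    for (kind in kinds) {
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        id <- sprintf("%s_%03d", kind, i)
        p <- draw_params(kind, period, ranges)
        sd_i <- if (is.null(noise_prop)) noise_sd else {
          noise_prop * (if (kind == "null") mean(ranges$A) else p$A)
        }
        rows[[k]] <- simulate_rhythm(kind, p, span = span,
                                     interval = interval,
                                     replicates = replicates,
                                     noise_sd = sd_i, feature = id)
        truths[[k]] <- tibble::tibble(
          feature = id, kind = kind,
          A = p$A %||% NA_real_, gamma = p$gamma %||% NA_real_,
          omega = p$omega %||% NA_real_, phi = p$phi %||% NA_real_,
          y = p$y %||% NA_real_, p_tau = p$p_tau %||% NA_real_,
          sigma = p$sigma %||% NA_real_, noise_sd = sd_i)
      }
    }
    list(data = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truths))
  })
}

#' Write a simulated panel to disk
#'
#' Writes the panel in the same wide CSV layout [read_rhythm_table()]
#' reads (columns `<time>_r<rep>`), plus the aligned truth table.
#'
#' @param panel Result of [simulate_panel()].
#' @param path Output CSV path for the data matrix.
#' @param truth_path Optional output CSV path for the truth table.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, truth_path = NULL) {
  wide <- panel$data |>
    dplyr::mutate(column = paste0(.data$time, "_", .data$replicate)) |>
    dplyr::select("feature", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  readr::write_csv(wide, path)
  if (!is.null(truth_path)) readr::write_csv(panel$truth, truth_path)
  invisible(path)
}
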