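#' Read a feature-by-time abundance table
#'
#' Reads wide or long CSV/TSV time-course tables into the long tibble
#' layout the rest of the package consumes.
#'
#' In the wide layout the first column holds the feature identifier and
#' every remaining column name encodes a timepoint and optional
#' replicate: `"ZT0_r1"`, `"CT12_2"`, `"24.5_2"`, or a bare numeric hour
#' (`ZT`/`CT` prefixes are zeitgeber/circadian-time conventions and are
#' stripped; the suffix `_r<k>` or `_<k>` labels the replicate). A column
#' name that cannot be parsed is an error naming the column — never a
#' silent guess. In the long layout the file must have columns
#' `feature`, `time`, `replicate`, `value`.
#'
#' Missing cells are dropped per feature with a message reporting the
#' count; they are never imputed.
#'
#' @param path Path to a delimited text file. The delimiter is sniffed
#'   from the extension (`.tsv`/`.txt` = tab, otherwise comma) unless
#'   `delim` is given.
#' @param layout `"wide"` or `"long"`.
#' @param delim Optional delimiter override.
#' @return Long tibble with columns `feature`, `time` (hours, ascending
#'   within feature), `replicate`, `value`.
#' @export
read_rhythm_table <- function(path, layout = c("wide", "long"), delim = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  # read everything as character and convert through base R's strtod,
  # which is correctly rounded, so written panels round-trip exactly
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (layout == "long") {
    need <- c("feature", "time", "replicate", "value")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop("long layout needs column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    out <- dplyr::as_tibble(raw[need])
    out$time <- suppressWarnings(as.numeric(out$time))
    out$value <- suppressWarnings(as.numeric(out$value))
    out$replicate <- as.character(out$replicate)
  } else {
    if (ncol(raw) < 2L) stop("wide layout needs a feature column plus at ",
                             "least one timepoint column", call. = FALSE)
    names(raw)[1] <- "feature"
    if (anyDuplicated(raw$feature)) {
      stop("duplicate feature identifier(s): ",
           paste(unique(raw$feature[duplicated(raw$feature)]),
                 collapse = ", "), call. = FALSE)
    }
    parsed <- parse_time_headers(names(raw)[-1])
    out <- raw |>
      tidyr::pivot_longer(-"feature", names_to = "column",
                          values_to = "value") |>
      dplyr::left_join(parsed, by = "column") |>
      dplyr::select("feature", "time", "replicate", "value")
    out$value <- suppressWarnings(as.numeric(out$value))
  }
  n_miss <- sum(!is.finite(out$value))
  if (n_miss > 0) {
    message("dropping ", n_miss, " missing value(s)")
    out <- out[is.finite(out$value), , drop = FALSE]
  }
  dplyr::arrange(out, .data$feature, .data$time, .data$replicate)
}

# Map wide-format column names to (time, replicate).
parse_time_headers <- function(cols) {
  rx <- "^(?:ZT|CT)?\\s*([0-9]+(?:\\.[0-9]+)?)(?:_r?([0-9]+))?$"
  m <- regmatches(cols, regexec(rx, cols, ignore.case = TRUE))
  bad <- cols[vapply(m, length, integer(1)) == 0L]
  if (length(bad)) {
    stop("cannot parse time from column name(s): ",
         paste(bad, collapse = ", "),
         " (expected e.g. 'ZT0_r1', 'CT12_2', '24.5_2', or a bare hour)",
         call. = FALSE)
  }
  tibble::tibble(
    column = cols,
    time = vapply(m, function(g) as.numeric(g[2]), numeric(1)),
    replicate = vapply(m, function(g) {
      if (nzchar(g[3])) paste0("r", g[3]) else "r1"
    }, character(1))
  )
}

#' Z-score normalize each feature
#'
#' Centers and scales each feature's values to mean 0 and standard
#' deviation 1, making downstream fits scale-free (rhythm calls become
#' invariant to affine transformations of a feature's values).
#' Zero-variance features are returned unchanged; the downstream
#' zero-amplitude fit handles them.
#'
#' @param data Long tibble with columns `feature` (optional for a single
#'   series), `time`, `value`.
#' @return The input with `value` standardized within feature.
#' @export
#' @examples
#' zscore_normalize(data.frame(time = 1:3, value = c(1, 2, 3)))$value
zscore_normalize <- function(data) {
  stopifnot(is.data.frame(data), "value" %in% names(data))
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) x else (x - mean(x)) / s
  }
  if ("feature" %in% names(data)) {
    data |>
      dplyr::group_by(.data$feature) |>
      dplyr::mutate(value = zs(.data$value)) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(dplyr::as_tibble(data), value = zs(.data$value))
  }
}

results_schema <- c("feature_id", "best_model", "A", "gamma", "omega",
                    "period_hours", "phi", "y", "p_tau", "sigma", "rmse",
                    "regulation", "f_stat", "f_p", "f_q", "tau", "tau_p",
                    "tau_q", "rhythmic")

#' Write per-feature rhythm calls to CSV
#'
#' Writes the results table of [detect_rhythms()] with a fixed,
#' deterministic column order (floats at 6 significant digits;
#' `period_hours = 2*pi/omega` is a derived convenience column), and
#' optionally a companion CSV of fitted values per observation.
#'
#' @param calls Tibble from [detect_rhythms()].
#' @param path Output CSV path for the results table.
#' @param fitted_path Optional output CSV path for per-observation fitted
#'   values (`feature_id`, `time`, `fitted`).
#' @return `path`, invisibly.
#' @export
write_rhythm_results <- function(calls, path, fitted_path = NULL) {
  stopifnot(is.data.frame(calls), nrow(calls) >= 1L)
  miss <- setdiff(results_schema, names(calls))
  if (length(miss)) stop("calls table is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- calls[results_schema]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  readr::write_csv(out, path, na = "")
  if (!is.null(fitted_path)) {
    if (!"fit" %in% names(calls)) {
      stop("`calls` carries no `fit` column; run detect_rhythms() with ",
           "keep_fits = TRUE", call. = FALSE)
    }
    fv <- purrr::map2_dfr(calls$feature_id, calls$fit, function(id, f) {
      tibble::tibble(feature_id = id, time = f$data$time,
                     fitted = signif(f$fitted, 6))
    })
    readr::write_csv(fv, fitted_path, na = "")
  }
  invisible(path)
}
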