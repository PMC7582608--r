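#' Names of the 16 indices, in fixed order
#'
#' The 11 HRV indices and 5 heartprint indices used for modeling, ordered
#' as they enter the combination search report.
#'
#' @return Character vector of 16 column names.
#' @export
hrvprint_feature_names <- function() {
  c("meanNN_lm", "SDCI", "meanNN", "meanCI", "LF_HF", "SDNN_lm",
    "LFnu", "NIBmax", "RMSSD", "HFnu", "sNIB", "SDNN",
    "PVCs_hour", "pNN50", "LF", "HF")
}

heartprint_feature_names <- function() {
  c("SDCI", "meanCI", "NIBmax", "sNIB", "PVCs_hour")
}

#' Extract the 16-index feature row of one recording
#'
#' The recording is truncated to its last `truncate_n` beats; heartprint
#' indices are computed on the truncated annotated series and HRV indices
#' on the derived NN series (PVC intervals replaced, see
#' [estimate_nn_series()]).
#'
#' @param series An [rr_series()].
#' @param cfg A [spectral_config()].
#' @param truncate_n Beats kept from the end of the recording (default 1000).
#' @return One-row tibble: `recording_id`, `patient_id`, `outcome`, then the
#'   16 index columns of [hrvprint_feature_names()].
#' @export
extract_features <- function(series, cfg = spectral_config(),
                             truncate_n = 1000) {
  trunc <- suppressWarnings(truncate_last_n(series, truncate_n))
  nn <- estimate_nn_series(trunc)
  row <- dplyr::bind_cols(hrv_indices(nn, cfg), heartprint_summary(trunc))
  dplyr::bind_cols(
    tibble::tibble(recording_id = attr(series, "recording_id"),
                   patient_id = attr(series, "patient_id"),
                   outcome = attr(series, "outcome")),
    row[, hrvprint_feature_names()]
  )
}

#' Extract the feature table of a cohort
#'
#' @param cohort A tibble with a list-column `series` of [rr_series()]
#'   objects (as returned by [generate_cohort()]), or a bare list of series.
#' @inheritParams extract_features
#' @return Feature table: one row per recording (see [extract_features()]).
#' @export
extract_feature_table <- function(cohort, cfg = spectral_config(),
                                  truncate_n = 1000) {
  series_list <- if (is.data.frame(cohort)) cohort$series else cohort
  purrr::map_dfr(series_list, extract_features, cfg = cfg,
                 truncate_n = truncate_n)
}

#' Impute undefined heartprint indices with training medians
#'
#' Recordings with fewer than 2 PVCs have undefined pattern statistics
#' (`NA`); before scaling and modeling these are filled with the median of
#' the defined training values of the same column.
#'
#' @param table Feature table to impute.
#' @param medians Named numeric vector of per-column medians to use; when
#'   `NULL` (the default) medians are computed from `table` itself, which
#'   is only appropriate for a training table.
#' @return List with `table` (imputed) and `medians` (named vector, for
#'   reuse on a test table).
#' @export
impute_heartprint <- function(table, medians = NULL) {
  cols <- intersect(heartprint_feature_names(), names(table))
  if (is.null(medians)) {
    medians <- vapply(table[cols], function(x) stats::median(x, na.rm = TRUE),
                      numeric(1))
  }
  for (cl in cols) {
    nas <- is.na(table[[cl]])
    if (any(nas)) table[[cl]][nas] <- medians[[cl]]
  }
  list(table = table, medians = medians)
}

#' Fit a per-column min-max scaler on a training table
#'
#' Each index is mapped to `(x - min) / (max - min)` so that the training
#' values of every column span exactly \[0, 1\].  The fitted minima and
#' ranges are reused unchanged on test data (see [apply_minmax()]), so test
#' values may legitimately fall outside \[0, 1\]; they are never clipped.
#' A constant training column has zero range and is mapped to 0 with a
#' warning.
#'
#' @param train Training feature table (no missing values in `cols`).
#' @param cols Columns to scale (default: the 16 indices).
#' @return An object of class `minmax_scaler`.
#' @export
fit_minmax <- function(train, cols = hrvprint_feature_names()) {
  cols <- intersect(cols, names(train))
  if (nrow(train) < 2L) stop("need at least 2 training rows", call. = FALSE)
  mins <- vapply(train[cols], min, numeric(1))
  maxs <- vapply(train[cols], max, numeric(1))
  if (any(maxs == mins)) {
    warning("constant training column(s) ",
            paste(cols[maxs == mins], collapse = ", "),
            " will be scaled to 0", call. = FALSE)
  }
  structure(list(cols = cols, min = mins, range = maxs - mins),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler A [fit_minmax()] object.
#' @param table Feature table whose scaled columns must all be present.
#' @return `table` with the scaler's columns replaced by scaled values.
#' @export
apply_minmax <- function(scaler, table) {
  missing <- setdiff(scaler$cols, names(table))
  if (length(missing)) {
    stop("table lacks scaler column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cl in scaler$cols) {
    rg <- scaler$range[[cl]]
    table[[cl]] <- if (rg == 0) 0 else (table[[cl]] - scaler$min[[cl]]) / rg
  }
  table
}

#' @export
print.minmax_scaler <- function(x, ...) {
  cat(sprintf("<minmax_scaler> %d columns\n", length(x$cols)))
  print(tibble::tibble(column = x$cols, min = unname(x$min),
                       range = unname(x$range)))
  invisible(x)
}

#' @rdname tidy.hrvprint_svm
#' @export
tidy.minmax_scaler <- function(x, ...) {
  tibble::tibble(column = x$cols, min = unname(x$min), range = unname(x$range))
}
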