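#' Beat-annotated RR-interval series
#'
#' An `rr_series` is a tibble with one row per RR interval, holding the
#' interval duration in seconds and the type of the beat that terminates it
#' (`"N"` for sinus, `"V"` for a premature ventricular complex).  Recording
#' metadata travel as attributes so the object can flow through dplyr verbs
#' that preserve attributes, and are restored by the package's own functions.
#'
#' @param intervals Numeric vector of RR-interval durations in seconds; all
#'   strictly positive and finite.
#' @param labels Character vector over `{"N", "V"}`, same length as
#'   `intervals`; each label annotates the beat that *ends* the interval.
#' @param recording_id,patient_id Opaque identifier strings.
#' @param outcome Recording-level class label: `"pre_event"` (recording ends
#'   just before a ventricular tachyarrhythmia episode) or `"control"`.
#'
#' @return A tibble of class `rr_series` with columns `interval` (seconds)
#'   and `label`, and attributes `recording_id`, `patient_id`, `outcome`.
#' @export
#' @examples
#' rr_series(c(0.8, 0.8, 0.5), c("N", "N", "V"))
rr_series <- function(intervals, labels,
                      recording_id = "rec", patient_id = "pat",
                      outcome = c("control", "pre_event")) {
  outcome <- match.arg(outcome)
  labels <- as.character(labels)
  validate_rr(intervals, labels)
  out <- tibble::tibble(interval = as.numeric(intervals), label = labels)
  attr(out, "recording_id") <- as.character(recording_id)
  attr(out, "patient_id") <- as.character(patient_id)
  attr(out, "outcome") <- outcome
  class(out) <- c("rr_series", class(out))
  out
}

validate_rr <- function(intervals, labels) {
  if (length(intervals) == 0L) {
    stop("rr_series must contain at least one interval", call. = FALSE)
  }
  if (length(intervals) != length(labels)) {
    stop("`intervals` and `labels` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(intervals)) || any(intervals <= 0)) {
    stop("all intervals must be strictly positive and finite", call. = FALSE)
  }
  bad <- which(!labels %in% c("N", "V"))
  if (length(bad)) {
    stop(sprintf("invalid beat label '%s' at position %d (must be 'N' or 'V')",
                 labels[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %s (patient %s, %s): %d beats, %d PVCs, %.1f s\n",
              attr(x, "recording_id"), attr(x, "patient_id"),
              attr(x, "outcome"), nrow(x), sum(x$label == "V"),
              sum(x$interval)))
  NextMethod()
}

# carry rr_series class + metadata onto a plain tibble (used after subsetting)
restore_rr <- function(df, template) {
  attr(df, "recording_id") <- attr(template, "recording_id")
  attr(df, "patient_id") <- attr(template, "patient_id")
  attr(df, "outcome") <- attr(template, "outcome")
  if (!inherits(df, "rr_series")) class(df) <- c("rr_series", class(df))
  df
}

#' Cumulative beat times of a series
#'
#' Beat `k` occurs at the cumulative sum of the first `k` intervals,
#' taking the start of the recording as time zero.
#'
#' @param series An [rr_series()].
#' @return Numeric vector of beat times in seconds, one per interval.
#' @export
beat_times <- function(series) cumsum(series$interval)
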