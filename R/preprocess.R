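#' Truncate a recording to its last n beats
#'
#' Recordings of unequal length are standardized by keeping only the final
#' `n` intervals (the beats closest to the event or to the end of a control
#' recording).  Shorter recordings are returned unchanged with a warning.
#'
#' @param series An [rr_series()].
#' @param n Number of trailing beats to keep (default 1000).
#' @return An [rr_series()] of `min(n, nrow(series))` beats with the same
#'   metadata.
#' @export
truncate_last_n <- function(series, n = 1000) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  len <- nrow(series)
  if (len < n) {
    warning(sprintf("recording %s has only %d beats (< %d); returned unchanged",
                    attr(series, "recording_id"), len, n), call. = FALSE)
    return(series)
  }
  out <- series[seq.int(len - n + 1L, len), ]
  restore_rr(out, series)
}

#' Check that the tail of a recording is free of PVCs
#'
#' PVCs at the very end of a pre-event recording can be the first beats of
#' the tachyarrhythmia itself; recordings are required to end in sinus
#' rhythm so the classifier is not handed the event onset.
#'
#' @param series An [rr_series()].
#' @param tail_beats Number of trailing beats to inspect (default 10).
#' @return `TRUE` if none of the final `tail_beats` labels is `"V"`.
#' @export
pvc_free_tail <- function(series, tail_beats = 10) {
  len <- nrow(series)
  if (!is.numeric(tail_beats) || length(tail_beats) != 1L || tail_beats < 1) {
    stop("`tail_beats` must be a single integer >= 1", call. = FALSE)
  }
  if (tail_beats > len) {
    stop(sprintf("tail_beats (%d) exceeds recording length (%d)",
                 tail_beats, len), call. = FALSE)
  }
  !any(series$label[seq.int(len - tail_beats + 1L, len)] == "V")
}

#' Derive the sinus-only (NN) interval series
#'
#' Every interval involved in a PVC — the V-labeled interval itself (the
#' coupling interval) and the interval immediately following it (which ends
#' the compensatory pause, so is not a normal-to-normal interval) — is
#' replaced by a value linearly interpolated between the nearest intervals
#' not involved in any PVC.  Replacement preserves series length and the
#' local trend of the tachogram; N intervals not adjacent to a PVC are
#' never altered.
#'
#' @param series An [rr_series()].
#' @return A tibble of class `nn_series` with column `interval` (seconds)
#'   and attributes `source_recording_id` and `n_replaced`.
#' @export
estimate_nn_series <- function(series) {
  iv <- series$interval
  lab <- series$label
  n <- length(iv)
  is_v <- lab == "V"
  follows_v <- c(FALSE, is_v[-n])
  replace_idx <- which(is_v | follows_v)
  keep_idx <- setdiff(seq_len(n), replace_idx)
  if (length(keep_idx) < 2L) {
    stop("fewer than 2 sinus intervals available; cannot interpolate",
         call. = FALSE)
  }
  out <- iv
  if (length(replace_idx)) {
    out[replace_idx] <- stats::approx(keep_idx, iv[keep_idx],
                                      xout = replace_idx, rule = 2)$y
  }
  nn <- tibble::tibble(interval = out)
  attr(nn, "source_recording_id") <- attr(series, "recording_id")
  attr(nn, "n_replaced") <- length(replace_idx)
  class(nn) <- c("nn_series", class(nn))
  nn
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> from %s: %d intervals, %d replaced\n",
              attr(x, "source_recording_id"), nrow(x), attr(x, "n_replaced")))
  NextMethod()
}
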