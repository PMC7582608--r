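#' Coupling intervals of a recording
#'
#' The coupling interval (CI) of a PVC is the interval from the preceding
#' sinus beat to the PVC — i.e. the duration of the V-labeled RR interval
#' itself, since labels annotate intervals by their terminating beat.  A V
#' interval immediately preceded by another V has no preceding sinus beat
#' and is excluded; a V in first position is kept (its interval starts at
#' the recording onset).
#'
#' @param series An [rr_series()].
#' @return Numeric vector of coupling intervals in ms (possibly empty).
#' @export
coupling_intervals <- function(series) {
  lab <- series$label
  is_v <- lab == "V"
  prev_n <- c(TRUE, lab[-length(lab)] == "N")  # first interval counts
  series$interval[is_v & prev_n] * 1000
}

#' NIB sequence of a recording
#'
#' For each consecutive pair of PVCs, the number of intervening sinus (N)
#' beats strictly between them.
#'
#' @param series An [rr_series()].
#' @return Integer vector of length `(number of V beats) - 1`; empty with a
#'   warning when fewer than 2 PVCs are present.
#' @export
nib_sequence <- function(series) {
  v_pos <- which(series$label == "V")
  if (length(v_pos) < 2L) {
    warning("fewer than 2 PVCs; NIB sequence is empty", call. = FALSE)
    return(integer(0))
  }
  diff(v_pos) - 1L
}

#' The 5 heartprint indices of a recording
#'
#' PVC density plus coupling-interval and NIB-pattern statistics:
#' `PVCs_hour` (count per hour of recording), `meanCI` and `SDCI` (ms),
#' `NIBmax` (the most frequent NIB value; ties broken toward the smaller
#' value) and `sNIB` (how many times that modal value occurs).  When fewer
#' than 2 PVCs are present the pattern statistics are undefined and
#' reported as `NA`, never as a silent 0; downstream modeling imputes them
#' with training-set medians.
#'
#' @param series An [rr_series()].
#' @return One-row tibble: `PVCs_hour`, `meanCI`, `SDCI`, `NIBmax`, `sNIB`.
#' @export
heartprint_summary <- function(series) {
  duration_h <- sum(series$interval) / 3600
  if (duration_h <= 0) stop("zero-duration series", call. = FALSE)
  n_v <- sum(series$label == "V")
  out <- tibble::tibble(PVCs_hour = n_v / duration_h,
                        meanCI = NA_real_, SDCI = NA_real_,
                        NIBmax = NA_real_, sNIB = NA_real_)
  if (n_v < 2L) return(out)
  ci <- coupling_intervals(series)
  nib <- nib_sequence(series)
  counts <- table(nib)
  modal <- as.integer(names(counts)[counts == max(counts)])
  out$meanCI <- mean(ci)
  out$SDCI <- if (length(ci) >= 2L) stats::sd(ci) else NA_real_
  out$NIBmax <- min(modal)
  out$sNIB <- as.numeric(max(counts))
  out
}
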