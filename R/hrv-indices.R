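#' Spectral analysis configuration
#'
#' Settings for the frequency-domain HRV indices: the NN tachogram is
#' cubic-spline interpolated to a uniform 3 Hz grid, split into 5-minute
#' segments, linearly detrended, and its power spectral density estimated
#' by Welch's method with a 300-sample Hann window and 50% overlap.  Band
#' powers are integrals of the one-sided density over the low-frequency
#' (0.04-0.15 Hz) and high-frequency (0.15-0.4 Hz) bands, in ms^2.
#'
#' @param resample_hz Uniform sampling rate for the interpolated tachogram.
#' @param window_len Welch window length in samples.
#' @param overlap_fraction Fractional overlap of consecutive windows.
#' @param lf_band,hf_band Frequency bands in Hz, `c(low, high)`.
#' @param segment_seconds Length of the analysis segments in seconds.
#' @param last_minute_seconds Window for the last-minute indices in seconds.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(resample_hz = 3, window_len = 300,
                            overlap_fraction = 0.5,
                            lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                            segment_seconds = 300, last_minute_seconds = 60) {
  stopifnot(
    lf_band[1] > 0, lf_band[1] < lf_band[2],
    lf_band[2] == hf_band[1], hf_band[1] < hf_band[2],
    hf_band[2] < resample_hz / 2,
    window_len / resample_hz <= segment_seconds,
    overlap_fraction >= 0, overlap_fraction < 1
  )
  structure(list(resample_hz = resample_hz, window_len = window_len,
                 overlap_fraction = overlap_fraction,
                 lf_band = lf_band, hf_band = hf_band,
                 segment_seconds = segment_seconds,
                 last_minute_seconds = last_minute_seconds),
            class = "spectral_config")
}

nn_intervals_ms <- function(nn) {
  iv <- if (is.data.frame(nn)) nn$interval else nn
  iv * 1000
}

#' Time-domain HRV indices
#'
#' @param nn An `nn_series` (or numeric vector of NN intervals in seconds).
#' @return One-row tibble: `meanNN` and `SDNN` (ms; sample SD), `RMSSD`
#'   (ms; root-mean-square of successive differences), `pNN50` (% of
#'   successive differences strictly greater than 50 ms).
#' @export
time_domain_indices <- function(nn) {
  x <- nn_intervals_ms(nn)
  if (length(x) < 2L) stop("need at least 2 NN intervals", call. = FALSE)
  d <- diff(x)
  tibble::tibble(
    meanNN = mean(x),
    SDNN = stats::sd(x),
    RMSSD = sqrt(mean(d^2)),
    pNN50 = 100 * mean(abs(d) > 50)
  )
}

#' Last-minute HRV indices
#'
#' Mean and SD of the NN intervals over the final `window_s` seconds of the
#' recording: the maximal suffix of intervals whose cumulative duration does
#' not exceed the window (at least 2 intervals are always used).
#'
#' @param nn An `nn_series` (or numeric vector of NN intervals in seconds).
#' @param window_s Window length in seconds (default 60).
#' @return One-row tibble with `meanNN_lm` and `SDNN_lm` in ms.
#' @export
last_minute_indices <- function(nn, window_s = 60) {
  iv <- if (is.data.frame(nn)) nn$interval else nn
  total <- sum(iv)
  if (total < window_s) {
    stop(sprintf("recording lasts %.1f s, shorter than the %g s window",
                 total, window_s), call. = FALSE)
  }
  from_end <- rev(cumsum(rev(iv)))  # from_end[k] = duration of suffix k..n
  keep <- which(from_end <= window_s)
  if (length(keep) < 2L) keep <- seq.int(length(iv) - 1L, length(iv))
  x <- iv[keep] * 1000
  tibble::tibble(meanNN_lm = mean(x), SDNN_lm = stats::sd(x))
}

#' Resample an NN tachogram onto a uniform time grid
#'
#' The NN duration is treated as a signal sampled at beat times (each
#' interval observed at the time of its terminating beat) and interpolated
#' with a cubic spline onto the grid `k / resample_hz` seconds, restricted
#' to the span of the beat times (no extrapolation).
#'
#' @param nn An `nn_series` (or numeric vector of NN intervals in seconds).
#' @param cfg A [spectral_config()].
#' @return Tibble with columns `time` (s) and `nn_ms`.
#' @export
resample_nn <- function(nn, cfg = spectral_config()) {
  iv <- if (is.data.frame(nn)) nn$interval else nn
  if (length(iv) < 4L) stop("need at least 4 beats for cubic interpolation",
                            call. = FALSE)
  t_beat <- cumsum(iv)
  fs <- cfg$resample_hz
  k <- seq.int(ceiling(t_beat[1] * fs), floor(t_beat[length(t_beat)] * fs))
  grid <- k / fs
  f <- stats::splinefun(t_beat, iv * 1000, method = "fmm")
  tibble::tibble(time = grid, nn_ms = f(grid))
}

# Welch PSD: linear detrend, Hann-windowed overlapping periodograms,
# one-sided density so that band integrals are in ms^2.
welch_psd <- function(x, cfg) {
  n_win <- cfg$window_len
  if (length(x) < n_win) {
    stop(sprintf("signal of %d samples shorter than one %d-sample window",
                 length(x), n_win), call. = FALSE)
  }
  fs <- cfg$resample_hz
  idx <- seq_along(x)
  x <- stats::residuals(stats::lm.fit(cbind(1, idx), x))
  hop <- max(1L, round(n_win * (1 - cfg$overlap_fraction)))
  starts <- seq.int(1L, length(x) - n_win + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n_win - 1)) / (n_win - 1))
  s2 <- sum(w^2)
  half <- floor(n_win / 2)
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + n_win - 1L)] * w
    sp <- abs(stats::fft(seg))^2 / (fs * s2)
    p <- sp[2:(half + 1L)]            # drop DC
    scale2 <- rep(2, half)
    if (n_win %% 2 == 0) scale2[half] <- 1   # Nyquist bin not doubled
    acc <- acc + p * scale2
  }
  tibble::tibble(freq = fs * seq_len(half) / n_win, psd = acc / length(starts))
}

#' Band powers of a uniformly sampled NN signal
#'
#' Linear trends are removed, the power spectral density is estimated by
#' Welch's method (Hann window of `window_len` samples, 50% overlap), and
#' the low- and high-frequency powers are the density integrals over their
#' bands.  The LF/HF boundary bin is assigned to HF.
#'
#' @param signal Numeric vector (ms) sampled at `cfg$resample_hz`, or the
#'   tibble returned by [resample_nn()].
#' @param cfg A [spectral_config()].
#' @return One-row tibble with `LF` and `HF` in ms^2.
#' @export
welch_band_powers <- function(signal, cfg = spectral_config()) {
  x <- if (is.data.frame(signal)) signal$nn_ms else signal
  psd <- welch_psd(x, cfg)
  df <- psd$freq[2] - psd$freq[1]
  lf <- psd$freq >= cfg$lf_band[1] & psd$freq < cfg$lf_band[2]
  hf <- psd$freq >= cfg$hf_band[1] & psd$freq <= cfg$hf_band[2]
  tibble::tibble(LF = sum(psd$psd[lf]) * df, HF = sum(psd$psd[hf]) * df)
}

#' Segment-averaged frequency-domain HRV indices
#'
#' The resampled tachogram is split into consecutive non-overlapping
#' 5-minute segments anchored at the recording end (so the most recent data
#' are always covered; a leading partial segment is dropped).  Per segment,
#' LF and HF come from [welch_band_powers()], the normalized powers are
#' `LFnu = 100 * LF / (LF + HF)` and `HFnu = 100 * HF / (LF + HF)`, and
#' `LF_HF = LF / HF`.  Reported values are across-segment means; a segment
#' with zero HF power is excluded from the averages with a warning.
#'
#' @param nn An `nn_series` (or numeric vector of NN intervals in seconds).
#' @param cfg A [spectral_config()].
#' @return One-row tibble: `LF`, `HF` (ms^2), `LFnu`, `HFnu`, `LF_HF`.
#' @export
spectral_indices <- function(nn, cfg = spectral_config()) {
  iv <- if (is.data.frame(nn)) nn$interval else nn
  if (sum(iv) < cfg$segment_seconds) {
    stop(sprintf("recording lasts %.1f s, shorter than one %g s segment",
                 sum(iv), cfg$segment_seconds), call. = FALSE)
  }
  sig <- resample_nn(nn, cfg)$nn_ms
  seg_len <- as.integer(round(cfg$segment_seconds * cfg$resample_hz))
  n_seg <- length(sig) %/% seg_len
  offset <- length(sig) - n_seg * seg_len  # leading partial segment dropped
  rows <- purrr::map(seq_len(n_seg), function(i) {
    seg <- sig[(offset + (i - 1L) * seg_len + 1L):(offset + i * seg_len)]
    welch_band_powers(seg, cfg)
  })
  bp <- dplyr::bind_rows(rows)
  ok <- bp$HF > 0
  if (!all(ok)) {
    warning(sprintf("%d segment(s) with zero HF power excluded from averages",
                    sum(!ok)), call. = FALSE)
    if (!any(ok)) {
      return(tibble::tibble(LF = NA_real_, HF = NA_real_, LFnu = NA_real_,
                            HFnu = NA_real_, LF_HF = NA_real_))
    }
  }
  bp <- bp[ok, ]
  tibble::tibble(
    LF = mean(bp$LF), HF = mean(bp$HF),
    LFnu = mean(100 * bp$LF / (bp$LF + bp$HF)),
    HFnu = mean(100 * bp$HF / (bp$LF + bp$HF)),
    LF_HF = mean(bp$LF / bp$HF)
  )
}

#' All 11 HRV indices of a recording
#'
#' Convenience wrapper binding [time_domain_indices()],
#' [spectral_indices()] and [last_minute_indices()] into a single row.
#'
#' @inheritParams spectral_indices
#' @return One-row tibble with columns `meanNN`, `SDNN`, `RMSSD`, `pNN50`,
#'   `LF`, `HF`, `LFnu`, `HFnu`, `LF_HF`, `meanNN_lm`, `SDNN_lm`.
#' @export
hrv_indices <- function(nn, cfg = spectral_config()) {
  dplyr::bind_cols(
    time_domain_indices(nn),
    spectral_indices(nn, cfg),
    last_minute_indices(nn, cfg$last_minute_seconds)
  )
}
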