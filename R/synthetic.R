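#' Parameters of a synthetic annotated RR recording
#'
#' The sinus (NN) tachogram is a two-sinusoid-plus-noise model:
#' `NN(t) = mean_nn + lf_amp * sin(2*pi*0.10*t + phi1)
#'        + hf_amp * sin(2*pi*0.30*t + phi2) + noise`,
#' with seeded random phases — the minimal generator with controllable LF
#' (0.10 Hz) and HF (0.30 Hz) oscillatory content.  PVCs are inserted as a
#' run of events separated by NIB gaps drawn from `nib_weights`, each PVC
#' replacing a scheduled beat with a V-labeled coupling interval drawn from
#' a truncated normal, followed by a fully compensatory pause
#' (`2 * local NN - CI`, the textbook PVC timing).  The last 10 beats are
#' kept PVC-free.
#'
#' @param n_beats Number of RR intervals (default 1000).
#' @param mean_nn Mean NN interval, ms.
#' @param sd_noise SD of the additive beat-to-beat noise, ms.
#' @param lf_amp,hf_amp Amplitudes of the 0.10 Hz and 0.30 Hz components, ms.
#' @param pvc_rate Target PVC density, events/hour.
#' @param ci_mean,ci_sd Coupling-interval mean and SD, ms; draws are
#'   truncated to `(0.2, 0.95) * mean_nn`.
#' @param nib_weights Named non-negative weights over candidate NIB values
#'   (names are the integer NIB values).
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_beats = 1000, mean_nn = 800, sd_noise = 13,
                         lf_amp = 20, hf_amp = 15, pvc_rate = 100,
                         ci_mean = 520, ci_sd = 60,
                         nib_weights = c("0" = 0.05, "1" = 0.35, "2" = 0.3,
                                         "3" = 0.15, "4" = 0.1, "5" = 0.05),
                         seed = NULL) {
  stopifnot(n_beats >= 1, mean_nn > ci_mean, ci_mean > 0,
            sd_noise >= 0, lf_amp >= 0, hf_amp >= 0, pvc_rate >= 0,
            ci_sd >= 0, all(nib_weights >= 0), sum(nib_weights) > 0,
            !is.null(names(nib_weights)))
  structure(as.list(environment()), class = "synth_params")
}

#' Preset parameter templates for the paired study conditions
#'
#' Centers follow the typical pre-event vs control contrasts seen in
#' implantable-defibrillator RR recordings: pre-event recordings have a
#' shorter mean NN interval (faster heart rate), a larger LF/HF ratio
#' (sympathetic predominance), more PVCs per hour and a shorter, more
#' premature mean coupling interval.
#'
#' @return A [synth_params()] object.
#' @export
preset_pre_event <- function() {
  synth_params(mean_nn = 676, sd_noise = 13, lf_amp = 25, hf_amp = 12,
               pvc_rate = 159, ci_mean = 520, ci_sd = 63,
               nib_weights = c("0" = 0.15, "1" = 0.35, "2" = 0.2,
                               "3" = 0.15, "4" = 0.1, "5" = 0.05))
}

#' @rdname preset_pre_event
#' @export
preset_control <- function() {
  synth_params(mean_nn = 787, sd_noise = 14, lf_amp = 20, hf_amp = 15,
               pvc_rate = 71, ci_mean = 575, ci_sd = 57,
               nib_weights = c("0" = 0.05, "1" = 0.2, "2" = 0.35,
                               "3" = 0.2, "4" = 0.12, "5" = 0.08))
}

# truncated-normal draws by rejection (falls back to clamping only if a
# value still escapes after many rounds; bounds are wide in practice)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Generate one synthetic annotated RR recording
#'
#' @param params A [synth_params()] object.
#' @param recording_id,patient_id,outcome Metadata for the resulting series.
#' @param seed Overrides `params$seed` when not `NULL`.
#' @return An [rr_series()] of `params$n_beats` intervals.
#' @export
generate_recording <- function(params, recording_id = "synth",
                               patient_id = "pat", outcome = "control",
                               seed = params$seed) {
  p <- params
  with_seed(seed, {
    mean_s <- p$mean_nn / 1000
    phi <- stats::runif(2, 0, 2 * pi)
    nn <- numeric(p$n_beats)
    t <- 0
    for (k in seq_len(p$n_beats)) {
      v <- mean_s +
        (p$lf_amp * sin(2 * pi * 0.10 * t + phi[1]) +
           p$hf_amp * sin(2 * pi * 0.30 * t + phi[2]) +
           stats::rnorm(1, 0, p$sd_noise)) / 1000
      nn[k] <- max(v, 0.2 * mean_s)
      t <- t + nn[k]
    }
    intervals <- nn
    labels <- rep("N", p$n_beats)

    duration_h <- p$n_beats * mean_s / 3600
    m <- round(p$pvc_rate * duration_h)
    if (m >= 1) {
      nib_vals <- as.integer(names(p$nib_weights))
      gaps <- if (m > 1) {
        sample(nib_vals, m - 1, replace = TRUE, prob = p$nib_weights)
      } else integer(0)
      rel <- cumsum(c(0L, gaps + 1L))      # PVC positions relative to start
      last_ok <- p$n_beats - 11L           # keeps 10 trailing beats PVC-free
      rel <- rel[rel <= last_ok - 2L]      # truncate an overlong run
      span <- if (length(rel)) rel[length(rel)] else 0L
      start <- if (last_ok - span >= 2L) {
        sample(2:(last_ok - span), 1)
      } else 2L
      v_idx <- start + rel
      ci <- rtrunc_norm(length(v_idx), p$ci_mean, p$ci_sd,
                        0.2 * p$mean_nn, 0.95 * p$mean_nn) / 1000
      for (j in seq_along(v_idx)) {
        i <- v_idx[j]
        base <- nn[i]
        intervals[i] <- ci[j]
        labels[i] <- "V"
        if (!((i + 1L) %in% v_idx)) {
          intervals[i + 1L] <- max(2 * base - ci[j], 0.1 * mean_s)
        }
      }
    }
    rr_series(intervals, labels, recording_id = recording_id,
              patient_id = patient_id, outcome = outcome)
  })
}

#' Specification of a synthetic paired cohort
#'
#' Each patient gets multiplicatively jittered copies of the two outcome
#' templates (one shared log-normal multiplier set per patient, so the
#' within-patient pairing is real), emulating the paired pre-event/control
#' design of follow-up recordings from the same implanted device.
#'
#' @param n_patients Number of patients.
#' @param pre,control [synth_params()] templates for the two outcomes.
#' @param recordings_per_patient Length-2 counts `c(pre, control)`.
#' @param jitter_sd SD of the between-patient log-normal multiplier.
#' @param seed Integer seed for the whole cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20, pre = preset_pre_event(),
                        control = preset_control(),
                        recordings_per_patient = c(1, 1),
                        jitter_sd = 0.1, seed = 1) {
  stopifnot(n_patients >= 1, inherits(pre, "synth_params"),
            inherits(control, "synth_params"), jitter_sd >= 0,
            all(recordings_per_patient >= 0))
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic paired cohort
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with one row per recording: `recording_id`, `patient_id`,
#'   `outcome` and a list-column `series` of [rr_series()] objects.  Fully
#'   reproducible from `spec$seed`.
#' @export
generate_cohort <- function(spec) {
  jitter_params <- function(p, mult) {
    for (nm in names(mult)) p[[nm]] <- p[[nm]] * mult[[nm]]
    p
  }
  with_seed(spec$seed, {
    rows <- purrr::map_dfr(seq_len(spec$n_patients), function(i) {
      pid <- sprintf("P%03d", i)
      mult <- exp(stats::rnorm(7, 0, spec$jitter_sd))
      names(mult) <- c("mean_nn", "sd_noise", "lf_amp", "hf_amp",
                       "pvc_rate", "ci_mean", "ci_sd")
      templates <- list(pre_event = jitter_params(spec$pre, mult),
                        control = jitter_params(spec$control, mult))
      counts <- c(pre_event = spec$recordings_per_patient[1],
                  control = spec$recordings_per_patient[2])
      purrr::map_dfr(names(templates), function(oc) {
        purrr::map_dfr(seq_len(counts[[oc]]), function(j) {
          rid <- sprintf("%s_%s_%d", pid, oc, j)
          s <- generate_recording(templates[[oc]], recording_id = rid,
                                  patient_id = pid, outcome = oc,
                                  seed = NULL)
          tibble::tibble(recording_id = rid, patient_id = pid,
                         outcome = oc, series = list(s))
        })
      })
    })
    rows
  })
}
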