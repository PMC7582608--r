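# Independent brute-force oracles used to freeze expected values.

# AUC by explicit concordant / discordant / tie counting over all
# positive-negative pairs (ties count 1/2)
oracle_auc <- function(scores, positive) {
  p <- scores[positive]
  n <- scores[!positive]
  s <- 0
  for (a in p) {
    for (b in n) s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(p) * length(n))
}

# single forward scan over beat labels: coupling intervals (ms) and NIB
oracle_ci_nib <- function(intervals, labels) {
  ci <- numeric(0)
  nib <- integer(0)
  last_v <- NA_integer_
  run_n <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == "V") {
      if (i == 1L || labels[i - 1L] == "N") ci <- c(ci, intervals[i] * 1000)
      if (!is.na(last_v)) nib <- c(nib, run_n)
      last_v <- i
      run_n <- 0L
    } else {
      if (!is.na(last_v)) run_n <- run_n + 1L
    }
  }
  list(ci = ci, nib = nib)
}

# naive two-pass time-domain indices (ms in, ms out)
oracle_time_domain <- function(x_ms) {
  n <- length(x_ms)
  m <- sum(x_ms) / n
  ss <- 0
  for (v in x_ms) ss <- ss + (v - m)^2
  d <- x_ms[-1] - x_ms[-n]
  sq <- 0
  gt50 <- 0
  for (v in d) {
    sq <- sq + v^2
    if (abs(v) > 50) gt50 <- gt50 + 1
  }
  list(meanNN = m, SDNN = sqrt(ss / (n - 1)), RMSSD = sqrt(sq / (n - 1)),
       pNN50 = 100 * gt50 / (n - 1))
}

# a random valid annotated series for fuzz/property tests
random_rr_series <- function(n = 60, pvc_prob = 0.15, id = "fuzz") {
  labels <- ifelse(stats::runif(n) < pvc_prob, "V", "N")
  intervals <- stats::runif(n, 0.4, 1.2)
  rr_series(intervals, labels, recording_id = id)
}

# the four non-spectral modeling indices for a whole cohort, skipping the
# Welch pipeline where it is not under test
nonspectral_features <- function(co) {
  purrr::map_dfr(co$series, function(s) {
    tr <- truncate_last_n(s, 1000)
    nn <- estimate_nn_series(tr)
    dplyr::bind_cols(
      tibble::tibble(recording_id = attr(s, "recording_id"),
                     patient_id = attr(s, "patient_id"),
                     outcome = attr(s, "outcome")),
      last_minute_indices(nn), time_domain_indices(nn)[, "meanNN"],
      heartprint_summary(tr)[, c("SDCI", "meanCI")])
  })
}

# quick feature rows (meanNN, PVCs/h, meanCI only) for direction-of-effect
# checks, avoiding the spectral pipeline where it is not under test
cheap_features <- function(series) {
  nn <- estimate_nn_series(truncate_last_n(series, 1000))
  hp <- heartprint_summary(series)
  tibble::tibble(outcome = attr(series, "outcome"),
                 meanNN = mean(nn$interval) * 1000,
                 PVCs_hour = hp$PVCs_hour, meanCI = hp$meanCI)
}
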