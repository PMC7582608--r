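#' Build a patient-paired 10-fold cross-validation plan
#'
#' For each eligible patient (one having at least one pre-event and one
#' control recording) a single pair of recordings is selected — one of each
#' outcome, drawn uniformly at random when a patient has several.  Patients
#' are then distributed across `k` folds as evenly as possible, with both
#' recordings of a patient always in the same fold.  Because every patient
#' contributes exactly one recording of each class, every fold has equal
#' numbers of pre-event and control recordings, fixing the class prevalence
#' (and hence the chance-level threshold) at 0.5.
#'
#' @param table Feature table with `patient_id`, `recording_id`, `outcome`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed making pair selection and fold assignment
#'   reproducible.
#' @return A tibble of class `fold_plan` with columns `patient_id`, `fold`,
#'   `pre_recording_id`, `control_recording_id`; attribute `k`.
#' @export
build_paired_folds <- function(table, k = 10, seed = 1) {
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  by_pat <- split(table[, c("recording_id", "outcome")], table$patient_id)
  eligible <- names(by_pat)[vapply(by_pat, function(d) {
    any(d$outcome == "pre_event") && any(d$outcome == "control")
  }, logical(1))]
  dropped <- setdiff(names(by_pat), eligible)
  if (length(dropped)) {
    message("excluded ", length(dropped),
            " patient(s) lacking a pre-event/control pair: ",
            paste(dropped, collapse = ", "))
  }
  if (length(eligible) < k) {
    stop(sprintf("only %d eligible patients for %d folds",
                 length(eligible), k), call. = FALSE)
  }
  with_seed(seed, {
    pairs <- purrr::map_dfr(eligible, function(p) {
      d <- by_pat[[p]]
      pre <- d$recording_id[d$outcome == "pre_event"]
      ctl <- d$recording_id[d$outcome == "control"]
      tibble::tibble(
        patient_id = p,
        pre_recording_id = if (length(pre) > 1) sample(pre, 1) else pre,
        control_recording_id = if (length(ctl) > 1) sample(ctl, 1) else ctl
      )
    })
    ord <- sample.int(nrow(pairs))
    pairs <- pairs[ord, ]
    pairs$fold <- rep_len(seq_len(k), nrow(pairs))
  })
  out <- pairs[, c("patient_id", "fold", "pre_recording_id",
                   "control_recording_id")]
  attr(out, "k") <- k
  class(out) <- c("fold_plan", class(out))
  out
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
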