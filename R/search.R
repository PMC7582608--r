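# Per-split preparation shared by all combinations and grid points: for
# each fold, impute + min-max scale using the 9 training folds only (the
# scaler is refit inside every split, so no test information leaks), and
# hand back ready-made matrices.
prepare_folds <- function(table, plan) {
  feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                   c("recording_id", "patient_id", "outcome"))
  purrr::map(sort(unique(plan$fold)), function(f) {
    test_ids <- c(plan$pre_recording_id[plan$fold == f],
                  plan$control_recording_id[plan$fold == f])
    train_ids <- c(plan$pre_recording_id[plan$fold != f],
                   plan$control_recording_id[plan$fold != f])
    train <- table[match(train_ids, table$recording_id), ]
    test <- table[match(test_ids, table$recording_id), ]
    imp <- impute_heartprint(train)
    scaler <- suppressWarnings(fit_minmax(imp$table, cols = feats))
    train_s <- apply_minmax(scaler, imp$table)
    test_s <- apply_minmax(scaler,
                           impute_heartprint(test, imp$medians)$table)
    list(x_train = as.matrix(train_s[, feats]),
         y_train = train_s$outcome,
         x_test = as.matrix(test_s[, feats]),
         y_test = test_s$outcome)
  })
}

# score one (feature set, C, gamma) over all prepared folds; plain numeric
# return because this sits in the innermost loop of the grid search
score_folds_raw <- function(prep, features, cost, gamma) {
  k <- length(prep)
  auc <- numeric(k)
  acc <- numeric(k)
  for (i in seq_len(k)) {
    fd <- prep[[i]]
    fit <- fit_rbf_svm(fd$x_train[, features, drop = FALSE], fd$y_train,
                       cost, gamma)
    margin <- rbf_margin(fit, fd$x_test[, features, drop = FALSE])
    pos <- fd$y_test == "pre_event"
    auc[i] <- auc_rank(margin, pos)
    acc[i] <- 100 * mean((margin > 0) == pos)
  }
  c(auc_mean = mean(auc), auc_sd = stats::sd(auc),
    acc_mean = mean(acc), acc_sd = stats::sd(acc))
}

# best (C, gamma) for a feature set; ties broken by smaller C then smaller
# gamma (grid enumerated cost-major, gamma-minor, so the first maximum wins)
best_grid_point <- function(prep, features, grid) {
  best <- NULL
  best_pars <- c(NA_real_, NA_real_)
  for (cost in grid$cost) {
    for (gamma in grid$gamma) {
      sc <- score_folds_raw(prep, features, cost, gamma)
      if (is.null(best) || sc[["auc_mean"]] > best[["auc_mean"]]) {
        best <- sc
        best_pars <- c(cost, gamma)
      }
    }
  }
  tibble::tibble(cost = best_pars[1], gamma = best_pars[2],
                 auc_mean = best[["auc_mean"]], auc_sd = best[["auc_sd"]],
                 acc_mean = best[["acc_mean"]], acc_sd = best[["acc_sd"]])
}

#' Cross-validated performance of one index set and hyperparameter pair
#'
#' For each fold of the plan, the RBF-SVM is trained on the other folds'
#' recordings (with imputation and min-max scaling refit on those folds
#' only) and the held-out recordings are ranked by decision margin; AUC is
#' the rank statistic and accuracy is taken at the margin-0 threshold.
#'
#' @param table Raw feature table.
#' @param plan A [build_paired_folds()] plan.
#' @param features Index columns to use.
#' @param cost,gamma RBF-SVM hyperparameters.
#' @return One-row tibble: `auc_mean`, `auc_sd`, `acc_mean`, `acc_sd`
#'   (mean and SD across folds; accuracy in percent).
#' @export
cross_validated_score <- function(table, plan, features, cost, gamma) {
  stopifnot(all(features %in% names(table)))
  sc <- score_folds_raw(prepare_folds(table, plan), features, cost, gamma)
  tibble::tibble(auc_mean = sc[["auc_mean"]], auc_sd = sc[["auc_sd"]],
                 acc_mean = sc[["acc_mean"]], acc_sd = sc[["acc_sd"]])
}

#' Greedy forward search over index combinations with grid re-optimization
#'
#' Starts from the best of all two-index combinations, then repeatedly adds
#' the single index that maximizes the cross-validated mean AUC, refitting
#' the full (C, gamma) grid at every step, until `max_size` indices are
#' included.  This yields a nested chain of index sets, one row per size.
#'
#' @param table Raw feature table.
#' @param plan A [build_paired_folds()] plan.
#' @param grid Hyperparameter grids from [hyperparameter_grids()].
#' @param features Candidate index columns (default: all 16).
#' @param max_size Largest combination size to examine.
#' @return Tibble of class `hrvprint_search`, one row per combination size:
#'   `size`, `added` (index added at this step), `features` (list-column),
#'   `cost`, `gamma`, `auc_mean`, `auc_sd`, `acc_mean`, `acc_sd`.
#' @export
greedy_search <- function(table, plan, grid = hyperparameter_grids(),
                          features = hrvprint_feature_names(),
                          max_size = length(features)) {
  stopifnot(length(features) >= 2, all(features %in% names(table)))
  max_size <- min(max_size, length(features))
  prep <- prepare_folds(table, plan)

  pairs <- utils::combn(features, 2, simplify = FALSE)
  pair_best <- purrr::map_dfr(pairs, best_grid_point, prep = prep,
                              grid = grid)
  top <- which.max(pair_best$auc_mean)
  current <- pairs[[top]]
  rows <- dplyr::bind_cols(
    tibble::tibble(size = 2L, added = paste(current, collapse = "+"),
                   features = list(current)),
    pair_best[top, ]
  )

  while (length(current) < max_size) {
    remaining <- setdiff(features, current)
    cand <- purrr::map_dfr(remaining, function(fx) {
      best_grid_point(prep, c(current, fx), grid)
    })
    pick <- which.max(cand$auc_mean)
    current <- c(current, remaining[pick])
    rows <- dplyr::bind_rows(rows, dplyr::bind_cols(
      tibble::tibble(size = length(current), added = remaining[pick],
                     features = list(current)),
      cand[pick, ]
    ))
  }
  class(rows) <- c("hrvprint_search", class(rows))
  rows
}

#' Pick the final combination sizes from a search result
#'
#' Returns the combination with the highest mean AUC and the one with the
#' highest mean accuracy (possibly the same); ties go to the smaller size.
#'
#' @param result A [greedy_search()] result.
#' @return Tibble with rows `best_auc` and `best_accuracy` (column
#'   `criterion`), carrying the selected size, features and
#'   hyperparameters.
#' @export
select_final <- function(result) {
  stopifnot(nrow(result) > 0)
  pick <- function(metric) {
    best <- max(result[[metric]])
    cand <- result[result[[metric]] == best, ]
    cand[which.min(cand$size), ]
  }
  out <- dplyr::bind_rows(pick("auc_mean"), pick("acc_mean"))
  dplyr::bind_cols(tibble::tibble(criterion = c("best_auc", "best_accuracy")),
                   out)
}
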