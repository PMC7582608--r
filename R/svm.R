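#' Hyperparameter grids for the RBF-SVM search
#'
#' Cost is an arithmetic grid, 0.5 to 10 in steps of 0.5 (20 values);
#' gamma is a geometric grid, `2^e` for exponents -15 to 3 in steps of 0.5
#' (37 values).
#'
#' @param cost_range,cost_step Arithmetic grid for the soft-margin cost.
#' @param gamma_exponents Exponents `e` of the `2^e` gamma grid.
#' @return List with numeric vectors `cost` and `gamma`.
#' @export
hyperparameter_grids <- function(cost_range = c(0.5, 10), cost_step = 0.5,
                                 gamma_exponents = seq(-15, 3, by = 0.5)) {
  list(cost = seq(cost_range[1], cost_range[2], by = cost_step),
       gamma = 2^gamma_exponents)
}

# Fit a binary RBF-SVM (libsvm via e1071) and keep only what is needed to
# compute decision margins natively: support vectors, dual coefficients,
# rho, and the sign that orients positive margins toward "pre_event".
fit_rbf_svm <- function(X, y, cost, gamma) {
  y <- factor(y, levels = c("control", "pre_event"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data contain a single class", call. = FALSE)
  }
  m <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                  cost = cost, gamma = gamma, scale = FALSE)
  positive_first <- m$levels[m$labels[1]] == "pre_event"
  list(sv = unname(as.matrix(m$SV)), coefs = as.numeric(m$coefs),
       rho = m$rho, gamma = gamma, cost = cost,
       flip = if (positive_first) 1 else -1)
}

# decision margins (positive = pre_event) for rows of matrix X
rbf_margin <- function(fit, X) {
  X <- as.matrix(X)
  d2 <- outer(rowSums(X^2), rowSums(fit$sv^2), "+") - 2 * X %*% t(fit$sv)
  K <- exp(-fit$gamma * pmax(d2, 0))
  fit$flip * (as.vector(K %*% fit$coefs) - fit$rho)
}

#' Train the final RBF-SVM on a full training table
#'
#' Undefined heartprint values are imputed with the training medians, a
#' min-max scaler is fitted on all training rows, and the SVM is trained on
#' every recording (not only the cross-validation pairs).  The returned
#' model bundles the scaler, imputation medians and index list, so it can
#' score raw feature tables directly and be serialized to plain text.
#'
#' @param table Raw (unscaled) feature table with `outcome`.
#' @param features Character vector of index columns to use.
#' @param cost,gamma RBF-SVM hyperparameters (both > 0).
#' @return An object of class `hrvprint_svm`.
#' @export
train_final <- function(table, features, cost, gamma) {
  stopifnot(cost > 0, gamma > 0, all(features %in% names(table)))
  imp <- impute_heartprint(table)
  scaler <- fit_minmax(imp$table, cols = features)
  scaled <- apply_minmax(scaler, imp$table)
  fit <- fit_rbf_svm(as.matrix(scaled[, features]), scaled$outcome,
                     cost, gamma)
  structure(list(features = features, cost = cost, gamma = gamma,
                 scaler = scaler, medians = imp$medians,
                 sv = fit$sv, coefs = fit$coefs, rho = fit$rho,
                 flip = fit$flip, n_train = nrow(table)),
            class = "hrvprint_svm")
}

#' Score recordings with a trained model
#'
#' @param object An [train_final()] model.
#' @param newdata Raw feature table containing the model's index columns.
#' @param type `"margin"` for the signed decision value (positive =
#'   pre-event) or `"class"` for the label at the margin-0 threshold.
#' @param ... Unused.
#' @return Numeric margins or a character vector of labels.
#' @export
predict.hrvprint_svm <- function(object, newdata, type = c("margin", "class"),
                                 ...) {
  type <- match.arg(type)
  scaled <- apply_minmax(object$scaler,
                         impute_heartprint(newdata, object$medians)$table)
  margin <- rbf_margin(object, as.matrix(scaled[, object$features]))
  if (type == "margin") margin else
    ifelse(margin > 0, "pre_event", "control")
}

#' Evaluate a trained model on a held-out feature table
#'
#' Recordings are ranked by decision margin; AUC comes from the rank
#' statistic with a Hanley-McNeil 95% confidence interval, and accuracy at
#' the margin-0 threshold with a Wilson 95% interval.
#'
#' @param model An [train_final()] model.
#' @param test_table Raw feature table with `outcome` (both classes
#'   present), scaled internally with the *training* scaler.
#' @return One-row tibble of class `hrvprint_eval`: `auc`, `auc_lower`,
#'   `auc_upper`, `accuracy` (percent), `accuracy_lower`, `accuracy_upper`,
#'   `n`.  Scores and labels are kept as attributes for [autoplot()].
#' @export
evaluate_model <- function(model, test_table) {
  margin <- predict(model, test_table, type = "margin")
  pos <- test_table$outcome == "pre_event"
  if (!any(pos) || all(pos)) {
    stop("test table must contain both outcomes", call. = FALSE)
  }
  auc <- auc_rank(margin, pos)
  auc_ci <- auc_hanley_ci(auc, sum(pos), sum(!pos))
  correct <- sum((margin > 0) == pos)
  acc_ci <- wilson_ci(correct, length(pos))
  out <- tibble::tibble(
    auc = auc, auc_lower = auc_ci[["lower"]], auc_upper = auc_ci[["upper"]],
    accuracy = 100 * correct / length(pos),
    accuracy_lower = 100 * acc_ci[["lower"]],
    accuracy_upper = 100 * acc_ci[["upper"]],
    n = length(pos)
  )
  attr(out, "scores") <- margin
  attr(out, "positive") <- pos
  class(out) <- c("hrvprint_eval", class(out))
  out
}

#' @export
print.hrvprint_svm <- function(x, ...) {
  cat(sprintf(
    "<hrvprint_svm> RBF SVM: %d support vectors, C = %g, gamma = %g\n",
    nrow(x$sv), x$cost, x$gamma))
  cat("indices:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a trained model to a plain-text JSON bundle
#'
#' Stores support vectors, dual coefficients, rho, hyperparameters, scaler
#' and imputation medians; [read_hrvprint_model()] reconstructs a model
#' whose decision margins are bit-identical to the original's.
#'
#' @param model An [train_final()] model.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_hrvprint_model <- function(model, path) {
  payload <- list(
    features = model$features, cost = model$cost, gamma = model$gamma,
    scaler = list(cols = model$scaler$cols,
                  min = as.list(model$scaler$min),
                  range = as.list(model$scaler$range)),
    medians = as.list(model$medians),
    sv = model$sv, coefs = model$coefs, rho = model$rho,
    flip = model$flip, n_train = model$n_train
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hrvprint_model
#' @export
read_hrvprint_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- structure(list(cols = p$scaler$cols,
                           min = unlist(p$scaler$min),
                           range = unlist(p$scaler$range)),
                      class = "minmax_scaler")
  structure(list(features = p$features, cost = p$cost, gamma = p$gamma,
                 scaler = scaler, medians = unlist(p$medians),
                 sv = matrix(unlist(p$sv), nrow = nrow(p$sv)),
                 coefs = p$coefs, rho = p$rho, flip = p$flip,
                 n_train = p$n_train),
            class = "hrvprint_svm")
}
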