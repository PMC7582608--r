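#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style tidiers for fitted objects
#'
#' `tidy()` on a trained SVM returns one row per support vector (its dual
#' coefficient); on a scaler, one row per scaled column.  `glance()`
#' returns a one-row model summary.
#'
#' @param x A `hrvprint_svm`, `minmax_scaler`, `hrvprint_search` or
#'   `hrvprint_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hrvprint_svm <- function(x, ...) {
  tibble::tibble(support_vector = seq_along(x$coefs),
                 dual_coef = x$coefs * x$flip)
}

#' @rdname tidy.hrvprint_svm
#' @export
glance.hrvprint_svm <- function(x, ...) {
  tibble::tibble(n_support_vectors = length(x$coefs),
                 n_features = length(x$features),
                 cost = x$cost, gamma = x$gamma, n_train = x$n_train)
}

#' @rdname tidy.hrvprint_svm
#' @export
tidy.hrvprint_search <- function(x, ...) {
  out <- x
  out$features <- vapply(out$features, paste, character(1), collapse = ", ")
  tibble::as_tibble(out)
}

#' @rdname tidy.hrvprint_svm
#' @export
glance.hrvprint_search <- function(x, ...) {
  sel <- select_final(x)
  tibble::tibble(
    best_auc_size = sel$size[sel$criterion == "best_auc"],
    best_auc = sel$auc_mean[sel$criterion == "best_auc"],
    best_accuracy_size = sel$size[sel$criterion == "best_accuracy"],
    best_accuracy = sel$acc_mean[sel$criterion == "best_accuracy"]
  )
}
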