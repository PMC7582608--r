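#' Plot a greedy-search profile
#'
#' Mean cross-validated AUC (with an across-fold SD ribbon) and accuracy
#' against combination size.
#'
#' @param object A `hrvprint_search` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrvprint_search <- function(object, ...) {
  d <- tibble::tibble(size = object$size,
                      auc = object$auc_mean, auc_sd = object$auc_sd,
                      accuracy = object$acc_mean / 100)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$auc - .data$auc_sd,
                                      ymax = .data$auc + .data$auc_sd),
                         alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$auc, colour = "AUC")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$auc, colour = "AUC")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$accuracy,
                                    colour = "Accuracy / 100")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$accuracy,
                                     colour = "Accuracy / 100")) +
    ggplot2::labs(x = "number of indices", y = "cross-validated performance",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of an evaluation
#'
#' @param object A `hrvprint_eval` result from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrvprint_eval <- function(object, ...) {
  scores <- attr(object, "scores")
  pos <- attr(object, "positive")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  d <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(fpr = mean(scores[!pos] >= t),
                   tpr = mean(scores[pos] >= t))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                                  object$auc, object$auc_lower,
                                  object$auc_upper)) +
    ggplot2::theme_minimal()
}

#' Plot a tachogram with PVC annotations
#'
#' RR-interval duration against beat time; PVC-terminated intervals are
#' highlighted.
#'
#' @param series An [rr_series()].
#' @return A ggplot object.
#' @export
plot_tachogram <- function(series) {
  d <- tibble::tibble(time = beat_times(series),
                      rr_ms = series$interval * 1000,
                      beat = factor(series$label, levels = c("N", "V")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$rr_ms,
                                  colour = .data$beat)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(N = "grey40", V = "firebrick"),
                                 drop = FALSE) +
    ggplot2::labs(x = "time (s)", y = "RR interval (ms)", colour = "beat") +
    ggplot2::theme_minimal()
}
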