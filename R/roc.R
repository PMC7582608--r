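#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney form: the probability that a randomly chosen positive
#' scores higher than a randomly chosen negative, with ties counted 1/2.
#' Midranks make this exactly the concordant-pair count normalization.
#'
#' @param scores Numeric ranking scores (larger = more positive-like).
#' @param positive Logical vector, `TRUE` for the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hanley-McNeil standard error based 95% CI for an AUC
auc_hanley_ci <- function(auc, n1, n0, level = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
}

# Wilson score interval for a proportion
wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}
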