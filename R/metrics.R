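#' Performance measures
#'
#' The six test-set measures used to compare the model variants: root mean
#' squared error on the (log) outcome scale for the continuous outcome, and
#' AUC, area under the precision-recall curve, Brier score and predictive
#' Bernoulli likelihood for the binary outcome.
#'
#' `roc_auc()` is the Mann-Whitney probability that a randomly chosen
#' positive outranks a randomly chosen negative, ties counted 1/2 (computed
#' via midranks). `pr_auc()` integrates precision over recall step-wise
#' across all observed thresholds (no linear interpolation between points).
#' `bernoulli_likelihood()` clips probabilities to `[1e-12, 1 - 1e-12]`
#' before evaluating.
#'
#' @param y Observed outcomes; 0/1 for the binary measures.
#' @param mu_hat,p_hat Predictions: conditional means (gaussian, log scale)
#'   or probabilities.
#' @return A scalar.
#' @name performance-measures
NULL

#' @rdname performance-measures
#' @export
rmse <- function(y, mu_hat) {
  if (length(y) == 0L) abort("empty input")
  if (length(y) != length(mu_hat)) abort("length mismatch")
  sqrt(mean((y - mu_hat)^2))
}

#' @rdname performance-measures
#' @export
roc_auc <- function(y, p_hat) {
  check_binary(y, p_hat)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) abort("AUC undefined: both classes must be present")
  r <- rank(p_hat)  # midranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname performance-measures
#' @export
pr_auc <- function(y, p_hat) {
  check_binary(y, p_hat)
  n1 <- sum(y == 1)
  if (n1 == 0L) abort("AUPRC undefined: no positive cases")
  o <- order(p_hat, decreasing = TRUE)
  ys <- y[o]
  ps <- p_hat[o]
  # group tied scores: confusion counts change only at distinct thresholds
  last <- cumsum(rle(ps)$lengths)
  tp <- cumsum(ys)[last]
  fp <- (seq_along(ys) - cumsum(ys))[last]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' @rdname performance-measures
#' @export
brier_score <- function(y, p_hat) {
  check_binary(y, p_hat)
  mean((y - p_hat)^2)
}

#' @rdname performance-measures
#' @export
bernoulli_likelihood <- function(y, p_hat) {
  check_binary(y, p_hat)
  p <- pmin(pmax(p_hat, 1e-12), 1 - 1e-12)
  mean(p^y * (1 - p)^(1 - y))
}

check_binary <- function(y, p_hat) {
  if (length(y) == 0L) abort("empty input")
  if (length(y) != length(p_hat)) abort("length mismatch")
  if (!all(y %in% c(0, 1))) abort("y must be coded 0/1")
  invisible(TRUE)
}
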