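#' Coefficient-path plot
#'
#' One line per variable: coefficient against the penalty on a reversed log
#' scale, so the null model sits at the right and penalization relaxes
#' leftwards.
#'
#' @param object An `hl_path`.
#' @param highlight Optional variable names drawn in colour on top of the
#'   grey background paths.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hl_path <- function(object, highlight = NULL, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lambda, y = .data$estimate,
                                       group = .data$term))
  if (is.null(highlight)) {
    p <- p + ggplot2::geom_line(alpha = 0.6)
  } else {
    p <- p +
      ggplot2::geom_line(data = dplyr::filter(d, !.data$term %in% highlight),
                         colour = "grey70") +
      ggplot2::geom_line(data = dplyr::filter(d, .data$term %in% highlight),
                         ggplot2::aes(colour = .data$term), linewidth = 0.8)
  }
  p +
    ggplot2::scale_x_continuous(trans = c("log10", "reverse")) +
    ggplot2::labs(x = expression(lambda), y = "coefficient",
                  title = sprintf("Coefficient paths (%s)", object$variant)) +
    ggplot2::theme_minimal()
}

#' Tuning-curve plot
#'
#' The criterion (CV deviance with a one-standard-error ribbon, or AIC/BIC)
#' against the penalty, with the chosen penalty marked -- the
#' BIC-versus-lambda picture used to read off the selected model.
#'
#' @param object An `hl_tuning`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hl_tuning <- function(object, ...) {
  d <- object$curve
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lambda, y = .data$estimate))
  if (any(is.finite(d$se))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$estimate - .data$se,
                   ymax = .data$estimate + .data$se),
      alpha = 0.2)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$chosen_lambda, linetype = "dashed") +
    ggplot2::scale_x_continuous(trans = c("log10", "reverse")) +
    ggplot2::labs(x = expression(lambda), y = toupper(object$criterion),
                  title = sprintf("%s tuning curve (%s)",
                                  toupper(object$criterion), object$variant)) +
    ggplot2::theme_minimal()
}

#' Experiment summary plot
#'
#' Mean of one performance measure per variant and criterion with error bars
#' (SD over replicates by default, mirroring the figure convention; switch to
#' standard errors with `error = "se"`).
#'
#' @param object An `hl_experiment`.
#' @param metric Which metric to plot; defaults to the family's headline
#'   measure (RMSE or AUC).
#' @param error `"sd"` or `"se"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hl_experiment <- function(object, metric = NULL, error = c("sd", "se"), ...) {
  error <- match.arg(error)
  metric <- metric %||% if (object$family == "gaussian") "rmse" else "auc"
  d <- dplyr::filter(object$aggregate, .data$metric == !!metric)
  d$err <- if (error == "sd") d$sd else d$se
  ggplot2::ggplot(d, ggplot2::aes(x = .data$criterion, y = .data$mean,
                                  fill = .data$variant)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$err, ymax = .data$mean + .data$err),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(y = metric, x = "tuning criterion",
                  title = sprintf("%s by variant and criterion (error bars: %s)",
                                  metric, error)) +
    ggplot2::theme_minimal()
}

#' Variable-importance plot
#'
#' @param object An `hl_importance` table.
#' @param top Show at most this many variables (ordered by rate).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hl_importance <- function(object, top = 15L, ...) {
  d <- head(tibble::as_tibble(object), top)
  d$variable <- factor(d$variable, levels = rev(d$variable))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$top_rate, y = .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "share of replicates in the top 5", y = NULL,
                  title = "Top-5 stability variable importance") +
    ggplot2::theme_minimal()
}
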