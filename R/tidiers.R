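#' Tidy a fitted model
#'
#' @param x An `hl_fit`.
#' @param include_cluster Also return hospital effects (dummy coefficients or
#'   predicted random intercepts) as rows with `term_type = "cluster"`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `term_type`.
#' @export
tidy.hl_fit <- function(x, include_cluster = FALSE, ...) {
  out <- tibble::tibble(
    term = c("(Intercept)", names(x$beta)),
    estimate = c(x$intercept, unname(x$beta)),
    term_type = c("intercept", rep("fixed", length(x$beta)))
  )
  if (include_cluster && length(x$cluster_effects)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = names(x$cluster_effects),
      estimate = unname(x$cluster_effects),
      term_type = "cluster"
    ))
  }
  out
}

#' @rdname tidy.hl_fit
#' @export
glance.hl_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, family = x$family, estimator = x$estimator,
    lambda = x$lambda, alpha = x$alpha,
    n_selected = sum(x$beta != 0), df = x$df,
    logLik = x$loglik, AIC = x$aic, BIC = x$bic,
    tau = x$tau, phi = x$phi %||% NA_real_,
    converged = x$converged, n_iter = x$n_iter, nobs = x$n
  )
}

#' Tidy a regularization path
#'
#' @param x An `hl_path`.
#' @param ... Unused.
#' @return Long tibble: one row per penalty x variable, with the coefficient.
#' @export
tidy.hl_path <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fits, function(f) {
    tibble::tibble(lambda = f$lambda, term = names(f$beta),
                   estimate = unname(f$beta))
  }))
}

#' @rdname tidy.hl_path
#' @export
glance.hl_path <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fits, glance))
}

#' Tidy a tuning result
#'
#' @param x An `hl_tuning`.
#' @param ... Unused.
#' @return The criterion curve: `lambda`, `estimate`, `se`.
#' @export
tidy.hl_tuning <- function(x, ...) x$curve

#' @rdname tidy.hl_tuning
#' @export
glance.hl_tuning <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, criterion = x$criterion,
    chosen_lambda = x$chosen_lambda, n_selected = x$n_selected,
    lambda_min = x$lambda_min, lambda_1se = x$lambda_1se
  )
}

#' Tidy an experiment
#'
#' @param x An `hl_experiment`.
#' @param ... Unused.
#' @return `tidy()`: the per-replicate metric table; `glance()`: the
#'   aggregated means with standard errors.
#' @export
tidy.hl_experiment <- function(x, ...) x$metrics

#' @rdname tidy.hl_experiment
#' @export
glance.hl_experiment <- function(x, ...) x$aggregate

#' @export
tidy.hl_lambda_grid <- function(x, ...) {
  tibble::tibble(position = seq_along(x$values), lambda = x$values)
}
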