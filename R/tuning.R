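# Dispatch helpers shared by tuning and evaluation ---------------------------

# One fit / one path for a named variant, so tuning code is variant-agnostic.
fit_variant <- function(data, lambda, variant, alpha = 1, init = NULL, ...) {
  switch(variant,
    no_hosps = fit_lasso(data, lambda, alpha = alpha, init = init, ...),
    hosps_fixed = fit_lasso(data, lambda, alpha = alpha,
                            include_cluster_dummies = TRUE, init = init, ...),
    hosps_random = fit_mixed_lasso(data, lambda, init = init, ...),
    abort(paste0("unknown variant: ", variant))
  )
}

fit_variant_path <- function(data, grid, variant, alpha = 1, estimator = "classic") {
  if (variant == "hosps_random") {
    fit_mixed_path(data, grid, final_re = identical(estimator, "post"))
  } else {
    path <- fit_lasso_path(data, grid, alpha = alpha,
                           include_cluster_dummies = variant == "hosps_fixed")
    if (identical(estimator, "post")) {
      path$fits <- lapply(path$fits, function(f) post_lasso_refit(data, f))
    }
    path
  }
}

#' Build the 100-value penalty grid
#'
#' Constructs a descending, log-linearly spaced grid of exactly `n_lambda`
#' penalties obeying two certified rules: the model at the first (largest)
#' value selects no variable at all, and the model at the fifth value already
#' selects at least one. The top of the grid is the KKT bound
#' `max_j |x_j' r0| / n` on the null-model residual `r0` (intercept only, or
#' intercept plus predicted random intercepts for the random-effects
#' variant), inflated by a small safety factor; the bottom is
#' `lam_max * ratio`, with `ratio` halved until the fifth-value rule holds.
#' Both rules are verified by actually fitting, and the verdicts stored in
#' the returned object.
#'
#' @param data A standardized `hl_dataset`.
#' @param variant `"no_hosps"`, `"hosps_fixed"` or `"hosps_random"`.
#' @param alpha Elastic-net mixing (fixed-effects variants).
#' @param n_lambda Grid length.
#' @param ratio Initial ratio of the smallest to the largest penalty.
#' @param safety Multiplier on the KKT bound so the top of the grid is a null
#'   model even under floating-point slack.
#' @param max_retries Bound on the number of times `ratio` may be halved.
#' @return An `hl_lambda_grid` with `values`, `lam_max`, the final `ratio`,
#'   and the certification results.
#' @export
build_lambda_grid <- function(data, variant = c("no_hosps", "hosps_fixed", "hosps_random"),
                              alpha = 1, n_lambda = 100L, ratio = 1e-3,
                              safety = 1.05, max_retries = 20L) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "hl_dataset"))
  y <- data$y
  n <- length(y)

  if (variant == "hosps_random") {
    null_fit <- fit_variant(data, lambda = Inf, variant = "hosps_random")
    r0 <- if (data$family == "gaussian") {
      y - predict(null_fit, data)
    } else {
      y - predict(null_fit, data, type = "response")
    }
    des_X <- data$X
  } else {
    r0 <- y - mean(y)
    des_X <- build_design(data, variant == "hosps_fixed")$X
  }
  bound <- max(abs(drop(crossprod(des_X, r0)))) / n / alpha
  if (!is.finite(bound) || bound <= 0) {
    abort("cannot build a lambda grid: no predictor has a nonzero score at the null model")
  }
  lam_max <- safety * bound

  nz_at <- function(lam) {
    f <- fit_variant(data, lam, variant, alpha = alpha)
    sum(c(f$beta, if (variant == "hosps_fixed") f$cluster_effects) != 0)
  }

  nz1 <- nz_at(lam_max)
  tries <- 0L
  while (nz1 > 0 && tries < max_retries) {  # never expected: KKT bound certified
    lam_max <- lam_max * 2
    nz1 <- nz_at(lam_max)
    tries <- tries + 1L
  }
  if (nz1 > 0) abort("could not certify a null model at the top of the grid")

  tries <- 0L
  repeat {
    values <- exp(seq(log(lam_max), log(lam_max * ratio), length.out = n_lambda))
    nz5 <- nz_at(values[5])
    if (nz5 >= 1L) break
    tries <- tries + 1L
    if (tries > max_retries) {
      abort("could not satisfy the first-five-values rule: no variable enters the model")
    }
    ratio <- ratio / 2
  }

  structure(
    list(values = values, lam_max = lam_max, ratio = ratio,
         spacing = "log-linear", variant = variant, alpha = alpha,
         certified = TRUE, n_selected_at_1 = nz1, n_selected_at_5 = nz5),
    class = "hl_lambda_grid"
  )
}

#' @export
print.hl_lambda_grid <- function(x, ...) {
  cat(sprintf(
    "<hl_lambda_grid> %d values, %.4g .. %.4g (%s, variant %s); null at top, %d selected at value 5\n",
    length(x$values), x$values[1], x$values[length(x$values)], x$spacing,
    x$variant, x$n_selected_at_5))
  invisible(x)
}

# Held-out deviance: MSE on the modelling scale (gaussian) or -2 x mean
# Bernoulli log-likelihood (binomial).
heldout_deviance <- function(fit, test) {
  # a penalized dummy for a hospital absent from a row-wise CV fold is zero,
  # so unseen hospitals get a zero effect here (outer splits never need this)
  pred <- predict(fit, test, type = "response",
                  unknown_cluster = if (fit$variant == "hosps_fixed") "zero" else "error")
  if (fit$family == "gaussian") {
    mean((test$y - pred)^2)
  } else {
    p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    -2 * mean(test$y * log(p) + (1 - test$y) * log(1 - p))
  }
}

# Fold assignment. Fixed-effects variants use plain row-wise folds; the
# random-effects variant needs every hospital in every training portion, so
# folds are drawn within each cluster (round-robin after a shuffle) and
# single-row clusters are pinned to fold 0 (always training).
make_cv_folds <- function(data, k, cluster_aware) {
  n <- length(data$y)
  if (!cluster_aware) {
    return(sample(rep_len(seq_len(k), n)))
  }
  fold <- integer(n)
  for (lab in unique(data$cluster)) {
    rows <- which(data$cluster == lab)
    if (length(rows) == 1L) {
      fold[rows] <- 0L
    } else {
      start <- sample.int(k, 1L)
      fold[sample(rows)] <- 1L + (start + seq_along(rows) - 2L) %% k
    }
  }
  fold
}

#' Tune the penalty by internal cross-validation
#'
#' Fits the path on each training portion, measures held-out deviance per
#' penalty, and picks `lambda_min` (deviance minimizer; largest penalty wins
#' ties) or `lambda_1se` (largest penalty whose mean deviance is within one
#' standard error of the minimum). The chosen penalty is then refitted on all
#' of `data`. Defaults follow the study design: 10 folds for the
#' fixed-effects variants, 5 cluster-aware folds for the random-effects
#' variant.
#'
#' @inheritParams build_lambda_grid
#' @param grid An [build_lambda_grid()] result.
#' @param k Number of folds; `NULL` picks the variant default.
#' @param criterion `"cv_min"` or `"cv_1se"`.
#' @param estimator `"classic"` or `"post"` (tune on post-LASSO refits).
#' @param seed Optional seed for the fold draw.
#' @return An `hl_tuning`: chosen penalty and fit, the deviance curve with
#'   standard errors, and both candidate penalties.
#' @export
tune_cv <- function(data, grid, variant = c("no_hosps", "hosps_fixed", "hosps_random"),
                    alpha = 1, k = NULL, criterion = c("cv_min", "cv_1se"),
                    estimator = c("classic", "post"), seed = NULL) {
  variant <- match.arg(variant)
  criterion <- match.arg(criterion)
  estimator <- match.arg(estimator)
  if (is.null(k)) k <- if (variant == "hosps_random") 5L else 10L
  if (k < 2L) abort("k must be >= 2")
  if (!is.null(seed)) set.seed(seed)

  fold <- make_cv_folds(data, k, cluster_aware = variant == "hosps_random")
  values <- grid_values(grid)
  dev <- matrix(NA_real_, length(values), k)
  for (f in seq_len(k)) {
    tr <- subset_dataset(data, which(fold != f))
    va <- subset_dataset(data, which(fold == f))
    if (variant == "hosps_random") {
      missing <- setdiff(unique(va$cluster), unique(tr$cluster))
      if (length(missing)) {
        abort(paste0("fold ", f, " leaves hospital(s) out of training: ",
                     paste(missing, collapse = ", "),
                     "; use cluster-aware folding"))
      }
    }
    path <- fit_variant_path(tr, grid, variant, alpha, estimator)
    dev[, f] <- vapply(path$fits, heldout_deviance, numeric(1), test = va)
  }
  cvm <- rowMeans(dev)
  cvse <- apply(dev, 1, sd) / sqrt(k)

  i_min <- which.min(cvm)          # first index = largest lambda on ties
  i_1se <- which(cvm <= cvm[i_min] + cvse[i_min])[1]
  lambda_min <- values[i_min]
  lambda_1se <- values[i_1se]

  chosen_lambda <- if (criterion == "cv_min") lambda_min else lambda_1se
  chosen_fit <- refit_at(data, chosen_lambda, variant, alpha, estimator)

  new_tuning(
    criterion = criterion, chosen_lambda = chosen_lambda,
    curve = tibble::tibble(lambda = values, estimate = cvm, se = cvse),
    chosen_fit = chosen_fit, variant = variant,
    lambda_min = lambda_min, lambda_1se = lambda_1se
  )
}

refit_at <- function(data, lambda, variant, alpha, estimator) {
  fit <- fit_variant(data, lambda, variant, alpha = alpha)
  if (identical(estimator, "post")) {
    fit <- if (variant == "hosps_random") {
      mixed_post_refit(data, fit)
    } else {
      post_lasso_refit(data, fit)
    }
  }
  fit
}

#' Tune the penalty by AIC or BIC
#'
#' Fits the path once on all of `data`, computes `AIC = -2 loglik + 2 df` and
#' `BIC = -2 loglik + log(n) df` at every penalty, and picks the minimizer
#' (largest penalty wins ties). With `estimator = "post"` the information
#' criteria are computed from the unpenalized refits.
#'
#' @inheritParams tune_cv
#' @param criterion `"aic"` or `"bic"`.
#' @return An `hl_tuning` with the criterion curve (for the BIC-versus-lambda
#'   plot) and the chosen fit.
#' @export
tune_ic <- function(data, grid, variant = c("no_hosps", "hosps_fixed", "hosps_random"),
                    alpha = 1, criterion = c("aic", "bic"),
                    estimator = c("classic", "post")) {
  variant <- match.arg(variant)
  criterion <- match.arg(criterion)
  estimator <- match.arg(estimator)
  values <- grid_values(grid)
  path <- fit_variant_path(data, grid, variant, alpha, estimator)
  crit <- vapply(path$fits, function(f) if (criterion == "aic") f$aic else f$bic,
                 numeric(1))
  i <- which.min(crit)  # descending grid: first minimum = largest lambda
  new_tuning(
    criterion = criterion, chosen_lambda = values[i],
    curve = tibble::tibble(lambda = values, estimate = crit, se = NA_real_),
    chosen_fit = path$fits[[i]], variant = variant,
    lambda_min = NA_real_, lambda_1se = NA_real_, path = path
  )
}

new_tuning <- function(criterion, chosen_lambda, curve, chosen_fit, variant,
                       lambda_min, lambda_1se, path = NULL) {
  structure(
    list(
      criterion = criterion, chosen_lambda = chosen_lambda, curve = curve,
      chosen_fit = chosen_fit, variant = variant,
      n_selected = sum(chosen_fit$beta != 0),
      lambda_min = lambda_min, lambda_1se = lambda_1se, path = path
    ),
    class = "hl_tuning"
  )
}

#' @export
print.hl_tuning <- function(x, ...) {
  cat(sprintf(
    "<hl_tuning> %s / %s: chosen lambda = %.4g, %d variable(s) selected\n",
    x$variant, x$criterion, x$chosen_lambda, x$n_selected))
  invisible(x)
}
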