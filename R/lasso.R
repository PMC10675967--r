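#' Fit a penalized regression at one penalty value
#'
#' Minimizes the (1/n)-scaled negative log-likelihood plus the elastic-net
#' penalty `lambda * sum_j pf_j (alpha |beta_j| + (1 - alpha)/2 beta_j^2)` by
#' cyclic coordinate descent with soft-thresholding; the binomial family runs
#' an iteratively reweighted least-squares outer loop around the same core.
#' The intercept is never penalized. With `include_cluster_dummies = TRUE`
#' ("hospitals fixed" variant) reference-coded hospital indicators are
#' appended and, by default, penalized like any other predictor.
#'
#' @param data A standardized `hl_dataset` (see [scale_unit_variance()]).
#' @param lambda Penalty value, >= 0.
#' @param alpha Elastic-net mixing; 1 is the LASSO, the near-LASSO variant
#'   uses 0.99999.
#' @param include_cluster_dummies Append penalized hospital dummies
#'   (reference level = first hospital in sorted label order).
#' @param penalize_dummies Set `FALSE` to exempt the hospital dummies from
#'   the penalty.
#' @param init Optional previous `hl_fit` used as a warm start.
#' @param tol Coordinate-descent convergence tolerance on the largest
#'   coefficient update per sweep.
#' @param max_sweeps Sweep budget; exceeding it flags (not raises) the fit.
#'
#' @return An `hl_fit` with the intercept, sparse fixed coefficients, any
#'   hospital dummy coefficients, the penalty, effective degrees of freedom
#'   (number of nonzero coefficients including the intercept), log-likelihood
#'   at the estimates, and AIC/BIC.
#' @seealso [fit_lasso_path()], [post_lasso_refit()], [fit_mixed_lasso()]
#' @export
fit_lasso <- function(data, lambda, alpha = 1,
                      include_cluster_dummies = FALSE,
                      penalize_dummies = TRUE,
                      init = NULL, tol = 1e-7, max_sweeps = 1e5) {
  stopifnot(inherits(data, "hl_dataset"), lambda >= 0, alpha > 0, alpha <= 1)
  des <- build_design(data, include_cluster_dummies, penalize_dummies)
  fit_lasso_design(des, data, lambda, alpha, init, tol, max_sweeps)
}

# Design-matrix bundle shared by fit/tuning code so dummies are built once.
build_design <- function(data, include_cluster_dummies, penalize_dummies = TRUE) {
  X <- data$X
  p <- ncol(X)
  pf <- rep(1, p)
  levels <- sort(unique(data$cluster))
  dummy_names <- character(0)
  if (include_cluster_dummies) {
    if (length(levels) < 2L) abort("cluster dummies need >= 2 hospitals")
    f <- factor(data$cluster, levels = levels)
    D <- outer(as.integer(f), seq_along(levels)[-1], function(a, b) as.numeric(a == b))
    dummy_names <- paste0(".hosp:", levels[-1])
    colnames(D) <- dummy_names
    X <- cbind(X, D)
    pf <- c(pf, rep(if (penalize_dummies) 1 else 0, ncol(D)))
  }
  list(X = X, pf = pf, p = p, levels = levels, dummy_names = dummy_names,
       variant = if (include_cluster_dummies) "hosps_fixed" else "no_hosps")
}

fit_lasso_design <- function(des, data, lambda, alpha, init = NULL,
                             tol = 1e-7, max_sweeps = 1e5) {
  X <- des$X
  y <- data$y
  n <- length(y)
  pd <- ncol(X)
  beta0 <- if (!is.null(init)) init_coefs(init, des) else rep(0, pd)
  b00 <- if (!is.null(init)) init$intercept else
    if (data$family == "binomial") qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)) else mean(y)

  if (data$family == "gaussian") {
    res <- .cd_elnet(X, y, rep(1, n), lambda, alpha, des$pf,
                     beta0, b00, tol, as.integer(max_sweeps))
    beta <- res$beta
    b0 <- res$intercept
    converged <- res$converged
    n_iter <- res$n_sweeps
    rss <- sum(res$residual^2)
    phi <- sqrt(rss / n)
    loglik <- -n / 2 * (log(2 * pi * phi^2) + 1)
  } else {
    beta <- beta0
    b0 <- b00
    converged <- FALSE
    n_iter <- 0L
    dev_old <- Inf
    eta <- drop(b0 + X %*% beta)
    for (it in seq_len(100L)) {
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-5)
      z <- eta + (y - mu) / w
      res <- .cd_elnet(X, z, w, lambda, alpha, des$pf,
                       beta, b0, tol, as.integer(max_sweeps))
      beta <- res$beta
      b0 <- res$intercept
      eta <- drop(b0 + X %*% beta)
      dev <- binomial_deviance(y, plogis(eta))
      n_iter <- n_iter + res$n_sweeps
      if (lambda == 0 && (max(abs(c(b0, beta))) > 1e3 || dev < 1e-2)) {
        # a (near-)zero total deviance means the classes are separated: every
        # fitted probability is within ~1e-4 of its label, which no finite
        # MLE attains, so the unpenalized estimate does not exist
        abort("coefficients diverging at lambda = 0 (complete separation?)")
      }
      if (abs(dev_old - dev) < 1e-8 * (abs(dev) + 0.1)) {
        converged <- res$converged
        break
      }
      dev_old <- dev
    }
    mu <- plogis(eta)
    loglik <- bernoulli_loglik(y, mu)
    phi <- NULL
  }

  split <- split_coefs(beta, des)
  make_fit(
    intercept = b0, beta = split$beta, cluster_effects = split$cluster_effects,
    tau = 0, phi = phi, lambda = lambda, alpha = alpha,
    df = 1L + sum(beta != 0), loglik = loglik, n = n,
    estimator = "classic", converged = converged, n_iter = n_iter,
    family = data$family, variant = des$variant,
    cluster_levels = des$levels
  )
}

init_coefs <- function(init, des) {
  b <- rep(0, ncol(des$X))
  names(b) <- colnames(des$X)
  common <- intersect(names(init$beta), names(b))
  b[common] <- init$beta[common]
  if (length(des$dummy_names) && length(init$cluster_effects)) {
    dn <- paste0(".hosp:", names(init$cluster_effects))
    common <- intersect(dn, names(b))
    b[common] <- init$cluster_effects[sub("^\\.hosp:", "", common)]
  }
  unname(b)
}

split_coefs <- function(beta, des) {
  names(beta) <- colnames(des$X)
  fixed <- beta[seq_len(des$p)]
  ce <- numeric(0)
  if (length(des$dummy_names)) {
    ce <- c(0, unname(beta[des$dummy_names]))   # reference hospital at 0
    names(ce) <- des$levels
  }
  list(beta = fixed, cluster_effects = ce)
}

make_fit <- function(intercept, beta, cluster_effects, tau, phi, lambda, alpha,
                     df, loglik, n, estimator, converged, n_iter, family,
                     variant, cluster_levels) {
  structure(
    list(
      intercept = intercept, beta = beta, cluster_effects = cluster_effects,
      tau = tau, phi = phi, lambda = lambda, alpha = alpha,
      df = df, loglik = loglik,
      aic = -2 * loglik + 2 * df,
      bic = -2 * loglik + log(n) * df,
      estimator = estimator, converged = converged, n_iter = n_iter,
      family = family, variant = variant, cluster_levels = cluster_levels,
      n = n
    ),
    class = "hl_fit"
  )
}

#' @export
print.hl_fit <- function(x, ...) {
  cat(sprintf(
    "<hl_fit> %s / %s (%s), lambda = %.4g: %d of %d predictors selected, df = %d\n",
    x$variant, x$family, x$estimator, x$lambda,
    sum(x$beta != 0), length(x$beta), x$df))
  if (x$variant == "hosps_random") {
    cat(sprintf("  random-intercept SD tau = %.4g\n", x$tau))
  }
  invisible(x)
}

binomial_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

bernoulli_loglik <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Fit a whole regularization path
#'
#' Fits [fit_lasso()] at every grid value in descending order, handing each
#' fit to the next as a warm start.
#'
#' @inheritParams fit_lasso
#' @param grid An [build_lambda_grid()] object (or a descending numeric
#'   vector of penalties).
#' @return An `hl_path`: the grid plus one `hl_fit` per penalty, aligned.
#' @export
fit_lasso_path <- function(data, grid, alpha = 1,
                           include_cluster_dummies = FALSE,
                           penalize_dummies = TRUE, tol = 1e-7,
                           max_sweeps = 1e5) {
  values <- grid_values(grid)
  des <- build_design(data, include_cluster_dummies, penalize_dummies)
  fits <- vector("list", length(values))
  init <- NULL
  for (k in seq_along(values)) {
    fits[[k]] <- fit_lasso_design(des, data, values[k], alpha, init,
                                  tol, max_sweeps)
    init <- fits[[k]]
  }
  new_path(grid, fits, data$family, des$variant)
}

grid_values <- function(grid) {
  v <- if (inherits(grid, "hl_lambda_grid")) grid$values else as.numeric(grid)
  if (is.unsorted(rev(v), strictly = TRUE)) abort("lambda values must be strictly decreasing")
  v
}

new_path <- function(grid, fits, family, variant) {
  structure(list(grid = grid, fits = fits, family = family, variant = variant),
            class = "hl_path")
}

#' @export
print.hl_path <- function(x, ...) {
  nz <- vapply(x$fits, function(f) sum(f$beta != 0), integer(1))
  cat(sprintf("<hl_path> %s / %s: %d penalties, selected variables %d..%d\n",
              x$variant, x$family, length(x$fits), min(nz), max(nz)))
  invisible(x)
}

#' Refit the selected variables without penalty (post-LASSO)
#'
#' Takes a penalized fit's active set (nonzero coefficients, including any
#' active hospital dummies) and refits it by unpenalized least squares /
#' maximum likelihood. Coefficients outside the active set stay at zero. A
#' separated binomial refit is flagged and falls back to the penalized
#' estimates.
#'
#' @param data The same standardized `hl_dataset` used for `fit`.
#' @param fit A classic `hl_fit` from [fit_lasso()].
#' @return An `hl_fit` with `estimator = "post"`.
#' @export
post_lasso_refit <- function(data, fit) {
  stopifnot(inherits(fit, "hl_fit"))
  if (fit$variant == "hosps_random") {
    abort("use fit_mixed_lasso(final_re = TRUE) for the random-effects variant")
  }
  des <- build_design(data, fit$variant == "hosps_fixed")
  full <- c(fit$beta,
            if (length(fit$cluster_effects)) setNames(
              fit$cluster_effects[-1], paste0(".hosp:", names(fit$cluster_effects)[-1])))
  active <- names(full)[full != 0]
  Xa <- des$X[, active, drop = FALSE]
  y <- data$y
  n <- length(y)

  beta_new <- setNames(rep(0, ncol(des$X)), colnames(des$X))
  converged <- TRUE
  if (data$family == "gaussian") {
    ls <- lm.fit(cbind(`(Intercept)` = 1, Xa), y)
    cf <- ls$coefficients
    cf[is.na(cf)] <- 0
    b0 <- cf[1]
    beta_new[active] <- cf[-1]
    rss <- sum((y - ls$fitted.values)^2)
    phi <- sqrt(rss / n)
    loglik <- -n / 2 * (log(2 * pi * phi^2) + 1)
  } else {
    gf <- suppressWarnings(
      glm.fit(cbind(`(Intercept)` = 1, Xa), y, family = binomial()))
    cf <- gf$coefficients
    cf[is.na(cf)] <- 0
    if (!gf$converged || any(abs(cf) > 30)) {
      # separation: keep the penalized estimates, flag the result
      out <- fit
      out$estimator <- "post"
      out$converged <- FALSE
      return(out)
    }
    b0 <- cf[1]
    beta_new[active] <- cf[-1]
    loglik <- bernoulli_loglik(y, gf$fitted.values)
    phi <- NULL
  }

  split <- split_coefs(unname(beta_new), des)
  make_fit(
    intercept = unname(b0), beta = split$beta,
    cluster_effects = split$cluster_effects,
    tau = 0, phi = phi, lambda = fit$lambda, alpha = fit$alpha,
    df = 1L + length(active), loglik = loglik, n = n,
    estimator = "post", converged = converged, n_iter = 1L,
    family = data$family, variant = fit$variant, cluster_levels = des$levels
  )
}

#' Predict from a fitted model
#'
#' @param object An `hl_fit`.
#' @param data An `hl_dataset` whose predictor columns match (and are scaled
#'   like) the training data.
#' @param type `"response"` (gaussian: conditional mean on the modelling
#'   scale, i.e. log-days; binomial: probability) or `"link"`.
#' @param unknown_cluster What to do when `data` contains a hospital the
#'   model was not trained on: `"error"` (default -- the sub-sampling design
#'   guarantees coverage, so this signals a broken split) or `"zero"` (use a
#'   zero hospital effect, the value a penalized dummy for an absent hospital
#'   would take anyway).
#' @param ... Unused.
#' @return Numeric vector of predictions. Variants with hospital effects
#'   require every hospital in `data` to have been present in training --
#'   guaranteed by the coverage constraint of [make_subsamples()].
#' @export
predict.hl_fit <- function(object, data, type = c("response", "link"),
                           unknown_cluster = c("error", "zero"), ...) {
  type <- match.arg(type)
  unknown_cluster <- match.arg(unknown_cluster)
  stopifnot(inherits(data, "hl_dataset"))
  X <- data$X[, names(object$beta), drop = FALSE]
  eta <- drop(object$intercept + X %*% object$beta)
  if (object$variant != "no_hosps") {
    ce <- object$cluster_effects
    unknown <- setdiff(unique(data$cluster), names(ce))
    if (length(unknown)) {
      if (unknown_cluster == "error") {
        abort(paste0(
          "hospital(s) not seen in training: ", paste(unknown, collapse = ", "),
          "; the sub-sampling design requires every test hospital in the training data"))
      }
      ce <- c(ce, setNames(rep(0, length(unknown)), unknown))
    }
    eta <- eta + unname(ce[data$cluster])
  }
  if (type == "link" || object$family == "gaussian") eta else plogis(eta)
}

#' Largest KKT violation of a penalized fit
#'
#' Checks the subgradient conditions of the elastic-net objective at the
#' returned estimates: for zero coefficients the score must lie within the
#' penalty threshold, for nonzero ones it must equal it with the matching
#' sign. Returns the largest absolute violation (0 at an exact optimum);
#' fixed-effects variants only.
#'
#' @param fit A classic `hl_fit`.
#' @param data The dataset it was fitted on.
#' @return Scalar violation magnitude.
#' @export
kkt_violation <- function(fit, data) {
  stopifnot(inherits(fit, "hl_fit"), fit$estimator == "classic")
  des <- build_design(data, fit$variant == "hosps_fixed")
  beta <- c(fit$beta,
            if (length(fit$cluster_effects)) fit$cluster_effects[-1])
  n <- length(data$y)
  eta <- drop(fit$intercept + des$X %*% beta)
  resid <- if (fit$family == "gaussian") data$y - eta else data$y - plogis(eta)
  score <- drop(crossprod(des$X, resid)) / n -
    fit$lambda * (1 - fit$alpha) * des$pf * beta
  thr <- fit$lambda * fit$alpha * des$pf
  viol_zero <- pmax(abs(score) - thr, 0)[beta == 0]
  viol_nz <- abs(score - thr * sign(beta))[beta != 0]
  viol_int <- abs(mean(resid))
  max(c(viol_zero, viol_nz, viol_int, 0))
}
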