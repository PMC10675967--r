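#' L1-penalized random-intercept (mixed) model
#'
#' The "hospitals random" estimator: a generalized linear mixed model with a
#' random intercept per hospital, `b_h ~ N(0, tau^2)`, whose fixed effects
#' carry an L1 penalty. Fitting alternates three exact/blockwise steps until
#' joint convergence:
#'
#' 1. given `(tau, phi)`, update `(beta, b0)` by coordinate descent with
#'    soft-thresholding on a per-hospital whitened working problem that
#'    profiles out the random intercepts exactly (for the binomial family the
#'    working response is the usual PQL linearization);
#' 2. given `beta`, recover the predicted intercepts as ridge-shrunken cluster
#'    means of the working residuals, shrinkage `n_h / (n_h + phi^2/tau^2)`
#'    for the gaussian family and its weighted analogue for the binomial;
#' 3. update the variance components by an EM-type moment step that adds the
#'    conditional variance of each `b_h` to its squared prediction (so the
#'    estimate does not collapse from shrinkage alone).
#'
#' The intercept and `tau` are never penalized. `tau` hitting zero is a valid
#' boundary solution (the model degenerates to the plain LASSO) and is
#' reported, not raised. For the gaussian family the reported log-likelihood
#' is the exact marginal likelihood; for the binomial family a Laplace
#' approximation at the predicted intercepts.
#'
#' @inheritParams fit_lasso
#' @param init Optional warm start: an `hl_fit` from a previous penalty.
#' @param tau_zero Force `tau = 0` (no random effects); the fit then equals
#'   [fit_lasso()] without dummies.
#' @param variance_update How the variance components are updated at fixed
#'   fixed effects: `"moment"` (default) iterates the EM-type moment step
#'   with shrinkage correction; `"profile"` maximizes the working-model
#'   marginal likelihood directly by a line search over the variance ratio.
#'   Both target the same stationary equations and agree at convergence.
#' @param outer_tol Convergence tolerance on the largest parameter change per
#'   outer iteration.
#' @param max_outer Outer-iteration budget.
#' @return An `hl_fit` with `variant = "hosps_random"`: `cluster_effects` are
#'   the predicted random intercepts, `tau` the estimated random-intercept
#'   SD, `phi` the residual SD (gaussian). Degrees of freedom count the
#'   nonzero fixed effects, the intercept, `tau`, and (gaussian) `phi`.
#' @seealso [fit_mixed_path()], [predict.hl_fit()]
#' @export
fit_mixed_lasso <- function(data, lambda, init = NULL, tau_zero = FALSE,
                            tol = 1e-7, outer_tol = 1e-6, max_outer = 500L,
                            max_sweeps = 1e5,
                            variance_update = c("moment", "profile")) {
  stopifnot(inherits(data, "hl_dataset"), lambda >= 0)
  variance_update <- match.arg(variance_update)
  X <- data$X
  y <- data$y
  n <- length(y)
  p <- ncol(X)
  levels <- sort(unique(data$cluster))
  H <- length(levels)
  cl <- match(data$cluster, levels)
  nh <- tabulate(cl, H)
  single_cluster <- H < 2L
  if (single_cluster) {
    warning("single hospital: tau is unidentifiable and fixed at 0")
    tau_zero <- TRUE
  }
  pf <- rep(1, p)
  gaussian <- data$family == "gaussian"

  # starting values: moment decomposition of the outcome around cluster means
  beta <- if (!is.null(init)) {
    b <- rep(0, p); names(b) <- colnames(X)
    common <- intersect(names(init$beta), names(b))
    b[common] <- init$beta[common]
    unname(b)
  } else rep(0, p)
  b <- if (!is.null(init) && length(init$cluster_effects) == H &&
           identical(names(init$cluster_effects), levels)) {
    unname(init$cluster_effects)
  } else rep(0, H)
  if (!is.null(init) && init$variant == "hosps_random" && init$tau > 0) {
    tau2 <- init$tau^2
    phi2 <- if (gaussian) init$phi^2 else 1
    b0 <- init$intercept
  } else if (gaussian) {
    cm <- drop(rowsum(y, cl)) / nh
    within <- y - cm[cl]
    phi2 <- max(var(within), 1e-4 * var(y), 1e-8)
    tau2 <- if (tau_zero) 0 else max(var(cm) - phi2 * mean(1 / nh), 0.05 * var(y))
    b0 <- mean(y)
  } else {
    phi2 <- 1
    tau2 <- if (tau_zero) 0 else 0.25
    b0 <- qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  }
  if (tau_zero) tau2 <- 0

  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_outer)) {
    beta_old <- beta; b_old <- b; tau2_old <- tau2; phi2_old <- phi2; b00 <- b0

    # working problem: gaussian uses the data directly, binomial the usual
    # IRLS linearization at the current linear predictor
    if (gaussian) {
      w <- rep(1, n)
      z <- y
    } else {
      eta <- b0 + drop(X %*% beta) + b[cl]
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-5)
      z <- eta + (y - mu) / w
    }

    if (tau2 > 0) {
      # Profile the random intercepts out of the working least-squares
      # problem: with V_h = I + (tau2/phi2) * s_h s_h' (s_h the square-root
      # working weights of cluster h), V_h^{-1/2} subtracts c_h times the
      # weighted cluster sum from every row. One coordinate-descent call on
      # the whitened data then solves the joint (beta, b0, b) block exactly
      # at the current variance components -- the alternation between beta
      # and b that this replaces converges slowly whenever predictors are
      # strongly cluster-structured.
      sw <- drop(rowsum(w, cl))
      ch <- (1 - 1 / sqrt(1 + (tau2 / phi2) * sw)) / sw
      zt <- z - (ch * drop(rowsum(w * z, cl)))[cl]
      Xt <- cbind(X - ch[cl] * rowsum(w * X, cl)[cl, , drop = FALSE],
                  `.b0` = 1 - (ch * sw)[cl])
      res <- .cd_elnet(Xt, zt, w, lambda, 1, c(pf, 0), c(beta, b0), 0,
                       tol, as.integer(max_sweeps), FALSE)
      beta <- res$beta[seq_len(p)]
      b0 <- res$beta[p + 1L]
      e <- z - b0 - drop(X %*% beta)
      swe <- drop(rowsum(w * e, cl))
      ss <- if (gaussian) sum(e^2) else NULL
      if (variance_update == "profile") {
        # line search on the working-model marginal likelihood, profiled
        # over the variance ratio r = tau2/phi2 (binomial: phi2 = 1, r =
        # tau2); e'V^{-1}e and log|V| have per-cluster closed forms
        ssw <- if (gaussian) ss else sum(w * e^2)
        nllr <- function(lr) {
          r <- exp(lr)
          quad <- ssw - sum(r / (1 + r * sw) * swe^2)
          if (gaussian) n * log(quad / n) + sum(log1p(r * sw))
          else quad + sum(log1p(r * sw))
        }
        opt <- optimize(nllr, c(log(1e-10), log(1e6)), tol = 1e-12)
        r <- exp(opt$minimum)
        if (gaussian) {
          phi2 <- (ssw - sum(r / (1 + r * sw) * swe^2)) / n
          tau2 <- if (tau_zero) 0 else r * phi2
        } else {
          phi2 <- 1
          tau2 <- if (tau_zero) 0 else r
        }
        b <- if (tau2 > 0) swe / (sw + phi2 / tau2) else rep(0, H)
      } else {
      # inner EM on (b, tau2[, phi2]) at fixed beta: all cluster statistics
      # are precomputed, so each pass is O(#hospitals)
      for (em in seq_len(1000L)) {
        b <- swe / (sw + phi2 / tau2)
        v <- 1 / (sw / phi2 + 1 / tau2)
        tau2_new <- if (tau_zero) 0 else mean(b^2 + v)
        if (gaussian) {
          phi2_new <- (ss - 2 * sum(b * swe) + sum(sw * b^2) + sum(sw * v)) / n
        } else {
          phi2_new <- 1
        }
        done <- abs(sqrt(tau2_new) - sqrt(tau2)) < 1e-8 &&
          abs(sqrt(phi2_new) - sqrt(phi2)) < 1e-8
        tau2 <- tau2_new; phi2 <- phi2_new
        if (done || tau2 < 1e-8) break
      }
      }
      if (tau2 < 1e-8) { tau2 <- 0; b <- rep(0, H) }
    } else {
      res <- .cd_elnet(X, z, w, lambda, 1, pf, beta, b0,
                       tol, as.integer(max_sweeps))
      beta <- res$beta; b0 <- res$intercept
      b <- rep(0, H)
      if (gaussian) phi2 <- sum((z - b0 - drop(X %*% beta))^2) / n
    }

    if (!tau_zero && tau2 < 1e-8) { tau2 <- 0; b <- rep(0, H) }

    delta <- max(abs(c(beta - beta_old, b - b_old, b0 - b00,
                       sqrt(tau2) - sqrt(tau2_old),
                       if (gaussian) sqrt(phi2) - sqrt(phi2_old))))
    if (delta < outer_tol) { converged <- TRUE; break }
  }

  ll <- mixed_loglik(y, X, cl, nh, b0, beta, b, tau2, phi2, gaussian)
  df <- sum(beta != 0) + 2L + as.integer(gaussian)  # + intercept + tau (+ phi)
  make_fit(
    intercept = b0, beta = setNames(beta, colnames(X)),
    cluster_effects = setNames(b, levels),
    tau = sqrt(tau2), phi = if (gaussian) sqrt(phi2) else NULL,
    lambda = lambda, alpha = 1, df = df, loglik = ll, n = n,
    estimator = "classic", converged = converged, n_iter = it,
    family = data$family, variant = "hosps_random", cluster_levels = levels
  )
}

# Marginal log-likelihood: exact for gaussian (compound-symmetric covariance
# per cluster), Laplace approximation at the predicted intercepts for
# binomial.
mixed_loglik <- function(y, X, cl, nh, b0, beta, b, tau2, phi2, gaussian) {
  eta_fixed <- b0 + drop(X %*% beta)
  if (gaussian) {
    r <- y - eta_fixed
    if (tau2 == 0) {
      n <- length(y)
      return(-0.5 * (n * log(2 * pi * phi2) + sum(r^2) / phi2))
    }
    S <- drop(rowsum(r, cl))
    ss <- drop(rowsum(r^2, cl))
    -0.5 * sum(
      nh * log(2 * pi * phi2) + log1p(nh * tau2 / phi2) +
        (ss - tau2 * S^2 / (phi2 + nh * tau2)) / phi2
    )
  } else {
    eta <- eta_fixed + b[cl]
    mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    ll_cond <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (tau2 == 0) return(ll_cond)
    w <- mu * (1 - mu)
    sw <- drop(rowsum(w, cl))
    ll_cond - sum(b^2) / (2 * tau2) - 0.5 * sum(log1p(tau2 * sw))
  }
}

#' Fit the mixed-model regularization path
#'
#' Descending-penalty path with warm starts: each fit hands its fixed
#' effects, predicted intercepts and variance components to the next. With
#' `final_re = TRUE` every fit is followed by an unpenalized mixed refit on
#' its active set (the post-LASSO analogue for the random-effects variant).
#'
#' @inheritParams fit_mixed_lasso
#' @param grid An [build_lambda_grid()] object or descending numeric vector.
#' @param final_re Refit each active set without penalty.
#' @return An `hl_path` over `hl_fit`s with `variant = "hosps_random"`.
#' @export
fit_mixed_path <- function(data, grid, final_re = FALSE, tol = 1e-7,
                           outer_tol = 1e-6, max_outer = 500L) {
  values <- grid_values(grid)
  fits <- vector("list", length(values))
  init <- NULL
  for (k in seq_along(values)) {
    f <- fit_mixed_lasso(data, values[k], init = init, tol = tol,
                         outer_tol = outer_tol, max_outer = max_outer)
    init <- f
    if (final_re) f <- mixed_post_refit(data, f, tol, outer_tol, max_outer)
    fits[[k]] <- f
  }
  new_path(grid, fits, data$family, "hosps_random")
}

# Unpenalized mixed ML on the active set; zeros preserved elsewhere.
mixed_post_refit <- function(data, fit, tol = 1e-7, outer_tol = 1e-6,
                             max_outer = 500L) {
  active <- names(fit$beta)[fit$beta != 0]
  sub <- if (length(active)) select_predictors(data, active) else NULL
  refit <- if (is.null(sub)) {
    dnull <- data
    dnull$X <- matrix(0, nrow(data$X), 1, dimnames = list(NULL, ".null"))
    dnull$var_names <- ".null"
    fit_mixed_lasso(dnull, lambda = 1, init = NULL, tol = tol,
                    outer_tol = outer_tol, max_outer = max_outer)
  } else {
    fit_mixed_lasso(sub, lambda = 0, init = NULL, tol = tol,
                    outer_tol = outer_tol, max_outer = max_outer)
  }
  beta <- setNames(rep(0, length(fit$beta)), names(fit$beta))
  if (!is.null(sub)) beta[active] <- refit$beta
  out <- make_fit(
    intercept = refit$intercept, beta = beta,
    cluster_effects = refit$cluster_effects,
    tau = refit$tau, phi = refit$phi, lambda = fit$lambda, alpha = 1,
    df = sum(beta != 0) + 2L + as.integer(data$family == "gaussian"),
    loglik = refit$loglik, n = refit$n,
    estimator = "post", converged = refit$converged, n_iter = refit$n_iter,
    family = data$family, variant = "hosps_random",
    cluster_levels = refit$cluster_levels
  )
  out
}
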