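# Independent oracles and small data builders used across the test files.
# Everything here is deliberately written from first principles (brute force,
# generic solvers, closed forms) rather than reusing package internals.

# ---- datasets ---------------------------------------------------------------

# A small clustered dataset with continuous + binary predictors.
toy_dataset <- function(n = 60, p = 4, H = 5, family = "gaussian", seed = 1,
                        standardized = FALSE) {
  set.seed(seed)
  X <- cbind(
    matrix(rnorm(n * ceiling(p / 2)), n),
    matrix(rbinom(n * floor(p / 2), 1, 0.4), n)
  )[, seq_len(p), drop = FALSE]
  colnames(X) <- sprintf("x%02d", seq_len(p))
  cl <- sprintf("H%02d", sample.int(H, n, replace = TRUE))
  eta <- 0.5 + X %*% rnorm(p, 0, 0.5)
  y <- if (family == "gaussian") {
    drop(eta) + rnorm(n)
  } else {
    rbinom(n, 1, plogis(drop(eta)))
  }
  df <- data.frame(hospital_id = cl, outcome = y, X, check.names = FALSE)
  d <- clustered_dataset(df, family = family)
  d$standardized <- standardized
  d
}

# ---- elastic-net objective and a general-purpose convex solver --------------

# (1/(2n)) sum w (y - b0 - X beta)^2 + lambda sum pf (alpha|b| + (1-alpha)/2 b^2)
elnet_objective <- function(X, y, b0, beta, lambda, alpha = 1,
                            pf = rep(1, ncol(X)), w = rep(1, length(y))) {
  r <- y - b0 - drop(X %*% beta)
  sum(w * r^2) / (2 * length(y)) +
    lambda * sum(pf * (alpha * abs(beta) + (1 - alpha) / 2 * beta^2))
}

# FISTA (accelerated proximal gradient with function-value restart) on the
# same objective, intercept as an unpenalized coordinate. Generic first-order
# solver, nothing shared with the coordinate-descent core.
fista_elnet <- function(X, y, lambda, alpha = 1, pf = rep(1, ncol(X)),
                        w = rep(1, length(y)), max_iter = 50000L) {
  n <- nrow(X)
  Xa <- cbind(`(Intercept)` = 1, X)
  pfa <- c(0, pf)
  G <- crossprod(Xa * w, Xa) / n
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) +
    lambda * (1 - alpha) * max(pfa)
  obj <- function(b) {
    r <- y - drop(Xa %*% b)
    sum(w * r^2) / (2 * n) +
      lambda * sum(pfa * (alpha * abs(b) + (1 - alpha) / 2 * b^2))
  }
  th <- rep(0, ncol(Xa))
  z <- th
  t_k <- 1
  f_prev <- obj(th)
  for (it in seq_len(max_iter)) {
    g <- -drop(crossprod(Xa * w, y - drop(Xa %*% z))) / n +
      lambda * (1 - alpha) * pfa * z
    u <- z - g / L
    shift <- lambda * alpha * pfa / L
    th_new <- sign(u) * pmax(abs(u) - shift, 0)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- th_new + (t_k - 1) / t_new * (th_new - th)
    if (obj(th_new) > obj(th)) {  # restart the momentum
      z <- th_new
      t_new <- 1
    }
    th <- th_new
    t_k <- t_new
    if (it %% 200L == 0L) {
      f <- obj(th)
      if (abs(f_prev - f) < 1e-14 * (1 + abs(f))) break
      f_prev <- f
    }
  }
  list(intercept = th[1], beta = th[-1], objective = obj(th))
}

# ---- metric oracles ---------------------------------------------------------

auc_oracle <- function(y, p) {
  pp <- p[y == 1]
  pn <- p[y == 0]
  cmp <- outer(pp, pn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive threshold enumeration with step-wise integration.
prauc_oracle <- function(y, p) {
  th <- sort(unique(p), decreasing = TRUE)
  rec <- numeric(length(th))
  prec <- numeric(length(th))
  for (i in seq_along(th)) {
    called <- p >= th[i]
    rec[i] <- sum(y == 1 & called) / sum(y == 1)
    prec[i] <- sum(y == 1 & called) / sum(called)
  }
  sum(diff(c(0, rec)) * prec)
}

# ---- balanced one-way random-intercept ML closed forms ----------------------

# y_hi = mu + b_h + e_hi with H clusters of equal size m; ML (not REML):
#   phi2_hat = SSW / (N - H),  lambda_hat = SSB / H (= phi2 + m tau2),
#   tau2_hat = max(0, (lambda_hat - phi2_hat) / m),
#   b_hat = (m tau2 / lambda) (ybar_h - ybar)
oneway_ml <- function(y, cluster) {
  cl <- factor(cluster)
  m <- as.integer(table(cl)[1])
  stopifnot(all(table(cl) == m))
  H <- nlevels(cl)
  N <- length(y)
  ybar_h <- tapply(y, cl, mean)
  ybar <- mean(y)
  SSW <- sum((y - ybar_h[cl])^2)
  SSB <- m * sum((ybar_h - ybar)^2)
  phi2 <- SSW / (N - H)
  lam <- SSB / H
  tau2 <- max(0, (lam - phi2) / m)
  b <- if (tau2 > 0) (m * tau2 / lam) * (ybar_h - ybar) else rep(0, H)
  list(mu = ybar, phi2 = phi2, tau2 = tau2,
       b = setNames(as.numeric(b), levels(cl)))
}
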