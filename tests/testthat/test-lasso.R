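test_that("gaussian fits agree with glmnet at matched penalties", {
  d <- toy_dataset(n = 80, p = 6, seed = 31)
  for (lam in c(0.3, 0.05, 0.01)) {
    f <- fit_lasso(d, lam, tol = 1e-9)
    g <- glmnet::glmnet(d$X, d$y, family = "gaussian", alpha = 1,
                        lambda = lam, standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(f$beta), as.numeric(g$beta), tolerance = 1e-6)
    expect_equal(f$intercept, as.numeric(g$a0), tolerance = 1e-6)
  }
})

test_that("binomial fits agree with glmnet at matched penalties", {
  d <- toy_dataset(n = 120, p = 5, family = "binomial", seed = 32)
  for (lam in c(0.05, 0.01)) {
    f <- fit_lasso(d, lam, tol = 1e-9)
    g <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 1,
                        lambda = lam, standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(f$beta), as.numeric(g$beta), tolerance = 1e-5)
    expect_equal(f$intercept, as.numeric(g$a0), tolerance = 1e-5)
  }
})

test_that("fits satisfy the KKT certificate", {
  for (s in 1:5) {
    d <- toy_dataset(n = 50, p = 5, seed = 40 + s,
                     family = if (s %% 2) "gaussian" else "binomial")
    f <- fit_lasso(d, 0.05, tol = 1e-9)
    expect_lt(kkt_violation(f, d), 1e-6)
    fd <- fit_lasso(d, 0.05, include_cluster_dummies = TRUE, tol = 1e-9)
    expect_lt(kkt_violation(fd, d), 1e-6)
  }
})

test_that("the solution is invariant to warm starts", {
  d <- toy_dataset(n = 60, p = 5, seed = 44)
  cold <- fit_lasso(d, 0.02, tol = 1e-10)
  warm <- fit_lasso(d, 0.02, init = fit_lasso(d, 0.5), tol = 1e-10)
  expect_equal(cold$beta, warm$beta, tolerance = 1e-7)
})

test_that("penalty scale equivariance: scaling y scales the solution", {
  d <- toy_dataset(n = 50, p = 4, seed = 45)
  f1 <- fit_lasso(d, 0.1, tol = 1e-10)
  d2 <- d
  d2$y <- 3 * d$y
  f2 <- fit_lasso(d2, 0.3, tol = 1e-10)
  expect_equal(3 * f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(3 * f1$intercept, f2$intercept, tolerance = 1e-6)
})

test_that("hospital dummies are reference-coded and optionally unpenalized", {
  d <- toy_dataset(n = 70, p = 3, H = 4, seed = 46)
  f <- fit_lasso(d, 0.02, include_cluster_dummies = TRUE)
  expect_identical(names(f$cluster_effects), sort(unique(d$cluster)))
  expect_equal(unname(f$cluster_effects[1]), 0)  # reference hospital

  fu <- fit_lasso(d, 1e6, include_cluster_dummies = TRUE,
                  penalize_dummies = FALSE)
  expect_true(all(fu$beta == 0))           # fixed effects fully penalized
  expect_gt(max(abs(fu$cluster_effects)), 0)  # dummies unpenalized, still fit
})

test_that("separation at lambda = 0 raises an informative error", {
  df <- data.frame(hospital_id = rep("a", 20),
                   outcome = rep(c(0, 1), each = 10),
                   x1 = rep(c(-1, 1), each = 10) + rnorm(20, 0, 1e-4))
  d <- clustered_dataset(df, family = "binomial")
  expect_error(fit_lasso(d, 0), "separation")
})

test_that("the path warm-starts through the grid and is reproducible", {
  d <- toy_dataset(n = 60, p = 5, seed = 47)
  grid <- build_lambda_grid(d, "no_hosps")
  path <- fit_lasso_path(d, grid)
  expect_length(path$fits, 100L)
  expect_true(all(path$fits[[1]]$beta == 0))
  direct <- fit_lasso(d, grid$values[60], tol = 1e-9)
  expect_equal(path$fits[[60]]$beta, direct$beta, tolerance = 1e-6)
})

test_that("post-LASSO refit equals unpenalized LS / ML on the active set", {
  d <- toy_dataset(n = 70, p = 5, seed = 48)
  f <- fit_lasso(d, 0.05)
  pf <- post_lasso_refit(d, f)
  active <- names(f$beta)[f$beta != 0]
  ols <- lm(d$y ~ d$X[, active, drop = FALSE])
  expect_equal(unname(pf$beta[active]), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(pf$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_true(all(pf$beta[setdiff(names(pf$beta), active)] == 0))
  expect_identical(pf$estimator, "post")

  db <- toy_dataset(n = 100, p = 4, family = "binomial", seed = 49)
  fb <- fit_lasso(db, 0.03)
  pb <- post_lasso_refit(db, fb)
  activeb <- names(fb$beta)[fb$beta != 0]
  ml <- glm(db$y ~ db$X[, activeb, drop = FALSE], family = binomial())
  expect_equal(unname(pb$beta[activeb]), unname(coef(ml)[-1]), tolerance = 1e-6)
})

test_that("predictions add hospital effects and police unknown hospitals", {
  d <- toy_dataset(n = 60, p = 3, H = 4, seed = 50)
  f <- fit_lasso(d, 0.01, include_cluster_dummies = TRUE)
  pred <- predict(f, d)
  manual <- f$intercept + drop(d$X %*% f$beta) +
    unname(f$cluster_effects[d$cluster])
  expect_equal(pred, manual)

  other <- d
  other$cluster[1] <- "H99"
  expect_error(predict(f, other), "not seen in training")
  p0 <- predict(f, other, unknown_cluster = "zero")
  expect_equal(p0[-1], pred[-1])
  expect_equal(p0[1], f$intercept + sum(d$X[1, ] * f$beta))
})

test_that("information criteria follow the stated degrees-of-freedom rule", {
  d <- toy_dataset(n = 60, p = 4, seed = 51)
  f <- fit_lasso(d, 0.05)
  expect_equal(f$df, 1L + sum(f$beta != 0))
  expect_equal(f$aic, -2 * f$loglik + 2 * f$df)
  expect_equal(f$bic, -2 * f$loglik + log(f$n) * f$df)
})
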