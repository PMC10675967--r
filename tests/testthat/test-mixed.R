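mixed_toy <- function(n_hospitals = 15, size = c(8, 15), tau = 0.5,
                      family = "gaussian", seed = 1) {
  cfg <- scenario_config(
    n_hospitals = n_hospitals, hospital_size_range = size,
    n_comorbidity_vars = 5, tau = tau, seed = seed,
    outcome_family = if (family == "binomial") "binomial" else "gaussian-log",
    base_rate = if (family == "binomial") qlogis(0.3) else 2
  )
  d <- simulate_hospital_data(cfg)
  prep <- preprocess_global(d)
  scale_unit_variance(prep$data)$train
}

test_that("the unpenalized gaussian fit matches lme4 maximum likelihood", {
  d <- mixed_toy(seed = 61)
  f <- fit_mixed_lasso(d, 0)
  df <- tibble::as_tibble(d)
  fm <- lme4::lmer(outcome ~ . - hospital_id + (1 | hospital_id),
                   data = df, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fm))
  expect_equal(f$tau, sqrt(vc$vcov[1]), tolerance = 1e-5)
  expect_equal(f$phi, sqrt(vc$vcov[2]), tolerance = 1e-5)
  fe <- lme4::fixef(fm)
  expect_equal(unname(f$beta[names(fe)[-1]]), unname(fe[-1]), tolerance = 1e-5)
  expect_equal(f$intercept, unname(fe[1]), tolerance = 1e-5)
  expect_equal(unname(f$cluster_effects),
               lme4::ranef(fm)$hospital_id[[1]], tolerance = 1e-5)
  expect_equal(f$loglik, as.numeric(logLik(fm)), tolerance = 1e-6)
})

test_that("the unpenalized binomial fit is close to glmer (nAGQ = 0)", {
  d <- mixed_toy(n_hospitals = 25, size = c(20, 35), family = "binomial",
                 seed = 62)
  f <- fit_mixed_lasso(d, 0)
  df <- tibble::as_tibble(d)
  gm <- lme4::glmer(outcome ~ . - hospital_id + (1 | hospital_id),
                    data = df, family = binomial, nAGQ = 0)
  vc <- as.data.frame(lme4::VarCorr(gm))
  # PQL versus adaptive quadrature: agreement is approximate by design
  expect_equal(f$tau, sqrt(vc$vcov[1]), tolerance = 0.1)
  fe <- lme4::fixef(gm)
  expect_equal(unname(f$beta[names(fe)[-1]]), unname(fe[-1]), tolerance = 0.05)
})

test_that("the profile-likelihood variance update reaches the same solution", {
  d <- mixed_toy(seed = 66)
  fm <- fit_mixed_lasso(d, 0.02)
  fp <- fit_mixed_lasso(d, 0.02, variance_update = "profile")
  expect_equal(fp$tau, fm$tau, tolerance = 1e-5)
  expect_equal(fp$phi, fm$phi, tolerance = 1e-5)
  expect_equal(fp$beta, fm$beta, tolerance = 1e-5)
  expect_equal(fp$loglik, fm$loglik, tolerance = 1e-6)

  # binomial away from the tau = 0 boundary (near it the two updates may
  # land on either side of the truncation threshold)
  cfgb <- scenario_config(
    n_hospitals = 30, hospital_size_range = c(25, 40),
    n_comorbidity_vars = 5, tau = 1, seed = 67,
    outcome_family = "binomial", base_rate = qlogis(0.3)
  )
  db <- scale_unit_variance(preprocess_global(
    simulate_hospital_data(cfgb))$data)$train
  bm <- fit_mixed_lasso(db, 0.01)
  bp <- fit_mixed_lasso(db, 0.01, variance_update = "profile")
  expect_equal(bp$tau, bm$tau, tolerance = 1e-4)
  expect_equal(bp$beta, bm$beta, tolerance = 1e-4)
})

test_that("tau = 0 reduces the mixed model to the plain LASSO", {
  d <- mixed_toy(seed = 63)
  f0 <- fit_mixed_lasso(d, 0.05, tau_zero = TRUE)
  fl <- fit_lasso(d, 0.05)
  expect_equal(f0$beta, fl$beta, tolerance = 1e-6)
  expect_equal(f0$intercept, fl$intercept, tolerance = 1e-6)
  expect_equal(f0$tau, 0)
  expect_true(all(f0$cluster_effects == 0))
})

test_that("a single hospital forces tau to zero with a warning", {
  df <- data.frame(hospital_id = rep("only", 30), outcome = rnorm(30, 5),
                   x1 = rnorm(30), x2 = rbinom(30, 1, 0.5))
  d <- clustered_dataset(df, family = "gaussian")
  expect_warning(f <- fit_mixed_lasso(d, 0.1), "single hospital")
  expect_equal(f$tau, 0)
})

test_that("strong penalization yields the intercept-plus-intercepts null model", {
  d <- mixed_toy(seed = 64)
  f <- fit_mixed_lasso(d, Inf)
  expect_true(all(f$beta == 0))
  expect_gt(f$tau, 0)
  expect_equal(f$df, 3L)  # intercept + tau + phi
})

test_that("the mixed path warm-starts and the final_re refit is unpenalized", {
  d <- mixed_toy(seed = 65)
  grid <- build_lambda_grid(d, "hosps_random")
  path <- fit_mixed_path(d, grid)
  expect_length(path$fits, 100L)
  expect_true(all(path$fits[[1]]$beta == 0))
  direct <- fit_mixed_lasso(d, grid$values[50])
  expect_equal(path$fits[[50]]$beta, direct$beta, tolerance = 1e-5)

  f <- path$fits[[50]]
  post <- hosplasso:::mixed_post_refit(d, f)
  expect_identical(post$estimator, "post")
  active <- names(f$beta)[f$beta != 0]
  expect_true(all(post$beta[setdiff(names(post$beta), active)] == 0))
  # the refit solves the unpenalized mixed ML on the active set
  sub <- hosplasso:::select_predictors(d, active)
  full <- fit_mixed_lasso(sub, 0)
  expect_equal(unname(post$beta[active]), unname(full$beta), tolerance = 1e-6)
  expect_equal(post$tau, full$tau, tolerance = 1e-6)
})

test_that("mixed predictions include the predicted random intercepts", {
  d <- mixed_toy(seed = 66)
  f <- fit_mixed_lasso(d, 0.05)
  pred <- predict(f, d)
  manual <- f$intercept + drop(d$X %*% f$beta) +
    unname(f$cluster_effects[d$cluster])
  expect_equal(pred, manual)
})
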