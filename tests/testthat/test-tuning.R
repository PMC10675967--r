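test_that("the penalty grid obeys its construction contract", {
  d <- toy_dataset(n = 80, p = 6, seed = 91)
  for (variant in c("no_hosps", "hosps_fixed", "hosps_random")) {
    g <- build_lambda_grid(d, variant)
    expect_s3_class(g, "hl_lambda_grid")
    expect_length(g$values, 100L)
    expect_true(all(diff(g$values) < 0))
    expect_true(g$certified)
    expect_equal(g$n_selected_at_1, 0L)
    expect_gte(g$n_selected_at_5, 1L)
    # log-linear spacing: constant ratio between neighbours
    expect_equal(diff(log(g$values)), rep(diff(log(g$values))[1], 99))
  }
})

test_that("the top of the grid sits just above the hand-computed KKT bound", {
  d <- toy_dataset(n = 60, p = 5, seed = 92)
  g <- build_lambda_grid(d, "no_hosps")
  bound <- max(abs(crossprod(d$X, d$y - mean(d$y)))) / length(d$y)
  expect_equal(g$lam_max, 1.05 * bound)
})

test_that("cluster-aware folds keep every hospital in every training part", {
  d <- toy_dataset(n = 90, p = 3, H = 8, seed = 93)
  # add a single-patient hospital
  d$cluster[1] <- "SINGLETON"
  set.seed(1)
  fold <- hosplasso:::make_cv_folds(d, 5L, cluster_aware = TRUE)
  expect_equal(fold[1], 0L)  # singleton pinned to the always-train fold
  for (f in 1:5) {
    tr_cl <- unique(d$cluster[fold != f])
    expect_setequal(tr_cl, unique(d$cluster))
  }
})

test_that("cross-validation tuning returns a coherent result", {
  d <- toy_dataset(n = 120, p = 6, seed = 94)
  g <- build_lambda_grid(d, "no_hosps")
  tn <- tune_cv(d, g, "no_hosps", criterion = "cv_min", seed = 5)
  expect_s3_class(tn, "hl_tuning")
  expect_true(tn$lambda_1se >= tn$lambda_min)
  expect_equal(tn$chosen_lambda, tn$lambda_min)
  expect_equal(nrow(tn$curve), 100L)
  expect_true(all(is.finite(tn$curve$estimate)))
  # the returned fit is the refit at the chosen penalty
  expect_equal(tn$chosen_fit$lambda, tn$chosen_lambda)

  # reproducible given the seed
  tn2 <- tune_cv(d, g, "no_hosps", criterion = "cv_min", seed = 5)
  expect_equal(tn$curve$estimate, tn2$curve$estimate)

  t1se <- tune_cv(d, g, "no_hosps", criterion = "cv_1se", seed = 5)
  expect_equal(t1se$chosen_lambda, t1se$lambda_1se)
  expect_lte(sum(t1se$chosen_fit$beta != 0), sum(tn$chosen_fit$beta != 0))
})

test_that("information-criterion tuning picks the minimizer, largest lambda on ties", {
  d <- toy_dataset(n = 100, p = 6, seed = 95)
  g <- build_lambda_grid(d, "no_hosps")
  tn <- tune_ic(d, g, "no_hosps", criterion = "bic")
  crit <- vapply(tn$path$fits, function(f) f$bic, numeric(1))
  expect_equal(tn$chosen_lambda, g$values[which.min(crit)])
  # which.min returns the first (= largest-lambda) index among exact ties
  expect_equal(which.min(c(2, 1, 1, 3)), 2L)

  ta <- tune_ic(d, g, "no_hosps", criterion = "aic")
  # AIC penalizes complexity less, so it never selects fewer variables
  expect_gte(ta$n_selected, tn$n_selected)
})

test_that("post-estimator tuning tunes on unpenalized refits", {
  d <- toy_dataset(n = 90, p = 5, seed = 96)
  g <- build_lambda_grid(d, "no_hosps")
  tn <- tune_ic(d, g, "no_hosps", criterion = "bic", estimator = "post")
  expect_identical(tn$chosen_fit$estimator, "post")
  active <- names(tn$chosen_fit$beta)[tn$chosen_fit$beta != 0]
  ols <- lm(d$y ~ d$X[, active, drop = FALSE])
  expect_equal(unname(tn$chosen_fit$beta[active]), unname(coef(ols)[-1]),
               tolerance = 1e-8)
})

test_that("mixed-variant cross-validation uses cluster-aware folds", {
  cfg <- scenario_config(n_hospitals = 10, hospital_size_range = c(8, 14),
                         n_comorbidity_vars = 4, seed = 97)
  d <- scale_unit_variance(preprocess_global(simulate_hospital_data(cfg))$data)$train
  g <- build_lambda_grid(d, "hosps_random")
  tn <- tune_cv(d, g, "hosps_random", criterion = "cv_min", seed = 7)
  expect_s3_class(tn$chosen_fit, "hl_fit")
  expect_identical(tn$chosen_fit$variant, "hosps_random")
  expect_true(all(is.finite(tn$curve$estimate)))
})
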