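test_that("sub-sampling splits obey size, coverage and reproducibility", {
  d <- toy_dataset(n = 200, p = 3, H = 12, seed = 101)
  sp <- make_subsamples(d, R = 20L, seed = 5)
  expect_length(sp$splits, 20L)
  for (s in sp$splits) {
    expect_length(s$test_idx, round(200 / 20))
    expect_length(intersect(s$train_idx, s$test_idx), 0L)
    expect_setequal(c(s$train_idx, s$test_idx), seq_len(200))
    # every test hospital has at least one training row
    expect_true(all(d$cluster[s$test_idx] %in% d$cluster[s$train_idx]))
  }
  sp2 <- make_subsamples(d, R = 20L, seed = 5)
  expect_identical(sp$checksums, sp2$checksums)
  expect_false(identical(sp$checksums,
                         make_subsamples(d, R = 20L, seed = 6)$checksums))
})

test_that("a single-patient hospital is always in training", {
  d <- toy_dataset(n = 120, p = 3, H = 6, seed = 102)
  d$cluster[7] <- "LONE"
  sp <- make_subsamples(d, R = 20L, seed = 3)
  for (s in sp$splits) expect_true(7 %in% s$train_idx)
})

test_that("the index checksum is order-insensitive and deterministic", {
  cs <- hosplasso:::index_checksum
  expect_identical(cs(c(3, 1, 2)), cs(1:3))
  expect_identical(cs(1:50), cs(1:50))
  expect_false(identical(cs(1:50), cs(2:51)))
})

test_that("variable importance ranks by |coefficient| and formats labels", {
  mk <- function(beta) {
    structure(list(beta = beta, intercept = 0, cluster_effects = numeric(0),
                   family = "gaussian", variant = "no_hosps"),
              class = "hl_fit")
  }
  b1 <- c(a = 0.9, b = -0.8, c = 0.7, d = 0.6, e = 0.5, f = 0.4, g = 0)
  b2 <- c(a = 0.9, b = -0.8, c = 0.7, d = 0.6, e = 0, f = 0.4, g = 0.3)
  imp <- variable_importance(list(mk(b1), mk(b2)), k = 5L)
  expect_s3_class(imp, "hl_importance")
  expect_equal(imp$top_rate[imp$variable == "a"], 1)
  expect_equal(imp$top_rate[imp$variable == "e"], 0.5)
  expect_equal(imp$top_rate[imp$variable == "g"], 0)
  expect_identical(imp$label[imp$variable == "a"], "100% (.90)")
  expect_identical(imp$label[imp$variable == "g"], "0% (-)")
  expect_identical(imp$label[imp$variable == "b"], "100% (-.80)")

  # fewer than k nonzero coefficients: take all, record the shortfall
  b3 <- c(a = 0.2, b = 0, c = 0, d = 0, e = 0, f = 0, g = 0)
  imp2 <- variable_importance(list(mk(b3)), k = 5L)
  expect_equal(attr(imp2, "shortfall_replicates"), 1L)
  expect_equal(sum(imp2$n_top), 1L)

  # ties at the cut break by variable order
  b4 <- c(a = 0.5, b = 0.5, c = 0.5, d = 0.5, e = 0.5, f = 0.5, g = 0.5)
  imp3 <- variable_importance(list(mk(b4)), k = 5L)
  expect_equal(imp3$n_top[match(letters[1:7], imp3$variable)],
               c(1L, 1L, 1L, 1L, 1L, 0L, 0L))
})

test_that("run_experiment scores every variant on identical splits", {
  cfg <- scenario_config(n_hospitals = 12, hospital_size_range = c(10, 16),
                         n_comorbidity_vars = 5, seed = 103)
  d <- preprocess_global(simulate_hospital_data(cfg))$data
  sp <- make_subsamples(d, R = 3L, seed = 11)
  ex <- run_experiment(d, sp, variants = c("no_hosps", "hosps_fixed"),
                       criteria = c("cv_min", "bic"), cv_seed = 12)
  expect_s3_class(ex, "hl_experiment")
  expect_identical(ex$split_checksums, sp$checksums)
  # 3 replicates x 2 variants x 2 criteria x 1 gaussian metric
  expect_equal(nrow(ex$metrics), 12L)
  expect_setequal(unique(ex$metrics$metric), "rmse")
  expect_true(all(is.finite(ex$metrics$value)))
  agg <- ex$aggregate
  expect_equal(nrow(agg), 4L)
  expect_equal(agg$se, agg$sd / sqrt(agg$n))
  expect_true(all(ex$importance$variant %in% c("no_hosps", "hosps_fixed")))
  expect_true(all(ex$log$n_selected >= 0, na.rm = TRUE))
})

test_that("cv_1se is skipped for the random-effects variant by default", {
  cfg <- scenario_config(n_hospitals = 10, hospital_size_range = c(8, 12),
                         n_comorbidity_vars = 4, seed = 104)
  d <- preprocess_global(simulate_hospital_data(cfg))$data
  sp <- make_subsamples(d, R = 2L, seed = 21)
  ex <- run_experiment(d, sp, variants = "hosps_random",
                       criteria = c("cv_min", "cv_1se"), cv_seed = 22)
  expect_setequal(unique(ex$metrics$criterion), "cv_min")
})

test_that("binomial experiments report the four binary metrics", {
  cfg <- scenario_config(n_hospitals = 10, hospital_size_range = c(15, 25),
                         n_comorbidity_vars = 4, outcome_family = "binomial",
                         base_rate = qlogis(0.3), seed = 105)
  d <- preprocess_global(simulate_hospital_data(cfg))$data
  sp <- make_subsamples(d, R = 2L, seed = 31)
  ex <- run_experiment(d, sp, variants = "no_hosps", criteria = "bic",
                       cv_seed = 32)
  expect_setequal(unique(ex$metrics$metric),
                  c("auc", "auprc", "brier", "bernoulli_lik"))
})
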