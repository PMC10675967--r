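make_df_dataset <- function(df, family = "gaussian") {
  clustered_dataset(df, family = family)
}

test_that("positive-outcome filter and log transform behave and compose", {
  df <- data.frame(hospital_id = rep(c("a", "b"), 4),
                   outcome = c(3, 0, 2, -1, 5, 1, 4, 2),
                   x1 = rnorm(8))
  d <- make_df_dataset(df)
  st <- filter_positive_outcome(d)
  expect_equal(st$report$n_excluded_nonpositive, 2L)
  expect_true(all(st$data$y > 0))

  lt <- log_transform_outcome(st$data)
  expect_equal(lt$y, log(st$data$y))
  expect_identical(lt$outcome_transform, "log")
  expect_error(log_transform_outcome(d), "positive")

  db <- toy_dataset(family = "binomial", seed = 5)
  expect_error(filter_positive_outcome(db), "gaussian")
  expect_error(log_transform_outcome(db), "gaussian")
})

test_that("zero-variance predictors are dropped and reported", {
  df <- data.frame(hospital_id = rep("a", 6), outcome = rnorm(6),
                   x1 = rnorm(6), x2 = rep(1, 6), x3 = rep(0, 6))
  d <- make_df_dataset(df)
  zv <- drop_zero_variance(d)
  expect_identical(colnames(zv$data$X), "x1")
  expect_identical(zv$report$dropped_zero_variance, c("x2", "x3"))

  d_all <- make_df_dataset(df[, c("hospital_id", "outcome", "x2", "x3")])
  expect_error(drop_zero_variance(d_all), "all predictor")
})

test_that("collinearity filter keeps the member closest to the outcome", {
  # three mutually duplicated columns -> exactly one survivor, the one with
  # the largest |cor(., y)|
  set.seed(71)
  base <- rnorm(50)
  y <- base + rnorm(50, 0, 0.4)
  df <- data.frame(hospital_id = rep("a", 50), outcome = y,
                   dup1 = base, dup2 = base, dup3 = base + rnorm(50, 0, 0.01),
                   other = rnorm(50))
  d <- make_df_dataset(df)
  out <- drop_collinear(d, threshold = 0.95)
  survivors <- colnames(out$data$X)
  expect_length(intersect(survivors, c("dup1", "dup2", "dup3")), 1L)
  expect_true("other" %in% survivors)
  cors <- abs(cor(df[c("dup1", "dup2", "dup3")], y))
  expect_identical(intersect(survivors, c("dup1", "dup2", "dup3")),
                   rownames(cors)[which.max(cors)])
  expect_equal(nrow(out$report$dropped_correlated), 2L)
})

test_that("single-pass mode skips pairs that already lost a member", {
  set.seed(72)
  base <- rnorm(40)
  df <- data.frame(hospital_id = rep("a", 40), outcome = base + rnorm(40),
                   a = base, b = base, c = base)
  d <- make_df_dataset(df)
  once <- drop_collinear(d, threshold = 0.95, iterative = FALSE)
  iter <- drop_collinear(d, threshold = 0.95, iterative = TRUE)
  expect_length(colnames(once$data$X), 1L)
  expect_identical(colnames(once$data$X), colnames(iter$data$X))
})

test_that("scaling divides by training SDs and applies them to the test set", {
  tr <- toy_dataset(n = 40, p = 3, seed = 6)
  te <- toy_dataset(n = 15, p = 3, seed = 7)
  sc <- scale_unit_variance(tr, te)
  s <- apply(tr$X, 2, sd)
  expect_equal(apply(sc$train$X, 2, sd), setNames(rep(1, 3), colnames(tr$X)))
  expect_equal(sc$test$X, sweep(te$X, 2, s, "/"))
  expect_true(sc$train$standardized)
  expect_equal(sc$report$scale_factors, s)

  const <- tr
  const$X[, 2] <- 1
  expect_error(scale_unit_variance(const), "zero training SD")
})

test_that("the global pipeline applies the rules in order, without scaling", {
  cfg <- scenario_config(n_hospitals = 10, hospital_size_range = c(8, 12),
                         n_comorbidity_vars = 5, seed = 13)
  d <- simulate_hospital_data(cfg)
  prep <- preprocess_global(d)
  expect_identical(prep$data$outcome_transform, "log")
  expect_false(prep$data$standardized)
  expect_true(all(prep$data$y == log(d$y[d$y > 0])))
  # idempotent on already-transformed data
  again <- preprocess_global(prep$data)
  expect_equal(again$data$y, prep$data$y)
  expect_equal(again$data$X, prep$data$X)
})
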