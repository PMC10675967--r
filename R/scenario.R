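#' Configure a synthetic hospital-data scenario
#'
#' Describes the generative model behind [simulate_hospital_data()]: a set of
#' hospitals of unequal size, each with a random intercept on the link scale,
#' patient-level predictors (a planned-admission indicator whose prevalence is
#' structurally confounded across hospitals, a continuous age, and a block of
#' Elixhauser-style binary comorbidity indicators), and either a positively
#' skewed continuous outcome (length of stay; linear model on the log scale)
#' or a rare binary outcome (mortality).
#'
#' Defaults emulate the structure of national hospital administrative data:
#' 80 hospitals of 20--80 patients, 30 comorbidity indicators with prevalence
#' 2--40%, 14.5% of hospitals with no planned admissions and 22.5% with only
#' planned admissions, a mean stay of about 7 days with intra-class
#' correlation near 0.12 on the log scale, and 4% mortality for the binomial
#' family.
#'
#' @param n_hospitals Number of hospitals (>= 2).
#' @param hospital_size_range Integer `(min, max)` patients per hospital;
#'   sizes are drawn uniformly on this range.
#' @param n_comorbidity_vars Number of binary comorbidity indicators.
#' @param comorbidity_prevalence_range `(low, high)` range from which each
#'   indicator's population prevalence is drawn.
#' @param beta_true Fixed-effect coefficients on the link scale. Either a
#'   full-length vector in column order (`planned_admission`, `age`, then the
#'   comorbidities) or a named vector matching a subset of those names
#'   (unnamed variables get 0). `NULL` gives the default signal: 0.1 on
#'   planned admission, 0.005 per year of age, 0.2 on the first five
#'   comorbidities.
#' @param tau Between-hospital (random-intercept) SD on the link scale.
#' @param confound_fractions `(f0, f1)`: share of hospitals with planned-
#'   admission prevalence exactly 0 and exactly 1; the remainder draw a
#'   prevalence uniformly on (0.1, 0.9).
#' @param outcome_family `"gaussian-log"` (raw positive outcome, linear on
#'   the log scale) or `"binomial"`.
#' @param base_rate Intercept on the link scale; default `2` (about 7.4 days)
#'   for gaussian-log, `qlogis(0.04)` for binomial.
#' @param noise_sd Residual SD on the log scale (gaussian-log only).
#' @param seed Integer RNG seed; generation is bit-reproducible given it.
#'
#' @return A validated `hl_scenario` list.
#' @export
scenario_config <- function(n_hospitals = 80,
                            hospital_size_range = c(20, 80),
                            n_comorbidity_vars = 30,
                            comorbidity_prevalence_range = c(0.02, 0.4),
                            beta_true = NULL,
                            tau = 0.3,
                            confound_fractions = c(0.145, 0.225),
                            outcome_family = c("gaussian-log", "binomial"),
                            base_rate = NULL,
                            noise_sd = 0.8,
                            seed = 1L) {
  outcome_family <- match.arg(outcome_family)
  if (is.null(base_rate)) {
    base_rate <- if (outcome_family == "gaussian-log") 2 else qlogis(0.04)
  }
  vn <- c("planned_admission", "age",
          sprintf("comorb_%02d", seq_len(n_comorbidity_vars)))
  p <- length(vn)
  beta <- rep(0, p)
  names(beta) <- vn
  if (is.null(beta_true)) {
    beta["planned_admission"] <- 0.1
    beta["age"] <- 0.005
    k <- min(5L, n_comorbidity_vars)
    beta[sprintf("comorb_%02d", seq_len(k))] <- 0.2
  } else if (!is.null(names(beta_true))) {
    bad <- setdiff(names(beta_true), vn)
    if (length(bad)) abort(paste0("beta_true names not in scenario: ",
                                  paste(bad, collapse = ", ")))
    beta[names(beta_true)] <- beta_true
  } else {
    if (length(beta_true) != p) {
      abort(sprintf("beta_true must have length %d (got %d)", p, length(beta_true)))
    }
    beta[] <- beta_true
  }
  cfg <- structure(
    list(
      n_hospitals = as.integer(n_hospitals),
      hospital_size_range = as.integer(hospital_size_range),
      n_comorbidity_vars = as.integer(n_comorbidity_vars),
      comorbidity_prevalence_range = as.numeric(comorbidity_prevalence_range),
      beta_true = beta,
      tau = as.numeric(tau),
      confound_fractions = as.numeric(confound_fractions),
      outcome_family = outcome_family,
      base_rate = as.numeric(base_rate),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed),
      var_names = vn
    ),
    class = "hl_scenario"
  )
  validate_scenario(cfg)
  cfg
}

validate_scenario <- function(cfg) {
  cf <- cfg$confound_fractions
  if (length(cf) != 2L || any(cf < 0) || sum(cf) > 1) {
    abort("confound_fractions must be two nonnegative shares summing to <= 1")
  }
  if (cfg$tau < 0) abort("tau must be >= 0")
  if (cfg$outcome_family == "gaussian-log" && cfg$noise_sd <= 0) {
    abort("noise_sd must be > 0 for the gaussian-log family")
  }
  if (cfg$n_hospitals < 2L) abort("n_hospitals must be >= 2")
  sr <- cfg$hospital_size_range
  if (length(sr) != 2L || sr[1] < 1L || sr[2] < sr[1]) {
    abort("hospital_size_range must be (min, max) with min >= 1")
  }
  pr <- cfg$comorbidity_prevalence_range
  if (length(pr) != 2L || pr[1] <= 0 || pr[2] >= 1 || pr[2] < pr[1]) {
    abort("comorbidity_prevalence_range must lie strictly inside (0, 1)")
  }
  invisible(cfg)
}

#' Simulate a clustered hospital dataset
#'
#' Draws data from the scenario's generative model: hospital sizes uniform on
#' the configured range, hospital intercepts `b_h ~ N(0, tau^2)`, planned-
#' admission prevalence per hospital following `confound_fractions` (a share
#' of all-0 hospitals, a share of all-1 hospitals, the remainder uniform on
#' 0.1--0.9), comorbidity indicators Bernoulli with per-variable prevalence,
#' age uniform on 18--95 years, and linear predictor
#' `eta = base_rate + X beta_true + b_h`. The gaussian-log family returns
#' `y = exp(eta + N(0, noise_sd^2))`, so the raw outcome is positively skewed
#' and `log(y)` is the linear model's scale; the binomial family returns
#' `y ~ Bernoulli(plogis(eta))`.
#'
#' One global RNG stream draws the hospital-level quantities and then seeds
#' one sub-stream per hospital, so a hospital's patients do not depend on the
#' order in which other hospitals are generated.
#'
#' @param config An [scenario_config()] object.
#' @return An [clustered_dataset()] (`hl_dataset`); gaussian-log scenarios
#'   come back with `family = "gaussian"` and the raw (untransformed)
#'   positive outcome.
#' @export
#' @examples
#' d <- simulate_hospital_data(scenario_config(n_hospitals = 10,
#'                                             hospital_size_range = c(5, 15),
#'                                             seed = 7))
#' d
simulate_hospital_data <- function(config) {
  validate_scenario(config)
  simulate_engine(config, between_effect = 0, confounded = FALSE)
}

#' Simulate the hospital-confounded scenario
#'
#' Like [simulate_hospital_data()], but the planned-admission variable's
#' association with the outcome is purely structural: its within-hospital
#' coefficient is forced to zero and each hospital's intercept is shifted by
#' `between_effect` times that hospital's planned-admission prevalence. A
#' pooled (cluster-ignoring) regression then sees a planned-admission effect
#' that a within-hospital analysis does not -- the situation in which
#' random-intercept selection should demote the variable.
#'
#' @inheritParams simulate_hospital_data
#' @param between_effect Link-scale effect of hospital-level planned-
#'   admission prevalence on the hospital intercept.
#' @export
simulate_confounded_data <- function(config, between_effect) {
  validate_scenario(config)
  simulate_engine(config, between_effect = between_effect, confounded = TRUE)
}

simulate_engine <- function(cfg, between_effect, confounded) {
  set.seed(cfg$seed)
  H <- cfg$n_hospitals
  sizes <- sample(seq(cfg$hospital_size_range[1], cfg$hospital_size_range[2]),
                  H, replace = TRUE)
  b <- rnorm(H, 0, cfg$tau)

  # planned-admission prevalence per hospital: all-0 block, all-1 block,
  # remainder with hospital-specific prevalence in (0.1, 0.9)
  n0 <- round(cfg$confound_fractions[1] * H)
  n1 <- round(cfg$confound_fractions[2] * H)
  status <- sample(rep(c("zero", "one", "mid"), c(n0, n1, H - n0 - n1)))
  pi_h <- ifelse(status == "zero", 0,
                 ifelse(status == "one", 1, NA_real_))
  pi_h[is.na(pi_h)] <- runif(sum(is.na(pi_h)), 0.1, 0.9)

  prev <- runif(cfg$n_comorbidity_vars,
                cfg$comorbidity_prevalence_range[1],
                cfg$comorbidity_prevalence_range[2])
  hosp_seed <- sample.int(.Machine$integer.max, H)

  beta <- cfg$beta_true
  if (confounded) {
    beta["planned_admission"] <- 0
    b <- b + between_effect * pi_h
  }

  rows <- vector("list", H)
  labels <- sprintf("H%03d", seq_len(H))
  for (h in seq_len(H)) {
    set.seed(hosp_seed[h])
    m <- sizes[h]
    planned <- rbinom(m, 1, pi_h[h])
    age <- runif(m, 18, 95)
    com <- vapply(prev, function(q) rbinom(m, 1, q), integer(m))
    if (m == 1L) com <- matrix(com, nrow = 1L)
    X <- cbind(planned_admission = planned, age = age, com)
    colnames(X) <- cfg$var_names
    eta <- cfg$base_rate + drop(X %*% beta) + b[h]
    y <- if (cfg$outcome_family == "gaussian-log") {
      exp(eta + rnorm(m, 0, cfg$noise_sd))
    } else {
      rbinom(m, 1, plogis(eta))
    }
    rows[[h]] <- list(X = X, y = y, cluster = rep(labels[h], m))
  }

  X <- do.call(rbind, lapply(rows, `[[`, "X"))
  out <- new_dataset(
    X,
    unlist(lapply(rows, `[[`, "y")),
    unlist(lapply(rows, `[[`, "cluster")),
    family = if (cfg$outcome_family == "binomial") "binomial" else "gaussian"
  )
  attr(out, "truth") <- list(beta = beta, b = setNames(b, labels),
                             tau = cfg$tau, pi_h = setNames(pi_h, labels),
                             base_rate = cfg$base_rate)
  out
}

#' Round-trip a scenario configuration through YAML
#'
#' @param config An `hl_scenario`.
#' @param path File path.
#' @export
write_scenario_config <- function(config, path) {
  validate_scenario(config)
  x <- unclass(config)
  x$beta_true <- as.list(x$beta_true)
  yaml::write_yaml(x, path)
  invisible(config)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  scenario_config(
    n_hospitals = x$n_hospitals,
    hospital_size_range = unlist(x$hospital_size_range),
    n_comorbidity_vars = x$n_comorbidity_vars,
    comorbidity_prevalence_range = unlist(x$comorbidity_prevalence_range),
    beta_true = unlist(x$beta_true),
    tau = x$tau,
    confound_fractions = unlist(x$confound_fractions),
    outcome_family = x$outcome_family,
    base_rate = x$base_rate,
    noise_sd = x$noise_sd,
    seed = x$seed
  )
}
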