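#' Draw the outer sub-sampling splits
#'
#' Each of the `R` replicates puts `round(n/20)` randomly chosen rows in the
#' test set and the rest in training, then repairs the draw so that every
#' hospital appearing in the test set keeps at least one training row (a
#' hospital's predicted effect is only usable if the hospital was seen in
#' training). Repair moves one uniformly chosen test row of each uncovered
#' hospital back to training and redraws a replacement test row from
#' hospitals that still have at least two training rows. Test sets of
#' different replicates may overlap; the splits are drawn once and reused by
#' every model variant.
#'
#' @param data An `hl_dataset`.
#' @param R Number of replicates.
#' @param seed Seed for the split draw.
#' @param test_fraction Share of rows per test set.
#' @return An `hl_subsamples`: the splits plus a checksum per split so
#'   reports can verify that all variants consumed identical partitions.
#' @export
make_subsamples <- function(data, R = 20L, seed = 1L, test_fraction = 1 / 20) {
  stopifnot(inherits(data, "hl_dataset"))
  n <- length(data$y)
  m <- round(n * test_fraction)
  if (m < 1L) abort("dataset too small for the requested test fraction")
  set.seed(seed)

  splits <- vector("list", R)
  for (r in seq_len(R)) {
    test <- sort(sample.int(n, m))
    guard <- 0L
    repeat {
      in_test <- logical(n)
      in_test[test] <- TRUE
      train_counts <- table(data$cluster[!in_test])
      uncovered <- setdiff(unique(data$cluster[in_test]), names(train_counts))
      if (!length(uncovered)) break
      guard <- guard + 1L
      if (guard > 10L * m) {
        abort(paste0("cannot satisfy the hospital-coverage constraint; ",
                     "offending hospital(s): ", paste(uncovered, collapse = ", ")))
      }
      for (lab in uncovered) {
        rows <- test[data$cluster[test] == lab]
        give_back <- if (length(rows) == 1L) rows else sample(rows, 1L)
        test <- setdiff(test, give_back)
        in_test[give_back] <- FALSE
        train_counts <- table(data$cluster[!in_test])
        rich <- names(train_counts)[train_counts >= 2L]
        candidates <- which(!in_test & data$cluster %in% rich)
        candidates <- setdiff(candidates, give_back)
        if (!length(candidates)) {
          abort(paste0("cannot satisfy the hospital-coverage constraint; ",
                       "offending hospital(s): ", lab))
        }
        add <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
        test <- sort(c(test, add))
        in_test[add] <- TRUE
      }
    }
    splits[[r]] <- list(train_idx = setdiff(seq_len(n), test),
                        test_idx = test, replicate = r)
  }
  structure(
    list(
      splits = splits, seed = seed, n = n, R = R,
      checksums = tibble::tibble(
        replicate = seq_len(R),
        checksum = vapply(splits, function(s) index_checksum(s$test_idx),
                          character(1))
      )
    ),
    class = "hl_subsamples"
  )
}

# Small deterministic hash of an index set, for the comparability record.
index_checksum <- function(idx) {
  h <- 0
  for (v in as.numeric(sort(idx))) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.hl_subsamples <- function(x, ...) {
  sizes <- vapply(x$splits, function(s) length(s$test_idx), integer(1))
  cat(sprintf("<hl_subsamples> %d replicates of %d rows, test size %d\n",
              x$R, x$n, sizes[1]))
  invisible(x)
}

#' Top-5 stability-based variable importance
#'
#' For each replicate's cross-validation-selected model, the five variables
#' with the largest absolute (standardized-scale) coefficients are recorded;
#' a variable's importance is the share of replicates in which it made that
#' top five, reported together with its mean coefficient over those
#' replicates. Ties at the cut are broken by variable order; replicates with
#' fewer than five nonzero coefficients contribute all of them and the
#' shortfall is recorded.
#'
#' @param fits List of `hl_fit`s, one per replicate, all from the same
#'   variant and the same splits.
#' @param k Size of the top set.
#' @return An `hl_importance` tibble: `variable`, `top_rate`, `mean_coef`,
#'   `n_top`, and a display `label` like `"100% (.16)"`.
#' @export
variable_importance <- function(fits, k = 5L) {
  stopifnot(length(fits) >= 1L)
  R <- length(fits)
  vars <- unique(unlist(lapply(fits, function(f) names(f$beta))))
  count <- setNames(numeric(length(vars)), vars)
  coefsum <- count
  shortfall <- 0L
  for (f in fits) {
    b <- f$beta
    nz <- which(b != 0)
    if (length(nz) < k) shortfall <- shortfall + 1L
    ord <- nz[order(-abs(b[nz]), nz)]
    top <- head(ord, k)
    count[names(b)[top]] <- count[names(b)[top]] + 1
    coefsum[names(b)[top]] <- coefsum[names(b)[top]] + b[top]
  }
  out <- tibble::tibble(
    variable = vars,
    top_rate = unname(count) / R,
    mean_coef = ifelse(count > 0, unname(coefsum) / unname(count), NA_real_),
    n_top = as.integer(unname(count))
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$top_rate),
                        is.na(.data$mean_coef), dplyr::desc(abs(.data$mean_coef)))
  out$label <- importance_label(out$top_rate, out$mean_coef)
  attr(out, "n_replicates") <- R
  attr(out, "shortfall_replicates") <- shortfall
  class(out) <- c("hl_importance", class(out))
  out
}

# "100% (.16)" / "0% (-)" display used in importance tables
importance_label <- function(rate, mean_coef) {
  coef_txt <- ifelse(
    is.na(mean_coef), "-",
    sub("^(-?)0\\.", "\\1.", sprintf("%.2f", mean_coef))
  )
  sprintf("%d%% (%s)", round(100 * rate), coef_txt)
}

#' Run the full sub-sampling comparison
#'
#' The outer experiment: for every replicate, preprocess the training split
#' (zero-variance removal and unit-variance scaling with training statistics
#' applied to the test split), build the penalty grid, tune every requested
#' variant under every requested criterion, predict the test split, and
#' score. Identical splits are consumed by every variant. The
#' cross-validation-selected (`cv_min`) fits additionally feed the top-5
#' variable-importance table per variant.
#'
#' Per-replicate model failures are recorded in the log and excluded from
#' aggregation with a warning rather than aborting the experiment.
#'
#' @param data A globally preprocessed `hl_dataset` (outcome already on the
#'   modelling scale; see [preprocess_global()]). Scaling must be left to
#'   this function.
#' @param splits An [make_subsamples()] object on the same rows.
#' @param variants Subset of `"no_hosps"`, `"hosps_fixed"`, `"hosps_random"`.
#' @param criteria Subset of `"cv_min"`, `"cv_1se"`, `"aic"`, `"bic"`.
#'   `cv_1se` is skipped for the random-effects variant (mirroring its
#'   absence there in the study design) unless `allow_cv1se_random`.
#' @param estimator `"classic"` or `"post"`.
#' @param alpha Elastic-net mixing for the fixed-effects variants.
#' @param cv_seed Seed stream for the internal cross-validation folds.
#' @param allow_cv1se_random Also compute `cv_1se` for the random variant.
#' @param importance_k Top-set size for [variable_importance()].
#' @return An `hl_experiment` with elements `metrics` (per replicate, long),
#'   `aggregate` (mean, SE over replicates as SD/sqrt(R), SD), `importance`,
#'   `log`, and `split_checksums`.
#' @export
run_experiment <- function(data, splits,
                           variants = c("no_hosps", "hosps_fixed", "hosps_random"),
                           criteria = c("cv_min", "cv_1se", "aic", "bic"),
                           estimator = c("classic", "post"),
                           alpha = 1, cv_seed = 1L,
                           allow_cv1se_random = FALSE,
                           importance_k = 5L) {
  stopifnot(inherits(data, "hl_dataset"), inherits(splits, "hl_subsamples"))
  estimator <- match.arg(estimator)
  variants <- match.arg(variants, several.ok = TRUE)
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (splits$n != length(data$y)) abort("splits were drawn for a different dataset")

  metrics_rows <- list()
  log_rows <- list()
  cv_fits <- lapply(setNames(variants, variants), function(v) list())

  for (s in splits$splits) {
    r <- s$replicate
    tr <- subset_dataset(data, s$train_idx)
    te <- subset_dataset(data, s$test_idx)
    zv <- drop_zero_variance(tr)
    tr <- zv$data
    te <- select_predictors(te, colnames(tr$X))
    sc <- scale_unit_variance(tr, te)
    tr <- sc$train
    te <- sc$test

    for (v in variants) {
      crit_v <- criteria
      if (v == "hosps_random" && !allow_cv1se_random) {
        crit_v <- setdiff(crit_v, "cv_1se")
      }
      step <- tryCatch({
        grid <- build_lambda_grid(tr, v, alpha = alpha)
        fits <- list()
        if (any(c("cv_min", "cv_1se") %in% crit_v)) {
          cvres <- tune_cv(tr, grid, v, alpha = alpha, estimator = estimator,
                           seed = cv_seed * 1000L + r)
          if ("cv_min" %in% crit_v) fits$cv_min <- cvres$chosen_fit
          if ("cv_1se" %in% crit_v) {
            fits$cv_1se <- refit_at(tr, cvres$lambda_1se, v, alpha, estimator)
          }
        }
        if (any(c("aic", "bic") %in% crit_v)) {
          path <- fit_variant_path(tr, grid, v, alpha, estimator)
          for (ic in intersect(c("aic", "bic"), crit_v)) {
            crit_vals <- vapply(path$fits, function(f) f[[ic]], numeric(1))
            fits[[ic]] <- path$fits[[which.min(crit_vals)]]
          }
        }
        fits
      }, error = function(e) e)

      if (inherits(step, "error")) {
        warning(sprintf("replicate %d, variant %s failed: %s",
                        r, v, conditionMessage(step)), call. = FALSE)
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          replicate = r, variant = v, criterion = NA_character_,
          lambda = NA_real_, n_selected = NA_integer_,
          converged = NA, error = conditionMessage(step))
        next
      }

      if (!is.null(step$cv_min)) cv_fits[[v]][[length(cv_fits[[v]]) + 1L]] <- step$cv_min

      for (cr in names(step)) {
        fit <- step[[cr]]
        vals <- score_fit(fit, te)
        metrics_rows[[length(metrics_rows) + 1L]] <- tibble::tibble(
          replicate = r, variant = v, criterion = cr,
          metric = names(vals), value = unname(vals))
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          replicate = r, variant = v, criterion = cr,
          lambda = fit$lambda, n_selected = sum(fit$beta != 0),
          converged = fit$converged, error = NA_character_)
      }
    }
  }

  metrics <- dplyr::bind_rows(metrics_rows)
  aggregate <- metrics |>
    dplyr::group_by(.data$variant, .data$criterion, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )

  importance <- dplyr::bind_rows(lapply(variants, function(v) {
    if (!length(cv_fits[[v]])) return(NULL)
    imp <- variable_importance(cv_fits[[v]], k = importance_k)
    dplyr::mutate(tibble::as_tibble(imp), variant = v, .before = 1)
  }))

  structure(
    list(
      metrics = metrics, aggregate = aggregate, importance = importance,
      log = dplyr::bind_rows(log_rows), split_checksums = splits$checksums,
      family = data$family,
      meta = list(variants = variants, criteria = criteria,
                  estimator = estimator, alpha = alpha, R = splits$R)
    ),
    class = "hl_experiment"
  )
}

score_fit <- function(fit, test) {
  pred <- predict(fit, test, type = "response")
  if (fit$family == "gaussian") {
    c(rmse = rmse(test$y, pred))
  } else {
    c(
      auc = tryCatch(roc_auc(test$y, pred), error = function(e) NA_real_),
      auprc = tryCatch(pr_auc(test$y, pred), error = function(e) NA_real_),
      brier = brier_score(test$y, pred),
      bernoulli_lik = bernoulli_likelihood(test$y, pred)
    )
  }
}

#' @export
print.hl_experiment <- function(x, ...) {
  cat(sprintf("<hl_experiment> %s family, %d replicates, variants: %s\n",
              x$family, x$meta$R, paste(x$meta$variants, collapse = ", ")))
  print(x$aggregate, n = 20)
  invisible(x)
}
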