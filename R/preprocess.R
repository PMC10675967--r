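#' Data-preparation rules for clustered hospital data
#'
#' Five operations, applied in a fixed order: keep positive outcomes (gaussian
#' only), log-transform the outcome, drop zero-variance predictors, drop one
#' member of each highly correlated predictor pair, and scale predictors to
#' unit variance using training-set SDs. Each returns the transformed
#' dataset(s) plus an `hl_preprocess_report` recording what was done.
#'
#' The correlation filter is intended to run once on the full data before
#' sub-sampling; zero-variance removal and scaling are re-applied per
#' training split (a variable can be constant within a split while varying
#' overall).
#'
#' @name preprocess
NULL

new_report <- function(...) {
  rep <- list(
    dropped_correlated = tibble::tibble(kept = character(), dropped = character(),
                                        abs_correlation = numeric()),
    dropped_zero_variance = character(0),
    scale_factors = NULL,
    outcome_transform = "none",
    n_excluded_nonpositive = 0L
  )
  extras <- list(...)
  # plain element-wise assignment: modifyList() would merge tibbles recursively
  rep[names(extras)] <- extras
  structure(rep, class = "hl_preprocess_report")
}

#' @export
print.hl_preprocess_report <- function(x, ...) {
  cat("<hl_preprocess_report>\n")
  cat(sprintf("  rows excluded (y <= 0): %d\n", x$n_excluded_nonpositive))
  cat(sprintf("  outcome transform: %s\n", x$outcome_transform))
  cat(sprintf("  zero-variance drops: %s\n",
              if (length(x$dropped_zero_variance)) paste(x$dropped_zero_variance, collapse = ", ") else "none"))
  cat(sprintf("  correlation drops: %d pair(s)\n", nrow(x$dropped_correlated)))
  invisible(x)
}

#' @rdname preprocess
#' @param data An `hl_dataset` with `family = "gaussian"`.
#' @return `filter_positive_outcome()`: list with elements `data` (rows with
#'   `y <= 0` removed) and `report`.
#' @export
filter_positive_outcome <- function(data) {
  stopifnot(inherits(data, "hl_dataset"))
  if (data$family != "gaussian") abort("positive-outcome filter applies to the gaussian family")
  keep <- data$y > 0
  if (!any(keep)) abort("no rows with positive outcome remain")
  list(
    data = subset_dataset(data, which(keep)),
    report = new_report(n_excluded_nonpositive = sum(!keep))
  )
}

#' @rdname preprocess
#' @return `log_transform_outcome()`: the dataset with `y` replaced by
#'   `log(y)`; predictions and error metrics then live on the log scale.
#' @export
log_transform_outcome <- function(data) {
  stopifnot(inherits(data, "hl_dataset"))
  if (data$family != "gaussian") abort("log transform applies to the gaussian family")
  if (any(data$y <= 0)) abort("outcome must be positive; run filter_positive_outcome() first")
  out <- data
  out$y <- log(data$y)
  out$outcome_transform <- "log"
  out
}

#' @rdname preprocess
#' @return `drop_zero_variance()`: list with `data` (constant predictor
#'   columns removed) and `report`.
#' @export
drop_zero_variance <- function(data) {
  stopifnot(inherits(data, "hl_dataset"))
  rng <- apply(data$X, 2, function(x) diff(range(x)))
  drop <- rng == 0
  if (all(drop)) abort("all predictor columns are constant")
  list(
    data = select_predictors(data, !drop),
    report = new_report(dropped_zero_variance = colnames(data$X)[drop])
  )
}

#' @rdname preprocess
#' @param threshold Absolute pairwise Pearson correlation above which one
#'   member of a predictor pair is removed (the one with the smaller absolute
#'   correlation with the outcome).
#' @param iterative If `TRUE` (default) offending pairs are re-examined after
#'   every removal, processed in order of descending `|r|` with ties broken
#'   by column order; if `FALSE` a single pass over the original pairs is
#'   made in the same order, skipping pairs that already lost a member.
#' @return `drop_collinear()`: list with `data` and `report` (each removal
#'   recorded as kept/dropped/|r|).
#' @export
drop_collinear <- function(data, threshold = 0.95, iterative = TRUE) {
  stopifnot(inherits(data, "hl_dataset"))
  if (ncol(data$X) < 2L) abort("need >= 2 predictors")
  X <- data$X
  y <- data$y
  cor_y <- abs(suppressWarnings(cor(X, y)))[, 1]
  cor_y[is.na(cor_y)] <- 0

  offending_pairs <- function(C, alive) {
    idx <- which(abs(C) > threshold & upper.tri(C), arr.ind = TRUE)
    if (nrow(idx) == 0L) return(idx)
    keep <- alive[idx[, 1]] & alive[idx[, 2]]
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) == 0L) return(idx)
    r <- abs(C)[idx]
    idx[order(-r, idx[, 1], idx[, 2]), , drop = FALSE]
  }
  drop_from_pair <- function(i, j) {
    # remove the member less correlated with the outcome; tie -> later column
    if (cor_y[i] < cor_y[j]) i else if (cor_y[j] < cor_y[i]) j else max(i, j)
  }

  C <- suppressWarnings(cor(X))
  C[is.na(C)] <- 0
  alive <- rep(TRUE, ncol(X))
  log <- list()

  if (iterative) {
    repeat {
      idx <- offending_pairs(C, alive)
      if (nrow(idx) == 0L) break
      i <- idx[1, 1]; j <- idx[1, 2]
      d <- drop_from_pair(i, j); k <- if (d == i) j else i
      alive[d] <- FALSE
      log[[length(log) + 1L]] <- tibble::tibble(
        kept = colnames(X)[k], dropped = colnames(X)[d],
        abs_correlation = abs(C[i, j]))
    }
  } else {
    idx <- offending_pairs(C, alive)
    for (row in seq_len(nrow(idx))) {
      i <- idx[row, 1]; j <- idx[row, 2]
      if (!alive[i] || !alive[j]) next
      d <- drop_from_pair(i, j); k <- if (d == i) j else i
      alive[d] <- FALSE
      log[[length(log) + 1L]] <- tibble::tibble(
        kept = colnames(X)[k], dropped = colnames(X)[d],
        abs_correlation = abs(C[i, j]))
    }
  }

  report <- new_report(
    dropped_correlated = if (length(log)) dplyr::bind_rows(log) else
      new_report()$dropped_correlated
  )
  list(data = select_predictors(data, alive), report = report)
}

#' @rdname preprocess
#' @param train,test `hl_dataset`s sharing the same predictor columns. The
#'   per-column SD is computed on `train` only and the same factors divide
#'   both sets (no mean-centering by default; the intercept absorbs means).
#' @param center Also subtract training means (off by default).
#' @return `scale_unit_variance()`: list with `train`, `test` (or `NULL`) and
#'   `report` carrying the scale factors.
#' @export
scale_unit_variance <- function(train, test = NULL, center = FALSE) {
  stopifnot(inherits(train, "hl_dataset"))
  s <- apply(train$X, 2, sd)
  if (any(s == 0)) {
    abort(paste0("zero training SD for: ",
                 paste(colnames(train$X)[s == 0], collapse = ", "),
                 "; run drop_zero_variance() first"))
  }
  mu <- if (center) colMeans(train$X) else rep(0, ncol(train$X))
  rescale <- function(d) {
    d$X <- sweep(sweep(d$X, 2, mu, "-"), 2, s, "/")
    d$standardized <- TRUE
    d$scale_factors <- s
    d
  }
  list(
    train = rescale(train),
    test = if (!is.null(test)) rescale(test) else NULL,
    report = new_report(scale_factors = s)
  )
}

#' Run the global preparation pipeline
#'
#' Applies, in order: positive-outcome filter and log transform (gaussian
#' only), zero-variance removal, and the pairwise-correlation filter. Scaling
#' is deliberately not part of the global pass -- it is recomputed on each
#' training split (see [run_experiment()]).
#'
#' @param data An `hl_dataset`.
#' @param cor_threshold Passed to [drop_collinear()].
#' @param iterative Passed to [drop_collinear()].
#' @return List with `data` and a merged `report`.
#' @export
preprocess_global <- function(data, cor_threshold = 0.95, iterative = TRUE) {
  rep_all <- new_report()
  if (data$family == "gaussian" && data$outcome_transform == "none") {
    st <- filter_positive_outcome(data)
    rep_all$n_excluded_nonpositive <- st$report$n_excluded_nonpositive
    data <- log_transform_outcome(st$data)
    rep_all$outcome_transform <- "log"
  }
  zv <- drop_zero_variance(data)
  rep_all$dropped_zero_variance <- zv$report$dropped_zero_variance
  co <- drop_collinear(zv$data, threshold = cor_threshold, iterative = iterative)
  rep_all$dropped_correlated <- co$report$dropped_correlated
  list(data = co$data, report = rep_all)
}

report_to_json <- function(report, path) {
  x <- list(
    dropped_correlated = report$dropped_correlated,
    dropped_zero_variance = report$dropped_zero_variance,
    scale_factors = as.list(report$scale_factors %||% list()),
    outcome_transform = report$outcome_transform,
    n_excluded_nonpositive = report$n_excluded_nonpositive
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
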