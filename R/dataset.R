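#' Bundle patient-level data into a clustered dataset
#'
#' The unit every stage of the pipeline consumes: a numeric predictor matrix,
#' an outcome, and a hospital (cluster) label per row. Binary predictors are
#' coded 0/1; the gaussian family carries a positive continuous outcome
#' (length of stay) that is usually log-transformed by
#' [log_transform_outcome()] before modelling, the binomial family a 0/1
#' outcome (in-hospital mortality).
#'
#' @param data A data frame with one row per patient.
#' @param outcome Name of the outcome column.
#' @param cluster Name of the hospital-identifier column.
#' @param family `"gaussian"` (continuous outcome) or `"binomial"` (0/1).
#' @param standardized Set when predictors have already been scaled to unit
#'   variance; [scale_unit_variance()] sets it for you.
#'
#' @return An object of class `hl_dataset`: a list with elements `X`
#'   (numeric matrix), `y`, `cluster` (character), `var_names`, `family`,
#'   `standardized`, and bookkeeping fields filled in by preprocessing.
#' @seealso [simulate_hospital_data()], [read_clustered_csv()]
#' @export
#' @examples
#' df <- tibble::tibble(
#'   hospital_id = rep(c("a", "b"), each = 4),
#'   outcome = rexp(8) + 1,
#'   x1 = rbinom(8, 1, 0.5),
#'   x2 = rnorm(8)
#' )
#' d <- clustered_dataset(df, family = "gaussian")
#' d
clustered_dataset <- function(data, outcome = "outcome", cluster = "hospital_id",
                              family = c("gaussian", "binomial"),
                              standardized = FALSE) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column '", outcome, "' not found"))
  }
  if (!cluster %in% names(data)) {
    abort(paste0("cluster column '", cluster, "' not found"))
  }
  y <- data[[outcome]]
  cl <- as.character(data[[cluster]])
  pred_cols <- setdiff(names(data), c(outcome, cluster))
  if (length(pred_cols) == 0L) abort("no predictor columns")
  X <- as.matrix(data[pred_cols])
  if (!is.numeric(X)) abort("predictor columns must be numeric")
  storage.mode(X) <- "double"
  new_dataset(X, y, cl, family, standardized)
}

new_dataset <- function(X, y, cluster, family, standardized = FALSE,
                        scale_factors = NULL, outcome_transform = "none") {
  validate_dataset_parts(X, y, cluster, family)
  structure(
    list(
      X = X, y = as.numeric(y), cluster = as.character(cluster),
      var_names = colnames(X), family = family,
      standardized = isTRUE(standardized),
      scale_factors = scale_factors,
      outcome_transform = outcome_transform
    ),
    class = "hl_dataset"
  )
}

validate_dataset_parts <- function(X, y, cluster, family) {
  if (length(y) != nrow(X) || length(cluster) != nrow(X)) {
    abort("lengths of outcome, cluster and predictor rows must agree")
  }
  if (is.null(colnames(X))) abort("predictor matrix must have column names")
  if (anyNA(X) || anyNA(y) || anyNA(cluster)) abort("missing values are not supported")
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    abort("binomial outcome must be coded 0/1")
  }
  if (family == "gaussian" && !all(is.finite(y))) {
    abort("gaussian outcome must be finite")
  }
  invisible(TRUE)
}

#' @export
print.hl_dataset <- function(x, ...) {
  cat(sprintf(
    "<hl_dataset> %d patients, %d predictors, %d hospitals, family = %s%s\n",
    nrow(x$X), ncol(x$X), length(unique(x$cluster)), x$family,
    if (x$standardized) " (standardized)" else ""
  ))
  invisible(x)
}

#' @export
dim.hl_dataset <- function(x) dim(x$X)

#' Convert a clustered dataset back to a tibble
#'
#' @param x An `hl_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `hospital_id`, `outcome`, then predictors.
#' @importFrom tibble as_tibble
#' @export
as_tibble.hl_dataset <- function(x, ...) {
  tibble::as_tibble(cbind(
    data.frame(hospital_id = x$cluster, outcome = x$y, stringsAsFactors = FALSE),
    as.data.frame(x$X)
  ))
}

# Row subset preserving metadata; used by splits, folds, filters.
subset_dataset <- function(data, idx) {
  new_dataset(
    data$X[idx, , drop = FALSE], data$y[idx], data$cluster[idx],
    data$family, data$standardized,
    scale_factors = data$scale_factors,
    outcome_transform = data$outcome_transform
  )
}

# Column subset of the predictors.
select_predictors <- function(data, keep) {
  out <- data
  out$X <- data$X[, keep, drop = FALSE]
  out$var_names <- colnames(out$X)
  if (!is.null(out$scale_factors)) {
    out$scale_factors <- out$scale_factors[colnames(out$X)]
  }
  out
}

#' Read / write clustered datasets as CSV
#'
#' The on-disk layout is: first column `hospital_id` (character), second the
#' outcome, remaining columns the predictors; a header row is required. Files
#' written by [write_clustered_csv()] round-trip losslessly through
#' [read_clustered_csv()].
#'
#' @param path File path.
#' @param family Outcome family of the stored data.
#' @param delim Field delimiter.
#' @return An `hl_dataset` (reader); the input, invisibly (writer).
#' @export
read_clustered_csv <- function(path, family = c("gaussian", "binomial"),
                               delim = ",") {
  family <- match.arg(family)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 3L) abort("need hospital_id, outcome and >= 1 predictor column")
  names(df)[1:2] <- c("hospital_id", "outcome")
  clustered_dataset(df, family = family)
}

#' @rdname read_clustered_csv
#' @param data An `hl_dataset` to write.
#' @export
write_clustered_csv <- function(data, path, delim = ",") {
  stopifnot(inherits(data, "hl_dataset"))
  readr::write_delim(as_tibble(data), path, delim = delim, progress = FALSE)
  invisible(data)
}
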