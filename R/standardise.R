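# Autoscaling: per-column centering and unit-variance scaling, fitted on
# training data only and applied unchanged to new data.

#' Fit column standardisation statistics
#'
#' Computes per-column means and population (divisor `n`) standard
#' deviations on a training matrix.  Columns with zero variance are
#' flagged; [standardise_apply()] maps them to zero rather than dropping
#' them, so the `p`-point indexing of coefficient vectors is preserved.
#'
#' @param X_train numeric matrix with at least 2 rows.
#' @return A list of class `scaler_stats` with `mean`, `sd` and
#'   `constant_mask` (logical, `TRUE` where `sd == 0`).
#' @export
standardise_fit <- function(X_train) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 2) stop("standardise_fit needs n >= 2 rows")
  mu <- colMeans(X_train)
  sdev <- sqrt(colMeans(sweep(X_train, 2, mu, "-")^2))
  sdev[sdev < 1e-12] <- 0
  structure(list(mean = mu, sd = sdev, constant_mask = sdev == 0),
            class = "scaler_stats")
}

#' Apply fitted standardisation to a matrix
#'
#' @param X numeric matrix whose column count matches `stats`.
#' @param stats a `scaler_stats` object from [standardise_fit()].
#' @return Matrix of the same shape: `(x - mean) / sd` per column, with
#'   constant training columns mapped to 0.
#' @export
standardise_apply <- function(X, stats) {
  stopifnot(inherits(stats, "scaler_stats"))
  X <- as.matrix(X)
  if (ncol(X) != length(stats$mean))
    stop("column count mismatch: X has ", ncol(X), ", scaler expects ",
         length(stats$mean))
  sd_safe <- ifelse(stats$constant_mask, 1, stats$sd)
  Z <- sweep(sweep(X, 2, stats$mean, "-"), 2, sd_safe, "/")
  if (any(stats$constant_mask)) Z[, stats$constant_mask] <- 0
  Z
}

#' Run the full conditioning chain on a fingerprint matrix
#'
#' Convenience pipeline: airPLS baseline removal, COW alignment to a
#' reference, then standardisation statistics fitted on the result.  The
#' first two steps are sample-wise and involve no response, so they may be
#' applied to a full dataset before splitting; the scaler should be
#' refitted per training set.
#'
#' @param fm a [fingerprint_matrix].
#' @param airpls an [airpls_params] object, or `NULL` to skip baseline
#'   removal.
#' @param cow a [cow_params] object, or `NULL` to skip alignment.
#' @return A list with `fm` (conditioned fingerprints) and `scaler`
#'   (fitted [standardise_fit()] statistics on the conditioned matrix).
#' @export
preprocess_fingerprints <- function(fm, airpls = airpls_params(),
                                    cow = cow_params()) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  if (!is.null(airpls)) fm <- correct_baseline(fm, airpls)
  if (!is.null(cow)) fm <- align_set(fm, cow)
  list(fm = fm, scaler = standardise_fit(fm$X))
}
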