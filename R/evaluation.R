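# Performance metrics, goodness grading, one-way ANOVA, and the
# bootstrap out-of-bag experiment harness.

#' Mean squared error
#'
#' `sum((predicted - observed)^2) / m`.  Applied to a held-out set this is
#' the test error; applied to the fitting set it is the training error.
#'
#' @param predicted,observed numeric vectors of equal length (m >= 1).
#' @return Scalar MSE.
#' @export
mse <- function(predicted, observed) {
  if (length(predicted) == 0) stop("mse of empty vectors is undefined")
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ")
  mean((predicted - observed)^2)
}

#' Absolute percent difference between prediction and observation
#'
#' `100 * |predicted - observed| / |observed|`; undefined when the observed
#' value is zero.
#'
#' @param predicted,observed numeric scalars or equal-length vectors;
#'   `observed` must be nonzero.
#' @return Percent difference(s), `>= 0`.
#' @export
percent_difference <- function(predicted, observed) {
  if (any(observed == 0))
    stop("percent difference undefined for observed value 0")
  100 * abs(predicted - observed) / abs(observed)
}

GOODNESS_LABELS <- c("Excellent", "Good", "Acceptable", "Poor")

#' Grade the goodness of a prediction
#'
#' Bins the absolute percent difference between predicted and observed
#' bioactivity: `<= 10` Excellent, `(10, 20]` Good, `(20, 30]` Acceptable,
#' `> 30` Poor.  The 2%-of-mean assay replicate variability motivates the
#' 10% "excellent" threshold.
#'
#' @param pct non-negative percent difference(s).
#' @return Character vector of grades (factor levels Excellent, Good,
#'   Acceptable, Poor).
#' @export
grade_goodness <- function(pct) {
  if (any(pct < 0)) stop("percent difference must be >= 0")
  cut(pct, breaks = c(-Inf, 10, 20, 30, Inf), labels = GOODNESS_LABELS,
      right = TRUE)
}

#' Draw one bootstrap train / out-of-bag test split
#'
#' The training set is `n` draws with replacement from the row indices; the
#' test set is the out-of-bag complement (on average about 36.8% of the
#' rows).  In the rare event that a draw covers every row, the split is
#' redrawn with an incremented sub-seed (recorded in the result).
#'
#' @param n number of rows (>= 2).
#' @param seed integer seed.
#' @return A list of class `split_pair` with `train_indices` (multiset,
#'   length `n`), `test_indices`, `seed` and `redraws`.
#' @export
bootstrap_split <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (n < 2) stop("need n >= 2 for a bootstrap split")
  redraws <- 0L
  repeat {
    train <- withr::with_seed(seed + redraws,
                              sample.int(n, n, replace = TRUE))
    test <- setdiff(seq_len(n), train)
    if (length(test) > 0) break
    redraws <- redraws + 1L
    if (redraws > 1000L) stop("could not draw a split with non-empty OOB set")
  }
  structure(list(train_indices = train, test_indices = test,
                 seed = seed, redraws = redraws),
            class = "split_pair")
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition for `k >= 2` groups, with the
#' F statistic, its upper-tail p-value and the 5% critical value.  The sums
#' of squares are extracted from a standard linear-model fit.
#'
#' @param groups list of `k` numeric vectors, each with at least 2 values.
#' @return A list of class `anova_summary` with `ss_between`, `ss_within`,
#'   `ss_total`, `df_between`, `df_within`, `ms_between`, `ms_within`,
#'   `f_stat`, `p_value`, `f_crit` and a `degenerate` flag (set, with `NA`
#'   F, when the within-group variance is zero).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("one-way ANOVA needs >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  gf <- factor(rep(seq_along(groups), sizes))
  df_b <- length(groups) - 1L
  df_w <- length(values) - length(groups)
  within_var <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                           numeric(1)))
  if (within_var < 1e-300) {
    grand <- mean(values)
    ss_b <- sum(sizes * (vapply(groups, mean, numeric(1)) - grand)^2)
    return(structure(list(ss_between = ss_b, ss_within = 0,
                          ss_total = ss_b, df_between = df_b,
                          df_within = df_w, ms_between = ss_b / df_b,
                          ms_within = 0, f_stat = NA_real_,
                          p_value = NA_real_,
                          f_crit = stats::qf(0.95, df_b, df_w),
                          degenerate = TRUE),
                     class = "anova_summary"))
  }
  tab <- stats::anova(stats::lm(values ~ gf))
  structure(list(ss_between = tab$`Sum Sq`[1], ss_within = tab$`Sum Sq`[2],
                 ss_total = sum(tab$`Sum Sq`), df_between = tab$Df[1],
                 df_within = tab$Df[2], ms_between = tab$`Mean Sq`[1],
                 ms_within = tab$`Mean Sq`[2], f_stat = tab$`F value`[1],
                 p_value = tab$`Pr(>F)`[1],
                 f_crit = stats::qf(0.95, tab$Df[1], tab$Df[2]),
                 degenerate = FALSE),
            class = "anova_summary")
}

#' @export
#' @method print anova_summary
print.anova_summary <- function(x, ...) {
  cat("one-way ANOVA\n")
  cat(sprintf("  %-16s %10s %4s %10s %9s %9s %8s\n",
              "Source", "SS", "df", "MS", "F", "P-value", "F crit"))
  cat(sprintf("  %-16s %10.5f %4d %10.5f %9s %9s %8.5f\n", "Between groups",
              x$ss_between, x$df_between, x$ms_between,
              ifelse(is.na(x$f_stat), "NA", sprintf("%.5f", x$f_stat)),
              ifelse(is.na(x$p_value), "NA", sprintf("%.5f", x$p_value)),
              x$f_crit))
  cat(sprintf("  %-16s %10.5f %4d %10.5f\n", "Within groups",
              x$ss_within, x$df_within, x$ms_within))
  cat(sprintf("  %-16s %10.5f %4d\n", "Total", x$ss_total,
              x$df_between + x$df_within))
  if (x$degenerate) cat("  (degenerate: zero within-group variance)\n")
  invisible(x)
}

MODEL_ORDER <- c("PCR", "PLSR", "OPLS", "EN", "SMLR")

#' Run the bootstrap model-comparison experiment
#'
#' Repeats a bootstrap train / out-of-bag test split `n_splits` times; on
#' each training set fits the four base learners and the stacked model,
#' evaluates test MSE, training MSE, and the mean absolute percent
#' difference on the test set; and compares the five models with one-way
#' ANOVA on the test-MSE columns and on the percent differences (analysed
#' on the proportion scale; the F statistic is scale invariant).
#'
#' Hyperparameters are selected once per training set by internal
#' cross-validation and shared between the standalone base models and the
#' stacking construction.  The scaler is refitted on every training set and
#' applied to its test set.
#'
#' @param X raw (conditioned but unscaled) predictor matrix, `n x p`.
#' @param y response vector (nonzero values, since percent differences are
#'   undefined at 0).
#' @param configs optional named list of four fixed [base_learner_config]s;
#'   `NULL` selects them per training set.
#' @param n_splits number of bootstrap splits (default 10).
#' @param seed master seed; ten child seeds are spawned from it and
#'   recorded in the report.
#' @param n_folds folds for stacking/hyperparameter CV.
#' @param lam_grid meta-model penalty grid.
#' @return An object of class `experiment_report`: list with matrices
#'   `mse_test`, `mse_training`, `mean_pct_difference` (each
#'   `n_splits x 5`, plus a `"Mean"` row), `column_means`, `anova_mse`,
#'   `anova_diff`, `split_seeds` and `seed`.
#' @export
run_experiment <- function(X, y, configs = NULL, n_splits = 10L, seed = 1L,
                           n_folds = 10L,
                           lam_grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1)) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  split_seeds <- withr::with_seed(seed,
                                  sample.int(.Machine$integer.max - 1001L,
                                             n_splits))
  mse_test <- matrix(NA_real_, n_splits, 5,
                     dimnames = list(seq_len(n_splits), MODEL_ORDER))
  mse_train <- mse_test
  pct_diff <- mse_test
  for (s in seq_len(n_splits)) {
    sp <- bootstrap_split(n, split_seeds[s])
    Xtr_raw <- X[sp$train_indices, , drop = FALSE]
    ytr <- y[sp$train_indices]
    Xte_raw <- X[sp$test_indices, , drop = FALSE]
    yte <- y[sp$test_indices]
    scaler <- standardise_fit(Xtr_raw)
    Xtr <- standardise_apply(Xtr_raw, scaler)
    Xte <- standardise_apply(Xte_raw, scaler)
    cfgs <- configs
    if (is.null(cfgs))
      cfgs <- select_all_configs(Xtr, ytr, n_folds = min(n_folds, nrow(Xtr)),
                                 seed = split_seeds[s])
    fits <- lapply(cfgs, function(cfg) fit_base_learner(Xtr, ytr, cfg))
    sm <- fit_smlr(Xtr, ytr, configs = cfgs, n_folds = min(n_folds, nrow(Xtr)),
                   lam_grid = lam_grid, seed = split_seeds[s])
    sm$scaler <- scaler
    all_fits <- c(fits, list(SMLR = sm))
    for (m in seq_along(all_fits)) {
      pr_te <- predict(all_fits[[m]], Xte)
      pr_tr <- predict(all_fits[[m]], Xtr)
      mse_test[s, m] <- mse(pr_te, yte)
      mse_train[s, m] <- mse(pr_tr, ytr)
      pct_diff[s, m] <- mean(percent_difference(pr_te, yte))
    }
  }
  add_mean_row <- function(M) rbind(M, Mean = colMeans(M))
  anova_mse <- one_way_anova(asplit(mse_test, 2))
  anova_diff <- one_way_anova(asplit(pct_diff / 100, 2))
  structure(list(mse_test = add_mean_row(mse_test),
                 mse_training = add_mean_row(mse_train),
                 mean_pct_difference = add_mean_row(pct_diff),
                 column_means = list(mse_test = colMeans(mse_test),
                                     mse_training = colMeans(mse_train),
                                     mean_pct_difference = colMeans(pct_diff)),
                 anova_mse = anova_mse, anova_diff = anova_diff,
                 split_seeds = split_seeds, seed = seed),
            class = "experiment_report")
}

#' @export
#' @method print experiment_report
print.experiment_report <- function(x, ...) {
  cat("bootstrap out-of-bag model comparison\n\n")
  cat("test MSE per split:\n")
  print(round(x$mse_test, 5))
  cat("\nmean percent difference per split (%):\n")
  print(round(x$mean_pct_difference, 4))
  cat("\nANOVA on test MSE:\n")
  print(x$anova_mse)
  cat("\nANOVA on percent differences (proportion scale):\n")
  print(x$anova_diff)
  invisible(x)
}
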