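# The stacking core: out-of-fold meta-training matrix, non-negative ridge
# meta-learner, combined original-space coefficients.

#' Create a balanced cross-validation fold plan
#'
#' Randomly partitions `n` samples into `n_folds` folds whose sizes differ
#' by at most one.  Reproducible for a given seed.
#'
#' @param n sample count (>= `n_folds`).
#' @param n_folds number of folds (default 10).
#' @param seed integer RNG seed.
#' @return A list of class `fold_plan` with `assignments` (length-`n`
#'   integer vector of fold labels), `n_folds` and `seed`.
#' @export
make_fold_plan <- function(n, n_folds = 10L, seed = 1L) {
  n <- as.integer(n); n_folds <- as.integer(n_folds)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n < n_folds) stop("need n >= n_folds (got n = ", n,
                        ", n_folds = ", n_folds, ")")
  assignments <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  structure(list(assignments = assignments, n_folds = n_folds, seed = seed),
            class = "fold_plan")
}

#' Build the out-of-fold meta-training matrix
#'
#' For each fold `j`, fits every base learner on the complement of fold `j`
#' and fills the rows of fold `j` in that learner's column with its
#' held-out predictions.  Every entry is therefore produced by a model that
#' never saw that sample, so the matrix reflects unbiased base-learner
#' performance.
#'
#' @param X standardised predictor matrix, `n x p`.
#' @param y response vector of length `n`.
#' @param plan a [make_fold_plan()] object over the rows of `X`.
#' @param configs named list of four [base_learner_config]s in the order
#'   PCR, PLSR, OPLS, EN.
#' @return A list of class `meta_training_matrix` with `V` (`n x 4` matrix
#'   of out-of-fold predictions), `y` and `learner_order`.
#' @export
build_meta_training <- function(X, y, plan, configs) {
  stopifnot(inherits(plan, "fold_plan"))
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(plan$assignments) != n)
    stop("fold plan covers ", length(plan$assignments),
         " samples but X has ", n, " rows")
  order_k <- names(configs)
  if (is.null(order_k)) order_k <- vapply(configs, `[[`, "", "kind")
  V <- matrix(NA_real_, n, length(configs),
              dimnames = list(NULL, order_k))
  for (j in seq_len(plan$n_folds)) {
    hold <- which(plan$assignments == j)
    Xtr <- X[-hold, , drop = FALSE]; ytr <- y[-hold]
    for (k in seq_along(configs)) {
      fit <- tryCatch(fit_base_learner(Xtr, ytr, configs[[k]]),
                      error = function(e)
                        stop("base learner ", order_k[k], " failed on fold ",
                             j, ": ", conditionMessage(e)))
      V[hold, k] <- predict(fit, X[hold, , drop = FALSE])
    }
  }
  structure(list(V = V, y = y, learner_order = order_k),
            class = "meta_training_matrix")
}

#' Fit the non-negative ridge meta-model
#'
#' Solves `argmin_{alpha >= 0} sum_n (y_n - sum_k alpha_k V_nk)^2
#' + lam * sum_k alpha_k^2` exactly, as non-negative least squares on the
#' design augmented with `sqrt(lam) * I` rows.  There is no intercept, so
#' the weights remain interpretable as model weights.
#'
#' @param meta a `meta_training_matrix` from [build_meta_training()].
#' @param lam ridge penalty `>= 0` on the stacking weights.
#' @return A list of class `meta_model` with `alpha` (named non-negative
#'   weights), `lam` and `learner_order`.
#' @export
fit_nonneg_ridge <- function(meta, lam = 0) {
  stopifnot(inherits(meta, "meta_training_matrix"))
  if (lam < 0) stop("lam must be >= 0")
  V <- meta$V
  if (all(V == 0)) stop("all-zero meta-training matrix")
  k <- ncol(V)
  A <- rbind(V, sqrt(lam) * diag(k))
  b <- c(meta$y, rep(0, k))
  alpha <- tryCatch(pracma::lsqnonneg(A, b)$x, error = function(e) {
    # base predictions can be exactly collinear (PLSR and OPLS often
    # coincide for a single response); at lam = 0 the active-set solve can
    # then hit a singular system — stabilise with a vanishing ridge
    eps <- 1e-10 * max(colSums(V^2))
    pracma::lsqnonneg(rbind(V, sqrt(lam + eps) * diag(k)), b)$x
  })
  alpha[alpha < 0] <- 0   # guard against numerical -0
  names(alpha) <- meta$learner_order
  structure(list(alpha = alpha, lam = lam,
                 learner_order = meta$learner_order),
            class = "meta_model")
}

#' Select the meta-model ridge penalty by cross-validation
#'
#' Evaluates each candidate penalty by cross-validated squared error of the
#' non-negative ridge on the out-of-fold prediction matrix.  Ties break
#' toward the largest penalty (favouring shrinkage, since base-learner
#' predictions are usually strongly correlated).
#'
#' @param meta a `meta_training_matrix`.
#' @param grid numeric vector of candidate penalties (default
#'   `c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1)`).
#' @param plan a [make_fold_plan()] over the rows of `V` (reused from the
#'   stacking construction by default).
#' @return The selected penalty (scalar).
#' @export
select_meta_lambda <- function(meta, grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1),
                               plan = NULL) {
  stopifnot(inherits(meta, "meta_training_matrix"))
  grid <- sort(unique(as.numeric(grid)), decreasing = TRUE)
  if (length(grid) == 0) stop("empty lambda grid")
  if (length(grid) == 1) return(grid)
  n <- nrow(meta$V)
  if (is.null(plan)) plan <- make_fold_plan(n, min(10L, n), seed = 1L)
  cv_sse <- rep(0, length(grid))
  for (j in seq_len(plan$n_folds)) {
    hold <- which(plan$assignments == j)
    sub <- structure(list(V = meta$V[-hold, , drop = FALSE],
                          y = meta$y[-hold],
                          learner_order = meta$learner_order),
                     class = "meta_training_matrix")
    for (g in seq_along(grid)) {
      mm <- fit_nonneg_ridge(sub, grid[g])
      pred <- as.numeric(meta$V[hold, , drop = FALSE] %*% mm$alpha)
      cv_sse[g] <- cv_sse[g] + sum((pred - meta$y[hold])^2)
    }
  }
  best <- 1; best_sse <- cv_sse[1]   # descending grid: ties keep largest
  for (g in seq_along(grid)[-1])
    if (cv_sse[g] < best_sse - 1e-12) {
      best <- g; best_sse <- cv_sse[g]
    }
  grid[best]
}

#' Combine base-learner coefficients with stacking weights
#'
#' The stacked model's coefficients in original predictor space are the
#' alpha-weighted sum of the base learners' coefficient vectors; the
#' intercepts combine with the same weights.
#'
#' @param base_models list of four `fitted_linear_model`s with equal-length
#'   coefficient vectors.
#' @param meta a `meta_model`.
#' @return List with `beta` (length-p vector) and `intercept`.
#' @export
combine_coefficients <- function(base_models, meta) {
  stopifnot(inherits(meta, "meta_model"))
  p <- length(base_models[[1]]$beta)
  for (bm in base_models)
    if (length(bm$beta) != p)
      stop("coefficient length mismatch across base models")
  beta <- rep(0, p); intercept <- 0
  for (k in seq_along(base_models)) {
    beta <- beta + meta$alpha[k] * base_models[[k]]$beta
    intercept <- intercept + meta$alpha[k] * base_models[[k]]$intercept
  }
  list(beta = beta, intercept = intercept)
}

#' Fit a stacked multivariate linear regression model
#'
#' The full stacking procedure: (1) build the out-of-fold meta-training
#' matrix over a 10-fold plan; (2) select the ridge penalty and fit the
#' non-negative ridge meta-model; (3) refit all four base learners on the
#' complete training set; (4) assemble the combined coefficient vector and
#' intercept.
#'
#' @param X standardised predictor matrix, `n x p` with `n >= 12`.
#' @param y response vector of length `n`.
#' @param configs named list of four [base_learner_config]s (order PCR,
#'   PLSR, OPLS, EN), or `NULL` to select hyperparameters by internal
#'   cross-validation on `(X, y)` once, reusing them inside the
#'   meta-training folds.
#' @param n_folds folds for the meta-training construction (default 10).
#' @param lam_grid candidate meta-model penalties.
#' @param seed integer seed controlling fold assignment (and hyperparameter
#'   selection folds).
#' @param normalize_alpha if `TRUE`, rescale the fitted weights to sum to
#'   one; this enforces the guarantee that every stacked prediction lies
#'   within the range of the base-learner predictions (when it is off, the
#'   literal ridge solution is kept).
#' @return An object of class `smlr_model`: list with `base_models`,
#'   `meta`, `beta`, `intercept`, `configs`, `fold_plan` and (optionally
#'   attached by the caller) `scaler`.
#' @export
fit_smlr <- function(X, y, configs = NULL, n_folds = 10L,
                     lam_grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1),
                     seed = 1L, normalize_alpha = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < n_folds + 2L)
    stop("need n >= n_folds + 2 samples for stacking (got ", n, ")")
  if (is.null(configs))
    configs <- select_all_configs(X, y, n_folds = n_folds, seed = seed)
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, `[[`, "", "kind")
  plan <- make_fold_plan(n, n_folds, seed)
  meta_tr <- build_meta_training(X, y, plan, configs)
  lam <- select_meta_lambda(meta_tr, lam_grid, plan)
  meta <- fit_nonneg_ridge(meta_tr, lam)
  if (normalize_alpha) {
    s <- sum(meta$alpha)
    if (s > 0) meta$alpha <- meta$alpha / s
    meta$normalized <- TRUE
  }
  base_models <- lapply(configs, function(cfg) fit_base_learner(X, y, cfg))
  comb <- combine_coefficients(base_models, meta)
  structure(list(base_models = base_models, meta = meta,
                 beta = comb$beta, intercept = comb$intercept,
                 configs = configs, fold_plan = plan, scaler = NULL),
            class = "smlr_model")
}

#' Predict from a stacked model
#'
#' Two mathematically equivalent routes are available: `"meta"` obtains the
#' four base-learner predictions and combines them with the stacking
#' weights; `"coefficients"` applies the combined coefficient vector
#' directly.  They agree to numerical precision.
#'
#' @param object an `smlr_model`.
#' @param X matrix of new samples (standardised with the same scaler as the
#'   training data).
#' @param route `"meta"` (default) or `"coefficients"`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
#' @method predict smlr_model
predict.smlr_model <- function(object, X,
                               route = c("meta", "coefficients"), ...) {
  route <- match.arg(route)
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (route == "coefficients")
    return(as.numeric(object$intercept + X %*% object$beta))
  V <- vapply(object$base_models, function(bm) predict(bm, X),
              numeric(nrow(X)))
  V <- matrix(V, nrow = nrow(X))
  as.numeric(V %*% object$meta$alpha)
}

#' @export
#' @method print smlr_model
print.smlr_model <- function(x, ...) {
  cat("stacked multivariate linear regression model\n")
  cat("  stacking weights (lambda =", format(x$meta$lam), "):\n")
  for (k in seq_along(x$meta$alpha))
    cat(sprintf("    %-5s %.5f\n", x$meta$learner_order[k], x$meta$alpha[k]))
  cat(sprintf("  p = %d predictors\n", length(x$beta)))
  invisible(x)
}
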