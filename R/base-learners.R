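# The four linear base learners.  All of them return the same structure: a
# coefficient vector in the (standardised) predictor space plus an
# intercept, so downstream code can treat them interchangeably.  The
# response is mean-centered inside each learner and the mean restored in
# the intercept; X is assumed to be standardised upstream.

BASE_LEARNER_KINDS <- c("PCR", "PLSR", "OPLS", "EN")

#' Base learner configuration
#'
#' @param kind one of `"PCR"`, `"PLSR"`, `"OPLS"`, `"EN"`.
#' @param n_components latent-variable count for PCR/PLSR; for OPLS the
#'   total count (1 predictive + `n_components - 1` orthogonal).
#' @param en_l1,en_l2 elastic-net penalty weights (>= 0) on the l1 norm and
#'   half the squared l2 norm of the coefficients.
#' @param selection `"fixed"` (use as given) or `"cv"` (was chosen by
#'   cross-validation; informational).
#' @return A list of class `base_learner_config`.
#' @export
base_learner_config <- function(kind, n_components = NULL,
                                en_l1 = NULL, en_l2 = NULL,
                                selection = "fixed") {
  kind <- match.arg(kind, BASE_LEARNER_KINDS)
  if (kind == "EN") {
    if (is.null(en_l1)) en_l1 <- 0
    if (is.null(en_l2)) en_l2 <- 0
    if (en_l1 < 0 || en_l2 < 0) stop("elastic-net penalties must be >= 0")
  } else {
    if (is.null(n_components)) n_components <- 2L
    n_components <- as.integer(n_components)
    if (n_components < 1) stop("n_components must be >= 1")
  }
  structure(list(kind = kind, n_components = n_components,
                 en_l1 = en_l1, en_l2 = en_l2, selection = selection),
            class = "base_learner_config")
}

new_fitted_linear_model <- function(kind, beta, intercept, hyperparams,
                                    X, y) {
  beta <- as.numeric(beta)
  if (any(!is.finite(beta)) || !is.finite(intercept))
    stop(kind, ": non-finite coefficients")
  fit <- structure(list(kind = kind, beta = beta,
                        intercept = as.numeric(intercept),
                        hyperparams = hyperparams, train_mse = NA_real_),
                   class = "fitted_linear_model")
  fit$train_mse <- mse(predict(fit, X), y)
  fit
}

#' Predict from a fitted linear model
#'
#' All base learners are affine: `prediction = intercept + X %*% beta`.
#'
#' @param object a `fitted_linear_model`.
#' @param X numeric matrix with `length(beta)` columns (or a single row
#'   vector).
#' @param ... unused.
#' @return Numeric vector of predictions, one per row of `X`.
#' @export
#' @method predict fitted_linear_model
predict.fitted_linear_model <- function(object, X, ...) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(object$beta))
    stop("X has ", ncol(X), " columns; model expects ", length(object$beta))
  as.numeric(object$intercept + X %*% object$beta)
}

#' @export
#' @method print fitted_linear_model
print.fitted_linear_model <- function(x, ...) {
  cat(sprintf("%s model: p = %d, train MSE = %.5g\n",
              x$kind, length(x$beta), x$train_mse))
  invisible(x)
}

# -- internal path fitters (centered data in, per-component betas out) ------

# PCR: regress centered y on the leading principal-component scores of
# centered X, then fold loadings back into original-space coefficients.
.pcr_path <- function(Xc, yc, max_comp) {
  sv <- svd(Xc, nu = max_comp, nv = max_comp)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  a_max <- min(max_comp, rank)
  if (a_max < 1) stop("degenerate predictor matrix: rank 0 after centering")
  betas <- matrix(0, ncol(Xc), a_max)
  # scores are orthogonal, so the regression is a per-component projection
  g <- numeric(a_max)
  for (a in seq_len(a_max)) {
    ta <- sv$u[, a] * sv$d[a]
    g[a] <- sum(ta * yc) / sv$d[a]^2
    betas[, a] <- if (a == 1) sv$v[, 1] * g[1] else
      betas[, a - 1] + sv$v[, a] * g[a]
  }
  list(betas = betas, achieved = a_max)
}

# PLS1 (NIPALS, single response): sequential deflation of X only; each
# weight vector maximises covariance with the current response residual.
.pls1_path <- function(Xc, yc, max_comp, tol = 1e-12) {
  p <- ncol(Xc)
  E <- Xc
  W <- matrix(0, p, 0); P <- matrix(0, p, 0); q <- numeric(0)
  for (a in seq_len(max_comp)) {
    w <- as.numeric(crossprod(E, yc))
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t_sc <- as.numeric(E %*% w)
    tt <- sum(t_sc^2)
    if (tt < tol) break
    p_load <- as.numeric(crossprod(E, t_sc)) / tt
    q_a <- sum(yc * t_sc) / tt
    E <- E - tcrossprod(t_sc, p_load)
    W <- cbind(W, w); P <- cbind(P, p_load); q <- c(q, q_a)
  }
  achieved <- ncol(W)
  if (achieved < 1)   # no covariance between X and y: the null model
    return(list(betas = matrix(0, p, 1), achieved = 1L, degenerate = TRUE))
  betas <- matrix(0, p, achieved)
  for (a in seq_len(achieved)) {
    Ra <- W[, 1:a, drop = FALSE] %*%
      solve(crossprod(P[, 1:a, drop = FALSE], W[, 1:a, drop = FALSE]))
    betas[, a] <- Ra %*% q[1:a]
  }
  list(betas = betas, achieved = achieved)
}

# OPLS (single response): strip successive X-variation components that are
# orthogonal to y, then fit a 1-component PLS on the filtered matrix.
# Column a of the returned betas is the model with (a - 1) orthogonal
# components.
.opls_path <- function(Xc, yc, max_ortho, tol = 1e-12) {
  p <- ncol(Xc)
  w <- as.numeric(crossprod(Xc, yc))
  nw <- sqrt(sum(w^2))
  if (nw < tol)       # no covariance between X and y: the null model
    return(list(betas = matrix(0, p, 1), achieved = 1L, degenerate = TRUE))
  w <- w / nw
  E <- Xc
  betas <- matrix(0, p, max_ortho + 1)
  w_orth <- matrix(0, p, 0); p_orth <- matrix(0, p, 0)
  for (k in 0:max_ortho) {
    b1 <- .pls1_path(E, yc, 1L)$betas[, 1]
    # map the filtered-space coefficients back through the deflations
    if (k > 0)
      for (i in k:1)
        b1 <- b1 - w_orth[, i] * sum(p_orth[, i] * b1)
    betas[, k + 1] <- b1
    if (k == max_ortho) break
    t_sc <- as.numeric(E %*% w)
    p_load <- as.numeric(crossprod(E, t_sc)) / sum(t_sc^2)
    wo <- p_load - sum(w * p_load) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) {  # no orthogonal structure left
      betas <- betas[, 1:(k + 1), drop = FALSE]
      break
    }
    wo <- wo / nwo
    to <- as.numeric(E %*% wo)
    po <- as.numeric(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    w_orth <- cbind(w_orth, wo); p_orth <- cbind(p_orth, po)
  }
  list(betas = betas, achieved = ncol(betas))
}

.center <- function(X, y) {
  xbar <- colMeans(X)
  ybar <- mean(y)
  list(Xc = sweep(X, 2, xbar, "-"), yc = y - ybar, xbar = xbar, ybar = ybar)
}

.latent_fit <- function(X, y, config, path_fun, n_requested) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < 2) stop("need n >= 2 samples")
  cen <- .center(X, y)
  if (all(abs(cen$Xc) < 1e-14))
    stop("degenerate predictor matrix: all rows equal")
  path <- path_fun(cen$Xc, cen$yc)
  a <- min(n_requested, path$achieved)
  if (a < n_requested)
    warning(config$kind, ": reduced components from ", n_requested,
            " to ", a, " (rank/degeneracy limit)")
  beta <- path$betas[, a]
  hp <- config
  hp$n_components_achieved <- if (config$kind == "OPLS") a else a
  new_fitted_linear_model(config$kind, beta,
                          cen$ybar - sum(cen$xbar * beta), hp, X, y)
}

#' Fit principal component regression
#'
#' Projects column-centered X onto its leading principal components and
#' regresses y on the scores, folding the loadings back into an
#' original-space coefficient vector.
#'
#' @param X predictor matrix (standardised), `n x p`.
#' @param y response vector of length `n`.
#' @param config a [base_learner_config] with `kind = "PCR"`; its
#'   `n_components` is capped at the rank of centered `X` (with a warning).
#' @return A `fitted_linear_model`.
#' @export
fit_pcr <- function(X, y, config = base_learner_config("PCR")) {
  stopifnot(config$kind == "PCR")
  nc <- config$n_components
  .latent_fit(X, y, config,
              function(Xc, yc) .pcr_path(Xc, yc, nc), nc)
}

#' Fit partial least squares regression (PLS1)
#'
#' NIPALS-type sequential deflation for a single response: each latent
#' direction maximises covariance with the current response residual; only
#' X is deflated.  Degenerate (zero-covariance) steps stop the sequence
#' early, recording the achieved component count.
#'
#' @inheritParams fit_pcr
#' @param config a [base_learner_config] with `kind = "PLSR"`.
#' @return A `fitted_linear_model`.
#' @export
fit_plsr <- function(X, y, config = base_learner_config("PLSR")) {
  stopifnot(config$kind == "PLSR")
  nc <- config$n_components
  .latent_fit(X, y, config,
              function(Xc, yc) .pls1_path(Xc, yc, nc), nc)
}

#' Fit orthogonal projections to latent structures (OPLS)
#'
#' Removes `n_components - 1` components of X-variation orthogonal to y,
#' then fits a one-component PLS on the filtered matrix.  For a single
#' response this gives training predictions identical to PLSR with
#' `n_components` components.
#'
#' @inheritParams fit_pcr
#' @param config a [base_learner_config] with `kind = "OPLS"`;
#'   `n_components` counts 1 predictive plus `n_components - 1` orthogonal
#'   components.
#' @return A `fitted_linear_model`.
#' @export
fit_opls <- function(X, y, config = base_learner_config("OPLS")) {
  stopifnot(config$kind == "OPLS")
  nc <- config$n_components
  .latent_fit(X, y, config,
              function(Xc, yc) .opls_path(Xc, yc, nc - 1L), nc)
}

# translate (en_l1, en_l2) into glmnet's (alpha, lambda).  glmnet's printed
# objective is lambda * (alpha |b|_1 + (1-alpha)/2 |b|_2^2), but because it
# standardises y internally the ridge term it actually applies is scaled by
# 1/sd(y) relative to the l1 term; the mapping compensates so that the
# stated (en_l1, en_l2) objective is solved exactly.
.en_to_glmnet <- function(en_l1, en_l2, y) {
  sdy <- sqrt(mean((y - mean(y))^2))
  lam <- en_l1 + en_l2 * sdy
  alpha <- ifelse(lam > 0, en_l1 / pmax(lam, .Machine$double.xmin), 1)
  list(alpha = alpha, lambda = lam)
}

.glmnet_to_en <- function(alpha, lambda, y) {
  sdy <- sqrt(mean((y - mean(y))^2))
  list(en_l1 = lambda * alpha,
       en_l2 = if (sdy > 0) lambda * (1 - alpha) / sdy else lambda * (1 - alpha))
}

#' Fit an elastic net
#'
#' Minimises `||y - b0 - X b||^2 / (2n) + en_l1 ||b||_1 + en_l2 ||b||_2^2 / 2`
#' by coordinate descent (via \pkg{glmnet}; columns are not re-scaled, X is
#' assumed standardised).  With both penalties zero the exact least-squares
#' solution is returned.
#'
#' @inheritParams fit_pcr
#' @param config a [base_learner_config] with `kind = "EN"`.
#' @return A `fitted_linear_model`.
#' @export
fit_en <- function(X, y, config = base_learner_config("EN")) {
  stopifnot(config$kind == "EN")
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < 2) stop("need n >= 2 samples")
  if (stats::sd(y) == 0)   # constant response: the null model
    return(new_fitted_linear_model("EN", rep(0, ncol(X)), mean(y), config,
                                   X, y))
  if (config$en_l1 == 0 && config$en_l2 == 0) {
    fit <- stats::lm.fit(cbind(1, X), y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    return(new_fitted_linear_model("EN", cf[-1], cf[1], config, X, y))
  }
  if (ncol(X) < 2) stop("elastic net needs >= 2 predictors")
  gp <- .en_to_glmnet(config$en_l1, config$en_l2, y)
  gfit <- glmnet::glmnet(X, y, alpha = gp$alpha,
                         lambda = .lambda_path_to(gp$lambda),
                         standardize = FALSE, thresh = 1e-12)
  # the warm-started path ends exactly at the target lambda, so the last
  # path solution is the requested one (no interpolation involved)
  cf <- as.numeric(glmnet::coef.glmnet(gfit, s = gp$lambda))
  new_fitted_linear_model("EN", cf[-1], cf[1], config, X, y)
}

# a short decreasing path ending at the target lambda; glmnet's coordinate
# descent warm-starts along it and is more reliable than a length-1 path
.lambda_path_to <- function(lambda) {
  if (lambda <= 0) return(NULL)
  exp(seq(log(lambda * 100), log(lambda), length.out = 10))
}

#' Fit any base learner from its configuration
#'
#' @inheritParams fit_pcr
#' @param config a [base_learner_config] of any kind.
#' @return A `fitted_linear_model`.
#' @export
fit_base_learner <- function(X, y, config) {
  switch(config$kind,
         PCR = fit_pcr(X, y, config),
         PLSR = fit_plsr(X, y, config),
         OPLS = fit_opls(X, y, config),
         EN = fit_en(X, y, config),
         stop("unknown learner kind: ", config$kind))
}

# -- hyperparameter selection ------------------------------------------------

#' Select base-learner hyperparameters by cross-validation
#'
#' Picks the grid point minimising the mean cross-validated squared error.
#' Ties break toward the simpler model: fewer latent components, or (for
#' the elastic net) the larger penalty.
#'
#' For the latent-variable learners the default grid is component counts
#' `1 .. min(15, n - 2)`; for the elastic net it is the l1 fraction
#' `{0.1, 0.5, 0.9}` crossed with a 10-point logarithmic penalty-strength
#' path descending from the smallest penalty that zeroes every coefficient.
#'
#' @param X predictor matrix (standardised), `n x p`.
#' @param y response vector.
#' @param kind learner kind, one of `"PCR"`, `"PLSR"`, `"OPLS"`, `"EN"`.
#' @param grid for latent learners an integer vector of component counts;
#'   for `"EN"` a data frame with columns `en_l1`, `en_l2`.  `NULL` uses
#'   the defaults above.
#' @param n_folds number of CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return A resolved [base_learner_config] with `selection = "cv"`.
#' @export
select_hyperparameters <- function(X, y, kind, grid = NULL, n_folds = 10L,
                                   seed = 1L) {
  kind <- match.arg(kind, BASE_LEARNER_KINDS)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  n_folds <- min(as.integer(n_folds), n)
  plan <- make_fold_plan(n, n_folds, seed)
  if (kind == "EN")
    .select_en(X, y, grid, plan)
  else
    .select_latent(X, y, kind, grid, plan)
}

.select_latent <- function(X, y, kind, grid, plan) {
  n <- nrow(X)
  if (is.null(grid)) grid <- seq_len(max(1L, min(15L, n - 2L)))
  grid <- sort(unique(as.integer(grid)))
  if (length(grid) == 0) stop("empty hyperparameter grid")
  max_comp <- max(grid)
  path_fun <- switch(kind,
                     PCR = function(Xc, yc) .pcr_path(Xc, yc, max_comp),
                     PLSR = function(Xc, yc) .pls1_path(Xc, yc, max_comp),
                     OPLS = function(Xc, yc) .opls_path(Xc, yc, max_comp - 1L))
  sse <- rep(0, max_comp); m_ok <- rep(0L, max_comp)
  achieved_min <- max_comp
  for (j in seq_len(plan$n_folds)) {
    hold <- which(plan$assignments == j)
    Xtr <- X[-hold, , drop = FALSE]; ytr <- y[-hold]
    cen <- .center(Xtr, ytr)
    path <- path_fun(cen$Xc, cen$yc)
    achieved_min <- min(achieved_min, path$achieved)
    Xh <- sweep(X[hold, , drop = FALSE], 2, cen$xbar, "-")
    pred <- Xh %*% path$betas + cen$ybar   # one column per component count
    err <- (pred - y[hold])^2
    a_ok <- seq_len(path$achieved)
    sse[a_ok] <- sse[a_ok] + colSums(err[, a_ok, drop = FALSE])
    m_ok[a_ok] <- m_ok[a_ok] + length(hold)
  }
  usable <- grid[grid <= achieved_min]
  if (length(usable) == 0)
    stop("no grid point achievable on every fold for ", kind)
  cv_mse <- sse[usable] / m_ok[usable]
  best <- usable[1]; best_mse <- cv_mse[1]
  for (i in seq_along(usable)[-1])         # ascending: ties keep the
    if (cv_mse[i] < best_mse - 1e-12) {    # smaller component count
      best <- usable[i]; best_mse <- cv_mse[i]
    }
  cfg <- base_learner_config(kind, n_components = best, selection = "cv")
  cfg$cv_mse <- best_mse
  cfg
}

# the default candidate set lives in glmnet's (alpha, lambda)
# parameterisation: l1 fraction {0.1, 0.5, 0.9} crossed with a 10-point
# log-spaced strength path descending from the all-zero penalty
.default_en_grid <- function(X, y) {
  yc <- y - mean(y)
  n <- nrow(X)
  grids <- lapply(c(0.1, 0.5, 0.9), function(a) {
    lam_max <- max(max(abs(crossprod(X, yc))) / (n * a), 1e-6)
    data.frame(alpha = a,
               lambda = exp(seq(log(lam_max), log(lam_max * 1e-3),
                                length.out = 10)))
  })
  do.call(rbind, grids)
}

.select_en <- function(X, y, grid, plan) {
  if (is.null(grid)) {
    grid <- .default_en_grid(X, y)
  } else {
    gp <- .en_to_glmnet(grid$en_l1, grid$en_l2, y)
    grid <- data.frame(alpha = gp$alpha, lambda = gp$lambda,
                       en_l1 = grid$en_l1, en_l2 = grid$en_l2)
  }
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  alphas <- unique(grid$alpha)
  sse <- rep(0, nrow(grid)); m_ok <- rep(0L, nrow(grid))
  for (j in seq_len(plan$n_folds)) {
    hold <- which(plan$assignments == j)
    Xtr <- X[-hold, , drop = FALSE]; ytr <- y[-hold]
    for (a in alphas) {
      rows <- which(grid$alpha == a)
      lam_seq <- sort(unique(grid$lambda[rows]), decreasing = TRUE)
      gfit <- glmnet::glmnet(Xtr, ytr, alpha = a, lambda = lam_seq,
                             standardize = FALSE, thresh = 1e-9)
      pred <- glmnet::predict.glmnet(gfit, X[hold, , drop = FALSE],
                                     s = grid$lambda[rows])
      err <- sweep(pred, 1, y[hold], "-")^2
      sse[rows] <- sse[rows] + colSums(err)
      m_ok[rows] <- m_ok[rows] + length(hold)
    }
  }
  cv_mse <- sse / m_ok
  # ties prefer the larger penalty strength (strongest regularisation)
  ord <- order(-grid$lambda, grid$alpha)
  best <- ord[1]; best_mse <- cv_mse[ord[1]]
  for (i in ord[-1])
    if (cv_mse[i] < best_mse - 1e-12) {
      best <- i; best_mse <- cv_mse[i]
    }
  if (is.null(grid$en_l1)) {
    en <- .glmnet_to_en(grid$alpha[best], grid$lambda[best], y)
  } else {
    en <- list(en_l1 = grid$en_l1[best], en_l2 = grid$en_l2[best])
  }
  cfg <- base_learner_config("EN", en_l1 = en$en_l1, en_l2 = en$en_l2,
                             selection = "cv")
  cfg$cv_mse <- best_mse
  cfg
}

#' Select configurations for all four base learners
#'
#' Runs [select_hyperparameters()] for PCR, PLSR, OPLS and EN on one
#' training set.
#'
#' @inheritParams select_hyperparameters
#' @return Named list of four resolved [base_learner_config] objects, in
#'   the canonical order PCR, PLSR, OPLS, EN.
#' @export
select_all_configs <- function(X, y, n_folds = 10L, seed = 1L) {
  out <- lapply(BASE_LEARNER_KINDS, function(k)
    select_hyperparameters(X, y, k, n_folds = n_folds, seed = seed))
  names(out) <- BASE_LEARNER_KINDS
  out
}
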