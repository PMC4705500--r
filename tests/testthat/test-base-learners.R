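# The four base learners and their oracle equivalences.

test_that("PCR and PLSR reduce to OLS at full rank", {
  withr::with_seed(42, {
    X <- matrix(rnorm(60), 12, 5)
    y <- rnorm(12)
  })
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  for (fit in list(fit_pcr(X, y, base_learner_config("PCR", 5)),
                   fit_plsr(X, y, base_learner_config("PLSR", 5)))) {
    expect_equal(unname(c(fit$intercept, fit$beta)), unname(ols),
                 tolerance = 1e-8)
    expect_equal(predict(fit, X), as.numeric(cbind(1, X) %*% ols),
                 tolerance = 1e-8)
  }
})

test_that("constant responses give the null model", {
  withr::with_seed(1, X <- matrix(rnorm(40), 8, 5))
  y <- rep(3.5, 8)
  for (kind in c("PCR", "PLSR", "OPLS")) {
    # degenerate component requests shrink with a warning
    fit <- suppressWarnings(fit_base_learner(X, y, base_learner_config(kind, 2)))
    expect_lt(max(abs(fit$beta)), 1e-10)
    expect_equal(fit$intercept, 3.5, tolerance = 1e-10)
  }
})

test_that("PCR with one dominant signal-bearing component fits in 1 LV", {
  withr::with_seed(9, {
    n <- 20; p <- 30
    dir <- rnorm(p); dir <- dir / sqrt(sum(dir^2))
    scores <- rnorm(n, 0, 5)                # dominant variance direction
    X <- outer(scores, dir) + matrix(rnorm(n * p, 0, 0.01), n, p)
    y <- 2 * scores
  })
  fit <- fit_pcr(X, y, base_learner_config("PCR", 1))
  r2 <- 1 - fit$train_mse / mean((y - mean(y))^2)
  expect_gt(r2, 0.99)
})

test_that("PLSR special cases: p = 1 slope and orthonormal columns", {
  withr::with_seed(3, { x <- rnorm(15); y <- 2 * x + rnorm(15) })
  fit <- fit_plsr(matrix(x), y, base_learner_config("PLSR", 1))
  expect_equal(fit$beta, cov(x, y) * (14 / 15) / (var(x) * 14 / 15),
               tolerance = 1e-10)

  # orthonormal centered columns, 1 component: beta proportional to X'y
  withr::with_seed(4, M <- matrix(rnorm(100), 20, 5))
  Q <- qr.Q(qr(sweep(M, 2, colMeans(M))))
  yq <- withr::with_seed(5, rnorm(20))
  fit1 <- fit_plsr(Q, yq, base_learner_config("PLSR", 1))
  xy <- as.numeric(crossprod(Q, yq - mean(yq)))
  expect_lt(max(abs(fit1$beta / xy - fit1$beta[1] / xy[1])), 1e-8)
})

test_that("single-response OPLS(1 + k) equals PLSR(k + 1) predictions", {
  withr::with_seed(10, {
    X <- matrix(rnorm(80), 10, 8)
    y <- rnorm(10)
  })
  for (k in 0:3) {
    opls <- fit_opls(X, y, base_learner_config("OPLS", k + 1L))
    plsr <- fit_plsr(X, y, base_learner_config("PLSR", k + 1L))
    expect_lt(max(abs(predict(opls, X) - predict(plsr, X))), 1e-6)
  }
  # rank-1 X aligned with y: nothing orthogonal to remove
  withr::with_seed(11, {
    s <- rnorm(12); d <- rnorm(6)
    X1 <- outer(s, d); y1 <- 3 * s
  })
  o <- suppressWarnings(fit_opls(X1, y1, base_learner_config("OPLS", 2)))
  p1 <- fit_plsr(X1, y1, base_learner_config("PLSR", 1))
  expect_equal(suppressWarnings(predict(o, X1)), predict(p1, X1),
               tolerance = 1e-8)
})

test_that("elastic net limits: OLS at zero penalty, null at the death point", {
  withr::with_seed(42, {
    X <- matrix(rnorm(60), 12, 5)
    y <- rnorm(12)
  })
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  e0 <- fit_en(X, y, base_learner_config("EN", en_l1 = 0, en_l2 = 0))
  expect_equal(unname(c(e0$intercept, e0$beta)), unname(ols),
               tolerance = 1e-6)

  lmax <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  e1 <- fit_en(X, y, base_learner_config("EN", en_l1 = lmax * 1.001,
                                         en_l2 = 0))
  expect_equal(e1$beta, rep(0, 5))
  expect_equal(e1$intercept, mean(y), tolerance = 1e-10)
})

test_that("elastic net matches a brute-force grid oracle", {
  withr::with_seed(8, {
    X <- matrix(rnorm(60), 20, 3)
    X <- sweep(X, 2, colMeans(X))          # centered: intercept = mean(y)
    b_true <- c(1, -0.5, 0)
    y <- as.numeric(X %*% b_true) + rnorm(20, 0, 0.1)
  })
  l1 <- 0.05; l2 <- 0.05
  fit <- fit_en(X, y, base_learner_config("EN", en_l1 = l1, en_l2 = l2))
  # coarse global grid, then refinement around its optimum
  obj <- function(b) en_objective(X, y, mean(y), b, l1, l2)
  grid_opt <- function(centre, half, step) {
    axes <- lapply(centre, function(c0) seq(c0 - half, c0 + half, by = step))
    g <- as.matrix(expand.grid(axes))
    vals <- apply(g, 1, obj)
    g[which.min(vals), ]
  }
  b_coarse <- grid_opt(c(0, 0, 0), 1.5, 0.05)
  b_fine <- grid_opt(b_coarse, 0.06, 0.002)
  b_finest <- grid_opt(b_fine, 0.0025, 1e-4)
  expect_lt(max(abs(fit$beta - b_finest)), 1e-3)
  expect_lte(obj(fit$beta), obj(b_finest) + 1e-8)
})

test_that("elastic net solutions satisfy the KKT conditions", {
  withr::with_seed(12, {
    X <- matrix(rnorm(200), 20, 10)
    y <- as.numeric(X[, 1] - X[, 2]) + rnorm(20, 0, 0.2)
  })
  for (pen in list(c(0.02, 0.01), c(0.1, 0), c(0.01, 0.1))) {
    fit <- fit_en(X, y, base_learner_config("EN", en_l1 = pen[1],
                                            en_l2 = pen[2]))
    r <- y - fit$intercept - as.numeric(X %*% fit$beta)
    grad <- -as.numeric(crossprod(X, r)) / nrow(X) + pen[2] * fit$beta
    active <- abs(fit$beta) > 1e-12
    expect_lt(max(abs(grad[active] + pen[1] * sign(fit$beta[active])), 0),
              1e-6)
    expect_lt(max(abs(grad[!active]), 0), pen[1] + 1e-6)
    expect_lt(max(abs(mean(r)), 0), 1e-8)   # intercept stationarity
  }
})

test_that("stored coefficients reproduce training predictions exactly", {
  withr::with_seed(20, {
    X <- matrix(rnorm(25 * 12), 25, 12)
    y <- rnorm(25)
  })
  cfgs <- list(base_learner_config("PCR", 4),
               base_learner_config("PLSR", 4),
               base_learner_config("OPLS", 3),
               base_learner_config("EN", en_l1 = 0.05, en_l2 = 0.02))
  for (cfg in cfgs) {
    fit <- fit_base_learner(X, y, cfg)
    manual <- fit$intercept + as.numeric(X %*% fit$beta)
    expect_lt(max(abs(predict(fit, X) - manual)), 1e-8)
    # exact affine linearity
    x1 <- X[1, ]; x2 <- X[2, ]; a <- 0.3
    expect_equal(predict(fit, a * x1 + (1 - a) * x2),
                 a * predict(fit, x1) + (1 - a) * predict(fit, x2),
                 tolerance = 1e-10)
  }
})

test_that("prediction validates dimensions and handles trivial models", {
  fit <- structure(list(kind = "PCR", beta = rep(0, 4), intercept = 2.5,
                        hyperparams = NULL, train_mse = 0),
                   class = "fitted_linear_model")
  expect_equal(predict(fit, matrix(rnorm(12), 3, 4)), rep(2.5, 3))
  expect_error(predict(fit, matrix(1, 1, 3)), "expects")
})

test_that("CV hyperparameter selection finds planted structure", {
  # one grid point returns that point
  withr::with_seed(2, { X <- matrix(rnorm(200), 20, 10); y <- rnorm(20) })
  cfg <- select_hyperparameters(X, y, "PLSR", grid = 3, seed = 1)
  expect_equal(cfg$n_components, 3L)
  engrid <- data.frame(en_l1 = 0.1, en_l2 = 0.2)
  cfg_en <- select_hyperparameters(X, y, "EN", grid = engrid, seed = 1)
  expect_equal(c(cfg_en$en_l1, cfg_en$en_l2), c(0.1, 0.2))

  # noiseless rank-2 truth: PLSR CV picks 2 components
  withr::with_seed(30, {
    n <- 40; p <- 15
    T2 <- matrix(rnorm(n * 2), n, 2) %*% diag(c(3, 2))
    P2 <- matrix(rnorm(2 * p), 2, p)
    X2 <- T2 %*% P2
    y2 <- as.numeric(T2 %*% c(1, -1))
  })
  sel <- select_hyperparameters(X2, y2, "PLSR", grid = 1:6, seed = 4)
  expect_equal(sel$n_components, 2L)
})

test_that("on pure noise, EN selection drifts to the strongest penalties", {
  hits <- 0L
  for (seed in 1:20) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(30 * 20), 30, 20)
      y <- rnorm(30)
    })
    cfg <- select_hyperparameters(X, y, "EN", seed = seed)
    grid <- smlr:::.default_en_grid(X, y)
    sdy <- sqrt(mean((y - mean(y))^2))
    strength <- cfg$en_l1 + cfg$en_l2 * sdy    # glmnet-scale penalty
    # in the top quartile of the penalty-strength grid
    if (strength >= stats::quantile(grid$lambda, 0.75))
      hits <- hits + 1L
  }
  expect_gte(hits, 11L)
})
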