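# Fold plans, the out-of-fold meta matrix, the non-negative ridge
# meta-learner, and the assembled stacked model.

test_that("fold plans are balanced and reproducible", {
  p1 <- make_fold_plan(20, 10, seed = 1)
  expect_equal(as.integer(table(p1$assignments)), rep(2L, 10))

  p2 <- make_fold_plan(23, 10, seed = 1)
  sizes <- as.integer(table(p2$assignments))
  expect_true(all(sizes %in% 2:3))
  expect_lte(diff(range(sizes)), 1L)

  expect_identical(make_fold_plan(23, 10, seed = 5)$assignments,
                   make_fold_plan(23, 10, seed = 5)$assignments)
  differing <- vapply(1:10, function(s)
    !identical(make_fold_plan(23, 10, seed = s)$assignments,
               make_fold_plan(23, 10, seed = s + 100)$assignments),
    logical(1))
  expect_gte(sum(differing), 9L)

  expect_error(make_fold_plan(5, 10), "n >= n_folds")
})

test_that("meta-training entries are fold-complement predictions", {
  # with zero X-y covariance every learner predicts the training mean, so
  # column entries must equal the fold-complement means of y
  withr::with_seed(6, X <- matrix(rnorm(200), 20, 10))
  y <- rep(c(1, 2), each = 10)
  plan <- make_fold_plan(20, 5, seed = 2)
  cfg <- list(PLSR = base_learner_config("PLSR", 1))
  # make y carry no information about X by using constant y per learner run
  y_const <- rep(4, 20)
  mt <- build_meta_training(X, y_const, plan, cfg)
  for (j in 1:5) {
    hold <- which(plan$assignments == j)
    expect_equal(unname(mt$V[hold, 1]), rep(mean(y_const[-hold]), length(hold)),
                 tolerance = 1e-10)
  }

  # shape and completeness on the full four-learner set
  withr::with_seed(7, yr <- rnorm(20))
  cfgs <- list(PCR = base_learner_config("PCR", 2),
               PLSR = base_learner_config("PLSR", 2),
               OPLS = base_learner_config("OPLS", 2),
               EN = base_learner_config("EN", en_l1 = 0.05, en_l2 = 0.05))
  mt4 <- build_meta_training(X, yr, plan, cfgs)
  expect_equal(dim(mt4$V), c(20L, 4L))
  expect_false(anyNA(mt4$V))
  expect_identical(mt4$learner_order, c("PCR", "PLSR", "OPLS", "EN"))
})

test_that("rich learners track a noiseless linear response out of fold", {
  withr::with_seed(8, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    y <- as.numeric(X %*% c(1, -2, 0.5, 0, 0, 1))
  })
  plan <- make_fold_plan(40, 10, seed = 3)
  cfgs <- list(PCR = base_learner_config("PCR", 6),
               PLSR = base_learner_config("PLSR", 6),
               OPLS = base_learner_config("OPLS", 6),
               EN = base_learner_config("EN", en_l1 = 0, en_l2 = 0))
  mt <- build_meta_training(X, y, plan, cfgs)
  for (k in 1:4) {
    r2 <- 1 - mean((mt$V[, k] - y)^2) / mean((y - mean(y))^2)
    expect_gt(r2, 0.95)
  }
})

test_that("out-of-fold purity: permuted responses kill the association", {
  withr::with_seed(13, {
    X <- matrix(rnorm(40 * 30), 40, 30)
    y <- as.numeric(X %*% c(rep(1, 5), rep(0, 25))) + rnorm(40, 0, 0.1)
    y_perm <- sample(y)
  })
  plan <- make_fold_plan(40, 10, seed = 9)
  cfgs <- list(PCR = base_learner_config("PCR", 3),
               PLSR = base_learner_config("PLSR", 3),
               OPLS = base_learner_config("OPLS", 2),
               EN = base_learner_config("EN", en_l1 = 0.05, en_l2 = 0.05))
  mt <- build_meta_training(X, y_perm, plan, cfgs)
  r2 <- vapply(1:4, function(k)
    max(0, 1 - mean((mt$V[, k] - y_perm)^2) / mean((y_perm - mean(y_perm))^2)),
    numeric(1))
  expect_lt(mean(r2), 0.1)
})

test_that("non-negative ridge meta-learner solves the constrained problem", {
  withr::with_seed(14, y <- rnorm(25) + 2)
  mt1 <- structure(list(V = cbind(perfect = y), y = y,
                        learner_order = "perfect"),
                   class = "meta_training_matrix")
  expect_equal(unname(fit_nonneg_ridge(mt1, 0)$alpha), 1, tolerance = 1e-10)

  mt2 <- structure(list(V = cbind(anti = -y), y = y, learner_order = "anti"),
                   class = "meta_training_matrix")
  expect_equal(unname(fit_nonneg_ridge(mt2, 0)$alpha), 0)

  # k = 2 against a fine non-negative grid oracle at lam = 0.1
  withr::with_seed(15, {
    V <- matrix(rnorm(50), 25, 2)
    yy <- 0.6 * V[, 1] + 0.2 * V[, 2] + rnorm(25, 0, 0.3)
  })
  mt3 <- structure(list(V = V, y = yy, learner_order = c("a", "b")),
                   class = "meta_training_matrix")
  mm <- fit_nonneg_ridge(mt3, 0.1)
  obj <- function(a) sum((yy - V %*% a)^2) + 0.1 * sum(a^2)
  g <- as.matrix(expand.grid(seq(0, 1.5, 5e-4), seq(0, 1.5, 5e-4)))
  best <- g[which.min(colSums((yy - tcrossprod(V, g))^2) +
                        0.1 * rowSums(g^2)), ]
  expect_lt(max(abs(unname(mm$alpha) - best)), 1e-3)

  mt0 <- structure(list(V = matrix(0, 10, 2), y = rnorm(10),
                        learner_order = c("a", "b")),
                   class = "meta_training_matrix")
  expect_error(fit_nonneg_ridge(mt0), "all-zero")
  expect_error(fit_nonneg_ridge(mt3, -1), ">= 0")
})

test_that("meta lambda selection honours trivial grids and collinearity", {
  withr::with_seed(16, {
    V <- matrix(rnorm(60), 30, 2)
    y <- V[, 1] + rnorm(30, 0.1)
  })
  mt <- structure(list(V = V, y = y, learner_order = c("a", "b")),
                  class = "meta_training_matrix")
  expect_equal(select_meta_lambda(mt, grid = 0), 0)
  expect_equal(select_meta_lambda(mt, grid = 0.5), 0.5)

  # perfectly collinear base predictions: shrinkage engages most of the time
  positive <- 0L
  for (seed in 1:20) {
    withr::with_seed(seed, {
      v <- rnorm(30)
      yy <- v + rnorm(30, 0, 0.4)
      Vd <- cbind(v, v, v, v)
    })
    mtd <- structure(list(V = Vd, y = yy,
                          learner_order = c("a", "b", "c", "d")),
                     class = "meta_training_matrix")
    lam <- select_meta_lambda(mtd, plan = make_fold_plan(30, 10, seed))
    if (lam > 0) positive <- positive + 1L
  }
  expect_gte(positive, 11L)
})

test_that("combined coefficients are the exact weighted sum", {
  mk <- function(kind, beta, intercept)
    structure(list(kind = kind, beta = beta, intercept = intercept,
                   hyperparams = NULL, train_mse = 0),
              class = "fitted_linear_model")
  meta <- structure(list(alpha = c(0.5, 0.5, 0, 0), lam = 0,
                         learner_order = c("PCR", "PLSR", "OPLS", "EN")),
                    class = "meta_model")
  bms <- list(mk("PCR", c(1, 0), 1), mk("PLSR", c(0, 1), 3),
              mk("OPLS", c(9, 9), 9), mk("EN", c(-9, -9), -9))
  cc <- combine_coefficients(bms, meta)
  expect_equal(cc$beta, c(0.5, 0.5))
  expect_equal(cc$intercept, 2)

  # identical betas, weights summing to one: combination preserved
  b <- c(0.3, -1, 2)
  meta2 <- structure(list(alpha = c(0.25, 0.25, 0.25, 0.25), lam = 0,
                          learner_order = meta$learner_order),
                     class = "meta_model")
  bms2 <- lapply(c("PCR", "PLSR", "OPLS", "EN"), mk, beta = b, intercept = 1)
  expect_equal(combine_coefficients(bms2, meta2)$beta, b, tolerance = 1e-12)

  # random weights against independent summation
  withr::with_seed(17, {
    a <- runif(4)
    betas <- replicate(4, rnorm(6), simplify = FALSE)
  })
  meta3 <- structure(list(alpha = a, lam = 0,
                          learner_order = meta$learner_order),
                     class = "meta_model")
  bms3 <- Map(mk, c("PCR", "PLSR", "OPLS", "EN"), betas, as.list(runif(4)))
  manual <- Reduce(`+`, Map(function(w, b) w * b, a, betas))
  expect_equal(combine_coefficients(unname(bms3), meta3)$beta, manual,
               tolerance = 1e-12)

  bms_bad <- list(mk("PCR", c(1, 2), 0), mk("PLSR", c(1, 2, 3), 0),
                  mk("OPLS", c(1, 2), 0), mk("EN", c(1, 2), 0))
  expect_error(combine_coefficients(bms_bad, meta), "mismatch")
})

test_that("fitted stacked models are internally consistent", {
  prob <- sparse_problem(n = 30, p = 25, k = 3, noise = 0.1, seed = 18)
  Z <- standardise_apply(prob$X, standardise_fit(prob$X))
  sm <- fit_smlr(Z, prob$y, seed = 21)

  expect_true(all(sm$meta$alpha >= 0))
  manual_beta <- Reduce(`+`, Map(function(a, m) a * m$beta,
                                 sm$meta$alpha, sm$base_models))
  expect_lt(max(abs(sm$beta - manual_beta)), 1e-10)

  Znew <- matrix(rnorm(10 * 25), 10, 25)
  expect_lt(max(abs(predict(sm, Znew, route = "meta") -
                      predict(sm, Znew, route = "coefficients"))), 1e-8)

  sm_again <- fit_smlr(Z, prob$y, seed = 21)
  expect_identical(sm$meta$alpha, sm_again$meta$alpha)

  # degenerate weight patterns propagate exactly
  sm2 <- sm
  sm2$meta$alpha <- c(PCR = 1, PLSR = 0, OPLS = 0, EN = 0)
  expect_equal(predict(sm2, Znew, route = "meta"),
               predict(sm2$base_models$PCR, Znew))
  sm2$meta$alpha <- c(PCR = 0, PLSR = 0, OPLS = 0, EN = 0)
  expect_equal(predict(sm2, Znew, route = "meta"), rep(0, 10))
})

test_that("alpha normalization bounds predictions by the base range", {
  prob <- sparse_problem(n = 30, p = 15, k = 2, noise = 0.2, seed = 19)
  Z <- standardise_apply(prob$X, standardise_fit(prob$X))
  sm <- fit_smlr(Z, prob$y, seed = 22, normalize_alpha = TRUE)
  expect_equal(sum(sm$meta$alpha), 1, tolerance = 1e-10)
  Znew <- matrix(rnorm(20 * 15), 20, 15)
  V <- vapply(sm$base_models, function(bm) predict(bm, Znew), numeric(20))
  pred <- predict(sm, Znew)
  expect_true(all(pred >= apply(V, 1, min) - 1e-10))
  expect_true(all(pred <= apply(V, 1, max) + 1e-10))
})

test_that("the EN-matched sparse truth earns the largest stacking weight", {
  wins <- 0L
  for (seed in 1:20) {
    prob <- sparse_problem(n = 40, p = 80, k = 3, noise = 0.05,
                           seed = seed + 400)
    Z <- standardise_apply(prob$X, standardise_fit(prob$X))
    sm <- fit_smlr(Z, prob$y, seed = seed)
    if (which.max(sm$meta$alpha) == 4L) wins <- wins + 1L
  }
  expect_gte(wins, 11L)
})

test_that("model JSON round trip preserves predictions and schema", {
  prob <- sparse_problem(n = 25, p = 12, k = 2, noise = 0.1, seed = 23)
  scaler <- standardise_fit(prob$X)
  Z <- standardise_apply(prob$X, scaler)
  sm <- fit_smlr(Z, prob$y, seed = 24)
  sm$scaler <- scaler

  f <- withr::local_tempfile(fileext = ".json")
  serialize_model(sm, f)
  sm2 <- deserialize_model(f)
  Znew <- matrix(rnorm(8 * 12), 8, 12)
  expect_lt(max(abs(predict(sm, Znew) - predict(sm2, Znew))), 1e-12)
  expect_lt(max(abs(predict(sm, Znew, route = "coefficients") -
                      predict(sm2, Znew, route = "coefficients"))), 1e-12)
  expect_equal(sm2$scaler$mean, unname(scaler$mean), tolerance = 1e-12)

  # schema guards
  obj <- jsonlite::read_json(f)
  obj$alpha <- NULL
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, auto_unbox = TRUE, digits = NA)
  expect_error(deserialize_model(f2), "alpha")

  obj2 <- jsonlite::read_json(f)
  expect_identical(obj2$version, "1.0")
  obj2$version <- "99"
  jsonlite::write_json(obj2, f2, auto_unbox = TRUE, digits = NA)
  expect_error(deserialize_model(f2), "version")
})
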