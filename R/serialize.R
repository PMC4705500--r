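# JSON serialization of fitted stacked models, including the scaler, so a
# model can be applied to new fingerprints without the training data.

SMLR_SCHEMA_VERSION <- "1.0"

#' Serialize a stacked model to JSON
#'
#' Writes the stacking weights, per-learner coefficients, intercepts and
#' hyperparameters, the combined coefficient vector, and (if present) the
#' standardisation statistics.  Numbers are written at full precision so a
#' round trip preserves predictions to better than 1e-12.
#'
#' @param model an `smlr_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
serialize_model <- function(model, path) {
  stopifnot(inherits(model, "smlr_model"))
  base <- lapply(model$base_models, function(bm) {
    hp <- bm$hyperparams
    list(kind = bm$kind, beta = bm$beta, intercept = bm$intercept,
         hyperparams = list(n_components = hp$n_components,
                            en_l1 = hp$en_l1, en_l2 = hp$en_l2,
                            selection = hp$selection))
  })
  scaler <- if (!is.null(model$scaler))
    list(mean = model$scaler$mean, sd = model$scaler$sd,
         constant_mask = model$scaler$constant_mask)
  obj <- list(version = SMLR_SCHEMA_VERSION,
              learner_order = model$meta$learner_order,
              alpha = as.numeric(model$meta$alpha),
              lam = model$meta$lam,
              base = unname(base),
              beta_smlr = model$beta,
              intercept_smlr = model$intercept,
              scaler = scaler)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a stacked model back from JSON
#'
#' @param path path to a file written by [serialize_model()].
#' @return An `smlr_model` whose predictions agree with the original to
#'   better than 1e-12.
#' @export
deserialize_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("version", "learner_order", "alpha", "lam", "base",
                "beta_smlr", "intercept_smlr")
  missing_f <- setdiff(required, names(obj))
  if (length(missing_f))
    stop("model JSON is missing required fields: ",
         paste(missing_f, collapse = ", "))
  if (!identical(as.character(obj$version), SMLR_SCHEMA_VERSION))
    stop("unsupported model schema version: ", obj$version,
         " (expected ", SMLR_SCHEMA_VERSION, ")")
  base_models <- lapply(seq_along(obj$base$kind), function(i) {
    hp <- as.list(obj$base$hyperparams[i, ])
    cfg <- base_learner_config(obj$base$kind[i],
                               n_components = hp$n_components,
                               en_l1 = hp$en_l1, en_l2 = hp$en_l2,
                               selection = hp$selection)
    structure(list(kind = obj$base$kind[i],
                   beta = as.numeric(obj$base$beta[[i]]),
                   intercept = obj$base$intercept[i],
                   hyperparams = cfg, train_mse = NA_real_),
              class = "fitted_linear_model")
  })
  names(base_models) <- obj$base$kind
  alpha <- as.numeric(obj$alpha)
  names(alpha) <- obj$learner_order
  meta <- structure(list(alpha = alpha, lam = obj$lam,
                         learner_order = obj$learner_order),
                    class = "meta_model")
  scaler <- NULL
  if (!is.null(obj$scaler))
    scaler <- structure(list(mean = as.numeric(obj$scaler$mean),
                             sd = as.numeric(obj$scaler$sd),
                             constant_mask = as.logical(obj$scaler$constant_mask)),
                        class = "scaler_stats")
  structure(list(base_models = base_models, meta = meta,
                 beta = as.numeric(obj$beta_smlr),
                 intercept = obj$intercept_smlr,
                 configs = lapply(base_models, `[[`, "hyperparams"),
                 fold_plan = NULL, scaler = scaler),
            class = "smlr_model")
}
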