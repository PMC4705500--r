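# Synthetic chromatographic fingerprint generator with known ground truth.
# Emulates the statistical structure of HPLC-DAD fingerprint datasets:
# Gaussian peaks on a shared retention grid, sample-wise retention drift,
# slowly varying baselines, heteroscedastic detector noise, and a response
# that is a sparse linear function of the true peak concentrations.

#' Synthetic dataset configuration
#'
#' Defaults mirror the geometry of a 72-extract HPLC fingerprint study on
#' a 70-minute run, with the point count scaled to 2101 for desk-speed
#' work; `full_scale = TRUE` restores the 10,501-point grid.
#'
#' @param n_samples number of samples (default 72).
#' @param n_points retention grid size (default 2101; >= 50).
#' @param run_time chromatographic run length in minutes (default 70).
#' @param n_peaks size of the peak library shared by all samples (default
#'   30, of the order of the countable peaks in a real fingerprint).
#' @param n_active number of peaks contributing to the bioactivity
#'   (default 5; must not exceed `n_peaks`).
#' @param peak_width_range Gaussian peak sigma range, minutes (default
#'   0.15-0.5).
#' @param shift_sd sample-wise retention jitter standard deviation, in grid
#'   points (default 2).
#' @param baseline_amplitude scale of the smooth polynomial baseline, mAU
#'   (default 30).
#' @param noise_sd detector noise floor, mAU (default 1); the noise is
#'   heteroscedastic, its standard deviation growing linearly with the
#'   local signal (doubling at 100 mAU).
#' @param response_noise_sd assay noise on the response; `NULL` (default)
#'   uses 2% of the mean noiseless response, matching typical replicate
#'   variability of flow-cytometric bioactivity assays.
#' @param full_scale if `TRUE`, use a 10,501-point grid regardless of
#'   `n_points`.
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 72L, n_points = 2101L,
                             run_time = 70, n_peaks = 30L, n_active = 5L,
                             peak_width_range = c(0.15, 0.5),
                             shift_sd = 2, baseline_amplitude = 30,
                             noise_sd = 1, response_noise_sd = NULL,
                             full_scale = FALSE, seed = 1L) {
  if (full_scale) n_points <- 10501L
  n_points <- as.integer(n_points)
  n_samples <- as.integer(n_samples)
  n_peaks <- as.integer(n_peaks); n_active <- as.integer(n_active)
  if (n_points < 50) stop("n_points must be >= 50")
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (n_active > n_peaks) stop("n_active must be <= n_peaks")
  if (n_active < 1) stop("n_active must be >= 1")
  if (shift_sd < 0 || baseline_amplitude < 0 || noise_sd < 0)
    stop("noise/shift/baseline amplitudes must be >= 0")
  if (!is.null(response_noise_sd) && response_noise_sd < 0)
    stop("response_noise_sd must be >= 0")
  if (length(peak_width_range) != 2 || any(peak_width_range <= 0) ||
      peak_width_range[1] > peak_width_range[2])
    stop("peak_width_range must be an increasing positive pair")
  structure(list(n_samples = n_samples, n_points = n_points,
                 run_time = run_time, n_peaks = n_peaks,
                 n_active = n_active, peak_width_range = peak_width_range,
                 shift_sd = shift_sd,
                 baseline_amplitude = baseline_amplitude,
                 noise_sd = noise_sd, response_noise_sd = response_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic fingerprint dataset with known ground truth
#'
#' Each sample's chromatogram is a concentration-weighted sum of shared
#' Gaussian peaks (with a per-sample retention shift), plus a smooth
#' random cubic baseline and heteroscedastic white noise.  The response is
#' a sparse positive linear function of the true concentrations plus assay
#' noise.  The lowest peak of the library is always part of the active
#' set, so at least one bioactive component is of below-median intensity —
#' the regime where whole-fingerprint regression is needed at all.
#'
#' @param config a [synthetic_config].
#' @return A list with `fm` ([fingerprint_matrix]), `rv`
#'   ([response_vector]) and `truth` (list: `peak_centers`, `peak_widths`,
#'   `peak_heights`, `concentrations`, `active_weights`, `true_responses`,
#'   `shifts`).  Identical seeds give bitwise-identical output.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    n <- config$n_samples; p <- config$n_points; k <- config$n_peaks
    time <- seq(0, config$run_time, length.out = p)
    dt <- config$run_time / (p - 1)
    centers <- sort(stats::runif(k, 0.05 * config$run_time,
                                 0.95 * config$run_time))
    widths <- stats::runif(k, config$peak_width_range[1],
                           config$peak_width_range[2])
    heights <- stats::rlnorm(k, meanlog = log(40), sdlog = 0.8)
    conc <- matrix(stats::rlnorm(n * k, meanlog = 0, sdlog = 0.4), n, k)
    # active set always contains the smallest peak of the library
    low <- which.min(heights)
    active <- c(low, sample(setdiff(seq_len(k), low),
                            config$n_active - 1L))
    active_weights <- rep(0, k)
    active_weights[active] <- stats::runif(config$n_active, 0.5, 1.5)
    true_y <- as.numeric(conc %*% active_weights)
    shifts <- stats::rnorm(n, 0, config$shift_sd) * dt   # minutes
    X <- matrix(0, n, p)
    for (i in seq_len(n)) {
      G <- exp(-outer(time, centers + shifts[i], "-")^2 /
                 rep(2 * widths^2, each = p))
      signal <- as.numeric(G %*% (conc[i, ] * heights))
      if (config$baseline_amplitude > 0) {
        u <- time / config$run_time
        cf <- stats::runif(4, -1, 1)
        b <- cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3
        b <- (b - min(b)) / max(1e-9, max(b) - min(b))
        signal <- signal + config$baseline_amplitude * b
      }
      if (config$noise_sd > 0)
        signal <- signal +
          stats::rnorm(p) * config$noise_sd * (1 + pmax(signal, 0) / 100)
      X[i, ] <- signal
    }
    rns <- config$response_noise_sd
    if (is.null(rns)) rns <- 0.02 * mean(true_y)
    y <- true_y + if (rns > 0) stats::rnorm(n, 0, rns) else 0
    ids <- sprintf("s%02d", seq_len(n))
    list(fm = fingerprint_matrix(X, time, ids),
         rv = response_vector(y, ids),
         truth = list(peak_centers = centers, peak_widths = widths,
                      peak_heights = heights, concentrations = conc,
                      active_weights = active_weights,
                      true_responses = true_y, shifts = shifts))
  })
}

#' Corrupt clean fingerprints with known shift, baseline and noise
#'
#' Adds fresh retention jitter (whole-trace shift by linear interpolation),
#' a random smooth baseline and white noise to a fingerprint matrix.  The
#' caller keeps the clean input as ground truth, which makes the
#' conditioning chain testable: baseline removal and alignment should
#' recover the clean features.
#'
#' @param fm a clean [fingerprint_matrix].
#' @param shift_sd retention jitter sd in grid points.
#' @param baseline_amplitude baseline scale, mAU.
#' @param noise_sd white-noise sd, mAU.
#' @param seed integer RNG seed.
#' @return A corrupted [fingerprint_matrix] of the same shape.
#' @export
degrade <- function(fm, shift_sd = 0, baseline_amplitude = 0, noise_sd = 0,
                    seed = 1L) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  if (shift_sd < 0 || baseline_amplitude < 0 || noise_sd < 0)
    stop("amplitudes must be >= 0")
  withr::with_seed(seed, {
    X <- fm$X
    n <- nrow(X); p <- ncol(X)
    idx <- seq_len(p)
    for (i in seq_len(n)) {
      row <- X[i, ]
      if (shift_sd > 0) {
        s <- stats::rnorm(1, 0, shift_sd)
        row <- stats::approx(idx, row, xout = idx - s, rule = 2)$y
      }
      if (baseline_amplitude > 0) {
        u <- idx / p
        cf <- stats::runif(4, -1, 1)
        b <- cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3
        b <- (b - min(b)) / max(1e-9, max(b) - min(b))
        row <- row + baseline_amplitude * b
      }
      if (noise_sd > 0) row <- row + stats::rnorm(p, 0, noise_sd)
      X[i, ] <- row
    }
    fingerprint_matrix(X, fm$time, fm$sample_ids)
  })
}
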