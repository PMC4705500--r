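# Adaptive iteratively reweighted penalised least squares (airPLS)
# baseline estimation: Whittaker smoothing with weights that decay
# exponentially, over iterations, for points sitting above the running
# baseline, so peaks are progressively excluded from the fit.

#' airPLS parameters
#'
#' @param lam smoothness penalty on the second differences of the baseline
#'   (dimensionless, > 0).  Larger values give stiffer baselines; the
#'   default 1e5 keeps chromatographic peaks (widths of a few hundred
#'   points) out of the baseline while following drifts over thousands of
#'   points.
#' @param max_iter iteration cap (>= 1).
#' @param tol convergence threshold in (0, 1): iteration stops when the sum
#'   of negative residuals falls below `tol` times the total absolute
#'   signal.
#' @return A list of class `airpls_params`.
#' @export
airpls_params <- function(lam = 1e5, max_iter = 30L, tol = 1e-3) {
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam <= 0)
    stop("lam must be a positive scalar")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (!is.numeric(tol) || tol <= 0 || tol >= 1)
    stop("tol must be in (0, 1)")
  structure(list(lam = lam, max_iter = max_iter, tol = tol),
            class = "airpls_params")
}

#' Estimate a chromatographic baseline with airPLS
#'
#' Iteratively fits a Whittaker smoother (penalised least squares with a
#' second-difference roughness penalty) in which points lying above the
#' current baseline estimate are down-weighted, the weights of points below
#' it growing exponentially with the iteration counter.  Peaks are thereby
#' excluded from the fit while slow drifts are followed.
#'
#' @param signal numeric intensity vector (length >= 3, finite).
#' @param params an [airpls_params] object.
#' @return Numeric baseline vector of the same length as `signal`.
#' @references Zhang, Chen and Liang's adaptive iteratively reweighted
#'   penalised least squares algorithm for baseline correction.
#' @export
airpls_baseline <- function(signal, params = airpls_params()) {
  if (!inherits(params, "airpls_params")) params <- do.call(airpls_params, params)
  x <- as.numeric(signal)
  m <- length(x)
  if (m < 3) stop("signal must have length >= 3")
  if (any(!is.finite(x))) stop("signal must be finite")

  w <- rep(1, m)
  total_abs <- sum(abs(x))
  z <- x
  for (it in seq_len(params$max_iter)) {
    z <- .whittaker_solve(x, w, params$lam)
    d <- x - z
    neg <- d < 0
    ssn <- sum(abs(d[neg]))
    if (ssn < params$tol * total_abs || ssn == 0) break
    w[!neg] <- 0
    w[neg] <- exp(it * abs(d[neg]) / ssn)
    # anchor the endpoints so the baseline cannot drift free there
    w[1] <- exp(it * max(abs(d[neg])) / ssn)
    w[m] <- w[1]
  }
  z
}

#' Baseline-correct every fingerprint in a matrix
#'
#' Applies [airpls_baseline()] row by row and subtracts the estimated
#' baseline from each fingerprint.  Rows are processed independently.
#'
#' @param fm a [fingerprint_matrix].
#' @param params an [airpls_params] object.
#' @return A [fingerprint_matrix] of baseline-corrected intensities.
#' @export
correct_baseline <- function(fm, params = airpls_params()) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  Xc <- fm$X
  for (i in seq_len(nrow(Xc))) {
    b <- tryCatch(airpls_baseline(Xc[i, ], params),
                  error = function(e) stop("baseline correction failed on row ",
                                           i, " (", fm$sample_ids[i], "): ",
                                           conditionMessage(e)))
    Xc[i, ] <- Xc[i, ] - b
  }
  fingerprint_matrix(Xc, fm$time, fm$sample_ids)
}
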