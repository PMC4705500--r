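# Correlation optimized warping (COW): piecewise-linear time warping that
# aligns a chromatogram to a reference by maximising the summed Pearson
# correlation of corresponding segments, with segment-boundary shifts
# chosen by dynamic programming.

#' COW parameters
#'
#' @param segment_length points per warping segment (integer >= 5, and
#'   > `2 * slack`).  The default of 100 points corresponds to roughly the
#'   width of one chromatographic peak on typical HPLC grids.
#' @param slack maximum shift of an interior segment boundary, in points
#'   (integer >= 0).
#' @param reference_index row of the fingerprint matrix to align against,
#'   or `NULL` to pick the sample with maximal mean correlation to all
#'   other samples (a deterministic rule).
#' @return A list of class `cow_params`.
#' @export
cow_params <- function(segment_length = 100L, slack = 5L,
                       reference_index = NULL) {
  segment_length <- as.integer(segment_length)
  slack <- as.integer(slack)
  if (segment_length < 5) stop("segment_length must be >= 5")
  if (slack < 0) stop("slack must be >= 0")
  if (segment_length <= 2L * slack)
    stop("segment_length must exceed 2 * slack (got ", segment_length,
         " vs slack ", slack, ")")
  structure(list(segment_length = segment_length, slack = slack,
                 reference_index = reference_index),
            class = "cow_params")
}

#' Align one chromatogram to a reference by COW
#'
#' The reference axis is cut into segments of approximately
#' `segment_length` points.  Interior segment boundaries on the sample may
#' shift by up to `slack` points either way; each admissible combination of
#' boundary shifts linearly interpolates the sample segment onto the
#' reference segment grid and scores it by Pearson correlation.  Dynamic
#' programming finds the boundary shifts maximising the summed score, with
#' ties broken toward the smaller absolute shift (so self-alignment is the
#' exact identity).  Endpoints are fixed.
#'
#' @param sample numeric intensity vector to warp.
#' @param reference numeric intensity vector of the same length.
#' @param params a [cow_params] object.
#' @return The warped sample, same length as `reference`.
#' @export
cow_align <- function(sample, reference, params = cow_params()) {
  if (!inherits(params, "cow_params")) params <- do.call(cow_params, params)
  sample <- as.numeric(sample); reference <- as.numeric(reference)
  m <- length(reference)
  if (length(sample) != m)
    stop("sample and reference lengths differ (", length(sample),
         " vs ", m, ")")
  if (m < 2L * params$segment_length)
    stop("signal too short for segment_length ", params$segment_length,
         ": need >= ", 2L * params$segment_length, " points")

  n_seg <- max(2L, as.integer(round((m - 1) / params$segment_length)))
  bounds <- as.integer(round(seq(1, m, length.out = n_seg + 1)))
  .cow_warp(sample, reference, bounds, params$slack)
}

#' Choose a deterministic alignment reference
#'
#' Returns the index of the fingerprint with the greatest mean Pearson
#' correlation to all other fingerprints.
#'
#' @param fm a [fingerprint_matrix] with n >= 1 rows.
#' @return Integer row index.
#' @export
choose_reference <- function(fm) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  n <- nrow(fm$X)
  if (n == 1) return(1L)
  cc <- suppressWarnings(stats::cor(t(fm$X)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 0
  which.max(rowSums(cc) / (n - 1))
}

#' Align all fingerprints in a matrix to a reference
#'
#' @param fm a [fingerprint_matrix].
#' @param params a [cow_params] object; if `reference_index` is `NULL` the
#'   reference is chosen with [choose_reference()].
#' @return A [fingerprint_matrix] of aligned fingerprints.
#' @export
align_set <- function(fm, params = cow_params()) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  if (!inherits(params, "cow_params")) params <- do.call(cow_params, params)
  ref_i <- params$reference_index
  if (is.null(ref_i)) ref_i <- choose_reference(fm)
  ref_i <- as.integer(ref_i)
  if (ref_i < 1 || ref_i > nrow(fm$X))
    stop("reference_index out of range: ", ref_i)
  reference <- fm$X[ref_i, ]
  Xa <- fm$X
  for (i in seq_len(nrow(Xa))) {
    Xa[i, ] <- tryCatch(cow_align(fm$X[i, ], reference, params),
                        error = function(e) stop("alignment failed on row ", i,
                                                 " (", fm$sample_ids[i], "): ",
                                                 conditionMessage(e)))
  }
  out <- fingerprint_matrix(Xa, fm$time, fm$sample_ids)
  attr(out, "reference_index") <- ref_i
  out
}
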