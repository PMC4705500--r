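# Domain containers: fingerprint matrices, response vectors, CSV dialects.

#' Construct a fingerprint matrix
#'
#' A fingerprint matrix holds `n` chromatographic fingerprints sampled on a
#' shared retention-time grid: an `n x p` matrix of detector intensities
#' (mAU) whose columns correspond to the `p` points of the time axis
#' (minutes).
#'
#' @param X numeric matrix, `n x p`, one fingerprint per row.
#' @param time numeric vector of length `p`; strictly increasing retention
#'   times in minutes.
#' @param sample_ids character vector of `n` unique sample labels.  Defaults
#'   to the rownames of `X`, or `"s1" ... "sn"`.
#' @return An object of class `fingerprint_matrix`: a list with elements
#'   `X`, `time` and `sample_ids`.
#' @examples
#' fm <- fingerprint_matrix(matrix(rnorm(6), 2, 3), time = c(0, 0.5, 1))
#' dim(fm$X)
#' @export
fingerprint_matrix <- function(X, time, sample_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  time <- as.numeric(time)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(X)))
  }
  sample_ids <- as.character(sample_ids)
  validate_time_axis(time)
  if (ncol(X) != length(time))
    stop("ncol(X) [", ncol(X), "] does not match time axis length [",
         length(time), "]")
  if (length(sample_ids) != nrow(X))
    stop("length(sample_ids) does not match nrow(X)")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique; duplicated: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(X)))
    stop("fingerprint intensities must be finite (no NA/NaN/Inf)")
  rownames(X) <- sample_ids
  structure(list(X = X, time = time, sample_ids = sample_ids),
            class = "fingerprint_matrix")
}

validate_time_axis <- function(time) {
  if (length(time) < 2)
    stop("time axis needs at least 2 points")
  if (any(!is.finite(time)))
    stop("time axis must be finite")
  if (any(diff(time) <= 0))
    stop("time axis must be strictly increasing")
  invisible(time)
}

#' @export
#' @method print fingerprint_matrix
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("fingerprint_matrix: %d samples x %d time points (%.4g-%.4g min)\n",
              nrow(x$X), ncol(x$X), x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' @export
#' @method dim fingerprint_matrix
dim.fingerprint_matrix <- function(x) dim(x$X)

#' Construct a response vector
#'
#' Scalar bioactivity capacities (e.g. CD80 expression level), one per
#' sample, aligned to a fingerprint matrix by sample id.
#'
#' @param y numeric vector of responses.
#' @param sample_ids character labels, same length as `y`, unique.
#' @return An object of class `response_vector`.
#' @export
response_vector <- function(y, sample_ids = NULL) {
  y <- as.numeric(y)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(y))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(y))
    stop("length(sample_ids) does not match length(y)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in response: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(y)))
    stop("responses must be finite")
  names(y) <- sample_ids
  structure(list(y = y, sample_ids = sample_ids), class = "response_vector")
}

#' @export
#' @method print response_vector
print.response_vector <- function(x, ...) {
  cat(sprintf("response_vector: %d samples, range [%.4g, %.4g]\n",
              length(x$y), min(x$y), max(x$y)))
  invisible(x)
}

# -- CSV dialect -------------------------------------------------------------
# Header row: "sample_id", then retention times in decimal minutes.
# Data rows: id, then p intensities.  '.' decimal, ',' separator.

#' Read a fingerprint matrix from CSV
#'
#' The expected dialect: a header row `sample_id,<t1>,<t2>,...` whose time
#' points are strictly increasing decimal minutes, followed by one row per
#' sample (`id,<p intensities>`).
#'
#' @param path path to a UTF-8 CSV file.
#' @return A [fingerprint_matrix].
#' @seealso [write_fingerprint_csv()]
#' @export
read_fingerprint_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("fingerprint CSV needs a header and at least one data row: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "sample_id")
    stop("fingerprint CSV header must start with 'sample_id' followed by ",
         ">= 2 time points")
  time <- suppressWarnings(as.numeric(header[-1]))
  if (any(is.na(time)))
    stop("non-numeric time point in header at column ",
         which(is.na(time))[1] + 1L)
  validate_time_axis(time)
  p <- length(time)
  n <- length(lines) - 1L
  X <- matrix(NA_real_, n, p)
  ids <- character(n)
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(cells) != p + 1L)
      stop("ragged row at line ", i + 1L, ": expected ", p + 1L,
           " fields, found ", length(cells))
    ids[i] <- cells[1]
    vals <- suppressWarnings(as.numeric(cells[-1]))
    if (any(is.na(vals)))
      stop("non-numeric intensity at line ", i + 1L, ", column ",
           which(is.na(vals))[1] + 1L)
    X[i, ] <- vals
  }
  fingerprint_matrix(X, time, ids)
}

#' Write a fingerprint matrix to CSV
#'
#' Values are printed with 15 significant digits so that a read/write
#' round trip is lossless to well below 1e-12 relative error.
#'
#' @param fm a [fingerprint_matrix].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_fingerprint_csv <- function(fm, path) {
  stopifnot(inherits(fm, "fingerprint_matrix"))
  if (length(fm$sample_ids) == 0 || any(!nzchar(fm$sample_ids)))
    stop("sample_ids must be non-empty before writing")
  fmt <- function(x) sprintf("%.15g", x)
  header <- paste(c("sample_id", fmt(fm$time)), collapse = ",")
  rows <- vapply(seq_len(nrow(fm$X)), function(i) {
    paste(c(fm$sample_ids[i], fmt(fm$X[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a response vector from CSV
#'
#' Expects a two-column file `sample_id,y` with a header row.
#'
#' @param path path to the CSV file.
#' @return A [response_vector] in file order.
#' @export
read_response_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character"))
  if (ncol(df) != 2)
    stop("response CSV must have exactly two columns (sample_id,y)")
  y <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(y)))
    stop("non-numeric response at data row ", which(is.na(y))[1])
  response_vector(y, df[[1]])
}

#' Write a response vector to CSV
#' @param rv a [response_vector].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_response_csv <- function(rv, path) {
  stopifnot(inherits(rv, "response_vector"))
  writeLines(c("sample_id,y",
               paste(rv$sample_ids, sprintf("%.15g", rv$y), sep = ",")),
             path)
  invisible(path)
}

#' Pair a fingerprint matrix with its responses
#'
#' Aligns a response vector to a fingerprint matrix by sample id.  The row
#' order of the fingerprint matrix is authoritative; the response file may
#' list samples in any order.
#'
#' @param fm a [fingerprint_matrix].
#' @param rv a [response_vector] with the same set of sample ids.
#' @return A list with `X` (n x p matrix), `y` (length-n vector named by
#'   sample id), `time`, and `sample_ids`.
#' @export
pair_dataset <- function(fm, rv) {
  stopifnot(inherits(fm, "fingerprint_matrix"),
            inherits(rv, "response_vector"))
  missing_ids <- setdiff(fm$sample_ids, rv$sample_ids)
  extra_ids <- setdiff(rv$sample_ids, fm$sample_ids)
  if (length(missing_ids) || length(extra_ids))
    stop("sample id mismatch between fingerprints and responses; ",
         "missing from responses: [",
         paste(missing_ids, collapse = ", "), "]; not in fingerprints: [",
         paste(extra_ids, collapse = ", "), "]")
  y <- rv$y[match(fm$sample_ids, rv$sample_ids)]
  list(X = fm$X, y = y, time = fm$time, sample_ids = fm$sample_ids)
}
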