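#' DC suppression by slow-time mean subtraction
#'
#' First of the two consecutive mean-subtraction steps: from every fast-time
#' row, subtract that row's mean over slow time. Removes per-sample constant
#' components (and, as a side effect of averaging over chirps, any return
#' that is constant across chirps).
#'
#' @param cube A [raw_cube()] or a plain numeric matrix (fast time x slow
#'   time) with at least 2 columns.
#' @return A numeric matrix of the same shape with zero row means.
#' @export
suppress_dc <- function(cube) {
  R <- if (inherits(cube, "raw_cube")) cube$samples else cube
  if (!is.matrix(R) || length(R) == 0) stop("empty or non-matrix input", call. = FALSE)
  if (ncol(R) < 2) stop("need at least 2 slow-time samples", call. = FALSE)
  R - rowMeans(R)
}

#' Static-component suppression by fast-time mean subtraction
#'
#' Second mean-subtraction step: from every slow-time column (one chirp),
#' subtract that chirp's mean over fast time, zeroing each chirp's residual
#' offset.
#'
#' @param rbar Numeric matrix (fast time x slow time), at least 2 rows;
#'   normally the output of [suppress_dc()].
#' @param provenance Optional source [raw_cube()] carried along as metadata.
#' @return A `clean_cube`: list with `samples` (zero-column-mean matrix) and
#'   `provenance`.
#' @export
suppress_clutter <- function(rbar, provenance = NULL) {
  if (!is.matrix(rbar) || length(rbar) == 0) stop("empty or non-matrix input", call. = FALSE)
  if (nrow(rbar) < 2) stop("need at least 2 fast-time samples", call. = FALSE)
  Y <- sweep(rbar, 2L, colMeans(rbar))
  structure(list(samples = Y, provenance = provenance), class = "clean_cube")
}

#' Full two-step preprocessing chain
#'
#' Applies [suppress_dc()] then [suppress_clutter()]. Note the two printed
#' formulas are named "DC" and "static clutter" suppression in the order
#' given, although by convention the slow-time average is what removes static
#' clutter; the chain as a whole removes both.
#'
#' @param cube A [raw_cube()].
#' @return A `clean_cube`.
#' @export
preprocess_cube <- function(cube) {
  stopifnot(inherits(cube, "raw_cube"))
  suppress_clutter(suppress_dc(cube), provenance = cube)
}

#' @export
print.clean_cube <- function(x, ...) {
  cat(sprintf("<clean_cube> %d x %d (row/col mean-subtracted)\n",
              nrow(x$samples), ncol(x$samples)))
  invisible(x)
}
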