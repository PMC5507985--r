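#' Expression matrix with detection flags
#'
#' Container for a miRNA-by-sample intensity matrix together with per-cell
#' detection flags (signal above background) and a processing-state marker.
#' Raw matrices hold non-negative background-corrected intensities;
#' normalized matrices hold values on a log2-like (generalized-log) scale.
#'
#' @param values Numeric matrix (miRNAs in rows, samples in columns) with
#'   unique, non-empty dimnames.
#' @param detected Logical matrix of the same dimensions, or \code{NULL} for
#'   all-detected.
#' @param state Either \code{"raw"} or \code{"normalized"}.
#'
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values}, \code{detected}, \code{state}.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("mir", 1:3), c("s1", "s2"))))
#' dim(m$values)
#' @export
expression_matrix <- function(values, detected = NULL, state = c("raw", "normalized")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) fail("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    fail("values must have miRNA row names and sample column names")
  }
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(values), ncol(values), dimnames = dimnames(values))
  } else if (is.matrix(detected) && is.null(dimnames(detected)) &&
             identical(dim(detected), dim(values))) {
    dimnames(detected) <- dimnames(values)
  }
  m <- structure(list(values = values, detected = detected, state = state),
                 class = "ExpressionMatrix")
  validate_expression_matrix(m)
}

#' Validate an ExpressionMatrix
#'
#' Enforces the container invariants: matching dimensions of values and
#' flags, unique miRNA and sample identifiers, and non-negative values when
#' \code{state == "raw"}.
#'
#' @param m An \code{ExpressionMatrix}.
#' @return \code{m}, invisibly usable, after validation (errors otherwise).
#' @export
validate_expression_matrix <- function(m) {
  if (!inherits(m, "ExpressionMatrix")) fail("not an ExpressionMatrix")
  v <- m$values; d <- m$detected
  if (!identical(dim(v), dim(d))) fail("values and detected must have identical dimensions")
  if (!is.logical(d)) fail("detected must be a logical matrix")
  if (!identical(dimnames(v), dimnames(d))) fail("values and detected dimnames differ")
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup)) fail("duplicate miRNA IDs: %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(v)[duplicated(colnames(v))]
  if (length(dup)) fail("duplicate sample IDs: %s", paste(unique(dup), collapse = ", "))
  if (anyNA(v)) fail("values contain missing entries")
  if (m$state == "raw" && any(v < 0)) fail("raw intensities must be non-negative")
  if (!m$state %in% c("raw", "normalized")) fail("state must be 'raw' or 'normalized'")
  m
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d miRNAs x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("  detected cells: %.1f%%\n", 100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix
#'
#' @param x An \code{ExpressionMatrix}.
#' @param i Row (miRNA) index or names.
#' @param j Column (sample) index or names.
#' @param ... Ignored.
#' @return The subsetted \code{ExpressionMatrix}.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_matrix(x$values[i, j, drop = FALSE],
                    x$detected[i, j, drop = FALSE],
                    state = x$state)
}

# number of samples each miRNA is detected in
detected_counts <- function(m) rowSums(m$detected)
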