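# Normalization and filtering of raw expression matrices.

#' Generalized log2 transform
#'
#' \code{glog2(x, c) = log2((x + sqrt(x^2 + c^2)) / 2)}. Behaves like
#' \code{log2(x)} for \code{x >> c}, is linear near zero, and is defined (and
#' strictly increasing) for all real \code{x} when \code{c > 0}. At
#' \code{c = 0} it reduces to \code{log2(x)} for positive \code{x}.
#'
#' @param x Numeric vector or matrix.
#' @param c Non-negative glog offset.
#' @return Transformed values, same shape as \code{x}.
#' @export
glog2 <- function(x, c) {
  if (c < 0) fail("glog offset must be >= 0")
  log2((x + sqrt(x^2 + c^2)) / 2)
}

#' Variance-stabilizing normalization
#'
#' Per-sample affine calibration followed by a generalized-log transform.
#' Each sample is calibrated to a common location/scale using its median and
#' MAD (robust to the skewed intensity distributions of miRNA arrays), then
#' transformed with \code{\link{glog2}} whose offset \code{c} is, by
#' default, estimated from the spread of the low-intensity quartile - the
#' regime where additive noise dominates and plain \code{log2} inflates
#' variance. The transform is strictly monotone within every sample, so
#' per-sample rank orders (and detection flags) are unchanged.
#'
#' @param m A raw \code{ExpressionMatrix}.
#' @param c glog offset; estimated from the data when \code{NULL}.
#' @param calibrate Apply the median/MAD affine calibration (default
#'   \code{TRUE}). With \code{calibrate = FALSE} and \code{c = 0} the result
#'   is exactly \code{log2(values)}.
#' @return A normalized \code{ExpressionMatrix} (state \code{"normalized"}).
#' @export
glog_normalize <- function(m, c = NULL, calibrate = TRUE) {
  validate_expression_matrix(m)
  if (m$state != "raw") fail("glog_normalize expects a raw matrix")
  v <- m$values
  if (calibrate) {
    sds <- apply(v, 2, stats::sd)
    if (any(sds == 0)) {
      fail("zero-variance sample(s): %s",
           paste(colnames(v)[sds == 0], collapse = ", "))
    }
    med <- apply(v, 2, stats::median)
    scl <- apply(v, 2, stats::mad)
    scl[scl == 0] <- sds[scl == 0]  # MAD can degenerate on spiky samples
    ref_med <- stats::median(med)
    ref_scl <- stats::median(scl)
    v <- sweep(v, 2, med, "-")
    v <- sweep(v, 2, ref_scl / scl, "*")
    v <- v + ref_med
  }
  if (is.null(c)) {
    low <- v[v <= stats::quantile(v, 0.25)]
    c <- stats::mad(low)
    if (!is.finite(c) || c == 0) c <- max(stats::sd(low), 1e-8)
  }
  out <- glog2(v, c)
  dimnames(out) <- dimnames(m$values)
  res <- expression_matrix(out, m$detected, state = "normalized")
  attr(res, "glog_c") <- c
  res
}

#' Filter miRNAs by detection count
#'
#' Keeps exactly the miRNAs detected in at least \code{min_samples} samples;
#' the sample set and the order of retained miRNAs are unchanged. The
#' operation is idempotent.
#'
#' @param m An \code{ExpressionMatrix}.
#' @param min_samples Minimum detected-sample count (default 5; 0 keeps
#'   everything).
#' @return The filtered \code{ExpressionMatrix}.
#' @export
detection_filter <- function(m, min_samples = 5L) {
  validate_expression_matrix(m)
  if (min_samples < 0) fail("min_samples must be >= 0")
  keep <- detected_counts(m) >= min_samples
  m[keep, ]
}

#' Select the highest-variance miRNAs
#'
#' Returns the \code{n} miRNAs with the largest row variance (sample
#' variance, denominator n-1), in their original matrix order. Ties at the
#' selection boundary are broken by miRNA ID (lexicographic, C collation)
#' so the selection is reproducible.
#'
#' @param m A normalized \code{ExpressionMatrix}.
#' @param n Number of miRNAs to keep.
#' @return The reduced \code{ExpressionMatrix}.
#' @export
top_variance <- function(m, n = 50L) {
  validate_expression_matrix(m)
  if (m$state != "normalized") fail("top_variance expects a normalized matrix")
  if (n < 1) fail("n must be >= 1")
  if (n > nrow(m$values)) {
    fail("n (%d) exceeds the number of miRNAs (%d)", n, nrow(m$values))
  }
  rv <- apply(m$values, 1, stats::var)
  ord <- order(-rv, rownames(m$values), method = "radix")
  keep <- sort(ord[seq_len(n)])
  m[keep, ]
}
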