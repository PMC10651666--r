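#' Median-of-ratios size factors
#'
#' Computes one positive scaling factor per sample using the median-of-ratios
#' construction: reference genes are those with a nonzero count in every
#' sample; each sample's factor is the median over reference genes of the
#' count divided by that gene's geometric mean across samples. Factors are
#' rescaled to have geometric mean exactly 1, so the overall counting scale
#' is preserved.
#'
#' @param counts A [count_matrix()] or a numeric count matrix.
#' @return Numeric vector of positive size factors, one per sample, named by
#'   sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m)  # b has twice a's depth
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (!is.matrix(m) || ncol(m) < 2) stopf("at least 2 samples are required")
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stopf("normalization failed: no gene has nonzero counts in every sample")
  }
  lg <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(m)
  sf
}

#' Normalize a count matrix by size factors
#'
#' @param counts A [count_matrix()] or numeric matrix.
#' @param sf Size factors; computed with [size_factors()] when missing.
#' @return Matrix of normalized counts (counts divided column-wise by `sf`).
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  sweep(m, 2, sf, "/")
}
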