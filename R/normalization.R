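#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed with the median-of-ratios formula:
#' each row's geometric mean across samples is a pseudo-reference, and a
#' sample's factor is the median over rows of count / geometric mean. Rows
#' whose geometric mean is zero (any zero count) are excluded from the
#' medians. Normalized counts are raw counts divided by the factor.
#'
#' @param counts Non-negative numeric matrix (features x samples), or a
#'   [segment_counts()] object (its count matrix is used).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
median_ratio_size_factors <- function(counts) {
  if (inherits(counts, "segment_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok))
    stop("no row with all-positive counts; add a pseudo-count or filter ",
         "all-zero segments before normalization")
  sf <- apply(counts, 2, function(col)
    exp(stats::median((log(col) - loggeo)[ok])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor; too many zero counts")
  sf
}

#' Per-segment fold changes between conditions
#'
#' For every segment, the ratio of the mean normalized depth over the test
#' condition's replicates to the mean over the reference condition's
#' replicates. Segments whose reference mean is zero get `NA`.
#'
#' @param x A [segment_counts()] object.
#' @param size_factors Optional size factors (computed from the counts when
#'   missing).
#' @return Data.frame with gene_id, segment_index and `fc`.
#' @export
segment_fold_changes <- function(x, size_factors = NULL) {
  stopifnot(inherits(x, "segment_counts"))
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(x)
  norm <- sweep(x$depth, 2, size_factors, "/")
  ref <- x$condition == levels(x$condition)[1]
  m_ref <- rowMeans(norm[, ref, drop = FALSE])
  m_test <- rowMeans(norm[, !ref, drop = FALSE])
  fc <- ifelse(m_ref == 0, NA_real_, m_test / m_ref)
  data.frame(gene_id = x$gene_id, segment_index = x$segment_index,
             fc = fc, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Input p-values must lie in
#' [0, 1]; `NA`s are propagated.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted values (monotone in `p`).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
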