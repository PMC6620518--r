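#' Median-of-ratios size factors
#'
#' Computes the per-sample size factor of the median-of-ratios procedure:
#' each sample's factor is the median, over reference genes, of the ratio of
#' its count to that gene's geometric mean across samples. Reference genes
#' are those with strictly positive counts in every sample (genes with any
#' zero are excluded so the geometric mean is defined). Real-valued counts —
#' e.g. in-silico mixtures — are accepted.
#'
#' @param m a [count_matrix()] or a numeric genes-by-samples matrix.
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else m
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`m` must be a count_matrix or numeric matrix")
  }
  if (ncol(counts) < 2L) abort("size factors need >= 2 samples")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    abort("no gene has strictly positive counts in every sample; size factors undefined")
  }
  lc <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lc)   # log geometric mean per reference gene
  sf <- exp(apply(lc - geo, 2, stats::median))
  names(sf) <- colnames(counts)
  sf
}

#' Depth-normalize counts for classification
#'
#' Scales each sample by its size factor and applies the classifier-facing
#' transform `log2(count / factor + 1)`. Shape and dimnames are preserved.
#'
#' @param m a [count_matrix()] or numeric matrix.
#' @param f positive size factors, one per sample (default
#'   [size_factors()] of `m`).
#' @return numeric matrix of normalized log2 expression.
#' @export
normalize_counts <- function(m, f = size_factors(m)) {
  counts <- if (inherits(m, "count_matrix")) m$counts else m
  if (length(f) != ncol(counts)) {
    abort("size factors (%d) do not match samples (%d)",
          length(f), ncol(counts))
  }
  if (any(!is.finite(f)) || any(f <= 0)) abort("size factors must be > 0")
  if (!is.null(names(f)) && !is.null(colnames(counts)) &&
      !identical(names(f), colnames(counts))) {
    if (!setequal(names(f), colnames(counts))) {
      abort("size factor names do not match sample names")
    }
    f <- f[colnames(counts)]
  }
  log2(sweep(counts, 2, f, "/") + 1)
}
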