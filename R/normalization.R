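#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: for each gene expressed in every
#' sample, form the ratio of its count in a sample to its across-sample
#' geometric mean; the sample's size factor is the median of these ratios,
#' rescaled so the size factors themselves have geometric mean 1.
#'
#' @param counts integer gene-by-sample matrix, or a `count_dataset`.
#' @return named positive numeric vector, one entry per sample, geometric
#'   mean 1.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "count_dataset")) counts <- counts$counts
  stopifnot(is.matrix(counts))
  log_geo <- rowMeans(log(counts))      # -Inf for genes with any zero
  use <- is.finite(log_geo)
  if (!any(use))
    stop2("no gene has nonzero counts in all samples; cannot normalize")
  log_ratios <- log(counts[use, , drop = FALSE]) - log_geo[use]
  sf <- exp(apply(log_ratios, 2L, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}
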