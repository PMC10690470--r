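#' Significance rule for shrunken fold changes
#'
#' A gene is called significantly regulated in a comparison when its
#' Benjamini-Hochberg adjusted p-value is at most `padj_max` and the
#' absolute shrunken log2 fold change is at least `abs_lfc_min`. Both
#' boundaries are inclusive. Defaults: adjusted p <= 0.01 and |shrunken
#' log2 FC| >= 1.
#'
#' @param padj_max adjusted p-value ceiling (> 0).
#' @param abs_lfc_min minimum absolute shrunken log2 fold change (> 0).
#' @return a `calling_config` list.
#' @export
calling_config <- function(padj_max = 0.01, abs_lfc_min = 1) {
  if (padj_max <= 0 || abs_lfc_min <= 0)
    stop2("both thresholds must be positive")
  structure(list(padj_max = padj_max, abs_lfc_min = abs_lfc_min),
            class = "calling_config")
}

#' Apply the significance rule to a contrast result
#'
#' @param result a `contrast_result` with shrunken fold changes filled
#'   (see [shrink_lfc()]); calling on raw estimates is refused so the rule
#'   is never silently applied to unshrunken values.
#' @param config a [calling_config()].
#' @return the result with the `significant` column filled (`NA` for genes
#'   whose statistics are missing).
#' @export
call_significant <- function(result, config = calling_config()) {
  stopifnot(inherits(result, "contrast_result"),
            inherits(config, "calling_config"))
  if (all(is.na(result$lfc_shrunk)))
    stop2("shrunken fold changes are missing; run shrink_lfc() first")
  result$significant <- result$padj <= config$padj_max &
    abs(result$lfc_shrunk) >= config$abs_lfc_min
  result
}

#' Tally regulated genes per comparison
#'
#' @param results named list of called `contrast_result`s (names are the
#'   comparison labels, e.g. `"ATP vs mock at 3 h"`).
#' @return list with `per_comparison` (named integer vector of significant
#'   genes per comparison) and `union` (number of genes significant in at
#'   least one comparison).
#' @export
count_regulated <- function(results) {
  if (!length(results)) stop2("no contrast results supplied")
  for (r in results) {
    stopifnot(inherits(r, "contrast_result"))
    if (all(is.na(r$significant)))
      stop2("significance calls missing for comparison '",
            r$comparison[1L], "'; run call_significant() first")
  }
  per <- vapply(results, function(r) sum(r$significant, na.rm = TRUE),
                integer(1))
  if (is.null(names(results)))
    names(per) <- vapply(results, function(r) r$comparison[1L], "")
  sig_genes <- unique(unlist(lapply(results, function(r)
    r$gene[which(r$significant)])))
  list(per_comparison = per, union = length(sig_genes),
       union_genes = sig_genes)
}

#' Gene-by-comparison matrix of shrunken fold changes
#'
#' Assembles the matrix behind fold-change heat maps: rows are the
#' requested genes in the requested order, columns the comparisons in the
#' order given. Values are taken verbatim from the contrast results.
#'
#' @param results named list of `contrast_result`s with `lfc_shrunk`
#'   filled.
#' @param genes character vector of gene ids (non-empty; all must be
#'   present in every result).
#' @return numeric matrix genes x comparisons.
#' @export
lfc_heatmap_matrix <- function(results, genes) {
  if (!length(genes)) stop2("'genes' must be non-empty")
  if (!length(results)) stop2("no contrast results supplied")
  cols <- names(results)
  if (is.null(cols))
    cols <- vapply(results, function(r) r$comparison[1L], "")
  m <- matrix(NA_real_, length(genes), length(results),
              dimnames = list(genes, cols))
  for (j in seq_along(results)) {
    r <- results[[j]]
    idx <- match(genes, r$gene)
    if (anyNA(idx))
      stop2("gene(s) absent from comparison '", cols[j], "': ",
            paste(genes[is.na(idx)], collapse = ", "))
    m[, j] <- r$lfc_shrunk[idx]
  }
  m
}
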