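#' Variance-stabilizing transform of normalized counts
#'
#' Two monotone transforms of size-factor-normalized counts `q = count/sf`:
#'
#' * `"log"` (default): `log2(q + 0.5)` — the shifted-log transform; simple
#'   and adequate for sample-level summaries such as PCA.
#' * `"trend"`: the closed-form variance-stabilizer implied by the fitted
#'   dispersion trend `alpha(mu) = a0 + a1/mu`, under which
#'   `var = (1 + a1) mu + a0 mu^2`; integrating `1/sqrt(var)` gives
#'   `2/sqrt(a0) * asinh(sqrt(a0 q / (1 + a1)))`, reported divided by
#'   `log(2)` so large counts approach the log2 scale.
#'
#' @param counts integer gene-by-sample matrix or `count_dataset`.
#' @param size_factors per-sample factors.
#' @param method `"log"` or `"trend"`.
#' @param trend_coef named numeric `c(a0, a1)`; required for
#'   `method = "trend"` (take it from `attr(estimate_dispersions(...),
#'   "trend_coef")`).
#' @return numeric gene-by-sample matrix.
#' @export
vst <- function(counts, size_factors, method = c("log", "trend"),
                trend_coef = NULL) {
  if (inherits(counts, "count_dataset")) counts <- counts$counts
  method <- match.arg(method)
  if (any(counts < 0)) stop2("counts must be non-negative")
  if (length(size_factors) != ncol(counts) || any(size_factors <= 0))
    stop2("one positive size factor per sample is required")
  q <- sweep(counts, 2L, size_factors, "/")
  if (method == "log") return(log2(q + 0.5))
  if (is.null(trend_coef) || !all(c("a0", "a1") %in% names(trend_coef)))
    stop2("'trend_coef' with named a0, a1 is required for method = 'trend'")
  a0 <- trend_coef[["a0"]]
  a1 <- trend_coef[["a1"]]
  if (a0 <= 0) stop2("trend a0 must be positive for the asinh transform")
  2 / sqrt(a0) * asinh(sqrt(a0 * q / (1 + a1))) / log(2)
}

#' PCA of samples on a transformed expression matrix
#'
#' Singular value decomposition of the gene-centered matrix; samples are
#' projected onto the principal axes. Sign convention: each component is
#' flipped so that its largest-magnitude gene loading is positive, making
#' scores deterministic. Variance-explained fractions are relative to the
#' total variance across all components.
#'
#' @param x numeric gene-by-sample matrix (e.g. from [vst()]).
#' @param n_components number of components to return (at most
#'   `min(n_samples, n_genes)`).
#' @return list with `scores` (samples x components), `loadings`
#'   (genes x components, orthonormal columns), `variance_explained`
#'   (fractions), `sdev`.
#' @export
pca_samples <- function(x, n_components = 2L) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) stop2("PCA needs at least two samples")
  if (n_components > min(dim(x)))
    stop2("n_components exceeds the matrix rank bound")
  xc <- x - rowMeans(x)                 # center each gene
  sv <- svd(t(xc), nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u[, seq_len(n_components), drop = FALSE], 2L,
                  sv$d[seq_len(n_components)] * flip, "*")
  loadings <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 2L,
                    flip, "*")
  rownames(scores) <- colnames(x)
  rownames(loadings) <- rownames(x)
  colnames(scores) <- colnames(loadings) <-
    paste0("PC", seq_len(n_components))
  var_all <- sv$d^2 / max(sum(sv$d^2), .Machine$double.eps)
  list(scores = scores, loadings = loadings,
       variance_explained = var_all[seq_len(n_components)],
       sdev = sv$d / sqrt(max(ncol(x) - 1L, 1L)))
}
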