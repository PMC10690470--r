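# Negative-binomial GLM with log link, fitted per gene by IRLS.
# Internally everything is on the natural-log scale; coefficients, standard
# errors and contrasts are converted to log2 only at the interface.

LOG2 <- log(2)

# One gene: IRLS for NB(mu, alpha) with log link and offset log(sf).
# Returns beta (natural log), covariance matrix, deviance, iterations,
# convergence flag.
nb_irls_single <- function(y, X, offset, alpha, tol = 1e-6, max_iter = 100L) {
  p <- ncol(X)
  beta <- tryCatch(
    qr.solve(X, log(pmax(y, 0.5)) - offset),
    error = function(e) rep(0, p))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    if (any(!is.finite(w)) || all(w < 1e-12)) break
    z <- (eta - offset) + (y - mu) / mu
    sw <- sqrt(w)
    ls <- tryCatch(stats::.lm.fit(X * sw, z * sw),
                   error = function(e) NULL)
    if (is.null(ls) || ls$rank < p) break
    new_beta <- ls$coefficients[order(ls$pivot)]
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  fisher <- t(X * w) %*% X
  cov <- tryCatch(solve(fisher), error = function(e) matrix(NA_real_, p, p))
  dev <- -2 * sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  list(beta = beta, cov = cov, deviance = dev, iter = it,
       converged = converged)
}

#' Fit the negative-binomial GLM gene by gene
#'
#' Iteratively reweighted least squares on the log link with per-sample
#' offsets `log(size factor)` and fixed per-gene dispersions. Convergence
#' is declared when the largest coefficient update falls below `tol`
#' (natural-log scale) or after `max_iter` iterations; non-converged genes
#' are flagged, never dropped. Standard errors come from the inverse Fisher
#' information at the optimum.
#'
#' @param counts integer gene-by-sample matrix or `count_dataset`.
#' @param size_factors per-sample positive factors
#'   (see [estimate_size_factors()]).
#' @param dispersions per-gene NB dispersion `alpha` (var = mu + alpha*mu^2),
#'   a single value recycled or a vector of length `nrow(counts)`; typically
#'   the `final` column of [estimate_dispersions()].
#' @param design a `design_matrix` (full rank enforced at construction).
#' @param tol,max_iter IRLS stopping rule.
#' @return object of class `nb_fit`: `coefficients` and `se` are
#'   gene-by-coefficient matrices in log2 units, `cov` a list of
#'   per-gene covariance matrices (log2^2 units), plus `deviance`,
#'   `iterations`, `converged`, `dispersions`, and the design.
#' @export
fit_nb_glm <- function(counts, size_factors, dispersions, design,
                       tol = 1e-6, max_iter = 100L) {
  if (inherits(counts, "count_dataset")) counts <- counts$counts
  X <- unclass(design)
  attributes(X)[setdiff(names(attributes(X)), c("dim", "dimnames"))] <- NULL
  if (nrow(X) != ncol(counts))
    stop2("design rows and count columns disagree")
  if (!is.null(rownames(X)) &&
      !identical(rownames(X), colnames(counts)))
    stop2("design row order does not match count column order")
  if (length(size_factors) != ncol(counts))
    stop2("one size factor per sample is required")
  if (any(size_factors <= 0)) stop2("size factors must be positive")
  ng <- nrow(counts)
  if (length(dispersions) == 1L) dispersions <- rep(dispersions, ng)
  if (length(dispersions) != ng)
    stop2("one dispersion per gene is required")
  if (any(!is.na(dispersions) & dispersions <= 0))
    stop2("dispersions must be positive")

  offset <- log(size_factors)
  p <- ncol(X)
  beta <- matrix(NA_real_, ng, p, dimnames = list(rownames(counts),
                                                  colnames(X)))
  se <- beta
  covs <- vector("list", ng)
  names(covs) <- rownames(counts)
  dev <- iter <- stats::setNames(rep(NA_real_, ng), rownames(counts))
  conv <- stats::setNames(rep(FALSE, ng), rownames(counts))
  all_zero <- rowSums(counts) == 0

  for (g in seq_len(ng)) {
    if (all_zero[g] || is.na(dispersions[g])) next
    fit <- nb_irls_single(counts[g, ], X, offset, dispersions[g],
                          tol = tol, max_iter = max_iter)
    beta[g, ] <- fit$beta / LOG2
    se[g, ] <- sqrt(pmax(diag(fit$cov), 0)) / LOG2
    covs[[g]] <- fit$cov / LOG2^2
    dev[g] <- fit$deviance
    iter[g] <- fit$iter
    conv[g] <- fit$converged
  }
  structure(list(coefficients = beta, se = se, cov = covs,
                 deviance = dev, iterations = iter, converged = conv,
                 all_zero = all_zero, dispersions = dispersions,
                 size_factors = size_factors, design = design,
                 df_residual = nrow(X) - p),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("nb_fit: %d genes, %d coefficients; %d converged, %d all-zero\n",
              nrow(x$coefficients), ncol(x$coefficients),
              sum(x$converged), sum(x$all_zero)))
  invisible(x)
}

#' Wald test of a linear contrast of GLM coefficients
#'
#' For each gene computes the contrast estimate `c' beta` (log2 fold
#' change), its standard error `sqrt(c' Cov c)` and the two-sided Wald
#' p-value, then Benjamini-Hochberg-adjusts the p-values within this
#' comparison. The Wald statistic is referred to a t distribution with the
#' design's residual degrees of freedom — the small-sample-honest version
#' of the asymptotic normal tail, which it approaches as replication
#' grows; with few residual df the normal reference is measurably liberal.
#'
#' @param fit an `nb_fit`.
#' @param contrast named contrast vector over the design columns, e.g.
#'   from [contrast_treatment_vs_mock()].
#' @return data frame of class `contrast_result` with columns `gene`,
#'   `lfc_mle`, `se`, `wald_p`, `padj`, and columns `lfc_shrunk` /
#'   `significant` initialized to `NA` for the shrinkage and calling
#'   stages; the comparison label is kept in the `comparison` column.
#' @export
wald_contrast <- function(fit, contrast) {
  stopifnot(inherits(fit, "nb_fit"))
  cn <- colnames(fit$coefficients)
  if (is.null(names(contrast)) || !all(names(contrast) %in% cn))
    stop2("contrast names must match design coefficients")
  w <- stats::setNames(numeric(length(cn)), cn)
  w[names(contrast)] <- contrast
  if (all(w == 0)) stop2("contrast vector is identically zero")
  label <- attr(contrast, "label")
  if (is.null(label)) label <- paste(names(contrast)[contrast != 0],
                                     collapse = "+")
  ng <- nrow(fit$coefficients)
  lfc <- drop(fit$coefficients %*% w)
  se <- vapply(seq_len(ng), function(g) {
    V <- fit$cov[[g]]
    if (is.null(V) || anyNA(V)) return(NA_real_)
    sqrt(max(drop(t(w) %*% V %*% w), 0))
  }, numeric(1))
  z <- lfc / se
  df <- fit$df_residual
  p <- if (!is.null(df) && is.finite(df) && df >= 1) {
    2 * stats::pt(-abs(z), df = df)
  } else {
    2 * stats::pnorm(-abs(z))
  }
  res <- data.frame(gene = rownames(fit$coefficients),
                    comparison = label,
                    lfc_mle = lfc, se = se, wald_p = p,
                    padj = bh_adjust(p),
                    lfc_shrunk = NA_real_, significant = NA,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validated wrapper over the step-up false-discovery-rate adjustment:
#' values must lie in `[0, 1]`; missing values are propagated and do not
#' count toward the number of tests.
#'
#' @param p numeric vector of p-values (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop2("'p' must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop2("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
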