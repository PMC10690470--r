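# Empirical-Bayes shrinkage of log2 fold changes under a zero-centered
# scale mixture of normals: lfc_g ~ sum_k w_k N(0, sigma_k^2), observed
# lfc_mle_g ~ N(lfc_g, se_g^2). The mixture weights are fit by penalized
# EM on the marginal likelihood; posterior means then have a closed form
# per component. The unimodal-at-zero assumption matches adaptive
# shrinkage; normal components (rather than uniforms) are used for their
# conjugate closed-form posteriors.

#' Fit the zero-centered mixture prior for fold-change shrinkage
#'
#' Maximizes the marginal likelihood
#' `prod_g sum_k w_k N(lfc_g; 0, sigma_k^2 + se_g^2)` over the simplex of
#' mixture weights by EM, with a pseudo-count penalty on the null (sigma =
#' 0) component that biases the prior toward zero effect when the data
#' allow. The scale grid is fixed: a point mass at 0 plus a geometric
#' ladder from `min(se)/10` to `2 * max(|lfc|)`.
#'
#' @param lfc_mle per-gene fold-change estimates (log2).
#' @param se per-gene positive standard errors (log2).
#' @param n_components number of grid scales including the null point
#'   mass.
#' @param null_pseudocount Dirichlet pseudo-count added to the null
#'   component during the M step (larger = stronger bias to zero).
#' @param tol EM stops when the penalized log-likelihood improves by less
#'   than this.
#' @param max_iter iteration cap.
#' @return object of class `shrinkage_prior`: `scales` (increasing, first
#'   element 0), `weights` (simplex), `loglik` (marginal log-likelihood
#'   trace), `converged`.
#' @export
fit_lfc_prior <- function(lfc_mle, se, n_components = 20,
                          null_pseudocount = 10, tol = 1e-8,
                          max_iter = 20000L) {
  ok <- is.finite(lfc_mle) & is.finite(se) & se > 0
  if (sum(ok) < 10L)
    stop2("fewer than 10 usable genes; the prior is unidentifiable")
  x <- lfc_mle[ok]
  s <- se[ok]
  lo <- min(s) / 10
  hi <- max(2 * max(abs(x)), lo * 2)
  scales <- c(0, exp(seq(log(lo), log(hi), length.out = n_components - 1L)))
  K <- length(scales)
  ng <- length(x)

  # ng x K matrix of log N(x; 0, sigma_k^2 + se^2), scaled per gene by its
  # row maximum so the likelihoods can be exponentiated safely; the scaling
  # constant only shifts the log-likelihood by sum(row_max)
  log_lik <- vapply(seq_len(K), function(k) {
    stats::dnorm(x, 0, sqrt(scales[k]^2 + s^2), log = TRUE)
  }, numeric(ng))
  row_max <- apply(log_lik, 1L, max)
  lik <- exp(log_lik - row_max)
  ll_const <- sum(row_max)

  pen <- c(null_pseudocount, rep(1, K - 1L))  # Dirichlet(pen) prior
  w <- rep(1 / K, K)
  ll_trace <- pll_trace <- numeric(max_iter)
  converged <- FALSE
  pll_old <- -Inf
  it_done <- 0L
  for (it in seq_len(max_iter)) {
    marg <- drop(lik %*% w)                # scaled marginal per gene
    ll <- sum(log(marg)) + ll_const
    pll <- ll + sum((pen - 1) * log(pmax(w, 1e-300)))
    it_done <- it
    ll_trace[it] <- ll
    pll_trace[it] <- pll
    if (is.finite(pll_old) && pll - pll_old < tol) { converged <- TRUE; break }
    pll_old <- pll
    # M step: column sums of responsibilities r_gk = w_k lik_gk / marg_g
    csum <- w * drop(crossprod(lik, 1 / marg))
    w <- pmax(csum + pen - 1, 0)
    w <- w / sum(w)
  }
  ll_trace <- ll_trace[seq_len(it_done)]
  pll_trace <- pll_trace[seq_len(it_done)]
  structure(list(scales = scales, weights = w, loglik = ll_trace,
                 penalized_loglik = pll_trace, converged = converged),
            class = "shrinkage_prior")
}

#' Posterior-mean shrunken fold changes
#'
#' Given the fitted mixture prior, each gene's posterior over components
#' has responsibilities `r_k proportional to w_k N(lfc; 0, sigma_k^2 +
#' se^2)`; within component k the posterior mean is the conjugate-normal
#' shrinkage `lfc * sigma_k^2 / (sigma_k^2 + se^2)`. The returned estimate
#' is the responsibility-weighted average, which always lies between 0 and
#' the input estimate (same sign, smaller magnitude).
#'
#' @param prior a `shrinkage_prior` from [fit_lfc_prior()].
#' @param lfc_mle,se per-gene estimates and standard errors (log2).
#' @return data frame with columns `mean` (posterior mean log2 fold
#'   change) and `sd` (posterior standard deviation); rows follow the
#'   input order, `NA` where the inputs were unusable.
#' @export
posterior_mean_lfc <- function(prior, lfc_mle, se) {
  stopifnot(inherits(prior, "shrinkage_prior"))
  out <- data.frame(mean = rep(NA_real_, length(lfc_mle)),
                    sd = NA_real_)
  ok <- is.finite(lfc_mle) & is.finite(se) & se > 0
  if (!any(ok)) return(out)
  x <- lfc_mle[ok]
  s <- se[ok]
  K <- length(prior$scales)
  ng <- length(x)
  lw <- vapply(seq_len(K), function(k) {
    stats::dnorm(x, 0, sqrt(prior$scales[k]^2 + s^2), log = TRUE) +
      log(pmax(prior$weights[k], 1e-300))
  }, numeric(ng))
  lw <- matrix(lw, ng, K)
  m <- apply(lw, 1L, max)
  r <- exp(lw - (m + log(rowSums(exp(lw - m)))))
  shrink_factor <- matrix(vapply(seq_len(K), function(k) {
    prior$scales[k]^2 / (prior$scales[k]^2 + s^2)
  }, numeric(ng)), ng, K)
  comp_mean <- shrink_factor * x                 # ng x K
  comp_var <- matrix(vapply(seq_len(K), function(k) {
    prior$scales[k]^2 * s^2 / (prior$scales[k]^2 + s^2)
  }, numeric(ng)), ng, K)
  post_mean <- rowSums(r * comp_mean)
  post_var <- rowSums(r * (comp_var + comp_mean^2)) - post_mean^2
  out$mean[ok] <- post_mean
  out$sd[ok] <- sqrt(pmax(post_var, 0))
  out
}

#' Shrink the fold changes of a contrast result
#'
#' Convenience wrapper: fits the mixture prior on one comparison's
#' estimates and fills the `lfc_shrunk` column.
#'
#' @param result a `contrast_result` from [wald_contrast()].
#' @param ... passed to [fit_lfc_prior()].
#' @return the result with `lfc_shrunk` filled and the fitted prior in
#'   attribute `prior`.
#' @export
shrink_lfc <- function(result, ...) {
  stopifnot(inherits(result, "contrast_result"))
  prior <- fit_lfc_prior(result$lfc_mle, result$se, ...)
  post <- posterior_mean_lfc(prior, result$lfc_mle, result$se)
  result$lfc_shrunk <- post$mean
  attr(result, "prior") <- prior
  result
}
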