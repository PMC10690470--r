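# Shared fixtures: small simulation configs, a noise-free integer-mean
# dataset with known coefficients, and toy gene-set collections.

small_config <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 200, treatments = c("mock", "ATP"),
                   time_points = c(1, 2, 3), n_replicates = 3,
                   dispersion = c(a0 = 0.05, a1 = 2), seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

null_config <- function(seed = 1L, ...) {
  small_config(seed = seed, fraction_responsive = 0, mock_drift_sd = 0, ...)
}

# Noise-free fixture: counts equal their means exactly, and all log2
# coefficients are integers so that the means are integers. Returns the
# counts, metadata, design and the true coefficient vector in design order.
noise_free_fixture <- function(time_grid = c(1, 2, 3, 4, 6),
                               treatments = c("mock", "Ap4A", "ATP",
                                              "ADP", "UTP", "UDP"),
                               n_replicates = 3, baseline = 6,
                               drift = NULL, increments = NULL,
                               seed = 42L) {
  set.seed(seed)
  trt_eff <- setdiff(treatments, "mock")
  nt <- length(time_grid)
  if (is.null(drift)) drift <- sample(0:1, nt - 1L, replace = TRUE)
  if (is.null(increments)) {
    increments <- matrix(sample(c(-1L, 0L, 1L, 2L), length(trt_eff) * nt,
                                replace = TRUE), length(trt_eff), nt,
                         dimnames = list(trt_eff, time_grid))
  }
  meta <- expand.grid(replicate = seq_len(n_replicates),
                      time_h = time_grid, treatment = treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%gh_r%d", meta$treatment, meta$time_h,
                         meta$replicate)
  meta <- meta[, c("sample", "treatment", "time_h", "replicate")]
  design <- build_cumulative_design(meta, time_grid, treatments, "mock")

  beta_true <- stats::setNames(numeric(ncol(design)), colnames(design))
  beta_true["Intercept"] <- baseline + 0   # first drift step absorbed
  if (nt > 1L) beta_true[paste0("after_", time_grid[-1L])] <- drift
  for (a in trt_eff)
    beta_true[paste0(a, ":after_", time_grid)] <- increments[a, ]

  log2mu <- drop(unclass(design) %*% beta_true)
  counts <- matrix(as.integer(round(2^log2mu)), nrow = 1L)
  # several identical genes so matrix-shaped code paths are exercised
  counts <- rbind(gene1 = counts[1L, ], gene2 = counts[1L, ] * 2L,
                  gene3 = as.integer(2^(log2mu + 1)))
  colnames(counts) <- meta$sample
  list(counts = counts, meta = meta, design = design,
       beta_true = beta_true, increments = increments,
       time_grid = time_grid, treatments = treatments)
}

toy_collection <- function() {
  gene_set_collection(list(
    T_disjoint_a = paste0("g", 1:10),
    T_disjoint_b = paste0("g", 11:20),
    T_disjoint_c = paste0("g", 21:30),
    T_overlap_a = paste0("g", 31:50),
    T_overlap_b = paste0("g", c(31:48, 51, 52)),
    T_overlap_c = paste0("g", c(31:48, 53, 54))
  ), descriptions = c(T_disjoint_a = "a", T_disjoint_b = "b",
                      T_disjoint_c = "c", T_overlap_a = "oa",
                      T_overlap_b = "ob", T_overlap_c = "oc"))
}

# Independent log-gamma hypergeometric oracle: upper-tail P(X >= k) by
# explicit enumeration of point masses, using only lgamma().
hyper_upper_tail <- function(k, K, n, N) {
  lchoose2 <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  hi <- min(K, n)
  if (k > hi) return(0)
  x <- k:hi
  terms <- lchoose2(K, x) + lchoose2(N - K, n - x) - lchoose2(N, n)
  sum(exp(terms))
}
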