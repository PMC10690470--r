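# Two-group helper design used across GLM tests
two_group_design <- function(n_per = 3L) {
  meta <- data.frame(sample = sprintf("s%d", seq_len(2L * n_per)),
                     treatment = rep(c("mock", "ATP"), each = n_per),
                     time_h = 1)
  build_cumulative_design(meta, 1, c("mock", "ATP"), "mock")
}

test_that("constant counts yield a flat fit with intercept log2(count/sf)", {
  X <- two_group_design()
  counts <- matrix(64L, 2, 6,
                   dimnames = list(c("g1", "g2"), rownames(X)))
  fit <- fit_nb_glm(counts, rep(1, 6), 0.05, X)
  expect_true(all(fit$converged))
  expect_equal(unname(fit$coefficients[, "Intercept"]), c(6, 6),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[, "ATP:after_1"]), c(0, 0),
               tolerance = 1e-6)
})

test_that("near-Poisson two-group fit equals log2 ratio of normalized means", {
  X <- two_group_design(4L)
  mock <- c(400L, 404L, 396L, 400L)
  atp <- c(1600L, 1616L, 1584L, 1600L)
  counts <- matrix(c(mock, atp), 1, 8,
                   dimnames = list("g1", rownames(X)))
  fit <- fit_nb_glm(counts, rep(1, 8), 1e-8, X)
  expect_equal(unname(fit$coefficients[1, "ATP:after_1"]),
               log2(mean(atp) / mean(mock)), tolerance = 1e-6)
})

test_that("planted one-interval increment is recovered on low-noise counts", {
  # deterministic means with a +1 log2 step: alpha ~ 0 so the MLE must
  # land within 0.05 of the planted coefficient
  grid <- c(1, 2)
  meta <- expand.grid(replicate = 1:3, time_h = grid,
                      treatment = c("mock", "ATP"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%g_%d", meta$treatment, meta$time_h,
                         meta$replicate)
  X <- build_cumulative_design(meta, grid, c("mock", "ATP"), "mock")
  set.seed(4)
  log2mu <- 13 + (meta$treatment == "ATP" & meta$time_h >= 2) * 1
  counts <- matrix(rpois(nrow(meta), 2^log2mu), 1, nrow(meta),
                   dimnames = list("g1", meta$sample))
  fit <- fit_nb_glm(counts, rep(1, nrow(meta)), 1e-6, X)
  expect_lt(abs(fit$coefficients[1, "ATP:after_2"] - 1), 0.05)
  expect_lt(abs(fit$coefficients[1, "ATP:after_1"]), 0.05)
})

test_that("IRLS optimum matches a brute-force likelihood scan", {
  # one gene, intercept-only model: profile the NB log-likelihood on a
  # fine grid of the single coefficient and compare to the IRLS solution
  set.seed(8)
  y <- rnbinom(12, mu = 90, size = 1 / 0.08)
  meta <- data.frame(sample = sprintf("s%d", 1:12), treatment = "mock",
                     time_h = 1)
  X <- build_cumulative_design(meta, 1, "mock", "mock")
  fit <- fit_nb_glm(matrix(y, 1, dimnames = list("g1", meta$sample)),
                    rep(1, 12), 0.08, X)
  grid_beta <- seq(log(30), log(300), length.out = 20001)
  ll <- vapply(grid_beta, function(b)
    sum(dnbinom(y, mu = exp(b), size = 1 / 0.08, log = TRUE)), numeric(1))
  best <- grid_beta[which.max(ll)] / log(2)
  expect_lt(abs(fit$coefficients[1, "Intercept"] - best), 1e-3)
})

test_that("contrast estimates are offset invariant", {
  cfg <- small_config(n_genes = 60, seed = 31L, fraction_responsive = 0.3)
  sim <- simulate_timecourse(cfg)
  counts <- sim$dataset$counts
  meta <- sim$dataset$samples
  X <- build_cumulative_design(meta, cfg$time_points, cfg$treatments, "mock")
  sf <- estimate_size_factors(counts)

  fit1 <- fit_nb_glm(counts, sf, 0.05, X)
  counts2 <- counts
  counts2[, 1] <- counts2[, 1] * 2L
  fit2 <- fit_nb_glm(counts2, sf * c(2, rep(1, length(sf) - 1L)), 0.05, X)
  w <- contrast_treatment_vs_mock(X, "ATP", 3)
  r1 <- wald_contrast(fit1, w)
  r2 <- wald_contrast(fit2, w)
  expect_equal(r1$lfc_mle, r2$lfc_mle, tolerance = 1e-4)
  expect_equal(r1$se, r2$se, tolerance = 1e-4)
})

test_that("wald p-values are uniform under the null and monotone in se", {
  cfg <- null_config(n_genes = 2000, seed = 19L)
  sim <- simulate_timecourse(cfg)
  res <- with(sim, {
    X <- build_cumulative_design(dataset$samples, cfg$time_points,
                                 cfg$treatments, "mock")
    sf <- estimate_size_factors(dataset$counts)
    disp <- estimate_dispersions(dataset$counts, sf, X)
    fit <- fit_nb_glm(dataset$counts, sf, disp$final, X)
    wald_contrast(fit, contrast_treatment_vs_mock(X, "ATP", 2))
  })
  p <- res$wald_p[!is.na(res$wald_p)]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)

  # p -> 1 monotonically as se grows at fixed lfc
  ps <- 2 * pnorm(-abs(1 / c(0.5, 1, 2, 4, 8)))
  expect_true(all(diff(ps) > 0))
})

test_that("zero and incompatible contrasts are rejected", {
  X <- two_group_design()
  counts <- matrix(50L, 1, 6, dimnames = list("g1", rownames(X)))
  fit <- fit_nb_glm(counts, rep(1, 6), 0.1, X)
  w <- stats::setNames(numeric(2), colnames(X))
  expect_error(wald_contrast(fit, w), "identically zero")
  bad <- stats::setNames(1, "nonexistent")
  expect_error(wald_contrast(fit, bad), "match design coefficients")
})

test_that("all-zero genes are flagged and never fitted", {
  X <- two_group_design()
  counts <- rbind(g1 = rep(30L, 6), g2 = rep(0L, 6))
  colnames(counts) <- rownames(X)
  fit <- fit_nb_glm(counts, rep(1, 6), 0.1, X)
  expect_true(fit$all_zero["g2"])
  expect_true(all(is.na(fit$coefficients["g2", ])))
  expect_false(fit$converged["g2"])
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, NA, 0.5, 0.01)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[!is.na(adj)],
               stats::p.adjust(p[!is.na(p)], method = "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # adjusted never below raw
  set.seed(6)
  q <- runif(100)
  expect_true(all(bh_adjust(q) >= q))
})

test_that("null type-I error is nominal once replication supports the normal tail", {
  # at 8 replicates per cell the Wald normal approximation is adequate;
  # the rejection rate at 0.05 must sit within 3 Monte-Carlo SEs
  fractions <- vapply(1:2, function(seed) {
    cfg <- sim_config(n_genes = 1500, treatments = c("mock", "ATP"),
                      time_points = c(1, 2, 3), n_replicates = 8,
                      dispersion = c(a0 = 0.05, a1 = 2),
                      fraction_responsive = 0, mock_drift_sd = 0,
                      seed = seed)
    sim <- simulate_timecourse(cfg)
    X <- build_cumulative_design(sim$dataset$samples, cfg$time_points,
                                 cfg$treatments, "mock")
    sf <- estimate_size_factors(sim$dataset$counts)
    disp <- estimate_dispersions(sim$dataset$counts, sf, X)
    fit <- fit_nb_glm(sim$dataset$counts, sf, disp$final, X)
    res <- wald_contrast(fit, contrast_treatment_vs_mock(X, "ATP", 3))
    mean(res$wald_p < 0.05, na.rm = TRUE)
  }, numeric(1))
  mc3 <- 3 * sqrt(0.05 * 0.95 / 1500)
  expect_true(all(abs(fractions - 0.05) < mc3))
})
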