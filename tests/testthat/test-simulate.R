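test_that("config validation rejects impossible settings", {
  expect_error(sim_config(treatments = c("ATP", "UTP")), "mock label")
  expect_error(sim_config(time_points = c(2, 1)), "strictly increasing")
  expect_error(sim_config(fraction_responsive = 1.5), "fraction_responsive")
  expect_error(sim_config(dispersion = c(-0.1, 1)), "a0 > 0")
  expect_error(sim_config(null_treatments = "XTP"), "null_treatments")
})

test_that("identical seeds give bitwise-identical datasets", {
  cfg <- small_config(seed = 7L)
  a <- simulate_timecourse(cfg)
  b <- simulate_timecourse(cfg)
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$truth$treatment_increments, b$truth$treatment_increments)
  c <- simulate_timecourse(small_config(seed = 8L))
  expect_false(identical(a$dataset$counts, c$dataset$counts))
})

test_that("a null configuration plants no effects anywhere", {
  sim <- simulate_timecourse(null_config())
  expect_true(all(sim$truth$treatment_increments == 0))
  expect_false(any(sim$truth$responsive))
  expect_true(all(ground_truth_lfc(sim$truth, "ATP", 3) == 0))
})

test_that("mock arm and null treatments carry zero increments", {
  cfg <- small_config(treatments = c("mock", "ATP", "UDP"),
                      null_treatments = "UDP", fraction_responsive = 0.5)
  sim <- simulate_timecourse(cfg)
  expect_true(all(sim$truth$treatment_increments[, "mock", ] == 0))
  expect_true(all(sim$truth$treatment_increments[, "UDP", ] == 0))
  expect_gt(sum(sim$truth$treatment_increments[, "ATP", ] != 0), 0)
})

test_that("counts obey the NB moment identity var = mu + alpha*mu^2", {
  # fixed alpha = 0.1, no effects, unit size factors, one condition cell
  # with many replicates; pooled mean-bins must recover the quadratic
  cfg <- sim_config(n_genes = 2000, treatments = c("mock", "ATP"),
                    time_points = 1, n_replicates = 50,
                    baseline_log2_range = c(3, 10),
                    dispersion = c(a0 = 0.1, a1 = 0),
                    fraction_responsive = 0, mock_drift_sd = 0,
                    size_factor_range = c(1, 1), seed = 11L)
  sim <- simulate_timecourse(cfg)
  m <- rowMeans(sim$dataset$counts)
  v <- apply(sim$dataset$counts, 1L, var)
  bins <- cut(log2(m), breaks = 7)
  obs <- tapply(v, bins, mean)
  pred <- tapply(m + 0.1 * m^2, bins, mean)
  keep <- !is.na(obs) & tabulate(bins)[seq_along(obs)] >= 50
  expect_true(all(abs(obs[keep] / pred[keep] - 1) < 0.10))
})

test_that("per-condition empirical means converge to the generative means", {
  cfg <- sim_config(n_genes = 50, treatments = c("mock", "ATP"),
                    time_points = 1, n_replicates = 200,
                    baseline_log2_range = c(6, 10),
                    dispersion = c(a0 = 0.05, a1 = 1),
                    fraction_responsive = 0.3, mock_drift_sd = 0,
                    size_factor_range = c(1, 1), seed = 3L)
  sim <- simulate_timecourse(cfg)
  atp <- sim$dataset$samples$treatment == "ATP"
  mu_true <- 2^(sim$truth$baseline_log2 +
                  sim$truth$treatment_increments[, "ATP", 1])
  rel_err <- abs(rowMeans(sim$dataset$counts[, atp]) / mu_true - 1)
  expect_lt(median(rel_err), 0.05)
  expect_lt(max(rel_err), 0.15)
})

test_that("ground-truth LFC is the cumulative sum of interval increments", {
  sim <- simulate_timecourse(small_config(fraction_responsive = 1,
                                          seed = 5L))
  inc <- sim$truth$treatment_increments[, "ATP", ]
  expect_equal(ground_truth_lfc(sim$truth, "ATP", 1), unname(inc[, 1]))
  expect_equal(ground_truth_lfc(sim$truth, "ATP", 3),
               unname(rowSums(inc)))
  expect_error(ground_truth_lfc(sim$truth, "mock", 3), "mock")
  expect_error(ground_truth_lfc(sim$truth, "ATP", 9), "not in the simulated")
  expect_error(ground_truth_lfc(sim$truth, "XTP", 3), "unknown treatment")
})

test_that("factorial truth is additive without interactions and shifted with them", {
  cfg <- small_config(treatments = c("mock", "ATP"), seed = 9L)
  no_int <- simulate_factorial(cfg,
    genotype_effect = list(fraction = 0.3, min = 0.5, max = 1.5,
                           prob_positive = 0.5),
    interaction_effect = list(fraction = 0, min = 0.5, max = 1,
                              prob_positive = 0.5))
  expect_equal(ground_truth_lfc_ko(no_int$truth, "ATP"),
               no_int$truth$genotype_lfc)
  expect_equal(ground_truth_lfc_ko(no_int$truth, "mock"),
               no_int$truth$genotype_lfc)

  with_int <- simulate_factorial(cfg,
    interaction_effect = list(fraction = 0.5, min = 2, max = 2,
                              prob_positive = 1))
  delta <- ground_truth_lfc_ko(with_int$truth, "ATP") -
    ground_truth_lfc_ko(with_int$truth, "mock")
  hit <- with_int$truth$interaction_lfc[, "ATP"] != 0
  expect_true(all(delta[hit] == 2))
  expect_true(all(delta[!hit] == 0))
})

test_that("factorial counts obey the same moment identity", {
  cfg <- sim_config(n_genes = 1500, treatments = c("mock", "ATP"),
                    n_replicates = 40, baseline_log2_range = c(3, 9),
                    dispersion = c(a0 = 0.1, a1 = 0),
                    fraction_responsive = 0, size_factor_range = c(1, 1),
                    seed = 13L)
  sim <- simulate_factorial(cfg,
    genotype_effect = list(fraction = 0, min = 1, max = 1,
                           prob_positive = 0.5))
  ntc_mock <- sim$dataset$samples$genotype == "NTC" &
    sim$dataset$samples$treatment == "mock"
  y <- sim$dataset$counts[, ntc_mock]
  m <- rowMeans(y)
  v <- apply(y, 1L, var)
  bins <- cut(log2(m), breaks = 6)
  obs <- tapply(v, bins, mean)
  pred <- tapply(m + 0.1 * m^2, bins, mean)
  keep <- !is.na(obs) & tabulate(bins)[seq_along(obs)] >= 40
  expect_true(all(abs(obs[keep] / pred[keep] - 1) < 0.12))
})

test_that("null datasets are exchangeable across arms within a time point", {
  sim <- simulate_timecourse(null_config(seed = 21L,
                                         size_factor_range = c(1, 1)))
  meta <- sim$dataset$samples
  at3 <- meta$time_h == 3
  mock_mean <- rowMeans(sim$dataset$counts[, at3 & meta$treatment == "mock"])
  atp_mean <- rowMeans(sim$dataset$counts[, at3 & meta$treatment == "ATP"])
  # paired per-gene comparison: no systematic shift between arms
  lr <- log2((atp_mean + 1) / (mock_mean + 1))
  expect_lt(abs(mean(lr)), 0.05)
  expect_gt(stats::t.test(lr)$p.value, 0.001)
})
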