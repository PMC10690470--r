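test_that("Fisher p equals brute-force hypergeometric enumeration", {
  # worked case k=3, K=10, n=5, N=100: sum of point masses for X in 3..5
  universe <- paste0("g", 1:100)
  term <- paste0("g", 1:10)
  hits <- c(paste0("g", 1:3), "g50", "g60")
  coll <- gene_set_collection(list(T1 = term))
  res <- fisher_enrichment(hits, universe, coll)
  expect_equal(res$p, hyper_upper_tail(3, 10, 5, 100), tolerance = 1e-12)
  expect_identical(c(res$k, res$K, res$n, res$N), c(3L, 10L, 5L, 100L))

  # no in-set hit: upper tail from zero is 1
  res0 <- fisher_enrichment(c("g50", "g60"), universe, coll)
  expect_equal(res0$p, 1)

  # term equal to the universe: k = n forced, p = 1
  coll_u <- gene_set_collection(list(TU = universe))
  resu <- fisher_enrichment(hits, universe, coll_u)
  expect_equal(resu$p, 1)

  expect_error(fisher_enrichment("gX", universe, coll), "subset")
  expect_error(fisher_enrichment("g1", character(0), coll), "empty universe")
})

test_that("Fisher p matches the log-gamma oracle on 1000 random tables", {
  set.seed(101)
  max_rel <- 0
  for (i in 1:1000) {
    N <- sample(20:500, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    p_pkg <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_oracle <- hyper_upper_tail(k, K, n, N)
    max_rel <- max(max_rel, abs(p_pkg - p_oracle) / p_oracle)
  }
  expect_lt(max_rel, 1e-10)
})

test_that("candidate filter is boundary-inclusive and monotone", {
  res <- data.frame(
    term = c("A", "A", "B", "C"),
    comparison = c("c1", "c2", "c1", "c1"),
    k = 1L, K = 2L, n = 3L, N = 10L, odds_ratio = 1,
    p = c(0.01, 0.001, 0.002, 5e-5))
  cand <- candidate_terms(res, p_max = 0.001)
  expect_identical(cand$term, c("C", "A"))          # sorted by best p
  expect_identical(cand$best_comparison, c("c1", "c2"))
  # B at 0.002 dropped; lowering p_max shrinks the set
  cand2 <- candidate_terms(res, p_max = 1e-4)
  expect_identical(cand2$term, "C")
  expect_true(all(cand2$term %in% cand$term))
})

test_that("disjoint significant terms are all selected with additive objective", {
  cand <- data.frame(term = c("T_disjoint_a", "T_disjoint_b", "T_disjoint_c"),
                     best_p = c(1e-6, 1e-5, 1e-4),
                     best_comparison = "c1", stringsAsFactors = FALSE)
  universe <- paste0("g", 1:60)
  sol <- select_cover(cand, toy_collection(), universe)
  expect_setequal(sol$selected, cand$term)
  expect_equal(sol$objective, 6 + 5 + 4, tolerance = 1e-12)
  ex <- select_cover(cand, toy_collection(), universe, solver = "exhaustive")
  expect_setequal(ex$selected, cand$term)
  expect_equal(ex$objective, sol$objective, tolerance = 1e-12)
})

test_that("accumulated overlap penalties drop a redundant term at lambda = 1", {
  # three terms sharing an 18-gene core (pairwise Jaccard 18/22): the
  # weakest near-duplicate loses more penalty against the two already
  # selected than its own evidence adds, so enumeration excludes it
  cand <- data.frame(term = c("T_overlap_a", "T_overlap_b", "T_overlap_c"),
                     best_p = c(1e-6, 1e-5, 1e-4),
                     best_comparison = "c1", stringsAsFactors = FALSE)
  universe <- paste0("g", 1:60)
  coll <- toy_collection()
  ex <- select_cover(cand, coll, universe, lambda = 1,
                     solver = "exhaustive")
  expect_setequal(ex$selected, c("T_overlap_a", "T_overlap_b"))
  gr <- select_cover(cand, coll, universe, lambda = 1)
  expect_setequal(gr$selected, ex$selected)

  # a single overlapping pair never loses its weaker member: the pairwise
  # penalty lambda*J*min(s) is below the weaker score whenever J < 1
  pair <- cand[1:2, ]
  ex2 <- select_cover(pair, coll, universe, lambda = 1,
                      solver = "exhaustive")
  expect_setequal(ex2$selected, pair$term)
})

test_that("lambda = 0 selects every candidate", {
  cand <- data.frame(term = c("T_overlap_a", "T_overlap_b"),
                     best_p = c(1e-6, 1e-5), best_comparison = "c1",
                     stringsAsFactors = FALSE)
  sol <- select_cover(cand, toy_collection(), paste0("g", 1:60), lambda = 0)
  expect_setequal(sol$selected, cand$term)
})

test_that("reported objective equals its recomputation from parts", {
  recompute <- function(sol, lambda) {
    s <- sol$score[sol$selected]
    val <- sum(s)
    if (length(s) > 1L) {
      for (i in seq_along(s)[-1L]) for (j in seq_len(i - 1L)) {
        val <- val - lambda *
          sol$jaccard[sol$selected[i], sol$selected[j]] * min(s[i], s[j])
      }
    }
    val
  }
  cand <- data.frame(term = names(toy_collection()),
                     best_p = c(1e-6, 1e-4, 1e-3, 1e-5, 1e-3, 1e-4),
                     best_comparison = "c1", stringsAsFactors = FALSE)
  sol <- select_cover(cand, toy_collection(), paste0("g", 1:60), lambda = 1.5)
  expect_equal(sol$objective, recompute(sol, 1.5), tolerance = 1e-12)
})

test_that("greedy achieves >= 90% of the exhaustive optimum on random instances", {
  set.seed(103)
  ratios <- numeric(200)
  for (i in 1:200) {
    k <- sample(3:12, 1)
    universe <- paste0("g", 1:80)
    sets <- lapply(seq_len(k), function(j)
      sample(universe, sample(5:30, 1)))
    names(sets) <- sprintf("T%02d", seq_len(k))
    coll <- gene_set_collection(sets)
    cand <- data.frame(term = names(sets),
                       best_p = 10^(-runif(k, 3.2, 8)),
                       best_comparison = "c1", stringsAsFactors = FALSE)
    gr <- select_cover(cand, coll, universe, lambda = 1)
    ex <- select_cover(cand, coll, universe, lambda = 1,
                       solver = "exhaustive")
    ratios[i] <- if (ex$objective > 0) gr$objective / ex$objective else 1
  }
  expect_true(all(ratios >= 0.9))
  expect_gt(mean(ratios > 0.999), 0.8)   # usually exactly optimal

  expect_error(select_cover(
    data.frame(term = sprintf("T%02d", 1:16), best_p = 1e-4,
               best_comparison = "c"),
    gene_set_collection(setNames(lapply(1:16, function(i) "g1"),
                                 sprintf("T%02d", 1:16))),
    "g1", solver = "exhaustive"), "15 candidates")
})
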