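# Over-representation analysis of significant genes against a gene-set
# collection, followed by selection of a minimally redundant subset of
# enriched terms. The selection objective rewards each term's evidence
# (-log10 p) and penalizes pairwise membership overlap (Jaccard), so
# near-duplicate terms do not crowd the reported table.

#' Fisher over-representation test for every term in a collection
#'
#' For each term (intersected with the universe first) the one-sided
#' over-representation p-value is the hypergeometric upper tail
#' `P(X >= k)` where `k` = significant genes in the term, `K` = term size
#' within the universe, `n` = number of significant genes, `N` = universe
#' size — the one-sided Fisher exact test.
#'
#' @param hits character vector of significant gene ids (must be a subset
#'   of `universe`).
#' @param universe character vector of all tested gene ids.
#' @param collection a `gene_set_collection`.
#' @param comparison optional label recorded with each row.
#' @return data frame with columns `term`, `comparison`, `k`, `K`, `n`,
#'   `N`, `odds_ratio`, `p`; terms with empty universe intersection are
#'   omitted.
#' @export
fisher_enrichment <- function(hits, universe, collection,
                              comparison = NA_character_) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  if (!length(universe)) stop2("empty universe")
  hits <- unique(hits)
  if (length(setdiff(hits, universe)))
    stop2("'hits' must be a subset of 'universe'")
  n <- length(hits)
  N <- length(universe)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, hits))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.eps)
    data.frame(term = id, comparison = comparison, k = k, K = K,
               n = n, N = N, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(), comparison = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), odds_ratio = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}

#' Candidate enriched terms across comparisons
#'
#' Keeps terms whose unadjusted Fisher p-value is at or below `p_max` in at
#' least one comparison (boundary inclusive), recording each term's best p
#' and the comparison achieving it. No multiple-testing correction is
#' applied at this stage.
#'
#' @param results data frame from one or more [fisher_enrichment()] calls
#'   (rows from several comparisons may be concatenated).
#' @param p_max unadjusted p-value threshold (default 0.001).
#' @return data frame with columns `term`, `best_p`, `best_comparison`,
#'   sorted by `best_p` then term id.
#' @export
candidate_terms <- function(results, p_max = 0.001) {
  if (!nrow(results)) {
    return(data.frame(term = character(), best_p = numeric(),
                      best_comparison = character()))
  }
  sp <- split(results, results$term)
  rows <- lapply(sp, function(d) {
    i <- which.min(d$p)
    data.frame(term = d$term[1L], best_p = d$p[i],
               best_comparison = d$comparison[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$best_p <= p_max, , drop = FALSE]
  out <- out[order(out$best_p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

jaccard_matrix <- function(sets) {
  k <- length(sets)
  J <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      J[i, j] <- J[j, i] <- if (uni) inter / uni else 0
    }
  }
  J
}

cover_objective <- function(selected, score, J, lambda) {
  if (!length(selected)) return(0)
  s <- score[selected]
  val <- sum(s)
  if (length(selected) > 1L) {
    for (i in seq_along(selected)[-1L]) {
      for (j in seq_len(i - 1L)) {
        val <- val - lambda * J[selected[i], selected[j]] *
          min(s[i], s[j])
      }
    }
  }
  val
}

#' Select a minimally redundant subset of enriched terms
#'
#' Maximizes
#' `F(S) = sum_{t in S} (-log10 p_t)
#'         - lambda * sum_{t<u in S} Jaccard(t, u) * min(-log10 p_t, -log10 p_u)`
#' over subsets of the candidate terms. The greedy solver repeatedly adds
#' the term with the largest positive objective gain (ties broken by
#' smaller best p, then term id) until no addition helps; the exhaustive
#' solver enumerates every subset and is the internal ground truth,
#' permitted for at most 15 candidates.
#'
#' With `lambda = 0` there is no overlap penalty and every candidate is
#' selected.
#'
#' @param candidates data frame from [candidate_terms()].
#' @param collection a `gene_set_collection` (members are intersected with
#'   `universe` before overlaps are computed).
#' @param universe character vector of tested gene ids.
#' @param lambda overlap penalty weight (default 1).
#' @param solver `"greedy"` or `"exhaustive"`.
#' @return object of class `cover_solution`: `selected` term ids,
#'   `objective`, `score` (-log10 best p per candidate), `jaccard`
#'   (candidate pairwise overlap matrix), `solver`.
#' @export
select_cover <- function(candidates, collection, universe,
                         lambda = 1, solver = c("greedy", "exhaustive")) {
  solver <- match.arg(solver)
  if (!nrow(candidates)) stop2("no candidate terms to select from")
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- candidates$term
  missing <- setdiff(ids, names(collection))
  if (length(missing))
    stop2("candidate term(s) absent from collection: ",
          paste(missing, collapse = ", "))
  sets <- lapply(collection[ids], intersect, y = unique(universe))
  names(sets) <- ids
  score <- stats::setNames(-log10(pmax(candidates$best_p, 1e-300)), ids)
  J <- jaccard_matrix(sets)

  if (solver == "exhaustive") {
    k <- length(ids)
    if (k > 15L)
      stop2("exhaustive enumeration is limited to 15 candidates")
    best <- character(0)
    best_val <- 0
    for (mask in seq_len(2^k) - 1L) {
      sel <- ids[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0]
      val <- cover_objective(sel, score, J, lambda)
      if (val > best_val + 1e-12) { best <- sel; best_val <- val }
    }
    selected <- best
    objective <- best_val
  } else {
    # deterministic greedy: candidate order by (best p, term id)
    order_ids <- candidates$term[order(candidates$best_p, candidates$term)]
    selected <- character(0)
    current <- 0
    repeat {
      gains <- vapply(setdiff(order_ids, selected), function(t) {
        cover_objective(c(selected, t), score, J, lambda) - current
      }, numeric(1))
      if (!length(gains) || max(gains) <= 1e-12) break
      pick <- names(gains)[which.max(gains)]
      selected <- c(selected, pick)
      current <- current + gains[[pick]]
    }
    objective <- cover_objective(selected, score, J, lambda)
  }
  structure(list(selected = selected, objective = objective,
                 score = score, jaccard = J, lambda = lambda,
                 solver = solver),
            class = "cover_solution")
}
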