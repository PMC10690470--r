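#' Run the full time-course differential-expression analysis in memory
#'
#' Chains every stage on a joined count dataset: median-of-ratios size
#' factors, dispersion estimation with trend shrinkage, NB GLM fit under
#' the cumulative step-effect design, one treatment-versus-mock Wald
#' contrast per (treatment, time) with per-comparison BH adjustment,
#' empirical-Bayes fold-change shrinkage per comparison, significance
#' calling, regulated-gene tallies, and variance-stabilized PCA.
#'
#' @param dataset a `count_dataset` whose metadata has `treatment` and
#'   `time_h` columns.
#' @param mock untreated reference label (default `"mock"`).
#' @param calling a [calling_config()].
#' @param vst_method passed to [vst()].
#' @param drop_all_zero drop genes with zero counts in every sample before
#'   fitting (they are reported in `dropped_genes`).
#' @return list with `size_factors`, `dispersions`, `fit`, `contrasts`
#'   (named list of called `contrast_result`s), `regulated` (from
#'   [count_regulated()]), `pca`, `vst`, `dropped_genes`, `design`.
#' @export
run_timecourse <- function(dataset, mock = "mock",
                           calling = calling_config(),
                           vst_method = "log",
                           drop_all_zero = TRUE) {
  stopifnot(inherits(dataset, "count_dataset"))
  meta <- dataset$samples
  if (!all(c("treatment", "time_h") %in% names(meta)))
    stop2("metadata needs 'treatment' and 'time_h' columns")
  counts <- dataset$counts
  dropped <- character(0)
  if (drop_all_zero) {
    zero <- rowSums(counts) == 0
    dropped <- rownames(counts)[zero]
    counts <- counts[!zero, , drop = FALSE]
  }
  time_grid <- sort(unique(meta$time_h))
  treatments <- unique(meta$treatment)
  design <- build_cumulative_design(meta, time_grid, treatments, mock)

  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, design)
  fit <- fit_nb_glm(counts, sf, disp$final, design)

  contrasts <- list()
  for (a in setdiff(treatments, mock)) {
    for (t in time_grid) {
      cw <- contrast_treatment_vs_mock(design, a, t)
      res <- wald_contrast(fit, cw)
      res <- shrink_lfc(res)
      res <- call_significant(res, calling)
      contrasts[[attr(cw, "label")]] <- res
    }
  }
  regulated <- count_regulated(contrasts)

  tc <- attr(disp, "trend_coef")
  v <- vst(counts, sf, method = vst_method,
           trend_coef = if (vst_method == "trend") tc else NULL)
  pca <- pca_samples(v, n_components = min(2L, ncol(v) - 1L))

  list(size_factors = sf, dispersions = disp, fit = fit,
       contrasts = contrasts, regulated = regulated,
       vst = v, pca = pca, dropped_genes = dropped, design = design,
       calling = calling)
}

#' Run the knockout-by-treatment factorial analysis in memory
#'
#' Same stages as [run_timecourse()] but under the factorial design, with
#' one knockout-versus-reference contrast per treatment.
#'
#' @param dataset a `count_dataset` whose metadata has `genotype` and
#'   `treatment` columns.
#' @param genotypes length-2 labels, reference first.
#' @param mock untreated treatment label.
#' @param calling a [calling_config()].
#' @return as [run_timecourse()], with contrasts keyed by treatment.
#' @export
run_factorial <- function(dataset, genotypes = c("NTC", "KO"),
                          mock = "mock", calling = calling_config()) {
  stopifnot(inherits(dataset, "count_dataset"))
  meta <- dataset$samples
  if (!all(c("genotype", "treatment") %in% names(meta)))
    stop2("metadata needs 'genotype' and 'treatment' columns")
  counts <- dataset$counts
  zero <- rowSums(counts) == 0
  dropped <- rownames(counts)[zero]
  counts <- counts[!zero, , drop = FALSE]
  treatments <- unique(meta$treatment)
  design <- build_factorial_design(meta, genotypes, treatments, mock)
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, design)
  fit <- fit_nb_glm(counts, sf, disp$final, design)
  contrasts <- list()
  for (a in treatments) {
    cw <- contrast_ko_vs_ref(design, a)
    res <- wald_contrast(fit, cw)
    res <- shrink_lfc(res)
    res <- call_significant(res, calling)
    contrasts[[attr(cw, "label")]] <- res
  }
  v <- vst(counts, sf)
  pca <- pca_samples(v, n_components = min(2L, ncol(v) - 1L))
  list(size_factors = sf, dispersions = disp, fit = fit,
       contrasts = contrasts, regulated = count_regulated(contrasts),
       vst = v, pca = pca, dropped_genes = dropped, design = design,
       calling = calling)
}

#' Enrichment stage: ORA plus redundancy-minimized term selection
#'
#' Runs [fisher_enrichment()] of each comparison's significant genes
#' against the collection (universe = all fitted genes), pools the
#' results, filters candidates at the unadjusted p threshold and selects
#' the minimally overlapping subset.
#'
#' @param contrasts named list of called `contrast_result`s.
#' @param collection a `gene_set_collection`.
#' @param universe gene universe (defaults to the genes of the first
#'   contrast).
#' @param p_max candidate threshold on the unadjusted Fisher p.
#' @param lambda overlap penalty for [select_cover()].
#' @return list with `enrichment` (pooled per-comparison table),
#'   `candidates`, `cover` (a `cover_solution`, or NULL when no candidate
#'   passes).
#' @export
run_enrichment <- function(contrasts, collection, universe = NULL,
                           p_max = 0.001, lambda = 1) {
  if (is.null(universe)) universe <- contrasts[[1L]]$gene
  tabs <- lapply(contrasts, function(r) {
    hits <- r$gene[which(r$significant)]
    fisher_enrichment(hits, universe, collection,
                      comparison = r$comparison[1L])
  })
  enr <- do.call(rbind, tabs)
  rownames(enr) <- NULL
  cand <- candidate_terms(enr, p_max = p_max)
  cover <- if (nrow(cand)) {
    select_cover(cand, collection, universe, lambda = lambda)
  } else NULL
  list(enrichment = enr, candidates = cand, cover = cover)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the whole pipeline from files and write every output
#'
#' File-level front end: reads counts + metadata (or simulates a dataset
#' when `counts_path` is NULL), runs the time-course analysis, optionally
#' the enrichment stage (skipped with a warning when `gmt_path` is NULL),
#' and writes per-contrast result TSVs, the regulated-count table, PCA
#' scores and variance, enrichment and cover TSVs, a JSON run manifest and
#' a log file under `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param counts_path,metadata_path input TSVs; both NULL to simulate.
#' @param gmt_path optional GMT file for the enrichment stage.
#' @param config optional [sim_config()] used when simulating.
#' @param mock untreated reference label.
#' @param calling a [calling_config()].
#' @param seed root seed recorded in the manifest and used for simulation.
#' @return invisibly, the in-memory result of [run_timecourse()] plus the
#'   enrichment list.
#' @export
run_all <- function(out_dir, counts_path = NULL, metadata_path = NULL,
                    gmt_path = NULL, config = NULL, mock = "mock",
                    calling = calling_config(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                paste0(...)), file = log_path, append = TRUE)
  }
  cat("", file = log_path)

  if (is.null(counts_path)) {
    if (is.null(config)) config <- sim_config(seed = seed)
    log_line("simulating dataset (", config$n_genes, " genes)")
    sim <- simulate_timecourse(config)
    dataset <- sim$dataset
    write_count_dataset(dataset, file.path(out_dir, "counts.tsv"),
                        file.path(out_dir, "metadata.tsv"))
  } else {
    if (is.null(metadata_path))
      stop2("metadata_path is required with counts_path")
    log_line("reading ", counts_path)
    dataset <- read_count_dataset(counts_path, metadata_path)
  }

  log_line("fitting NB GLM and contrasts")
  res <- run_timecourse(dataset, mock = mock, calling = calling)

  for (label in names(res$contrasts)) {
    fn <- file.path(out_dir, paste0(
      "contrast_", gsub("[^A-Za-z0-9._-]+", "_", label), ".tsv"))
    write_tsv(res$contrasts[[label]], fn)
  }
  counts_tab <- data.frame(comparison = names(res$regulated$per_comparison),
                           n_significant = res$regulated$per_comparison)
  write_tsv(counts_tab, file.path(out_dir, "regulated_counts.tsv"))
  write_tsv(data.frame(sample = rownames(res$pca$scores), res$pca$scores),
            file.path(out_dir, "pca_scores.tsv"))
  write_tsv(data.frame(component = seq_along(res$pca$variance_explained),
                       variance_explained = res$pca$variance_explained),
            file.path(out_dir, "pca_variance.tsv"))
  write_tsv(data.frame(sample = names(res$size_factors),
                       size_factor = res$size_factors),
            file.path(out_dir, "size_factors.tsv"))

  enrich_res <- NULL
  if (!is.null(gmt_path)) {
    log_line("enrichment against ", gmt_path)
    collection <- read_gmt(gmt_path)
    enrich_res <- run_enrichment(res$contrasts, collection)
    write_tsv(enrich_res$enrichment, file.path(out_dir, "enrichment.tsv"))
    write_tsv(enrich_res$candidates,
              file.path(out_dir, "enrichment_candidates.tsv"))
    if (!is.null(enrich_res$cover)) {
      write_tsv(data.frame(term = enrich_res$cover$selected,
                           score = enrich_res$cover$score[
                             enrich_res$cover$selected]),
                file.path(out_dir, "enrichment_cover.tsv"))
    } else {
      write_tsv(data.frame(term = character(), score = numeric()),
                file.path(out_dir, "enrichment_cover.tsv"))
    }
  } else {
    log_line("no GMT supplied; enrichment stage skipped")
    warning("no GMT collection supplied; enrichment stage skipped",
            call. = FALSE)
  }

  manifest <- list(
    package = "stepDE",
    version = as.character(utils::packageVersion("stepDE")),
    r_version = R.version.string,
    seed = seed,
    thresholds = list(padj_max = calling$padj_max,
                      abs_lfc_min = calling$abs_lfc_min),
    mock = mock,
    n_genes = nrow(dataset$counts),
    n_samples = ncol(dataset$counts),
    simulated = is.null(counts_path),
    enrichment_run = !is.null(gmt_path),
    union_regulated = res$regulated$union,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("done; union regulated genes: ", res$regulated$union)
  invisible(c(res, list(enrichment = enrich_res)))
}

#' Read a simulation configuration from YAML
#'
#' Accepts the [sim_config()] argument names as top-level YAML keys;
#' unknown keys are an error.
#'
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(sim_config))
  bad <- setdiff(names(y), allowed)
  if (length(bad))
    stop2("unknown simulation config key(s): ", paste(bad, collapse = ", "))
  do.call(sim_config, y)
}
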