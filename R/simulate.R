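#' Simulation configuration for synthetic nucleotide-stimulation counts
#'
#' Defines the generative model used by [simulate_timecourse()] and
#' [simulate_factorial()]: log-linear negative-binomial counts with a
#' mean-dependent dispersion trend `alpha(mu) = a0 + a1/mu`, per-sample
#' library size factors, a small log2 drift shared by all arms at each time
#' interval, and treatment-specific per-interval log2 increments planted in
#' a minority of responsive genes. Increments persist at all later times,
#' so true fold changes accumulate over the time course.
#'
#' Defaults emulate a nucleotide-stimulation experiment in macrophages:
#' six arms (untreated mock plus Ap4A, ATP, ADP, UTP, UDP at 500 uM),
#' sampled at 1, 2, 3, 4 and 6 h with 3 replicates per condition, and
#' 3'-UMI count depths spanning baselines of log2 mean 2-12.
#'
#' @param n_genes number of genes (default 5000).
#' @param treatments treatment labels including the mock label.
#' @param mock label of the untreated reference arm.
#' @param time_points strictly increasing sampling times in hours.
#' @param n_replicates replicates per (treatment, time) condition.
#' @param baseline_log2_range range of per-gene baseline log2 mean counts.
#' @param dispersion length-2 numeric `c(a0, a1)` for the trend
#'   `alpha(mu) = a0 + a1/mu`; requires `a0 > 0`, `a1 >= 0` so that
#'   `alpha(mu) > 0` for all `mu > 0`.
#' @param fraction_responsive fraction of genes carrying treatment effects.
#' @param effect_increment list with `min`, `max` (log2 magnitude range of a
#'   per-interval increment, 0 excluded) and `prob_positive` (probability
#'   that a responsive gene's effect direction is up; the sign is drawn
#'   once per gene and treatment so effects accumulate coherently).
#' @param mock_drift_sd standard deviation (log2) of the per-interval drift
#'   shared by every arm; 0 disables drift.
#' @param size_factor_range range of the per-sample library size factors
#'   (drawn uniformly).
#' @param null_treatments treatments forced to carry no effects in any gene
#'   (beyond the mock arm), emulating an inert stimulus.
#' @param seed root random seed; all randomness is derived from it through
#'   named substreams (R's default Mersenne-Twister generator), so a config
#'   reproduces its dataset bit for bit.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       treatments = c("mock", "Ap4A", "ATP", "ADP",
                                      "UTP", "UDP"),
                       mock = "mock",
                       time_points = c(1, 2, 3, 4, 6),
                       n_replicates = 3,
                       baseline_log2_range = c(2, 12),
                       dispersion = c(a0 = 0.05, a1 = 2),
                       fraction_responsive = 0.1,
                       effect_increment = list(min = 0.2, max = 0.8,
                                               prob_positive = 0.5),
                       mock_drift_sd = 0.05,
                       size_factor_range = c(0.7, 1.4),
                       null_treatments = character(),
                       seed = 1L) {
  if (!mock %in% treatments)
    stop2(sprintf("mock label '%s' absent from treatments", mock))
  if (length(time_points) < 1L || is.unsorted(time_points, strictly = TRUE))
    stop2("'time_points' must be strictly increasing")
  if (n_replicates < 1L) stop2("'n_replicates' must be >= 1")
  if (fraction_responsive < 0 || fraction_responsive > 1)
    stop2("'fraction_responsive' must lie in [0, 1]")
  if (length(dispersion) != 2L || dispersion[1L] <= 0 || dispersion[2L] < 0)
    stop2("'dispersion' must be c(a0, a1) with a0 > 0 and a1 >= 0")
  if (any(size_factor_range <= 0))
    stop2("'size_factor_range' must be positive")
  if (effect_increment$min <= 0 || effect_increment$max < effect_increment$min)
    stop2("'effect_increment' needs 0 < min <= max")
  extra <- setdiff(null_treatments, treatments)
  if (length(extra))
    stop2("null_treatments not in treatments: ", paste(extra, collapse = ", "))
  structure(list(
    n_genes = as.integer(n_genes), treatments = treatments, mock = mock,
    time_points = time_points, n_replicates = as.integer(n_replicates),
    baseline_log2_range = baseline_log2_range,
    dispersion = stats::setNames(as.numeric(dispersion), c("a0", "a1")),
    fraction_responsive = fraction_responsive,
    effect_increment = effect_increment,
    mock_drift_sd = mock_drift_sd,
    size_factor_range = size_factor_range,
    null_treatments = null_treatments,
    seed = as.integer(seed),
    rng = "Mersenne-Twister via named substream seeds"
  ), class = "sim_config")
}

dispersion_at <- function(mu, disp) disp[["a0"]] + disp[["a1"]] / mu

# Draw gene x treatment effect signs and gene x treatment x interval
# magnitudes for responsive genes; zero elsewhere.
draw_increments <- function(cfg, eligible_trts) {
  ng <- cfg$n_genes
  nt <- length(cfg$time_points)
  responsive <- matrix(FALSE, ng, length(cfg$treatments),
                       dimnames = list(NULL, cfg$treatments))
  inc <- array(0, dim = c(ng, length(cfg$treatments), nt),
               dimnames = list(NULL, cfg$treatments, cfg$time_points))
  is_resp <- stats::runif(ng) < cfg$fraction_responsive
  for (a in eligible_trts) {
    responsive[, a] <- is_resp
    sign_a <- ifelse(stats::runif(ng) < cfg$effect_increment$prob_positive,
                     1, -1)
    mag <- matrix(stats::runif(ng * nt, cfg$effect_increment$min,
                               cfg$effect_increment$max), ng, nt)
    inc[, a, ] <- ifelse(is_resp, 1, 0) * sign_a * mag
  }
  list(responsive = responsive, increments = inc)
}

#' Simulate a treatment time course of negative-binomial counts
#'
#' Generates a gene-by-sample integer count matrix under the cumulative
#' step-effect model together with the complete ground truth (planted
#' increments, responsive genes, size factors, dispersions), so estimator
#' recovery can be scored exactly.
#'
#' For sample s in arm a at time t, counts are drawn NB with mean
#' `sf_s * 2^(b_g + sum_{ti<=t} drift_g,ti + sum_{ti<=t} inc_g,a,ti)` and
#' dispersion `alpha(mu) = a0 + a1/mu`. Mock and `null_treatments` carry no
#' increments.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a `count_dataset`: `$counts` integer matrix,
#'   `$samples` metadata data frame with columns sample, treatment, time_h,
#'   replicate) and `truth` (a `ground_truth`: `$drift_increments`
#'   gene x time, `$treatment_increments` gene x treatment x time,
#'   `$responsive`, `$size_factors`, `$dispersions`).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  ng <- cfg$n_genes
  times <- cfg$time_points
  nt <- length(times)

  baseline <- with_substream(cfg$seed, "baseline",
    stats::runif(ng, cfg$baseline_log2_range[1L], cfg$baseline_log2_range[2L]))
  drift <- with_substream(cfg$seed, "drift",
    matrix(stats::rnorm(ng * nt, 0, cfg$mock_drift_sd), ng, nt,
           dimnames = list(NULL, times)))
  eligible <- setdiff(cfg$treatments, c(cfg$mock, cfg$null_treatments))
  eff <- with_substream(cfg$seed, "effects", draw_increments(cfg, eligible))

  meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      time_h = times, treatment = cfg$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%gh_r%d", meta$treatment, meta$time_h,
                         meta$replicate)
  meta <- meta[, c("sample", "treatment", "time_h", "replicate")]
  ns <- nrow(meta)

  sf <- with_substream(cfg$seed, "sizefactors",
    stats::runif(ns, cfg$size_factor_range[1L], cfg$size_factor_range[2L]))
  names(sf) <- meta$sample

  gene_ids <- sprintf("gene%05d", seq_len(ng))
  counts <- matrix(0L, ng, ns, dimnames = list(gene_ids, meta$sample))
  cum_drift <- t(apply(drift, 1L, cumsum))
  if (nt == 1L) cum_drift <- matrix(drift, ng, 1L)
  counts <- with_substream(cfg$seed, "counts", {
    for (s in seq_len(ns)) {
      ti <- match(meta$time_h[s], times)
      log2mu <- baseline + cum_drift[, ti] +
        rowSums(eff$increments[, meta$treatment[s], seq_len(ti), drop = FALSE])
      mu <- sf[s] * 2^log2mu
      alpha <- dispersion_at(mu, cfg$dispersion)
      counts[, s] <- stats::rnbinom(ng, mu = mu, size = 1 / alpha)
    }
    counts
  })

  truth <- structure(list(
    drift_increments = drift,
    treatment_increments = eff$increments,
    responsive = eff$responsive,
    size_factors = sf,
    dispersions = dispersion_at(2^baseline, cfg$dispersion),
    baseline_log2 = baseline,
    mock = cfg$mock, time_points = times, treatments = cfg$treatments
  ), class = "ground_truth")

  list(dataset = count_dataset(counts, meta), truth = truth)
}

#' Simulate a genotype-by-treatment factorial count dataset
#'
#' Emulates a knockout experiment at a single time point: two genotypes
#' (reference and knockout) crossed with an untreated arm plus one or more
#' treatments. Per gene, log2 mean = baseline + genotype main effect +
#' treatment main effect + genotype:treatment interaction; counts are NB
#' with the same dispersion trend and size-factor model as the time course.
#'
#' @param config a [sim_config()]; `time_points` is ignored,
#'   `fraction_responsive` and `effect_increment` parameterize the
#'   treatment main effects.
#' @param genotypes length-2 labels, reference first.
#' @param genotype_effect list `(fraction, min, max, prob_positive)` for
#'   genotype main-effect log2 shifts.
#' @param interaction_effect same shape, for genotype:treatment
#'   interactions (the knockout-dependent part of the treatment response).
#' @return list with `dataset` (metadata columns sample, genotype,
#'   treatment, replicate) and `truth` carrying `genotype_lfc`,
#'   `treatment_lfc` (gene x treatment) and `interaction_lfc`
#'   (gene x treatment).
#' @export
simulate_factorial <- function(config,
                               genotypes = c("NTC", "KO"),
                               genotype_effect = list(fraction = 0.02,
                                                      min = 0.5, max = 1.5,
                                                      prob_positive = 0.5),
                               interaction_effect = list(fraction = 0.05,
                                                         min = 0.5, max = 2,
                                                         prob_positive = 0.5)) {
  stopifnot(inherits(config, "sim_config"))
  if (length(genotypes) != 2L) stop2("exactly two genotype labels required")
  cfg <- config
  ng <- cfg$n_genes
  trt_eff <- setdiff(cfg$treatments, c(cfg$mock, cfg$null_treatments))

  draw_shift <- function(spec, n, ncol = 1L) {
    hit <- stats::runif(n) < spec$fraction
    sgn <- ifelse(stats::runif(n) < spec$prob_positive, 1, -1)
    mag <- matrix(stats::runif(n * ncol, spec$min, spec$max), n, ncol)
    ifelse(hit, 1, 0) * sgn * mag
  }

  baseline <- with_substream(cfg$seed, "baseline",
    stats::runif(ng, cfg$baseline_log2_range[1L], cfg$baseline_log2_range[2L]))
  geno_lfc <- with_substream(cfg$seed, "genotype",
    as.numeric(draw_shift(genotype_effect, ng)))
  trt_spec <- list(fraction = cfg$fraction_responsive,
                   min = cfg$effect_increment$min,
                   max = cfg$effect_increment$max,
                   prob_positive = cfg$effect_increment$prob_positive)
  trt_lfc <- with_substream(cfg$seed, "treatment", {
    m <- matrix(0, ng, length(cfg$treatments),
                dimnames = list(NULL, cfg$treatments))
    for (a in trt_eff) m[, a] <- as.numeric(draw_shift(trt_spec, ng))
    m
  })
  int_lfc <- with_substream(cfg$seed, "interaction", {
    m <- matrix(0, ng, length(cfg$treatments),
                dimnames = list(NULL, cfg$treatments))
    for (a in trt_eff) m[, a] <- as.numeric(draw_shift(interaction_effect, ng))
    m
  })

  meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      treatment = cfg$treatments, genotype = genotypes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%s_r%d", meta$genotype, meta$treatment,
                         meta$replicate)
  meta <- meta[, c("sample", "genotype", "treatment", "replicate")]
  ns <- nrow(meta)
  sf <- with_substream(cfg$seed, "sizefactors",
    stats::runif(ns, cfg$size_factor_range[1L], cfg$size_factor_range[2L]))
  names(sf) <- meta$sample

  gene_ids <- sprintf("gene%05d", seq_len(ng))
  counts <- matrix(0L, ng, ns, dimnames = list(gene_ids, meta$sample))
  counts <- with_substream(cfg$seed, "counts", {
    for (s in seq_len(ns)) {
      is_ko <- meta$genotype[s] == genotypes[2L]
      a <- meta$treatment[s]
      log2mu <- baseline + if (is_ko) geno_lfc else 0
      log2mu <- log2mu + trt_lfc[, a] + if (is_ko) int_lfc[, a] else 0
      mu <- sf[s] * 2^log2mu
      alpha <- dispersion_at(mu, cfg$dispersion)
      counts[, s] <- stats::rnbinom(ng, mu = mu, size = 1 / alpha)
    }
    counts
  })

  truth <- structure(list(
    genotype_lfc = geno_lfc, treatment_lfc = trt_lfc,
    interaction_lfc = int_lfc, size_factors = sf,
    dispersions = dispersion_at(2^baseline, cfg$dispersion),
    baseline_log2 = baseline, mock = cfg$mock,
    treatments = cfg$treatments, genotypes = genotypes
  ), class = "ground_truth_factorial")

  list(dataset = count_dataset(counts, meta), truth = truth)
}

#' True cumulative log2 fold change of a treatment versus mock
#'
#' Oracle for contrast recovery on simulated data: the planted
#' treatment-versus-mock log2 fold change at `time` is the sum of that
#' treatment's per-interval increments over grid times up to `time` (the
#' shared drift cancels between arms).
#'
#' @param truth `ground_truth` from [simulate_timecourse()].
#' @param treatment non-mock treatment label.
#' @param time a time point present in the simulated grid.
#' @return per-gene numeric vector of true log2 fold changes.
#' @export
ground_truth_lfc <- function(truth, treatment, time) {
  stopifnot(inherits(truth, "ground_truth"))
  if (identical(treatment, truth$mock))
    stop2("the mock arm has no fold change against itself")
  if (!treatment %in% truth$treatments)
    stop2(sprintf("unknown treatment '%s'", treatment))
  ti <- match(time, truth$time_points)
  if (is.na(ti))
    stop2(sprintf("time %s h not in the simulated grid", format(time)))
  rowSums(truth$treatment_increments[, treatment, seq_len(ti), drop = FALSE])
}

#' True knockout-versus-reference log2 fold change within a treatment
#'
#' @param truth `ground_truth_factorial` from [simulate_factorial()].
#' @param treatment treatment label (the untreated arm is allowed).
#' @return per-gene numeric vector: genotype main effect plus the
#'   genotype:treatment interaction for `treatment`.
#' @export
ground_truth_lfc_ko <- function(truth, treatment) {
  stopifnot(inherits(truth, "ground_truth_factorial"))
  if (!treatment %in% truth$treatments)
    stop2(sprintf("unknown treatment '%s'", treatment))
  truth$genotype_lfc + truth$interaction_lfc[, treatment]
}
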