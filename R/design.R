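#' Cumulative step-effect design matrix for a treatment time course
#'
#' Builds the samples-by-coefficients indicator matrix for the cumulative
#' step-effect time-course model. Each grid time `t_i` from the second
#' onward contributes an `after_<t_i>` drift column that switches on at
#' `t_i` and stays on at all later times (shared by every arm, including
#' the untreated control), and each non-control treatment `a` contributes
#' interaction columns `<a>:after_<t_i>` for every grid time that switch
#' on the same way but only for samples of that arm. A
#' treatment-versus-control log2 fold change at time `t` is then the sum
#' of that treatment's interaction coefficients over grid times up to `t`.
#'
#' There is no pre-treatment (t = 0) sample, so a drift step at the first
#' grid time would be on for every sample and aliased with the intercept;
#' it is therefore absorbed, and the intercept is the control-arm baseline
#' at the first measured time. Treatment contrasts only involve
#' interaction columns and are unaffected by this choice.
#'
#' @param samples data frame with columns `sample`, `treatment`, `time_h`
#'   (one row per sample).
#' @param time_grid strictly increasing vector of the design time points in
#'   hours; every sample's `time_h` must lie on this grid.
#' @param treatments character vector of allowed treatment labels.
#' @param mock label of the untreated reference arm (must be in
#'   `treatments`).
#' @return a `design_matrix`: numeric 0/1 matrix with rownames = sample ids
#'   and named coefficient columns, carrying the grid, treatment set and
#'   reference label as attributes.
#' @examples
#' s <- data.frame(sample = c("m1", "a1"),
#'                 treatment = c("mock", "ATP"), time_h = c(1, 3))
#' build_cumulative_design(s, time_grid = c(1, 2, 3, 4, 6),
#'                         treatments = c("mock", "ATP"), mock = "mock")
#' @export
build_cumulative_design <- function(samples, time_grid, treatments, mock) {
  validate_sample_table(samples, c("sample", "treatment", "time_h"))
  if (is.unsorted(time_grid, strictly = TRUE))
    stop2("'time_grid' must be strictly increasing")
  if (!mock %in% treatments)
    stop2(sprintf("mock label '%s' is not among the declared treatments", mock))
  bad <- setdiff(unique(samples$treatment), treatments)
  if (length(bad))
    stop2("unknown treatment label(s): ", paste(bad, collapse = ", "))
  off <- setdiff(unique(samples$time_h), time_grid)
  if (length(off))
    stop2("sample time(s) off the declared grid: ", paste(off, collapse = ", "))

  n <- nrow(samples)
  trt_eff <- setdiff(treatments, mock)
  # Without pre-treatment (t = 0) samples the first drift step is on for
  # every sample and would alias the intercept, so it is absorbed: drift
  # columns exist for the second grid time onward and the intercept is the
  # control-arm baseline at the first measured time. Treatment interaction
  # columns exist for every grid time and treatment contrasts are
  # unaffected.
  drift_times <- time_grid[-1L]
  after_cols <- if (length(drift_times)) paste0("after_", drift_times)
                else character(0)
  int_cols <- if (length(trt_eff)) {
    as.vector(t(outer(trt_eff, time_grid,
                      function(a, t) paste0(a, ":after_", t))))
  } else character(0)
  cols <- c("Intercept", after_cols, int_cols)
  X <- matrix(0, n, length(cols), dimnames = list(samples$sample, cols))
  X[, "Intercept"] <- 1
  for (i in seq_along(time_grid)) {
    on <- samples$time_h >= time_grid[i]
    if (time_grid[i] %in% drift_times)
      X[, paste0("after_", time_grid[i])] <- as.numeric(on)
    for (a in trt_eff) {
      X[, paste0(a, ":after_", time_grid[i])] <-
        as.numeric(on & samples$treatment == a)
    }
  }
  new_design_matrix(X, kind = "timecourse", time_grid = time_grid,
                    treatments = treatments, mock = mock)
}

#' Knockout-by-treatment factorial design matrix
#'
#' Builds the dummy-coded design for a two-genotype by treatment factorial
#' at a single time point: intercept (reference genotype, untreated),
#' `knockout` indicator, one `treatment_<a>` column per non-reference
#' treatment, and all `knockout:treatment_<a>` interactions.
#'
#' @param samples data frame with columns `sample`, `genotype`, `treatment`.
#' @param genotypes length-2 character vector, reference genotype first
#'   (e.g. `c("NTC", "KO")`).
#' @param treatments allowed treatment labels.
#' @param mock reference (untreated) treatment label.
#' @return a `design_matrix` (see [build_cumulative_design()]).
#' @export
build_factorial_design <- function(samples, genotypes, treatments, mock) {
  validate_sample_table(samples, c("sample", "genotype", "treatment"))
  if (length(genotypes) != 2L)
    stop2("exactly two genotype levels are required (reference first)")
  if (!mock %in% treatments)
    stop2(sprintf("mock label '%s' is not among the declared treatments", mock))
  bad <- setdiff(unique(c(samples$genotype)), genotypes)
  if (length(bad))
    stop2("unknown genotype label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$treatment), treatments)
  if (length(bad))
    stop2("unknown treatment label(s): ", paste(bad, collapse = ", "))

  ko <- genotypes[2L]
  trt_eff <- setdiff(treatments, mock)
  cols <- c("Intercept", "knockout", paste0("treatment_", trt_eff),
            paste0("knockout:treatment_", trt_eff))
  X <- matrix(0, nrow(samples), length(cols),
              dimnames = list(samples$sample, cols))
  X[, "Intercept"] <- 1
  X[, "knockout"] <- as.numeric(samples$genotype == ko)
  for (a in trt_eff) {
    is_a <- samples$treatment == a
    X[, paste0("treatment_", a)] <- as.numeric(is_a)
    X[, paste0("knockout:treatment_", a)] <-
      as.numeric(is_a & samples$genotype == ko)
  }
  new_design_matrix(X, kind = "factorial", treatments = treatments,
                    mock = mock, genotypes = genotypes)
}

new_design_matrix <- function(X, kind, ...) {
  check_full_rank(X)
  structure(X, class = c("design_matrix", class(X)),
            kind = kind, ...)
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop2("design matrix is rank deficient; aliased column(s): ",
          paste(aliased, collapse = ", "))
  }
  invisible(X)
}

validate_sample_table <- function(samples, needed) {
  if (!is.data.frame(samples) || nrow(samples) == 0L)
    stop2("'samples' must be a non-empty data frame")
  missing <- setdiff(needed, names(samples))
  if (length(missing))
    stop2("sample table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(samples$sample))
    stop2("duplicate sample ids in sample table")
  invisible(samples)
}

#' Contrast: treatment versus untreated control within a time point
#'
#' Returns the contrast vector whose inner product with the fitted
#' coefficients gives the log2 fold change of `treatment` versus the
#' control arm at `time`. Under the cumulative parameterization the shared
#' drift columns cancel between arms, so the contrast puts weight 1 on
#' every `<treatment>:after_<t_i>` column with `t_i <= time` and 0
#' elsewhere.
#'
#' @param design a `design_matrix` from [build_cumulative_design()].
#' @param treatment non-control treatment label.
#' @param time time point (hours), on the design grid.
#' @return named numeric vector over the design columns, with a
#'   `"label"` attribute such as `"ATP vs mock at 3 h"`.
#' @export
contrast_treatment_vs_mock <- function(design, treatment, time) {
  stopifnot(inherits(design, "design_matrix"))
  if (!identical(attr(design, "kind"), "timecourse"))
    stop2("contrast_treatment_vs_mock() needs a time-course design")
  mock <- attr(design, "mock")
  grid <- attr(design, "time_grid")
  if (identical(treatment, mock))
    stop2("the control arm cannot be contrasted against itself")
  if (!treatment %in% attr(design, "treatments"))
    stop2(sprintf("unknown treatment '%s'", treatment))
  if (!time %in% grid)
    stop2(sprintf("time %s h is not on the design grid", format(time)))
  w <- stats::setNames(numeric(ncol(design)), colnames(design))
  on <- grid[grid <= time]
  w[paste0(treatment, ":after_", on)] <- 1
  attr(w, "label") <- sprintf("%s vs %s at %g h", treatment, mock, time)
  w
}

#' Contrast: knockout versus reference genotype within a treatment
#'
#' For the factorial design, the KO-versus-reference log2 fold change within
#' treatment `a` is `knockout + knockout:treatment_a` (just `knockout` for
#' the untreated arm).
#'
#' @param design a factorial `design_matrix`.
#' @param treatment treatment label (may be the untreated arm).
#' @return named contrast vector with a `"label"` attribute.
#' @export
contrast_ko_vs_ref <- function(design, treatment) {
  stopifnot(inherits(design, "design_matrix"))
  if (!identical(attr(design, "kind"), "factorial"))
    stop2("contrast_ko_vs_ref() needs a factorial design")
  if (!treatment %in% attr(design, "treatments"))
    stop2(sprintf("unknown treatment '%s'", treatment))
  gen <- attr(design, "genotypes")
  w <- stats::setNames(numeric(ncol(design)), colnames(design))
  w["knockout"] <- 1
  if (!identical(treatment, attr(design, "mock")))
    w[paste0("knockout:treatment_", treatment)] <- 1
  attr(w, "label") <- sprintf("%s vs %s in %s", gen[2L], gen[1L], treatment)
  w
}
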