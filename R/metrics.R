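#' Inbreeding coefficient from IBD-tracking labels
#'
#' The proportion of IBD-tracking loci at which the two labels carried by an
#' individual are identical (identity-by-descent relative to the base
#' population, whose haplotypes are uniquely labelled).
#'
#' @param labels1,labels2 integer label vectors, one per haplotype.
#' @return a proportion in `[0, 1]`.
#' @export
inbreeding_coefficient <- function(labels1, labels2) {
  if (length(labels1) != length(labels2))
    stop("the two label vectors must have equal length")
  if (anyNA(labels1) || anyNA(labels2))
    stop("unlabelled IBD locus encountered")
  mean(labels1 == labels2)
}

#' Rate of inbreeding from a mean-inbreeding series
#'
#' `dF = 1 - exp(beta)`, where `beta` is the slope of the ordinary
#' least-squares regression of `ln(1 - F_u)` on generation `u` over
#' `[gen_lo, gen_hi]`. Under a constant per-generation rate `x`,
#' `F_u = 1 - (1 - x)^u` and the estimator returns `x` exactly.
#'
#' @param F_series mean inbreeding per generation; names are generation
#'   numbers (unnamed vectors are taken to start at generation 0).
#' @param gen_lo,gen_hi regression window (defaults 5 and 20).
#' @return the per-generation rate of inbreeding.
#' @export
rate_of_inbreeding <- function(F_series, gen_lo = 5L, gen_hi = 20L) {
  u <- gen_names(F_series)
  sel <- u >= gen_lo & u <= gen_hi
  if (sum(sel) < 2L) stop("fewer than two generations in the window")
  f <- F_series[sel]
  if (any(f >= 1)) stop("F = 1 in the regression window; log(1-F) undefined")
  beta <- coef(lm(log(1 - f) ~ u[sel]))[[2L]]
  1 - exp(beta)
}

gen_names <- function(x) {
  if (is.null(names(x))) seq_along(x) - 1L else as.numeric(names(x))
}

#' Rate of genetic gain from a mean-TBV series
#'
#' The mean over `u` in `[gen_lo, gen_hi]` of the one-generation gains
#' `Gbar_u - Gbar_{u-1}` (which telescopes to
#' `(Gbar_hi - Gbar_{lo-1}) / (hi - lo + 1)`).
#'
#' @param tbv_means mean true breeding value per generation; names are
#'   generation numbers (unnamed vectors start at generation 0).
#' @inheritParams rate_of_inbreeding
#' @return the per-generation rate of gain.
#' @export
rate_of_gain <- function(tbv_means, gen_lo = 5L, gen_hi = 20L) {
  u <- gen_names(tbv_means)
  need <- (gen_lo - 1L):gen_hi
  if (!all(need %in% u)) stop("the series does not cover the window")
  g <- tbv_means[match(need, u)]
  mean(diff(g))
}

#' Genetic variance per generation
#'
#' The population (n-denominator) variance of true breeding values within
#' each cohort.
#'
#' @param tbv_by_gen list of per-cohort TBV vectors (one per generation).
#' @return numeric vector of variances.
#' @export
genetic_variance_series <- function(tbv_by_gen) {
  vapply(tbv_by_gen, function(x) {
    if (length(x) < 2L) stop("a cohort with at least 2 animals is required")
    pop_var(x)
  }, numeric(1))
}

#' Number of contributing ancestors per generation
#'
#' Counts, for each ancestor generation, the ancestors whose long-term
#' genetic contribution to the target cohort exceeds `threshold`
#' (default 0, i.e. any positive contribution).
#'
#' @param contributions data frame with columns `generation` and a
#'   contribution column named by `column` (default `"r_ped"`).
#' @param threshold contribution threshold.
#' @param column which contribution column to count.
#' @return named integer vector, one count per ancestor generation present.
#' @export
contributing_ancestor_counts <- function(contributions, threshold = 0,
                                         column = "r_ped") {
  stopifnot(column %in% names(contributions))
  r <- contributions[[column]]
  tapply(r > threshold, contributions$generation, sum)
}

#' Dispersion of contributions around the Mendelian-sampling regression
#'
#' Regresses long-term genetic contributions on Mendelian-sampling terms
#' over the ancestors with a positive contribution and returns the
#' population SD of the residuals — the deviation of the realised
#' contributions from the ideal threshold-linear relationship.
#'
#' @param r long-term contributions.
#' @param m Mendelian-sampling terms aligned with `r` (NA rows dropped).
#' @return residual SD, or NA (with a warning) when fewer than 3 ancestors
#'   contribute.
#' @export
contribution_regression_sd <- function(r, m) {
  keep <- !is.na(r) & !is.na(m) & r > 0
  if (sum(keep) < 3L) {
    warning("fewer than 3 contributing ancestors; diagnostic skipped")
    return(NA_real_)
  }
  res <- residuals(lm(r[keep] ~ m[keep]))
  sqrt(pop_var(res))
}

#' Summarise one replicate into the assessment criteria
#'
#' Computes the rate of inbreeding and gain over the regression window, the
#' final-generation inbreeding and genetic variance, the mean prediction
#' accuracy, the average per-generation number of contributing ancestors,
#' and the residual SDs of the contribution regressions (pedigree- and,
#' when tracked, genomic-based).
#'
#' @param res a `replicate_result` from [run_scheme()].
#' @param dF_window `c(lo, hi)` regression window; default
#'   `c(5, n_generations)`.
#' @return a one-row data frame.
#' @export
summarize_replicate <- function(res, dF_window = NULL) {
  ngen <- res$config$n_generations
  if (is.null(dF_window)) dF_window <- c(min(5L, ngen - 1L), ngen)
  out <- data.frame(
    dF = rate_of_inbreeding(res$F_mean, dF_window[1], dF_window[2]),
    dG = rate_of_gain(res$tbv_mean, dF_window[1], dF_window[2]),
    F_final = unname(res$F_mean[as.character(ngen)]),
    var_final = unname(res$tbv_var[as.character(ngen)]),
    accuracy = mean(res$accuracy, na.rm = TRUE),
    onset_generation = onset_generation(res$F_mean)
  )
  a <- res$ancestors
  if (!is.null(a$r_ped)) {
    out$n_contrib <- mean(contributing_ancestor_counts(a))
    out$sd_ped <- suppressWarnings(
      contribution_regression_sd(a$r_ped, a$mst))
  } else {
    out$n_contrib <- NA_real_; out$sd_ped <- NA_real_
  }
  out$sd_gen <- if (!is.null(a$r_gen)) suppressWarnings(
    contribution_regression_sd(a$r_gen, a$mst)) else NA_real_
  out
}

#' First generation with positive mean inbreeding
#'
#' @param F_series mean inbreeding per generation (names = generations).
#' @return the earliest generation whose cohort mean inbreeding exceeds
#'   zero, or NA if inbreeding never arises.
#' @export
onset_generation <- function(F_series) {
  u <- gen_names(F_series)
  pos <- which(F_series > 0)
  if (length(pos) == 0L) return(NA_real_)
  u[min(pos)]
}
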