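#' Breeding-scheme configuration
#'
#' Five presets matching the simulated pig-style schemes: 20 sires
#' throughout, and
#' \itemize{
#'   \item scheme 1: 120 dams, litter 10, h2 = 0.1 (1200 offspring/gen)
#'   \item scheme 2: 20 dams, litter 60, h2 = 0.1 (1200)
#'   \item scheme 3: 20 dams, litter 20, h2 = 0.1 (400)
#'   \item scheme 4: 40 dams, litter 10, h2 = 0.1 (400)
#'   \item scheme 5: 40 dams, litter 10, h2 = 0.4 (400)
#' }
#' Explicit arguments override the preset.
#'
#' @param scheme preset number 1-5, or NULL for a fully explicit config.
#' @param n_sires,n_dams,litter_size,h2 scheme parameters.
#' @param n_generations number of selected generations; cohorts run from
#'   generation 0 (base) to `n_generations` (final offspring).
#' @param strategy `"RAND"`, `"MC"` or `"MCAC"`.
#' @param info_source `"pedigree"` or `"genomic"` (ignored for RAND).
#' @param track_contributions `"both"`, `"pedigree"` or `"none"`:
#'   which long-term contribution diagnostics to compute on the final
#'   cohort.
#' @param lambda optional fixed ridge penalty; by default the SNP-BLUP
#'   value from [choose_lambda()] is recomputed each generation from the
#'   training allele frequencies.
#' @param mcac_restarts,mcac_max_sweeps,mcac_method MCAC search controls
#'   passed to [allocate_mcac()].
#' @return an object of class `scheme_config` (a list).
#' @export
scheme_config <- function(scheme = NULL, n_sires = 20L, n_dams = NULL,
                          litter_size = NULL, h2 = NULL,
                          n_generations = 20L,
                          strategy = c("RAND", "MC", "MCAC"),
                          info_source = c("pedigree", "genomic"),
                          track_contributions = c("both", "pedigree",
                                                  "none"),
                          lambda = NULL, mcac_restarts = 2L,
                          mcac_max_sweeps = 1000L,
                          mcac_method = "first") {
  strategy <- match.arg(strategy)
  info_source <- match.arg(info_source)
  track_contributions <- match.arg(track_contributions)
  presets <- list(
    `1` = list(n_dams = 120L, litter_size = 10L, h2 = 0.1),
    `2` = list(n_dams = 20L, litter_size = 60L, h2 = 0.1),
    `3` = list(n_dams = 20L, litter_size = 20L, h2 = 0.1),
    `4` = list(n_dams = 40L, litter_size = 10L, h2 = 0.1),
    `5` = list(n_dams = 40L, litter_size = 10L, h2 = 0.4)
  )
  if (!is.null(scheme)) {
    ps <- presets[[as.character(scheme)]]
    if (is.null(ps)) stop("unknown scheme preset: ", scheme)
    if (is.null(n_dams)) n_dams <- ps$n_dams
    if (is.null(litter_size)) litter_size <- ps$litter_size
    if (is.null(h2)) h2 <- ps$h2
  }
  if (is.null(n_dams) || is.null(litter_size) || is.null(h2))
    stop("n_dams, litter_size and h2 must be set (or use a preset)")
  ratio <- check_ratio(n_sires, n_dams, NULL)
  cfg <- list(scheme = if (is.null(scheme)) NA_integer_ else
                as.integer(scheme),
              n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              litter_size = as.integer(litter_size), h2 = h2,
              mating_ratio = ratio,
              n_total = as.integer(n_dams) * as.integer(litter_size),
              n_generations = as.integer(n_generations),
              strategy = strategy, info_source = info_source,
              track_contributions = track_contributions,
              lambda = lambda, mcac_restarts = as.integer(mcac_restarts),
              mcac_max_sweeps = as.integer(mcac_max_sweeps),
              mcac_method = mcac_method)
  class(cfg) <- "scheme_config"
  cfg
}

#' @export
print.scheme_config <- function(x, ...) {
  cat(sprintf(
    "Scheme %s: %d sires x %d dams (ratio %d), litter %d, h2 = %.2f\n",
    ifelse(is.na(x$scheme), "(custom)", x$scheme), x$n_sires, x$n_dams,
    x$mating_ratio, x$litter_size, x$h2))
  cat(sprintf("  %s / %s, %d generations, N_total = %d\n", x$strategy,
              if (x$strategy == "RAND") "-" else x$info_source,
              x$n_generations, x$n_total))
  invisible(x)
}

# ---- cohort helpers -------------------------------------------------------

new_cohort <- function(id, sex, sire, dam, generation, H, tbv, phen) {
  structure(list(id = id, sex = sex, sire = sire, dam = dam,
                 generation = generation, H = H, tbv = tbv, phen = phen,
                 gebv = rep(NA_real_, length(id))),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Cohort of %d animals, generation %d (mean TBV %.3f, var TBV %.4f)\n",
    length(x$id), x$generation, mean(x$tbv), pop_var(x$tbv)))
  invisible(x)
}

#' Extract allele counts for a cohort
#'
#' Sums the two haplotypes at the loci of the requested panel role; rows are
#' individuals, columns loci.
#'
#' @param cohort a cohort from [make_base_population()] or
#'   [produce_offspring()].
#' @param panels the `loci_panel` of the run.
#' @param role `"marker"` or `"qtl"`.
#' @return integer matrix of 0/1/2 allele counts.
#' @export
cohort_geno <- function(cohort, panels, role = c("marker", "qtl")) {
  role <- match.arg(role)
  rows <- if (role == "marker") panels$marker_rows else panels$qtl_rows
  n <- length(cohort$id)
  odd <- seq(1L, 2L * n, by = 2L)
  t(cohort$H[rows, odd, drop = FALSE] +
      cohort$H[rows, odd + 1L, drop = FALSE])
}

#' Per-individual inbreeding from IBD-tracking labels
#'
#' The proportion of the 2000 (by default) IBD-tracking loci at which an
#' individual carries two identical founder-haplotype labels.
#'
#' @inheritParams cohort_geno
#' @return numeric vector, one coefficient per individual.
#' @export
cohort_inbreeding <- function(cohort, panels) {
  rows <- panels$ibd_rows
  n <- length(cohort$id)
  odd <- seq(1L, 2L * n, by = 2L)
  colMeans(cohort$H[rows, odd, drop = FALSE] ==
             cohort$H[rows, odd + 1L, drop = FALSE])
}

panel_chr_index <- function(panels) {
  chr <- panels$breed_map$chr
  cnt <- tabulate(chr, nbins = panels$n_chromosomes)
  list(off = c(0L, cumsum(cnt)[-length(cnt)]), n = cnt)
}

# ---- stage 2: base population --------------------------------------------

#' Sample the base population from the founders
#'
#' Draws `n_sires + n_dams` distinct animals from the last founder
#' generation, assigns the first `n_sires` of the draw as males and the rest
#' as females, copies their marker and QTL alleles onto the breeding-phase
#' locus map, and labels every haplotype with a unique allele at all
#' IBD-tracking loci (so base inbreeding is exactly zero and descent from
#' base haplotypes is directly observable). QTL effects are scaled on this
#' cohort so its genetic variance equals `h2`, and phenotypes are assigned.
#'
#' @param founders a `founder_pop`.
#' @param panels a `loci_panel` from [build_panels()].
#' @param raw_effects raw QTL effects from [sample_qtl_effects()].
#' @param config a [scheme_config()].
#' @return list with `cohort` (generation 0) and `arch` (`trait_arch`).
#' @export
make_base_population <- function(founders, panels, raw_effects, config) {
  n_base <- config$n_sires + config$n_dams
  if (founders$ne < n_base)
    stop(sprintf("founder population of %d cannot supply %d base animals",
                 founders$ne, n_base))
  idx <- sample.int(founders$ne, n_base)
  hapcols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  bm <- panels$breed_map
  H <- matrix(0L, nrow(bm), 2L * n_base)
  from <- !is.na(bm$founder_locus)
  H[from, ] <- founders$haplotypes[bm$founder_locus[from], hapcols]
  H[panels$ibd_rows, ] <- matrix(seq_len(2L * n_base),
                                 length(panels$ibd_rows), 2L * n_base,
                                 byrow = TRUE)
  sex <- rep(c("M", "F"), c(config$n_sires, config$n_dams))
  cohort <- new_cohort(id = seq_len(n_base), sex = sex,
                       sire = rep(NA_integer_, n_base),
                       dam = rep(NA_integer_, n_base),
                       generation = 0L, H = H,
                       tbv = numeric(n_base), phen = numeric(n_base))
  qg <- cohort_geno(cohort, panels, "qtl")
  arch <- scale_effects(raw_effects, qg, config$h2)
  cohort$tbv <- true_breeding_value(qg, arch)
  cohort$phen <- phenotype(cohort$tbv, arch$env_variance)
  list(cohort = cohort, arch = arch)
}

# ---- selection and reproduction ------------------------------------------

#' Truncation selection on GEBV
#'
#' Ranks each sex by decreasing GEBV (ties broken by increasing id, so
#' selection is deterministic) and returns the top `n_sires` males and top
#' `n_dams` females.
#'
#' @param cohort a cohort with `gebv` filled in.
#' @param n_sires,n_dams numbers to select.
#' @return list with `sires` and `dams` (ids).
#' @export
select_parents <- function(cohort, n_sires, n_dams) {
  ord <- order(-cohort$gebv, cohort$id)
  males <- cohort$id[ord][cohort$sex[ord] == "M"]
  females <- cohort$id[ord][cohort$sex[ord] == "F"]
  if (length(males) < n_sires || length(females) < n_dams)
    stop(sprintf("cohort has %d males / %d females but %d / %d are needed",
                 length(males), length(females), n_sires, n_dams))
  list(sires = males[seq_len(n_sires)], dams = females[seq_len(n_dams)])
}

#' Produce the next cohort from a mating plan
#'
#' Each mating yields `litter_size` offspring. Gametes are dropped through
#' the full breeding-phase locus map, so marker, QTL and IBD-tracking loci
#' are co-inherited on shared crossovers; no mutation occurs during the
#' breeding phase (IBD labels stay intact). Sexes alternate within a litter
#' starting with a male, TBV and phenotype are assigned at birth.
#'
#' @param plan a [mating_plan].
#' @param parents the parents' cohort.
#' @param panels the `loci_panel` of the run.
#' @param arch the scaled `trait_arch`.
#' @param start_id first offspring id (ids are consecutive integers).
#' @return the offspring cohort.
#' @export
produce_offspring <- function(plan, parents, panels, arch,
                              start_id = max(parents$id) + 1L) {
  sl <- match(plan$sire, parents$id)
  dl <- match(plan$dam, parents$id)
  if (anyNA(sl) || anyNA(dl))
    stop("mating plan references an animal outside the parent cohort")
  lit <- plan$litter_size
  n_off <- sum(lit)
  off_s <- rep(sl, times = lit)
  off_d <- rep(dl, times = lit)
  par_seq <- as.vector(rbind(off_d, off_s)) # maternal, paternal per child
  ci <- panel_chr_index(panels)
  G <- cpp_drop_gametes(parents$H, 2L * par_seq - 1L, 2L * par_seq,
                        ci$off, ci$n, panels$breed_map$pos,
                        panels$chromosome_length, 0)
  sex <- unlist(lapply(lit, function(l) rep_len(c("M", "F"), l)),
                use.names = FALSE)
  cohort <- new_cohort(id = seq.int(start_id, length.out = n_off),
                       sex = sex,
                       sire = rep(plan$sire, times = lit),
                       dam = rep(plan$dam, times = lit),
                       generation = parents$generation + 1L, H = G,
                       tbv = numeric(n_off), phen = numeric(n_off))
  qg <- cohort_geno(cohort, panels, "qtl")
  cohort$tbv <- true_breeding_value(qg, arch)
  cohort$phen <- phenotype(cohort$tbv, arch$env_variance)
  cohort
}

# ---- ancestor bookkeeping -------------------------------------------------
# Only selected parents (plus the base animals) can ever contribute to
# descendants, so pedigree A and contribution L are maintained over that set
# alone, grown one generation at a time by the standard recursions.

anc_init <- function(base, X = NULL) {
  n <- length(base$id)
  ids <- as.character(base$id)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  L <- diag(n); dimnames(L) <- list(ids, ids)
  list(id = base$id, gen = rep(0L, n), tbv = base$tbv,
       mst = rep(NA_real_, n), A = A, L = L, X = X)
}

anc_add <- function(anc, cohort, sel_ids, X_sel = NULL) {
  loc <- match(sel_ids, cohort$id)
  si <- match(cohort$sire[loc], anc$id)
  di <- match(cohort$dam[loc], anc$id)
  if (anyNA(si) || anyNA(di))
    stop("selected animal has a parent outside the ancestor set")
  n_new <- length(sel_ids)
  ids_new <- as.character(sel_ids)

  B <- 0.5 * (anc$A[si, , drop = FALSE] + anc$A[di, , drop = FALSE])
  N2 <- 0.5 * (B[, si, drop = FALSE] + B[, di, drop = FALSE])
  diag(N2) <- 1 + 0.5 * anc$A[cbind(si, di)]
  A <- rbind(cbind(anc$A, t(B)), cbind(B, N2))

  Lnew <- 0.5 * (anc$L[si, , drop = FALSE] + anc$L[di, , drop = FALSE])
  L <- rbind(cbind(anc$L, matrix(0, nrow(anc$L), n_new)),
             cbind(Lnew, diag(n_new)))
  ids <- c(rownames(anc$A), ids_new)
  dimnames(A) <- list(ids, ids)
  dimnames(L) <- list(ids, ids)

  tbv_new <- cohort$tbv[loc]
  list(id = c(anc$id, sel_ids),
       gen = c(anc$gen, rep(cohort$generation, n_new)),
       tbv = c(anc$tbv, tbv_new),
       mst = c(anc$mst,
               tbv_new - 0.5 * (anc$tbv[si] + anc$tbv[di])),
       A = A, L = L,
       X = if (is.null(anc$X)) NULL else rbind(anc$X, X_sel))
}

# allocation dispatcher: builds the cost input the strategy needs and
# returns the generation's mating plan
make_plan <- function(config, anc, sel, p_cand) {
  ls <- config$litter_size
  if (config$strategy == "RAND")
    return(allocate_random(sel$sires, sel$dams, config$mating_ratio, ls))
  genomic <- config$info_source == "genomic"
  if (config$strategy == "MC") {
    relmat <- if (genomic) {
      keep <- p_cand > 0 & p_cand < 1
      rows <- match(as.character(c(sel$sires, sel$dams)),
                    rownames(anc$X))
      genomic_G(anc$X[rows, keep, drop = FALSE], p = p_cand[keep])
    } else anc$A
    fb <- coancestry_block(relmat, sel$sires, sel$dams)
    return(allocate_mc(fb, config$mating_ratio, ls, config$info_source))
  }
  # MCAC: contribution matrix over all tracked ancestors
  L <- if (genomic) {
    keep <- p_cand > 0 & p_cand < 1
    contribution_L(genomic_G(anc$X[, keep, drop = FALSE],
                             p = p_cand[keep]))
  } else anc$L
  allocate_mcac(L, sel$sires, sel$dams, config$mating_ratio, ls,
                restarts = config$mcac_restarts,
                max_sweeps = config$mcac_max_sweeps,
                method = config$mcac_method,
                info_source = config$info_source)
}

# ---- stage 3: one replicate ----------------------------------------------

#' Run one replicate of a breeding scheme
#'
#' Executes generations 0 to `n_generations`: the base population (all of
#' which are parents) is mated by the configured strategy to produce
#' generation 1; from then on every cohort is genotyped and phenotyped, a
#' ridge-regression (SNP-BLUP) model is fitted to the phenotypes of the
#' current and previous generation, candidates are truncation-selected on
#' predicted breeding values, mates are allocated, and the next cohort is
#' bred. The run is fully reproducible from `seed`.
#'
#' @param config a [scheme_config()].
#' @param founders a `founder_pop`; simulated with defaults when NULL.
#' @param panels optional `loci_panel`; built from `founders` when NULL.
#' @param raw_effects optional raw QTL effects; sampled when NULL.
#' @param seed optional integer seed (set before base sampling, so
#'   replicates with different seeds are independent given the founders).
#' @return An object of class `replicate_result`: list with `config`,
#'   per-generation vectors `F_mean`, `tbv_mean`, `tbv_var` (generations
#'   0..n), `accuracy` and `objective` (selection generations), `plans`
#'   (the mating plan of each generation), `pedigree`
#'   (data frame over all cohort animals), `ancestors` (data frame with
#'   id, generation, tbv, Mendelian-sampling term and — when tracked —
#'   long-term contributions `r_ped`/`r_gen` to the final cohort).
#' @export
run_scheme <- function(config, founders = NULL, panels = NULL,
                       raw_effects = NULL, seed = NULL) {
  stopifnot(inherits(config, "scheme_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(founders)) founders <- sim_founders()
  if (is.null(panels)) panels <- build_panels(founders)
  if (is.null(raw_effects))
    raw_effects <- sample_qtl_effects(length(panels$qtl_loci))

  bp <- make_base_population(founders, panels, raw_effects, config)
  arch <- bp$arch
  current <- bp$cohort
  prev <- NULL
  ngen <- config$n_generations
  need_X <- config$info_source == "genomic" ||
    config$track_contributions == "both"

  Xcur <- cohort_geno(current, panels, "marker")
  rownames(Xcur) <- as.character(current$id)
  p_base <- colMeans(Xcur) / 2
  anc <- anc_init(current, X = if (need_X) Xcur else NULL)

  gens <- 0:ngen
  F_mean <- tbv_mean <- tbv_var <- setNames(rep(NA_real_, ngen + 1L),
                                            gens)
  accuracy <- objective <- setNames(rep(NA_real_, ngen), 0:(ngen - 1L))
  plans <- setNames(vector("list", ngen), 0:(ngen - 1L))
  ped <- vector("list", ngen + 1L)
  record <- function(cohort) {
    g <- as.character(cohort$generation)
    F_mean[g] <<- mean(cohort_inbreeding(cohort, panels))
    tbv_mean[g] <<- mean(cohort$tbv)
    tbv_var[g] <<- pop_var(cohort$tbv)
    ped[[cohort$generation + 1L]] <<- data.frame(
      id = cohort$id, sire = cohort$sire, dam = cohort$dam,
      generation = cohort$generation, sex = cohort$sex,
      tbv = cohort$tbv, gebv = cohort$gebv)
  }
  record(current)

  Xprev <- NULL
  for (u in 0:(ngen - 1L)) {
    if (u == 0L) {
      sel <- list(sires = current$id[current$sex == "M"],
                  dams = current$id[current$sex == "F"])
    } else {
      Xtrain <- rbind(Xprev, Xcur)
      ytrain <- c(prev$phen, current$phen)
      p_train <- colMeans(Xtrain) / 2
      lam <- if (is.null(config$lambda))
        choose_lambda(config$h2, p_train) else config$lambda
      fit <- fit_ridge(Xtrain, ytrain, lam, method = "dual")
      current$gebv <- predict_gebv(fit, Xcur)
      accuracy[as.character(u)] <- cor(current$gebv, current$tbv)
      ped[[u + 1L]]$gebv <- current$gebv
      sel <- select_parents(current, config$n_sires, config$n_dams)
      anc <- anc_add(anc, current, c(sel$sires, sel$dams),
                     X_sel = if (need_X)
                       Xcur[match(c(sel$sires, sel$dams), current$id), ,
                            drop = FALSE] else NULL)
    }
    p_cand <- colMeans(Xcur) / 2
    plan <- make_plan(config, anc, sel, p_cand)
    objective[as.character(u)] <- attr(plan, "objective")
    plans[[as.character(u)]] <- plan
    offspring <- produce_offspring(plan, current, panels, arch)
    prev <- current; Xprev <- Xcur
    current <- offspring
    Xcur <- cohort_geno(current, panels, "marker")
    rownames(Xcur) <- as.character(current$id)
    record(current)
  }

  ancestors <- data.frame(id = anc$id, generation = anc$gen,
                          tbv = anc$tbv, mst = anc$mst)
  if (config$track_contributions != "none") {
    si <- match(current$sire, anc$id)
    di <- match(current$dam, anc$id)
    rows_final <- 0.5 * (anc$L[si, , drop = FALSE] +
                           anc$L[di, , drop = FALSE])
    ancestors$r_ped <- colMeans(rows_final)
  }
  if (config$track_contributions == "both") {
    # centre at base-generation frequencies: contributions are measured
    # relative to the base population (centring at the target cohort's own
    # frequencies would force its mean contribution to zero)
    keep <- p_base > 0 & p_base < 1
    Xall <- rbind(anc$X[, keep, drop = FALSE], Xcur[, keep, drop = FALSE])
    Gfull <- genomic_G(Xall, p = p_base[keep])
    Lg <- contribution_L(Gfull)
    fin <- nrow(anc$X) + seq_len(length(current$id))
    ancestors$r_gen <- colMeans(Lg[fin, seq_len(nrow(anc$X)),
                                   drop = FALSE])
  }

  structure(list(config = config, F_mean = F_mean, tbv_mean = tbv_mean,
                 tbv_var = tbv_var, accuracy = accuracy,
                 objective = objective, plans = plans,
                 pedigree = do.call(rbind, ped), ancestors = ancestors,
                 seed = seed),
            class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  ngen <- x$config$n_generations
  cat(sprintf(
    "Replicate: %s/%s, %d generations; final F = %.4f, mean TBV = %.3f\n",
    x$config$strategy,
    if (x$config$strategy == "RAND") "-" else x$config$info_source,
    ngen, x$F_mean[[as.character(ngen)]],
    x$tbv_mean[[as.character(ngen)]]))
  invisible(x)
}

# ---- replicated experiments ----------------------------------------------

#' Run a replicated experiment over one or more scheme configurations
#'
#' Runs `n_replicates` independent replicates of every configuration and
#' summarises the assessment criteria. With `shared_founders = TRUE`
#' (the default, mirroring a single founder stage reused by all base /
#' selected stages) one founder population, locus panel and raw QTL effect
#' vector are simulated from `base_seed` and shared; replicate `r` then
#' runs with seed `base_seed + r`, so the same replicate number sees the
#' same base animals across configurations. With `shared_founders = FALSE`
#' each replicate simulates its own founder population.
#'
#' @param configs a `scheme_config` or list of them.
#' @param n_replicates replicates per configuration.
#' @param base_seed integer; all randomness derives from it.
#' @param shared_founders share one founder stage across replicates?
#' @param founders optional pre-simulated `founder_pop` (implies sharing).
#' @param founder_args list of arguments for [sim_founders()] when founders
#'   are simulated internally.
#' @param panel_args list of arguments for [build_panels()].
#' @param dF_window generations used for the log-linear inbreeding-rate
#'   regression and the gain window, default `c(5, n_generations)`.
#' @return list with `replicates` (one row per config x replicate: dF, dG,
#'   final-generation variance and inbreeding, mean contributing-ancestor
#'   count, residual SDs), `summary` (mean and SD over replicates),
#'   and `series` (per-generation mean F and genetic variance, long
#'   format).
#' @export
run_experiment <- function(configs, n_replicates = 10L, base_seed = 1L,
                           shared_founders = TRUE, founders = NULL,
                           founder_args = list(), panel_args = list(),
                           dF_window = NULL) {
  if (inherits(configs, "scheme_config")) configs <- list(configs)
  shared <- shared_founders || !is.null(founders)
  if (shared && is.null(founders)) {
    set.seed(base_seed)
    founders <- do.call(sim_founders, founder_args)
  }
  shared_panels <- NULL
  shared_effects <- NULL
  if (shared) {
    set.seed(base_seed)
    shared_panels <- do.call(build_panels, c(list(founders), panel_args))
    shared_effects <- sample_qtl_effects(length(shared_panels$qtl_loci))
  }
  rep_rows <- list()
  series_rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    label <- sprintf("%s_%s", cfg$strategy,
                     if (cfg$strategy == "RAND") "na" else cfg$info_source)
    for (r in seq_len(n_replicates)) {
      fp <- founders; pn <- shared_panels; fx <- shared_effects
      if (!shared) {
        set.seed(base_seed + r)
        fp <- do.call(sim_founders, founder_args)
        pn <- do.call(build_panels, c(list(fp), panel_args))
        fx <- sample_qtl_effects(length(pn$qtl_loci))
      }
      res <- run_scheme(cfg, fp, pn, fx, seed = base_seed + r)
      rep_rows[[length(rep_rows) + 1L]] <-
        cbind(data.frame(scheme = cfg$scheme, strategy = cfg$strategy,
                         info = cfg$info_source, label = label,
                         replicate = r),
              summarize_replicate(res, dF_window))
      series_rows[[length(series_rows) + 1L]] <- data.frame(
        scheme = cfg$scheme, strategy = cfg$strategy,
        info = cfg$info_source, label = label, replicate = r,
        generation = as.integer(names(res$F_mean)),
        F_mean = unname(res$F_mean), tbv_mean = unname(res$tbv_mean),
        tbv_var = unname(res$tbv_var))
    }
  }
  replicates <- do.call(rbind, rep_rows)
  num <- vapply(replicates, is.numeric, logical(1)) &
    !(names(replicates) %in% c("scheme", "replicate"))
  agg_mean <- stats::aggregate(replicates[num],
                               by = replicates[c("label", "scheme")], mean,
                               na.rm = TRUE)
  agg_sd <- stats::aggregate(replicates[num],
                             by = replicates[c("label", "scheme")], sd,
                             na.rm = TRUE)
  names(agg_sd)[-(1:2)] <- paste0(names(agg_sd)[-(1:2)], "_sd")
  list(replicates = replicates,
       summary = merge(agg_mean, agg_sd, by = c("label", "scheme")),
       series = do.call(rbind, series_rows))
}
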