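#' Mating plans
#'
#' A mating plan is a data frame with one row per mating (`sire`, `dam`,
#' `litter_size`) plus attributes `strategy`, `info_source` and `objective`
#' (the value of the allocation criterion, NA for random mating). Every dam
#' appears exactly once; every sire appears exactly `mating_ratio` times.
#'
#' @name mating_plan
NULL

new_mating_plan <- function(sires, dams, litter_size, strategy,
                            info_source = NA_character_, objective = NA_real_) {
  plan <- data.frame(sire = sires, dam = dams, litter_size = litter_size,
                     stringsAsFactors = FALSE)
  attr(plan, "strategy") <- strategy
  attr(plan, "info_source") <- info_source
  attr(plan, "objective") <- objective
  class(plan) <- c("mating_plan", "data.frame")
  plan
}

check_ratio <- function(n_sires, n_dams, mating_ratio) {
  if (is.null(mating_ratio)) mating_ratio <- n_dams / n_sires
  if (mating_ratio != round(mating_ratio) ||
      n_dams != mating_ratio * n_sires)
    stop(sprintf(
      "%d dams cannot be split over %d sires at a mating ratio of %s",
      n_dams, n_sires, format(mating_ratio)))
  as.integer(mating_ratio)
}

#' Random mate allocation
#'
#' Dams are assigned uniformly at random to sire slots (each sire holds
#' `mating_ratio` slots).
#'
#' @param sire_ids,dam_ids selected parents; `length(dam_ids)` must equal
#'   `mating_ratio * length(sire_ids)`.
#' @param mating_ratio dams per sire; inferred when NULL.
#' @param litter_size offspring per mating (recorded in the plan).
#' @return a [mating_plan].
#' @export
allocate_random <- function(sire_ids, dam_ids, mating_ratio = NULL,
                            litter_size = 1L) {
  ratio <- check_ratio(length(sire_ids), length(dam_ids), mating_ratio)
  slots <- rep(sire_ids, each = ratio)
  new_mating_plan(slots, sample(dam_ids), litter_size, "RAND")
}

#' Minimum-coancestry mate allocation
#'
#' Pairs selected sires and dams so that the average coancestry of the
#' proposed matings is minimal. Each sire's row of the coancestry block is
#' duplicated `mating_ratio` times and the resulting square problem is
#' solved exactly as a min-cost assignment. Inputs are ordered by sire and
#' dam id before solving, so ties are broken deterministically in lexical
#' order.
#'
#' @param fblock coancestry block from [coancestry_block()], sires in rows,
#'   dams in columns, with id dimnames.
#' @param mating_ratio dams per sire; inferred when NULL.
#' @param litter_size offspring per mating (recorded in the plan).
#' @param info_source tag recorded in the plan (`"pedigree"` or
#'   `"genomic"`).
#' @return a [mating_plan]; its `objective` attribute is the realised mean
#'   coancestry of the pairs.
#' @export
allocate_mc <- function(fblock, mating_ratio = NULL, litter_size = 1L,
                        info_source = NA_character_) {
  fblock <- as.matrix(fblock)
  if (any(!is.finite(fblock)))
    stop("coancestry block has non-finite entries")
  sires <- rownames(fblock); dams <- colnames(fblock)
  if (is.null(sires) || is.null(dams))
    stop("coancestry block must carry sire/dam ids as dimnames")
  ratio <- check_ratio(length(sires), length(dams), mating_ratio)
  so <- order(sires); do <- order(dams)
  fblock <- fblock[so, do, drop = FALSE]
  sires <- sires[so]; dams <- dams[do]
  cost <- fblock[rep(seq_along(sires), each = ratio), , drop = FALSE]
  assign <- cpp_assignment(cost)
  slots <- rep(sires, each = ratio)
  obj <- mean(cost[cbind(seq_along(assign), assign)])
  new_mating_plan(slots, dams[assign], litter_size, "MC",
                  info_source, obj)
}

#' MCAC objective: summed absolute covariance of ancestral contributions
#'
#' For a contribution matrix `C` (ancestors x matings), returns the sum over
#' unordered ancestor pairs of the absolute (population) covariance of their
#' contribution profiles across matings. With unequal litters, matings can
#' be weighted by litter size.
#'
#' @param C contributions, ancestors x matings (e.g. from
#'   [contributions_to_matings()]).
#' @param weights optional per-mating weights (e.g. litter sizes).
#' @return a non-negative scalar.
#' @export
mcac_objective <- function(C, weights = NULL) {
  C <- as.matrix(C)
  if (ncol(C) < 2L)
    stop("covariance is undefined for a single mating")
  if (nrow(C) < 2L) stop("at least two ancestors are required")
  w <- if (is.null(weights)) rep(1, ncol(C)) else as.numeric(weights)
  if (length(w) != ncol(C)) stop("one weight per mating is required")
  w <- w / sum(w)
  Cc <- C - drop(C %*% w)
  Cov <- tcrossprod(sweep(Cc, 2L, w, "*"), Cc)
  (sum(abs(Cov)) - sum(abs(diag(Cov)))) / 2
}

#' Mate allocation minimising covariance between ancestral contributions
#'
#' Local search over dam-swap exchanges: starting from a random assignment
#' of dams to sire slots, dam swaps between pairs of matings are applied
#' whenever they strictly decrease [mcac_objective()] of the implied
#' contribution matrix, until a full pass finds no improvement (or
#' `max_sweeps` passes). The best of `restarts` seeded restarts is
#' returned; the result is deterministic given the RNG state.
#' `method = "first"` (default) applies each improving swap as soon as it is
#' found; `"best"` applies only the best swap per pass.
#'
#' @param L contribution matrix (rows = individuals incl. all parents,
#'   columns = ancestors), e.g. from [contribution_L()].
#' @param sire_ids,dam_ids selected parents (rows of `L`).
#' @param mating_ratio dams per sire; inferred when NULL.
#' @param litter_size offspring per mating (recorded in the plan).
#' @param restarts number of random restarts (default 10).
#' @param max_sweeps cap on improvement passes per restart (default 200).
#' @param method `"first"` or `"best"` improvement.
#' @param info_source tag recorded in the plan.
#' @return a [mating_plan]; its `objective` attribute is the realised MCAC
#'   objective.
#' @export
allocate_mcac <- function(L, sire_ids, dam_ids, mating_ratio = NULL,
                          litter_size = 1L, restarts = 10L,
                          max_sweeps = 200L,
                          method = c("first", "best"),
                          info_source = NA_character_) {
  method <- match.arg(method)
  ratio <- check_ratio(length(sire_ids), length(dam_ids), mating_ratio)
  sire_ids <- sort(as.character(sire_ids))
  dam_ids <- sort(as.character(dam_ids))
  ids <- rownames(L)
  s <- match(sire_ids, ids); d <- match(dam_ids, ids)
  if (anyNA(s) || anyNA(d))
    stop("parent id absent from the contribution matrix")
  slots <- rep(seq_along(sire_ids), each = ratio)
  S <- 0.5 * t(L[s[slots], , drop = FALSE])   # ancestors x matings
  V <- 0.5 * t(L[d, , drop = FALSE])          # ancestors x dams
  n <- length(dam_ids)
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- cpp_mcac_search(S, V, sample.int(n), slots,
                           as.integer(max_sweeps), method == "best")
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  new_mating_plan(rep(sire_ids, each = ratio), dam_ids[best$assignment],
                  litter_size, "MCAC", info_source, best$objective)
}
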