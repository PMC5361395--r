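# Independent oracles and shared fixtures for the test suite.

# --- gene dropping ---------------------------------------------------------
# Drops unlinked loci through a pedigree. Founders receive unique labels per
# haplotype; every offspring allele is drawn from the parent's two alleles
# with a fair coin, independently per locus. This is the brute-force
# reference for additive relationships, coancestry, inbreeding and genome
# shares, independent of any package code path.

drop_index <- function(ped) {
  id <- as.character(ped$id)
  unknown <- function(x) is.na(x) | x == 0 | x == "0"
  si <- match(as.character(ped$sire), id)
  di <- match(as.character(ped$dam), id)
  si[unknown(ped$sire)] <- NA_integer_
  di[unknown(ped$dam)] <- NA_integer_
  list(si = si, di = di, n = nrow(ped))
}

gene_drop <- function(ped, n_loci) {
  ix <- drop_index(ped)
  a1 <- matrix(0L, n_loci, ix$n)
  a2 <- matrix(0L, n_loci, ix$n)
  lab <- 0L
  for (i in seq_len(ix$n)) {
    s <- ix$si[i]; d <- ix$di[i]
    if (is.na(s)) {
      lab <- lab + 1L
      a1[, i] <- lab
    } else {
      pick <- runif(n_loci) < 0.5
      a1[, i] <- ifelse(pick, a1[, s], a2[, s])
    }
    if (is.na(d)) {
      lab <- lab + 1L
      a2[, i] <- lab
    } else {
      pick <- runif(n_loci) < 0.5
      a2[, i] <- ifelse(pick, a1[, d], a2[, d])
    }
  }
  list(a1 = a1, a2 = a2)
}

# estimated additive relationship matrix (2 * coancestry; diagonal 1 + F)
gene_drop_A <- function(ped, n_loci = 20000L) {
  gd <- gene_drop(ped, n_loci)
  n <- ncol(gd$a1)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      f <- mean((gd$a1[, i] == gd$a1[, j]) + (gd$a1[, i] == gd$a2[, j]) +
                  (gd$a2[, i] == gd$a1[, j]) + (gd$a2[, i] == gd$a2[, j])) / 4
      A[i, j] <- A[j, i] <- 2 * f
    }
  }
  diag(A) <- 1 + colMeans(gd$a1 == gd$a2)
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# expected genome share of each founder-generation ancestor in a target set
gene_drop_share <- function(ped, target_ids, n_loci = 20000L) {
  gd <- gene_drop(ped, n_loci)
  ix <- match(as.character(target_ids), as.character(ped$id))
  founders <- which(is.na(drop_index(ped)$si))
  share <- numeric(nrow(ped))
  for (i in founders) {
    labs <- unique(c(gd$a1[1, i], gd$a2[1, i])) # labels of founder i
    share[i] <- mean((gd$a1[, ix, drop = FALSE] %in% labs) +
                       (gd$a2[, ix, drop = FALSE] %in% labs)) / 2
  }
  setNames(share, ped$id)
}

# a random multi-generation pedigree with discrete generations
random_pedigree <- function(n_founders, n_gen, n_per_gen, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- data.frame(id = seq_len(n_founders), sire = 0L, dam = 0L,
                    generation = 0L)
  prev <- ped$id
  nxt <- n_founders
  for (g in seq_len(n_gen)) {
    ids <- nxt + seq_len(n_per_gen)
    nxt <- nxt + n_per_gen
    par <- t(vapply(ids, function(i) sample(prev, 2L), numeric(2)))
    ped <- rbind(ped, data.frame(id = ids, sire = par[, 1],
                                 dam = par[, 2], generation = g))
    prev <- ids
  }
  ped
}

# brute-force minimum of an assignment problem by enumerating permutations
perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  out <- NULL
  for (k in seq_along(v))
    out <- rbind(out, cbind(v[k], perms(v[-k])))
  out
}

brute_force_assignment <- function(cost) {
  pp <- perms(seq_len(ncol(cost)))
  best <- Inf
  for (r in seq_len(nrow(pp))) {
    val <- sum(cost[cbind(seq_len(nrow(cost)), pp[r, ])])
    if (val < best) best <- val
  }
  best
}

# --- shared small-scale simulation fixture --------------------------------
# One founder population + panels + raw effects reused across test files
# (built once per session; sized so a full scheme run takes ~1 s).

.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (!is.null(.fixture_cache$sim)) return(.fixture_cache$sim)
  fp <- sim_founders(ne = 60, n_generations = 250,
                     map = genome_map(4, 600), seed = 9001)
  pn <- build_panels(fp, qtl_count = 200, n_ibd = 400, seed = 9002)
  set.seed(9003)
  eff <- sample_qtl_effects(length(pn$qtl_loci))
  .fixture_cache$sim <- list(fp = fp, pn = pn, eff = eff)
  .fixture_cache$sim
}
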