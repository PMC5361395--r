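#' Define an equally spaced genome map
#'
#' The genome consists of `n_chromosomes` chromosomes of equal genetic length
#' carrying `loci_per_chromosome` equally spaced biallelic loci each. Locus
#' positions (Morgans) are placed at the midpoints of equal bins,
#' `(j - 0.5) * chromosome_length / loci_per_chromosome`, so that the
#' recombination fraction between any two adjacent loci is identical.
#' The default — four 1 Morgan chromosomes with 10000 loci each — is a
#' pig-like genome reduced to a tractable size for scheme simulation.
#'
#' @param n_chromosomes number of chromosomes.
#' @param loci_per_chromosome loci per chromosome.
#' @param chromosome_length genetic length of each chromosome in Morgans.
#' @return An object of class `genome_map`: a list with the dimensions above
#'   plus per-locus vectors `chr` (chromosome index) and `pos` (Morgans).
#' @export
genome_map <- function(n_chromosomes = 4L, loci_per_chromosome = 10000L,
                       chromosome_length = 1) {
  n_chromosomes <- as.integer(n_chromosomes)
  loci_per_chromosome <- as.integer(loci_per_chromosome)
  if (n_chromosomes < 1L || loci_per_chromosome < 2L)
    stop("genome map needs at least one chromosome with two loci")
  if (chromosome_length <= 0)
    stop("chromosome length must be positive")
  pos1 <- (seq_len(loci_per_chromosome) - 0.5) *
    chromosome_length / loci_per_chromosome
  structure(list(
    n_chromosomes = n_chromosomes,
    loci_per_chromosome = loci_per_chromosome,
    chromosome_length = chromosome_length,
    total_loci = n_chromosomes * loci_per_chromosome,
    chr = rep(seq_len(n_chromosomes), each = loci_per_chromosome),
    pos = rep(pos1, times = n_chromosomes)
  ), class = "genome_map")
}

#' Simulate a founder population by neutral Fisher-Wright inheritance
#'
#' Runs a monoecious Wright-Fisher population of `ne` diploids for
#' `n_generations` discrete generations: each offspring draws two parents
#' uniformly with replacement (selfing allowed), gametes are formed by
#' meiosis with a Poisson number of crossovers per chromosome (mean equal to
#' the chromosome length in Morgans, breakpoints uniform), and every
#' transmitted allele flips state 0 <-> 1 with probability `mutation_rate`
#' (recurrent, reversible mutation). The burn-in starts from all loci fixed
#' for allele 0 unless `init` supplies a haplotype matrix; mutation-drift-
#' recombination equilibrium is reached within a long burn-in.
#'
#' @param ne effective (= census) population size; default 200.
#' @param n_generations number of burn-in generations; default 2000.
#' @param map a [genome_map()].
#' @param mutation_rate per-locus, per-meiosis allele-flip probability. The
#'   default 2.5e-4 gives `4*Ne*mu = 0.2` at `Ne = 200`, the scaled mutation
#'   rate that yields a U-shaped allele-frequency spectrum with roughly 30%
#'   of loci fixed, about 8250 marker-eligible loci on the default genome,
#'   and adjacent-locus LD in the range reported for pig breeds (see the
#'   methods vignette for the calibration argument).
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param init optional initial haplotype matrix (`total_loci` x `2*ne`).
#' @return An object of class `founder_pop`: list with `map`, `haplotypes`
#'   (integer matrix, loci in rows, `2*ne` haplotype columns; columns
#'   `2i-1`, `2i` belong to individual `i`), `ne`, `n_generations`,
#'   `mutation_rate`.
#' @examples
#' fp <- sim_founders(ne = 20, n_generations = 50,
#'                    map = genome_map(1, 100), seed = 1)
#' fixation_fraction(fp)
#' @export
sim_founders <- function(ne = 200L, n_generations = 2000L,
                         map = genome_map(), mutation_rate = 2.5e-4,
                         seed = NULL, init = NULL) {
  ne <- as.integer(ne)
  n_generations <- as.integer(n_generations)
  if (is.na(ne) || ne < 2L)
    stop("'ne' must be an integer >= 2")
  if (is.na(n_generations) || n_generations < 1L)
    stop("'n_generations' must be a positive integer")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("'mutation_rate' must lie in [0, 1)")
  stopifnot(inherits(map, "genome_map"))
  if (!is.null(seed)) set.seed(seed)
  haps <- cpp_wf_burnin(ne, n_generations, map$n_chromosomes,
                        map$loci_per_chromosome, map$chromosome_length,
                        mutation_rate, init)
  structure(list(map = map, haplotypes = haps, ne = ne,
                 n_generations = n_generations,
                 mutation_rate = mutation_rate),
            class = "founder_pop")
}

#' @export
print.founder_pop <- function(x, ...) {
  cat("Founder population: Ne =", x$ne, "after", x$n_generations,
      "Wright-Fisher generations\n")
  cat("  genome:", x$map$n_chromosomes, "x", x$map$loci_per_chromosome,
      "loci,", x$map$chromosome_length, "Morgan each\n")
  cat(sprintf("  fixed loci: %.1f%%\n", 100 * fixation_fraction(x)))
  invisible(x)
}

as_haplotypes <- function(x) {
  if (inherits(x, "founder_pop")) x$haplotypes else as.matrix(x)
}

#' Single meiosis on a genome map
#'
#' Forms one gamete from an individual's two haplotypes: per chromosome, a
#' Poisson(`chromosome_length`) number of crossovers is placed uniformly,
#' transmission starts from a fair-coin haplotype and switches at each
#' crossover; each transmitted allele then mutates (flips) with probability
#' `mutation_rate`. With zero crossovers one haplotype is transmitted
#' intact.
#'
#' @param haplotypes matrix with `total_loci` rows and 2 columns, the
#'   parent's haplotype pair.
#' @param map the [genome_map()] the haplotypes live on.
#' @param mutation_rate per-locus allele-flip probability (default 0).
#' @return integer vector: the gamete.
#' @export
meiosis <- function(haplotypes, map, mutation_rate = 0) {
  stopifnot(inherits(map, "genome_map"))
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != 2L || nrow(haplotypes) != map$total_loci)
    stop("a parent must supply two haplotypes covering the whole map")
  lpc <- map$loci_per_chromosome
  off <- (seq_len(map$n_chromosomes) - 1L) * lpc
  drop(cpp_drop_gametes(haplotypes, 1L, 2L, off,
                        rep(lpc, map$n_chromosomes), map$pos,
                        map$chromosome_length, mutation_rate))
}

#' Linkage disequilibrium between neighbouring loci
#'
#' Computes r-squared for every within-chromosome pair of adjacent map loci
#' at which both loci segregate, from haplotype frequencies:
#' `R2 = (p_AB - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B))`.
#' With `maf > 0` the pairs are further restricted to loci whose minor
#' allele frequency exceeds the threshold; `maf = 0.05` restricts the
#' summary to the marker-eligible (common) loci, the convention under which
#' LD is reported from SNP arrays and the one used for the founder-stage
#' calibration summary.
#'
#' @param x a `founder_pop` or a 0/1 haplotype matrix (loci x haplotypes).
#' @param map a [genome_map()]; taken from `x` when it is a `founder_pop`.
#' @param maf minor-allele-frequency threshold applied to both loci of a
#'   pair (default 0: all segregating pairs).
#' @return list with `mean`, `sd` (over pairs) and `n_pairs`.
#' @export
adjacent_ld <- function(x, map = NULL, maf = 0) {
  H <- as_haplotypes(x)
  if (is.null(map) && inherits(x, "founder_pop")) map <- x$map
  if (is.null(map)) stop("a genome map is required")
  p <- rowMeans(H)
  seg <- p > 0 & p < 1 & pmin(p, 1 - p) > maf
  n <- nrow(H)
  i <- seq_len(n - 1L)
  adj <- i[map$chr[i] == map$chr[i + 1L] & seg[i] & seg[i + 1L]]
  if (length(adj) == 0L)
    stop("no adjacent pair with both loci segregating")
  pab <- rowMeans(H[adj, , drop = FALSE] * H[adj + 1L, , drop = FALSE])
  pa <- p[adj]; pb <- p[adj + 1L]
  r2 <- (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
  list(mean = mean(r2), sd = stats::sd(r2), n_pairs = length(r2))
}

#' Fraction of fixed loci
#'
#' Proportion of loci with zero allele variance across all haplotypes.
#'
#' @param x a `founder_pop` or a haplotype matrix (loci x haplotypes).
#' @return a proportion in `[0, 1]`.
#' @export
fixation_fraction <- function(x) {
  H <- as_haplotypes(x)
  p <- rowMeans(H)
  mean(p == H[, 1L])  # monomorphic iff every haplotype equals the first
}

#' Select marker, QTL and IBD-tracking locus panels from a founder population
#'
#' Markers are every second locus, in map order, among segregating loci with
#' minor allele frequency above `marker_maf` (the selection is anchored at
#' element `marker_phase` of the eligible list). QTL are a random sample of
#' `qtl_count` loci with MAF above `qtl_maf` drawn from the remaining
#' segregating loci, so markers and QTL are disjoint. IBD-tracking loci are
#' `n_ibd` fresh positions placed uniformly at random across the genome,
#' interleaved between map loci; they carry no alleles until base-population
#' labelling and are never used for selection.
#'
#' @param founders a `founder_pop`.
#' @param marker_maf MAF threshold for markers (default 0.05).
#' @param qtl_count number of QTL (default 2000).
#' @param qtl_maf MAF threshold for QTL (default 0.01).
#' @param n_ibd number of IBD-tracking loci (default 2000).
#' @param marker_phase 1 or 2: which element of the eligible list anchors the
#'   every-second rule (default 2).
#' @param marker_step spacing of the marker selection along the eligible
#'   list (default 2, the every-second rule; larger steps thin the panel
#'   for scaled-down experiments).
#' @param seed optional integer seed.
#' @return An object of class `loci_panel`: list with `marker_loci` and
#'   `qtl_loci` (founder locus indices), `breed_map` (data frame `chr`,
#'   `pos`, `role`, `founder_locus` for the combined breeding-phase map, one
#'   row per marker/QTL/IBD locus in map order), and row indices
#'   `marker_rows`, `qtl_rows`, `ibd_rows` into `breed_map`.
#' @export
build_panels <- function(founders, marker_maf = 0.05, qtl_count = 2000L,
                         qtl_maf = 0.01, n_ibd = 2000L, marker_phase = 2L,
                         marker_step = 2L, seed = NULL) {
  stopifnot(inherits(founders, "founder_pop"))
  if (!is.null(seed)) set.seed(seed)
  map <- founders$map
  p <- rowMeans(founders$haplotypes)
  maf <- pmin(p, 1 - p)
  seg <- maf > 0

  eligible <- which(seg & maf > marker_maf)
  if (length(eligible) < marker_phase)
    stop("too few segregating loci above the marker MAF threshold")
  marker_loci <- eligible[seq.int(marker_phase, length(eligible),
                           by = as.integer(marker_step))]

  qtl_pool <- setdiff(which(seg & maf > qtl_maf), marker_loci)
  if (length(qtl_pool) < qtl_count)
    stop(sprintf(
      "only %d loci eligible as QTL but %d requested (short by %d)",
      length(qtl_pool), qtl_count, qtl_count - length(qtl_pool)))
  qtl_loci <- sort(sample(qtl_pool, qtl_count))

  ibd_chr <- sample.int(map$n_chromosomes, n_ibd, replace = TRUE)
  ibd_pos <- runif(n_ibd, 0, map$chromosome_length)

  bm <- rbind(
    data.frame(chr = map$chr[marker_loci], pos = map$pos[marker_loci],
               role = "marker", founder_locus = marker_loci),
    data.frame(chr = map$chr[qtl_loci], pos = map$pos[qtl_loci],
               role = "qtl", founder_locus = qtl_loci),
    data.frame(chr = ibd_chr, pos = ibd_pos, role = "ibd",
               founder_locus = NA_integer_)
  )
  bm <- bm[order(bm$chr, bm$pos), ]
  rownames(bm) <- NULL

  structure(list(
    marker_loci = marker_loci,
    qtl_loci = qtl_loci,
    breed_map = bm,
    marker_rows = which(bm$role == "marker"),
    qtl_rows = which(bm$role == "qtl"),
    ibd_rows = which(bm$role == "ibd"),
    chromosome_length = map$chromosome_length,
    n_chromosomes = map$n_chromosomes
  ), class = "loci_panel")
}

#' @export
print.loci_panel <- function(x, ...) {
  cat("Locus panels:", length(x$marker_loci), "markers,",
      length(x$qtl_loci), "QTL,", length(x$ibd_rows),
      "IBD-tracking loci\n")
  invisible(x)
}

#' Export founder genotypes in PLINK-style .ped/.map text dialect
#'
#' Alleles are coded 1/2; one row per individual in the .ped file, one row
#' per locus in the .map file (positions written in centiMorgans).
#'
#' @param founders a `founder_pop`.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return the two file paths, invisibly.
#' @export
write_pedmap <- function(founders, prefix) {
  stopifnot(inherits(founders, "founder_pop"))
  H <- founders$haplotypes
  map <- founders$map
  n <- ncol(H) / 2L
  mapfile <- paste0(prefix, ".map")
  pedfile <- paste0(prefix, ".ped")
  write.table(
    data.frame(chr = map$chr, id = sprintf("L%d", seq_len(map$total_loci)),
               cm = 100 * map$pos, bp = seq_len(map$total_loci)),
    mapfile, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  con <- file(pedfile, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    g <- rbind(H[, 2L * i - 1L], H[, 2L * i]) + 1L
    writeLines(paste(c("FAM", sprintf("F%d", i), "0", "0", "0", "-9",
                       as.character(g)), collapse = " "), con)
  }
  invisible(c(pedfile, mapfile))
}
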