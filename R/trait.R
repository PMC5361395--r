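#' Sample raw QTL substitution effects
#'
#' Effect magnitudes follow a gamma distribution with the given shape (scale
#' fixed at 1; the subsequent scaling to the target heritability absorbs any
#' scale), and each effect is assigned a positive or negative sign with
#' probability one half, independently.
#'
#' @param n_qtl number of QTL.
#' @param shape gamma shape parameter; default 1.48, the value estimated for
#'   QTL effect distributions in pigs.
#' @param seed optional integer seed.
#' @return numeric vector of signed raw effects.
#' @export
sample_qtl_effects <- function(n_qtl, shape = 1.48, seed = NULL) {
  if (n_qtl < 1L) stop("'n_qtl' must be at least 1")
  if (shape <= 0) stop("gamma shape must be positive")
  if (!is.null(seed)) set.seed(seed)
  rgamma(n_qtl, shape = shape, scale = 1) *
    sample(c(-1, 1), n_qtl, replace = TRUE)
}

#' Scale QTL effects to a target base-generation heritability
#'
#' Raw effects are multiplied by `sqrt(h2 / var(raw TBV))`, where the
#' variance is the empirical (population, n-denominator) variance of raw
#' true breeding values in the base cohort. After scaling, the base-cohort
#' genetic variance equals `h2` exactly, and with environmental variance
#' `1 - h2` base phenotypes have mean ~0 and variance ~1.
#'
#' @param raw_effects signed raw effects from [sample_qtl_effects()].
#' @param qtl_geno base-cohort QTL allele counts, individuals x QTL,
#'   values 0/1/2.
#' @param h2 target heritability (0 < h2 < 1).
#' @return An object of class `trait_arch`: list with `effects` (scaled
#'   substitution effects), `h2`, `env_variance` (= 1 - h2), `scale_factor`.
#' @export
scale_effects <- function(raw_effects, qtl_geno, h2) {
  qtl_geno <- as.matrix(qtl_geno)
  if (ncol(qtl_geno) != length(raw_effects))
    stop("genotype matrix and effect vector disagree on the number of QTL")
  if (nrow(qtl_geno) < 2L) stop("base cohort must contain several animals")
  if (h2 <= 0 || h2 >= 1) stop("'h2' must lie strictly between 0 and 1")
  raw_tbv <- drop(qtl_geno %*% raw_effects)
  v <- pop_var(raw_tbv)
  if (v <= 1e-12 * max(1, mean(raw_tbv^2)))
    stop("raw breeding values have zero variance; cannot scale")
  sf <- sqrt(h2 / v)
  structure(list(effects = raw_effects * sf, h2 = h2,
                 env_variance = 1 - h2, scale_factor = sf),
            class = "trait_arch")
}

# population (n-denominator) variance, the convention used throughout
pop_var <- function(x) mean((x - mean(x))^2)

#' True breeding values from QTL genotypes
#'
#' TBV is the sum over QTL of allele count times the scaled substitution
#' effect (alleles summed over both haplotypes; purely additive trait).
#'
#' @param qtl_geno allele counts, individuals x QTL (or a vector for one
#'   individual).
#' @param arch a `trait_arch`.
#' @return numeric vector of TBVs.
#' @export
true_breeding_value <- function(qtl_geno, arch) {
  stopifnot(inherits(arch, "trait_arch"))
  if (is.null(dim(qtl_geno))) qtl_geno <- matrix(qtl_geno, nrow = 1L)
  if (ncol(qtl_geno) != length(arch$effects))
    stop("genotypes do not cover all QTL")
  if (anyNA(qtl_geno)) stop("missing QTL genotypes")
  drop(qtl_geno %*% arch$effects)
}

#' Phenotypes from breeding values
#'
#' `y = TBV + e` with `e ~ N(0, env_variance)`. The environmental variance
#' is identical in all generations, so heritability declines as selection
#' erodes the genetic variance (Bulmer effect).
#'
#' @param tbv vector of true breeding values.
#' @param env_variance environmental variance (>= 0).
#' @return numeric vector of phenotypes.
#' @export
phenotype <- function(tbv, env_variance) {
  if (env_variance < 0) stop("environmental variance must be non-negative")
  tbv + rnorm(length(tbv), sd = sqrt(env_variance))
}

#' Mendelian-sampling terms
#'
#' The deviation of an individual's true breeding value from the mean of its
#' parents' true breeding values, `TBV_i - (TBV_sire + TBV_dam)/2`; the
#' within-family component of merit. Defined only for individuals with both
#' parents known: rows with a missing parent TBV are dropped with a warning.
#'
#' @param tbv individual TBVs.
#' @param tbv_sire,tbv_dam parental TBVs aligned with `tbv` (NA = unknown).
#' @param id optional identifiers for the returned names.
#' @return named numeric vector of Mendelian-sampling terms.
#' @export
mendelian_sampling <- function(tbv, tbv_sire, tbv_dam, id = NULL) {
  ok <- !is.na(tbv_sire) & !is.na(tbv_dam)
  if (!all(ok))
    warning(sum(!ok), " individuals with unknown parents excluded")
  m <- tbv[ok] - (tbv_sire[ok] + tbv_dam[ok]) / 2
  if (!is.null(id)) names(m) <- id[ok]
  m
}

#' Write a trait architecture as tab-separated text
#'
#' One row per QTL: locus id, chromosome, position (Morgans), scaled
#' substitution effect.
#'
#' @param arch a `trait_arch`.
#' @param panels the `loci_panel` whose QTL the architecture describes.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_architecture <- function(arch, panels, path) {
  stopifnot(inherits(arch, "trait_arch"))
  bm <- panels$breed_map[panels$qtl_rows, ]
  utils::write.table(
    data.frame(locus = bm$founder_locus, chromosome = bm$chr,
               position_morgans = bm$pos, effect = arch$effects),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
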