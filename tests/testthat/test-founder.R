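test_that("genome map is equally spaced, increasing, with the right size", {
  gm <- genome_map(3, 50, 1.5)
  expect_equal(gm$total_loci, 150L)
  expect_true(all(tapply(gm$pos, gm$chr, function(p) all(diff(p) > 0))))
  expect_equal(unique(round(diff(gm$pos[1:50]), 12)), 1.5 / 50)
  expect_error(genome_map(0, 10), "at least one chromosome")
})

test_that("meiosis transmits an identical haplotype pair unchanged", {
  gm <- genome_map(2, 40)
  h <- matrix(rep(rbinom(80, 1, 0.5), 2), ncol = 2)
  set.seed(1)
  for (i in 1:10) expect_identical(meiosis(h, gm), h[, 1])
})

test_that("meiosis segregates fairly and shows ~1 crossover per Morgan", {
  gm <- genome_map(1, 2000)
  h <- cbind(rep(0L, 2000), rep(1L, 2000)) # fully informative parent
  set.seed(42)
  gam <- replicate(10000, meiosis(h, gm))
  # per-locus transmission frequency of allele 1 ~ 0.5 (Mendelian)
  freq <- rowMeans(gam)
  expect_lt(abs(mean(freq) - 0.5), 3 * sqrt(0.25 / 10000))
  # observed haplotype switches estimate the Poisson(1) crossover count
  switches <- colSums(gam[-1, ] != gam[-2000, ])
  expect_lt(abs(mean(switches) - 1), 3 * sqrt(1 / 10000) + 0.01)
})

test_that("no variation arises without mutation; alleles are conserved", {
  gm <- genome_map(2, 30)
  fp <- sim_founders(ne = 10, n_generations = 20, map = gm,
                     mutation_rate = 0, seed = 3)
  expect_true(all(fp$haplotypes == 0L))
  # offspring alleles at every locus come from the parental alleles
  h <- cbind(sample(c(0L, 5L), 60, TRUE), sample(c(0L, 7L), 60, TRUE))
  set.seed(4)
  g <- meiosis(h, gm)
  expect_true(all(g == h[, 1] | g == h[, 2]))
})

test_that("neutral Wright-Fisher drift fixes alleles at their frequency", {
  gm <- genome_map(1, 2)
  init <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), nrow = 2) # p = 0.5
  set.seed(7)
  final_p <- replicate(200, {
    fp <- sim_founders(ne = 2, n_generations = 50, map = gm,
                       mutation_rate = 0, init = init)
    mean(fp$haplotypes[1, ])
  })
  expect_true(all(final_p %in% c(0, 1))) # fixed after 50 gens at ne = 2
  expect_lt(abs(mean(final_p) - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("per-generation drift variance is ~ p(1-p)/(2 ne)", {
  ne <- 50L
  gm <- genome_map(1, 2)
  init <- matrix(rep(rep(c(1L, 0L), each = ne), each = 2), nrow = 2)
  set.seed(8)
  dp <- replicate(400, {
    fp <- sim_founders(ne = ne, n_generations = 1, map = gm,
                       mutation_rate = 0, init = init)
    mean(fp$haplotypes[1, ]) - 0.5
  })
  v_exp <- 0.25 / (2 * ne)
  expect_lt(abs(mean(dp^2) - v_exp), 3 * v_exp * sqrt(2 / 400))
})

test_that("adjacent LD matches hand-computed haplotype frequencies", {
  gm <- genome_map(1, 2)
  # perfect coupling: haplotypes 11 and 00 only
  H <- cbind(matrix(1L, 2, 4), matrix(0L, 2, 4))
  expect_equal(adjacent_ld(H, gm)$mean, 1)
  # independence at expected products: 25 haplotypes, p = q = 0.6/...
  H2 <- rbind(rep(c(1L, 0L), c(15, 10)),
              c(rep(c(1L, 0L), c(9, 6)), rep(c(1L, 0L), c(6, 4))))
  expect_equal(adjacent_ld(H2, gm)$mean, 0)
  # 8 listed haplotypes over 3 segregating loci, oracle by frequency
  gm3 <- genome_map(1, 3)
  H3 <- matrix(c(1, 1, 0, 1, 0, 0, 0, 1, 1, 1, 1, 0,
                 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 0, 1), nrow = 3)
  r2_pair <- function(a, b) {
    pa <- mean(a); pb <- mean(b); pab <- mean(a * b)
    (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
  }
  oracle <- mean(c(r2_pair(H3[1, ], H3[2, ]), r2_pair(H3[2, ], H3[3, ])))
  expect_equal(adjacent_ld(H3, gm3)$mean, oracle)
  # error when nothing segregates
  expect_error(adjacent_ld(matrix(1L, 2, 4), gm), "segregating")
})

test_that("fixation fraction counts monomorphic loci", {
  H <- rbind(matrix(0L, 3, 6),
             matrix(rep(c(0L, 1L), each = 3), 3, 6))
  expect_equal(fixation_fraction(H), 0.5)
  expect_equal(fixation_fraction(matrix(1L, 4, 8)), 1)
})

test_that("panel construction follows the every-second rule and MAF gates", {
  gm <- genome_map(1, 12)
  # loci 1..10 segregate at MAF 0.25; loci 11-12 fixed
  H <- rbind(matrix(rep(c(1L, 0L), c(2, 6)), 10, 8, byrow = TRUE),
             matrix(0L, 2, 8))
  fp <- structure(list(map = gm, haplotypes = H, ne = 4L,
                       n_generations = 0L, mutation_rate = 0),
                  class = "founder_pop")
  pn <- build_panels(fp, qtl_count = 2, n_ibd = 5, seed = 1)
  expect_equal(pn$marker_loci, c(2L, 4L, 6L, 8L, 10L))
  expect_length(pn$qtl_loci, 2L)
  expect_length(intersect(pn$marker_loci, pn$qtl_loci), 0L)
  pn1 <- build_panels(fp, qtl_count = 2, n_ibd = 5, marker_phase = 1L,
                      seed = 1)
  expect_equal(pn1$marker_loci, c(1L, 3L, 5L, 7L, 9L))
  # infeasible QTL request names the shortfall
  expect_error(build_panels(fp, qtl_count = 8, n_ibd = 5, seed = 1),
               "short by 3")
  # breeding map is ordered and IBD loci are interleaved fresh positions
  expect_true(all(diff(pn$breed_map$pos[pn$breed_map$chr == 1]) > 0))
  expect_true(all(is.na(pn$breed_map$founder_locus[pn$ibd_rows])))
})

test_that("founder simulation is reproducible from its seed", {
  gm <- genome_map(2, 50)
  a <- sim_founders(ne = 10, n_generations = 30, map = gm, seed = 99)
  b <- sim_founders(ne = 10, n_generations = 30, map = gm, seed = 99)
  expect_identical(a$haplotypes, b$haplotypes)
})

test_that("configuration errors are caught", {
  expect_error(sim_founders(ne = 1), "ne")
  expect_error(sim_founders(ne = 10, n_generations = 0), "positive")
  expect_error(sim_founders(ne = 10, mutation_rate = 1), "mutation_rate")
})
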