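test_that("pedigree A reproduces textbook values", {
  ped <- data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3),
                    dam = c(0, 0, 2, 2, 4))
  A <- pedigree_A(ped)
  expect_equal(unname(A["3", "1"]), 0.5)  # parent-offspring
  expect_equal(unname(A["3", "4"]), 0.5)  # full sibs
  expect_equal(unname(A["3", "3"]), 1.0)
  expect_equal(unname(A["5", "5"]), 1.25) # offspring of full sibs
  expect_true(isSymmetric(A))
  expect_error(pedigree_A(data.frame(id = 1:2, sire = c(2, 0),
                                     dam = c(0, 0))),
               "ordered|cyclic")
})

test_that("pedigree A matches gene-dropping coancestry on a random pedigree", {
  ped <- random_pedigree(8, 3, 8, seed = 11)[, 1:3]
  A <- pedigree_A(ped)
  set.seed(12)
  A_hat <- gene_drop_A(ped, n_loci = 20000L)
  expect_lt(max(abs(A - A_hat)), 0.05)
})

test_that("genomic G single-marker terms are the Yang cross-products", {
  X <- rbind(a = c(1), b = c(1))
  G <- genomic_G(X, p = 0.5)
  expect_equal(unname(G["a", "b"]), 0)       # (1-1)(1-1)/0.5
  X2 <- rbind(a = c(2), b = c(0))
  G2 <- genomic_G(X2, p = 0.5)
  expect_equal(unname(G2["a", "a"]), 2)      # (2-1)^2 / 0.5
  expect_equal(unname(G2["a", "b"]), -2)
  expect_error(genomic_G(X2, p = 1), "filtered")
})

test_that("E[G] = A on genotypes dropped through a known pedigree", {
  ped <- random_pedigree(12, 2, 19, seed = 21)[, 1:3] # 50 individuals
  A <- pedigree_A(ped)
  m <- 5000L
  set.seed(22)
  p <- runif(m, 0.2, 0.8)
  gd <- gene_drop(ped, m)
  # founder haplotype labels -> alleles drawn Bernoulli(p) per label
  labs <- sort(unique(c(gd$a1[, ped$sire == 0], gd$a2[, ped$sire == 0])))
  allele <- matrix(rbinom(m * length(labs), 1, p), m, length(labs))
  Y <- allele[cbind(rep(seq_len(m), nrow(ped)), c(gd$a1))] +
    allele[cbind(rep(seq_len(m), nrow(ped)), c(gd$a2))]
  dim(Y) <- c(m, nrow(ped))
  X <- t(Y) # individuals x markers
  G <- genomic_G(X, p = p)
  expect_lt(mean(abs(G - A)), 0.05)
})

test_that("coancestry block is half the relationship, exactly", {
  ped <- random_pedigree(6, 2, 6, seed = 31)[, 1:3]
  A <- pedigree_A(ped)
  sires <- as.character(c(13, 14, 15)); dams <- as.character(c(16, 17, 18))
  f <- coancestry_block(A, sires, dams)
  expect_equal(unname(f), unname(0.5 * A[sires, dams]))
  # full sibs: f = 0.25 = their offspring's inbreeding coefficient
  ped2 <- data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 2))
  A2 <- pedigree_A(ped2)
  expect_equal(unname(coancestry_block(A2, "3", "4")[1, 1]), 0.25)
  expect_error(coancestry_block(A2, "3", "99"), "not present")
})

test_that("contribution L: recursion and LDL' of A agree exactly", {
  ped <- random_pedigree(4, 3, 4, seed = 41)[, 1:3]
  L_rec <- contribution_L(ped)
  # founder rows are unit vectors; offspring of two founders get 1/2, 1/2
  expect_equal(unname(L_rec[1, ]), c(1, rep(0, nrow(ped) - 1)))
  off <- which(ped$sire != 0)[1]
  expect_equal(unname(L_rec[off, c(ped$sire[off], ped$dam[off])]),
               c(0.5, 0.5))
  L_ldl <- contribution_L(pedigree_A(ped))
  expect_equal(L_ldl, L_rec, tolerance = 1e-10)
})

test_that("pedigree L accounts for complete ancestry", {
  ped <- random_pedigree(6, 4, 10, seed = 51)[, 1:3]
  L <- contribution_L(ped)
  founders <- as.character(ped$id[ped$sire == 0])
  expect_equal(unname(rowSums(L[, founders])), rep(1, nrow(ped)))
})

test_that("contributions to matings average the parents' L rows", {
  ped <- data.frame(id = 1:6, sire = c(0, 0, 0, 0, 1, 3),
                    dam = c(0, 0, 0, 0, 2, 4))
  L <- contribution_L(ped)
  C <- contributions_to_matings(L, sires = c(1, 5, 5), dams = c(2, 6, 4))
  expect_equal(dim(C), c(6L, 3L))
  # mating of two founders: 1/2 at each
  expect_equal(unname(C[, 1]), c(0.5, 0.5, 0, 0, 0, 0))
  # hand-averaged rows for the other columns
  expect_equal(unname(C[, 2]), unname(0.5 * (L["5", ] + L["6", ])))
  expect_equal(unname(C[, 3]), unname(0.5 * (L["5", ] + L["4", ])))
  expect_error(contributions_to_matings(L, 1, 99), "absent")
})

test_that("long-term contributions equal gene-dropping genome shares", {
  ped <- random_pedigree(6, 4, 12, seed = 61)
  L <- contribution_L(ped[, 1:3])
  target <- ped$id[ped$generation == 4]
  r <- long_term_contributions(L, target)
  founders <- ped$generation == 0
  set.seed(62)
  share <- gene_drop_share(ped, target, n_loci = 20000L)
  expect_lt(max(abs(r[founders] - share[founders])), 0.03)
  # contributions of any one generation sum to 1 over the target cohort
  for (g in 0:3) {
    anc_g <- as.character(ped$id[ped$generation == g])
    expect_equal(sum(r[anc_g]), 1, tolerance = 1e-10)
  }
  # a founder with no descendants contributes zero
  ped2 <- data.frame(id = 1:4, sire = c(0, 0, 0, 1), dam = c(0, 0, 0, 2))
  r2 <- long_term_contributions(contribution_L(ped2), 4)
  expect_equal(unname(r2["3"]), 0)
  expect_equal(unname(r2[c("1", "2")]), c(0.5, 0.5))
})

test_that("genomic G diagonal tends to 1 + mean inbreeding", {
  ped <- random_pedigree(10, 3, 16, seed = 71)[, 1:3]
  A <- pedigree_A(ped)
  m <- 8000L
  set.seed(72)
  p <- runif(m, 0.2, 0.8)
  gd <- gene_drop(ped, m)
  labs <- sort(unique(c(gd$a1[, ped$sire == 0], gd$a2[, ped$sire == 0])))
  allele <- matrix(rbinom(m * length(labs), 1, p), m, length(labs))
  Y <- allele[cbind(rep(seq_len(m), nrow(ped)), c(gd$a1))] +
    allele[cbind(rep(seq_len(m), nrow(ped)), c(gd$a2))]
  dim(Y) <- c(m, nrow(ped))
  X <- t(Y) # individuals x markers
  G <- genomic_G(X, p = p, diag_method = "yang")
  expect_lt(abs(mean(diag(G)) - mean(diag(A))), 0.05)
})
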