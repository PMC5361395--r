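Package: matesim
Title: Stochastic Simulation of Breeding Schemes with Genomic Mate Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time stochastic simulator of closed animal breeding
    schemes under genomic truncation selection. Founder genomes arise from a
    neutral Fisher-Wright burn-in with recurrent mutation and Poisson
    recombination; an additive trait with gamma-distributed QTL effects is
    scaled to a target heritability; breeding values are predicted by
    SNP-BLUP ridge regression; and selected sires and dams are paired at
    random, by minimum-coancestry mating (exact min-cost assignment), or by
    minimising the covariance between ancestral genetic contributions (MCAC),
    each driven by pedigree or genomic relationships. Identity-by-descent is
    tracked with uniquely labelled neutral loci, yielding rates of inbreeding
    and genetic gain, genetic-variance trajectories, and the dispersion of
    long-term genetic contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
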