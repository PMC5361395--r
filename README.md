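# matesim

Stochastic simulation of closed animal-breeding schemes under genomic
truncation selection, with pluggable mate-allocation strategies.

## The problem

In a closed breeding population under truncation selection on predicted
breeding values, the same information that drives selection concentrates
ancestry: relatives get co-selected, genetic contributions of a few
ancestors balloon, and inbreeding accumulates at a rate ΔF that erodes
genetic variance and future gain. *Mate allocation* — deciding which
selected sire is paired with which selected dam — is the one lever that
costs nothing and touches no selection decision. matesim exists to quantify
how much that lever is worth, and in particular whether driving it with
genomic relationships beats driving it with pedigree relationships.

Three strategies are implemented:

* **RAND** — dams assigned to sire slots uniformly at random (the
  reference point);
* **MC** (minimum-coancestry mating) — minimise the mean coancestry
  f<sub>ij</sub> = ½ relationship(i,j) of the proposed pairs, solved
  *exactly* as a min-cost assignment (f equals the prospective offspring's
  inbreeding coefficient);
* **MCAC** — minimise Σ<sub>a&lt;b</sub> |cov(C<sub>a·</sub>, C<sub>b·</sub>)|,
  the summed absolute covariance between ancestors' genetic-contribution
  profiles across the proposed matings, where
  C<sub>am</sub> = ½(L<sub>sire(m),a</sub> + L<sub>dam(m),a</sub>) and L is
  the normed lower-triangular ancestral-contribution matrix (pedigree
  recursion, or the unit-triangular LDL′ factor of the genomic relationship
  matrix G); solved by a screened local search over dam swaps.

Both MC and MCAC run from either the pedigree A matrix or the marker-based
G matrix (Yang-type single-marker cross-products), so the pedigree-versus-
genomic comparison is a switch, not a rewrite.

Around the strategies sits a complete simulator: a Wright–Fisher founder
burn-in (4 × 1 Morgan chromosomes, 40 000 loci, recurrent mutation, Poisson
recombination) that delivers realistic LD and a U-shaped frequency
spectrum; marker/QTL panels (≈8250 markers with MAF > 0.05, 2000 QTL with
gamma-distributed effects scaled so base genetic variance equals h²);
SNP-BLUP ridge-regression prediction trained on the phenotypes of the
current and previous generation; and 2000 uniquely-labelled IBD-tracking
loci, so an individual's inbreeding coefficient is simply the fraction of
IBD loci carrying two identical base-haplotype labels. Rates are estimated
as ΔF = 1 − e^β (β the OLS slope of ln(1 − F<sub>u</sub>) on generation,
generations 5–20) and ΔG (mean one-generation gain over the same window).

## A worked example

A small hierarchical scheme (20 sires × 20 dams, litters of 20, h² = 0.1),
three strategies, two replicates each:

```r
library(matesim)

founders <- sim_founders(ne = 60, n_generations = 250,
                         map = genome_map(4, 600), seed = 9001)
ex <- run_experiment(
  list(scheme_config(3, strategy = "RAND"),
       scheme_config(3, strategy = "MC",   info_source = "pedigree"),
       scheme_config(3, strategy = "MC",   info_source = "genomic")),
  n_replicates = 2, base_seed = 42, founders = founders,
  panel_args = list(qtl_count = 200, n_ibd = 400))
ex$summary[, c("label", "dF", "dG", "var_final", "F_final")]
#>         label         dF         dG   var_final   F_final
#> 1  MC_genomic 0.04837637 0.10146492 0.014384155 0.5824875
#> 2 MC_pedigree 0.06285942 0.11425282 0.010034262 0.6804219
#> 3     RAND_na 0.09543271 0.09434384 0.005157567 0.8216094
```

Reading this: random mating loses heterozygosity at ΔF ≈ 0.095 per
generation in this deliberately tiny population and retains a final-cohort
genetic variance of 0.005 (from 0.1 in the base generation); pairing the
same selected parents by minimum coancestry cuts ΔF by ~34%, and computing
that coancestry from markers instead of the pedigree cuts it by a further
~23% — without costing any rate of gain ΔG. Those are the three numbers
the simulator exists to put on the table. `run_scheme()` gives the
per-generation trajectories (`F_mean`, `tbv_mean`, `tbv_var`, `accuracy`)
and the long-term contribution diagnostics of a single replicate;
`ex$series` holds the trajectories for every replicate above.

A command-line front end (`inst/cli/matesim`) wraps the same functions:
`matesim founders`, `matesim run`, `matesim summarize`.

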