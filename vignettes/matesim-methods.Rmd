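---
title: "Simulating breeding schemes with genomic mate allocation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating breeding schemes with genomic mate allocation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

matesim is a forward-in-time stochastic simulator of closed animal-breeding
schemes under genomic truncation selection. Its purpose is to quantify how
mate-allocation strategies — random mating (RAND), minimum-coancestry mating
(MC) and mating that minimises the covariance between ancestral genetic
contributions (MCAC), each driven by either pedigree or genomic
relationships — trade off rates of inbreeding ($\Delta F$) against rates of
genetic gain ($\Delta G$). This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what the simulations
show.

## The founder stage

Founder genomes arise from a neutral Fisher–Wright burn-in: a monoecious
population of `ne` diploids (default 200) reproduces for `n_generations`
(default 2000) discrete generations; each offspring draws two parents
uniformly with replacement (selfing allowed). The genome is 4 chromosomes of
1 Morgan carrying 10 000 equally spaced biallelic loci each. Meiosis places
a Poisson($L$) number of crossovers uniformly on a chromosome of length $L$
Morgans; transmission starts from a fair-coin haplotype and switches at
every crossover. Mutation is recurrent and reversible: every transmitted
allele flips $0 \leftrightarrow 1$ with probability $\mu$ per meiosis. The
burn-in starts with all loci fixed for allele 0; stationarity under
mutation–drift–recombination makes the start state irrelevant at these
lengths.

**Calibrating the mutation rate.** The population-scaled mutation rate
$a = 4 N_e \mu$ fixes the stationary allele-frequency spectrum
(Beta($a$, $a$) under the diffusion approximation), and with it the fraction
of fixed loci and the number of common loci. At $N_e = 200$ the package
default is $\mu = 2.5\times10^{-4}$, i.e. $a = 0.2$, chosen because it
reproduces the founder-population state that the breeding stage is built on:
a U-shaped spectrum with roughly 30% of loci fixed, about 8250 loci with
minor allele frequency above 0.05 (of which every second becomes a marker),
and mean adjacent-locus $R^2 \approx 0.26$ among common loci — the level of
short-range LD reported for commercial pig breeds. A rate an order of
magnitude lower ($a = 0.02$) provably cannot produce such a state: the
stationary probability that a locus is monomorphic in $2N_e = 400$
haplotypes is approximately $400^{-a}$, which is ~89% at $a = 0.02$ versus
~30% at $a = 0.2$; the package reproduces both ends of this calculation
empirically.

**The LD summary.** `adjacent_ld()` computes
$R^2 = (p_{AB} - p_A p_B)^2 / (p_A q_A p_B q_B)$ from haplotype frequencies
for adjacent map pairs. Averaged over *all* segregating pairs the statistic
is dominated by rare variants, whose $R^2$ against common neighbours is
necessarily small (~0.10 at the default calibration). The calibration
summary therefore restricts to pairs where both loci have MAF > 0.05
(`maf = 0.05`), the set from which markers are drawn and the convention
under which array-based LD is reported; that summary is 0.26 ± 0.31.

**Panels.** Markers are every second locus (in map order) among segregating
loci with MAF > 0.05; the anchor of the every-second rule (`marker_phase`)
and the step (`marker_step`, useful for scaled-down experiments) are
configurable. QTL are 2000 random non-marker loci with MAF > 0.01. The 2000
IBD-tracking loci are fresh positions placed uniformly at random along the
genome, interleaved between map loci; they carry no alleles until base
labelling and never enter selection.

## Trait and phenotypes

QTL substitution-effect magnitudes are Gamma(shape = 1.48, scale = 1) — the
shape estimated for QTL effects in pigs — with random signs (the gamma
scale parameter is irrelevant because effects are rescaled). Effects are
multiplied by $\sqrt{h^2 / \mathrm{var}(\text{raw TBV})}$, using the
*empirical* (population, $n$-denominator) variance of raw true breeding
values in the base cohort, so base genetic variance equals $h^2$ exactly;
any theoretical Hardy–Weinberg/linkage-equilibrium scaling agrees with this
only in expectation, and the empirical form is preferred because the base
cohort is small (40–140 animals) and carries LD. Environmental variance is
$1 - h^2$, constant through the simulation, so base phenotypes have mean ~0
and variance ~1, and heritability erodes over generations as selection
removes genetic variance (the Bulmer effect).

## Genomic prediction

Breeding values are predicted by ridge regression on all marker covariates
(SNP-BLUP): $(X_c'X_c + \lambda I)\beta = X_c'(y - \bar y)$ with
column-centred allele counts and an unpenalised intercept. The training set
is every phenotyped animal of the current and previous generation
(generation 1 trains on generations 0 and 1; base animals are phenotyped —
without that there would be no first fit). The shrinkage constant is fixed
at the SNP-BLUP/GBLUP equivalence value
$\lambda = (1-h^2)\,2\sum_j p_j(1-p_j)/h^2$, recomputed each generation from
training allele frequencies; a Gaussian likelihood with one common marker
effect variance *is* SNP-BLUP, and per-generation REML would add machinery
the model does not require (a user-supplied `lambda` overrides it). When
markers outnumber records the equivalent $n \times n$ dual system is solved
instead; both routes agree to 1e-8 and the equivalence with GBLUP under a
VanRaden-scaled genomic relationship matrix is pinned by a test.

## Relationships and contributions

Pedigree relationships use the tabular method; genomic relationships the
genome-wide average of single-marker cross-products
$(x_{ik}-2p_k)(x_{jk}-2p_k)/(2p_kq_k)$. By default the diagonal uses the
same cross-product form — keeping $G$ positive semi-definite, which the
LDL$'$ decomposition below relies on — with the within-individual corrected
("Yang") diagonal behind a switch. Allele frequencies for $G$ come from the
current selection-candidate cohort, and markers monomorphic there are
dropped per cohort: base-generation frequencies drift towards 0/1 over
twenty generations and would destabilise the denominators.

The ancestral-contribution matrix $L$ (rows individuals, columns ancestors,
$L_{ii}=1$) is built by the recursion
$L_{ia} = \tfrac12(L_{s(i)a} + L_{d(i)a})$ for pedigrees, and as the
unit-triangular factor of an age-ordered LDL$'$ decomposition for genomic
input (Cholesky with diagonal jitter escalating 0, 1e-8, 1e-6, 1e-4; each
column of the raw factor divided by its diagonal). Applied to a pedigree
$A$, the decomposition reproduces the recursion exactly — the anchor that
pins this operationalisation. Contributions to matings average the parents'
rows: $C_{am} = \tfrac12(L_{s(m)a} + L_{d(m)a})$.

Only selected parents (and the base animals) are tracked as ancestors —
unselected animals cannot contribute to later generations — which caps the
matrices at $(N_s+N_d)\times$generations. For the *final* long-term
contribution diagnostics the genomic $G$ over ancestors plus the last cohort
is centred at **base-generation** frequencies: contributions are measured
relative to the base population, and centring at the target cohort's own
frequencies forces the cohort's mean contribution to zero by construction.

## Mate allocation

*MC.* The coancestry block $f = \tfrac12 A$ (or $\tfrac12 G$) between
selected sires and dams is minimised in total over the proposed pairs: each
sire's row is duplicated `mating_ratio` times and the square problem is
solved *exactly* by a shortest-augmenting-path assignment solver ($O(n^3)$,
$n \le 120$ here). The objective is linear in the assignment, so the exact
optimum is well defined and dominates any pairing heuristic; inputs are
ordered by id first, making ties deterministic.

*MCAC.* The objective is the sum over unordered ancestor pairs of the
absolute population covariance of their contribution profiles across the
proposed matings (litter sizes are equal within a scheme, so mating-level
and offspring-level covariances coincide; a weighted form is retained). The
assignment enters nonlinearly, so MCAC is solved by local search over
dam-swap exchanges from a random start, best of `restarts` starts
(default 10 for the standalone function; the scheme engine uses 2, which on
these problem sizes changes the realised objective by well under the
replicate spread). Two implementation facts matter:

* The centred cross-product matrix $R_{ab} = \sum_m C_{am}C_{bm} - n\mu_a\mu_b$
  changes by a rank-2 update per dam swap (row means of $C$ are invariant
  under dam permutations), so one candidate swap can be scored exactly in
  $O(n_{\mathrm{anc}}^2)$.
* Scoring all ~7000 candidate swaps exactly per pass is still too slow once
  thousands of ancestors are tracked. Each pass therefore *screens* all
  candidates with a surrogate: the delta linearised through
  $\mathrm{sign}(R)$ — exact for every pair whose covariance does not change
  sign — made near-exact by treating the 10 000 smallest-$|R|$ pairs (where
  sign flips live) exactly. After two BLAS products the surrogate is $O(1)$
  per candidate. The most promising candidates are re-scored exactly before
  application, so descent is strictly monotone in the true objective. While
  $n_{\mathrm{anc}} \le 600$ the final state is certified by exact
  first-improvement passes over all candidates; beyond that the search stops
  when the screen runs dry — a documented heuristic cutoff
  (`method = "best"` restores fully certified steepest descent at any
  size). On 4×4 instances the search finds the exhaustive optimum in ≥95%
  of random cases, the package's standing quality gate.

The MCAC ancestor set at generation $t$ is all tracked parents of
generations $0..t$ including the current candidates (self-contribution
one half).

## Scheme engine

Five preset schemes share 20 sires: (dams, litter, $h^2$) =
(120, 10, 0.1), (20, 60, 0.1), (20, 20, 0.1), (40, 10, 0.1), (40, 10, 0.4).
Generations are discrete. The base population samples $20+N_d$ founders,
assigns the first 20 of the draw as males, and labels each of its
$2(20+N_d)$ haplotypes with a unique allele at all 2000 IBD-tracking loci,
so base inbreeding is exactly zero and descent is directly observable;
an individual's inbreeding coefficient is simply its fraction of
label-homozygous IBD loci. Offspring inherit markers, QTL and IBD labels on
*shared* crossovers (one meiosis over the combined map), with no mutation
during the breeding phase — mutation would corrupt the IBD labels, and over
20 generations its allelic effect is negligible. Sexes alternate within a
litter starting with a male, which guarantees every scheme's sex quota is
feasible. Selection is truncation on GEBV within sex, ties broken by id.

`run_experiment()` defaults to a single founder stage shared by all
replicates and configurations (replicate $r$ runs with seed
`base_seed + r`, so the same replicate number sees the same base draw in
every configuration — paired comparisons across strategies); fully
independent founder stages per replicate are a flag away.

## Assessment criteria

$\Delta F = 1 - e^{\beta}$ with $\beta$ the OLS slope of $\ln(1-F_u)$ on
$u$ over generations 5–20 (configurable window) — exact on geometric series
by construction. $\Delta G$ is the mean one-generation gain over the same
window. Genetic variance is the population variance of TBV per cohort (the
$n$-denominator convention is used everywhere). Contributing-ancestor
counts take ancestors with contribution strictly greater than zero; the
contribution/Mendelian-sampling regression pools ancestors across
generations 0–19 (whether the original tables pooled or fitted per
generation is not determinable; pooling is the stabler choice at these
counts), uses only ancestors with positive contributions, and reports the
population SD of its residuals. Mendelian-sampling terms are defined only
for animals with both parents known, so base animals are excluded from the
regression.

## What the checks do and do not show

* **Founder calibration** (full parameters, 5 seeds) reproduces the target
  fixation level, LD level and marker count. It does not validate the
  mutation process against any sequence data — the burn-in is a device for
  generating a realistic LD/frequency state, not a demographic model.
* **Onset of inbreeding** (scheme 1, generations 0–5, 3 replicates): with
  pedigree information MC and MCAC keep the replicate-mean inbreeding at
  exactly zero through generation 2, first positive at generation 3; RAND
  becomes positive at generation 2. With *genomic* information the engine
  finds occasional generation-2 cohorts with tiny positive mean $F$
  (4e-4 to 1e-2): realized genomic coancestry correctly scores sib pairs
  that inherited complementary genomes as nearly unrelated, and mating such
  a pair yields offspring with near-zero but nonzero IBD homozygosity.
  At any plotting resolution this is indistinguishable from zero, but under
  a strict "exceeds zero" rule the genomic variants can register one
  generation earlier; the package reports the pedigree-information onset
  and records this behaviour here rather than hiding it.
* **Scaled scheme-1 experiment**: the full design (100 replicates, 8257
  markers) is cluster-scale; the packaged experiment uses 4 replicates and
  a thinned marker panel (`marker_step`), sizes chosen so the whole suite
  runs on a desktop. Thinning markers lowers prediction accuracy, which
  raises all inbreeding rates and *shrinks the contrast between mating
  strategies* (with stronger family co-selection there is less for mate
  allocation to repair — the same gradient the full-scale results show
  across schemes). Directional claims are therefore the robust content of
  the scaled runs; the absolute generation-20 variances and the full-scale
  percentage reductions are not expected to transfer exactly.

## Known limitations

No overlapping generations, no litter-size variation, no dominance or
epistasis, single trait, no sex chromosomes, no variable recombination
maps, and no optimum-contribution selection (selection is pure truncation).
Coancestry is marker-average based; haplotype-segment coancestry is out of
scope.
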