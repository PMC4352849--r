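---
title: "Statistical methods for forensic STR population studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for forensic STR population studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpop)
```

strpop implements, as one pipeline, the statistical analyses of an autosomal
STR population study in forensic genetics: per-locus forensic parameters,
exact tests of Hardy-Weinberg equilibrium (HWE) and pairwise linkage
disequilibrium (LD), Weir-Cockerham Fst with permutation p-values, Nei's DA
genetic distance, distance-based phylogenetic trees with bootstrap-over-loci
support, and PCA of population allele frequencies. This vignette describes
the statistical models, the conventions adopted where several exist in the
literature, and the checks the package's own simulator makes possible.

## Data model

Genotypes live in a long tibble — one row per individual per locus, columns
`population`, `sample`, `locus`, `allele_1`, `allele_2` — so every analysis
function is a plain data-frame-in, tibble-out verb that composes with dplyr.
Allele labels use repeat-count nomenclature with microvariant suffixes
("13", "13.2"); pairs are unordered and stored in ladder order. A missing
genotype keeps its row with both alleles `NA`: missing data are deleted
locus by locus (`n` may differ across loci), never individual by individual,
which is how partial profiles are handled in forensic practice.

Allele frequencies are maximum-likelihood gene-copy proportions,
$p_i = c_i / 2n_l$, carrying the per-locus typed count $n_l$. Frequency
tables can also be read directly from the wide CSV layout used by published
population tables (rows = alleles, columns = loci), which is how reference
populations whose raw genotypes were never deposited enter the pipeline.

For GenePop interchange, microvariant allele $R.P$ is encoded as the
three-digit integer $10R + P$ (so "13.2" is 132 and "14" is 140); GenePop
has no native microvariant notation, and the convention is written into the
title line of every file so it travels with the data.

## Forensic parameters

For a frequency vector $p$ and observed heterozygosity $h$ (fraction of
heterozygous individuals, $H = 1 - h$):

* expected heterozygosity $HE = 1 - \sum_i p_i^2$;
* polymorphism information content
  $PIC = 1 - \sum p_i^2 - (\sum p_i^2)^2 + \sum p_i^4$ (Botstein's form);
* power of discrimination $PD = 1 - \sum_j G_j^2$ over **observed** genotype
  proportions $G_j$;
* probability of exclusion $PE = h^2(1 - 2hH^2)$ (Brenner form);
* typical paternity index $TPI = 1 / (2(1-h))$.

Three conventions deserve comment, because alternatives exist:

* **HE carries no small-sample correction** by default. The unbiased
  $2n/(2n-1)$ variant is available (`corrected = TRUE`) but off: the
  uncorrected form is what the Powerstats-style worksheets used by forensic
  population reports compute, and it is the form that reproduces published
  tables digit for digit.
* **PD uses observed genotype proportions**, not HWE-expected ones, so it is
  only computable from genotypes. The API enforces this:
  `power_of_discrimination()` takes a genotype table, never a frequency
  vector.
* **PE depends on observed heterozygosity only.** Allele-frequency-based PE
  variants exist but are out of scope.

Cumulative powers multiply across loci as $1 - \prod_l (1 - v_l)$. The
complement product is accumulated in log space: across a 21-locus panel the
cumulative PD is $1 - 6\times10^{-20}$, indistinguishable from 1 in double
precision, so `combined_power()` reports the complement and its $\log_{10}$
alongside.

Reported tables round half-up to 4 decimals (`round_half_up()`), matching
forensic reporting conventions; internal computation is always at full
precision. Frequency-vector inputs are validated to sum to 1 within 0.005,
a tolerance chosen so that published columns rounded to 4 decimals pass.

## Hardy-Weinberg exact test

The test conditions on the observed allele counts (Guo & Thompson): the
p-value is the total conditional probability of genotype tables no more
probable than the observed one (the "probability" statistic, not the
U-score — the choice matters only for directional alternatives). Two
engines share that definition:

* **Complete enumeration** walks every genotype table consistent with the
  allele counts. It is used automatically when the table space is at most
  `enum_limit` (20,000 tables by default) — in practice 2-allele loci at any
  study size and 3-allele loci up to a few hundred individuals. The p-value
  is then exact and `se = 0`.
* **A Markov chain** otherwise: one step picks two individuals and swaps one
  randomly chosen allele between them. Because the conditional distribution
  of tables is the one induced by uniform random pairing of the $2n$ gene
  copies — an exchangeable distribution — this swap is measure-preserving
  and the chain accepts every proposal. Defaults are 10,000 dememorization
  steps and 100 batches of 5,000 iterations (the defaults popularised by
  the Genepop program); the standard error is estimated from batch means.
  Chains run in C++ on R's own RNG stream, so results are bit-reproducible
  under `set.seed()`/`seed =`.

Probability ties are compared with a relative tolerance of $10^{-9}$ so that
symmetric tables with equal probability land on the same side of the
threshold on every platform. A monomorphic locus has a single attainable
table and returns $p = 1$ exactly.

## Linkage disequilibrium and the locus-exclusion rule

Gametic phase is unknown in population STR data, so LD is tested on the
*genotypic* contingency table: rows are one locus's genotypes, columns the
other's, one count per individual. The statistic is the log-likelihood
ratio $G$; the null distribution comes from permuting one locus's genotype
column across individuals (which fixes both margins, so only
$\sum O \log O$ needs recomputing per replicate). The p-value is the raw
proportion of permuted statistics at or above the observed one — no $+1$
correction, so 0.0000 and 1.0000 are attainable, as published tables print
them — with a binomial Monte-Carlo standard error.

Bonferroni correction over $m$ tests declares significance iff
$p < \alpha/m$ strictly; for a 21-locus panel that is $0.05/210 = 0.00024$
over locus pairs and $0.05/21 = 0.00238$ over loci. The locus-exclusion
rule used before frequency-based distance and tree analyses removes every
locus appearing in at least one significant pair. Note the rule inherits
the family-wise 5% error of its correction: across 210 pairs, one run in
twenty will exclude an innocent pair, which is why the package's validation
of the rule uses replicate simulated studies rather than a single dataset.

## Population differentiation

Fst between two populations is estimated by Weir & Cockerham's $\theta$:
per allele, the variance decomposition into among-population ($a$),
between-individual-within-population ($b$) and within-individual ($c$)
components, with $\theta = \sum a / \sum(a+b+c)$ summed over alleles — and,
for the overall value, summed over loci. Summing components is not the same
as averaging per-locus estimates; the component sum is the standard
multi-locus estimator and is what a locus-by-locus AMOVA reports. Negative
estimates are reported as-is (they are the estimator's way of saying "no
detectable differentiation"), never clipped, since published pairwise
tables print values like −0.0018. A locus monomorphic across both
populations contributes nothing and is flagged rather than failing.

Permutation p-values reassign whole individuals (all loci together) to the
two populations, preserving within-individual structure; $p$ is again a raw
proportion, with 10,000 permutations by default.

Under the simulator's Balding-Nichols model (below) the estimator is
recoverable: with a true divergence of 0.05, 200 individuals per population
and 10 loci, the mean overall $\theta$ across 200 replicate studies sits
within 0.01 of 0.05 (this is one of the suite's acceptance checks).

## Distances, trees, bootstrap

Nei's DA distance between frequency tables $x$ and $y$ over $L$ loci is

$$D_A = 1 - \frac{1}{L}\sum_l \sum_i \sqrt{x_{il}\, y_{il}},$$

summing over the union of alleles (an allele absent from one population
contributes 0 — never an error; a *locus* absent from one table is an
error, because silently dropping loci changes the average). DA is bounded
in $[0,1]$, zero iff the tables agree, and is computed on the locus subset
surviving LD exclusion when reproducing a published workflow.

Two agglomerative tree builders operate on any symmetric distance matrix:

* **UPGMA**: size-weighted average linkage; merge heights are halved into
  branch lengths, so trees are ultrametric by construction and reproduce an
  ultrametric input's cophenetic matrix exactly.
* **Neighbor-joining**: the Saitou-Nei Q-criterion, which recovers additive
  matrices exactly. A negative branch-length estimate is clipped to zero
  with the deficit moved to its sister branch, preserving the path length
  through the node (the convention tree-drawing practice expects).

Both break ties deterministically — among equal-minimum entries, the
lexicographically smallest pair of cluster labels wins (a cluster is
labelled by its smallest member) — so the same matrix gives the same tree
on every platform. Trees are `ape::phylo` objects; `to_newick()` writes
Newick with 15 significant digits and quotes labels containing
metacharacters, and support values ride as internal node labels.

Bootstrap-over-loci resamples loci with replacement, rebuilds the DA matrix
and tree per replicate, and scores each internal edge of the full-data tree
by the fraction of replicates containing the same bipartition of the
populations (bipartitions are canonicalised by the side not containing the
alphabetically first population). With a single locus every resample is
identical and the procedure is flagged as degenerate.

## PCA of allele frequencies

The feature matrix is populations × (locus, allele) over the union of
observed alleles, absent alleles scoring 0. Columns are mean-centred but
**not** variance-scaled — the classical convention for allele-frequency
PCA, where scaling would inflate the influence of rare alleles; a scaled
variant sits behind `scale = TRUE`. Scores and explained-variance fractions
come from the SVD (via `prcomp`), truncated to
$\min(\text{populations}-1, \text{features})$ components; in the full-rank
case the fractions sum to 1, and they are validated in the test suite
against an independent eigendecomposition of the feature covariance.

## The synthetic study generator

No raw genotypes accompany most published STR population tables, so the
package carries a generator whose defaults emulate a typical multi-
population study: 11 populations × 21 loci × 100 individuals, 4–25 alleles
per locus drawn from a 7–24 repeat ladder with a 5% microvariant rate,
symmetric-Dirichlet(1) ancestral frequencies, and per-population divergence
0.02 (within the 0–0.09 range such studies report). Each piece is chosen to
make a pipeline stage's ground truth recoverable:

* **Balding-Nichols divergence** — descendant frequencies drawn from
  $\mathrm{Dirichlet}(p\,(1-F_{st})/F_{st})$ — has $F_{st}$ as an explicit
  parameter with expectation $p$, giving the Fst estimator a known target.
* **Genotype sampling** with inbreeding $f$ gives
  $P(ii) = p_i^2 + f p_i(1-p_i)$ and $P(ij) = 2p_ip_j(1-f)$: $f=0$ is exact
  HWE (the null for calibration of the exact test), $f>0$ a controlled
  alternative.
* **LD injection** replaces chosen disjoint locus pairs with biallelic
  haplotype sampling at gametic disequilibrium $D$; the biallelic
  restriction keeps the feasible range of $D$ exact. Multi-allelic LD can
  be produced by pooling haplotypes, but is not part of the default
  generator.

The generator is deterministic given its config seed. What it does *not*
emulate: stepwise mutation dynamics, genuine linkage maps, null alleles,
allelic dropout, or population admixture. Passing the simulation-based
checks therefore demonstrates correctness of the estimators under their own
model assumptions, not robustness to those artefacts of real data.

## Validation scale and limitations

The suite's heavier calibrations are sized to run in minutes on one CPU:
1,000 null replicates for the uniformity of HWE p-values
(Kolmogorov-Smirnov at 1%), 200 replicate two-population studies for Fst
recovery, 20,000 permutations per locus pair for the LD exclusion check,
and tree-recovery properties at up to 10 taxa. These sizes are the
package's own trade-off between statistical resolution and runtime.

Known limitations: no mixture or kinship statistics beyond TPI, no
theta-corrected match probabilities, no haplotype-frequency EM (LD is
genotypic only), Fst for two populations at a time (no multi-level AMOVA),
and no likelihood or Bayesian phylogenetics — the trees are distance-based
summaries, as in the studies this package serves.
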