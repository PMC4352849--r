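# Shared fixtures and independent oracles used across the suite.

# tiny genotype tibble from a compact spec: list(sample = c(a1, a2, ...))
geno_from_pairs <- function(pairs, locus = "L1", population = "pop1") {
  genotype_table(
    data.frame(
      sample = names(pairs), locus = locus,
      allele_1 = vapply(pairs, `[`, "", 1),
      allele_2 = vapply(pairs, `[`, "", 2)
    ),
    population = population
  )
}

# genotype tibble realising given gene-copy counts per allele (pairing is
# arbitrary: frequencies do not depend on it)
geno_from_counts <- function(counts, locus = "L1", population = "pop1") {
  copies <- rep(names(counts), counts)
  n <- length(copies) / 2
  genotype_table(
    data.frame(
      sample = sprintf("s%03d", seq_len(n)), locus = locus,
      allele_1 = copies[seq_len(n)],
      allele_2 = copies[n + seq_len(n)]
    ),
    population = population
  )
}

# Levene's closed-form exact HWE distribution for a 2-allele locus:
# P(h heterozygotes | allele counts c1, c2), h running over the parity-
# feasible range. Independent of the package's table enumeration.
levene_two_allele <- function(c1, c2) {
  n <- (c1 + c2) / 2
  hs <- seq(c1 %% 2, min(c1, c2), by = 2)
  lp <- lfactorial(n) + lfactorial(c1) + lfactorial(c2) - lfactorial(2 * n) +
    hs * log(2) - lfactorial((c1 - hs) / 2) - lfactorial((c2 - hs) / 2) -
    lfactorial(hs)
  list(h = hs, prob = exp(lp))
}

levene_p_value <- function(c1, c2, h_obs) {
  d <- levene_two_allele(c1, c2)
  p_obs <- d$prob[d$h == h_obs]
  sum(d$prob[d$prob <= p_obs + 1e-12])
}

# random ultrametric distance matrix via average-linkage clustering of
# random points (its cophenetic matrix is ultrametric by construction)
random_ultrametric <- function(n, seed) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * 4), n)
    rownames(x) <- paste0("t", seq_len(n))
    as.matrix(stats::cophenetic(stats::hclust(stats::dist(x), "average")))
  })
}

# multi-population frequency tibble diverged from one ancestral set
diverged_freq_table <- function(pop_fst, n_loci = 20, k = 6, seed = 1) {
  withr::with_seed(seed, {
    anc <- dplyr::bind_rows(lapply(seq_len(n_loci), function(i) {
      dplyr::mutate(sample_ancestral_frequencies(k),
        locus = sprintf("L%02d", i), .before = 1
      )
    }))
    dplyr::bind_rows(lapply(names(pop_fst), function(p) {
      out <- dplyr::bind_rows(lapply(split(anc, anc$locus), function(x) {
        x$freq <- diverge_balding_nichols(x$freq, pop_fst[[p]])
        x
      }))
      dplyr::mutate(out, population = p, n = 100, .before = 1)
    }))
  })
}
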