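#' Configuration of the multi-population STR study simulator
#'
#' Parameterizes [make_study_fixture()], which emulates the design of a
#' forensic multi-population STR study: one set of ancestral allele
#' frequencies per locus, per-population Balding-Nichols divergence with a
#' known Fst, Hardy-Weinberg (or inbred) genotype sampling, and optional
#' injected two-locus disequilibrium. The defaults mirror a typical study of
#' this kind: 11 populations, 21 loci, 100 individuals per population,
#' Fst 0.02, alleles drawn from a 7-24 repeat ladder with occasional
#' microvariants.
#'
#' @param n_populations number of populations.
#' @param n_individuals individuals per population (single value or vector
#'   of length `n_populations`).
#' @param n_loci number of loci.
#' @param alleles_per_locus inclusive range `c(min, max)` of allele counts
#'   per locus.
#' @param dirichlet_concentration symmetric-Dirichlet concentration of the
#'   ancestral frequencies.
#' @param fst Balding-Nichols divergence per population, each in `[0, 1)`
#'   (recycled; 0 = identical to the ancestral pool).
#' @param inbreeding_f per-population inbreeding coefficient in `[0, 1]`
#'   (recycled).
#' @param ld_pairs optional data frame `locus_a`, `locus_b`, `d` of disjoint
#'   locus pairs to regenerate as linked biallelic pairs with gametic
#'   disequilibrium coefficient `d`.
#' @param microvariant_rate fraction of allele labels given a partial-repeat
#'   suffix.
#' @param seed integer seed: identical configs give identical datasets.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 11, n_individuals = 100, n_loci = 21,
                       alleles_per_locus = c(4, 25),
                       dirichlet_concentration = 1, fst = 0.02,
                       inbreeding_f = 0, ld_pairs = NULL,
                       microvariant_rate = 0.05, seed = 1) {
  stopifnot(
    n_populations >= 1, all(n_individuals >= 1), n_loci >= 1,
    length(alleles_per_locus) == 2, alleles_per_locus[1] >= 1,
    alleles_per_locus[2] >= alleles_per_locus[1],
    dirichlet_concentration > 0,
    all(fst >= 0 & fst < 1), all(inbreeding_f >= 0 & inbreeding_f <= 1),
    microvariant_rate >= 0, microvariant_rate <= 1
  )
  if (!is.null(ld_pairs)) {
    stopifnot(all(c("locus_a", "locus_b", "d") %in% names(ld_pairs)))
    involved <- c(ld_pairs$locus_a, ld_pairs$locus_b)
    if (anyDuplicated(involved)) abort("ld_pairs must involve disjoint loci")
  }
  structure(
    list(
      n_populations = as.integer(n_populations),
      n_individuals = rep_len(as.integer(n_individuals), n_populations),
      n_loci = as.integer(n_loci),
      alleles_per_locus = as.integer(alleles_per_locus),
      dirichlet_concentration = dirichlet_concentration,
      fst = rep_len(fst, n_populations),
      inbreeding_f = rep_len(inbreeding_f, n_populations),
      ld_pairs = ld_pairs,
      microvariant_rate = microvariant_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Ancestral allele frequencies for one locus
#'
#' Draws `k` allele labels from a realistic STR ladder (consecutive repeat
#' counts within 7-24, with a `microvariant_rate` chance of a partial-repeat
#' variant; extra microvariant labels are added when `k` exceeds the ladder)
#' and a symmetric Dirichlet frequency vector over them.
#'
#' @param k number of alleles.
#' @param concentration symmetric-Dirichlet concentration.
#' @param microvariant_rate chance an allele label carries a ".1"-".3"
#'   suffix.
#' @param seed integer seed (`NULL`: session RNG).
#' @return a tibble `allele`, `freq` in ladder order, frequencies summing
#'   to 1.
#' @export
sample_ancestral_frequencies <- function(k, concentration = 1,
                                         microvariant_rate = 0.05,
                                         seed = NULL) {
  if (k < 1) abort("k must be at least 1")
  with_seed_or_rng(seed, {
    ladder_len <- min(k, 18L)
    starts <- 7:(24 - ladder_len + 1)
    start <- starts[sample.int(length(starts), 1)] # robust to length-1 ranges
    reps <- seq(start, length.out = ladder_len)
    partial <- ifelse(runif(ladder_len) < microvariant_rate,
      sample(1:3, ladder_len, replace = TRUE), 0L
    )
    labels <- format_allele(reps, partial)
    extra <- k - ladder_len
    if (extra > 0) {
      # ladder exhausted: remaining alleles are microvariants of ladder rungs
      pool <- setdiff(
        as.vector(outer(reps, 1:3, format_allele)), labels
      )
      labels <- c(labels, sample(pool, extra))
    }
    labels <- allele_sort(unique(labels))
    stopifnot(length(labels) == k)
    g <- rgamma(k, shape = concentration)
    tibble::tibble(allele = labels, freq = g / sum(g))
  })
}

#' Balding-Nichols divergence of allele frequencies
#'
#' Draws descendant frequencies from `Dirichlet(p * (1 - fst) / fst)` around
#' the ancestral vector `p`; the expectation is `p` and the dispersion is
#' governed by `fst` (0 returns `p` unchanged; near 1 the descendant
#' population is nearly fixed for one allele).
#'
#' @param freqs ancestral frequency tibble (`allele`, `freq`) or numeric
#'   vector.
#' @param fst divergence parameter in `[0, 1)`.
#' @param seed integer seed (`NULL`: session RNG).
#' @return same shape as `freqs`, with descendant frequencies.
#' @export
diverge_balding_nichols <- function(freqs, fst, seed = NULL) {
  if (fst < 0 || fst >= 1) abort("fst must be in [0, 1)")
  p <- if (is.data.frame(freqs)) freqs$freq else freqs
  if (fst == 0) return(freqs)
  new_p <- with_seed_or_rng(seed, {
    g <- rgamma(length(p), shape = p * (1 - fst) / fst)
    if (sum(g) == 0) { # numerically degenerate: fix on a random allele
      g[sample.int(length(p), 1)] <- 1
    }
    g / sum(g)
  })
  if (is.data.frame(freqs)) {
    freqs$freq <- new_p
    freqs
  } else {
    new_p
  }
}

#' Sample diploid genotypes at one locus
#'
#' Draws `n` diploid genotypes from allele frequencies with inbreeding
#' coefficient `f`: with probability `f` the two gene copies are identical
#' by descent (one draw, homozygous), otherwise independent draws, giving
#' `P(ii) = p_i^2 + f p_i (1 - p_i)` and `P(ij) = 2 p_i p_j (1 - f)`.
#' `f = 0` is exact Hardy-Weinberg sampling.
#'
#' @param freqs frequency tibble (`allele`, `freq`) or named numeric vector.
#' @param n individuals.
#' @param inbreeding_f inbreeding coefficient in `[0, 1]`.
#' @param locus,population,samples identifiers for the returned tibble.
#' @param seed integer seed (`NULL`: session RNG).
#' @return a genotype tibble column (one locus).
#' @export
sample_genotypes <- function(freqs, n, inbreeding_f = 0, locus = "L1",
                             population = "pop1", samples = NULL,
                             seed = NULL) {
  if (n < 1) abort("n must be at least 1")
  if (inbreeding_f < 0 || inbreeding_f > 1) abort("inbreeding_f must be in [0, 1]")
  if (is.data.frame(freqs)) {
    labels <- freqs$allele
    p <- freqs$freq
  } else {
    labels <- names(freqs)
    p <- unname(freqs)
    if (is.null(labels)) labels <- as.character(seq_along(p))
  }
  if (is.null(samples)) samples <- sprintf("%s_%04d", population, seq_len(n))
  with_seed_or_rng(seed, {
    a1 <- sample(labels, n, replace = TRUE, prob = p)
    a2 <- sample(labels, n, replace = TRUE, prob = p)
    ibd <- runif(n) < inbreeding_f
    a2[ibd] <- a1[ibd]
    genotype_table(
      data.frame(sample = samples, locus = locus, allele_1 = a1, allele_2 = a2),
      population = population
    )
  })
}

#' Sample a pair of loci in gametic disequilibrium
#'
#' Biallelic two-locus sampling: haplotype frequencies are
#' `p(AB) = p_a p_b + D`, `p(Ab) = p_a (1 - p_b) - D`,
#' `p(aB) = (1 - p_a) p_b - D`, `p(ab) = (1 - p_a)(1 - p_b) + D`, and each
#' individual is two independent haplotypes. `d = 0` gives independent
#' loci; an infeasible `d` (negative haplotype frequency) is an error
#' reporting the feasible range.
#'
#' @param p_a,p_b frequency of the first allele at each locus.
#' @param d gametic disequilibrium coefficient.
#' @param n individuals.
#' @param loci length-2 locus names.
#' @param alleles_a,alleles_b length-2 allele labels per locus.
#' @param population,samples identifiers.
#' @param seed integer seed (`NULL`: session RNG).
#' @return a genotype tibble with the two locus columns.
#' @export
sample_linked_pair <- function(p_a, p_b, d, n, loci = c("L1", "L2"),
                               alleles_a = c("10", "11"),
                               alleles_b = c("10", "11"),
                               population = "pop1", samples = NULL,
                               seed = NULL) {
  lo <- max(-p_a * p_b, -(1 - p_a) * (1 - p_b))
  hi <- min(p_a * (1 - p_b), (1 - p_a) * p_b)
  if (d < lo || d > hi) {
    abort(sprintf(
      "d = %g is infeasible for p_a = %g, p_b = %g: feasible range [%g, %g]",
      d, p_a, p_b, lo, hi
    ))
  }
  hap <- c(
    p_a * p_b + d, p_a * (1 - p_b) - d,
    (1 - p_a) * p_b - d, (1 - p_a) * (1 - p_b) + d
  )
  if (is.null(samples)) samples <- sprintf("%s_%04d", population, seq_len(n))
  with_seed_or_rng(seed, {
    h1 <- sample(4, n, replace = TRUE, prob = hap)
    h2 <- sample(4, n, replace = TRUE, prob = hap)
    al_a <- function(h) alleles_a[ifelse(h <= 2, 1, 2)]
    al_b <- function(h) alleles_b[ifelse(h %% 2 == 1, 1, 2)]
    genotype_table(
      data.frame(
        sample = rep(samples, 2),
        locus = rep(loci, each = n),
        allele_1 = c(al_a(h1), al_b(h1)),
        allele_2 = c(al_a(h2), al_b(h2))
      ),
      population = population
    )
  })
}

#' Generate a full synthetic multi-population study
#'
#' Draws one ancestral frequency set, diverges it per population under the
#' Balding-Nichols model, samples genotypes (with optional inbreeding), and
#' regenerates any requested locus pairs as linked biallelic pairs. Returns
#' the data together with the generating ground truth so every pipeline
#' stage can be checked against known parameters.
#'
#' @param config a [sim_config()].
#' @return a list: `genotypes` (one genotype tibble, all populations),
#'   `truth` (list: `ancestral` frequency tibble, `population_freqs`,
#'   `fst`, `inbreeding_f`, `ld_pairs`), and `config`.
#' @export
make_study_fixture <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    loci <- sprintf("L%02d", seq_len(config$n_loci))
    pops <- sprintf("pop%02d", seq_len(config$n_populations))
    k_range <- seq(config$alleles_per_locus[1], config$alleles_per_locus[2])
    k_per_locus <- k_range[sample.int(length(k_range), config$n_loci, replace = TRUE)]
    ancestral <- purrr::map2_dfr(loci, k_per_locus, function(l, k) {
      dplyr::mutate(
        sample_ancestral_frequencies(
          k, config$dirichlet_concentration, config$microvariant_rate
        ),
        locus = l, .before = 1
      )
    })
    pop_freqs <- purrr::imap_dfr(pops, function(p, pi) {
      purrr::map_dfr(loci, function(l) {
        anc <- ancestral[ancestral$locus == l, c("allele", "freq")]
        div <- diverge_balding_nichols(anc, config$fst[pi])
        dplyr::mutate(div, population = p, locus = l, .before = 1)
      })
    })
    geno <- purrr::imap_dfr(pops, function(p, pi) {
      n <- config$n_individuals[pi]
      samples <- sprintf("%s_%04d", p, seq_len(n))
      purrr::map_dfr(loci, function(l) {
        fr <- pop_freqs[pop_freqs$population == p & pop_freqs$locus == l,
          c("allele", "freq")]
        fr <- fr[fr$freq > 0, ]
        sample_genotypes(fr, n,
          inbreeding_f = config$inbreeding_f[pi],
          locus = l, population = p, samples = samples
        )
      })
    })
    if (!is.null(config$ld_pairs)) {
      for (row in seq_len(nrow(config$ld_pairs))) {
        la <- config$ld_pairs$locus_a[row]
        lb <- config$ld_pairs$locus_b[row]
        dd <- config$ld_pairs$d[row]
        for (pi in seq_along(pops)) {
          p <- pops[pi]
          n <- config$n_individuals[pi]
          samples <- sprintf("%s_%04d", p, seq_len(n))
          linked <- sample_linked_pair(
            0.5, 0.5, dd, n,
            loci = c(la, lb), population = p, samples = samples
          )
          geno <- geno[!(geno$population == p & geno$locus %in% c(la, lb)), ]
          geno <- dplyr::bind_rows(geno, linked)
        }
      }
      geno <- dplyr::arrange(
        geno, .data$population, match(.data$locus, loci), .data$sample
      )
    }
    list(
      genotypes = geno,
      truth = list(
        ancestral = ancestral,
        population_freqs = pop_freqs,
        fst = setNames(config$fst, pops),
        inbreeding_f = setNames(config$inbreeding_f, pops),
        ld_pairs = config$ld_pairs
      ),
      config = config
    )
  })
}
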