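#' Genotypic linkage-disequilibrium exact test
#'
#' Tests non-random association between the genotypes of two loci without
#' assuming known gametic phase: the statistic is the log-likelihood ratio
#' (G) of the individuals' two-locus genotype contingency table, and the
#' null distribution is obtained by permuting one locus's genotypes across
#' individuals. The p-value is the raw proportion of permuted G at or above
#' the observed G (so 0 and 1 are attainable), with a binomial Monte-Carlo
#' standard error. A locus that is monomorphic in the data carries no
#' information and returns `p = 1`; a pair whose genotype columns are
#' identical is flagged as degenerate (perfect association).
#'
#' `ld_pairwise()` runs the test on every pair of loci, `choose(L, 2)` tests
#' for L loci.
#'
#' @param geno a single-population genotype tibble.
#' @param locus_a,locus_b the locus pair to test.
#' @param n_perm permutation replicates.
#' @param seed integer seed (`NULL`: session RNG).
#' @return a tibble with one row per pair: `locus_a`, `locus_b`, `g_stat`,
#'   `p_value`, `se`, `n_perm`, `degenerate`.
#' @export
ld_exact_test <- function(geno, locus_a, locus_b, n_perm = 10000, seed = NULL) {
  with_seed_or_rng(seed, ld_test_pair(geno, locus_a, locus_b, n_perm))
}

#' @rdname ld_exact_test
#' @param loci optional subset of loci (default: all loci in `geno`).
#' @export
ld_pairwise <- function(geno, loci = NULL, n_perm = 10000, seed = NULL) {
  if (is.null(loci)) loci <- unique(geno$locus)
  if (length(loci) < 2) abort("need at least two loci")
  pairs <- t(combn(sort(loci), 2))
  with_seed_or_rng(seed, {
    purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      ld_test_pair(geno, pairs[i, 1], pairs[i, 2], n_perm)
    })
  })
}

ld_test_pair <- function(geno, locus_a, locus_b, n_perm) {
  ga <- geno[geno$locus == locus_a & !is.na(geno$allele_1), ]
  gb <- geno[geno$locus == locus_b & !is.na(geno$allele_1), ]
  if (nrow(ga) == 0 || nrow(gb) == 0) {
    abort(paste0("no typed individuals at ", locus_a, " or ", locus_b))
  }
  common <- intersect(ga$sample, gb$sample)
  if (length(common) < 2) {
    abort("need at least 2 individuals typed at both loci")
  }
  ga <- ga[match(common, ga$sample), ]
  gb <- gb[match(common, gb$sample), ]
  code_a <- paste(ga$allele_1, ga$allele_2)
  code_b <- paste(gb$allele_1, gb$allele_2)
  base <- tibble::tibble(
    locus_a = locus_a, locus_b = locus_b,
    g_stat = NA_real_, p_value = 1, se = 0,
    n_perm = 0L, degenerate = FALSE
  )
  ka <- length(unique(code_a))
  kb <- length(unique(code_b))
  if (length(unique(c(ga$allele_1, ga$allele_2))) == 1 ||
      length(unique(c(gb$allele_1, gb$allele_2))) == 1) {
    return(base) # a monomorphic locus: no information, p = 1
  }
  degenerate <- identical(code_a, code_b)
  if (degenerate) {
    warn(paste0(
      "loci ", locus_a, " and ", locus_b,
      " have identical genotype columns (perfect association)"
    ))
  }
  r <- cpp_ld_perm(
    match(code_a, unique(code_a)), match(code_b, unique(code_b)),
    ka, kb, as.integer(n_perm)
  )
  tibble::tibble(
    locus_a = locus_a, locus_b = locus_b, g_stat = r$g,
    p_value = r$p, se = r$se, n_perm = as.integer(n_perm),
    degenerate = degenerate
  )
}

#' Bonferroni correction
#'
#' Family-wise error control at level `alpha` over `m` tests: a test is
#' significant iff its p-value is strictly below `alpha / m`.
#'
#' @param p_values numeric vector of p-values (names, if present, label the
#'   tests in the report).
#' @param alpha family-wise significance level.
#' @return an object of class `bonferroni_report`: a list with `m`, `alpha`,
#'   `threshold` (`alpha/m`) and `significant`, a tibble of the significant
#'   tests (`test`, `p_value`). `tidy()` returns all tests with a
#'   `significant` flag.
#' @export
#' @examples
#' bonferroni(c(a = 0.0001, b = 0.3), alpha = 0.05)
bonferroni <- function(p_values, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  m <- length(p_values)
  if (m < 1) abort("need at least one p-value")
  labs <- if (is.null(names(p_values))) as.character(seq_len(m)) else names(p_values)
  thr <- alpha / m
  sig <- p_values < thr
  structure(
    list(
      m = m, alpha = alpha, threshold = thr,
      significant = tibble::tibble(
        test = labs[sig],
        p_value = unname(p_values[sig])
      ),
      tests = tibble::tibble(
        test = labs, p_value = unname(p_values),
        significant = unname(sig)
      )
    ),
    class = "bonferroni_report"
  )
}

#' @export
print.bonferroni_report <- function(x, ...) {
  cat(sprintf(
    "Bonferroni correction: m = %d tests, alpha = %g, threshold = %g\n",
    x$m, x$alpha, x$threshold
  ))
  cat(sprintf("%d significant test(s)\n", nrow(x$significant)))
  if (nrow(x$significant) > 0) print(x$significant)
  invisible(x)
}

#' @exportS3Method
tidy.bonferroni_report <- function(x, ...) {
  x$tests
}

#' @exportS3Method
glance.bonferroni_report <- function(x, ...) {
  tibble::tibble(
    m = x$m, alpha = x$alpha, threshold = x$threshold,
    n_significant = nrow(x$significant)
  )
}

#' Locus exclusion by pairwise linkage disequilibrium
#'
#' The pre-filter applied before frequency-based distance and tree analyses:
#' every locus appearing in at least one Bonferroni-significant pairwise LD
#' test is removed, and the retained loci are returned sorted by name.
#'
#' @param ld_tbl pairwise LD results from [ld_pairwise()] (must cover all
#'   `choose(L, 2)` pairs of the panel).
#' @param alpha family-wise level for the Bonferroni correction over all
#'   pairs.
#' @return character vector of retained locus names, sorted.
#' @export
ld_locus_exclusion <- function(ld_tbl, alpha = 0.05) {
  loci <- sort(unique(c(ld_tbl$locus_a, ld_tbl$locus_b)))
  expected <- choose(length(loci), 2)
  if (nrow(ld_tbl) != expected) {
    abort(paste0(
      "pairwise table has ", nrow(ld_tbl), " pairs but ", expected,
      " are required for ", length(loci), " loci"
    ))
  }
  rep <- bonferroni(
    setNames(ld_tbl$p_value, paste(ld_tbl$locus_a, ld_tbl$locus_b, sep = ":")),
    alpha = alpha
  )
  sig <- ld_tbl[ld_tbl$p_value < rep$threshold, ]
  sort(setdiff(loci, unique(c(sig$locus_a, sig$locus_b))))
}
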