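#' Chain parameters for the Hardy-Weinberg Markov chain test
#'
#' Defaults follow the Genepop convention: 10,000 dememorization steps, then
#' 100 batches of 5,000 iterations; the p-value is the mean batch proportion
#' and the Monte-Carlo standard error is the batch-means standard error.
#'
#' @param dememorization burn-in steps.
#' @param batches number of batches.
#' @param iterations steps per batch.
#' @return a list of validated chain parameters.
#' @export
hwe_chain <- function(dememorization = 10000, batches = 100, iterations = 5000) {
  if (dememorization < 0 || batches < 1 || iterations < 1) {
    abort("invalid chain parameters: need dememorization >= 0, batches >= 1, iterations >= 1")
  }
  list(
    dememorization = as.integer(dememorization),
    batches = as.integer(batches),
    iterations = as.integer(iterations)
  )
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' The conditional exact test of Guo & Thompson: given the observed allele
#' counts, the p-value is the total conditional probability of all genotype
#' tables whose probability does not exceed that of the observed table (the
#' "probability" test). Small table spaces are summed by complete
#' enumeration (exact, `se = 0`); larger ones are sampled with a
#' switch-update Markov chain whose stationary distribution is the
#' conditional table distribution, reporting a batch-means standard error.
#' A monomorphic locus has a single attainable table, so `p = 1`.
#'
#' @param geno a genotype tibble; the test runs per population and locus.
#' @param loci optional subset of loci.
#' @param method `"auto"` chooses enumeration when the table space is at
#'   most `enum_limit` tables, otherwise the Markov chain.
#' @param chain chain parameters from [hwe_chain()].
#' @param enum_limit table-space bound for automatic enumeration.
#' @param seed integer seed for the Markov chain (`NULL`: session RNG).
#' @return a tibble with one row per population and locus: `population`,
#'   `locus`, `n`, `k` (alleles), `method`, `statistic` (always
#'   `"probability"`), `p_value`, `se`, `n_steps` (tables summed or chain
#'   steps), `seed`.
#' @references Guo SW, Thompson EA (1992) Performing the exact test of
#'   Hardy-Weinberg proportion for multiple alleles. Biometrics 48:361-372.
#' @export
hwe_exact_test <- function(geno, loci = NULL,
                           method = c("auto", "enumeration", "mcmc"),
                           chain = hwe_chain(), enum_limit = 2e5,
                           seed = NULL) {
  method <- match.arg(method)
  typed <- dplyr::filter(geno, !is.na(.data$allele_1))
  if (!is.null(loci)) typed <- dplyr::filter(typed, .data$locus %in% loci)
  groups <- dplyr::group_split(typed, .data$population, .data$locus)
  with_seed_or_rng(seed, {
    res <- purrr::map_dfr(groups, function(g) {
      r <- hwe_test_one(g$allele_1, g$allele_2, method, chain, enum_limit)
      tibble::tibble(
        population = g$population[1], locus = g$locus[1],
        n = nrow(g), k = r$k, method = r$method,
        statistic = "probability", p_value = r$p, se = r$se,
        n_steps = r$n_steps,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
      )
    })
  })
}

hwe_test_one <- function(a1, a2, method, chain, enum_limit) {
  n <- length(a1)
  if (n < 2 && method != "auto") abort("need at least 2 typed individuals")
  alleles <- allele_sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k == 1) {
    return(list(p = 1, se = 0, method = "degenerate", n_steps = 1, k = 1L))
  }
  i1 <- match(a1, alleles)
  i2 <- match(a2, alleles)
  counts <- tabulate(c(i1, i2), nbins = k)
  if (method == "auto") {
    # counting is itself recursive, so only attempt it where the table space
    # can plausibly be small (dof = k(k+1)/2 - k grows fast with k)
    worth_counting <- k == 2 || (k == 3 && n <= 200) || (k == 4 && n <= 25)
    n_tab <- if (worth_counting) count_hwe_tables(counts, limit = enum_limit) else NA
    method <- if (!is.na(n_tab)) "enumeration" else "mcmc"
  }
  if (method == "enumeration") {
    enum <- hwe_enumerate(counts)
    l_obs <- hwe_table_logrel(tabulate_pairs(i1, i2, k))
    tol <- 1e-9 * (1 + abs(l_obs))
    p <- sum(exp(enum$logp[enum$logrel <= l_obs + tol]))
    list(p = min(p, 1), se = 0, method = "enumeration",
      n_steps = length(enum$logp), k = k)
  } else {
    gm <- cbind(i1, i2) - 1L
    r <- cpp_hwe_chain(gm, k, chain$dememorization, chain$batches,
      chain$iterations)
    list(p = r$p, se = r$se, method = "mcmc", n_steps = r$n_steps, k = k)
  }
}

# Genotype count matrix (upper triangle used) from allele index vectors.
tabulate_pairs <- function(i1, i2, k) {
  f <- matrix(0L, k, k)
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  for (t in seq_along(lo)) f[lo[t], hi[t]] <- f[lo[t], hi[t]] + 1L
  f
}

# Relative log-probability of a genotype table: h*log(2) - sum(lgamma(f+1)).
hwe_table_logrel <- function(f) {
  up <- f[upper.tri(f, diag = TRUE)]
  h <- sum(f[upper.tri(f)])
  h * log(2) - sum(lgamma(up + 1))
}

# Enumerate all genotype count tables consistent with the allele counts.
# Returns, per table, the relative log term and the full conditional log
# probability (which sums to 1 over tables). Recursion peels off allele 1:
# choose its homozygote count and its pairings with each later allele, then
# recurse on the reduced counts.
hwe_enumerate <- function(counts) {
  n <- sum(counts) / 2
  const <- lgamma(n + 1) + sum(lgamma(counts + 1)) - lgamma(2 * n + 1)
  buf <- numeric(1024)
  cnt_out <- 0L
  push <- function(x) {
    if (cnt_out == length(buf)) buf[2 * length(buf)] <<- NA_real_ # grow
    cnt_out <<- cnt_out + 1L
    buf[cnt_out] <<- x
  }
  rec <- function(cnt, acc_logfact, acc_het) {
    k <- length(cnt)
    if (k == 0) {
      push(acc_het * log(2) - acc_logfact)
      return(invisible())
    }
    if (k == 1) {
      if (cnt[1] %% 2 == 0) {
        f11 <- cnt[1] / 2
        push(acc_het * log(2) - acc_logfact - lgamma(f11 + 1))
      }
      return(invisible())
    }
    c1 <- cnt[1]
    rest <- cnt[-1]
    # partition c1 copies of allele 1 into 2*f11 + sum(f1j)
    for (f11 in 0:(c1 %/% 2)) {
      het_total <- c1 - 2 * f11
      # compositions of het_total over the k-1 later alleles, bounded by rest
      comps <- bounded_compositions(het_total, pmin(rest, het_total))
      for (ci in seq_len(nrow(comps))) {
        f1j <- comps[ci, ]
        rec(
          rest - f1j,
          acc_logfact + lgamma(f11 + 1) + sum(lgamma(f1j + 1)),
          acc_het + het_total
        )
      }
    }
    invisible()
  }
  rec(counts, 0, 0)
  logrel <- buf[seq_len(cnt_out)]
  list(logrel = logrel, logp = const + logrel)
}

# All nonnegative integer vectors summing to `total` with elementwise upper
# bounds; returned as a matrix with one composition per row.
bounded_compositions <- function(total, bounds) {
  m <- length(bounds)
  if (m == 1) {
    if (total <= bounds[1]) return(matrix(total, 1, 1))
    return(matrix(0L, 0, 1))
  }
  out <- list()
  for (v in 0:min(total, bounds[1])) {
    sub <- bounded_compositions(total - v, bounds[-1])
    if (nrow(sub) > 0) out[[length(out) + 1]] <- cbind(v, sub)
  }
  if (length(out) == 0) return(matrix(0L, 0, m))
  unname(do.call(rbind, out))
}

# Count tables without materialising them; NA if the count exceeds `limit`.
count_hwe_tables <- function(counts, limit) {
  total <- 0
  rec <- function(cnt) {
    if (total > limit) return(invisible())
    k <- length(cnt)
    if (k == 0) {
      total <<- total + 1
      return(invisible())
    }
    if (k == 1) {
      if (cnt[1] %% 2 == 0) total <<- total + 1
      return(invisible())
    }
    c1 <- cnt[1]
    rest <- cnt[-1]
    for (f11 in 0:(c1 %/% 2)) {
      het_total <- c1 - 2 * f11
      comps <- bounded_compositions(het_total, pmin(rest, het_total))
      for (ci in seq_len(nrow(comps))) {
        rec(rest - comps[ci, ])
        if (total > limit) return(invisible())
      }
    }
    invisible()
  }
  rec(counts)
  if (total > limit) NA else total
}
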