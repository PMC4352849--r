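#' Pairwise population differentiation (Weir-Cockerham theta)
#'
#' Estimates Fst between two populations from genotype data with the
#' Weir-Cockerham (1984) theta: a two-level variance decomposition
#' (among-population a, between-individual-within-population b, within-
#' individual c) summed over alleles, with alleles treated as unordered
#' states. Per-locus theta is `sum(a) / sum(a + b + c)` over that locus's
#' alleles; the overall theta sums components over loci (not a mean of
#' per-locus estimates). Negative estimates are reported as-is. A locus
#' monomorphic across both populations has no variance to apportion; its
#' theta is reported as 0 and flagged.
#'
#' Permutation p-values shuffle whole individuals between the two
#' populations and report the raw proportion of permuted theta at or above
#' the observed (0 and 1 attainable).
#'
#' @param geno_a,geno_b genotype tibbles for the two populations
#'   (alternatively a single tibble holding exactly two populations in
#'   `geno_a`).
#' @param loci optional locus subset.
#' @param n_perm permutation replicates (0 skips permutation p-values).
#' @param seed integer seed (`NULL`: session RNG).
#' @return an object of class `str_fst`: list with `populations`,
#'   `per_locus` (tibble `locus`, `theta`, `p_value`, `monomorphic`),
#'   `overall`, `overall_p`, `n_perm`, `seed`. `tidy()` returns the
#'   per-locus tibble; `glance()` a one-row overall summary.
#' @references Weir BS, Cockerham CC (1984) Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
pairwise_fst <- function(geno_a, geno_b = NULL, loci = NULL, n_perm = 10000,
                         seed = NULL) {
  if (is.null(geno_b)) {
    pops <- split_populations(geno_a)
    if (length(pops) != 2) {
      abort("`geno_a` must contain exactly two populations when `geno_b` is NULL")
    }
    geno_b <- pops[[2]]
    geno_a <- pops[[1]]
  }
  pa <- unique(geno_a$population)[1]
  pb <- unique(geno_b$population)[1]
  if (identical(pa, pb)) pb <- paste0(pb, ".2")
  if (is.null(loci)) loci <- intersect(unique(geno_a$locus), unique(geno_b$locus))
  if (length(loci) == 0) abort("no shared loci between the populations")

  obs <- fst_components(geno_a, geno_b, loci)
  informative <- !obs$monomorphic
  if (!any(informative)) abort("no informative locus: all loci are monomorphic")
  theta_l <- ifelse(obs$monomorphic, 0, obs$a / (obs$a + obs$b + obs$c))
  overall <- sum(obs$a[informative]) /
    sum(obs$a[informative] + obs$b[informative] + obs$c[informative])

  p_l <- rep(NA_real_, length(loci))
  p_overall <- NA_real_
  if (n_perm > 0) {
    if (n_perm < 100) abort("use at least 100 permutations")
    perm <- with_seed_or_rng(seed, {
      fst_permute(geno_a, geno_b, loci, n_perm)
    })
    ge_l <- rep(0L, length(loci))
    ge_ov <- 0L
    for (r in seq_len(n_perm)) {
      tl <- perm$theta[, r]
      ge_l <- ge_l + as.integer(!is.na(tl) & tl >= theta_l - 1e-12)
      if (perm$overall[r] >= overall - 1e-12) ge_ov <- ge_ov + 1L
    }
    p_l <- ge_l / n_perm
    p_l[obs$monomorphic] <- 1
    p_overall <- ge_ov / n_perm
  }
  structure(
    list(
      populations = c(pa, pb),
      per_locus = tibble::tibble(
        locus = loci, theta = theta_l, p_value = p_l,
        monomorphic = obs$monomorphic
      ),
      overall = overall, overall_p = p_overall,
      n_perm = as.integer(n_perm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "str_fst"
  )
}

#' @rdname pairwise_fst
#' @export
overall_fst <- function(geno_a, geno_b = NULL, loci = NULL) {
  pairwise_fst(geno_a, geno_b, loci = loci, n_perm = 0)$overall
}

#' @rdname pairwise_fst
#' @param locus a single locus name.
#' @export
fst_permutation_p <- function(geno_a, geno_b = NULL, locus, n_perm = 10000,
                              seed = NULL) {
  fit <- pairwise_fst(geno_a, geno_b, loci = locus, n_perm = n_perm, seed = seed)
  fit$per_locus$p_value[1]
}

#' @export
print.str_fst <- function(x, ...) {
  cat(sprintf(
    "Weir-Cockerham Fst: %s vs %s\noverall theta = %.4f",
    x$populations[1], x$populations[2], x$overall
  ))
  if (!is.na(x$overall_p)) {
    cat(sprintf(" (p = %.4f, %d permutations)", x$overall_p, x$n_perm))
  }
  cat("\n")
  print(x$per_locus)
  invisible(x)
}

#' @exportS3Method
tidy.str_fst <- function(x, ...) {
  dplyr::mutate(x$per_locus,
    population_a = x$populations[1],
    population_b = x$populations[2], .before = 1
  )
}

#' @exportS3Method
glance.str_fst <- function(x, ...) {
  tibble::tibble(
    population_a = x$populations[1], population_b = x$populations[2],
    overall_theta = x$overall, overall_p = x$overall_p,
    n_loci = nrow(x$per_locus), n_perm = x$n_perm
  )
}

# Weir-Cockerham variance components per locus for two populations.
# Returns a/b/c summed over alleles, plus a monomorphic flag.
fst_components <- function(geno_a, geno_b, loci) {
  a_v <- b_v <- c_v <- numeric(length(loci))
  mono <- logical(length(loci))
  for (i in seq_along(loci)) {
    la <- geno_a[geno_a$locus == loci[i] & !is.na(geno_a$allele_1), ]
    lb <- geno_b[geno_b$locus == loci[i] & !is.na(geno_b$allele_1), ]
    comp <- wc_components(
      cbind(la$allele_1, la$allele_2),
      cbind(lb$allele_1, lb$allele_2)
    )
    a_v[i] <- comp$a
    b_v[i] <- comp$b
    c_v[i] <- comp$c
    mono[i] <- comp$monomorphic
  }
  list(a = a_v, b = b_v, c = c_v, monomorphic = mono)
}

# Core WC (1984) components from two populations' allele matrices (n_i x 2,
# character labels). r = 2 populations.
wc_components <- function(ma, mb) {
  n1 <- nrow(ma)
  n2 <- nrow(mb)
  if (n1 == 0 || n2 == 0) return(list(a = 0, b = 0, c = 0, monomorphic = TRUE))
  alleles <- unique(c(ma, mb))
  if (length(alleles) < 2) {
    return(list(a = 0, b = 0, c = 0, monomorphic = TRUE))
  }
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    p1 <- mean(ma == al)
    p2 <- mean(mb == al)
    h1 <- mean(xor(ma[, 1] == al, ma[, 2] == al))
    h2 <- mean(xor(mb[, 1] == al, mb[, 2] == al))
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a
    b_tot <- b_tot + b
    c_tot <- c_tot + cc
  }
  list(a = a_tot, b = b_tot, c = c_tot, monomorphic = FALSE)
}

# Permute whole individuals between the two populations; per replicate
# return per-locus theta (NA where monomorphic in the permuted split) and
# the overall theta.
fst_permute <- function(geno_a, geno_b, loci, n_perm) {
  # pre-extract per-locus allele matrices keyed by individual
  ind_a <- unique(geno_a$sample)
  ind_b <- unique(geno_b$sample)
  all_ind <- c(paste0("A:", ind_a), paste0("B:", ind_b))
  n1 <- length(ind_a)
  ntot <- length(all_ind)
  mats <- lapply(loci, function(l) {
    la <- geno_a[geno_a$locus == l, ]
    lb <- geno_b[geno_b$locus == l, ]
    m <- rbind(
      cbind(la$allele_1, la$allele_2)[match(ind_a, la$sample), , drop = FALSE],
      cbind(lb$allele_1, lb$allele_2)[match(ind_b, lb$sample), , drop = FALSE]
    )
    m
  })
  theta <- matrix(NA_real_, length(loci), n_perm)
  overall <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    idx <- sample.int(ntot)
    ia <- idx[seq_len(n1)]
    ib <- idx[-seq_len(n1)]
    a_s <- b_s <- c_s <- 0
    for (li in seq_along(loci)) {
      m <- mats[[li]]
      ma <- m[ia, , drop = FALSE]
      mb <- m[ib, , drop = FALSE]
      ma <- ma[!is.na(ma[, 1]), , drop = FALSE]
      mb <- mb[!is.na(mb[, 1]), , drop = FALSE]
      comp <- wc_components(ma, mb)
      if (!comp$monomorphic) {
        tot <- comp$a + comp$b + comp$c
        theta[li, r] <- if (tot != 0) comp$a / tot else NA_real_
        a_s <- a_s + comp$a
        b_s <- b_s + comp$b
        c_s <- c_s + comp$c
      }
    }
    overall[r] <- if ((a_s + b_s + c_s) != 0) a_s / (a_s + b_s + c_s) else NA_real_
  }
  list(theta = theta, overall = overall)
}
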