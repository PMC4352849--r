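#' Nei's DA genetic distance
#'
#' The allele-sharing distance of Nei, Tajima & Tateno (1983):
#' `DA = 1 - (1/L) * sum_l sum_i sqrt(x_il * y_il)`, averaging over the L
#' requested loci and summing over the union of alleles at each locus (an
#' allele absent from one population contributes `sqrt(x * 0) = 0`). DA lies
#' in `[0, 1]`, is 0 iff the two frequency tables are identical over the
#' locus set, and 1 iff the populations share no allele at any locus.
#'
#' @param freqs a frequency tibble holding both populations (see
#'   [allele_frequencies()] / [read_frequency_csv()]).
#' @param pop_a,pop_b population ids in `freqs`.
#' @param loci loci to average over (default: all loci shared by the two
#'   populations' tables; a requested locus absent from either table is an
#'   error).
#' @return a single distance in `[0, 1]`.
#' @export
#' @examples
#' f <- tibble::tibble(
#'   population = c("x", "x", "y", "y"), locus = "L1",
#'   allele = c("10", "11", "10", "11"), n = 50,
#'   freq = c(0.5, 0.5, 0.25, 0.75)
#' )
#' nei_da(f, "x", "y")
nei_da <- function(freqs, pop_a, pop_b, loci = NULL) {
  fa <- freqs[freqs$population == pop_a, ]
  fb <- freqs[freqs$population == pop_b, ]
  if (nrow(fa) == 0 || nrow(fb) == 0) {
    abort("population not found in the frequency table")
  }
  if (is.null(loci)) loci <- intersect(unique(fa$locus), unique(fb$locus))
  for (l in loci) {
    if (!l %in% fa$locus || !l %in% fb$locus) {
      abort(paste0("locus ", sQuote(l), " is missing from one population's table"))
    }
  }
  shared <- vapply(loci, function(l) {
    xa <- fa[fa$locus == l, ]
    xb <- fb[fb$locus == l, ]
    alleles <- union(xa$allele, xb$allele)
    x <- setNames(rep(0, length(alleles)), alleles)
    y <- x
    x[xa$allele] <- xa$freq
    y[xb$allele] <- xb$freq
    sum(sqrt(x * y))
  }, numeric(1))
  1 - mean(shared)
}

#' Population distance matrix
#'
#' Symmetric matrix of [nei_da()] distances over all population pairs in a
#' frequency table.
#'
#' @param freqs a multi-population frequency tibble.
#' @param loci locus subset to use (typically the loci retained by
#'   [ld_locus_exclusion()] when reproducing a published workflow).
#' @return a symmetric numeric matrix with population dimnames, zero
#'   diagonal, and the loci used stored in `attr(, "loci_used")`.
#' @export
da_matrix <- function(freqs, loci = NULL) {
  pops <- unique(freqs$population)
  if (length(pops) < 2) abort("need at least 2 populations")
  if (is.null(loci)) {
    loci <- Reduce(intersect, lapply(pops, function(p) {
      unique(freqs$locus[freqs$population == p])
    }))
  }
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1]) {
    for (j in seq_len(i - 1)) {
      d[i, j] <- d[j, i] <- nei_da(freqs, pops[i], pops[j], loci = loci)
    }
  }
  attr(d, "loci_used") <- loci
  d
}
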