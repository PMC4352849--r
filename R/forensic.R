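#' Per-locus forensic parameters from frequency vectors
#'
#' The scalar statistics of a forensic STR population table, in the
#' conventions of the Powerstats worksheet family:
#'
#' * expected heterozygosity `HE = 1 - sum(p_i^2)` (no small-sample
#'   correction by default; `corrected = TRUE` applies the `2n/(2n-1)`
#'   unbiased factor),
#' * polymorphism information content (Botstein)
#'   `PIC = 1 - sum(p^2) - (sum(p^2))^2 + sum(p^4)`,
#' * probability of exclusion (Brenner form, from observed heterozygosity h,
#'   H = 1 - h) `PE = h^2 (1 - 2 h H^2)`,
#' * typical paternity index `TPI = 1 / (2 (1 - h))`.
#'
#' @param p numeric vector of allele frequencies at one locus (sums to 1).
#' @param corrected apply the `2n/(2n-1)` unbiased correction to HE.
#' @param n typed individuals (needed only when `corrected = TRUE`).
#' @return a single numeric value (`probability_of_exclusion()` and
#'   `typical_paternity_index()` are vectorised over `ho`).
#' @seealso [locus_summary_table()] for the assembled per-locus table.
#' @export
#' @examples
#' expected_heterozygosity(c(0.5, 0.5))
#' pic(c(0.5, 0.5))
expected_heterozygosity <- function(p, corrected = FALSE, n = NULL) {
  check_simplex(p)
  he <- 1 - sum(p^2)
  if (corrected) {
    if (is.null(n)) abort("`n` is required when corrected = TRUE")
    he <- he * 2 * n / (2 * n - 1)
  }
  he
}

#' @rdname expected_heterozygosity
#' @export
pic <- function(p) {
  check_simplex(p)
  s2 <- sum(p^2)
  1 - s2 - s2^2 + sum(p^4)
}

#' @rdname expected_heterozygosity
#' @param ho observed heterozygosity (fraction of heterozygous individuals).
#' @export
probability_of_exclusion <- function(ho) {
  stopifnot(all(ho >= 0 & ho <= 1))
  h <- ho
  H <- 1 - ho
  h^2 * (1 - 2 * h * H^2)
}

#' @rdname expected_heterozygosity
#' @param inf_sentinel value returned (with a warning) when `ho == 1`, where
#'   the paternity index is infinite.
#' @export
typical_paternity_index <- function(ho, inf_sentinel = Inf) {
  stopifnot(all(ho >= 0 & ho <= 1))
  out <- ifelse(ho < 1, 1 / (2 * (1 - ho)), inf_sentinel)
  if (any(ho == 1)) {
    warn("observed heterozygosity of 1 gives an infinite paternity index")
  }
  out
}

check_simplex <- function(p) {
  # tolerance accommodates published tables rounded to 4 decimals
  if (length(p) < 1 || any(p < 0) || abs(sum(p) - 1) > 5e-3) {
    abort("`p` must be a vector of allele frequencies summing to 1")
  }
  invisible(p)
}

#' Genotype-based per-locus statistics
#'
#' `observed_heterozygosity()` is the fraction of typed individuals carrying
#' two distinct alleles. `power_of_discrimination()` is
#' `PD = 1 - sum(G_j^2)` over *observed* genotype proportions `G_j` (the
#' Powerstats convention), so it requires genotypes, not just an allele
#' frequency table.
#'
#' @param geno a genotype tibble (see [genotype_table()]).
#' @return a tibble with one row per population and locus: `population`,
#'   `locus`, `n` and the statistic (`ho` or `pd`).
#' @export
observed_heterozygosity <- function(geno) {
  per_locus_genotype_stat(geno, function(a1, a2) mean(a1 != a2), "ho")
}

#' @rdname observed_heterozygosity
#' @export
power_of_discrimination <- function(geno) {
  per_locus_genotype_stat(geno, function(a1, a2) {
    gj <- table(paste(a1, a2)) / length(a1)
    1 - sum(gj^2)
  }, "pd")
}

per_locus_genotype_stat <- function(geno, f, name) {
  typed <- dplyr::filter(geno, !is.na(.data$allele_1))
  empty <- dplyr::anti_join(
    dplyr::distinct(geno, .data$population, .data$locus),
    dplyr::distinct(typed, .data$population, .data$locus),
    by = c("population", "locus")
  )
  if (nrow(empty) > 0) {
    abort(paste0("no typed individuals at locus ", sQuote(empty$locus[1])))
  }
  typed |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      n = dplyr::n(),
      "{name}" := f(.data$allele_1, .data$allele_2),
      .groups = "drop"
    )
}

#' Cumulative power over loci
#'
#' Combines independent per-locus powers (PD or PE) multiplicatively:
#' `combined = 1 - prod(1 - v_l)`. The complement product is accumulated in
#' log space, so the combined power is reported meaningfully even when it
#' rounds to 1 in double precision (cumulative PD across a full forensic
#' panel routinely does).
#'
#' @param values per-locus powers, each in `[0, 1]`.
#' @return a one-row tibble: `combined` (`1 - prod(1 - v)`), `complement`
#'   (`prod(1 - v)`) and `log10_complement`.
#' @export
#' @examples
#' combined_power(c(0.9, 0.99))
combined_power <- function(values) {
  stopifnot(all(values >= 0 & values <= 1))
  lg <- sum(log1p(-values))
  tibble::tibble(
    combined = -expm1(lg),
    complement = exp(lg),
    log10_complement = lg / log(10)
  )
}

#' Assemble the per-locus forensic summary table
#'
#' One row per locus with the full parameter set of a forensic STR population
#' report: typed count, observed/expected heterozygosity, PIC, PD, PE, TPI
#' and the Hardy-Weinberg exact-test p-value. Values are kept at full
#' precision; round at the reporting layer (e.g. `round_half_up(x, 4)`).
#'
#' @param geno a single-population genotype tibble.
#' @param hwe compute the HWE exact test per locus (can be slow for many
#'   loci; disable with `FALSE`, giving `NA` p-values).
#' @param hwe_method,chain,seed passed to [hwe_exact_test()].
#' @return a tibble with columns `population`, `locus`, `n`, `ho`, `he`,
#'   `pic`, `pd`, `pe`, `tpi`, `hwe_p`.
#' @export
locus_summary_table <- function(geno, hwe = TRUE, hwe_method = "auto",
                                chain = hwe_chain(), seed = NULL) {
  freqs <- allele_frequencies(geno)
  by_freq <- freqs |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      he = expected_heterozygosity(.data$freq),
      pic = pic(.data$freq),
      .groups = "drop"
    )
  out <- observed_heterozygosity(geno) |>
    dplyr::left_join(power_of_discrimination(geno),
      by = c("population", "locus", "n")
    ) |>
    dplyr::left_join(by_freq, by = c("population", "locus")) |>
    dplyr::mutate(
      pe = probability_of_exclusion(.data$ho),
      tpi = ifelse(.data$ho < 1, 1 / (2 * (1 - .data$ho)), Inf)
    )
  if (hwe) {
    hp <- hwe_exact_test(geno, method = hwe_method, chain = chain, seed = seed)
    out <- dplyr::left_join(out,
      dplyr::select(hp, "population", "locus", hwe_p = "p_value"),
      by = c("population", "locus")
    )
  } else {
    out$hwe_p <- NA_real_
  }
  dplyr::select(
    out, "population", "locus", "n", "ho", "he", "pic", "pd",
    "pe", "tpi", "hwe_p"
  )
}

#' Plot a locus summary table
#'
#' Dot plot of observed vs expected heterozygosity (and optionally the other
#' bounded statistics) per locus, a quick visual check of a population table.
#'
#' @param summary_tbl output of [locus_summary_table()].
#' @param stats which columns to show.
#' @return a ggplot object.
#' @export
plot_locus_summary <- function(summary_tbl, stats = c("ho", "he", "pic", "pd", "pe")) {
  long <- summary_tbl |>
    dplyr::select("locus", dplyr::all_of(stats)) |>
    tidyr::pivot_longer(-"locus", names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$locus, y = .data$value,
    colour = .data$statistic, group = .data$statistic
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "value", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
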