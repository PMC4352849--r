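#' Genotype tables
#'
#' The package stores diploid STR genotypes as a long tibble with one row per
#' individual per locus and columns `population`, `sample`, `locus`,
#' `allele_1`, `allele_2`. Allele pairs are unordered and kept in canonical
#' ladder order (`allele_1` never ranks above `allele_2`); a missing genotype
#' keeps its row with both alleles `NA`, so per-locus typed counts can differ
#' across loci (per-locus deletion of missing data, standard forensic
#' practice).
#'
#' `genotype_table()` builds/validates such a tibble from its columns;
#' `read_genotype_csv()` reads the wide CSV dialect (a `Sample` column then
#' one column per locus with `"a/b"` or `"a,b"` cells; blank = missing).
#'
#' @param data a data frame with columns `sample`, `locus`, `allele_1`,
#'   `allele_2`, and optionally `population`.
#' @param population population identifier used when `data` has no
#'   `population` column (and for `read_genotype_csv()`).
#' @return a tibble with columns `population`, `sample`, `locus`,
#'   `allele_1`, `allele_2`.
#' @export
#' @examples
#' genotype_table(
#'   data.frame(
#'     sample = c("s1", "s1"), locus = c("D2S441", "D2S441x"),
#'     allele_1 = c("14", "10"), allele_2 = c("13.2", "11")
#'   ),
#'   population = "demo"
#' )
genotype_table <- function(data, population = "pop1") {
  need <- c("sample", "locus", "allele_1", "allele_2")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("genotype data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"population" %in% names(data)) data$population <- population
  pair <- canonical_pair(as.character(data$allele_1), as.character(data$allele_2))
  out <- tibble::tibble(
    population = as.character(data$population),
    sample = as.character(data$sample),
    locus = as.character(data$locus),
    allele_1 = unname(pair[, 1]),
    allele_2 = unname(pair[, 2])
  )
  half <- xor(is.na(out$allele_1), is.na(out$allele_2))
  if (any(half)) {
    abort("genotypes must have both alleles present or both missing")
  }
  dup <- duplicated(out[, c("population", "sample", "locus")])
  if (any(dup)) {
    abort(paste0(
      "duplicate genotype record(s) for sample(s): ",
      paste(unique(out$sample[dup]), collapse = ", ")
    ))
  }
  out
}

#' @rdname genotype_table
#' @param path file to read.
#' @param sep allele separator regex inside a genotype cell.
#' @export
read_genotype_csv <- function(path, population = NULL, sep = "[/,]") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  wide <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!"Sample" %in% names(wide)) {
    abort("genotype CSV must have a leading 'Sample' column")
  }
  if (anyDuplicated(wide$Sample)) {
    abort(paste0(
      "duplicate sample id(s): ",
      paste(unique(wide$Sample[duplicated(wide$Sample)]), collapse = ", ")
    ))
  }
  loci <- setdiff(names(wide), "Sample")
  if (length(loci) == 0) abort("genotype CSV has no locus columns")
  long <- tidyr::pivot_longer(wide, -"Sample",
    names_to = "locus", values_to = "cell"
  )
  cell <- stringr::str_trim(dplyr::coalesce(long$cell, ""))
  parts <- stringr::str_split_fixed(cell, sep, 2)
  bad <- cell != "" & (parts[, 1] == "" | parts[, 2] == "")
  a1 <- ifelse(cell == "", NA_character_, stringr::str_trim(parts[, 1]))
  a2 <- ifelse(cell == "", NA_character_, stringr::str_trim(parts[, 2]))
  ok1 <- is.na(a1) | grepl("^[0-9]+(\\.[1-3])?$", a1)
  ok2 <- is.na(a2) | grepl("^[0-9]+(\\.[1-3])?$", a2)
  bad <- bad | !ok1 | !ok2
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0(
      "malformed genotype cell ", sQuote(long$cell[i]),
      " for sample ", sQuote(long$Sample[i]),
      " at locus ", sQuote(long$locus[i])
    ))
  }
  genotype_table(
    data.frame(
      sample = long$Sample, locus = long$locus,
      allele_1 = a1, allele_2 = a2
    ),
    population = if (is.null(population)) {
      tools::file_path_sans_ext(basename(path))
    } else {
      population
    }
  )
}

#' Allele frequencies from genotypes
#'
#' Tallies gene copies per locus and population: `p_i = c_i / (2 n_l)` where
#' `c_i` counts copies of allele i among the `n_l` individuals typed at locus
#' l. Only observed alleles appear (no zero-frequency rows); missing
#' genotypes are excluded locus by locus.
#'
#' @param geno a genotype tibble (see [genotype_table()]).
#' @return a frequency tibble with columns `population`, `locus`, `allele`,
#'   `count` (gene copies), `n` (typed individuals at the locus) and `freq`,
#'   ordered by allele ladder position within locus.
#' @export
allele_frequencies <- function(geno) {
  typed <- dplyr::filter(geno, !is.na(.data$allele_1))
  empty <- dplyr::anti_join(
    dplyr::distinct(geno, .data$population, .data$locus),
    dplyr::distinct(typed, .data$population, .data$locus),
    by = c("population", "locus")
  )
  if (nrow(empty) > 0) {
    abort(paste0("no data at locus ", sQuote(empty$locus[1]),
      " (population ", empty$population[1], ")"))
  }
  long <- tidyr::pivot_longer(typed, c("allele_1", "allele_2"),
    values_to = "allele"
  )
  out <- long |>
    dplyr::count(.data$population, .data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(n = sum(.data$count) / 2, freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$population, .data$locus, allele_rank(.data$allele))
  out
}

#' Count distinct observed alleles
#'
#' Number of (locus, allele) pairs with positive frequency, summed over loci
#' (and over populations if several are present).
#'
#' @param freqs a frequency tibble (see [allele_frequencies()]).
#' @return integer count.
#' @export
count_observed_alleles <- function(freqs) {
  sum(freqs$freq > 0)
}

#' Read and write allele-frequency CSV tables
#'
#' The frequency CSV layout mirrors published STR population tables: rows are
#' allele labels (ladder order), columns are loci, cells are frequencies and
#' blank cells mean the allele was not observed at that locus.
#'
#' @param path file to read or write.
#' @param population population id to attach to the table.
#' @param n typed individuals per locus: a single number, or a named vector
#'   by locus.
#' @return `read_frequency_csv()`: a frequency tibble (`population`, `locus`,
#'   `allele`, `n`, `freq`). `write_frequency_csv()`: `path`, invisibly.
#' @export
read_frequency_csv <- function(path, population, n) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  wide <- readr::read_csv(path, col_types = readr::cols(
    Allele = readr::col_character(), .default = readr::col_double()
  ))
  if (!"Allele" %in% names(wide)) abort("frequency CSV must have an 'Allele' column")
  out <- wide |>
    tidyr::pivot_longer(-"Allele", names_to = "locus", values_to = "freq") |>
    dplyr::filter(!is.na(.data$freq), .data$freq > 0) |>
    dplyr::rename(allele = "Allele") |>
    dplyr::mutate(
      population = population,
      n = if (length(n) == 1) unname(n) else unname(n[.data$locus])
    ) |>
    dplyr::select("population", "locus", "allele", "n", "freq") |>
    dplyr::arrange(.data$locus, allele_rank(.data$allele))
  out
}

#' @rdname read_frequency_csv
#' @param freqs a frequency tibble for a single population.
#' @export
write_frequency_csv <- function(freqs, path) {
  wide <- freqs |>
    dplyr::mutate(.rank = allele_rank(.data$allele)) |>
    dplyr::arrange(.data$.rank) |>
    dplyr::select("allele", "locus", "freq") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "freq") |>
    dplyr::rename(Allele = "allele")
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

# Split a multi-population genotype tibble into a named list of
# single-population tibbles, preserving first-appearance order.
split_populations <- function(geno) {
  ids <- unique(geno$population)
  setNames(lapply(ids, function(p) geno[geno$population == p, ]), ids)
}
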