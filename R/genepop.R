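#' GenePop interchange
#'
#' Writes and reads genotype tables in the GenePop file format (title line,
#' locus list, `Pop` blocks, one `id ,  aaabbb ...` record per individual).
#' GenePop's fixed-width numeric allele codes have no native microvariant
#' notation, so allele `"R.P"` is encoded as the 3-digit integer `10*R + P`
#' (`"13.2"` -> `132`, `"14"` -> `140`); the mapping is stated on the title
#' line of every file written. Missing genotypes are the standard `000000`
#' code. `read_genepop(write_genepop(x))` is the identity on alleles,
#' missingness and population structure.
#'
#' @param geno a genotype tibble, possibly multi-population.
#' @param path file to write or read.
#' @param title optional extra title text (the microvariant convention is
#'   always appended).
#' @return `write_genepop()`: `path`, invisibly. `read_genepop()`: a genotype
#'   tibble.
#' @export
write_genepop <- function(geno, path, title = "strpop genotype export") {
  loci <- unique(geno$locus)
  info <- allele_info(stats::na.omit(unique(c(geno$allele_1, geno$allele_2))))
  bad <- info$label[info$repeat_units > 99]
  if (length(bad) > 0) {
    abort(paste0(
      "allele(s) not encodable in 3-digit GenePop fields: ",
      paste(sQuote(bad), collapse = ", ")
    ))
  }
  enc <- function(lab) {
    ifelse(is.na(lab), "000", {
      i <- allele_info(lab)
      sprintf("%03d", i$repeat_units * 10L + i$partial_repeat)
    })
  }
  wide <- geno |>
    dplyr::mutate(code = paste0(enc(.data$allele_1), enc(.data$allele_2))) |>
    dplyr::select("population", "sample", "locus", "code") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "code",
      values_fill = "000000")
  lines <- c(
    paste0(title, " | allele code = 10*repeat + partial (e.g. 13.2 -> 132, 14 -> 140)"),
    loci
  )
  for (pop in unique(wide$population)) {
    lines <- c(lines, "Pop")
    blk <- wide[wide$population == pop, , drop = FALSE]
    recs <- apply(as.matrix(blk[, loci, drop = FALSE]), 1, paste, collapse = " ")
    lines <- c(lines, paste0(pop, ":", blk$sample, " ,  ", recs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genepop
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[stringr::str_trim(lines) != ""]
  is_pop <- toupper(stringr::str_trim(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("no 'Pop' line found: not a GenePop file")
  locus_lines <- lines[2:(first_pop - 1)]
  loci <- stringr::str_trim(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  dec <- function(code) {
    v <- as.integer(code)
    ifelse(v == 0L, NA_character_, format_allele(v %/% 10L, v %% 10L))
  }
  rows <- list()
  pop_idx <- 0L
  for (i in seq(first_pop, length(lines))) {
    if (is_pop[i]) {
      pop_idx <- pop_idx + 1L
      next
    }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2) abort(paste0("malformed GenePop record: ", lines[i]))
    id <- stringr::str_trim(parts[1])
    pop_id <- id
    if (grepl(":", id)) {
      pop_id <- sub(":.*$", "", id)
      id <- sub("^[^:]*:", "", id)
    } else {
      pop_id <- paste0("pop", pop_idx)
    }
    codes <- strsplit(stringr::str_trim(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(codes) != length(loci)) {
      abort(paste0(
        "record for ", sQuote(id), " has ", length(codes),
        " genotypes but ", length(loci), " loci are declared"
      ))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      population = pop_id, sample = id, locus = loci,
      allele_1 = dec(substr(codes, 1, 3)),
      allele_2 = dec(substr(codes, 4, 6))
    )
  }
  genotype_table(dplyr::bind_rows(rows))
}
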