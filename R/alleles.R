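#' STR allele nomenclature
#'
#' STR alleles are named by their repeat count, with microvariant alleles
#' (incomplete repeats) carrying a partial-repeat suffix: `"13"` is thirteen
#' full repeats, `"13.2"` is thirteen repeats plus two bases. `allele_info()`
#' parses labels into their components; `allele_sort()` orders labels by
#' repeat count, then partial repeat, the order in which allele ladders and
#' frequency tables are conventionally printed.
#'
#' Parsing round-trips: `allele_info(x)$label` is identical to the canonical
#' form of `x` (no leading zeros, no trailing ".0").
#'
#' @param labels character vector of allele labels such as `"13"`, `"13.2"`.
#' @return `allele_info()`: a tibble with columns `label` (canonical text
#'   form), `repeat_units` (integer) and `partial_repeat` (integer, 0 for a
#'   complete repeat, otherwise 1-3). `allele_sort()`: the input labels in
#'   ladder order. `allele_rank()`: numeric sort keys.
#' @export
#' @examples
#' allele_info(c("13", "13.2", "9.1"))
#' allele_sort(c("14", "13.2", "9", "13"))
allele_info <- function(labels) {
  labels <- as.character(labels)
  ok <- is.na(labels) | grepl("^[0-9]+(\\.[1-3])?$", labels)
  if (any(!ok)) {
    bad <- unique(labels[!ok])
    abort(paste0(
      "Malformed allele label(s): ",
      paste(sQuote(bad), collapse = ", "),
      ". Expected forms like \"13\" or \"13.2\" (partial repeat 1-3)."
    ))
  }
  rep_units <- as.integer(sub("\\..*$", "", labels))
  partial <- ifelse(grepl("\\.", labels),
    as.integer(sub("^.*\\.", "", labels)), 0L
  )
  partial[is.na(labels)] <- NA_integer_
  tibble::tibble(
    label = format_allele(rep_units, partial),
    repeat_units = rep_units,
    partial_repeat = partial
  )
}

#' @rdname allele_info
#' @param repeat_units,partial_repeat integer vectors of allele components.
#' @export
format_allele <- function(repeat_units, partial_repeat = 0L) {
  ifelse(
    is.na(repeat_units), NA_character_,
    ifelse(partial_repeat > 0L,
      paste0(repeat_units, ".", partial_repeat),
      as.character(repeat_units)
    )
  )
}

#' @rdname allele_info
#' @export
allele_rank <- function(labels) {
  info <- allele_info(labels)
  info$repeat_units + info$partial_repeat / 10
}

#' @rdname allele_info
#' @export
allele_sort <- function(labels) {
  labels[order(allele_rank(labels))]
}

# Canonicalise an unordered genotype: the two alleles of each pair sorted in
# ladder order, so {a,b} and {b,a} store identically. Returns a two-column
# character matrix.
canonical_pair <- function(a, b) {
  swap <- !is.na(a) & !is.na(b) & allele_rank(a) > allele_rank(b)
  a2 <- ifelse(swap, b, a)
  b2 <- ifelse(swap, a, b)
  cbind(allele_1 = a2, allele_2 = b2)
}
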