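#' PCA of population allele frequencies
#'
#' Builds the populations x (locus, allele) frequency matrix over the union
#' of observed alleles (an allele absent from a population scores 0),
#' centres each column on its mean (no unit-variance scaling by default, the
#' classical convention for allele-frequency PCA), and decomposes it by SVD.
#' At most `min(populations - 1, features)` components are returned; the
#' explained-variance fractions are non-increasing and sum to 1 in the
#' full-rank case.
#'
#' @param freqs a multi-population frequency tibble.
#' @param loci locus subset (default: loci shared by all populations).
#' @param scale also scale columns to unit variance before decomposition.
#' @return an object of class `str_pca`: list with `scores` (tibble,
#'   `population` then `PC1`, `PC2`, ...), `explained` (variance fractions),
#'   `features` (tibble `locus`, `allele` per column), `sdev` and
#'   `rotation`. Methods: `tidy()` (long scores), `glance()` (one-row
#'   summary), `autoplot()` (PC1-PC2 scatter).
#' @export
pca_populations <- function(freqs, loci = NULL, scale = FALSE) {
  pops <- unique(freqs$population)
  if (length(pops) < 2) abort("need at least 2 populations for a PCA")
  if (is.null(loci)) {
    loci <- Reduce(intersect, lapply(pops, function(p) {
      unique(freqs$locus[freqs$population == p])
    }))
  }
  sub <- freqs[freqs$locus %in% loci, ]
  wide <- sub |>
    dplyr::mutate(feature = paste(.data$locus, .data$allele, sep = "|")) |>
    dplyr::select("population", "feature", "freq") |>
    tidyr::pivot_wider(
      names_from = "feature", values_from = "freq", values_fill = 0
    )
  x <- as.matrix(wide[, -1])
  rownames(x) <- wide$population
  if (scale) {
    keep <- apply(x, 2, sd) > 0
    x <- x[, keep, drop = FALSE]
  }
  fit <- prcomp(x, center = TRUE, scale. = scale)
  n_comp <- min(nrow(x) - 1, ncol(x))
  total_var <- sum(fit$sdev^2)
  explained <- (fit$sdev^2 / total_var)[seq_len(n_comp)]
  scores <- tibble::as_tibble(fit$x[, seq_len(n_comp), drop = FALSE])
  feat <- do.call(rbind, strsplit(colnames(x), "|", fixed = TRUE))
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(population = rownames(x)), scores
      ),
      explained = explained,
      features = tibble::tibble(locus = feat[, 1], allele = feat[, 2]),
      sdev = fit$sdev[seq_len(n_comp)],
      rotation = fit$rotation[, seq_len(n_comp), drop = FALSE],
      loci_used = loci, scaled = scale
    ),
    class = "str_pca"
  )
}

#' @export
print.str_pca <- function(x, ...) {
  cat(sprintf(
    "PCA of allele frequencies: %d populations, %d (locus, allele) features, %d loci\n",
    nrow(x$scores), nrow(x$features), length(x$loci_used)
  ))
  pct <- 100 * x$explained
  cat(
    "explained variance (%):",
    paste(sprintf("%.2f", head(pct, 5)), collapse = ", "),
    if (length(pct) > 5) "...\n" else "\n"
  )
  print(x$scores)
  invisible(x)
}

#' @exportS3Method
tidy.str_pca <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(-"population",
      names_to = "component", values_to = "score"
    ) |>
    dplyr::mutate(
      explained = x$explained[as.integer(sub("PC", "", .data$component))]
    )
}

#' @exportS3Method
glance.str_pca <- function(x, ...) {
  tibble::tibble(
    n_populations = nrow(x$scores),
    n_features = nrow(x$features),
    n_components = length(x$explained),
    var_pc1 = x$explained[1],
    var_pc2 = if (length(x$explained) >= 2) x$explained[2] else NA_real_,
    cum_var_2 = sum(head(x$explained, 2))
  )
}

#' @exportS3Method
autoplot.str_pca <- function(object, ...) {
  if (ncol(object$scores) < 3) {
    abort("need at least two components to plot")
  }
  pct <- 100 * object$explained
  ggplot2::ggplot(object$scores, ggplot2::aes(
    x = .data$PC1, y = .data$PC2, label = .data$population
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.2f%%)", pct[1]),
      y = sprintf("PC2 (%.2f%%)", pct[2])
    ) +
    ggplot2::theme_minimal()
}
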