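named_matrix <- function(v, labs) {
  matrix(v, length(labs), length(labs), dimnames = list(labs, labs))
}

test_that("UPGMA handles the textbook small cases", {
  d2 <- named_matrix(c(0, 3, 3, 0), c("A", "B"))
  t2 <- upgma(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(sort(t2$edge.length), c(1.5, 1.5))

  d3 <- named_matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), c("A", "B", "C"))
  t3 <- upgma(d3)
  coph <- cophenetic(t3)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 6)
  expect_equal(coph["B", "C"], 6)
  # heights 1 and 3: C branches 3 from the root
  expect_true(ape::is.ultrametric(t3, tol = 1e-9))
})

test_that("UPGMA reproduces ultrametric inputs exactly (cophenetic identity)", {
  for (seed in 1:5) {
    n <- sample(4:9, 1)
    d <- random_ultrametric(n, seed)
    tr <- upgma(d)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d, tolerance = 1e-8)
    # independent average-linkage oracle agrees on merge heights
    hc <- stats::hclust(as.dist(d), "average")
    expect_equal(sort(unique(round(ape::node.depth.edgelength(tr), 8))) |> max(),
      max(hc$height) / 2, tolerance = 1e-8)
  }
})

test_that("non-symmetric input is rejected", {
  d <- named_matrix(c(0, 1, 2, 0), c("A", "B"))
  expect_error(upgma(d), "symmetric")
  expect_error(neighbor_joining(named_matrix(0, "A")), "at least 3")
})

test_that("NJ exactly recovers random additive trees up to 10 taxa", {
  withr::with_seed(61, {
    for (i in 1:8) {
      n <- sample(4:10, 1)
      ref <- ape::rtree(n, rooted = FALSE)
      ref$edge.length <- runif(length(ref$edge.length), 0.05, 1)
      d <- cophenetic(ref)
      est <- neighbor_joining(d)
      expect_equal(as.numeric(ape::dist.topo(ref, est)), 0)
      expect_equal(cophenetic(est)[rownames(d), colnames(d)], d,
        tolerance = 1e-6)
      # independent implementation agrees on the topology
      expect_equal(as.numeric(ape::dist.topo(ape::nj(d), est)), 0)
    }
  })
})

test_that("NJ on an ultrametric matrix matches the UPGMA topology", {
  for (seed in 11:13) {
    d <- random_ultrametric(6, seed)
    t_nj <- neighbor_joining(d)
    t_up <- ape::unroot(upgma(d))
    expect_equal(as.numeric(ape::dist.topo(t_nj, t_up)), 0)
  }
})

test_that("a star-like equidistant matrix yields zero-length internal edges", {
  d <- named_matrix(2, c("A", "B", "C", "D"))
  diag(d) <- 0
  tr <- neighbor_joining(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
})

test_that("Newick round-trips preserve topology, lengths and support", {
  expect_match(to_newick(upgma(named_matrix(c(0, 1, 1, 0), c("A", "B")))),
    "^\\(A:0\\.5,B:0\\.5\\);$")
  withr::with_seed(71, {
    tr <- ape::rtree(8)
    back <- from_newick(to_newick(tr))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
    labs <- tr$tip.label
    expect_equal(cophenetic(back)[labs, labs], cophenetic(tr)[labs, labs],
      tolerance = 1e-12)
  })
  tr2 <- from_newick("((A:1,B:1)0.87:0.5,C:1.5);")
  expect_equal(tr2$node.label, c("", "0.87"))
  expect_identical(from_newick(to_newick(tr2))$node.label, tr2$node.label)
})

test_that("labels with metacharacters are quoted in Newick output", {
  d <- named_matrix(c(0, 1, 1, 0), c("pop (north)", "pop,b"))
  txt <- to_newick(upgma(d))
  expect_match(txt, "'pop \\(north\\)'")
})

test_that("bootstrap over loci attaches bipartition support", {
  freqs <- diverged_freq_table(
    list(A1 = 0.005, A2 = 0.005, B1 = 0.005, B2 = 0.005),
    n_loci = 15, seed = 81
  )
  # one replicate: supports are exactly 0 or 1 (or NA at the root)
  b1 <- bootstrap_over_loci(freqs, n_reps = 1, method = "upgma", seed = 5)
  s <- attr(b1, "support")
  expect_true(all(is.na(s) | s %in% c(0, 1)))
  # same seed, same resamples: identical supports
  b2 <- bootstrap_over_loci(freqs, n_reps = 25, method = "nj", seed = 6)
  b3 <- bootstrap_over_loci(freqs, n_reps = 25, method = "nj", seed = 6)
  expect_identical(attr(b2, "support"), attr(b3, "support"))
})

test_that("well-separated clades receive high bootstrap support", {
  withr::with_seed(91, {
    anc <- dplyr::bind_rows(lapply(1:20, function(i) {
      dplyr::mutate(sample_ancestral_frequencies(6),
        locus = sprintf("L%02d", i), .before = 1)
    }))
    div <- function(fr, fst) {
      dplyr::bind_rows(lapply(split(fr, fr$locus), function(x) {
        x$freq <- diverge_balding_nichols(x$freq, fst)
        x
      }))
    }
    clade_a <- div(anc, 0.1)
    clade_b <- div(anc, 0.1)
    mk <- function(br, nm) dplyr::mutate(div(br, 0.005), population = nm, n = 100, .before = 1)
    freqs <- dplyr::bind_rows(
      mk(clade_a, "A1"), mk(clade_a, "A2"), mk(clade_b, "B1"), mk(clade_b, "B2")
    )
  })
  bt <- bootstrap_over_loci(freqs, n_reps = 100, method = "nj", seed = 7)
  s <- attr(bt, "support")
  expect_gte(min(s, na.rm = TRUE), 0.95)
})
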