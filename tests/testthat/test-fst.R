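make_two_pops <- function(freq_a, freq_b, n = 50, loci = "L1", seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(
      sample_genotypes(freq_a, n, locus = loci, population = "A"),
      sample_genotypes(freq_b, n, locus = loci, population = "B")
    )
  })
}

test_that("identical data relabelled as two populations gives theta <= 0", {
  g <- sample_genotypes(c("10" = 0.4, "11" = 0.6), 40, seed = 3, population = "A")
  g2 <- dplyr::mutate(g, population = "B", sample = paste0("b", sample))
  fit <- pairwise_fst(g, g2, n_perm = 0)
  expect_lte(fit$overall, 0)
  expect_true(all(fit$per_locus$theta <= 0))
})

test_that("populations fixed for different alleles give theta = 1", {
  g <- dplyr::bind_rows(
    geno_from_pairs(setNames(rep(list(c("10", "10")), 20), paste0("a", 1:20)),
      population = "A"),
    geno_from_pairs(setNames(rep(list(c("12", "12")), 20), paste0("b", 1:20)),
      population = "B")
  )
  fit <- pairwise_fst(g, n_perm = 0)
  expect_equal(fit$overall, 1)
  p <- fst_permutation_p(g, locus = "L1", n_perm = 1000, seed = 9)
  expect_equal(p, 0)
})

test_that("theta is bounded, symmetric, and overall reduces correctly", {
  g <- make_two_pops(
    c("10" = 0.3, "11" = 0.7), c("10" = 0.7, "11" = 0.3),
    n = 60, seed = 17
  )
  pops <- split(g, g$population)
  f_ab <- pairwise_fst(pops$A, pops$B, n_perm = 0)
  f_ba <- pairwise_fst(pops$B, pops$A, n_perm = 0)
  expect_equal(f_ab$overall, f_ba$overall)
  expect_true(abs(f_ab$overall) <= 1)
  # single locus: overall equals the per-locus estimate
  expect_equal(f_ab$overall, f_ab$per_locus$theta[1])
  expect_equal(overall_fst(pops$A, pops$B), f_ab$overall)
})

test_that("a monomorphic locus is flagged and leaves overall theta unchanged", {
  g <- make_two_pops(
    c("10" = 0.3, "11" = 0.7), c("10" = 0.7, "11" = 0.3),
    n = 60, seed = 17
  )
  mono <- dplyr::bind_rows(
    geno_from_pairs(setNames(rep(list(c("9", "9")), 60), sprintf("A_%04d", 1:60)),
      locus = "M", population = "A"),
    geno_from_pairs(setNames(rep(list(c("9", "9")), 60), sprintf("B_%04d", 1:60)),
      locus = "M", population = "B")
  )
  g_all <- dplyr::bind_rows(g, mono)
  base <- pairwise_fst(g[g$population == "A", ], g[g$population == "B", ], n_perm = 0)
  with_m <- pairwise_fst(
    g_all[g_all$population == "A", ], g_all[g_all$population == "B", ],
    n_perm = 0
  )
  expect_equal(with_m$overall, base$overall)
  expect_true(with_m$per_locus$monomorphic[with_m$per_locus$locus == "M"])
  expect_equal(with_m$per_locus$theta[with_m$per_locus$locus == "M"], 0)
})

test_that("permutation p is reproducible and label-symmetric within noise", {
  g <- make_two_pops(
    c("10" = 0.35, "11" = 0.65), c("10" = 0.6, "11" = 0.4),
    n = 40, seed = 23
  )
  pops <- split(g, g$population)
  p1 <- fst_permutation_p(pops$A, pops$B, locus = "L1", n_perm = 400, seed = 7)
  p1b <- fst_permutation_p(pops$A, pops$B, locus = "L1", n_perm = 400, seed = 7)
  expect_identical(p1, p1b)
  p2 <- fst_permutation_p(pops$B, pops$A, locus = "L1", n_perm = 400, seed = 7)
  expect_lt(abs(p1 - p2), 0.1) # same statistic, independent permutation draws
})

test_that("theta recovers the generator Fst in a reduced replicate study", {
  withr::with_seed(55, {
    th <- replicate(30, {
      anc <- lapply(1:5, function(i) sample_ancestral_frequencies(6))
      gen <- function(nm) {
        dplyr::bind_rows(lapply(1:5, function(i) {
          f <- diverge_balding_nichols(anc[[i]], 0.05)
          f <- f[f$freq > 0, ]
          sample_genotypes(f, 100, locus = sprintf("L%d", i), population = nm)
        }))
      }
      overall_fst(gen("A"), gen("B"))
    })
  })
  se <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - 0.05), 3 * se + 0.01)
})

test_that("tidy and glance expose the per-locus and overall views", {
  g <- make_two_pops(
    c("10" = 0.3, "11" = 0.7), c("10" = 0.7, "11" = 0.3),
    n = 30, seed = 2
  )
  fit <- pairwise_fst(g, n_perm = 200, seed = 4)
  td <- tidy(fit)
  expect_named(td, c("population_a", "population_b", "locus", "theta",
    "p_value", "monomorphic"))
  gl <- glance(fit)
  expect_equal(gl$n_perm, 200L)
  expect_true(gl$overall_p >= 0 && gl$overall_p <= 1)
})
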