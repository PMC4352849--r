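test_that("ancestral frequency draws live on the simplex with valid labels", {
  withr::with_seed(5, {
    for (i in 1:50) {
      k <- sample(1:25, 1)
      fr <- sample_ancestral_frequencies(k)
      expect_equal(sum(fr$freq), 1, tolerance = 1e-12)
      expect_equal(nrow(fr), k)
      info <- allele_info(fr$allele)
      expect_true(all(info$repeat_units >= 7 & info$repeat_units <= 24))
    }
  })
  expect_error(sample_ancestral_frequencies(0), "at least 1")
  expect_equal(sample_ancestral_frequencies(1, seed = 1)$freq, 1)
  # high concentration approaches the uniform vector
  fr <- sample_ancestral_frequencies(5, concentration = 1e6, seed = 2)
  expect_true(all(abs(fr$freq - 0.2) < 1e-2))
})

test_that("Balding-Nichols divergence is centred on the ancestral vector", {
  p <- c(0.5, 0.3, 0.2)
  expect_identical(diverge_balding_nichols(p, 0), p)
  withr::with_seed(31, {
    draws <- replicate(10000, diverge_balding_nichols(p, 0.05))
    m <- rowMeans(draws)
    se <- sqrt(p * (1 - p) * 0.05 / 10000)
    expect_true(all(abs(m - p) < 3 * se))
    # near-complete drift: most draws close to fixation
    fixed <- replicate(200, max(diverge_balding_nichols(p, 0.99)))
    expect_gte(mean(fixed >= 0.99), 0.9)
  })
  expect_error(diverge_balding_nichols(p, 1), "\\[0, 1\\)")
})

test_that("genotype sampling honours the inbreeding coefficient", {
  g1 <- sample_genotypes(c("10" = 0.4, "11" = 0.6), 200, inbreeding_f = 1, seed = 3)
  expect_true(all(g1$allele_1 == g1$allele_2))
  g0 <- sample_genotypes(c("10" = 0.5, "11" = 0.5), 1e5, seed = 4)
  het <- mean(g0$allele_1 != g0$allele_2)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("inbreeding is detected by the HWE test with high power", {
  withr::with_seed(41, {
    rej <- replicate(15, {
      p <- rgamma(5, 1)
      p <- setNames(p / sum(p), as.character(10:14))
      g <- sample_genotypes(p, 275, inbreeding_f = 0.2)
      hwe_exact_test(g, method = "mcmc", chain = hwe_chain(1000, 20, 500))$p_value < 0.05
    })
  })
  expect_gte(mean(rej), 0.8)
})

test_that("linked-pair sampling respects marginals and feasibility", {
  expect_error(sample_linked_pair(0.5, 0.5, 0.3, 10), "feasible range")
  # maximal D with p = q = 0.5: only two haplotypes, loci perfectly coupled
  g <- sample_linked_pair(0.5, 0.5, 0.25, 100, seed = 6)
  wide <- tidyr::pivot_wider(g, id_cols = "sample", names_from = "locus",
    values_from = c("allele_1", "allele_2"))
  expect_true(all(wide$allele_1_L1 == wide$allele_1_L2 &
    wide$allele_2_L1 == wide$allele_2_L2))
  # D = 0: marginal allele frequencies match the request within 3 se
  g0 <- sample_linked_pair(0.3, 0.7, 0, 2000, seed = 7)
  f1 <- mean(c(g0$allele_1[g0$locus == "L1"], g0$allele_2[g0$locus == "L1"]) == "10")
  expect_lt(abs(f1 - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
})

test_that("study fixtures are deterministic and correctly shaped", {
  cfg <- sim_config(n_populations = 3, n_individuals = c(20, 30, 40),
    n_loci = 5, seed = 77)
  fx1 <- make_study_fixture(cfg)
  fx2 <- make_study_fixture(cfg)
  expect_identical(fx1, fx2)
  expect_equal(nrow(fx1$genotypes), (20 + 30 + 40) * 5)
  expect_equal(length(unique(fx1$genotypes$population)), 3)
  expect_equal(names(fx1$truth$fst), c("pop01", "pop02", "pop03"))
  per_locus_sums <- tapply(
    fx1$truth$population_freqs$freq,
    paste(fx1$truth$population_freqs$population, fx1$truth$population_freqs$locus),
    sum
  )
  expect_true(all(abs(per_locus_sums - 1) < 1e-9))
  # a different seed changes the data
  fx3 <- make_study_fixture(sim_config(n_populations = 3,
    n_individuals = c(20, 30, 40), n_loci = 5, seed = 78))
  expect_false(identical(fx1$genotypes, fx3$genotypes))
})

test_that("config validation catches out-of-range parameters", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(inbreeding_f = 2))
  expect_error(sim_config(ld_pairs = data.frame(
    locus_a = c("L01", "L01"), locus_b = c("L02", "L03"), d = 0.1
  )), "disjoint")
})
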