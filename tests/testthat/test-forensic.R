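test_that("frequency-based statistics reproduce published per-locus values", {
  fp <- system.file("extdata", "guanzhong_han_allele_freqs.csv", package = "strpop")
  fr <- read_frequency_csv(fp, population = "GZH", n = 275)
  p_1627 <- fr$freq[fr$locus == "D1S1627"]
  expect_equal(round_half_up(pic(p_1627), 4), 0.5325)
  expect_equal(round_half_up(expected_heterozygosity(p_1627), 4), 0.5940)
  # count-reconstructed frequencies (printed values are rounded to 4 dp)
  recount <- function(locus) {
    cnt <- round(fr$freq[fr$locus == locus] * 550)
    cnt / sum(cnt)
  }
  expect_equal(round_half_up(pic(recount("D19S433")), 4), 0.7916)
  expect_equal(round_half_up(expected_heterozygosity(recount("D19S433")), 4), 0.8147)
  expect_equal(round_half_up(expected_heterozygosity(recount("D6S474")), 4), 0.7000)
})

test_that("PE and TPI follow the observed-heterozygosity closed forms", {
  expect_equal(round_half_up(probability_of_exclusion(218 / 275), 4), 0.5856)
  expect_equal(round_half_up(probability_of_exclusion(161 / 275), 4), 0.2738)
  expect_equal(probability_of_exclusion(0), 0)
  expect_equal(round_half_up(typical_paternity_index(217 / 275), 4), 2.3707)
  expect_equal(round_half_up(typical_paternity_index(191 / 275), 4), 1.6369)
  expect_equal(typical_paternity_index(0.5), 1)
  expect_warning(out <- typical_paternity_index(1), "infinite")
  expect_identical(out, Inf)
  # monotone increasing in observed heterozygosity
  h <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(probability_of_exclusion(h)) > 0))
  expect_true(all(diff(typical_paternity_index(h)) > 0))
})

test_that("trivial frequency vectors give closed-form statistics", {
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(1), 0)
  expect_error(expected_heterozygosity(c(0.5, 0.4)), "summing to 1")
})

test_that("PIC never exceeds expected heterozygosity on the simplex", {
  withr::with_seed(7, {
    for (i in 1:200) {
      k <- sample(2:20, 1)
      p <- rgamma(k, shape = runif(1, 0.2, 3))
      p <- p / sum(p)
      expect_lte(pic(p), expected_heterozygosity(p) + 1e-12)
    }
  })
})

test_that("observed statistics come from genotype tallies", {
  g <- geno_from_pairs(list(
    s1 = c("10", "11"), s2 = c("10", "10"), s3 = c("11", "12"), s4 = c("12", "12")
  ))
  expect_equal(observed_heterozygosity(g)$ho, 0.5)
  # all genotypes distinct: PD = 1 - 1/n
  expect_equal(power_of_discrimination(g)$pd, 1 - 4 * (1 / 4)^2)
  g_same <- geno_from_pairs(list(s1 = c("10", "10"), s2 = c("10", "10")))
  expect_equal(power_of_discrimination(g_same)$pd, 0)
  expect_equal(observed_heterozygosity(g_same)$ho, 0)
  # brute-force recount oracle on a random locus
  withr::with_seed(11, {
    gr <- sample_genotypes(c("8" = 0.3, "9" = 0.5, "10" = 0.2), 80)
    cnt <- table(paste(gr$allele_1, gr$allele_2))
    expect_equal(power_of_discrimination(gr)$pd, 1 - sum((cnt / 80)^2))
    expect_equal(observed_heterozygosity(gr)$ho, mean(gr$allele_1 != gr$allele_2))
  })
})

test_that("under HWE sampling HO converges to 1 - sum(p^2)", {
  g <- sample_genotypes(c("10" = 0.5, "11" = 0.5), 1e5, seed = 123)
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(observed_heterozygosity(g)$ho - 0.5), 3 * se)
})

test_that("combined power multiplies in log space and is monotone", {
  v <- c(0.9, 0.99, 0.95)
  cp <- combined_power(v)
  expect_equal(cp$combined, 1 - prod(1 - v), tolerance = 1e-12)
  expect_equal(combined_power(0.7)$combined, 0.7)
  expect_equal(combined_power(c(0.5, 1, 0.2))$combined, 1)
  # monotone non-decreasing as loci are appended
  withr::with_seed(3, {
    vs <- runif(15)
    cum <- vapply(seq_along(vs), function(i) combined_power(vs[1:i])$combined, 0)
    expect_true(all(diff(cum) >= 0))
    expect_equal(cum[15], 1 - prod(1 - vs), tolerance = 1e-12)
  })
})

test_that("locus summary assembles the per-locus statistics consistently", {
  fx <- make_study_fixture(sim_config(
    n_populations = 1, n_individuals = 50, n_loci = 3,
    alleles_per_locus = c(3, 5), seed = 5
  ))
  g <- fx$genotypes
  s <- locus_summary_table(g, chain = hwe_chain(500, 10, 300), seed = 2)
  expect_equal(nrow(s), 3)
  expect_true(all(s$ho >= 0 & s$ho <= 1))
  expect_true(all(s$pic <= s$he + 1e-12))
  expect_true(all(s$tpi >= 0.5 | s$ho == 1))
  # composition identity with the individual operations
  expect_equal(s$ho, observed_heterozygosity(g)$ho)
  expect_equal(s$pd, power_of_discrimination(g)$pd)
  fr <- allele_frequencies(g)
  he_direct <- vapply(split(fr, fr$locus), function(x) {
    expected_heterozygosity(x$freq)
  }, 0)
  expect_equal(s$he, unname(he_direct[s$locus]))
  expect_equal(s$pe, probability_of_exclusion(s$ho))
})

test_that("a monomorphic locus yields zero statistics and HWE p of 1", {
  g <- geno_from_pairs(
    list(s1 = c("10", "10"), s2 = c("10", "10"), s3 = c("10", "10")),
    locus = "MONO"
  )
  s <- locus_summary_table(g)
  expect_equal(unlist(s[, c("ho", "he", "pic", "pd", "pe")]),
    c(ho = 0, he = 0, pic = 0, pd = 0, pe = 0))
  expect_equal(s$hwe_p, 1)
})
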