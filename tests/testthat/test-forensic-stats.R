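test_that("allele frequencies are direct counts over usable alleles", {
  gt <- tiny_gt()
  p <- allele_frequencies(gt, "TPOX")
  expect_equal(as.numeric(p), c(0.75, 0.25))
  expect_equal(names(p), c("8", "9"))
  expect_equal(attr(p, "n2"), 4L)
  expect_error(allele_frequencies(gt, "FGA"), "FGA")
})

test_that("frequency estimation matches a naive tally oracle exactly", {
  cfg <- sim_config(n_individuals = 50, seed = 13,
                    loci = default_panel(n_loci = 3, seed = 13))
  gt <- simulate_genotypes(cfg)
  for (l in gt$loci) {
    tally <- table(c(gt$allele1[, l], gt$allele2[, l]))
    oracle <- as.numeric(tally) / sum(tally)
    names(oracle) <- names(tally)
    p <- allele_frequencies(gt, l)
    sa <- sort_alleles(names(oracle))
    expect_equal(as.numeric(p[sa]), unname(oracle[sa]))
    expect_equal(sort(names(p)), sort(names(oracle)))
  }
})

test_that("the MAF floor is 5/2N", {
  expect_equal(round(maf_floor(543), 4), 0.0046)
  expect_equal(maf_floor(250), 0.01)
  expect_equal(maf_floor(5), 0.5)
  expect_error(maf_floor(0), "n_individuals")
})

test_that("heterozygosities follow their definitions", {
  gt <- tiny_gt()
  expect_equal(observed_heterozygosity(gt, "TPOX"), 0.5)
  hom <- genotype_table(matrix(c("8", "9"), 2), matrix(c("8", "9"), 2),
                        c("a", "b"), "L")
  expect_equal(observed_heterozygosity(hom, "L"), 0)
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(c(0.5, 0.5), n2 = 100, unbiased = TRUE),
               0.5 * 100 / 99)
  # He of the printed TPOX spectrum
  expect_equal(round(expected_heterozygosity(bahrain_freqs()$freqs$TPOX), 4),
               0.6675)
})

test_that("PIC follows the Botstein formula", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(1), 0)
  expect_equal(round(pic(bahrain_freqs()$freqs$TPOX), 4), 0.6215)
})

test_that("PIC never exceeds expected heterozygosity (Dirichlet sweep)", {
  set.seed(42)
  for (i in 1:200) {
    p <- sample_frequency_vector(sample(2:30, 1), concentration = runif(1, 0.3, 3))
    expect_lte(pic(p), expected_heterozygosity(p) + 1e-12)
    expect_lt(pic(p), 1)
    expect_gte(pic(p), 0)
  }
})

test_that("match probability agrees with the genotype-enumeration oracle", {
  # observed mode: two genotype classes of equal size
  gt <- genotype_table(matrix(c("8", "8", "8", "8"), 4),
                       matrix(c("8", "8", "9", "9"), 4),
                       sprintf("s%d", 1:4), "L")
  expect_equal(match_probability(gt, "L", mode = "observed"), 0.5)
  # expected mode closed form and oracle equality to 1e-12
  expect_equal(match_probability(c(0.5, 0.5), mode = "expected"), 0.375)
  expect_equal(round(match_probability(bahrain_freqs()$freqs$TPOX,
                                       mode = "expected"), 4), 0.1566)
  set.seed(7)
  for (i in 1:50) {
    p <- sample_frequency_vector(sample(2:20, 1))
    pm <- match_probability(p, mode = "expected")
    expect_equal(pm, pm_enumeration_oracle(p), tolerance = 1e-12)
    expect_gte(pm, sum(p^2)^2)
    expect_lte(pm, sum(p^2))
  }
})

test_that("PE and TPI reproduce published values and their limits", {
  expect_equal(round(power_of_exclusion(0.7919), 4), 0.5841)
  expect_equal(round(power_of_exclusion(0.9208), 4), 0.8381)
  expect_equal(power_of_exclusion(1), 1)
  expect_equal(power_of_exclusion(0), 0)
  expect_error(power_of_exclusion(1.1), "heterozygosity")
  expect_equal(round(typical_paternity_index(0.7919), 4), 2.4027)
  expect_equal(typical_paternity_index(0.5), 1)
  expect_equal(typical_paternity_index(0.75), 2)
  expect_error(typical_paternity_index(1), "unbounded")
  # strict monotonicity
  h <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(power_of_exclusion(h)) > 0))
  expect_true(all(diff(typical_paternity_index(h)) > 0))
})

test_that("locus summaries are internally consistent compositions", {
  cfg <- sim_config(n_individuals = 60, seed = 19,
                    loci = default_panel(n_loci = 2, seed = 19))
  gt <- simulate_genotypes(cfg)
  l <- gt$loci[1]
  s <- locus_summary(gt, l)
  p <- allele_frequencies(gt, l)
  ho <- observed_heterozygosity(gt, l)
  expect_equal(s$Na, length(p))
  expect_equal(s$Ho, ho)
  expect_equal(s$PIC, pic(as.numeric(p)))
  expect_equal(s$PM, match_probability(gt, l, mode = "observed"))
  expect_equal(s$PD, 1 - s$PM)
  expect_equal(s$PD_expected, 1 - s$PM_expected)
  expect_equal(s$PE, power_of_exclusion(ho))
  expect_equal(s$TPI, typical_paternity_index(ho))
  # monomorphic locus degenerates cleanly
  mono <- genotype_table(matrix("8", 5), matrix("8", 5),
                         sprintf("s%d", 1:5), "M")
  sm <- locus_summary(mono, "M")
  expect_equal(sm[c("Na", "Ho", "PIC", "PD")],
               data.frame(Na = 1L, Ho = 0, PIC = 0, PD = 0))
  expect_equal(sm$TPI, 0.5)
})

test_that("locus summary matches a spreadsheet-style oracle on a fixture", {
  counts <- c("8" = 30, "9" = 40, "9.3" = 20, "10" = 10)
  gt <- gt_from_counts(counts, "LX")
  s <- locus_summary(gt, "LX")
  p <- counts / 100
  expect_equal(s$Na, 4L)
  expect_equal(s$MAF, 5 / 100)
  expect_equal(s$He, (1 - sum(p^2)) * 100 / 99)
  expect_equal(s$PIC, 1 - sum(p^2) - sum(p^2)^2 + sum(p^4))
  expect_equal(s$PM_expected, 2 * sum(p^2)^2 - sum(p^4))
  g <- paste(pmin(gt$allele1[, 1], gt$allele2[, 1]),
             pmax(gt$allele1[, 1], gt$allele2[, 1]), sep = "/")
  expect_equal(s$PM, sum((table(g) / 50)^2))
  expect_equal(s$Ho, mean(gt$allele1[, 1] != gt$allele2[, 1]))
})

test_that("combined statistics multiply per-locus match probabilities", {
  cs <- combined_stats(c(0.1, 0.1))
  expect_equal(cs$cmp, 0.01)
  expect_equal(cs$cpd, 0.99)
  expect_equal(combined_stats(0.3)$cmp, 0.3)
  expect_error(combined_stats(numeric(0)), "at least one")
  expect_error(combined_stats(c(0.5, 1.2)), "0, 1")
  # permutation invariance and multiplicativity over disjoint sets
  set.seed(3)
  pm <- runif(12)
  expect_equal(combined_stats(pm)$cmp, combined_stats(rev(pm))$cmp)
  expect_equal(combined_stats(pm)$cmp,
               combined_stats(pm[1:5])$cmp * combined_stats(pm[6:12])$cmp)
})

test_that("observed statistics converge to HWE expectations at large N", {
  p <- c("8" = 0.45, "9" = 0.35, "10" = 0.2)
  gt <- simulate_genotypes(sim_config(n_individuals = 10000,
                                      loci = list(LZ = p), fis = 0, seed = 6))
  s <- locus_summary(gt, "LZ")
  he <- 1 - sum(p^2)
  expect_lt(abs(s$Ho - he), 3 * sqrt(he * (1 - he) / 10000))
  expect_lt(abs(s$PD - s$PD_expected), 0.01)
})
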