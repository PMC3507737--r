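test_that("per-locus statistics match hand computations", {
  # two individuals, both heterozygous AB: p = (1/2, 1/2)
  gt <- genotype_table(c("a", "b"), "p", "parent", NA,
                       rbind(c(1, 2), c(1, 2)), "L1")
  s <- per_locus_stats(gt)
  expect_equal(s$ho, 1)
  expect_equal(s$he, 0.5)
  expect_equal(s$f, -1)

  # monomorphic: He = 0, F undefined
  gt2 <- genotype_table(c("a", "b"), "p", "parent", NA,
                        rbind(c(1, 1), c(1, 1)), "L1")
  s2 <- per_locus_stats(gt2)
  expect_equal(s2$ho, 0)
  expect_equal(s2$he, 0)
  expect_true(is.na(s2$f))

  # He is invariant to allele relabeling
  gt3 <- genotype_table(c("a", "b", "c"), "p", "parent", NA,
                        rbind(c(1, 2), c(2, 3), c(1, 1)), "L1")
  gt4 <- genotype_table(c("a", "b", "c"), "p", "parent", NA,
                        rbind(c(9, 5), c(5, 7), c(9, 9)), "L1")
  expect_equal(per_locus_stats(gt3)$he, per_locus_stats(gt4)$he)
})

test_that("fixation index is near zero for a large HWE sample", {
  cfg <- sim_config(n_pops = 1, parents_per_pop = 10000, n_loci = 11,
                    alleles_per_locus = 8, theta = 0.1, f_inbreeding = 0,
                    seed = 19)
  gt <- simulate_island_populations(cfg)
  s <- per_locus_stats(gt)
  expect_lt(abs(mean(s$f)), 0.02)
})

test_that("HWE chi-square matches hand-computed counts", {
  # 20 individuals all heterozygous AB: expected (5, 10, 5), chi2 = 20
  al <- cbind(rep(1L, 20), rep(2L, 20))
  h <- hwe_chi_square(al)
  expect_equal(h$chi2, 20)
  expect_equal(h$df, 1)

  # exact Hardy-Weinberg proportions: chi2 = 0, p = 1
  al2 <- rbind(matrix(1L, 5, 2), cbind(rep(1L, 10), rep(2L, 10)),
               matrix(2L, 5, 2))
  h2 <- hwe_chi_square(al2)
  expect_equal(h2$chi2, 0)
  expect_equal(h2$p, 1)

  expect_error(hwe_chi_square(matrix(1L, 5, 2)), "monomorphic")

  # statistic invariant under allele label permutation
  al3 <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 3L), c(3L, 3L), c(1L, 3L))
  al3b <- al3; al3b[al3 == 1L] <- 7L; al3b[al3 == 3L] <- 1L
  al3b[al3 == 2L] <- 3L
  expect_equal(hwe_chi_square(al3)$chi2, hwe_chi_square(al3b)$chi2)
})

test_that("Dunn-Sidak correction follows its closed form", {
  expect_equal(sidak_alpha(0.05, 1), 0.05)
  expect_equal(sidak_alpha(0.05, 2), 1 - sqrt(0.95))
  # family-wise identity holds to machine precision
  for (n in c(3, 11, 99, 500)) {
    a <- sidak_alpha(0.05, n)
    expect_equal((1 - a)^n, 0.95, tolerance = 1e-12)
  }
  expect_error(sidak_alpha(1.2, 10), "alpha")
  expect_error(sidak_alpha(0.05, 0), "n_tests")
})

test_that("pooling offspring that clone their parents leaves F unchanged", {
  cfg <- sim_config(n_pops = 2, parents_per_pop = 12, n_loci = 5, seed = 23)
  p <- simulate_island_populations(cfg)
  clones <- genotype_table(
    c(p$samples, paste0(p$samples, "_c")),
    c(p$population, p$population),
    c(p$generation, rep("offspring", length(p$samples))),
    c(p$mother, p$samples),
    rbind(p$alleles, p$alleles), p$loci)
  chk <- pooling_fis_check(clones)
  expect_true(all(abs(chk$delta) < 1e-12))

  # population lacking offspring is skipped with a log entry
  one <- subset_genotypes(clones, clones$population == "pop01" |
                            clones$generation == "parent")
  chk2 <- pooling_fis_check(one)
  expect_equal(attr(chk2, "skipped"), "pop02")
  expect_equal(chk2$population, "pop01")
})

test_that("selfed progeny arrays inflate pooled F", {
  set.seed(29)
  pos <- replicate(20, {
    cfg <- sim_config(n_pops = 1, parents_per_pop = 12, n_loci = 6,
                      alleles_per_locus = 6, f_inbreeding = 0,
                      seed = sample.int(1e6, 1))
    p <- simulate_island_populations(cfg)
    fams <- simulate_progeny_arrays(p, t_true = 0, offspring_per_family = 6,
                                    seed = sample.int(1e6, 1))
    pooling_fis_check(fams)$delta > 0
  })
  expect_gte(mean(pos), 0.95)
})

test_that("hwe test table applies the corrected threshold", {
  cfg <- sim_config(n_pops = 3, parents_per_pop = 12, n_loci = 4, seed = 31)
  gt <- simulate_island_populations(cfg)
  tab <- hwe_test_table(gt)
  expect_equal(attr(tab, "alpha_corrected"),
               sidak_alpha(0.05, nrow(tab)))
  expect_identical(tab$significant, tab$p < attr(tab, "alpha_corrected"))
})
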