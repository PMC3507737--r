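test_that("generators are seed-deterministic and pass validation", {
  cfg <- sim_config(n_pops = 3, parents_per_pop = 5:6, n_loci = 4, seed = 9)
  a <- simulate_island_populations(cfg)
  b <- simulate_island_populations(cfg)
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$samples, b$samples)
  expect_s3_class(a, "genotype_table")

  f1 <- simulate_progeny_arrays(a, t_true = 0.7, offspring_per_family = 3,
                                seed = 4)
  f2 <- simulate_progeny_arrays(a, t_true = 0.7, offspring_per_family = 3,
                                seed = 4)
  expect_identical(f1$alleles, f2$alleles)

  t1 <- simulate_parent_offspring_trait(f1, h2_true = 0.5, env_sd = 0.1,
                                        seed = 2)
  t2 <- simulate_parent_offspring_trait(f1, h2_true = 0.5, env_sd = 0.1,
                                        seed = 2)
  expect_identical(t1$oridonin_pct, t2$oridonin_pct)
})

test_that("complete inbreeding forces homozygosity", {
  cfg <- sim_config(n_pops = 2, parents_per_pop = 15, n_loci = 5,
                    f_inbreeding = 1, seed = 3)
  gt <- simulate_island_populations(cfg)
  a1 <- gt$alleles[, seq(1, 9, 2)]
  a2 <- gt$alleles[, seq(2, 10, 2)]
  expect_true(all(a1 == a2))
})

test_that("undiverged population without inbreeding is at HWE", {
  # chi-square rejection rate across replicate loci is ~ alpha
  set.seed(41)
  rej <- replicate(200, {
    cfg <- sim_config(n_pops = 1, parents_per_pop = 200, n_loci = 1,
                      alleles_per_locus = 4, theta = 0, f_inbreeding = 0,
                      seed = sample.int(1e6, 1))
    gt <- simulate_island_populations(cfg)
    h <- tryCatch(hwe_chi_square(locus_alleles(gt, 1)),
                  error = function(e) NULL)
    if (is.null(h)) NA else h$p < 0.05
  })
  rate <- mean(rej, na.rm = TRUE)
  expect_gt(rate, 0.05 - 2.5 * sqrt(0.05 * 0.95 / 200))
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 200))
})

test_that("progeny arrays obey the mixed-mating model mechanics", {
  cfg <- sim_config(n_pops = 1, parents_per_pop = 20, n_loci = 4,
                    alleles_per_locus = 6, seed = 7)
  mothers <- simulate_island_populations(cfg)

  # full selfing from a homozygous mother reproduces the mother exactly
  hom <- mothers
  hom$alleles[] <- hom$alleles[, rep(seq(1, 7, 2), each = 2)]
  fams0 <- simulate_progeny_arrays(hom, t_true = 0, offspring_per_family = 4,
                                   seed = 1)
  off_rows <- which(fams0$generation == "offspring")
  midx <- match(fams0$mother[off_rows], fams0$samples)
  expect_true(all(fams0$alleles[off_rows, , drop = FALSE] ==
                    fams0$alleles[midx, , drop = FALSE]))

  # full outcrossing: every offspring carries >= 1 maternal allele per locus
  fams1 <- simulate_progeny_arrays(mothers, t_true = 1,
                                   offspring_per_family = 4, seed = 2)
  off1_rows <- which(fams1$generation == "offspring")
  midx1 <- match(fams1$mother[off1_rows], fams1$samples)
  for (l in 1:4) {
    oa <- locus_alleles(fams1, l)[off1_rows, , drop = FALSE]
    ma <- locus_alleles(fams1, l)[midx1, , drop = FALSE]
    carries <- oa[, 1] == ma[, 1] | oa[, 1] == ma[, 2] |
      oa[, 2] == ma[, 1] | oa[, 2] == ma[, 2]
    expect_true(all(carries))
  }

  expect_error(simulate_progeny_arrays(
    genotype_table("m", "p", "parent", NA, cbind(0L, 0L), "l1"),
    t_true = 1, offspring_per_family = 2, seed = 1),
    "missing maternal genotypes")
})

test_that("trait model reproduces the one-parent regression slope", {
  cfg <- sim_config(n_pops = 1, parents_per_pop = 500, n_loci = 1,
                    alleles_per_locus = 2, seed = 5)
  p <- simulate_island_populations(cfg)
  fams <- simulate_progeny_arrays(p, t_true = 1, offspring_per_family = 4,
                                  seed = 6)

  # h2 = 1, no environment: slope is exactly the expectation 1/2 up to noise
  tt <- simulate_parent_offspring_trait(fams, h2_true = 1, env_sd = 0,
                                        trait_mean = 1, seed = 7)
  fit <- suppressWarnings(parent_offspring_regression(family_means(tt, fams)))
  expect_lt(abs(fit$slope - 0.5), 3 * fit$se)

  # h2 = 0: slope indistinguishable from 0
  tt0 <- simulate_parent_offspring_trait(fams, h2_true = 0, env_sd = 0.05,
                                         trait_mean = 1, seed = 8)
  fit0 <- suppressWarnings(parent_offspring_regression(family_means(tt0, fams)))
  expect_lt(abs(fit0$slope), 3 * fit0$se)

  expect_error(simulate_parent_offspring_trait(fams, h2_true = 1,
                                               env_sd = 0.1),
               "env_sd")
})

test_that("tree character simulation counts its own changes", {
  tr <- ape::rcoal(25)
  # zero rates: monomorphic at the root state, zero steps
  bc0 <- simulate_binary_character_on_tree(tr, 0, 0, seed = 1)
  expect_equal(length(unique(as.integer(bc0))), 1L)
  expect_equal(attr(bc0, "true_changes"), 0L)

  # realised changes bound parsimony steps from above
  for (s in 1:10) {
    bc <- simulate_binary_character_on_tree(tr, 1.5, 1.5, seed = s)
    if (length(unique(as.integer(bc))) < 2) next
    steps <- parsimony_steps(tr, bc, "hard")
    expect_gte(attr(bc, "true_changes"), steps)
  }

  ur <- ape::rcoal(5)
  ur$edge.length <- NULL
  expect_error(simulate_binary_character_on_tree(ur, 1, 1, seed = 1),
               "branch lengths")
})

test_that("saturating evolution erases phylogenetic signal", {
  # with rates high relative to every branch the tip states are nearly
  # independent and the reshuffle test should rarely call inertia
  tr <- ape::rtree(30)
  tr$edge.length <- rep(1, nrow(tr$edge))
  set.seed(11)
  notsmall <- 0; n_ok <- 0
  for (i in 1:100) {
    bc <- simulate_binary_character_on_tree(tr, 10, 10,
                                            seed = sample.int(1e6, 1))
    if (length(unique(as.integer(bc))) < 2) next
    n_ok <- n_ok + 1
    res <- character_reshuffle_test(tr, bc, n_reshuffles = 99,
                                    seed = sample.int(1e6, 1))
    if (res$p_value > 0.05) notsmall <- notsmall + 1
  }
  expect_gte(notsmall / n_ok, 0.9)
})
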