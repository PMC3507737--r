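make_arrays <- function(t_true, n_parents = 30, offspring = 4, n_loci = 6,
                        seed = 1) {
  cfg <- sim_config(n_pops = 1, parents_per_pop = n_parents,
                    n_loci = n_loci, alleles_per_locus = 8, theta = 0.1,
                    f_inbreeding = 0, seed = seed)
  p <- simulate_island_populations(cfg)
  simulate_progeny_arrays(p, t_true = t_true, offspring_per_family = offspring,
                          seed = seed + 1)
}

test_that("EM log-likelihood is monotone and estimates are deterministic", {
  fams <- make_arrays(0.7, seed = 3)
  e1 <- em_mating_system(fams)
  expect_true(all(diff(e1$ll_trace) >= -1e-8))
  e2 <- em_mating_system(fams)
  expect_identical(e1$tm, e2$tm)
  expect_true(e1$converged)
  expect_gte(e1$tm, 0); expect_lte(e1$tm, 1)
  expect_equal(e1$tm_minus_ts, e1$tm - e1$ts)
})

test_that("fully outcrossed and fully selfed arrays push t to the boundary", {
  fams1 <- make_arrays(1, seed = 5)
  expect_gt(em_mating_system(fams1)$tm, 0.9)
  fams0 <- make_arrays(0, seed = 6)
  expect_lt(em_mating_system(fams0)$tm, 0.1)
})

test_that("offspring with a non-maternal allele is certainly outcrossed", {
  # mother 1/1 at every locus, offspring carries allele 2: selfing
  # likelihood is zero, so the fitted outcrossing rate is driven to 1
  n_loci <- 3
  al_m <- matrix(1L, 2, 2 * n_loci)
  al_o <- matrix(rep(c(1L, 2L), n_loci), 4, 2 * n_loci, byrow = TRUE)
  gt <- genotype_table(c("m1", "m2", "o1", "o2", "o3", "o4"),
                       "p", c("parent", "parent", rep("offspring", 4)),
                       c(NA, NA, "m1", "m1", "m2", "m2"),
                       rbind(al_m, al_o), paste0("L", 1:n_loci))
  est <- em_mating_system(gt)
  expect_gt(est$tm, 0.999)
})

test_that("estimates are invariant to family order", {
  fams <- make_arrays(0.8, n_parents = 12, seed = 7)
  perm <- sample(seq_along(fams$samples))
  shuffled <- subset_genotypes(fams, perm)
  a <- em_mating_system(fams)
  b <- em_mating_system(shuffled)
  expect_equal(a$tm, b$tm, tolerance = 1e-8)
  expect_equal(a$ts, b$ts, tolerance = 1e-8)
  expect_equal(a$f_mat, b$f_mat, tolerance = 1e-6)
})

test_that("maternal inbreeding coefficient responds to inbred parents", {
  cfg_in <- sim_config(n_pops = 1, parents_per_pop = 60, n_loci = 8,
                       alleles_per_locus = 6, theta = 0.1,
                       f_inbreeding = 0.5, seed = 8)
  p_in <- simulate_island_populations(cfg_in)
  f_in <- simulate_progeny_arrays(p_in, 0.9, 2, seed = 9)
  cfg_out <- sim_config(n_pops = 1, parents_per_pop = 60, n_loci = 8,
                        alleles_per_locus = 6, theta = 0.1,
                        f_inbreeding = 0, seed = 8)
  p_out <- simulate_island_populations(cfg_out)
  f_out <- simulate_progeny_arrays(p_out, 0.9, 2, seed = 9)
  expect_gt(em_mating_system(f_in)$f_mat,
            em_mating_system(f_out)$f_mat + 0.2)
})

test_that("bootstrap SEs are seeded, and collapse for cloned families", {
  fams <- make_arrays(0.8, n_parents = 10, offspring = 3, seed = 11)
  b1 <- bootstrap_mating_system(fams, B = 15, seed = 2)
  b2 <- bootstrap_mating_system(fams, B = 15, seed = 2)
  expect_identical(b1$se, b2$se)
  expect_error(bootstrap_mating_system(fams, B = 1), "B must be")

  # identical replicated families: resampling cannot change the data much
  one <- subset_genotypes(fams, fams$samples %in% c(
    fams$samples[1], fams$samples[fams$mother %in% fams$samples[1]]))
  clones <- one
  for (k in 2:6) {
    copy <- one
    copy$samples <- paste0(one$samples, "_", k)
    copy$mother <- ifelse(is.na(one$mother), NA,
                          paste0(one$mother, "_", k))
    clones <- genotype_table(
      c(clones$samples, copy$samples),
      c(clones$population, copy$population),
      c(clones$generation, copy$generation),
      c(clones$mother, copy$mother),
      rbind(clones$alleles, copy$alleles), one$loci)
  }
  bc <- bootstrap_mating_system(clones, B = 10, seed = 3)
  expect_lt(bc$se[["tm"]], 1e-6)
})
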