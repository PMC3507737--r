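test_that("genotypic distance reproduces the canonical per-locus values", {
  gt <- genotype_table(letters[1:5], "p", "parent", NA,
                       rbind(c(1, 1), c(2, 2), c(2, 3), c(1, 2), c(1, 3)),
                       "L1")
  d <- genotypic_distance(gt)
  expect_equal(d["a", "a"], 0)   # AA-AA
  expect_equal(d["a", "b"], 4)   # AA-BB
  expect_equal(d["a", "c"], 3)   # AA-BC
  expect_equal(d["a", "d"], 1)   # AA-AB
  expect_equal(d["d", "e"], 1)   # AB-AC

  # additivity across loci
  gt2 <- genotype_table(c("x", "y"), "p", "parent", NA,
                        rbind(c(1, 1, 1, 1), c(2, 2, 2, 2)),
                        c("L1", "L2"))
  expect_equal(genotypic_distance(gt2)["x", "y"], 8)
})

test_that("genotypic distance agrees with the enumerated case table", {
  # every unordered genotype pair over 4 alleles, against an independent
  # classification of the pair type
  gen <- t(utils::combn(4, 2))
  gen <- rbind(cbind(1:4, 1:4), gen)  # 10 genotypes
  for (i in seq_len(nrow(gen))) for (j in seq_len(nrow(gen))) {
    gt <- genotype_table(c("a", "b"), "p", "parent", NA,
                         rbind(gen[i, ], gen[j, ]), "L1")
    expect_equal(unname(genotypic_distance(gt)["a", "b"]),
                 smouse_peakall_case(gen[i, ], gen[j, ]),
                 info = paste(gen[i, ], collapse = "/"))
  }
})

test_that("missing loci are dropped pairwise and empty overlap is flagged", {
  gt <- genotype_table(c("a", "b", "c"), "p", "parent", NA,
                       rbind(c(1, 1, 0, 0), c(2, 2, 1, 1), c(0, 0, 1, 2)),
                       c("L1", "L2"))
  d <- genotypic_distance(gt)
  expect_equal(d["a", "b"], 4)       # only L1 shared
  expect_equal(d["b", "c"], 1)       # only L2 shared
  expect_true(is.na(d["a", "c"]))    # no shared locus
  expect_true(attr(d, "incomplete"))
})

test_that("scalar distance handles traits, coordinates and the log transform", {
  d1 <- scalar_distance_matrix(c(a = 0.2, b = 0.5))
  expect_equal(d1["a", "b"], 0.3)
  xy <- rbind(p = c(0, 0), q = c(3, 4))
  expect_equal(scalar_distance_matrix(xy)["p", "q"], 5)
  dup <- rbind(p = c(0, 0), q = c(0, 0))
  expect_error(scalar_distance_matrix(dup, transform = "log"), "zero distance")
  dl <- scalar_distance_matrix(xy, transform = "log")
  expect_equal(dl["p", "q"], log(5))
})

test_that("PCoA recovers Euclidean configurations", {
  # collinear points: a single axis carries all variation
  d <- scalar_distance_matrix(c(a = 0, b = 1, c = 3))
  pc <- pcoa(d)
  expect_equal(pc$percent[1], 100)

  # Euclidean-embeddable input is reconstructed exactly
  set.seed(5)
  X <- matrix(rnorm(15 * 5), 15)
  dm <- distance_matrix(as.matrix(stats::dist(X)))
  pc2 <- pcoa(dm)
  rec <- as.matrix(stats::dist(pc2$coordinates))
  expect_lt(max(abs(rec - unclass(dm))), 1e-8)
  expect_equal(sum(pc2$percent), 100)
  expect_true(all(diff(pc2$eigenvalues) <= 1e-9))
})

test_that("PCoA matches the reference implementation in ape", {
  skip_if_not_installed("ape")
  set.seed(6)
  X <- matrix(rnorm(12 * 3), 12)
  dm <- distance_matrix(as.matrix(stats::dist(X)))
  mine <- pcoa(dm)
  ref <- ape::pcoa(as.dist(unclass(dm)))
  k <- min(ncol(mine$coordinates), ncol(ref$vectors))
  expect_equal(abs(mine$coordinates[, 1:k]), abs(ref$vectors[, 1:k]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("separated populations split on the first coordinate", {
  seps <- vapply(1:5, function(s) {
    cfg <- sim_config(n_pops = 2, parents_per_pop = 15, n_loci = 40,
                      alleles_per_locus = 6, theta = 0.5, seed = s)
    gt <- simulate_island_populations(cfg)
    pc <- pcoa(genotypic_distance(gt))
    ax1 <- pc$coordinates[, 1]
    g <- split(ax1, gt$population)
    abs(mean(g[[1]]) - mean(g[[2]])) /
      sqrt(mean(c(var(g[[1]]), var(g[[2]]))))
  }, numeric(1))
  expect_gt(median(seps), 4)
})

test_that("Mantel test behaves on identical, scaled and shuffled input", {
  set.seed(9)
  X <- matrix(rnorm(15 * 3), 15)
  d1 <- distance_matrix(as.matrix(stats::dist(X)))
  d2 <- distance_matrix(2 * unclass(d1))
  m <- mantel_test(d1, d2, n_permutations = 199, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 200)

  m1 <- mantel_test(d1, d2, n_permutations = 99, seed = 7)
  m2 <- mantel_test(d1, d2, n_permutations = 99, seed = 7)
  expect_identical(m1$p, m2$p)

  # r invariant to affine transforms of either matrix's entries
  d3 <- distance_matrix(as.matrix(stats::dist(matrix(rnorm(15 * 2), 15))))
  r_base <- mantel_test(d1, d3, 99, seed = 2)$r
  d3aff <- distance_matrix(0.5 * unclass(d3) + 3 -
                             diag(3, nrow(unclass(d3))))
  expect_equal(mantel_test(d1, d3aff, 99, seed = 2)$r, r_base)

  expect_error(mantel_test(d1, distance_matrix(matrix(0, 15, 15))),
               "constant matrix")
})

test_that("Mantel statistic agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(10)
  d1 <- distance_matrix(as.matrix(stats::dist(matrix(rnorm(18 * 3), 18))))
  d2 <- distance_matrix(as.matrix(stats::dist(matrix(rnorm(18 * 3), 18))))
  mine <- mantel_test(d1, d2, 99, seed = 1)
  ref <- vegan::mantel(stats::as.dist(unclass(d1)),
                       stats::as.dist(unclass(d2)), permutations = 49)
  expect_equal(mine$r, unname(ref$statistic))
})

test_that("synthetic gradient populations show isolation by distance", {
  set.seed(12)
  hits <- replicate(20, {
    cfg <- sim_config(n_pops = 6, parents_per_pop = 8, n_loci = 8,
                      alleles_per_locus = 6, theta = 0.3,
                      seed = sample.int(1e6, 1))
    gt <- simulate_island_populations(cfg)
    dgen <- genotypic_distance(gt)
    dgeo <- scalar_distance_matrix(cbind(gt$lon, gt$lat),
                                   transform = "log", labels = gt$samples)
    m <- mantel_test(dgen, dgeo, n_permutations = 99,
                     seed = sample.int(1e6, 1))
    m$r > 0 && m$p <= 0.05
  })
  expect_gte(mean(hits), 0.9)
})
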