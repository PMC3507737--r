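test_that("step counts match hand-computable cases", {
  t1 <- load_newick("((A,B),(C,D));")
  bc <- binary_character(c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(parsimony_steps(t1, bc, "soft"), 1L)
  expect_equal(parsimony_steps(t1, bc, "hard"), 1L)

  star <- load_newick("(A,B,C,D,E);")
  bs <- binary_character(c(A = 0, B = 0, C = 0, D = 1, E = 1))
  expect_equal(parsimony_steps(star, bs, "hard"), 2L)
  expect_equal(parsimony_steps(star, bs, "soft"), 1L)

  mono <- binary_character(c(A = 1, B = 1, C = 1, D = 1, E = 1))
  expect_equal(parsimony_steps(star, mono, "soft"), 0L)
  expect_error(parsimony_steps(t1, binary_character(c(A = 1, B = 0)),
                               "hard"),
               "tip without state")
})

test_that("soft steps never exceed hard steps and respect the minority bound", {
  set.seed(31)
  for (i in 1:40) {
    tr <- random_polytomous_tree(sample(5:12, 1))
    st <- setNames(sample(0:1, length(tr$tip.label), replace = TRUE),
                   tr$tip.label)
    if (length(unique(st)) < 2) next
    bc <- binary_character(st)
    soft <- parsimony_steps(tr, bc, "soft")
    hard <- parsimony_steps(tr, bc, "hard")
    expect_lte(soft, hard)
    expect_lte(hard, min(sum(st == 0), sum(st == 1)))
    expect_gte(soft, 1L)
  }
})

test_that("hard step counts agree with an independent Sankoff implementation", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (i in 1:20) {
    tr <- random_polytomous_tree(sample(5:10, 1))
    st <- setNames(sample(0:1, length(tr$tip.label), replace = TRUE),
                   tr$tip.label)
    if (length(unique(st)) < 2) next
    dat <- phangorn::phyDat(matrix(as.character(st), ncol = 1,
                                   dimnames = list(names(st), NULL)),
                            type = "USER", levels = c("0", "1"))
    ref <- as.integer(phangorn::parsimony(tr, dat, method = "sankoff"))
    expect_equal(parsimony_steps(tr, binary_character(st), "hard"), ref)
  }
})

test_that("maximum steps equals the brute-force maximum over arrangements", {
  set.seed(17)
  for (i in 1:15) {
    ntip <- sample(4:7, 1)
    tr <- random_polytomous_tree(ntip)
    n1 <- sample(seq_len(ntip - 1), 1)
    for (mode in c("hard", "soft")) {
      combs <- utils::combn(ntip, n1)
      best <- 0L
      for (j in seq_len(ncol(combs))) {
        st <- setNames(rep(0L, ntip), tr$tip.label)
        st[combs[, j]] <- 1L
        best <- max(best, parsimony_steps(tr, binary_character(st), mode))
      }
      expect_equal(max_parsimony_steps(tr, n1, mode), best)
    }
  }
})

test_that("homoplasy indices follow their defining formulas", {
  # a character needing a single step is homoplasy-free
  t1 <- load_newick("((A,B),(C,D));")
  h1 <- homoplasy_indices(t1, binary_character(c(A = 1, B = 1, C = 0, D = 0)))
  expect_equal(h1$ci, 1)
  expect_equal(h1$ri, 1)

  # resolved 6-tip tree, 3 present / 3 absent: g = min(3, 3) = 3
  t2 <- load_newick("(((A,B),(C,D)),(E,F));")
  st <- c(A = 1, B = 0, C = 1, D = 0, E = 1, F = 0)
  h2 <- homoplasy_indices(t2, binary_character(st))
  steps <- parsimony_steps(t2, binary_character(st), "soft")
  expect_equal(h2$max_steps, 3L)
  expect_equal(h2$ci, 1 / steps)
  expect_equal(h2$ri, (3 - steps) / (3 - 1))

  expect_error(homoplasy_indices(t1, binary_character(
    c(A = 1, B = 1, C = 1, D = 1))), "monomorphic")
})

test_that("reshuffle test is reproducible and preserves the state multiset", {
  tr <- ape::rcoal(20)
  bc <- simulate_binary_character_on_tree(tr, 0.8, 0.8, seed = 21)
  if (length(unique(as.integer(bc))) < 2)
    bc <- simulate_binary_character_on_tree(tr, 0.8, 0.8, seed = 22)
  r1 <- character_reshuffle_test(tr, bc, n_reshuffles = 200, seed = 5)
  r2 <- character_reshuffle_test(tr, bc, n_reshuffles = 200, seed = 5)
  expect_identical(r1$null_mean, r2$null_mean)
  expect_identical(r1$null_steps, r2$null_steps)
  expect_gte(r1$p_value, 1 / 201)
  expect_lte(r1$p_value, 1)
  # null steps stay within the bounds of the reshuffled multiset
  n1 <- sum(as.integer(bc) == 1)
  expect_true(all(r1$null_steps >= 1 &
                    r1$null_steps <= min(n1, 20 - n1)))
  expect_error(character_reshuffle_test(
    tr, binary_character(setNames(rep(1, 20), tr$tip.label))),
    "monomorphic")
})

test_that("reshuffle p-values are calibrated for exchangeable characters", {
  # when the observed character is itself a random arrangement, the
  # randomised-tie version of the permutation p-value is exactly uniform;
  # the reported add-one p must be conservative (>= the randomised one)
  tr <- ape::rcoal(22)
  set.seed(77)
  n1 <- 8
  p_rand <- numeric(200)
  for (i in 1:200) {
    st <- setNames(sample(c(rep(1L, n1), rep(0L, 22 - n1))), tr$tip.label)
    res <- character_reshuffle_test(tr, binary_character(st),
                                    n_reshuffles = 99,
                                    seed = sample.int(1e6, 1))
    nl <- res$null_steps
    obs <- res$observed_steps
    p_rand[i] <- (sum(nl < obs) + runif(1) * (1 + sum(nl == obs))) / 100
    expect_gte(res$p_value, (1 + sum(nl < obs)) / 100)
  }
  expect_gt(stats::ks.test(p_rand, "punif")$p.value, 0.01)
})
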