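# Independent oracles and fixture builders shared across tests.

# ---- brute-force soft-parsimony oracle ------------------------------------
# Trees as nested lists; tips are label strings. Enumerates every binary
# resolution of every polytomy (children treated as atomic units) and takes
# the minimum Fitch length. Exponential, only for small trees.

phylo_to_nested <- function(tree) {
  ntip <- length(tree$tip.label)
  ch <- vector("list", ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1]]] <- c(ch[[tree$edge[e, 1]]], tree$edge[e, 2])
  build <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    lapply(ch[[v]], build)
  }
  build(ntip + 1)
}

# all rooted binary shapes over n atomic items (insertion over index shapes,
# never descending into the items)
binary_shapes <- function(items) {
  subst <- function(shape) {
    if (!is.list(shape)) return(items[[shape]])
    list(subst(shape[[1]]), subst(shape[[2]]))
  }
  idx_shapes <- function(k) {
    if (k == 1) return(list(1L))
    if (k == 2) return(list(list(1L, 2L)))
    prev <- idx_shapes(k - 1)
    insert_all <- function(T, x) {
      res <- list(list(T, x))
      if (is.list(T)) {
        for (i in 1:2)
          for (R in insert_all(T[[i]], x)) {
            T2 <- T; T2[[i]] <- R
            res[[length(res) + 1]] <- T2
          }
      }
      res
    }
    out <- list()
    for (p in prev) out <- c(out, insert_all(p, k))
    out
  }
  lapply(idx_shapes(length(items)), subst)
}

all_resolutions <- function(node) {
  if (!is.list(node)) return(list(node))
  kid_res <- lapply(node, all_resolutions)
  combos <- expand.grid(lapply(kid_res, seq_along))
  out <- list()
  for (r in seq_len(nrow(combos))) {
    kids <- lapply(seq_along(kid_res),
                   function(i) kid_res[[i]][[combos[r, i]]])
    out <- c(out, binary_shapes(kids))
  }
  out
}

fitch_nested <- function(node, st) {
  if (!is.list(node)) return(list(set = st[[node]], cost = 0))
  a <- fitch_nested(node[[1]], st)
  b <- fitch_nested(node[[2]], st)
  i <- intersect(a$set, b$set)
  if (length(i)) list(set = i, cost = a$cost + b$cost)
  else list(set = union(a$set, b$set), cost = a$cost + b$cost + 1)
}

soft_parsimony_oracle <- function(tree, states) {
  nested <- phylo_to_nested(tree)
  min(vapply(all_resolutions(nested),
             function(r) fitch_nested(r, as.list(states))$cost, numeric(1)))
}

# random rooted tree with polytomies (collapse short internal edges)
random_polytomous_tree <- function(ntip, p_collapse = 0.6) {
  tr <- ape::rtree(ntip)
  tr$edge.length <- runif(nrow(tr$edge))
  internal <- tr$edge[, 2] > ntip
  tr$edge.length[internal] <-
    ifelse(runif(sum(internal)) < p_collapse, 0, 1)
  tr <- ape::di2multi(tr, tol = 0.5)
  tr$edge.length <- NULL
  tr
}

# ---- Smouse-Peakall squared-distance case table ---------------------------
# Independent of the package's count-vector implementation: classifies the
# genotype pair and returns the published per-locus value.
smouse_peakall_case <- function(g1, g2) {
  s1 <- sort(g1); s2 <- sort(g2)
  hom1 <- s1[1] == s1[2]; hom2 <- s2[1] == s2[2]
  shared <- length(intersect(s1, s2))
  if (identical(s1, s2)) return(0)              # AA-AA or AB-AB
  if (hom1 && hom2) return(4)                   # AA-BB
  if (hom1 != hom2) {                           # hom vs het
    if (shared >= 1) return(1)                  # AA-AB
    return(3)                                   # AA-BC
  }
  if (shared == 1) return(1)                    # AB-AC
  return(2)                                     # AB-CD
}

# ---- small fixtures --------------------------------------------------------
tiny_genotype_table <- function() {
  genotype_table(
    samples = c("m1", "m2", "o1", "o2"),
    population = "p1",
    generation = c("parent", "parent", "offspring", "offspring"),
    mother = c(NA, NA, "m1", "m1"),
    alleles = rbind(c(101, 103, 105, 105),
                    c(101, 101, 105, 107),
                    c(101, 103, 105, 107),
                    c(103, 103, 105, 105)),
    loci = c("locA", "locB"),
    lat = c(0, 0, 0, 0), lon = c(0, 1, 0, 0))
}

two_pop_fixed <- function(n_per = 10, n_loci = 11) {
  al <- matrix(0L, 2 * n_per, 2 * n_loci)
  al[1:n_per, ] <- 2L
  al[(n_per + 1):(2 * n_per), ] <- 4L
  genotype_table(paste0("s", seq_len(2 * n_per)),
                 rep(c("A", "B"), each = n_per), "parent", NA,
                 al, paste0("L", seq_len(n_loci)))
}

# slope p-value without lm, for fast permutation loops
slope_p <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), n - 2)
}
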