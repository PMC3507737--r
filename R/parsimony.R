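#' @keywords internal
#' Children list and postorder node sequence for a rooted phylo tree.
tree_structure <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  children <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge)))
    children[[tree$edge[e, 1L]]] <-
      c(children[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  if (any(lengths(children[(ntip + 1L):nnode]) < 2L))
    stop("internal nodes must have at least 2 children")
  # postorder: children before parents
  post <- integer(0)
  stack <- ntip + 1L  # root
  visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    visit <- c(visit, v)
    if (v > ntip) stack <- c(stack, children[[v]])
  }
  post <- rev(visit)
  list(ntip = ntip, nnode = nnode, children = children, postorder = post,
       root = ntip + 1L)
}

tip_states_for <- function(tree, char) {
  if (!all(tree$tip.label %in% names(char)))
    stop("tip without state: ",
         paste(setdiff(tree$tip.label, names(char)), collapse = ", "))
  as.integer(char[tree$tip.label])
}

#' Parsimony step count of a binary character, hard or soft polytomies
#'
#' `hard` counts the minimum number of state changes on the tree as given,
#' treating every multifurcation as a true simultaneous divergence
#' (unit-cost Sankoff, exact on multifurcating trees). `soft` treats every
#' multifurcation as unresolved and returns the exact minimum Fitch length
#' over all binary resolutions of every polytomy; for a two-state character
#' this minimum has a closed-form node recursion (children that prefer the
#' opposite state can always be grouped under a single stem change), so no
#' enumeration is needed.
#'
#' @param tree a rooted `phylo`; branch lengths are ignored.
#' @param char a [binary_character()] covering every tip.
#' @param mode `"soft"` or `"hard"`.
#' @return integer number of steps.
#' @export
parsimony_steps <- function(tree, char, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  ts <- tree_structure(tree)
  if (ts$ntip < 2L) stop("tree must have at least 2 tips")
  states <- tip_states_for(tree, char)
  big <- ts$ntip + 10L
  c0 <- c1 <- rep(big, ts$nnode)
  c0[seq_len(ts$ntip)] <- ifelse(states == 0L, 0L, big)
  c1[seq_len(ts$ntip)] <- ifelse(states == 1L, 0L, big)
  for (v in ts$postorder) {
    if (v <= ts$ntip) next
    ch <- ts$children[[v]]
    k0 <- pmin(c0[ch], big); k1 <- pmin(c1[ch], big)
    if (mode == "soft" && length(ch) >= 3L) {
      m <- pmin(k0, k1)
      c0[v] <- sum(m) + as.integer(any(k0 > m))
      c1[v] <- sum(m) + as.integer(any(k1 > m))
    } else {
      c0[v] <- sum(pmin(k0, k1 + 1L))
      c1[v] <- sum(pmin(k1, k0 + 1L))
    }
  }
  as.integer(min(c0[ts$root], c1[ts$root]))
}

#' Maximum parsimony steps over arrangements of the observed states
#'
#' The largest step count any permutation of the tip-state multiset can
#' require on this tree, under the same polytomy treatment as the observed
#' count. This is the `g` of the retention index. Computed by dynamic
#' programming over (number of "present" tips in the subtree, preferred root
#' state), maximising the subtree step count; on a fully resolved tree with
#' both states present it equals `min(n_present, n_absent)`.
#'
#' @inheritParams parsimony_steps
#' @param n_present number of tips carrying the derived (present) state.
#' @return integer maximum number of steps.
#' @export
max_parsimony_steps <- function(tree, n_present, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  ts <- tree_structure(tree)
  if (n_present < 0 || n_present > ts$ntip)
    stop("n_present out of range")
  NEG <- -1e9
  # per node: matrix (k+1) x 3 classes (1 = prefers 0, 2 = prefers 1,
  # 3 = indifferent), entry = max achievable subtree min-cost
  tab <- vector("list", ts$nnode)
  sub_tips <- integer(ts$nnode)
  for (v in ts$postorder) {
    if (v <= ts$ntip) {
      m <- matrix(NEG, 2L, 3L)
      m[1L, 1L] <- 0  # k = 0, tip absent
      m[2L, 2L] <- 0  # k = 1, tip present
      tab[[v]] <- m
      sub_tips[v] <- 1L
      next
    }
    ch <- ts$children[[v]]
    sub_tips[v] <- sum(sub_tips[ch])
    soft_node <- mode == "soft" && length(ch) >= 3L
    if (soft_node) {
      # partial state: (k, intersection of preferred-state sets) -> max sum(m)
      # subsets coded 1 = {0}, 2 = {1}, 3 = {0,1}, 4 = empty
      P <- matrix(NEG, 1L, 4L)
      P[1L, 3L] <- 0
      inter_op <- rbind(c(1L, 4L, 1L), c(4L, 2L, 2L), c(1L, 2L, 3L),
                        c(4L, 4L, 4L))
      kacc <- 0L
      for (w in ch) {
        Tw <- tab[[w]]
        kw <- nrow(Tw) - 1L
        Q <- matrix(NEG, kacc + kw + 1L, 4L)
        for (ka in 0L:kacc) for (ia in 1L:4L) {
          if (P[ka + 1L, ia] <= NEG) next
          for (kc in 0L:kw) for (cc in 1L:3L) {
            mv <- Tw[kc + 1L, cc]
            if (mv <= NEG) next
            ni <- inter_op[ia, cc]
            val <- P[ka + 1L, ia] + mv
            if (val > Q[ka + kc + 1L, ni]) Q[ka + kc + 1L, ni] <- val
          }
        }
        P <- Q; kacc <- kacc + kw
      }
      M <- matrix(NEG, kacc + 1L, 3L)
      for (k in 0L:kacc) {
        for (ia in 1L:3L)
          if (P[k + 1L, ia] > M[k + 1L, ia]) M[k + 1L, ia] <- P[k + 1L, ia]
        if (P[k + 1L, 4L] > NEG) {
          val <- P[k + 1L, 4L] + 1
          if (val > M[k + 1L, 3L]) M[k + 1L, 3L] <- val
        }
      }
      tab[[v]] <- M
    } else {
      # partial state: (k, a0 - a1) -> max min(a0, a1); Sankoff accumulation
      # child effective vectors: class1 (m, m+1), class2 (m+1, m), class3 (m,m)
      dmax <- length(ch)
      P <- matrix(NEG, 1L, 2L * dmax + 1L)  # diff index = d + dmax + 1
      P[1L, dmax + 1L] <- 0
      kacc <- 0L; dacc <- 0L
      for (w in ch) {
        Tw <- tab[[w]]
        kw <- nrow(Tw) - 1L
        Q <- matrix(NEG, kacc + kw + 1L, 2L * dmax + 1L)
        for (ka in 0L:kacc) for (di in seq_len(2L * dmax + 1L)) {
          base <- P[ka + 1L, di]
          if (base <= NEG) next
          d <- di - dmax - 1L
          a0 <- base + max(d, 0); a1 <- base + max(-d, 0)
          for (kc in 0L:kw) for (cc in 1L:3L) {
            mv <- Tw[kc + 1L, cc]
            if (mv <= NEG) next
            v0 <- mv + as.numeric(cc == 2L)
            v1 <- mv + as.numeric(cc == 1L)
            b0 <- a0 + v0; b1 <- a1 + v1
            nd <- b0 - b1
            nd <- max(min(nd, dmax), -dmax)
            val <- min(b0, b1)
            j <- nd + dmax + 1L
            if (val > Q[ka + kc + 1L, j]) Q[ka + kc + 1L, j] <- val
          }
        }
        P <- Q; kacc <- kacc + kw
      }
      M <- matrix(NEG, kacc + 1L, 3L)
      for (k in 0L:kacc) for (di in seq_len(2L * dmax + 1L)) {
        if (P[k + 1L, di] <= NEG) next
        d <- di - dmax - 1L
        cl <- if (d < 0L) 1L else if (d > 0L) 2L else 3L
        if (P[k + 1L, di] > M[k + 1L, cl]) M[k + 1L, cl] <- P[k + 1L, di]
      }
      tab[[v]] <- M
    }
  }
  M <- tab[[ts$root]]
  res <- max(M[n_present + 1L, ])
  if (res <= NEG) stop("no arrangement with that many present tips")
  as.integer(res)
}

#' Consistency and retention indices of a binary character
#'
#' CI = m / steps with m = 1 (a binary character with both states present
#' needs at least one change); RI = (g - steps) / (g - m) with g the maximum
#' steps any arrangement of the observed state multiset can require on this
#' tree (computed consistently with the polytomy `mode`).
#'
#' @inheritParams parsimony_steps
#' @param steps optionally precomputed observed steps.
#' @return list with `steps`, `min_steps`, `max_steps`, `ci`, `ri`.
#' @export
homoplasy_indices <- function(tree, char, mode = c("soft", "hard"),
                              steps = NULL) {
  mode <- match.arg(mode)
  states <- tip_states_for(tree, char)
  n1 <- sum(states == 1L)
  if (n1 == 0L || n1 == length(states))
    stop("monomorphic character: CI/RI undefined")
  if (is.null(steps)) steps <- parsimony_steps(tree, char, mode)
  m <- 1L
  g <- max_parsimony_steps(tree, n1, mode)
  list(steps = steps, min_steps = m, max_steps = g,
       ci = m / steps,
       ri = if (g > m) (g - steps) / (g - m) else NA_real_)
}

#' Character-reshuffle test of phylogenetic lability
#'
#' Compares the observed parsimony step count with a null distribution
#' obtained by randomly permuting the observed tip states among the tips,
#' preserving the state multiset. The one-sided alternative is "fewer steps
#' than random" (phylogenetic inertia), with the add-one permutation
#' convention `p = (1 + #\{null <= observed\}) / (n + 1)`.
#'
#' @inheritParams parsimony_steps
#' @param n_reshuffles number of random reshuffles (the study used 1000).
#' @param seed integer RNG seed.
#' @return list of class `lability_result`: observed steps, min/max steps,
#'   CI, RI, null mean/sd, reshuffle count, p-value, mode, seed.
#' @export
character_reshuffle_test <- function(tree, char, n_reshuffles = 1000,
                                     mode = c("soft", "hard"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_reshuffles >= 1)
  states <- tip_states_for(tree, char)
  if (length(unique(states)) < 2L)
    stop("monomorphic character: no test possible")
  obs <- parsimony_steps(tree, char, mode)
  hi <- homoplasy_indices(tree, char, mode, steps = obs)
  set.seed(seed)
  labs <- tree$tip.label
  null_steps <- vapply(seq_len(n_reshuffles), function(i) {
    perm <- binary_character(stats::setNames(sample(states), labs))
    parsimony_steps(tree, perm, mode)
  }, integer(1))
  structure(
    list(observed_steps = obs, min_steps = hi$min_steps,
         max_steps = hi$max_steps, ci = hi$ci, ri = hi$ri,
         null_mean = mean(null_steps), null_sd = stats::sd(null_steps),
         null_steps = null_steps, n_reshuffles = n_reshuffles,
         p_value = (1 + sum(null_steps <= obs)) / (n_reshuffles + 1),
         polytomy_mode = mode, seed = seed),
    class = "lability_result")
}

#' @export
print.lability_result <- function(x, ...) {
  cat(sprintf("Chemotype lability (%s polytomies)\n", x$polytomy_mode))
  cat(sprintf("  steps = %d (min %d, max %d)  CI = %.3f  RI = %.3f\n",
              x$observed_steps, x$min_steps, x$max_steps, x$ci, x$ri))
  cat(sprintf("  reshuffle null: mean = %.3f, sd = %.3f (n = %d)\n",
              x$null_mean, x$null_sd, x$n_reshuffles))
  cat(sprintf("  one-sided p (fewer steps than random) = %.4g\n", x$p_value))
  invisible(x)
}
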