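#' @keywords internal
#' Recode a genotype table as per-locus integer allele matrices (NA = missing).
allele_codes <- function(gt) {
  lapply(seq_along(gt$loci), function(l) {
    al <- locus_alleles(gt, l)
    codes <- sort(unique(al[al > 0L]))
    m <- matrix(match(al, codes), ncol = 2L)
    m[al == 0L] <- NA_integer_
    list(codes = codes, K = length(codes), idx = m)
  })
}

rdirichlet_rows <- function(alpha_mat) {
  x <- matrix(stats::rgamma(length(alpha_mat), shape = alpha_mat, rate = 1),
              nrow = nrow(alpha_mat))
  x <- pmax(x, 1e-300)
  x / rowSums(x)
}

admix_deviance <- function(ac, Q, P) {
  dev <- 0
  for (l in seq_along(ac)) {
    for (cpy in 1:2) {
      a <- ac[[l]]$idx[, cpy]
      ok <- !is.na(a)
      like <- rowSums(Q[ok, , drop = FALSE] *
                        t(P[[l]][, a[ok], drop = FALSE]))
      dev <- dev - 2 * sum(log(pmax(like, 1e-300)))
    }
  }
  dev
}

#' Bayesian admixture clustering by Gibbs sampling
#'
#' The standard non-spatial admixture model with uncorrelated allele
#' frequencies: each allele copy of individual i originates from cluster z
#' with probability `Q[i, z]`, and is then drawn from that cluster's allele
#' frequencies at its locus. Priors are `Q[i, ] ~ Dirichlet(alpha)` and
#' `P[z, l, ] ~ Dirichlet(1)`; the sampler alternates the latent origins z,
#' P, and Q. The deviance `-2 log L` is recorded every post-burn-in sweep
#' and `DIC = mean(D) + (mean(D) - D(posterior mean))`. Missing allele
#' copies contribute nothing to the likelihood.
#'
#' @param genotypes a [genotype_table()].
#' @param k number of clusters (>= 1, <= sample count).
#' @param sweeps total Gibbs sweeps (> burn_in).
#' @param burn_in sweeps discarded before accumulating posterior means.
#' @param alpha Dirichlet concentration of the admixture prior.
#' @param seed integer RNG seed.
#' @return list of class `admixture_run`: `k`, `Q` (posterior mean, rows on
#'   the simplex), `P` (per locus, cluster x allele posterior means),
#'   `deviance` trace, `dic`, `sweeps`, `burn_in`, `seed`.
#' @export
gibbs_admixture <- function(genotypes, k, sweeps = 600, burn_in = 200,
                            alpha = 1, seed = 1L) {
  gt <- genotypes
  n <- length(gt$samples)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds sample count")
  if (sweeps <= burn_in || burn_in < 0) stop("need sweeps > burn_in >= 0")
  set.seed(seed)
  ac <- allele_codes(gt)
  L <- length(ac)
  Q <- matrix(1 / k, n, k)
  P <- lapply(ac, function(a) rdirichlet_rows(matrix(1, k, a$K)))
  z <- lapply(ac, function(a)
    matrix(sample.int(k, 2L * n, replace = TRUE), n, 2L))
  Qsum <- matrix(0, n, k)
  Psum <- lapply(ac, function(a) matrix(0, k, a$K))
  dev_trace <- numeric(0)
  kept <- 0L
  for (s in seq_len(sweeps)) {
    cluster_counts <- matrix(0, n, k)
    for (l in seq_len(L)) {
      acnt <- matrix(0, k, ac[[l]]$K)
      for (cpy in 1:2) {
        a <- ac[[l]]$idx[, cpy]
        ok <- which(!is.na(a))
        if (length(ok)) {
          w <- Q[ok, , drop = FALSE] * t(P[[l]][, a[ok], drop = FALSE])
          # rowwise categorical draw via inverse CDF
          cw <- w / rowSums(w)
          if (k > 1L) {
            cum <- t(apply(cw, 1L, cumsum))
            u <- stats::runif(length(ok))
            zi <- max.col(cum >= u, ties.method = "first")
          } else zi <- rep(1L, length(ok))
          z[[l]][ok, cpy] <- zi
          ii <- cbind(zi, a[ok])
          for (r in seq_len(nrow(ii)))
            acnt[ii[r, 1L], ii[r, 2L]] <- acnt[ii[r, 1L], ii[r, 2L]] + 1
          cluster_counts[cbind(ok, zi)] <- cluster_counts[cbind(ok, zi)] + 1
        }
      }
      P[[l]] <- rdirichlet_rows(1 + acnt)
    }
    Q <- rdirichlet_rows(alpha + cluster_counts)
    if (s > burn_in) {
      kept <- kept + 1L
      Qsum <- Qsum + Q
      for (l in seq_len(L)) Psum[[l]] <- Psum[[l]] + P[[l]]
      dev_trace <- c(dev_trace, admix_deviance(ac, Q, P))
    }
  }
  Qbar <- Qsum / kept
  Pbar <- lapply(seq_len(L), function(l) {
    m <- Psum[[l]] / kept
    colnames(m) <- ac[[l]]$codes
    m
  })
  names(Pbar) <- gt$loci
  rownames(Qbar) <- gt$samples
  dbar <- mean(dev_trace)
  dhat <- admix_deviance(ac, Qbar, Pbar)
  structure(list(k = k, Q = Qbar, P = Pbar, deviance = dev_trace,
                 dic = dbar + (dbar - dhat), sweeps = sweeps,
                 burn_in = burn_in, alpha = alpha, seed = seed),
            class = "admixture_run")
}

#' Choose the number of clusters from a DIC curve
#'
#' Reports the mean DIC per k and applies an elbow rule: the chosen k is the
#' smallest k whose improvement when moving to the next k falls below
#' `frac` of the total DIC range (the "approach an asymptote" reading of a
#' DIC-vs-k plot). A flat curve yields the smallest k. All DIC values are
#' returned so the curve can be inspected, as practitioners normally do.
#'
#' @param runs list of `admixture_run` objects (>= 2 distinct k), or a named
#'   numeric vector of DIC values with k as names.
#' @param frac improvement threshold as a fraction of the DIC range.
#' @return list of class `k_selection`: `k`, `dic` (mean per k), `frac`.
#' @export
select_k <- function(runs, frac = 0.05) {
  if (is.numeric(runs)) {
    dic <- runs
    ks <- as.integer(names(dic))
  } else {
    ks_all <- vapply(runs, function(r) r$k, numeric(1))
    dic_all <- vapply(runs, function(r) r$dic, numeric(1))
    ks <- sort(unique(ks_all))
    dic <- vapply(ks, function(k) mean(dic_all[ks_all == k]), numeric(1))
  }
  if (length(ks) < 2L) stop("need at least two values of k")
  o <- order(ks)
  ks <- ks[o]; dic <- dic[o]
  rng <- max(dic) - min(dic)
  chosen <- ks[length(ks)]
  if (rng <= 0) {
    chosen <- ks[1L]
  } else {
    improve <- -diff(dic)  # improvement moving from ks[i] to ks[i + 1]
    below <- which(improve < frac * rng)
    if (length(below)) chosen <- ks[min(below)]
  }
  structure(list(k = chosen, dic = stats::setNames(dic, ks), frac = frac),
            class = "k_selection")
}

all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Align cluster labels across replicate admixture runs
#'
#' Cluster labels are arbitrary per run; this finds, for each run, the label
#' permutation maximising the summed dot product between its Q rows and the
#' first run's (exhaustive over all k! permutations for k <= 8, greedy
#' column matching beyond), then averages the aligned Q matrices into a
#' consensus — the Greedy strategy of the CLUMPP label-alignment approach.
#'
#' @param runs list of >= 2 `admixture_run` objects (or bare Q matrices)
#'   with identical samples and k.
#' @return list of class `aligned_runs`: `consensus` Q, `permutations`
#'   (one per run), `scores` (alignment score per run).
#' @export
align_runs <- function(runs) {
  Qs <- lapply(runs, function(r) if (is.list(r)) r$Q else r)
  if (length(Qs) < 2L) stop("need at least two runs")
  k <- ncol(Qs[[1L]])
  ref <- Qs[[1L]]
  for (q in Qs) {
    if (!identical(dim(q), dim(ref)))
      stop("runs differ in samples or k")
    if (!is.null(rownames(q)) && !identical(rownames(q), rownames(ref)))
      stop("mismatched sample sets")
  }
  perms <- vector("list", length(Qs))
  scores <- numeric(length(Qs))
  perms[[1L]] <- seq_len(k)
  scores[1L] <- sum(ref * ref)
  acc <- ref
  for (i in seq_along(Qs)[-1L]) {
    G <- crossprod(ref, Qs[[i]])  # G[a, b] = sum_j ref[j,a] * Q[j,b]
    if (k <= 8L) {
      best <- NULL; bs <- -Inf
      for (p in all_perms(k)) {
        s <- sum(G[cbind(seq_len(k), p)])
        if (s > bs) { bs <- s; best <- p }
      }
    } else {
      best <- integer(k); used_row <- logical(k); used_col <- logical(k)
      for (step in seq_len(k)) {
        Gm <- G
        Gm[used_row, ] <- -Inf
        Gm[, used_col] <- -Inf
        idx <- which(Gm == max(Gm), arr.ind = TRUE)[1L, ]
        best[idx[1L]] <- idx[2L]
        used_row[idx[1L]] <- TRUE; used_col[idx[2L]] <- TRUE
      }
    }
    perms[[i]] <- best
    scores[i] <- sum(G[cbind(seq_len(k), best)])
    acc <- acc + Qs[[i]][, best, drop = FALSE]
  }
  consensus <- acc / length(Qs)
  consensus <- consensus / rowSums(consensus)
  dimnames(consensus) <- dimnames(ref)
  structure(list(consensus = consensus, permutations = perms,
                 scores = scores, k = k, n_runs = length(Qs)),
            class = "aligned_runs")
}
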