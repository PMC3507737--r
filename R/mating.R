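#' @keywords internal
#' Precompute per-offspring, per-locus likelihood ingredients for the mixed
#' mating model: selfing genotype probabilities (constants) and the
#' outcross probability as a sparse linear function of pollen frequencies
#' (at most two allele coefficients per offspring-locus).
mating_prep <- function(gt) {
  off <- which(gt$generation == "offspring" & !is.na(gt$mother))
  if (length(off) == 0L) stop("no offspring with mother links")
  moms <- unique(gt$mother[off])
  midx <- match(moms, gt$samples)
  if (anyNA(midx)) stop("unresolved mother IDs")
  mom_all <- gt$alleles[midx, , drop = FALSE]
  if (any(mom_all == 0L)) stop("missing maternal genotypes")
  fam_of <- match(gt$mother[off], moms)
  L <- length(gt$loci)
  loci <- vector("list", L)
  for (l in seq_len(L)) {
    oa <- locus_alleles(gt, l)[off, , drop = FALSE]
    ma <- mom_all[, c(2L * l - 1L, 2L * l), drop = FALSE][fam_of, ,
                                                          drop = FALSE]
    codes <- sort(unique(c(ma[ma > 0L], oa[oa > 0L])))
    K <- length(codes)
    x <- pmin(oa[, 1L], oa[, 2L]); y <- pmax(oa[, 1L], oa[, 2L])
    g1 <- pmin(ma[, 1L], ma[, 2L]); g2 <- pmax(ma[, 1L], ma[, 2L])
    miss <- x == 0L
    het <- g1 != g2
    selfp <- numeric(length(x))
    # selfing: Mendelian from the mother
    selfp[!het] <- as.numeric(x[!het] == g1[!het] & y[!het] == g1[!het])
    hh <- which(het)
    selfp[hh] <- ifelse(
      x[hh] == y[hh],
      0.25 * (x[hh] == g1[hh] | x[hh] == g2[hh]),
      0.5 * (x[hh] == g1[hh] & y[hh] == g2[hh]))
    # outcross: one maternal gamete (1/2 each if het), one pollen allele
    pm <- ifelse(het, 0.5, 1)
    i1 <- i2 <- integer(length(x))
    co1 <- co2 <- numeric(length(x))
    hom_o <- x == y & !miss
    # offspring homozygous {x,x}: maternal gamete must be x
    can <- hom_o & (x == g1 | x == g2)
    i1[can] <- match(x[can], codes)
    co1[can] <- pm[can] * ifelse(het[can] & x[can] == g1[can] &
                                   x[can] == g2[can], 2, 1)
    het_o <- x != y & !miss
    m_x <- het_o & (x == g1 | x == g2)  # maternal gamete x, pollen y
    i1[m_x] <- match(y[m_x], codes)
    co1[m_x] <- pm[m_x]
    m_y <- het_o & (y == g1 | y == g2)  # maternal gamete y, pollen x
    i2[m_y] <- match(x[m_y], codes)
    co2[m_y] <- pm[m_y]
    selfp[miss] <- 1; i1[miss] <- 0L; i2[miss] <- 0L
    # pollen initialised from the parental allele pool
    par_idx <- which(gt$generation == "parent")
    pa <- locus_alleles(gt, l)[par_idx, , drop = FALSE]
    pa <- pa[pa > 0L]
    cnt <- as.numeric(table(factor(pa, levels = codes))) + 1
    loci[[l]] <- list(codes = codes, K = K, selfp = selfp, i1 = i1, i2 = i2,
                      co1 = co1, co2 = co2, miss = miss,
                      p_init = cnt / sum(cnt))
  }
  # an offspring carrying no maternal allele at some locus is impossible
  # under both mixture components (a genotyping error, not a mating event):
  # drop it rather than distort the likelihood
  impossible <- rep(FALSE, length(off))
  for (l in seq_len(L)) {
    lc <- loci[[l]]
    impossible <- impossible |
      (lc$selfp == 0 & lc$i1 == 0L & lc$i2 == 0L & !lc$miss)
  }
  if (any(impossible)) {
    warning(sum(impossible),
            " offspring impossible under the mating model dropped")
    keep <- !impossible
    loci <- lapply(loci, function(lc) {
      for (nm in c("selfp", "i1", "i2", "co1", "co2", "miss"))
        lc[[nm]] <- lc[[nm]][keep]
      lc
    })
    fam_of <- fam_of[keep]
    off <- off[keep]
  }
  list(loci = loci, n_off = length(off), fam_of = fam_of, moms = moms,
       mom_alleles = mom_all, n_loci = L)
}

outcross_prob <- function(lc, p, idx) {
  v <- numeric(length(idx))
  h1 <- lc$i1[idx] > 0L
  v[h1] <- lc$co1[idx][h1] * p[lc$i1[idx][h1]]
  h2 <- lc$i2[idx] > 0L
  v[h2] <- v[h2] + lc$co2[idx][h2] * p[lc$i2[idx][h2]]
  v[lc$miss[idx]] <- 1
  v
}

em_core <- function(prep, which_loci, off_idx, max_iter, tol, eps) {
  t_hat <- 0.9
  pf <- lapply(prep$loci[which_loci], function(lc) lc$p_init)
  nl <- length(which_loci)
  n <- length(off_idx)
  Lself <- rep(1, n)
  for (j in seq_len(nl))
    Lself <- Lself * prep$loci[[which_loci[j]]]$selfp[off_idx]
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Lout <- rep(1, n)
    for (j in seq_len(nl))
      Lout <- Lout * outcross_prob(prep$loci[[which_loci[j]]], pf[[j]],
                                   off_idx)
    mix <- t_hat * Lout + (1 - t_hat) * Lself
    bad <- mix <= 0
    w <- ifelse(bad, 0.5, t_hat * Lout / pmax(mix, 1e-300))
    ll <- sum(log(pmax(mix, 1e-300)))
    ll_trace <- c(ll_trace, ll)
    if (ll < ll_old - 1e-8)
      stop("EM log-likelihood decreased: internal error")
    # M-step
    t_hat <- mean(w)
    t_hat <- min(max(t_hat, 1e-9), 1 - 1e-9)
    for (j in seq_len(nl)) {
      lc <- prep$loci[[which_loci[j]]]
      p <- pf[[j]]
      pl <- outcross_prob(lc, p, off_idx)
      cnt <- rep(eps, lc$K)
      h1 <- lc$i1[off_idx] > 0L & !lc$miss[off_idx] & pl > 0
      if (any(h1)) {
        a <- lc$i1[off_idx][h1]
        wt <- w[h1] * lc$co1[off_idx][h1] * p[a] / pl[h1]
        cnt <- cnt + as.numeric(tapply(wt, factor(a, levels = seq_len(lc$K)),
                                       sum, default = 0))
      }
      h2 <- lc$i2[off_idx] > 0L & !lc$miss[off_idx] & pl > 0
      if (any(h2)) {
        a <- lc$i2[off_idx][h2]
        wt <- w[h2] * lc$co2[off_idx][h2] * p[a] / pl[h2]
        cnt <- cnt + as.numeric(tapply(wt, factor(a, levels = seq_len(lc$K)),
                                       sum, default = 0))
      }
      pf[[j]] <- cnt / sum(cnt)
    }
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(t = t_hat, pollen = pf, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, iterations = length(ll_trace),
       converged = converged)
}

fmat_mle <- function(mom_alleles, n_loci) {
  ll_of_f <- function(f) {
    tot <- 0
    for (l in seq_len(n_loci)) {
      a <- mom_alleles[, c(2L * l - 1L, 2L * l), drop = FALSE]
      codes <- sort(unique(as.vector(a)))
      p <- as.numeric(table(factor(as.vector(a), levels = codes))) /
        (2 * nrow(a))
      i1 <- match(a[, 1L], codes); i2 <- match(a[, 2L], codes)
      hom <- i1 == i2
      pr <- ifelse(hom, p[i1]^2 + f * p[i1] * (1 - p[i1]),
                   2 * p[i1] * p[i2] * (1 - f))
      tot <- tot + sum(log(pmax(pr, 1e-12)))
    }
    tot
  }
  stats::optimize(ll_of_f, interval = c(-0.999, 0.999), maximum = TRUE)$maximum
}

#' Mixed-mating-system estimation from maternal progeny arrays
#'
#' EM estimation of the multilocus outcrossing rate `tm` under the mixture
#' model: an offspring is selfed with probability `1 - t` (both gametes
#' Mendelian from its known mother) or outcrossed with probability `t` (one
#' maternal gamete, one pollen allele from pollen-pool frequencies, which
#' are estimated jointly in the M-step). Single-locus rates are estimated by
#' the same EM per locus and averaged (unweighted) into `ts`; `tm - ts`
#' estimates biparental inbreeding. The maternal inbreeding coefficient
#' `F_mat` is maximised separately from the maternal genotypes under
#' `P(hom) = p^2 + F p (1 - p)`, `P(het) = 2 p q (1 - F)`.
#'
#' @param genotypes a [genotype_table()] with offspring carrying `mother`
#'   links; maternal genotypes must be complete.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param eps additive smoothing for pollen allele counts (guards alleles
#'   absent from the posterior-weighted outcross gametes).
#' @return list of class `mating_estimate`: `tm`, `ts`, `tm_minus_ts`,
#'   `f_mat`, `pollen_freqs`, `n_families`, `n_offspring`, `loglik`,
#'   `ll_trace`, `iterations`, `converged`.
#' @export
em_mating_system <- function(genotypes, max_iter = 500, tol = 1e-6,
                             eps = 1e-6) {
  prep <- mating_prep(genotypes)
  all_off <- seq_len(prep$n_off)
  ml <- em_core(prep, seq_len(prep$n_loci), all_off, max_iter, tol, eps)
  t_l <- vapply(seq_len(prep$n_loci), function(l)
    em_core(prep, l, all_off, max_iter, tol, eps)$t, numeric(1))
  ts <- mean(t_l)
  fm <- fmat_mle(prep$mom_alleles, prep$n_loci)
  pollen <- lapply(seq_len(prep$n_loci), function(l)
    stats::setNames(ml$pollen[[l]], prep$loci[[l]]$codes))
  structure(list(tm = ml$t, ts = ts, tm_minus_ts = ml$t - ts,
                 ts_per_locus = t_l, f_mat = fm, pollen_freqs = pollen,
                 n_families = length(prep$moms), n_offspring = prep$n_off,
                 loglik = ml$loglik, ll_trace = ml$ll_trace,
                 iterations = ml$iterations, converged = ml$converged),
            class = "mating_estimate")
}

#' @export
print.mating_estimate <- function(x, ...) {
  cat(sprintf(
    "Mating system (%d families, %d offspring):\n  tm = %.3f  ts = %.3f  tm - ts = %.3f  F_mat = %.3f\n  logL = %.2f after %d EM iterations (%sconverged)\n",
    x$n_families, x$n_offspring, x$tm, x$ts, x$tm_minus_ts, x$f_mat,
    x$loglik, x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Per-population mating-system estimates
#'
#' Runs the EM separately within each population (each has its own pollen
#' pool, so pooling populations would misstate the outcross likelihood and
#' bias the rates), with optional family-bootstrap standard errors.
#' Populations without usable progeny arrays are skipped.
#'
#' @inheritParams em_mating_system
#' @param B bootstrap replicates for SEs (0 skips the bootstrap).
#' @param seed integer RNG seed for the bootstrap.
#' @return data.frame with one row per population: `n_families`,
#'   `n_offspring`, `tm`, `ts`, `tm_minus_ts`, `f_mat` and (when `B > 1`)
#'   their bootstrap SEs.
#' @export
mating_system_by_population <- function(genotypes, B = 0, seed = 1L,
                                        max_iter = 500, tol = 1e-6,
                                        eps = 1e-6) {
  out <- list()
  for (popn in unique(genotypes$population)) {
    sub <- subset_genotypes(genotypes, genotypes$population == popn)
    est <- tryCatch(em_mating_system(sub, max_iter, tol, eps),
                    error = function(e) NULL)
    if (is.null(est)) next
    row <- data.frame(population = popn, n_families = est$n_families,
                      n_offspring = est$n_offspring, tm = est$tm,
                      ts = est$ts, tm_minus_ts = est$tm_minus_ts,
                      f_mat = est$f_mat, stringsAsFactors = FALSE)
    if (B > 1) {
      bt <- bootstrap_mating_system(sub, B = B, seed = seed,
                                    max_iter = min(max_iter, 200),
                                    tol = max(tol, 1e-5), eps = eps)
      row$tm_se <- bt$se[["tm"]]
      row$ts_se <- bt$se[["ts"]]
      row$tm_minus_ts_se <- bt$se[["tm_minus_ts"]]
      row$f_mat_se <- bt$se[["f_mat"]]
    }
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0L) stop("no population with usable progeny arrays")
  do.call(rbind, out)
}

#' Bootstrap standard errors for mating-system estimates
#'
#' Resamples maternal families with replacement, re-runs the EM on each
#' resample, and reports the standard deviation of the bootstrap estimates.
#'
#' @inheritParams em_mating_system
#' @param B bootstrap replicates (>= 2).
#' @param seed integer RNG seed.
#' @return list with `se` (named: tm, ts, tm_minus_ts, f_mat), `boot`
#'   (B x 4 matrix of replicate estimates), `B`, `seed`.
#' @export
bootstrap_mating_system <- function(genotypes, B = 1000, seed = 1L,
                                    max_iter = 200, tol = 1e-5,
                                    eps = 1e-6) {
  if (B < 2) stop("B must be >= 2")
  prep <- mating_prep(genotypes)
  if (length(prep$moms) < 2) stop("need >= 2 families")
  set.seed(seed)
  fam_members <- split(seq_len(prep$n_off), prep$fam_of)
  est <- matrix(NA_real_, B, 4,
                dimnames = list(NULL, c("tm", "ts", "tm_minus_ts", "f_mat")))
  for (b in seq_len(B)) {
    fams <- sample.int(length(prep$moms), replace = TRUE)
    off_idx <- unlist(fam_members[fams], use.names = FALSE)
    ml <- em_core(prep, seq_len(prep$n_loci), off_idx, max_iter, tol, eps)
    t_l <- vapply(seq_len(prep$n_loci), function(l)
      em_core(prep, l, off_idx, max_iter, tol, eps)$t, numeric(1))
    mom_rows <- prep$mom_alleles[fams, , drop = FALSE]
    est[b, ] <- c(ml$t, mean(t_l), ml$t - mean(t_l),
                  fmat_mle(mom_rows, prep$n_loci))
  }
  list(se = apply(est, 2, stats::sd), boot = est, B = B, seed = seed)
}
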