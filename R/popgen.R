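#' Per-locus summary statistics by population
#'
#' For each (population, locus) cell with at least one non-missing genotype:
#' sample size `n`, allele count `na`, observed heterozygosity `ho`,
#' expected heterozygosity `he = 1 - sum(p^2)` from sample allele
#' frequencies (no small-sample correction, matching the convention of the
#' standard microsatellite toolkits), and fixation index `f = 1 - ho / he`
#' (`NA` when `he = 0`). Cells without data are emitted with `n = 0` and
#' missing statistics.
#'
#' @param genotypes a [genotype_table()].
#' @param generation restrict to `"parent"`, `"offspring"`, or `"all"`.
#'   Population-variation analyses conventionally use parents only.
#' @return data.frame with one row per (population, locus).
#' @export
per_locus_stats <- function(genotypes, generation = "parent") {
  gt <- genotypes
  if (generation != "all")
    gt <- subset_genotypes(gt, gt$generation == generation)
  if (length(gt$samples) == 0L) stop("empty genotype table")
  pops <- unique(gt$population)
  out <- list()
  for (popn in pops) {
    rows <- gt$population == popn
    for (l in seq_along(gt$loci)) {
      al <- locus_alleles(gt, l)[rows, , drop = FALSE]
      ok <- al[, 1L] > 0L
      n <- sum(ok)
      if (n == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          population = popn, locus = gt$loci[l], n = 0L, na = NA_integer_,
          ho = NA_real_, he = NA_real_, f = NA_real_)
        next
      }
      a <- al[ok, , drop = FALSE]
      p <- as.numeric(table(c(a[, 1L], a[, 2L]))) / (2 * n)
      he <- 1 - sum(p^2)
      ho <- mean(a[, 1L] != a[, 2L])
      out[[length(out) + 1L]] <- data.frame(
        population = popn, locus = gt$loci[l], n = n, na = length(p),
        ho = ho, he = he, f = if (he > 0) 1 - ho / he else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Population means and standard errors across loci
#'
#' Averages `na`, `ho`, `he` and `f` across loci within each population,
#' with the standard error `sd / sqrt(n_loci)`. `f` is averaged over the
#' per-locus fixation indices (not recomputed from mean ho/he), matching
#' how the per-population fixation index is conventionally tabulated.
#'
#' @param locus_stats data.frame from [per_locus_stats()].
#' @return data.frame, one row per population, columns `<stat>_mean` and
#'   `<stat>_se`.
#' @export
population_summary <- function(locus_stats) {
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  do.call(rbind, lapply(split(locus_stats, locus_stats$population),
    function(d) {
      s <- vapply(d[c("na", "ho", "he", "f")], msd, numeric(2))
      data.frame(population = d$population[1L],
                 n = round(mean(d$n[d$n > 0])),
                 na_mean = s["mean", "na"], na_se = s["se", "na"],
                 ho_mean = s["mean", "ho"], ho_se = s["se", "ho"],
                 he_mean = s["mean", "he"], he_se = s["se", "he"],
                 f_mean = s["mean", "f"], f_se = s["se", "f"],
                 stringsAsFactors = FALSE)
    }))
}

#' Chi-square test for Hardy-Weinberg equilibrium at one locus
#'
#' Expected genotype counts come from sample allele frequencies
#' (`n * p_i^2` for homozygotes, `2 n p_i p_j` for heterozygotes) over all
#' `k (k + 1) / 2` genotype classes, with `df = k (k - 1) / 2`. Rare classes
#' are not pooled.
#'
#' @param alleles two-column integer matrix of allele pairs (rows with 0 are
#'   dropped as missing).
#' @return list with `chi2`, `df`, `p`, `n`, `k` (allele count).
#' @export
hwe_chi_square <- function(alleles) {
  a <- alleles[alleles[, 1L] > 0L, , drop = FALSE]
  n <- nrow(a)
  codes <- sort(unique(c(a[, 1L], a[, 2L])))
  k <- length(codes)
  if (k < 2L) stop("monomorphic locus: HWE test undefined")
  p <- as.numeric(table(factor(c(a[, 1L], a[, 2L]), levels = codes))) / (2 * n)
  i1 <- match(pmin(a[, 1L], a[, 2L]), codes)
  i2 <- match(pmax(a[, 1L], a[, 2L]), codes)
  chi2 <- 0
  for (i in seq_len(k)) for (j in i:k) {
    obs <- sum(i1 == i & i2 == j)
    exp <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
    if (exp > 0) chi2 <- chi2 + (obs - exp)^2 / exp
  }
  df <- k * (k - 1L) / 2L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       n = n, k = k)
}

#' HWE tests for every (population, locus) cell
#'
#' @param genotypes a [genotype_table()].
#' @param generation as in [per_locus_stats()].
#' @param alpha nominal significance level, Dunn-Sidak corrected for the
#'   number of testable cells.
#' @return data.frame of tests with the corrected alpha as attribute
#'   `"alpha_corrected"` and a `significant` flag at that level.
#' @export
hwe_test_table <- function(genotypes, generation = "parent", alpha = 0.05) {
  gt <- genotypes
  if (generation != "all")
    gt <- subset_genotypes(gt, gt$generation == generation)
  out <- list()
  for (popn in unique(gt$population)) {
    rows <- gt$population == popn
    for (l in seq_along(gt$loci)) {
      al <- locus_alleles(gt, l)[rows, , drop = FALSE]
      res <- tryCatch(hwe_chi_square(al), error = function(e) NULL)
      if (is.null(res)) next
      out[[length(out) + 1L]] <- data.frame(
        population = popn, locus = gt$loci[l], n = res$n, k = res$k,
        chi2 = res$chi2, df = res$df, p = res$p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  a_corr <- sidak_alpha(alpha, nrow(tab))
  tab$significant <- tab$p < a_corr
  attr(tab, "alpha_corrected") <- a_corr
  attr(tab, "n_tests") <- nrow(tab)
  tab
}

#' Dunn-Sidak multiple-testing correction
#'
#' `alpha' = 1 - (1 - alpha)^(1/n)`, the per-test level keeping the
#' family-wise error at `alpha` over `n` independent tests.
#'
#' @param alpha nominal family-wise level in (0, 1).
#' @param n_tests number of tests, >= 1.
#' @return corrected per-test alpha.
#' @export
sidak_alpha <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  1 - (1 - alpha)^(1 / n_tests)
}

#' Effect of pooling parents and offspring on the inbreeding coefficient
#'
#' Computes the across-loci mean fixation index F on parents only and on
#' parents + offspring pooled, per population. Progeny arrays are family
#' samples, not random population samples, so pooling inflates F when
#' selfing or family structure is present; a clearly positive delta is the
#' reason population-variation analyses are restricted to parents.
#'
#' @param genotypes a [genotype_table()] containing both generations.
#' @return data.frame per population: `f_parents`, `f_pooled`, `delta`;
#'   populations lacking a generation are skipped (attribute `"skipped"`).
#' @export
pooling_fis_check <- function(genotypes) {
  gt <- genotypes
  mean_f <- function(tab) {
    s <- per_locus_stats(tab, generation = "all")
    mean(s$f, na.rm = TRUE)
  }
  out <- list(); skipped <- character(0)
  for (popn in unique(gt$population)) {
    sub <- subset_genotypes(gt, gt$population == popn)
    if (!all(c("parent", "offspring") %in% sub$generation)) {
      skipped <- c(skipped, popn)
      next
    }
    fp <- mean_f(subset_genotypes(sub, sub$generation == "parent"))
    fa <- mean_f(sub)
    out[[length(out) + 1L]] <- data.frame(
      population = popn, f_parents = fp, f_pooled = fa, delta = fa - fp,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  res
}
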