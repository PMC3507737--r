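#' Parent value / mean offspring value pairs per maternal family
#'
#' Offspring values are averaged among measured siblings; families whose
#' mother is unmeasured (or has no measured offspring) are dropped and
#' counted in the `dropped` attribute.
#'
#' @param traits a [trait_table()].
#' @param genotypes a [genotype_table()] supplying the mother links.
#' @param populations optional character vector restricting to these
#'   populations (the study re-fits within *I. rubescens* only).
#' @return data.frame with columns `family`, `parent_value`,
#'   `offspring_mean`, `n_offspring`; attribute `dropped` counts unusable
#'   families.
#' @export
family_means <- function(traits, genotypes, populations = NULL) {
  gt <- genotypes
  if (!is.null(populations))
    gt <- subset_genotypes(gt, gt$population %in% populations)
  val <- stats::setNames(traits$oridonin_pct, traits$sample)
  moms <- unique(stats::na.omit(gt$mother))
  if (length(moms) == 0L) stop("zero usable families: no mother links")
  rows <- lapply(moms, function(m) {
    pv <- val[m]
    kids <- gt$samples[!is.na(gt$mother) & gt$mother == m]
    kv <- val[kids]
    kv <- kv[!is.na(kv)]
    if (is.na(pv) || length(kv) == 0L) return(NULL)
    data.frame(family = m, parent_value = unname(pv),
               offspring_mean = mean(kv), n_offspring = length(kv),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("zero usable families: no measured mother/offspring")
  out <- do.call(rbind, rows[keep])
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Narrow-sense heritability from offspring-on-one-parent regression
#'
#' Ordinary least squares of mean offspring value on the value of the single
#' known (maternal) parent. Because one parent contributes half the additive
#' value, the expected slope is `h2 / 2`, so `h2 = 2 * slope` (Falconer's
#' one-parent formula). The slope is tested with a two-sided t-test on
#' `n - 2` degrees of freedom. Families are unweighted regardless of sibling
#' count.
#'
#' @param pairs data.frame from [family_means()] (columns `parent_value`,
#'   `offspring_mean`).
#' @return list of class `herit_result`: `n_families`, `slope`, `intercept`,
#'   `se`, `t`, `p`, `h2`, `h2_out_of_range` warning flag.
#' @export
parent_offspring_regression <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 families")
  if (stats::var(pairs$parent_value) == 0)
    stop("zero variance in parent values")
  fit <- stats::lm(offspring_mean ~ parent_value, data = pairs)
  sm <- summary(fit)$coefficients
  b <- sm["parent_value", "Estimate"]
  se <- sm["parent_value", "Std. Error"]
  h2 <- 2 * b
  out <- list(n_families = nrow(pairs), slope = b,
              intercept = sm["(Intercept)", "Estimate"], se = se,
              t = sm["parent_value", "t value"],
              p = sm["parent_value", "Pr(>|t|)"], h2 = h2,
              h2_out_of_range = (h2 < 0 || h2 > 1))
  if (out$h2_out_of_range)
    warning(sprintf("h2 estimate %.3f outside [0, 1]", h2))
  structure(out, class = "herit_result")
}

#' @export
print.herit_result <- function(x, ...) {
  cat(sprintf(
    "Parent-offspring regression: n = %d families\n  b = %.3f (SE %.3f), t = %.2f, p = %.3g\n  h2 = 2b = %.3f%s\n",
    x$n_families, x$slope, x$se, x$t, x$p, x$h2,
    if (x$h2_out_of_range) "  [outside [0,1]]" else ""))
  invisible(x)
}
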