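#' Fit an LC/MS calibration curve
#'
#' Least-squares line `area = slope * conc + intercept` through the standard
#' series (the study ran seven oridonin standards from 1.5 to 100 ng/uL,
#' integrating peak areas at UV 254 nm and MS+347; each channel gets its own
#' curve).
#'
#' @param conc standard concentrations, ng/uL (>= 2 distinct values).
#' @param area integrated peak areas (>= 0).
#' @param channel tag, e.g. `"UV254"` or `"MS+347"`.
#' @return list of class `calibration_curve`: `slope`, `intercept`, `r2`,
#'   `conc_range`, `channel`, `n`.
#' @export
fit_calibration <- function(conc, area, channel = "UV254") {
  if (length(conc) != length(area)) stop("conc and area lengths differ")
  if (length(unique(conc)) < 2L)
    stop("need at least 2 distinct standard concentrations")
  if (any(area < 0)) stop("negative peak areas")
  fit <- stats::lm(area ~ conc)
  sst <- sum((area - mean(area))^2)
  ssr <- sum(stats::residuals(fit)^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = if (sst > 0) 1 - ssr / sst else NA_real_,
                 conc_range = range(conc), channel = channel,
                 n = length(conc)),
            class = "calibration_curve")
}

#' Convert peak areas to percent dry weight
#'
#' Inverts the calibration (`conc = (area - intercept) / slope`) and scales
#' by the extraction protocol: the dried sample (`mass_mg`) is extracted and
#' redissolved in `volume_ul` of methanol, so
#' `pct = conc * volume_ul / (mass_mg * 1e6) * 100` (ng/uL x uL = ng;
#' 1e6 ng = 1 mg). This formula is reconstructed from the stated protocol
#' (20 mL methanol, 200-500 mg leaf) rather than quoted from any source.
#' Concentrations outside the calibration range are flagged as
#' extrapolated; negative inferred concentrations are clamped to zero with
#' a warning.
#'
#' @param area peak area (vectorised).
#' @param curve a [fit_calibration()] curve with positive slope.
#' @param mass_mg dried sample mass, mg (recycled).
#' @param volume_ul extract volume, uL (default 20 mL).
#' @param sample optional sample IDs.
#' @param threshold pharmacopoeia threshold, percent dry weight.
#' @return data.frame of class `quant_result`: `sample`, `conc`,
#'   `percent_dry_weight`, `above_threshold`, `extrapolated`.
#' @export
quantify_percent_dry_weight <- function(area, curve, mass_mg,
                                        volume_ul = 20000, sample = NULL,
                                        threshold = 0.25) {
  if (curve$slope <= 0) stop("non-positive calibration slope")
  if (any(mass_mg <= 0)) stop("sample mass must be positive")
  conc <- (area - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("negative inferred concentration clamped to 0")
    conc <- pmax(conc, 0)
  }
  extrap <- conc < curve$conc_range[1L] | conc > curve$conc_range[2L]
  mass <- rep_len(mass_mg, length(area))
  pct <- conc * volume_ul / (mass * 1e6) * 100
  df <- data.frame(
    sample = if (is.null(sample)) as.character(seq_along(area)) else sample,
    conc = conc, percent_dry_weight = pct,
    above_threshold = pct >= threshold, extrapolated = extrap,
    stringsAsFactors = FALSE)
  class(df) <- c("quant_result", "data.frame")
  df
}

#' Replicate repeatability as mean relative uncertainty
#'
#' Per sample: the mean absolute deviation of replicate percent-dry-weight
#' values from their mean, divided by that mean, times 100; the statistic is
#' the across-sample mean. Samples whose replicate mean is zero are excluded
#' with a warning.
#'
#' @param sample sample ID per replicate measurement.
#' @param pct percent-dry-weight value per replicate measurement.
#' @return list: `mean_relative_uncertainty_pct`, `per_sample` (named),
#'   `n_samples`, `n_excluded`.
#' @export
replicate_relative_uncertainty <- function(sample, pct) {
  grp <- split(pct, sample)
  grp <- grp[lengths(grp) >= 2L]
  if (length(grp) == 0L) stop("need >= 2 replicates for >= 1 sample")
  mu <- vapply(grp, mean, numeric(1))
  zero <- mu == 0
  if (any(zero)) warning(sum(zero), " sample(s) with zero replicate mean excluded")
  rel <- vapply(grp[!zero], function(x) mean(abs(x - mean(x))) / mean(x) * 100,
                numeric(1))
  if (length(rel) == 0L) stop("no sample with non-zero replicate mean")
  list(mean_relative_uncertainty_pct = mean(rel), per_sample = rel,
       n_samples = length(rel), n_excluded = sum(zero))
}
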