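#' Scale a causal estimate and convert to an odds ratio
#'
#' Multiplies the raw log-odds estimate (per unit of the exposure) by
#' `multiplier` and exponentiates, together with its confidence bounds.
#' The default multiplier 1.1 expresses the effect per 10% increase of the
#' log-scale exposure under the convention of multiplying the estimate by
#' 1.1; the conventional alternative `log(1.1)` (effect per 10% increase
#' of the raw-scale exposure) is available via
#' `multiplier = per_10pct_multiplier()`. A monotone transform, so the
#' p-value is unchanged.
#'
#' @param result One-row results data.frame (from [mr_ivw()] and friends,
#'   or the `primary` element of an [mr_fit()]).
#' @param multiplier Positive scale factor applied to the log-odds
#'   estimate before exponentiation (default 1.1).
#' @return data.frame with `raw_beta`, `scale_multiplier`, `or_scaled`,
#'   `or_ci_low`, `or_ci_high`, `pvalue`.
#' @export
scale_to_or <- function(result, multiplier = 1.1) {
  stopifnot(multiplier > 0)
  data.frame(raw_beta = result$beta, scale_multiplier = multiplier,
             or_scaled = exp(result$beta * multiplier),
             or_ci_low = exp(result$ci_low * multiplier),
             or_ci_high = exp(result$ci_high * multiplier),
             pvalue = result$pvalue, stringsAsFactors = FALSE)
}

#' Multiplier for effects per 10% increase of the raw-scale exposure
#'
#' `log(1.1)`: the conventional conversion when the exposure GWAS is on
#' the natural-log scale and effects are wanted per 10% increase of the
#' untransformed exposure.
#'
#' @return `log(1.1)`.
#' @export
per_10pct_multiplier <- function() log(1.1)

#' Statistical power for MR with a binary outcome
#'
#' The standard non-centrality approximation for two-sample MR power with
#' a binary outcome (as implemented by the mRnd calculator): with case
#' fraction K and alternative odds ratio OR,
#' b = K (OR / (1 + K (OR - 1)) - 1), v = (K (1 - K) - b^2) / (N r2),
#' and power is the upper-tail probability of a chi-square(1, ncp = b^2/v)
#' beyond the central chi-square critical value at `alpha`.
#'
#' @param n_total Total outcome-GWAS sample size.
#' @param case_fraction Proportion of cases K in (0, 1).
#' @param r2_xz Proportion of exposure variance explained by the
#'   instruments.
#' @param or_alt Odds ratio under the alternative (> 0).
#' @param alpha Test size (default 0.05).
#' @return Power in [0, 1].
#' @export
mr_power_binary <- function(n_total, case_fraction, r2_xz, or_alt,
                            alpha = 0.05) {
  stopifnot(n_total > 0, case_fraction > 0, case_fraction < 1,
            r2_xz > 0, r2_xz < 1, or_alt > 0, alpha > 0, alpha < 1)
  K <- case_fraction
  b <- K * (or_alt / (1 + K * (or_alt - 1)) - 1)
  if (K * (1 - K) <= b^2) stop("degenerate variance: K(1-K) <= b^2")
  v <- (K * (1 - K) - b^2) / (n_total * r2_xz)
  ncp <- b^2 / v
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}
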