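#' Cochran's Q heterogeneity test for the IVW model
#'
#' Q = sum of inverse-variance-weighted squared deviations of the per-SNP
#' Wald ratios about the IVW pooled estimate, referred to a chi-square
#' distribution with n - 1 degrees of freedom.
#'
#' @param ratios Wald-ratio data.frame from [wald_ratios()] (n >= 2 rows).
#' @return data.frame with `source`, `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(ratios) {
  n <- nrow(ratios)
  if (n < 2) stop("Cochran's Q requires at least 2 instruments")
  w <- ratios$weight
  beta <- sum(w * ratios$ratio) / sum(w)
  q <- sum(w * (ratios$ratio - beta)^2)
  data.frame(source = "ivw", q = q, df = n - 1,
             pvalue = stats::pchisq(q, df = n - 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Rucker's Q' heterogeneity test for the MR-Egger model
#'
#' Weighted residual sum of squares about the fitted Egger regression
#' line, referred to chi-square with n - 2 degrees of freedom. Always
#' bounded above by the IVW Q (the intercept absorbs part of the
#' heterogeneity).
#'
#' @param instruments Harmonized-instrument data.frame (n >= 3 rows).
#' @return data.frame with `source`, `q`, `df`, `pvalue`.
#' @export
rucker_q <- function(instruments) {
  n <- nrow(instruments)
  if (n < 3) stop("Rucker's Q' requires at least 3 instruments")
  fit <- egger_wls(instruments)
  data.frame(source = "egger", q = fit$q_prime, df = fit$df,
             pvalue = stats::pchisq(fit$q_prime, df = fit$df,
                                    lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' MR-Egger intercept test for directional horizontal pleiotropy
#'
#' The Egger intercept estimates the average pleiotropic effect; a
#' two-sided t test with n - 2 degrees of freedom of intercept = 0 is the
#' standard test for directional horizontal pleiotropy.
#'
#' @param instruments Harmonized-instrument data.frame (n >= 3 rows).
#' @return data.frame with `egger_intercept`, `intercept_se`, `pvalue`.
#' @export
egger_intercept_test <- function(instruments) {
  res <- mr_egger(instruments)
  data.frame(egger_intercept = res$intercept,
             intercept_se = res$intercept_se,
             pvalue = res$intercept_p, stringsAsFactors = FALSE)
}

# IVW slope of beta_outcome on beta_exposure (zero intercept) leaving SNP j
# out, vectorised: given sims as matrices (rows = simulations).
loo_ivw_slopes <- function(g, G, w) {
  num <- g * G * w
  den <- g^2 * w
  (sum(num) - num) / (sum(den) - den)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based detection of horizontal pleiotropy. The observed
#' statistic is the sum over SNPs of leave-one-out weighted squared
#' residuals of the outcome effect about the IVW prediction fitted without
#' that SNP. Its null distribution is built by parametric simulation:
#' exposure effects resampled about their estimates, outcome effects about
#' the leave-one-out IVW predictions. The global p-value is the proportion
#' of simulated statistics at least as large as observed; per-SNP outlier
#' p-values compare each SNP's observed squared residual with its own
#' simulated distribution, Bonferroni-corrected by the number of SNPs.
#' When outliers are flagged, the outlier-corrected IVW estimate is
#' computed and a distortion test compares the observed estimate shift
#' with that of random pseudo-outlier sets of the same size.
#'
#' @param instruments Harmonized-instrument data.frame (n >= 4 rows).
#' @param n_sim Number of simulations (default 1000).
#' @param seed Integer seed.
#' @param outlier_alpha Significance threshold for the Bonferroni-corrected
#'   per-SNP outlier test (default 0.05).
#' @param n_distortion Random outlier sets for the distortion test
#'   (default 1000).
#' @return List of class `mr_presso` with `global_rss_observed`,
#'   `global_pvalue`, `outlier_pvalues` (named, Bonferroni-corrected),
#'   `outliers_flagged`, `distortion_pvalue`, `corrected_estimate`
#'   (one-row results data.frame or `NULL`).
#' @export
mr_presso <- function(instruments, n_sim = 1000, seed = 1L,
                      outlier_alpha = 0.05, n_distortion = 1000) {
  n <- nrow(instruments)
  if (n < 4) stop("MR-PRESSO requires at least 4 instruments")
  g <- instruments$beta_exposure
  G <- instruments$beta_outcome
  sg <- instruments$se_exposure
  sG <- instruments$se_outcome
  w <- 1 / sG^2

  beta_loo <- loo_ivw_slopes(g, G, w)
  res_obs <- w * (G - g * beta_loo)^2
  rss_obs <- sum(res_obs)

  set.seed(seed)
  g_star <- matrix(stats::rnorm(n_sim * n, rep(g, each = n_sim),
                                rep(sg, each = n_sim)), nrow = n_sim)
  G_star <- matrix(stats::rnorm(n_sim * n, rep(g * beta_loo, each = n_sim),
                                rep(sG, each = n_sim)), nrow = n_sim)
  num <- sweep(g_star * G_star, 2, w, `*`)
  den <- sweep(g_star^2, 2, w, `*`)
  beta_loo_star <- (rowSums(num) - num) / (rowSums(den) - den)
  res_star <- sweep((G_star - g_star * beta_loo_star)^2, 2, w, `*`)
  rss_star <- rowSums(res_star)

  global_p <- (sum(rss_star >= rss_obs) + 1) / (n_sim + 1)

  per_snp_p <- vapply(seq_len(n), function(j) {
    (sum(res_star[, j] >= res_obs[j]) + 1) / (n_sim + 1)
  }, numeric(1))
  outlier_p <- pmin(1, per_snp_p * n)
  names(outlier_p) <- as.character(instruments$rsid)
  flagged <- names(outlier_p)[outlier_p < outlier_alpha]
  if (length(flagged) == n) stop("all instruments flagged as outliers")

  corrected <- NULL
  distortion_p <- NA_real_
  if (length(flagged) > 0) {
    keep <- !(as.character(instruments$rsid) %in% flagged)
    corrected <- mr_ivw(wald_ratios(instruments[keep, , drop = FALSE]), "fe")
    full <- mr_ivw(wald_ratios(instruments), "fe")
    d_obs <- corrected$beta - full$beta
    n_out <- length(flagged)
    d_rand <- vapply(seq_len(n_distortion), function(b) {
      drop_idx <- sample.int(n, n_out)
      rr <- wald_ratios(instruments[-drop_idx, , drop = FALSE])
      mr_ivw(rr, "fe")$beta - full$beta
    }, numeric(1))
    distortion_p <- (sum(abs(d_rand) >= abs(d_obs)) + 1) / (n_distortion + 1)
  }
  structure(list(global_rss_observed = rss_obs, global_pvalue = global_p,
                 outlier_pvalues = outlier_p, outliers_flagged = flagged,
                 distortion_pvalue = distortion_p,
                 corrected_estimate = corrected, n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("MR-PRESSO (", x$n_sim, " simulations)\n", sep = "")
  cat(sprintf("  Global RSS: %.3f  p = %.4g\n",
              x$global_rss_observed, x$global_pvalue))
  if (length(x$outliers_flagged)) {
    cat("  Outliers:", paste(x$outliers_flagged, collapse = ", "), "\n")
    cat(sprintf("  Distortion p = %.4g\n", x$distortion_pvalue))
    cat(sprintf("  Outlier-corrected IVW beta = %.4f (se %.4f)\n",
                x$corrected_estimate$beta, x$corrected_estimate$se))
  } else {
    cat("  No outliers flagged\n")
  }
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the causal effect excluding each instrument in turn. An
#' instrument is flagged influential when the remaining-set confidence
#' interval crosses the null while the full-set interval does not.
#'
#' @param instruments Harmonized-instrument data.frame (n >= 2 rows).
#' @param method Estimator used for the re-fits (currently fixed-effect
#'   IVW, the primary-method default).
#' @return data.frame with one row per excluded SNP: `excluded_rsid`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `influential`.
#' @export
leave_one_out <- function(instruments, method = "ivw_fe") {
  stopifnot(method == "ivw_fe")
  n <- nrow(instruments)
  if (n < 2) stop("leave-one-out requires at least 2 instruments")
  full <- mr_ivw(wald_ratios(instruments), "fe")
  full_excl_null <- full$ci_low > 0 || full$ci_high < 0
  rows <- lapply(seq_len(n), function(j) {
    fit <- mr_ivw(wald_ratios(instruments[-j, , drop = FALSE]), "fe")
    crosses <- fit$ci_low <= 0 && fit$ci_high >= 0
    data.frame(excluded_rsid = as.character(instruments$rsid[j]),
               beta = fit$beta, se = fit$se, ci_low = fit$ci_low,
               ci_high = fit$ci_high, pvalue = fit$pvalue,
               influential = full_excl_null && crosses,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flowchart selection of the primary MR method
#'
#' Encodes the decision rule: with neither horizontal pleiotropy nor
#' between-SNP heterogeneity detected, fixed-effect IVW; with
#' heterogeneity but no pleiotropy, IVW with multiplicative random effects
#' (MR-PRESSO is then also run and reported); with pleiotropy, MR-Egger.
#' "Detected" means p < `alpha`.
#'
#' @param pleiotropy data.frame from [egger_intercept_test()] (or any list
#'   with a `pvalue` field).
#' @param heterogeneity data.frame from [cochran_q()] (or any list with a
#'   `pvalue` field).
#' @param alpha Detection threshold (default 0.05).
#' @return List of class `method_decision` with `pleiotropy_detected`,
#'   `heterogeneity_detected`, `primary_method`, `rationale`.
#' @export
select_method <- function(pleiotropy, heterogeneity, alpha = 0.05) {
  p_pleio <- pleiotropy$pvalue[1]
  p_het <- heterogeneity$pvalue[1]
  pleio <- p_pleio < alpha
  het <- p_het < alpha
  if (pleio) {
    method <- "egger"
    why <- "horizontal pleiotropy detected: MR-Egger regression"
  } else if (het) {
    method <- "ivw_mre"
    why <- paste("heterogeneity without pleiotropy: IVW with multiplicative",
                 "random effects (MR-PRESSO also reported)")
  } else {
    method <- "ivw_fe"
    why <- "neither pleiotropy nor heterogeneity detected: fixed-effect IVW"
  }
  structure(list(pleiotropy_detected = pleio, heterogeneity_detected = het,
                 primary_method = method, rationale = why),
            class = "method_decision")
}

#' @export
print.method_decision <- function(x, ...) {
  cat("Primary method:", x$primary_method, "\n ", x$rationale, "\n")
  invisible(x)
}

#' Direction concordance across estimators
#'
#' TRUE when the signs of all causal estimates agree; an exactly zero
#' estimate is compatible with either sign.
#'
#' @param results Results data.frame with a `beta` column (>= 2 rows).
#' @return Logical scalar.
#' @export
direction_concordance <- function(results) {
  if (nrow(results) < 2) stop("need at least 2 results")
  s <- sign(results$beta)
  s <- s[s != 0]
  length(unique(s)) <= 1
}
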