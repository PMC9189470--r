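Z95 <- stats::qnorm(0.975)

mr_result_row <- function(method, beta, se, pvalue, n_snp,
                          ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                          intercept = NA_real_, intercept_se = NA_real_,
                          intercept_p = NA_real_) {
  data.frame(method = method, n_snp = n_snp, beta = beta, se = se,
             ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
             intercept = intercept, intercept_se = intercept_se,
             intercept_p = intercept_p, stringsAsFactors = FALSE)
}

two_sided_normal_p <- function(beta, se) {
  if (se == 0) return(if (beta == 0) 1 else 0)
  2 * stats::pnorm(-abs(beta / se))
}

#' Per-SNP Wald ratio estimates
#'
#' The per-SNP causal estimate underlying every summary-data MR method:
#' ratio of the SNP-outcome effect to the SNP-exposure effect, with the
#' first-order standard error se(outcome) / |beta_exposure| and
#' inverse-variance weight.
#'
#' @param instruments Harmonized-instrument data.frame with columns
#'   `rsid`, `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`.
#' @return data.frame with columns `rsid`, `ratio`, `se_ratio`, `weight`.
#' @export
wald_ratios <- function(instruments) {
  g <- instruments$beta_exposure
  if (any(g == 0)) {
    stop("zero exposure effect for SNP(s): ",
         paste(instruments$rsid[g == 0], collapse = ", "))
  }
  se <- instruments$se_outcome / abs(g)
  data.frame(rsid = as.character(instruments$rsid),
             ratio = instruments$beta_outcome / g,
             se_ratio = se, weight = 1 / se^2, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted mean of the per-SNP Wald ratios with inverse-variance weights.
#' Under the fixed-effect model (`"fe"`) the standard error is
#' sqrt(1 / sum(w)); under multiplicative random effects (`"mre"`) it is
#' inflated by sqrt(Q / (n - 1)) when Cochran's Q about the pooled estimate
#' exceeds its degrees of freedom (never deflated below the fixed-effect
#' standard error).
#'
#' @param ratios Wald-ratio data.frame from [wald_ratios()].
#' @param effects_model `"fe"` (fixed effect) or `"mre"` (multiplicative
#'   random effects).
#' @return One-row results data.frame (method, n_snp, beta, se, ci_low,
#'   ci_high, pvalue, ...).
#' @export
mr_ivw <- function(ratios, effects_model = c("fe", "mre")) {
  effects_model <- match.arg(effects_model)
  n <- nrow(ratios)
  if (n < 1) stop("IVW requires at least one instrument")
  w <- ratios$weight
  beta <- sum(w * ratios$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  if (effects_model == "mre" && n > 1) {
    q <- sum(w * (ratios$ratio - beta)^2)
    se <- se * max(1, sqrt(q / (n - 1)))
  }
  mr_result_row(paste0("ivw_", effects_model), beta, se,
                two_sided_normal_p(beta, se), n)
}

# Weighted least squares of beta_outcome on beta_exposure with the
# instruments oriented so every exposure effect is positive. Shared by the
# Egger estimator and the Q' / intercept diagnostics.
egger_wls <- function(instruments) {
  flip <- sign(instruments$beta_exposure)
  x <- instruments$beta_exposure * flip
  y <- instruments$beta_outcome * flip
  w <- 1 / instruments$se_outcome^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- summary(fit)$coefficients
  resid_q <- sum(w * stats::residuals(fit)^2)
  list(intercept = cf[1, 1], intercept_se = cf[1, 2],
       slope = cf[2, 1], slope_se = cf[2, 2],
       q_prime = resid_q, df = nrow(instruments) - 2, x = x, y = y, w = w)
}

#' MR-Egger regression estimate
#'
#' Weighted least-squares regression of outcome effects on exposure
#' effects with an unconstrained intercept, instruments oriented so all
#' exposure effects are positive. The slope is the pleiotropy-adjusted
#' causal estimate; the intercept estimates the average directional
#' pleiotropic effect. Inference uses the t distribution with n - 2
#' degrees of freedom, reflecting the two estimated parameters.
#'
#' @param instruments Harmonized-instrument data.frame (n >= 3 rows).
#' @return One-row results data.frame including `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(instruments) {
  n <- nrow(instruments)
  if (n < 3) stop("MR-Egger requires at least 3 instruments")
  fit <- egger_wls(instruments)
  tq <- stats::qt(0.975, df = fit$df)
  p_of <- function(est, se) {
    if (se == 0) return(if (est == 0) 1 else 0)
    2 * stats::pt(-abs(est / se), df = fit$df)
  }
  mr_result_row("egger", fit$slope, fit$slope_se,
                p_of(fit$slope, fit$slope_se), n,
                ci_low = fit$slope - tq * fit$slope_se,
                ci_high = fit$slope + tq * fit$slope_se,
                intercept = fit$intercept, intercept_se = fit$intercept_se,
                intercept_p = p_of(fit$intercept, fit$intercept_se))
}

# Weighted median of `x` with weights `w`: linear interpolation of the
# order statistics against standardized cumulative weights at 0.5.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] <= 0.5) return(x[length(s)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(ratios, point_fun, n_boot, seed) {
  if (n_boot < 1) return(NA_real_)
  set.seed(seed)
  n <- nrow(ratios)
  reps <- vapply(seq_len(n_boot), function(b) {
    point_fun(stats::rnorm(n, ratios$ratio, ratios$se_ratio))
  }, numeric(1))
  stats::sd(reps)
}

#' Weighted-median causal estimate
#'
#' Median of the inverse-variance-weighted empirical distribution of the
#' Wald ratios; consistent when at least half the weight comes from valid
#' instruments. The standard error is obtained by parametric bootstrap
#' (each ratio resampled from its normal sampling distribution).
#'
#' @param ratios Wald-ratio data.frame (n >= 3 rows).
#' @param n_boot Bootstrap replicates for the standard error (default
#'   1000; 0 skips the bootstrap, leaving se/CI/p `NA`).
#' @param seed Integer seed for the bootstrap.
#' @return One-row results data.frame.
#' @export
mr_weighted_median <- function(ratios, n_boot = 1000, seed = 1L) {
  n <- nrow(ratios)
  if (n < 3) stop("weighted median requires at least 3 instruments")
  w <- ratios$weight
  beta <- weighted_median_point(ratios$ratio, w)
  se <- boot_se(ratios, function(b) weighted_median_point(b, w), n_boot, seed)
  p <- if (is.na(se)) NA_real_ else two_sided_normal_p(beta, se)
  mr_result_row("weighted_median", beta, se, p, n,
                ci_low = beta - Z95 * se, ci_high = beta + Z95 * se)
}

# Modal estimate: argmax over a fine grid of the normal-kernel-smoothed
# weighted density of the ratios. Bandwidth is the classic rule of thumb
# 0.9 min(sd, mad/0.6745) n^{-1/5} scaled by `bandwidth_factor`; the raw
# (unscaled) median absolute deviation is used. Ties go to the smallest
# grid value. Returns NA bandwidth when the ratios are all identical.
weighted_mode_point <- function(x, w, bandwidth_factor = 1, grid_n = 512) {
  mad_raw <- stats::median(abs(x - stats::median(x)))
  h <- bandwidth_factor * 0.9 * min(stats::sd(x), mad_raw / 0.6745) *
    length(x)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(list(mode = x[1], bandwidth = 0))
  w <- w / sum(w)
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, x, h)), numeric(1))
  list(mode = grid[which.max(dens)], bandwidth = h)
}

#' Weighted-mode causal estimate
#'
#' Mode of the kernel-smoothed weighted empirical density of the Wald
#' ratios; consistent when the largest group of instruments sharing a
#' causal estimate is valid (ZEMPA). Standard error by the same parametric
#' bootstrap as the weighted median. When all ratios coincide (zero
#' bandwidth) the common value is returned with the fixed-effect IVW
#' standard error.
#'
#' @param ratios Wald-ratio data.frame (n >= 3 rows).
#' @param bandwidth_factor Multiplier on the rule-of-thumb kernel
#'   bandwidth (default 1).
#' @param n_boot,seed As in [mr_weighted_median()].
#' @return One-row results data.frame.
#' @export
mr_weighted_mode <- function(ratios, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1L) {
  n <- nrow(ratios)
  if (n < 3) stop("weighted mode requires at least 3 instruments")
  w <- ratios$weight
  pt_est <- weighted_mode_point(ratios$ratio, w, bandwidth_factor)
  if (pt_est$bandwidth == 0) {
    se <- sqrt(1 / sum(w))
    return(mr_result_row("weighted_mode", pt_est$mode, se,
                         two_sided_normal_p(pt_est$mode, se), n))
  }
  point <- function(b) weighted_mode_point(b, w, bandwidth_factor)$mode
  se <- boot_se(ratios, point, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else two_sided_normal_p(pt_est$mode, se)
  mr_result_row("weighted_mode", pt_est$mode, se, p, n)
}
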