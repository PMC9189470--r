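#' Configuration for a synthetic two-sample GWAS study
#'
#' Collects the ground-truth parameters of [simulate_study()]. The
#' defaults emulate the study shape the package is validated against: a
#' log-scale quantitative exposure GWAS with 8 independent instruments
#' explaining 2.65% of variance in 7827 individuals, and a binary-outcome
#' GWAS on the log-odds scale with biobank-scale case/control counts.
#'
#' @param n_snps Number of instruments (default 8).
#' @param n_exposure Exposure GWAS sample size (default 7827).
#' @param n_outcome_cases,n_outcome_controls Outcome GWAS case/control
#'   counts (defaults 6000 and 190000).
#' @param beta_causal True causal effect on the outcome log-odds per unit
#'   (SD) of the log-scale exposure (default 0).
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero direct effects) or
#'   `"directional"`.
#' @param pleiotropy_mean Mean direct effect under directional pleiotropy.
#' @param pleiotropy_sd SD of the per-SNP direct effects (balanced or
#'   directional).
#' @param inside_violation When TRUE the direct effects are correlated
#'   with instrument strength (violating InSIDE).
#' @param target_r2 Total exposure variance explained by the instruments
#'   (default 0.0265).
#' @param n_outliers,outlier_shift_se Number of planted outlier
#'   instruments and their outcome-effect displacement in units of the
#'   outcome standard error.
#' @param maf_range Range minor-allele frequencies are drawn from
#'   (default c(0.1, 0.45)).
#' @param palindromic_frac Fraction of SNPs assigned complementary (A/T or
#'   C/G) allele pairs (default 0).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snps = 8, n_exposure = 7827,
                       n_outcome_cases = 6000, n_outcome_controls = 190000,
                       beta_causal = 0,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       inside_violation = FALSE, target_r2 = 0.0265,
                       n_outliers = 0, outlier_shift_se = 0,
                       maf_range = c(0.1, 0.45), palindromic_frac = 0,
                       seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(n_snps >= 1, n_exposure > 0, n_outcome_cases > 0,
            n_outcome_controls > 0, target_r2 > 0, target_r2 < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_outliers >= 0, n_outliers <= n_snps,
            palindromic_frac >= 0, palindromic_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Per-SNP standard errors under standard large-sample approximations:
# quantitative standardized trait se^2 = 1/(2p(1-p) n); binary-trait
# log-odds se^2 = 1/(2p(1-p) N K(1-K)), i.e. the logistic score
# information with case fraction K.
se_quantitative <- function(maf, n) sqrt(1 / (2 * maf * (1 - maf) * n))

se_logistic <- function(maf, n_cases, n_controls) {
  n <- n_cases + n_controls
  k <- n_cases / n
  sqrt(1 / (2 * maf * (1 - maf) * n * k * (1 - k)))
}

#' Simulate a two-sample GWAS summary-statistics study with known truth
#'
#' Generates paired exposure/outcome summary statistics at the
#' summary-statistic level. Minor-allele frequencies are drawn uniformly;
#' true exposure effects are drawn and rescaled so the realized explained
#' variance sum(2 p (1-p) gamma^2) equals `target_r2` exactly; standard
#' errors follow the large-sample approximations for a standardized
#' quantitative trait (exposure) and a logistic log-odds association
#' (outcome). True outcome effects are `beta_causal * gamma + alpha` with
#' per-SNP direct (pleiotropic) effects `alpha` per the pleiotropy
#' specification; observed effects add normal estimation noise; planted
#' outliers displace the observed outcome effect by a stated multiple of
#' its standard error. Instruments are LD-independent; the emitted LD
#' reference is the implied identity.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, exposure/outcome TSVs, an
#'   LD TSV and a JSON ground-truth file are written there.
#' @return List of class `simulated_study`: `exposure`, `outcome`
#'   (summary-statistics data.frames), `ld` (an [ld_reference()]),
#'   `instruments` (the harmonized truth-aligned instrument table),
#'   `truth` (config plus realized `gamma`, `alpha`, `Gamma`, and
#'   `outlier_rsids`), and file paths when `dir` was given.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$n_snps
  maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
  # effects are reported for the exposure-increasing allele (the oriented
  # frame in which directional pleiotropy is defined) and instruments are,
  # by construction, genome-wide-significant SNPs, so true effects are a
  # shifted half-normal bounded away from zero
  gamma_raw <- 0.3 + abs(stats::rnorm(k))
  het <- 2 * maf * (1 - maf)
  gamma <- gamma_raw * sqrt(config$target_r2 / sum(het * gamma_raw^2))
  if (sum(het * gamma^2) > 1) stop("infeasible target_r2 for this maf draw")
  se_g <- se_quantitative(maf, config$n_exposure)

  alpha <- switch(config$pleiotropy,
    none = rep(0, k),
    balanced = stats::rnorm(k, 0, config$pleiotropy_sd),
    directional = stats::rnorm(k, config$pleiotropy_mean,
                               config$pleiotropy_sd))
  if (config$inside_violation && config$pleiotropy != "none") {
    # tie direct effects to instrument strength (InSIDE violated)
    alpha <- alpha + 0.5 * config$pleiotropy_sd * scale(gamma)[, 1]
  }
  Gamma <- config$beta_causal * gamma + alpha
  se_G <- se_logistic(maf, config$n_outcome_cases, config$n_outcome_controls)

  beta_exp_obs <- stats::rnorm(k, gamma, se_g)
  beta_out_obs <- stats::rnorm(k, Gamma, se_G)
  outlier_idx <- integer(0)
  if (config$n_outliers > 0) {
    outlier_idx <- sample.int(k, config$n_outliers)
    beta_out_obs[outlier_idx] <- beta_out_obs[outlier_idx] +
      config$outlier_shift_se * se_G[outlier_idx]
  }

  rsid <- sprintf("rs%07d", sample.int(9999999, k))
  pal <- stats::runif(k) < config$palindromic_frac
  pairs_nonpal <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  pairs_pal <- list(c("A", "T"), c("C", "G"))
  alleles <- t(vapply(seq_len(k), function(j) {
    if (pal[j]) pairs_pal[[sample.int(2, 1)]] else
      pairs_nonpal[[sample.int(4, 1)]]
  }, character(2)))

  mk_sumstats <- function(beta, se, n) {
    data.frame(rsid = rsid, effect_allele = alleles[, 1],
               other_allele = alleles[, 2], eaf = maf, beta = beta, se = se,
               pvalue = 2 * stats::pnorm(-abs(beta / se)), n = n,
               stringsAsFactors = FALSE)
  }
  exposure <- mk_sumstats(beta_exp_obs, se_g, config$n_exposure)
  outcome <- mk_sumstats(beta_out_obs, se_G,
                         config$n_outcome_cases + config$n_outcome_controls)
  instruments <- data.frame(
    rsid = rsid, beta_exposure = beta_exp_obs, se_exposure = se_g,
    beta_outcome = beta_out_obs, se_outcome = se_G,
    eaf_exposure = maf, eaf_outcome = maf,
    action_taken = "none", stringsAsFactors = FALSE)
  truth <- c(unclass(config),
             list(gamma = gamma, alpha = alpha, Gamma = Gamma, maf = maf,
                  outlier_rsids = rsid[outlier_idx],
                  realized_r2 = sum(het * gamma^2)))
  study <- structure(list(exposure = exposure, outcome = outcome,
                          ld = ld_reference(), instruments = instruments,
                          truth = truth),
                     class = "simulated_study")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    study$exposure_file <- file.path(dir, "exposure.tsv")
    study$outcome_file <- file.path(dir, "outcome.tsv")
    study$ld_file <- file.path(dir, "ld.tsv")
    write_sumstats(exposure, study$exposure_file)
    write_sumstats(outcome, study$outcome_file)
    utils::write.table(
      data.frame(rsid_a = character(), rsid_b = character(), r2 = numeric()),
      study$ld_file, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}

#' Fixed-seed eight-instrument fixture study
#'
#' A deterministic synthetic study shaped like the validation target: 8
#' instruments, 2.65% exposure variance explained, exposure n = 7827,
#' biobank-magnitude case/control counts, no pleiotropy, true causal
#' effect -0.1 on the log-odds scale. Used as the default end-to-end test
#' input.
#'
#' @param dir Optional directory to write the study files to.
#' @return A `simulated_study` (see [simulate_study()]).
#' @export
make_paper_fixture <- function(dir = NULL) {
  simulate_study(sim_config(n_snps = 8, n_exposure = 7827,
                            n_outcome_cases = 6000,
                            n_outcome_controls = 190000,
                            beta_causal = -0.1, target_r2 = 0.0265,
                            seed = 20220405L),
                 dir = dir)
}
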