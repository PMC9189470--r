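#' Default pipeline configuration
#'
#' Thresholds and Monte-Carlo settings for [mr_analyze()] /
#' [mr_pipeline()]. Any subset can be overridden by name.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list: `p_threshold` (5e-8), `clump_r2` (0.1),
#'   `clump_window_kb` (10000), `maf_min` (0.05), `proxy_r2` (0.9),
#'   `palindrome_eaf_window` (0.08), `alpha` (0.05), `scale_multiplier`
#'   (1.1), `n_boot` (1000), `presso_sims` (1000), `seed` (1),
#'   `r2_exposure` (0.0265), `power_or` (c(1.1, 1.3)).
#' @export
mr_config <- function(...) {
  cfg <- list(p_threshold = 5e-8, clump_r2 = 0.1, clump_window_kb = 10000,
              maf_min = 0.05, proxy_r2 = 0.9, palindrome_eaf_window = 0.08,
              alpha = 0.05, scale_multiplier = 1.1, n_boot = 1000,
              presso_sims = 1000, seed = 1L, r2_exposure = 0.0265,
              power_or = c(1.1, 1.3))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Analyse one exposure/outcome pair end to end
#'
#' Runs the complete workflow for a single outcome: instrument selection
#' on the exposure GWAS (significance filter, LD clumping, MAF filter),
#' proxy lookup for instruments absent from the outcome GWAS,
#' harmonization, [mr_fit()], leave-one-out influence analysis,
#' instrument-strength statistics, odds-ratio scaling of the primary
#' estimate and (when case/control counts are supplied) binary-outcome
#' power at the configured alternatives.
#'
#' @param exposure,outcome Summary-statistics data.frames (see
#'   [read_sumstats()]).
#' @param ld An [ld_reference()].
#' @param config List from [mr_config()].
#' @param outcome_label Label used in reports.
#' @param n_cases,n_controls Outcome case/control counts for the power
#'   calculation (optional).
#' @return List of class `mr_analysis` with elements `outcome_label`,
#'   `selected`, `instruments`, `fit`, `loo`, `strength`, `scaled`,
#'   `power` (data.frame or `NULL`), `config`.
#' @export
mr_analyze <- function(exposure, outcome, ld = ld_reference(),
                       config = mr_config(), outcome_label = "outcome",
                       n_cases = NULL, n_controls = NULL) {
  selected <- select_instruments(exposure, ld,
                                 p_threshold = config$p_threshold,
                                 clump_r2 = config$clump_r2,
                                 clump_window_kb = config$clump_window_kb,
                                 maf_min = config$maf_min)
  if (nrow(selected) == 0) stop("no instruments pass selection")
  # proxy lookup for instruments missing from the outcome GWAS
  missing <- setdiff(selected$rsid, outcome$rsid)
  for (rs in missing) {
    proxy <- find_proxy(rs, outcome$rsid, ld, r2_min = config$proxy_r2)
    if (!is.na(proxy) && !(proxy %in% selected$rsid)) {
      # the proxy stands in for the requested SNP on the outcome side only
      # when it is also measured in the exposure GWAS
      if (proxy %in% exposure$rsid) {
        selected <- selected[selected$rsid != rs, , drop = FALSE]
        selected <- rbind(selected, exposure[match(proxy, exposure$rsid), ])
      }
    }
  }
  instruments <- harmonize(selected, outcome,
                           palindrome_eaf_window = config$palindrome_eaf_window)
  if (nrow(instruments) < 3) stop("fewer than 3 harmonized instruments")
  fit <- mr_fit(instruments, alpha = config$alpha, n_boot = config$n_boot,
                presso_sims = config$presso_sims, seed = config$seed,
                outcome = outcome_label)
  loo <- leave_one_out(instruments)
  strength <- instrument_strength(instruments, config$r2_exposure,
                                  n_exposure = max(exposure$n, na.rm = TRUE))
  scaled <- scale_to_or(fit$primary, config$scale_multiplier)
  power <- NULL
  if (!is.null(n_cases) && !is.null(n_controls)) {
    n_total <- n_cases + n_controls
    kfrac <- n_cases / n_total
    power <- do.call(rbind, lapply(config$power_or, function(or) {
      data.frame(or_alt = or,
                 power = mr_power_binary(n_total, kfrac,
                                         config$r2_exposure, or,
                                         alpha = config$alpha))
    }))
  }
  structure(list(outcome_label = outcome_label, selected = selected,
                 instruments = instruments, fit = fit, loo = loo,
                 strength = strength, scaled = scaled, power = power,
                 config = config),
            class = "mr_analysis")
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat("MR analysis:", x$outcome_label, "\n")
  print(x$fit)
  cat(sprintf("\nPrimary OR (x%.4g): %.3f (%.3f, %.3f)\n",
              x$scaled$scale_multiplier, x$scaled$or_scaled,
              x$scaled$or_ci_low, x$scaled$or_ci_high))
  invisible(x)
}

#' Run the pipeline over several outcomes and write the report bundle
#'
#' Applies [mr_analyze()] to each outcome and writes the report files via
#' [make_report()].
#'
#' @param exposure Summary-statistics data.frame.
#' @param outcomes Named list of outcome summary-statistics data.frames.
#' @param ld An [ld_reference()].
#' @param config List from [mr_config()].
#' @param out_dir Output directory for the report bundle (created if
#'   needed); `NULL` skips writing.
#' @param outcome_meta Optional data.frame with columns `outcome`,
#'   `n_cases`, `n_controls` enabling the power calculation.
#' @return Named list of `mr_analysis` objects, invisibly when `out_dir`
#'   is given.
#' @export
mr_pipeline <- function(exposure, outcomes, ld = ld_reference(),
                        config = mr_config(), out_dir = NULL,
                        outcome_meta = NULL) {
  stopifnot(length(outcomes) >= 1, !is.null(names(outcomes)))
  analyses <- lapply(names(outcomes), function(lab) {
    ncase <- nctrl <- NULL
    if (!is.null(outcome_meta) && lab %in% outcome_meta$outcome) {
      i <- match(lab, outcome_meta$outcome)
      ncase <- outcome_meta$n_cases[i]
      nctrl <- outcome_meta$n_controls[i]
    }
    mr_analyze(exposure, outcomes[[lab]], ld, config, outcome_label = lab,
               n_cases = ncase, n_controls = nctrl)
  })
  names(analyses) <- names(outcomes)
  if (!is.null(out_dir)) make_report(analyses, out_dir)
  invisible(analyses)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Write the report bundle for a set of analyses
#'
#' Emits, under `out_dir`: `summary.tsv` (one row per outcome:
#' heterogeneity Q and p, Egger intercept and p, chosen method, primary OR
#' with CI and p, significance flags at the nominal and
#' Bonferroni-corrected levels, power at the configured alternatives, mean
#' per-SNP F and I2-GX), `four_methods.tsv` (every estimator for every
#' outcome with OR scaling), per-outcome `scatter_<outcome>.tsv` (the
#' per-SNP effects and standard errors behind the scatter plots),
#' per-outcome `loo_<outcome>.tsv` (leave-one-out results), and
#' `manifest.json` (seeds, thresholds, package version). A human-readable
#' `summary_rounded.tsv` rounds ORs/CIs to 2 decimals and p-values to 3;
#' the machine files keep full precision.
#'
#' @param analyses Named list of `mr_analysis` objects.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
make_report <- function(analyses, out_dir) {
  stopifnot(length(analyses) >= 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  m <- length(analyses)
  alpha <- analyses[[1]]$config$alpha
  bonf <- bonferroni_threshold(alpha, m)

  summary_rows <- lapply(analyses, function(a) {
    het <- a$fit$heterogeneity[a$fit$heterogeneity$source == "ivw", ]
    pw <- a$power
    row <- data.frame(
      outcome = a$outcome_label, n_snp = nrow(a$instruments),
      q = het$q, q_pvalue = het$pvalue,
      egger_intercept = a$fit$pleiotropy$egger_intercept,
      intercept_pvalue = a$fit$pleiotropy$pvalue,
      primary_method = a$fit$decision$primary_method,
      or = a$scaled$or_scaled, or_ci_low = a$scaled$or_ci_low,
      or_ci_high = a$scaled$or_ci_high, pvalue = a$scaled$pvalue,
      sig_nominal = a$scaled$pvalue < alpha,
      sig_bonferroni = a$scaled$pvalue < bonf,
      mean_per_snp_f = a$strength$mean_per_snp_f,
      f_summary = a$strength$f_overall, i2_gx = a$strength$i2_gx,
      stringsAsFactors = FALSE)
    if (!is.null(pw)) {
      for (i in seq_len(nrow(pw))) {
        row[[sprintf("power_or_%.1f", pw$or_alt[i])]] <- pw$power[i]
      }
    }
    row
  })
  summary_tab <- do.call(rbind, summary_rows)
  utils::write.table(summary_tab, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hr <- summary_tab
  or_cols <- c("or", "or_ci_low", "or_ci_high")
  hr[or_cols] <- lapply(hr[or_cols], round, 2)
  p_cols <- c("q_pvalue", "intercept_pvalue", "pvalue")
  hr[p_cols] <- lapply(hr[p_cols], round, 3)
  utils::write.table(hr, file.path(out_dir, "summary_rounded.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  four <- do.call(rbind, lapply(analyses, function(a) {
    res <- a$fit$results
    sc <- scale_to_or(res, a$config$scale_multiplier)
    cbind(data.frame(outcome = a$outcome_label, stringsAsFactors = FALSE),
          res[, c("method", "n_snp", "beta", "se", "ci_low", "ci_high",
                  "pvalue")],
          sc[, c("or_scaled", "or_ci_low", "or_ci_high")])
  }))
  utils::write.table(four, file.path(out_dir, "four_methods.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  for (a in analyses) {
    scatter <- a$instruments[, c("rsid", "beta_exposure", "se_exposure",
                                 "beta_outcome", "se_outcome")]
    utils::write.table(scatter,
                       file.path(out_dir,
                                 paste0("scatter_", a$outcome_label, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(a$loo,
                       file.path(out_dir,
                                 paste0("loo_", a$outcome_label, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfg <- analyses[[1]]$config
  manifest <- list(
    package = "mrkit",
    version = as.character(utils::packageVersion("mrkit")),
    outcomes = vapply(analyses, function(a) a$outcome_label, character(1)),
    config = cfg,
    bonferroni_threshold = bonf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
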