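#' Fit the full set of two-sample MR estimators with diagnostics
#'
#' The central fitting function. From a table of harmonized instruments it
#' computes the per-SNP Wald ratios, the four causal estimators
#' (fixed-effect IVW, multiplicative-random-effects IVW, MR-Egger,
#' weighted median, weighted mode), the heterogeneity (Cochran's Q,
#' Rucker's Q') and horizontal-pleiotropy (Egger intercept) diagnostics,
#' and applies the flowchart rule to choose the primary method. MR-PRESSO
#' is run when the flowchart reaches the heterogeneity-without-pleiotropy
#' branch (or when `run_presso = TRUE`); when PRESSO flags outliers the
#' outlier-corrected IVW estimate is reported as primary.
#'
#' @param instruments Harmonized-instrument data.frame with columns
#'   `rsid`, `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`
#'   (see [harmonize()] or [simulate_study()]).
#' @param alpha Detection threshold for the flowchart tests (default
#'   0.05).
#' @param n_boot Bootstrap replicates for the weighted median/mode
#'   standard errors (default 1000).
#' @param presso_sims MR-PRESSO simulation count (default 1000).
#' @param seed Integer seed for all Monte-Carlo components.
#' @param run_presso Force MR-PRESSO regardless of the flowchart branch
#'   (`NULL`, the default, runs it only on the heterogeneity branch).
#' @param outcome Optional outcome label stored in the fit.
#' @return Object of class `mr_fit`: list with `instruments`, `wald`,
#'   `results` (five-method data.frame), `heterogeneity` (IVW and Egger
#'   rows), `pleiotropy`, `decision`, `presso` (or `NULL`), `primary`
#'   (one-row data.frame), `alpha`, `seed`, `outcome`, `call`.
#' @seealso [leave_one_out()], [instrument_strength()], [scale_to_or()]
#' @examples
#' study <- simulate_study(sim_config(n_snps = 8, seed = 7))
#' fit <- mr_fit(study$instruments, n_boot = 100, seed = 7)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(instruments, alpha = 0.05, n_boot = 1000,
                   presso_sims = 1000, seed = 1L, run_presso = NULL,
                   outcome = NULL) {
  cl <- match.call()
  n <- nrow(instruments)
  if (n < 3) stop("mr_fit requires at least 3 instruments")
  ratios <- wald_ratios(instruments)
  results <- rbind(
    mr_ivw(ratios, "fe"),
    mr_ivw(ratios, "mre"),
    mr_egger(instruments),
    mr_weighted_median(ratios, n_boot = n_boot, seed = seed),
    mr_weighted_mode(ratios, n_boot = n_boot, seed = seed + 1L)
  )
  het <- rbind(cochran_q(ratios), rucker_q(instruments))
  pleio <- egger_intercept_test(instruments)
  decision <- select_method(pleio, het[het$source == "ivw", ], alpha)
  presso <- NULL
  want_presso <- isTRUE(run_presso) ||
    (is.null(run_presso) && decision$primary_method == "ivw_mre" && n >= 4)
  if (want_presso) {
    presso <- mr_presso(instruments, n_sim = presso_sims, seed = seed + 2L)
  }
  primary <- results[results$method == decision$primary_method, , drop = FALSE]
  if (!is.null(presso) && length(presso$outliers_flagged) > 0 &&
      decision$primary_method == "ivw_mre") {
    primary <- presso$corrected_estimate
    primary$method <- "presso_corrected_ivw"
    decision$primary_method <- "presso_corrected_ivw"
    decision$rationale <- paste(decision$rationale,
                                "| PRESSO flagged outliers: outlier-corrected",
                                "IVW reported as primary")
  }
  structure(list(instruments = instruments, wald = ratios, results = results,
                 heterogeneity = het, pleiotropy = pleio, decision = decision,
                 presso = presso, primary = primary, alpha = alpha,
                 n_boot = n_boot, seed = seed, outcome = outcome, call = cl),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample MR fit",
      if (!is.null(x$outcome)) paste0("(outcome: ", x$outcome, ")"),
      "\n")
  cat("Instruments:", nrow(x$instruments), "\n\n")
  tab <- x$results[, c("method", "n_snp", "beta", "se", "ci_low", "ci_high",
                       "pvalue")]
  print(format(tab, digits = digits), row.names = FALSE)
  cat("\nPrimary method:", x$decision$primary_method, "\n")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nHeterogeneity:\n")
  print(format(f$heterogeneity, digits = digits), row.names = FALSE)
  cat("\nHorizontal pleiotropy (Egger intercept):\n")
  print(format(f$pleiotropy, digits = digits), row.names = FALSE)
  cat("\n", f$decision$rationale, "\n", sep = "")
  if (!is.null(f$presso)) { cat("\n"); print(f$presso) }
  cat("\nDirection concordant across methods:",
      direction_concordance(f$results), "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, method = NULL, ...) {
  res <- object$results
  if (is.null(method)) {
    stats::setNames(res$beta, res$method)
  } else {
    res$beta[res$method == method]
  }
}

#' @export
confint.mr_fit <- function(object, parm = NULL, level = 0.95, ...) {
  res <- object$results
  if (!is.null(parm)) res <- res[res$method %in% parm, , drop = FALSE]
  out <- as.matrix(res[, c("ci_low", "ci_high")])
  rownames(out) <- res$method
  out
}

#' Residuals of an MR fit
#'
#' Weighted residuals of the outcome effects about the fitted line of the
#' chosen method (through the origin for IVW, with intercept for Egger),
#' on the scale in which their squares sum to the respective Q statistic.
#'
#' @param object An `mr_fit`.
#' @param method `"ivw_fe"`, `"ivw_mre"` or `"egger"`.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
residuals.mr_fit <- function(object, method = "ivw_fe", ...) {
  ins <- object$instruments
  flip <- sign(ins$beta_exposure)
  x <- ins$beta_exposure * flip
  y <- ins$beta_outcome * flip
  w <- 1 / ins$se_outcome^2
  if (method == "egger") {
    b <- object$results[object$results$method == "egger", ]
    r <- y - b$intercept - b$beta * x
  } else {
    b <- object$results[object$results$method == method, ]
    r <- y - b$beta * x
  }
  stats::setNames(r * sqrt(w), as.character(ins$rsid))
}

#' Scatter plot of an MR fit
#'
#' SNP-exposure effects against SNP-outcome effects (oriented so exposure
#' effects are positive), with per-SNP 95% error bars and the fitted lines
#' of the requested methods. This is the data behind the standard MR
#' scatter diagnostic.
#'
#' @param x An `mr_fit`.
#' @param methods Methods whose fitted lines are drawn.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, methods = c("ivw_fe", "egger"), ...) {
  ins <- x$instruments
  flip <- sign(ins$beta_exposure)
  gx <- ins$beta_exposure * flip
  gy <- ins$beta_outcome * flip
  graphics::plot(gx, gy, pch = 19,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 xlim = range(0, gx + 1.96 * ins$se_exposure),
                 ...)
  graphics::arrows(gx, gy - 1.96 * ins$se_outcome, gx,
                   gy + 1.96 * ins$se_outcome,
                   angle = 90, code = 3, length = 0.02)
  graphics::arrows(gx - 1.96 * ins$se_exposure, gy,
                   gx + 1.96 * ins$se_exposure, gy,
                   angle = 90, code = 3, length = 0.02)
  cols <- stats::setNames(seq_along(methods) + 1, methods)
  for (m in methods) {
    b <- x$results[x$results$method == m, ]
    icpt <- if (m == "egger") b$intercept else 0
    graphics::abline(icpt, b$beta, col = cols[[m]])
  }
  graphics::legend("topleft", legend = methods, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
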