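#' Read a pairwise LD reference table
#'
#' The LD reference is a plain TSV with columns `rsid_a`, `rsid_b`, `r2`
#' and, optionally, `chrom_a`, `pos_a`, `chrom_b`, `pos_b`. r-squared is
#' stored symmetrically; the diagonal r2(i, i) = 1 is implied and need not
#' be listed.
#'
#' @param path Path to the TSV.
#' @return An object of class `ld_reference`: a list with `pairs`
#'   (data.frame `rsid_a`, `rsid_b`, `r2`) and `positions` (data.frame
#'   `rsid`, `chrom`, `pos`, possibly empty).
#' @export
read_ld <- function(path) {
  dat <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("rsid_a", "rsid_b", "r2")
  if (!all(need %in% names(dat))) {
    stop("LD reference must have columns rsid_a, rsid_b, r2")
  }
  positions <- NULL
  if (all(c("chrom_a", "pos_a", "chrom_b", "pos_b") %in% names(dat))) {
    positions <- unique(rbind(
      data.frame(rsid = dat$rsid_a, chrom = dat$chrom_a, pos = dat$pos_a,
                 stringsAsFactors = FALSE),
      data.frame(rsid = dat$rsid_b, chrom = dat$chrom_b, pos = dat$pos_b,
                 stringsAsFactors = FALSE)))
  }
  ld_reference(dat[, need], positions)
}

#' Construct an LD reference object
#'
#' @param pairs data.frame with columns `rsid_a`, `rsid_b`, `r2` in [0, 1].
#' @param positions Optional data.frame with columns `rsid`, `chrom`, `pos`
#'   used for distance windowing during clumping.
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(pairs = NULL, positions = NULL) {
  if (is.null(pairs)) {
    pairs <- data.frame(rsid_a = character(), rsid_b = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1, na.rm = TRUE)) {
    stop("r2 values must lie in [0, 1]")
  }
  structure(list(pairs = pairs, positions = positions),
            class = "ld_reference")
}

# Symmetric lookup; absent pairs are unlinked (r2 = 0), identity pairs 1.
ld_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  p <- ld$pairs
  hit <- (p$rsid_a == a & p$rsid_b == b) | (p$rsid_a == b & p$rsid_b == a)
  if (!any(hit)) return(0)
  max(p$r2[hit])
}

#' Filter SNPs on association p-value
#'
#' Retains SNPs whose exposure p-value is below the genome-wide
#' significance threshold, preserving input order.
#'
#' @param snps Summary-statistics data.frame.
#' @param threshold Retain rows with `pvalue < threshold` (default 5e-8).
#' @return Filtered data.frame.
#' @export
filter_pvalue <- function(snps, threshold = 5e-8) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- snps[snps$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter SNPs on minor allele frequency
#'
#' Removes SNPs with minor allele frequency below `maf_min`; a SNP at
#' exactly the boundary is retained. Rows with missing eaf are kept and
#' counted in a warning.
#'
#' @param snps Summary-statistics data.frame.
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @return Filtered data.frame.
#' @export
filter_maf <- function(snps, maf_min = 0.05) {
  maf <- pmin(snps$eaf, 1 - snps$eaf)
  missing <- is.na(maf)
  if (any(missing)) {
    warning(sum(missing), " SNP(s) with missing eaf retained by MAF filter")
  }
  out <- snps[missing | maf >= maf_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of significant SNPs
#'
#' Orders candidates by ascending p-value (ties broken by rsid) and accepts
#' each SNP unless it is in LD (`r2 >= r2_max`) with an already-accepted
#' SNP, so of any linked pair only the SNP with the lower p-value is
#' retained. When positions are available in the LD reference, only pairs
#' within `window_kb` kilobases on the same chromosome are tested;
#' otherwise every pair is tested. Pairs absent from the LD reference are
#' treated as unlinked.
#'
#' @param snps Summary-statistics data.frame.
#' @param ld An [ld_reference()] object.
#' @param r2_max Clumping threshold (default 0.1).
#' @param window_kb Window size in kb (default 10000).
#' @return The retained SNPs, ordered by ascending p-value.
#' @export
clump_snps <- function(snps, ld, r2_max = 0.1, window_kb = 10000) {
  if (nrow(snps) == 0) return(snps)
  ord <- order(snps$pvalue, snps$rsid)
  cand <- snps[ord, , drop = FALSE]
  pos <- ld$positions
  within_window <- function(a, b) {
    if (is.null(pos)) return(TRUE)
    ia <- match(a, pos$rsid); ib <- match(b, pos$rsid)
    if (is.na(ia) || is.na(ib)) return(TRUE)
    pos$chrom[ia] == pos$chrom[ib] &&
      abs(pos$pos[ia] - pos$pos[ib]) <= window_kb * 1000
  }
  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    conflict <- FALSE
    for (j in accepted) {
      if (within_window(cand$rsid[i], cand$rsid[j]) &&
          ld_r2(ld, cand$rsid[i], cand$rsid[j]) >= r2_max) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) accepted <- c(accepted, i)
  }
  out <- cand[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find an LD proxy for a missing SNP
#'
#' Returns the available SNP with the highest r-squared to `target`
#' strictly above `r2_min`, or `NA` when none qualifies. Ties are broken
#' by lexicographically smallest rsid; the target itself (r2 = 1) is
#' returned when available.
#'
#' @param target rsID requested.
#' @param available Character vector of rsIDs present in the outcome GWAS.
#' @param ld An [ld_reference()] object.
#' @param r2_min Minimum LD with the target (default 0.9, strict
#'   inequality).
#' @return A single rsID or `NA_character_`.
#' @export
find_proxy <- function(target, available, ld, r2_min = 0.9) {
  if (length(available) == 0) return(NA_character_)
  r2 <- vapply(available, function(a) ld_r2(ld, target, a), numeric(1))
  ok <- r2 > r2_min
  if (!any(ok)) return(NA_character_)
  best <- max(r2[ok])
  cands <- sort(available[ok][r2[ok] == best])
  cands[1]
}

#' Instrument-strength statistics
#'
#' Quantifies the collective strength of an instrument set. `f_overall` is
#' the textbook summary F-statistic
#' \deqn{F = \frac{R^2 / k}{(1 - R^2)/(n - k - 1)}}{F = (R2/k) / ((1-R2)/(n-k-1))}
#' from the exposure variance explained; `per_snp_f` are the per-SNP Wald
#' statistics (beta/se)^2 whose mean is the commonly reported "mean F".
#' `i2_gx` is the regression-dilution statistic for the MR-Egger slope,
#' computed from the heterogeneity of the exposure effects oriented to
#' positive sign: I2GX = max(0, (Q_GX - (k-1)) / Q_GX) with
#' Q_GX the inverse-variance-weighted sum of squares of the oriented
#' exposure effects about their weighted mean.
#'
#' @param instruments Harmonized-instrument data.frame (needs
#'   `beta_exposure`, `se_exposure`).
#' @param r2_exposure Proportion of exposure variance explained by the
#'   instrument set, in (0, 1).
#' @param n_exposure Exposure GWAS sample size (> k + 1).
#' @return List of class `instrument_strength` with `f_overall`,
#'   `per_snp_f`, `mean_per_snp_f`, `i2_gx`, `r2_exposure`, `k`.
#' @export
instrument_strength <- function(instruments, r2_exposure, n_exposure) {
  k <- nrow(instruments)
  if (k == 0) stop("no instruments")
  stopifnot(r2_exposure > 0, r2_exposure < 1, n_exposure > k + 1)
  g <- instruments$beta_exposure
  s <- instruments$se_exposure
  f_overall <- (r2_exposure / k) / ((1 - r2_exposure) / (n_exposure - k - 1))
  per_snp_f <- (g / s)^2
  w <- 1 / s^2
  ga <- abs(g) # Egger orientation: exposure effects taken positive
  gbar <- sum(w * ga) / sum(w)
  q_gx <- sum(w * (ga - gbar)^2)
  i2_gx <- if (q_gx > 0) max(0, (q_gx - (k - 1)) / q_gx) else 0
  structure(list(f_overall = f_overall, per_snp_f = per_snp_f,
                 mean_per_snp_f = mean(per_snp_f), i2_gx = i2_gx,
                 r2_exposure = r2_exposure, k = k),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat("Instrument strength (k =", x$k, ")\n")
  cat(sprintf("  R^2 explained:        %.4f\n", x$r2_exposure))
  cat(sprintf("  F (summary formula):  %.1f\n", x$f_overall))
  cat(sprintf("  mean per-SNP F:       %.1f\n", x$mean_per_snp_f))
  cat(sprintf("  I2-GX:                %.1f%%\n", 100 * x$i2_gx))
  invisible(x)
}

#' Select instruments from an exposure GWAS
#'
#' Applies the standard quality-control cascade: genome-wide significance
#' filter, LD clumping, and minor-allele-frequency filter.
#'
#' @param exposure Summary-statistics data.frame.
#' @param ld An [ld_reference()] object.
#' @param p_threshold Significance threshold (default 5e-8).
#' @param clump_r2,clump_window_kb Clumping parameters (defaults 0.1,
#'   10000).
#' @param maf_min MAF threshold (default 0.05).
#' @return Filtered, clumped summary-statistics data.frame.
#' @export
select_instruments <- function(exposure, ld = ld_reference(),
                               p_threshold = 5e-8, clump_r2 = 0.1,
                               clump_window_kb = 10000, maf_min = 0.05) {
  out <- filter_pvalue(exposure, p_threshold)
  out <- clump_snps(out, ld, r2_max = clump_r2, window_kb = clump_window_kb)
  filter_maf(out, maf_min)
}
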