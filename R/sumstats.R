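#' @keywords internal
"_PACKAGE"

VALID_ALLELES <- c("A", "C", "G", "T")

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Default column mapping for summary-statistics files
#'
#' Maps the internal field names to the column names expected in a
#' delimited summary-statistics file. Pass a modified copy to
#' [read_sumstats()] when a file uses different headers.
#'
#' @return Named character vector: internal name -> file column name.
#' @export
default_column_map <- function() {
  c(rsid = "SNP", effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pvalue = "pval", n = "samplesize")
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited file with a header line, remaps columns
#' via `column_map`, normalises alleles to upper case and validates every
#' row. Rows violating the record invariants (identical alleles, alleles
#' other than A/C/G/T, non-positive standard error, p-value outside (0, 1],
#' allele frequency outside [0, 1]) are dropped with a warning giving the
#' count; `eaf` and `n` may be missing (NA).
#'
#' @param path Path to the file. The delimiter is taken from the extension
#'   (".csv" means comma, anything else tab) unless `sep` is given.
#' @param column_map Named character vector mapping internal names
#'   (`rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`) to file column names; see [default_column_map()].
#'   `eaf` and `n` columns are optional in the file.
#' @param sep Field separator; `NULL` (default) to infer from the extension.
#' @return A `data.frame` with columns `rsid`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, one row per valid
#'   SNP, with attribute `n_skipped` giving the number of dropped rows.
#' @export
read_sumstats <- function(path, column_map = default_column_map(), sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  map <- default_column_map()
  map[names(column_map)] <- column_map
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(map[mandatory], names(raw))
  if (length(missing_cols) > 0) {
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  get_col <- function(field, numeric = FALSE) {
    col <- map[[field]]
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    x <- raw[[col]]
    if (numeric) suppressWarnings(as.numeric(x)) else as.character(x)
  }
  dat <- data.frame(
    rsid = get_col("rsid"),
    effect_allele = toupper(trimws(get_col("effect_allele"))),
    other_allele = toupper(trimws(get_col("other_allele"))),
    eaf = get_col("eaf", numeric = TRUE),
    beta = get_col("beta", numeric = TRUE),
    se = get_col("se", numeric = TRUE),
    pvalue = get_col("pvalue", numeric = TRUE),
    n = get_col("n", numeric = TRUE),
    stringsAsFactors = FALSE
  )
  valid <- validate_sumstats(dat)
  n_skipped <- sum(!valid)
  if (n_skipped > 0) {
    warning(sprintf("%d row(s) of %s failed validation and were skipped",
                    n_skipped, path))
  }
  dat <- dat[valid, , drop = FALSE]
  if (nrow(dat) == 0) stop("no valid summary-statistics rows in ", path)
  rownames(dat) <- NULL
  attr(dat, "n_skipped") <- n_skipped
  dat
}

# Row-wise invariant check; returns a logical keep-vector.
validate_sumstats <- function(dat) {
  ok <- !is.na(dat$rsid) & nzchar(dat$rsid) &
    dat$effect_allele %in% VALID_ALLELES &
    dat$other_allele %in% VALID_ALLELES &
    dat$effect_allele != dat$other_allele &
    !is.na(dat$beta) & is.finite(dat$beta) &
    !is.na(dat$se) & dat$se > 0 &
    !is.na(dat$pvalue) & dat$pvalue > 0 & dat$pvalue <= 1
  ok & (is.na(dat$eaf) | (dat$eaf >= 0 & dat$eaf <= 1)) &
    (is.na(dat$n) | dat$n > 0)
}

#' Write GWAS summary statistics to a delimited text file
#'
#' Inverse of [read_sumstats()]: writes the standard columns under the
#' names given by `column_map`.
#'
#' @inheritParams read_sumstats
#' @param dat Summary-statistics `data.frame` as returned by
#'   [read_sumstats()] or [simulate_study()].
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(dat, path, column_map = default_column_map(), sep = "\t") {
  fields <- c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se",
              "pvalue", "n")
  out <- dat[, fields]
  map <- default_column_map()
  map[names(column_map)] <- column_map
  names(out) <- unname(map[fields])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are complementary (A/T or
#' C/G), so the strand cannot be resolved from the alleles alone.
#'
#' @param a1,a2 Single alleles, one of A/C/G/T (case-insensitive).
#' @return Logical (vectorised over `a1`, `a2`).
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  if (!all(a1 %in% VALID_ALLELES) || !all(a2 %in% VALID_ALLELES)) {
    stop("invalid allele; expected one of A/C/G/T")
  }
  unname(ALLELE_COMPLEMENT[a1] == a2)
}

flip_strand <- function(a) unname(ALLELE_COMPLEMENT[toupper(a)])

#' Harmonize one exposure/outcome SNP pair onto a common effect allele
#'
#' Expresses the outcome association on the exposure's effect allele.
#' Non-palindromic pairs are matched directly, by allele swap (outcome beta
#' negated, eaf complemented), or after strand complementation; pairs whose
#' allele sets cannot be reconciled are dropped. Palindromic SNPs (A/T or
#' C/G) cannot be oriented from alleles alone: they are retained only when
#' both allele frequencies are present, both lie outside the ambiguity
#' window `0.5 +/- palindrome_eaf_window`, and the frequencies agree on the
#' orientation; otherwise they are dropped. `palindrome_eaf_window = Inf`
#' reproduces the strict policy of always excluding palindromic SNPs.
#'
#' @param exposure,outcome Single-row records (lists or one-row data
#'   frames) with fields `rsid`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se` (exposure and outcome must share `rsid`).
#' @param palindrome_eaf_window Half-width w of the frequency ambiguity
#'   window around 0.5 (default 0.08: drop when either eaf is in
#'   [0.42, 0.58]).
#' @return One-row `data.frame` with columns `rsid`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `eaf_exposure`,
#'   `eaf_outcome` and `action_taken` (one of `"none"`,
#'   `"outcome_flipped"`, `"dropped_palindromic"`,
#'   `"dropped_incompatible"`). For dropped SNPs the outcome columns are NA.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  exposure <- as.list(exposure); outcome <- as.list(outcome)
  if (!identical(as.character(exposure$rsid), as.character(outcome$rsid))) {
    stop("rsid mismatch: ", exposure$rsid, " vs ", outcome$rsid)
  }
  ea <- toupper(exposure$effect_allele); oa <- toupper(exposure$other_allele)
  eb <- toupper(outcome$effect_allele); ob <- toupper(outcome$other_allele)
  for (a in c(ea, oa, eb, ob)) {
    if (!a %in% VALID_ALLELES) stop("invalid allele '", a, "' for ", exposure$rsid)
  }
  res <- data.frame(
    rsid = as.character(exposure$rsid),
    beta_exposure = exposure$beta, se_exposure = exposure$se,
    beta_outcome = NA_real_, se_outcome = NA_real_,
    eaf_exposure = if (is.null(exposure$eaf)) NA_real_ else exposure$eaf,
    eaf_outcome = NA_real_,
    action_taken = NA_character_, stringsAsFactors = FALSE
  )
  drop <- function(reason) { res$action_taken <- reason; res }

  out_beta <- outcome$beta
  out_eaf <- if (is.null(outcome$eaf)) NA_real_ else outcome$eaf

  if (is_palindromic(ea, oa)) {
    # Strand is unresolvable from alleles; outcome allele set must at least
    # coincide with the exposure's (a palindromic pair is its own complement).
    if (!setequal(c(eb, ob), c(ea, oa))) return(drop("dropped_incompatible"))
    exp_eaf <- res$eaf_exposure
    if (is.na(exp_eaf) || is.na(out_eaf)) return(drop("dropped_palindromic"))
    w <- palindrome_eaf_window
    ambiguous <- function(f) f >= 0.5 - w && f <= 0.5 + w
    if (ambiguous(exp_eaf) || ambiguous(out_eaf)) return(drop("dropped_palindromic"))
    action <- "none"
    if (eb != ea) { # reported on the opposite allele label
      out_beta <- -out_beta; out_eaf <- 1 - out_eaf; action <- "outcome_flipped"
    }
    # Orientation check: after label alignment the frequencies must fall on
    # the same side of 0.5, else the outcome study is on the other strand
    # and the reported allele label is misleading -> unresolvable.
    if ((exp_eaf < 0.5) != (out_eaf < 0.5)) return(drop("dropped_palindromic"))
    res$beta_outcome <- out_beta; res$se_outcome <- outcome$se
    res$eaf_outcome <- out_eaf; res$action_taken <- action
    return(res)
  }

  if (eb == ea && ob == oa) {
    action <- "none"
  } else if (eb == oa && ob == ea) {
    out_beta <- -out_beta
    if (!is.na(out_eaf)) out_eaf <- 1 - out_eaf
    action <- "outcome_flipped"
  } else {
    ebf <- flip_strand(eb); obf <- flip_strand(ob)
    if (ebf == ea && obf == oa) {
      action <- "none"
    } else if (ebf == oa && obf == ea) {
      out_beta <- -out_beta
      if (!is.na(out_eaf)) out_eaf <- 1 - out_eaf
      action <- "outcome_flipped"
    } else {
      return(drop("dropped_incompatible"))
    }
  }
  res$beta_outcome <- out_beta; res$se_outcome <- outcome$se
  res$eaf_outcome <- out_eaf; res$action_taken <- action
  res
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins two summary-statistics tables on `rsid` and applies
#' [harmonize_pair()] to every shared SNP.
#'
#' @param exposure,outcome Summary-statistics data frames (see
#'   [read_sumstats()]).
#' @inheritParams harmonize_pair
#' @param audit_file Optional path; when given, a two-column TSV
#'   (`rsid`, `action_taken`) covering every shared SNP is written there.
#' @return `data.frame` of harmonized instruments (dropped SNPs excluded),
#'   with the full audit table (including drops) in attribute `"audit"`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                      audit_file = NULL) {
  shared <- intersect(exposure$rsid, outcome$rsid)
  rows <- lapply(shared, function(rs) {
    harmonize_pair(exposure[match(rs, exposure$rsid), ],
                   outcome[match(rs, outcome$rsid), ],
                   palindrome_eaf_window = palindrome_eaf_window)
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    rsid = character(), beta_exposure = numeric(), se_exposure = numeric(),
    beta_outcome = numeric(), se_outcome = numeric(),
    eaf_exposure = numeric(), eaf_outcome = numeric(),
    action_taken = character(), stringsAsFactors = FALSE
  )
  audit <- out[, c("rsid", "action_taken")]
  if (!is.null(audit_file)) {
    utils::write.table(audit, audit_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  kept <- out[!grepl("^dropped", out$action_taken), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "audit") <- audit
  kept
}
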