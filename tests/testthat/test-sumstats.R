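test_that("well-formed files round-trip through read_sumstats", {
  dat <- rbind(make_snp("rs1"), make_snp("rs2", ea = "C", oa = "T"),
               make_snp("rs3", beta = -0.05))
  path <- write_sumstats_file(dat)
  got <- read_sumstats(path)
  expect_equal(nrow(got), 3)
  expect_equal(attr(got, "n_skipped"), 0)
  expect_equal(got$beta, dat$beta)
  expect_equal(got$rsid, dat$rsid)
})

test_that("invalid rows are skipped with a warning, alleles are upper-cased", {
  dat <- rbind(make_snp("rs1"), make_snp("rs2", se = 0),
               make_snp("rs3", ea = "a", oa = "t", eaf = 0.2))
  path <- write_sumstats_file(dat)
  expect_warning(got <- read_sumstats(path), "skipped")
  expect_equal(got$rsid, c("rs1", "rs3"))
  expect_equal(attr(got, "n_skipped"), 1)
  expect_equal(got$effect_allele[2], "A")
  expect_equal(got$other_allele[2], "T")
})

test_that("missing mandatory columns and empty files are fatal", {
  dat <- make_snp("rs1")
  path <- tempfile(fileext = ".tsv")
  out <- dat[, setdiff(names(dat), "se")]
  names(out) <- c("SNP", "effect_allele", "other_allele", "eaf", "beta",
                  "pval", "samplesize")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "mandatory")

  bad <- make_snp("rs1", se = -1)
  path2 <- write_sumstats_file(bad)
  suppressWarnings(expect_error(read_sumstats(path2), "no valid"))
})

test_that("column remapping and csv dialect are honoured", {
  dat <- make_snp("rs9", beta = 0.2)
  path <- tempfile(fileext = ".csv")
  out <- dat
  names(out) <- c("marker", "A1", "A2", "freq", "b", "stderr", "p", "N")
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  got <- read_sumstats(path, column_map = c(
    rsid = "marker", effect_allele = "A1", other_allele = "A2",
    eaf = "freq", beta = "b", se = "stderr", pvalue = "p", n = "N"))
  expect_equal(got$beta, 0.2)
  expect_equal(got$rsid, "rs9")
})

test_that("palindromic allele pairs are recognised", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("t", "a"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
  expect_error(is_palindromic("A", "N"), "allele")
})

test_that("harmonization follows the allele truth table", {
  # hand-written truth table: exposure A/G beta 0.1 eaf 0.3 against every
  # reconcilable and irreconcilable outcome orientation (outcome beta 0.3,
  # eaf 0.8)
  exp <- make_snp("rs1", ea = "A", oa = "G", eaf = 0.3, beta = 0.1)
  cases <- list(
    list(ea = "A", oa = "G", action = "none",            beta = 0.3, eaf = 0.8),
    list(ea = "G", oa = "A", action = "outcome_flipped", beta = -0.3, eaf = 0.2),
    list(ea = "T", oa = "C", action = "none",            beta = 0.3, eaf = 0.8),
    list(ea = "C", oa = "T", action = "outcome_flipped", beta = -0.3, eaf = 0.2),
    list(ea = "A", oa = "C", action = "dropped_incompatible"),
    list(ea = "C", oa = "A", action = "dropped_incompatible"),
    list(ea = "A", oa = "T", action = "dropped_incompatible"),
    list(ea = "C", oa = "G", action = "dropped_incompatible")
  )
  for (cs in cases) {
    out <- make_snp("rs1", ea = cs$ea, oa = cs$oa, eaf = 0.8, beta = 0.3)
    h <- harmonize_pair(exp, out)
    expect_equal(h$action_taken, cs$action, info = paste(cs$ea, cs$oa))
    if (!grepl("dropped", cs$action)) {
      expect_equal(h$beta_outcome, cs$beta, info = paste(cs$ea, cs$oa))
      expect_equal(h$eaf_outcome, cs$eaf, info = paste(cs$ea, cs$oa))
      expect_equal(h$beta_exposure, 0.1)
    }
  }
})

test_that("palindromic SNPs follow the frequency rules", {
  # ambiguous frequency inside the default window [0.42, 0.58] -> dropped
  exp_amb <- make_snp("rs1", ea = "A", oa = "T", eaf = 0.49)
  out <- make_snp("rs1", ea = "A", oa = "T", eaf = 0.2, beta = 0.3)
  expect_equal(harmonize_pair(exp_amb, out)$action_taken,
               "dropped_palindromic")

  # clear concordant frequencies, same labels -> retained unchanged
  exp <- make_snp("rs1", ea = "A", oa = "T", eaf = 0.2, beta = 0.1)
  h <- harmonize_pair(exp, out)
  expect_equal(h$action_taken, "none")
  expect_equal(h$beta_outcome, 0.3)

  # swapped labels with complementary frequency -> flipped
  out_sw <- make_snp("rs1", ea = "T", oa = "A", eaf = 0.8, beta = 0.3)
  h2 <- harmonize_pair(exp, out_sw)
  expect_equal(h2$action_taken, "outcome_flipped")
  expect_equal(h2$beta_outcome, -0.3)
  expect_equal(h2$eaf_outcome, 0.2)

  # discordant frequencies (strand mismatch) -> dropped
  out_disc <- make_snp("rs1", ea = "A", oa = "T", eaf = 0.8, beta = 0.3)
  expect_equal(harmonize_pair(exp, out_disc)$action_taken,
               "dropped_palindromic")

  # missing outcome eaf -> always dropped
  out_na <- make_snp("rs1", ea = "A", oa = "T", eaf = NA, beta = 0.3)
  expect_equal(harmonize_pair(exp, out_na)$action_taken,
               "dropped_palindromic")

  # infinite window reproduces the always-exclude policy
  expect_equal(harmonize_pair(exp, out,
                              palindrome_eaf_window = Inf)$action_taken,
               "dropped_palindromic")
})

test_that("harmonization preserves magnitudes and is involutive", {
  set.seed(42)
  pairs_all <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("A", "T"),
                    c("C", "G"))
  for (i in 1:40) {
    al <- pairs_all[[sample.int(5, 1)]]
    exp <- make_snp("rsX", ea = al[1], oa = al[2],
                    eaf = runif(1, 0.05, 0.95), beta = rnorm(1))
    swap <- runif(1) < 0.5
    out_al <- if (swap) rev(al) else al
    out <- make_snp("rsX", ea = out_al[1], oa = out_al[2],
                    eaf = if (swap) 1 - exp$eaf else exp$eaf,
                    beta = rnorm(1), se = 0.05)
    h <- harmonize_pair(exp, out)
    if (!grepl("dropped", h$action_taken)) {
      expect_equal(abs(h$beta_outcome), abs(out$beta))
      expect_equal(h$se_outcome, out$se)
      expect_equal(h$se_exposure, exp$se)
    }
    # involution: re-reporting the outcome on the other allele changes nothing
    out_flip <- out
    out_flip$effect_allele <- out$other_allele
    out_flip$other_allele <- out$effect_allele
    out_flip$beta <- -out$beta
    out_flip$eaf <- 1 - out$eaf
    h2 <- harmonize_pair(exp, out_flip)
    # same retention decision; harmonized values identical when retained
    expect_equal(grepl("dropped", h2$action_taken),
                 grepl("dropped", h$action_taken))
    if (!grepl("dropped", h$action_taken)) {
      expect_equal(h2$beta_outcome, h$beta_outcome)
      expect_equal(h2$eaf_outcome, h$eaf_outcome)
    }
  }
})

test_that("non-palindromic consistent input passes through bit-identically", {
  exp <- make_snp("rs1", ea = "A", oa = "G", beta = 0.123456789)
  out <- make_snp("rs1", ea = "A", oa = "G", beta = -0.987654321, se = 0.5,
                  eaf = 0.77)
  h <- harmonize_pair(exp, out)
  expect_identical(h$beta_outcome, out$beta)
  expect_identical(h$se_outcome, out$se)
  expect_identical(h$eaf_outcome, out$eaf)
  expect_identical(h$action_taken, "none")
})

test_that("harmonize joins on rsid and writes the audit trail", {
  exp <- rbind(make_snp("rs1"), make_snp("rs2", ea = "C", oa = "T"),
               make_snp("rs3", ea = "A", oa = "T", eaf = 0.5))
  out <- rbind(make_snp("rs1", beta = 0.3), make_snp("rs2", ea = "T", oa = "C",
                                                     beta = 0.2, eaf = 0.6),
               make_snp("rs3", ea = "A", oa = "T", beta = 0.1),
               make_snp("rs4"))
  audit_file <- tempfile(fileext = ".tsv")
  h <- harmonize(exp, out, audit_file = audit_file)
  expect_equal(nrow(h), 2)
  expect_equal(h$beta_outcome[h$rsid == "rs2"], -0.2)
  audit <- read.delim(audit_file)
  expect_equal(nrow(audit), 3) # rs4 not shared
  expect_equal(audit$action_taken[audit$rsid == "rs3"],
               "dropped_palindromic")
  expect_error(harmonize_pair(make_snp("rs1"), make_snp("rs2")), "mismatch")
})
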