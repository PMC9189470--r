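# Small constructors used across the suite.

make_snp <- function(rsid = "rs1", ea = "A", oa = "G", eaf = 0.3,
                     beta = 0.1, se = 0.02, pvalue = NULL, n = 7827) {
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = pvalue, n = n,
             stringsAsFactors = FALSE)
}

make_instruments <- function(beta_exposure, se_exposure, beta_outcome,
                             se_outcome, rsid = NULL) {
  k <- length(beta_exposure)
  if (is.null(rsid)) rsid <- sprintf("rs%03d", seq_len(k))
  data.frame(rsid = rsid, beta_exposure = beta_exposure,
             se_exposure = rep_len(se_exposure, k),
             beta_outcome = beta_outcome,
             se_outcome = rep_len(se_outcome, k),
             eaf_exposure = 0.3, eaf_outcome = 0.3,
             action_taken = "none", stringsAsFactors = FALSE)
}

random_instruments <- function(k, seed) {
  set.seed(seed)
  make_instruments(beta_exposure = rnorm(k, 0.1, 0.05),
                   se_exposure = runif(k, 0.01, 0.03),
                   beta_outcome = rnorm(k, 0.02, 0.03),
                   se_outcome = runif(k, 0.01, 0.05))
}

write_sumstats_file <- function(dat, path = tempfile(fileext = ".tsv")) {
  write_sumstats(dat, path)
  path
}
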