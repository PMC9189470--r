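---
title: "Two-sample Mendelian randomization with mrkit: models, diagnostics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (here, a log-scale
circulating biomarker such as adiponectin) on an outcome (here, binary
disease status such as a gastrointestinal cancer), from GWAS summary
statistics alone. Because alleles are randomized at meiosis, a variant
that robustly affects the exposure and influences the outcome *only
through* the exposure provides a confounding-resistant estimate of the
causal effect. Two-sample MR takes the SNP–exposure associations
$(\hat\gamma_j, \sigma_{X_j})$ and the SNP–outcome associations
$(\hat\Gamma_j, \sigma_{Y_j})$ from two different studies of the same
ancestry.

`mrkit` implements the complete workflow: instrument quality control,
allele harmonization, four causal estimators, heterogeneity/pleiotropy
diagnostics with a flowchart that picks the primary method, outlier and
influence analysis, instrument-strength statistics, binary-outcome power,
and report generation — plus a synthetic summary-statistics generator with
known ground truth used to validate every stage.

## Instrument selection and harmonization

Instruments are selected from the exposure GWAS by

1. a significance filter, `filter_pvalue()`, default $p < 5\times10^{-8}$;
2. greedy LD clumping, `clump_snps()`, default $r^2 < 0.1$ within a
   10{,}000 kb window: candidates are ranked by ascending $p$-value (ties
   broken by rsID so the result is permutation-invariant) and a SNP is
   dropped when it is in LD with an already-accepted SNP — of any linked
   pair only the lower-$p$ SNP survives. When the LD reference carries no
   positions the window constraint is skipped (every pair is tested);
   pairs absent from the reference are treated as unlinked, and logged.
3. a minor-allele-frequency filter, `filter_maf()`, default MAF $\ge 5\%$.
   Because the rule removes variants *below* 5%, a SNP at exactly the
   boundary is retained.

Instruments absent from the outcome GWAS may be replaced by a proxy in
strong LD (`find_proxy()`, default $r^2 > 0.9$, strict; ties broken by
lexicographically smallest rsID).

`harmonize()` expresses both associations on the exposure's effect
allele. Non-palindromic pairs are matched directly, by allele swap
(outcome beta negated, frequency complemented), or after strand
complementation (A↔T, C↔G). Palindromic SNPs (A/T, C/G) cannot be
oriented from allele labels; they are kept only when both allele
frequencies exist, both fall outside the ambiguity window
$0.5 \pm w$ (default $w = 0.08$, i.e. drop when either frequency is in
$[0.42, 0.58]$), and the frequencies agree on the orientation.
Setting $w = \infty$ reproduces the strict "always exclude palindromic
SNPs" policy; the window is configurable precisely because practice
varies between correcting and excluding. A SNP with a missing frequency
is always dropped — it cannot be oriented safely. Indels are rejected at
parse time: the instrument set is SNPs only. Harmonization never changes
the magnitude of any beta or any standard error, and is involutive: it
does not matter which strand or allele order the outcome study happened
to report.

## The four estimators

All methods start from the per-SNP Wald ratio
$\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order standard error
$\sigma_{Y_j}/|\hat\gamma_j|$ and weight $w_j$ equal to its inverse
variance.

**IVW.** $\hat\beta_{IVW} = \sum w_j\hat\beta_j / \sum w_j$. Under the
fixed-effect model, $se = (\sum w_j)^{-1/2}$; under multiplicative random
effects the standard error is inflated by
$\max\{1, \sqrt{Q/(n-1)}\}$ with $Q$ Cochran's statistic about the pooled
estimate — under-dispersion never shrinks the fixed-effect standard
error. Fixed-effect IVW is algebraically the zero-intercept weighted
least-squares slope of $\hat\Gamma$ on $\hat\gamma$ with weights
$1/\sigma_{Y_j}^2$; the test suite checks this identity to $10^{-10}$.

**MR-Egger.** Weighted least squares
$\hat\Gamma_j = \alpha + \beta\,\hat\gamma_j$ with weights
$1/\sigma_{Y_j}^2$, after orienting every instrument so
$\hat\gamma_j > 0$. The slope is the pleiotropy-adjusted causal estimate;
the intercept $\alpha$ estimates the mean directional pleiotropic effect,
and its two-sided $t_{n-2}$ test is the horizontal-pleiotropy test.
Egger inference uses the $t$ reference with $n-2$ degrees of freedom
because two parameters are estimated from few points; IVW uses the normal
reference.

**Weighted median.** Order the ratios; form standardized cumulative
weights $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i$; interpolate
$\hat\beta_{(j)}$ against $s_j$ linearly at $s = 0.5$. Consistent when at
least half the weight comes from valid instruments.

**Weighted mode.** The argmax over a 512-point grid spanning
$[\min_j \hat\beta_j - 3h,\ \max_j \hat\beta_j + 3h]$ of the
normal-kernel weighted density with bandwidth
$h = \phi\, \cdot 0.9\,\min(sd, \mathrm{mad}/0.6745)\,n^{-1/5}$,
where mad is the raw (unscaled) median absolute deviation and the
bandwidth factor $\phi$ defaults to 1. Argmax ties are broken toward the
smallest value. If every ratio coincides the bandwidth is zero and the
common value is returned with the fixed-effect IVW standard error.

The median and mode have no closed-form standard error; both use a
parametric bootstrap (default 1000 replicates, explicitly seeded):
each ratio is resampled from $N(\hat\beta_j, se_j^2)$ and the estimator
re-applied; the standard error is the standard deviation across
replicates. The replicate count and bandwidth factor are configurable
because the literature the methods come from does not fix them.

## Diagnostics and the flowchart

- **Cochran's Q** (`cochran_q()`): $Q=\sum w_j(\hat\beta_j -
  \hat\beta_{IVW})^2$, $\chi^2_{n-1}$ under homogeneity.
- **Rücker's Q′** (`rucker_q()`): the weighted residual sum of squares
  about the Egger line, $\chi^2_{n-2}$; always $Q' \le Q$ since the
  intercept can only absorb heterogeneity.
- **Egger intercept test** (`egger_intercept_test()`): directional
  pleiotropy, $t_{n-2}$.
- **MR-PRESSO** (`mr_presso()`): the observed statistic is
  $RSS = \sum_j w_j(\hat\Gamma_j - \hat\gamma_j\hat\beta_{-j})^2$, where
  $\hat\beta_{-j}$ is the IVW estimate fitted without SNP $j$. The null
  distribution is simulated (default 1000 draws) by resampling
  $\gamma^*_j \sim N(\hat\gamma_j, \sigma^2_{X_j})$ and
  $\Gamma^*_j \sim N(\hat\gamma_j\hat\beta_{-j}, \sigma^2_{Y_j})$ and
  recomputing the statistic. Monte-Carlo $p$-values use the
  $(c+1)/(n_{sim}+1)$ convention so they are never exactly zero. The
  per-SNP outlier test compares each SNP's observed squared residual with
  its own simulated distribution, Bonferroni-corrected by $n$ (flag when
  corrected $p<0.05$ by default). When outliers are flagged, the
  outlier-corrected IVW estimate is computed and a distortion test
  compares the resulting shift with the shifts produced by 1000 random
  pseudo-outlier sets of the same size.
- **Leave-one-out** (`leave_one_out()`): fixed-effect IVW re-estimated
  excluding each SNP; an instrument is *influential* when the full-set
  confidence interval excludes the null but the remaining-set interval
  crosses it.

`select_method()` encodes the decision rule applied per outcome, with
"detected" meaning $p < \alpha$ (default 0.05, configurable):

| pleiotropy | heterogeneity | primary method |
|---|---|---|
| no | no | fixed-effect IVW |
| no | yes | multiplicative-random-effects IVW (MR-PRESSO also run) |
| yes | any | MR-Egger |

The heterogeneity input to the flowchart is the IVW Q (matching the
candidate primary method); Q′ is reported alongside. On the
heterogeneity branch both remedies exist; `mr_fit()` reports the MRE IVW
as primary unless PRESSO flags outliers, in which case the
outlier-corrected IVW becomes primary — PRESSO exists to correct, not
merely to detect. `direction_concordance()` records whether all four
estimators agree in sign (an exact zero is compatible with either sign).

## Instrument strength

Two F-statistics circulate in applied work and they answer the question
at different granularity, so `instrument_strength()` reports both:

- the summary formula
  $F = \dfrac{R^2/k}{(1-R^2)/(n-k-1)}$ from the total exposure variance
  explained ($R^2$), instrument count $k$ and exposure sample size $n$;
- the per-SNP Wald statistics $(\hat\gamma_j/\sigma_{X_j})^2$ and their
  mean, the commonly quoted "mean F".

For $R^2 = 2.65\%$, $k = 8$, $n = 7827$ the summary formula gives
$F \approx 26.6$; a reported mean F near 90 for the same configuration
can only be the per-SNP mean, which is why both are always printed.

$I^2_{GX}$ quantifies the expected regression dilution of the Egger
slope from measurement error in $\hat\gamma$:
$I^2_{GX} = \max\{0, (Q_{GX} - (k-1))/Q_{GX}\}$ where $Q_{GX}$ is the
inverse-variance-weighted sum of squares of the *positively oriented*
exposure effects about their weighted mean (the orientation Egger uses;
floored at zero).

## Reporting scale and power

Estimates are on the log-odds scale per unit of the (log-scale)
exposure. `scale_to_or()` multiplies the estimate and its confidence
bounds by a factor and exponentiates. The default multiplier is 1.1,
the "multiply by 1.1 then exponentiate" convention for effects per 10%
increase of the log-transformed exposure; because that phrase is
non-standard, the conventional alternative $\ln(1.1)\approx 0.0953$
(per 10% increase of the raw-scale exposure) is available as
`per_10pct_multiplier()`. Both are monotone transforms, so $p$-values
are unchanged.

`mr_power_binary()` implements the standard non-centrality approximation
for binary-outcome MR power: with case fraction $K$ and alternative odds
ratio $OR$,
$b = K\left(\frac{OR}{1+K(OR-1)} - 1\right)$,
$v = \frac{K(1-K)-b^2}{N\,R^2_{XZ}}$, and power is the upper-tail
probability of $\chi^2_1(ncp = b^2/v)$ beyond the central
$\chi^2_1$ critical value at $\alpha$. At $OR = 1$ the power equals
$\alpha$ exactly. Reports compute power at the two conventional
alternatives $OR = 1.1/0.9$ and $1.3/0.7$ with $R^2_{XZ}$ defaulting to
0.0265. `bonferroni_threshold()` supplies the family-wise corrected
per-test threshold ($0.05/6 \approx 0.0083$ for six outcomes).

`make_report()` writes full-precision machine TSVs plus a human-readable
summary rounded to 2 decimals for ORs/CIs and 3 for $p$-values, and a
JSON manifest recording seeds, thresholds and the package version, so a
report regenerated from the same inputs is byte-identical.

## The synthetic generator

`simulate_study()` works at the summary-statistic level — the pipeline
consumes nothing else, and it keeps the generator fast and transparent.
For each of $k$ instruments:

- MAF $p_j \sim U(0.1, 0.45)$ by default;
- true exposure effects are drawn as a shifted half-normal
  $0.3 + |N(0,1)|$ and rescaled so the realized explained variance
  $\sum_j 2p_j(1-p_j)\gamma_j^2$ equals `target_r2` *exactly* (default
  0.0265). Two modelling choices are deliberate: effects are positive
  because summary-MR instruments are conventionally oriented to the
  exposure-increasing allele — the frame in which directional pleiotropy
  is defined — and they are bounded away from zero because real
  instruments pass a genome-wide-significance filter, so a generator that
  produces near-null true effects would create sign-flip artefacts no
  selected instrument set exhibits;
- the exposure is treated as a variance-1 log-scale trait, so
  $\sigma_{X_j} = (2p_j(1-p_j)\,n_X)^{-1/2}$ (default $n_X = 7827$);
- true outcome effects are $\Gamma_j = \beta\,\gamma_j + \alpha_j$ with
  direct effects $\alpha_j$ per the pleiotropy specification: none,
  balanced ($N(0, sd)$) or directional ($N(mean, sd)$), optionally
  correlated with instrument strength to violate InSIDE;
- outcome standard errors use the logistic large-sample approximation
  $\sigma_{Y_j} = (2p_j(1-p_j)\,N\,K(1-K))^{-1/2}$ for a GWAS of $N$
  individuals with case fraction $K$ (defaults 6000 cases / 190,000
  controls, biobank magnitude);
- observed betas add normal estimation noise; planted outliers displace
  the observed outcome beta by a stated multiple of $\sigma_{Y_j}$;
  $p$-values are Wald tests; alleles are assigned with a configurable
  palindromic fraction (default 0).

Instruments are LD-independent by default (the emitted LD reference is
the implied identity); LD structure is exercised separately through the
clumping unit tests. `make_paper_fixture()` freezes one such study —
8 instruments, $R^2 = 2.65\%$, $n_X = 7827$, 6000/190,000 outcome, true
$\beta = -0.1$ — as the deterministic end-to-end input, shipped under
`inst/extdata/`.

What the generator does *not* emulate: LD between instruments beyond the
identity/block toggle, winner's-curse inflation of the selected
$\hat\gamma_j$, sample overlap between exposure and outcome studies,
mixed-model association artefacts, or population stratification. Passing
tests therefore demonstrate correctness of the estimators and the
calibration of the tests under clean two-sample conditions, not
robustness to those real-data complications.

## Validation design and problem sizes

The suite validates each estimator against an independent oracle (WLS
normal equations solved directly, dense grid scans of the median and mode
definitions, hand-summed Q statistics) and then checks statistical
behaviour by Monte Carlo, with every replicate seeded:

- *parameter recovery*: 200 replicates of a 50-instrument study with
  $\beta = 0.2$, $R^2 = 0.4$, $n_X = 8000$ and a 10k/10k outcome.
  The explained variance is deliberately large so that the mean per-SNP
  F is ≈64 and weak-instrument attenuation (≈0.003 on $\beta = 0.2$,
  analytically) cannot confound the bias check; fixed-effect IVW must
  recover the truth within ±0.02 with 95% CI coverage in [0.93, 0.97];
- *calibration*: the Egger intercept test under balanced pleiotropy and
  the PRESSO global test under homogeneous data must reject at 2–9%
  (nominal 5%) over 400 and 300 replicates;
- *detection*: a 10-standard-error planted outlier must be flagged by
  PRESSO in ≥90% of 100 runs.

These sizes complete in about a minute in total; they are the package's
chosen compromise between Monte-Carlo error (binomial standard error
≈1.5% at 200 replicates) and routine-test turnaround.
`scripts/acceptance.R` re-runs the same quantities from scratch under a
caller-supplied seed.

## Known limitations

- LD is consumed, never computed: the package expects an external
  pairwise $r^2$ table (e.g. derived from a matched reference panel).
- No genome-build liftover and no multi-allelic variants; rsID is the
  join key.
- The Egger estimator inherits its usual weaknesses at low $I^2_{GX}$
  (regression dilution) and small $k$; the package reports $I^2_{GX}$
  precisely so users can judge this.
- The replication of a published six-outcome analysis requires the
  original exposure/outcome summary files, which are redistributed by
  their own repositories and not shipped here; the corresponding
  acceptance test documents the expected file layout and remains failing
  until those files are supplied locally.
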