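test_that("Wald ratios and their first-order standard errors", {
  ins <- make_instruments(beta_exposure = c(0.1, 0.2, -0.1),
                          se_exposure = 0.02,
                          beta_outcome = c(0.05, 0, 0.05),
                          se_outcome = 0.02)
  r <- wald_ratios(ins)
  expect_equal(r$ratio, c(0.5, 0, -0.5))
  expect_equal(r$se_ratio, c(0.2, 0.1, 0.2))
  expect_equal(r$weight, 1 / r$se_ratio^2)
  ins$beta_exposure[2] <- 0
  expect_error(wald_ratios(ins), "rs002")
})

test_that("IVW reduces to the closed-form weighted mean", {
  one <- wald_ratios(make_instruments(0.1, 0.02, 0.05, 0.02))
  for (m in c("fe", "mre")) {
    fit <- mr_ivw(one, m)
    expect_equal(fit$beta, 0.5)
    expect_equal(fit$se, 0.2)
  }
  three <- data.frame(rsid = c("a", "b", "c"), ratio = c(0.2, 0.4, 0.6),
                      se_ratio = 0.1, weight = 100)
  fit <- mr_ivw(three, "fe")
  expect_equal(fit$beta, 0.4)
  expect_equal(fit$se, 0.1 / sqrt(3))
  expect_equal(fit$ci_low, 0.4 - qnorm(0.975) * fit$se)
  # homogeneity floor: identical ratios give MRE se equal to FE se
  same <- data.frame(rsid = c("a", "b", "c"), ratio = 0.3, se_ratio = 0.1,
                     weight = 100)
  expect_equal(mr_ivw(same, "mre")$se, mr_ivw(same, "fe")$se)
  expect_error(mr_ivw(three[0, ], "fe"), "at least one")
})

test_that("MRE IVW inflates but never deflates the FE standard error", {
  for (seed in 1:20) {
    r <- wald_ratios(random_instruments(8, seed))
    expect_gte(mr_ivw(r, "mre")$se, mr_ivw(r, "fe")$se)
  }
})

test_that("fixed-effect IVW equals zero-intercept WLS algebraically", {
  for (seed in 1:100) {
    ins <- random_instruments(sample(3:30, 1), seed)
    r <- wald_ratios(ins)
    w <- 1 / ins$se_outcome^2
    slope_wls <- sum(w * ins$beta_exposure * ins$beta_outcome) /
      sum(w * ins$beta_exposure^2)
    expect_equal(mr_ivw(r, "fe")$beta, slope_wls, tolerance = 1e-10)
  }
})

test_that("Egger regression recovers exact linear data", {
  g <- c(0.05, 0.1, 0.15, 0.2)
  ins <- make_instruments(g, 0.01, 0.01 + 0.3 * g,
                          se_outcome = c(0.02, 0.04, 0.03, 0.05))
  fit <- mr_egger(ins)
  expect_equal(fit$beta, 0.3, tolerance = 1e-8)
  expect_equal(fit$intercept, 0.01, tolerance = 1e-8)
  expect_equal(rucker_q(ins)$q, 0, tolerance = 1e-12)

  prop <- make_instruments(g, 0.01, 0.5 * g, 0.03)
  fitp <- mr_egger(prop)
  expect_equal(fitp$beta, 0.5, tolerance = 1e-8)
  expect_equal(fitp$intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(ins[1:2, ]), "at least 3")
})

test_that("Egger matches the weighted normal equations solved directly", {
  g <- c(0.04, 0.11, 0.07, 0.2)
  G <- c(0.011, 0.04, 0.019, 0.07)
  sG <- c(0.02, 0.05, 0.01, 0.03)
  ins <- make_instruments(g, 0.01, G, sG)
  w <- 1 / sG^2
  # independent oracle: solve the 2x2 weighted normal equations
  A <- matrix(c(sum(w), sum(w * g), sum(w * g), sum(w * g^2)), 2, 2)
  b <- c(sum(w * G), sum(w * g * G))
  ab <- solve(A, b)
  fit <- mr_egger(ins)
  expect_equal(fit$intercept, ab[1], tolerance = 1e-10)
  expect_equal(fit$beta, ab[2], tolerance = 1e-10)
})

test_that("Egger with zero intercept reproduces fixed-effect IVW", {
  for (seed in 1:20) {
    ins <- random_instruments(10, seed)
    flip <- sign(ins$beta_exposure)
    x <- ins$beta_exposure * flip
    y <- ins$beta_outcome * flip
    w <- 1 / ins$se_outcome^2
    constrained <- sum(w * x * y) / sum(w * x^2)
    expect_equal(constrained, mr_ivw(wald_ratios(ins), "fe")$beta,
                 tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the cumulative weight function", {
  eq <- data.frame(rsid = letters[1:3], ratio = c(0.1, 0.4, 0.9),
                   se_ratio = 0.1, weight = 1)
  expect_equal(mr_weighted_median(eq, n_boot = 0)$beta, 0.4)
  same <- data.frame(rsid = letters[1:4], ratio = 0.25, se_ratio = 0.1,
                     weight = c(1, 2, 3, 4))
  expect_equal(mr_weighted_median(same, n_boot = 0)$beta, 0.25)

  # dense-scan oracle of the interpolated definition
  r <- data.frame(rsid = letters[1:3], ratio = c(0.1, 0.2, 0.3),
                  se_ratio = c(1, 1, 1 / sqrt(8)), weight = c(1, 1, 8))
  est <- mr_weighted_median(r, n_boot = 0)$beta
  s <- (cumsum(r$weight) - r$weight / 2) / sum(r$weight)
  grid_s <- seq(s[1], s[3], by = 1e-6)
  grid_b <- approx(s, r$ratio, xout = grid_s, ties = "ordered")$y
  oracle <- grid_b[which.min(abs(grid_s - 0.5))]
  expect_equal(est, oracle, tolerance = 1e-5)
  expect_equal(est, 0.2 + (0.5 - 0.15) / 0.45 * 0.1, tolerance = 1e-9)
  expect_error(mr_weighted_median(r[1:2, ]), "at least 3")
})

test_that("weighted mode finds the dominant cluster, not the mean", {
  same <- data.frame(rsid = letters[1:3], ratio = 0.7, se_ratio = 0.1,
                     weight = 100)
  fit_same <- mr_weighted_mode(same, n_boot = 0)
  expect_equal(fit_same$beta, 0.7)
  expect_equal(fit_same$se, 0.1 / sqrt(3)) # FE fallback at zero bandwidth

  clus <- data.frame(rsid = letters[1:4], ratio = c(0.3, 0.31, 0.29, 1.5),
                     se_ratio = 0.1, weight = 1)
  est <- mr_weighted_mode(clus, n_boot = 0)$beta
  expect_lt(abs(est - 0.3), 0.1)
  expect_gt(abs(est - mean(clus$ratio)), 0.2)
  # grid-argmax oracle with the same bandwidth rule
  x <- clus$ratio
  h <- 0.9 * min(sd(x), median(abs(x - median(x))) / 0.6745) * 4^(-0.2)
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = 512)
  dens <- sapply(grid, function(g) sum(0.25 * dnorm(g, x, h)))
  expect_equal(est, grid[which.max(dens)])

  sym <- data.frame(rsid = letters[1:3], ratio = c(-0.4, 0, 0.4),
                    se_ratio = 0.1, weight = 1)
  expect_lt(abs(mr_weighted_mode(sym, n_boot = 0)$beta), 0.02)
})

test_that("bootstrap standard errors are seeded and reproducible", {
  r <- wald_ratios(random_instruments(6, 1))
  a <- mr_weighted_median(r, n_boot = 200, seed = 7)
  b <- mr_weighted_median(r, n_boot = 200, seed = 7)
  c <- mr_weighted_median(r, n_boot = 200, seed = 8)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_gt(a$se, 0)
  m1 <- mr_weighted_mode(r, n_boot = 200, seed = 7)
  m2 <- mr_weighted_mode(r, n_boot = 200, seed = 7)
  expect_identical(m1$se, m2$se)
})

test_that("all estimators are invariant to jointly negating an instrument", {
  ins <- random_instruments(8, 5)
  neg <- ins
  idx <- c(2, 5)
  neg$beta_exposure[idx] <- -neg$beta_exposure[idx]
  neg$beta_outcome[idx] <- -neg$beta_outcome[idx]
  r0 <- wald_ratios(ins); r1 <- wald_ratios(neg)
  expect_equal(mr_ivw(r1, "fe")$beta, mr_ivw(r0, "fe")$beta)
  expect_equal(mr_ivw(r1, "mre")$se, mr_ivw(r0, "mre")$se)
  expect_equal(mr_egger(neg)$beta, mr_egger(ins)$beta)
  expect_equal(mr_egger(neg)$intercept, mr_egger(ins)$intercept)
  expect_equal(mr_weighted_median(r1, n_boot = 0)$beta,
               mr_weighted_median(r0, n_boot = 0)$beta)
  expect_equal(mr_weighted_mode(r1, n_boot = 0)$beta,
               mr_weighted_mode(r0, n_boot = 0)$beta)
})

test_that("all four estimators recover the causal effect on average", {
  # strong-instrument scenario: 50 SNPs explaining 40% of exposure variance
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 4)
  for (i in seq_len(n_rep)) {
    study <- simulate_study(sim_config(
      n_snps = 50, n_exposure = 8000, n_outcome_cases = 10000,
      n_outcome_controls = 10000, beta_causal = 0.2, target_r2 = 0.4,
      seed = 5000 + i))
    ins <- study$instruments
    r <- wald_ratios(ins)
    est[i, ] <- c(mr_ivw(r, "fe")$beta, mr_egger(ins)$beta,
                  mr_weighted_median(r, n_boot = 0)$beta,
                  mr_weighted_mode(r, n_boot = 0)$beta)
  }
  means <- colMeans(est)
  for (j in 1:4) expect_lt(abs(means[j] - 0.2), 0.02)
})

test_that("Egger stays unbiased under InSIDE directional pleiotropy while IVW shifts", {
  n_rep <- 150
  ivw_est <- egger_est <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    study <- simulate_study(sim_config(
      n_snps = 50, n_exposure = 8000, n_outcome_cases = 10000,
      n_outcome_controls = 10000, beta_causal = 0.2, target_r2 = 0.4,
      pleiotropy = "directional", pleiotropy_mean = 0.02,
      pleiotropy_sd = 0.005, seed = 9000 + i))
    ins <- study$instruments
    ivw_est[i] <- mr_ivw(wald_ratios(ins), "fe")$beta
    egger_est[i] <- mr_egger(ins)$beta
  }
  expect_lt(abs(mean(egger_est) - 0.2), 0.03)
  # IVW absorbs the mean pleiotropic effect into its slope
  expect_gt(mean(ivw_est) - 0.2, 0.05)
})
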