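test_that("Egger point fit recovers a noiseless line and requires 3 instruments", {
  g <- c(0.02, 0.05, 0.08, 0.11)
  tab <- make_table(g = g, sg = rep(0.01, 4),
                    G = 0.1 + 2 * g, sG = rep(0.01, 4))
  fit <- mr_egger(tab, bootstrap_reps = 200, seed = 1)
  expect_equal(fit$estimate[fit$term == "intercept"], 0.1, tolerance = 1e-10)
  expect_equal(fit$estimate[fit$term == "slope"], 2, tolerance = 1e-10)

  expect_error(mr_egger(tab[1:2, ], 100, 1), "at least 3")
  degenerate <- make_table(g = rep(0.05, 4), sg = rep(0.01, 4),
                           G = rep(0.01, 4), sG = rep(0.01, 4))
  expect_error(mr_egger(degenerate, 100, 1), "collinear")
})

test_that("Egger bootstrap SEs are seed-reproducible and converge between 5k and 10k reps", {
  sim <- simulate_reference_fixture(seed = 11)
  tab <- harmonize(sim$exposure, sim$outcome)
  a <- mr_egger(tab, bootstrap_reps = 500, seed = 99)
  b <- mr_egger(tab, bootstrap_reps = 500, seed = 99)
  expect_identical(a$se, b$se)

  se5 <- mr_egger(tab, bootstrap_reps = 5000, seed = 42)$se
  se10 <- mr_egger(tab, bootstrap_reps = 10000, seed = 43)$se
  cv <- abs(se5 - se10) / ((se5 + se10) / 2)
  expect_true(all(cv < 0.05))
})

test_that("Egger intercept and slope CIs show ~95% coverage under balanced pleiotropy", {
  model <- sim_model(theta = 0.1, pleiotropy = "balanced",
                     pleiotropy_sd = 0.004,
                     gamma_mean = 0.09, gamma_sd = 0.025)
  cover <- t(vapply(1:400, function(r) {
    sim <- simulate_summary_stats(model, seed = 20000 + r)
    tab <- harmonize(sim$exposure, sim$outcome)
    fit <- mr_egger(tab, bootstrap_reps = 300, seed = r)
    lo <- fit$estimate - 1.959964 * fit$se
    hi <- fit$estimate + 1.959964 * fit$se
    c(int = lo[1] <= 0 & 0 <= hi[1], slope = lo[2] <= 0.1 & 0.1 <= hi[2])
  }, logical(2)))
  expect_gt(mean(cover[, "int"]), 0.90)
  expect_gt(mean(cover[, "slope"]), 0.90)
})

test_that("I2GX matches hand arithmetic and degenerates to zero dispersion", {
  same <- make_table(g = rep(0.05, 3), sg = rep(0.01, 3),
                     G = rep(0.01, 3), sG = rep(0.01, 3))
  expect_equal(i2_gx(same)$i2_gx, 0)

  two <- make_table(g = c(0.02, 0.04), sg = c(0.001, 0.001),
                    G = c(0.01, 0.01), sG = c(0.01, 0.01))
  res <- i2_gx(two)
  expect_equal(res$q_gx, 200)
  expect_equal(res$i2_gx, 0.995)
  expect_equal(res$attenuation_bias, 0.005)
  expect_error(i2_gx(two[1, ]), "single instrument")
})

test_that("SIMEX reduces to the naive Egger fit without measurement error", {
  sim <- simulate_reference_fixture(seed = 21)
  tab <- harmonize(sim$exposure, sim$outcome)
  naive <- mr_egger(tab, bootstrap_reps = 200, seed = 1)

  # lambda grid {0}: naive fit, exactly
  only0 <- mr_egger_simex(tab, lambda_grid = 0, seed = 1, se_boot_reps = 0)
  expect_equal(only0$estimate, naive$estimate, tolerance = 1e-12)

  # sigma_gamma = 0: slope(lambda) constant, extrapolation is the naive fit
  tab0 <- tab; tab0$se_exp <- rep(1e-12, nrow(tab0))
  naive0 <- mr_egger(tab0, bootstrap_reps = 200, seed = 1)
  sx <- mr_egger_simex(tab0, reps_per_lambda = 50, seed = 2, se_boot_reps = 0)
  expect_equal(sx$estimate, naive0$estimate, tolerance = 1e-6)
  means <- attr(sx, "lambda_means")
  expect_lt(max(abs(means$slope - means$slope[1])), 1e-6)

  expect_error(mr_egger_simex(tab, lambda_grid = c(0, 1)), "3 points")
  expect_error(mr_egger_simex(tab, lambda_grid = c(0.5, 1, 1.5)), "start at 0")
})

test_that("SIMEX corrects Egger slope attenuation under weak instruments", {
  # strong measurement error in the SNP-exposure estimates attenuates
  # the naive Egger slope; the extrapolated slope should sit closer to
  # the truth on average
  model <- sim_model(theta = 0.3, gamma_mean = 0.08, gamma_sd = 0.03,
                     pleiotropy = "balanced", pleiotropy_sd = 0.003,
                     n_exposure = 2000)
  errs <- t(vapply(1:120, function(r) {
    sim <- simulate_summary_stats(model, seed = 31000 + r)
    tab <- harmonize(sim$exposure, sim$outcome)
    naive <- mr_egger(tab, bootstrap_reps = 100, seed = r)
    sx <- mr_egger_simex(tab, reps_per_lambda = 100, seed = r,
                         se_boot_reps = 0)
    c(naive = naive$estimate[2], simex = sx$estimate[2])
  }, numeric(2)))
  expect_lt(abs(mean(errs[, "simex"]) - 0.3), abs(mean(errs[, "naive"]) - 0.3))
})

test_that("doubling SIMEX replicates leaves the extrapolation within Monte-Carlo error", {
  sim <- simulate_reference_fixture(seed = 33)
  tab <- harmonize(sim$exposure, sim$outcome)
  s1 <- mr_egger_simex(tab, reps_per_lambda = 1000, seed = 5, se_boot_reps = 0)
  s2 <- mr_egger_simex(tab, reps_per_lambda = 2000, seed = 6, se_boot_reps = 0)
  expect_equal(s1$estimate[2], s2$estimate[2], tolerance = 0.05)
})

test_that("weighted median matches the cumulative-sum oracle and the sample median", {
  set.seed(404)
  for (i in 1:50) {
    k <- sample(3:15, 1)
    theta <- rnorm(k); w <- runif(k, 0.5, 3)
    expect_equal(mrsummary:::weighted_median(theta, w),
                 wmedian_oracle(theta, w))
  }
  # equal weights: interpolated sample median convention
  for (i in 1:20) {
    k <- sample(3:11, 1)
    theta <- rnorm(k)
    got <- mrsummary:::weighted_median(theta, rep(1, k))
    expect_equal(got, wmedian_oracle(theta, rep(1, k)))
    if (k %% 2 == 1) expect_equal(got, median(theta))
  }
})

test_that("penalized weighted median: odd-count median, degenerate case, and errors", {
  tab <- make_table(g = rep(0.1, 3), sg = rep(1e-6, 3),
                    G = 0.1 * c(0.1, 0.2, 0.9), sG = rep(1e-3, 3))
  # equal weights by construction; ratios are 0.1, 0.2, 0.9
  wr <- wald_ratios(tab)
  expect_equal(mrsummary:::pwm_point(wr$beta, 1 / wr$se^2), 0.2)

  est <- mr_weighted_median(tab, bootstrap_reps = 500, seed = 9)
  expect_equal(est$beta, 0.2, tolerance = 1e-6)

  # all ratios identical: estimate c, tiny bootstrap SE
  tabc <- make_table(g = c(0.05, 0.08, 0.1), sg = rep(1e-5, 3),
                     G = 0.25 * c(0.05, 0.08, 0.1), sG = rep(1e-5, 3))
  estc <- mr_weighted_median(tabc, bootstrap_reps = 500, seed = 9)
  expect_equal(estc$beta, 0.25, tolerance = 1e-4)
  expect_lt(estc$se, 1e-3)

  expect_error(mr_weighted_median(tab[1:2, ], 100, 1), "at least 3")
})

test_that("multivariable MR reduces to the through-origin slope when the covariate is null", {
  set.seed(505)
  tab <- random_table(with_cov = TRUE)
  w <- 1 / tab$se_out^2
  slope <- sum(w * tab$beta_exp * tab$beta_out) / sum(w * tab$beta_exp^2)

  # all-zero covariate: the point estimate reduces to the slope exactly
  zeros <- mrsummary:::mvmr_solve(tab$beta_exp, rep(0, nrow(tab)),
                                  tab$beta_out, w)
  expect_equal(zeros[1], slope, tolerance = 1e-12)
  expect_equal(zeros[2], 0)

  # covariate orthogonal to the exposure in the weighted inner product:
  # the adjusted exposure coefficient equals the unadjusted slope
  v <- tab$beta_cov
  d_orth <- v - tab$beta_exp * sum(w * tab$beta_exp * v) /
    sum(w * tab$beta_exp^2)
  tab$beta_cov <- d_orth
  fit <- mr_mvmr(tab, bootstrap_reps = 200, seed = 2)
  expect_equal(fit$estimate[fit$term == "exposure"], slope, tolerance = 1e-10)

  collinear <- make_table(g = c(0.02, 0.05, 0.08), sg = rep(0.01, 3),
                          G = c(0.01, 0.02, 0.03), sG = rep(0.01, 3),
                          d = 2 * c(0.02, 0.05, 0.08), sd_ = rep(0.01, 3))
  expect_error(mr_mvmr(collinear, 100, 1), "collinear")
})

test_that("multivariable MR recovers the direct effect under an active tobacco path", {
  model <- sim_model(theta = 0.1, gamma_mean = 0.09, gamma_sd = 0.02,
                     tobacco = list(delta_mean = 0.06, delta_sd = 0.02,
                                    theta_t = 0.3))
  ests <- t(vapply(1:500, function(r) {
    sim <- simulate_summary_stats(model, seed = 40000 + r)
    tab <- harmonize(sim$exposure, sim$outcome, sim$covariate)
    mv <- mrsummary:::mvmr_solve(tab$beta_exp, tab$beta_cov, tab$beta_out,
                                 1 / tab$se_out^2)
    ivw <- mr_ivw(wald_ratios(tab), "fixed")$beta
    c(mvmr = mv[1], ivw = ivw)
  }, numeric(2)))
  mc_se <- sd(ests[, "mvmr"]) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, "mvmr"]) - 0.1), 2 * mc_se)
  # univariable IVW absorbs the tobacco path and lands above the direct effect
  expect_gt(mean(ests[, "ivw"]), 0.1 + 4 * sd(ests[, "ivw"]) / sqrt(nrow(ests)))
})

test_that("penalized weighted median resists 40% invalid instruments where IVW fails", {
  theta_true <- 0.1
  ests <- t(vapply(1:500, function(r) {
    set.seed(60000 + r)
    k <- 10
    g <- rnorm(k, 0.09, 0.015); sg <- rep(0.01, k)
    alpha <- c(rep(0, 6), rep(0.03, 4))     # 4 of 10 SNPs pleiotropic
    G <- theta_true * g + alpha
    sG <- rep(0.004, k)
    tab <- make_table(g = g + rnorm(k, 0, sg), sg = sg,
                      G = G + rnorm(k, 0, sG), sG = sG)
    wr <- wald_ratios(tab)
    c(pwm = mrsummary:::pwm_point(wr$beta, 1 / wr$se^2),
      ivw = mr_ivw(wr, "fixed")$beta)
  }, numeric(2)))
  mc_pwm <- sd(ests[, "pwm"]) / sqrt(nrow(ests))
  mc_ivw <- sd(ests[, "ivw"]) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, "pwm"]) - theta_true), 2 * mc_pwm)
  expect_gt(abs(mean(ests[, "ivw"]) - theta_true), 2 * mc_ivw)
})
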