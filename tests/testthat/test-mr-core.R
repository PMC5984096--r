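test_that("Wald ratio and delta-method SE match the closed form and its limits", {
  # zero numerator: se reduces to sigma_Gamma / gamma
  tab0 <- make_table(g = 0.05, sg = 0.01, G = 0, sG = 0.002)
  wr0 <- wald_ratios(tab0)
  expect_equal(wr0$beta, 0)
  expect_equal(wr0$se, 0.002 / 0.05)

  tab <- make_table(g = 0.05, sg = 0.01, G = 0.006, sG = 0.002)
  wr <- wald_ratios(tab)
  expect_equal(wr$beta, 0.12)
  expect_equal(wr$se, sqrt(0.002^2 / 0.05^2 + 0.006^2 * 0.01^2 / 0.05^4))
  expect_equal(wr$se, 0.04664762, tolerance = 1e-6)
  # frozen Monte-Carlo oracle (1e6 draws of Gamma/gamma, SD of the ratio,
  # seed 42): 0.05267. The first-order expansion sits below it by the
  # expected truncation gap at instrument z = 5.
  expect_lt(abs(wr$se - 0.05267) / 0.05267, 0.15)

  # ratio is invariant to rescaling both associations
  tab2 <- make_table(g = 0.10, sg = 0.02, G = 0.012, sG = 0.004)
  expect_equal(wald_ratios(tab2)$beta, wr$beta)

  # gamma = 0 is an error naming the SNP
  tabz <- make_table(g = c(0.05, 0), sg = rep(0.01, 2),
                     G = rep(0.01, 2), sG = rep(0.01, 2))
  expect_error(wald_ratios(tabz), "rs2")
})

test_that("IVW pooling: identity, homogeneity, and the WLS-through-origin oracle", {
  one <- tibble::tibble(beta = 0.08, se = 0.03)
  for (mode in c("fixed", "random")) {
    pooled <- mr_ivw(one, mode)
    expect_equal(pooled$beta, 0.08)
    expect_equal(pooled$se, 0.03)
    expect_equal(pooled$q_df, 0L)
  }
  same <- tibble::tibble(beta = rep(0.08, 5), se = rep(0.03, 5))
  fr <- mr_ivw(same, "fixed"); rr <- mr_ivw(same, "random")
  expect_equal(rr$tau2, 0)
  expect_equal(rr$i2, 0)
  expect_equal(rr$beta, fr$beta)
  expect_equal(rr$se, fr$se)

  # fixed-effect IVW on first-order ratios == weighted through-origin
  # regression slope, solved via the normal equations
  set.seed(101)
  for (i in 1:25) {
    tab <- random_table()
    ivw <- mr_ivw(wald_ratios(tab, se_method = "delta1"), "fixed")
    w <- 1 / tab$se_out^2
    slope <- sum(w * tab$beta_exp * tab$beta_out) / sum(w * tab$beta_exp^2)
    expect_equal(ivw$beta, slope, tolerance = 1e-10)
  }
})

test_that("IVW respects ordering and variance relations on random tables", {
  set.seed(202)
  for (i in 1:25) {
    tab <- random_table()
    wr <- wald_ratios(tab)
    fixed <- mr_ivw(wr, "fixed"); random <- mr_ivw(wr, "random")
    expect_gte(random$se, fixed$se)
    if (random$tau2 == 0) expect_equal(random$se, fixed$se) else
      expect_gt(random$se, fixed$se)
    expect_gte(fixed$beta, min(wr$beta))
    expect_lte(fixed$beta, max(wr$beta))
    expect_gte(random$beta, min(wr$beta))
    expect_lte(random$beta, max(wr$beta))
  }
})

test_that("DerSimonian-Laird pooling agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(303)
  wr <- wald_ratios(random_table())
  ours <- mr_ivw(wr, "random")
  ref <- metafor::rma(yi = wr$beta, sei = wr$se, method = "DL")
  expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$se, ref$se, tolerance = 1e-8)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
})

test_that("fixed-effect CI covers the true effect in ~95% of replicates", {
  model <- sim_model(pleiotropy = "none")
  hits <- vapply(1:1000, function(r) {
    sim <- simulate_summary_stats(model, seed = 5000 + r)
    tab <- harmonize(sim$exposure, sim$outcome)
    est <- mr_ivw(wald_ratios(tab), "fixed")
    ci <- est$beta + c(-1, 1) * 1.959964 * est$se
    ci[1] <= model$theta && model$theta <= ci[2]
  }, logical(1))
  # binomial(1000, .95) 3-sigma band
  expect_gt(mean(hits), 0.925)
  expect_lt(mean(hits), 0.975)
})

test_that("users-vs-nonusers transformation rescales correctly", {
  est0 <- mrsummary:::new_mr_estimate(0, 0.05, "ivw_fixed", 10)
  tr0 <- to_users_vs_nonusers(est0, 0.43)
  expect_equal(tr0$beta, 0)
  tr0r <- to_users_vs_nonusers(est0, 0.43, method = "risk_solve")
  expect_equal(tr0r$beta, 0, tolerance = 1e-10)

  est <- mrsummary:::new_mr_estimate(log(1.08), 0.028, "ivw_fixed", 10)
  tr <- to_users_vs_nonusers(est, 0.43)
  expect_equal(tr$beta, log(1.08) / (0.43 * 0.57))
  expect_equal(tr$or, 1.369, tolerance = 2e-3)
  expect_identical(tr$scale, "users_vs_nonusers")

  # monotone in beta at fixed prevalence
  ors <- vapply(seq(0.01, 0.2, length.out = 8), function(b) {
    to_users_vs_nonusers(mrsummary:::new_mr_estimate(b, 0.02, "ivw_fixed", 10),
                         0.43)$or
  }, numeric(1))
  expect_true(all(diff(ors) > 0))

  expect_error(to_users_vs_nonusers(est, exposure_prevalence = 1.2), "0, 1")
  expect_error(to_users_vs_nonusers(tr, 0.43), "per_log_unit")
})

test_that("CI bounds follow the 1.959964 convention on every estimate", {
  est <- mrsummary:::new_mr_estimate(0.3, 0.1, "wald", 1)
  expect_equal(est$ci_low, exp(0.3 - 1.959964 * 0.1))
  expect_equal(est$ci_high, exp(0.3 + 1.959964 * 0.1))
  expect_true(est$ci_low < est$or && est$or < est$ci_high)
})
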