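# ---- internal weighted least-squares helpers (closed form, vectorizable) ----

# intercept + slope of y ~ x with weights w (vectors)
wls_line <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  den <- sw * swxx - swx^2
  if (abs(den) < .Machine$double.eps * sw * swxx) {
    abort("collinear design: SNP-exposure estimates are all equal")
  }
  slope <- (sw * swxy - swx * swy) / den
  c(intercept = (swy - slope * swx) / sw, slope = slope)
}

# rows of X, Y are bootstrap replicates; w is the fixed weight vector.
# returns list of per-replicate intercepts and slopes
wls_line_mat <- function(X, Y, w) {
  W <- matrix(w, nrow(X), ncol(X), byrow = TRUE)
  sw <- sum(w)
  swx <- rowSums(W * X); swy <- rowSums(W * Y)
  swxx <- rowSums(W * X^2); swxy <- rowSums(W * X * Y)
  den <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / den
  list(intercept = (swy - slope * swx) / sw, slope = slope)
}

# weighted through-origin slope(s): y ~ 0 + x, weights w
wls_origin_mat <- function(X, Y, w) {
  W <- matrix(w, nrow(X), ncol(X), byrow = TRUE)
  rowSums(W * X * Y) / rowSums(W * X^2)
}

# parametric redraw of the summary estimates, re-oriented so the
# exposure effect is positive (both betas flip sign together, so the
# implied ratio is preserved)
redraw_oriented <- function(g, sg, G, sG, reps, redraw_exposure = TRUE) {
  k <- length(g)
  Gs <- matrix(rnorm(reps * k, mean = rep(G, each = reps),
                     sd = rep(sG, each = reps)), reps, k)
  if (redraw_exposure) {
    gs <- matrix(rnorm(reps * k, mean = rep(g, each = reps),
                       sd = rep(sg, each = reps)), reps, k)
  } else {
    gs <- matrix(g, reps, k, byrow = TRUE)
  }
  s <- sign(gs); s[s == 0] <- 1
  list(g = abs(gs), G = s * Gs)
}

# ---- MR-Egger ----------------------------------------------------------------

#' MR-Egger regression with parametric-bootstrap standard errors
#'
#' Weighted linear regression of the SNP-outcome effects on the
#' SNP-exposure effects with a free intercept,
#' \eqn{\hat\Gamma_j = \beta_{0E} + \beta_{1E}\hat\gamma_j}, weights
#' \eqn{1/\sigma_{\Gamma j}^2}. A nonzero intercept indicates directional
#' pleiotropy; the slope is a pleiotropy-adjusted causal estimate. All
#' rows are first oriented so the exposure effect is positive
#' ([orient_exposure_increasing()]). Standard errors are the standard
#' deviation of the estimates over parametric bootstrap replicates: each
#' replicate redraws \eqn{\hat\Gamma_j \sim N(\hat\Gamma_j,
#' \sigma_{\Gamma j}^2)} (and, by default, \eqn{\hat\gamma_j} likewise),
#' re-orients, and refits. P-values use the normal approximation
#' estimate / bootstrap-SE (`t_df` switches to a t reference with
#' k - 2 degrees of freedom).
#'
#' @param table an instrument table with at least 3 SNPs.
#' @param bootstrap_reps number of parametric bootstrap replicates
#'   (default 10000).
#' @param seed RNG seed for the bootstrap.
#' @param redraw_exposure redraw the SNP-exposure estimates as well as
#'   the SNP-outcome estimates (default `TRUE`)?
#' @param t_df use a t reference distribution instead of the normal?
#' @return an object of class `mr_egger_fit`: a two-row tibble
#'   (`term` = intercept, slope) with `estimate`, `se`, `pval`, plus
#'   attributes `bootstrap_reps`, `seed`, `method`.
#' @export
mr_egger <- function(table, bootstrap_reps = 10000, seed = 20170124,
                     redraw_exposure = TRUE, t_df = FALSE) {
  if (nrow(table) < 3) abort("MR-Egger needs at least 3 instruments")
  table <- orient_exposure_increasing(table)
  g <- table$beta_exp; G <- table$beta_out
  w <- 1 / table$se_out^2
  fit <- wls_line(g, G, w)
  withr_seed(seed, {
    rd <- redraw_oriented(g, table$se_exp, G, table$se_out,
                          bootstrap_reps, redraw_exposure)
    boot <- wls_line_mat(rd$g, rd$G, w)
  })
  se <- c(sd(boot$intercept), sd(boot$slope))
  pv <- if (t_df) {
    2 * stats::pt(-abs(fit / se), df = length(g) - 2)
  } else {
    two_sided_p(fit / se)
  }
  out <- tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(fit), se = se, pval = pv
  )
  structure(out, class = c("mr_egger_fit", class(out)),
            bootstrap_reps = bootstrap_reps, seed = seed, method = "egger")
}

# local seed scope so callers' RNG state is untouched
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' @export
tidy.mr_egger_fit <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.mr_egger_fit <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"),
                 bootstrap_reps = attr(x, "bootstrap_reps"),
                 seed = attr(x, "seed"))
}

# extract a fit term as a one-row mr_estimate
egger_term_estimate <- function(fit, term, n_snps, method = attr(fit, "method")) {
  row <- fit[fit$term == term, ]
  new_mr_estimate(row$estimate, row$se, method = method, n_snps = n_snps)
}

# ---- I2GX weak-instrument statistic -----------------------------------------

#' I2GX: expected attenuation of the MR-Egger slope under NOME violation
#'
#' MR-Egger assumes the SNP-exposure estimates carry no measurement
#' error (the NOME assumption). When they do, the Egger slope is
#' attenuated. The \eqn{I^2_{GX}} statistic quantifies the expected
#' reliability: with weights \eqn{w_j = 1/\sigma_{\gamma j}^2} and
#' weighted mean \eqn{\bar\gamma_w},
#' \eqn{Q_{GX} = \sum w_j(\hat\gamma_j - \bar\gamma_w)^2} and
#' \eqn{I^2_{GX} = \max(0, (Q_{GX} - (k-1))/Q_{GX})}. The attenuation
#' (relative bias) of the Egger slope is reported as
#' \eqn{1 - I^2_{GX}}. Note that published analyses sometimes quote a
#' bias figure that is not \eqn{1 - I^2_{GX}}; this function reports the
#' definitional quantity only.
#'
#' @param table an instrument table with at least 2 SNPs.
#' @return a one-row tibble: `k`, `q_gx`, `i2_gx`, `attenuation_bias`.
#' @export
i2_gx <- function(table) {
  k <- nrow(table)
  if (k < 2) abort("I2GX is undefined for a single instrument")
  g <- table$beta_exp; w <- 1 / table$se_exp^2
  gbar <- sum(w * g) / sum(w)
  q <- sum(w * (g - gbar)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  tibble::tibble(k = k, q_gx = q, i2_gx = i2, attenuation_bias = 1 - i2)
}

# ---- SIMEX correction of the Egger fit --------------------------------------

#' SIMEX-adjusted MR-Egger
#'
#' Simulation extrapolation corrects the attenuation of the MR-Egger
#' slope caused by measurement error in the SNP-exposure estimates
#' (NOME violation). For each inflation factor \eqn{\lambda} on a grid,
#' extra noise \eqn{N(0, \lambda\sigma_{\gamma j}^2)} is added to the
#' SNP-exposure estimates and the Egger fit recomputed; the average
#' coefficients are modelled as a quadratic in \eqn{\lambda} and
#' extrapolated back to \eqn{\lambda = -1}, the no-measurement-error
#' limit. With a grid of `{0}` alone the naive Egger fit is returned
#' exactly.
#'
#' @param table an instrument table with at least 3 SNPs.
#' @param lambda_grid ordered non-negative inflation factors starting at
#'   0 (default `seq(0, 2, 0.25)`).
#' @param reps_per_lambda simulation replicates per grid point
#'   (default 1000).
#' @param seed RNG seed.
#' @param se_boot_reps outer parametric-bootstrap replicates used for
#'   the standard error of the extrapolated coefficients; each replicate
#'   reruns the whole SIMEX procedure at `se_reps_per_lambda`
#'   replicates per grid point. Set to 0 to skip (SEs reported as `NA`).
#' @param se_reps_per_lambda per-lambda replicates inside the SE
#'   bootstrap (default 100).
#' @return an `mr_egger_fit` (method `"egger_simex"`) with attribute
#'   `lambda_means`, a tibble of the per-lambda averaged coefficients.
#' @export
mr_egger_simex <- function(table, lambda_grid = seq(0, 2, by = 0.25),
                           reps_per_lambda = 1000, seed = 20170124,
                           se_boot_reps = 100, se_reps_per_lambda = 100) {
  if (nrow(table) < 3) abort("SIMEX-Egger needs at least 3 instruments")
  check_lambda_grid(lambda_grid)
  table <- orient_exposure_increasing(table)
  g <- table$beta_exp; G <- table$beta_out
  sg <- table$se_exp; w <- 1 / table$se_out^2

  if (length(lambda_grid) == 1) {
    fit <- wls_line(g, G, w)
    out <- tibble::tibble(term = c("intercept", "slope"),
                          estimate = unname(fit), se = NA_real_,
                          pval = NA_real_)
    return(structure(out, class = c("mr_egger_fit", class(out)),
                     bootstrap_reps = 0L, seed = seed, method = "egger_simex",
                     lambda_means = tibble::tibble(
                       lambda = 0, intercept = fit[["intercept"]],
                       slope = fit[["slope"]])))
  }

  point <- withr_seed(seed, simex_extrapolate(g, G, sg, w, lambda_grid,
                                              reps_per_lambda,
                                              keep_means = TRUE))
  se <- c(NA_real_, NA_real_)
  if (se_boot_reps > 0) {
    boot <- withr_seed(stage_seed(seed, "simex_se"), {
      rd <- redraw_oriented(g, sg, G, table$se_out, se_boot_reps, TRUE)
      vapply(seq_len(se_boot_reps), function(b) {
        simex_extrapolate(rd$g[b, ], rd$G[b, ], sg, w, lambda_grid,
                          se_reps_per_lambda)$coef
      }, numeric(2))
    })
    se <- apply(boot, 1, sd)
  }
  est <- point$coef
  out <- tibble::tibble(
    term = c("intercept", "slope"), estimate = est, se = se,
    pval = ifelse(is.na(se), NA_real_, two_sided_p(est / se))
  )
  structure(out, class = c("mr_egger_fit", class(out)),
            bootstrap_reps = se_boot_reps, seed = seed,
            method = "egger_simex", lambda_means = point$means)
}

check_lambda_grid <- function(grid) {
  if (length(grid) < 1 || grid[1] != 0 || any(diff(grid) <= 0) || any(grid < 0)) {
    abort("`lambda_grid` must start at 0 and be strictly increasing")
  }
  if (length(grid) > 1 && length(grid) < 3) {
    abort("`lambda_grid` needs at least 3 points to fit a quadratic")
  }
  invisible(grid)
}

# core SIMEX loop: mean Egger coefficients per lambda, quadratic
# extrapolation to lambda = -1; consumes RNG state (callers scope the seed)
simex_extrapolate <- function(g, G, sg, w, lambda_grid, reps, keep_means = FALSE) {
  k <- length(g)
  means <- purrr::map(lambda_grid, function(lam) {
    if (lam == 0) {
      fit <- wls_line(g, G, w)
      c(fit[["intercept"]], fit[["slope"]])
    } else {
      noise <- matrix(rnorm(reps * k, sd = rep(sqrt(lam) * sg, each = reps)),
                      reps, k)
      gs <- matrix(g, reps, k, byrow = TRUE) + noise
      fit <- wls_line_mat(gs, matrix(G, reps, k, byrow = TRUE), w)
      c(mean(fit$intercept), mean(fit$slope))
    }
  })
  m <- do.call(rbind, means)
  extrap <- vapply(1:2, function(j) {
    cf <- coef(lm(m[, j] ~ lambda_grid + I(lambda_grid^2)))
    unname(cf[1] - cf[2] + cf[3])   # evaluate the quadratic at lambda = -1
  }, numeric(1))
  res <- list(coef = extrap)
  if (keep_means) {
    res$means <- tibble::tibble(lambda = lambda_grid,
                                intercept = m[, 1], slope = m[, 2])
  }
  res
}

# ---- penalized weighted median ----------------------------------------------

# interpolated weighted median: sort, standardized cumulative weights
# S_j = (cumsum(w) - w/2) / sum(w), linear interpolation to the 50% point
weighted_median <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  s <- (cumsum(w) - 0.5 * w) / sum(w)
  if (0.5 <= s[1]) return(theta[1])
  k <- length(theta)
  if (0.5 >= s[k]) return(theta[k])
  i <- max(which(s <= 0.5))
  theta[i] + (theta[i + 1] - theta[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# one penalized-weighted-median evaluation from ratio estimates and weights
pwm_point <- function(theta, w, penalty = 20) {
  wm0 <- weighted_median(theta, w)
  qj <- pchisq(w * (theta - wm0)^2, df = 1, lower.tail = FALSE)
  weighted_median(theta, w * pmin(1, penalty * qj))
}

#' Penalized weighted median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios, with inverse-variance
#' weights (first-order delta method), is a consistent causal estimate
#' even when up to 50% of the weight comes from invalid instruments.
#' The penalized variant first computes the provisional weighted median,
#' then down-weights instruments whose ratio is heterogeneous with it:
#' \eqn{Q_j = w_j(\hat\theta_j - \hat\theta_{WM})^2}, \eqn{q_j} the
#' upper-tail \eqn{\chi^2_1} probability at \eqn{Q_j}, and
#' \eqn{w^*_j = w_j \min(1, 20 q_j)}. The estimate is the weighted
#' median under \eqn{w^*}; its standard error comes from the parametric
#' bootstrap (as in [mr_egger()]).
#'
#' @inheritParams mr_egger
#' @param penalty penalization constant (default 20).
#' @return a one-row `mr_estimate` tibble (method `weighted_median`).
#' @export
mr_weighted_median <- function(table, bootstrap_reps = 10000,
                               seed = 20170124, penalty = 20,
                               redraw_exposure = TRUE) {
  if (nrow(table) < 3) abort("weighted median needs at least 3 instruments")
  wr <- wald_ratios(table)
  est <- pwm_point(wr$beta, 1 / wr$se^2, penalty)
  withr_seed(seed, {
    rd <- redraw_oriented(table$beta_exp, table$se_exp,
                          table$beta_out, table$se_out,
                          bootstrap_reps, redraw_exposure)
    theta <- rd$G / rd$g
    # delta-method variance recomputed per replicate
    SG2 <- matrix(table$se_out^2, bootstrap_reps, nrow(table), byrow = TRUE)
    Sg2 <- matrix(table$se_exp^2, bootstrap_reps, nrow(table), byrow = TRUE)
    v <- SG2 / rd$g^2 + rd$G^2 * Sg2 / rd$g^4
    boot <- vapply(seq_len(bootstrap_reps), function(b) {
      pwm_point(theta[b, ], 1 / v[b, ], penalty)
    }, numeric(1))
  })
  new_mr_estimate(est, sd(boot), method = "weighted_median",
                  n_snps = nrow(table))
}

# ---- multivariable MR --------------------------------------------------------

#' Multivariable MR: direct exposure effect adjusting for a covariate
#'
#' Weighted multivariable regression of the SNP-outcome effects on the
#' SNP-exposure and SNP-covariate effects jointly, with no intercept and
#' weights \eqn{1/\sigma_{\Gamma j}^2}:
#' \eqn{\hat\Gamma_j = \theta_c \hat\gamma_j + \theta_t \hat\delta_j +
#' \epsilon_j}. \eqn{\theta_c} is the direct effect of the exposure on
#' the outcome adjusted for pathways through the covariate (here,
#' cannabis adjusted for tobacco). Standard errors come from the
#' parametric bootstrap, redrawing all three sets of estimates.
#'
#' @inheritParams mr_egger
#' @return an object of class `mr_mvmr_fit`: a two-row tibble
#'   (`term` = exposure, covariate) with `estimate`, `se`, `pval`, plus
#'   bootstrap attributes.
#' @export
mr_mvmr <- function(table, bootstrap_reps = 10000, seed = 20170124) {
  if (!"beta_cov" %in% names(table)) {
    abort("multivariable MR needs covariate associations (harmonize with `covariate =`)")
  }
  if (nrow(table) < 3) abort("multivariable MR needs at least 3 instruments")
  if (anyNA(table$beta_cov)) abort("covariate associations missing for some SNPs")
  g <- table$beta_exp; d <- table$beta_cov; G <- table$beta_out
  w <- 1 / table$se_out^2
  est <- mvmr_solve(g, d, G, w)
  k <- nrow(table)
  withr_seed(seed, {
    Gs <- matrix(rnorm(bootstrap_reps * k, rep(G, each = bootstrap_reps),
                       rep(table$se_out, each = bootstrap_reps)),
                 bootstrap_reps, k)
    gs <- matrix(rnorm(bootstrap_reps * k, rep(g, each = bootstrap_reps),
                       rep(table$se_exp, each = bootstrap_reps)),
                 bootstrap_reps, k)
    ds <- matrix(rnorm(bootstrap_reps * k, rep(d, each = bootstrap_reps),
                       rep(table$se_cov, each = bootstrap_reps)),
                 bootstrap_reps, k)
    boot <- mvmr_solve_mat(gs, ds, Gs, w)
  })
  se <- c(sd(boot$theta_c), sd(boot$theta_t))
  out <- tibble::tibble(
    term = c("exposure", "covariate"),
    estimate = est, se = se, pval = two_sided_p(est / se)
  )
  structure(out, class = c("mr_mvmr_fit", class(out)),
            bootstrap_reps = bootstrap_reps, seed = seed, method = "mvmr")
}

mvmr_solve <- function(g, d, G, w) {
  a11 <- sum(w * g^2); a12 <- sum(w * g * d); a22 <- sum(w * d^2)
  b1 <- sum(w * g * G); b2 <- sum(w * d * G)
  if (a22 == 0) {
    # no covariate signal at all: the model reduces to the
    # through-origin exposure regression
    return(c(b1 / a11, 0))
  }
  det <- a11 * a22 - a12^2
  if (det < 1e-10 * a11 * a22) {
    abort("exposure and covariate effects are collinear: design is rank-deficient")
  }
  c((a22 * b1 - a12 * b2) / det, (a11 * b2 - a12 * b1) / det)
}

mvmr_solve_mat <- function(gs, ds, Gs, w) {
  W <- matrix(w, nrow(gs), ncol(gs), byrow = TRUE)
  a11 <- rowSums(W * gs^2); a12 <- rowSums(W * gs * ds); a22 <- rowSums(W * ds^2)
  b1 <- rowSums(W * gs * Gs); b2 <- rowSums(W * ds * Gs)
  det <- a11 * a22 - a12^2
  list(theta_c = (a22 * b1 - a12 * b2) / det,
       theta_t = (a11 * b2 - a12 * b1) / det)
}

#' @export
tidy.mr_mvmr_fit <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.mr_mvmr_fit <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"),
                 bootstrap_reps = attr(x, "bootstrap_reps"),
                 seed = attr(x, "seed"))
}
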