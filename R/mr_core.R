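#' Per-SNP Wald ratios with delta-method standard errors
#'
#' The instrumental-variable estimate for each SNP is the SNP-outcome
#' log-odds effect divided by the SNP-exposure log-odds effect,
#' \eqn{\hat\theta_j = \hat\Gamma_j / \hat\gamma_j}. Its standard error
#' is the first-order delta-method approximation
#' \deqn{se_j = \sqrt{\sigma_{\Gamma j}^2/\hat\gamma_j^2 +
#'   \hat\Gamma_j^2 \sigma_{\gamma j}^2/\hat\gamma_j^4}.}
#'
#' @param table an instrument table from [harmonize()].
#' @param se_method `"delta2"` (default): the two-term expansion above;
#'   `"delta1"`: the leading term \eqn{\sigma_{\Gamma j}/|\hat\gamma_j|}
#'   only, which treats the SNP-exposure estimate as fixed and makes
#'   fixed-effect IVW pooling algebraically identical to the weighted
#'   through-origin regression of outcome on exposure effects.
#' @return a tibble with one row per SNP: `rsid`, `beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `pval` (ratio scale: outcome log-OR per
#'   log-odds unit of exposure).
#' @export
wald_ratios <- function(table, se_method = c("delta2", "delta1")) {
  se_method <- match.arg(se_method)
  if (any(table$beta_exp == 0)) {
    abort(paste0("undefined Wald ratio (exposure beta = 0) for: ",
                 paste(table$rsid[table$beta_exp == 0], collapse = ", ")))
  }
  g <- table$beta_exp; G <- table$beta_out
  sg <- table$se_exp;  sG <- table$se_out
  beta <- G / g
  se <- if (se_method == "delta1") {
    sG / abs(g)
  } else {
    sqrt(sG^2 / g^2 + G^2 * sg^2 / g^4)
  }
  tibble::tibble(
    rsid = table$rsid, beta = beta, se = se,
    or = exp(beta),
    ci_low = exp(beta - Z95 * se), ci_high = exp(beta + Z95 * se),
    pval = two_sided_p(beta / se)
  )
}

#' Inverse-variance-weighted pooling of per-SNP causal estimates
#'
#' Pools Wald ratios across instruments by inverse-variance weighting.
#' Fixed-effect: weights \eqn{w_j = 1/se_j^2}, pooled
#' \eqn{\hat\beta = \sum w_j \beta_j / \sum w_j},
#' \eqn{se = 1/\sqrt{\sum w_j}}. Random-effects: DerSimonian-Laird
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w))} with
#' re-weighting \eqn{w_j^* = 1/(se_j^2 + \tau^2)}. Cochran's
#' \eqn{Q = \sum w_j (\beta_j - \hat\beta_{fixed})^2} and
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q)} are attached to the result in
#' either mode.
#'
#' @param estimates a tibble with columns `beta` and `se`, typically from
#'   [wald_ratios()].
#' @param mode `"fixed"` or `"random"`.
#' @return a one-row `mr_estimate` tibble with heterogeneity columns
#'   `q`, `q_df`, `tau2`, `i2`.
#' @export
mr_ivw <- function(estimates, mode = c("fixed", "random")) {
  mode <- match.arg(mode)
  if (nrow(estimates) == 0) abort("no estimates to pool")
  b <- estimates$beta; w <- 1 / estimates$se^2
  k <- length(b)
  beta_fixed <- sum(w * b) / sum(w)
  if (k == 1) {
    q <- 0; df <- 0L; tau2 <- 0; i2 <- 0
  } else {
    q <- sum(w * (b - beta_fixed)^2)
    df <- k - 1L
    tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
    i2 <- if (q > 0) max(0, (q - df) / q) else 0
  }
  if (mode == "fixed") {
    beta <- beta_fixed; se <- 1 / sqrt(sum(w))
  } else {
    ws <- 1 / (estimates$se^2 + tau2)
    beta <- sum(ws * b) / sum(ws); se <- 1 / sqrt(sum(ws))
  }
  new_mr_estimate(beta, se, method = paste0("ivw_", mode), n_snps = k,
                  q = q, q_df = df, tau2 = tau2, i2 = i2)
}

#' Convert a per-log-unit estimate to a users-vs-nonusers odds ratio
#'
#' The instrument GWAS measures the exposure on the log-odds scale, so
#' pooled MR estimates are "per 1-log-unit increase in odds of ever
#' use". This converts them to the contrast of interest, ever-users vs
#' never-users. The default (`method = "linear_rescale"`) divides the
#' log-OR and its standard error by \eqn{p(1-p)}, the variance of the
#' binary exposure at prevalence \eqn{p} — the linear-probability
#' approximation that links a per-log-odds-of-exposure slope to a
#' one-unit (never to ever) change in exposure status. The alternative
#' (`method = "risk_solve"`) carries the rescaled relative effect through
#' the population lifetime risk \eqn{K = p k_1 + (1-p) k_0}, solving for
#' the risk in users \eqn{k_1} and returning the odds ratio
#' \eqn{[k_1/(1-k_1)]/[k_0/(1-k_0)]}.
#'
#' @param estimate a one-row `mr_estimate` on the `per_log_unit` scale.
#' @param exposure_prevalence proportion of ever-users in the exposure
#'   GWAS population, in (0,1). Default 0.43.
#' @param population_risk lifetime outcome risk K, used by
#'   `"risk_solve"` only. Default 0.007.
#' @param method `"linear_rescale"` (default) or `"risk_solve"`.
#' @return the estimate re-expressed on the `users_vs_nonusers` scale.
#' @export
to_users_vs_nonusers <- function(estimate, exposure_prevalence = 0.43,
                                 population_risk = 0.007,
                                 method = c("linear_rescale", "risk_solve")) {
  method <- match.arg(method)
  p <- exposure_prevalence
  if (!(is.finite(p) && p > 0 && p < 1)) {
    abort("`exposure_prevalence` must lie in (0, 1)")
  }
  if (!identical(estimate$scale, "per_log_unit")) {
    abort("estimate is not on the per_log_unit scale")
  }
  scale_f <- 1 / (p * (1 - p))
  beta2 <- estimate$beta * scale_f
  se2 <- estimate$se * scale_f
  if (method == "risk_solve") {
    K <- population_risk
    if (!(is.finite(K) && K > 0 && K < 1)) {
      abort("`population_risk` must lie in (0, 1)")
    }
    # relative risk of users vs nonusers implied by the rescaled effect;
    # K = p*k1 + (1-p)*k0 with k1 = rr*k0 pins down both risks
    or_to <- function(b) {
      rr <- exp(b)
      k0 <- K / (p * rr + (1 - p))
      k1 <- rr * k0
      (k1 / (1 - k1)) / (k0 / (1 - k0))
    }
    beta_out <- log(or_to(beta2))
    # delta method on the composed map at the point estimate
    eps <- 1e-6
    deriv <- (log(or_to(beta2 + eps)) - log(or_to(beta2 - eps))) / (2 * eps)
    se_out <- abs(deriv) * se2
  } else {
    beta_out <- beta2
    se_out <- se2
  }
  new_mr_estimate(beta_out, se_out, method = estimate$method,
                  n_snps = estimate$n_snps, scale = "users_vs_nonusers")
}

#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble::as_tibble(x)[, c("method", "n_snps", "scale", "beta", "se",
                           "or", "ci_low", "ci_high", "pval")]
}

#' @export
glance.mr_estimate <- function(x, ...) {
  cols <- intersect(c("method", "n_snps", "q", "q_df", "tau2", "i2"), names(x))
  tibble::as_tibble(x)[, cols]
}

#' Broom-style accessors
#'
#' `tidy()` returns the estimate columns of a fitted object as a plain
#' tibble; `glance()` returns one row of fit-level summaries
#' (heterogeneity statistics, bootstrap settings).
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
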