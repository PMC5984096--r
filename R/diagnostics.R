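# ---- instrument strength -----------------------------------------------------

#' Instrument strength: per-SNP and cumulative F and R-squared
#'
#' Per SNP, \eqn{F_j = (\hat\gamma_j/\sigma_{\gamma j})^2} and the
#' variance in the exposure explained is approximated from the summary
#' statistics as \eqn{R^2_j = F_j/(F_j + n - 2)}. With independent
#' instruments the cumulative \eqn{R^2} is the sum of the per-SNP
#' values, and the cumulative F-statistic is
#' \eqn{(R^2/k)\,\big((n-k-1)/(1-R^2)\big)}. When effect-allele
#' frequencies are available, `r2_method = "eaf"` uses the alternative
#' \eqn{R^2_j = 2f_j(1-f_j)\hat\gamma_j^2 \, p(1-p)} on the observed
#' (0/1) exposure scale via `exposure_prevalence`.
#'
#' @param table an instrument table.
#' @param n_exposure sample size of the exposure GWAS; must exceed the
#'   number of SNPs plus one.
#' @param r2_method `"f"` (default, from the F statistic) or `"eaf"`.
#' @param exposure_prevalence exposure prevalence used by the `"eaf"`
#'   method.
#' @return a list of class `instrument_strength`: `$per_snp`, a tibble
#'   with `rsid`, `f_stat`, `r2`; and `$cumulative`, a one-row tibble
#'   with `k`, `n_exposure`, `cumulative_r2`, `cumulative_f`.
#' @export
instrument_strength <- function(table, n_exposure,
                                r2_method = c("f", "eaf"),
                                exposure_prevalence = 0.43) {
  r2_method <- match.arg(r2_method)
  k <- nrow(table)
  if (!(is.finite(n_exposure) && n_exposure > k + 1)) {
    abort("`n_exposure` must be a sample size larger than n_snps + 1")
  }
  f <- (table$beta_exp / table$se_exp)^2
  r2 <- if (r2_method == "eaf") {
    if (anyNA(table$eaf_exp)) abort("`eaf` required for r2_method = \"eaf\"")
    p <- exposure_prevalence
    2 * table$eaf_exp * (1 - table$eaf_exp) * table$beta_exp^2 * p * (1 - p)
  } else {
    f / (f + n_exposure - 2)
  }
  cum_r2 <- sum(r2)
  cum_f <- (cum_r2 / k) * ((n_exposure - k - 1) / (1 - cum_r2))
  structure(
    list(per_snp = tibble::tibble(rsid = table$rsid, f_stat = f, r2 = r2),
         cumulative = tibble::tibble(k = k, n_exposure = n_exposure,
                                     cumulative_r2 = cum_r2,
                                     cumulative_f = cum_f)),
    class = "instrument_strength")
}

#' @export
tidy.instrument_strength <- function(x, ...) x$per_snp

#' @export
glance.instrument_strength <- function(x, ...) x$cumulative

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: %d SNPs, cumulative R2 = %.3f%%, F = %.1f\n",
              x$cumulative$k, 100 * x$cumulative$cumulative_r2,
              x$cumulative$cumulative_f))
  print(x$per_snp)
  invisible(x)
}

# ---- power -------------------------------------------------------------------

#' Power of a summary-data MR analysis with a binary outcome
#'
#' Standard normal approximation: with total sample size
#' \eqn{N = n_{cases} + n_{controls}}, case fraction \eqn{\phi}, and
#' instrument variance explained \eqn{R^2}, the power to detect an odds
#' ratio `target_or` at two-sided level \eqn{\alpha} is
#' \deqn{\Phi\big(|\ln OR|\sqrt{N R^2 \phi(1-\phi)} - z_{1-\alpha/2}\big).}
#' At `target_or = 1` the one-tail rejection convention gives
#' \eqn{\alpha/2}.
#'
#' @param n_cases,n_controls outcome GWAS counts.
#' @param r2 instrument variance explained, in (0, 1).
#' @param target_or detectable odds ratio (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @return a one-row tibble with the inputs and `power`.
#' @export
mr_power <- function(n_cases, n_controls, r2, target_or, alpha = 0.05) {
  if (any(c(n_cases, n_controls) <= 0) || target_or <= 0 ||
      !(alpha > 0 && alpha < 1) || r2 < 0 || r2 >= 1) {
    abort("invalid power parameters")
  }
  if (r2 == 0) warn("r2 = 0: no instrument information, power equals the type-I rate")
  n <- n_cases + n_controls
  phi <- n_cases / n
  z <- abs(log(target_or)) * sqrt(n * r2 * phi * (1 - phi)) - qnorm(1 - alpha / 2)
  tibble::tibble(n_cases = n_cases, n_controls = n_controls, r2 = r2,
                 target_or = target_or, alpha = alpha, power = pnorm(z))
}

# ---- influence ---------------------------------------------------------------

#' Leave-one-out analysis of the pooled estimate
#'
#' Recomputes the fixed-effect IVW estimate k times, omitting each SNP
#' in turn, to show whether any single instrument drives the pooled
#' result.
#'
#' @param table an instrument table with at least 2 SNPs.
#' @param transform convert each estimate to the users-vs-nonusers
#'   scale?
#' @param exposure_prevalence passed to [to_users_vs_nonusers()] when
#'   `transform = TRUE`.
#' @return a tibble, one row per omitted SNP (`excluded_rsid` plus the
#'   `mr_estimate` columns), in input order.
#' @export
leave_one_out <- function(table, transform = FALSE, exposure_prevalence = 0.43) {
  if (nrow(table) < 2) abort("leave-one-out needs at least 2 instruments")
  purrr::map_dfr(seq_len(nrow(table)), function(i) {
    est <- mr_ivw(wald_ratios(table[-i, ]), mode = "fixed")
    if (transform) est <- to_users_vs_nonusers(est, exposure_prevalence)
    dplyr::bind_cols(tibble::tibble(excluded_rsid = table$rsid[i]),
                     tidy(est))
  })
}

#' Per-SNP influence statistics for the IVW model
#'
#' Externally studentized residuals and Cook's distances from the
#' IVW-equivalent model: the weighted no-intercept regression of the
#' SNP-outcome effects on the SNP-exposure effects with weights
#' \eqn{1/\sigma_{\Gamma j}^2}. An absolute studentized residual above 2
#' is flagged as a potential outlier; a Cook's distance above
#' `cooks_cutoff` (default 4/k) flags an influential instrument.
#' Flags are reported, never enforced.
#'
#' @param table an instrument table with at least 3 SNPs.
#' @param cooks_cutoff influence flag threshold (default `4/nrow(table)`).
#' @return a tibble: `rsid`, `studentized_residual`, `cooks_d`,
#'   `hat_value`, `outlier` (|r| > 2), `influential` (Cook's d above
#'   cutoff).
#' @export
influence_stats <- function(table, cooks_cutoff = NULL) {
  if (nrow(table) < 3) abort("influence statistics need at least 3 instruments")
  cooks_cutoff <- cooks_cutoff %||% (4 / nrow(table))
  fit <- lm(beta_out ~ 0 + beta_exp, data = table, weights = 1 / table$se_out^2)
  h <- stats::hatvalues(fit)
  # numerically exact fits leave the studentized scale undefined (0/0);
  # report zero influence rather than amplified rounding noise
  if (summary(fit)$sigma < 1e-10 * max(abs(table$beta_out), 1e-12)) {
    r <- rep(0, nrow(table)); d <- rep(0, nrow(table))
  } else {
    r <- rstudent(fit)
    d <- cooks.distance(fit)
    r[!is.finite(r)] <- 0
    d[!is.finite(d)] <- 0
  }
  tibble::tibble(
    rsid = table$rsid,
    studentized_residual = unname(r),
    cooks_d = unname(d),
    hat_value = unname(h),
    outlier = abs(unname(r)) > 2,
    influential = unname(d) > cooks_cutoff
  )
}

#' MR analysis restricted to a subset of instruments
#'
#' Runs the core pipeline (Wald ratios, fixed-effect IVW, optional
#' users-vs-nonusers transformation) on a named subset of SNPs, e.g.
#' instruments with known functional roles.
#'
#' @param table an instrument table.
#' @param rsids character vector of SNPs to keep; all must be present.
#' @param transform convert to the users-vs-nonusers scale
#'   (default `TRUE`)?
#' @param exposure_prevalence passed to [to_users_vs_nonusers()].
#' @return a one-row `mr_estimate` tibble.
#' @export
subset_analysis <- function(table, rsids, transform = TRUE,
                            exposure_prevalence = 0.43) {
  missing <- setdiff(rsids, table$rsid)
  if (length(missing)) {
    abort(paste0("rsid(s) not in table: ", paste(missing, collapse = ", ")))
  }
  sub <- table[table$rsid %in% rsids, , drop = FALSE]
  est <- mr_ivw(wald_ratios(sub), mode = "fixed")
  if (transform) est <- to_users_vs_nonusers(est, exposure_prevalence)
  est
}
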