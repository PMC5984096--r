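#' Standard error of a log odds ratio from a printed 95% CI
#'
#' Assumes the interval is symmetric on the log scale:
#' \eqn{se = (\ln CI_{high} - \ln CI_{low}) / (2 \times 1.959964)}. When
#' a point estimate is supplied and the two log-scale half-widths differ
#' by more than 5%, a warning is raised and the average half-width used.
#'
#' @param ci_low,ci_high positive 95% confidence bounds on the OR scale.
#' @param or optional point estimate, used only for the asymmetry check.
#' @return the standard error of the log-OR.
#' @export
#' @examples
#' se_from_ci(1.10, 2.00)
se_from_ci <- function(ci_low, ci_high, or = NULL) {
  if (any(!is.finite(c(ci_low, ci_high))) || any(ci_low <= 0) ||
      any(ci_high <= ci_low)) {
    abort("confidence bounds must be positive with ci_low < ci_high")
  }
  if (!is.null(or)) {
    lo <- log(or) - log(ci_low); hi <- log(ci_high) - log(or)
    asym <- abs(hi - lo) / pmax(lo, hi)
    if (any(asym > 0.05)) {
      warn("CI asymmetric on the log scale by >5%; using the average half-width")
    }
  }
  (log(ci_high) - log(ci_low)) / (2 * Z95)
}

#' Read a table of observational study estimates
#'
#' Expects columns `label`, `or`, `ci_low`, `ci_high`, and optionally
#' `n_cases`, `n_controls`, `outcome_class`. Rows with a missing OR or
#' CI are dropped with a message (the packaged fixture ships placeholder
#' rows for studies whose estimates must be transcribed from their
#' source publications).
#'
#' @param path CSV (or TSV) file of study estimates.
#' @return a tibble of usable study rows.
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  s <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  need <- c("label", "or", "ci_low", "ci_high")
  miss <- setdiff(need, names(s))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  usable <- is.finite(s$or) & is.finite(s$ci_low) & is.finite(s$ci_high) &
    s$ci_low > 0 & s$or > s$ci_low & s$ci_high > s$or
  if (any(!usable)) {
    inform(paste0("dropped studies without usable estimates: ",
                  paste(s$label[!usable], collapse = ", ")))
  }
  tibble::as_tibble(s[usable, , drop = FALSE])
}

#' Random-effects meta-analysis of observational odds ratios
#'
#' DerSimonian-Laird pooling on the log-OR scale: standard errors are
#' reconstructed from the printed CIs with [se_from_ci()], then pooled
#' with the same moment estimator of between-study variance as
#' [mr_ivw()] in random mode. Heterogeneity (`q`, `tau2`, `i2`) is
#' attached; `i2` is a proportion (multiply by 100 for the conventional
#' percentage).
#'
#' @param studies a tibble from [read_studies()] (columns `label`, `or`,
#'   `ci_low`, `ci_high`).
#' @return a one-row `mr_estimate` tibble (method `meta_random`,
#'   `n_snps` = number of studies, scale `users_vs_nonusers`).
#' @export
meta_random_effects <- function(studies) {
  if (nrow(studies) == 0) abort("no studies to pool")
  if (nrow(studies) == 1) {
    warn("single study: returning it unchanged")
  }
  est <- tibble::tibble(
    beta = log(studies$or),
    se = purrr::map2_dbl(studies$ci_low, studies$ci_high, se_from_ci)
  )
  pooled <- mr_ivw(est, mode = "random")
  pooled$method <- "meta_random"
  pooled$scale <- "users_vs_nonusers"
  pooled
}

#' Chi-square heterogeneity test between two pooled estimates
#'
#' Tests whether two estimates of the same contrast differ more than
#' their sampling errors allow:
#' \eqn{\chi^2 = (\beta_a - \beta_b)^2 / (se_a^2 + se_b^2)} on 1 degree
#' of freedom. Symmetric in its arguments. Both estimates must be on the
#' same scale; build one from published numbers with
#' [estimate_from_or()].
#'
#' @param a,b one-row `mr_estimate` tibbles.
#' @return a one-row tibble: `chi2`, `df`, `pval`.
#' @export
#' @examples
#' compare_estimates(
#'   estimate_from_or(1.37, 1.09, 1.67, method = "mr"),
#'   estimate_from_or(1.43, 1.19, 1.67, method = "observational"))
compare_estimates <- function(a, b) {
  if (!identical(a$scale, b$scale)) {
    abort(sprintf("estimates are on different scales (%s vs %s)", a$scale, b$scale))
  }
  chi2 <- (a$beta - b$beta)^2 / (a$se^2 + b$se^2)
  tibble::tibble(chi2 = chi2, df = 1L,
                 pval = pchisq(chi2, df = 1, lower.tail = FALSE))
}
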