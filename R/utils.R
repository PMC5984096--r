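#' Build a causal-estimate row
#'
#' Internal constructor for the one-row tibble used by every estimator:
#' a log odds ratio with its standard error, 95% CI on the OR scale,
#' two-sided normal p-value, method label, number of instruments and scale.
#'
#' @param beta log odds ratio.
#' @param se standard error of `beta` (> 0).
#' @param method method label, e.g. `"ivw_fixed"`.
#' @param n_snps number of instruments behind the estimate.
#' @param scale `"per_log_unit"` or `"users_vs_nonusers"`.
#' @param ... extra scalar columns appended after the core ones.
#' @return a one-row tibble with class `"mr_estimate"`.
#' @keywords internal
new_mr_estimate <- function(beta, se, method, n_snps,
                            scale = "per_log_unit", ...) {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  out <- tibble::tibble(
    method  = method,
    n_snps  = as.integer(n_snps),
    scale   = scale,
    beta    = beta,
    se      = se,
    or      = exp(beta),
    ci_low  = exp(beta - Z95 * se),
    ci_high = exp(beta + Z95 * se),
    pval    = two_sided_p(beta / se),
    ...
  )
  class(out) <- c("mr_estimate", class(out))
  out
}

# two-sided normal p, clamped into (0, 1]
two_sided_p <- function(z) {
  p <- 2 * pnorm(-abs(z))
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Turn a printed odds ratio and 95% CI into an estimate row
#'
#' Reconstructs the log-OR and its standard error from an odds ratio and
#' its 95% confidence bounds, assuming the interval is symmetric on the
#' log scale. Useful for feeding published numbers into
#' [compare_estimates()].
#'
#' @param or odds ratio (> 0).
#' @param ci_low,ci_high 95% confidence bounds on the OR scale.
#' @param method label recorded in the `method` column.
#' @param scale scale label (default `"users_vs_nonusers"`).
#' @param n_snps instruments behind the estimate, if known.
#' @return a one-row `mr_estimate` tibble.
#' @export
#' @examples
#' estimate_from_or(1.37, 1.09, 1.67, method = "ivw_fixed")
estimate_from_or <- function(or, ci_low, ci_high, method = "external",
                             scale = "users_vs_nonusers", n_snps = NA_integer_) {
  if (!(is.finite(or) && or > 0 && ci_low > 0 && ci_high > ci_low)) {
    abort("`or`, `ci_low`, `ci_high` must be positive with ci_low < ci_high.")
  }
  se <- se_from_ci(ci_low, ci_high)
  new_mr_estimate(log(or), se, method = method, n_snps = n_snps, scale = scale)
}

# deterministic per-stage seed fan-out: adding a stage never perturbs
# the randomness of earlier stages
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 10007 * h) %% 2147483647L)
}

# format numerics for report TSVs at 6 significant digits
signif6 <- function(x) if (is.numeric(x)) signif(x, 6) else x
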