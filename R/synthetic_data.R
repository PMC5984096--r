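# non-complementary allele pairs used for simulated SNPs (strand-safe)
NONPALINDROMIC_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Specify a generative model for two-sample MR summary statistics
#'
#' Encodes the data-generating assumptions of two-sample MR with
#' independent instruments: each SNP has a true log-odds effect
#' \eqn{\gamma_j} on the (binary) exposure; its true effect on the
#' outcome is \eqn{\Gamma_j = \theta\gamma_j + \alpha_j +
#' \theta_t\delta_j}, composed of the causal path, an optional
#' (horizontal) pleiotropy term \eqn{\alpha_j}, and an optional second
#' exposure path through a covariate such as tobacco
#' (\eqn{\delta_j} = SNP-covariate effect, \eqn{\theta_t} its effect on
#' the outcome). Standard errors follow the case-control log-odds
#' approximation \eqn{\sigma_j \approx 1/\sqrt{2f_j(1-f_j)\,n\,\phi(1-\phi)}}
#' with allele frequency \eqn{f_j} and case (or ever-user) fraction
#' \eqn{\phi}; observed estimates are the truths plus normal sampling
#' noise. Defaults mirror the cannabis-schizophrenia study conditions:
#' 10 SNPs, exposure GWAS of 32,330 with ever-use prevalence 0.43,
#' outcome GWAS of 34,241 cases / 45,604 controls, instrument effects
#' sized so per-SNP z-statistics sit near 4.8.
#'
#' @param n_snps number of independent instruments.
#' @param theta true causal log-OR per log-odds unit of exposure.
#' @param maf_range range of simulated allele frequencies, in (0, 0.5].
#' @param gamma_mean,gamma_sd mean and SD of the true SNP-exposure
#'   log-odds effects.
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero \eqn{\alpha_j})
#'   or `"directional"` (nonzero mean).
#' @param pleiotropy_mean,pleiotropy_sd parameters of \eqn{\alpha_j}.
#' @param inside_violation if `TRUE`, \eqn{\alpha_j} is made
#'   proportional to \eqn{\gamma_j} (breaking the InSIDE assumption) —
#'   a stress switch for the robust estimators.
#' @param tobacco `NULL`, or a list with `delta_mean`, `delta_sd`
#'   (true SNP-covariate effects), `theta_t` (covariate-outcome
#'   effect), `n` and `phi` (covariate GWAS size and case fraction).
#' @param n_exposure exposure GWAS sample size.
#' @param exposure_prevalence ever-user fraction in the exposure GWAS.
#' @param n_outcome_cases,n_outcome_controls outcome GWAS counts.
#' @return a list of class `sim_model`.
#' @export
sim_model <- function(n_snps = 10, theta = log(1.08),
                      maf_range = c(0.10, 0.45),
                      gamma_mean = 0.083, gamma_sd = 0.010,
                      pleiotropy = c("none", "balanced", "directional"),
                      pleiotropy_mean = 0, pleiotropy_sd = 0,
                      inside_violation = FALSE,
                      tobacco = NULL,
                      n_exposure = 32330, exposure_prevalence = 0.43,
                      n_outcome_cases = 34241, n_outcome_controls = 45604) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(n_snps >= 1, n_exposure > 0, n_outcome_cases > 0,
            n_outcome_controls > 0, pleiotropy_sd >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(tobacco)) {
    need <- c("delta_mean", "delta_sd", "theta_t")
    if (!all(need %in% names(tobacco))) {
      abort("`tobacco` needs delta_mean, delta_sd, theta_t")
    }
    tobacco$n <- tobacco$n %||% 111898
    tobacco$phi <- tobacco$phi %||% (51984 / 111898)
  }
  structure(list(
    n_snps = n_snps, theta = theta, maf_range = maf_range,
    gamma_mean = gamma_mean, gamma_sd = gamma_sd,
    pleiotropy = pleiotropy, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, inside_violation = inside_violation,
    tobacco = tobacco,
    n_exposure = n_exposure, exposure_prevalence = exposure_prevalence,
    n_outcome_cases = n_outcome_cases,
    n_outcome_controls = n_outcome_controls), class = "sim_model")
}

# standard error of a log-odds effect from allele frequency, sample
# size and case fraction
logodds_se <- function(f, n, phi) 1 / sqrt(2 * f * (1 - f) * n * phi * (1 - phi))

sim_alleles <- function(k) {
  idx <- sample.int(nrow(NONPALINDROMIC_PAIRS), k, replace = TRUE)
  list(ea = NONPALINDROMIC_PAIRS[idx, 1], oa = NONPALINDROMIC_PAIRS[idx, 2])
}

assoc_tibble <- function(rsid, ea, oa, f, beta, se, n) {
  tibble::tibble(
    rsid = rsid, effect_allele = ea, other_allele = oa, eaf = f,
    beta = beta, se = se, pval = two_sided_p(beta / se), n = n)
}

#' Simulate exposure, outcome and covariate summary-statistics tables
#'
#' Draws one realization of the model described in [sim_model()]:
#' true per-SNP effects, their standard errors from the stated sample
#' sizes and allele frequencies, and observed estimates with normal
#' sampling noise. Fully reproducible under `seed`.
#'
#' @param model a [sim_model()].
#' @param seed RNG seed.
#' @return a list: `exposure`, `outcome` and (when the model has a
#'   tobacco path) `covariate` tibbles in the canonical summary-stats
#'   layout, plus `truth` — a list with the model parameters and a
#'   per-SNP tibble of the true `gamma`, `alpha`, `delta`, `Gamma`.
#' @export
simulate_summary_stats <- function(model, seed = 1) {
  stopifnot(inherits(model, "sim_model"))
  withr_seed(seed, {
    k <- model$n_snps
    rsid <- sprintf("rs%07d", seq_len(k) * 7 + 9000000)
    al <- sim_alleles(k)
    f <- runif(k, model$maf_range[1], model$maf_range[2])
    gamma <- rnorm(k, model$gamma_mean, model$gamma_sd)
    alpha <- switch(model$pleiotropy,
      none = rep(0, k),
      balanced = rnorm(k, 0, model$pleiotropy_sd),
      directional = rnorm(k, model$pleiotropy_mean, model$pleiotropy_sd))
    if (model$inside_violation && model$pleiotropy != "none") {
      alpha <- model$pleiotropy_mean + model$pleiotropy_sd *
        (gamma - model$gamma_mean) / model$gamma_sd
    }
    has_cov <- !is.null(model$tobacco)
    delta <- if (has_cov) {
      rnorm(k, model$tobacco$delta_mean, model$tobacco$delta_sd)
    } else rep(0, k)
    theta_t <- if (has_cov) model$tobacco$theta_t else 0
    Gamma <- model$theta * gamma + alpha + theta_t * delta

    p_exp <- model$exposure_prevalence
    se_exp <- logodds_se(f, model$n_exposure, p_exp)
    n_out <- model$n_outcome_cases + model$n_outcome_controls
    phi_out <- model$n_outcome_cases / n_out
    se_out <- logodds_se(f, n_out, phi_out)

    out <- list(
      exposure = assoc_tibble(rsid, al$ea, al$oa, f,
                              gamma + rnorm(k, 0, se_exp), se_exp,
                              model$n_exposure),
      outcome = assoc_tibble(rsid, al$ea, al$oa, f,
                             Gamma + rnorm(k, 0, se_out), se_out, n_out)
    )
    if (has_cov) {
      se_cov <- logodds_se(f, model$tobacco$n, model$tobacco$phi)
      out$covariate <- assoc_tibble(rsid, al$ea, al$oa, f,
                                    delta + rnorm(k, 0, se_cov), se_cov,
                                    model$tobacco$n)
    }
    out$truth <- list(
      theta = model$theta, theta_t = theta_t, seed = seed,
      per_snp = tibble::tibble(rsid = rsid, maf = f, gamma = gamma,
                               alpha = alpha, delta = delta, Gamma = Gamma))
    out
  })
}

#' Deterministically calibrated 10-SNP reference fixture
#'
#' A synthetic stand-in for the 10-instrument cannabis/schizophrenia
#' data set, built so the features the pipeline relies on hold by
#' construction: 10 independent SNPs; observed SNP-exposure z-statistics
#' spaced over 4.6-5.0, i.e. every exposure p-value inside
#' (1e-7, 1e-5); exposure GWAS size 32,330; outcome GWAS 34,241 cases /
#' 45,604 controls; true causal log-OR `log(1.08)` per log-odds unit;
#' and a tobacco covariate whose true per-SNP effects are positive on
#' average but vary independently of the instrument effects (keeping
#' the multivariable design well-conditioned), with no direct tobacco
#' path to the outcome. The exposure z-band is imposed exactly (only
#' the outcome and covariate estimates carry sampling noise) so that
#' fixture properties are deterministic. This is synthetic data, not
#' the published estimates.
#'
#' @param seed RNG seed for the outcome/covariate noise.
#' @return as [simulate_summary_stats()]: `exposure`, `outcome`,
#'   `covariate`, `truth`.
#' @export
simulate_reference_fixture <- function(seed = 20170124) {
  k <- 10
  theta <- log(1.08)
  withr_seed(seed, {
    rsid <- sprintf("rs%07d", seq_len(k) * 13 + 8000000)
    idx <- rep_len(seq_len(nrow(NONPALINDROMIC_PAIRS)), k)
    f <- seq(0.10, 0.45, length.out = k)
    z <- seq(4.6, 5.0, length.out = k)
    p_exp <- 0.43
    n_exp <- 32330
    se_exp <- logodds_se(f, n_exp, p_exp)
    gamma_hat <- z * se_exp                 # observed z fixed by design
    n_out <- 34241 + 45604
    phi_out <- 34241 / n_out
    se_out <- logodds_se(f, n_out, phi_out)
    Gamma <- theta * gamma_hat
    n_cov <- 111898
    phi_cov <- 51984 / n_cov
    se_cov <- logodds_se(f, n_cov, phi_cov)
    # positive on average, independent per-SNP spread (fixed permutation)
    perm <- c(3, 8, 1, 10, 5, 2, 7, 4, 9, 6)
    delta <- 0.04 + 0.015 * (perm - mean(perm)) / sd(perm)
    list(
      exposure = assoc_tibble(rsid, NONPALINDROMIC_PAIRS[idx, 1],
                              NONPALINDROMIC_PAIRS[idx, 2], f,
                              gamma_hat, se_exp, n_exp),
      outcome = assoc_tibble(rsid, NONPALINDROMIC_PAIRS[idx, 1],
                             NONPALINDROMIC_PAIRS[idx, 2], f,
                             Gamma + rnorm(k, 0, se_out), se_out, n_out),
      covariate = assoc_tibble(rsid, NONPALINDROMIC_PAIRS[idx, 1],
                               NONPALINDROMIC_PAIRS[idx, 2], f,
                               delta + rnorm(k, 0, se_cov), se_cov, n_cov),
      truth = list(theta = theta, theta_t = 0, seed = seed,
                   per_snp = tibble::tibble(rsid = rsid, maf = f,
                                            gamma = gamma_hat, alpha = 0,
                                            delta = delta,
                                            Gamma = Gamma))
    )
  })
}

#' Write a simulated data set to disk
#'
#' Emits the exposure/outcome/covariate tables as TSVs in the canonical
#' layout plus a `truth.json` sidecar, so the files can be read back
#' with [read_summary_table()].
#'
#' @param sim result of [simulate_summary_stats()] or
#'   [simulate_reference_fixture()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (default `"synthetic"`).
#' @return the written paths, invisibly.
#' @export
write_sim_tables <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in intersect(c("exposure", "outcome", "covariate"), names(sim))) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".tsv"))
    write_summary_table(sim[[nm]], p)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, paste0(prefix, "_truth.json"))
  truth <- sim$truth
  truth$per_snp <- as.data.frame(truth$per_snp)
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}
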