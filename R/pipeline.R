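#' Assemble (or read) a pipeline configuration
#'
#' Collects every input and tuning knob of the full analysis in one
#' validated list. Table arguments may be file paths (read with
#' [read_summary_table()] / [read_studies()]) or tibbles already in the
#' canonical layout. `read_mr_config()` builds the same object from a
#' YAML file whose keys are this function's arguments.
#'
#' @param exposure,outcome SNP association tables (paths or tibbles).
#' @param covariate optional covariate trait table (e.g. smoking).
#' @param studies optional observational study estimates (path or
#'   tibble: `label`, `or`, `ci_low`, `ci_high`, ...).
#' @param column_maps optional named list of column maps (entries
#'   `exposure`, `outcome`, `covariate`) passed to
#'   [read_summary_table()].
#' @param exposure_prevalence ever-exposed fraction in the exposure
#'   GWAS, used by the users-vs-nonusers transformation (default 0.43).
#' @param population_risk lifetime outcome risk for the `risk_solve`
#'   transformation (default 0.007).
#' @param transform_method `"linear_rescale"` (default) or
#'   `"risk_solve"`.
#' @param bootstrap_reps parametric-bootstrap replicates for Egger,
#'   weighted median and multivariable MR (default 10000, minimum 100).
#' @param simex list of SIMEX settings (`lambda_grid`,
#'   `reps_per_lambda`, `se_boot_reps`, `se_reps_per_lambda`).
#' @param run_simex,run_mvmr stage switches.
#' @param subset_rsids optional rsids for a restricted analysis.
#' @param target_or detectable OR for the power calculation; defaults
#'   to the pooled observational OR when studies are supplied.
#' @param n_outcome_cases,n_outcome_controls outcome GWAS case/control
#'   counts used by the power calculation (defaults: the schizophrenia
#'   GWAS, 34,241 / 45,604).
#' @param seed global seed; per-stage seeds are derived from it so
#'   adding a stage never changes another stage's draws.
#' @return a list of class `mr_config`.
#' @export
mr_config <- function(exposure, outcome, covariate = NULL, studies = NULL,
                      column_maps = NULL,
                      exposure_prevalence = 0.43, population_risk = 0.007,
                      transform_method = c("linear_rescale", "risk_solve"),
                      bootstrap_reps = 10000,
                      simex = list(), run_simex = TRUE, run_mvmr = TRUE,
                      subset_rsids = NULL, target_or = NULL,
                      n_outcome_cases = 34241, n_outcome_controls = 45604,
                      seed = 20170124) {
  transform_method <- match.arg(transform_method)
  if (bootstrap_reps < 100) abort("`bootstrap_reps` must be at least 100")
  simex_defaults <- list(lambda_grid = seq(0, 2, by = 0.25),
                         reps_per_lambda = 1000,
                         se_boot_reps = 100, se_reps_per_lambda = 100)
  simex <- utils::modifyList(simex_defaults, simex)
  check_lambda_grid(simex$lambda_grid)
  for (nm in c("exposure", "outcome", "covariate", "studies")) {
    x <- get(nm)
    if (is.character(x) && !file.exists(x)) {
      abort(sprintf("%s file not found: %s", nm, x))
    }
  }
  structure(list(
    exposure = exposure, outcome = outcome, covariate = covariate,
    studies = studies, column_maps = column_maps,
    exposure_prevalence = exposure_prevalence,
    population_risk = population_risk,
    transform_method = transform_method,
    bootstrap_reps = bootstrap_reps, simex = simex,
    run_simex = run_simex, run_mvmr = run_mvmr,
    subset_rsids = subset_rsids, target_or = target_or,
    n_outcome_cases = n_outcome_cases,
    n_outcome_controls = n_outcome_controls,
    seed = as.integer(seed)), class = "mr_config")
}

#' @rdname mr_config
#' @param path YAML file of configuration values.
#' @export
read_mr_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$simex$lambda_grid)) {
    vals$simex$lambda_grid <- as.numeric(vals$simex$lambda_grid)
  }
  do.call(mr_config, vals)
}

load_assoc <- function(x, map) {
  if (is.character(x)) read_summary_table(x, column_map = map) else
    validate_summary_stats(x)
}

#' Run the full two-sample MR analysis
#'
#' Executes every stage on the configured inputs: harmonization and
#' orientation; per-SNP Wald ratios; fixed- and random-effects IVW with
#' the users-vs-nonusers transformation; MR-Egger with its pleiotropy
#' test, the I2GX statistic and (optionally) the SIMEX correction; the
#' penalized weighted median; multivariable MR when a covariate is
#' supplied; leave-one-out, influence, subset, instrument-strength and
#' power diagnostics; and, when observational studies are supplied,
#' their random-effects meta-analysis and chi-square comparisons with
#' the genetic estimate. Any stage failure halts the pipeline with the
#' stage name; there are no silent partial results.
#'
#' @param config an [mr_config()].
#' @return a list of class `mr_report`: tibbles `estimates`, `per_snp`,
#'   `loo`, `influence`, `strength` (+`strength_cumulative`),
#'   `meta_obs`, `comparisons`, `pleiotropy`, `power`, the harmonized
#'   `table`, and a `summary` list of scalars (seeds, drop counts,
#'   settings).
#' @export
run_mr_pipeline <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  cm <- config$column_maps %||% list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  exposure <- stage("read_exposure", load_assoc(config$exposure, cm$exposure))
  outcome  <- stage("read_outcome", load_assoc(config$outcome, cm$outcome))
  covariate <- if (!is.null(config$covariate)) {
    stage("read_covariate", load_assoc(config$covariate, cm$covariate))
  }
  tab <- stage("harmonize", harmonize(exposure, outcome, covariate))
  tab <- stage("orient", orient_exposure_increasing(tab))

  per_snp <- stage("wald", wald_ratios(tab))
  p <- config$exposure_prevalence
  transform <- function(est) {
    to_users_vs_nonusers(est, p, config$population_risk,
                         method = config$transform_method)
  }
  ivw_f <- stage("ivw_fixed", mr_ivw(per_snp, "fixed"))
  ivw_r <- stage("ivw_random", mr_ivw(per_snp, "random"))

  egger <- stage("egger", mr_egger(tab, config$bootstrap_reps,
                                   seed = stage_seed(config$seed, "egger")))
  i2 <- stage("i2gx", i2_gx(tab))
  simex_fit <- if (config$run_simex) {
    stage("simex", mr_egger_simex(
      tab, lambda_grid = config$simex$lambda_grid,
      reps_per_lambda = config$simex$reps_per_lambda,
      seed = stage_seed(config$seed, "simex"),
      se_boot_reps = config$simex$se_boot_reps,
      se_reps_per_lambda = config$simex$se_reps_per_lambda))
  }
  wm <- stage("weighted_median",
              mr_weighted_median(tab, config$bootstrap_reps,
                                 seed = stage_seed(config$seed, "median")))
  mvmr_fit <- if (config$run_mvmr && "beta_cov" %in% names(tab)) {
    stage("mvmr", mr_mvmr(tab, config$bootstrap_reps,
                          seed = stage_seed(config$seed, "mvmr")))
  }

  k <- nrow(tab)
  estimates <- dplyr::bind_rows(
    tidy(ivw_f), tidy(transform(ivw_f)),
    tidy(ivw_r), tidy(transform(ivw_r)),
    tidy(egger_term_estimate(egger, "slope", k)),
    if (!is.null(simex_fit) && is.finite(simex_fit$se[2])) {
      tidy(egger_term_estimate(simex_fit, "slope", k))
    },
    tidy(wm), tidy(transform(wm)),
    if (!is.null(mvmr_fit)) {
      mv <- egger_term_estimate(mvmr_fit, "exposure", k, method = "mvmr")
      dplyr::bind_rows(tidy(mv), tidy(transform(mv)))
    }
  )

  loo <- stage("leave_one_out", leave_one_out(tab, transform = TRUE,
                                              exposure_prevalence = p))
  infl <- stage("influence", influence_stats(tab))
  n_exp <- stats::median(tab$n_exp, na.rm = TRUE)
  strength <- stage("strength", instrument_strength(tab, n_exposure = n_exp))
  subset_est <- if (!is.null(config$subset_rsids)) {
    stage("subset", subset_analysis(tab, config$subset_rsids,
                                    transform = TRUE, exposure_prevalence = p))
  }

  meta <- NULL; comparisons <- NULL; power <- NULL
  if (!is.null(config$studies)) {
    studies <- stage("read_studies", if (is.character(config$studies)) {
      read_studies(config$studies)
    } else tibble::as_tibble(config$studies))
    meta <- stage("meta_obs", meta_random_effects(studies))
    mr_users <- transform(ivw_f)
    comparisons <- stage("compare", dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(comparison = "mr_vs_observational_pooled"),
                       compare_estimates(mr_users, meta)),
      purrr::map_dfr(seq_len(nrow(studies)), function(i) {
        st <- estimate_from_or(studies$or[i], studies$ci_low[i],
                               studies$ci_high[i], method = studies$label[i])
        dplyr::bind_cols(
          tibble::tibble(comparison = paste0("mr_vs_", studies$label[i])),
          compare_estimates(mr_users, st))
      })))
  }
  target <- config$target_or %||% (if (!is.null(meta)) meta$or)
  if (!is.null(target)) {
    power <- stage("power", mr_power(
      n_cases = config$n_outcome_cases, n_controls = config$n_outcome_controls,
      r2 = strength$cumulative$cumulative_r2,
      target_or = target))
  }

  report <- list(
    config = config,
    table = tab,
    per_snp = per_snp,
    estimates = estimates,
    pleiotropy = tibble::tibble(
      egger_intercept = egger$estimate[1], egger_intercept_se = egger$se[1],
      pval_pleiotropy = egger$pval[1],
      i2_gx = i2$i2_gx, attenuation_bias = i2$attenuation_bias),
    egger = egger, simex = simex_fit, mvmr = mvmr_fit,
    loo = loo, influence = infl,
    strength = strength$per_snp, strength_cumulative = strength$cumulative,
    subset = subset_est,
    meta_obs = meta, comparisons = comparisons, power = power,
    summary = list(
      seed = config$seed,
      n_snps_exposure = nrow(exposure), n_snps_harmonized = k,
      dropped = setdiff(exposure$rsid, tab$rsid),
      exposure_prevalence = p,
      bootstrap_reps = config$bootstrap_reps,
      stage_seeds = list(
        egger = stage_seed(config$seed, "egger"),
        simex = stage_seed(config$seed, "simex"),
        median = stage_seed(config$seed, "median"),
        mvmr = stage_seed(config$seed, "mvmr"))))
  class(report) <- "mr_report"
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("Two-sample MR report: %d instruments (seed %d)\n",
              x$summary$n_snps_harmonized, x$summary$seed))
  print(x$estimates)
  cat(sprintf("Egger intercept p = %.3f; I2GX = %.1f%%\n",
              x$pleiotropy$pval_pleiotropy, 100 * x$pleiotropy$i2_gx))
  invisible(x)
}

#' @export
tidy.mr_report <- function(x, ...) x$estimates

#' @export
glance.mr_report <- function(x, ...) {
  tibble::tibble(
    n_snps = x$summary$n_snps_harmonized,
    seed = x$summary$seed,
    pval_pleiotropy = x$pleiotropy$pval_pleiotropy,
    i2_gx = x$pleiotropy$i2_gx,
    cumulative_r2 = x$strength_cumulative$cumulative_r2)
}

#' Write a report bundle to disk
#'
#' Emits a deterministic file set: `estimates.tsv`, `per_snp.tsv`,
#' `loo.tsv`, `influence.tsv`, `strength.tsv`, `meta_obs.tsv` (omitted
#' when the stage did not run, and noted as omitted in the summary) and
#' `summary.json`. TSV floats are written at 6 significant digits;
#' the JSON carries full precision.
#'
#' @param report an `mr_report`.
#' @param outdir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_mr_report <- function(report, outdir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) abort(paste0("directory not writable: ", outdir))
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    readr::write_tsv(dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                                     signif6)), path)
    path
  }
  paths <- c(
    emit(report$estimates, "estimates.tsv"),
    emit(report$per_snp, "per_snp.tsv"),
    emit(report$loo, "loo.tsv"),
    emit(report$influence, "influence.tsv"),
    emit(dplyr::bind_cols(report$strength,
                          report$strength_cumulative[rep(1, nrow(report$strength)),
                                                     c("cumulative_r2", "cumulative_f")]),
         "strength.tsv"))
  omitted <- character(0)
  if (!is.null(report$meta_obs)) {
    paths <- c(paths, emit(dplyr::bind_rows(tidy(report$meta_obs)), "meta_obs.tsv"))
  } else omitted <- c(omitted, "meta_obs")
  if (is.null(report$subset)) omitted <- c(omitted, "subset")
  summary <- list(
    seed = report$summary$seed,
    n_snps = report$summary$n_snps_harmonized,
    dropped_snps = report$summary$dropped,
    omitted_stages = omitted,
    estimates = as.data.frame(report$estimates),
    pleiotropy = as.data.frame(report$pleiotropy),
    strength = as.data.frame(report$strength_cumulative),
    subset = if (!is.null(report$subset)) as.data.frame(tidy(report$subset)),
    comparisons = if (!is.null(report$comparisons)) as.data.frame(report$comparisons),
    power = if (!is.null(report$power)) as.data.frame(report$power))
  jpath <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, jpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(paths, jpath))
}
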