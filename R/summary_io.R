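#' Read a GWAS summary-statistics table
#'
#' Reads a delimited (tab or comma) text file of per-SNP association
#' estimates into the canonical layout used throughout the package:
#' `rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#' `n`. Headers differ between consortia, so a `column_map` renames file
#' columns to the canonical names. Rows with a missing beta or standard
#' error, or a non-positive standard error, are rejected with a message
#' giving the reason and the row.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(rsid = "SNP", beta = "logOR")`. Columns
#'   already canonically named need no entry. `eaf`, `pval` and `n` are
#'   optional.
#' @param delim field delimiter; `NULL` (default) picks tab for `.tsv`/
#'   `.txt` and comma for `.csv`.
#' @return a tibble of validated associations, alleles upper-cased.
#' @export
read_summary_table <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      abort(paste0("mapped column(s) not in file: ",
                   paste(missing_src, collapse = ", ")))
    }
    raw <- dplyr::rename(raw, !!!setNames(unname(column_map), names(column_map)))
  }
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(paste0("required column(s) missing: ", paste(miss, collapse = ", ")))
  }
  for (opt in c("eaf", "pval", "n")) if (!opt %in% names(raw)) raw[[opt]] <- NA_real_
  out <- dplyr::transmute(
    raw,
    rsid = as.character(.data$rsid),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele  = toupper(as.character(.data$other_allele)),
    eaf  = as.numeric(.data$eaf),
    beta = as.numeric(.data$beta),
    se   = as.numeric(.data$se),
    pval = as.numeric(.data$pval),
    n    = as.numeric(.data$n)
  )
  validate_summary_stats(out, source = path)
}

#' Validate a summary-statistics tibble
#'
#' Enforces the row-level invariants: alleles in A/C/G/T and distinct,
#' finite beta and positive standard error. Offending rows are dropped
#' with an informative message; a reported p-value inconsistent with
#' `|beta/se|` by more than a factor of 10 draws a warning (it usually
#' signals a mis-mapped column).
#'
#' @param assoc tibble in the canonical layout.
#' @param source label used in messages.
#' @return the validated tibble.
#' @export
validate_summary_stats <- function(assoc, source = "summary table") {
  assoc <- tibble::as_tibble(assoc)
  bad_beta <- !is.finite(assoc$beta)
  bad_se   <- !is.finite(assoc$se) | assoc$se <= 0
  bad_alle <- !(assoc$effect_allele %in% c("A", "C", "G", "T")) |
    !(assoc$other_allele %in% c("A", "C", "G", "T")) |
    assoc$effect_allele == assoc$other_allele
  reject <- bad_beta | bad_se | bad_alle
  if (any(reject)) {
    reasons <- dplyr::case_when(
      bad_beta ~ "missing or non-numeric beta",
      bad_se   ~ "non-positive standard error",
      TRUE     ~ "invalid allele pair"
    )
    for (i in which(reject)) {
      inform(sprintf("%s: rejected row %d (%s): %s",
                     source, i, assoc$rsid[i], reasons[i]))
    }
    assoc <- assoc[!reject, , drop = FALSE]
  }
  ok_p <- is.finite(assoc$pval) & assoc$pval > 0 & assoc$pval <= 1
  if (any(ok_p)) {
    implied <- two_sided_p(assoc$beta[ok_p] / assoc$se[ok_p])
    off <- abs(log10(implied) - log10(assoc$pval[ok_p])) > 1
    if (any(off)) {
      warn(sprintf(
        "%s: %d row(s) have p-values inconsistent with beta/se by >10x (e.g. %s)",
        source, sum(off), assoc$rsid[ok_p][which(off)[1]]))
    }
  }
  if (anyDuplicated(assoc$rsid)) {
    abort(paste0(source, ": duplicated rsid(s): ",
                 paste(unique(assoc$rsid[duplicated(assoc$rsid)]), collapse = ", ")))
  }
  assoc
}

#' Write a summary-statistics table
#'
#' @param assoc tibble in the canonical layout.
#' @param path output path; tab-delimited unless it ends in `.csv`.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(assoc, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(assoc, path, delim = delim)
  invisible(path)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) unname(COMPLEMENT[ea]) == oa

# align one trait's associations to the exposure's effect allele.
# returns the trait tibble with flipped beta/eaf where alleles are swapped;
# errors on allele pairs that are neither identical nor swapped.
align_to_reference <- function(ref, trait, trait_name) {
  m <- dplyr::inner_join(
    dplyr::select(ref, "rsid", ref_ea = "effect_allele", ref_oa = "other_allele"),
    trait, by = "rsid")
  same <- m$effect_allele == m$ref_ea & m$other_allele == m$ref_oa
  swap <- m$effect_allele == m$ref_oa & m$other_allele == m$ref_ea
  bad  <- !(same | swap)
  if (any(bad)) {
    abort(sprintf(
      "allele pair mismatch between exposure and %s for: %s",
      trait_name, paste(m$rsid[bad], collapse = ", ")))
  }
  m$beta[swap] <- -m$beta[swap]
  m$eaf[swap]  <- 1 - m$eaf[swap]
  m$effect_allele <- m$ref_ea
  m$other_allele  <- m$ref_oa
  dplyr::select(m, -"ref_ea", -"ref_oa")
}

#' Harmonize exposure, outcome and optional covariate associations
#'
#' Matches SNPs across traits by rsid and expresses every association per
#' copy of the same reference allele (the exposure's effect allele).
#' Where the outcome (or covariate) reports the opposite allele, its beta
#' sign is flipped and the effect-allele frequency replaced by its
#' complement. SNPs absent from the outcome (or covariate, when given)
#' are dropped with a message. Palindromic SNPs (A/T, C/G) with an
#' ambiguous frequency (effect-allele frequency in \[0.42, 0.58\]) draw a
#' warning but are never auto-dropped: strand resolution is left to the
#' analyst.
#'
#' @param exposure,outcome tibbles in the canonical layout
#'   ([read_summary_table()]).
#' @param covariate optional third trait (e.g. ever-smoking) in the same
#'   layout.
#' @return an instrument table: one row per SNP with columns
#'   `rsid`, `ref_allele`, `other_allele`, then `eaf/beta/se/pval/n`
#'   suffixed `_exp`, `_out` and (if given) `_cov`.
#' @export
harmonize <- function(exposure, outcome, covariate = NULL) {
  exposure <- validate_summary_stats(exposure, "exposure")
  outcome  <- validate_summary_stats(outcome, "outcome")
  if (nrow(exposure) == 0) abort("exposure table is empty")
  out_al <- align_to_reference(exposure, outcome, "outcome")
  keep <- exposure$rsid %in% out_al$rsid
  if (!all(keep)) {
    inform(paste0("dropped (absent from outcome): ",
                  paste(exposure$rsid[!keep], collapse = ", ")))
  }
  exposure <- exposure[keep, , drop = FALSE]
  if (nrow(exposure) == 0) abort("no overlapping rsids between exposure and outcome")
  tab <- dplyr::inner_join(
    dplyr::rename_with(exposure, ~ paste0(.x, "_exp"), !dplyr::any_of(c("rsid", "effect_allele", "other_allele"))),
    dplyr::rename_with(
      dplyr::select(out_al, -"effect_allele", -"other_allele"),
      ~ paste0(.x, "_out"), -"rsid"),
    by = "rsid")
  if (!is.null(covariate)) {
    covariate <- validate_summary_stats(covariate, "covariate")
    cov_al <- align_to_reference(exposure, covariate, "covariate")
    keep2 <- tab$rsid %in% cov_al$rsid
    if (!all(keep2)) {
      inform(paste0("dropped (absent from covariate): ",
                    paste(tab$rsid[!keep2], collapse = ", ")))
    }
    tab <- tab[keep2, , drop = FALSE]
    if (nrow(tab) == 0) abort("no overlapping rsids with covariate")
    tab <- dplyr::inner_join(
      tab,
      dplyr::rename_with(
        dplyr::select(cov_al, -"effect_allele", -"other_allele"),
        ~ paste0(.x, "_cov"), -"rsid"),
      by = "rsid")
  }
  tab <- dplyr::rename(tab, ref_allele = "effect_allele")
  pal <- is_palindromic(tab$ref_allele, tab$other_allele) &
    is.finite(tab$eaf_exp) & tab$eaf_exp >= 0.42 & tab$eaf_exp <= 0.58
  if (any(pal)) {
    warn(paste0("palindromic SNP(s) with ambiguous allele frequency ",
                "(eaf in [0.42, 0.58]), strand cannot be verified: ",
                paste(tab$rsid[pal], collapse = ", ")))
  }
  class(tab) <- c("instrument_table", class(tab))
  tab
}

#' Orient all rows so the exposure effect is positive
#'
#' Flips the reference allele of every row whose SNP-exposure beta is
#' negative, negating the exposure, outcome and covariate betas and
#' complementing the allele frequencies. Per-SNP Wald ratios are
#' unchanged by construction. Rows with an exposure beta of exactly zero
#' are kept unflipped with a warning.
#'
#' @param table an instrument table from [harmonize()].
#' @return the table with every `beta_exp >= 0`.
#' @export
orient_exposure_increasing <- function(table) {
  flip <- table$beta_exp < 0
  if (any(table$beta_exp == 0)) {
    warn(paste0("exposure beta exactly 0 for: ",
                paste(table$rsid[table$beta_exp == 0], collapse = ", "),
                " (row kept unflipped)"))
  }
  if (!any(flip)) return(table)
  swap_ref <- table$ref_allele[flip]
  table$ref_allele[flip]   <- table$other_allele[flip]
  table$other_allele[flip] <- swap_ref
  for (col in intersect(c("beta_exp", "beta_out", "beta_cov"), names(table))) {
    table[[col]][flip] <- -table[[col]][flip]
  }
  for (col in intersect(c("eaf_exp", "eaf_out", "eaf_cov"), names(table))) {
    table[[col]][flip] <- 1 - table[[col]][flip]
  }
  table
}

#' Split an instrument table back into per-trait tables
#'
#' Inverse of [harmonize()]: recovers the exposure, outcome and (if
#' present) covariate association tables, all expressed on the shared
#' reference allele.
#'
#' @param table an instrument table.
#' @return named list of canonical-layout tibbles
#'   (`exposure`, `outcome`, and `covariate` when present).
#' @export
split_instruments <- function(table) {
  pull_trait <- function(sfx) {
    tibble::tibble(
      rsid = table$rsid,
      effect_allele = table$ref_allele,
      other_allele  = table$other_allele,
      eaf  = table[[paste0("eaf_", sfx)]],
      beta = table[[paste0("beta_", sfx)]],
      se   = table[[paste0("se_", sfx)]],
      pval = table[[paste0("pval_", sfx)]],
      n    = table[[paste0("n_", sfx)]]
    )
  }
  out <- list(exposure = pull_trait("exp"), outcome = pull_trait("out"))
  if ("beta_cov" %in% names(table)) out$covariate <- pull_trait("cov")
  out
}
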