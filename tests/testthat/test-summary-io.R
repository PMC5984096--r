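test_that("reading a delimited table preserves rows, rejects bad ones, and is deterministic", {
  path <- withr::local_tempfile(fileext = ".tsv")
  assoc <- make_assoc(beta = seq(-0.05, 0.04, length.out = 10),
                      se = rep(0.01, 10))
  readr::write_tsv(assoc, path)
  got <- read_summary_table(path)
  expect_equal(nrow(got), 10)
  expect_identical(got, read_summary_table(path))

  # mapped headers
  renamed <- dplyr::rename(assoc, SNP = rsid, EA = effect_allele, logOR = beta)
  readr::write_tsv(renamed, path)
  got2 <- read_summary_table(path, column_map = c(rsid = "SNP",
                                                  effect_allele = "EA",
                                                  beta = "logOR"))
  expect_equal(got2$beta, assoc$beta)
  expect_error(read_summary_table(path, column_map = c(beta = "nonexistent")),
               "nonexistent")

  # non-positive SE rejected with a reason
  bad <- assoc; bad$se[3] <- 0
  readr::write_tsv(bad, path)
  expect_message(got3 <- read_summary_table(path), "non-positive standard error")
  expect_equal(nrow(got3), 9)
  expect_false(bad$rsid[3] %in% got3$rsid)
})

test_that("alleles are upper-cased and csv files are auto-detected", {
  path <- withr::local_tempfile(fileext = ".csv")
  assoc <- make_assoc(beta = 0.05, se = 0.01, ea = "a", oa = "g")
  readr::write_csv(assoc, path)
  got <- read_summary_table(path)
  expect_identical(got$effect_allele, "A")
  expect_identical(got$other_allele, "G")
})

test_that("harmonize flips swapped alleles, keeps identical ones, errors on mismatch", {
  expo <- make_assoc(beta = 0.05, se = 0.01, ea = "A", oa = "G", eaf = 0.3)
  out_swapped <- make_assoc(beta = -0.02, se = 0.01, ea = "G", oa = "A",
                            eaf = 0.7)
  tab <- harmonize(expo, out_swapped)
  expect_equal(tab$beta_out, 0.02)
  expect_equal(tab$eaf_out, 0.3)
  expect_identical(tab$ref_allele, "A")

  out_same <- make_assoc(beta = 0.03, se = 0.01, ea = "A", oa = "G")
  expect_equal(harmonize(expo, out_same)$beta_out, 0.03)

  out_bad <- make_assoc(beta = 0.03, se = 0.01, ea = "C", oa = "T")
  expect_error(harmonize(expo, out_bad), "allele pair mismatch")
})

test_that("harmonize drops SNPs absent from the outcome and errors on zero overlap", {
  expo <- make_assoc(beta = c(0.05, 0.04), se = c(0.01, 0.01))
  out <- make_assoc(beta = 0.02, se = 0.01, rsid = "rs1")
  expect_message(tab <- harmonize(expo, out), "absent from outcome")
  expect_equal(tab$rsid, "rs1")
  out_none <- make_assoc(beta = 0.02, se = 0.01, rsid = "rsX")
  expect_error(suppressMessages(harmonize(expo, out_none)), "no overlapping")
})

test_that("ambiguous palindromic SNPs warn but are kept", {
  expo <- make_assoc(beta = 0.05, se = 0.01, ea = "A", oa = "T", eaf = 0.5)
  out <- make_assoc(beta = 0.02, se = 0.01, ea = "A", oa = "T", eaf = 0.5)
  expect_warning(tab <- harmonize(expo, out), "palindromic")
  expect_equal(nrow(tab), 1)
  # unambiguous frequency: no warning
  expo2 <- make_assoc(beta = 0.05, se = 0.01, ea = "A", oa = "T", eaf = 0.2)
  out2 <- make_assoc(beta = 0.02, se = 0.01, ea = "A", oa = "T", eaf = 0.2)
  expect_no_warning(harmonize(expo2, out2))
})

test_that("re-harmonizing a harmonized table is the identity", {
  sim <- simulate_reference_fixture(seed = 3)
  tab <- harmonize(sim$exposure, sim$outcome, sim$covariate)
  parts <- split_instruments(tab)
  tab2 <- harmonize(parts$exposure, parts$outcome, parts$covariate)
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
})

test_that("orientation makes exposure betas positive and preserves Wald ratios", {
  tab <- make_table(g = c(-0.04, 0.05, 0.06), sg = rep(0.01, 3),
                    G = c(0.01, -0.02, 0.03), sG = rep(0.01, 3))
  before <- tab$beta_out / tab$beta_exp
  oriented <- orient_exposure_increasing(tab)
  expect_true(all(oriented$beta_exp >= 0))
  expect_equal(oriented$beta_exp[1], 0.04)
  expect_equal(oriented$beta_out[1], -0.01)
  expect_identical(oriented$ref_allele[1], "G")
  expect_equal(oriented$beta_out / oriented$beta_exp, before)
  # idempotent on an already-positive table
  expect_identical(orient_exposure_increasing(oriented), oriented)
  # zero exposure beta: kept, with a warning
  tab0 <- make_table(g = c(0, 0.05, 0.04), sg = rep(0.01, 3),
                     G = rep(0.01, 3), sG = rep(0.01, 3))
  expect_warning(kept <- orient_exposure_increasing(tab0), "exactly 0")
  expect_equal(kept$beta_exp[1], 0)
})

test_that("instrument tables round-trip through disk at full precision", {
  sim <- simulate_reference_fixture(seed = 5)
  tab <- harmonize(sim$exposure, sim$outcome)
  parts <- split_instruments(tab)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(parts$exposure, path)
  back <- read_summary_table(path)
  expect_equal(back$beta, parts$exposure$beta, tolerance = 1e-12)
  expect_equal(back$se, parts$exposure$se, tolerance = 1e-12)
})

test_that("inconsistent p-values draw a warning", {
  assoc <- make_assoc(beta = 0.05, se = 0.01)
  assoc$pval <- 0.9   # |z| = 5 implies p ~ 6e-7
  expect_warning(validate_summary_stats(assoc), "inconsistent")
})
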