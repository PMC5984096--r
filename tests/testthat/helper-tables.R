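# build a canonical association tibble from vectors
make_assoc <- function(beta, se, rsid = sprintf("rs%d", seq_along(beta)),
                       ea = "A", oa = "G", eaf = 0.3, n = 10000) {
  tibble::tibble(
    rsid = rsid, effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), n = n)
}

# build a harmonized instrument table directly (skips harmonize())
make_table <- function(g, sg, G, sG, d = NULL, sd_ = NULL,
                       rsid = sprintf("rs%d", seq_along(g))) {
  tab <- tibble::tibble(
    rsid = rsid, ref_allele = "A", other_allele = "G",
    eaf_exp = 0.3, beta_exp = g, se_exp = sg,
    pval_exp = 2 * pnorm(-abs(g / sg)), n_exp = 32330,
    eaf_out = 0.3, beta_out = G, se_out = sG,
    pval_out = 2 * pnorm(-abs(G / sG)), n_out = 79845)
  if (!is.null(d)) {
    tab$eaf_cov <- 0.3; tab$beta_cov <- d; tab$se_cov <- sd_
    tab$pval_cov <- 2 * pnorm(-abs(d / sd_)); tab$n_cov <- 111898
  }
  class(tab) <- c("instrument_table", class(tab))
  tab
}

# a random well-behaved table for property loops
random_table <- function(k = 10, with_cov = FALSE) {
  g <- runif(k, 0.03, 0.12); sg <- runif(k, 0.01, 0.02)
  G <- runif(k, -0.02, 0.03); sG <- runif(k, 0.005, 0.02)
  if (with_cov) {
    make_table(g, sg, G, sG, d = runif(k, -0.02, 0.05),
               sd_ = runif(k, 0.005, 0.02))
  } else {
    make_table(g, sg, G, sG)
  }
}

# brute-force interpolated weighted median: full cumulative-sum scan
wmedian_oracle <- function(theta, w) {
  o <- order(theta); theta <- theta[o]; w <- w[o]
  s <- (cumsum(w) - 0.5 * w) / sum(w)
  stats::approx(c(0, s, 1), c(theta[1], theta, theta[length(theta)]),
                xout = 0.5, ties = "ordered")$y
}
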