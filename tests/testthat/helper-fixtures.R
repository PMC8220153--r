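# Fixture builders shared across test files.  All fixtures are built in
# code; nothing is read from disk except files the tests themselves write.

# Harmonized-instrument set straight from vectors.
make_h <- function(beta_x, beta_y, se_x = rep(0.01, length(beta_x)),
                   se_y = rep(0.01, length(beta_x)),
                   pvalue_y = rep(0.5, length(beta_x)),
                   snp = paste0("rs", seq_along(beta_x))) {
  sexmr:::new_harmonized(data.frame(
    snp = snp, beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
    pvalue_y = pvalue_y, stringsAsFactors = FALSE
  ))
}

# Minimal sumstat table with default single-SNV alleles.
make_table <- function(snp, beta, se, pvalue = rep(0.5, length(snp)),
                       effect_allele = rep("A", length(snp)),
                       other_allele = rep("G", length(snp)),
                       n = 10000, stratum = "combined",
                       trait_label = "trait") {
  sumstat_table(data.frame(
    snp = snp, chr = "1", pos = seq_along(snp),
    effect_allele = effect_allele, other_allele = other_allele,
    beta = beta, se = se, pvalue = pvalue, n = n,
    stringsAsFactors = FALSE
  ), trait_label = trait_label, stratum = stratum)
}

# Random harmonized fixture with strong instruments and known theta.
random_h <- function(k, theta, seed, se_x = 0.003, se_y = 0.005) {
  withr::with_seed(seed, {
    bx_true <- runif(k, 0.02, 0.08) * sample(c(-1, 1), k, replace = TRUE)
    make_h(beta_x = bx_true + rnorm(k, 0, se_x),
           beta_y = theta * bx_true + rnorm(k, 0, se_y),
           se_x = rep(se_x, k), se_y = rep(se_y, k))
  })
}
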