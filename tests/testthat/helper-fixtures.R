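# Builders for small in-code fixtures shared across test files.

make_stats <- function(snp_id, beta, se, eaf = 0.3, pval = NULL, n = 3757,
                       chrom = "1", pos = NULL, effect_allele = "A",
                       other_allele = "G", trait_id = "exp") {
  k <- length(snp_id)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  if (is.null(pos)) pos <- seq_len(k) * 10000L
  data.frame(
    snp_id = snp_id, chrom = rep_len(chrom, k), pos = as.integer(pos),
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k), beta = beta, se = se, pval = rep_len(pval, k),
    n = rep_len(n, k), trait_id = rep_len(trait_id, k),
    stringsAsFactors = FALSE
  )
}

# Dense toy LD panel from an explicit r2 matrix.
make_ld <- function(snp_id, r2, chrom = "1", pos = NULL) {
  if (is.null(pos)) pos <- seq_along(snp_id) * 10000L
  ld_panel(snp_id, rep_len(chrom, length(snp_id)), pos, r2)
}

# Harmonized-set-shaped data frame straight from effect vectors.
make_h <- function(bx, sex, by, sey) {
  data.frame(beta_exp = bx, se_exp = sex, beta_out = by, se_out = sey)
}

# Textbook Benjamini-Hochberg step-up, written independently of the
# implementation under test.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
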