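# Fixtures built in code, and independent oracles used by several files.

# A minimal GWAS tibble with sensible defaults.
make_gwas <- function(ids, beta, se, eaf = 0.3, n = 10000,
                      chrom = "1", pos = NULL,
                      ea = "A", oa = "G", pval = NULL,
                      trait_name = "trait", trait_type = "quantitative") {
  k <- length(ids)
  tab <- tibble::tibble(
    variant_id = ids, chrom = chrom,
    pos = pos %||% (seq_len(k) * 1000L),
    effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
    eaf = rep_len(eaf, k), beta = beta, se = se,
    pval = pval %||% pmax(2 * pnorm(-abs(beta / se)),
                          .Machine$double.xmin),
    n = n)
  gwas_table(tab, trait_name = trait_name, trait_type = trait_type)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A harmonized set straight from paired effects (bypasses allele logic).
make_harmonized <- function(bx, sx, by, sy, n_exposure = 1e5,
                            n_outcome = 1e5, ids = NULL) {
  k <- length(bx)
  structure(
    tibble::tibble(
      variant_id = ids %||% sprintf("v%d", seq_len(k)),
      effect_allele = "A", other_allele = "G",
      beta_exposure = bx, se_exposure = sx,
      beta_outcome = by, se_outcome = sy,
      eaf = 0.3, eaf_outcome = 0.3,
      n_exposure = n_exposure, n_outcome = n_outcome),
    class = c("mr_harmonized", class(tibble::tibble())))
}

# Independent weighted-median oracle: explicit sort + cumulative-weight
# interpolation written from the definition.
oracle_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  ww <- w[ord] / sum(w)
  cum <- numeric(length(r))
  running <- 0
  for (i in seq_along(r)) {
    cum[i] <- running + ww[i] / 2
    running <- running + ww[i]
  }
  if (0.5 <= cum[1]) return(r[1])
  for (i in 2:length(r)) {
    if (cum[i] >= 0.5) {
      return(r[i - 1] + (r[i] - r[i - 1]) * (0.5 - cum[i - 1]) /
               (cum[i] - cum[i - 1]))
    }
  }
  r[length(r)]
}

# Brute-force probability-space colocalization oracle for small regions:
# per-variant approximate Bayes factors computed directly and the five
# hypothesis weights summed explicitly.
oracle_coloc <- function(beta1, se1, beta2, se2, w1 = 0.15, w2 = 0.15,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  abf <- function(b, s, w) {
    r <- w^2 / (w^2 + s^2)
    sqrt(1 - r) * exp(r * (b / s)^2 / 2)
  }
  bf1 <- abf(beta1, se1, w1)
  bf2 <- abf(beta2, se2, w2)
  k <- length(bf1)
  h3 <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) h3 <- h3 + bf1[i] * bf2[j]
    }
  }
  w <- c(H0 = 1,
         H1 = p1 * sum(bf1),
         H2 = p2 * sum(bf2),
         H3 = p1 * p2 * h3,
         H4 = p12 * sum(bf1 * bf2))
  w / sum(w)
}
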