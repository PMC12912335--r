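# Synthetic GWAS summary statistics with known causal, mediation,
# pleiotropy, and LD structure. Simulation operates at the summary-
# statistic level (no individual genotypes): every estimator in the
# package consumes only (beta, se, eaf, n, R), for which the standardized
# model se_j = 1/sqrt(2 f_j (1 - f_j) n) and beta_j ~ N(true beta_j,
# se_j^2) is sufficient.

default_alleles <- function(k) {
  # non-palindromic pair so harmonization never drops simulated variants
  list(ea = rep("A", k), oa = rep("G", k))
}

#' Simulate a GWAS table from known true effects
#'
#' Standard errors follow the standardized-trait model
#' `se_j = 1/sqrt(2 f_j (1 - f_j) n)`; observed betas are drawn
#' independently as `N(true_beta_j, se_j^2)` with two-sided normal
#' p-values. Binary traits are simulated directly on the log-OR scale
#' with `n` the effective sample size (cases + controls by default
#' convention).
#'
#' @param true_betas Numeric vector of true per-allele effects.
#' @param mafs Effect-allele frequencies in (0, 0.5].
#' @param n Sample size (> 2).
#' @param seed Seed; identical inputs give identical tables.
#' @param trait_name,trait_type Passed to [gwas_table()].
#' @param variant_ids,chrom,pos Optional variant annotation; defaults are
#'   generated.
#' @return A `gwas_tbl`.
#' @export
simulate_gwas_from_truth <- function(true_betas, mafs, n, seed = NULL,
                                     trait_name = "trait",
                                     trait_type = "quantitative",
                                     variant_ids = NULL, chrom = "1",
                                     pos = NULL) {
  k <- length(true_betas)
  if (length(mafs) != k) abort("`true_betas` and `mafs` lengths differ.")
  if (any(mafs <= 0 | mafs > 0.5)) abort("MAFs must lie in (0, 0.5].")
  if (n <= 2) abort("`n` must exceed 2.")
  se <- 1 / sqrt(2 * mafs * (1 - mafs) * n)
  beta <- with_seed_if(seed, rnorm(k, true_betas, se))
  al <- default_alleles(k)
  gwas_table(
    tibble(variant_id = variant_ids %||% sprintf("snp_%d", seq_len(k)),
           chrom = chrom, pos = pos %||% (seq_len(k) * 10000L),
           effect_allele = al$ea, other_allele = al$oa,
           eaf = mafs, beta = beta, se = se,
           pval = znorm_p(beta / se), n = n),
    trait_name = trait_name, trait_type = trait_type)
}

#' Ground truth for a statin-proteome-disease scenario
#'
#' Defines the generative model behind [simulate_statin_scenario()] and
#' [simulate_two_step_scenario()]: a single cis instrument in the drug
#' target gene with per-allele effect `b_ldl < 0` on LDL cholesterol
#' (SD units); per-protein effects `gamma_p` expressed per SD *reduction*
#' in LDL (so the variant's effect on protein p is `-gamma_p * b_ldl`);
#' per-protein effects `theta_p` on disease (log OR per SD protein); and a
#' direct, non-proteomic effect `delta` of LDL reduction on disease. The
#' variant's total disease effect per SD LDL reduction is
#' `delta + sum(theta * gamma)`, and the true proportion mediated by
#' protein p is `theta_p * gamma_p / (delta + sum(theta * gamma))`.
#'
#' Defaults emulate the published study conditions: mediator planted at
#' step-1 beta -0.63, step-2 log OR 0.60, total effect -0.49 (hence truth
#' proportion ~0.77), LDL GWAS n 173,082, proteomic n 35,000 (replication
#' 35,559), disease effective n 184,305 (replication 218,792).
#'
#' @param n_proteins Number of proteins in the panel.
#' @param mediator_index Index of the planted mediator.
#' @param gamma Per-protein effects per SD LDL reduction (default: zeros
#'   with `-0.63` at the mediator).
#' @param theta Per-protein log OR effects on disease (default: zeros
#'   with `0.6` at the mediator).
#' @param total_effect Total drug-on-disease effect per SD LDL reduction;
#'   fixes `delta = total_effect - sum(theta * gamma)`.
#' @param b_ldl Instrument per-allele LDL effect (negative: the coded
#'   allele lowers LDL).
#' @param n_ldl,n_protein,n_protein_replication,n_disease,n_disease_replication
#'   Per-trait sample sizes.
#' @param k_pqtl Instruments per protein for the step-2 panels.
#' @param seed Scenario seed.
#' @return A list of class `statin_truth`.
#' @export
statin_truth <- function(n_proteins = 100, mediator_index = 1,
                         gamma = NULL, theta = NULL,
                         total_effect = -0.49, b_ldl = -0.1,
                         n_ldl = 173082, n_protein = 35000,
                         n_protein_replication = 35559,
                         n_disease = 184305,
                         n_disease_replication = 218792,
                         k_pqtl = 15, seed = 1) {
  if (b_ldl == 0) abort("`b_ldl` must be nonzero.")
  if (is.null(gamma)) {
    gamma <- rep(0, n_proteins)
    gamma[mediator_index] <- -0.63
  }
  if (is.null(theta)) {
    theta <- rep(0, n_proteins)
    theta[mediator_index] <- 0.6
  }
  stopifnot(length(gamma) == n_proteins, length(theta) == n_proteins)
  delta <- total_effect - sum(theta * gamma)
  structure(list(
    n_proteins = n_proteins, proteins = sprintf("protein_%03d",
                                                seq_len(n_proteins)),
    mediator_index = mediator_index, gamma = gamma, theta = theta,
    delta = delta, total_effect = total_effect, b_ldl = b_ldl,
    n_ldl = n_ldl, n_protein = n_protein,
    n_protein_replication = n_protein_replication,
    n_disease = n_disease, n_disease_replication = n_disease_replication,
    k_pqtl = k_pqtl, seed = seed), class = "statin_truth")
}

cis_variant_row <- function(truth) {
  list(id = "cis_1", chrom = "5", pos = 74648000L)
}

# Fast path for scenario builders: rows are valid by construction
# (positive se, p guarded into (0, 1]), so full validation is skipped.
gwas_tbl_unchecked <- function(df, trait_name, trait_type) {
  structure(as_tibble(df), trait_name = trait_name,
            trait_type = trait_type,
            class = c("gwas_tbl", class(tibble())))
}

# One single-variant table per protein from a vector of observed betas.
protein_tables_at_cis <- function(obs_beta, se, maf, n, v, names) {
  setNames(map(seq_along(obs_beta), function(p) {
    gwas_tbl_unchecked(
      tibble(variant_id = v$id, chrom = v$chrom, pos = v$pos,
             effect_allele = "A", other_allele = "G", eaf = maf,
             beta = obs_beta[p], se = se,
             pval = znorm_p(obs_beta[p] / se), n = n),
      names[p], "quantitative")
  }), names)
}

#' Simulate the cis-instrument scenario (step-1 inputs)
#'
#' Generates, from a [statin_truth()], observed summary statistics at the
#' single cis instrument for LDL cholesterol, every protein in the panel,
#' and the disease. The instrument's true LDL effect is `b_ldl < 0`; each
#' protein's true per-allele effect is `gamma_p * (-b_ldl)` and the
#' disease's true per-allele log OR is
#' `(delta + sum(theta * gamma)) * (-b_ldl)` — the total effect implied
#' by the mediation structure.
#'
#' @param truth A [statin_truth()].
#' @param seed Overrides `truth$seed` when supplied.
#' @return A list: `ldl`, `proteins` (named list), `disease` (all
#'   `gwas_tbl`s at the cis variant), `instrument` (variant id), `truth`.
#' @export
simulate_statin_scenario <- function(truth, seed = NULL) {
  seed <- seed %||% truth$seed
  v <- cis_variant_row(truth)
  maf <- with_seed_if(seed, runif(1, 0.2, 0.45))
  per_allele_reduction <- -truth$b_ldl
  mk <- function(true_beta, n, sub, name, type = "quantitative") {
    simulate_gwas_from_truth(true_beta, maf, n, seed = seed + sub,
                             trait_name = name, trait_type = type,
                             variant_ids = v$id, chrom = v$chrom,
                             pos = v$pos)
  }
  se_prot <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_protein)
  obs_prot <- with_seed_if(seed + 100L, {
    rnorm(truth$n_proteins, truth$gamma * per_allele_reduction, se_prot)
  })
  proteins <- protein_tables_at_cis(obs_prot, se_prot, maf,
                                    truth$n_protein, v, truth$proteins)
  disease_true <- truth$total_effect * per_allele_reduction
  list(ldl = mk(truth$b_ldl, truth$n_ldl, 1L, "LDL"),
       proteins = proteins,
       disease = mk(disease_true, truth$n_disease, 2L, "disease", "binary"),
       instrument = v$id, truth = truth)
}

#' Simulate a multi-SNP pQTL instrument panel with configurable pleiotropy
#'
#' Per-variant true protein effects are drawn from `N(0.15, 0.05^2)` with
#' random signs; outcome true effects are `theta * b_j + alpha_j` where
#' the pleiotropy `alpha` follows the configuration: `"none"` (all zero),
#' `"balanced"` (mean-zero normal), `"directional"` (a fraction of
#' variants shifted by a common mean), or `"single_outlier"` (one
#' variant's alpha set to `size` outcome standard errors). Variants are
#' LD-free by construction, emulating a post-pruning instrument set.
#'
#' @param k Number of instruments.
#' @param theta True causal effect of the protein on the outcome.
#' @param pleiotropy List: `type` one of `"none"`, `"balanced"`,
#'   `"directional"`, `"single_outlier"`; `sd` (balanced/directional
#'   noise sd, default 0.05); `prop` (directional fraction, default 0.4);
#'   `mean` (directional shift, default 0.5); `size` (outlier magnitude
#'   in outcome SEs, default 10).
#' @param n_exposure,n_outcome Sample sizes.
#' @param seed Seed.
#' @param protein Trait label for the exposure.
#' @return A list: `exposure` and `outcome` (`gwas_tbl`s over the same
#'   variants) and `truth` (per-variant `b`, `alpha`, `theta`,
#'   `outlier_index`).
#' @export
simulate_pqtl_panel <- function(k = 20, theta = 0.5,
                                pleiotropy = list(type = "none"),
                                n_exposure = 35000, n_outcome = 184305,
                                seed = 1, protein = "protein") {
  if (k < 1) abort("`k` must be at least 1.")
  type <- pleiotropy$type %||% "none"
  cfg <- list(sd = pleiotropy$sd %||% 0.05,
              prop = pleiotropy$prop %||% 0.4,
              mean = pleiotropy$mean %||% 0.5,
              size = pleiotropy$size %||% 10)
  dat <- with_seed_if(seed, {
    mafs <- runif(k, 0.05, 0.5)
    b <- abs(rnorm(k, 0.15, 0.05)) * sample(c(-1, 1), k, replace = TRUE)
    se_out <- 1 / sqrt(2 * mafs * (1 - mafs) * n_outcome)
    alpha <- switch(
      type,
      none = rep(0, k),
      balanced = rnorm(k, 0, cfg$sd),
      directional = {
        a <- rep(0, k)
        idx <- seq_len(max(1, round(cfg$prop * k)))
        a[idx] <- cfg$mean
        a
      },
      single_outlier = {
        a <- rep(0, k)
        a[k] <- cfg$size * se_out[k]
        a
      },
      abort(sprintf("unknown pleiotropy type '%s'", type)))
    list(mafs = mafs, b = b, alpha = alpha)
  })
  ids <- sprintf("pqtl_%s_%d", protein, seq_len(k))
  exposure <- simulate_gwas_from_truth(
    dat$b, dat$mafs, n_exposure, seed = seed + 7L, trait_name = protein,
    variant_ids = ids)
  outcome <- simulate_gwas_from_truth(
    theta * dat$b + dat$alpha, dat$mafs, n_outcome, seed = seed + 8L,
    trait_name = "outcome", trait_type = "binary", variant_ids = ids)
  list(exposure = exposure, outcome = outcome,
       truth = list(b = dat$b, alpha = dat$alpha, theta = theta,
                    outlier_index = if (type == "single_outlier") k else
                      NA_integer_))
}

#' Simulate LD-structured regional statistics for two traits
#'
#' Builds an AR(1) LD correlation matrix `R` with parameter `rho` and,
#' per trait, draws the z-vector from `MVN(R lambda, R)` with `lambda`
#' nonzero only at the causal indices (`lambda_c = effect * sqrt(n)`).
#' Betas are reconstructed as `z * se` with
#' `se = 1/sqrt(2 f (1 - f) n)`. The `"shared"` configuration places one
#' common causal variant; `"distinct"` places two causal variants far
#' enough apart that their LD r-squared is below 0.01; `"none"` leaves
#' both traits flat.
#'
#' @param n_variants Number of variants in the region (>= 2).
#' @param rho AR(1) LD correlation, |rho| < 1.
#' @param causal `"none"`, `"shared"`, or `"distinct"`.
#' @param effect1,effect2 Causal effect sizes per trait (default 0.038,
#'   giving |z| ~ 12 at the default n).
#' @param n1,n2 Per-trait sample sizes.
#' @param trait_types Character 2-vector of trait types.
#' @param seed Seed.
#' @return A list: `trait1`, `trait2` ([regional_assoc()]s), `ld`
#'   ([ld_matrix()]), `truth` (causal indices).
#' @export
simulate_region_pair <- function(n_variants = 200, rho = 0.5,
                                 causal = c("shared", "distinct", "none"),
                                 effect1 = 0.038, effect2 = 0.038,
                                 n1 = 100000, n2 = 100000,
                                 trait_types = c("quantitative",
                                                 "quantitative"),
                                 seed = 1) {
  causal <- arg_match(causal)
  if (abs(rho) >= 1) abort("`rho` must satisfy |rho| < 1.")
  if (n_variants < 2) abort("need at least 2 variants.")
  r_mat <- rho^abs(outer(seq_len(n_variants), seq_len(n_variants), "-"))
  idx <- switch(causal,
                none = integer(0),
                shared = round(n_variants / 2),
                distinct = c(round(n_variants / 4),
                             round(3 * n_variants / 4)))
  ids <- sprintf("reg_%d", seq_len(n_variants))
  out <- with_seed_if(seed, {
    mafs <- runif(n_variants, 0.05, 0.5)
    mk_trait <- function(effect, n, causal_idx) {
      lambda <- rep(0, n_variants)
      if (length(causal_idx) > 0) lambda[causal_idx] <- effect * sqrt(n)
      z <- drop(MASS::mvrnorm(1, r_mat %*% lambda, r_mat))
      se <- 1 / sqrt(2 * mafs * (1 - mafs) * n)
      tibble(variant_id = ids, beta = z * se, se = se, eaf = mafs, n = n)
    }
    list(t1 = mk_trait(effect1, n1, if (causal == "distinct") idx[1] else
      idx),
      t2 = mk_trait(effect2, n2, if (causal == "distinct") idx[2] else
        idx))
  })
  list(trait1 = regional_assoc(out$t1, "trait1", trait_types[1]),
       trait2 = regional_assoc(out$t2, "trait2", trait_types[2]),
       ld = ld_matrix(ids, r_mat),
       truth = list(causal = causal, causal_indices = idx, rho = rho))
}

#' Simulate the full two-step pipeline scenario
#'
#' Extends [simulate_statin_scenario()] into a complete, seeded input
#' bundle for [run_pipeline()]: the cis-instrument tables, replication
#' protein tables (independent noise, replication sample size), per-
#' protein multi-SNP pQTL panels against primary and replication disease
#' GWAS, a reverse-MR bundle (disease instruments with null true effects
#' on the proteins), and colocalization region pairs (shared causal
#' variant) for every drug-affected protein.
#'
#' @inheritParams simulate_statin_scenario
#' @return A pipeline config list (see [run_pipeline()]) plus `truth`.
#' @export
simulate_two_step_scenario <- function(truth, seed = NULL) {
  seed <- seed %||% truth$seed
  base <- simulate_statin_scenario(truth, seed)
  per_allele_reduction <- -truth$b_ldl

  maf <- base$ldl$eaf[1]
  se_rep <- 1 / sqrt(2 * maf * (1 - maf) * truth$n_protein_replication)
  obs_rep <- with_seed_if(seed + 5000L, {
    rnorm(truth$n_proteins, truth$gamma * per_allele_reduction, se_rep)
  })
  proteins_replication <- protein_tables_at_cis(
    obs_rep, se_rep, maf, truth$n_protein_replication,
    list(id = base$instrument, chrom = "5", pos = base$ldl$pos[1]),
    truth$proteins)

  pqtl <- list(); disease_rows <- list(); disease_rep_rows <- list()
  extra_rows <- list()
  for (p in seq_len(truth$n_proteins)) {
    name <- truth$proteins[p]
    pan <- simulate_pqtl_panel(
      k = truth$k_pqtl, theta = truth$theta[p],
      pleiotropy = list(type = "none"),
      n_exposure = truth$n_protein, n_outcome = truth$n_disease,
      seed = seed + 10000L + p, protein = name)
    pan_rep <- simulate_gwas_from_truth(
      truth$theta[p] * pan$truth$b, pan$exposure$eaf,
      truth$n_disease_replication, seed = seed + 20000L + p,
      trait_name = "disease_replication", trait_type = "binary",
      variant_ids = pan$exposure$variant_id)
    pqtl[[name]] <- pan$exposure
    disease_rows[[name]] <- as_tibble(pan$outcome)
    disease_rep_rows[[name]] <- as_tibble(pan_rep)
  }
  disease_tab <- gwas_table(
    bind_rows(as_tibble(base$disease), list_rbind(unname(disease_rows))),
    trait_name = "disease", trait_type = "binary")
  disease_rep_tab <- gwas_table(
    list_rbind(unname(disease_rep_rows)),
    trait_name = "disease_replication", trait_type = "binary")

  # reverse MR: strong disease instruments, truly null on every protein
  k_rev <- 30
  rev_dat <- with_seed_if(seed + 30000L, {
    list(mafs = runif(k_rev, 0.05, 0.5),
         b = abs(rnorm(k_rev, 0.1, 0.03)) *
           sample(c(-1, 1), k_rev, replace = TRUE))
  })
  rev_ids <- sprintf("ihd_%d", seq_len(k_rev))
  reverse <- list(
    instruments = simulate_gwas_from_truth(
      rev_dat$b, rev_dat$mafs, truth$n_disease, seed = seed + 30001L,
      trait_name = "disease", trait_type = "binary",
      variant_ids = rev_ids),
    proteins = setNames(map(seq_len(truth$n_proteins), function(p) {
      simulate_gwas_from_truth(
        rep(0, k_rev), rev_dat$mafs, truth$n_protein,
        seed = seed + 30100L + p, trait_name = truth$proteins[p],
        variant_ids = rev_ids)
    }), truth$proteins))

  affected <- which(truth$gamma != 0)
  coloc_regions <- setNames(map(affected, function(p) {
    rp <- simulate_region_pair(
      n_variants = 200, rho = 0.5, causal = "shared",
      effect1 = 0.038, effect2 = 0.038,
      n1 = truth$n_ldl, n2 = truth$n_protein,
      seed = seed + 40000L + p)
    attr(rp$trait1, "trait_name") <- "LDL"
    attr(rp$trait2, "trait_name") <- truth$proteins[p]
    rp
  }), truth$proteins[affected])

  list(instrument = base$instrument, ldl = base$ldl,
       proteins = base$proteins,
       proteins_replication = proteins_replication,
       pqtl = pqtl, disease = disease_tab,
       disease_replication = disease_rep_tab,
       reverse = reverse, coloc = coloc_regions,
       fdr = 0.05, pqtl_p_threshold = 1.7e-11,
       seed = seed, truth = truth)
}
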