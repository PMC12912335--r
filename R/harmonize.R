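#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants by id, aligns the outcome associations to the
#' exposure's effect allele, and drops variants that cannot be aligned.
#' Alignment rules, applied per shared variant:
#'
#' * alleles identical: keep as is;
#' * outcome effect/other allele swapped: negate the outcome beta and
#'   replace its eaf by `1 - eaf`;
#' * alleles match only after strand-complementing both outcome alleles:
#'   treated as a strand flip and aligned the same way;
#' * palindromic variants (A/T or C/G): dropped when either trait's eaf is
#'   missing or lies within `0.5 +/- palindrome_eaf_window`; otherwise the
#'   strand is inferred from eaf concordance (discordant frequencies imply
#'   an allele swap);
#' * irreconcilable alleles: dropped.
#'
#' @param exposure,outcome `gwas_tbl` tables (see [gwas_table()]).
#' @param palindrome_eaf_window Half-width of the ambiguous eaf window
#'   around 0.5 for palindromic variants (default 0.08, i.e. drop when eaf
#'   is inside \[0.42, 0.58\]).
#' @return A tibble of class `mr_harmonized` with one row per aligned
#'   variant: `variant_id`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`, `eaf`,
#'   `eaf_outcome`, `n_exposure`, `n_outcome`. Attributes: `exposure`,
#'   `outcome` (trait names) and `report`, a tibble of per-reason counts
#'   (kept, swapped, strand-flipped, dropped palindromic/incompatible).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    abort("both tables must be non-empty.")
  }
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) abort("no shared variants between the two tables.")

  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  status <- vapply(seq_along(shared), function(i) {
    align_status(ex$effect_allele[i], ex$other_allele[i],
                 ou$effect_allele[i], ou$other_allele[i],
                 ex$eaf[i], ou$eaf[i], palindrome_eaf_window)
  }, character(1))

  swap <- status %in% c("swapped", "strand_swapped", "palindromic_swapped")
  keep <- !startsWith(status, "dropped")

  out <- tibble(
    variant_id = shared,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    beta_outcome = ifelse(swap, -ou$beta, ou$beta),
    se_outcome = ou$se,
    eaf = ex$eaf,
    eaf_outcome = ifelse(swap, 1 - ou$eaf, ou$eaf),
    n_exposure = ex$n,
    n_outcome = ou$n
  )[keep, ]
  if (nrow(out) == 0) abort("no variants remain after harmonization.")

  report <- tibble(status = names(table(status)),
                   n = as.integer(table(status)))
  structure(out,
            exposure = attr(exposure, "trait_name") %||% "exposure",
            outcome = attr(outcome, "trait_name") %||% "outcome",
            report = report,
            class = c("mr_harmonized", class(out)))
}

# Classify how one outcome record aligns to the exposure orientation.
align_status <- function(ea_x, oa_x, ea_y, oa_y, eaf_x, eaf_y, window) {
  if (is_palindromic(ea_x, oa_x)) {
    # For A/T and C/G variants swap and strand flip are indistinguishable
    # from the alleles alone; allele frequency must arbitrate.
    same <- (ea_y == ea_x && oa_y == oa_x) ||
      (complement_allele(ea_y) == ea_x && complement_allele(oa_y) == oa_x)
    swapped <- (ea_y == oa_x && oa_y == ea_x) ||
      (complement_allele(ea_y) == oa_x && complement_allele(oa_y) == ea_x)
    if (!same && !swapped) return("dropped_incompatible")
    if (is.na(eaf_x) || is.na(eaf_y)) return("dropped_palindromic")
    if (abs(eaf_x - 0.5) <= window || abs(eaf_y - 0.5) <= window) {
      return("dropped_palindromic")
    }
    concordant <- (eaf_x < 0.5) == (eaf_y < 0.5)
    return(if (concordant) "kept" else "palindromic_swapped")
  }
  if (ea_y == ea_x && oa_y == oa_x) return("kept")
  if (ea_y == oa_x && oa_y == ea_x) return("swapped")
  if (complement_allele(ea_y) == ea_x && complement_allele(oa_y) == oa_x) {
    return("strand_kept")
  }
  if (complement_allele(ea_y) == oa_x && complement_allele(oa_y) == ea_x) {
    return("strand_swapped")
  }
  "dropped_incompatible"
}

#' Harmonization report
#'
#' @param x An `mr_harmonized` tibble.
#' @return The per-reason count tibble recorded during harmonization.
#' @export
harmonization_report <- function(x) {
  attr(x, "report") %||% tibble(status = character(), n = integer())
}
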