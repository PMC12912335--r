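#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param pvals Numeric p-values, each in (0, 1].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) abort("empty p-value list.")
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

# Align one variant record of `tab` to the orientation of a reference
# record (same variant, possibly different coded allele); returns the
# aligned beta or NA when the alleles are irreconcilable or ambiguous.
align_to_reference <- function(tab, ref) {
  i <- match(ref$variant_id, tab$variant_id)
  if (is.na(i)) return(NA_real_)
  status <- align_status(ref$effect_allele, ref$other_allele,
                         tab$effect_allele[i], tab$other_allele[i],
                         ref$eaf, tab$eaf[i], 0)
  if (startsWith(status, "dropped")) return(NA_real_)
  swap <- status %in% c("swapped", "strand_swapped", "palindromic_swapped")
  c(beta = if (swap) -tab$beta[i] else tab$beta[i], se = tab$se[i],
    n = tab$n[i])
}

#' Step-1 screen: drug-target instrument against a protein panel
#'
#' For a single cis instrument, estimates the effect of genetically
#' proxied drug exposure on each protein as a Wald ratio scaled per unit
#' (SD) reduction in the risk-factor trait (LDL cholesterol for statins):
#' the instrument is oriented to the LDL-lowering allele, and each protein
#' association is divided by the LDL-lowering effect. Benjamini-Hochberg
#' FDR is applied across all analyzable proteins.
#'
#' @param instrument A variant id, or an `mr_instruments` /`gwas_tbl`
#'   whose first row is the instrument.
#' @param ldl `gwas_tbl` for the scaling trait containing the instrument.
#' @param proteins Named list of `gwas_tbl` tables, one per protein.
#' @param fdr_threshold Selection threshold on the q-value (default 0.05).
#' @return A tibble of class `mr_screen`: `protein`, `beta` (per SD LDL
#'   reduction), `se`, `pval`, `fdr_q`, `selected`, `direction`
#'   (`"lowered"`/`"raised"`). Attributes: `instrument`, `skipped`
#'   (proteins without an alignable record).
#' @export
step1_screen <- function(instrument, ldl, proteins, fdr_threshold = 0.05) {
  id <- if (is.character(instrument)) instrument[1] else
    instrument$variant_id[1]
  i <- match(id, ldl$variant_id)
  if (is.na(i)) abort(sprintf("instrument %s absent from the LDL table.", id))
  ref <- ldl[i, ]
  if (ref$beta == 0) abort("instrument has zero LDL effect.")
  # effect of the allele on the *reduction* in LDL; the scaled Wald ratio
  # -beta_protein/beta_ldl is invariant to which allele is coded
  ldl_lowering <- -ref$beta

  rows <- imap(proteins, function(tab, name) {
    al <- align_to_reference(tab, ref)
    if (length(al) == 1 && is.na(al[1])) return(NULL)
    beta <- unname(al["beta"]) / ldl_lowering
    se <- unname(al["se"]) / abs(ldl_lowering)
    tibble(protein = name, beta = beta, se = se,
           pval = znorm_p(beta / se), n_protein = unname(al["n"]))
  })
  skipped <- names(proteins)[map_lgl(rows, is.null)]
  out <- list_rbind(compact(rows))
  if (nrow(out) == 0) abort("no protein could be analyzed.")
  out <- out |>
    mutate(fdr_q = bh_fdr(.data$pval),
           selected = .data$fdr_q < fdr_threshold,
           direction = ifelse(.data$beta < 0, "lowered", "raised"))
  structure(out, instrument = id, fdr_threshold = fdr_threshold,
            skipped = skipped,
            class = c("mr_screen", class(out)))
}

#' Step-2 MR: selected proteins against a disease outcome
#'
#' For each protein's instrument set: harmonizes against the outcome GWAS,
#' fits the auto-model IVW (multiplicative random effects with three or
#' more variants, fixed effects otherwise; a single variant falls back to
#' the Wald ratio), and — when three or more variants are available — the
#' weighted-median and weighted-mode estimators, leave-one-out analysis,
#' and (with four or more) MR-PRESSO. Benjamini-Hochberg FDR is applied to
#' the IVW p-values across proteins.
#'
#' @param instruments Named list of `mr_instruments`/`gwas_tbl` tables of
#'   protein associations for each protein's instruments.
#' @param outcome `gwas_tbl` of outcome associations.
#' @param fdr_threshold FDR selection threshold (default 0.05).
#' @param sensitivity Run the robust estimators where applicable.
#' @param n_boot Bootstrap resamples for median/mode SEs.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Base seed; per-protein seeds are derived from it.
#' @return A list of class `mr_step2`: `ivw` (per-protein tibble with
#'   `fdr_q` and `selected`), `all_methods` (long tibble over methods),
#'   `details` (per-protein list with the harmonized set, leave-one-out
#'   table and `mr_presso` object), `skipped` (tibble of proteins that
#'   could not be analyzed, with reasons).
#' @export
step2_outcome_mr <- function(instruments, outcome, fdr_threshold = 0.05,
                             sensitivity = TRUE, n_boot = 1000,
                             n_sim = 1000, seed = NULL) {
  skipped <- list()
  details <- list()
  rows <- list()
  method_rows <- list()
  for (p in names(instruments)) {
    pseed <- if (is.null(seed)) NULL else
      (seed + match(p, names(instruments))) %% .Machine$integer.max
    h <- tryCatch(harmonize(instruments[[p]], outcome),
                  error = function(e) NULL)
    if (is.null(h)) {
      skipped[[p]] <- tibble(protein = p, reason = "not harmonizable")
      next
    }
    k <- nrow(h)
    ivw <- mr_ivw(h, "auto")
    methods <- list(mutate(ivw, protein = p, .before = 1))
    det <- list(harmonized = h)
    if (sensitivity && k >= 3) {
      methods <- c(methods, list(
        mutate(mr_weighted_median(h, n_boot, pseed), protein = p, .before = 1),
        mutate(mr_weighted_mode(h, 1, n_boot,
                                if (is.null(pseed)) NULL else pseed + 1L),
               protein = p, .before = 1)))
      det$leave_one_out <- mr_leave_one_out(h)
      if (k >= 4) {
        det$presso <- mr_presso(h, n_sim = n_sim,
                                seed = if (is.null(pseed)) NULL else
                                  pseed + 2L)
        if (!is.null(det$presso$corrected)) {
          methods <- c(methods, list(
            mutate(det$presso$corrected, protein = p, .before = 1)))
        }
      }
    } else if (sensitivity && k < 3) {
      skipped[[paste0(p, "_sens")]] <-
        tibble(protein = p,
               reason = sprintf("sensitivity skipped: only %d variant(s)", k))
    }
    details[[p]] <- det
    rows[[p]] <- mutate(ivw, protein = p, .before = 1)
    method_rows[[p]] <- list_rbind(methods)
  }
  if (length(rows) == 0) abort("no protein could be analyzed.")
  ivw_tab <- list_rbind(unname(rows)) |>
    mutate(fdr_q = bh_fdr(.data$pval),
           selected = .data$fdr_q < fdr_threshold)
  skipped_tab <- if (length(skipped) > 0) {
    list_rbind(unname(skipped))
  } else {
    tibble(protein = character(), reason = character())
  }
  structure(list(ivw = ivw_tab,
                 all_methods = list_rbind(unname(method_rows)),
                 skipped = skipped_tab,
                 details = details),
            class = "mr_step2")
}

#' Select direction-consistent mediators
#'
#' A protein is a candidate mediator of a protective (negative) total
#' effect when the drug raises it and it lowers disease risk, or the drug
#' lowers it and it raises risk — i.e. the step-1 and step-2 betas have
#' opposite signs so their product matches the sign of the total effect.
#' Inconsistent proteins are retained with the reason recorded.
#'
#' @param step1 An `mr_screen` result (or tibble with `protein`, `beta`).
#' @param step2 The `ivw` tibble of a [step2_outcome_mr()] result (or any
#'   tibble with `protein`, `beta`).
#' @param total_effect_sign Sign of the total drug-on-disease effect
#'   (default -1, protective).
#' @return A tibble: `protein`, `step1_beta`, `step2_beta`,
#'   `step1_direction`, `step2_direction`, `consistent`, `reason`.
#' @export
select_mediators <- function(step1, step2, total_effect_sign = -1) {
  if (inherits(step2, "mr_step2")) step2 <- step2$ivw
  merged <- dplyr::inner_join(
    transmute(as_tibble(step1), protein = .data$protein,
              step1_beta = .data$beta),
    transmute(as_tibble(step2), protein = .data$protein,
              step2_beta = .data$beta),
    by = "protein")
  merged |>
    mutate(
      step1_direction = ifelse(.data$step1_beta < 0, "lowered", "raised"),
      step2_direction = dplyr::case_when(
        .data$step2_beta > 0 ~ "raises risk",
        .data$step2_beta < 0 ~ "lowers risk",
        TRUE ~ "no effect"),
      consistent = .data$step1_beta != 0 & .data$step2_beta != 0 &
        sign(.data$step1_beta * .data$step2_beta) == sign(total_effect_sign),
      reason = dplyr::case_when(
        .data$consistent ~ "direction-consistent mediator",
        .data$step2_beta == 0 ~ "no step-2 effect",
        TRUE ~ "directions do not fit the total effect"))
}

#' Mediation effects by the product of coefficients
#'
#' The indirect effect is the product of the step-1 (drug on mediator) and
#' step-2 (mediator on outcome) estimates; the proportion mediated is the
#' indirect effect divided by the total effect. Proportions outside
#' \[0, 1\] are returned as computed with a warning flag, not clamped.
#'
#' @param step1_beta Effect of the drug exposure on the mediator.
#' @param step2_beta Effect of the mediator on the outcome (log OR).
#' @param total_effect Total effect of the drug exposure on the outcome
#'   (log OR, nonzero).
#' @param mediator Optional mediator name.
#' @return A one-row tibble: `mediator`, `step1_beta`, `step2_beta`,
#'   `total_effect`, `indirect_effect`, `proportion_mediated`,
#'   `out_of_range`.
#' @export
mediation_effects <- function(step1_beta, step2_beta, total_effect,
                              mediator = NA_character_) {
  stopifnot_scalar_num(step1_beta, "step1_beta")
  stopifnot_scalar_num(step2_beta, "step2_beta")
  stopifnot_scalar_num(total_effect, "total_effect")
  if (total_effect == 0) abort("total effect must be nonzero.")
  indirect <- step1_beta * step2_beta
  prop <- indirect / total_effect
  out_of_range <- prop < 0 || prop > 1
  if (out_of_range) {
    warn(sprintf("proportion mediated %.3f lies outside [0, 1]", prop))
  }
  tibble(mediator = mediator, step1_beta = step1_beta,
         step2_beta = step2_beta, total_effect = total_effect,
         indirect_effect = indirect, proportion_mediated = prop,
         out_of_range = out_of_range)
}

#' Replication check across estimate tables
#'
#' An association replicates when the protein is present in the
#' replication table with the same effect direction and replication
#' p-value below `alpha`; proteins absent from the replication panel are
#' flagged missing (not failed).
#'
#' @param primary,replication Tibbles keyed by `protein` with `beta` and
#'   `pval` columns.
#' @param alpha Replication significance level (default 0.05).
#' @return A tibble: `protein`, `replicated`, `direction_consistent`,
#'   `missing`.
#' @export
replication_check <- function(primary, replication, alpha = 0.05) {
  rep_tab <- transmute(as_tibble(replication), protein = .data$protein,
                       beta_rep = .data$beta, pval_rep = .data$pval)
  transmute(as_tibble(primary), protein = .data$protein,
            beta_primary = .data$beta) |>
    left_join(rep_tab, by = "protein") |>
    mutate(missing = is.na(.data$beta_rep),
           direction_consistent = !.data$missing &
             sign(.data$beta_primary) == sign(.data$beta_rep),
           replicated = .data$direction_consistent &
             .data$pval_rep < alpha) |>
    mutate(replicated = ifelse(.data$missing, NA, .data$replicated),
           direction_consistent = ifelse(.data$missing, NA,
                                         .data$direction_consistent)) |>
    select("protein", "replicated", "direction_consistent", "missing",
           "beta_primary", "beta_rep", "pval_rep")
}
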