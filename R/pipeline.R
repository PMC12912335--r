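#' Run the two-step MR mediation pipeline
#'
#' Orchestrates the full analysis on a config bundle (see
#' [simulate_two_step_scenario()] for the synthetic counterpart):
#'
#' 1. step-1 screen of the cis instrument against the protein panel with
#'    FDR selection;
#' 2. replication of the step-1 associations in an independent panel,
#'    when provided;
#' 3. step-2 MR of each step-1-selected protein on the disease (auto
#'    FE/MRE IVW plus sensitivity estimators), FDR over the primary
#'    outcome's p-values; replication outcome and fixed-effect
#'    meta-analysis when provided;
#' 4. direction-consistency mediator selection and product-of-
#'    coefficients mediation against the cis-instrument total effect;
#' 5. reverse MR (disease as exposure against each selected protein) with
#'    the Steiger directionality test, when provided;
#' 6. ABF colocalization of the scaling trait and each mediator over the
#'    cis region, when provided.
#'
#' Per-protein failures are logged and skipped; the pipeline continues.
#' All stochastic steps are seeded from `config$seed`, so identical
#' configs give identical outputs.
#'
#' @param config A named list. Required: `instrument` (variant id), `ldl`,
#'   `disease` (`gwas_tbl`s), `proteins`, `pqtl` (named lists of
#'   `gwas_tbl`s). Optional: `proteins_replication`,
#'   `disease_replication`, `reverse` (list with `instruments` and
#'   `proteins`), `coloc` (named list of region pairs with `trait1`,
#'   `trait2`), `extra_outcomes` (named list of `gwas_tbl`s), `fdr`
#'   (default 0.05), `pqtl_p_threshold` (default 1.7e-11), `n_boot`,
#'   `n_sim`, `seed`.
#' @return A list of class `mr_pipeline`: `step1`, `step1_replication`,
#'   `step2` (`mr_step2`), `step2_replication`, `meta`, `total_effect`,
#'   `mediators`, `mediation`, `reverse`, `coloc`, `log`.
#' @export
run_pipeline <- function(config) {
  required <- c("instrument", "ldl", "disease", "proteins", "pqtl")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0) {
    abort(sprintf("config is missing required key(s): %s",
                  paste(missing_keys, collapse = ", ")))
  }
  fdr <- config$fdr %||% 0.05
  seed <- config$seed %||% 1L
  n_boot <- config$n_boot %||% 1000
  n_sim <- config$n_sim %||% 1000
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  step1 <- step1_screen(config$instrument, config$ldl, config$proteins,
                        fdr_threshold = fdr)
  selected <- step1$protein[step1$selected]
  note("step1: %d/%d proteins selected at FDR < %g",
       length(selected), nrow(step1), fdr)

  step1_replication <- NULL
  if (!is.null(config$proteins_replication) && length(selected) > 0) {
    rep_screen <- tryCatch(
      step1_screen(config$instrument, config$ldl,
                   config$proteins_replication, fdr_threshold = fdr),
      error = function(e) NULL)
    if (!is.null(rep_screen)) {
      step1_replication <- replication_check(
        filter(as_tibble(step1), .data$selected), rep_screen)
      note("step1 replication: %d/%d replicated",
           sum(step1_replication$replicated, na.rm = TRUE),
           nrow(step1_replication))
    }
  }

  analyzable <- intersect(selected, names(config$pqtl))
  absent <- setdiff(selected, names(config$pqtl))
  if (length(absent) > 0) {
    note("no pQTL instruments for: %s", paste(absent, collapse = ", "))
  }
  if (length(analyzable) == 0) {
    abort("no step-1-selected protein has pQTL instruments.")
  }
  instr_sets <- setNames(map(analyzable, function(p) {
    select_pqtl_instruments(config$pqtl[[p]],
                            p_threshold = config$pqtl_p_threshold %||%
                              1.7e-11)
  }), analyzable)

  step2 <- step2_outcome_mr(instr_sets, config$disease,
                            fdr_threshold = fdr, n_boot = n_boot,
                            n_sim = n_sim, seed = seed + 100L)
  note("step2: %d/%d proteins selected at FDR < %g",
       sum(step2$ivw$selected), nrow(step2$ivw), fdr)

  step2_replication <- NULL
  meta <- NULL
  if (!is.null(config$disease_replication)) {
    step2_replication <- step2_outcome_mr(
      instr_sets, config$disease_replication, fdr_threshold = fdr,
      sensitivity = FALSE, seed = seed + 200L)
    meta <- list_rbind(map(analyzable, function(p) {
      a <- filter(step2$ivw, .data$protein == p)
      b <- filter(step2_replication$ivw, .data$protein == p)
      if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
      mutate(meta_fixed(bind_rows(select(a, -"protein"),
                                  select(b, -"protein"))),
             protein = p, .before = 1)
    }))
  }

  # total effect of the drug exposure on disease, on the step-1 scale
  h_total <- harmonize(config$ldl[config$ldl$variant_id ==
                                    step1_instrument(step1), ],
                       config$disease)
  # orient to the LDL-lowering allele: per SD reduction in LDL
  total <- mr_wald_ratio(mutate(h_total,
                                beta_exposure = -.data$beta_exposure))
  note("total effect: %.3f (se %.3f)", total$beta, total$se)

  mediators <- select_mediators(step1, step2$ivw,
                                total_effect_sign = sign(total$beta))
  mediators <- left_join(mediators,
                         select(step2$ivw, "protein", step2_selected =
                                  "selected"),
                         by = "protein")
  consistent <- mediators$protein[mediators$consistent &
                                    mediators$step2_selected]
  note("mediators (direction-consistent, step2 FDR-selected): %s",
       if (length(consistent) > 0) paste(consistent, collapse = ", ")
       else "none")

  mediation <- if (length(consistent) == 0) {
    tibble()
  } else {
    list_rbind(map(consistent, function(p) {
      mediation_effects(
        step1_beta = step1$beta[step1$protein == p],
        step2_beta = step2$ivw$beta[step2$ivw$protein == p],
        total_effect = total$beta, mediator = p)
    }))
  }

  reverse <- NULL
  if (!is.null(config$reverse)) {
    reverse <- list_rbind(map(analyzable, function(p) {
      tab <- config$reverse$proteins[[p]]
      if (is.null(tab)) return(NULL)
      h <- tryCatch(harmonize(config$reverse$instruments, tab),
                    error = function(e) NULL)
      if (is.null(h)) return(NULL)
      est <- mr_ivw(h, "auto")
      st <- mr_steiger(h)
      tibble(protein = p, beta = est$beta, se = est$se, pval = est$pval,
             n_snps = est$n_snps, model = est$model,
             steiger_correct = st$correct_direction,
             steiger_pval = st$pval)
    }))
    if (!is.null(reverse) && nrow(reverse) > 0) {
      reverse <- mutate(reverse, fdr_q = bh_fdr(.data$pval))
    }
  }

  coloc <- NULL
  if (!is.null(config$coloc)) {
    coloc <- list_rbind(map(intersect(consistent, names(config$coloc)),
                            function(p) {
      res <- coloc_abf(config$coloc[[p]]$trait1, config$coloc[[p]]$trait2)
      tibble(protein = p, !!!as.list(res$pp),
             n_variants = res$n_variants)
    }))
  }

  extra <- NULL
  if (!is.null(config$extra_outcomes) && length(consistent) > 0) {
    extra <- list_rbind(imap(config$extra_outcomes, function(tab, oname) {
      s <- step2_outcome_mr(instr_sets[consistent], tab,
                            fdr_threshold = fdr, sensitivity = FALSE,
                            seed = seed + 300L)
      mutate(s$ivw, outcome = oname, .before = 1)
    }))
  }

  structure(list(step1 = step1, step1_replication = step1_replication,
                 step2 = step2, step2_replication = step2_replication,
                 meta = meta, total_effect = total,
                 mediators = mediators, mediation = mediation,
                 reverse = reverse, coloc = coloc, extra = extra,
                 log = log_lines, seed = seed),
            class = "mr_pipeline")
}

step1_instrument <- function(step1) attr(step1, "instrument")

#' Write pipeline results as delimited tables plus a JSON summary
#'
#' Each tabular component is written as a TSV under `dir`; a
#' `summary.json` records the mediation results, total effect, selected
#' proteins, seed, and log.
#'
#' @param result An `mr_pipeline` result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x) > 0) {
      readr::write_tsv(as_tibble(x), file.path(dir, paste0(name, ".tsv")))
    }
  }
  emit(result$step1, "step1_screen")
  emit(result$step1_replication, "step1_replication")
  emit(result$step2$ivw, "step2_ivw")
  emit(result$step2$all_methods, "step2_all_methods")
  if (!is.null(result$step2_replication)) {
    emit(result$step2_replication$ivw, "step2_replication_ivw")
  }
  emit(result$meta, "step2_meta")
  emit(result$mediators, "mediators")
  emit(result$mediation, "mediation")
  emit(result$reverse, "reverse_mr")
  emit(result$coloc, "coloc")
  emit(result$extra, "extra_outcomes")
  summary <- list(
    seed = result$seed,
    total_effect = as.list(result$total_effect[1,
                                               c("beta", "se", "pval")]),
    selected_step1 = result$step1$protein[result$step1$selected],
    selected_step2 = result$step2$ivw$protein[result$step2$ivw$selected],
    mediation = if (nrow(result$mediation %||% tibble()) > 0) {
      as.list(result$mediation)
    },
    log = result$log)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @export
print.mr_pipeline <- function(x, ...) {
  cat("Two-step MR mediation pipeline\n")
  for (l in x$log) cat(" -", l, "\n")
  if (!is.null(x$mediation) && nrow(x$mediation) > 0) {
    cat("\nMediation:\n")
    print(as_tibble(x$mediation))
  }
  invisible(x)
}
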