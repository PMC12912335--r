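# broom-style tidiers for the package's result objects.

#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) {
  x$outlier_pvals
}

#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(global_rss = x$global_rss, global_pval = x$global_pval,
         n_outliers = length(x$outlier_indices),
         beta_full = x$estimate_full$beta,
         beta_corrected = if (is.null(x$corrected)) NA_real_ else
           x$corrected$beta,
         distortion_pval = x$distortion_pval %||% NA_real_,
         n_sim = x$n_sim)
}

#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(hypothesis = names(x$pp), posterior = unname(x$pp))
}

#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble(!!!as.list(x$pp), n_variants = x$n_variants,
         p1 = x$priors[["p1"]], p2 = x$priors[["p2"]],
         p12 = x$priors[["p12"]])
}

#' @method tidy mr_step2
#' @export
tidy.mr_step2 <- function(x, ...) {
  x$all_methods
}

#' @method glance mr_step2
#' @export
glance.mr_step2 <- function(x, ...) {
  tibble(n_proteins = nrow(x$ivw), n_selected = sum(x$ivw$selected),
         n_skipped = nrow(x$skipped))
}

#' @method tidy mr_screen
#' @export
tidy.mr_screen <- function(x, ...) {
  as_tibble(x)
}

#' @method glance mr_screen
#' @export
glance.mr_screen <- function(x, ...) {
  tibble(n_proteins = nrow(x), n_selected = sum(x$selected),
         n_lowered = sum(x$selected & x$direction == "lowered"),
         n_raised = sum(x$selected & x$direction == "raised"),
         instrument = attr(x, "instrument"),
         fdr_threshold = attr(x, "fdr_threshold"))
}

#' @method glance mr_pipeline
#' @export
glance.mr_pipeline <- function(x, ...) {
  tibble(
    n_proteins_screened = nrow(x$step1),
    n_step1_selected = sum(x$step1$selected),
    n_step2_selected = sum(x$step2$ivw$selected),
    n_mediators = if (is.null(x$mediation)) 0L else nrow(x$mediation),
    total_effect = x$total_effect$beta,
    proportion_mediated = if (!is.null(x$mediation) &&
                              nrow(x$mediation) > 0) {
      x$mediation$proportion_mediated[1]
    } else {
      NA_real_
    })
}
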