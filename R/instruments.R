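#' Define a gene region
#'
#' Coordinates are 1-based and inclusive.
#'
#' @param gene_name Gene symbol (e.g. `"HMGCR"`).
#' @param chrom Chromosome as character.
#' @param start,end Region boundaries (`start <= end`).
#' @return A `gene_region` list.
#' @export
gene_region <- function(gene_name, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    abort("`start` must not exceed `end`.")
  }
  structure(list(gene_name = gene_name, chrom = as.character(chrom),
                 start = start, end = end),
            class = "gene_region")
}

#' HMGCR gene region (GRCh37)
#'
#' Convenience region for the statin drug-target gene used to build
#' cis instruments for genetically mimicked statins.
#'
#' @return A `gene_region`.
#' @export
hmgcr_region <- function() {
  gene_region("HMGCR", "5", 74632154L, 74657929L)
}

#' Greedy LD pruning of summary-statistic records
#'
#' Repeatedly keeps the remaining variant with the smallest p-value and
#' discards every other remaining variant whose LD r-squared with it is at
#' or above `r2_threshold` (the rule retains pairs with `r2 < threshold`
#' strictly). Ties on p-value are broken by lexicographic variant id, so
#' the result is deterministic regardless of input order.
#'
#' @param records A `gwas_tbl` (or compatible tibble) of candidate variants.
#' @param ld An [ld_matrix()] covering every candidate variant.
#' @param r2_threshold LD r-squared threshold.
#' @return The pruned tibble, ordered by p-value.
#' @export
ld_prune <- function(records, ld, r2_threshold) {
  absent <- setdiff(records$variant_id, ld$variant_ids)
  if (length(absent) > 0) {
    abort(sprintf("variant(s) absent from LD matrix: %s",
                  paste(absent, collapse = ", ")))
  }
  ord <- order(records$pval, records$variant_id)
  records <- records[ord, ]
  r2 <- ld$r[records$variant_id, records$variant_id, drop = FALSE]^2
  keep <- logical(nrow(records))
  remaining <- seq_len(nrow(records))
  while (length(remaining) > 0) {
    lead <- remaining[1]
    keep[lead] <- TRUE
    remaining <- remaining[r2[lead, remaining] < r2_threshold]
  }
  records[keep, ]
}

new_instrument_set <- function(records, exposure_name, meta) {
  records <- as_tibble(records) |>
    mutate(f_stat = f_statistic(.data$beta, .data$se),
           weak = .data$f_stat <= 10)
  structure(records, exposure_name = exposure_name, selection = meta,
            class = c("mr_instruments", class(records)))
}

#' Select cis instruments for a drug target
#'
#' Filters a GWAS table to the gene region plus a symmetric flank
#' (boundaries inclusive, as in "100 kb on either side"), applies the
#' p-value threshold, LD-prunes the survivors, and optionally returns only
#' the lead (smallest-p) variant — the construction used for genetic
#' proxies of pharmacological LDL lowering.
#'
#' @param gwas A `gwas_tbl` with positional information.
#' @param region A [gene_region()].
#' @param flank_bp Flank added to both sides of the region (default 100 kb).
#' @param p_threshold Association p-value threshold (default 5e-8).
#' @param ld An [ld_matrix()]; `NULL` skips pruning (use only for inputs
#'   already pruned), recorded in the selection metadata.
#' @param r2_threshold LD r-squared threshold (default 0.05).
#' @param lead_only If `TRUE`, return only the smallest-p survivor.
#' @return An `mr_instruments` tibble with per-variant F-statistics and a
#'   `selection` attribute recording the thresholds.
#' @export
select_cis_instruments <- function(gwas, region, flank_bp = 100000,
                                   p_threshold = 5e-8, ld = NULL,
                                   r2_threshold = 0.05, lead_only = FALSE) {
  hits <- gwas |>
    filter(.data$chrom == region$chrom,
           .data$pos >= region$start - flank_bp,
           .data$pos <= region$end + flank_bp,
           .data$pval < p_threshold)
  if (nrow(hits) == 0) {
    abort(sprintf("no variant in %s +/- %d bp passes p < %g",
                  region$gene_name, flank_bp, p_threshold))
  }
  hits <- if (is.null(ld)) {
    hits[order(hits$pval, hits$variant_id), ]
  } else {
    ld_prune(hits, ld, r2_threshold)
  }
  if (lead_only) hits <- hits[1, ]
  new_instrument_set(
    hits, attr(gwas, "trait_name") %||% "exposure",
    list(region = region$gene_name, flank_bp = flank_bp,
         p_threshold = p_threshold, r2_threshold = r2_threshold,
         pruned = !is.null(ld), lead_only = lead_only))
}

#' Select pQTL (or disease) instruments genome-wide
#'
#' Applies the association p-value threshold, LD-prunes survivors, and
#' computes per-variant F-statistics, flagging any with F at or below 10
#' as weak. Defaults follow the proteomic instrument convention
#' (`p < 1.7e-11`, LD `r2 < 0.01`); disease instruments for reverse MR use
#' the same machinery with `p_threshold = 5e-8` and `r2_threshold = 0.001`.
#'
#' @inheritParams select_cis_instruments
#' @return An `mr_instruments` tibble.
#' @export
select_pqtl_instruments <- function(gwas, p_threshold = 1.7e-11, ld = NULL,
                                    r2_threshold = 0.01) {
  if (nrow(gwas) == 0) abort("empty GWAS table.")
  hits <- filter(gwas, .data$pval < p_threshold)
  if (nrow(hits) == 0) {
    abort(sprintf("no variant passes p < %g for '%s'", p_threshold,
                  attr(gwas, "trait_name") %||% "exposure"))
  }
  hits <- if (is.null(ld)) {
    hits[order(hits$pval, hits$variant_id), ]
  } else {
    ld_prune(hits, ld, r2_threshold)
  }
  new_instrument_set(
    hits, attr(gwas, "trait_name") %||% "exposure",
    list(p_threshold = p_threshold, r2_threshold = r2_threshold,
         pruned = !is.null(ld)))
}
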