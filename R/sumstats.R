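#' Construct a validated GWAS summary-statistics table
#'
#' A GWAS table is a tibble with one row per variant and the canonical
#' columns `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`. `beta` is the per-effect-allele
#' association (SD units for quantitative traits, log odds ratio for binary
#' traits), `se` its standard error, `eaf` the effect-allele frequency
#' (may be `NA`), and `n` the effective sample size (for binary traits the
#' default convention is cases + controls).
#'
#' Row-level invariants enforced: `se > 0`, `pval` in (0, 1], `eaf` in
#' \[0, 1\] when present, `pos >= 1`, effect and other allele differ
#' (case-insensitively), and `variant_id` unique.
#'
#' @param x A data frame with the canonical columns (extra columns are kept).
#' @param trait_name Character label for the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param mode `"strict"` errors on any invalid row or duplicate id;
#'   `"lenient"` drops offending rows (keeping the first of any duplicate
#'   id) and reports the count via a message.
#' @return A tibble of class `gwas_tbl` with attributes `trait_name` and
#'   `trait_type`.
#' @export
gwas_table <- function(x, trait_name = "trait",
                       trait_type = c("quantitative", "binary"),
                       mode = c("strict", "lenient")) {
  trait_type <- arg_match(trait_type)
  mode <- arg_match(mode)
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x) |>
    mutate(
      variant_id = as.character(.data$variant_id),
      chrom = as.character(.data$chrom),
      pos = as.integer(.data$pos),
      effect_allele = toupper(as.character(.data$effect_allele)),
      other_allele = toupper(as.character(.data$other_allele))
    )
  if (nrow(x) == 0) abort("GWAS table has no rows.")

  bad <- !(is.finite(x$se) & x$se > 0) |
    !(is.finite(x$pval) & x$pval > 0 & x$pval <= 1) |
    (!is.na(x$eaf) & !(x$eaf >= 0 & x$eaf <= 1)) |
    !(is.finite(x$pos) & x$pos >= 1) |
    !is.finite(x$beta) |
    (x$effect_allele == x$other_allele)
  dup <- duplicated(x$variant_id)
  if (mode == "strict") {
    if (any(bad)) {
      abort(sprintf("invalid summary-statistic row(s): %s",
                    paste(x$variant_id[bad], collapse = ", ")))
    }
    if (any(dup)) {
      abort(sprintf("duplicate variant_id(s): %s",
                    paste(unique(x$variant_id[dup]), collapse = ", ")))
    }
  } else {
    drop <- bad | dup
    if (any(drop)) {
      inform(sprintf("dropped %d invalid or duplicated row(s) from '%s'",
                     sum(drop), trait_name))
      x <- x[!drop, , drop = FALSE]
    }
    if (nrow(x) == 0) abort("no valid rows remain after filtering.")
  }
  structure(x, trait_name = trait_name, trait_type = trait_type,
            class = c("gwas_tbl", class(x)))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row (dialect
#' auto-detected from the header line, overridable), renames columns to the
#' canonical set through `column_map`, and validates via [gwas_table()].
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column names. Canonical names
#'   already present in the file need no entry.
#' @param delim Field delimiter; `NULL` auto-detects (`\t` if the header
#'   contains a tab, `,` otherwise).
#' @inheritParams gwas_table
#' @return A `gwas_tbl` tibble.
#' @export
read_gwas <- function(path, column_map = NULL, trait_name = "trait",
                      trait_type = c("quantitative", "binary"),
                      delim = NULL, mode = c("strict", "lenient")) {
  trait_type <- arg_match(trait_type)
  mode <- arg_match(mode)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) abort(sprintf("empty file: %s", path))
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  dat <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(dat) == 0L) abort(sprintf("no data rows in %s", path))
  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(dat))
    if (length(absent) > 0) {
      abort(sprintf("mapped column(s) not in file: %s",
                    paste(absent, collapse = ", ")))
    }
    for (canon in names(column_map)) {
      names(dat)[names(dat) == column_map[[canon]]] <- canon
    }
  }
  gwas_table(dat, trait_name = trait_name, trait_type = trait_type,
             mode = mode)
}

#' Write GWAS summary statistics to delimited text
#'
#' @param x A `gwas_tbl` (or compatible data frame).
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_gwas <- function(x, path, delim = "\t") {
  readr::write_delim(as_tibble(x), path, delim = delim)
  invisible(path)
}

#' Construct, read or write an LD correlation matrix
#'
#' The file format is whitespace-delimited: the first row lists the variant
#' ids, each following row one row of the square correlation matrix `r`
#' (signed correlations, so LD r-squared is `r^2`). The matrix must be
#' symmetric with unit diagonal, entries in \[-1, 1\], and positive
#' semi-definite within tolerance 1e-8.
#'
#' @param variant_ids Character vector of variant ids.
#' @param r Square numeric correlation matrix.
#' @return An `ld_matrix` object (list with `variant_ids` and `r`).
#' @export
ld_matrix <- function(variant_ids, r) {
  r <- as.matrix(r)
  k <- length(variant_ids)
  if (!is.numeric(r) || nrow(r) != k || ncol(r) != k) {
    abort("`r` must be a square numeric matrix matching `variant_ids`.")
  }
  if (anyDuplicated(variant_ids)) abort("duplicate variant ids in LD matrix.")
  if (max(abs(r - t(r))) > 1e-8) abort("LD matrix must be symmetric.")
  if (max(abs(diag(r) - 1)) > 1e-8) abort("LD matrix diagonal must be 1.")
  if (any(r < -1 - 1e-8 | r > 1 + 1e-8)) abort("LD entries must be in [-1, 1].")
  ev <- eigen((r + t(r)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("LD matrix must be positive semi-definite.")
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r = r),
            class = "ld_matrix")
}

#' @rdname ld_matrix
#' @param path Path to a whitespace-delimited LD matrix file.
#' @export
read_ld_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort("LD matrix file must have ids plus rows.")
  ids <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  r <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  ld_matrix(ids, r)
}

#' @rdname ld_matrix
#' @param ld An `ld_matrix` object.
#' @export
write_ld_matrix <- function(ld, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ld$variant_ids, collapse = " "), con)
  utils::write.table(format(ld$r, digits = 15, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Instrument-strength F-statistic
#'
#' For a single variant the approximate F-statistic is `(beta/se)^2`;
#' values above 10 are conventionally taken to indicate an adequately
#' strong instrument.
#'
#' @param beta,se Per-allele association and its standard error (`se > 0`).
#' @return Numeric F-statistic(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) abort("`se` must be positive.")
  (beta / se)^2
}

#' Variance in a trait explained by a variant
#'
#' From summary statistics: with `t = beta/se`, `r2 = t^2 / (t^2 + n - 2)`.
#' This is the per-variant input to the Steiger directionality test.
#'
#' @inheritParams f_statistic
#' @param n Sample size (> 2).
#' @return Numeric r-squared value(s) in \[0, 1).
#' @export
variance_explained <- function(beta, se, n) {
  if (any(!is.finite(se) | se <= 0)) abort("`se` must be positive.")
  if (any(!is.finite(n) | n <= 2)) abort("`n` must exceed 2.")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}
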