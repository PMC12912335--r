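#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Detects horizontally pleiotropic outlier variants by comparing each
#' variant's squared residual from the leave-one-out IVW fit against a
#' seeded parametric simulation under no pleiotropy.
#'
#' Observed statistic: `RSS = sum_j (b_out_j - b_loo(-j) * b_exp_j)^2`,
#' where `b_loo(-j)` is the fixed-effect IVW estimate computed without
#' variant `j`. Each of `n_sim` simulated datasets draws
#' `b_exp_j* ~ N(b_exp_j, se_exp_j^2)` and
#' `b_out_j* ~ N(b_loo(-j) * b_exp_j, se_out_j^2)` and recomputes the same
#' statistic. The global p-value is the add-one empirical tail
#' `(r + 1)/(n_sim + 1)`. Per-variant outlier p-values are the empirical
#' tails of each observed squared residual in its simulated distribution,
#' Bonferroni-adjusted by the number of variants; variants with adjusted
#' p below `outlier_alpha` are outliers. When outliers are found, the
#' corrected estimate is the auto-model IVW on the remaining variants and
#' the distortion test compares the induced shift against the distribution
#' of shifts from removing random subsets of the same size.
#'
#' @param h A harmonized set with at least four variants.
#' @param n_sim Number of simulated datasets (default 1000).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   outlier test (default 0.05).
#' @param seed Seed; the whole procedure is deterministic given it.
#' @return An object of class `mr_presso`: a list with `global_rss`,
#'   `global_pval`, `outlier_indices` (variant ids), `outlier_pvals`
#'   (tibble), `estimate_full`, `corrected` (`mr_result` or `NULL`),
#'   `distortion_pval` (or `NULL`), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  check_harmonized(h)
  k <- nrow(h)
  if (k < 4) abort("MR-PRESSO requires at least four variants.")
  x <- h$beta_exposure; sx <- h$se_exposure
  y <- h$beta_outcome; sy <- h$se_outcome
  w <- sy^-2

  loo_fit <- function(xv, yv) {
    s1 <- sum(w * xv * yv); s2 <- sum(w * xv^2)
    (s1 - w * xv * yv) / (s2 - w * xv^2)
  }
  b_loo <- loo_fit(x, y)
  resid_obs <- (y - b_loo * x)^2
  rss_obs <- sum(resid_obs)

  sim <- with_seed_if(seed, {
    xs <- matrix(rnorm(k * n_sim, x, sx), nrow = k)
    ys <- matrix(rnorm(k * n_sim, b_loo * x, sy), nrow = k)
    s1 <- colSums(w * xs * ys)
    s2 <- colSums(w * xs^2)
    b_loo_s <- (rep(s1, each = k) - w * xs * ys) /
      (rep(s2, each = k) - w * xs^2)
    dim(b_loo_s) <- c(k, n_sim)
    res <- (ys - b_loo_s * xs)^2
    list(res = res, rss = colSums(res))
  })

  global_pval <- (sum(sim$rss >= rss_obs) + 1) / (n_sim + 1)
  p_out <- (rowSums(sim$res >= resid_obs) + 1) / (n_sim + 1)
  p_adj <- pmin(1, p_out * k)
  outlier <- p_adj < outlier_alpha
  ids <- h$variant_id %||% as.character(seq_len(k))

  outlier_pvals <- tibble(variant_id = ids, resid_sq = resid_obs,
                          pval = p_out, pval_bonferroni = p_adj,
                          outlier = outlier)
  full <- mr_ivw(h, "auto")
  corrected <- NULL
  distortion_pval <- NULL
  if (any(outlier) && sum(!outlier) >= 2) {
    corrected <- mr_ivw(h[!outlier, ], "auto")
    corrected$method <- "presso_corrected"
    d_obs <- (full$beta - corrected$beta) / corrected$beta
    n_out <- sum(outlier)
    s1_all <- sum(w * x * y); s2_all <- sum(w * x^2)
    d_sim <- with_seed_if(if (is.null(seed)) NULL else seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(k, n_out)
        bsub <- (s1_all - sum(w[drop_idx] * x[drop_idx] * y[drop_idx])) /
          (s2_all - sum(w[drop_idx] * x[drop_idx]^2))
        (full$beta - bsub) / bsub
      }, numeric(1))
    })
    distortion_pval <- (sum(abs(d_sim) >= abs(d_obs)) + 1) / (n_sim + 1)
  }
  structure(list(global_rss = rss_obs, global_pval = global_pval,
                 outlier_indices = ids[outlier],
                 outlier_pvals = outlier_pvals,
                 estimate_full = full, corrected = corrected,
                 distortion_pval = distortion_pval,
                 n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS %.4g, global p %.4g, %d outlier(s)\n",
              x$global_rss, x$global_pval, length(x$outlier_indices)))
  if (!is.null(x$corrected)) {
    cat(sprintf("  corrected IVW beta %.4g (se %.4g), distortion p %.4g\n",
                x$corrected$beta, x$corrected$se, x$distortion_pval))
  }
  invisible(x)
}
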