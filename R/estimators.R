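new_mr_result <- function(method, model, beta, se, n_snps, notes = NA_character_) {
  structure(
    tibble(method = method, model = model, beta = beta, se = se,
           pval = znorm_p(beta / se), n_snps = as.integer(n_snps),
           notes = notes),
    class = c("mr_result", class(tibble())))
}

check_harmonized <- function(h) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!all(need %in% names(h))) {
    abort("input must be a harmonized set with exposure/outcome betas and SEs.")
  }
  if (any(h$se_exposure <= 0) || any(h$se_outcome <= 0)) {
    abort("all standard errors must be positive.")
  }
  h
}

# Per-variant Wald ratios with first- or second-order SEs.
ratio_estimates <- function(h, se_method = c("first_order", "second_order")) {
  se_method <- arg_match(se_method)
  bx <- h$beta_exposure; sx <- h$se_exposure
  by <- h$beta_outcome; sy <- h$se_outcome
  ratio <- by / bx
  se <- if (se_method == "first_order") {
    sy / abs(bx)
  } else {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  }
  tibble(variant_id = h$variant_id %||% as.character(seq_along(bx)),
         ratio = ratio, se_ratio = se)
}

#' Wald ratio estimate from a single variant
#'
#' The causal effect of the exposure on the outcome proxied by one
#' instrument: `beta_outcome / beta_exposure`. The default first-order
#' standard error is `se_outcome / |beta_exposure|`; the second-order
#' option adds the exposure-side uncertainty,
#' `sqrt(se_out^2/b_exp^2 + b_out^2 se_exp^2 / b_exp^4)`.
#'
#' @param h A harmonized set (see [harmonize()]) with exactly one variant.
#' @param se_method `"first_order"` (default) or `"second_order"`.
#' @return A one-row `mr_result` tibble (`method`, `model`, `beta`, `se`,
#'   `pval`, `n_snps`, `notes`).
#' @export
mr_wald_ratio <- function(h, se_method = c("first_order", "second_order")) {
  check_harmonized(h)
  if (nrow(h) != 1) abort("Wald ratio requires exactly one variant.")
  if (h$beta_exposure == 0) abort("exposure beta is zero.")
  r <- ratio_estimates(h, se_method)
  new_mr_result("wald", "none", r$ratio, r$se_ratio, 1L)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Combines per-variant Wald ratios with first-order inverse-variance
#' weights; equivalent to weighted least squares of the outcome betas on
#' the exposure betas through the origin with weights `se_outcome^-2`.
#' Under the fixed-effects (FE) model the SE is `(sum w)^-1/2`; the
#' multiplicative random-effects (MRE) model inflates it by
#' `sqrt(max(1, Q/(k-1)))` where `Q` is Cochran's heterogeneity statistic.
#' `model = "auto"` uses MRE with three or more variants and FE otherwise.
#'
#' @param h A harmonized set with at least one variant (a single variant
#'   delegates to [mr_wald_ratio()]).
#' @param model `"auto"`, `"FE"`, or `"MRE"`.
#' @return A one-row `mr_result` tibble.
#' @export
mr_ivw <- function(h, model = c("auto", "FE", "MRE")) {
  model <- arg_match(model)
  check_harmonized(h)
  zero <- h$beta_exposure == 0
  if (any(zero)) {
    warn(sprintf("dropping %d variant(s) with zero exposure beta", sum(zero)))
    h <- h[!zero, ]
  }
  k <- nrow(h)
  if (k == 0) abort("all variants had zero exposure beta.")
  if (k == 1) return(mr_wald_ratio(h))
  r <- ratio_estimates(h, "first_order")
  w <- r$se_ratio^-2
  beta <- sum(w * r$ratio) / sum(w)
  se_fe <- sum(w)^-0.5
  if (model == "auto") model <- if (k >= 3) "MRE" else "FE"
  se <- if (model == "MRE") {
    q <- sum(w * (r$ratio - beta)^2)
    se_fe * sqrt(max(1, q / (k - 1)))
  } else {
    se_fe
  }
  new_mr_result("ivw", model, beta, se, k)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (ratio_j - beta_FE)^2` over per-variant Wald ratios with
#' first-order inverse-variance weights, compared to a chi-square with
#' `k - 1` degrees of freedom.
#'
#' @param h A harmonized set with at least two variants.
#' @return A one-row tibble: `Q`, `df`, `pval`.
#' @export
cochran_q <- function(h) {
  check_harmonized(h)
  if (nrow(h) < 2) abort("Q requires at least two variants.")
  r <- ratio_estimates(h, "first_order")
  w <- r$se_ratio^-2
  beta <- sum(w * r$ratio) / sum(w)
  q <- sum(w * (r$ratio - beta)^2)
  tibble(Q = q, df = nrow(h) - 1L,
         pval = pchisq(q, df = nrow(h) - 1L, lower.tail = FALSE))
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]; w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(ratio[1])
  if (0.5 >= cum[length(cum)]) return(ratio[length(ratio)])
  approx(cum, ratio, xout = 0.5, ties = "ordered")$y
}

weighted_mode_point <- function(ratio, w, phi = 1, grid_n = 512L) {
  k <- length(ratio)
  spread <- min(sd(ratio), stats::IQR(ratio) / 1.349)
  h_bw <- phi * 0.9 * spread * k^(-1 / 5)
  if (!is.finite(h_bw) || h_bw <= 0) h_bw <- 1e-8
  grid <- seq(min(ratio) - 3 * h_bw, max(ratio) + 3 * h_bw,
              length.out = grid_n)
  dens <- colSums((w / sum(w)) * exp(-0.5 * (outer(ratio, grid, "-") / h_bw)^2))
  grid[which.max(dens)]
}

# Parametric bootstrap SE shared by the median and mode estimators:
# per-variant exposure and outcome betas are resampled from
# normal(estimate, se^2) and the point estimator recomputed.
bootstrap_se <- function(h, point_fun, n_boot, seed) {
  k <- nrow(h)
  with_seed_if(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(k, h$beta_exposure, h$se_exposure)
      by <- rnorm(k, h$beta_outcome, h$se_outcome)
      ratio <- by / bx
      w <- (h$se_outcome / abs(bx))^-2
      point_fun(ratio, w)
    }, numeric(1))
    sd(est)
  })
}

#' Weighted-median MR estimate
#'
#' The median of the per-variant Wald ratios weighted by first-order
#' inverse variances: ratios are sorted, the normalized cumulative weight
#' computed, and the estimate obtained by linear interpolation at
#' cumulative weight 0.5. Consistent when at least half the weight comes
#' from valid instruments. The SE is the standard deviation of the
#' estimate over `n_boot` parametric-bootstrap resamples.
#'
#' @param h A harmonized set with at least three variants.
#' @param n_boot Bootstrap resamples for the SE (default 1000).
#' @param seed Seed making the bootstrap reproducible.
#' @return A one-row `mr_result` tibble.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  check_harmonized(h)
  if (nrow(h) < 3) abort("weighted median requires at least three variants.")
  r <- ratio_estimates(h, "first_order")
  beta <- weighted_median_point(r$ratio, r$se_ratio^-2)
  se <- bootstrap_se(h, weighted_median_point, n_boot, seed)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  new_mr_result("weighted_median", "none", beta, se, nrow(h),
                notes = sprintf("n_boot=%d;seed=%s", n_boot,
                                seed %||% "NULL"))
}

#' Weighted-mode MR estimate
#'
#' The mode of the inverse-variance-weighted Gaussian kernel density of
#' the per-variant Wald ratios, evaluated on a 512-point grid spanning the
#' ratios plus three bandwidths. The bandwidth follows a modified Silverman
#' rule, `h = phi * 0.9 * min(sd, IQR/1.349) * k^(-1/5)`, floored at a
#' small epsilon for degenerate ratio sets. Consistent when the largest
#' group of instruments sharing a causal estimate (the plurality) is valid.
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth inflation factor (default 1).
#' @return A one-row `mr_result` tibble.
#' @export
mr_weighted_mode <- function(h, phi = 1, n_boot = 1000, seed = NULL) {
  check_harmonized(h)
  if (nrow(h) < 3) abort("weighted mode requires at least three variants.")
  r <- ratio_estimates(h, "first_order")
  beta <- weighted_mode_point(r$ratio, r$se_ratio^-2, phi)
  se <- bootstrap_se(h, function(ratio, w) weighted_mode_point(ratio, w, phi),
                     n_boot, seed)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  new_mr_result("weighted_mode", "none", beta, se, nrow(h),
                notes = sprintf("phi=%g;n_boot=%d;seed=%s", phi, n_boot,
                                seed %||% "NULL"))
}

#' Leave-one-out IVW analysis
#'
#' Refits the auto-model IVW estimate with each variant omitted in turn,
#' to reveal single variants that drive the pooled estimate.
#'
#' @param h A harmonized set with at least three variants.
#' @return A tibble of class `mr_loo`: one `mr_result` row per omitted
#'   variant, labelled by `omitted`.
#' @export
mr_leave_one_out <- function(h) {
  check_harmonized(h)
  if (nrow(h) < 3) abort("leave-one-out requires at least three variants.")
  out <- map(seq_len(nrow(h)), function(j) {
    mutate(mr_ivw(h[-j, ], model = "auto"),
           omitted = h$variant_id[j], .before = 1)
  }) |> list_rbind()
  structure(out, full = mr_ivw(h, "auto"),
            class = c("mr_loo", class(out)))
}

#' Steiger directionality test
#'
#' Compares the variance in the exposure and in the outcome explained by
#' the instrument (summing [variance_explained()] over its variants). The
#' test statistic is the difference of Fisher-transformed correlations
#' `sqrt(r2)` divided by `sqrt(1/(n_exp - 3) + 1/(n_out - 3))`, with a
#' two-sided normal p-value. The inferred causal direction is correct when
#' the instrument explains more variance in the exposure than in the
#' outcome.
#'
#' @param h A harmonized set.
#' @param n_exposure,n_outcome Sample sizes (> 3); default to the
#'   per-variant `n` columns of `h`.
#' @return A one-row tibble: `r2_exposure`, `r2_outcome`,
#'   `correct_direction`, `zscore`, `pval`.
#' @export
mr_steiger <- function(h, n_exposure = NULL, n_outcome = NULL) {
  check_harmonized(h)
  n_exposure <- n_exposure %||% h$n_exposure
  n_outcome <- n_outcome %||% h$n_outcome
  if (any(n_exposure <= 3) || any(n_outcome <= 3)) {
    abort("sample sizes must exceed 3.")
  }
  r2x <- sum(variance_explained(h$beta_exposure, h$se_exposure, n_exposure))
  r2y <- sum(variance_explained(h$beta_outcome, h$se_outcome, n_outcome))
  nx <- mean(n_exposure); ny <- mean(n_outcome)
  z <- (atanh(sqrt(min(r2x, 1 - 1e-12))) - atanh(sqrt(min(r2y, 1 - 1e-12)))) /
    sqrt(1 / (nx - 3) + 1 / (ny - 3))
  tibble(r2_exposure = r2x, r2_outcome = r2y,
         correct_direction = r2x > r2y, zscore = z,
         pval = if (z == 0) 1 else znorm_p(z))
}

#' Fixed-effect meta-analysis of MR estimates
#'
#' Inverse-variance pooling of two or more estimates on the same scale:
#' `beta = sum(b/se^2) / sum(1/se^2)`, `se = (sum se^-2)^-1/2`.
#'
#' @param estimates A tibble of `mr_result` rows (needs `beta` and `se`).
#' @return A one-row `mr_result` with `method = "meta"`.
#' @export
meta_fixed <- function(estimates) {
  if (nrow(estimates) < 2) abort("meta-analysis requires >= 2 estimates.")
  w <- estimates$se^-2
  beta <- sum(w * estimates$beta) / sum(w)
  new_mr_result("meta", "FE", beta, sum(w)^-0.5,
                sum(estimates$n_snps %||% 1L),
                notes = sprintf("pooled=%d", nrow(estimates)))
}
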