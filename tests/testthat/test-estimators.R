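test_that("Wald ratio matches hand-computed first/second-order values", {
  h <- make_harmonized(0.5, 0.1, 0.2, 0.05)
  w1 <- mr_wald_ratio(h)
  expect_equal(w1$beta, 0.4)
  expect_equal(w1$se, 0.1)
  w2 <- mr_wald_ratio(h, "second_order")
  expect_equal(w2$se, sqrt(0.05^2 / 0.5^2 + 0.2^2 * 0.1^2 / 0.5^4))
  expect_equal(w2$se, 0.1281, tolerance = 1e-3)
  expect_equal(mr_wald_ratio(make_harmonized(0.5, 0.1, 0, 0.05))$beta, 0)
  expect_error(mr_wald_ratio(make_harmonized(0, 0.1, 0.2, 0.05)), "zero")
  expect_error(mr_wald_ratio(make_harmonized(c(1, 1), c(.1, .1),
                                             c(.2, .2), c(.05, .05))),
               "one variant")
})

test_that("IVW reduces to the Wald ratio for one variant and floors MRE", {
  h1 <- make_harmonized(0.5, 0.1, 0.2, 0.05)
  expect_equal(mr_ivw(h1)$beta, mr_wald_ratio(h1)$beta)
  # three identical ratios: Q = 0, MRE scale floored at 1
  h3 <- make_harmonized(c(0.5, 0.4, 0.25), c(0.1, 0.1, 0.1),
                        c(0.2, 0.16, 0.1), c(0.05, 0.05, 0.05))
  fit <- mr_ivw(h3, "auto")
  expect_equal(fit$beta, 0.4)
  expect_equal(fit$model, "MRE")
  expect_equal(cochran_q(h3)$Q, 0, tolerance = 1e-20)
  expect_equal(fit$se, mr_ivw(h3, "FE")$se)
})

test_that("IVW(FE) equals the WLS-through-origin oracle", {
  set.seed(101)
  for (i in 1:20) {
    bx <- rnorm(5, 0.2, 0.05); sx <- runif(5, 0.01, 0.03)
    by <- 0.4 * bx + rnorm(5, 0, 0.02); sy <- runif(5, 0.01, 0.05)
    h <- make_harmonized(bx, sx, by, sy)
    fit <- mr_ivw(h, "FE")
    wls <- lm(by ~ 0 + bx, weights = sy^-2)
    expect_equal(fit$beta, unname(coef(wls)), tolerance = 1e-10)
    se_oracle <- sqrt(vcov(wls)[1, 1]) / summary(wls)$sigma
    expect_equal(fit$se, unname(se_oracle), tolerance = 1e-10)
  }
})

test_that("Cochran's Q matches hand computation and permutes freely", {
  h <- make_harmonized(c(1, 1), c(0.05, 0.05), c(0.2, 0.4), c(0.1, 0.1))
  q <- cochran_q(h)
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1L)
  h5 <- make_harmonized(rnorm(5, 0.2, 0.02), rep(0.01, 5),
                        rnorm(5, 0.1, 0.05), runif(5, 0.02, 0.06))
  expect_equal(cochran_q(h5)$Q, cochran_q(h5[c(3, 1, 5, 2, 4), ])$Q)
  expect_error(cochran_q(h5[1, ]), "two variants")
})

test_that("weighted median interpolates cumulative weights at 0.5", {
  # equal weights over {0.1 .. 0.5}: midpoint exactly
  h <- make_harmonized(rep(1, 5), rep(0.01, 5), seq(0.1, 0.5, 0.1),
                       rep(0.1, 5))
  expect_equal(mr_weighted_median(h, n_boot = 20, seed = 1)$beta, 0.3)
  # degenerate ratios return the common value
  hc <- make_harmonized(rep(1, 4), rep(0.01, 4), rep(0.7, 4), rep(0.1, 4))
  expect_equal(mr_weighted_median(hc, n_boot = 20, seed = 1)$beta, 0.7)
  # random instances agree with the independent interpolation oracle
  set.seed(5)
  for (i in 1:10) {
    k <- sample(3:9, 1)
    bx <- rnorm(k, 0.3, 0.05); sy <- runif(k, 0.02, 0.1)
    by <- rnorm(k, 0.15, 0.08)
    hh <- make_harmonized(bx, rep(0.01, k), by, sy)
    ratio <- by / bx
    w <- (sy / abs(bx))^-2
    expect_equal(mr_weighted_median(hh, n_boot = 5, seed = 1)$beta,
                 oracle_weighted_median(ratio, w), tolerance = 1e-10)
  }
  # deterministic given the seed
  a <- mr_weighted_median(h, n_boot = 50, seed = 9)
  b <- mr_weighted_median(h, n_boot = 50, seed = 9)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(h[1:2, ]), "three")
})

test_that("weighted mode finds the plurality cluster", {
  hc <- make_harmonized(rep(1, 4), rep(0.01, 4), rep(0.7, 4), rep(0.1, 4))
  expect_equal(mr_weighted_mode(hc, n_boot = 20, seed = 1)$beta, 0.7,
               tolerance = 1e-6)
  # 5 ratios near 0.4 vs 2 outliers near 1.5 with comparable weights
  ratios <- c(0.38, 0.39, 0.40, 0.41, 0.42, 1.5, 1.52)
  h <- make_harmonized(rep(1, 7), rep(0.01, 7), ratios, rep(0.1, 7))
  est <- mr_weighted_mode(h, n_boot = 20, seed = 1)$beta
  expect_gt(est, 0.3)
  expect_lt(est, 0.5)
  # invariant to variant order
  perm <- c(6, 2, 7, 1, 5, 3, 4)
  expect_equal(mr_weighted_mode(h[perm, ], n_boot = 20, seed = 1)$beta, est)
  expect_error(mr_weighted_mode(h[1:2, ]), "three")
})

test_that("Steiger test compares explained variance with Fisher's z", {
  # hand construction: r2_exposure 0.04, r2_outcome ~0.001, n = 100,000
  n <- 1e5
  t_exp <- sqrt(0.04 * (n - 2) / (1 - 0.04))
  t_out <- sqrt(0.001 * (n - 2) / (1 - 0.001))
  h <- make_harmonized(t_exp * 0.01, 0.01, t_out * 0.01, 0.01)
  st <- mr_steiger(h)
  expect_true(st$correct_direction)
  expect_lt(st$pval, 1e-10)
  z_hand <- (atanh(0.2) - atanh(sqrt(0.001))) / sqrt(2 / (n - 3))
  expect_equal(st$zscore, z_hand, tolerance = 1e-6)
  # equal explained variance: z = 0, p = 1
  he <- make_harmonized(0.05, 0.01, 0.05, 0.01)
  ste <- mr_steiger(he)
  expect_equal(ste$zscore, 0)
  expect_equal(ste$pval, 1)
  # swapping exposure and outcome negates z and flips the flag
  hswap <- make_harmonized(t_out * 0.01, 0.01, t_exp * 0.01, 0.01)
  stswap <- mr_steiger(hswap)
  expect_equal(stswap$zscore, -st$zscore, tolerance = 1e-12)
  expect_false(stswap$correct_direction)
  expect_error(mr_steiger(h, n_exposure = 3, n_outcome = 100), "exceed 3")
})

test_that("leave-one-out produces one estimate per omitted variant", {
  h <- make_harmonized(rep(1, 5), rep(0.01, 5), rep(0.4, 5), rep(0.1, 5))
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), 5L)
  expect_equal(loo$beta, rep(0.4, 5))
  expect_error(mr_leave_one_out(h[1:2, ]), "three")
})

test_that("fixed-effect meta-analysis pools by inverse variance", {
  est <- dplyr::bind_rows(
    mr_wald_ratio(make_harmonized(1, 0.01, 0.6, 0.1)),
    mr_wald_ratio(make_harmonized(1, 0.01, 0.0, 0.3)))
  pooled <- meta_fixed(est)
  expect_equal(pooled$beta, 0.54, tolerance = 1e-10)
  expect_equal(pooled$se, sqrt(1 / (100 + 1 / 0.09)), tolerance = 1e-10)
  expect_equal(pooled$se, 0.0949, tolerance = 1e-3)
  # equal SEs: arithmetic mean; pooling with itself halves the variance
  e2 <- dplyr::bind_rows(mr_wald_ratio(make_harmonized(1, .01, .2, .1)),
                         mr_wald_ratio(make_harmonized(1, .01, .4, .1)))
  expect_equal(meta_fixed(e2)$beta, 0.3)
  self <- meta_fixed(dplyr::bind_rows(e2[1, ], e2[1, ]))
  expect_equal(self$se^2, e2$se[1]^2 / 2)
  expect_error(meta_fixed(e2[1, ]), ">= 2")
})

test_that("estimators are scale- and sign-equivariant", {
  set.seed(77)
  h <- make_harmonized(rnorm(6, 0.2, 0.03), runif(6, 0.005, 0.02),
                       rnorm(6, 0.1, 0.04), runif(6, 0.02, 0.05))
  for (fit in list(function(x) mr_ivw(x, "FE"),
                   function(x) mr_ivw(x, "MRE"),
                   function(x) mr_weighted_median(x, n_boot = 30, seed = 2),
                   function(x) mr_weighted_mode(x, n_boot = 30, seed = 2))) {
    base <- fit(h)
    c_scale <- 2.5
    scaled <- dplyr::mutate(h, beta_outcome = beta_outcome * c_scale,
                            se_outcome = se_outcome * c_scale)
    s <- fit(scaled)
    expect_equal(s$beta, c_scale * base$beta, tolerance = 1e-8)
    expect_equal(s$se, c_scale * base$se, tolerance = 1e-8)
    flipped <- dplyr::mutate(h, beta_exposure = -beta_exposure)
    expect_equal(fit(flipped)$beta, -base$beta, tolerance = 1e-8)
  }
})

test_that("the MRE standard error never undercuts the FE one", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(3:12, 1)
    h <- make_harmonized(rnorm(k, 0.2, 0.05), runif(k, 0.005, 0.02),
                         rnorm(k, 0.1, 0.06), runif(k, 0.01, 0.05))
    expect_gte(mr_ivw(h, "MRE")$se, mr_ivw(h, "FE")$se)
  }
})
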