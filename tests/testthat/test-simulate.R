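test_that("the generator is a pure function of truth and seed", {
  a <- simulate_gwas_from_truth(c(0.1, 0), c(0.3, 0.2), 5000, seed = 4)
  b <- simulate_gwas_from_truth(c(0.1, 0), c(0.3, 0.2), 5000, seed = 4)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_gwas_from_truth(c(0.1, 0), c(0.3, 0.2), 5000, seed = 5)
  expect_false(identical(a$beta, c$beta))
})

test_that("standard errors follow the standardized-trait model", {
  maf <- c(0.1, 0.3, 0.5)
  tab <- simulate_gwas_from_truth(rep(0, 3), maf, 10000, seed = 1)
  expect_equal(tab$se, 1 / sqrt(2 * maf * (1 - maf) * 10000))
  tab4 <- simulate_gwas_from_truth(rep(0, 3), maf, 40000, seed = 1)
  expect_equal(tab4$se, tab$se / 2)
  expect_error(simulate_gwas_from_truth(0, 0.6, 100), "0, 0.5")
  expect_error(simulate_gwas_from_truth(0, 0.3, 2), "exceed 2")
})

test_that("observed effects are unbiased within Monte-Carlo error", {
  # 2,000 iid replicates of one variant, checked against 3 se / sqrt(n)
  n_rep <- 2000
  truth_beta <- 0.12
  maf <- 0.25
  tab <- simulate_gwas_from_truth(rep(truth_beta, n_rep),
                                  rep(maf, n_rep), 5000, seed = 99)
  se <- tab$se[1]
  expect_lt(abs(mean(tab$beta) - truth_beta), 3 * se / sqrt(n_rep))
  expect_lt(abs(sd(tab$beta) - se), 3 * se / sqrt(n_rep))
})

test_that("generated tables satisfy the summary-statistic invariants", {
  for (seed in 1:5) {
    tab <- simulate_gwas_from_truth(rnorm(50, 0, 0.1),
                                    runif(50, 0.05, 0.5), 20000,
                                    seed = seed)
    expect_s3_class(tab, "gwas_tbl")  # constructor enforces invariants
    expect_true(all(tab$pval > 0 & tab$pval <= 1))
  }
})

test_that("the statin scenario encodes the mediation structure", {
  truth <- statin_truth(n_proteins = 10, mediator_index = 2, seed = 20)
  expect_equal(truth$delta + sum(truth$theta * truth$gamma),
               truth$total_effect)
  sc <- simulate_statin_scenario(truth)
  expect_equal(names(sc$proteins), truth$proteins)
  expect_equal(sc$ldl$variant_id, sc$instrument)
  expect_identical(attr(sc$disease, "trait_type"), "binary")
  # same seed twice: identical bundle
  sc2 <- simulate_statin_scenario(truth)
  expect_identical(as.data.frame(sc$ldl), as.data.frame(sc2$ldl))
  expect_identical(as.data.frame(sc$proteins[[3]]),
                   as.data.frame(sc2$proteins[[3]]))
})

test_that("pleiotropy configurations shape the pQTL panel as declared", {
  bal <- simulate_pqtl_panel(k = 200, theta = 0.5,
                             pleiotropy = list(type = "balanced",
                                               sd = 0.05), seed = 8)
  expect_lt(abs(mean(bal$truth$alpha)), 0.02)
  dir <- simulate_pqtl_panel(k = 20, theta = 0.5,
                             pleiotropy = list(type = "directional",
                                               prop = 0.4, mean = 0.5),
                             seed = 8)
  expect_equal(sum(dir$truth$alpha != 0), 8)
  expect_true(all(dir$truth$alpha[dir$truth$alpha != 0] == 0.5))
  out <- simulate_pqtl_panel(k = 12, theta = 0.5,
                             pleiotropy = list(type = "single_outlier",
                                               size = 10), seed = 8)
  expect_equal(sum(out$truth$alpha != 0), 1)
  expect_error(simulate_pqtl_panel(k = 0), "at least 1")
  expect_error(simulate_pqtl_panel(k = 5,
                                   pleiotropy = list(type = "bogus")),
               "unknown pleiotropy")
})

test_that("region pairs carry AR(1) LD and the declared causal layout", {
  rp <- simulate_region_pair(n_variants = 50, rho = 0.5,
                             causal = "distinct", seed = 14)
  expect_equal(rp$ld$r[1, 2], 0.5)
  expect_equal(rp$ld$r[1, 3], 0.25)
  idx <- rp$truth$causal_indices
  expect_length(idx, 2)
  # distinct causal variants are effectively unlinked
  expect_lt(rp$ld$r[idx[1], idx[2]]^2, 0.01)
  shared <- simulate_region_pair(n_variants = 50, causal = "shared",
                                 seed = 14)
  expect_length(shared$truth$causal_indices, 1)
  expect_error(simulate_region_pair(rho = 1), "rho")
  # determinism
  a <- simulate_region_pair(n_variants = 30, seed = 2)
  b <- simulate_region_pair(n_variants = 30, seed = 2)
  expect_identical(a$trait1$beta, b$trait1$beta)
})
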