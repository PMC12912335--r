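test_that("BH adjustment matches the step-up rule computed by hand", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.03, 0.5)),
               c(0.004, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("q-values dominate p-values and are permutation-invariant", {
  set.seed(8)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("the step-1 screen recovers planted proteins with signed effects", {
  n_prot <- 100
  planted_idx <- c(3, 40, 77)
  gamma <- rep(0, n_prot)
  gamma[planted_idx] <- c(0.5, -0.5, 0.5)
  truth_names <- NULL
  recovered <- matrix(FALSE, 10, 3)
  false_pos <- integer(10)
  sign_ok <- TRUE
  for (r in 1:10) {
    truth <- statin_truth(n_proteins = n_prot, gamma = gamma,
                          theta = rep(0, n_prot), seed = 200 + r)
    sc <- simulate_statin_scenario(truth)
    screen <- step1_screen(sc$instrument, sc$ldl, sc$proteins)
    hits <- screen[screen$selected, ]
    planted_names <- truth$proteins[planted_idx]
    recovered[r, ] <- planted_names %in% hits$protein
    false_pos[r] <- sum(!hits$protein %in% planted_names)
    found <- hits[hits$protein %in% planted_names, ]
    sign_ok <- sign_ok &&
      all(sign(found$beta) ==
            sign(gamma[planted_idx][match(found$protein, planted_names)]))
    sign_ok <- sign_ok && all(abs(found$beta -
      gamma[planted_idx][match(found$protein, planted_names)]) < 0.35)
  }
  # each planted protein recovered in nearly every replicate, with the
  # right sign and magnitude; chance false positives stay near the BH rate
  expect_true(all(colMeans(recovered) >= 0.8))
  expect_true(sign_ok)
  expect_lte(mean(false_pos), 0.5)
})

test_that("the screen is invariant to the instrument's coded allele", {
  truth <- statin_truth(n_proteins = 20, mediator_index = 4, seed = 6)
  sc <- simulate_statin_scenario(truth)
  screen <- step1_screen(sc$instrument, sc$ldl, sc$proteins)
  flip <- function(tab) {
    flipped <- dplyr::mutate(
      tibble::as_tibble(tab), beta = -beta, eaf = 1 - eaf,
      effect_allele = "G", other_allele = "A")
    gwas_table(flipped, trait_name = attr(tab, "trait_name"))
  }
  sc_flipped <- list(ldl = flip(sc$ldl),
                     proteins = lapply(sc$proteins, flip))
  screen2 <- step1_screen(sc$instrument, sc_flipped$ldl,
                          sc_flipped$proteins)
  expect_equal(screen2$beta, screen$beta, tolerance = 1e-12)
  expect_error(step1_screen("rs_nowhere", sc$ldl, sc$proteins), "absent")
})

test_that("proteins missing the instrument are reported, not fatal", {
  truth <- statin_truth(n_proteins = 5, seed = 3)
  sc <- simulate_statin_scenario(truth)
  sc$proteins[[2]] <- make_gwas("rs_other", 0.1, 0.02)
  screen <- step1_screen(sc$instrument, sc$ldl, sc$proteins)
  expect_equal(nrow(screen), 4L)
  expect_equal(attr(screen, "skipped"), truth$proteins[2])
})

test_that("step-2 runs IVW plus sensitivity, FDR across proteins", {
  truth <- statin_truth(n_proteins = 3, mediator_index = 1,
                        gamma = c(-0.63, -0.5, 0.4),
                        theta = c(0.6, 0, 0), k_pqtl = 6, seed = 13)
  cfg <- simulate_two_step_scenario(truth)
  sets <- lapply(cfg$pqtl, select_pqtl_instruments)
  s2 <- step2_outcome_mr(sets, cfg$disease, n_boot = 30, n_sim = 200,
                         seed = 4)
  expect_equal(sort(s2$ivw$protein), sort(truth$proteins))
  med <- s2$ivw[s2$ivw$protein == truth$proteins[1], ]
  expect_true(med$selected)
  expect_lt(abs(med$beta - 0.6), 0.15)
  expect_equal(med$model, "MRE")
  expect_true(all(c("ivw", "weighted_median", "weighted_mode") %in%
                    s2$all_methods$method))
  expect_s3_class(s2$details[[truth$proteins[1]]]$presso, "mr_presso")
})

test_that("two-variant sets fall back to FE and skip sensitivity", {
  pan <- simulate_pqtl_panel(k = 2, theta = 0.5, seed = 31)
  s2 <- step2_outcome_mr(list(p1 = pan$exposure), pan$outcome, seed = 1)
  expect_equal(s2$ivw$model, "FE")
  expect_match(s2$skipped$reason, "only 2 variant")
  expect_false("weighted_median" %in% s2$all_methods$method)
})

test_that("mediator selection encodes the direction-consistency rule", {
  step1 <- tibble::tibble(protein = c("PLA2G7", "COL6A3", "NULLP"),
                          beta = c(-0.63, 0.42, 0.5))
  step2 <- tibble::tibble(protein = c("PLA2G7", "COL6A3", "NULLP"),
                          beta = c(0.60, 0.30, 0))
  dec <- select_mediators(step1, step2, total_effect_sign = -1)
  expect_true(dec$consistent[dec$protein == "PLA2G7"])
  expect_false(dec$consistent[dec$protein == "COL6A3"])
  expect_false(dec$consistent[dec$protein == "NULLP"])
  expect_equal(dec$reason[dec$protein == "NULLP"], "no step-2 effect")
})

test_that("mediation identities hold exactly, with range warnings", {
  m <- mediation_effects(-0.63, 0.6, -0.49, mediator = "PLA2G7")
  expect_identical(m$indirect_effect, -0.63 * 0.6)
  expect_identical(m$proportion_mediated, (-0.63 * 0.6) / -0.49)
  expect_equal(mediation_effects(1, -0.49, -0.49)$proportion_mediated, 1)
  expect_equal(mediation_effects(0, 0.6, -0.49)$proportion_mediated, 0)
  expect_warning(out <- mediation_effects(0.5, 0.6, -0.49), "outside")
  expect_true(out$out_of_range)
  expect_error(mediation_effects(0.1, 0.2, 0), "nonzero")
})

test_that("replication logic distinguishes replicated, failed and missing", {
  primary <- tibble::tibble(protein = c("PLA2G7", "ANGPTL1", "PTPRZ1"),
                            beta = c(-0.63, -0.42, -0.38),
                            pval = c(1.9e-10, 2.6e-5, 3.9e-5))
  replication <- tibble::tibble(protein = c("PLA2G7", "ANGPTL1"),
                                beta = c(-0.47, 0.01),
                                pval = c(9.42e-5, 0.96))
  chk <- replication_check(primary, replication)
  expect_true(chk$replicated[chk$protein == "PLA2G7"])
  expect_false(chk$replicated[chk$protein == "ANGPTL1"])
  expect_true(chk$missing[chk$protein == "PTPRZ1"])
  expect_true(is.na(chk$replicated[chk$protein == "PTPRZ1"]))
})
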