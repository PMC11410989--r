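# Rejection-rate harness.

test_that("MCSE follows the binomial formula and estimates are reproducible", {
  expect_equal(mcse_proportion(0.5, 500), sqrt(0.25 / 500))
  expect_equal(mcse_proportion(0, 100), 0)

  sc <- pleiotropy_scenario(n = 3000, n_chp = 2, n_cnhp = 2, rho_zc = 0.08)
  a <- run_power_study(sc, tests = c("grt", "bonf", "indep", "r2perm"),
                       n_sim = 12, n_perm = 99, seed = 5)
  b <- run_power_study(sc, tests = c("grt", "bonf", "indep", "r2perm"),
                       n_sim = 12, n_perm = 99, seed = 5)
  expect_identical(a$p_values, b$p_values)
  expect_true(all(a$estimates$rejection_pct >= 0 & a$estimates$rejection_pct <= 1))
  expect_equal(a$estimates$mcse,
               mcse_proportion(a$estimates$rejection_pct, 12))
})

test_that("all four tests are computed on the same dataset per repetition", {
  sc <- pleiotropy_scenario(n = 2000, n_chp = 1, n_cnhp = 1, rho_zc = 0.1)
  ps <- run_power_study(sc, tests = c("grt", "r2perm", "bonf", "indep"),
                        n_sim = 6, n_perm = 99, seed = 11)
  expect_identical(colnames(ps$p_values), c("grt", "r2perm", "bonf", "indep"))
  expect_false(anyNA(ps$p_values))
  # bonf and indep share p_min, so they order identically
  expect_true(all((ps$p_values[, "bonf"] >= ps$p_values[, "indep"])))
})

test_that("early stopping does not change rejection decisions in the harness", {
  sc <- pleiotropy_scenario(n = 2500, n_chp = 2, n_cnhp = 2, rho_zc = 0.05)
  fast <- run_power_study(sc, tests = "grt", n_sim = 15, n_perm = 200,
                          seed = 9, early_stop = TRUE)
  slow <- run_power_study(sc, tests = "grt", n_sim = 15, n_perm = 200,
                          seed = 9, early_stop = FALSE)
  expect_identical(fast$estimates$rejection_pct, slow$estimates$rejection_pct)
  expect_identical((fast$p_values < 0.05), (slow$p_values < 0.05))
})

test_that("every test holds its type-I error under both null mechanisms", {
  # selection scenario, whole cohort (no selection applied)
  sc_a <- selection_scenario(n_invited = 1500, n_cs = 3, n_cns = 2,
                             r2_zx = 0.05, r2_cxs = 0.1)
  null_a <- run_power_study(sc_a, tests = c("grt", "bonf", "indep", "r2perm"),
                            n_sim = 300, n_perm = 99, seed = 21,
                            select = FALSE)
  # pleiotropy scenario, non-pleiotropic SNP
  sc_b <- pleiotropy_scenario(n = 1500, n_chp = 2, n_cnhp = 3, rho_zc = 0.1)
  null_b <- run_power_study(sc_b, tests = c("grt", "bonf", "indep", "r2perm"),
                            n_sim = 300, n_perm = 99, seed = 22,
                            instrument = "nhp")
  bound <- 2.58 * sqrt(0.05 * 0.95 / 300)
  for (est in list(null_a$estimates, null_b$estimates)) {
    expect_true(all(est$rejection_pct < 0.05 + bound))
    # permutation tests are exact, not conservative
    perm_rows <- est$test %in% c("grt", "r2perm")
    expect_true(all(est$rejection_pct[perm_rows] > 0.05 - bound))
  }
})

test_that("power rises with the pleiotropic effect and detects strong signals", {
  p_small <- run_power_study(pleiotropy_scenario(n = 4000, rho_zc = 0.01,
                                                 n_chp = 2, n_cnhp = 2),
                             tests = "grt", n_sim = 30, n_perm = 199, seed = 3)
  p_large <- run_power_study(pleiotropy_scenario(n = 4000, rho_zc = 0.1,
                                                 n_chp = 2, n_cnhp = 2),
                             tests = "grt", n_sim = 30, n_perm = 199, seed = 3)
  expect_gte(p_large$estimates$rejection_pct,
             p_small$estimates$rejection_pct)
  expect_gt(p_large$estimates$rejection_pct, 0.8)
})

test_that("selection power study detects a strong collider mechanism", {
  sc <- selection_scenario(n_invited = 40000, p_selected = 0.1,
                           n_cs = 2, n_cns = 1, r2_zx = 0.3,
                           r2_cxs = 0.5, r2_cx_total = 0.3)
  ps <- run_power_study(sc, tests = c("grt", "indep"), n_sim = 15,
                        n_perm = 199, seed = 8)
  expect_gt(ps$estimates$rejection_pct[ps$estimates$test == "grt"], 0.9)
  # the same mechanism is invisible without conditioning on selection
  ps0 <- run_power_study(sc, tests = "grt", n_sim = 15, n_perm = 199,
                         seed = 8, select = FALSE)
  expect_lt(ps0$estimates$rejection_pct, 0.35)
})

test_that("halving the covariate set cannot systematically raise power", {
  sc_full <- selection_scenario(n_invited = 30000, p_selected = 0.1,
                                n_cs = 4, n_cns = 2, r2_zx = 0.3,
                                r2_cxs = 0.3, r2_cx_total = 0.3)
  sc_half <- selection_scenario(n_invited = 30000, p_selected = 0.1,
                                n_cs = 4, n_cns = 2, r2_zx = 0.3,
                                r2_cxs = 0.3, r2_cx_total = 0.3,
                                covariate_subset_fraction = 0.5)
  p_full <- run_power_study(sc_full, tests = "grt", n_sim = 25,
                            n_perm = 199, seed = 12)
  p_half <- run_power_study(sc_half, tests = "grt", n_sim = 25,
                            n_perm = 199, seed = 12)
  expect_lte(p_half$estimates$rejection_pct,
             p_full$estimates$rejection_pct + 0.15)
})
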