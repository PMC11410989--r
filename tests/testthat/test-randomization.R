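# Permutation engine and the two permutation tests.

test_that("vectorized engine matches a per-permutation loop oracle (both routes)", {
  # continuous instrument -> gather route
  d <- make_null_data(m = 150, n = 4, seed = 21, kind = "grs")
  ctx <- grtest:::balance_context(d$z, d$C, quiet = TRUE)
  res <- grtest:::run_permutations(ctx, c("mahalanobis", "max_r2"), 60,
                                   seed = 17, chunk_size = 60)
  idx <- grtest:::full_perm_chunk(17, 150, 1, 60)
  md_oracle <- sapply(1:60, function(j) mahalanobis_distance(d$z[idx[, j]], d$C)$md)
  r2_oracle <- sapply(1:60, function(j) max(cor(d$z[idx[, j]], d$C)^2))
  expect_equal(res$mahalanobis$perm_stats, md_oracle, tolerance = 1e-10)
  expect_equal(res$max_r2$perm_stats, r2_oracle, tolerance = 1e-10)

  # dosage instrument -> subset-sum route
  d2 <- make_null_data(m = 200, n = 3, seed = 22, kind = "dosage")
  ctx2 <- grtest:::balance_context(d2$z, d2$C, quiet = TRUE)
  g <- grtest:::ctx_groups(ctx2)
  expect_false(is.null(g))
  res2 <- grtest:::run_permutations(ctx2, "mahalanobis", 40, seed = 23,
                                    chunk_size = 40)
  sidx <- grtest:::subset_perm_chunk(23, ctx2$m, g$K, 1, 40)
  md2_oracle <- sapply(1:40, function(j) {
    zp <- rep(g$v0, ctx2$m)
    t0 <- 0
    for (a in seq_along(g$values)) {
      zp[sidx[(t0 + 1):(t0 + g$sizes[a]), j]] <- g$values[a]
      t0 <- t0 + g$sizes[a]
    }
    mahalanobis_distance(zp, d2$C)$md
  })
  expect_equal(res2$mahalanobis$perm_stats, md2_oracle, tolerance = 1e-10)
})

test_that("results are deterministic in (z, C, seed, n_perm)", {
  d <- make_null_data(m = 80, n = 3, seed = 4)
  a <- global_randomization_test(d$z, d$C, n_perm = 99, seed = 42)
  b <- global_randomization_test(d$z, d$C, n_perm = 99, seed = 42)
  expect_identical(a$perm_stats, b$perm_stats)
  expect_identical(a$p_value, b$p_value)
  c_ <- global_randomization_test(d$z, d$C, n_perm = 99, seed = 43)
  expect_false(identical(a$perm_stats, c_$perm_stats))
})

test_that("P value rules behave as specified, including exact zero", {
  # make the observed statistic overwhelming: covariate equal to z
  set.seed(5)
  z <- rnorm(60)
  C <- cbind(z + rnorm(60, sd = 1e-6), rnorm(60))
  paper <- global_randomization_test(z, C, n_perm = 199, seed = 1)
  add1 <- global_randomization_test(z, C, n_perm = 199, seed = 1,
                                    p_rule = "add_one")
  expect_identical(paper$p_value, 0)
  expect_equal(add1$p_value, 1 / 200)
  expect_true(all(paper$perm_stats < paper$observed))
})

test_that("P value is invariant to rescaling of z and of the covariates", {
  d <- make_null_data(m = 100, n = 4, seed = 6)
  base <- global_randomization_test(d$z, d$C, n_perm = 199, seed = 9)
  z10 <- global_randomization_test(10 * d$z, d$C, n_perm = 199, seed = 9)
  crs <- global_randomization_test(d$z, sweep(d$C, 2, c(100, 0.01, 3, 42), `*`),
                                   n_perm = 199, seed = 9)
  expect_identical(base$p_value, z10$p_value)
  expect_identical(base$p_value, crs$p_value)
  # the statistic itself scales with 1/scale(z)
  expect_equal(z10$observed, base$observed / 10, tolerance = 1e-10)
})

test_that("max-r2 test: identity statistic and algebraic relation to meandiff", {
  set.seed(8)
  z <- rnorm(50)
  res <- max_r2_permutation_test(z, cbind(z), n_perm = 99, seed = 2)
  expect_equal(res$observed, 1)
  expect_identical(res$p_value, 0)

  d <- make_null_data(m = 70, n = 5, seed = 30)
  r2 <- max_r2_permutation_test(d$z, d$C, n_perm = 9, seed = 3)
  md <- mean_difference(d$z, d$C)
  expect_equal(r2$observed,
               max((md * sd(d$z) / apply(d$C, 2, sd))^2),
               tolerance = 1e-12)
})

test_that("null P values are approximately Uniform(0,1)", {
  n_rep <- 1000
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- make_null_data(m = 40, n = 3, seed = 2000 + i)
    p[i] <- global_randomization_test(d$z, d$C, n_perm = 99,
                                      seed = 2000 + i)$p_value
  }
  # paper rule on a null: p is uniform on {0, 1/99, ..., 1}
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("joint row shuffles leave the permutation distribution unchanged", {
  d <- make_null_data(m = 120, n = 3, seed = 44)
  set.seed(99)
  ord <- sample(120)
  a <- global_randomization_test(d$z, d$C, n_perm = 299, seed = 5)
  b <- global_randomization_test(d$z[ord], d$C[ord, ], n_perm = 299, seed = 5)
  expect_equal(a$observed, b$observed, tolerance = 1e-10)
  expect_gt(suppressWarnings(ks.test(a$perm_stats, b$perm_stats)$p.value), 0.01)
})

test_that("adding a strongly associated covariate cannot weaken the max-r2 signal", {
  set.seed(12)
  z <- rnorm(200)
  C <- matrix(rnorm(600), 200, 3)
  strong <- 0.8 * z + rnorm(200, sd = 0.6)
  p_without <- max_r2_permutation_test(z, C, n_perm = 199, seed = 6)$p_value
  p_with <- max_r2_permutation_test(z, cbind(C, strong), n_perm = 199,
                                    seed = 6)$p_value
  expect_lte(p_with, p_without + 0.02)
})

test_that("early stopping preserves the rejection decision", {
  for (i in 1:20) {
    d <- make_null_data(m = 60, n = 3, seed = 500 + i)
    ctx <- grtest:::balance_context(d$z, d$C, quiet = TRUE)
    full <- grtest:::run_permutations(ctx, "mahalanobis", 200, seed = i,
                                      chunk_size = 25)
    stopc <- grtest:::stop_count_for(0.05, 200, "paper")
    trunc <- grtest:::run_permutations(ctx, "mahalanobis", 200, seed = i,
                                       chunk_size = 25, stop_count = stopc)
    p_full <- grtest:::perm_p_value(full$mahalanobis$count, 200, "paper")
    p_trunc <- grtest:::perm_p_value(trunc$mahalanobis$count,
                                     trunc$mahalanobis$n_used, "paper")
    expect_identical(p_full < 0.05, p_trunc < 0.05)
  }
})
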