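# Balance statistics: per-covariate mean differences and the generalized
# Mahalanobis distance.

test_that("mean difference equals the simple-regression slope", {
  # perfect correlation with equal SDs gives slope 1
  expect_equal(unname(mean_difference(c(0, 0, 1, 1), cbind(c(0, 0, 1, 1)))), 1)

  # exactly orthogonal covariate gives 0
  z <- c(0, 1, 2, 0, 1, 2)
  c0 <- c(1, -1, 0, -1, 1, 0)  # cor(z, c0) = 0
  expect_equal(unname(mean_difference(z, cbind(c0))), 0)

  # least-squares oracle on the printed 6-point example
  c1 <- c(0.1, 0.9, 2.2, -0.2, 1.1, 1.9)
  expect_equal(unname(mean_difference(z, cbind(c1))),
               unname(coef(lm(c1 ~ z))[2]), tolerance = 1e-10)

  # oracle across instrument kinds on random fixtures
  for (kind in c("grs", "dosage", "binary")) {
    d <- make_null_data(m = 80, n = 4, seed = 11, kind = kind)
    md <- mean_difference(d$z, d$C)
    slopes <- apply(d$C, 2, function(y) unname(coef(lm(y ~ d$z))[2]))
    expect_equal(unname(md), unname(slopes), tolerance = 1e-10)
  }
})

test_that("generalized MD reduces to the two-group form for binary instruments", {
  # 20-row fixture, single covariate: |mean diff| / SD
  set.seed(3)
  zb <- rep(c(0, 1), each = 10)
  C1 <- matrix(rnorm(20), ncol = 1)
  b <- mahalanobis_distance(zb, C1)
  oracle <- abs(mean(C1[zb == 1, ]) - mean(C1[zb == 0, ])) / sd(C1)
  expect_equal(b$md, oracle, tolerance = 1e-10)

  # multi-covariate random fixtures
  for (seed in 1:3) {
    d <- make_null_data(m = 60, n = 4, seed = seed, kind = "binary")
    g <- mahalanobis_distance(d$z, d$C)
    diff <- colMeans(d$C[d$z == 1, , drop = FALSE]) -
      colMeans(d$C[d$z == 0, , drop = FALSE])
    two_group <- sqrt(drop(t(diff) %*% solve(cov(d$C)) %*% diff))
    expect_equal(g$md, two_group, tolerance = 1e-10)
  }
})

test_that("MD is invariant to covariate rescaling but scales inversely with z", {
  d <- make_null_data(m = 120, n = 5, seed = 7)
  base <- mahalanobis_distance(d$z, d$C)

  scales <- c(0.01, 3, 100, 7e3, 0.5)
  rescaled <- mahalanobis_distance(d$z, sweep(d$C, 2, scales, `*`))
  expect_equal(rescaled$md, base$md, tolerance = 1e-8)

  # affine recoding (shift + scale)
  affine <- mahalanobis_distance(d$z, sweep(d$C, 2, scales, `*`) + 5)
  expect_equal(affine$md, base$md, tolerance = 1e-8)

  # instrument scale: md(k * z) = md(z) / k
  zk <- 10 * d$z
  expect_equal(mahalanobis_distance(zk, d$C)$md, base$md / 10,
               tolerance = 1e-10)
})

test_that("MD is ~0 when every covariate is orthogonal to z", {
  d <- make_null_data(m = 90, n = 3, seed = 5)
  # residualize each covariate on z so meandiff is exactly zero
  C_orth <- apply(d$C, 2, function(y) resid(lm(y ~ d$z)))
  colnames(C_orth) <- colnames(d$C)
  b <- mahalanobis_distance(d$z, C_orth)
  expect_lt(b$md, 1e-10)
  expect_equal(unname(b$meandiff), rep(0, 3), tolerance = 1e-12)
})

test_that("degenerate inputs raise informative errors; singular covariance falls back", {
  d <- make_null_data(m = 50, n = 3, seed = 2)
  Cbad <- d$C
  Cbad[, 2] <- 4.2
  colnames(Cbad) <- c("a", "flat", "b")
  expect_error(mahalanobis_distance(d$z, Cbad), "flat")
  expect_error(mean_difference(rep(1, 50), d$C), "zero variance")
  Cinf <- d$C
  Cinf[4, 1] <- Inf
  expect_error(mahalanobis_distance(d$z, Cinf), "non-finite")

  # duplicated column: singular correlation -> pseudo-inverse with warning
  Cdup <- cbind(d$C, dup = d$C[, 1])
  expect_warning(b <- mahalanobis_distance(d$z, Cdup), "pseudo-inverse")
  expect_equal(b$cov_rank, 3)
  # on the rank-deficient set the MD must match the reduced-set MD
  expect_equal(b$md, mahalanobis_distance(d$z, d$C)$md, tolerance = 1e-6)
})

test_that("complete-case filtering drops rows jointly and reports the count", {
  d <- make_null_data(m = 40, n = 2, seed = 9)
  z <- d$z
  C <- d$C
  z[3] <- NA
  C[10, 2] <- NA
  expect_message(b <- mahalanobis_distance(z, C), "removed 2 of 40")
  expect_equal(b$n_obs, 38)
})

test_that("bias transform divides by the exposure mean difference and preserves MD", {
  expect_equal(bias_transform(c(0.2, -0.1), c(0, 0, 1, 1), c(0.1, -0.1, 0.35, 0.65)),
               c(0.4, -0.2))

  d <- make_null_data(m = 150, n = 4, seed = 13)
  x <- 0.5 * d$z + rnorm(150)
  md <- mean_difference(d$z, d$C)
  bias <- bias_transform(md, d$z, x)
  dx <- unname(mean_difference(d$z, cbind(x)))
  expect_equal(bias, md / dx, tolerance = 1e-12)

  # affine invariance: MD computed on the bias scale equals MD on the raw scale
  b_raw <- mahalanobis_distance(d$z, d$C)
  scale_mat <- diag(1 / dx, 4)
  expect_equal(sqrt(drop(t(bias) %*% solve(scale_mat %*% cov(d$C) %*% scale_mat) %*% bias)),
               b_raw$md, tolerance = 1e-8)

  # zero instrument-exposure association -> error
  x_orth <- resid(lm(rnorm(150) ~ d$z))
  expect_error(bias_transform(md, d$z, x_orth), "relevance")
})
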