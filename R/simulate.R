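# Data-generating mechanisms for the two simulation studies:
#   A. selection (collider) bias: covariates and exposure drive study
#      participation, inducing instrument-covariate association within the
#      selected subsample;
#   B. horizontal pleiotropy: a SNP directly shifts part of the covariate set.

#' Selection-bias simulation scenario
#'
#' Parameter bundle for the collider-bias data-generating mechanism. A cohort
#' of `n_invited` individuals carries a standard-normal genetic risk score
#' `z`, unit-variance covariates `C` (blocks `cs_*` affecting selection and
#' `cns_*` not affecting selection), and a unit-variance exposure `x` built
#' from `z` and all covariates. Participation is a Gaussian
#' liability-threshold mechanism driven by `x` and the `cs` block, calibrated
#' so a fraction `p_selected` participates. Within participants, conditioning
#' on the selection collider induces instrument-covariate association even
#' though `z` is independent of `C` in the full cohort.
#'
#' @param n_invited invited cohort size (default 920,000: one tenth of a
#'   9.2-million invitation campaign with realistic scale).
#' @param p_selected participation fraction (default 0.055, a 5.5% recruitment
#'   rate).
#' @param n_cs,n_cns number of covariates affecting / not affecting selection.
#' @param r_c pairwise covariate correlation: a constant in (-1, 1), or
#'   `"random"` to draw each pairwise correlation from N(0, `r_c_sd`) and
#'   repair to the nearest positive-definite correlation matrix.
#' @param r_c_sd SD of random pairwise correlations (default 0.1).
#' @param r2_zx variance of the exposure explained by the instrument.
#' @param r2_cxs latent-scale variance share of the selection liability
#'   explained jointly by `x` and the `cs` covariates.
#' @param r2_cx_total total variance of the exposure explained by all
#'   covariates jointly (held constant as covariate counts change; equal
#'   per-covariate coefficients). Default 0.2.
#' @param selection_split fraction of `r2_cxs` carried by the exposure path;
#'   the remainder is spread equally over the `cs` covariates (default 0.5,
#'   an equal split).
#' @param covariate_subset_fraction fraction of each covariate block made
#'   available to the tests (see [covariate_subset()]).
#' @return object of class `selection_scenario`.
#' @export
selection_scenario <- function(n_invited = 920000, p_selected = 0.055,
                               n_cs = 10, n_cns = 2,
                               r_c = 0, r_c_sd = 0.1,
                               r2_zx = 0.05, r2_cxs = 0.05,
                               r2_cx_total = 0.2, selection_split = 0.5,
                               covariate_subset_fraction = 1) {
  stopifnot(n_invited >= 10, n_cs >= 1, n_cns >= 0,
            p_selected > 0, p_selected < 1,
            r2_zx >= 0, r2_zx < 1, r2_cxs >= 0, r2_cxs < 1,
            r2_cx_total >= 0, r2_cx_total < 1,
            selection_split >= 0, selection_split <= 1,
            covariate_subset_fraction > 0, covariate_subset_fraction <= 1)
  if (r2_zx + r2_cx_total >= 1) {
    stop("infeasible variance budget: r2_zx + r2_cx_total must be < 1",
         call. = FALSE)
  }
  check_r_c(r_c)
  structure(
    list(n_invited = as.integer(n_invited), p_selected = p_selected,
         n_cs = as.integer(n_cs), n_cns = as.integer(n_cns),
         r_c = r_c, r_c_sd = r_c_sd,
         r2_zx = r2_zx, r2_cxs = r2_cxs,
         r2_cx_total = r2_cx_total, selection_split = selection_split,
         covariate_subset_fraction = covariate_subset_fraction),
    class = c("selection_scenario", "grt_scenario"))
}

#' Horizontal-pleiotropy simulation scenario
#'
#' Parameter bundle for the pleiotropy data-generating mechanism: two
#' biallelic SNPs drawn as Hardy-Weinberg dosages at effect allele frequency
#' `effect_allele_freq` (so genotype probabilities \eqn{(1-q)^2, 2q(1-q),
#' q^2}; 0.64 / 0.32 / 0.04 at q = 0.2). The horizontally pleiotropic SNP
#' `z_hp` shifts each of `n_chp` covariates with correlation `rho_zc`
#' (variance explained `rho_zc^2`); the non-pleiotropic SNP `z_nhp` and the
#' remaining `n_cnhp` covariates are independent of it. All covariates have
#' unit variance; residual inter-covariate correlation follows `r_c`.
#'
#' @param n sample size (default 500,000, a UK Biobank-scale cohort).
#' @param n_chp,n_cnhp numbers of covariates affected / unaffected by the
#'   pleiotropic SNP.
#' @param rho_zc correlation between the (standardized) pleiotropic SNP
#'   dosage and each affected covariate.
#' @param effect_allele_freq effect allele frequency (default 0.2).
#' @inheritParams selection_scenario
#' @return object of class `pleiotropy_scenario`.
#' @export
pleiotropy_scenario <- function(n = 500000, n_chp = 5, n_cnhp = 5,
                                rho_zc = 0.001, r_c = 0, r_c_sd = 0.1,
                                effect_allele_freq = 0.2) {
  stopifnot(n >= 10, n_chp >= 1, n_cnhp >= 0,
            abs(rho_zc) < 1,
            effect_allele_freq > 0, effect_allele_freq < 1)
  check_r_c(r_c)
  structure(
    list(n = as.integer(n), n_chp = as.integer(n_chp),
         n_cnhp = as.integer(n_cnhp), rho_zc = rho_zc,
         r_c = r_c, r_c_sd = r_c_sd,
         effect_allele_freq = effect_allele_freq),
    class = c("pleiotropy_scenario", "grt_scenario"))
}

check_r_c <- function(r_c) {
  ok <- (is.numeric(r_c) && length(r_c) == 1L && abs(r_c) < 1) ||
    (is.character(r_c) && identical(r_c, "random"))
  if (!ok) stop("'r_c' must be a correlation in (-1, 1) or \"random\"",
                call. = FALSE)
  invisible(r_c)
}

# Covariate correlation matrix: constant (equicorrelation) or random pairwise
# N(0, sd) repaired to the nearest positive-definite correlation matrix
# (Higham projection via Matrix::nearPD, eigenvalue floor 1e-8).
build_correlation_matrix <- function(n, r_c, r_c_sd, seed, stream) {
  if (is.numeric(r_c)) {
    R <- matrix(r_c, n, n)
    diag(R) <- 1
    if (r_c < 0 && n > 1) {
      # equicorrelation is PD only for r > -1/(n-1)
      if (r_c <= -1 / (n - 1)) {
        stop("constant correlation ", r_c, " is not positive definite for ",
             n, " covariates", call. = FALSE)
      }
    }
    attr(R, "repaired") <- FALSE
    return(R)
  }
  off <- rnorm_stream(seed, stream, n * (n - 1) / 2) * r_c_sd
  R <- diag(n)
  R[upper.tri(R)] <- off
  R <- R + t(R)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  if (min(ev) < 1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE, eig.tol = 1e-8,
                                  posd.tol = 1e-8)$mat)
    repaired <- TRUE
  }
  attr(R, "repaired") <- repaired
  R
}

# Internal stream layout per dataset seed:
#   stream 1: correlation draws, 2: covariate normals, 3: instrument,
#   4: exposure noise, 5: selection noise / second SNP.

#' Generate one selection-bias dataset
#'
#' Draws a full invited cohort under a [selection_scenario()]: multivariate
#' normal covariates, an independent standard-normal genetic risk score `z`,
#' the exposure `x`, and a liability-threshold participation indicator.
#'
#' Construction, writing \eqn{s} for the latent selection liability:
#' \itemize{
#'   \item `C` multivariate normal, mean 0, unit variances, correlation per
#'     the scenario; `z ~ N(0,1)` independent of `C`.
#'   \item `x = sqrt(r2_zx) z + a * rowSums(C) + e`, with `a` chosen so the
#'     covariates jointly explain `r2_cx_total` of the unit exposure
#'     variance.
#'   \item `s = eta + e_s` with `eta` a weighted sum of `x` and the `cs`
#'     covariates, rescaled analytically so `Var(eta) = r2_cxs` exactly
#'     (`Var(e_s) = 1 - r2_cxs`), and the threshold `qnorm(1 - p_selected)`
#'     so that the expected participation fraction equals `p_selected`.
#' }
#'
#' @param scenario a [selection_scenario()].
#' @param seed integer master seed.
#' @return list of class `selection_data` with `z`, `C`, `x`,
#'   `selected` (logical mask), `scenario`, `seed`, and the analytic
#'   selection parameters in `details`.
#' @export
generate_selection_dataset <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "selection_scenario"))
  seed <- check_seed(seed)
  sc <- scenario
  m <- sc$n_invited
  n <- sc$n_cs + sc$n_cns
  R <- build_correlation_matrix(n, sc$r_c, sc$r_c_sd, seed, 1)

  C <- rnorm_mat_stream(seed, 2, m, n)
  if (!(is.numeric(sc$r_c) && sc$r_c == 0)) C <- C %*% chol(R)
  colnames(C) <- c(sprintf("cs_%d", seq_len(sc$n_cs)),
                   if (sc$n_cns > 0) sprintf("cns_%d", seq_len(sc$n_cns)))

  # GRS draws carry a 16-bit quantile-cell representation (empirical risk
  # scores are finitely granular) which also enables the fast coded
  # permutation kernel at this sample size
  z <- rnorm_coded_stream(seed, 3, m)

  # exposure: equal covariate coefficients, total covariate share fixed
  a <- if (sc$r2_cx_total > 0) sqrt(sc$r2_cx_total / sum(R)) else 0
  b_z <- sqrt(sc$r2_zx)
  sd_e <- sqrt(1 - sc$r2_zx - sc$r2_cx_total)
  x <- b_z * z + a * rowSums(C) + sd_e * rnorm_stream(seed, 4, m)

  # selection liability
  s_idx <- seq_len(sc$n_cs)
  R_ss <- sum(R[s_idx, s_idx])
  u0 <- sqrt(sc$r2_cxs * sc$selection_split)
  v0 <- if (sc$r2_cxs > 0 && sc$selection_split < 1) {
    sqrt(sc$r2_cxs * (1 - sc$selection_split) / R_ss)
  } else 0
  cov_x_cs_sum <- a * sum(R[, s_idx])       # Cov(x, sum of cs covariates)
  var_eta0 <- u0^2 + v0^2 * R_ss + 2 * u0 * v0 * cov_x_cs_sum
  k <- if (var_eta0 > 0) sqrt(sc$r2_cxs / var_eta0) else 0
  eta <- if (k > 0) k * (u0 * x + v0 * rowSums(C[, s_idx, drop = FALSE])) else 0
  s_star <- eta + sqrt(1 - sc$r2_cxs) * rnorm_stream(seed, 5, m)
  tau <- qnorm(1 - sc$p_selected)

  structure(
    list(z = z, C = C, x = x, selected = s_star > tau,
         scenario = sc, seed = seed,
         details = list(correlation = R, a = a, b_z = b_z,
                        u = k * u0, v = k * v0, tau = tau,
                        repaired = isTRUE(attr(R, "repaired")))),
    class = "selection_data")
}

#' Generate one horizontal-pleiotropy dataset
#'
#' Draws a [pleiotropy_scenario()] sample: two Hardy-Weinberg SNP dosages and
#' a covariate set in which each affected covariate is
#' `rho_zc * z_std + sqrt(1 - rho_zc^2) * residual`, with `z_std` the
#' population-standardized pleiotropic dosage, so every covariate has unit
#' variance and squared SNP-covariate correlation `rho_zc^2`. Residuals are
#' multivariate normal with the scenario's correlation structure; the
#' non-pleiotropic SNP is independent of everything.
#'
#' @param scenario a [pleiotropy_scenario()].
#' @param seed integer master seed.
#' @return list of class `pleiotropy_data` with `z_hp`, `z_nhp`, `C`,
#'   `scenario`, `seed`, `details`.
#' @export
generate_pleiotropy_dataset <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "pleiotropy_scenario"))
  seed <- check_seed(seed)
  sc <- scenario
  m <- sc$n
  n <- sc$n_chp + sc$n_cnhp
  q <- sc$effect_allele_freq
  p0 <- (1 - q)^2
  p1 <- 2 * q * (1 - q)
  R <- build_correlation_matrix(n, sc$r_c, sc$r_c_sd, seed, 1)

  Cres <- rnorm_mat_stream(seed, 2, m, n)
  if (!(is.numeric(sc$r_c) && sc$r_c == 0)) Cres <- Cres %*% chol(R)

  z_hp <- dosage_stream(seed, 3, m, p0, p1)
  z_nhp <- dosage_stream(seed, 5, m, p0, p1)
  z_std <- (z_hp - 2 * q) / sqrt(2 * q * (1 - q))

  C <- Cres
  hp <- seq_len(sc$n_chp)
  rho <- sc$rho_zc
  C[, hp] <- rho * z_std + sqrt(1 - rho^2) * Cres[, hp, drop = FALSE]
  colnames(C) <- c(sprintf("chp_%d", hp),
                   if (sc$n_cnhp > 0) sprintf("cnhp_%d", seq_len(sc$n_cnhp)))

  structure(
    list(z_hp = instrument_vector(as.numeric(z_hp), "dosage"),
         z_nhp = instrument_vector(as.numeric(z_nhp), "dosage"),
         C = C, scenario = sc, seed = seed,
         details = list(correlation = R,
                        genotype_probs = c(p0 = p0, p1 = p1, p2 = 1 - p0 - p1),
                        repaired = isTRUE(attr(R, "repaired")))),
    class = "pleiotropy_data")
}

#' Restrict a covariate matrix to a deterministic subset of each block
#'
#' Emulates the situation where only part of the relevant covariate set is
#' measured: keeps the first `ceiling(fraction * count)` columns of each
#' named covariate block (`cs_*`/`cns_*` or `chp_*`/`cnhp_*`; unprefixed
#' matrices are treated as a single block). Deterministic and seed-free.
#'
#' @param C covariate matrix with block-prefixed column names.
#' @param fraction fraction of each block to keep, in (0, 1].
#' @return covariate matrix with fewer columns.
#' @export
covariate_subset <- function(C, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  C <- as_covariate_matrix(C)
  if (fraction == 1) return(C)
  prefix <- sub("_[0-9]+$", "", colnames(C))
  keep <- unlist(lapply(unique(prefix), function(p) {
    cols <- which(prefix == p)
    cols[seq_len(ceiling(fraction * length(cols)))]
  }), use.names = FALSE)
  keep <- sort(keep)
  if (!length(keep)) stop("covariate subset is empty", call. = FALSE)
  C[, keep, drop = FALSE]
}
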