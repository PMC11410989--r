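#' Per-covariate mean difference per unit of the instrument
#'
#' For each covariate \eqn{C_i}, computes
#' \deqn{meandiff(C_i) = cor(z, C_i) \, SD(C_i) / SD(z),}
#' the mean difference in \eqn{C_i} per 1-unit higher instrument. This is
#' algebraically identical to the slope of the simple linear regression of
#' \eqn{C_i} on \eqn{z}, but costs one cross-product instead of a model fit.
#'
#' @param z genetic instrument: binary 0/1, SNP dosage 0/1/2, or a continuous
#'   genetic risk score. Length must match `nrow(C)`.
#' @param C numeric matrix or data frame of covariates (one row per
#'   participant). Rows with missing values in `z` or `C` are dropped jointly.
#' @return named numeric vector of length `ncol(C)`, in covariate units per
#'   unit of `z`.
#' @examples
#' z <- c(0, 0, 1, 1)
#' mean_difference(z, cbind(a = c(0, 0, 1, 1)))  # slope 1
#' @export
mean_difference <- function(z, C) {
  ctx <- balance_context(z, C)
  md <- drop(ctx_obs_cor(ctx)) * ctx$sd_C / ctx$sd_z
  setNames(md, colnames(ctx$C))
}

#' Generalized Mahalanobis distance of covariate imbalance
#'
#' Global balance statistic
#' \deqn{MD = \sqrt{meandiff(C)^T \, [cov(C)]^{-1} \, meandiff(C)},}
#' where \eqn{meandiff(C)} is the vector of per-covariate mean differences per
#' unit of the instrument (see [mean_difference()]) and \eqn{cov(C)} is the
#' unbiased sample covariance of the covariates. For a binary instrument this
#' reduces exactly to the classical two-group form
#' \eqn{\sqrt{(\bar C_1 - \bar C_0)^T cov(C)^{-1} (\bar C_1 - \bar C_0)}}.
#'
#' MD is invariant to affine recoding of the covariates but not to the scale
#' of the instrument (multiplying `z` by k divides MD by k); the permutation
#' P value of [global_randomization_test()] is invariant to both.
#'
#' If the covariate covariance is singular the Moore-Penrose pseudo-inverse is
#' used with a warning and the effective rank is recorded in `cov_rank`.
#'
#' @inheritParams mean_difference
#' @return an object of class `balance_stat`: a list with elements `md`
#'   (non-negative scalar), `meandiff` (length-`ncol(C)` vector), `cov_rank`,
#'   `n_obs`, `n_covariates`.
#' @export
mahalanobis_distance <- function(z, C) {
  ctx <- balance_context(z, C)
  r <- ctx_obs_cor(ctx)
  md <- ctx_md(ctx, r)
  structure(
    list(md = as.numeric(md),
         meandiff = setNames(drop(r) * ctx$sd_C / ctx$sd_z, colnames(ctx$C)),
         cov_rank = ctx$whitener$rank,
         n_obs = ctx$m,
         n_covariates = ctx$n),
    class = "balance_stat")
}

#' @method print balance_stat
#' @export
print.balance_stat <- function(x, ...) {
  cat("Mahalanobis balance statistic\n")
  cat("  MD =", format(x$md, digits = 4),
      " (", x$n_covariates, "covariates,", x$n_obs, "observations)\n")
  if (x$cov_rank < x$n_covariates) {
    cat("  note: covariance rank", x$cov_rank, "<", x$n_covariates,
        "(pseudo-inverse used)\n")
  }
  invisible(x)
}

#' Convert covariate mean differences to bias-scale measures
#'
#' Divides each covariate mean difference per unit instrument by the exposure
#' mean difference per unit instrument, turning imbalance into a bias measure
#' (covariate shift per unit shift in exposure attributable to the
#' instrument). Because MD is affinely invariant, the Mahalanobis distance of
#' the transformed vector equals that of the raw vector, so the global test is
#' identical on either scale.
#'
#' @param meandiff numeric vector of covariate mean differences (or a
#'   `balance_stat` object), as produced by [mean_difference()].
#' @param z the instrument used to compute `meandiff`.
#' @param x exposure vector, same length as `z`.
#' @return numeric vector `meandiff / meandiff_exposure`.
#' @export
bias_transform <- function(meandiff, z, x) {
  if (inherits(meandiff, "balance_stat")) meandiff <- meandiff$meandiff
  if (!is.numeric(meandiff)) stop("'meandiff' must be numeric", call. = FALSE)
  dx <- unname(mean_difference(z, cbind(exposure = x)))
  if (abs(dx) < .ZERO_VAR_TOL) {
    stop("exposure mean difference per unit instrument is zero; ",
         "bias is undefined (relevance assumption fails)", call. = FALSE)
  }
  meandiff / dx
}
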