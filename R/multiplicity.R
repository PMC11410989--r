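#' Per-covariate association P values
#'
#' Two-sided P value of the univariable linear association between the
#' instrument and each covariate, from the t test on the simple-regression
#' slope: \eqn{t = r \sqrt{(m - 2) / (1 - r^2)}} on `m - 2` degrees of
#' freedom, where `r` is the Pearson correlation. The P value is identical
#' whichever variable is regressed on which.
#'
#' @inheritParams mean_difference
#' @return named numeric vector of length `ncol(C)`.
#' @export
individual_pvalues <- function(z, C) {
  ctx <- balance_context(z, C)
  setNames(pvalues_from_cor(drop(ctx_obs_cor(ctx)), ctx$m),
           colnames(ctx$C))
}

pvalues_from_cor <- function(r, m) {
  if (m < 3L) stop("need at least 3 observations for association P values",
                   call. = FALSE)
  r2 <- pmin(r^2, 1)
  p <- ifelse(r2 >= 1, 0,
              2 * pt(-abs(r) * sqrt((m - 2) / (1 - r2)), df = m - 2))
  as.numeric(p)
}

#' Effective number of independent tests from spectral decomposition
#'
#' Estimates how many independent comparisons a correlated covariate set
#' represents, from the eigenvalues \eqn{\lambda} of the covariate correlation
#' matrix.
#'
#' Estimators:
#' \describe{
#'   \item{`"liji"` (default)}{Li & Ji:
#'     \eqn{N_I = \sum_i [ I(\lambda_i \ge 1) + (\lambda_i - \lfloor \lambda_i \rfloor) ]}.
#'     Integer-consistent in the limits: n identical covariates give 1, n
#'     uncorrelated covariates give n.}
#'   \item{`"nyholt"`}{Nyholt:
#'     \eqn{N_I = 1 + (n - 1) (1 - Var(\lambda) / n)}.}
#' }
#'
#' @param C covariate matrix (>= 3 rows).
#' @param method `"liji"` or `"nyholt"`.
#' @return a scalar in `[1, ncol(C)]`.
#' @export
effective_number_of_tests <- function(C, method = c("liji", "nyholt")) {
  method <- match.arg(method)
  C <- as_covariate_matrix(C)
  if (nrow(C) < 3L) {
    stop("need at least 3 rows to estimate the covariate correlation matrix",
         call. = FALSE)
  }
  Rc <- cor(C, use = "pairwise.complete.obs")
  if (anyNA(Rc)) stop("covariate correlation matrix contains NA", call. = FALSE)
  eff_tests_from_eigen(eigen(Rc, symmetric = TRUE, only.values = TRUE)$values,
                       ncol(C), method)
}

eff_tests_from_eigen <- function(lambda, n, method) {
  lambda <- pmax(lambda, 0)
  ni <- switch(method,
    liji = {
      # epsilon-protected floor: an eigenvalue at k - 1e-12 must count as k
      fl <- floor(lambda + 1e-8)
      sum(as.numeric(lambda >= 1 - 1e-8) + pmax(lambda - fl, 0))
    },
    nyholt = 1 + (n - 1) * (1 - var(lambda) / n))
  min(max(ni, 1), n)
}

#' Individual-covariate comparator tests with multiplicity correction
#'
#' Runs the per-covariate univariable association tests
#' ([individual_pvalues()]) and combines them into the two comparator tests:
#' \describe{
#'   \item{test-Bonf}{`min(1, p_min * n)`, Bonferroni over the nominal number
#'     of covariates `n`.}
#'   \item{test-indep}{`min(1, p_min * N_I)`, where `N_I` is the effective
#'     number of independent tests from [effective_number_of_tests()].}
#' }
#' Because `N_I <= n` always, the test-indep P value never exceeds the
#' Bonferroni one.
#'
#' @inheritParams mean_difference
#' @param method estimator passed to [effective_number_of_tests()].
#' @return object of class `imbalance_tests`: `per_covariate_p`, `p_min`,
#'   `n_tests_nominal`, `n_tests_effective`, `p_bonf`, `p_indep`.
#' @export
covariate_imbalance_tests <- function(z, C, method = c("liji", "nyholt")) {
  method <- match.arg(method)
  ctx <- balance_context(z, C)
  p <- setNames(
    pvalues_from_cor(drop(ctx_obs_cor(ctx)), ctx$m),
    colnames(ctx$C))
  n <- ctx$n
  ni <- eff_tests_from_eigen(
    eigen(ctx$Rc, symmetric = TRUE, only.values = TRUE)$values, n, method)
  p_min <- min(p)
  structure(
    list(per_covariate_p = p,
         p_min = p_min,
         n_tests_nominal = n,
         n_tests_effective = ni,
         p_bonf = min(1, p_min * n),
         p_indep = min(1, p_min * ni),
         method = method),
    class = "imbalance_tests")
}

#' @method print imbalance_tests
#' @export
print.imbalance_tests <- function(x, ...) {
  cat("Individual-covariate imbalance tests\n")
  cat("  per-covariate P values:\n")
  print(signif(x$per_covariate_p, 3))
  cat("  test-Bonf : p =", format_pval(x$p_bonf),
      sprintf("(%d tests)\n", x$n_tests_nominal))
  cat("  test-indep: p =", format_pval(x$p_indep),
      sprintf("(%.3g effective tests, %s)\n", x$n_tests_effective, x$method))
  invisible(x)
}

#' @rdname covariate_imbalance_tests
#' @return `test_bonf()` and `test_indep()` return the scalar corrected
#'   P value.
#' @export
test_bonf <- function(z, C) {
  covariate_imbalance_tests(z, C)$p_bonf
}

#' @rdname covariate_imbalance_tests
#' @export
test_indep <- function(z, C, method = c("liji", "nyholt")) {
  covariate_imbalance_tests(z, C, method = method)$p_indep
}
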