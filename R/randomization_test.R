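#' Global randomization test of joint covariate balance
#'
#' Permutation test of whether a genetic instrument is "as-if randomized" with
#' respect to a covariate set. The procedure is:
#' \enumerate{
#'   \item choose the covariate set `C` (scenario-dependent);
#'   \item compute the observed test statistic `T`, the generalized
#'     Mahalanobis distance of per-unit covariate mean differences
#'     (see [mahalanobis_distance()]);
#'   \item permute the instrument `n_perm` times, holding `C` fixed, and
#'     recompute the statistic `t` for each permutation;
#'   \item report the P value as the proportion of permutations with
#'     `t >= T` (ties count as exceedances).
#' }
#' A small P value is evidence of covariate imbalance, i.e. against the
#' instrument's independence / exclusion restriction assumptions (selection
#' bias or horizontal pleiotropy in a Mendelian randomization analysis).
#'
#' The default P value rule (`"paper"`, count / n_perm) can return exactly 0
#' when the observed statistic exceeds every permuted one; `"add_one"` uses
#' (1 + count) / (1 + n_perm), which is never 0 and is the usual choice when
#' a proper P value is required downstream.
#'
#' @inheritParams mean_difference
#' @param n_perm number of permutations (default 5000).
#' @param seed integer master seed for the permutation stream. Results are
#'   identical across platforms for fixed `(z, C, seed, n_perm)`.
#' @param p_rule `"paper"` for count / n_perm, `"add_one"` for
#'   (1 + count) / (1 + n_perm).
#' @param statistic `"mahalanobis"` (the global balance statistic) or
#'   `"max_r2"` (maximum squared instrument-covariate correlation; see
#'   [max_r2_permutation_test()]).
#' @param chunk_size number of permutations processed per cross-product block
#'   (performance only; default adapts to sample size).
#' @return an object of class `grt_result`: list with `observed`,
#'   `perm_stats`, `p_value`, `settings`, `n_obs`, `n_covariates`,
#'   `statistic`, and (for the Mahalanobis statistic) `balance`, the observed
#'   [mahalanobis_distance()] decomposition.
#' @examples
#' set.seed(1)
#' z <- rbinom(200, 2, 0.3)
#' C <- matrix(rnorm(600), 200, 3)
#' global_randomization_test(z, C, n_perm = 199, seed = 7)
#' @export
global_randomization_test <- function(z, C, n_perm = 5000, seed = 1,
                                      p_rule = c("paper", "add_one"),
                                      statistic = c("mahalanobis", "max_r2"),
                                      chunk_size = NULL) {
  p_rule <- match.arg(p_rule)
  statistic <- match.arg(statistic)
  seed <- check_seed(seed)
  ctx <- balance_context(z, C)
  res <- run_permutations(ctx, statistic, n_perm, seed,
                          chunk_size = chunk_size)[[statistic]]
  out <- list(
    observed = res$observed,
    perm_stats = res$perm_stats,
    p_value = perm_p_value(res$count, n_perm, p_rule),
    settings = list(n_perm = n_perm, seed = seed, statistic = statistic,
                    p_rule = p_rule),
    n_obs = ctx$m,
    n_covariates = ctx$n,
    statistic = statistic)
  if (statistic == "mahalanobis") {
    r <- ctx_obs_cor(ctx)
    out$balance <- structure(
      list(md = res$observed,
           meandiff = setNames(drop(r) * ctx$sd_C / ctx$sd_z, colnames(ctx$C)),
           cov_rank = ctx$whitener$rank,
           n_obs = ctx$m, n_covariates = ctx$n),
      class = "balance_stat")
  }
  class(out) <- "grt_result"
  out
}

#' Maximum-r2 permutation comparator test
#'
#' Identical permutation scheme to [global_randomization_test()] but with test
#' statistic \eqn{\max_i cor(z, C_i)^2}, the largest squared Pearson
#' correlation between the instrument and any single covariate.
#'
#' @inheritParams global_randomization_test
#' @return a `grt_result` object.
#' @export
max_r2_permutation_test <- function(z, C, n_perm = 5000, seed = 1,
                                    p_rule = c("paper", "add_one"),
                                    chunk_size = NULL) {
  global_randomization_test(z, C, n_perm = n_perm, seed = seed,
                            p_rule = match.arg(p_rule), statistic = "max_r2",
                            chunk_size = chunk_size)
}

#' @method print grt_result
#' @export
print.grt_result <- function(x, ...) {
  name <- switch(x$statistic,
                 mahalanobis = "Global randomization test (Mahalanobis distance)",
                 max_r2 = "Permutation test (max r^2)")
  cat(name, "\n")
  cat("  observations:", x$n_obs, "  covariates:", x$n_covariates, "\n")
  cat("  observed statistic:", format(x$observed, digits = 4), "\n")
  cat("  permutations:", x$settings$n_perm,
      " (seed ", x$settings$seed, ", rule '", x$settings$p_rule, "')\n", sep = "")
  cat("  P value:", format_pval(x$p_value), "\n")
  invisible(x)
}

# P values printed with 3 significant figures, full precision kept in objects
format_pval <- function(p) {
  ifelse(p == 0, "0 (below permutation resolution)", format(signif(p, 3)))
}
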