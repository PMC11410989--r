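#' Monte Carlo standard error of a rejection proportion
#'
#' \eqn{\sqrt{p (1 - p) / n_{sim}}}.
#'
#' @param p rejection proportion in `[0, 1]`.
#' @param n_sim number of simulation repetitions.
#' @return standard error.
#' @export
mcse_proportion <- function(p, n_sim) {
  stopifnot(all(p >= 0 & p <= 1), n_sim >= 1)
  sqrt(p * (1 - p) / n_sim)
}

#' Rejection-rate study over simulated datasets
#'
#' Runs a full power / type-I-error study for one scenario: in each of
#' `n_sim` repetitions a fresh dataset is generated, the requested tests are
#' all applied to the same dataset, and the rejection indicator at level
#' `alpha` is recorded. Reported per test: the rejection proportion, its
#' Monte Carlo standard error, and the per-repetition P values.
#'
#' For a [selection_scenario()] the tests are applied to the genetic risk
#' score within the selected subsample (`select = TRUE`, estimating power to
#' detect collider bias) or to the full invited cohort (`select = FALSE`,
#' a null configuration estimating type-I error). For a
#' [pleiotropy_scenario()] the tests are applied to the pleiotropic SNP
#' (`instrument = "hp"`, power) or the non-pleiotropic SNP
#' (`instrument = "nhp"`, type-I error) on the full sample.
#'
#' Tests: `"grt"` (global randomization test, Mahalanobis statistic),
#' `"r2perm"` (max-r2 permutation test), `"bonf"` and `"indep"`
#' (per-covariate regression with Bonferroni / effective-number-of-tests
#' correction). The two permutation tests share one permutation stream per
#' repetition; every repetition uses its own independently seeded stream, so
#' rejection decisions are independent across repetitions and the binomial
#' MCSE is valid.
#'
#' With `early_stop = TRUE` (default) a repetition's permutation loop stops
#' as soon as the exceedance count guarantees `p >= alpha`; the rejection
#' decision is identical to the full run, only the recorded P value of
#' non-rejected repetitions becomes a truncated estimate (flagged per
#' repetition).
#'
#' @param scenario a [selection_scenario()] or [pleiotropy_scenario()].
#' @param tests character subset of `c("grt", "r2perm", "bonf", "indep")`.
#' @param n_sim number of simulation repetitions (500 gives MCSE <= 0.022).
#' @param alpha rejection threshold (0.05; 0.1 as a lenient sensitivity).
#' @param n_perm permutations per repetition (5000 default; 1000 gives
#'   desk-scale runs with P value granularity 0.001).
#' @param seed integer master seed; repetition r derives its own data and
#'   permutation streams from it.
#' @param select (selection scenarios) apply the selection mask before
#'   testing; `FALSE` tests the full cohort, where the instrument is
#'   independent of the covariates by construction.
#' @param instrument (pleiotropy scenarios) `"hp"` or `"nhp"`.
#' @param p_rule,chunk_size passed to the permutation engine.
#' @param early_stop stop permutations once non-rejection is certain.
#' @param ni_method effective-number-of-tests estimator for `"indep"`.
#' @param verbose print a progress message every 50 repetitions.
#' @return object of class `power_study`: `estimates` (data frame with one
#'   row per test: `test`, `rejection_pct`, `mcse`, `n_sim`, `alpha`),
#'   `p_values` (n_sim x tests matrix), `failures`, `scenario`, `settings`.
#' @export
run_power_study <- function(scenario,
                            tests = c("grt", "r2perm", "bonf", "indep"),
                            n_sim = 500, alpha = 0.05, n_perm = 5000,
                            seed = 1, select = TRUE,
                            instrument = c("hp", "nhp"),
                            p_rule = c("paper", "add_one"),
                            chunk_size = NULL, early_stop = TRUE,
                            ni_method = c("liji", "nyholt"),
                            verbose = FALSE) {
  tests <- match.arg(tests, several.ok = TRUE)
  p_rule <- match.arg(p_rule)
  instrument <- match.arg(instrument)
  ni_method <- match.arg(ni_method)
  seed <- check_seed(seed)
  stopifnot(inherits(scenario, "grt_scenario"), n_sim >= 1, n_perm >= 1,
            alpha > 0, alpha < 1)

  perm_tests <- intersect(tests, c("grt", "r2perm"))
  stat_names <- c(grt = "mahalanobis", r2perm = "max_r2")[perm_tests]
  indiv_tests <- intersect(tests, c("bonf", "indep"))
  stop_count <- if (early_stop) stop_count_for(alpha, n_perm, p_rule) else NULL

  pvals <- matrix(NA_real_, n_sim, length(tests),
                  dimnames = list(NULL, tests))
  truncated <- logical(n_sim)
  failures <- list()

  for (r in seq_len(n_sim)) {
    rep_seed <- derive_seed(seed, r)
    # every repetition gets its own permutation stream: sharing one stream
    # across repetitions would correlate their rejection decisions and
    # invalidate the binomial Monte Carlo standard error
    rep_perm_seed <- derive_seed(seed, 400000 + r)
    res <- tryCatch(
      power_study_rep(scenario, rep_seed, rep_perm_seed, tests, stat_names,
                      indiv_tests, n_perm, p_rule, chunk_size, stop_count,
                      select, instrument, ni_method),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(rep = r,
                                                message = conditionMessage(res))
      next
    }
    pvals[r, names(res$p)] <- res$p
    truncated[r] <- res$truncated
    if (verbose && r %% 50 == 0) {
      message("repetition ", r, "/", n_sim)
    }
  }

  ok <- rowSums(is.na(pvals)) == 0
  n_eff <- sum(ok)
  if (n_eff == 0) stop("all repetitions failed", call. = FALSE)
  rej <- colMeans(pvals[ok, , drop = FALSE] < alpha)
  estimates <- data.frame(
    test = tests,
    rejection_pct = as.numeric(rej),
    mcse = mcse_proportion(as.numeric(rej), n_eff),
    n_sim = n_eff,
    alpha = alpha,
    row.names = NULL)

  structure(
    list(estimates = estimates, p_values = pvals,
         truncated = truncated, failures = failures,
         scenario = scenario,
         settings = list(n_sim = n_sim, alpha = alpha, n_perm = n_perm,
                         seed = seed, p_rule = p_rule, select = select,
                         instrument = instrument, early_stop = early_stop,
                         ni_method = ni_method)),
    class = "power_study")
}

power_study_rep <- function(scenario, rep_seed, perm_seed, tests, stat_names,
                            indiv_tests, n_perm, p_rule, chunk_size,
                            stop_count, select, instrument, ni_method) {
  if (inherits(scenario, "selection_scenario")) {
    dat <- generate_selection_dataset(scenario, rep_seed)
    C <- covariate_subset(dat$C, scenario$covariate_subset_fraction)
    if (select) {
      z <- subset_keep_codes(dat$z, dat$selected)
      C <- C[dat$selected, , drop = FALSE]
    } else {
      z <- dat$z
    }
  } else {
    dat <- generate_pleiotropy_dataset(scenario, rep_seed)
    z <- if (instrument == "hp") dat$z_hp else dat$z_nhp
    C <- dat$C
  }

  ctx <- balance_context(z, C, quiet = TRUE)
  p <- setNames(numeric(0), character(0))
  truncated <- FALSE

  if (length(stat_names)) {
    perm <- run_permutations(ctx, unname(stat_names), n_perm, perm_seed,
                             chunk_size = chunk_size, stop_count = stop_count)
    for (tn in names(stat_names)) {
      pr <- perm[[stat_names[[tn]]]]
      p[tn] <- perm_p_value(pr$count, pr$n_used, p_rule)
      truncated <- truncated || pr$early_stopped
    }
  }

  if (length(indiv_tests)) {
    r_obs <- drop(ctx_obs_cor(ctx))
    pv <- pvalues_from_cor(r_obs, ctx$m)
    p_min <- min(pv)
    if ("bonf" %in% indiv_tests) p["bonf"] <- min(1, p_min * ctx$n)
    if ("indep" %in% indiv_tests) {
      ni <- eff_tests_from_eigen(
        eigen(ctx$Rc, symmetric = TRUE, only.values = TRUE)$values,
        ctx$n, ni_method)
      p["indep"] <- min(1, p_min * ni)
    }
  }

  list(p = p[tests[tests %in% names(p)]], truncated = truncated)
}

#' @method print power_study
#' @export
print.power_study <- function(x, ...) {
  type <- if (inherits(x$scenario, "selection_scenario")) {
    if (x$settings$select) "selection bias (selected subsample)"
    else "selection scenario, full cohort (null)"
  } else {
    if (x$settings$instrument == "hp") "horizontal pleiotropy (pleiotropic SNP)"
    else "pleiotropy scenario, non-pleiotropic SNP (null)"
  }
  cat("Rejection-rate study:", type, "\n")
  cat("  n_sim =", x$settings$n_sim, " n_perm =", x$settings$n_perm,
      " alpha =", x$settings$alpha, "\n")
  est <- x$estimates
  est$rejection_pct <- sprintf("%.3f", est$rejection_pct)
  est$mcse <- sprintf("%.3f", est$mcse)
  print(est, row.names = FALSE)
  if (length(x$failures)) {
    cat("  failed repetitions:", length(x$failures), "\n")
  }
  invisible(x)
}
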