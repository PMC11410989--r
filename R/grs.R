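#' Build a weighted genetic risk score from SNP dosages
#'
#' Computes, per participant, the weighted sum of effect-allele dosages:
#' \eqn{GRS_j = \sum_s w_s \, d_{js}}. Weights are assumed to be oriented to
#' the effect allele of the dosage coding (the usual GWAS convention); no
#' silent allele flipping is performed. If `dosage_alleles` is supplied, a
#' strict check errors on any SNP whose counted allele differs from the
#' weight table's `effect_allele`.
#'
#' @param dosages numeric matrix of allele dosages in `[0, 2]`, one row per
#'   participant, with SNP ids as column names.
#' @param weights data frame with columns `snp_id`, `effect_allele`, `weight`
#'   (per-allele effect on the exposure), as returned by [read_weights()].
#' @param dosage_alleles optional named character vector (names = SNP ids)
#'   giving the allele counted by each dosage column, enabling the strict
#'   allele check.
#' @return numeric genetic risk score vector (`kind = "grs"`), one value per
#'   participant.
#' @examples
#' d <- cbind(rs1 = c(2, 0), rs2 = c(0, 1))
#' w <- data.frame(snp_id = c("rs1", "rs2"),
#'                 effect_allele = c("A", "G"), weight = c(0.5, 0.25))
#' build_grs(d, w)  # 1.0, 0.25
#' @export
build_grs <- function(dosages, weights, dosage_alleles = NULL) {
  weights <- validate_weights(weights)
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) {
    stop("dosage matrix must have SNP ids as column names", call. = FALSE)
  }
  missing_snps <- setdiff(weights$snp_id, colnames(dosages))
  if (length(missing_snps)) {
    stop("weights refer to SNPs absent from the dosage matrix: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  d <- dosages[, weights$snp_id, drop = FALSE]
  rng <- range(d, na.rm = TRUE)
  if (rng[1] < -1e-8 || rng[2] > 2 + 1e-8) {
    stop("dosages must lie in [0, 2]; observed range [",
         format(rng[1]), ", ", format(rng[2]), "]", call. = FALSE)
  }
  if (!is.null(dosage_alleles)) {
    da <- dosage_alleles[weights$snp_id]
    bad <- which(!is.na(da) & da != weights$effect_allele)
    if (length(bad)) {
      stop("effect allele mismatch for SNP(s): ",
           paste(weights$snp_id[bad], collapse = ", "),
           " (weights are not oriented to the counted allele)", call. = FALSE)
    }
  }
  grs <- drop(d %*% weights$weight)
  instrument_vector(grs, kind = "grs")
}

validate_weights <- function(weights) {
  need <- c("snp_id", "effect_allele", "weight")
  if (!is.data.frame(weights) || !all(need %in% names(weights))) {
    stop("weights must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(weights$snp_id)) {
    stop("duplicate snp_id in weights: ",
         paste(unique(weights$snp_id[duplicated(weights$snp_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(weights$weight) || any(!is.finite(weights$weight))) {
    stop("weights must be finite numbers", call. = FALSE)
  }
  weights$snp_id <- as.character(weights$snp_id)
  weights$effect_allele <- as.character(weights$effect_allele)
  weights
}

#' Per-SNP randomization filtering of a SNP panel
#'
#' Runs [global_randomization_test()] for each SNP dosage column against a
#' covariate set chosen to flag horizontal pleiotropy, and partitions the
#' panel into excluded SNPs (`p < threshold`) and retained SNPs. The retained
#' set can then be used to rebuild a genetic risk score whose constituent
#' variants show no evidence of association with the covariates
#' ("randomization filtering").
#'
#' No multiplicity correction is applied across SNPs: the screening threshold
#' is deliberately lenient because the cost of keeping a pleiotropic SNP
#' exceeds that of dropping a valid one. Monomorphic SNP columns cannot be
#' tested; they are skipped with a warning, kept in `retained`, and listed in
#' `skipped`.
#'
#' @param dosages numeric matrix of SNP dosages (columns named by SNP id).
#' @param C covariate matrix.
#' @param n_perm,seed,p_rule as in [global_randomization_test()]. Each SNP
#'   uses its own permutation stream derived from `seed`, so the report is
#'   reproducible SNP by SNP.
#' @param threshold exclusion threshold on the per-SNP P value, in (0, 1)
#'   (default 0.05; 0.001 is a common stricter sensitivity choice).
#' @return object of class `grt_filter`: `per_snp_p` (named vector),
#'   `threshold`, `excluded`, `retained`, `skipped`.
#' @export
snpwise_randomization_filter <- function(dosages, C, n_perm = 5000, seed = 1,
                                         threshold = 0.05,
                                         p_rule = c("paper", "add_one")) {
  p_rule <- match.arg(p_rule)
  seed <- check_seed(seed)
  if (!(threshold > 0 && threshold < 1)) {
    stop("'threshold' must be in (0, 1)", call. = FALSE)
  }
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  }
  snps <- colnames(dosages)
  p <- setNames(rep(NA_real_, length(snps)), snps)
  skipped <- character(0)
  for (s in seq_along(snps)) {
    d <- dosages[, s]
    if (sd(d, na.rm = TRUE) <= .ZERO_VAR_TOL || all(is.na(d))) {
      warning("SNP ", snps[s], " is monomorphic; skipped", call. = FALSE)
      skipped <- c(skipped, snps[s])
      next
    }
    res <- global_randomization_test(d, C, n_perm = n_perm,
                                     seed = derive_seed(seed, s),
                                     p_rule = p_rule)
    p[s] <- res$p_value
  }
  excluded <- snps[!is.na(p) & p < threshold]
  structure(
    list(per_snp_p = p,
         threshold = threshold,
         excluded = excluded,
         retained = setdiff(snps, excluded),
         skipped = skipped,
         settings = list(n_perm = n_perm, seed = seed, p_rule = p_rule)),
    class = "grt_filter")
}

#' @method print grt_filter
#' @export
print.grt_filter <- function(x, ...) {
  cat("Per-SNP randomization filter (threshold p <", x$threshold, ")\n")
  cat("  tested:", sum(!is.na(x$per_snp_p)),
      " excluded:", length(x$excluded),
      " retained:", length(x$retained), "\n")
  if (length(x$skipped)) {
    cat("  skipped (monomorphic):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a probit-scale estimate to an approximate odds ratio
#'
#' Returns `exp(1.6 * beta)`: the logistic and probit link functions satisfy
#' `logit(p) ~= 1.6 * probit(p)` over the central probability range, so 1.6
#' times a probit index difference approximates a log odds ratio.
#'
#' @param beta probit regression coefficient (difference in probit index).
#' @param scale logistic/probit scaling constant (default 1.6).
#' @return approximate odds ratio.
#' @examples
#' probit_to_or(0)        # 1
#' probit_to_or(-0.0281)  # ~0.956
#' @export
probit_to_or <- function(beta, scale = 1.6) {
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    stop("'beta' must be finite", call. = FALSE)
  }
  exp(scale * beta)
}
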