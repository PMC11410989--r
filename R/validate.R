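# Input validation shared by every test. All computations run on a "balance
# context": jointly complete-case filtered instrument + covariate matrix with
# analytic centering (no matrix copies), standard deviations, and a
# (pseudo-)inverse factor of the covariate correlation matrix.

.ZERO_VAR_TOL <- 1e-12

guess_instrument_kind <- function(z) {
  u <- unique(z[!is.na(z)])
  if (all(u %in% c(0, 1))) return("binary")
  if (all(u %in% c(0, 1, 2))) return("dosage")
  "grs"
}

#' Construct an instrument vector
#'
#' Light wrapper that validates a genetic instrument: a binary 0/1 indicator,
#' a SNP dosage in \{0, 1, 2\}, or a continuous genetic risk score.
#'
#' @param values numeric vector of length >= 2 with non-zero variance.
#' @param kind one of `"auto"`, `"binary"`, `"dosage"`, `"grs"`. With
#'   `"auto"` the kind is inferred from the observed values.
#' @return a numeric vector with attribute `kind`.
#' @export
instrument_vector <- function(values, kind = c("auto", "binary", "dosage", "grs")) {
  kind <- match.arg(kind)
  if (!is.numeric(values)) stop("instrument must be numeric", call. = FALSE)
  if (length(values) < 2L) stop("instrument must have length >= 2", call. = FALSE)
  if (kind == "auto") kind <- guess_instrument_kind(values)
  structure(as.numeric(values), kind = kind)
}

check_no_infinite <- function(x, what) {
  # range() is a single allocation-free pass; NAs are removed upstream
  rg <- suppressWarnings(range(x))
  if (any(is.infinite(rg))) stop("non-finite values in ", what, call. = FALSE)
}

as_covariate_matrix <- function(C) {
  if (is.data.frame(C)) C <- as.matrix(C)
  if (is.null(dim(C))) C <- matrix(C, ncol = 1L)
  if (!is.numeric(C)) stop("covariates must be numeric", call. = FALSE)
  if (ncol(C) < 1L) stop("need at least one covariate column", call. = FALSE)
  if (is.null(colnames(C))) colnames(C) <- paste0("C", seq_len(ncol(C)))
  C
}

# Joint complete-case filtering of instrument, covariates and (optionally) an
# exposure. NaN counts as missing; infinities are an error.
complete_case_filter <- function(z, C, x = NULL, quiet = FALSE) {
  any_na <- anyNA(z) || anyNA(C) || (!is.null(x) && anyNA(x))
  if (any_na) {
    keep <- !is.na(z) & stats::complete.cases(C)
    if (!is.null(x)) keep <- keep & !is.na(x)
    dropped <- sum(!keep)
    if (dropped > 0 && !quiet) {
      message("complete-case filtering removed ", dropped, " of ", length(z),
              " rows (", length(z) - dropped, " remain)")
    }
    z <- z[keep]
    C <- C[keep, , drop = FALSE]
    if (!is.null(x)) x <- x[keep]
  } else {
    dropped <- 0L
  }
  check_no_infinite(z, "instrument")
  check_no_infinite(C, "covariates")
  if (!is.null(x)) check_no_infinite(x, "exposure")
  if (length(z) < 2L) stop("fewer than 2 complete rows", call. = FALSE)
  list(z = z, C = C, x = x, n_dropped = dropped)
}

check_variances <- function(sd_z, sd_C, names_C) {
  zero_tol <- .ZERO_VAR_TOL
  if (sd_z <= zero_tol) {
    stop("instrument has zero variance (SD = ", format(sd_z), ")", call. = FALSE)
  }
  bad <- which(sd_C <= zero_tol)
  if (length(bad)) {
    stop("covariate column(s) with zero variance: ",
         paste(names_C[bad], collapse = ", "), call. = FALSE)
  }
}

# Build the shared computational context. C is kept uncentered; all centering
# happens analytically in the cross-product formulas.
#
# The correlation matrix of C is factored once: a Cholesky factor when it is
# positive definite, otherwise (rank-deficient covariates) a Moore-Penrose
# pseudo-inverse with a warning, recording the effective rank.
balance_context <- function(z, C, quiet = FALSE) {
  kind <- if (is.null(attr(z, "kind"))) guess_instrument_kind(z) else attr(z, "kind")
  C <- as_covariate_matrix(C)
  if (length(z) != nrow(C)) {
    stop("instrument length (", length(z), ") does not match covariate rows (",
         nrow(C), ")", call. = FALSE)
  }
  cc <- complete_case_filter(z, C, quiet = quiet)
  codes <- attr(cc$z, "grt_codes")
  code_table <- attr(cc$z, "grt_table")
  z <- as.numeric(cc$z)
  C <- cc$C
  m <- length(z)
  n <- ncol(C)

  z_sum <- sum(z)
  z_bar <- z_sum / m
  sd_z <- sqrt((sum(z^2) - m * z_bar^2) / (m - 1))
  col_means <- colMeans(C)
  S <- (crossprod(C) - m * tcrossprod(col_means)) / (m - 1)
  sd_C <- sqrt(pmax(diag(S), 0))
  check_variances(sd_z, sd_C, colnames(C))
  Rc <- S / tcrossprod(sd_C)
  diag(Rc) <- 1

  rank <- qr(Rc)$rank
  if (rank < n) {
    warning("covariate correlation matrix is singular (rank ", rank, " < ", n,
            "); using Moore-Penrose pseudo-inverse", call. = FALSE)
    whitener <- list(type = "pinv", W = MASS::ginv(Rc), rank = rank)
  } else {
    U <- tryCatch(chol(Rc), error = function(e) NULL)
    if (is.null(U)) {
      warning("covariate correlation matrix is numerically singular; ",
              "using Moore-Penrose pseudo-inverse", call. = FALSE)
      whitener <- list(type = "pinv", W = MASS::ginv(Rc), rank = rank)
    } else {
      whitener <- list(type = "chol", U = U, rank = n)
    }
  }

  e <- new.env(parent = emptyenv())  # lazy per-context caches (Tc)
  list(z = z, C = C, m = m, n = n,
       z_sum = z_sum, z_bar = z_bar, col_means = col_means,
       sd_z = sd_z, sd_C = sd_C, Rc = Rc, whitener = whitener,
       kind = kind, n_dropped = cc$n_dropped,
       codes = codes, code_table = code_table, cache = e)
}

# Correlations of permuted instrument copies (columns of Z, same multiset of
# values as ctx$z) with every covariate. Because every column of Z has the
# same sum as z, centering reduces to subtracting col_means * z_sum.
# Returns an n x k matrix.
ctx_cor <- function(ctx, Z) {
  U <- crossprod(ctx$C, Z)
  (U - ctx$col_means * ctx$z_sum) / ((ctx$m - 1) * ctx$sd_z * ctx$sd_C)
}

# Same, from raw cross-products U = t(C) %*% Z (used by the subset kernel,
# whose output is already centered on the covariate side).
ctx_cor_from_centered_U <- function(ctx, U) {
  U / ((ctx$m - 1) * ctx$sd_z * ctx$sd_C)
}

# Observed instrument-covariate correlations (n x 1 matrix).
ctx_obs_cor <- function(ctx) {
  ctx_cor(ctx, matrix(ctx$z, ncol = 1L))
}

# Centered n x m transpose of C, built lazily (subset kernel only).
ctx_Tc <- function(ctx) {
  if (is.null(ctx$cache$Tc)) {
    ctx$cache$Tc <- .cpp_center_transpose(ctx$C, ctx$col_means)
  }
  ctx$cache$Tc
}

# Single-precision packed variant (large m; memory-bandwidth bound).
ctx_Tcf <- function(ctx) {
  if (is.null(ctx$cache$Tcf)) {
    ctx$cache$Tcf <- .cpp_center_transpose_f(ctx$C, ctx$col_means)
  }
  ctx$cache$Tcf
}

# Mahalanobis balance statistic from correlation columns: for each column r,
# md = sqrt(r' Rc^{-1} r) / sd(z). Equals sqrt(meandiff' cov(C)^{-1} meandiff).
ctx_md <- function(ctx, r) {
  r <- as.matrix(r)
  if (ctx$whitener$type == "chol") {
    Y <- backsolve(ctx$whitener$U, r, transpose = TRUE)
    q <- colSums(Y^2)
  } else {
    q <- colSums(r * (ctx$whitener$W %*% r))
  }
  sqrt(pmax(q, 0)) / ctx$sd_z
}

# max-r2 statistic per column
ctx_max_r2 <- function(ctx, r) {
  r <- as.matrix(r)
  if (ncol(r) == 1L) return(max(r^2))
  matrixStats_colMaxs(r^2)
}

matrixStats_colMaxs <- function(x) {
  # small-n column maxima without extra dependencies
  do.call(pmax, lapply(seq_len(nrow(x)), function(i) x[i, ]))
}

# Discrete-instrument decomposition: modal value first, then the remaining
# values with their counts. Used to route permutations through the
# subset-sum kernel when the instrument takes few distinct values.
ctx_groups <- function(ctx) {
  # cheap pre-screen: distinct count over a prefix only grows with more data
  head_n <- min(ctx$m, 1000L)
  if (length(unique(ctx$z[seq_len(head_n)])) > 4L) return(NULL)
  vals <- sort(unique(ctx$z))
  if (length(vals) > 4L) return(NULL)
  counts <- vapply(vals, function(v) sum(ctx$z == v), 0L)
  modal <- which.max(counts)
  K <- ctx$m - counts[modal]
  if (K / ctx$m > 0.6) return(NULL)
  list(v0 = vals[modal],
       values = vals[-modal],
       sizes = counts[-modal],
       K = as.integer(K))
}
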