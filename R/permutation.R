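# Vectorized permutation engine.
#
# All permutation statistics are functions of the correlations between the
# permuted instrument and the covariates, so each chunk of permutations is
# one cross-product of the covariates with the permuted instrument copies.
# Two routes produce those cross-products:
#
#   * general (continuous) instruments: gather permuted copies of z with an
#     interleaved prefetching kernel (cache-resident 16-bit codes when the
#     instrument carries them) and hit BLAS once per chunk;
#   * discrete instruments (binary / dosage, <= 4 distinct values): permuting
#     z is equivalent to assigning uniform disjoint row subsets to the
#     non-modal values, so each permutation is a couple of subset sums over
#     centered covariate rows (~36% of the rows for a Hardy-Weinberg dosage
#     at allele frequency 0.2) - no gather, no BLAS.
#
# Permutation index chunks are pure functions of (seed, m or (m, K),
# chunk id), so any result can be reproduced from its seed alone.

default_chunk_size <- function(m) {
  # small chunks keep early stopping effective at large m; tiny samples get
  # big chunks so the BLAS call dominates the R overhead
  if (m >= 200000) return(64L)
  if (m >= 10000) return(128L)
  512L
}

# Full-permutation index chunk (gather route).
full_perm_chunk <- function(seed, m, chunk_id, chunk_size) {
  perm_chunk(seed, m, chunk_id, chunk_size)
}

# Ordered-subset index chunk (discrete route). K is rounded up to a 4096
# granularity; the first sum(sizes) rows of a longer ordered subset are a
# uniform ordered subset of that length.
subset_perm_chunk <- function(seed, m, K, chunk_id, chunk_size) {
  K_star <- min(m, as.integer(4096 * ceiling(K / 4096)))
  .cpp_perm_subset_chunk(stream_seed(seed, chunk_id, 1), m, K_star, chunk_size)
}

# Smallest permutation exceedance count that already implies p >= alpha, i.e.
# the earliest point at which a non-rejection is certain.
stop_count_for <- function(alpha, n_perm, p_rule) {
  counts <- 0:n_perm
  p <- if (p_rule == "paper") counts / n_perm else (1 + counts) / (1 + n_perm)
  counts[match(TRUE, p >= alpha)]
}

# Run the permutation scheme once for one or several statistics.
#
# statistics: character subset of c("mahalanobis", "max_r2").
# stop_count: if non-NULL, stop permuting once every requested statistic has
#   at least this exceedance count (the p >= alpha decision is then final).
# Returns, per statistic: observed, perm_stats, count, n_used, early_stopped.
run_permutations <- function(ctx, statistics, n_perm, seed,
                             chunk_size = NULL, stop_count = NULL) {
  if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  if (is.null(chunk_size)) chunk_size <- default_chunk_size(ctx$m)
  stat_fun <- list(mahalanobis = ctx_md, max_r2 = ctx_max_r2)[statistics]

  observed <- vapply(stat_fun, function(f) as.numeric(f(ctx, ctx_obs_cor(ctx))), 0)
  groups <- ctx_groups(ctx)

  perm_stats <- lapply(statistics, function(s) numeric(0))
  names(perm_stats) <- statistics
  counts <- setNames(numeric(length(statistics)), statistics)

  done <- 0L
  chunk_id <- 0L
  early <- FALSE
  while (done < n_perm) {
    chunk_id <- chunk_id + 1L
    k <- min(chunk_size, n_perm - done)
    r <- perm_cor_chunk(ctx, groups, seed, chunk_id, chunk_size, k)
    for (s in statistics) {
      st <- stat_fun[[s]](ctx, r)
      perm_stats[[s]] <- c(perm_stats[[s]], st)
      counts[s] <- counts[s] + sum(st >= observed[s])
    }
    done <- done + k
    if (!is.null(stop_count) && all(counts >= stop_count) && done < n_perm) {
      early <- TRUE
      break
    }
  }

  lapply(setNames(statistics, statistics), function(s) {
    list(observed = observed[[s]],
         perm_stats = perm_stats[[s]],
         count = counts[[s]],
         n_used = done,
         early_stopped = early)
  })
}

# Correlation columns for one chunk of permutations (k columns).
perm_cor_chunk <- function(ctx, groups, seed, chunk_id, chunk_size, k) {
  if (!is.null(groups)) {
    idx <- subset_perm_chunk(seed, ctx$m, groups$K, chunk_id, chunk_size)
    if (k < ncol(idx)) idx <- idx[, seq_len(k), drop = FALSE]
    # beyond ~200k rows the kernel is memory-bandwidth/latency bound; the
    # packed single-precision covariate copy halves the traffic (stat error
    # ~1e-7, far below permutation tie resolution)
    U <- if (ctx$m >= 200000) {
      .cpp_subset_crossprod_f(ctx_Tcf(ctx), ctx$n, ctx$m, idx,
                              as.integer(groups$sizes),
                              as.numeric(groups$values - groups$v0))
    } else {
      .cpp_subset_crossprod(ctx_Tc(ctx), idx,
                            as.integer(groups$sizes),
                            as.numeric(groups$values - groups$v0))
    }
    ctx_cor_from_centered_U(ctx, U)
  } else {
    idx <- full_perm_chunk(seed, ctx$m, chunk_id, chunk_size)
    if (k < ncol(idx)) idx <- idx[, seq_len(k), drop = FALSE]
    Zp <- if (!is.null(ctx$codes)) {
      .cpp_gather_coded(ctx$codes, ctx$code_table, idx)
    } else {
      .cpp_gather(ctx$z, idx)
    }
    ctx_cor(ctx, Zp)
  }
}

perm_p_value <- function(count, n_perm, p_rule) {
  if (p_rule == "paper") count / n_perm else (1 + count) / (1 + n_perm)
}
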