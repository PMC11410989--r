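# Seed plumbing for the package's versioned generator (xoshiro256++ in src/).
#
# A user-facing master seed is an integer in [0, 2^31 - 1]. Internal streams
# are derived as master * 2^20 + 2 * stream + parity, which is exact in double
# precision (< 2^53) and collision-free for stream < 2^19. Data streams use
# parity 0, permutation streams parity 1, so the two never overlap.

.MAX_SEED <- 2^31 - 1
.MAX_STREAM <- 2^19 - 1

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed) ||
      seed < 0 || seed > .MAX_SEED || seed != floor(seed)) {
    stop("'seed' must be a single integer in [0, ", .MAX_SEED, "]", call. = FALSE)
  }
  as.numeric(seed)
}

stream_seed <- function(seed, stream, parity = 0) {
  stopifnot(stream >= 0, stream <= .MAX_STREAM, parity %in% c(0, 1))
  seed * 2^20 + 2 * stream + parity
}

# Derive a new master seed (e.g. one per SNP in the filtering workflow) so
# that each derived analysis has its own full stream space.
derive_seed <- function(seed, index) {
  ((seed + 1) * 48271 + index * 1299709) %% (2^31 - 1)
}

rnorm_stream <- function(seed, stream, n) {
  .cpp_rnorm(stream_seed(seed, stream, 0), n)
}

rnorm_mat_stream <- function(seed, stream, m, n) {
  matrix(.cpp_rnorm(stream_seed(seed, stream, 0), m * n), m, n)
}

dosage_stream <- function(seed, stream, n, p0, p1) {
  .cpp_dosage(stream_seed(seed, stream, 0), n, p0, p1)
}

# Standard normal draws discretized to 2^16 quantile cells, carrying their
# uint16 codes so the permutation engine can use the cache-resident coded
# gather at very large m. The discretization emulates the finite granularity
# of an empirical genetic risk score; moment error < 1e-4.
rnorm_coded_stream <- function(seed, stream, n) {
  r <- .cpp_rnorm_coded(stream_seed(seed, stream, 0), n)
  structure(r$values, grt_codes = r$codes, grt_table = r$table, kind = "grs")
}

# Subset a vector while carrying its uint16 code representation along
# (ordinary subsetting drops attributes).
subset_keep_codes <- function(z, mask) {
  codes <- attr(z, "grt_codes")
  out <- as.numeric(z)[mask]
  if (!is.null(codes)) {
    pos <- which(mask)
    byte_idx <- rep(2L * (pos - 1L), each = 2L) + c(1L, 2L)
    attr(out, "grt_codes") <- codes[byte_idx]
    attr(out, "grt_table") <- attr(z, "grt_table")
    attr(out, "kind") <- attr(z, "kind")
  }
  out
}

# Permutation indices for one chunk: a pure function of (seed, m, chunk),
# independent of everything else, hence safely memoizable.
perm_chunk <- function(seed, m, chunk_id, chunk_size) {
  .cpp_perm_chunk(stream_seed(seed, chunk_id, 1), m, chunk_size)
}
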