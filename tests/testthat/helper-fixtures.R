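# Shared fixture builders. Everything is generated in code with fixed seeds;
# no data files.

make_null_data <- function(m = 100, n = 3, seed = 1, kind = c("grs", "dosage", "binary")) {
  kind <- match.arg(kind)
  set.seed(seed)
  z <- switch(kind,
              grs = rnorm(m),
              dosage = {
                repeat {
                  z <- sample(0:2, m, replace = TRUE, prob = c(0.64, 0.32, 0.04))
                  if (length(unique(z)) > 1) break
                }
                z
              },
              binary = {
                repeat {
                  z <- rbinom(m, 1, 0.4)
                  if (length(unique(z)) > 1) break
                }
                z
              })
  C <- matrix(rnorm(m * n), m, n,
              dimnames = list(NULL, paste0("c", seq_len(n))))
  list(z = z, C = C)
}

# covariate matrix whose *sample* correlation matrix is exactly R:
# orthonormalize iid columns, then impose chol(R)
make_exact_cor_data <- function(m, R, seed = 1) {
  n <- ncol(R)
  set.seed(seed)
  X <- matrix(rnorm(m * n), m, n)
  X <- scale(X, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X))
  C <- Q %*% chol(R) * sqrt(m - 1)
  colnames(C) <- paste0("c", seq_len(n))
  C
}

make_dosage_panel <- function(m = 300, k = 3, seed = 1) {
  set.seed(seed)
  q <- seq(0.2, 0.4, length.out = k)
  d <- sapply(q, function(qq) sample(0:2, m, TRUE, c((1 - qq)^2, 2 * qq * (1 - qq), qq^2)))
  colnames(d) <- paste0("rs", seq_len(k))
  d
}
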