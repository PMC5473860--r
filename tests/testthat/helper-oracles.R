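# Independent oracles kept deliberately naive: explicit projection matrices,
# per-pair loops, textbook formulas. They never call the code paths they check.

# orthogonal projection onto the column space of A
proj_cols <- function(a) a %*% solve(crossprod(a)) %*% t(a)

# matrix correlation corr(A, B) = tr(A'B) / sqrt(tr(A'A) tr(B'B))
matrix_corr <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))

# RM via the explicit projection definition corr(X, Pk X)
rm_oracle <- function(x, k) {
  pk <- proj_cols(x[, k, drop = FALSE])
  sqrt(sum(diag(t(x) %*% pk %*% x)) / sum(diag(crossprod(x))))
}

# GCD via explicit projections: tr(Pk Pg) / sqrt(k g)
gcd_oracle <- function(x, k, g_set) {
  ev <- eigen(stats::cor(x), symmetric = TRUE)
  scores <- x %*% ev$vectors[, g_set, drop = FALSE]
  pk <- proj_cols(x[, k, drop = FALSE])
  pg <- proj_cols(scores)
  sum(pk * pg) / sqrt(length(k) * length(g_set))
}

# RV via the configuration-similarity definition corr(XX', Pk XX' Pk)
rv_oracle <- function(x, k) {
  pk <- proj_cols(x[, k, drop = FALSE])
  cfg <- x %*% t(x)
  matrix_corr(cfg, pk %*% cfg %*% pk)
}

# random standardized trait matrix (z-scores, full rank with prob 1)
random_standardized <- function(n, p, seed) {
  set.seed(seed)
  standardize_traits(trait_matrix(matrix(rnorm(n * p), n, p)))
}

# n x p data whose sample correlation matrix is exactly the identity:
# orthonormalize against the constant vector, then rescale to unit variance
identity_correlation_data <- function(n, p, seed = 1) {
  stopifnot(n > p + 1)
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
  z <- scale(q)
  dimnames(z) <- list(paste0("sp", 1:n), paste0("T", 1:p))
  tm <- trait_matrix(z[, , drop = FALSE])
  attr(tm, "standardized") <- TRUE
  tm
}

# naive per-pair Euclidean distance loop
dist_oracle <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  d
}

all_nonempty_subsets <- function(p) {
  unlist(lapply(seq_len(p), function(k) utils::combn(p, k, simplify = FALSE)),
         recursive = FALSE)
}
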