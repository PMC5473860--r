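#' Eigenvalues of the trait correlation matrix
#'
#' The eigenvalue profile of the p x p Pearson correlation matrix underlies
#' every dimensionality rule here and the subset-selection criteria; its
#' eigenvalues sum to p.
#'
#' @param tm a [trait_matrix()] with no constant trait
#' @return list of class `"eigen_profile"` with `eigenvalues` (descending,
#'   tiny negatives clipped to 0), `vectors` (columns are eigenvectors,
#'   sign-fixed so the largest-magnitude loading of each is positive),
#'   `total` (their sum) and `p`.
#' @export
correlation_eigenvalues <- function(tm) {
  x <- unclass(as_trait_matrix(tm))
  v <- apply(x, 2L, stats::var)
  if (any(v == 0))
    stop("constant trait: ", paste(colnames(x)[v == 0], collapse = ", "))
  r <- stats::cor(x)
  ev <- eigen(r, symmetric = TRUE)
  lam <- ev$values
  if (any(lam < -1e-10))
    stop("correlation matrix has a substantially negative eigenvalue")
  lam <- pmax(lam, 0)
  vec <- fix_eigenvector_signs(ev$vectors)
  rownames(vec) <- colnames(x)
  colnames(vec) <- paste0("PC", seq_along(lam))
  structure(list(eigenvalues = lam, vectors = vec, total = sum(lam),
                 p = ncol(x)),
            class = "eigen_profile")
}

# deterministic sign: largest |loading| of each eigenvector made positive,
# first occurrence on ties
fix_eigenvector_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' @export
print.eigen_profile <- function(x, ...) {
  cat("Correlation eigenvalues (p =", x$p, "):\n")
  print(round(x$eigenvalues, 4L))
  invisible(x)
}

#' Kaiser's rule
#'
#' Counts correlation-matrix eigenvalues strictly greater than 1, the
#' classical components-to-retain rule.
#'
#' @param ep an `"eigen_profile"` from [correlation_eigenvalues()]
#' @return integer count
#' @export
kaiser_count <- function(ep) {
  sum(ep$eigenvalues > 1)
}

#' Horn's parallel analysis
#'
#' Compares each observed eigenvalue with the distribution of the same-rank
#' eigenvalue across correlation matrices of `n_iter` uncorrelated
#' standard-normal datasets of identical shape. Components are retained from
#' rank 1 upward while the observed eigenvalue exceeds its reference
#' threshold, stopping at the first failure.
#'
#' @param tm a [trait_matrix()] (n >= 3 species)
#' @param n_iter number of random reference datasets (default 1000, min 10)
#' @param rule `"mean"` (default) or `"p95"`: summary of the reference
#'   eigenvalue distribution used as the threshold
#' @param seed integer seed; results are bit-reproducible given
#'   (n_iter, rule, seed)
#' @return list with `pa_k` (retained count), `thresholds` (per-rank
#'   reference eigenvalues), `observed`, and the settings.
#' @export
parallel_analysis <- function(tm, n_iter = 1000L, rule = c("mean", "p95"),
                              seed = 1L) {
  rule <- match.arg(rule)
  if (n_iter < 10L) stop("n_iter must be at least 10")
  x <- unclass(as_trait_matrix(tm))
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3L) stop("need at least 3 species")
  observed <- correlation_eigenvalues(x)$eigenvalues
  ref <- matrix(NA_real_, n_iter, p)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (i in seq_len(n_iter)) {
    r <- stats::cor(matrix(stats::rnorm(n * p), n, p))
    ref[i, ] <- sort(eigen(r, symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE)
  }
  thresholds <- if (rule == "mean") colMeans(ref) else
    apply(ref, 2L, stats::quantile, probs = 0.95, names = FALSE)
  exceeds <- observed > thresholds
  pa_k <- if (exceeds[1L]) {
    first_fail <- which(!exceeds)
    if (length(first_fail) == 0L) p else first_fail[1L] - 1L
  } else 0L
  list(pa_k = as.integer(pa_k), thresholds = thresholds, observed = observed,
       n_iter = as.integer(n_iter), rule = rule, seed = as.integer(seed))
}

# set.seed scoped to a computation; restores the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Scree elbow heuristic
#'
#' Automates the visual scree test: the elbow is placed where the eigenvalue
#' profile decelerates most, i.e. one rank before the position maximizing
#' the second difference of the profile. Always advisory; ties go to the
#' smallest rank.
#'
#' @param ep an `"eigen_profile"`; needs p >= 3
#' @return integer elbow rank, or `NA_integer_` when p < 3
#' @export
scree_elbow <- function(ep) {
  lam <- ep$eigenvalues
  p <- length(lam)
  if (p < 3L) return(NA_integer_)
  mid <- 2:(p - 1L)
  accel <- lam[mid - 1L] - 2 * lam[mid] + lam[mid + 1L]
  as.integer(mid[which.max(accel)] - 1L)
}

#' Estimate the intrinsic dimensionality of a trait matrix
#'
#' Runs Kaiser's rule, parallel analysis and the scree heuristic and reports
#' a consensus: the majority value of the three estimates, with ties (all
#' three distinct) resolved to parallel analysis. A user `override` is
#' recorded alongside, not instead of, the consensus.
#'
#' @param tm a [trait_matrix()]
#' @param n_iter,rule,seed passed to [parallel_analysis()]
#' @param override optional integer: a user-imposed dimensionality
#' @return list of class `"dimensionality_report"` with `kaiser_k`, `pa_k`,
#'   `scree_k`, `consensus_k`, `k` (override if given, else consensus),
#'   `pa_thresholds`, `eigenvalues`, and settings.
#' @export
estimate_dimensionality <- function(tm, n_iter = 1000L,
                                    rule = c("mean", "p95"), seed = 1L,
                                    override = NULL) {
  rule <- match.arg(rule)
  ep <- correlation_eigenvalues(tm)
  pa <- parallel_analysis(tm, n_iter = n_iter, rule = rule, seed = seed)
  kk <- kaiser_count(ep)
  sk <- scree_elbow(ep)
  ks <- c(kaiser = kk, pa = pa$pa_k, scree = sk)
  tab <- table(ks[!is.na(ks)])
  consensus <- if (any(tab >= 2L)) as.integer(names(tab)[tab >= 2L][1L])
               else pa$pa_k
  structure(list(kaiser_k = as.integer(kk), pa_k = pa$pa_k,
                 scree_k = sk, consensus_k = consensus,
                 k = if (is.null(override)) consensus
                     else as.integer(override),
                 override = if (is.null(override)) NA_integer_
                            else as.integer(override),
                 pa_thresholds = pa$thresholds, eigenvalues = ep$eigenvalues,
                 n_iter = pa$n_iter, rule = pa$rule, seed = pa$seed),
            class = "dimensionality_report")
}

#' @export
print.dimensionality_report <- function(x, ...) {
  cat("Intrinsic dimensionality estimates\n")
  cat(sprintf("  Kaiser's rule:      %d\n", x$kaiser_k))
  cat(sprintf("  Parallel analysis:  %d (%s of %d iterations, seed %d)\n",
              x$pa_k, x$rule, x$n_iter, x$seed))
  cat(sprintf("  Scree elbow:        %s (advisory heuristic)\n",
              ifelse(is.na(x$scree_k), "-", x$scree_k)))
  cat(sprintf("  Consensus:          %d\n", x$consensus_k))
  if (!is.na(x$override))
    cat(sprintf("  User override:      %d (used as k)\n", x$override))
  invisible(x)
}
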