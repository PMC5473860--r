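#' Build a criterion workspace for subset scoring
#'
#' Caches the matrices every subset criterion reuses: the p x p matrix S of
#' second moments of the standardized traits (the trait correlation matrix),
#' its square S^2, and its eigenstructure. Scoring a subset then only touches
#' small principal submatrices, which makes the complete search cheap.
#'
#' @param tm a standardized [trait_matrix()] (see [standardize_traits()]);
#'   unstandardized input is rejected.
#' @return list of class `"criterion_workspace"` with `X`, `S`, `S2`,
#'   `eigenvalues`, `vectors`, `trait_names`, `n`, `p`.
#' @export
build_workspace <- function(tm) {
  x <- as_trait_matrix(tm)
  if (!is_centered_unit(unclass(x)))
    stop("workspace requires standardized traits; call standardize_traits()")
  x <- unclass(x)
  s <- stats::cor(x)
  ev <- eigen(s, symmetric = TRUE)
  vec <- fix_eigenvector_signs(ev$vectors)
  rownames(vec) <- colnames(x)
  structure(list(X = x, S = s, S2 = s %*% s,
                 eigenvalues = pmax(ev$values, 0), vectors = vec,
                 trait_names = colnames(x), n = nrow(x), p = ncol(x)),
            class = "criterion_workspace")
}

#' @export
print.criterion_workspace <- function(x, ...) {
  cat(sprintf("Criterion workspace: %d species x %d traits\n", x$n, x$p))
  invisible(x)
}

# subsets may be trait names or integer indices; returns sorted indices
resolve_subset <- function(ws, subset) {
  if (length(subset) == 0L) stop("empty trait subset")
  if (is.character(subset)) {
    idx <- match(subset, ws$trait_names)
    if (anyNA(idx))
      stop("unknown trait(s): ", paste(subset[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(subset)
    if (any(idx < 1L | idx > ws$p)) stop("trait index out of range 1..", ws$p)
  }
  if (anyDuplicated(idx)) stop("duplicated traits in subset")
  sort(idx)
}

# inverse of a principal submatrix; falls back to the Moore-Penrose
# pseudo-inverse for collinear subsets so the complete search can sweep them
sub_inverse <- function(sk) {
  inv <- tryCatch(solve(sk), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    warning("singular trait submatrix; using Moore-Penrose pseudo-inverse",
            call. = FALSE)
    inv <- MASS::ginv(sk)
  }
  inv
}

#' RM coefficient of a trait subset
#'
#' Matrix correlation between the standardized trait matrix X and its
#' orthogonal projection onto the subspace spanned by the selected trait
#' columns: RM = sqrt(tr(S^2[k,k] S[k,k]^-1) / tr(S)). RM^2 is the fraction
#' of total trait variation the subset explains, the direct analogue of the
#' variance explained by the first k principal components.
#'
#' @param ws a [build_workspace()] result
#' @param subset trait names or indices (nonempty)
#' @return RM in \[0, 1\]
#' @export
rm_coefficient <- function(ws, subset) {
  k <- resolve_subset(ws, subset)
  val <- sum(diag(ws$S2[k, k, drop = FALSE] %*%
                  sub_inverse(ws$S[k, k, drop = FALSE]))) /
    sum(diag(ws$S))
  sqrt(min(max(val, 0), 1))
}

#' Yanai's Generalized Coefficient of Determination (GCD)
#'
#' Similarity between the subspace spanned by a trait subset and the
#' subspace spanned by selected principal components:
#' GCD = tr(S_G[k,k] S[k,k]^-1) / sqrt(g k), where S_G keeps only the g
#' spectral terms of S indexed by `pc_set`. 1 means identical subspaces,
#' 0 orthogonal ones.
#'
#' @inheritParams rm_coefficient
#' @param pc_set indices of the principal components defining the target
#'   subspace (default: the first `length(subset)` PCs)
#' @return GCD in \[0, 1\]
#' @export
gcd_coefficient <- function(ws, subset, pc_set = NULL) {
  k <- resolve_subset(ws, subset)
  if (is.null(pc_set)) pc_set <- seq_along(k)
  g <- as.integer(pc_set)
  if (length(g) == 0L) stop("empty PC set")
  if (anyDuplicated(g)) stop("repeated PC indices")
  if (any(g < 1L | g > ws$p)) stop("PC index out of range 1..", ws$p)
  vg <- ws$vectors[, g, drop = FALSE]
  sg <- vg %*% (ws$eigenvalues[g] * t(vg))   # rank-g spectral truncation of S
  val <- sum(diag(sg[k, k, drop = FALSE] %*%
                  sub_inverse(ws$S[k, k, drop = FALSE]))) /
    sqrt(length(g) * length(k))
  min(max(val, 0), 1)
}

#' RV coefficient of a trait subset
#'
#' Similarity of two point configurations of the species — one from all
#' standardized traits, one from the subset-projected traits — invariant to
#' translation, rigid rotation and global rescaling:
#' RV = sqrt(tr((S^2[k,k] S[k,k]^-1)^2)) / sqrt(tr(S^2)).
#'
#' @inheritParams rm_coefficient
#' @return RV in \[0, 1\]
#' @export
rv_coefficient <- function(ws, subset) {
  k <- resolve_subset(ws, subset)
  m <- ws$S2[k, k, drop = FALSE] %*% sub_inverse(ws$S[k, k, drop = FALSE])
  val <- sqrt(max(sum(diag(m %*% m)), 0)) / sqrt(sum(diag(ws$S2)))
  min(max(val, 0), 1)
}

criterion_fun <- function(criterion, pc_set) {
  switch(criterion,
         RM = function(ws, k) rm_coefficient(ws, k),
         GCD = function(ws, k) gcd_coefficient(ws, k, pc_set),
         RV = function(ws, k) rv_coefficient(ws, k))
}

#' Find the best trait subset of a given size under one criterion
#'
#' Exhaustively scans all choose(p, k) subsets (the default for the trait
#' counts this method targets), or runs seeded simulated annealing with
#' restarts when the enumeration would exceed `exhaustive_cap`. Ties go to
#' the lexicographically smallest subset.
#'
#' @inheritParams gcd_coefficient
#' @param k subset size (1..p)
#' @param criterion `"RM"`, `"GCD"` or `"RV"`
#' @param search `"exhaustive"` or `"anneal"`; `"auto"` (default) picks
#'   exhaustive while choose(p, k) <= `exhaustive_cap`
#' @param exhaustive_cap largest enumeration size accepted (default 2^15)
#' @param seed seed for annealing (ignored by exhaustive search)
#' @param restarts annealing restarts (default 5)
#' @return list of class `"subset_score"`: `subset` (trait names), `indices`,
#'   `criterion`, `value`, `pc_set`, `pct_variation` (100 RM^2 of the chosen
#'   subset) and `search`.
#' @export
best_subset <- function(ws, k, criterion = c("RM", "GCD", "RV"),
                        pc_set = NULL, search = c("auto", "exhaustive",
                                                  "anneal"),
                        exhaustive_cap = 32768, seed = 1L, restarts = 5L) {
  criterion <- match.arg(criterion)
  search <- match.arg(search)
  k <- as.integer(k)
  if (k < 1L || k > ws$p) stop("subset size k must be in 1..", ws$p)
  if (criterion == "GCD" && is.null(pc_set)) pc_set <- seq_len(k)
  score <- criterion_fun(criterion, pc_set)
  n_comb <- choose(ws$p, k)
  if (search == "auto")
    search <- if (n_comb <= exhaustive_cap) "exhaustive" else "anneal"
  if (search == "exhaustive" && n_comb > exhaustive_cap)
    stop("choose(p, k) = ", n_comb, " exceeds the exhaustive cap; ",
         "use search = \"anneal\" or raise exhaustive_cap")

  if (search == "exhaustive") {
    combos <- utils::combn(ws$p, k)
    best_val <- -Inf
    best_idx <- NULL
    for (j in seq_len(ncol(combos))) {    # combn order is lexicographic,
      v <- score(ws, combos[, j])         # so ties keep the smallest subset
      if (v > best_val + 1e-12) {
        best_val <- v
        best_idx <- combos[, j]
      }
    }
  } else {
    ann <- anneal_subset(ws, k, score, seed = seed, restarts = restarts)
    best_val <- ann$value
    best_idx <- ann$subset
  }
  subset_score(ws, best_idx, criterion, best_val, pc_set, search)
}

subset_score <- function(ws, idx, criterion, value, pc_set, search) {
  structure(list(subset = ws$trait_names[idx], indices = as.integer(idx),
                 criterion = criterion, value = value,
                 pc_set = if (is.null(pc_set)) NA else as.integer(pc_set),
                 pct_variation = 100 * rm_coefficient(ws, idx)^2,
                 search = search),
            class = "subset_score")
}

#' @export
print.subset_score <- function(x, ...) {
  cat(sprintf("%s = %.4f for {%s} (%.1f%% of total variation; %s search)\n",
              x$criterion, x$value, paste(x$subset, collapse = ", "),
              x$pct_variation, x$search))
  invisible(x)
}

# seeded simulated annealing over fixed-size subsets: swap one member for a
# non-member, geometric cooling, several restarts; returns the best visited
anneal_subset <- function(ws, k, score, seed = 1L, restarts = 5L,
                          n_steps = 2000L, t0 = 0.1, cooling = 0.995) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  best_val <- -Inf
  best_idx <- NULL
  for (r in seq_len(restarts)) {
    cur <- sort(sample.int(ws$p, k))
    cur_val <- score(ws, cur)
    temp <- t0
    for (s in seq_len(n_steps)) {
      cand <- cur
      out_pool <- setdiff(seq_len(ws$p), cur)
      if (length(out_pool) == 0L) break
      cand[sample.int(k, 1L)] <- out_pool[sample.int(length(out_pool), 1L)]
      cand <- sort(cand)
      cand_val <- score(ws, cand)
      if (cand_val >= cur_val ||
          stats::runif(1L) < exp((cand_val - cur_val) / temp)) {
        cur <- cand
        cur_val <- cand_val
      }
      if (cur_val > best_val + 1e-12 ||
          (abs(cur_val - best_val) <= 1e-12 && !is.null(best_idx) &&
           lex_less(cur, best_idx))) {
        best_val <- cur_val
        best_idx <- cur
      }
      temp <- temp * cooling
    }
  }
  list(subset = best_idx, value = best_val)
}

lex_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0L && d[nz[1L]] < 0
}

#' Score one subset by all three criteria
#'
#' Convenience for reporting a user-supplied subset (for example the
#' highest-loadings subset) under RM, GCD and RV at once.
#'
#' @inheritParams gcd_coefficient
#' @return data.frame with columns `criterion`, `value`, `pct_variation`
#'   (100 RM^2 and 100 RV^2 for RM/RV rows; GCD row repeats the GCD value
#'   scaled to percent, its own notion of explained information).
#' @export
score_subset_all_criteria <- function(ws, subset, pc_set = NULL) {
  idx <- resolve_subset(ws, subset)
  if (is.null(pc_set)) pc_set <- seq_along(idx)
  rm_v <- rm_coefficient(ws, idx)
  gcd_v <- gcd_coefficient(ws, idx, pc_set)
  rv_v <- rv_coefficient(ws, idx)
  data.frame(criterion = c("RM", "GCD", "RV"),
             value = c(rm_v, gcd_v, rv_v),
             pct_variation = c(100 * rm_v^2, 100 * gcd_v, 100 * rv_v^2),
             stringsAsFactors = FALSE)
}

#' Highest-loadings trait subset
#'
#' For each of the first `k` principal components of the trait correlation
#' matrix, picks the trait with the largest absolute loading (sign ignored;
#' within-PC ties go to the smaller trait index). One trait can dominate
#' several components, so the returned subset may hold fewer than `k`
#' traits.
#'
#' @param tm a standardized [trait_matrix()]
#' @param k number of leading principal components to read loadings from
#' @return character vector of trait names (unique, ordered by first PC of
#'   appearance) with attribute `"per_pc"` naming the top trait of each PC.
#' @export
highest_loading_subset <- function(tm, k) {
  ep <- correlation_eigenvalues(tm)
  k <- as.integer(k)
  if (k < 1L || k > ep$p) stop("k must be in 1..", ep$p)
  per_pc <- vapply(seq_len(k), function(j)
    which.max(abs(ep$vectors[, j])), integer(1L))  # which.max: smallest on tie
  traits <- rownames(ep$vectors)[per_pc]
  out <- unique(traits)
  attr(out, "per_pc") <- stats::setNames(traits, paste0("PC", seq_len(k)))
  out
}

#' Principal-component scores as pseudo-traits
#'
#' Projects the standardized traits onto the first `k` eigenvectors of the
#' correlation matrix. The score columns (PC1..PCk) can be used anywhere a
#' trait matrix is — the axis-based way of measuring functional diversity.
#' With k = p the projection is a rigid rotation, so all distance-based
#' indices are unchanged.
#'
#' @param tm a standardized [trait_matrix()]
#' @param k number of components (at most the rank of the matrix)
#' @return a [trait_matrix()] of scores with attributes `"pc_scores" = TRUE`
#'   (so index functions skip re-standardization) and
#'   `"cum_pct_variance"` (cumulative percent variance of the k components).
#' @export
pc_scores <- function(tm, k) {
  x <- as_trait_matrix(tm)
  if (!is_standardized(unclass(x), tol = 1e-6))
    x <- standardize_traits(x)
  ep <- correlation_eigenvalues(x)
  k <- as.integer(k)
  rank_x <- sum(ep$eigenvalues > 1e-10)
  if (k < 1L || k > rank_x)
    stop("k must be in 1..rank(X) = ", rank_x)
  scores <- unclass(x) %*% ep$vectors[, seq_len(k), drop = FALSE]
  out <- trait_matrix(scores)
  attr(out, "pc_scores") <- TRUE
  attr(out, "cum_pct_variance") <-
    100 * cumsum(ep$eigenvalues[seq_len(k)]) / ep$p
  out
}
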