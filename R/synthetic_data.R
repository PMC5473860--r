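#' Simulate a trait matrix with planted factor dimensionality
#'
#' Generates X = F L' + noise: `n_species` x `g` standard-normal factor
#' scores F and a p x g loading matrix L (block structure by default: traits
#' assigned to factors round-robin, loading `loading` on the own factor and
#' 0 elsewhere; `loading_style = "random"` draws all loadings uniformly and
#' renormalizes rows). This emulates field trait tables whose correlation
#' structure has a small number of latent dimensions (typically two to
#' four) with partial pairwise trait correlation, giving dimensionality
#' estimators and subset criteria a known truth.
#'
#' @param n_species number of species (rows)
#' @param p number of traits (columns)
#' @param g number of latent dimensions (1 <= g <= p)
#' @param loading loading magnitude on the own factor (default 0.8)
#' @param noise_sd standard deviation of the added Gaussian noise
#'   (default 0.6; must be > 0)
#' @param loading_style `"block"` (default) or `"random"`
#' @param seed integer seed; recorded in the output metadata
#' @return a [trait_matrix()] with attribute `"sim_config"` (list holding
#'   the full configuration, the true `g` and the loading matrix).
#' @export
simulate_trait_matrix <- function(n_species = 150L, p = 10L, g = 4L,
                                  loading = 0.8, noise_sd = 0.6,
                                  loading_style = c("block", "random"),
                                  seed = 1L) {
  loading_style <- match.arg(loading_style)
  if (g < 1L || g > p) stop("need 1 <= g <= p")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  f <- matrix(stats::rnorm(n_species * g), n_species, g)
  lam <- matrix(0, p, g)
  if (loading_style == "block") {
    for (j in seq_len(p)) lam[j, ((j - 1L) %% g) + 1L] <- loading
  } else {
    lam[] <- stats::runif(p * g, -1, 1)
    lam <- loading * lam / sqrt(rowSums(lam^2))
  }
  x <- f %*% t(lam) + matrix(stats::rnorm(n_species * p, sd = noise_sd),
                             n_species, p)
  dimnames(x) <- list(paste0("sp", seq_len(n_species)),
                      paste0("T", seq_len(p)))
  out <- trait_matrix(x)
  attr(out, "sim_config") <- list(n_species = n_species, p = p, g = g,
                                  loading = loading, noise_sd = noise_sd,
                                  loading_style = loading_style,
                                  seed = seed, loadings = lam)
  out
}

# uniform draw that stays fixed for a degenerate range (sample() would
# otherwise expand a single value m into 1:m)
sample_richness <- function(rr) {
  if (rr[1L] == rr[2L]) rr[1L] else sample(rr[1L]:rr[2L], 1L)
}

#' Simulate communities along a species-richness gradient
#'
#' Per community, draws a richness uniformly within `richness_range`,
#' assembles that many species (at random, or nested by the first trait),
#' and assigns abundances (equal, or lognormal with the given sd on the log
#' scale). Species absent from a community get abundance 0.
#'
#' @param tm a [trait_matrix()] providing the species pool
#' @param n_communities number of communities
#' @param richness_range integer (min, max) within \[1, n_species\]
#' @param assembly `"random"` (default) or `"nested"` (communities are
#'   nested prefixes of the species ranked by the first trait)
#' @param abundance `"equal"` or `"lognormal"`
#' @param lognormal_sd sd of log-abundance when `abundance = "lognormal"`
#' @param seed integer seed; recorded in the output metadata
#' @return a [community_matrix()] with attribute `"sim_config"`.
#' @export
simulate_communities <- function(tm, n_communities = 100L,
                                 richness_range = c(2L, 30L),
                                 assembly = c("random", "nested"),
                                 abundance = c("equal", "lognormal"),
                                 lognormal_sd = 1, seed = 1L) {
  assembly <- match.arg(assembly)
  abundance <- match.arg(abundance)
  tmx <- as_trait_matrix(tm)
  n <- nrow(tmx)
  rr <- as.integer(richness_range)
  if (length(rr) != 2L || rr[1L] < 1L || rr[2L] > n || rr[1L] > rr[2L])
    stop("richness_range must be within [1, ", n, "] with min <= max")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  rank_order <- order(unclass(tmx)[, 1L])
  a <- matrix(0, n_communities, n,
              dimnames = list(paste0("com", seq_len(n_communities)),
                              rownames(tmx)))
  for (i in seq_len(n_communities)) {
    s <- sample_richness(rr)
    sel <- if (assembly == "random") sample.int(n, s) else rank_order[1:s]
    a[i, sel] <- if (abundance == "equal") 1 else
      stats::rlnorm(s, sdlog = lognormal_sd)
  }
  out <- community_matrix(a)
  attr(out, "sim_config") <- list(n_communities = n_communities,
                                  richness_range = rr, assembly = assembly,
                                  abundance = abundance,
                                  lognormal_sd = lognormal_sd, seed = seed)
  out
}

#' Simulate communities with a planted richness-diversity association
#'
#' Assembles communities so that trait dispersion within the planted trait
#' subset is tightly and linearly coupled to species richness, while
#' dispersion in other trait combinations keeps ordinary random-assembly
#' scatter. For each community a richness s is drawn, then
#' `1 + strength * (n_candidates - 1)` random compositions of size s are
#' drawn and the one whose summed pairwise distance in the planted
#' subset's standardized trait space (its FAD) is closest to a linear
#' richness target is kept. The target is the chord of the expected
#' random-assembly FAD curve, choose(s, 2) * mean pool distance, across the
#' richness range, so the planted subset's diversity-richness relation is
#' both low-noise and near-linear. At `strength = 0` a single candidate is
#' drawn and assembly is purely random.
#'
#' @param tm a [trait_matrix()]
#' @param planted_subset trait names or indices of the planted subset
#' @param strength selection intensity in \[0, 1\]; 1 = full candidate set,
#'   0 = random assembly
#' @param n_candidates candidate compositions screened per community at
#'   strength 1 (default 40)
#' @param n_communities,richness_range,abundance,lognormal_sd,seed as in
#'   [simulate_communities()]
#' @return a [community_matrix()] with attribute `"sim_config"` recording
#'   the planted subset and strength.
#' @export
plant_association <- function(tm, planted_subset, strength = 1,
                              n_communities = 100L,
                              richness_range = c(2L, 30L),
                              n_candidates = 40L,
                              abundance = c("equal", "lognormal"),
                              lognormal_sd = 1, seed = 1L) {
  abundance <- match.arg(abundance)
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  tmx <- as_trait_matrix(tm)
  z <- unclass(standardize_traits(tmx))
  idx <- if (is.character(planted_subset))
    match(planted_subset, colnames(z)) else as.integer(planted_subset)
  if (length(idx) == 0L || anyNA(idx)) stop("invalid planted subset")
  n <- nrow(z)
  rr <- as.integer(richness_range)
  if (rr[1L] < 1L || rr[2L] > n || rr[1L] > rr[2L])
    stop("richness_range must be within [1, ", n, "]")
  d_sub <- as.matrix(stats::dist(z[, idx, drop = FALSE]))
  d_bar <- mean(d_sub[upper.tri(d_sub)])
  expected_fad <- function(s) choose(s, 2) * d_bar
  target <- function(s)                       # chord across the range
    expected_fad(rr[1L]) + (expected_fad(rr[2L]) - expected_fad(rr[1L])) *
      (s - rr[1L]) / max(rr[2L] - rr[1L], 1L)
  n_cand <- max(1L, 1L + round(strength * (n_candidates - 1L)))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  a <- matrix(0, n_communities, n,
              dimnames = list(paste0("com", seq_len(n_communities)),
                              rownames(z)))
  for (i in seq_len(n_communities)) {
    s <- sample_richness(rr)
    cands <- replicate(n_cand, sample.int(n, s), simplify = FALSE)
    fads <- vapply(cands, function(cc) sum(d_sub[cc, cc]) / 2, numeric(1L))
    sel <- cands[[which.min(abs(fads - target(s)))]]
    a[i, sel] <- if (abundance == "equal") 1 else
      stats::rlnorm(s, sdlog = lognormal_sd)
  }
  out <- community_matrix(a)
  attr(out, "sim_config") <- list(planted_subset = colnames(z)[idx],
                                  strength = strength,
                                  n_communities = n_communities,
                                  richness_range = rr,
                                  abundance = abundance,
                                  lognormal_sd = lognormal_sd, seed = seed)
  out
}

#' Small deterministic fixture: 6 species x 4 traits, 8 communities
#'
#' A fixed trait table and community table whose functional diversity
#' values were verified by hand at creation, for worked examples and tests.
#' Trait values are integers chosen so the standardized columns have simple
#' structure; communities span richness 1 to 6.
#'
#' @return list with `traits` (a [trait_matrix()]) and `communities`
#'   (a [community_matrix()]).
#' @export
fixture_small <- function() {
  traits <- matrix(c(
    # A    B    C    D
      2,   4,   1,   3,
      4,   8,   1,   5,
      6,   2,   3,   1,
      8,   6,   3,   7,
      10,  10,  5,   9,
      12,  12,  5,   11), nrow = 6L, byrow = TRUE,
    dimnames = list(paste0("sp", 1:6), c("A", "B", "C", "D")))
  communities <- matrix(c(
    # sp1 sp2 sp3 sp4 sp5 sp6
      1,  0,  0,  0,  0,  0,
      0,  2,  0,  0,  0,  0,
      1,  1,  0,  0,  0,  0,
      0,  0,  3,  1,  0,  0,
      2,  0,  1,  0,  1,  0,
      1,  1,  1,  1,  0,  0,
      0,  1,  1,  1,  1,  1,
      1,  1,  1,  1,  1,  1), nrow = 8L, byrow = TRUE,
    dimnames = list(paste0("com", 1:8), paste0("sp", 1:6)))
  list(traits = trait_matrix(traits),
       communities = community_matrix(communities))
}
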