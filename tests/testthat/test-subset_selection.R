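test_that("workspace caches the correlation structure of standardized traits", {
  z <- random_standardized(20, 6, seed = 1)
  ws <- build_workspace(z)
  expect_equal(ws$S, cor(unclass(z)), tolerance = 1e-12)
  expect_equal(ws$S2, ws$S %*% ws$S, tolerance = 1e-10)
  recon <- ws$vectors %*% (ws$eigenvalues * t(ws$vectors))
  expect_equal(recon, ws$S, tolerance = 1e-8, ignore_attr = TRUE)

  raw <- trait_matrix(matrix(rnorm(40, 10, 4), 10, 4))
  expect_error(build_workspace(raw), "standardized")

  # rank-deficient input (duplicated trait) tolerated
  set.seed(2)
  x <- matrix(rnorm(30), 10, 3)
  dup <- standardize_traits(trait_matrix(cbind(x, x[, 1])))
  ws_dup <- build_workspace(dup)
  expect_lt(min(ws_dup$eigenvalues), 1e-8)
})

test_that("criteria match explicit projection/configuration oracles", {
  for (s in 1:20) {
    z <- random_standardized(20, 6, seed = 100 + s)
    ws <- build_workspace(z)
    x <- unclass(z)
    subsets <- list(1L, c(1L, 3L), c(2L, 5L), c(1L, 4L, 6L), 1:5)
    for (k in subsets) {
      expect_equal(rm_coefficient(ws, k), rm_oracle(x, k), tolerance = 1e-10)
      expect_equal(rv_coefficient(ws, k), rv_oracle(x, k), tolerance = 1e-10)
      g <- seq_len(min(length(k), 3L))
      expect_equal(gcd_coefficient(ws, k, g), gcd_oracle(x, k, g),
                   tolerance = 1e-10)
    }
  }
})

test_that("criteria hit their analytic limits", {
  # full set: identical subspaces
  z <- random_standardized(15, 5, seed = 42)
  ws <- build_workspace(z)
  expect_equal(rm_coefficient(ws, 1:5), 1, tolerance = 1e-10)
  expect_equal(rv_coefficient(ws, 1:5), 1, tolerance = 1e-10)
  expect_equal(gcd_coefficient(ws, 1:5, 1:5), 1, tolerance = 1e-10)

  # exactly uncorrelated traits: RM = RV = sqrt(k/p) for every subset
  tm <- identity_correlation_data(20, 6, seed = 3)
  wsi <- build_workspace(tm)
  for (k in list(2L, c(1L, 4L), c(2L, 3L, 5L), 1:6)) {
    expect_equal(rm_coefficient(wsi, k), sqrt(length(k) / 6),
                 tolerance = 1e-9)
    expect_equal(rv_coefficient(wsi, k), sqrt(length(k) / 6),
                 tolerance = 1e-9)
  }

  # orthogonal subspaces: trait independent of the PC-1 plane has GCD 0
  set.seed(9)
  x1 <- scale(rnorm(25))[, 1]
  x3 <- scale(resid(lm(rnorm(25) ~ x1)))[, 1]     # exactly orthogonal to x1
  z3 <- trait_matrix(cbind(A = x1, B = x1, C = x3))
  attr(z3, "standardized") <- TRUE
  ws3 <- build_workspace(z3)
  expect_equal(ws3$eigenvalues, c(2, 1, 0), tolerance = 1e-9)
  expect_equal(gcd_coefficient(ws3, 3L, pc_set = 1L), 0, tolerance = 1e-10)

  expect_error(rm_coefficient(ws, integer(0)), "empty")
  expect_error(rm_coefficient(ws, 9L), "out of range")
  expect_error(gcd_coefficient(ws, 1:2, c(1L, 1L)), "repeated")
})

test_that("RM and RV never decrease when a trait is added", {
  z <- random_standardized(25, 7, seed = 55)
  ws <- build_workspace(z)
  for (sub in all_nonempty_subsets(7)) {
    if (length(sub) == 7) next
    rm0 <- rm_coefficient(ws, sub)
    rv0 <- rv_coefficient(ws, sub)
    for (extra in setdiff(1:7, sub)) {
      expect_gte(rm_coefficient(ws, c(sub, extra)), rm0 - 1e-10)
      expect_gte(rv_coefficient(ws, c(sub, extra)), rv0 - 1e-10)
    }
  }
})

test_that("criterion values ignore trait order and the S denominator", {
  set.seed(66)
  raw <- matrix(rnorm(120, 3, 2), 20, 6)
  z1 <- standardize_traits(trait_matrix(raw))
  z2 <- standardize_traits(trait_matrix(raw), sd_denominator = "n")
  perm <- c(4, 1, 6, 2, 5, 3)
  zp <- standardize_traits(trait_matrix(raw[, perm]))
  ws1 <- build_workspace(z1)
  ws2 <- build_workspace(z2)
  wsp <- build_workspace(zp)
  sub <- c(2L, 5L)                           # traits 2 and 5 of the original
  sub_p <- match(sub, perm)
  for (f in list(rm_coefficient, rv_coefficient)) {
    expect_equal(f(ws1, sub), f(ws2, sub), tolerance = 1e-10)
    expect_equal(f(ws1, sub), f(wsp, sub_p), tolerance = 1e-10)
  }
  expect_equal(gcd_coefficient(ws1, sub, 1:2), gcd_coefficient(ws2, sub, 1:2),
               tolerance = 1e-10)
})

test_that("best_subset finds the optimum; annealing matches exhaustive", {
  z <- random_standardized(30, 5, seed = 8)
  ws <- build_workspace(z)
  full <- best_subset(ws, 5, "RM")
  expect_equal(full$value, 1, tolerance = 1e-10)
  expect_equal(full$indices, 1:5)

  # planted redundancy: a duplicated trait is the one dropped at k = p - 1
  set.seed(10)
  x <- matrix(rnorm(100), 25, 4)
  dup <- standardize_traits(trait_matrix(cbind(x, x[, 2] * 2 + 1)))
  wsd <- build_workspace(dup)
  bs <- suppressWarnings(best_subset(wsd, 4, "RM"))
  expect_equal(rm_coefficient(wsd, bs$indices),
               suppressWarnings(rm_coefficient(wsd, 1:5)), tolerance = 1e-9)
  expect_true(!(2L %in% bs$indices) || !(5L %in% bs$indices))

  # exhaustive value dominates every enumerated subset
  best_rv <- best_subset(ws, 2, "RV")
  for (sub in combn(5, 2, simplify = FALSE))
    expect_gte(best_rv$value + 1e-10, rv_coefficient(ws, sub))

  # seeded annealing recovers the exhaustive optimum
  z10 <- random_standardized(40, 10, seed = 12)
  ws10 <- build_workspace(z10)
  for (crit in c("RM", "GCD", "RV")) {
    ex <- best_subset(ws10, 4, crit)
    an <- best_subset(ws10, 4, crit, search = "anneal", seed = 99)
    expect_equal(an$indices, ex$indices)
    expect_equal(an$value, ex$value, tolerance = 1e-9)
  }

  expect_error(best_subset(ws, 0, "RM"), "1..")
  expect_error(best_subset(ws10, 4, "RM", exhaustive_cap = 10,
                           search = "exhaustive"), "cap")
})

test_that("scoring one subset by all three criteria is consistent", {
  z <- random_standardized(20, 6, seed = 31)
  ws <- build_workspace(z)
  sc_full <- score_subset_all_criteria(ws, 1:6)
  expect_equal(sc_full$value, c(1, 1, 1), tolerance = 1e-10)

  sub <- c(2L, 4L, 5L)
  sc <- score_subset_all_criteria(ws, sub, pc_set = 1:3)
  expect_equal(sc$value[sc$criterion == "RM"], rm_coefficient(ws, sub))
  expect_equal(sc$value[sc$criterion == "GCD"],
               gcd_coefficient(ws, sub, 1:3))
  expect_equal(sc$value[sc$criterion == "RV"], rv_coefficient(ws, sub))
  expect_equal(sc$pct_variation[1], 100 * rm_coefficient(ws, sub)^2)
})

test_that("highest-loadings picks per-PC argmax traits and collapses repeats", {
  z <- random_standardized(30, 6, seed = 77)
  hl <- highest_loading_subset(z, 3)
  ep <- correlation_eigenvalues(z)
  for (j in 1:3)
    expect_equal(attr(hl, "per_pc")[[j]],
                 rownames(ep$vectors)[which.max(abs(ep$vectors[, j]))])

  # correlated-factor fixture in which one trait dominates two of the first
  # four PCs: the subset collapses below k
  tmc <- simulate_trait_matrix(50, 6, 2, loading = 0.9, noise_sd = 0.5,
                               seed = 2)
  zc <- standardize_traits(tmc)
  hl4 <- highest_loading_subset(zc, 4)
  per_pc <- attr(hl4, "per_pc")
  expect_equal(length(per_pc), 4L)
  expect_lt(length(hl4), 4L)           # repeats collapse
  expect_equal(as.vector(hl4), unique(unname(per_pc)))
  # per-PC picks agree with a direct eigenvector argmax oracle
  epc <- correlation_eigenvalues(zc)
  for (j in 1:4)
    expect_equal(unname(per_pc[j]),
                 rownames(epc$vectors)[which.max(abs(epc$vectors[, j]))])
})

test_that("PC scores are eigen-projections with cumulative variance metadata", {
  z <- random_standardized(30, 6, seed = 21)
  sc <- pc_scores(z, 3)
  ep <- correlation_eigenvalues(z)
  oracle <- unclass(z) %*% ep$vectors[, 1:3]
  for (j in 1:3) {
    agree <- max(abs(unclass(sc)[, j] - oracle[, j]))
    flipped <- max(abs(unclass(sc)[, j] + oracle[, j]))
    expect_lt(min(agree, flipped), 1e-10)    # per-axis sign freedom
  }
  expect_equal(attr(sc, "cum_pct_variance"),
               100 * cumsum(ep$eigenvalues[1:3]) / 6, tolerance = 1e-10)
  expect_error(pc_scores(z, 7), "rank")
})
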