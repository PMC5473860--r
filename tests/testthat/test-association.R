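test_that("species richness counts positive abundances", {
  cm <- community_matrix(matrix(c(0, 2, 0.1,
                                  1, 1, 1), 2, 3, byrow = TRUE,
                                dimnames = list(c("c1", "c2"),
                                                c("s1", "s2", "s3"))))
  expect_equal(unname(species_richness(cm)), c(2L, 3L))
  set.seed(50)
  a <- matrix(rbinom(80, 1, 0.4) * runif(80), 10, 8)
  a[rowSums(a) == 0, 1] <- 1
  cm2 <- community_matrix(a)
  naive <- vapply(seq_len(10), function(i) sum(a[i, ] > 0), integer(1))
  expect_equal(unname(species_richness(cm2)), naive)
})

test_that("linear COD matches closed-form r^2 and t-statistic formulas", {
  x <- c(2, 5, 8, 11)
  expect_equal(suppressWarnings(linear_cod(x, 2 * x)$cod), 1,
               tolerance = 1e-12)

  set.seed(8)
  x2 <- rnorm(30)
  y_perp <- resid(lm(rnorm(30) ~ x2))
  expect_lt(linear_cod(x2, y_perp)$cod, 1e-20)

  # 8-point fixture against the textbook formulas
  xf <- c(1, 2, 4, 5, 7, 8, 10, 12)
  yf <- c(0.3, 0.9, 1.4, 2.6, 2.2, 3.9, 4.1, 5.2)
  lc <- linear_cod(xf, yf)
  r <- cor(xf, yf)
  expect_equal(lc$cod, r^2, tolerance = 1e-12)
  tt <- r * sqrt((8 - 2) / (1 - r^2))
  expect_equal(lc$p_value, 2 * pt(abs(tt), df = 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(lc$slope, cov(xf, yf) / var(xf), tolerance = 1e-12)

  # degenerate responses are flagged, not scored zero
  dg <- linear_cod(xf, rep(2, 8))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$cod))
  expect_error(linear_cod(1:2, 1:2), "at least 3")
})

test_that("p-values bin into the six reporting classes", {
  expect_equal(as.character(p_bin(0.03)), "0.01<P<=0.05")
  expect_equal(as.character(p_bin(1e-20)), "P<=1e-20")   # boundary inclusive
  expect_equal(as.character(p_bin(0.5)), "P>0.05")
  expect_equal(as.character(p_bin(1e-21)), "P<=1e-20")
  expect_equal(as.character(p_bin(c(1e-12, 1e-7, 0.005))),
               c("1e-20<P<=1e-11", "1e-11<P<=1e-5", "1e-5<P<=0.01"))
  expect_true(is.ordered(p_bin(0.2)))
})

test_that("complete search enumerates every nonempty subset exactly once", {
  set.seed(15)
  tm <- simulate_trait_matrix(25, 7, 3, seed = 61)
  cm <- simulate_communities(tm, 40, c(2, 15), seed = 62)
  cs <- complete_search(tm, cm)
  expect_equal(cs$n_subsets, 2^7 - 1)
  expect_equal(nrow(cs$results), (2^7 - 1) * 4)
  # bijection with nonempty subsets, per index
  for (ind in c("FAD", "FD", "Q", "FDis")) {
    subs <- cs$results$subset[cs$results$index == ind]
    expect_equal(length(unique(subs)), 2^7 - 1)
  }
  oracle_subsets <- sort(vapply(all_nonempty_subsets(7), function(s)
    paste(paste0("T", s), collapse = ";"), character(1)))
  expect_equal(sort(unique(cs$results$subset)), oracle_subsets)

  # best row is the per-index maximum
  for (ind in cs$indices) {
    r <- cs$results[cs$results$index == ind, ]
    expect_equal(cs$best$cod[cs$best$index == ind], max(r$cod, na.rm = TRUE),
                 tolerance = 1e-12)
  }

  # by-size summaries cover all sizes
  expect_equal(sort(unique(cs$by_size$size)), 1:7)

  # k_range restriction
  cs2 <- complete_search(tm, cm, indices = "FAD", k_range = c(2, 3))
  expect_equal(cs2$n_subsets, choose(7, 2) + choose(7, 3))

  wide <- simulate_trait_matrix(20, 16, 4, seed = 63)
  cm_wide <- simulate_communities(wide, 10, c(2, 10), seed = 64)
  expect_error(complete_search(wide, cm_wide), "max_p")
})

test_that("complete search rows agree with fd_profile + linear_cod", {
  fx <- fixture_small()
  cs <- complete_search(fx$traits, fx$communities)
  rich <- species_richness(fx$communities)
  for (sub in list(c("A"), c("B", "D"), c("A", "C", "D"))) {
    prof <- fd_profile(fx$communities, fx$traits, subset = sub)
    key <- paste(sub, collapse = ";")
    for (ind in c("FAD", "FD", "Q", "FDis")) {
      row <- cs$results[cs$results$subset == key & cs$results$index == ind, ]
      # 1e-8: the search engine computes FDis distances via the expanded
      # square form, which loses a few digits to cancellation
      lc <- linear_cod(rich, prof[[ind]])
      expect_equal(row$cod, lc$cod, tolerance = 1e-6)
      expect_equal(row$slope, lc$slope, tolerance = 1e-6)
      expect_equal(row$p_value, lc$p_value, tolerance = 1e-6)
    }
  }
})

test_that("run_method composes selection, indices and regression", {
  tm <- simulate_trait_matrix(40, 8, 4, seed = 71)
  cm <- simulate_communities(tm, 50, c(2, 20), seed = 72)
  rich <- species_richness(cm)

  # PC with k = p reproduces the full-trait association exactly
  pc_full <- run_method(tm, cm, "PC", k = 8)
  prof_full <- fd_profile(cm, tm)
  for (ind in c("FAD", "FD", "Q", "FDis"))
    expect_equal(pc_full$cod[pc_full$index == ind],
                 linear_cod(rich, prof_full[[ind]])$cod, tolerance = 1e-9)

  # each method is reproducible by manual composition
  z <- standardize_traits(tm)
  ws <- build_workspace(z)
  for (m in c("RM", "GCD", "RV", "HL")) {
    res <- run_method(tm, cm, m, k = 4)
    sub <- if (m == "HL") highest_loading_subset(z, 4) else
      best_subset(ws, 4, criterion = m)$subset
    prof <- fd_profile(cm, tm, subset = sub)
    for (ind in c("FAD", "FD", "Q", "FDis"))
      expect_equal(res$cod[res$index == ind],
                   linear_cod(rich, prof[[ind]])$cod, tolerance = 1e-10)
    expect_equal(res$subset[1], paste(sub, collapse = ";"))
  }

  # RM drops a planted duplicate trait
  x <- unclass(tm)
  dup <- trait_matrix(cbind(x[, 1:7], T8 = x[, 1] * 3 + 2))
  cm_d <- simulate_communities(dup, 40, c(2, 20), seed = 73)
  res_d <- suppressWarnings(run_method(dup, cm_d, "RM", k = 7))
  chosen <- strsplit(res_d$subset[1], ";")[[1]]
  expect_false(all(c("T1", "T8") %in% chosen))
})

test_that("complete-search best COD dominates every selection method", {
  tm <- simulate_trait_matrix(30, 7, 4, seed = 81)
  cm <- simulate_communities(tm, 50, c(2, 15), seed = 82)
  cs <- complete_search(tm, cm)
  for (m in c("PC", "RM", "GCD", "RV", "HL")) {
    res <- run_method(tm, cm, m, k = 4)
    for (ind in c("FAD", "FD", "Q", "FDis")) {
      best <- cs$best$cod[cs$best$index == ind]
      expect_gte(best + 1e-9, res$cod[res$index == ind])
    }
  }
})

test_that("method comparison runs the two-way ANOVA with letter groups", {
  methods <- c("PC", "RM", "GCD", "RV", "HL", "CS")
  idx <- c("FAD", "FD", "Q", "FDis")
  grid0 <- expand.grid(dataset = paste0("d", 1:6), method = methods,
                       index = idx, stringsAsFactors = FALSE)

  # all CODs equal: one shared letter per index
  g1 <- transform(grid0, cod = 0.5)
  g1$cod <- g1$cod + rnorm(nrow(g1), sd = 1e-6)  # avoid exactly-zero MS
  mc1 <- compare_methods(g1)
  for (ind in idx)
    expect_equal(length(unique(
      mc1$letters$letters[mc1$letters$index == ind])), 1L)

  # one method shifted by +0.4 sits in its own letter group
  set.seed(90)
  g2 <- grid0
  g2$cod <- 0.4 + rnorm(nrow(g2), sd = 0.02) +
    ifelse(g2$method == "CS", 0.4, 0)
  mc2 <- compare_methods(g2)
  for (ind in idx) {
    li <- mc2$letters[mc2$letters$index == ind, ]
    cs_letter <- li$letters[li$method == "CS"]
    expect_false(cs_letter %in% li$letters[li$method != "CS"])
  }

  # missing cell rejected
  expect_error(compare_methods(g2[-1, ]), "incomplete")
})

test_that("ANOVA sums of squares match a normal-equations oracle", {
  set.seed(91)
  grid <- expand.grid(dataset = paste0("d", 1:3), method = c("A", "B", "C"),
                      index = c("I1", "I2"), stringsAsFactors = FALSE)
  grid$cod <- runif(nrow(grid), 0.2, 0.9)
  mc <- compare_methods(grid)
  tab <- mc$anova[[1]]
  rownames(tab) <- trimws(rownames(tab))

  # balanced-design decomposition from cell and marginal means
  y <- grid$cod
  gbar <- mean(y)
  ss <- function(means, reps) sum(reps * (means - gbar)^2)
  m_meth <- tapply(y, grid$method, mean)
  m_idx <- tapply(y, grid$index, mean)
  m_cell <- tapply(y, list(grid$method, grid$index), mean)
  ss_meth <- ss(m_meth, 6)
  ss_idx <- ss(m_idx, 9)
  ss_cells <- ss(m_cell, 3)
  ss_int <- ss_cells - ss_meth - ss_idx
  expect_equal(tab["method", "Sum Sq"], ss_meth, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tab["index", "Sum Sq"], ss_idx, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tab["method:index", "Sum Sq"], ss_int, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tab["Residuals", "Sum Sq"], sum((y - gbar)^2) - ss_cells,
               tolerance = 1e-10, ignore_attr = TRUE)
})
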