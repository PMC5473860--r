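#' Species richness per community
#'
#' @param cm a [community_matrix()]
#' @return named integer vector: count of species with positive abundance.
#' @export
species_richness <- function(cm) {
  a <- unclass(community_matrix(cm))
  stats::setNames(as.integer(rowSums(a > 0)), rownames(a))
}

#' Closeness of association: linear regression of an index on richness
#'
#' Ordinary least squares y = a + b x. The coefficient of determination
#' (COD, R^2) measures the closeness of association between a functional
#' diversity index and the ecosystem property; the two-sided p-value of the
#' slope tests it. A constant y (possible for degenerate index series) is
#' flagged degenerate with COD recorded as missing, so it cannot bias
#' summaries; a constant x is an error-level degeneracy flagged likewise.
#'
#' @param x numeric predictor (species richness), length >= 3
#' @param y numeric response (a functional diversity index)
#' @return one-row data.frame: `n`, `slope`, `intercept`, `cod`, `p_value`,
#'   `p_bin`, `degenerate`.
#' @export
linear_cod <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 communities")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(data.frame(n = length(x), slope = NA_real_, intercept = NA_real_,
                      cod = NA_real_, p_value = NA_real_,
                      p_bin = NA_character_, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- sm$coefficients[2L, 4L]
  data.frame(n = length(x), slope = stats::coef(fit)[[2L]],
             intercept = stats::coef(fit)[[1L]], cod = sm$r.squared,
             p_value = p, p_bin = p_bin(p), degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Bin a p-value into six reporting classes
#'
#' The six ordered classes used to color association landscapes:
#' P <= 1e-20; (1e-20, 1e-11\]; (1e-11, 1e-5\]; (1e-5, 0.01\];
#' (0.01, 0.05\]; P > 0.05.
#'
#' @param p p-value(s) in (0, 1\]
#' @return factor with the six ordered levels
#' @export
p_bin <- function(p) {
  levs <- c("P<=1e-20", "1e-20<P<=1e-11", "1e-11<P<=1e-5", "1e-5<P<=0.01",
            "0.01<P<=0.05", "P>0.05")
  cut(p, breaks = c(-Inf, 1e-20, 1e-11, 1e-5, 0.01, 0.05, Inf),
      labels = levs, right = TRUE, ordered_result = TRUE)
}

# ---- fast index engine shared by the complete search -----------------------
# Precomputes per-community presence/abundance matrices once; per subset it
# computes all four indices for all communities with matrix algebra:
#   FAD = b' D b / 2, Q = w' D w / 2, FDis via centroid distances,
#   FD via the edge x community incidence of the subset's UPGMA tree.
search_engine <- function(cm, tm) {
  tmx <- as_trait_matrix(tm)
  cmx <- reconcile_species(community_matrix(cm), tmx)
  x <- prepare_trait_space(tmx)
  a <- unclass(cmx)
  b <- (a > 0) * 1
  w <- a / rowSums(a)
  list(X = x, B = b, W = w, richness = as.integer(rowSums(b)),
       community_ids = rownames(a), trait_names = colnames(x))
}

engine_indices <- function(eng, idx, indices, include_root = FALSE) {
  xs <- eng$X[, idx, drop = FALSE]
  d <- as.matrix(stats::dist(xs))
  out <- list()
  if ("FAD" %in% indices)
    out$FAD <- rowSums((eng$B %*% d) * eng$B) / 2
  if ("Q" %in% indices)
    out$Q <- rowSums((eng$W %*% d) * eng$W) / 2
  if ("FDis" %in% indices) {
    cen <- eng$W %*% xs                       # m x k centroids
    e2 <- outer(rowSums(cen^2), rep(1, nrow(xs))) +
      outer(rep(1, nrow(cen)), rowSums(xs^2)) - 2 * cen %*% t(xs)
    out$FDis <- rowSums(eng$W * sqrt(pmax(e2, 0)))
  }
  if ("FD" %in% indices) {
    dm <- list(d = d, species_ids = rownames(eng$X), metric = "euclidean",
               trait_subset = colnames(xs))
    dg <- functional_dendrogram(dm)
    counts <- dg$edge_below %*% t(eng$B)      # edges x communities
    s <- eng$richness
    on_path <- if (include_root) counts > 0 else
      (counts > 0) & sweep(counts, 2L, s, "<")
    out$FD <- as.numeric(t(on_path) %*% dg$edge_lengths)
  }
  out[indices]
}

# closed-form OLS of y on x for many y columns at once
cod_batch <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  xc <- x - mean(x)
  yc <- sweep(y, 2L, colMeans(y), "-")
  sxy <- as.numeric(xc %*% yc)
  syy <- colSums(yc^2)
  slope <- sxy / sxx
  cod <- ifelse(syy > 0, sxy^2 / (sxx * syy), NA_real_)
  r2 <- pmin(cod, 1)
  tstat <- sqrt(pmax(r2, 0) * (n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  data.frame(slope = slope, cod = cod,
             p_value = ifelse(is.na(cod), NA_real_, p),
             degenerate = is.na(cod))
}

#' Complete search over all trait combinations
#'
#' Evaluates every nonempty trait subset (optionally restricted to sizes in
#' `k_range`): the four indices per community, then OLS against species
#' richness. This maps the whole landscape of possible conclusions and is
#' the benchmark the selection methods are compared with — its per-index
#' best COD dominates every method's by construction.
#'
#' @param tm a [trait_matrix()]
#' @param cm a [community_matrix()]
#' @param indices indices to compute (default all four)
#' @param k_range optional integer vector of subset sizes to include
#' @param max_p refuse trait matrices wider than this without an explicit
#'   raise (default 15; 2^15 - 1 subsets)
#' @param include_root passed to the FD subtree rule
#' @return list of class `"search_result"`: `results` (long data.frame:
#'   `subset` — ';'-joined trait names, `size`, `index`, `slope`, `cod`,
#'   `p_value`, `p_bin`, `degenerate`), `best` (per-index argmax row; ties
#'   to the smaller then lexicographically smallest subset), `by_size`
#'   (mean/sd/max of COD by subset size and index), `n_subsets`.
#' @export
complete_search <- function(tm, cm, indices = c("FAD", "FD", "Q", "FDis"),
                            k_range = NULL, max_p = 15L,
                            include_root = FALSE) {
  indices <- match.arg(indices, several.ok = TRUE)
  eng <- search_engine(cm, tm)
  p <- length(eng$trait_names)
  if (p > max_p)
    stop("p = ", p, " traits exceeds max_p = ", max_p,
         " (", 2^p - 1, " subsets); raise max_p to confirm")
  sizes <- if (is.null(k_range)) seq_len(p) else {
    kr <- as.integer(k_range)
    if (any(kr < 1L | kr > p)) stop("k_range outside 1..p")
    sort(unique(kr))
  }
  subsets <- unlist(lapply(sizes, function(k)
    utils::combn(p, k, simplify = FALSE)), recursive = FALSE)
  n_sub <- length(subsets)
  rows <- vector("list", n_sub)
  for (j in seq_len(n_sub)) {
    idx <- subsets[[j]]
    vals <- engine_indices(eng, idx, indices, include_root)
    y <- do.call(cbind, vals)
    cb <- cod_batch(eng$richness, y)
    rows[[j]] <- data.frame(
      subset = paste(eng$trait_names[idx], collapse = ";"),
      size = length(idx), index = indices, cb,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  results <- do.call(rbind, rows)
  results$p_bin <- p_bin(results$p_value)
  best <- do.call(rbind, lapply(indices, function(ind) {
    r <- results[results$index == ind & !results$degenerate, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    top <- r[r$cod >= max(r$cod) - 1e-12, , drop = FALSE]
    top <- top[order(top$size, top$subset), , drop = FALSE]
    top[1L, , drop = FALSE]
  }))
  by_size <- do.call(rbind, lapply(indices, function(ind) {
    r <- results[results$index == ind, , drop = FALSE]
    agg <- lapply(split(r$cod, r$size), function(v) {
      v <- v[!is.na(v)]
      c(mean = mean(v), sd = stats::sd(v), max = max(v), n = length(v))
    })
    data.frame(index = ind, size = as.integer(names(agg)),
               do.call(rbind, agg), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  structure(list(results = results, best = best, by_size = by_size,
                 n_subsets = n_sub, indices = indices,
                 trait_names = eng$trait_names),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("Complete search: %d trait subsets x %d indices\n",
              x$n_subsets, length(x$indices)))
  cat("Best subset per index:\n")
  print(x$best[, c("index", "subset", "size", "cod", "p_bin")],
        row.names = FALSE)
  invisible(x)
}

#' Run one trait-choice method end to end
#'
#' Selects a trait subset (or PC pseudo-traits) by the chosen method,
#' computes the functional diversity indices on it, and regresses each
#' against species richness.
#'
#' @param tm a [trait_matrix()]
#' @param cm a [community_matrix()]
#' @param method `"PC"`, `"RM"`, `"GCD"`, `"RV"` or `"HL"`
#' @param k dimensionality: number of PCs or subset size (e.g. the
#'   consensus of [estimate_dimensionality()])
#' @param indices indices to compute
#' @param pc_set PC index set for GCD (default first k)
#' @param ... passed to [best_subset()] (search, seed, ...)
#' @return data.frame, one row per index: `method`, `subset` (";"-joined;
#'   `"PC1..PCk"` for the axis method), `size`, `index`, `slope`, `cod`,
#'   `p_value`, `p_bin`, plus attribute `"selection"` holding the selection
#'   detail (criterion values or loadings).
#' @export
run_method <- function(tm, cm, method = c("PC", "RM", "GCD", "RV", "HL"),
                       k, indices = c("FAD", "FD", "Q", "FDis"),
                       pc_set = NULL, ...) {
  method <- match.arg(method)
  indices <- match.arg(indices, several.ok = TRUE)
  tms <- if (is_standardized(unclass(as_trait_matrix(tm)), tol = 1e-6))
    as_trait_matrix(tm) else standardize_traits(tm)
  selection <- NULL
  if (method == "PC") {
    space <- pc_scores(tms, k)
    subset_label <- paste0("PC1..PC", k)
    subset <- NULL
    size <- as.integer(k)
    selection <- list(cum_pct_variance = attr(space, "cum_pct_variance"))
  } else if (method == "HL") {
    subset <- highest_loading_subset(tms, k)
    space <- tms
    subset_label <- paste(subset, collapse = ";")
    size <- length(subset)
    ws <- build_workspace(tms)
    selection <- list(per_pc = attr(subset, "per_pc"),
                      scores = score_subset_all_criteria(ws, subset,
                                                         seq_len(k)))
  } else {
    ws <- build_workspace(tms)
    bs <- best_subset(ws, k, criterion = method, pc_set = pc_set, ...)
    subset <- bs$subset
    space <- tms
    subset_label <- paste(subset, collapse = ";")
    size <- length(subset)
    selection <- bs
  }
  prof <- fd_profile(cm, space, subset = subset, indices = indices)
  rich <- prof$richness
  out <- do.call(rbind, lapply(indices, function(ind) {
    lc <- linear_cod(rich, prof[[ind]])
    data.frame(method = method, subset = subset_label, size = size,
               index = ind, slope = lc$slope, cod = lc$cod,
               p_value = lc$p_value, p_bin = lc$p_bin,
               degenerate = lc$degenerate, stringsAsFactors = FALSE)
  }))
  attr(out, "selection") <- selection
  out
}

#' Compare trait-choice methods across datasets by two-way ANOVA
#'
#' Takes the closeness-of-association grid — one COD per (dataset, method,
#' index) with the complete-search entry being each dataset's per-index
#' maximum — and tests whether method choice affects COD and whether that
#' effect depends on the index: a two-way fixed-effects ANOVA of COD on
#' method, index and their interaction, with datasets as replicates. Within
#' each index, methods sharing no letter differ at `alpha` by Tukey's HSD.
#'
#' @param grid data.frame with columns `dataset`, `method`, `index`, `cod`;
#'   the method x index grid must be complete for every dataset and at
#'   least 2 datasets are required.
#' @param alpha level for the compact letter display (default 0.05)
#' @return list of class `"method_comparison"`: `anova` (the ANOVA table),
#'   `letters` (data.frame: index, method, mean COD, letter group),
#'   `grid`.
#' @export
compare_methods <- function(grid, alpha = 0.05) {
  need <- c("dataset", "method", "index", "cod")
  if (!all(need %in% names(grid)))
    stop("grid needs columns: ", paste(need, collapse = ", "))
  grid <- grid[, need]
  if (anyNA(grid$cod)) stop("missing COD cells in the comparison grid")
  counts <- table(grid$dataset, grid$method, grid$index)
  if (any(counts != 1L))
    stop("method x index grid incomplete or duplicated for some dataset")
  if (length(unique(grid$dataset)) < 2L) stop("need at least 2 datasets")
  grid$method <- factor(grid$method)
  grid$index <- factor(grid$index)
  fit <- stats::aov(cod ~ method * index, data = grid)
  letters <- do.call(rbind, lapply(levels(grid$index), function(ind) {
    gi <- droplevels(grid[grid$index == ind, ])
    mm <- tapply(gi$cod, gi$method, mean)
    fi <- stats::aov(cod ~ method, data = gi)
    glt <- multcomp::glht(fi, linfct = multcomp::mcp(method = "Tukey"))
    lt <- multcomp::cld(glt, level = alpha)$mcletters$Letters
    data.frame(index = ind, method = names(mm), mean_cod = as.numeric(mm),
               letters = as.character(lt[names(mm)]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(anova = summary(fit), letters = letters, grid = grid,
                 alpha = alpha),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Two-way ANOVA of COD on method and index (datasets as replicates)\n")
  print(x$anova)
  cat("\nPer-index Tukey HSD letter groups (alpha =", x$alpha, "):\n")
  print(x$letters, row.names = FALSE)
  invisible(x)
}
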