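#' Pairwise species distances in trait space
#'
#' Euclidean distances between species on the selected standardized trait
#' columns. Traits are standardized over the full species pool before
#' subsetting so every trait carries the same weight and subsets stay
#' comparable.
#'
#' @param tm a [trait_matrix()]; standardized internally if it is not
#'   already (PC-score matrices are used as given).
#' @param subset trait names or indices; default all traits.
#' @return a `"species_distance"` object: list with `d` (n x n symmetric
#'   matrix, zero diagonal), `species_ids`, `metric`, `trait_subset`.
#' @export
species_distance_matrix <- function(tm, subset = NULL) {
  x <- prepare_trait_space(tm)
  if (is.null(subset)) subset <- colnames(x)
  idx <- if (is.character(subset)) match(subset, colnames(x)) else
    as.integer(subset)
  if (length(idx) == 0L) stop("empty trait subset")
  if (anyNA(idx) || any(idx < 1L | idx > ncol(x)))
    stop("unknown trait(s) in subset")
  d <- as.matrix(stats::dist(x[, idx, drop = FALSE], method = "euclidean"))
  dimnames(d) <- list(rownames(x), rownames(x))
  structure(list(d = d, species_ids = rownames(x), metric = "euclidean",
                 trait_subset = colnames(x)[idx]),
            class = "species_distance")
}

# standardize unless already standardized or the matrix is PC scores
prepare_trait_space <- function(tm) {
  x <- as_trait_matrix(tm)
  if (isTRUE(attr(x, "pc_scores"))) return(unclass(x))
  if (!is_standardized(unclass(x), tol = 1e-6)) x <- standardize_traits(x)
  unclass(x)
}

#' Functional attribute diversity (FAD)
#'
#' Sum of pairwise trait-space distances over the species present in a
#' community (unordered pairs). Zero for a single species.
#'
#' @param present character vector of species present
#' @param dm a [species_distance_matrix()] result
#' @return nonnegative scalar
#' @export
fad <- function(present, dm) {
  idx <- match_species(present, dm$species_ids)
  if (length(idx) < 2L) return(0)
  sum(dm$d[idx, idx]) / 2
}

match_species <- function(present, pool) {
  if (length(present) == 0L) stop("no species present")
  idx <- match(present, pool)
  if (anyNA(idx))
    stop("unknown species: ", paste(present[is.na(idx)], collapse = ", "))
  idx
}

#' UPGMA functional dendrogram over the species pool
#'
#' Average-linkage (UPGMA) clustering of the full species pool on the
#' trait-space distances. One dendrogram is built per trait subset and
#' reused across all communities (the regional-dendrogram approach); node
#' heights are half the merge distances, so two species at distance d join
#' at height d/2 and contribute total branch length d.
#'
#' @param dm a [species_distance_matrix()] over at least 2 species
#' @return a `"functional_dendrogram"`: list with the `hclust` object,
#'   `edges` (data.frame: lengths and the tips below each edge, encoded as a
#'   membership matrix), `tip_labels`, `total_branch_length`.
#' @export
functional_dendrogram <- function(dm) {
  n <- length(dm$species_ids)
  if (n < 2L) stop("need at least 2 species to build a dendrogram")
  hc <- stats::hclust(stats::as.dist(dm$d), method = "average")
  node_h <- hc$height / 2           # ultrametric node heights
  n_merge <- nrow(hc$merge)
  # membership[m, ] marks the tips below internal node m
  membership <- matrix(FALSE, n_merge, n)
  edge_len <- numeric(2L * n_merge)
  edge_node <- integer(2L * n_merge)          # internal node each edge hangs from
  edge_child_tips <- vector("list", 2L * n_merge)
  e <- 0L
  for (m in seq_len(n_merge)) {
    for (child in hc$merge[m, ]) {
      e <- e + 1L
      if (child < 0L) {             # tip
        tipset <- -child
        child_h <- 0
      } else {                      # earlier merge
        tipset <- which(membership[child, ])
        child_h <- node_h[child]
      }
      membership[m, tipset] <- TRUE
      edge_len[e] <- node_h[m] - child_h
      edge_node[e] <- m
      edge_child_tips[[e]] <- tipset
    }
  }
  # edge x tip incidence: which tips lie below each edge
  below <- matrix(FALSE, 2L * n_merge, n)
  for (e in seq_len(2L * n_merge)) below[e, edge_child_tips[[e]]] <- TRUE
  colnames(below) <- hc$labels
  structure(list(hclust = hc, edge_lengths = edge_len, edge_below = below,
                 tip_labels = hc$labels,
                 total_branch_length = sum(edge_len), linkage = "average"),
            class = "functional_dendrogram")
}

#' @export
print.functional_dendrogram <- function(x, ...) {
  cat(sprintf(
    "UPGMA functional dendrogram: %d species, total branch length %.4f\n",
    length(x$tip_labels), x$total_branch_length))
  invisible(x)
}

#' Dendrogram functional diversity (FD)
#'
#' Total branch length of the minimal subtree of the pool dendrogram
#' spanning a community's species. By default the subtree stops at the last
#' common merge of the present species (no path above it), so a monoculture
#' has FD = 0 and the full pool recovers the whole tree's branch length.
#' `include_root = TRUE` adds the path from that merge up to the tree root,
#' a variant some implementations use.
#'
#' @param present character vector of species present
#' @param dg a [functional_dendrogram()]
#' @param include_root include the path above the species' last common
#'   merge (default FALSE)
#' @return nonnegative scalar
#' @export
fd_branch_length <- function(present, dg, include_root = FALSE) {
  idx <- match_species(present, dg$tip_labels)
  s <- length(idx)
  if (s < 2L && !include_root) return(0)
  pres <- logical(length(dg$tip_labels))
  pres[idx] <- TRUE
  counts <- dg$edge_below %*% pres        # present tips below each edge
  on_path <- if (include_root) counts > 0 else counts > 0 & counts < s
  sum(dg$edge_lengths[on_path])
}

#' Rao's quadratic entropy (Q)
#'
#' Abundance-weighted expected trait distance between two randomly drawn
#' individuals: Q = sum over unordered species pairs of d_ij p_i p_j, with
#' p the relative abundances. `convention = "ordered"` doubles the value
#' (summing ordered pairs) and `squared = TRUE` uses d^2/2 in place of d;
#' both variants circulate in functional diversity software.
#'
#' @param abund named numeric vector of abundances (relative or raw; raw
#'   values are normalized to sum 1 with a message)
#' @param dm a [species_distance_matrix()] result
#' @param convention `"unordered"` (default) or `"ordered"`
#' @param squared use squared half-distances (default FALSE)
#' @return nonnegative scalar
#' @export
rao_q <- function(abund, dm, convention = c("unordered", "ordered"),
                  squared = FALSE) {
  convention <- match.arg(convention)
  w <- normalize_abundances(abund)
  idx <- match_species(names(w), dm$species_ids)
  d <- dm$d[idx, idx, drop = FALSE]
  if (squared) d <- d^2 / 2
  q <- as.numeric(t(w) %*% d %*% w) / 2
  if (convention == "ordered") q <- 2 * q
  q
}

normalize_abundances <- function(abund) {
  if (is.null(names(abund))) stop("abundances must be named by species")
  if (any(abund < 0)) stop("negative abundance")
  abund <- abund[abund > 0]
  if (length(abund) == 0L) stop("no species with positive abundance")
  tot <- sum(abund)
  if (abs(tot - 1) > 1e-8) {
    message("normalizing abundances to relative abundances (sum was ",
            format(tot), ")")
    abund <- abund / tot
  }
  abund
}

#' Functional dispersion (FDis)
#'
#' Abundance-weighted mean distance of species to the community's
#' abundance-weighted centroid in the selected trait space. Zero for a
#' single species.
#'
#' @inheritParams rao_q
#' @param tm a [trait_matrix()] (standardized internally; PC scores used as
#'   given)
#' @param subset trait names or indices; default all traits
#' @return nonnegative scalar
#' @export
fdis <- function(abund, tm, subset = NULL) {
  x <- prepare_trait_space(tm)
  if (is.null(subset)) subset <- colnames(x)
  idx <- if (is.character(subset)) match(subset, colnames(x)) else
    as.integer(subset)
  if (length(idx) == 0L || anyNA(idx)) stop("invalid trait subset")
  w <- normalize_abundances(abund)
  sp <- match_species(names(w), rownames(x))
  xs <- x[sp, idx, drop = FALSE]
  centroid <- colSums(w * xs)
  dev <- sweep(xs, 2L, centroid, "-")
  sum(w * sqrt(rowSums(dev^2)))
}

#' Per-community functional diversity table
#'
#' Computes the requested indices for every community over one trait subset
#' (or PC pseudo-traits). FAD and FD use presence only; Q and FDis weight by
#' relative abundance. The dendrogram for FD is built once on the full pool
#' and pruned per community; `per_community_tree = TRUE` re-clusters each
#' community instead (sensitivity analysis).
#'
#' @param cm a [community_matrix()] whose species match `tm`'s
#' @param tm a [trait_matrix()]
#' @param subset trait names or indices; default all traits
#' @param indices any of `"FAD"`, `"FD"`, `"Q"`, `"FDis"`
#' @param include_root passed to [fd_branch_length()]
#' @param per_community_tree rebuild the UPGMA tree per community for FD
#' @return data.frame (one row per community) with `community`, `richness`,
#'   and one column per requested index; attribute `"trait_subset"` records
#'   the columns used.
#' @export
fd_profile <- function(cm, tm, subset = NULL,
                       indices = c("FAD", "FD", "Q", "FDis"),
                       include_root = FALSE, per_community_tree = FALSE) {
  indices <- match.arg(indices, several.ok = TRUE)
  tmx <- as_trait_matrix(tm)
  cmx <- reconcile_species(community_matrix(cm), tmx)
  x <- prepare_trait_space(tmx)
  if (is.null(subset)) subset <- colnames(x)
  dm <- species_distance_matrix(tmx, subset)
  dg <- if ("FD" %in% indices && !per_community_tree)
    functional_dendrogram(dm) else NULL
  a <- unclass(cmx)
  out <- data.frame(community = rownames(a),
                    richness = as.integer(rowSums(a > 0)),
                    stringsAsFactors = FALSE)
  for (ind in indices) out[[ind]] <- NA_real_
  for (i in seq_len(nrow(a))) {
    sel <- which(a[i, ] > 0)
    present <- colnames(a)[sel]
    w <- stats::setNames(a[i, sel] / sum(a[i, sel]), present)
    if ("FAD" %in% indices) out$FAD[i] <- fad(present, dm)
    if ("FD" %in% indices) {
      out$FD[i] <- if (per_community_tree) {
        if (length(present) < 2L) 0 else {
          sub_dm <- dm
          sub_dm$d <- dm$d[present, present, drop = FALSE]
          sub_dm$species_ids <- present
          functional_dendrogram(sub_dm)$total_branch_length
        }
      } else fd_branch_length(present, dg, include_root = include_root)
    }
    if ("Q" %in% indices)
      out$Q[i] <- suppressMessages(rao_q(w, dm))
    if ("FDis" %in% indices)
      out$FDis[i] <- suppressMessages(fdis(w, tmx, subset))
  }
  attr(out, "trait_subset") <- dm$trait_subset
  out
}
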