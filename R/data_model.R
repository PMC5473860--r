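#' Construct a species-by-trait matrix
#'
#' Validates and tags a numeric matrix of quantitative trait values with
#' species in rows and traits in columns. This is the central input object:
#' all dimensionality estimates, subset criteria and functional diversity
#' indices operate on it (usually after [standardize_traits()]).
#'
#' @param x numeric matrix (or data.frame of numerics) with unique rownames
#'   (species IDs) and unique colnames (trait names).
#' @return a numeric matrix of class `"trait_matrix"`. The attribute
#'   `"standardized"` records whether the columns are z-scores.
#' @export
trait_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("trait values must be numeric")
  if (anyNA(x)) stop("trait matrix contains missing values")
  if (nrow(x) < 2L) stop("need at least 2 species, got ", nrow(x))
  if (ncol(x) < 1L) stop("need at least 1 trait")
  if (is.null(rownames(x))) rownames(x) <- paste0("sp", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("trait", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicated species IDs: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicated trait names: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  structure(x, class = c("trait_matrix", class(matrix())),
            standardized = is_standardized(x))
}

# crude check used to tag matrices; tolerance matches the class invariant
is_standardized <- function(x, tol = 1e-9) {
  mu <- colMeans(x)
  v <- apply(x, 2L, stats::var)
  all(abs(mu) <= tol) && all(abs(v - 1) <= tol)
}

# centered with unit variance under either sd denominator (n-1 or n)
is_centered_unit <- function(x, tol = 1e-6) {
  n <- nrow(x)
  mu <- colMeans(x)
  v <- apply(x, 2L, stats::var)
  all(abs(mu) <= tol) &&
    (all(abs(v - 1) <= tol) || all(abs(v - n / (n - 1)) <= tol))
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("Trait matrix: %d species x %d traits%s\n", nrow(x), ncol(x),
              if (isTRUE(attr(x, "standardized"))) " (standardized)" else ""))
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Construct a community-by-species abundance matrix
#'
#' @param x numeric matrix (or data.frame) with communities in rows and
#'   species in columns; entries are nonnegative abundances. Every community
#'   must contain at least one individual.
#' @return a numeric matrix of class `"community_matrix"`.
#' @export
community_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("abundances must be numeric")
  if (anyNA(x)) stop("community matrix contains missing values")
  if (is.null(rownames(x))) rownames(x) <- paste0("com", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sp", seq_len(ncol(x)))
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative abundance at community '%s', species '%s'",
                 rownames(x)[neg[1L, 1L]], colnames(x)[neg[1L, 2L]]))
  empty <- rowSums(x) == 0
  if (any(empty))
    stop("empty community (all-zero row): ",
         paste(rownames(x)[empty], collapse = ", "))
  if (anyDuplicated(rownames(x))) stop("duplicated community IDs")
  if (anyDuplicated(colnames(x))) stop("duplicated species IDs")
  structure(x, class = c("community_matrix", class(matrix())))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community matrix: %d communities x %d species\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read a species-by-trait table from delimited text
#'
#' First column is the species ID; remaining columns are numeric traits.
#' The delimiter is auto-detected (comma vs tab) unless given.
#'
#' @param path file path (or connection) to a CSV/TSV with a header row.
#' @param sep field delimiter; `NULL` (default) auto-detects `,` vs tab.
#' @param na_action `"error"` (default) rejects rows with missing or
#'   non-numeric trait cells, naming the cell; `"drop"` drops such species
#'   with a message.
#' @return a [trait_matrix()].
#' @export
read_trait_table <- function(path, sep = NULL, na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  df <- read_delim_auto(path, sep)
  if (ncol(df) < 2L) stop("trait table needs a species ID column plus traits")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated species IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v) & trimws(as.character(v)) != "")
      if (length(bad) > 0L && na_action == "error")
        stop(sprintf("non-numeric trait value '%s' (species '%s', trait '%s')",
                     v[bad[1L]], ids[bad[1L]], names(vals)[j]))
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(as.data.frame(vals))
  rownames(m) <- ids
  incomplete <- rowSums(is.na(m)) > 0
  if (any(incomplete)) {
    if (na_action == "error") {
      rc <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing trait value (species '%s', trait '%s')",
                   ids[rc[1L]], colnames(m)[rc[2L]]))
    }
    message("dropping ", sum(incomplete), " species with incomplete traits: ",
            paste(ids[incomplete], collapse = ", "))
    m <- m[!incomplete, , drop = FALSE]
  }
  trait_matrix(m)
}

#' Read a community-by-species abundance table from delimited text
#'
#' First column is the community ID; remaining columns are species
#' abundances (header row gives species IDs).
#'
#' @inheritParams read_trait_table
#' @param traits optional [trait_matrix()]; if given, columns are reordered
#'   to match its species and a species unknown to the trait matrix is an
#'   error.
#' @return a [community_matrix()].
#' @export
read_community_table <- function(path, sep = NULL, traits = NULL) {
  df <- read_delim_auto(path, sep)
  if (ncol(df) < 2L) stop("community table needs an ID column plus species")
  ids <- as.character(df[[1L]])
  m <- as.matrix(as.data.frame(lapply(df[-1L], function(v)
    suppressWarnings(as.numeric(as.character(v))))))
  colnames(m) <- names(df)[-1L]
  if (anyNA(m)) stop("non-numeric or missing abundance value")
  rownames(m) <- ids
  cm <- community_matrix(m)
  if (!is.null(traits)) cm <- reconcile_species(cm, traits)
  cm
}

#' Align a community matrix with a trait matrix
#'
#' Reorders community-matrix columns to the trait matrix's species order.
#' A species observed in communities but lacking trait data is an error
#' (never silently dropped); species with traits but never observed are
#' kept as zero columns.
#'
#' @param cm a [community_matrix()]
#' @param tm a [trait_matrix()]
#' @return the reordered [community_matrix()].
#' @export
reconcile_species <- function(cm, tm) {
  missing_traits <- setdiff(colnames(cm), rownames(tm))
  if (length(missing_traits) > 0L)
    stop("species in community table without trait data: ",
         paste(missing_traits, collapse = ", "))
  full <- matrix(0, nrow(cm), nrow(tm),
                 dimnames = list(rownames(cm), rownames(tm)))
  full[, colnames(cm)] <- unclass(cm)
  community_matrix(full)
}

read_delim_auto <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"", fileEncoding = "UTF-8")
}

#' Write a trait or community matrix as delimited text
#'
#' Writes the matrix with its row IDs as the first column (`species` or
#' `community`), full precision, so a write/read round trip preserves values.
#'
#' @param x a [trait_matrix()] or [community_matrix()]
#' @param path output file path
#' @param sep field delimiter (default comma)
#' @export
write_table <- function(x, path, sep = ",") {
  idcol <- if (inherits(x, "community_matrix")) "community" else "species"
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idcol
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Average replicated trait observations into species means
#'
#' Functional diversity is computed from the average trait value of each
#' species; this collapses a long table of individual measurements to those
#' means.
#'
#' @param obs data.frame with columns `species`, `trait`, `value` (extra
#'   columns ignored).
#' @return a [trait_matrix()] of per-species arithmetic means; every
#'   (species, trait) combination must be observed at least once.
#' @export
aggregate_species_means <- function(obs) {
  need <- c("species", "trait", "value")
  if (!all(need %in% names(obs)))
    stop("observations need columns: ", paste(need, collapse = ", "))
  if (anyNA(obs$value)) stop("missing observation values")
  sp <- unique(as.character(obs$species))
  tr <- unique(as.character(obs$trait))
  m <- tapply(obs$value, list(factor(obs$species, sp), factor(obs$trait, tr)),
              mean)
  if (anyNA(m)) {
    rc <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("no observation for species '%s', trait '%s'",
                 sp[rc[1L]], tr[rc[2L]]))
  }
  trait_matrix(matrix(m, nrow = length(sp), ncol = length(tr),
                      dimnames = list(sp, tr)))
}

#' Standardize traits to zero mean and unit variance
#'
#' z-transforms each trait column so all traits carry the same weight in
#' distance-based indices and measurement units drop out. Standardization is
#' always over the full species pool; downstream subsetting selects columns
#' of this matrix without re-standardizing, which keeps subsets comparable.
#'
#' @param tm a [trait_matrix()]
#' @param sd_denominator `"n-1"` (sample standard deviation, default) or
#'   `"n"`; subset criteria and index comparisons are invariant to this
#'   choice, but the raw index values scale with it.
#' @return a standardized [trait_matrix()] (idempotent within tolerance).
#' @export
standardize_traits <- function(tm, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  x <- unclass(as_trait_matrix(tm))
  n <- nrow(x)
  mu <- colMeans(x)
  v <- apply(x, 2L, stats::var)
  if (any(v == 0))
    stop("constant trait (zero variance): ",
         paste(colnames(x)[v == 0], collapse = ", "))
  if (sd_denominator == "n") v <- v * (n - 1) / n
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sqrt(v), "/")
  out <- trait_matrix(z)
  attr(out, "standardized") <- TRUE
  out
}

as_trait_matrix <- function(x) {
  if (inherits(x, "trait_matrix")) x else trait_matrix(x)
}

#' Summarize pairwise Pearson correlations among traits
#'
#' Computes Pearson's r and a two-sided p-value for every unordered trait
#' pair and reports the percentage of pairs significant at `alpha`, a
#' one-number summary of trait redundancy.
#'
#' @param tm a [trait_matrix()] with at least 3 species
#' @param alpha significance level (default 0.05)
#' @return an object of class `"correlation_summary"`: list with `r_matrix`,
#'   `p_matrix` (symmetric, unit/zero diagonal), `alpha`, `n_pairs`, and
#'   `pct_significant` (`NA` when p = 1 trait leaves no pairs).
#' @export
trait_correlation_summary <- function(tm, alpha = 0.05) {
  x <- unclass(as_trait_matrix(tm))
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 species for correlation tests")
  v <- apply(x, 2L, stats::var)
  if (any(v == 0))
    stop("constant trait: ", paste(colnames(x)[v == 0], collapse = ", "))
  r <- stats::cor(x)
  # two-sided p from the t transform of r with n-2 df
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  pn <- ncol(x)
  n_pairs <- pn * (pn - 1L) / 2L
  pct <- if (n_pairs == 0L) NA_real_ else
    100 * sum(p[upper.tri(p)] <= alpha) / n_pairs
  structure(list(r_matrix = r, p_matrix = p, alpha = alpha,
                 n_pairs = n_pairs, pct_significant = pct),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  if (x$n_pairs == 0L) {
    cat("Trait correlation summary: single trait, no pairs\n")
  } else {
    cat(sprintf(
      "Trait correlation summary: %d pairs, %.1f%% significant at P <= %g\n",
      x$n_pairs, x$pct_significant, x$alpha))
  }
  invisible(x)
}
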