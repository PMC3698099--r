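#' Cophenetic distance matrix of a tree
#'
#' For every pair of leaves, the sum of branch lengths along the path
#' connecting them. On a cladogram with unit branch lengths this is the
#' path edge count.
#'
#' @param tree a `phylo` object with at least two leaves.
#' @return Square symmetric matrix with zero diagonal, dimnames = leaf
#'   labels.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L)
    stop("tree must have at least two leaves")
  ape::cophenetic.phylo(tree)
}

#' Inverse-distance spatial weights
#'
#' Converts a cophenetic distance matrix into the weight matrix used by
#' Moran's I: `w_ij = 1/d_ij` off the diagonal and `w_ii = 0`.
#'
#' @param D distance matrix from [cophenetic_distances()].
#' @return Weight matrix of the same dimension.
#' @export
inverse_distance_weights <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  off <- row(D) != col(D)
  if (any(D[off] <= 0))
    stop("zero off-diagonal distance found; deduplicate identical taxa ",
         "before computing inverse-distance weights")
  W <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  W[off] <- 1 / D[off]
  W
}

drop_na_pairs <- function(y, W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), length(y) == nrow(W))
  keep <- !is.na(y)
  list(y = y[keep], W = W[keep, keep, drop = FALSE])
}

#' Moran's I autocorrelation statistic
#'
#' Computes
#' \deqn{I = \frac{N}{\sum_{ij} w_{ij}}
#'   \frac{\sum_{ij} w_{ij} (y_i - \bar y)(y_j - \bar y)}
#'        {\sum_i (y_i - \bar y)^2}}
#' over the observations with non-missing trait values (rows and columns of
#' `W` for missing entries are dropped in tandem). The null expectation is
#' `-1/(N-1)`.
#'
#' @param y numeric trait vector aligned with the rows of `W`; may contain
#'   `NA`.
#' @param W weight matrix from [inverse_distance_weights()].
#' @return The statistic (a single number).
#' @export
morans_i <- function(y, W) {
  d <- drop_na_pairs(y, W)
  n <- length(d$y)
  if (n < 3L) stop("need at least 3 non-missing observations")
  z <- d$y - mean(d$y)
  s2 <- sum(z^2)
  if (s2 == 0) stop("trait is constant; Moran's I is undefined")
  as.numeric(n / sum(d$W) * (t(z) %*% d$W %*% z) / s2)
}

#' Moran's I significance test
#'
#' Tests phylogenetic autocorrelation of a trait against the null of no
#' autocorrelation. `method = "analytic"` uses the normal approximation
#' under the randomization assumption (mean `-1/(n-1)`, variance from the
#' standard weight sums and the trait kurtosis). `method = "permutation"`
#' shuffles trait values over the leaves and reports
#' `p = (1 + #{|I_perm - E| >= |I_obs - E|}) / (1 + n_permutations)`.
#'
#' @param y trait vector (NA allowed; dropped listwise).
#' @param W weight matrix.
#' @param method `"analytic"` (default) or `"permutation"`.
#' @param n_permutations number of label shuffles (>= 99) for the
#'   permutation method.
#' @param seed optional integer seed for the permutation method.
#' @return Object of class `moran_test`: list with `I`, `expected_I`,
#'   `variance_I` (analytic only), `p_value`, `n`, `method`,
#'   `n_permutations`, `seed`.
#' @export
morans_i_test <- function(y, W, method = c("analytic", "permutation"),
                          n_permutations = 999, seed = NULL) {
  method <- match.arg(method)
  d <- drop_na_pairs(y, W)
  n <- length(d$y)
  I_obs <- morans_i(d$y, d$W)
  E <- -1 / (n - 1)
  out <- list(I = I_obs, expected_I = E, variance_I = NA_real_,
              p_value = NA_real_, n = n, method = method,
              n_permutations = NA_integer_, seed = seed)
  if (method == "analytic") {
    out$variance_I <- moran_randomization_variance(d$y, d$W)
    out$p_value <- 2 * stats::pnorm(-abs(I_obs - E) / sqrt(out$variance_I))
  } else {
    if (n_permutations < 99L)
      stop("n_permutations must be at least 99")
    if (!is.null(seed)) set.seed(seed)
    I_perm <- vapply(seq_len(n_permutations), function(i) {
      morans_i(sample(d$y), d$W)
    }, 0)
    out$n_permutations <- as.integer(n_permutations)
    out$p_value <- (1 + sum(abs(I_perm - E) >= abs(I_obs - E))) /
      (1 + n_permutations)
  }
  class(out) <- "moran_test"
  out
}

# Randomization-assumption variance of Moran's I (Cliff & Ord; the same
# formula behind ape::Moran.I), including the sample-kurtosis term.
moran_randomization_variance <- function(y, W) {
  n <- length(y)
  if (n < 4L) stop("analytic variance needs n >= 4")
  z <- y - mean(y)
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  k <- (sum(z^4) / n) / (sum(z^2) / n)^2
  (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
     k * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - 1 / (n - 1)^2
}

#' @export
print.moran_test <- function(x, digits = 4, ...) {
  cat("Moran's I phylogenetic autocorrelation (", x$method, ")\n", sep = "")
  cat(sprintf("  I = %.*g, E[I] = %.*g, n = %d\n",
              digits, x$I, digits, x$expected_I, x$n))
  if (!is.na(x$variance_I))
    cat(sprintf("  Var[I] = %.*g\n", digits, x$variance_I))
  cat(sprintf("  two-sided P = %.*g\n", digits, x$p_value))
  invisible(x)
}

#' Serialize a Moran test to JSON
#' @param x a `moran_test`.
#' @param path output path.
#' @export
write_moran_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Build a cladogram from taxonomy lineages
#'
#' When no Newick tree is available, a tree is assembled from the lineage
#' strings of the catalog: each internal node is a shared lineage prefix,
#' each rank step is one edge of length 1, and each medicinal is a leaf at
#' the end of its lineage path (polytomies permitted). Two medicinals'
#' cophenetic distance is then the number of rank edges below their deepest
#' shared taxon. Medicinals sharing an identical full lineage hang as
#' siblings one edge below the terminal taxon.
#'
#' @param catalog a `tcm_catalog` where every record has a non-empty
#'   `lineage`.
#' @return A `phylo` object with leaves labeled by `medicinal_id`.
#' @export
build_tree_from_lineages <- function(catalog) {
  if (nrow(catalog) < 2L) stop("need at least 2 medicinals to build a tree")
  if (any(lengths(catalog$lineage) == 0L))
    stop("every medicinal needs a non-empty lineage")
  # consistency: a taxon name must always sit under the same parent taxon
  edges <- unique(do.call(rbind, lapply(catalog$lineage, function(l) {
    full <- c("__root__", l)
    cbind(parent = full[-length(full)], child = full[-1L])
  })))
  dup <- edges[duplicated(edges[, "child"]), "child"]
  if (length(dup) > 0L)
    stop("inconsistent lineages: taxon under two parents: ",
         paste(unique(dup), collapse = ", "))

  # recurse() returns, for a set of records whose lineage remainders start
  # below a common (implicit) parent node, the Newick part strings of that
  # node's children, each with its unit edge length. A medicinal whose
  # lineage ends at a taxon nobody else occupies or descends through
  # becomes the leaf for that taxon; otherwise the taxon is an internal
  # node and terminal medicinals hang one edge below it.
  recurse <- function(ids, lins) {
    heads <- vapply(lins, `[`, "", 1L)
    parts <- character(0)
    for (h in unique(heads)) {
      sel <- which(heads == h)
      remainder <- lapply(lins[sel], `[`, -1L)
      ends <- lengths(remainder) == 0L
      if (all(ends) && length(sel) == 1L) {
        parts <- c(parts, paste0(ids[sel], ":1"))
      } else {
        inner <- if (any(ends)) paste0(ids[sel][ends], ":1") else character(0)
        if (any(!ends))
          inner <- c(inner, recurse(ids[sel][!ends], remainder[!ends]))
        parts <- c(parts, paste0("(", paste(inner, collapse = ","), "):1"))
      }
    }
    parts
  }
  parts <- recurse(catalog$medicinal_id, catalog$lineage)
  nwk <- paste0("(", paste(parts, collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  tree$edge.length[is.na(tree$edge.length)] <- 1
  tree <- ape::collapse.singles(tree)
  tree
}
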