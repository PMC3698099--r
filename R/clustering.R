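#' Hierarchical clustering of a potency matrix
#'
#' Agglomerative clustering of entities (rows) or modification attributes
#' (columns) under Euclidean distance between the 18-attribute arrays.
#' Linkage defaults to complete (the default of the standard R tooling for
#' heatmaps); average and single are available. Input rows/columns are not
#' scaled by default; optional per-row z-scoring is behind a flag.
#'
#' @param matrix entities x 18 matrix from [potency_matrix()].
#' @param axis `"rows"` (cluster entities) or `"columns"` (cluster
#'   attributes).
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @param scale_rows z-score rows before computing distances.
#' @return An [stats::hclust] object (merge heights are the linkage
#'   distances; leaf order from the standard traversal).
#' @export
hierarchical_cluster <- function(matrix, axis = c("rows", "columns"),
                                 linkage = c("complete", "average", "single"),
                                 scale_rows = FALSE) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(matrix))
  if (scale_rows) {
    sds <- apply(matrix, 1L, stats::sd)
    sds[sds == 0] <- 1
    matrix <- (matrix - rowMeans(matrix)) / sds
  }
  m <- if (axis == "rows") matrix else t(matrix)
  if (nrow(m) < 2L) stop("need at least 2 items on the clustered axis")
  stats::hclust(stats::dist(m, method = "euclidean"), method = linkage)
}

#' Convert a dendrogram to Newick text
#'
#' Branch lengths derive from the merge heights (each node sits at half its
#' merge height, as in the standard ultrametric embedding).
#'
#' @param hc an [stats::hclust] object.
#' @return single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Export a clustered matrix with its dendrograms
#'
#' Writes the matrix reordered by the dendrogram leaf orders as TSV, each
#' dendrogram as Newick, and optionally a raster heatmap. Either dendrogram
#' may be `NULL` (axis left in input order); a supplied dendrogram must
#' match its axis length.
#'
#' @param matrix entities x attributes matrix.
#' @param row_dendro,col_dendro [stats::hclust] objects or `NULL`.
#' @param path output stem; writes `<path>_matrix.tsv`,
#'   `<path>_rows.nwk`, `<path>_cols.nwk`, and `<path>.png` if `image`.
#' @param image emit a raster heatmap (skipped without error when no
#'   graphics device is usable).
#' @return invisible character vector of the files written.
#' @export
export_clustered_matrix <- function(matrix, row_dendro = NULL,
                                    col_dendro = NULL, path, image = FALSE) {
  stopifnot(is.matrix(matrix))
  if (!is.null(row_dendro) && length(row_dendro$order) != nrow(matrix))
    stop("row dendrogram does not match the matrix rows")
  if (!is.null(col_dendro) && length(col_dendro$order) != ncol(matrix))
    stop("column dendrogram does not match the matrix columns")
  ro <- if (is.null(row_dendro)) seq_len(nrow(matrix)) else row_dendro$order
  co <- if (is.null(col_dendro)) seq_len(ncol(matrix)) else col_dendro$order
  m <- matrix[ro, co, drop = FALSE]
  files <- character(0)
  f <- paste0(path, "_matrix.tsv")
  utils::write.table(data.frame(entity_id = rownames(m), m,
                                check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  files <- c(files, f)
  if (!is.null(row_dendro)) {
    f <- paste0(path, "_rows.nwk")
    writeLines(dendrogram_newick(row_dendro), f)
    files <- c(files, f)
  }
  if (!is.null(col_dendro)) {
    f <- paste0(path, "_cols.nwk")
    writeLines(dendrogram_newick(col_dendro), f)
    files <- c(files, f)
  }
  if (image) {
    ok <- tryCatch({
      grDevices::png(paste0(path, ".png"), width = 800, height = 800)
      graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                      axes = FALSE, main = "potency heatmap")
      grDevices::dev.off()
      TRUE
    }, error = function(e) FALSE)
    if (ok) files <- c(files, paste0(path, ".png"))
  }
  invisible(files)
}
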