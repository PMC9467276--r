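#' Build a shared-nearest-neighbor graph
#'
#' For every cell the exact Euclidean k-nearest neighbors in PC space are
#' found (each cell is a member of its own neighbor set, following the
#' convention of graph-based scRNA-seq clustering tools, so the Jaccard
#' similarity of a cell with itself is 1). Cells are connected by the
#' Jaccard similarity of their neighbor sets; edges with weight at or below
#' the prune threshold are removed.
#'
#' @param embedding A `cell_embedding` from [scale_and_pca()], or a numeric
#'   matrix of cells x dimensions.
#' @param k Neighborhood size including the cell itself (default 20).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return An object of class `snn_graph`: list with `adjacency` (symmetric
#'   sparse weight matrix, zero diagonal), `neighbors` (cells x k index
#'   matrix), `k` and `prune`.
#' @export
build_snn <- function(embedding, k = 20, prune = 1 / 15) {
  coords <- if (inherits(embedding, "cell_embedding")) embedding$coords else embedding
  n <- nrow(coords)
  if (n <= k) stop(sprintf("need more cells (%d) than neighbors k = %d", n, k))

  nn <- knn_exact(coords, k)
  i <- rep(seq_len(n), each = k)
  adj <- Matrix::sparseMatrix(i = i, j = as.vector(t(nn)), x = 1,
                              dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)          # |N_i intersect N_j|
  shared <- methods::as(shared, "CsparseMatrix")
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)           # Jaccard from intersection
  jac@x[jac@x <= prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  rownames(jac) <- colnames(jac) <- rownames(coords)
  structure(list(adjacency = jac, neighbors = nn, k = k, prune = prune),
            class = "snn_graph")
}

# Exact k-nearest neighbors (self included) by blocked all-pairs distances.
# Ties are broken by index so the result is deterministic.
knn_exact <- function(coords, k, block = 1024L) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  out <- matrix(0L, n, k)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(coords[s:e, , drop = FALSE], coords)
    for (r in seq_len(e - s + 1L)) {
      out[s + r - 1L, ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}

#' Louvain community detection on an SNN graph
#'
#' Communities maximize resolution-parameterized modularity (the
#' configuration-model null with a resolution multiplier). Labels are dense
#' integers from 0, canonicalized by decreasing community size with ties
#' broken by the lowest member index; the run is seeded and reproducible.
#' Isolated vertices form singleton communities.
#'
#' @param graph An `snn_graph` from [build_snn()], or a symmetric sparse
#'   weight matrix.
#' @param resolution Modularity resolution (default 1).
#' @param seed Random seed for the community search.
#' @param provenance Label recorded on the result (e.g. `"top_level"` or a
#'   subset name).
#' @return An object of class `cluster_labels`: list with `cluster` (named
#'   integer vector, 0-based), `resolution`, `provenance`.
#' @export
louvain_cluster <- function(graph, resolution = 1, seed = 0L,
                            provenance = "top_level") {
  adj <- if (inherits(graph, "snn_graph")) graph$adjacency else graph
  if (nrow(adj) == 0) stop("empty graph")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  labels <- canonicalize_labels(as.integer(memb))
  names(labels) <- rownames(adj)
  structure(list(cluster = labels, resolution = resolution,
                 provenance = provenance),
            class = "cluster_labels")
}

# Relabel communities 0..K-1 by decreasing size, ties by lowest member index.
canonicalize_labels <- function(memb) {
  sizes <- table(memb)
  first <- tapply(seq_along(memb), memb, min)
  ord <- order(-as.integer(sizes), as.integer(first))
  old <- names(sizes)[ord]
  match(as.character(memb), old) - 1L
}

#' @export
print.cluster_labels <- function(x, ...) {
  k <- length(unique(x$cluster))
  cat(sprintf("cluster_labels (%s): %d cells in %d communities at resolution %g\n",
              x$provenance, length(x$cluster), k, x$resolution))
  invisible(x)
}

#' Two-dimensional UMAP layout of a PC embedding
#'
#' Visualization only; the layout is deterministic for a fixed seed.
#'
#' @param embedding A `cell_embedding` or numeric matrix (cells x dims) with
#'   at least 4 rows.
#' @param seed Random seed.
#' @param n_neighbors,min_dist Standard UMAP parameters.
#' @return A cells x 2 matrix of coordinates.
#' @export
umap_embed <- function(embedding, seed = 0L, n_neighbors = 30, min_dist = 0.3) {
  coords <- if (inherits(embedding, "cell_embedding")) embedding$coords else embedding
  if (nrow(coords) < 4) stop("at least 4 cells are required for a UMAP layout")
  set.seed(seed)
  out <- uwot::umap(coords, n_neighbors = min(n_neighbors, nrow(coords) - 1),
                    min_dist = min_dist, n_threads = 1, n_sgd_threads = 0,
                    batch = FALSE)
  rownames(out) <- rownames(coords)
  colnames(out) <- c("UMAP1", "UMAP2")
  out
}
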