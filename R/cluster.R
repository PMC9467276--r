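#' Clustering presets
#'
#' Named combinations of principal-component count and Louvain resolution
#' used for the top-level analysis and for the re-analysis of the three
#' major immune populations: `top_level` (16 PCs, resolution 1.0), `mo_ma`
#' (13, 1.2), `t_cell` (11, 0.5), `b_plasma` (8, 0.7).
#'
#' @param name Preset name.
#' @return List with `n_pcs` and `resolution`.
#' @export
cluster_preset <- function(name = c("top_level", "mo_ma", "t_cell", "b_plasma")) {
  name <- match.arg(name)
  switch(name,
         top_level = list(n_pcs = 16L, resolution = 1.0),
         mo_ma     = list(n_pcs = 13L, resolution = 1.2),
         t_cell    = list(n_pcs = 11L, resolution = 0.5),
         b_plasma  = list(n_pcs = 8L,  resolution = 0.7))
}

#' Run the normalization-to-communities chain on a count matrix
#'
#' Convenience wrapper executing log-normalization, variance-stabilized HVG
#' selection, scaling + PCA, SNN graph construction and Louvain community
#' detection with one call.
#'
#' @param x A QC-filtered [count_matrix].
#' @param n_pcs,resolution Embedding dimensionality and Louvain resolution
#'   (defaults from the `top_level` preset).
#' @param n_hvg Number of highly variable genes (default 2000).
#' @param k,prune SNN graph parameters (defaults 20 and 1/15).
#' @param scale_factor Normalization scale factor.
#' @param seed Seed for the community search.
#' @param provenance Provenance label stored on the cluster labels.
#' @return List of class `cluster_run` with `labels` (`cluster_labels`),
#'   `embedding`, `graph`, `hvg` and `normalized`.
#' @export
cluster_cells <- function(x, n_pcs = 16, resolution = 1.0, n_hvg = 2000,
                          k = 20, prune = 1 / 15, scale_factor = 1e4,
                          seed = 0L, provenance = "top_level") {
  normalized <- log_normalize(x, scale_factor)
  hvg <- select_hvg_vst(x, n_hvg = min(n_hvg, n_genes(x)))
  emb <- scale_and_pca(normalized, hvg, n_pcs = n_pcs)
  graph <- build_snn(emb, k = k, prune = prune)
  labels <- louvain_cluster(graph, resolution = resolution, seed = seed,
                            provenance = provenance)
  structure(list(labels = labels, embedding = emb, graph = graph,
                 hvg = hvg, normalized = normalized),
            class = "cluster_run")
}

#' Re-cluster a subset of cells with a preset
#'
#' The full chain (normalize, HVG, scale/PCA, SNN, Louvain) is recomputed on
#' the subset columns only, as in an independent re-analysis of one major
#' population.
#'
#' @param x The full [count_matrix] (raw counts).
#' @param cells Barcodes (or column indices) of the subset.
#' @param preset A preset name accepted by [cluster_preset()], or a list
#'   with `n_pcs` and `resolution`.
#' @param seed Seed for the community search.
#' @param k,prune,n_hvg,scale_factor As in [cluster_cells()].
#' @param provenance Provenance label; defaults to the preset name.
#' @return A `cluster_run` on the subset.
#' @export
subcluster <- function(x, cells, preset = "top_level", seed = 0L, k = 20,
                       prune = 1 / 15, n_hvg = 2000, scale_factor = 1e4,
                       provenance = NULL) {
  if (length(cells) == 0) stop("empty cell subset")
  if (is.character(preset)) {
    if (is.null(provenance)) provenance <- preset
    preset <- cluster_preset(preset)
  }
  if (is.null(provenance)) provenance <- "subset"
  sub <- subset_cells(x, cells)
  if (n_cells(sub) <= k)
    stop(sprintf("subset of %d cells is too small for k = %d neighbors",
                 n_cells(sub), k))
  cluster_cells(sub, n_pcs = preset$n_pcs, resolution = preset$resolution,
                n_hvg = n_hvg, k = k, prune = prune,
                scale_factor = scale_factor, seed = seed,
                provenance = provenance)
}
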