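test_that("explained variance is non-increasing and the run is reproducible", {
  sim <- small_balf_sim(seed = 4, n_cells = 300, n_genes = 1500)
  nm <- log_normalize(sim$matrix)
  hv <- select_hvg_vst(sim$matrix, 400)
  e1 <- scale_and_pca(nm, hv, n_pcs = 8)
  expect_true(all(diff(e1$variance_explained) <= 1e-10))
  e2 <- scale_and_pca(nm, hv, n_pcs = 8)
  expect_identical(e1$coords, e2$coords)
  expect_error(scale_and_pca(nm, hv, n_pcs = 10000), "exceeds")
})

test_that("the first component separates two planted populations", {
  pops <- list(population_spec("a", 0.5, paste0("A", 1:4), n_program_genes = 60),
               population_spec("b", 0.5, paste0("B", 1:4), n_program_genes = 60))
  cfg <- simulation_config(n_cells = 300, n_genes = 1500, populations = pops,
                           doublet_fraction = 0, seed = 4)
  sim <- simulate_balf(cfg)
  nm <- log_normalize(sim$matrix)
  hv <- select_hvg_vst(sim$matrix, 300)
  emb <- scale_and_pca(nm, hv, n_pcs = 5)
  truth <- as.integer(factor(sim$truth$cells$population))
  sil <- cluster::silhouette(truth, dist(emb$coords[, 1]))
  expect_gte(mean(sil[, 3]), 0.8)
})

test_that("exact k-nearest neighbors match an all-pairs distance oracle", {
  set.seed(11)
  coords <- matrix(rnorm(100 * 5), 100, 5,
                   dimnames = list(paste0("c", 1:100), NULL))
  nn <- scbalf:::knn_exact(coords, k = 10)
  d <- as.matrix(dist(coords))
  for (i in seq_len(100)) {
    expect_equal(sort(nn[i, ]), sort(order(d[i, ])[1:10]))
  }
  expect_true(all(nn[, 1] == seq_len(100)))  # self is always nearest
})

test_that("SNN weights are the Jaccard similarity of neighbor sets", {
  # ten coincident points and ten far away: within a block every cell shares
  # the same neighbor set (weight 1); across blocks sets are disjoint
  coords <- rbind(matrix(rnorm(10 * 2, sd = 1e-3), 10, 2),
                  matrix(rnorm(10 * 2, sd = 1e-3) + 100, 10, 2))
  rownames(coords) <- paste0("c", 1:20)
  g <- build_snn(coords, k = 10, prune = 1 / 15)
  a <- g$adjacency
  expect_true(all(a[1:10, 1:10][upper.tri(diag(10))] == 1))
  expect_true(all(a[1:10, 11:20] == 0))
  expect_equal(as.vector(Matrix::diag(a)), rep(0, 20))
  expect_true(Matrix::isSymmetric(a))
  expect_error(build_snn(coords, k = 25), "more cells")
})

test_that("disconnected cliques form separate communities, isolated cells singletons", {
  adj <- Matrix::bdiag(matrix(1, 10, 10), matrix(1, 10, 10))
  Matrix::diag(adj) <- 0
  rownames(adj) <- colnames(adj) <- paste0("c", 1:20)
  lab <- louvain_cluster(adj, resolution = 1, seed = 1)
  expect_equal(length(unique(lab$cluster)), 2)
  expect_equal(length(unique(lab$cluster[1:10])), 1)

  adj2 <- Matrix::bdiag(matrix(1, 5, 5), Matrix::Matrix(0, 2, 2))
  Matrix::diag(adj2) <- 0
  rownames(adj2) <- colnames(adj2) <- paste0("c", 1:7)
  lab2 <- louvain_cluster(adj2, seed = 1)
  expect_equal(length(unique(lab2$cluster)), 3)
  expect_equal(length(unique(lab2$cluster[6:7])), 2)
})

test_that("labels are canonical: densest community first, ids contiguous", {
  memb <- c(2L, 2L, 5L, 5L, 5L, 9L)
  out <- scbalf:::canonicalize_labels(memb)
  expect_equal(out, c(1L, 1L, 0L, 0L, 0L, 2L))
  expect_equal(sort(unique(out)), 0:2)
})

test_that("higher resolution yields at least as many communities", {
  sim <- small_balf_sim(seed = 3, n_cells = 400, n_genes = 1500, n_program = 40)
  run <- cluster_cells(sim$matrix, n_pcs = 10, n_hvg = 400, seed = 1)
  wins <- 0
  for (s in 1:20) {
    k_lo <- length(unique(louvain_cluster(run$graph, 0.5, seed = s)$cluster))
    k_hi <- length(unique(louvain_cluster(run$graph, 2.0, seed = s)$cluster))
    wins <- wins + (k_hi >= k_lo)
  }
  expect_gte(wins, 19)
})

test_that("permuting cells permutes the deterministic stages exactly", {
  sim <- small_balf_sim(seed = 3, n_cells = 400, n_genes = 1500, n_program = 40)
  run <- cluster_cells(sim$matrix, n_pcs = 10, n_hvg = 400,
                       resolution = 0.3, seed = 1)
  set.seed(99)
  perm <- sample(n_cells(sim$matrix))
  permuted <- count_matrix(sim$matrix$counts[, perm], gene_symbols(sim$matrix))
  runP <- cluster_cells(permuted, n_pcs = 10, n_hvg = 400,
                        resolution = 0.3, seed = 1)
  bc <- barcodes(sim$matrix)
  expect_equal(runP$embedding$coords[bc, ], run$embedding$coords[bc, ])
  expect_equal(runP$graph$adjacency[bc, bc], run$graph$adjacency[bc, bc])
  # with clean separation the partition itself is permutation-stable
  expect_equal(mclust::adjustedRandIndex(run$labels$cluster[bc],
                                         runP$labels$cluster[bc]), 1)
})

test_that("UMAP layouts are seeded, deterministic, and separate planted groups", {
  sim <- small_balf_sim(seed = 5, n_cells = 250, n_genes = 1200)
  run <- cluster_cells(sim$matrix, n_pcs = 8, n_hvg = 300, seed = 1)
  u1 <- umap_embed(run$embedding, seed = 7)
  u2 <- umap_embed(run$embedding, seed = 7)
  expect_identical(u1, u2)
  truth <- sim$truth$cells$population[match(rownames(u1),
                                            sim$truth$cells$barcode)]
  cent <- apply(u1, 2, tapply, truth, mean)
  inter <- mean(dist(cent))
  intra <- mean(vapply(split(seq_len(nrow(u1)), truth), function(i)
    mean(sqrt(rowSums((u1[i, , drop = FALSE] -
                       matrix(colMeans(u1[i, , drop = FALSE]),
                              length(i), 2, byrow = TRUE))^2))),
    numeric(1)))
  expect_gt(inter, intra)
  expect_error(umap_embed(u1[1:3, ]), "at least 4")
})
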