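#' Scale the highly variable genes and embed cells by PCA
#'
#' The normalized values of the selected genes are z-scored per gene,
#' clipped to `[-clip, clip]`, and decomposed by exact PCA (eigendecomposition
#' of the gene-gene crossproduct, which is exact and deterministic at the
#' cell numbers this pipeline targets). A fixed sign convention — each
#' component's largest-magnitude gene loading is positive — makes the
#' embedding reproducible across platforms.
#'
#' @param normalized A `norm_matrix` from [log_normalize()].
#' @param hvg An `hvg_result` from [select_hvg_vst()], or a character vector
#'   of gene identifiers to use directly.
#' @param n_pcs Number of principal components to keep.
#' @param clip Absolute bound applied to the z-scored values (default 10).
#' @return An object of class `cell_embedding`: list with `coords` (cells x
#'   n_pcs, barcodes as rownames), `variance_explained` (non-increasing) and
#'   `rotation` (genes x n_pcs loadings).
#' @export
scale_and_pca <- function(normalized, hvg, n_pcs, clip = 10) {
  stopifnot(inherits(normalized, "norm_matrix"))
  genes <- if (inherits(hvg, "hvg_result")) hvg$gene_id[hvg$selected] else hvg
  genes <- intersect(genes, rownames(normalized$data))
  if (!length(genes)) stop("no usable genes for PCA")
  n <- ncol(normalized$data)
  if (n_pcs < 1) stop("n_pcs must be at least 1")
  if (n_pcs > min(n, length(genes)))
    stop(sprintf("n_pcs = %d exceeds min(n_cells = %d, n_genes = %d)",
                 n_pcs, n, length(genes)))

  X <- as.matrix(normalized$data[genes, , drop = FALSE])  # genes x cells
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  keepsd <- sdv > 0
  X <- (X - mu) / ifelse(keepsd, sdv, 1)
  X[!keepsd, ] <- 0
  X[X > clip] <- clip
  X[X < -clip] <- -clip

  Y <- t(X)                                # cells x genes
  C <- crossprod(Y) / (n - 1)              # genes x genes
  eig <- eigen(C, symmetric = TRUE)
  val <- pmax(eig$values[seq_len(n_pcs)], 0)
  vec <- eig$vectors[, seq_len(n_pcs), drop = FALSE]
  # sign convention: dominant loading positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  coords <- Y %*% vec
  dimnames(coords) <- list(colnames(normalized$data),
                           paste0("PC", seq_len(n_pcs)))
  dimnames(vec) <- list(genes, colnames(coords))
  structure(list(coords = coords, variance_explained = val, rotation = vec),
            class = "cell_embedding")
}

#' @export
print.cell_embedding <- function(x, ...) {
  cat(sprintf("cell_embedding: %d cells x %d PCs\n",
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}
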