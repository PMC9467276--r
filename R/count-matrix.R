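#' Sparse gene-by-cell count matrix
#'
#' The central input of the pipeline: a sparse non-negative integer matrix
#' with genes as rows and cell barcodes as columns, together with a gene
#' symbol for every gene identifier (the symbol defaults to the identifier
#' when the features file carries no symbol column).
#'
#' @param counts A matrix coercible to [Matrix::dgCMatrix-class] with unique
#'   rownames (gene identifiers) and unique colnames (barcodes). Entries must
#'   be non-negative integers.
#' @param gene_symbols Character vector of symbols, one per gene; defaults to
#'   the gene identifiers.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_symbols = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene identifiers as rownames and barcodes as colnames")
  if (anyDuplicated(rownames(counts))) stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(counts))) stop("barcodes must be unique")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("counts must be non-negative integers")
  if (is.null(gene_symbols)) gene_symbols <- rownames(counts)
  if (length(gene_symbols) != nrow(counts))
    stop("gene_symbols must have one entry per gene")
  structure(list(counts = counts,
                 gene_symbols = as.character(gene_symbols)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d non-zero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname count_matrix
#' @export
gene_symbols <- function(x) x$gene_symbols

#' @rdname count_matrix
#' @export
barcodes <- function(x) colnames(x$counts)

#' @rdname count_matrix
#' @export
n_genes <- function(x) nrow(x$counts)

#' @rdname count_matrix
#' @export
n_cells <- function(x) ncol(x$counts)

#' Subset the cells of a count matrix
#'
#' @param x A `count_matrix`.
#' @param cells Barcodes or column indices to keep.
#' @return A `count_matrix` restricted to the requested cells; genes are
#'   never dropped.
#' @export
subset_cells <- function(x, cells) {
  if (is.character(cells)) {
    missing <- setdiff(cells, barcodes(x))
    if (length(missing))
      stop("unknown barcodes: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  count_matrix(x$counts[, cells, drop = FALSE], x$gene_symbols)
}

# Resolve a character vector of gene symbols or identifiers to row indices.
# Unknown entries are dropped; the caller decides whether that warrants a
# warning or an error.
resolve_genes <- function(x, genes) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x$data
  idx <- match(genes, x$gene_symbols)
  miss <- is.na(idx)
  idx[miss] <- match(genes[miss], rownames(counts))[miss]
  idx[!is.na(idx)]
}

#' Read a 10x-style sparse matrix triplet
#'
#' Reads a Matrix Market coordinate file together with the features and
#' barcodes TSVs (plain or gzip-compressed, the usual on-disk layout of
#' droplet scRNA-seq count matrices).
#'
#' @param path Directory containing `matrix.mtx[.gz]`, `features.tsv[.gz]`
#'   (or `genes.tsv[.gz]`) and `barcodes.tsv[.gz]`; alternatively a character
#'   vector of the three file paths in that order.
#' @return A [count_matrix].
#' @export
read_10x_mtx <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    pick <- function(names) {
      for (nm in names) {
        f <- file.path(path, nm)
        if (file.exists(f)) return(f)
      }
      stop("no ", names[1], " (or gzip variant) found in ", path)
    }
    mtx <- pick(c("matrix.mtx", "matrix.mtx.gz"))
    feat <- pick(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
    bc <- pick(c("barcodes.tsv", "barcodes.tsv.gz"))
  } else if (length(path) == 3) {
    mtx <- path[1]; feat <- path[2]; bc <- path[3]
  } else stop("path must be a directory or the three file paths (mtx, features, barcodes)")

  m <- Matrix::readMM(mtx)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  feats <- utils::read.delim(feat, header = FALSE, colClasses = "character")
  bcs <- readLines(bc)
  bcs <- bcs[nzchar(bcs)]
  if (nrow(feats) != nrow(m))
    stop(sprintf("format error: matrix header declares %d genes but features file has %d",
                 nrow(m), nrow(feats)))
  if (length(bcs) != ncol(m))
    stop(sprintf("format error: matrix header declares %d cells but barcodes file has %d",
                 ncol(m), length(bcs)))
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x))))
    stop("format error: matrix entries must be non-negative integers")
  rownames(m) <- feats[[1]]
  colnames(m) <- bcs
  sym <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  count_matrix(m, sym)
}

#' Write a 10x-style sparse matrix triplet
#'
#' @param x A [count_matrix].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the three files (`.gz` suffixes)?
#' @return Invisibly, the paths of the files written.
#' @export
write_10x_mtx <- function(x, dir, gzip = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(x$counts, mtx)
  feat <- file.path(dir, "features.tsv")
  utils::write.table(
    data.frame(gene_ids(x), gene_symbols(x), "Gene Expression"),
    feat, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  bc <- file.path(dir, "barcodes.tsv")
  writeLines(barcodes(x), bc)
  paths <- c(mtx, feat, bc)
  if (gzip) {
    paths <- vapply(paths, function(p) {
      gz <- paste0(p, ".gz")
      con <- gzfile(gz, "wb")
      writeLines(readLines(p), con)
      close(con)
      unlink(p)
      gz
    }, character(1))
  }
  invisible(unname(paths))
}

#' Log-normalized expression matrix
#'
#' Global-scale normalization: each count is divided by its cell's total,
#' multiplied by a fixed scale factor, and natural-log transformed with a
#' pseudo-count of one. Zero counts map to zero, so sparsity is preserved.
#'
#' @param x A [count_matrix]; every cell must have a positive total (run QC
#'   first).
#' @param scale_factor Target library size after rescaling (default 1e4, i.e.
#'   counts per ten thousand).
#' @return An object of class `norm_matrix` with fields `data` (sparse
#'   gene-by-cell matrix of log1p-normalized values), `scale_factor` and
#'   `gene_symbols`.
#' @export
log_normalize <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    bad <- barcodes(x)[totals == 0][1]
    stop("cell with zero total counts cannot be normalized: ", bad)
  }
  m <- x$counts
  percell <- rep.int(totals, diff(m@p))
  m@x <- log1p(m@x * scale_factor / percell)
  structure(list(data = m, scale_factor = scale_factor,
                 gene_symbols = x$gene_symbols),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix: %d genes x %d cells (ln(1 + c * %g / total))\n",
              nrow(x$data), ncol(x$data), x$scale_factor))
  invisible(x)
}
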