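#' Per-cell quality-control metrics
#'
#' Computes, for every barcode, the number of detected genes (count > 0),
#' the total UMI count, and the percentage of counts attributable to
#' mitochondrial genes. A cell with zero total counts has `pct_mito = 0` by
#' convention (it is removed by the minimum-genes filter regardless).
#'
#' @param x A [count_matrix].
#' @param mito_genes Character vector of mitochondrial gene identifiers or
#'   symbols. Entries absent from the matrix are dropped with a warning.
#' @param mito_pattern Used when `mito_genes` is `NULL`: case-insensitive
#'   regular expression matched against gene symbols (default the
#'   conventional `MT-` prefix).
#' @return A data.frame with columns `barcode`, `n_genes`, `total_counts`,
#'   `pct_mito`.
#' @export
compute_qc_metrics <- function(x, mito_genes = NULL, mito_pattern = "^MT-") {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (is.null(mito_genes)) {
    mito_idx <- grep(mito_pattern, gene_symbols(x), ignore.case = TRUE)
  } else {
    found <- resolve_genes(x, mito_genes)
    if (length(found) < length(unique(mito_genes)))
      warning("dropping ", length(unique(mito_genes)) - length(found),
              " mitochondrial gene(s) not present in the matrix")
    mito_idx <- found
  }
  n_genes <- diff(m@p)
  total <- Matrix::colSums(m)
  mito <- if (length(mito_idx)) Matrix::colSums(m[mito_idx, , drop = FALSE]) else
    numeric(ncol(m))
  pct <- ifelse(total > 0, 100 * mito / total, 0)
  data.frame(barcode = barcodes(x), n_genes = n_genes,
             total_counts = as.numeric(total), pct_mito = as.numeric(pct),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quality-control thresholds
#'
#' Cells are removed when they have fewer than `min_genes` detected genes,
#' more than `max_genes` detected genes, or more than `max_pct_mito` percent
#' mitochondrial counts. The removal rule uses strict inequalities, so cells
#' sitting exactly on a boundary are kept.
#'
#' @param min_genes,max_genes Bounds on the number of detected genes
#'   (defaults 200 and 6500).
#' @param max_pct_mito Maximum mitochondrial percentage (default 15).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 6500, max_pct_mito = 15) {
  if (min_genes > max_genes) stop("min_genes must not exceed max_genes")
  if (max_pct_mito < 0 || max_pct_mito > 100)
    stop("max_pct_mito must lie in [0, 100]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_pct_mito = max_pct_mito), class = "qc_thresholds")
}

#' Apply QC thresholds to a metrics table
#'
#' @param metrics A data.frame as returned by [compute_qc_metrics()].
#' @param thresholds A [qc_thresholds()] object.
#' @return The metrics table with added columns `kept` (logical) and
#'   `reason` (`"min_genes"`, `"max_genes"`, `"max_pct_mito"` or `""`;
#'   the first violated criterion in that order).
#' @export
apply_qc_thresholds <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(metrics),
            all(c("barcode", "n_genes", "pct_mito") %in% names(metrics)))
  low <- metrics$n_genes < thresholds$min_genes
  high <- metrics$n_genes > thresholds$max_genes
  mito <- metrics$pct_mito > thresholds$max_pct_mito
  metrics$kept <- !(low | high | mito)
  metrics$reason <- ifelse(low, "min_genes",
                    ifelse(high, "max_genes",
                    ifelse(mito, "max_pct_mito", "")))
  metrics
}

#' Filter cells by QC thresholds
#'
#' @param x A [count_matrix].
#' @param metrics Optional precomputed metrics covering every barcode of `x`
#'   (computed with default mitochondrial detection otherwise).
#' @param thresholds A [qc_thresholds()] object.
#' @param ... Passed to [compute_qc_metrics()] when metrics are computed here.
#' @return A list with `matrix` (the kept cells; genes unchanged) and
#'   `report` (the annotated metrics table for all input barcodes).
#' @export
filter_cells <- function(x, metrics = NULL, thresholds = qc_thresholds(), ...) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(metrics)) metrics <- compute_qc_metrics(x, ...)
  if (!setequal(metrics$barcode, barcodes(x)) ||
      nrow(metrics) != n_cells(x))
    stop("metrics must cover exactly the barcodes of the matrix")
  metrics <- metrics[match(barcodes(x), metrics$barcode), , drop = FALSE]
  report <- apply_qc_thresholds(metrics, thresholds)
  kept <- report$barcode[report$kept]
  list(matrix = subset_cells(x, kept), report = report)
}
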