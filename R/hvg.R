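#' Select highly variable genes by variance-stabilizing transformation
#'
#' Per-gene mean and variance are computed on the raw counts; a local
#' regression of log10(variance) on log10(mean) provides the expected
#' variance under the mean-variance trend; each count is standardized by the
#' trend's predicted standard deviation with values clipped at
#' sqrt(n_cells); genes are ranked by the variance of the clipped
#' standardized values and the top `n_hvg` are flagged. Constant genes have
#' standardized variance zero and are never selected ahead of varying genes.
#'
#' @param x A [count_matrix].
#' @param n_hvg Number of genes to select (default 2000). Values larger than
#'   the gene count select every gene with a warning.
#' @param trend_span Span of the loess mean-variance trend (default 0.3).
#' @return A data.frame of class `hvg_result` with one row per gene:
#'   `gene_id`, `mean`, `variance`, `variance_expected`,
#'   `variance_standardized`, `selected`, ordered as the input genes.
#' @export
select_hvg_vst <- function(x, n_hvg = 2000, trend_span = 0.3) {
  stopifnot(inherits(x, "count_matrix"))
  if (n_hvg <= 0) stop("n_hvg must be positive")
  m <- x$counts
  n <- ncol(m)
  if (n < 2) stop("at least two cells are required")
  if (n_hvg > nrow(m)) {
    warning("n_hvg exceeds the number of genes; selecting all genes")
    n_hvg <- nrow(m)
  }

  mu <- Matrix::rowSums(m) / n
  sumsq <- Matrix::rowSums(m^2)
  v <- (sumsq - n * mu^2) / (n - 1)
  v <- pmax(v, 0)

  fit_idx <- which(v > 0 & mu > 0)
  v_exp <- rep(0, nrow(m))
  std_var <- rep(0, nrow(m))
  if (length(fit_idx) >= 2) {
    lx <- log10(mu[fit_idx]); ly <- log10(v[fit_idx])
    fit <- stats::loess(ly ~ lx, span = trend_span, degree = 2,
                        family = "symmetric")
    v_exp[fit_idx] <- 10^stats::fitted(fit)

    clip <- sqrt(n)
    sd_exp <- sqrt(v_exp)
    # Clipped standardized variance on the sparse structure: the (n - nnz)
    # zero counts of a gene all standardize to -mu/sd.
    nnz <- tabulate(m@i + 1L, nbins = nrow(m))
    gene_of <- m@i + 1L
    z <- (m@x - mu[gene_of]) / sd_exp[gene_of]
    z <- pmin(z, clip)
    z0 <- -mu / sd_exp
    sum_z2 <- rep(0, nrow(m))
    tz <- tapply(z^2, gene_of, sum)
    sum_z2[as.integer(names(tz))] <- tz
    tot <- sum_z2 + (n - nnz) * z0^2
    std_var[fit_idx] <- tot[fit_idx] / (n - 1)
  }

  ord <- order(-std_var, -v, seq_len(nrow(m)))
  selected <- logical(nrow(m))
  selected[ord[seq_len(n_hvg)]] <- TRUE
  out <- data.frame(gene_id = rownames(m), mean = mu, variance = v,
                    variance_expected = v_exp,
                    variance_standardized = std_var,
                    selected = selected, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("hvg_result", "data.frame")
  out
}
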