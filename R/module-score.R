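#' Gene-set module score with expression-matched control bins
#'
#' All genes are binned into `n_bins` equal-frequency bins by the rank of
#' their mean normalized expression across cells. For each gene of the set,
#' `n_ctrl` control genes are drawn from its bin (seeded; with replacement
#' when the bin holds fewer than `n_ctrl` genes). The score of a cell is the
#' mean expression of the set minus the mean expression of the pooled
#' control draw, so a set of average genes scores near zero and shared
#' depth/coverage effects cancel.
#'
#' @param normalized A `norm_matrix` from [log_normalize()].
#' @param gene_set Character vector of gene symbols or identifiers. Members
#'   absent from the matrix are dropped with a warning; an empty effective
#'   set is an error.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes drawn per target gene (default 100).
#' @param seed Seed for the control draw.
#' @return Named numeric vector of per-cell scores with attribute `params`.
#' @export
module_score <- function(normalized, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 0L) {
  stopifnot(inherits(normalized, "norm_matrix"))
  m <- normalized$data
  idx <- resolve_genes(normalized, gene_set)
  idx <- unique(idx)
  if (length(idx) < length(unique(gene_set)))
    warning("dropping ", length(unique(gene_set)) - length(idx),
            " gene(s) of the set not present in the matrix")
  if (!length(idx)) stop("no gene of the set is present in the matrix")

  avg <- Matrix::rowMeans(m)
  n_bins <- min(n_bins, nrow(m))
  # equal-frequency bins on the rank of mean expression
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk * n_bins / nrow(m))

  set.seed(seed)
  ctrl <- integer(0)
  for (g in idx) {
    pool <- which(bin == bin[g])
    ctrl <- c(ctrl, if (length(pool) >= n_ctrl)
      sample(pool, n_ctrl) else sample(pool, n_ctrl, replace = TRUE))
  }
  target_score <- Matrix::colMeans(m[idx, , drop = FALSE])
  # ctrl may contain duplicates; subsetting replicates rows, so the mean
  # carries the multiplicity of the draw
  ctrl_score <- Matrix::colMeans(m[ctrl, , drop = FALSE])
  score <- as.numeric(target_score) - as.numeric(ctrl_score)
  names(score) <- colnames(m)
  attr(score, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
                                n_genes_used = length(idx))
  score
}

#' Cell-cycle state from S and G2M gene-set scores
#'
#' Two module scores are computed; a cell is `cycling` when its G2M score
#' strictly exceeds its S score and `resting` otherwise (ties rest). A
#' three-state mode additionally labels cells whose two scores are both
#' non-positive as `quiescent`.
#'
#' @param normalized A `norm_matrix`.
#' @param s_genes,g2m_genes Gene lists for the two phases (non-empty after
#'   intersection with the matrix).
#' @param seed Seed passed to [module_score()].
#' @param three_state Add the `quiescent` level for doubly non-positive
#'   scores?
#' @param ... Passed to [module_score()].
#' @return Named character vector of states with attribute `scores`
#'   (two-column matrix of the S and G2M scores).
#' @export
cell_cycle_state <- function(normalized, s_genes, g2m_genes, seed = 0L,
                             three_state = FALSE, ...) {
  if (!length(s_genes) || !length(g2m_genes))
    stop("both gene lists must be non-empty")
  s <- module_score(normalized, s_genes, seed = seed, ...)
  g2m <- module_score(normalized, g2m_genes, seed = seed + 1L, ...)
  state <- ifelse(g2m > s, "cycling", "resting")
  if (three_state) state[s <= 0 & g2m <= 0] <- "quiescent"
  names(state) <- names(s)
  attr(state, "scores") <- cbind(s_score = s, g2m_score = g2m)
  state
}

#' Kruskal-Wallis comparison of scores between groups
#'
#' Rank-based test of whether a per-cell score differs between two or more
#' groups, with tie correction and a chi-square reference distribution on
#' k - 1 degrees of freedom.
#'
#' @param scores Numeric vector (e.g. a module score).
#' @param groups Factor or vector of group labels, same length; every group
#'   must be non-empty.
#' @return List with `statistic` (H), `p_value` and `df`.
#' @export
score_group_test <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("at least two groups are required")
  if (any(tabulate(groups) == 0)) stop("every group must be non-empty")
  if (length(unique(scores)) == 1)  # full rank degeneracy: H = 0 by definition
    return(list(statistic = 0, p_value = 1, df = nlevels(groups) - 1))
  fit <- stats::kruskal.test(scores, groups)
  list(statistic = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter))
}
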