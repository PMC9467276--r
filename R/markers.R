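#' Two-sided Wilcoxon rank-sum p-value
#'
#' Normal approximation with tie correction and no continuity correction;
#' when both groups hold at most `exact_max` observations the exact
#' permutation distribution of the rank-sum statistic is used instead. The
#' exact path handles ties: it computes the full permutation null of the sum
#' of (doubled) midranks by dynamic programming, which is identical to
#' enumerating all group assignments.
#'
#' @param values Numeric vector of observations.
#' @param in_group Logical vector marking group 1.
#' @param exact_max Use the exact distribution when both group sizes are at
#'   most this (default 25).
#' @return Two-sided p-value.
#' @export
wilcox_rank_sum <- function(values, in_group, exact_max = 25) {
  n <- length(values)
  n1 <- sum(in_group)
  n2 <- n - n1
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(values)
  w <- sum(r[in_group])
  if (n1 <= exact_max && n2 <= exact_max)
    return(wilcox_exact_p(r, n1, w))
  mu <- n1 * (n + 1) / 2
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Exact two-sided p by dynamic programming over doubled midranks: counts,
# for every achievable rank-sum, the number of n1-subsets attaining it, then
# sums the probability of sums at least as far from the mean as observed.
wilcox_exact_p <- function(r, n1, w) {
  n <- length(r)
  r2 <- as.integer(round(2 * r))          # doubled midranks are integers
  total <- sum(r2)
  maxsum <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  minsum <- sum(sort(r2)[seq_len(n1)])
  # dp[[k]][s+1] = number of k-subsets with doubled-rank sum s
  dp <- matrix(0, nrow = n1 + 1, ncol = maxsum + 1)
  dp[1, 1] <- 1
  for (x in r2) {
    kmax <- n1
    for (k in kmax:1) {
      nzc <- which(dp[k, ] > 0)
      if (length(nzc)) {
        tgt <- nzc + x
        dp[k + 1, tgt] <- dp[k + 1, tgt] + dp[k, nzc]
      }
    }
  }
  counts <- dp[n1 + 1, ]
  sums <- which(counts > 0) - 1L
  probs <- counts[sums + 1L] / choose(n, n1)
  mu2 <- n1 * (n + 1)                      # doubled mean
  dev <- abs(2 * w - mu2)
  sum(probs[abs(sums - mu2) >= dev - 1e-9])
}

#' Marker genes of one cluster against the rest
#'
#' One-vs-rest differential expression on log-normalized values. Genes are
#' pre-filtered to those detected in at least `min_pct` of either group and
#' with average log2 fold change at least `logfc_floor`; surviving genes are
#' tested with the two-sided Wilcoxon rank-sum test ([wilcox_rank_sum()]) and
#' corrected by Benjamini-Hochberg over the tested genes. The fold change
#' follows the convention log2(mean(expm1(x)) + 1) of each group.
#'
#' @param normalized A `norm_matrix`.
#' @param labels A `cluster_labels` object or named vector of labels covering
#'   the cells of `normalized`.
#' @param target_cluster The cluster whose markers are sought.
#' @param min_pct Minimum detection fraction in the better group (default 0.1).
#' @param logfc_floor Minimum average log2 fold change (default 0.25).
#' @return data.frame with columns `gene`, `cluster`, `p_val`, `p_val_adj`,
#'   `avg_log2FC`, `pct.1`, `pct.2`, ordered by increasing p then decreasing
#'   fold change.
#' @export
find_markers <- function(normalized, labels, target_cluster, min_pct = 0.1,
                         logfc_floor = 0.25) {
  stopifnot(inherits(normalized, "norm_matrix"))
  lab <- if (inherits(labels, "cluster_labels")) labels$cluster else labels
  m <- normalized$data
  if (!is.null(names(lab))) lab <- lab[colnames(m)]
  if (length(lab) != ncol(m)) stop("labels must cover every cell")
  in_grp <- lab == target_cluster
  if (!any(in_grp)) stop("target cluster is empty")
  if (all(in_grp)) stop("complement of the target cluster is empty")

  n1 <- sum(in_grp); n2 <- sum(!in_grp)
  m_in <- m[, in_grp, drop = FALSE]
  m_out <- m[, !in_grp, drop = FALSE]
  pct1 <- Matrix::rowSums(m_in > 0) / n1
  pct2 <- Matrix::rowSums(m_out > 0) / n2
  mean_in <- Matrix::rowSums(expm1(m_in)) / n1
  mean_out <- Matrix::rowSums(expm1(m_out)) / n2
  lfc <- log2(mean_in + 1) - log2(mean_out + 1)

  test <- which(pmax(pct1, pct2) >= min_pct & lfc >= logfc_floor)
  p <- rep(NA_real_, length(test))
  if (length(test)) {
    dense <- as.matrix(m[test, , drop = FALSE])
    for (i in seq_along(test)) p[i] <- wilcox_rank_sum(dense[i, ], in_grp)
  }
  out <- data.frame(gene = rownames(m)[test],
                    cluster = rep(target_cluster, length(test)),
                    p_val = p,
                    p_val_adj = stats::p.adjust(p, method = "BH"),
                    avg_log2FC = lfc[test],
                    pct.1 = pct1[test], pct.2 = pct2[test],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_val, -out$avg_log2FC), , drop = FALSE]
}

#' Marker genes for every cluster
#'
#' Concatenates [find_markers()] over all clusters and flags rows passing
#' the significance rule (adjusted p below `alpha` and average log2 fold
#' change above `logfc_min`); non-significant rows are kept so the table can
#' be filtered either way.
#'
#' @param normalized A `norm_matrix`.
#' @param labels `cluster_labels` or named label vector with at least two
#'   clusters.
#' @param min_pct,logfc_floor Pre-filter thresholds, see [find_markers()].
#' @param alpha,logfc_min Significance rule (defaults 0.05 and 0.25).
#' @return data.frame as [find_markers()] plus a logical `significant`
#'   column.
#' @export
find_all_markers <- function(normalized, labels, min_pct = 0.1,
                             logfc_floor = 0.25, alpha = 0.05,
                             logfc_min = 0.25) {
  lab <- if (inherits(labels, "cluster_labels")) labels$cluster else labels
  clusters <- sort(unique(lab))
  if (length(clusters) < 2) stop("at least two clusters are required")
  out <- do.call(rbind, lapply(clusters, function(cl)
    find_markers(normalized, labels, cl, min_pct = min_pct,
                 logfc_floor = logfc_floor)))
  out$significant <- out$p_val_adj < alpha & out$avg_log2FC > logfc_min
  rownames(out) <- NULL
  out
}
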