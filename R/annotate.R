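#' Canonical marker panels for the major BALF immune cell types
#'
#' The default panels cover the six major immune populations of
#' bronchoalveolar lavage fluid: monocytes/macrophages (CD163, CD68),
#' dendritic cells (CD83, CCR7, FSCN1), T cells (CD2, CD3D, CD3E, CD3G),
#' B/plasma cells (MS4A1, CD79A, CD79B), neutrophils (TG, RGS2, LILRA5,
#' CSF3R) and mast cells (LTC4S, HPGDS, GCSAML, MS4A2).
#'
#' @param aliases Optional named character vector mapping panel symbols to
#'   the symbols used in the annotation at hand (useful for species whose
#'   references carry locus identifiers instead of symbols).
#' @return Named list of character vectors, one per major type.
#' @export
default_marker_panels <- function(aliases = NULL) {
  panels <- list(
    mo_ma      = c("CD163", "CD68"),
    dc         = c("CD83", "CCR7", "FSCN1"),
    t          = c("CD2", "CD3D", "CD3E", "CD3G"),
    b_plasma   = c("MS4A1", "CD79A", "CD79B"),
    neutrophil = c("TG", "RGS2", "LILRA5", "CSF3R"),
    mast       = c("LTC4S", "HPGDS", "GCSAML", "MS4A2"))
  if (!is.null(aliases)) {
    panels <- lapply(panels, function(g) {
      hit <- g %in% names(aliases)
      g[hit] <- aliases[g[hit]]
      g
    })
  }
  panels
}

#' Assign clusters to major cell types by panel module scores
#'
#' For every cluster the mean module score of each marker panel over the
#' member cells is computed; the cluster is assigned the top-scoring type
#' provided that score is positive and exceeds the runner-up by `margin`,
#' and is `"unassigned"` otherwise (with a warning on exact ties).
#'
#' @param normalized A `norm_matrix`.
#' @param labels `cluster_labels` or a named label vector.
#' @param panels Named list of marker gene sets (default
#'   [default_marker_panels()]).
#' @param seed Base seed for the control-gene draws (one offset per panel).
#' @param margin Minimum lead of the winning score (default 0.05).
#' @param ... Passed to [module_score()].
#' @return Object of class `cell_type_assignment`: list with `cluster_types`
#'   (named character vector cluster -> type), `cell_types` (per-cell types
#'   consistent with the cluster map), and `scores` (clusters x panels
#'   matrix of mean module scores).
#' @export
assign_major_types <- function(normalized, labels,
                               panels = default_marker_panels(), seed = 0L,
                               margin = 0.05, ...) {
  lab <- if (inherits(labels, "cluster_labels")) labels$cluster else labels
  m <- normalized$data
  if (!is.null(names(lab))) lab <- lab[colnames(m)]
  stopifnot(length(lab) == ncol(m))
  clusters <- sort(unique(lab))

  resolvable <- vapply(panels, function(g)
    length(resolve_genes(normalized, g)) > 0, logical(1))
  if (!all(resolvable)) {
    warning("dropping panel(s) with no genes in the matrix: ",
            paste(names(panels)[!resolvable], collapse = ", "))
    panels <- panels[resolvable]
  }
  if (!length(panels)) stop("no marker panel is resolvable against the matrix")

  # one shared seed so identical gene lists draw identical controls (and
  # therefore tie exactly)
  score_mat <- sapply(seq_along(panels), function(i) {
    s <- module_score(normalized, panels[[i]], seed = seed, ...)
    tapply(s, lab, mean)[as.character(clusters)]
  })
  score_mat <- matrix(score_mat, nrow = length(clusters),
                      dimnames = list(as.character(clusters), names(panels)))

  cluster_types <- apply(score_mat, 1, function(s) {
    ord <- order(s, decreasing = TRUE)
    top <- s[ord[1]]; second <- if (length(s) > 1) s[ord[2]] else -Inf
    if (top <= 0) return("unassigned")
    if (top - second < margin) {
      if (top == second) warning("tied panel scores; cluster left unassigned")
      return("unassigned")
    }
    names(s)[ord[1]]
  })
  cell_types <- unname(cluster_types[as.character(lab)])
  names(cell_types) <- colnames(m)
  structure(list(cluster_types = cluster_types, cell_types = cell_types,
                 scores = score_mat, margin = margin),
            class = "cell_type_assignment")
}

#' @export
print.cell_type_assignment <- function(x, ...) {
  cat("cell_type_assignment:\n")
  print(x$cluster_types)
  invisible(x)
}
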