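#' Default pipeline configuration
#'
#' Returns the full configuration of a pipeline run with every field at its
#' default: QC thresholds (200/6500 genes, 15 percent mitochondrial),
#' counts-per-10,000 log-normalization, 2,000 variance-stabilized HVGs, the
#' `top_level` clustering preset (16 PCs, Louvain resolution 1.0), k = 20
#' SNN neighbors with Jaccard prune 1/15, the canonical marker panels, the
#' three subset presets keyed by major type, and one seed per random stage.
#'
#' @return List of class `balf_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    qc = list(min_genes = 200, max_genes = 6500, max_pct_mito = 15,
              mito_pattern = "^MT-"),
    normalize = list(scale_factor = 1e4),
    hvg = list(n_hvg = 2000, trend_span = 0.3),
    cluster = list(preset = "top_level", n_pcs = 16, resolution = 1.0,
                   k = 20, prune = 1 / 15),
    annotate = list(n_bins = 24, n_ctrl = 100, margin = 0.05),
    markers = list(run = TRUE, min_pct = 0.1, logfc_floor = 0.25,
                   alpha = 0.05, logfc_min = 0.25),
    subsets = list(run = TRUE, min_cells = 50,
                   presets = list(mo_ma = "mo_ma", t = "t_cell",
                                  b_plasma = "b_plasma")),
    seeds = list(cluster = 0L, annotate = 0L, subcluster = 0L),
    panels = default_marker_panels()),
    class = "balf_config")
}

# deep-merge user values into the defaults, erroring on unknown keys
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !key %in% c("panels", "presets")) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Fills defaults ([default_pipeline_config()]) and checks every invariant;
#' unknown keys and invalid values are reported by name. An empty input
#' yields the full default configuration.
#'
#' @param config A (possibly partial) configuration list, or `NULL`.
#' @return A validated `balf_config`.
#' @export
validate_config <- function(config = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(config) && length(config)) {
    if (inherits(config, "balf_config")) config <- unclass(config)
    cfg <- merge_config(unclass(cfg), config)
    class(cfg) <- "balf_config"
  }
  if (cfg$qc$min_genes > cfg$qc$max_genes)
    stop("invalid configuration: qc.min_genes exceeds qc.max_genes")
  if (cfg$qc$max_pct_mito < 0 || cfg$qc$max_pct_mito > 100)
    stop("invalid configuration: qc.max_pct_mito outside [0, 100]")
  if (cfg$cluster$resolution <= 0)
    stop("invalid configuration: cluster.resolution must be positive")
  if (cfg$cluster$n_pcs < 1)
    stop("invalid configuration: cluster.n_pcs must be at least 1")
  if (cfg$hvg$n_hvg < 1)
    stop("invalid configuration: hvg.n_hvg must be at least 1")
  if (cfg$subsets$min_cells < cfg$cluster$k + 1)
    cfg$subsets$min_cells <- cfg$cluster$k + 1
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file; keys mirror
#'   [default_pipeline_config()]. An empty file yields the defaults.
#' @return A validated `balf_config`.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

stage_checksum <- function(obj) digest::digest(obj, algo = "md5")

#' Run the full BALF analysis pipeline
#'
#' Executes QC filtering, log-normalization, HVG selection, PCA, SNN
#' construction, Louvain clustering, marker-panel type assignment, optional
#' one-vs-rest marker detection, subset re-analysis of each major type with
#' enough cells, and the differential cell count, returning one classed
#' result object with a reproducibility manifest (per-stage checksums and
#' seeds; identical input and configuration reproduce identical checksums).
#'
#' @param x A [count_matrix], or a path readable by [read_10x_mtx()].
#' @param config A configuration accepted by [validate_config()].
#' @return Object of class `balf_run` with components `qc_report`,
#'   `cluster_run`, `assignment`, `markers`, `subsets`, `dcc`, `config` and
#'   `manifest`.
#' @export
balf_pipeline <- function(x, config = NULL) {
  cfg <- validate_config(config)
  if (is.character(x)) x <- read_10x_mtx(x)
  stopifnot(inherits(x, "count_matrix"))
  manifest <- list(package_version = as.character(utils::packageVersion("scbalf")),
                   config_checksum = stage_checksum(cfg),
                   input_checksum = stage_checksum(x$counts),
                   seeds = cfg$seeds, stages = list())
  tick <- function(name, value) {
    manifest$stages[[name]] <<- stage_checksum(value)
    value
  }

  qc <- filter_cells(x, thresholds = qc_thresholds(cfg$qc$min_genes,
                                                   cfg$qc$max_genes,
                                                   cfg$qc$max_pct_mito),
                     mito_pattern = cfg$qc$mito_pattern)
  tick("qc", qc$report)
  kept <- qc$matrix

  run <- cluster_cells(kept, n_pcs = cfg$cluster$n_pcs,
                       resolution = cfg$cluster$resolution,
                       n_hvg = cfg$hvg$n_hvg, k = cfg$cluster$k,
                       prune = cfg$cluster$prune,
                       scale_factor = cfg$normalize$scale_factor,
                       seed = cfg$seeds$cluster, provenance = "top_level")
  tick("cluster", run$labels$cluster)

  assignment <- assign_major_types(run$normalized, run$labels,
                                   panels = cfg$panels,
                                   seed = cfg$seeds$annotate,
                                   margin = cfg$annotate$margin,
                                   n_bins = cfg$annotate$n_bins,
                                   n_ctrl = cfg$annotate$n_ctrl)
  tick("assignment", assignment$cluster_types)

  markers <- NULL
  if (isTRUE(cfg$markers$run) && length(unique(run$labels$cluster)) > 1) {
    markers <- find_all_markers(run$normalized, run$labels,
                                min_pct = cfg$markers$min_pct,
                                logfc_floor = cfg$markers$logfc_floor,
                                alpha = cfg$markers$alpha,
                                logfc_min = cfg$markers$logfc_min)
    tick("markers", markers)
  }

  subsets <- list()
  if (isTRUE(cfg$subsets$run)) {
    for (type in names(cfg$subsets$presets)) {
      members <- names(assignment$cell_types)[assignment$cell_types == type]
      if (length(members) >= cfg$subsets$min_cells) {
        subsets[[type]] <- subcluster(kept, members,
                                      preset = cfg$subsets$presets[[type]],
                                      seed = cfg$seeds$subcluster,
                                      k = cfg$cluster$k,
                                      prune = cfg$cluster$prune,
                                      n_hvg = cfg$hvg$n_hvg,
                                      scale_factor = cfg$normalize$scale_factor)
        manifest$stages[[paste0("subset_", type)]] <-
          stage_checksum(subsets[[type]]$labels$cluster)
      }
    }
  }

  dcc <- suppressWarnings(collapse_to_cytology_classes(assignment))
  tick("dcc", dcc$percent)

  structure(list(qc_report = qc$report, cluster_run = run,
                 assignment = assignment, markers = markers,
                 subsets = subsets, dcc = dcc, config = cfg,
                 manifest = manifest),
            class = "balf_run")
}

#' @export
print.balf_run <- function(x, ...) {
  rep <- x$qc_report
  cat(sprintf("balf_run: %d/%d cells passed QC\n", sum(rep$kept), nrow(rep)))
  k <- length(unique(x$cluster_run$labels$cluster))
  cat(sprintf("  %d clusters at resolution %g -> types: %s\n", k,
              x$cluster_run$labels$resolution,
              paste(unique(x$assignment$cluster_types), collapse = ", ")))
  cat(sprintf("  lymphocyte/macrophage ratio: %.1f\n",
              lymphocyte_macrophage_ratio(x$dcc)$display))
  invisible(x)
}

#' @export
summary.balf_run <- function(object, ...) {
  cat("Quality control:\n")
  rep <- object$qc_report
  cat(sprintf("  %d cells in, %d removed (%s), %d retained\n", nrow(rep),
              sum(!rep$kept),
              paste(names(table(rep$reason[!rep$kept])),
                    table(rep$reason[!rep$kept]), sep = "=", collapse = ", "),
              sum(rep$kept)))
  cat("Clusters and types:\n")
  tab <- table(object$assignment$cell_types)
  for (nm in names(tab))
    cat(sprintf("  %-12s %5d cells\n", nm, tab[[nm]]))
  cat("Differential cell count (%):\n")
  print(round_half_up(object$dcc$percent, 1))
  if (!is.null(object$markers))
    cat(sprintf("Markers: %d significant rows of %d tested\n",
                sum(object$markers$significant), nrow(object$markers)))
  invisible(object)
}

#' Plot a pipeline run as a UMAP colored by assigned type
#'
#' @param x A `balf_run`.
#' @param seed Seed for the UMAP layout.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the 2-D coordinates.
#' @export
plot.balf_run <- function(x, seed = 0L, ...) {
  coords <- umap_embed(x$cluster_run$embedding, seed = seed)
  types <- factor(x$assignment$cell_types)
  cols <- grDevices::hcl.colors(max(3, nlevels(types)), "Dark 3")
  graphics::plot(coords, col = cols[as.integer(types)], pch = 16, cex = 0.4,
                 xlab = "UMAP1", ylab = "UMAP2", ...)
  graphics::legend("topright", legend = levels(types),
                   col = cols[seq_len(nlevels(types))], pch = 16, cex = 0.7)
  invisible(coords)
}
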