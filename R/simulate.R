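#' Specification of one planted cell population
#'
#' @param name Population name (one of the six major types, or a custom
#'   subtype name).
#' @param fraction Fraction of cells (non-negative; fractions across the
#'   populations of a configuration sum to 1 before doublet injection).
#' @param marker_genes Canonical panel symbols planted for this population.
#' @param marker_fold Multiplicative up-regulation of the panel genes
#'   (default 8; must exceed 1).
#' @param n_program_genes Number of additional population-specific
#'   "program" genes (default 100); real cell types differ in hundreds of
#'   genes, and a panel of 2-4 genes alone carries too little signal to
#'   drive clustering.
#' @param program_fold Up-regulation of the program genes (default 4).
#' @param parent_type Major type the population belongs to (defaults to its
#'   own name; set for subtypes).
#' @return List of class `population_spec`.
#' @export
population_spec <- function(name, fraction, marker_genes = character(0),
                            marker_fold = 8, n_program_genes = 100,
                            program_fold = 4, parent_type = name) {
  if (fraction < 0) stop("fraction must be non-negative")
  if (marker_fold <= 1) stop("marker_fold must exceed 1")
  structure(list(name = name, fraction = fraction,
                 marker_genes = marker_genes, marker_fold = marker_fold,
                 n_program_genes = n_program_genes,
                 program_fold = program_fold, parent_type = parent_type),
            class = "population_spec")
}

#' Configuration of a synthetic BALF cohort
#'
#' @param n_cells,n_genes Cohort dimensions.
#' @param populations List of [population_spec()] objects whose fractions
#'   sum to 1.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression rates.
#' @param nb_dispersion Negative-binomial size parameter shared by all
#'   genes (smaller = more over-dispersed).
#' @param depth_meanlog,depth_sdlog Log-normal parameters of per-cell
#'   sequencing depth (total UMIs).
#' @param mito_gene_count Number of mitochondrial genes (symbols carry the
#'   `MT-` prefix).
#' @param mito_fraction_mean,mito_fraction_kappa Beta-distributed per-cell
#'   mitochondrial fraction: mean and concentration.
#' @param doublet_fraction Fraction of cells replaced by heterotypic
#'   doublets (default 0.02).
#' @param doublet_pairing Character pair of population names whose rate
#'   vectors are summed (default monocyte/macrophage x T cell, emulating
#'   monocyte-lymphocyte complexes).
#' @param qc_fail_low_genes,qc_fail_high_mito Planted numbers of
#'   quality-control failures (cells forced below 200 detected genes /
#'   above 15 percent mitochondrial counts).
#' @param seed Seed of the generator.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_cells = 5000, n_genes = 10000,
                              populations,
                              baseline_meanlog = 0, baseline_sdlog = 1.5,
                              nb_dispersion = 2,
                              depth_meanlog = log(3000), depth_sdlog = 0.35,
                              mito_gene_count = 13,
                              mito_fraction_mean = 0.05,
                              mito_fraction_kappa = 60,
                              doublet_fraction = 0.02,
                              doublet_pairing = c("mo_ma", "t"),
                              qc_fail_low_genes = 0,
                              qc_fail_high_mito = 0,
                              seed = 1L) {
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-6) stop("population fractions must sum to 1")
  if (doublet_fraction < 0 || doublet_fraction >= 1)
    stop("doublet_fraction must lie in [0, 1)")
  if (qc_fail_low_genes + qc_fail_high_mito > n_cells)
    stop("more planted QC failures than cells")
  nms <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("population names must be unique")
  names(populations) <- nms
  if (doublet_fraction > 0 && !all(doublet_pairing %in% nms))
    stop("doublet_pairing must name existing populations")
  structure(list(n_cells = n_cells, n_genes = n_genes,
                 populations = populations,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 nb_dispersion = nb_dispersion,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 mito_gene_count = mito_gene_count,
                 mito_fraction_mean = mito_fraction_mean,
                 mito_fraction_kappa = mito_fraction_kappa,
                 doublet_fraction = doublet_fraction,
                 doublet_pairing = doublet_pairing,
                 qc_fail_low_genes = qc_fail_low_genes,
                 qc_fail_high_mito = qc_fail_high_mito,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default synthetic BALF cohort configuration
#'
#' 5,000 cells and 10,000 genes with the six major immune populations in
#' the proportions measured by scRNA-seq in an equine BALF cohort
#' ([reference_balf_dcc()]): the average scRNA-seq differential cell count
#' over the three horses, with lymphocytes split 95/5 between T and
#' B/plasma cells and macrophages split 90/10 between monocytes/macrophages
#' and dendritic cells. Marker panels are the canonical defaults
#' ([default_marker_panels()]); 2 percent of cells are monocyte x T-cell
#' doublet complexes; about 14 percent of cells carry planted QC failures
#' (the filtered fraction observed in the reference cohort).
#'
#' @param seed Generator seed.
#' @return A `sim_config`.
#' @export
default_balf_config <- function(seed = 1L) {
  # average scRNA-seq DCC over the three reference samples
  ref <- reference_balf_dcc()
  sc <- ref[ref$source == "scrnaseq", ]
  avg <- colMeans(sc[, c("lymphocytes", "macrophages", "neutrophils",
                         "mast_cells", "eosinophils")]) / 100
  avg <- avg / sum(avg)
  panels <- default_marker_panels()
  pops <- list(
    population_spec("t",          avg[["lymphocytes"]] * 0.95, panels$t),
    population_spec("b_plasma",   avg[["lymphocytes"]] * 0.05, panels$b_plasma),
    population_spec("mo_ma",      avg[["macrophages"]] * 0.90, panels$mo_ma),
    population_spec("dc",         avg[["macrophages"]] * 0.10, panels$dc),
    population_spec("neutrophil", avg[["neutrophils"]],        panels$neutrophil),
    population_spec("mast",       avg[["mast_cells"]],         panels$mast))
  simulation_config(n_cells = 5000, n_genes = 10000, populations = pops,
                    qc_fail_low_genes = 500, qc_fail_high_mito = 220,
                    seed = seed)
}

mito_symbols <- function(n) {
  base <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
            "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6",
            "MT-CYB")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("MT-G", seq_len(n - length(base))))
}

#' Simulate a BALF-like count matrix with known ground truth
#'
#' Gene baseline rates are drawn log-normal; each cell samples a population
#' by fraction and takes the baseline rate vector with its population's
#' panel and program genes multiplied by their fold changes; a per-cell
#' mitochondrial fraction (Beta) of the rate mass is allocated to the
#' mitochondrial genes; depth is log-normal; counts are negative-binomial
#' with shared dispersion around rate x depth. Doublet cells sum the rate
#' vectors of two parents and inflate depth 1.5-fold. Planted QC failures
#' are produced by collapsing depth (low-gene cells) or re-weighting the
#' mitochondrial fraction (high-mito cells). A fixed seed reproduces the
#' output bitwise.
#'
#' @param config A `sim_config`.
#' @return List with `matrix` (a [count_matrix]), `truth` (list of `cells`
#'   and `genes` data.frames) and `config`.
#' @export
simulate_balf <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes; N <- config$n_cells
  pops <- config$populations
  pnames <- names(pops)

  n_mito <- config$mito_gene_count
  if (n_mito >= G) stop("mito_gene_count must be smaller than n_genes")
  symbols <- paste0("gene", formatC(seq_len(G), width = 5, flag = "0"))
  ids <- symbols
  is_mito <- c(rep(TRUE, n_mito), rep(FALSE, G - n_mito))
  symbols[is_mito] <- mito_symbols(n_mito)

  # reserve gene slots: panel genes first (well-expressed), then programs
  free <- which(!is_mito)
  is_marker_of <- rep(NA_character_, G)
  marker_class <- rep(NA_character_, G)
  panel_idx <- list(); program_idx <- list()
  reserve <- function(k, what) {
    if (k > length(free)) stop("not enough genes for the ", what)
    take <- free[seq_len(k)]
    free <<- free[setdiff(seq_along(free), seq_len(k))]
    take
  }
  for (p in pnames) {
    take <- reserve(length(pops[[p]]$marker_genes), "marker panels")
    symbols[take] <- pops[[p]]$marker_genes
    is_marker_of[take] <- p; marker_class[take] <- "panel"
    panel_idx[[p]] <- take
  }
  for (p in pnames) {
    take <- reserve(pops[[p]]$n_program_genes, "population programs")
    is_marker_of[take] <- p; marker_class[take] <- "program"
    program_idx[[p]] <- take
  }
  if (anyDuplicated(symbols)) stop("marker panels collide with reserved symbols")

  base <- stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
  # the mitochondrial protein genes are co-transcribed from one polycistron,
  # so their relative levels are far more even than nuclear genes
  base[is_mito] <- stats::rlnorm(n_mito, config$baseline_meanlog, 0.4)
  # canonical markers are robustly detected genes: place panel (and program)
  # genes in the upper part of the baseline distribution
  hi <- exp(config$baseline_meanlog + config$baseline_sdlog)
  for (p in pnames) {
    base[panel_idx[[p]]] <- hi * stats::runif(length(panel_idx[[p]]), 0.8, 1.6)
    base[program_idx[[p]]] <- base[program_idx[[p]]] *
      stats::runif(length(program_idx[[p]]), 0.8, 1.25) + 0.25 * hi
  }

  # per-population rate vectors, normalized to sum 1 with the mitochondrial
  # mass removed (it is re-inserted per cell)
  rate <- sapply(pnames, function(p) {
    v <- base
    v[panel_idx[[p]]] <- v[panel_idx[[p]]] * pops[[p]]$marker_fold
    v[program_idx[[p]]] <- v[program_idx[[p]]] * pops[[p]]$program_fold
    v[is_mito] <- 0
    v / sum(v)
  })
  mito_rate <- base; mito_rate[!is_mito] <- 0
  mito_rate <- mito_rate / sum(mito_rate)

  population <- sample(pnames, N, replace = TRUE,
                       prob = vapply(pops, `[[`, numeric(1), "fraction"))
  is_doublet <- rep(FALSE, N)
  doublet_parents <- rep(NA_character_, N)
  n_dbl <- round(config$doublet_fraction * N)
  if (n_dbl > 0) {
    dbl <- sample(N, n_dbl)
    is_doublet[dbl] <- TRUE
    population[dbl] <- "doublet"
    doublet_parents[dbl] <- paste(config$doublet_pairing, collapse = "+")
  }

  depth <- stats::rlnorm(N, config$depth_meanlog, config$depth_sdlog)
  depth[is_doublet] <- depth[is_doublet] * 1.5
  mito_f <- stats::rbeta(N, config$mito_fraction_mean * config$mito_fraction_kappa,
                         (1 - config$mito_fraction_mean) * config$mito_fraction_kappa)

  planted_qc <- rep("", N)
  singlet <- which(!is_doublet)
  if (config$qc_fail_low_genes + config$qc_fail_high_mito > length(singlet))
    stop("more planted QC failures than singlet cells")
  fail <- sample(singlet, config$qc_fail_low_genes + config$qc_fail_high_mito)
  low <- utils::head(fail, config$qc_fail_low_genes)
  himito <- utils::tail(fail, config$qc_fail_high_mito)
  planted_qc[low] <- "low_genes"
  planted_qc[himito] <- "high_mito"
  depth[low] <- stats::runif(length(low), 60, 140)
  mito_f[himito] <- stats::runif(length(himito), 0.3, 0.5)

  dbl_rate <- if (n_dbl > 0)
    (rate[, config$doublet_pairing[1]] + rate[, config$doublet_pairing[2]]) / 2
  else NULL

  ii <- vector("list", N); xx <- vector("list", N)
  size <- config$nb_dispersion
  mito_rows <- which(is_mito)
  for (j in seq_len(N)) {
    rv <- if (is_doublet[j]) dbl_rate else rate[, population[j]]
    mu <- ((1 - mito_f[j]) * rv + mito_f[j] * mito_rate) * depth[j]
    cnt <- stats::rnbinom(G, size = size, mu = mu)
    if (planted_qc[j] == "high_mito") {
      # the plant must survive count noise: redraw (seeded) until the
      # realized mitochondrial share clears the conventional 15% threshold
      tries <- 0
      while (sum(cnt[mito_rows]) <= 0.16 * sum(cnt) && tries < 25) {
        cnt <- stats::rnbinom(G, size = size, mu = mu)
        tries <- tries + 1
      }
    }
    nz <- which(cnt > 0)
    ii[[j]] <- nz; xx[[j]] <- cnt[nz]
  }
  nnz <- lengths(ii)
  bc <- paste0("cell", formatC(seq_len(N), width = 5, flag = "0"))
  m <- Matrix::sparseMatrix(i = unlist(ii), j = rep.int(seq_len(N), nnz),
                            x = as.numeric(unlist(xx)), dims = c(G, N),
                            dimnames = list(ids, bc))
  major <- vapply(pops, `[[`, character(1), "parent_type")
  cells <- data.frame(
    barcode = bc, population = population,
    major_type = ifelse(is_doublet, NA_character_, unname(major[population])),
    is_doublet = is_doublet, doublet_parents = doublet_parents,
    planted_qc_failure = planted_qc, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = ids, symbol = symbols,
                      is_marker_of = is_marker_of,
                      marker_class = marker_class,
                      is_mito = is_mito, stringsAsFactors = FALSE)
  list(matrix = count_matrix(m, symbols),
       truth = list(cells = cells, genes = genes),
       config = config)
}

#' Plant an exact number of QC threshold violations in a metrics table
#'
#' Generates a per-cell QC metrics table (as [compute_qc_metrics()] would
#' produce) in which exactly the requested numbers of cells violate the
#' low-gene, high-gene and high-mitochondrial thresholds, each violation
#' planted in a distinct cell; all remaining cells satisfy every threshold
#' with margin. Useful for verifying the filter arithmetic on cohorts of a
#' prescribed size.
#'
#' @param n_cells Total cells.
#' @param n_low_genes,n_high_genes,n_high_mito Planted violation counts.
#' @param thresholds A [qc_thresholds()] object.
#' @param seed Seed.
#' @return Metrics data.frame with an extra `planted_violation` column.
#' @export
simulate_qc_metrics <- function(n_cells, n_low_genes = 0, n_high_genes = 0,
                                n_high_mito = 0,
                                thresholds = qc_thresholds(), seed = 1L) {
  n_bad <- n_low_genes + n_high_genes + n_high_mito
  if (n_bad > n_cells) stop("more planted violations than cells")
  set.seed(seed)
  n_genes <- round(stats::runif(n_cells, thresholds$min_genes + 50,
                                min(thresholds$max_genes - 500, 4000)))
  pct <- stats::runif(n_cells, 0, thresholds$max_pct_mito * 0.6)
  bad <- sample(n_cells, n_bad)
  lo <- bad[seq_len(n_low_genes)]
  hig <- bad[n_low_genes + seq_len(n_high_genes)]
  him <- bad[n_low_genes + n_high_genes + seq_len(n_high_mito)]
  n_genes[lo] <- round(stats::runif(length(lo), 20, thresholds$min_genes - 1))
  n_genes[hig] <- round(stats::runif(length(hig), thresholds$max_genes + 1,
                                     thresholds$max_genes + 3000))
  pct[him] <- stats::runif(length(him), thresholds$max_pct_mito + 1, 80)
  planted <- rep("", n_cells)
  planted[lo] <- "min_genes"; planted[hig] <- "max_genes"
  planted[him] <- "max_pct_mito"
  data.frame(barcode = paste0("cell", formatC(seq_len(n_cells), width = 5,
                                              flag = "0")),
             n_genes = n_genes,
             total_counts = n_genes * round(stats::runif(n_cells, 2, 6)),
             pct_mito = pct, planted_violation = planted,
             stringsAsFactors = FALSE)
}

#' Random toy genome annotation with known blocking truth
#'
#' Places single-transcript genes along `n_seqs` sequences in convergent
#' pairs: with probability `overlap_fraction` a pair is placed so close
#' that a downstream extension of either member would run into the other
#' (both blocked under the any-strand skip policy); otherwise the pair is
#' spread far apart (neither blocked). The returned truth lists the
#' transcripts that must be blocked, computed by a brute-force all-pairs
#' interval-overlap scan.
#'
#' @param n_genes Number of genes (rounded up to an even count).
#' @param n_seqs Number of sequences.
#' @param overlap_fraction Fraction of gene pairs planted to collide.
#' @param seed Seed.
#' @param ext_length Extension length the truth refers to (default 2000).
#' @return List with `annotation` (a [genome_annotation]) and
#'   `blocked_transcripts` (character vector of transcript ids).
#' @export
make_toy_annotation <- function(n_genes = 20, n_seqs = 2, overlap_fraction = 0.5,
                                seed = 1L, ext_length = 2000) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  set.seed(seed)
  n_pairs <- ceiling(n_genes / 2)
  seq_of_pair <- sort(rep_len(seq_len(n_seqs), n_pairs))
  rec <- list(); gid <- 0
  for (s in seq_len(n_seqs)) {
    pos <- 50000  # headroom so upstream extensions never leave the sequence
    for (pair in which(seq_of_pair == s)) {
      collide <- stats::runif(1) < overlap_fraction
      len1 <- round(stats::runif(1, 500, 3000))
      len2 <- round(stats::runif(1, 500, 3000))
      gap <- if (collide) round(stats::runif(1, 10, ext_length - 10)) else
        round(stats::runif(1, ext_length + 500, ext_length + 5000))
      g1 <- c(pos, pos + len1 - 1)
      g2 <- c(g1[2] + gap + 1, g1[2] + gap + len2)
      for (k in 1:2) {
        gid <- gid + 1
        span <- if (k == 1) g1 else g2
        strand <- if (k == 1) "+" else "-"   # convergent pair
        rec[[length(rec) + 1]] <- data.frame(
          seqid = paste0("chr", s),
          feature_kind = c("gene", "transcript", "exon"),
          start = span[1], end = span[2], strand = strand,
          id = paste0(c("g", "t", "e"), gid),
          parent = c(NA, paste0("g", gid), paste0("t", gid)),
          stringsAsFactors = FALSE)
      }
      pos <- g2[2] + ext_length + round(stats::runif(1, 2000, 8000))
    }
  }
  ann <- genome_annotation(do.call(rbind, rec))
  list(annotation = ann,
       blocked_transcripts = brute_force_blocked(ann, ext_length))
}

# O(n^2) all-pairs oracle: a transcript is blocked when its extension
# interval overlaps any gene span other than its own parent's.
brute_force_blocked <- function(ann, ext_length, scope = "any-strand") {
  r <- ann$records
  tx <- r[r$feature_kind == "transcript", , drop = FALSE]
  genes <- r[r$feature_kind == "gene", , drop = FALSE]
  blocked <- character(0)
  for (i in seq_len(nrow(tx))) {
    iv <- three_prime_extension_interval(tx[i, ], ext_length)
    if (is.null(iv)) next
    for (j in seq_len(nrow(genes))) {
      if (genes$id[j] == tx$parent[i]) next
      if (genes$seqid[j] != tx$seqid[i]) next
      if (scope == "same-strand" && genes$strand[j] != tx$strand[i]) next
      if (genes$start[j] <= iv[2] && genes$end[j] >= iv[1]) {
        blocked <- c(blocked, tx$id[i])
        break
      }
    }
  }
  blocked
}
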