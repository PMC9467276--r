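# shared fixtures and independent oracles

balf_panels <- default_marker_panels()

# four-population BALF-like cohort at test scale
small_balf_populations <- function(n_program = 60) {
  list(
    population_spec("t", 0.55, balf_panels$t, n_program_genes = n_program),
    population_spec("b_plasma", 0.15, balf_panels$b_plasma,
                    n_program_genes = n_program),
    population_spec("mo_ma", 0.20, balf_panels$mo_ma,
                    n_program_genes = n_program),
    population_spec("neutrophil", 0.10, balf_panels$neutrophil,
                    n_program_genes = n_program))
}

small_balf_sim <- function(seed = 1, n_cells = 600, n_genes = 2500,
                           n_program = 60, doublet_fraction = 0,
                           qc_fail_low_genes = 0, qc_fail_high_mito = 0, ...) {
  cfg <- simulation_config(n_cells = n_cells, n_genes = n_genes,
                           populations = small_balf_populations(n_program),
                           doublet_fraction = doublet_fraction,
                           qc_fail_low_genes = qc_fail_low_genes,
                           qc_fail_high_mito = qc_fail_high_mito,
                           seed = seed, ...)
  simulate_balf(cfg)
}

truth_labels <- function(sim) {
  stats::setNames(sim$truth$cells$population, sim$truth$cells$barcode)
}

# small random integer count matrix with row/col names
random_count_matrix <- function(n_genes = 100, n_cells = 50, density = 0.1,
                                seed = 1) {
  set.seed(seed)
  m <- Matrix::rsparsematrix(n_genes, n_cells, density = density)
  m@x <- abs(round(m@x * 10)) + 1
  m <- Matrix::drop0(m)
  rownames(m) <- paste0("g", seq_len(n_genes))
  colnames(m) <- paste0("c", seq_len(n_cells))
  count_matrix(m)
}

# write a GFF3 fixture file, returning the path
write_gff_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

toy_gene_lines <- c(
  "chr1\ttest\tgene\t100\t500\t.\t+\t.\tID=geneA",
  "chr1\ttest\tmRNA\t100\t500\t.\t+\t.\tID=mrnaA;Parent=geneA",
  "chr1\ttest\texon\t100\t500\t.\t+\t.\tID=exonA;Parent=mrnaA")

# one gene A (+ strand, mRNA/exon spanning 1000-2000) and one gene B at the
# requested coordinates; the canonical extension test geometry
two_gene_annotation <- function(b_start, b_end, b_strand = "+") {
  genome_annotation(data.frame(
    seqid = "chr1",
    feature_kind = c("gene", "transcript", "exon", "gene"),
    start = c(1000, 1000, 1000, b_start), end = c(2000, 2000, 2000, b_end),
    strand = c("+", "+", "+", b_strand),
    id = c("geneA", "mrnaA", "exonA", "geneB"),
    parent = c(NA, "geneA", "mrnaA", NA), stringsAsFactors = FALSE))
}

# independent interval-overlap oracle built on IRanges (a different engine
# than both the implementation and the generator's truth scan)
iranges_blocked <- function(ann, ext_length, scope = "any-strand") {
  r <- ann$records
  tx <- r[r$feature_kind == "transcript", , drop = FALSE]
  genes <- r[r$feature_kind == "gene", , drop = FALSE]
  blocked <- character(0)
  for (i in seq_len(nrow(tx))) {
    iv <- three_prime_extension_interval(tx[i, ], ext_length)
    if (is.null(iv)) next
    cand <- genes[genes$seqid == tx$seqid[i] & genes$id != tx$parent[i], ,
                  drop = FALSE]
    if (scope == "same-strand")
      cand <- cand[cand$strand == tx$strand[i], , drop = FALSE]
    if (!nrow(cand)) next
    hits <- IRanges::countOverlaps(
      IRanges::IRanges(iv[1], iv[2]),
      IRanges::IRanges(cand$start, cand$end))
    if (hits > 0) blocked <- c(blocked, tx$id[i])
  }
  blocked
}

# dense re-computation of per-cell QC metrics
dense_qc_oracle <- function(x, mito_idx) {
  d <- as.matrix(x$counts)
  tot <- colSums(d)
  data.frame(barcode = colnames(d),
             n_genes = colSums(d > 0),
             total_counts = tot,
             pct_mito = ifelse(tot > 0,
                               100 * colSums(d[mito_idx, , drop = FALSE]) / tot,
                               0),
             row.names = NULL, stringsAsFactors = FALSE)
}

# literal subset enumeration of the two-sided rank-sum p-value
enumeration_wilcox_p <- function(values, in_group) {
  n <- length(values); n1 <- sum(in_group)
  r <- rank(values)
  w_obs <- sum(r[in_group])
  mu <- n1 * (n + 1) / 2
  sums <- colSums(matrix(r[utils::combn(n, n1)], nrow = n1))
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
}
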