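test_that("the default BALF configuration mirrors the measured cohort", {
  cfg <- default_balf_config(seed = 3)
  fr <- vapply(cfg$populations, `[[`, numeric(1), "fraction")
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  lymph <- fr[["t"]] + fr[["b_plasma"]]
  expect_gte(lymph, 0.70)
  expect_lte(lymph, 0.80)
  expect_identical(default_balf_config(seed = 3), cfg)
  expect_equal(cfg$doublet_fraction, 0.02)
  expect_equal(cfg$doublet_pairing, c("mo_ma", "t"))
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  a <- small_balf_sim(seed = 17, n_cells = 200, n_genes = 800,
                      doublet_fraction = 0.02, qc_fail_low_genes = 10)
  b <- small_balf_sim(seed = 17, n_cells = 200, n_genes = 800,
                      doublet_fraction = 0.02, qc_fail_low_genes = 10)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth, b$truth)
  c <- small_balf_sim(seed = 18, n_cells = 200, n_genes = 800)
  expect_false(identical(a$matrix$counts, c$matrix$counts))
})

test_that("realized marker folds track the configured fold", {
  for (seed in 1:5) {
    sim <- small_balf_sim(seed = seed, n_cells = 800, n_genes = 2000,
                          n_program = 40)
    m <- sim$matrix$counts
    tot <- Matrix::colSums(m)
    cp <- m
    cp@x <- cp@x / rep.int(tot, diff(cp@p)) * 1e4
    gt <- sim$truth$genes
    pid <- gt$gene_id[!is.na(gt$is_marker_of) & gt$is_marker_of == "t" &
                        gt$marker_class == "panel"]
    inside <- sim$truth$cells$population == "t"
    fold <- mean(Matrix::rowMeans(cp[pid, inside, drop = FALSE])) /
      mean(Matrix::rowMeans(cp[pid, !inside, drop = FALSE]))
    expect_gte(fold, 0.6 * 8)
    expect_lte(fold, 1.4 * 8)
  }
})

test_that("library sizes realize the configured depth distribution", {
  sim <- small_balf_sim(seed = 19, n_cells = 1000, n_genes = 2000)
  tot <- Matrix::colSums(sim$matrix$counts)
  lm <- mean(log(tot))
  se <- stats::sd(log(tot)) / sqrt(length(tot))
  expect_lt(abs(lm - log(3000)), 3 * se)
})

test_that("planted QC failures and doublets are marked and effective", {
  sim <- small_balf_sim(seed = 20, n_cells = 400, n_genes = 1500,
                        doublet_fraction = 0.05, qc_fail_low_genes = 30,
                        qc_fail_high_mito = 20)
  tr <- sim$truth$cells
  expect_equal(sum(tr$planted_qc_failure == "low_genes"), 30)
  expect_equal(sum(tr$planted_qc_failure == "high_mito"), 20)
  expect_equal(sum(tr$is_doublet), round(0.05 * 400))
  met <- compute_qc_metrics(sim$matrix)
  low <- tr$planted_qc_failure == "low_genes"
  expect_true(all(met$n_genes[low] < 200))
  hi <- tr$planted_qc_failure == "high_mito"
  expect_true(all(met$pct_mito[hi] > 15))
  # doublets blend both parents: panel expression intermediate between them
  nm <- log_normalize(sim$matrix)
  for (pnl in list(balf_panels$t, balf_panels$mo_ma)) {
    idx <- scbalf:::resolve_genes(nm, pnl)
    e <- Matrix::colMeans(nm$data[idx, , drop = FALSE])
    parent_hi <- if (identical(pnl, balf_panels$t)) "t" else "mo_ma"
    hi_mean <- mean(e[!tr$is_doublet & tr$population == parent_hi])
    lo_mean <- mean(e[!tr$is_doublet & tr$population != parent_hi])
    dbl_mean <- mean(e[tr$is_doublet])
    expect_gt(dbl_mean, lo_mean)
    expect_lt(dbl_mean, hi_mean)
  }
})

test_that("infeasible configurations are rejected", {
  pops <- small_balf_populations()
  expect_error(simulation_config(n_cells = 10, populations = pops,
                                 qc_fail_low_genes = 8, qc_fail_high_mito = 8),
               "QC failures")
  expect_error(simulation_config(populations = pops, doublet_fraction = 1),
               "doublet_fraction")
  bad <- pops
  bad[[1]]$fraction <- 0.9
  expect_error(simulation_config(populations = bad), "sum to 1")
  expect_error(population_spec("x", fraction = -0.1), "non-negative")
  expect_error(population_spec("x", 0.5, marker_fold = 1), "marker_fold")
})

test_that("planted metrics tables violate thresholds exactly as requested", {
  met <- simulate_qc_metrics(1000, n_low_genes = 40, n_high_genes = 10,
                             n_high_mito = 25, seed = 2)
  out <- apply_qc_thresholds(met)
  expect_equal(sum(!out$kept), 75)
  expect_equal(out$reason[!out$kept], out$planted_violation[!out$kept])
  expect_error(simulate_qc_metrics(10, n_low_genes = 11), "more planted")
})

test_that("toy annotations hit their planted blocking extremes", {
  none <- make_toy_annotation(20, 2, overlap_fraction = 0, seed = 4)
  expect_length(none$blocked_transcripts, 0)
  rep0 <- extend_three_prime(none$annotation)$report
  expect_false(any(rep0$status == "blocked_overlap"))

  all_blocked <- make_toy_annotation(20, 2, overlap_fraction = 1, seed = 4)
  n_tx <- sum(all_blocked$annotation$records$feature_kind == "transcript")
  expect_length(all_blocked$blocked_transcripts, n_tx)
  expect_error(make_toy_annotation(10, overlap_fraction = 2), "overlap_fraction")
})
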