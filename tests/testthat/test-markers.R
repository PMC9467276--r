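make_norm <- function(d) {
  structure(list(data = methods::as(d, "CsparseMatrix"), scale_factor = 1e4,
                 gene_symbols = rownames(d)), class = "norm_matrix")
}

test_that("a perfectly separating gene is a maximal marker", {
  set.seed(51)
  d <- matrix(abs(rnorm(50 * 100, sd = 0.2)), 50, 100,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:100)))
  lab <- rep(c("in", "out"), each = 50)
  names(lab) <- colnames(d)
  d["g1", lab == "in"] <- 2
  d["g1", lab == "out"] <- 0
  res <- find_markers(make_norm(d), lab, "in")
  row <- res[res$gene == "g1", ]
  expect_equal(row$pct.1, 1)
  expect_equal(row$pct.2, 0)
  expect_lt(row$p_val_adj, 1e-6)
  expect_gt(row$avg_log2FC, 0)
})

test_that("the normal-approximation p-value matches the base rank-sum test", {
  set.seed(52)
  for (i in 1:20) {
    x <- rnorm(60)  # tie-free
    grp <- rep(c(TRUE, FALSE), each = 30)
    mine <- wilcox_rank_sum(x, grp, exact_max = 0)
    ref <- stats::wilcox.test(x[grp], x[!grp], exact = FALSE,
                              correct = FALSE)$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("small-sample p-values equal literal subset enumeration with ties", {
  set.seed(53)
  for (i in 1:10) {
    x <- sample(1:6, 17, replace = TRUE)  # heavy ties
    grp <- c(rep(TRUE, 8), rep(FALSE, 9))
    expect_equal(wilcox_rank_sum(x, grp), enumeration_wilcox_p(x, grp),
                 tolerance = 1e-10)
  }
  # degenerate: all values tied
  expect_equal(wilcox_rank_sum(rep(1, 17), c(rep(TRUE, 8), rep(FALSE, 9))), 1)
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum test", {
  set.seed(54)
  x <- rnorm(40)  # tie-free
  g <- rep(c("a", "b"), 20)
  kw <- score_group_test(x, g)$p_value
  w <- wilcox_rank_sum(x, g == "a", exact_max = 0)
  expect_equal(kw, w, tolerance = 1e-6)
})

test_that("marker tables concatenate one-vs-rest runs with a significance flag", {
  set.seed(55)
  d <- matrix(abs(rnorm(30 * 60, sd = 0.3)) + 0.2, 30, 60,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:60)))
  lab <- stats::setNames(rep(c("x", "y"), each = 30), colnames(d))
  d["g1", lab == "x"] <- d["g1", lab == "x"] + 2
  d["g2", lab == "y"] <- d["g2", lab == "y"] + 2
  nm <- make_norm(d)
  all_tab <- find_all_markers(nm, lab)
  x_tab <- find_markers(nm, lab, "x")
  y_tab <- find_markers(nm, lab, "y")
  expect_equal(nrow(all_tab), nrow(x_tab) + nrow(y_tab))
  expect_setequal(paste(all_tab$gene, all_tab$cluster),
                  c(paste(x_tab$gene, "x"), paste(y_tab$gene, "y")))
  expect_true(all_tab$significant[all_tab$gene == "g1" & all_tab$cluster == "x"])
  expect_error(find_all_markers(nm, stats::setNames(rep("x", 60), colnames(d))),
               "two clusters")
})

test_that("permuted labels produce few nominal discoveries", {
  sim <- small_balf_sim(seed = 12, n_cells = 300, n_genes = 2000)
  nm <- log_normalize(sim$matrix)
  set.seed(61)
  fake <- stats::setNames(sample(c("u", "v"), n_cells(sim$matrix), TRUE),
                          barcodes(sim$matrix))
  res <- find_markers(nm, fake, "u", min_pct = 0.1, logfc_floor = 0)
  expect_lt(mean(res$p_val < 0.05), 0.08)
})

test_that("planted panel markers top the fold-change ranking of their population", {
  hits <- 0
  for (seed in 1:10) {
    sim <- small_balf_sim(seed = seed, n_cells = 500, n_genes = 2500)
    nm <- log_normalize(sim$matrix)
    lab <- truth_labels(sim)
    gt <- sim$truth$genes
    ok <- TRUE
    for (pop in unique(lab)) {
      res <- find_markers(nm, lab, pop)
      top10 <- utils::head(res$gene[order(-res$avg_log2FC)], 10)
      panel <- gt$gene_id[!is.na(gt$is_marker_of) & gt$is_marker_of == pop &
                            gt$marker_class == "panel"]
      if (!all(panel %in% top10)) ok <- FALSE
    }
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("BH adjustment is monotone and never below the raw p", {
  sim <- small_balf_sim(seed = 13, n_cells = 200, n_genes = 1000)
  nm <- log_normalize(sim$matrix)
  res <- find_markers(nm, truth_labels(sim), "t")
  expect_true(all(res$p_val_adj >= res$p_val - 1e-15))
  ord <- order(res$p_val)
  expect_true(all(diff(res$p_val_adj[ord]) >= -1e-15))
})
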