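test_that("a toy GFF3 file parses into a linked three-record hierarchy", {
  ann <- parse_annotation(write_gff_fixture(toy_gene_lines))
  r <- ann$records
  expect_equal(nrow(r), 3)
  expect_setequal(r$feature_kind, c("gene", "transcript", "exon"))
  expect_equal(r$parent[r$id == "mrnaA"], "geneA")
  expect_equal(r$parent[r$id == "exonA"], "mrnaA")
  expect_true(all(r$start == 100 & r$end == 500 & r$strand == "+"))
})

test_that("record order in the file does not affect the parsed model", {
  sorted <- parse_annotation(write_gff_fixture(toy_gene_lines))
  shuffled <- parse_annotation(write_gff_fixture(toy_gene_lines[c(3, 1, 2)]))
  expect_identical(sorted$records, shuffled$records)
})

test_that("structural problems are reported by name and line", {
  dangling <- c(toy_gene_lines[1:2],
                "chr1\ttest\texon\t100\t500\t.\t+\t.\tID=exonA;Parent=missingID")
  expect_error(parse_annotation(write_gff_fixture(dangling)), "missingID")
  bad <- c(toy_gene_lines[1:2], "chr1\ttest\texon\t100")
  expect_error(parse_annotation(write_gff_fixture(bad)), "line 4")
})

test_that("GTF dialect yields the same gene/transcript/exon hierarchy", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\tgene\t100\t500\t.\t+\t.\tgene_id "geneA";',
    'chr1\ttest\ttranscript\t100\t500\t.\t+\t.\tgene_id "geneA"; transcript_id "mrnaA";',
    'chr1\ttest\texon\t100\t500\t.\t+\t.\tgene_id "geneA"; transcript_id "mrnaA";'),
    gtf)
  ann <- parse_annotation(gtf, dialect = "gtf")
  r <- ann$records
  expect_setequal(r$feature_kind, c("gene", "transcript", "exon"))
  expect_equal(r$parent[r$feature_kind == "transcript"], "geneA")
  expect_equal(r$parent[r$feature_kind == "exon"], "mrnaA")
})

test_that("extension intervals follow strand arithmetic with clamping", {
  plus <- list(start = 1, end = 2000, strand = "+")
  expect_equal(three_prime_extension_interval(plus, 2000), c(2001, 4000))
  minus <- list(start = 500, end = 900, strand = "-")
  expect_equal(three_prime_extension_interval(minus, 2000), c(1, 499))
  edge <- list(start = 1, end = 900, strand = "-")
  expect_null(three_prime_extension_interval(edge, 2000))
  expect_error(three_prime_extension_interval(plus, -5), "non-negative")
})

test_that("free transcripts extend, blocked ones skip, truncation stops short", {
  free <- extend_three_prime(two_gene_annotation(5000, 6000))
  expect_equal(free$report$status[free$report$transcript_id == "mrnaA"],
               "extended")
  r <- free$annotation$records
  expect_equal(r$end[r$id == "mrnaA"], 4000)
  expect_equal(r$end[r$id == "exonA"], 4000)
  expect_equal(r$end[r$id == "geneA"], 4000)

  blocked <- extend_three_prime(two_gene_annotation(3500, 6000))
  rep_a <- blocked$report[blocked$report$transcript_id == "mrnaA", ]
  expect_equal(rep_a$status, "blocked_overlap")
  expect_equal(rep_a$blocking_gene_id, "geneB")
  expect_equal(rep_a$new_end3, rep_a$old_end3)

  trunc <- extend_three_prime(two_gene_annotation(3500, 6000),
                              extension_policy(on_overlap = "truncate"))
  rep_t <- trunc$report[trunc$report$transcript_id == "mrnaA", ]
  expect_equal(rep_t$status, "truncated")
  expect_equal(rep_t$new_end3, 3499)
  expect_equal(trunc$annotation$records$end[
    trunc$annotation$records$id == "mrnaA"], 3499)
})

test_that("zero extension length is the identity", {
  ann <- two_gene_annotation(3500, 6000)
  res <- extend_three_prime(ann, extension_policy(0))
  expect_identical(res$annotation$records, ann$records)
  expect_true(all(res$report$status == "unchanged"))
})

test_that("same-strand scope ignores opposite-strand neighbors", {
  anti <- extend_three_prime(two_gene_annotation(3500, 6000, b_strand = "-"),
                             extension_policy(overlap_scope = "same-strand"))
  expect_equal(anti$report$status[anti$report$transcript_id == "mrnaA"],
               "extended")
  same <- extend_three_prime(two_gene_annotation(3500, 6000, b_strand = "-"),
                             extension_policy(overlap_scope = "any-strand"))
  expect_equal(same$report$status[same$report$transcript_id == "mrnaA"],
               "blocked_overlap")
})

test_that("blocked sets match an independent interval-overlap oracle", {
  for (seed in 1:20) {
    frac <- (seed %% 5) / 4
    toy <- make_toy_annotation(n_genes = 24, n_seqs = 2,
                               overlap_fraction = frac, seed = seed)
    for (scope in c("any-strand", "same-strand")) {
      res <- extend_three_prime(toy$annotation,
                                extension_policy(overlap_scope = scope))
      impl <- res$report$transcript_id[res$report$status == "blocked_overlap"]
      expect_setequal(impl, iranges_blocked(toy$annotation, 2000, scope))
    }
    # generator truth refers to the any-strand policy
    res <- extend_three_prime(toy$annotation)
    expect_setequal(res$report$transcript_id[res$report$status == "blocked_overlap"],
                    toy$blocked_transcripts)
  }
})

test_that("containment and report invariants hold after extension", {
  for (seed in c(3, 9)) {
    toy <- make_toy_annotation(n_genes = 30, overlap_fraction = 0.5, seed = seed)
    res <- extend_three_prime(toy$annotation)
    r <- res$annotation$records
    pidx <- match(r$parent, r$id)
    has <- !is.na(pidx)
    expect_true(all(r$start[has] >= r$start[pidx][has]))
    expect_true(all(r$end[has] <= r$end[pidx][has]))
    rep <- res$report
    ext <- rep$status == "extended"
    expect_true(all(abs(rep$new_end3[ext] - rep$old_end3[ext]) == 2000))
    blk <- rep$status == "blocked_overlap"
    expect_true(all(rep$new_end3[blk] == rep$old_end3[blk]))
    expect_true(all(!is.na(rep$blocking_gene_id[blk])))
  }
})

test_that("longer extensions never unblock a transcript under skip", {
  toy <- make_toy_annotation(n_genes = 30, overlap_fraction = 0.6, seed = 7)
  blocked_at <- function(len) {
    rep <- extend_three_prime(toy$annotation, extension_policy(len))$report
    rep$transcript_id[rep$status == "blocked_overlap"]
  }
  prev <- character(0)
  for (len in c(500, 1000, 2000, 4000)) {
    cur <- blocked_at(len)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("annotations round-trip through GFF3 text", {
  toy <- make_toy_annotation(n_genes = 16, overlap_fraction = 0.5, seed = 5)
  res <- extend_three_prime(toy$annotation)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(res$annotation, path)
  reparsed <- parse_annotation(path)
  cols <- c("seqid", "feature_kind", "start", "end", "strand", "id", "parent")
  orig <- res$annotation$records[cols]
  orig <- orig[order(orig$seqid, orig$start, orig$end, orig$id), ]
  rownames(orig) <- NULL
  expect_equal(reparsed$records[cols], orig)
})

test_that("large coordinates are written as plain integers", {
  ann <- genome_annotation(data.frame(
    seqid = "chr1", feature_kind = c("gene", "transcript"),
    start = c(1500000000, 1500000000), end = c(1500002000, 1500002000),
    strand = "+", id = c("gBig", "tBig"), parent = c(NA, "gBig"),
    stringsAsFactors = FALSE))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ann, path)
  body <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  expect_false(any(grepl("[eE]\\+", body)))
  expect_true(any(grepl("1500000000", body)))
})
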