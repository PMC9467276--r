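#' Hierarchical genome annotation model
#'
#' A flat table of annotation records (gene, transcript, exon, other) with
#' 1-based inclusive coordinates, strand, identifier and optional parent
#' link, plus optional sequence lengths. Invariants enforced at
#' construction: `1 <= start <= end`; unique identifiers; every parent
#' resolves; exons contained in their transcript, transcripts in their gene.
#'
#' @param records data.frame with columns `seqid`, `feature_kind` (one of
#'   `gene`, `transcript`, `exon`, `other`), `start`, `end`, `strand`
#'   (`+`/`-`), `id`, `parent` (NA for top-level records).
#' @param sequence_lengths Optional named numeric vector, seqid -> length.
#' @return Object of class `genome_annotation`.
#' @export
genome_annotation <- function(records, sequence_lengths = NULL) {
  need <- c("seqid", "feature_kind", "start", "end", "strand", "id", "parent")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  records <- records[c(need, setdiff(names(records), need))]
  records$start <- as.numeric(records$start)
  records$end <- as.numeric(records$end)
  if (any(records$start < 1) || any(records$start > records$end))
    stop("invalid coordinates: need 1 <= start <= end for every record")
  if (anyDuplicated(records$id))
    stop("duplicate identifiers: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  dangling <- setdiff(records$parent[!is.na(records$parent)], records$id)
  if (length(dangling))
    stop("structural error: Parent identifier(s) not found: ",
         paste(dangling, collapse = ", "))
  pidx <- match(records$parent, records$id)
  has_parent <- !is.na(pidx)
  if (any(has_parent &
          (records$start < records$start[pidx] |
           records$end > records$end[pidx])))
    stop("containment violated: child interval extends beyond its parent")
  rownames(records) <- NULL
  structure(list(records = records, sequence_lengths = sequence_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  tab <- table(x$records$feature_kind)
  cat("genome_annotation:",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "), "\n")
  invisible(x)
}

map_feature_kind <- function(type) {
  type <- as.character(type)
  kind <- rep("other", length(type))
  kind[type %in% c("gene", "pseudogene")] <- "gene"
  kind[type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA", "tRNA", "rRNA",
                   "primary_transcript", "V_gene_segment",
                   "C_gene_segment")] <- "transcript"
  kind[type == "exon"] <- "exon"
  kind
}

#' Parse a GFF3 or GTF annotation
#'
#' Reads the file through the standard GFF importer after a light
#' per-line structural pre-check (9 tab-separated columns) that reports the
#' first malformed line by number. For GTF input the `gene_id` /
#' `transcript_id` attributes are translated into the ID/Parent hierarchy;
#' the internal model is identical for both dialects.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` (default) or `"gtf"`.
#' @return A [genome_annotation].
#' @export
parse_annotation <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1]]
    stop(sprintf("parse error at line %d: expected 9 tab-delimited columns, found %d",
                 bad, nf[which(nf != 9)[1]]))
  }
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "gtf")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)

  if (dialect == "gff3") {
    id <- as.character(mc$ID)
    parent <- vapply(as.list(mc$Parent), function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  } else {
    kind0 <- map_feature_kind(type)
    id <- parent <- rep(NA_character_, length(gr))
    id[kind0 == "gene"] <- as.character(mc$gene_id[kind0 == "gene"])
    id[kind0 == "transcript"] <- as.character(mc$transcript_id[kind0 == "transcript"])
    parent[kind0 == "transcript"] <- as.character(mc$gene_id[kind0 == "transcript"])
    ex <- kind0 == "exon"
    parent[ex] <- as.character(mc$transcript_id[ex])
    id[ex] <- paste0(parent[ex], ":exon",
                     stats::ave(seq_len(sum(ex)), parent[ex], FUN = seq_along))
  }
  miss <- is.na(id)
  id[miss] <- paste0(".rec", which(miss))

  records <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    feature_kind = map_feature_kind(type),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = id, parent = parent, stringsAsFactors = FALSE)
  records$source_type <- type
  ga <- genome_annotation(records[order(records$seqid, records$start,
                                        records$end, records$id), ])
  ga$records$auto_id <- startsWith(ga$records$id, ".rec")
  ga
}

#' Write a genome annotation as GFF3
#'
#' The inverse of [parse_annotation()]: parsing the written file reproduces
#' the model. Coordinates are written as plain integers (never scientific
#' notation).
#'
#' @param x A [genome_annotation].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "genome_annotation"))
  r <- x$records
  type <- if ("source_type" %in% names(r)) r$source_type else
    c(gene = "gene", transcript = "mRNA", exon = "exon",
      other = "region")[r$feature_kind]
  gr <- GenomicRanges::GRanges(
    seqnames = r$seqid,
    ranges = IRanges::IRanges(start = r$start, end = r$end),
    strand = r$strand)
  auto <- if ("auto_id" %in% names(r)) r$auto_id else rep(FALSE, nrow(r))
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- ifelse(auto, NA_character_, r$id)
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(r$parent), NA_character_, r$parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Policy governing 3'-UTR extension
#'
#' @param extension_length Bases added downstream of every transcript's 3'
#'   end (default 2000).
#' @param overlap_scope Gene records considered as blockers: `"any-strand"`
#'   (default, conservative) or `"same-strand"`.
#' @param on_overlap `"skip"` (default: blocked transcripts are left
#'   unchanged) or `"truncate"` (extend to 1 bp short of the nearest
#'   blocking gene).
#' @param clamp_low Clamp extensions at position 1 (default TRUE).
#' @param clamp_high Clamp at the sequence length when known (default TRUE).
#' @return List of class `extension_policy`.
#' @export
extension_policy <- function(extension_length = 2000,
                             overlap_scope = c("any-strand", "same-strand"),
                             on_overlap = c("skip", "truncate"),
                             clamp_low = TRUE, clamp_high = TRUE) {
  if (extension_length < 0) stop("extension_length must be non-negative")
  structure(list(extension_length = extension_length,
                 overlap_scope = match.arg(overlap_scope),
                 on_overlap = match.arg(on_overlap),
                 clamp_low = clamp_low, clamp_high = clamp_high),
            class = "extension_policy")
}

#' Genomic interval a 3' extension would occupy
#'
#' For a `+` strand transcript ending at `end` the extension interval is
#' `[end + 1, end + length]`; for a `-` strand transcript starting at
#' `start` it is `[start - length, start - 1]`. The interval is clamped to
#' `[1, sequence_length]` and may be empty when there is no room.
#'
#' @param transcript One-row data.frame (or list) with `start`, `end`,
#'   `strand`.
#' @param length Extension length in bp (non-negative).
#' @param sequence_length Optional chromosome length for upper clamping.
#' @return Numeric `c(start, end)`, or `NULL` for an empty interval.
#' @export
three_prime_extension_interval <- function(transcript, length,
                                           sequence_length = NULL) {
  if (length < 0) stop("length must be non-negative")
  if (length == 0) return(NULL)
  if (transcript$strand == "+") {
    lo <- transcript$end + 1
    hi <- transcript$end + length
    if (!is.null(sequence_length)) hi <- min(hi, sequence_length)
  } else {
    lo <- max(1, transcript$start - length)
    hi <- transcript$start - 1
  }
  if (lo > hi) return(NULL)
  c(lo, hi)
}

#' Extend every transcript's 3' end unless a neighboring gene is in the way
#'
#' For each transcript the extension interval
#' ([three_prime_extension_interval()]) is tested for overlap against the
#' *input* gene spans (excluding the transcript's own parent gene, so
#' sibling isoforms never block each other) under the policy's strand
#' scope. Unblocked transcripts have their 3' boundary, their 3'-most exon
#' and their parent gene span moved; blocked transcripts are skipped (or
#' truncated to 1 bp short of the nearest blocker under
#' `on_overlap = "truncate"`). With `extension_length = 0` the operation is
#' the identity.
#'
#' @param x A [genome_annotation].
#' @param policy An [extension_policy()].
#' @return List with `annotation` (the extended model, invariants intact)
#'   and `report` (data.frame: `transcript_id`, `gene_id`, `strand`,
#'   `status` in extended/blocked_overlap/truncated/clamped/unchanged,
#'   `old_end3`, `new_end3`, `blocking_gene_id`).
#' @export
extend_three_prime <- function(x, policy = extension_policy()) {
  stopifnot(inherits(x, "genome_annotation"), inherits(policy, "extension_policy"))
  r <- x$records
  tx <- which(r$feature_kind == "transcript")
  report <- data.frame(transcript_id = r$id[tx], gene_id = r$parent[tx],
                       strand = r$strand[tx],
                       status = rep("unchanged", length(tx)),
                       old_end3 = ifelse(r$strand[tx] == "+", r$end[tx], r$start[tx]),
                       new_end3 = ifelse(r$strand[tx] == "+", r$end[tx], r$start[tx]),
                       blocking_gene_id = NA_character_,
                       stringsAsFactors = FALSE)
  if (!length(tx) || policy$extension_length == 0)
    return(list(annotation = x, report = report))

  genes <- r[r$feature_kind == "gene", , drop = FALSE]
  seqlen <- x$sequence_lengths
  exon_parent <- r$parent[r$feature_kind == "exon"]

  for (i in seq_along(tx)) {
    ti <- tx[i]
    slen <- if (!is.null(seqlen) && policy$clamp_high)
      unname(seqlen[r$seqid[ti]]) else NULL
    iv <- three_prime_extension_interval(r[ti, ], policy$extension_length, slen)
    plus <- r$strand[ti] == "+"
    want <- policy$extension_length
    if (is.null(iv)) {                     # no room at the chromosome edge
      report$status[i] <- "clamped"
      next
    }
    cand <- genes$seqid == r$seqid[ti] & genes$id != r$parent[ti]
    if (policy$overlap_scope == "same-strand")
      cand <- cand & genes$strand == r$strand[ti]
    hit <- cand & genes$start <= iv[2] & genes$end >= iv[1]

    if (any(hit)) {
      if (policy$on_overlap == "skip") {
        # nearest blocker in the direction of extension
        report$status[i] <- "blocked_overlap"
        report$blocking_gene_id[i] <- if (plus)
          genes$id[hit][which.min(genes$start[hit])] else
          genes$id[hit][which.max(genes$end[hit])]
        next
      }
      # truncate: stop 1 bp short of the nearest blocking gene
      if (plus) {
        bstart <- min(genes$start[hit])
        new3 <- bstart - 1
        blocker <- genes$id[hit][which.min(genes$start[hit])]
        if (new3 <= r$end[ti]) {
          report$status[i] <- "blocked_overlap"
          report$blocking_gene_id[i] <- blocker
          next
        }
      } else {
        bend <- max(genes$end[hit])
        new3 <- bend + 1
        blocker <- genes$id[hit][which.max(genes$end[hit])]
        if (new3 >= r$start[ti]) {
          report$status[i] <- "blocked_overlap"
          report$blocking_gene_id[i] <- blocker
          next
        }
      }
      report$status[i] <- "truncated"
      report$blocking_gene_id[i] <- blocker
    } else {
      new3 <- if (plus) iv[2] else iv[1]
      moved <- abs(new3 - report$old_end3[i])
      report$status[i] <- if (moved == want) "extended" else "clamped"
    }
    report$new_end3[i] <- new3

    # propagate to the transcript, its 3'-most exon, and the parent gene
    ex <- which(r$feature_kind == "exon" & r$parent == r$id[ti])
    if (plus) {
      r$end[ti] <- new3
      if (length(ex)) {
        e3 <- ex[which.max(r$end[ex])]
        r$end[e3] <- new3
      }
    } else {
      r$start[ti] <- new3
      if (length(ex)) {
        e3 <- ex[which.min(r$start[ex])]
        r$start[e3] <- new3
      }
    }
    gi <- which(r$id == r$parent[ti])
    if (length(gi)) {
      if (plus) r$end[gi] <- max(r$end[gi], new3)
      else r$start[gi] <- min(r$start[gi], new3)
    }
  }
  out <- genome_annotation(r, x$sequence_lengths)
  list(annotation = out, report = report)
}

#' Write an extension report as TSV
#'
#' @param report The report data.frame from [extend_three_prime()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_extension_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
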