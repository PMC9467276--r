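#' Differential cell count over the five cytology classes
#'
#' Percentages of lymphocytes, macrophages, neutrophils, mast cells and
#' eosinophils — the five leukocyte classes distinguishable under light
#' microscopy — plus the cell count and a source label. Constructed either
#' from per-cell type assignments ([collapse_to_cytology_classes()]) or
#' directly from percentages ([dcc_from_percentages()]).
#'
#' @name differential_cell_count
NULL

cytology_classes <- c("lymphocytes", "macrophages", "neutrophils",
                      "mast_cells", "eosinophils")

# major type -> cytology class (T and B/plasma counted as lymphocytes, DCs
# counted as macrophages under the microscope)
major_to_cytology <- c(t = "lymphocytes", b_plasma = "lymphocytes",
                       mo_ma = "macrophages", dc = "macrophages",
                       neutrophil = "neutrophils", mast = "mast_cells",
                       eosinophil = "eosinophils")

new_dcc <- function(percent, n_cells, source, n_unassigned = 0L,
                    counts = NULL) {
  stopifnot(setequal(names(percent), cytology_classes))
  percent <- percent[cytology_classes]
  structure(list(percent = percent, counts = counts,
                 n_cells = n_cells, n_unassigned = n_unassigned,
                 source = source), class = "dcc")
}

#' Collapse major-type assignments into cytology classes
#'
#' T and B/plasma cells are counted as lymphocytes, monocytes/macrophages
#' and dendritic cells as macrophages; neutrophils, mast cells and
#' eosinophils map to themselves. Unassigned cells are excluded from the
#' denominator and reported separately (with a warning).
#'
#' @param assignment A `cell_type_assignment` from [assign_major_types()],
#'   or a character vector of per-cell major types.
#' @param source Source label stored on the result (default `"scrnaseq"`).
#' @return A `dcc` object; `$percent` holds unrounded percentages (use
#'   [format()] or [compare_dcc()] for the 1-decimal display convention).
#' @export
collapse_to_cytology_classes <- function(assignment, source = "scrnaseq") {
  types <- if (inherits(assignment, "cell_type_assignment"))
    assignment$cell_types else assignment
  known <- types %in% names(major_to_cytology)
  n_un <- sum(!known)
  if (n_un > 0)
    warning(n_un, " unassigned cell(s) excluded from the differential count")
  types <- types[known]
  if (!length(types)) stop("no assigned cells to count")
  cls <- major_to_cytology[types]
  counts <- table(factor(cls, levels = cytology_classes))
  percent <- 100 * as.numeric(counts) / length(types)
  names(percent) <- cytology_classes
  new_dcc(percent, n_cells = length(types), source = source,
          n_unassigned = n_un, counts = as.integer(counts))
}

#' Build a differential cell count from percentages
#'
#' @param percent Named numeric vector over the five cytology classes (or a
#'   plain numeric of length 5 in the canonical order lymphocytes,
#'   macrophages, neutrophils, mast_cells, eosinophils). Must sum to 100
#'   within rounding tolerance.
#' @param source,n_cells Provenance label and (optional) cell count.
#' @return A `dcc` object.
#' @export
dcc_from_percentages <- function(percent, source = "cytology", n_cells = NA) {
  if (is.null(names(percent))) {
    stopifnot(length(percent) == 5)
    names(percent) <- cytology_classes
  }
  if (abs(sum(percent) - 100) > 0.5)
    stop("percentages must sum to 100 (within rounding tolerance)")
  new_dcc(percent, n_cells = n_cells, source = source)
}

# display rounding: half-up to one decimal (never banker's rounding, so the
# printed tables round the way clinical tables do)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Lymphocyte/macrophage ratio of a differential cell count
#'
#' @param dcc A `dcc` object.
#' @param digits Decimal places of the half-up-rounded display value.
#' @return List with `ratio` (unrounded) and `display` (rounded).
#' @export
lymphocyte_macrophage_ratio <- function(dcc, digits = 1) {
  stopifnot(inherits(dcc, "dcc"))
  mac <- dcc$percent[["macrophages"]]
  if (mac == 0) stop("undefined ratio: macrophage percentage is zero")
  ratio <- dcc$percent[["lymphocytes"]] / mac
  list(ratio = ratio, display = round_half_up(ratio, digits))
}

#' @export
print.dcc <- function(x, ...) {
  cat(sprintf("differential cell count (%s, n = %s):\n", x$source,
              format(x$n_cells)))
  print(round_half_up(x$percent, 1))
  invisible(x)
}

#' Tabulate several differential cell counts side by side
#'
#' Builds the wide comparison table of cytology and scRNA-seq counts: one
#' column per (sample, source) entry, rows the five cytology classes plus
#' the lymphocyte/macrophage ratio, every value half-up rounded to one
#' decimal.
#'
#' @param dccs Named list of `dcc` objects; names are the column keys and
#'   must be unique.
#' @return data.frame with six rows (`lymphocytes`, `macrophages`,
#'   `neutrophils`, `mast_cells`, `eosinophils`,
#'   `lymphocytes_macrophages_ratio`).
#' @export
compare_dcc <- function(dccs) {
  if (!length(dccs)) stop("at least one differential cell count is required")
  if (is.null(names(dccs)) || anyDuplicated(names(dccs)) || any(!nzchar(names(dccs))))
    stop("dccs must carry unique non-empty names (sample/source keys)")
  cols <- lapply(dccs, function(d) {
    stopifnot(inherits(d, "dcc"))
    c(round_half_up(d$percent, 1),
      lymphocytes_macrophages_ratio = lymphocyte_macrophage_ratio(d)$display)
  })
  out <- as.data.frame(cols, check.names = FALSE)
  rownames(out) <- c(cytology_classes, "lymphocytes_macrophages_ratio")
  out
}

#' Render a comparison table as Markdown
#'
#' @param table A data.frame from [compare_dcc()].
#' @return Character vector of Markdown lines.
#' @export
format_dcc_markdown <- function(table) {
  header <- paste0("| | ", paste(colnames(table), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(table) + 1), collapse = "|"), "|")
  rows <- vapply(seq_len(nrow(table)), function(i)
    paste0("| ", rownames(table)[i], " | ",
           paste(format(unlist(table[i, ]), nsmall = 1, trim = TRUE),
                 collapse = " | "), " |"), character(1))
  c(header, sep, rows)
}

#' Reference differential cell counts from an equine BALF cohort
#'
#' Published differential cell counts for three asthmatic horses in clinical
#' remission, measured three ways per horse: conventional cytology of the
#' fresh lavage fluid, cytology of the thawed cell suspension used for
#' sequencing, and the count reconstructed from single-cell RNA-seq major
#' cell types. Shipped as a plain TSV in `inst/extdata/`.
#'
#' @return data.frame with columns `sample`, `source`, and the five
#'   cytology classes (percentages).
#' @export
reference_balf_dcc <- function() {
  path <- system.file("extdata", "equine_balf_dcc.tsv", package = "scbalf",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
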