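#' Expression tables
#'
#' An expression table holds microarray-style intensities for `m` receptor
#' genes across `n` tissues. It is an ordinary tibble in wide form: a first
#' character column `gene` holding unique gene identifiers, followed by one
#' numeric column per tissue (unique tissue identifiers as column names).
#' All intensities must be finite and non-negative. Identifiers are
#' case-sensitive and compared byte-wise, so `"Olfr544"` and `"olfr544"` are
#' distinct genes.
#'
#' @name expression-table
#' @keywords internal
NULL

# Validate a wide expression tibble; returns list(genes, tissues) invisibly.
check_expression <- function(x, arg = "x") {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort(sprintf("`%s` must be a data frame with a `gene` column and at least one tissue column.", arg),
          class = "ectorank_malformed_input")
  }
  if (nrow(x) < 1L) {
    abort(sprintf("`%s` must contain at least one gene row.", arg),
          class = "ectorank_malformed_input")
  }
  genes <- as.character(x[[1L]])
  tissues <- names(x)[-1L]
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g) > 0L) {
    abort(sprintf("Duplicate gene identifier(s): %s.", paste(dup_g, collapse = ", ")),
          class = "ectorank_malformed_input")
  }
  dup_t <- unique(tissues[duplicated(tissues)])
  if (length(dup_t) > 0L) {
    abort(sprintf("Duplicate tissue identifier(s): %s.", paste(dup_t, collapse = ", ")),
          class = "ectorank_malformed_input")
  }
  for (j in seq_along(tissues)) {
    col <- x[[j + 1L]]
    if (!is.numeric(col)) {
      abort(sprintf("Column '%s' is not numeric.", tissues[j]),
            class = "ectorank_parse_error")
    }
    bad <- which(!is.finite(col) | col < 0)
    if (length(bad) > 0L) {
      abort(sprintf("Invalid intensity at gene '%s' (row %d), tissue '%s': values must be finite and >= 0.",
                    genes[bad[1L]], bad[1L], tissues[j]),
            class = "ectorank_parse_error")
    }
  }
  invisible(list(genes = genes, tissues = tissues))
}

# Wide tibble -> numeric matrix with gene rownames (genes x tissues).
as_intensity_matrix <- function(x) {
  ids <- check_expression(x)
  mat <- as.matrix(x[, -1L, drop = FALSE])
  rownames(mat) <- ids$genes
  mat
}

# Numeric matrix -> wide expression tibble.
as_expression_tibble <- function(mat, genes = rownames(mat), tissues = colnames(mat)) {
  out <- tibble::as_tibble(mat, .name_repair = "minimal")
  names(out) <- tissues
  dplyr::bind_cols(tibble::tibble(gene = genes), out)
}

#' Read an expression table from a TSV file
#'
#' The file carries tissue identifiers in the header row and gene identifiers
#' in the first column; all other cells are intensities. The header cell over
#' the gene column is ignored. Any newline convention is accepted; decimal
#' point is `"."` with no thousands separators.
#'
#' @param file Path to a tab-separated expression table.
#' @return A wide expression tibble (see [expression-table]).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tliver\tthymus", "olfr1\t1\t2", "olfr2\t3\t4"), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(file) {
  header <- readLines(file, n = 1L)
  header <- sub("\r$", "", header)
  fields <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  if (length(fields) < 2L) {
    abort("Expression table needs a gene column and at least one tissue column.",
          class = "ectorank_malformed_input")
  }
  tissues <- fields[-1L]
  dup_t <- unique(tissues[duplicated(tissues)])
  if (length(dup_t) > 0L) {
    abort(sprintf("Duplicate tissue identifier(s): %s.", paste(dup_t, collapse = ", ")),
          class = "ectorank_malformed_input")
  }
  raw <- readr::read_tsv(file, skip = 1L, col_names = c("gene", tissues),
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  out <- tibble::tibble(gene = raw$gene)
  for (j in seq_along(tissues)) {
    chr <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(chr))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      abort(sprintf("Cannot parse cell at gene '%s' (row %d), tissue '%s': '%s' is not a number.",
                    raw$gene[bad[1L]], bad[1L], tissues[j], chr[bad[1L]]),
            class = "ectorank_parse_error")
    }
    out[[tissues[j]]] <- num
  }
  check_expression(out)
  out
}

#' Write an expression table to a TSV file
#'
#' Doubles are written with enough digits to round-trip exactly through
#' [read_expression_matrix()]. Output uses UTF-8 and Unix newlines.
#'
#' @param x A wide expression tibble.
#' @param file Output path.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, file) {
  check_expression(x)
  readr::write_tsv(x, file, progress = FALSE)
  invisible(x)
}

ANNOTATION_COLS <- c("symbol", "accession", "title", "comment_leading_word")

#' Read receptor annotation records
#'
#' Annotation records are pre-extracted summaries of GenBank-style mRNA
#' entries, one per line in a TSV with columns `symbol`, `accession`,
#' `title` and `comment_leading_word` (the first word of the record's
#' comment section, possibly empty). `symbol` and `accession` must be
#' non-empty.
#'
#' @param file Path to the annotation TSV.
#' @return A tibble with one row per record, in file order.
#' @seealso [assess_validity()] for the validity screen applied to records.
#' @export
read_annotation_table <- function(file) {
  rec <- readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing <- setdiff(ANNOTATION_COLS, names(rec))
  if (length(missing) > 0L) {
    abort(sprintf("Annotation table is missing column(s): %s.", paste(missing, collapse = ", ")),
          class = "ectorank_malformed_input")
  }
  rec <- rec[ANNOTATION_COLS]
  if (nrow(rec) > 0L && any(!nzchar(rec$symbol) | !nzchar(rec$accession))) {
    abort("Annotation records must have non-empty symbol and accession.",
          class = "ectorank_malformed_input")
  }
  rec
}

#' Write receptor annotation records
#'
#' @param records A tibble with columns `symbol`, `accession`, `title`,
#'   `comment_leading_word`.
#' @param file Output path.
#' @return `records`, invisibly.
#' @export
write_annotation_table <- function(records, file) {
  missing <- setdiff(ANNOTATION_COLS, names(records))
  if (length(missing) > 0L) {
    abort(sprintf("Annotation table is missing column(s): %s.", paste(missing, collapse = ", ")),
          class = "ectorank_malformed_input")
  }
  readr::write_tsv(records[ANNOTATION_COLS], file, progress = FALSE)
  invisible(records)
}

#' Write a per-tissue candidate selection report
#'
#' Writes the output of [select_top_k()] as a TSV with columns `tissue`,
#' `rank`, `gene`, `tau`, `rank_sum`, sorted by tissue (byte order) and then
#' by ascending tau.
#'
#' @param selection A selection tibble from [select_top_k()].
#' @param file Output path.
#' @return `selection`, invisibly.
#' @export
write_selection_report <- function(selection, file) {
  cols <- c("tissue", "rank", "gene", "tau", "rank_sum")
  missing <- setdiff(cols, names(selection))
  if (length(missing) > 0L) {
    abort(sprintf("Selection is missing column(s): %s.", paste(missing, collapse = ", ")),
          class = "ectorank_malformed_input")
  }
  if (nrow(selection) == 0L) {
    abort("Selection is empty; nothing to report.", class = "ectorank_malformed_input")
  }
  ord <- order(selection$tissue, selection$tau, method = "radix")
  readr::write_tsv(selection[ord, cols], file, progress = FALSE)
  invisible(selection)
}
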