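#' Screen receptor annotation records for validity
#'
#' A receptor record counts as a valid, rankable gene only when all of the
#' following hold:
#'
#' * `accession_prefix` — the accession starts with `"NM_"` (a curated mRNA
#'   record, not a predicted `XM_`/`XR_` model);
#' * `comment_validated` — the first whitespace-delimited token of the
#'   record's comment, after stripping trailing `","` or `":"`, is exactly
#'   `VALIDATED` (case-sensitive: GenBank prints the review status in upper
#'   case);
#' * `title_partial` — the record title does not contain `"partial"`
#'   (case-insensitive), which would mark an incomplete coding sequence;
#' * `title_pseudo` — the title does not contain `"pseudo"`
#'   (case-insensitive), which would mark a pseudogene.
#'
#' @param records A tibble of annotation records with columns `symbol`,
#'   `accession`, `title`, `comment_leading_word`.
#' @return The input tibble with two added columns: `valid` (logical) and
#'   `failed_rules`, a list-column of character vectors naming every violated
#'   rule (empty when valid).
#' @examples
#' recs <- tibble::tibble(
#'   symbol = c("olfr544", "olfr9000"),
#'   accession = c("NM_020289", "XM_000001"),
#'   title = c("Mus musculus olfactory receptor 544 (Olfr544), mRNA",
#'             "predicted olfactory receptor pseudogene"),
#'   comment_leading_word = c("VALIDATED", "VALIDATED")
#' )
#' assess_validity(recs)
#' @export
assess_validity <- function(records) {
  missing <- setdiff(ANNOTATION_COLS, names(records))
  if (length(missing) > 0L) {
    abort(sprintf("Annotation records are missing column(s): %s.", paste(missing, collapse = ", ")),
          class = "ectorank_malformed_input")
  }
  if (nrow(records) > 0L && any(!nzchar(records$symbol) | !nzchar(records$accession))) {
    abort("Annotation records must have non-empty symbol and accession.",
          class = "ectorank_malformed_input")
  }
  token <- sub("^\\s*(\\S*).*$", "\\1", records$comment_leading_word)
  token <- sub("[,:]+$", "", token)
  ok <- cbind(
    accession_prefix  = startsWith(records$accession, "NM_"),
    comment_validated = token == "VALIDATED",
    title_partial     = !grepl("partial", records$title, ignore.case = TRUE),
    title_pseudo      = !grepl("pseudo", records$title, ignore.case = TRUE)
  )
  failed <- lapply(seq_len(nrow(records)), function(i) colnames(ok)[!ok[i, ]])
  dplyr::mutate(tibble::as_tibble(records),
                valid = rowSums(!ok) == 0L,
                failed_rules = failed)
}

#' Restrict an expression table to valid receptor genes
#'
#' Drops the rows of genes whose annotation record fails the validity screen
#' of [assess_validity()], preserving the original row order and the full
#' tissue set. Every gene in the table must have exactly one annotation
#' record (extra records for genes absent from the table are ignored).
#'
#' @param x A wide expression tibble.
#' @param records Annotation records covering every gene in `x`.
#' @return The row-subset of `x` whose genes are valid.
#' @export
restrict_to_valid <- function(x, records) {
  ids <- check_expression(x)
  counts <- table(records$symbol)
  n_rec <- as.integer(counts[ids$genes])
  n_rec[is.na(n_rec)] <- 0L
  bad <- ids$genes[n_rec != 1L]
  if (length(bad) > 0L) {
    abort(sprintf("Gene(s) without exactly one annotation record: %s.",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "ectorank_consistency_error")
  }
  decisions <- assess_validity(records)
  valid_symbols <- decisions$symbol[decisions$valid]
  x[ids$genes %in% valid_symbols, , drop = FALSE]
}
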