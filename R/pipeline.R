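#' Run the full candidate-screening pipeline
#'
#' Chains the stages of the screen on files: read the expression table and
#' annotation records, drop invalid receptor genes, compute the dual-rank
#' table, select the top-k candidates per tissue, and compare selected
#' versus non-selected genes with Welch t-tests. All artifacts are written
#' as TSV under `out_dir`:
#'
#' * `decisions.tsv` — per-record validity (symbol, valid, failed_rules);
#' * `filtered_matrix.tsv` — the expression table restricted to valid genes;
#' * `rank_table.tsv` — gene, tissue, within_rank, across_rank, rank_sum, tau;
#' * `selection.tsv` — the per-tissue top-k report;
#' * `validation.tsv` — tissue, n1, n2, t, df, p_two_sided;
#' * `manifest.tsv` — key-value echo of the configuration, package version
#'   and MD5 digests of the inputs.
#'
#' Outputs contain no timestamps, so identical inputs and configuration
#' give byte-identical artifacts.
#'
#' @param matrix_file Path to the expression TSV.
#' @param annotation_file Path to the annotation TSV.
#' @param out_dir Output directory (created if absent).
#' @param k Candidates per tissue (default 25).
#' @return Invisibly, a list with the in-memory `decisions`, `filtered`,
#'   `ranks`, `selection` and `validation` tibbles plus `paths`.
#' @export
run_pipeline <- function(matrix_file, annotation_file, out_dir, k = 25) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "ectorank_pipeline_error", parent = e)
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  x <- stage("read", read_expression_matrix(matrix_file))
  records <- stage("read", read_annotation_table(annotation_file))
  decisions <- stage("filter", assess_validity(records))
  filtered <- stage("filter", restrict_to_valid(x, records))
  ranks <- stage("rank", rank_table(filtered))
  selection <- stage("select", select_top_k(ranks, k))
  validation <- stage("validate", validate_selection(filtered, selection))

  paths <- list(
    decisions = file.path(out_dir, "decisions.tsv"),
    filtered = file.path(out_dir, "filtered_matrix.tsv"),
    ranks = file.path(out_dir, "rank_table.tsv"),
    selection = file.path(out_dir, "selection.tsv"),
    validation = file.path(out_dir, "validation.tsv"),
    manifest = file.path(out_dir, "manifest.tsv")
  )
  decisions_flat <- dplyr::mutate(
    decisions,
    failed_rules = purrr::map_chr(.data$failed_rules, paste, collapse = ";"))
  readr::write_tsv(decisions_flat[c("symbol", "valid", "failed_rules")],
                   paths$decisions, progress = FALSE)
  write_expression_matrix(filtered, paths$filtered)
  readr::write_tsv(ranks, paths$ranks, progress = FALSE)
  write_selection_report(selection, paths$selection)
  readr::write_tsv(validation[c("tissue", "n1", "n2", "t", "df", "p_two_sided")],
                   paths$validation, progress = FALSE)
  manifest <- tibble::tibble(
    key = c("package", "version", "k", "matrix_file", "matrix_md5",
            "annotation_file", "annotation_md5", "genes_total",
            "genes_valid", "tissues"),
    value = c("ectorank", as.character(utils::packageVersion("ectorank")),
              as.character(k), basename(matrix_file),
              unname(tools::md5sum(matrix_file)), basename(annotation_file),
              unname(tools::md5sum(annotation_file)),
              as.character(nrow(x)), as.character(nrow(filtered)),
              as.character(ncol(x) - 1L))
  )
  readr::write_tsv(manifest, paths$manifest, progress = FALSE)
  invisible(list(decisions = decisions, filtered = filtered, ranks = ranks,
                 selection = selection, validation = validation, paths = paths))
}
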