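#' Rank values in descending order
#'
#' Rank 1 always marks the largest value, matching the convention "the sixth
#' highest intensity has rank 6".
#'
#' Two tie policies are available. Under `"competition"` (min) ranking, tied
#' values share the rank `1 + (number of strictly greater values)`. Under
#' `"ordinal"` ranking the result is a permutation of `1..length(values)`;
#' ties are broken by ascending `tie_key`, compared byte-wise, so the result
#' is deterministic.
#'
#' @param values Numeric vector, non-empty, all finite.
#' @param policy `"competition"` or `"ordinal"`.
#' @param tie_key Character vector of unique identifiers, required under the
#'   ordinal policy whenever `values` contains ties.
#' @return Integer vector of ranks.
#' @examples
#' rank_descending(c(9, 5, 1))
#' rank_descending(c(5, 5, 1))                       # competition: 1, 1, 3
#' rank_descending(c(5, 5, 1), "ordinal", c("b", "a", "c"))
#' @export
rank_descending <- function(values, policy = c("competition", "ordinal"),
                            tie_key = NULL) {
  policy <- match.arg(policy)
  if (length(values) == 0L) {
    abort("Cannot rank an empty vector.", class = "ectorank_domain_error")
  }
  if (any(!is.finite(values))) {
    abort("Cannot rank non-finite values.", class = "ectorank_domain_error")
  }
  if (policy == "competition") {
    return(as.integer(rank(-values, ties.method = "min")))
  }
  if (anyDuplicated(values) && is.null(tie_key)) {
    abort("Ordinal ranking of tied values needs a `tie_key`.",
          class = "ectorank_domain_error")
  }
  ord <- if (is.null(tie_key)) {
    order(-values, method = "radix")
  } else {
    if (length(tie_key) != length(values)) {
      abort("`tie_key` must have the same length as `values`.",
            class = "ectorank_domain_error")
    }
    order(-values, tie_key, method = "radix")
  }
  ranks <- integer(length(values))
  ranks[ord] <- seq_along(values)
  ranks
}

#' Compute the dual-rank table for a gene-by-tissue expression table
#'
#' For each gene `i` and tissue `j` this computes:
#'
#' * `within_rank` — the competition rank of the intensity among all genes of
#'   tissue `j` (1 = most intense gene in that tissue);
#' * `across_rank` — the competition rank of the intensity among all tissues
#'   of gene `i` (1 = the gene's most intense tissue);
#' * `rank_sum` — their sum, in `[2, m + n]`;
#' * `tau` — the final score: the ordinal ascending rank of `rank_sum`
#'   within tissue `j`, ties broken by gene identifier (byte order), so tau
#'   is always a permutation of `1..m` per tissue. Low tau marks a gene that
#'   is simultaneously prominent in the tissue and preferentially expressed
#'   there relative to its other tissues.
#'
#' @param x A wide expression tibble (see [read_expression_matrix()]).
#' @return A long tibble with columns `gene`, `tissue`, `within_rank`,
#'   `across_rank`, `rank_sum`, `tau`; genes vary fastest, tissues keep the
#'   input column order.
#' @seealso [select_top_k()], [tau_oracle()]
#' @export
rank_table <- function(x) {
  mat <- as_intensity_matrix(x)
  m <- nrow(mat)
  n <- ncol(mat)
  genes <- rownames(mat)
  within <- vapply(seq_len(n), function(j) rank_descending(mat[, j]), integer(m))
  across <- t(vapply(seq_len(m), function(i) rank_descending(mat[i, ]), integer(n)))
  rank_sum <- within + across
  tau <- vapply(seq_len(n), function(j) {
    rank_descending(-rank_sum[, j], policy = "ordinal", tie_key = genes)
  }, integer(m))
  tibble::tibble(
    gene = rep(genes, times = n),
    tissue = rep(colnames(mat), each = m),
    within_rank = as.integer(within),
    across_rank = as.integer(across),
    rank_sum = as.integer(rank_sum),
    tau = as.integer(tau)
  )
}

#' Select the top-k candidate genes per tissue
#'
#' @param ranks A rank table from [rank_table()].
#' @param k Candidates per tissue (default 25). When `k >= m` all genes are
#'   returned.
#' @return A tibble with columns `tissue`, `rank` (1..min(k, m)), `gene`,
#'   `tau`, `rank_sum`, ordered by tissue (input order) then tau.
#' @export
select_top_k <- function(ranks, k = 25) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    abort("`k` must be a single integer >= 1.", class = "ectorank_domain_error")
  }
  k <- as.integer(k)
  ranks |>
    dplyr::mutate(tissue = factor(.data$tissue, levels = unique(.data$tissue))) |>
    dplyr::filter(.data$tau <= k) |>
    dplyr::arrange(.data$tissue, .data$tau) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(tissue = as.character(.data$tissue)) |>
    dplyr::select("tissue", "rank", "gene", "tau", "rank_sum")
}

# Byte-wise string "less than", used only by the oracle path.
byte_lt <- function(a, b) {
  ra <- utf8ToInt(a)
  rb <- utf8ToInt(b)
  n <- min(length(ra), length(rb))
  if (n > 0L) {
    for (k in seq_len(n)) {
      if (ra[k] != rb[k]) return(ra[k] < rb[k])
    }
  }
  length(ra) < length(rb)
}

#' Brute-force oracle for the dual-rank table
#'
#' Recomputes exactly the quantities of [rank_table()] by naive per-element
#' counting: each rank is `1 +` the number of strictly greater competitors,
#' and the final tau is obtained by exhaustive pairwise comparison of rank
#' sums (ties resolved by a byte-wise gene-identifier comparison). This path
#' shares no ranking code with [rank_table()] and exists as an independent
#' correctness check; it is quadratic and meant for modest matrices.
#'
#' @inheritParams rank_table
#' @return A long tibble with the same columns and ordering as
#'   [rank_table()].
#' @export
tau_oracle <- function(x) {
  mat <- as_intensity_matrix(x)
  m <- nrow(mat)
  n <- ncol(mat)
  genes <- rownames(mat)
  within <- matrix(0L, m, n)
  across <- matrix(0L, m, n)
  for (j in seq_len(n)) {
    col <- mat[, j]
    within[, j] <- 1L + colSums(outer(col, col, ">"))
  }
  for (i in seq_len(m)) {
    row <- mat[i, ]
    across[i, ] <- 1L + colSums(outer(row, row, ">"))
  }
  rank_sum <- within + across
  tau <- matrix(0L, m, n)
  for (j in seq_len(n)) {
    s <- rank_sum[, j]
    for (i in seq_len(m)) {
      below <- sum(s < s[i])
      tied <- which(s == s[i])
      tied <- tied[tied != i]
      for (i2 in tied) {
        if (byte_lt(genes[i2], genes[i])) below <- below + 1L
      }
      tau[i, j] <- 1L + below
    }
  }
  tibble::tibble(
    gene = rep(genes, times = n),
    tissue = rep(colnames(mat), each = m),
    within_rank = as.integer(within),
    across_rank = as.integer(across),
    rank_sum = as.integer(rank_sum),
    tau = as.integer(tau)
  )
}

#' Plot a per-tissue candidate selection
#'
#' Shows the selected genes of each tissue ordered by their final tau, with
#' the rank-sum that produced the score mapped to colour.
#'
#' @param selection A selection tibble from [select_top_k()].
#' @return A ggplot object.
#' @export
plot_selection <- function(selection) {
  ggplot2::ggplot(selection,
                  ggplot2::aes(x = .data$tau,
                               y = stats::reorder(.data$gene, -.data$tau),
                               colour = .data$rank_sum)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$tissue), scales = "free_y") +
    ggplot2::labs(x = "final rank τ (1 = strongest candidate)",
                  y = NULL, colour = "rank sum") +
    ggplot2::theme_minimal()
}
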