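# Shared fixture builders for the suite. Everything is generated in code;
# no fixture files.

# Random wide expression tibble; integer values force ties when ties = TRUE.
random_expression <- function(m, n, ties = FALSE, seed = NULL) {
  draw <- function() {
    vals <- if (ties) {
      sample(1:5, m * n, replace = TRUE) * 10
    } else {
      runif(m * n, 1, 1000)
    }
    mat <- matrix(vals, m, n,
                  dimnames = list(paste0("g", seq_len(m)),
                                  paste0("t", seq_len(n))))
    tibble::tibble(gene = rownames(mat)) |>
      dplyr::bind_cols(tibble::as_tibble(mat))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# The 3-gene x 2-tissue table whose ranks are enumerable by hand.
hand_expression <- function() {
  tibble::tibble(gene = c("g1", "g2", "g3"),
                 t1 = c(10, 5, 1),
                 t2 = c(1, 2, 3))
}

rank_of <- function(rt, gene, tissue) {
  rt[rt$gene == gene & rt$tissue == tissue, ]
}
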