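#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired t-test without the equal-variance assumption:
#' `t = (mean1 - mean2) / sqrt(var1/n1 + var2/n2)` with sample variances and
#' Welch–Satterthwaite degrees of freedom. The test itself is delegated to
#' [stats::t.test()]; this wrapper adds the group summaries and returns a
#' one-row tibble.
#'
#' @param group_a,group_b Numeric vectors with at least 2 finite values each.
#' @return A one-row tibble with columns `t`, `df`, `p_two_sided`, `n1`,
#'   `n2`, `mean1`, `mean2`, `var1`, `var2`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t_test <- function(group_a, group_b) {
  for (g in list(group_a, group_b)) {
    if (length(g) < 2L || any(!is.finite(g))) {
      abort("Each group needs >= 2 finite values.", class = "ectorank_domain_error")
    }
  }
  v1 <- var(group_a)
  v2 <- var(group_b)
  if (v1 == 0 && v2 == 0) {
    abort("Both groups have zero variance; the Welch statistic is undefined.",
          class = "ectorank_degenerate_data")
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_two_sided = ht$p.value,
    n1 = length(group_a),
    n2 = length(group_b),
    mean1 = mean(group_a),
    mean2 = mean(group_b),
    var1 = v1,
    var2 = v2
  )
}

#' Mann–Whitney U test with an exact small-sample null
#'
#' The statistic is `U = sum over pairs of [a > b] + 1/2 [a == b]`, counted
#' for the first group. When `n1 + n2 <= exact_max_n` the two-sided p-value
#' is computed exactly by enumerating all `choose(n1 + n2, n1)` assignments
#' of the pooled values to the two groups (doubling the smaller tail,
#' capped at 1), which handles ties without approximation. For larger
#' samples a normal approximation with tie-corrected variance and a 1/2
#' continuity correction is used.
#'
#' @param group_a,group_b Non-empty numeric vectors of finite values.
#' @param exact_max_n Largest pooled size for which the exact enumeration is
#'   used (default 16; `choose(16, 8) = 12870` labelings).
#' @return A one-row tibble with columns `u`, `p_two_sided`, `method`
#'   (`"exact_enumeration"` or `"normal_approximation"`), `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # u = 0, p = 1/3
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max_n = 16) {
  for (g in list(group_a, group_b)) {
    if (length(g) == 0L || any(!is.finite(g))) {
      abort("Each group must be non-empty with finite values.",
            class = "ectorank_domain_error")
    }
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  u_obs <- sum(outer(group_a, group_b, ">")) + 0.5 * sum(outer(group_a, group_b, "=="))
  z <- c(group_a, group_b)
  nn <- n1 + n2
  if (nn <= exact_max_n) {
    gt <- outer(z, z, ">") + 0.5 * outer(z, z, "==")
    labelings <- combn(nn, n1)
    us <- apply(labelings, 2L, function(idx) sum(gt[idx, -idx, drop = FALSE]))
    eps <- 1e-9
    p_lo <- mean(us <= u_obs + eps)
    p_hi <- mean(us >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact_enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie_sizes <- table(z)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_sizes^3 - tie_sizes) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      abort("All pooled values are tied; the Mann-Whitney null is degenerate.",
            class = "ectorank_degenerate_data")
    }
    zstat <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(zstat)))
    method <- "normal_approximation"
  }
  tibble::tibble(u = u_obs, p_two_sided = p, method = method, n1 = n1, n2 = n2)
}

#' Compare selected versus non-selected genes within one tissue
#'
#' Welch t-test of the intensities (in the given tissue) of the genes the
#' dual-rank screen selected against all remaining genes of the table. With
#' the 352-gene atlas and the default selection size this compares groups of
#' 25 and 327 genes.
#'
#' @param x The wide expression tibble the selection was derived from.
#' @param selection A selection tibble from [select_top_k()].
#' @param tissue Tissue identifier present in both `x` and `selection`.
#' @return A one-row tibble: `tissue` plus the [welch_t_test()] columns.
#' @export
compare_selected_vs_rest <- function(x, selection, tissue) {
  ids <- check_expression(x)
  if (!tissue %in% ids$tissues) {
    abort(sprintf("Tissue '%s' is not in the expression table.", tissue),
          class = "ectorank_consistency_error")
  }
  sel_genes <- selection$gene[selection$tissue == tissue]
  if (length(sel_genes) == 0L) {
    abort(sprintf("Selection has no genes for tissue '%s'.", tissue),
          class = "ectorank_consistency_error")
  }
  if (!all(sel_genes %in% ids$genes)) {
    abort("Selection contains genes absent from the expression table.",
          class = "ectorank_consistency_error")
  }
  values <- x[[tissue]]
  in_sel <- ids$genes %in% sel_genes
  if (all(in_sel)) {
    abort("All genes are selected; the complement group is empty.",
          class = "ectorank_degenerate_data")
  }
  res <- welch_t_test(values[in_sel], values[!in_sel])
  dplyr::bind_cols(tibble::tibble(tissue = tissue), res)
}

#' Validate a selection across all its tissues
#'
#' Runs [compare_selected_vs_rest()] for every tissue appearing in the
#' selection and binds the one-row results.
#'
#' @inheritParams compare_selected_vs_rest
#' @return A tibble with one row per tissue.
#' @export
validate_selection <- function(x, selection) {
  purrr::map_dfr(unique(selection$tissue),
                 function(ti) compare_selected_vs_rest(x, selection, ti))
}
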