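#' Simulate an atlas-style expression table with planted signals
#'
#' Draws a gene-by-tissue intensity table emulating a microarray expression
#' atlas restricted to receptor genes: positive, right-skewed baseline
#' intensities (log-normal) with a small set of (gene, tissue) pairs whose
#' signal is multiplied by a fold factor — the planted ectopic candidates a
#' screen should recover. The generator is a pure function of its parameters
#' and `seed`.
#'
#' @param m,n Gene and tissue counts (defaults 352 and 78, the size of the
#'   refined receptor atlas the method was designed around).
#' @param log_mean,log_sd Parameters of the log-normal baseline (defaults 6
#'   and 1 on the log scale).
#' @param planted Optional tibble/data frame with integer columns `gene`,
#'   `tissue` (1-based indices) and `fold` (> 1): multipliers applied to the
#'   baseline at those cells.
#' @param seed Integer seed.
#' @return A list with `expression` (wide tibble, genes `olfr1..olfrm`,
#'   tissues `tissue01..`) and `truth` (generator parameters plus the planted
#'   pairs with resolved identifiers).
#' @examples
#' sim <- simulate_expression(m = 20, n = 6, seed = 1,
#'                            planted = data.frame(gene = 3, tissue = 2, fold = 50))
#' sim$truth$planted
#' @export
simulate_expression <- function(m = 352, n = 78, log_mean = 6, log_sd = 1,
                                planted = NULL, seed = 1) {
  stopifnot(m >= 1, n >= 1, log_sd >= 0)
  genes <- paste0("olfr", seq_len(m))
  tissues <- sprintf("tissue%02d", seq_len(n))
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("gene", "tissue", "fold") %in% names(planted)))
    if (any(planted$gene < 1 | planted$gene > m |
            planted$tissue < 1 | planted$tissue > n)) {
      abort("Planted indices out of range.", class = "ectorank_domain_error")
    }
    if (any(planted$fold <= 1)) {
      abort("Planted fold multipliers must be > 1.", class = "ectorank_domain_error")
    }
  }
  mat <- withr::with_seed(seed, {
    out <- matrix(rlnorm(m * n, meanlog = log_mean, sdlog = log_sd), m, n)
    if (!is.null(planted)) {
      out[cbind(planted$gene, planted$tissue)] <-
        out[cbind(planted$gene, planted$tissue)] * planted$fold
    }
    out
  })
  rownames(mat) <- genes
  colnames(mat) <- tissues
  truth <- list(
    m = m, n = n, log_mean = log_mean, log_sd = log_sd, seed = seed,
    planted = if (is.null(planted)) {
      tibble::tibble(gene = integer(), tissue = integer(), fold = numeric(),
                     gene_id = character(), tissue_id = character())
    } else {
      dplyr::mutate(planted, gene_id = genes[.data$gene],
                    tissue_id = tissues[.data$tissue])
    }
  )
  list(expression = as_expression_tibble(mat), truth = truth)
}

#' Build the engineered worked-example atlas
#'
#' Constructs a tie-free 352-gene by 78-tissue table in which the focal gene
#' (`olfr190`) has, in the focal tissue (`thymus`), the 6th highest
#' intensity of the tissue and the 58th highest intensity of its own row,
#' and in which exactly six other genes of that tissue have a rank sum
#' strictly below 64 with no other gene at 64 — so the dual-rank score of
#' the focal pair is within-rank 6, across-rank 58, rank sum 64, tau 7.
#'
#' The construction is by design rather than search: five genes are placed
#' above the focal intensity in the focal tissue and given their row maximum
#' there (rank sums 2..6), one further gene just below the focal intensity
#' is treated the same way (rank sum 8), the focal row gets exactly 57
#' entries above the focal intensity, and every remaining gene's other
#' tissues are filled above its focal-tissue value, forcing its rank sum to
#' at least 86. Values within each band are random draws, so different seeds
#' give different matrices with the same rank structure. Before returning,
#' the construction is verified against the independent brute-force oracle
#' ([tau_oracle()]); a violation is a bug and raises an error.
#'
#' @param seed Integer seed.
#' @return A list with `expression` (wide tibble), `focal_gene`
#'   (`"olfr190"`) and `focal_tissue` (`"thymus"`).
#' @export
build_worked_example <- function(seed = 1) {
  m <- 352L
  n <- 78L
  genes <- paste0("olfr", seq_len(m))
  gi <- 190L
  mat <- withr::with_seed(seed, {
    tissues <- sprintf("t%02d", seq_len(n))
    pos <- sample.int(n, 1L)
    tissues[pos] <- "thymus"
    out <- matrix(NA_real_, m, n, dimnames = list(genes, tissues))
    others <- setdiff(seq_len(m), gi)
    role <- sample(others)
    top5 <- role[1:5]
    low_sum <- role[6L]
    rest <- role[-(1:6)]
    # focal tissue column
    out[top5, pos] <- sort(runif(5, 2600, 3000), decreasing = TRUE)
    out[gi, pos] <- 1000
    out[low_sum, pos] <- runif(1, 985, 995)
    out[rest, pos] <- runif(length(rest), 250, 980)
    # rows that must peak in the focal tissue (across-rank 1)
    for (i in c(top5, low_sum)) {
      out[i, -pos] <- runif(n - 1L, 100, 200)
    }
    # focal row: exactly 57 tissues above the focal intensity
    hi <- sample(setdiff(seq_len(n), pos), 57L)
    out[gi, hi] <- runif(57, 1100, 1200)
    out[gi, setdiff(seq_len(n), c(pos, hi))] <- runif(n - 58L, 100, 200)
    # all remaining genes peak away from the focal tissue (across-rank 78)
    for (i in rest) {
      out[i, -pos] <- runif(n - 1L, 1100, 1200)
    }
    out
  })
  expr <- as_expression_tibble(mat)
  oracle <- tau_oracle(expr)
  focal <- oracle[oracle$gene == "olfr190" & oracle$tissue == "thymus", ]
  col_sums <- oracle$rank_sum[oracle$tissue == "thymus"]
  ok <- focal$within_rank == 6L && focal$across_rank == 58L &&
    focal$rank_sum == 64L && focal$tau == 7L &&
    sum(col_sums < 64L) == 6L && sum(col_sums == 64L) == 1L
  if (!ok) {
    abort("Worked-example construction failed its oracle verification.",
          class = "ectorank_internal_error")
  }
  list(expression = expr, focal_gene = "olfr190", focal_tissue = "thymus")
}

#' Simulate annotation records with known validity
#'
#' Generates `n_valid` records passing every validity rule and `n_invalid`
#' records violating the four rule classes in rotation (non-`NM_` accession,
#' unreviewed comment, "partial" title, "pseudo" title), then shuffles the
#' rows. The returned truth map gives the intended validity of each symbol.
#'
#' @param n_valid,n_invalid Non-negative record counts.
#' @param seed Integer seed (controls the row shuffle).
#' @return A list with `records` (annotation tibble) and `truth`
#'   (tibble `symbol`, `valid`).
#' @export
simulate_annotations <- function(n_valid, n_invalid, seed = 1) {
  stopifnot(n_valid >= 0, n_invalid >= 0)
  mk_valid <- function(i) {
    tibble::tibble(
      symbol = paste0("olfr", i),
      accession = sprintf("NM_%06d", 100000L + i),
      title = sprintf("Mus musculus olfactory receptor %d (Olfr%d), mRNA", i, i),
      comment_leading_word = "VALIDATED"
    )
  }
  mk_invalid <- function(i, class_idx) {
    base <- mk_valid(i)
    switch(class_idx,
           dplyr::mutate(base, accession = sprintf("XM_%06d", 100000L + i)),
           dplyr::mutate(base, comment_leading_word = "PROVISIONAL"),
           dplyr::mutate(base, title = sprintf(
             "Mus musculus olfactory receptor %d (Olfr%d), partial cds", i, i)),
           dplyr::mutate(base, title = sprintf(
             "Mus musculus olfactory receptor pseudogene %d (Olfr%d-ps)", i, i)))
  }
  template <- tibble::tibble(symbol = character(), accession = character(),
                             title = character(), comment_leading_word = character())
  valid <- purrr::map_dfr(seq_len(n_valid), mk_valid)
  invalid <- purrr::map_dfr(seq_len(n_invalid), function(k) {
    mk_invalid(n_valid + k, ((k - 1L) %% 4L) + 1L)
  })
  records <- dplyr::bind_rows(template, valid, invalid)
  truth <- tibble::tibble(symbol = records$symbol,
                          valid = rep(c(TRUE, FALSE), c(n_valid, n_invalid)))
  if (nrow(records) > 1L) {
    ord <- withr::with_seed(seed, sample.int(nrow(records)))
    records <- records[ord, ]
    truth <- truth[ord, ]
  }
  list(records = records, truth = truth)
}

#' Simulate a qPCR Ct table from a known standard curve
#'
#' Produces the Ct table the quantification workflow consumes: a 5-point
#' 10-fold plasmid standard series (10 to 1e5 fM), one reference-gene row
#' per sample (the reference transcript at a common true concentration,
#' subject to the sample's loading factor), and the unknown targets. Every
#' Ct is `intercept + slope * log10(concentration x loading)` plus optional
#' Gaussian noise.
#'
#' @param samples Tibble with columns `sample_id`, `target_id`,
#'   `concentration` (true fM, > 0).
#' @param curve A `standard_curve` (see [standard_curve()]).
#' @param loadings Named numeric vector of per-sample loading factors
#'   (default: 1 for every sample). Normalization can only recover absolute
#'   concentrations exactly when the loadings have geometric mean 1.
#' @param reference_concentration True fM of the reference transcript in
#'   every sample before loading (default 1000).
#' @param noise_sd Gaussian Ct noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return A list with `ct_table` (tibble `sample_id`, `target_id`, `role`
#'   in standard/reference/unknown, `known_concentration` — fM for standards,
#'   `NA` otherwise — and `ct`) and `truth` (all generator inputs).
#' @export
simulate_qpcr <- function(samples, curve, loadings = NULL,
                          reference_concentration = 1000, noise_sd = 0,
                          seed = 1) {
  stopifnot(inherits(curve, "standard_curve"), noise_sd >= 0,
            all(c("sample_id", "target_id", "concentration") %in% names(samples)))
  if (any(samples$concentration <= 0)) {
    abort("True concentrations must be > 0.", class = "ectorank_domain_error")
  }
  sample_ids <- unique(samples$sample_id)
  if (is.null(loadings)) {
    loadings <- setNames(rep(1, length(sample_ids)), sample_ids)
  }
  if (!all(sample_ids %in% names(loadings))) {
    abort("Every sample needs a loading factor.", class = "ectorank_consistency_error")
  }
  ct_of <- function(conc) curve$intercept + curve$slope * log10(conc)
  std_conc <- 10^(1:5)
  std <- tibble::tibble(sample_id = paste0("std", 1:5),
                        target_id = "standard", role = "standard",
                        known_concentration = std_conc,
                        true_concentration = std_conc)
  ref <- tibble::tibble(sample_id = sample_ids,
                        target_id = "eEF2", role = "reference",
                        known_concentration = NA_real_,
                        true_concentration = reference_concentration *
                          unname(loadings[sample_ids]))
  unk <- tibble::tibble(sample_id = samples$sample_id,
                        target_id = samples$target_id, role = "unknown",
                        known_concentration = NA_real_,
                        true_concentration = samples$concentration *
                          unname(loadings[samples$sample_id]))
  tab <- dplyr::bind_rows(std, ref, unk)
  tab$ct <- withr::with_seed(seed, {
    ct_of(tab$true_concentration) + rnorm(nrow(tab), 0, noise_sd)
  })
  ct_table <- dplyr::select(tab, "sample_id", "target_id", "role",
                            "known_concentration", "ct")
  truth <- list(samples = tibble::as_tibble(samples), loadings = loadings,
                reference_concentration = reference_concentration,
                slope = curve$slope, intercept = curve$intercept,
                noise_sd = noise_sd, seed = seed)
  list(ct_table = ct_table, truth = truth)
}
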