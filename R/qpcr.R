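#' Construct a standard curve from known parameters
#'
#' Builds a `standard_curve` object directly from a slope and intercept,
#' e.g. for simulation. `slope` is in Ct units per log10(concentration in
#' fM); `intercept` is the Ct at 1 fM. Amplification efficiency is the
#' closed form `10^(-1/slope) - 1` (1.0 means perfect doubling each cycle,
#' slope `-1/log10(2) ≈ -3.3219`).
#'
#' @param slope,intercept Line parameters of Ct on log10(concentration).
#' @param r_squared Optional fit quality; `NA` for a curve not obtained by
#'   fitting.
#' @return A `standard_curve` object.
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_) {
  if (!is.finite(slope) || !is.finite(intercept)) {
    abort("Slope and intercept must be finite.", class = "ectorank_domain_error")
  }
  if (slope >= 0) {
    warn("Standard curve has a non-negative slope; the assay is not functioning as a dilution series.")
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         efficiency = 10^(-1 / slope) - 1,
         positive_slope = slope >= 0,
         n_points = NA_integer_, data = NULL, fit = NULL),
    class = "standard_curve"
  )
}

#' Fit a qPCR standard curve to a plasmid dilution series
#'
#' Least-squares line of Ct on log10(concentration) across the points of a
#' standard dilution series (e.g. a 10-fold plasmid series). Concentrations
#' are in fM.
#'
#' @param data A data frame with numeric columns `concentration` (fM, > 0)
#'   and `ct`, at least two distinct concentrations.
#' @return A `standard_curve` object with elements `slope`, `intercept`,
#'   `r_squared`, `efficiency` (`10^(-1/slope) - 1`), `n_points`, and the
#'   underlying [stats::lm] fit. A non-negative slope triggers a warning and
#'   sets the `positive_slope` flag, but the curve is still returned.
#' @examples
#' pts <- tibble::tibble(concentration = 10^(1:5),
#'                       ct = 40 - 3.3219 * log10(10^(1:5)))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(data) {
  missing <- setdiff(c("concentration", "ct"), names(data))
  if (length(missing) > 0L) {
    abort(sprintf("Dilution data is missing column(s): %s.", paste(missing, collapse = ", ")),
          class = "ectorank_malformed_input")
  }
  conc <- data$concentration
  ct <- data$ct
  if (any(!is.finite(conc)) || any(conc <= 0) || any(!is.finite(ct))) {
    abort("Concentrations must be finite and > 0, Ct values finite.",
          class = "ectorank_domain_error")
  }
  if (length(unique(conc)) < 2L) {
    abort("Need at least two distinct concentrations to fit a standard curve.",
          class = "ectorank_degenerate_data")
  }
  d <- data.frame(log_conc = log10(conc), ct = ct)
  fit <- lm(ct ~ log_conc, data = d)
  slope <- unname(stats::coef(fit)[["log_conc"]])
  intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  if (slope >= 0) {
    warn("Fitted standard curve has a non-negative slope; check the dilution series.")
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency = 10^(-1 / slope) - 1,
         positive_slope = slope >= 0,
         n_points = nrow(d), data = tibble::as_tibble(data), fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve: Ct =", format(x$intercept, digits = 6),
      if (x$slope < 0) "-" else "+", format(abs(x$slope), digits = 6),
      "* log10(conc fM)\n")
  cat("  efficiency:", sprintf("%.1f%%", 100 * x$efficiency),
      " r^2:", format(x$r_squared, digits = 4),
      " points:", x$n_points, "\n")
  invisible(x)
}

#' Tidy a standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return A tibble with one row per line parameter (`intercept`, `slope`),
#'   with standard errors when the curve was fitted.
#' @exportS3Method generics::tidy
tidy.standard_curve <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("intercept", "slope"),
                          estimate = c(x$intercept, x$slope),
                          std.error = NA_real_, statistic = NA_real_,
                          p.value = NA_real_))
  }
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(cf[, 1]),
    std.error = unname(cf[, 2]),
    statistic = unname(cf[, 3]),
    p.value = unname(cf[, 4])
  )
}

#' One-row summary of a standard curve
#'
#' @inheritParams tidy.standard_curve
#' @return A one-row tibble with `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `n_points`.
#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency = x$efficiency,
                 n_points = x$n_points)
}

#' Plot a standard curve with its dilution points
#'
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.standard_curve <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(object$data, log_conc = log10(.data$concentration)),
      ggplot2::aes(x = .data$log_conc, y = .data$ct))
  }
  p +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 concentration (fM)", y = "Ct",
      title = sprintf("Standard curve: slope %.3f, efficiency %.1f%%",
                      object$slope, 100 * object$efficiency)) +
    ggplot2::theme_minimal()
}

#' Convert Ct values to absolute concentrations
#'
#' Inverts the standard-curve line: `concentration = 10^((ct - intercept) /
#' slope)`, in fM. Lower Ct means more template.
#'
#' @param ct Numeric vector of finite Ct values.
#' @param curve A `standard_curve` with negative slope.
#' @return Numeric vector of concentrations (fM).
#' @export
ct_to_concentration <- function(ct, curve) {
  if (!inherits(curve, "standard_curve")) {
    abort("`curve` must be a standard_curve object.", class = "ectorank_domain_error")
  }
  if (curve$slope >= 0) {
    abort("Quantification needs a negative-slope standard curve.",
          class = "ectorank_domain_error")
  }
  if (any(!is.finite(ct))) {
    abort("Ct values must be finite.", class = "ectorank_domain_error")
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' Normalize target concentrations to a reference gene
#'
#' Removes per-sample loading differences using a reference transcript
#' (e.g. eEF-2) quantified in every sample on the same concentration scale:
#' each target concentration is multiplied by `(geometric mean of the
#' reference across samples) / (reference in that sample)`. Scaling by the
#' geometric mean keeps the normalized values in absolute fM units rather
#' than unitless ratios.
#'
#' @param targets A tibble of quantified targets with columns `sample_id`,
#'   `target_id`, `concentration`.
#' @param reference A tibble with columns `sample_id`, `concentration`
#'   (one row per sample) for the reference transcript.
#' @return `targets` with an added `normalized_concentration` column (fM).
#' @export
normalize_to_reference <- function(targets, reference) {
  for (nm in c("sample_id", "concentration")) {
    if (!nm %in% names(targets) || !nm %in% names(reference)) {
      abort(sprintf("Both tables need a '%s' column.", nm),
            class = "ectorank_malformed_input")
    }
  }
  if (anyDuplicated(reference$sample_id)) {
    abort("Reference table must have one row per sample.",
          class = "ectorank_consistency_error")
  }
  missing <- setdiff(unique(targets$sample_id), reference$sample_id)
  if (length(missing) > 0L) {
    abort(sprintf("No reference record for sample(s): %s.", paste(missing, collapse = ", ")),
          class = "ectorank_consistency_error")
  }
  if (any(!is.finite(reference$concentration)) || any(reference$concentration <= 0)) {
    abort("Reference concentrations must be finite and > 0.",
          class = "ectorank_domain_error")
  }
  gm <- exp(mean(log(reference$concentration)))
  ref_of <- setNames(reference$concentration, reference$sample_id)
  dplyr::mutate(tibble::as_tibble(targets),
                normalized_concentration =
                  .data$concentration * gm / unname(ref_of[.data$sample_id]))
}

#' Summarize biological replicates
#'
#' Mean and standard error (`sd / sqrt(n)`) of the normalized concentration
#' per group — by default per target, mirroring "mean fM ± SEM over
#' independent mice". A single replicate yields SEM 0 (with its `n = 1`
#' visible in the output).
#'
#' @param records A tibble of quantified records containing
#'   `normalized_concentration` (or `concentration` as a fallback).
#' @param ... Grouping columns (tidy-select style); defaults to `target_id`.
#' @return A tibble with the grouping columns plus `mean_fm`, `sem_fm`, `n`.
#' @examples
#' recs <- tibble::tibble(target_id = "olfr544", sample_id = 1:3,
#'                        normalized_concentration = c(1, 2, 3))
#' summarize_replicates(recs)   # mean 2, SEM 0.5774
#' @export
summarize_replicates <- function(records, ...) {
  value_col <- if ("normalized_concentration" %in% names(records)) {
    "normalized_concentration"
  } else if ("concentration" %in% names(records)) {
    "concentration"
  } else {
    abort("Records need a 'normalized_concentration' or 'concentration' column.",
          class = "ectorank_malformed_input")
  }
  groups <- rlang::enquos(...)
  if (length(groups) == 0L) groups <- rlang::quos(.data$target_id)
  records |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      mean_fm = mean(.data[[value_col]]),
      sem_fm = if (dplyr::n() > 1L) sd(.data[[value_col]]) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}
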