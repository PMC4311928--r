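perfect_slope <- -1 / log10(2)   # perfect doubling chemistry, about -3.3219

test_that("noiseless dilution series is recovered exactly, with 100% efficiency", {
  pts <- tibble::tibble(concentration = 10^(1:5),
                        ct = 40 - 3.3219 * log10(10^(1:5)))
  curve <- fit_standard_curve(pts)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-12)
  expect_equal(curve$intercept, 40, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_equal(curve$efficiency, 10^(1 / 3.3219) - 1, tolerance = 1e-12)
  expect_equal(curve$efficiency, 1, tolerance = 1e-4)

  expect_error(fit_standard_curve(tibble::tibble(concentration = c(10, 10),
                                                 ct = c(30, 31))),
               class = "ectorank_degenerate_data")
  expect_warning(fit_standard_curve(tibble::tibble(concentration = 10^(1:3),
                                                   ct = c(20, 25, 30))),
                 "slope")
})

test_that("noisy curve fits recover the slope within a practical band", {
  ok <- 0L
  for (s in 1:100) {
    sim <- simulate_qpcr(tibble::tibble(sample_id = "s1", target_id = "x",
                                        concentration = 100),
                         standard_curve(perfect_slope, 38),
                         noise_sd = 0.1, seed = s)
    std <- dplyr::filter(sim$ct_table, role == "standard")
    curve <- fit_standard_curve(tibble::tibble(concentration = std$known_concentration,
                                               ct = std$ct))
    if (abs(curve$slope - perfect_slope) <= 0.15) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("Ct inversion is the exact inverse of the curve and monotone", {
  curve <- standard_curve(perfect_slope, 40)
  expect_equal(ct_to_concentration(40, curve), 1, tolerance = 1e-12)
  conc <- 10^seq(-1, 5, by = 0.5)
  cts <- curve$intercept + curve$slope * log10(conc)
  expect_equal(ct_to_concentration(cts, curve), conc, tolerance = 1e-9)
  expect_true(all(diff(ct_to_concentration(seq(40, 10, by = -1), curve)) > 0))

  expect_error(ct_to_concentration(NA_real_, curve), class = "ectorank_domain_error")
  up <- suppressWarnings(standard_curve(2, 10))
  expect_error(ct_to_concentration(20, up), class = "ectorank_domain_error")
})

test_that("reference normalization removes loading and keeps fM units", {
  targets <- tibble::tibble(sample_id = c("m1", "m2", "m3"),
                            target_id = "olfr544",
                            concentration = c(100, 200, 300))
  # equal reference everywhere: identity
  ref_eq <- tibble::tibble(sample_id = c("m1", "m2", "m3"), concentration = 50)
  expect_equal(normalize_to_reference(targets, ref_eq)$normalized_concentration,
               targets$concentration)

  # a sample whose reference is 2x the geometric mean is halved
  ref <- tibble::tibble(sample_id = c("m1", "m2", "m3"),
                        concentration = c(2, 1, 1))
  gm <- exp(mean(log(ref$concentration)))
  out <- normalize_to_reference(targets, ref)
  expect_equal(out$normalized_concentration[1], 100 * gm / 2)

  expect_error(normalize_to_reference(targets, ref_eq[1:2, ]),
               "m3", class = "ectorank_consistency_error")
})

test_that("replicate summaries give mean, sd/sqrt(n) and the n=1 convention", {
  recs <- tibble::tibble(target_id = rep(c("a", "b", "c"), c(3, 3, 1)),
                         normalized_concentration = c(100, 100, 100, 1, 2, 3, 42))
  out <- summarize_replicates(recs)
  expect_equal(out$mean_fm, c(100, 2, 42))
  expect_equal(out$sem_fm, c(0, 1 / sqrt(3), 0))
  expect_equal(out$sem_fm[2], 0.5774, tolerance = 1e-4)
  expect_equal(out$n, c(3L, 3L, 1L))
})

test_that("the full quantification round trip recovers planted truth", {
  curve_true <- standard_curve(perfect_slope, 38)
  samples <- tidyr::expand_grid(sample_id = c("m1", "m2", "m3"),
                                target_id = c("olfr544", "olfr1386")) |>
    dplyr::mutate(concentration = rep(c(693.84, 434.88), 3))
  loadings <- c(m1 = 0.5, m2 = 1, m3 = 2)
  loadings <- loadings / exp(mean(log(loadings)))   # geometric mean 1

  quantify <- function(sim) {
    std <- dplyr::filter(sim$ct_table, role == "standard")
    fitted <- fit_standard_curve(tibble::tibble(
      concentration = std$known_concentration, ct = std$ct))
    unk <- dplyr::filter(sim$ct_table, role == "unknown") |>
      dplyr::mutate(concentration = ct_to_concentration(ct, fitted))
    ref <- dplyr::filter(sim$ct_table, role == "reference") |>
      dplyr::mutate(concentration = ct_to_concentration(ct, fitted))
    normalize_to_reference(unk, ref[c("sample_id", "concentration")])
  }

  # noiseless: exact recovery despite 4-fold loading differences
  sim0 <- simulate_qpcr(samples, curve_true, loadings = loadings, noise_sd = 0, seed = 1)
  out0 <- quantify(sim0)
  expect_equal(out0$normalized_concentration, samples$concentration,
               tolerance = 1e-9)

  # noisy: per-target means over the 3 mice recover truth within 20% for the
  # vast majority of runs, and without systematic bias across runs
  truth <- c(olfr1386 = 434.88, olfr544 = 693.84)
  rel <- sapply(1:50, function(s) {
    sim <- simulate_qpcr(samples, curve_true, loadings = loadings,
                         noise_sd = 0.2, seed = s)
    summ <- summarize_replicates(quantify(sim), .data$target_id)
    summ$mean_fm / truth[summ$target_id] - 1
  })
  expect_gte(mean(abs(rel) < 0.2), 0.85)
  expect_lt(max(abs(rowMeans(rel))), 0.05)
})

test_that("curve objects expose tidy, glance and autoplot views", {
  pts <- tibble::tibble(concentration = 10^(1:5),
                        ct = 38 + perfect_slope * log10(10^(1:5)) +
                          c(0.02, -0.01, 0, 0.01, -0.02))
  curve <- fit_standard_curve(pts)
  td <- tidy(curve)
  expect_identical(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], curve$slope)
  gl <- glance(curve)
  expect_identical(names(gl), c("slope", "intercept", "r_squared",
                                "efficiency", "n_points"))
  expect_equal(gl$n_points, 5L)
  expect_s3_class(autoplot(curve), "ggplot")
  expect_output(print(curve), "efficiency")
})
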