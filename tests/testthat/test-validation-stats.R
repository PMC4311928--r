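test_that("Welch statistic matches the closed formula on hand-evaluated cases", {
  # identical groups: t = 0, p = 1
  res <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p_two_sided, 1)

  # means 2 vs 3, variances 1: t = -1/sqrt(2/3), df = 4
  res <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$t, -1.224744871, tolerance = 1e-8)
  expect_equal(res$df, 4)
  expect_equal(res[, c("n1", "n2", "mean1", "mean2", "var1", "var2")],
               tibble::tibble(n1 = 3L, n2 = 3L, mean1 = 2, mean2 = 3,
                              var1 = 1, var2 = 1))

  # antisymmetry
  swapped <- welch_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_two_sided, res$p_two_sided)

  # Welch-Satterthwaite df stays inside its theoretical bounds
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- rnorm(sample(3:10, 1))
      b <- rnorm(sample(3:10, 1), sd = runif(1, 0.2, 3))
      res <- welch_t_test(a, b)
      expect_gte(res$df, min(length(a), length(b)) - 1)
      expect_lte(res$df, length(a) + length(b) - 2)
      expect_gte(res$p_two_sided, 0)
      expect_lte(res$p_two_sided, 1)
    }
  })

  expect_error(welch_t_test(c(1, 1, 1), c(2, 2)), class = "ectorank_degenerate_data")
  expect_error(welch_t_test(1, c(1, 2)), class = "ectorank_domain_error")
})

test_that("exact Mann-Whitney enumeration reproduces small-sample nulls", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$p_two_sided, 2 / 6)
  expect_identical(res$method, "exact_enumeration")

  # identical multisets sit at the null median
  res <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$u, 3 * 3 / 2)
  expect_equal(res$p_two_sided, 1)

  # reflection: u(a,b) + u(b,a) = n1 * n2, same p
  withr::with_seed(21, {
    for (i in 1:10) {
      a <- sample(1:8, 4, replace = TRUE)   # ties likely
      b <- sample(1:8, 5, replace = TRUE)
      ab <- mann_whitney_u(a, b)
      ba <- mann_whitney_u(b, a)
      expect_equal(ab$u + ba$u, 20)
      expect_equal(ab$p_two_sided, ba$p_two_sided)
    }
  })

  expect_error(mann_whitney_u(numeric(0), 1), class = "ectorank_domain_error")
})

test_that("exact p agrees with wilcox.test's independent exact path on tie-free data", {
  withr::with_seed(31, {
    for (i in 1:25) {
      n1 <- sample(2:5, 1)
      n2 <- sample(2:5, 1)
      pool <- sample(seq_len(100), n1 + n2)   # one draw, so no cross-group ties
      a <- pool[seq_len(n1)]
      b <- pool[-seq_len(n1)]
      ours <- mann_whitney_u(a, b)
      ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(ours$u, unname(ref$statistic))
      expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("normal approximation tracks the exact p for moderate samples", {
  withr::with_seed(55, {
    for (i in 1:20) {
      a <- rnorm(8)
      b <- rnorm(8, mean = runif(1, -1, 1))
      exact <- mann_whitney_u(a, b, exact_max_n = 16)
      approx <- mann_whitney_u(a, b, exact_max_n = 0)
      expect_identical(exact$method, "exact_enumeration")
      expect_identical(approx$method, "normal_approximation")
      expect_lt(abs(approx$p_two_sided - exact$p_two_sided), 0.02)
    }
  })
})

test_that("selected-vs-rest comparison books the right group sizes and detects signal", {
  planted <- tibble::tibble(gene = 1:4, tissue = 2, fold = 20)
  sim <- simulate_expression(m = 60, n = 5, planted = planted, seed = 9)
  rt <- rank_table(sim$expression)
  sel <- select_top_k(rt, 10)
  res <- compare_selected_vs_rest(sim$expression, sel, "tissue02")
  expect_equal(res$n1, 10L)
  expect_equal(res$n2, 50L)
  expect_gt(res$t, 0)
  expect_lt(res$p_two_sided, 0.05)

  all_sel <- select_top_k(rt, 60)
  expect_error(compare_selected_vs_rest(sim$expression, all_sel, "tissue02"),
               class = "ectorank_degenerate_data")
  expect_error(compare_selected_vs_rest(sim$expression, sel, "nowhere"),
               class = "ectorank_consistency_error")

  multi <- validate_selection(sim$expression, sel)
  expect_equal(nrow(multi), 5L)
  expect_true(all(multi$n1 == 10L & multi$n2 == 50L))
})
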