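test_that("exponential and power curve parameters solve the printed forms", {
  e <- solve_curve("exponential", 0.05, 25)
  expect_equal(e$b1, log(20) / 24, tolerance = 1e-12)
  expect_equal(e$b1, 0.124822, tolerance = 1e-4)
  expect_equal(e$b0, 0.05 * exp(e$b1), tolerance = 1e-12)
  expect_equal(e$b0, 0.056646, tolerance = 1e-4)
  expect_equal(learning_probability(1, e), 0.05, tolerance = 1e-12)

  p <- solve_curve("power", 0.05, 25)
  expect_equal(p$b0, 0.05, tolerance = 1e-12)
  expect_equal(p$b1, log(20) / log(25), tolerance = 1e-12)
  expect_equal(p$b1, 0.930650, tolerance = 1e-4)
  expect_equal(learning_probability(25, p), 0.0025, tolerance = 1e-12)
})

test_that("boundary conditions hold exactly for all forms on a grid", {
  for (form in c("exponential", "power", "reciprocal", "weibull")) {
    for (m in c(0.01, 0.05, 0.1, 0.3)) {
      for (s in c(5, 10, 25, 100, 200)) {
        cp <- solve_curve(form, m, s)
        p <- learning_probability(seq_len(s + 10), cp)
        expect_lt(abs(p[1] - m), 1e-12)
        expect_lte(p[s], 0.05 * m + 1e-12)
        expect_true(all(diff(p[seq_len(s)]) <= 1e-12)) # monotone non-increasing
        expect_true(all(p[(s + 1):(s + 10)] == 0))     # truncation to exactly 0
      }
    }
  }
})

test_that("unsupported forms and invalid case numbers error", {
  expect_error(solve_curve("logistic", 0.1, 10), "supported")
  cp <- solve_curve("power", 0.1, 10)
  expect_error(learning_probability(0, cp), ">= 1")
})

test_that("magnitude resolution follows the arm-specific mean risk", {
  led <- tibble::tibble(treatment = c(1L, 1L, 0L, 0L),
                        p_pt = c(0.10, 0.14, 0.5, 0.5))
  rel <- learning_spec("provider", "novel", "exponential", 0.5, "relative", 25)
  expect_equal(resolve_magnitude(rel, led), 0.5 * 0.12)
  abs_ <- learning_spec("provider", "novel", "exponential", 0.05, "absolute", 25)
  expect_equal(resolve_magnitude(abs_, led), 0.05)
  zero <- learning_spec("provider", "novel", "exponential", 0, "relative", 25)
  expect_equal(resolve_magnitude(zero, led), 0)
  none <- learning_spec("provider", "reference", "power", 0.3, "relative", 10)
  led0 <- dplyr::filter(led, treatment == 1L)
  expect_error(resolve_magnitude(none, led0), "no patients")
})

test_that("arms without a learning spec carry zero learning risk", {
  cfg <- quick_config(
    n_institutions = 3, seed = 13,
    learning = list(learning_spec("provider", "novel", "exponential",
                                  0.5, "relative", 25))
  )
  ds <- simulate_cohort(cfg)
  tr <- ds$truth
  expect_true(all(tr$p_prov[tr$treatment == 0] == 0))
  expect_true(all(tr$p_inst == 0))
  # novel patients within the learning window carry positive risk
  expect_true(all(tr$p_prov[tr$treatment == 1 & tr$CN_prov <= 25] > 0))
  expect_true(all(tr$p_prov[tr$treatment == 1 & tr$CN_prov > 25] == 0))
})

test_that("reference-arm learning is supported symmetrically", {
  cfg <- quick_config(
    n_institutions = 3, seed = 14,
    learning = list(learning_spec("provider", "reference", "power",
                                  0.4, "relative", 10))
  )
  tr <- simulate_cohort(cfg)$truth
  expect_true(any(tr$p_prov[tr$treatment == 0] > 0))
  expect_true(all(tr$p_prov[tr$treatment == 1] == 0))
})

test_that("curve preview tabulates the curve including truncation", {
  pv <- curve_preview("weibull", 0.08, 20)
  expect_equal(pv$p[1], 0.08, tolerance = 1e-12)
  expect_true(all(pv$p[pv$CN > 20] == 0))
  expect_equal(nrow(pv), 24)
})
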