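test_that("realized summaries report calibrated quantities and sane CIs", {
  cfg <- quick_config(n_institutions = 15, prevalence = 0.5,
                      event_rate = 0.10, treatment_or = 2.0, seed = 41)
  ds <- simulate_cohort(cfg)
  s <- summarize_dataset(ds$truth, cfg)
  g <- glance(s)
  expect_equal(g$n, ds$meta$n)
  expect_lt(abs(g$realized_prevalence - 0.5), 0.03)
  expect_lt(abs(g$realized_event_rate - 0.10), 0.02)
  expect_true(g$ci_low <= g$or_estimate && g$or_estimate <= g$ci_high)
  expect_identical(g$covered, g$ci_low <= 2 && 2 <= g$ci_high)
  td <- tidy(s)
  expect_equal(td$estimate, g$or_estimate)
})

test_that("feature comparison is calibrated under the null and powered under shift", {
  cube <- make_reference_cube(n = 3000, seed = 2)
  # null: a bootstrap of the reference is the reference distribution
  set.seed(77)
  boot <- dplyr::slice_sample(cube, n = 3000, replace = TRUE)
  cmp <- compare_features(boot, cube)
  ok <- cmp[!cmp$skipped, ]
  expect_gte(mean(!ok$flagged), 0.95)

  # power sanity: a +2 SD location shift on one feature is flagged
  shifted <- boot
  shifted$age <- shifted$age + 2 * sd(cube$age)
  cmp2 <- compare_features(shifted, cube)
  expect_true(any(cmp2$flagged[cmp2$feature == "age" & cmp2$test == "wilcoxon"]))

  # degenerate feature skipped; disjoint categorical levels error
  degen <- boot
  degen$male <- 1
  cmp3 <- compare_features(degen, cube)
  expect_true(cmp3$skipped[cmp3$feature == "male"])
  s2 <- tibble::tibble(grp = rep("x", 50))
  r2 <- tibble::tibble(grp = rep(c("a", "b"), 25))
  expect_error(compare_features(s2, r2), "grp")
})

test_that("coverage experiment pools CI coverage near the nominal level", {
  grid <- list(
    quick_config(n_institutions = 4, treatment_or = 1.0, seed = 1),
    quick_config(n_institutions = 4, treatment_or = 2.0, seed = 1)
  )
  cov <- coverage_experiment(grid, reps = 10, seed = 17)
  expect_equal(nrow(cov), 20)
  g <- glance(cov)
  expect_gte(g$coverage, 0.8) # 20 replicates: a loose binomial bound
  expect_true(all(cov$ci_low <= cov$ci_high))
  expect_true(all(cov$covered == (cov$ci_low <= cov$specified_or &
                                    cov$specified_or <= cov$ci_high)))
})

test_that("case-series curves expose injected learning and stay flat without it", {
  learn <- learning_spec("provider", "novel", "exponential", 0.6,
                         "relative", 25)
  with_l <- simulate_cohort(quick_config(n_institutions = 20, n_years = 4,
                                         seed = 71, learning = list(learn)))
  no_l <- simulate_cohort(quick_config(n_institutions = 20, n_years = 4,
                                       seed = 71))
  curves <- case_series_curve(with_l$truth, no_l$truth, cn_max = 45)
  expect_setequal(unique(curves$group),
                  c("reference", "novel_no_learning", "novel_with_learning"))
  expect_true(all(curves$estimate >= 0 & curves$estimate <= 1))
  expect_true(all(curves$conf.low <= curves$estimate &
                    curves$estimate <= curves$conf.high))

  wl <- curves[curves$group == "novel_with_learning", ]
  nl <- curves[curves$group == "novel_no_learning", ]
  # early elevation, late agreement
  expect_gt(wl$estimate[1], nl$conf.high[1])
  expect_lt(abs(wl$estimate[42] - nl$estimate[42]), 0.05)
  st <- stabilization_case(curves)
  expect_true(is.finite(st) && st <= 42)

  # flat without learning: novel curve varies little around its mean
  flat <- case_series_curve(no_l$truth, cn_max = 40)
  nv <- flat[flat$group == "novel_no_learning", ]
  expect_lt(max(nv$estimate) - min(nv$estimate), 0.06)

  expect_error(case_series_curve(dplyr::slice_head(no_l$truth, n = 60)),
               "fewer than 50")
})

test_that("plot methods return ggplot objects", {
  no_l <- simulate_cohort(quick_config(n_institutions = 8, seed = 3))
  curves <- case_series_curve(no_l$truth, cn_max = 20)
  expect_s3_class(autoplot(curves), "ggplot")
  expect_s3_class(plot_volume_mix(build_roster(tiny_cohort(5), 1)), "ggplot")
  expect_s3_class(plot_learning_curve("exponential", 0.05, 25), "ggplot")
})
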