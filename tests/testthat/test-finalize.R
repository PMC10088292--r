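test_that("label noise flips exactly the requested count", {
  out <- rep(0L, 10000)
  expect_identical(apply_noise(out, 0, seed = 1), out)
  expect_identical(apply_noise(out, 1, seed = 1), rep(1L, 10000))
  noisy <- apply_noise(out, 0.05, seed = 2)
  expect_equal(sum(noisy != out), 500)
  # flips are 0<->1 in both directions
  mixed <- rep(c(0L, 1L), 5000)
  noisy2 <- apply_noise(mixed, 0.1, seed = 3)
  flipped <- which(noisy2 != mixed)
  expect_equal(length(flipped), 1000)
  expect_true(all(noisy2[flipped] == 1L - mixed[flipped]))
})

test_that("missingness masks exactly the requested cell count, MCAR", {
  feats <- tibble::as_tibble(as.data.frame(matrix(rnorm(1000), 100, 10)))
  expect_identical(apply_missingness(feats, 0, seed = 1), feats)
  masked <- apply_missingness(feats, 0.1, seed = 1)
  expect_equal(sum(is.na(masked)), 100)

  # MCAR oracle: per-row missingness count is unrelated to outcome
  cfg <- quick_config(
    n_institutions = 12, seed = 33,
    finalization = finalization_spec(missing_fraction = 0.15)
  )
  ds <- simulate_cohort(cfg)
  miss <- rowSums(is.na(ds$public[, c("x_age", "x_sofa", "x_diabetes")]))
  fit <- glm(ds$public$outcome ~ miss, family = binomial())
  ci <- suppressMessages(confint.default(fit))["miss", ]
  expect_gt(0, ci[1])
  expect_lt(0, ci[2])
})

test_that("omitted variables vanish from the public file only", {
  cfg <- quick_config(
    n_institutions = 3, seed = 4,
    finalization = finalization_spec(omitted_features = c("sofa", "diabetes"))
  )
  ds <- simulate_cohort(cfg)
  expect_false(any(c("x_sofa", "x_diabetes") %in% names(ds$public)))
  expect_true(all(c("x_sofa", "x_diabetes") %in% names(ds$truth)))
  expect_true("x_age" %in% names(ds$public))
  expect_error(drop_omitted(tibble::tibble(a = 1), "b"), "unknown")
  expect_identical(drop_omitted(tibble::tibble(a = 1), character()),
                   tibble::tibble(a = 1))
})

test_that("finalization leaves the truth table's latent columns untouched", {
  base <- simulate_cohort(quick_config(n_institutions = 3, seed = 8))
  noisy <- simulate_cohort(quick_config(
    n_institutions = 3, seed = 8,
    finalization = finalization_spec(noise_fraction = 0.1,
                                     missing_fraction = 0.2,
                                     omitted_features = "sofa")
  ))
  for (col in c("p_pt", "p_prov", "p_inst", "p_event", "CN_prov", "CN_inst",
                "x_age", "x_sofa", "outcome_pre_noise")) {
    expect_identical(base$truth[[col]], noisy$truth[[col]])
  }
  expect_false(anyNA(noisy$truth))
  # with no finalization, public and truth outcomes agree
  expect_identical(base$public$outcome, base$truth$outcome_pre_noise)
})

test_that("omitting a confounder biases the naive treatment estimate", {
  # strong confounder: raises both novel-treatment odds and outcome odds
  cfg <- simulation_config(
    cohort = tiny_cohort(14),
    features = small_feature_spec(),
    treatment = treatment_model(0.5, c(diabetes = 4)),
    outcome = outcome_model(0.15, 1.5, c(diabetes = 4)),
    finalization = finalization_spec(omitted_features = "diabetes"),
    seed = 55
  )
  bias <- vapply(1:6, function(i) {
    ds <- simulate_cohort(cfg, seed = 50 + i)
    naive <- glm(outcome ~ x_age + treatment, family = binomial(),
                 data = ds$public)
    adj <- glm(outcome ~ x_age + x_diabetes + treatment, family = binomial(),
               data = ds$truth)
    coef(naive)["treatment"] - coef(adj)["treatment"]
  }, 0)
  expect_gt(mean(bias), 0) # naive estimate inflated toward the confounder
})
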