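flat_features <- function(n, p_feat = 0.5, seed = 1) {
  # one binary feature with known prevalence and identity scaling
  x <- tibble::tibble(flag = as.numeric(seq_len(n) <= round(p_feat * n)))
  attr(x, "scaling") <- tibble::tibble(column = "flag", center = 0, scale = 1)
  x
}

test_that("treatment intercept calibration hits closed forms", {
  x <- flat_features(1000)
  a <- calibrate_treatment_intercept(x, treatment_model(0.5))
  expect_equal(as.numeric(a), 0, tolerance = 1e-10)
  a2 <- calibrate_treatment_intercept(x, treatment_model(0.25))
  expect_equal(as.numeric(a2), log(1 / 3), tolerance = 1e-10)
  expect_lt(abs(mean(attr(a2, "p")) - 0.25), 1e-10)
})

test_that("intercept with feature effects matches a brute-force grid search", {
  x <- flat_features(2000, p_feat = 0.5)
  model <- treatment_model(0.25, c(flag = 2))
  a <- as.numeric(calibrate_treatment_intercept(x, model))
  # independent oracle: dense grid on alpha, pick the best
  grid <- seq(-4, 2, by = 1e-5)
  obj <- abs(0.5 * plogis(grid) + 0.5 * plogis(grid + log(2)) - 0.25)
  a_star <- grid[which.min(obj)]
  expect_lt(abs(a - a_star), 1e-4) # grid resolution bound
  expect_lt(abs(mean(plogis(a + log(2) * x$flag)) - 0.25), 1e-10)
})

test_that("realized prevalence concentrates on the target", {
  x <- flat_features(12000)
  out <- assign_treatment(x, treatment_model(0.25, c(flag = 1.5)), seed = 3)
  expect_lt(abs(mean(out$treatment) - 0.25), 0.02)
  # symmetric null model at 0.5
  outs <- vapply(1:30, function(i) {
    mean(assign_treatment(flat_features(400), treatment_model(0.5),
                          seed = i)$treatment)
  }, 0)
  expect_lt(abs(mean(outs) - 0.5), 0.02)
})

test_that("case-series bookkeeping reproduces the worked micro example", {
  # institution with two providers; provider B's first novel case arrives
  # after nine novel cases have accrued at the institution
  led <- tibble::tibble(
    patient_id = 1:10,
    provider_id = c(rep("A", 9), "B"),
    institution_id = 1,
    year = c(rep(1, 9), 2), # provider B's case in a later year: order is fixed
    treatment = rep(1L, 10)
  )
  idx <- index_case_series(led, seed = 1)
  b <- idx[idx$provider_id == "B", ]
  expect_equal(b$CN_prov, 1L)
  expect_equal(b$CN_inst, 10L)
})

test_that("single-provider institutions have CN_inst equal to CN_prov", {
  led <- tibble::tibble(
    patient_id = 1:40,
    provider_id = rep(1:2, each = 20),
    institution_id = rep(1:2, each = 20), # one provider per institution
    year = rep(1:2, 20),
    treatment = rep(c(0L, 1L), 20)
  )
  idx <- index_case_series(led, seed = 2)
  expect_identical(idx$CN_inst, idx$CN_prov)
})

test_that("case numbers are contiguous, ordered, and never mix arms", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 200
    led <- tibble::tibble(
      patient_id = seq_len(n),
      provider_id = sample(1:6, n, replace = TRUE),
      institution_id = NA_integer_,
      year = sample(1:3, n, replace = TRUE),
      treatment = rbinom(n, 1, 0.4)
    )
    led$institution_id <- (led$provider_id - 1) %/% 2 + 1
    idx <- index_case_series(led, seed = rep)

    # brute-force recount: within (provider, treatment), CNs are 1..m in the
    # global order; same within (institution, treatment)
    for (gcols in list(c("provider_id", "treatment"),
                       c("institution_id", "treatment"))) {
      cncol <- if (gcols[1] == "provider_id") "CN_prov" else "CN_inst"
      grp <- split(seq_len(n), idx[gcols])
      for (g in grp) {
        if (!length(g)) next
        expect_identical(sort(idx[[cncol]][g]), seq_along(g))
        expect_identical(idx[[cncol]][g], seq_along(g)) # already in order
      }
    }
    expect_true(all(idx$CN_inst >= idx$CN_prov))

    # later-year same-provider same-arm patients always rank later
    chk <- idx |>
      dplyr::group_by(provider_id, treatment) |>
      dplyr::summarise(ok = all(diff(CN_prov[order(year)] ) > 0 |
                                  diff(year[order(year)]) == 0),
                       .groups = "drop")
    expect_true(all(chk$ok))

    # arm totals: sum over providers of max CN equals arm size
    tot <- idx |>
      dplyr::filter(treatment == 1L) |>
      dplyr::group_by(provider_id) |>
      dplyr::summarise(m = max(CN_prov), .groups = "drop")
    expect_equal(sum(tot$m), sum(idx$treatment == 1L))
  }
})
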