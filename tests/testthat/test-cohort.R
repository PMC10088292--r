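test_that("provider counts follow the institution mix exactly", {
  cohort <- cohort_config(
    30,
    data.frame(providers = c(10, 5), fraction = c(0.5, 0.5)),
    data.frame(lo = c(20, 5), hi = c(30, 15), fraction = c(0.5, 0.5)),
    n_years = 2
  )
  roster <- build_roster(cohort, seed = 1)
  per_inst <- table(table(roster$institution_id))
  expect_equal(unname(per_inst[["10"]]), 15)
  expect_equal(unname(per_inst[["5"]]), 15)
  expect_equal(nrow(roster), 225)
})

test_that("entry modes set entry years as specified", {
  single <- build_roster(tiny_cohort(5, n_years = 4, entry_mode = "single"), 2)
  expect_true(all(single$entry_year == 1L))
  # volumes are zero before entry and positive from entry on
  annual <- build_roster(tiny_cohort(6, n_years = 4, entry_mode = "annual"), 3)
  vols <- as.matrix(dplyr::select(annual, dplyr::starts_with("volume_y")))
  for (i in seq_len(nrow(annual))) {
    ey <- annual$entry_year[i]
    if (ey > 1) expect_true(all(vols[i, seq_len(ey - 1)] == 0))
    expect_true(all(vols[i, ey:4] > 0))
  }
  # 10-provider institution over 4 years: 5 start in year 1, remainder (2,2,1)
  counts <- annual |>
    dplyr::group_by(institution_id) |>
    dplyr::summarise(k = dplyr::n(),
                     sched = list(tabulate(entry_year, 4)))
  ten <- counts[counts$k == 10, ]
  expect_gt(nrow(ten), 0)
  for (s in ten$sched) expect_equal(s, c(5L, 2L, 2L, 1L))
})

test_that("sample size is the exact sum of provider-year volumes", {
  roster <- tibble::tibble(
    provider_id = 1:2, institution_id = c(1, 1), entry_year = c(1, 1),
    volume_y1 = c(10L, 20L)
  )
  expect_equal(total_sample_size(roster), 30L)
  roster2 <- tibble::tibble(
    provider_id = 1, institution_id = 1, entry_year = 1,
    volume_y1 = 10L, volume_y2 = 10L
  )
  expect_equal(total_sample_size(roster2), 20L)

  r <- build_roster(tiny_cohort(8, n_years = 3, entry_mode = "annual"), 7)
  led <- assign_patients(r)
  expect_equal(nrow(led), total_sample_size(r))
  # per provider-year conservation
  vols <- as.matrix(dplyr::select(r, dplyr::starts_with("volume_y")))
  got <- led |> dplyr::count(provider_id, year)
  for (j in seq_len(nrow(got))) {
    expect_equal(got$n[j], unname(vols[got$provider_id[j], got$year[j]]))
  }
  # institution totals are sums of their providers' volumes
  inst <- led |> dplyr::count(institution_id)
  expected <- rowsum(rowSums(vols), r$institution_id)
  expect_equal(inst$n, as.vector(expected[as.character(inst$institution_id), ]))
})

test_that("providers entering late have no earlier patients", {
  r <- build_roster(tiny_cohort(6, n_years = 3, entry_mode = "annual"), 11)
  led <- assign_patients(r)
  late <- r$provider_id[r$entry_year == 2]
  if (length(late)) {
    expect_equal(sum(led$provider_id %in% late & led$year == 1), 0)
  }
})

test_that("evaluation-style rosters land in the plausible size band", {
  # institutions 5..30, 2 or 4 years, bimodal provider/volume mixes
  for (ni in c(5, 30)) {
    for (ny in c(2, 4)) {
      r <- build_roster(tiny_cohort(ni, n_years = ny), seed = ni * ny)
      n <- total_sample_size(r)
      expect_gte(n, 100)
      expect_lte(n, 16000) # soft band around the observed 559..14,690 range
    }
  }
})

test_that("realized volume mix recovers the configured class fractions", {
  # high (20-30) vs low (5-15) volume classes at 50/50 across many rosters
  set.seed(1)
  counts <- c(high = 0, low = 0)
  for (i in 1:500) {
    r <- build_roster(tiny_cohort(2), seed = i)
    vols <- as.matrix(dplyr::select(r, dplyr::starts_with("volume_y")))
    v <- vols[vols > 0]
    counts["high"] <- counts["high"] + sum(v >= 20)
    counts["low"] <- counts["low"] + sum(v <= 15)
  }
  prop_high <- counts[["high"]] / sum(counts)
  expect_lt(abs(prop_high - 0.5), 0.03)
  # ranges never violated
  r <- build_roster(tiny_cohort(10), seed = 99)
  vols <- as.matrix(dplyr::select(r, dplyr::starts_with("volume_y")))
  v <- vols[vols > 0]
  expect_true(all((v >= 20 & v <= 30) | (v >= 5 & v <= 15)))
})
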