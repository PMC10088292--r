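# Shared builders for small test cohorts. Everything is generated in code;
# no fixture files.

tiny_cohort <- function(n_institutions = 4, n_years = 2,
                        entry_mode = "single",
                        providers = c(10, 5), volumes = list(c(20, 30), c(5, 15))) {
  cohort_config(
    n_institutions = n_institutions,
    provider_mix = data.frame(providers = providers,
                              fraction = rep(1 / length(providers), length(providers))),
    volume_mix = data.frame(
      lo = vapply(volumes, `[`, 0, 1),
      hi = vapply(volumes, `[`, 0, 2),
      fraction = rep(1 / length(volumes), length(volumes))
    ),
    n_years = n_years,
    entry_mode = entry_mode
  )
}

small_feature_spec <- function() {
  feature_spec(
    features = list(
      list(name = "age", type = "continuous",
           dist = list(family = "normal", mean = 62, sd = 16)),
      list(name = "sofa", type = "continuous",
           dist = list(family = "gamma", shape = 2, rate = 0.5)),
      list(name = "diabetes", type = "binary", p = 0.3)
    ),
    correlations = list(list("age", "diabetes", 0.2), list("age", "sofa", 0.3))
  )
}

quick_config <- function(n_institutions = 6, n_years = 2,
                         prevalence = 0.5, event_rate = 0.10,
                         treatment_or = 2.0, learning = list(),
                         finalization = finalization_spec(), seed = 1L,
                         entry_mode = "single") {
  simulation_config(
    cohort = tiny_cohort(n_institutions, n_years, entry_mode),
    features = small_feature_spec(),
    treatment = treatment_model(prevalence, c(age = 1.3, diabetes = 1.5)),
    outcome = outcome_model(event_rate, treatment_or,
                            c(age = 1.4, diabetes = 1.6)),
    learning = learning,
    finalization = finalization,
    seed = seed
  )
}

# ledger skeleton with fixed structure for case-series tests
micro_ledger <- function() {
  tibble::tibble(
    patient_id = 1:12,
    provider_id = c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3, 3, 3),
    institution_id = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2),
    year = rep(1:2, 6),
    treatment = c(1, 0, 1, 1, 1, 0, 0, 1, 1, 0, 0, 1)
  )
}
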