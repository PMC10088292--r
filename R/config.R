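#' Cohort structure specification
#'
#' Describes who treats how many patients, where, and starting when: the
#' number of institutions, the mixture of provider counts per institution,
#' the mixture of annual case-volume classes across providers, the number of
#' simulated years, and whether providers all enter in year one or are
#' staggered annually.
#'
#' @param n_institutions Number of institutions (>= 1).
#' @param provider_mix Data frame with columns `providers` (providers per
#'   institution) and `fraction` (fraction of institutions); fractions must
#'   sum to 1. Bimodal mixes (e.g. large 10-provider and small 5-provider
#'   institutions in equal shares) are the typical use.
#' @param volume_mix Data frame with columns `lo`, `hi` (inclusive annual
#'   case-volume range) and `fraction` (fraction of providers); fractions
#'   must sum to 1.
#' @param n_years Number of simulated years (>= 1).
#' @param entry_mode `"single"` (all providers active from year 1) or
#'   `"annual"` (half enter in year 1, the rest spread evenly over later
#'   years).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_institutions,
                          provider_mix,
                          volume_mix,
                          n_years = 2,
                          entry_mode = c("single", "annual")) {
  entry_mode <- match.arg(entry_mode)
  out <- structure(
    list(
      n_institutions = as.integer(n_institutions),
      provider_mix = tibble::as_tibble(provider_mix),
      volume_mix = tibble::as_tibble(volume_mix),
      n_years = as.integer(n_years),
      entry_mode = entry_mode
    ),
    class = "cohort_config"
  )
  validate_cohort_config(out)
}

validate_cohort_config <- function(x) {
  if (x$n_institutions < 1L) stop("`n_institutions` must be >= 1", call. = FALSE)
  if (x$n_years < 1L) stop("`n_years` must be >= 1", call. = FALSE)
  pm <- x$provider_mix
  if (!all(c("providers", "fraction") %in% names(pm))) {
    stop("`provider_mix` needs columns `providers` and `fraction`", call. = FALSE)
  }
  vm <- x$volume_mix
  if (!all(c("lo", "hi", "fraction") %in% names(vm))) {
    stop("`volume_mix` needs columns `lo`, `hi` and `fraction`", call. = FALSE)
  }
  if (abs(sum(pm$fraction) - 1) > 1e-9) {
    stop("`provider_mix` fractions must sum to 1", call. = FALSE)
  }
  if (abs(sum(vm$fraction) - 1) > 1e-9) {
    stop("`volume_mix` fractions must sum to 1", call. = FALSE)
  }
  if (any(pm$providers < 1) || any(vm$lo < 1)) {
    stop("provider counts and case volumes must be >= 1", call. = FALSE)
  }
  if (any(vm$lo > vm$hi)) stop("volume ranges need `lo` <= `hi`", call. = FALSE)
  x
}

#' Treatment-assignment model specification
#'
#' The probability of receiving the novel (vs reference) treatment follows a
#' logistic model whose intercept is calibrated so the realized population
#' prevalence matches `prevalence`; `odds_ratios` give per-feature assignment
#' odds ratios (novel vs reference), features not listed have OR 1.
#' Continuous features enter standardized (per generating-pool SD), so each
#' OR is "per 1 SD".
#'
#' @param prevalence Target proportion of patients on the novel treatment,
#'   in (0, 1).
#' @param odds_ratios Named numeric vector of assignment odds ratios.
#' @return A `treatment_model` list.
#' @export
treatment_model <- function(prevalence, odds_ratios = NULL) {
  or <- as_or_vector(odds_ratios)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(prevalence = as.numeric(prevalence), odds_ratios = or),
    class = "treatment_model"
  )
}

#' Adverse-outcome risk model specification
#'
#' Patient/treatment risk `p_pt` follows a logistic model: per-feature odds
#' ratios, a treatment odds ratio (novel vs reference), and an intercept
#' calibrated so the mean of `p_pt` over the generated population equals
#' `event_rate` (the whole-population adverse outcome rate before any
#' learning effects).
#'
#' @param event_rate Target population adverse-outcome rate, in (0, 1).
#' @param treatment_or Odds ratio for the novel treatment (> 0).
#' @param odds_ratios Named numeric vector of feature odds ratios (per 1 SD
#'   for continuous features).
#' @return An `outcome_model` list.
#' @export
outcome_model <- function(event_rate, treatment_or = 1, odds_ratios = NULL) {
  or <- as_or_vector(odds_ratios)
  if (!is.numeric(event_rate) || event_rate <= 0 || event_rate >= 1) {
    stop("`event_rate` must lie in (0, 1)", call. = FALSE)
  }
  if (treatment_or <= 0) stop("`treatment_or` must be > 0", call. = FALSE)
  structure(
    list(
      event_rate = as.numeric(event_rate),
      treatment_or = as.numeric(treatment_or),
      odds_ratios = or
    ),
    class = "outcome_model"
  )
}

as_or_vector <- function(odds_ratios) {
  if (is.null(odds_ratios) || length(odds_ratios) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  or <- unlist(odds_ratios)
  if (is.null(names(or)) || any(!nzchar(names(or)))) {
    stop("odds ratios must be a named vector (feature name -> OR)", call. = FALSE)
  }
  if (any(or <= 0)) stop("all odds ratios must be > 0", call. = FALSE)
  or
}

#' Learning-curve specification
#'
#' Experiential-learning risk for one hierarchy level and one treatment arm.
#' The `magnitude` is the learning-associated adverse-outcome probability at
#' the first case; it may be absolute, or relative to the mean patient/
#' treatment risk among patients on that arm. `speed` is the number of cases
#' to mastery: the curve is solved so risk at case `speed` has fallen to 5%
#' of the initial magnitude ("95% of asymptotic performance") and is
#' truncated to exactly 0 beyond it.
#'
#' @param level `"provider"` or `"institution"`.
#' @param treatment `"novel"` or `"reference"` -- either arm may carry
#'   learning.
#' @param form `"power"`, `"exponential"`, `"reciprocal"` or `"weibull"`.
#' @param magnitude Initial learning-associated probability (absolute) or a
#'   fraction of mean arm risk (relative).
#' @param magnitude_type `"relative"` or `"absolute"`.
#' @param speed Cases to mastery (>= 2).
#' @param shape Shape parameter for the Weibull form (ignored otherwise).
#' @return A `learning_spec` list.
#' @export
learning_spec <- function(level = c("provider", "institution"),
                          treatment = c("novel", "reference"),
                          form = c("exponential", "power", "reciprocal", "weibull"),
                          magnitude,
                          magnitude_type = c("relative", "absolute"),
                          speed,
                          shape = 1.5) {
  level <- match.arg(level)
  treatment <- match.arg(treatment)
  form <- match.arg(form)
  magnitude_type <- match.arg(magnitude_type)
  if (magnitude < 0) stop("`magnitude` must be >= 0", call. = FALSE)
  if (magnitude_type == "absolute" && magnitude >= 1) {
    stop("absolute `magnitude` must lie in [0, 1)", call. = FALSE)
  }
  if (speed < 2) stop("`speed` must be >= 2", call. = FALSE)
  structure(
    list(
      level = level, treatment = treatment, form = form,
      magnitude = as.numeric(magnitude), magnitude_type = magnitude_type,
      speed = as.integer(speed), shape = as.numeric(shape)
    ),
    class = "learning_spec"
  )
}

#' Data-finalization options
#'
#' Optional departures from the clean generated dataset: flip the outcome
#' label for a fixed fraction of patients (noise), mask a fixed fraction of
#' feature cells completely at random, and drop named features from the
#' public file (omitted variables). The latent ground-truth file is never
#' altered.
#'
#' @param noise_fraction Fraction of patients whose outcome label is
#'   flipped, in \[0, 1\].
#' @param missing_fraction Fraction of feature cells masked, in \[0, 1\].
#' @param omitted_features Character vector of feature names dropped from
#'   the public dataset.
#' @param exact_counts If `TRUE` (default) exactly `round(fraction * N)`
#'   patients/cells are affected; if `FALSE`, independent per-unit Bernoulli
#'   selection is used instead.
#' @return A `finalization_spec` list.
#' @export
finalization_spec <- function(noise_fraction = 0,
                              missing_fraction = 0,
                              omitted_features = character(),
                              exact_counts = TRUE) {
  if (noise_fraction < 0 || noise_fraction > 1 ||
      missing_fraction < 0 || missing_fraction > 1) {
    stop("finalization fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      noise_fraction = as.numeric(noise_fraction),
      missing_fraction = as.numeric(missing_fraction),
      omitted_features = as.character(omitted_features),
      exact_counts = isTRUE(exact_counts)
    ),
    class = "finalization_spec"
  )
}

#' Full simulation configuration
#'
#' Bundles the cohort structure, the feature source (a [feature_spec()] or a
#' path to a reference cube CSV), the treatment and outcome models, any
#' learning specifications (at most one per level x treatment pair), the
#' finalization options, the master seed and the replicate count.
#'
#' @param cohort A [cohort_config()].
#' @param features A [feature_spec()], or a path to a reference cube CSV
#'   from which marginals and correlations are estimated.
#' @param treatment A [treatment_model()].
#' @param outcome An [outcome_model()].
#' @param learning List of [learning_spec()] objects (possibly empty).
#' @param finalization A [finalization_spec()].
#' @param seed Master integer seed.
#' @param n_replicates Number of replicate datasets (>= 1).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(cohort,
                              features,
                              treatment,
                              outcome,
                              learning = list(),
                              finalization = finalization_spec(),
                              seed = 1L,
                              n_replicates = 1L) {
  if (inherits(learning, "learning_spec")) learning <- list(learning)
  cfg <- structure(
    list(
      cohort = cohort,
      features = features,
      treatment = treatment,
      outcome = outcome,
      learning = learning,
      finalization = finalization,
      seed = as.integer(seed),
      n_replicates = as.integer(n_replicates)
    ),
    class = "simulation_config"
  )
  validate_config(cfg)
}

#' @rdname simulation_config
#' @param x Object to validate.
#' @export
validate_config <- function(x) {
  stopifnot(inherits(x, "simulation_config"))
  validate_cohort_config(x$cohort)
  if (!inherits(x$treatment, "treatment_model")) {
    stop("`treatment` must be a treatment_model()", call. = FALSE)
  }
  if (!inherits(x$outcome, "outcome_model")) {
    stop("`outcome` must be an outcome_model()", call. = FALSE)
  }
  if (!inherits(x$finalization, "finalization_spec")) {
    stop("`finalization` must be a finalization_spec()", call. = FALSE)
  }
  if (!(inherits(x$features, "feature_spec") ||
        (is.character(x$features) && length(x$features) == 1))) {
    stop("`features` must be a feature_spec() or a cube file path", call. = FALSE)
  }
  if (x$n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  keys <- vapply(x$learning, function(l) paste(l$level, l$treatment), "")
  if (anyDuplicated(keys)) {
    stop("at most one learning_spec per (level, treatment) pair; duplicated: ",
         keys[duplicated(keys)][1], call. = FALSE)
  }
  feat_names <- feature_names_of(x$features)
  if (!is.null(feat_names)) {
    bad <- setdiff(x$finalization$omitted_features, feat_names)
    if (length(bad)) {
      stop("omitted_features not among declared features: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    check_or_names(names(x$treatment$odds_ratios), feat_names, "treatment")
    check_or_names(names(x$outcome$odds_ratios), feat_names, "outcome")
  }
  x
}

feature_names_of <- function(features) {
  if (inherits(features, "feature_spec")) {
    vapply(features$features, `[[`, "", "name")
  } else {
    NULL # cube path: names known only after reading
  }
}

check_or_names <- function(or_names, feat_names, model) {
  # allow "feature.level" references to categorical indicator columns
  base <- sub("\\..*$", "", or_names)
  bad <- or_names[!(or_names %in% feat_names | base %in% feat_names)]
  if (length(bad)) {
    stop(sprintf("%s model odds ratios name unknown features: %s",
                 model, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

# ---- YAML serialization -----------------------------------------------------

#' Read and validate a simulation configuration from YAML
#'
#' Every specification parameter maps to a documented key in a nested YAML
#' file; [write_config()] is its inverse, and a parsed config re-serializes
#' to an equivalent config (round-trip). Missing required sections raise a
#' validation error naming the field; optional blocks (`learning`,
#' `finalization`) may be omitted.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated [simulation_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  config_from_list(raw)
}

#' @rdname load_config
#' @param config A [simulation_config()].
#' @return `write_config()` returns `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config_to_list(config), path, precision = 15L)
  invisible(path)
}

config_from_list <- function(raw) {
  need <- function(block, field) {
    if (is.null(block[[field]])) {
      stop("config is missing required field `", field, "`", call. = FALSE)
    }
    block[[field]]
  }
  co <- need(raw, "cohort")
  cohort <- cohort_config(
    n_institutions = need(co, "n_institutions"),
    provider_mix = mix_from_list(need(co, "provider_mix"), c("providers", "fraction")),
    volume_mix = mix_from_list(need(co, "volume_mix"), c("lo", "hi", "fraction")),
    n_years = need(co, "n_years"),
    entry_mode = co$entry_mode %||% "single"
  )
  fe <- need(raw, "features")
  features <- if (!is.null(fe$cube)) {
    fe$cube
  } else {
    feature_spec_from_list(need(fe, "spec"))
  }
  tm <- need(raw, "treatment_model")
  treatment <- treatment_model(
    prevalence = need(tm, "prevalence"),
    odds_ratios = unlist(tm$odds_ratios)
  )
  om <- need(raw, "outcome_model")
  outcome <- outcome_model(
    event_rate = need(om, "event_rate"),
    treatment_or = om$treatment_or %||% 1,
    odds_ratios = unlist(om$odds_ratios)
  )
  learning <- purrr::map(raw$learning %||% list(), function(l) {
    learning_spec(
      level = need(l, "level"), treatment = need(l, "treatment"),
      form = need(l, "form"), magnitude = need(l, "magnitude"),
      magnitude_type = l$magnitude_type %||% "relative",
      speed = need(l, "speed"), shape = l$shape %||% 1.5
    )
  })
  fz <- raw$finalization %||% list()
  finalization <- finalization_spec(
    noise_fraction = fz$noise_fraction %||% 0,
    missing_fraction = fz$missing_fraction %||% 0,
    omitted_features = fz$omitted_features %||% character(),
    exact_counts = fz$exact_counts %||% TRUE
  )
  simulation_config(
    cohort = cohort, features = features, treatment = treatment,
    outcome = outcome, learning = learning, finalization = finalization,
    seed = raw$seed %||% 1L, n_replicates = raw$n_replicates %||% 1L
  )
}

config_to_list <- function(config) {
  co <- config$cohort
  fe <- if (inherits(config$features, "feature_spec")) {
    list(spec = feature_spec_to_list(config$features))
  } else {
    list(cube = unclass(config$features))
  }
  list(
    seed = config$seed,
    n_replicates = config$n_replicates,
    cohort = list(
      n_institutions = co$n_institutions,
      n_years = co$n_years,
      entry_mode = co$entry_mode,
      provider_mix = purrr::transpose(as.list(co$provider_mix)),
      volume_mix = purrr::transpose(as.list(co$volume_mix))
    ),
    features = fe,
    treatment_model = list(
      prevalence = config$treatment$prevalence,
      odds_ratios = as.list(config$treatment$odds_ratios)
    ),
    outcome_model = list(
      event_rate = config$outcome$event_rate,
      treatment_or = config$outcome$treatment_or,
      odds_ratios = as.list(config$outcome$odds_ratios)
    ),
    learning = purrr::map(config$learning, function(l) {
      list(level = l$level, treatment = l$treatment, form = l$form,
           magnitude = l$magnitude, magnitude_type = l$magnitude_type,
           speed = l$speed, shape = l$shape)
    }),
    finalization = list(
      noise_fraction = config$finalization$noise_fraction,
      missing_fraction = config$finalization$missing_fraction,
      omitted_features = as.list(config$finalization$omitted_features),
      exact_counts = config$finalization$exact_counts
    )
  )
}

mix_from_list <- function(x, cols) {
  rows <- purrr::map(x, function(r) tibble::as_tibble(r[cols]))
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
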