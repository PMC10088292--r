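resolve_feature_spec <- function(features) {
  if (inherits(features, "feature_spec")) return(features)
  spec_from_cube(read_cube(features))
}

#' Run the full data-generating pipeline
#'
#' Executes every stage in order: roster building, patient assignment,
#' feature synthesis, treatment assignment and case-series indexing,
#' patient/treatment risk, learning-curve injection, outcome draws and
#' finalization. Each stage draws from its own seeded substream, so the
#' same `(config, seed)` pair always yields byte-identical datasets and
#' changing one stage's options leaves the others' draws untouched.
#'
#' @param config A [simulation_config()].
#' @param seed Master seed; defaults to the config's seed.
#' @param replicate Replicate index (>= 1); each replicate derives its own
#'   master seed deterministically.
#' @return A `learnsim_dataset` object: a list with `public` and `truth`
#'   tibbles, the provider `roster`, the `config`, and `meta` (calibrated
#'   intercepts, solved learning curves, feature-synthesis RMSR, sample
#'   size, replicate seed).
#' @export
simulate_cohort <- function(config, seed = config$seed, replicate = 1L) {
  validate_config(config)
  rseed <- replicate_seed(seed, replicate)

  roster <- build_roster(config$cohort, rseed)
  patients <- assign_patients(roster)
  n <- nrow(patients)

  spec <- resolve_feature_spec(config$features)
  feats <- simulate_features(spec, n, rseed)
  feat_names <- names(feats)
  scaling <- attr(feats, "scaling")

  ledger <- dplyr::bind_cols(patients, feats)
  attr(ledger, "scaling") <- scaling
  ledger <- assign_treatment(ledger, config$treatment, rseed)
  ledger <- index_case_series(ledger, rseed)
  ledger <- patient_risk(ledger, config$outcome)
  ledger <- apply_learning(ledger, config$learning)
  ledger <- draw_outcomes(ledger, rseed)

  fz <- config$finalization
  public_outcome <- apply_noise(ledger$outcome_pre_noise, fz$noise_fraction,
                                rseed, fz$exact_counts)
  ledger$outcome <- public_outcome

  pub_feats <- drop_omitted(ledger[feat_names], fz$omitted_features)
  pub_feats <- apply_missingness(pub_feats, fz$missing_fraction, rseed,
                                 fz$exact_counts)

  id_cols <- c("patient_id", "institution_id", "provider_id", "year")
  public <- dplyr::bind_cols(
    ledger[id_cols],
    prefix_features(pub_feats),
    ledger[c("treatment", "outcome")]
  )
  truth <- dplyr::bind_cols(
    ledger[id_cols],
    prefix_features(ledger[feat_names]),
    ledger[c("treatment", "CN_prov", "CN_inst", "p_treat", "p_pt", "p_prov",
             "p_inst", "p_noevent", "p_event", "outcome_pre_learning",
             "outcome_pre_noise", "outcome")]
  )

  structure(
    list(
      public = public,
      truth = truth,
      roster = roster,
      config = config,
      meta = list(
        n = n,
        seed = rseed,
        replicate = as.integer(replicate),
        treatment_intercept = attr(ledger, "treatment_intercept"),
        outcome_intercept = attr(ledger, "outcome_intercept"),
        curve_params = attr(ledger, "curve_params"),
        feature_rmsr = attr(feats, "rmsr"),
        feature_iterations = attr(feats, "iterations"),
        scaling = scaling
      )
    ),
    class = "learnsim_dataset"
  )
}

prefix_features <- function(df) {
  names(df) <- paste0("x_", names(df))
  df
}

#' @export
print.learnsim_dataset <- function(x, ...) {
  cat("<learnsim_dataset>\n")
  cat("  patients:    ", x$meta$n, "\n")
  cat("  providers:   ", nrow(x$roster), "\n")
  cat("  prevalence:  ", round(mean(x$truth$treatment), 4), "\n")
  cat("  event rate:  ", round(mean(x$truth$outcome), 4), "\n")
  if (length(x$meta$curve_params)) {
    cat("  learning:    ", paste(names(x$meta$curve_params), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a simulated dataset pair
#'
#' The public CSV contains only the observable columns (identifiers, year,
#' non-omitted features with missingness applied as empty fields, treatment,
#' outcome). The truth CSV is always complete: it retains omitted features,
#' unmasked values, case-series indices, every latent probability and the
#' pre-noise / pre-learning outcomes, at full double precision.
#'
#' @param dataset A `learnsim_dataset` from [simulate_cohort()].
#' @param public_path,truth_path Output CSV paths.
#' @return `write_dataset()`: the paths, invisibly. `read_dataset()`: a
#'   list with `public` and/or `truth` tibbles.
#' @export
write_dataset <- function(dataset, public_path, truth_path) {
  utils::write.csv(as.data.frame(dataset$public), public_path,
                   row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(dataset$truth), truth_path,
                   row.names = FALSE, na = "")
  invisible(c(public = public_path, truth = truth_path))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(public_path = NULL, truth_path = NULL) {
  rd <- function(p) {
    if (is.null(p)) return(NULL)
    tibble::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE,
                                      na.strings = ""))
  }
  list(public = rd(public_path), truth = rd(truth_path))
}

#' Simulate all replicates of a configuration to disk
#'
#' Runs [simulate_cohort()] for each replicate in the config and writes
#' `public_<r>.csv` / `truth_<r>.csv` pairs (plus the provider roster) to
#' `out_dir`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; defaults to the config's.
#' @return Tibble with one row per replicate: paths and realized summaries.
#' @export
simulate_to_dir <- function(config, out_dir, seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  purrr::map_dfr(seq_len(config$n_replicates), function(r) {
    ds <- simulate_cohort(config, seed = seed, replicate = r)
    pub <- file.path(out_dir, sprintf("public_%03d.csv", r))
    tru <- file.path(out_dir, sprintf("truth_%03d.csv", r))
    write_dataset(ds, pub, tru)
    utils::write.csv(as.data.frame(ds$roster),
                     file.path(out_dir, sprintf("roster_%03d.csv", r)),
                     row.names = FALSE)
    tibble::tibble(
      replicate = r, n = ds$meta$n, public = pub, truth = tru,
      prevalence = mean(ds$truth$treatment),
      event_rate = mean(ds$truth$outcome)
    )
  })
}
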