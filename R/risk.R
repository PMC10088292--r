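#' Calibrate the outcome-model intercept
#'
#' The population adverse-outcome rate pins the intercept of the logistic
#' risk model: the intercept is solved (to within 1e-10) so that the mean of
#' `p_pt` -- the probability of an adverse outcome due solely to patient
#' features and treatment -- over the realized population equals the
#' specified rate. Calibration happens after treatment assignment and
#' includes the treatment term, so the target is the whole-population rate.
#'
#' @param data Ledger tibble carrying feature columns and `treatment`.
#' @param model An [outcome_model()].
#' @param scaling Scaling metadata; defaults to the tibble's `"scaling"`
#'   attribute.
#' @return Intercept (log-odds scale).
#' @export
calibrate_outcome_intercept <- function(data, model,
                                        scaling = attr(data, "scaling")) {
  lp <- outcome_linear_predictor(data, model, scaling)
  calibrate_intercept(lp, model$event_rate)
}

outcome_linear_predictor <- function(data, model, scaling) {
  X <- feature_model_matrix(data, scaling)
  linear_predictor(X, model$odds_ratios) +
    log(model$treatment_or) * as.numeric(data$treatment)
}

#' Patient/treatment adverse-outcome probability
#'
#' Computes `p_pt`, the independent probability of an adverse outcome due
#' solely to patient features and treatment assignment: feature values are
#' multiplied by their log odds ratios, the treatment term added, and the
#' summed log-odds converted to the probability scale.
#'
#' @inheritParams calibrate_outcome_intercept
#' @param intercept Calibrated intercept; computed via
#'   [calibrate_outcome_intercept()] when `NULL`.
#' @return `data` with column `p_pt` appended and the intercept as
#'   attribute `"outcome_intercept"`.
#' @export
patient_risk <- function(data, model, intercept = NULL,
                         scaling = attr(data, "scaling")) {
  if (is.null(intercept)) {
    intercept <- calibrate_outcome_intercept(data, model, scaling)
  }
  lp <- outcome_linear_predictor(data, model, scaling)
  out <- dplyr::mutate(data, p_pt = stats::plogis(intercept + lp))
  attr(out, "outcome_intercept") <- intercept
  attr(out, "scaling") <- scaling
  out
}
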