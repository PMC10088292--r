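# Expanded, standardized model matrix for the logistic treatment/outcome
# models. `scaling` (from simulate_features) maps expanded column names to
# the generating pool's center/scale; categorical indicators are derived on
# the fly from the decoded feature column.
feature_model_matrix <- function(data, scaling) {
  if (is.null(scaling)) stop("feature scaling metadata is missing", call. = FALSE)
  cols <- purrr::map(seq_len(nrow(scaling)), function(i) {
    cn <- scaling$column[i]
    x <- if (cn %in% names(data)) {
      as.numeric(data[[cn]])
    } else {
      feat <- sub("\\.[^.]*$", "", cn)
      level <- sub("^.*\\.", "", cn)
      if (!feat %in% names(data)) stop("unknown model column: ", cn, call. = FALSE)
      as.numeric(as.character(data[[feat]]) == level)
    }
    (x - scaling$center[i]) / scaling$scale[i]
  })
  m <- do.call(cbind, cols)
  colnames(m) <- scaling$column
  m
}

linear_predictor <- function(X, odds_ratios) {
  if (length(odds_ratios) == 0) return(rep(0, nrow(X)))
  miss <- setdiff(names(odds_ratios), colnames(X))
  if (length(miss)) {
    stop("odds ratios name columns absent from the feature matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  drop(X[, names(odds_ratios), drop = FALSE] %*% log(odds_ratios))
}

# Monotone root-finding for the intercept alpha such that
# mean(plogis(alpha + lp)) = target; |delta| < 1e-10 guaranteed by a
# uniroot solve refined with Newton steps.
calibrate_intercept <- function(lp, target) {
  f <- function(a) mean(stats::plogis(a + lp)) - target
  a <- stats::uniroot(f, c(-50, 50), tol = 1e-14, extendInt = "upX")$root
  for (i in 1:3) {
    p <- stats::plogis(a + lp)
    g <- mean(p * (1 - p))
    if (g <= 0) break
    a <- a - (mean(p) - target) / g
  }
  a
}

#' Calibrate the treatment-assignment intercept
#'
#' Solves for the log-odds intercept at which the mean modeled probability
#' of receiving the novel treatment over the generated population equals
#' the target prevalence (to within 1e-10). Calibration is empirical -- on
#' the realized feature matrix of each dataset -- so small-sample deviation
#' between realized and specified prevalence is carried by the Bernoulli
#' assignment draws, not the model.
#'
#' @param data Feature tibble from [simulate_features()] (or a ledger
#'   containing its columns).
#' @param model A [treatment_model()].
#' @param scaling Scaling metadata; defaults to the tibble's `"scaling"`
#'   attribute.
#' @return Intercept (log-odds scale), with the per-patient probabilities
#'   as attribute `"p"`.
#' @export
calibrate_treatment_intercept <- function(data, model,
                                          scaling = attr(data, "scaling")) {
  X <- feature_model_matrix(data, scaling)
  lp <- linear_predictor(X, model$odds_ratios)
  a <- calibrate_intercept(lp, model$prevalence)
  structure(a, p = stats::plogis(a + lp))
}

#' Assign treatments from the calibrated logistic model
#'
#' Each patient independently receives the novel treatment (`treatment = 1`)
#' with their modeled probability; `treatment = 0` is the reference arm.
#'
#' @inheritParams calibrate_treatment_intercept
#' @param seed Master seed; draws use the `"treatment"` substream.
#' @return `data` with columns `p_treat` and `treatment` appended and the
#'   calibrated intercept as attribute `"treatment_intercept"`.
#' @export
assign_treatment <- function(data, model, seed = 1L,
                             scaling = attr(data, "scaling")) {
  a <- calibrate_treatment_intercept(data, model, scaling)
  p <- attr(a, "p")
  trt <- with_substream(seed, "treatment", {
    as.integer(stats::runif(length(p)) < p)
  })
  out <- dplyr::mutate(data, p_treat = p, treatment = trt)
  attr(out, "treatment_intercept") <- as.numeric(a)
  attr(out, "scaling") <- scaling
  out
}

#' Index treatment-specific case series
#'
#' Patients are ordered chronologically with a single random shuffle within
#' each simulated year, then `CN_prov` and `CN_inst` are read off as
#' cumulative treatment-specific case counts within each provider and each
#' institution. A patient with `CN_prov = 1` and `CN_inst = 10` was their
#' provider's first novel-treatment case but the tenth at the institution.
#'
#' @param data Ledger tibble with `year`, `provider_id`, `institution_id`
#'   and `treatment` columns.
#' @param seed Master seed; the shuffle uses the `"shuffle"` substream.
#' @return The ledger reordered chronologically, with integer columns
#'   `CN_prov` and `CN_inst` appended.
#' @export
index_case_series <- function(data, seed = 1L) {
  stopifnot(all(c("year", "provider_id", "institution_id", "treatment") %in%
                  names(data)))
  atts <- keep_attrs(data)
  ord <- with_substream(seed, "shuffle", {
    order(data$year, sample.int(nrow(data)))
  })
  out <- data[ord, ]
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$provider_id, .data$treatment),
    CN_prov = dplyr::row_number()
  )
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$institution_id, .data$treatment),
    CN_inst = dplyr::row_number()
  )
  out <- dplyr::ungroup(out)
  restore_attrs(out, atts)
}

keep_attrs <- function(data) {
  attributes(data)[c("scaling", "treatment_intercept", "outcome_intercept",
                     "curve_params")]
}

restore_attrs <- function(data, atts) {
  for (nm in names(atts)) {
    if (!is.null(atts[[nm]])) attr(data, nm) <- atts[[nm]]
  }
  data
}
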