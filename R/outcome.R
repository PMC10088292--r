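#' Combine independent risk components into the event probability
#'
#' Adverse outcomes arise from the union of three independent risks:
#' patient/treatment risk, provider learning and institutional learning.
#' The joint probability of *not* experiencing an event is
#' `p_noevent = (1 - p_pt) * (1 - p_prov) * (1 - p_inst)` and the event
#' probability is `p_event = 1 - p_noevent`. The combination is symmetric
#' in its arguments and satisfies
#' `max(p) <= p_event <= p_pt + p_prov + p_inst`.
#'
#' @param p_pt,p_prov,p_inst Probability vectors of equal length, each in
#'   \[0, 1\].
#' @return A tibble with columns `p_noevent` and `p_event`.
#' @export
combine_probabilities <- function(p_pt, p_prov, p_inst) {
  n <- length(p_pt)
  if (length(p_prov) != n || length(p_inst) != n) {
    stop("probability vectors must have equal length", call. = FALSE)
  }
  for (v in list(p_pt, p_prov, p_inst)) {
    if (any(v < 0 | v > 1)) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  p_noevent <- (1 - p_pt) * (1 - p_prov) * (1 - p_inst)
  tibble::tibble(p_noevent = p_noevent, p_event = 1 - p_noevent)
}

#' Draw binary outcomes
#'
#' Independent Bernoulli draws against each patient's event probability.
#' The same uniform draw is also compared against `p_pt` alone, recording
#' the outcome each patient would have had with all learning effects absent
#' (`outcome_pre_learning`); realized pre-learning event rates are
#' estimated from this column. The pre-noise outcome is kept as
#' `outcome_pre_noise` so that label noise applied later remains auditable.
#'
#' @param data Ledger with `p_pt`, `p_prov`, `p_inst`.
#' @param seed Master seed; draws use the `"outcome"` substream.
#' @return `data` with `p_noevent`, `p_event`, `outcome_pre_learning`,
#'   `outcome_pre_noise` and `outcome` appended.
#' @export
draw_outcomes <- function(data, seed = 1L) {
  atts <- keep_attrs(data)
  comb <- combine_probabilities(data$p_pt, data$p_prov, data$p_inst)
  u <- with_substream(seed, "outcome", stats::runif(nrow(data)))
  out <- dplyr::mutate(
    data,
    p_noevent = comb$p_noevent,
    p_event = comb$p_event,
    outcome_pre_learning = as.integer(u < .data$p_pt),
    outcome_pre_noise = as.integer(u < .data$p_event),
    outcome = .data$outcome_pre_noise
  )
  restore_attrs(out, atts)
}
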