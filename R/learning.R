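#' Resolve the initial magnitude of a learning curve
#'
#' An absolute magnitude is returned unchanged. A relative magnitude is the
#' specified fraction of the mean patient/treatment risk `p_pt` among
#' patients assigned to the spec's treatment arm, computed per dataset from
#' the realized population.
#'
#' @param spec A [learning_spec()].
#' @param data Ledger tibble with `p_pt` and `treatment` columns.
#' @return Initial learning-associated probability.
#' @export
resolve_magnitude <- function(spec, data) {
  if (spec$magnitude_type == "absolute") return(spec$magnitude)
  arm <- if (spec$treatment == "novel") 1L else 0L
  sel <- data$treatment == arm
  if (!any(sel)) {
    stop("no patients assigned the ", spec$treatment,
         " treatment; relative learning magnitude is undefined", call. = FALSE)
  }
  spec$magnitude * mean(data$p_pt[sel])
}

# residual risk left at the mastery case: curves are solved so the
# learning-associated probability at `speed` has fallen to 5% of the
# initial magnitude ("95% of asymptotic performance"), then truncated to 0.
.mastery_residual <- 0.05

#' Solve learning-curve parameters from form, magnitude and speed
#'
#' Each curve satisfies two boundary conditions: the value at case 1 equals
#' the initial magnitude `m`, and the value at case `speed` has declined to
#' 5% of `m`; beyond `speed` the curve is truncated to exactly 0 (mastery).
#' Supported forms, with `CN` the treatment-specific case number:
#' \describe{
#'   \item{exponential}{`p = b0 * exp(-b1 * CN)`, so `b1 = log(20)/(speed-1)`
#'     and `b0 = m * exp(b1)`.}
#'   \item{power}{`p = b0 * CN^(-b1)`, so `b0 = m` and
#'     `b1 = log(20)/log(speed)`.}
#'   \item{reciprocal}{`p = b0 * b1 / (CN + b1 - 1)` with `b0 = m` and
#'     `b1 = (speed - 1)/19`.}
#'   \item{weibull}{`p = b0 * exp(-(b1 * (CN - 1))^shape)` with `b0 = m` and
#'     `b1 = log(20)^(1/shape)/(speed - 1)`; `shape` defaults to 1.5.}
#' }
#'
#' @param form One of `"exponential"`, `"power"`, `"reciprocal"`,
#'   `"weibull"`.
#' @param magnitude Initial learning-associated probability, in (0, 1).
#' @param speed Cases to mastery (>= 2); also the truncation case.
#' @param shape Weibull shape parameter.
#' @return A `curve_params` list: `form`, `b0`, `b1`, `shape`,
#'   `truncation_case`, `magnitude`.
#' @export
solve_curve <- function(form, magnitude, speed, shape = 1.5) {
  forms <- c("exponential", "power", "reciprocal", "weibull")
  if (!form %in% forms) {
    stop("unsupported learning-curve form `", form, "`; supported: ",
         paste(forms, collapse = ", "), call. = FALSE)
  }
  stopifnot(magnitude > 0, magnitude < 1, speed >= 2)
  m <- magnitude
  s <- as.numeric(speed)
  r <- -log(.mastery_residual) # log(20)
  par <- switch(form,
    exponential = {
      b1 <- r / (s - 1)
      list(b0 = m * exp(b1), b1 = b1)
    },
    power = list(b0 = m, b1 = r / log(s)),
    reciprocal = {
      # m * b1 / (s + b1 - 1) = residual * m  =>  b1 = residual*(s-1)/(1-residual)
      list(b0 = m, b1 = .mastery_residual * (s - 1) / (1 - .mastery_residual))
    },
    weibull = list(b0 = m, b1 = r^(1 / shape) / (s - 1))
  )
  structure(
    list(form = form, b0 = par$b0, b1 = par$b1,
         shape = if (form == "weibull") shape else NA_real_,
         truncation_case = as.integer(speed), magnitude = m),
    class = "curve_params"
  )
}

#' Evaluate a learning curve at case numbers
#'
#' Applies the solved curve to a vector of 1-based case numbers; values
#' beyond the truncation case are exactly 0 (mastery reached).
#'
#' @param CN Integer vector of case numbers (>= 1).
#' @param params A `curve_params` from [solve_curve()].
#' @return Probability vector, same length as `CN`.
#' @export
learning_probability <- function(CN, params) {
  if (any(CN < 1)) stop("case numbers must be >= 1", call. = FALSE)
  CN <- as.numeric(CN)
  p <- switch(params$form,
    exponential = params$b0 * exp(-params$b1 * CN),
    power = params$b0 * CN^(-params$b1),
    reciprocal = params$b0 * params$b1 / (CN + params$b1 - 1),
    weibull = params$b0 * exp(-(params$b1 * (CN - 1))^params$shape)
  )
  p[CN > params$truncation_case] <- 0
  p
}

#' Attach learning-associated probabilities to a ledger
#'
#' For every learning specification, resolves its magnitude on the realized
#' population, solves the curve, and evaluates it at each affected patient's
#' treatment-specific case number. Patients on a (level, treatment) pair
#' with no specification get probability 0 at that level.
#'
#' @param data Ledger with `p_pt`, `treatment`, `CN_prov`, `CN_inst`.
#' @param learning List of [learning_spec()] objects.
#' @return `data` with columns `p_prov` and `p_inst` appended; solved
#'   curves are attached as attribute `"curve_params"` (a named list keyed
#'   `level:treatment`).
#' @export
apply_learning <- function(data, learning = list()) {
  atts <- keep_attrs(data)
  n <- nrow(data)
  p_prov <- rep(0, n)
  p_inst <- rep(0, n)
  curves <- list()
  for (spec in learning) {
    m <- resolve_magnitude(spec, data)
    if (m == 0) next # null learning: curve disabled
    params <- solve_curve(spec$form, m, spec$speed, spec$shape)
    arm <- if (spec$treatment == "novel") 1L else 0L
    sel <- data$treatment == arm
    cn <- if (spec$level == "provider") data$CN_prov[sel] else data$CN_inst[sel]
    p <- learning_probability(cn, params)
    if (spec$level == "provider") p_prov[sel] <- p else p_inst[sel] <- p
    curves[[paste(spec$level, spec$treatment, sep = ":")]] <- params
  }
  out <- dplyr::mutate(data, p_prov = p_prov, p_inst = p_inst)
  out <- restore_attrs(out, atts)
  attr(out, "curve_params") <- curves
  out
}

#' Tabulate a learning curve for plotting
#'
#' Convenience preview of a solved curve over its case series, including
#' the truncation to 0 beyond mastery.
#'
#' @inheritParams solve_curve
#' @param max_cases Largest case number tabulated (default: 20% past
#'   truncation).
#' @return A tibble with columns `CN` and `p`.
#' @export
curve_preview <- function(form, magnitude, speed, shape = 1.5,
                          max_cases = NULL) {
  params <- solve_curve(form, magnitude, speed, shape)
  if (is.null(max_cases)) max_cases <- ceiling(1.2 * speed)
  cn <- seq_len(max_cases)
  tibble::tibble(CN = cn, p = learning_probability(cn, params))
}
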