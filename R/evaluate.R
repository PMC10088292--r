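#' Estimate realized parameters from a generated dataset
#'
#' Computes, from a truth table, the realized novel-treatment prevalence,
#' the realized pre-learning event rate (from the auxiliary Bernoulli draw
#' against `p_pt` recorded at generation time), and the realized novel
#' treatment odds ratio with its Wald 95% CI from a correctly parameterized
#' logistic regression (outcome on the features carrying outcome odds
#' ratios, plus treatment).
#'
#' @param truth Truth tibble from [simulate_cohort()] (or read back via
#'   [read_dataset()]).
#' @param config The generating [simulation_config()].
#' @return A `learnsim_summary` object; see [glance.learnsim_summary()].
#' @export
summarize_dataset <- function(truth, config) {
  df <- outcome_design_frame(truth, config)
  fit <- tryCatch(
    stats::glm(outcome ~ ., data = df, family = stats::binomial()),
    error = function(e) NULL,
    warning = function(w) {
      suppressWarnings(
        stats::glm(outcome ~ ., data = df, family = stats::binomial())
      )
    }
  )
  est <- se <- NA_real_
  separation <- TRUE
  if (!is.null(fit)) {
    cf <- summary(fit)$coefficients
    if ("treatment" %in% rownames(cf)) {
      est <- cf["treatment", "Estimate"]
      se <- cf["treatment", "Std. Error"]
      separation <- !is.finite(se) || se > 50 || abs(est) > 15
    }
  }
  z <- stats::qnorm(0.975)
  ci <- if (separation) c(0, Inf) else exp(est + c(-z, z) * se)
  spec_or <- config$outcome$treatment_or
  structure(
    list(
      n = nrow(truth),
      realized_prevalence = mean(truth$treatment),
      realized_event_rate = mean(truth$outcome_pre_learning),
      realized_outcome_rate = mean(truth$outcome),
      specified_or = spec_or,
      or_estimate = if (separation) NA_real_ else exp(est),
      ci_low = ci[1],
      ci_high = ci[2],
      covered = spec_or >= ci[1] && spec_or <= ci[2],
      excludes_null = ci[1] > 1 || ci[2] < 1,
      separation = separation
    ),
    class = "learnsim_summary"
  )
}

# design frame for the correctly parameterized outcome fit: treatment plus
# exactly the terms carrying outcome odds ratios
outcome_design_frame <- function(truth, config) {
  terms <- names(config$outcome$odds_ratios)
  cols <- list(outcome = truth$outcome, treatment = truth$treatment)
  for (tm in terms) {
    xcol <- paste0("x_", tm)
    if (xcol %in% names(truth)) {
      cols[[tm]] <- as.numeric(truth[[xcol]])
    } else {
      feat <- paste0("x_", sub("\\.[^.]*$", "", tm))
      level <- sub("^.*\\.", "", tm)
      if (!feat %in% names(truth)) {
        stop("outcome model names a feature absent from the truth table: ",
             tm, call. = FALSE)
      }
      cols[[tm]] <- as.numeric(as.character(truth[[feat]]) == level)
    }
  }
  out <- tibble::as_tibble(cols)
  names(out) <- make.names(names(out))
  out
}

#' @rdname glance.learnsim_summary
#' @method tidy learnsim_summary
#' @export
tidy.learnsim_summary <- function(x, ...) {
  tibble::tibble(
    term = "treatment",
    estimate = x$or_estimate,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    specified = x$specified_or,
    covered = x$covered,
    excludes_null = x$excludes_null
  )
}

#' Broom-style accessors for realized-parameter summaries
#'
#' `glance()` returns a one-row tibble of realized vs specified parameters;
#' `tidy()` returns the treatment-effect row with its confidence interval
#' and coverage flags.
#'
#' @param x A `learnsim_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @method glance learnsim_summary
#' @export
glance.learnsim_summary <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    realized_prevalence = x$realized_prevalence,
    realized_event_rate = x$realized_event_rate,
    specified_or = x$specified_or,
    or_estimate = x$or_estimate,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    covered = x$covered,
    excludes_null = x$excludes_null,
    separation = x$separation
  )
}

#' @export
print.learnsim_summary <- function(x, ...) {
  cat("<learnsim_summary>\n")
  print(glance(x))
  invisible(x)
}

#' Compare synthetic feature distributions against a reference
#'
#' Continuous features are compared with the Wilcoxon rank-sum test
#' (location) and Levene's test (spread); binary and categorical features
#' with chi-squared tests. P-values are adjusted for multiplicity across
#' all tests of the comparison (Holm, by default). Features with a single
#' unique value are skipped and flagged; a categorical feature sharing no
#' levels with the reference is an error.
#'
#' @param synthetic Tibble of synthesized features (plain or `x_`-prefixed
#'   names).
#' @param reference Reference cube tibble (e.g. [make_reference_cube()]).
#' @param adjust Multiplicity adjustment method (see [stats::p.adjust()]).
#' @param alpha Flagging threshold on adjusted p-values.
#' @return Tibble with one row per (feature, test): `feature`, `type`,
#'   `test`, `statistic`, `p_value`, `p_adjusted`, `flagged`, `skipped`.
#' @export
compare_features <- function(synthetic, reference, adjust = "holm",
                             alpha = 0.05) {
  if (nrow(synthetic) == 0 || nrow(reference) == 0) {
    stop("both tables must be non-empty", call. = FALSE)
  }
  if (all(grepl("^x_", names(synthetic)))) {
    names(synthetic) <- sub("^x_", "", names(synthetic))
  }
  shared <- intersect(names(reference), names(synthetic))
  types <- attr(reference, "feature_types")
  rows <- purrr::map_dfr(shared, function(nm) {
    s <- synthetic[[nm]][!is.na(synthetic[[nm]])]
    r <- reference[[nm]][!is.na(reference[[nm]])]
    ty <- if (!is.null(types) && nm %in% names(types)) {
      types[[nm]]
    } else if (is.character(r) || is.factor(r)) {
      "categorical"
    } else if (all(r %in% c(0, 1))) {
      "binary"
    } else {
      "continuous"
    }
    if (ty == "categorical" &&
        length(intersect(unique(as.character(s)), unique(as.character(r)))) == 0) {
      stop("categorical feature `", nm,
           "` shares no levels with the reference", call. = FALSE)
    }
    if (length(unique(s)) < 2 || length(unique(r)) < 2) {
      return(tibble::tibble(feature = nm, type = ty, test = "none",
                            statistic = NA_real_, p_value = NA_real_,
                            skipped = TRUE))
    }
    if (ty == "continuous") {
      w <- stats::wilcox.test(as.numeric(s), as.numeric(r))
      lv <- car::leveneTest(
        y = c(as.numeric(s), as.numeric(r)),
        group = factor(rep(c("synthetic", "reference"), c(length(s), length(r))))
      )
      tibble::tibble(
        feature = nm, type = ty,
        test = c("wilcoxon", "levene"),
        statistic = c(unname(w$statistic), lv$`F value`[1]),
        p_value = c(w$p.value, lv$`Pr(>F)`[1]),
        skipped = FALSE
      )
    } else {
      s <- as.character(s)
      r <- as.character(r)
      tab <- table(
        group = rep(c("synthetic", "reference"), c(length(s), length(r))),
        value = c(s, r)
      )
      ch <- suppressWarnings(stats::chisq.test(tab))
      tibble::tibble(feature = nm, type = ty, test = "chisq",
                     statistic = unname(ch$statistic),
                     p_value = ch$p.value, skipped = FALSE)
    }
  })
  rows$p_adjusted <- NA_real_
  ok <- !rows$skipped
  rows$p_adjusted[ok] <- stats::p.adjust(rows$p_value[ok], method = adjust)
  rows$flagged <- !is.na(rows$p_adjusted) & rows$p_adjusted < alpha
  rows
}

#' Replicate-grid coverage experiment
#'
#' Generates replicate datasets over a grid of configurations with learning
#' disabled (or as configured), summarizes each with [summarize_dataset()],
#' and reports per-dataset rows suitable for pooled and stratified coverage
#' analysis of the novel-treatment odds ratio.
#'
#' @param grid A list of [simulation_config()] objects (cells).
#' @param reps Replicates per cell.
#' @param seed Master seed; dataset `j` of the experiment uses a
#'   deterministically derived seed.
#' @param progress Print a dot every 25 datasets.
#' @return A `learnsim_coverage` tibble: one row per generated dataset with
#'   cell index, realized n, realized prevalence and event rate, OR
#'   estimate, CI, `covered` and `excludes_null` flags.
#' @export
coverage_experiment <- function(grid, reps = 1, seed = 1L, progress = FALSE) {
  stopifnot(length(grid) >= 1)
  idx <- tidyr::expand_grid(cell = seq_along(grid), rep = seq_len(reps))
  rows <- purrr::map_dfr(seq_len(nrow(idx)), function(j) {
    cfg <- grid[[idx$cell[j]]]
    ds <- simulate_cohort(cfg, seed = replicate_seed(seed, j), replicate = 1L)
    g <- glance(summarize_dataset(ds$truth, cfg))
    if (progress && j %% 25 == 0) cat(".")
    dplyr::bind_cols(
      tibble::tibble(cell = idx$cell[j], rep = idx$rep[j],
                     specified_prevalence = cfg$treatment$prevalence,
                     specified_rate = cfg$outcome$event_rate),
      g
    )
  })
  if (progress) cat("\n")
  class(rows) <- c("learnsim_coverage", class(rows))
  rows
}

#' @rdname coverage_experiment
#' @param x A `learnsim_coverage` tibble.
#' @param ... Unused.
#' @return `glance()`: a one-row tibble with pooled coverage of the
#'   specified OR, pooled null-exclusion fraction among OR > 1 cells, mean
#'   realized-minus-specified prevalence and event-rate deviations, and the
#'   realized sample-size range.
#' @method glance learnsim_coverage
#' @export
glance.learnsim_coverage <- function(x, ...) {
  ok <- !x$separation
  tibble::tibble(
    datasets = nrow(x),
    coverage = mean(x$covered[ok]),
    exclusion_or_gt1 = mean(x$excludes_null[ok & x$specified_or > 1]),
    exclusion_or_eq1 = mean(x$excludes_null[ok & x$specified_or == 1]),
    prevalence_bias = mean(x$realized_prevalence - x$specified_prevalence),
    rate_bias = mean(x$realized_event_rate - x$specified_rate),
    n_min = min(x$n),
    n_max = max(x$n)
  )
}

#' Smoothed outcome-rate curves over the case series
#'
#' Fits binomial penalized-spline smoothers (via [mgcv::gam()]) of the
#' binary outcome on the treatment-specific case number at the provider or
#' institution level, with pointwise Wald 95% bands on the probability
#' scale, for three groups: the reference arm, the novel arm without
#' learning, and (when a with-learning truth table is supplied) the novel
#' arm with learning.
#'
#' @param truth_learning Truth tibble generated with the learning effect
#'   active (or a single table when `truth_no_learning` is `NULL`).
#' @param truth_no_learning Truth tibble from the same configuration with
#'   learning disabled; supplies the reference and no-learning novel
#'   groups.
#' @param level `"provider"` or `"institution"` case series.
#' @param cn_max Largest case number on the evaluation grid; defaults to
#'   the smallest group's 95th percentile of case numbers, so the grid
#'   stays where every group has data support.
#' @param k Spline basis dimension passed to `mgcv::s()`.
#' @return A `learnsim_curves` tibble: `group`, `CN`, `estimate`,
#'   `conf.low`, `conf.high`, with smoother metadata in attributes.
#' @export
case_series_curve <- function(truth_learning, truth_no_learning = NULL,
                              level = c("provider", "institution"),
                              cn_max = NULL, k = 10) {
  level <- match.arg(level)
  cn_col <- if (level == "provider") "CN_prov" else "CN_inst"
  base <- truth_no_learning %||% truth_learning
  groups <- list(
    reference = dplyr::filter(base, .data$treatment == 0L),
    novel_no_learning = dplyr::filter(base, .data$treatment == 1L)
  )
  if (!is.null(truth_no_learning)) {
    groups$novel_with_learning <-
      dplyr::filter(truth_learning, .data$treatment == 1L)
  }
  sizes <- vapply(groups, nrow, 0L)
  if (any(sizes < 50)) {
    stop("fewer than 50 observations in group(s): ",
         paste(names(sizes)[sizes < 50], collapse = ", "), call. = FALSE)
  }
  if (is.null(cn_max)) {
    cn_max <- floor(min(vapply(groups, function(g) {
      stats::quantile(g[[cn_col]], 0.95)
    }, 0)))
  }
  grid <- seq_len(cn_max)
  out <- purrr::map_dfr(names(groups), function(gn) {
    g <- groups[[gn]]
    d <- data.frame(outcome = g$outcome, CN = g[[cn_col]])
    kk <- min(k, length(unique(d$CN)) - 1)
    fit <- mgcv::gam(outcome ~ s(CN, k = kk), family = stats::binomial(),
                     data = d)
    pr <- mgcv::predict.gam(fit, newdata = data.frame(CN = grid),
                            type = "link", se.fit = TRUE)
    z <- stats::qnorm(0.975)
    tibble::tibble(
      group = gn, CN = grid,
      estimate = stats::plogis(pr$fit),
      conf.low = stats::plogis(pr$fit - z * pr$se.fit),
      conf.high = stats::plogis(pr$fit + z * pr$se.fit)
    )
  })
  attr(out, "smoother") <- sprintf(
    "binomial penalized regression spline, mgcv::gam, s(CN, k = %d), Wald pointwise 95%% bands", k)
  attr(out, "level") <- level
  class(out) <- c("learnsim_curves", class(out))
  out
}

#' Case number at which learning becomes indistinguishable from mastery
#'
#' The smallest case number `c` such that, for every case number from `c`
#' to the end of the evaluation grid, the with-learning smoothed curve does
#' not exceed the upper limit of the no-learning curve's pointwise 95%
#' band. The comparison is one-sided because learning-associated risk is
#' non-negative: only elevation above the no-learning band is evidence of
#' unresolved learning. With learning injected over a provider's first
#' `speed` cases, this stabilization point is expected near `speed`.
#'
#' @param curves A `learnsim_curves` with both `novel_with_learning` and
#'   `novel_no_learning` groups.
#' @return Integer case number (`NA` if the curves never stabilize).
#' @export
stabilization_case <- function(curves) {
  w <- dplyr::filter(curves, .data$group == "novel_with_learning")
  b <- dplyr::filter(curves, .data$group == "novel_no_learning")
  if (nrow(w) == 0 || nrow(b) == 0) {
    stop("curves must contain both novel groups", call. = FALSE)
  }
  b <- b[match(w$CN, b$CN), ]
  inside <- w$estimate <= b$conf.high
  if (!inside[length(inside)]) return(NA_integer_)
  # last exit from the band, plus one
  out <- which(!inside)
  if (length(out) == 0) return(min(w$CN))
  as.integer(w$CN[max(out)] + 1L)
}

#' Build the scaled-down evaluation grid
#'
#' Constructs the factorial grid of configurations used by the fidelity
#' study: treatment odds ratio x novel-treatment prevalence x population
#' event rate, crossed with institution counts and series lengths spanning
#' the sample-size range (small and moderate cohorts emphasized), learning
#' disabled, and a compact feature set with nontrivial assignment and
#' outcome odds ratios.
#'
#' @param ors,prevalences,rates Parameter levels to cross.
#' @param institutions,years Cohort sizes to cross.
#' @param features Feature spec used in every cell; the default is a
#'   compact three-feature specification (skewed and normal continuous
#'   features plus a binary comorbidity) with assignment ORs (age 1.3,
#'   diabetes 1.5) and outcome ORs (age 1.4, diabetes 1.6).
#' @return A list of [simulation_config()] objects.
#' @export
evaluation_grid <- function(ors = c(1.0, 1.5, 2.0),
                            prevalences = c(0.10, 0.25, 0.50),
                            rates = c(0.02, 0.05, 0.10),
                            institutions = c(5, 15, 30),
                            years = c(2, 4),
                            features = NULL) {
  features <- features %||% compact_feature_spec()
  cells <- tidyr::expand_grid(or = ors, prev = prevalences, rate = rates,
                              ni = institutions, ny = years)
  purrr::map(seq_len(nrow(cells)), function(i) {
    simulation_config(
      cohort = cohort_config(
        n_institutions = cells$ni[i],
        provider_mix = data.frame(providers = c(10, 5), fraction = c(0.5, 0.5)),
        volume_mix = data.frame(lo = c(20, 5), hi = c(30, 15),
                                fraction = c(0.5, 0.5)),
        n_years = cells$ny[i]
      ),
      features = features,
      treatment = treatment_model(cells$prev[i], c(age = 1.3, diabetes = 1.5)),
      outcome = outcome_model(cells$rate[i], cells$or[i],
                              c(age = 1.4, diabetes = 1.6)),
      seed = i
    )
  })
}

compact_feature_spec <- function() {
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

#' Reference-mean containment experiment
#'
#' Synthesizes replicate feature matrices of varying size from a reference
#' cube and checks, for every continuous feature, whether the reference
#' population mean lies inside the 95% confidence interval of the
#' synthesized sample mean. The average containment over features and
#' datasets is the headline fidelity figure (about 95% when synthesis is
#' faithful).
#'
#' @param cube Reference cube (e.g. [make_reference_cube()]).
#' @param sizes Integer vector: one synthesized dataset per entry.
#' @param seed Master seed; dataset `j` derives its own seed.
#' @return A tibble with one row per (dataset, continuous feature):
#'   `dataset`, `n`, `feature`, `mean`, `ci_low`, `ci_high`, `ref_mean`,
#'   `contained`.
#' @export
feature_containment_experiment <- function(cube, sizes, seed = 1L) {
  spec <- spec_from_cube(cube)
  types <- attr(cube, "feature_types")
  cont_feats <- if (!is.null(types)) {
    names(types)[types == "continuous"]
  } else {
    names(cube)[vapply(cube, function(v) is.numeric(v) && !all(v %in% 0:1), TRUE)]
  }
  ref_means <- vapply(cont_feats, function(nm) mean(cube[[nm]], na.rm = TRUE), 0)
  purrr::map_dfr(seq_along(sizes), function(j) {
    n <- sizes[j]
    x <- simulate_features(spec, n, seed = replicate_seed(seed, j))
    purrr::map_dfr(cont_feats, function(nm) {
      v <- x[[nm]]
      half <- stats::qnorm(0.975) * stats::sd(v) / sqrt(n)
      m <- mean(v)
      tibble::tibble(
        dataset = j, n = n, feature = nm, mean = m,
        ci_low = m - half, ci_high = m + half, ref_mean = ref_means[[nm]],
        contained = ref_means[[nm]] >= m - half & ref_means[[nm]] <= m + half
      )
    })
  })
}
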