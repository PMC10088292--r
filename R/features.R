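#' Feature specification for synthetic patients
#'
#' Declares the marginal distribution of each patient feature and the target
#' correlation structure among them. Marginals are either parametric
#' (`normal`, `lognormal`, `gamma`, `uniform` for continuous features; a
#' prevalence for binary; level probabilities for categorical) or empirical
#' pools estimated from a reference data cube via [spec_from_cube()].
#' Categorical features are handled through their indicator coding: each
#' level becomes a 0/1 column named `feature.level` for correlation
#' purposes.
#'
#' @param features A list of feature definitions. Each is a list with
#'   `name`, `type` (`"continuous"`, `"binary"`, `"categorical"`) and either
#'   a parametric definition (`dist = list(family = , ...)` for continuous,
#'   `p` for binary, `levels` + `probs` for categorical) or an empirical
#'   `pool` of observed values.
#' @param correlations Target correlations: either a list of
#'   `(name1, name2, r)` triplets over (indicator-coded) column names, or a
#'   full symmetric matrix with unit diagonal whose dimnames are the
#'   expanded column names. Unlisted pairs default to 0 (within-feature
#'   indicator pairs of a parametric categorical default to their
#'   multinomial value).
#' @param max_iterations Maximum iterations of the rank-substitution loop.
#' @param patience Stop after this many iterations without improvement in
#'   the root-mean-square residual (RMSR) versus the target.
#' @param pd_floor Eigenvalue floor used when repairing a non-positive-
#'   definite working correlation matrix.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(features,
                         correlations = NULL,
                         max_iterations = 50,
                         patience = 10,
                         pd_floor = 1e-6) {
  nm <- vapply(features, function(f) f$name %||% "", "")
  if (any(!nzchar(nm))) stop("every feature needs a `name`", call. = FALSE)
  if (anyDuplicated(nm)) {
    stop("feature named more than once: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  features <- purrr::map(features, validate_feature_def)
  spec <- structure(
    list(
      features = features,
      correlations = correlations,
      controls = list(
        max_iterations = as.integer(max_iterations),
        patience = as.integer(patience),
        pd_floor = as.numeric(pd_floor)
      )
    ),
    class = "feature_spec"
  )
  # fail early on malformed correlation input
  invisible(target_corr_matrix(spec))
  spec
}

validate_feature_def <- function(f) {
  f$type <- match.arg(f$type, c("continuous", "binary", "categorical"))
  if (f$type == "categorical") {
    if (is.null(f$pool)) {
      if (is.null(f$levels) || length(f$levels) < 2) {
        stop("categorical feature `", f$name, "` needs >= 2 levels", call. = FALSE)
      }
      if (is.null(f$probs)) f$probs <- rep(1 / length(f$levels), length(f$levels))
      if (abs(sum(f$probs) - 1) > 1e-9) {
        stop("level probabilities of `", f$name, "` must sum to 1", call. = FALSE)
      }
    }
  } else if (f$type == "binary") {
    if (is.null(f$pool)) {
      if (is.null(f$p) || f$p < 0 || f$p > 1) {
        stop("binary feature `", f$name, "` needs prevalence `p` in [0, 1]",
             call. = FALSE)
      }
    }
  } else {
    if (is.null(f$pool) && is.null(f$dist)) {
      stop("continuous feature `", f$name,
           "` needs a `dist` definition or an empirical `pool`", call. = FALSE)
    }
  }
  f
}

# quantile function of a supported parametric family
marginal_quantile_fun <- function(dist) {
  family <- match.arg(dist$family,
                      c("normal", "lognormal", "gamma", "uniform"))
  switch(family,
    normal = function(p) stats::qnorm(p, dist$mean %||% 0, dist$sd %||% 1),
    lognormal = function(p) stats::qlnorm(p, dist$meanlog %||% 0, dist$sdlog %||% 1),
    gamma = function(p) stats::qgamma(p, shape = dist$shape, rate = dist$rate %||% 1),
    uniform = function(p) stats::qunif(p, dist$min %||% 0, dist$max %||% 1)
  )
}

# Expansion plan: one row per synthesized (indicator-coded) column.
expansion_plan <- function(spec) {
  rows <- purrr::map(spec$features, function(f) {
    if (is_constant_feature(f)) {
      return(tibble::tibble(column = f$name, feature = f$name, type = f$type,
                            level = NA_character_, constant = TRUE))
    }
    if (f$type == "categorical") {
      lev <- if (!is.null(f$pool)) sort(unique(as.character(f$pool))) else as.character(f$levels)
      tibble::tibble(column = paste(f$name, lev, sep = "."), feature = f$name,
                     type = f$type, level = lev, constant = FALSE)
    } else {
      tibble::tibble(column = f$name, feature = f$name, type = f$type,
                     level = NA_character_, constant = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}

is_constant_feature <- function(f) {
  !is.null(f$pool) && length(unique(f$pool[!is.na(f$pool)])) < 2
}

# Target correlation matrix over expanded non-constant columns.
target_corr_matrix <- function(spec) {
  plan <- dplyr::filter(expansion_plan(spec), !.data$constant)
  cols <- plan$column
  k <- length(cols)
  if (is.matrix(spec$correlations)) {
    m <- spec$correlations
    if (is.null(dimnames(m)) || !setequal(rownames(m), cols)) {
      stop("correlation matrix dimnames must match expanded column names",
           call. = FALSE)
    }
    m <- m[cols, cols, drop = FALSE]
  } else {
    m <- diag(k)
    dimnames(m) <- list(cols, cols)
    # parametric categorical: within-feature indicators carry their
    # theoretical multinomial correlation
    for (f in spec$features) {
      if (f$type == "categorical" && is.null(f$pool)) {
        cn <- paste(f$name, f$levels, sep = ".")
        p <- f$probs
        for (a in seq_along(cn)) for (b in seq_along(cn)) {
          if (a != b) {
            m[cn[a], cn[b]] <- -sqrt(p[a] * p[b] / ((1 - p[a]) * (1 - p[b])))
          }
        }
      }
    }
    for (tr in spec$correlations %||% list()) {
      a <- as.character(tr[[1]]); b <- as.character(tr[[2]])
      r <- as.numeric(tr[[3]])
      if (!(a %in% cols) || !(b %in% cols)) {
        stop("correlation names unknown column: ", a, " / ", b, call. = FALSE)
      }
      if (abs(r) > 1) stop("correlations must lie in [-1, 1]", call. = FALSE)
      m[a, b] <- r
      m[b, a] <- r
    }
  }
  if (any(abs(m - t(m)) > 1e-12)) stop("target correlation matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-12)) stop("target correlation matrix must have unit diagonal", call. = FALSE)
  check_target_repairable(m, spec$controls$pd_floor)
}

# Validation only: the target is stored as estimated/declared; the working
# intermediate matrix is repaired inside the synthesis loop.
check_target_repairable <- function(m, pd_floor) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= pd_floor) return(m)
  rep <- repair_pd(m, pd_floor)
  if (max(abs(rep - m)) > 0.05) {
    stop(sprintf(
      "target correlation matrix is not positive definite (eigenvalue %.4g) and cannot be repaired without distorting targets",
      min(ev)), call. = FALSE)
  }
  m
}

#' Repair a correlation matrix to positive definiteness
#'
#' Eigenvalue clipping: eigenvalues below `floor` are raised to `floor`, the
#' matrix is reconstructed and rescaled to unit diagonal.
#'
#' @param m Symmetric matrix.
#' @param floor Eigenvalue floor.
#' @return A positive-definite correlation matrix.
#' @export
repair_pd <- function(m, floor = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- stats::cov2cor(out)
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' Estimate a feature specification from a reference data cube
#'
#' Takes a patient-level table (e.g. an EHR-derived cube) and returns a
#' [feature_spec()] whose marginals are the complete-case empirical pools of
#' each column and whose target correlation matrix is the pairwise
#' correlation of the cube, with categorical features expanded to indicator
#' coding. Constant columns are kept as marginals but dropped from the
#' correlation targets (their correlation is undefined), with a warning.
#'
#' @param cube A data frame, one row per patient. Column types determine
#'   feature types: numeric columns with values in \{0, 1\} are binary,
#'   other numerics continuous, character/factor columns categorical. An
#'   attribute `"feature_types"` (named character vector), as set by
#'   [read_cube()], overrides the inference.
#' @inheritParams feature_spec
#' @return A `feature_spec` whose correlation slot is a matrix over the
#'   indicator-expanded columns.
#' @export
spec_from_cube <- function(cube, max_iterations = 50, patience = 10,
                           pd_floor = 1e-6) {
  cube <- tibble::as_tibble(cube)
  if (nrow(cube) < 2) stop("reference cube needs >= 2 rows", call. = FALSE)
  types <- attr(cube, "feature_types")
  defs <- purrr::map(names(cube), function(nm) {
    v <- cube[[nm]]
    pool <- v[!is.na(v)]
    if (length(pool) == 0) stop("column `", nm, "` is all-missing", call. = FALSE)
    ty <- if (!is.null(types) && nm %in% names(types)) {
      types[[nm]]
    } else if (is.character(v) || is.factor(v)) {
      "categorical"
    } else if (all(pool %in% c(0, 1))) {
      "binary"
    } else {
      "continuous"
    }
    list(name = nm, type = ty,
         pool = if (ty == "categorical") as.character(pool) else as.numeric(pool))
  })
  spec <- structure(
    list(features = defs, correlations = NULL,
         controls = list(max_iterations = as.integer(max_iterations),
                         patience = as.integer(patience),
                         pd_floor = as.numeric(pd_floor))),
    class = "feature_spec"
  )
  plan <- expansion_plan(spec)
  if (any(plan$constant)) {
    warning("constant column(s) excluded from correlation targets: ",
            paste(unique(plan$feature[plan$constant]), collapse = ", "),
            call. = FALSE)
  }
  live <- dplyr::filter(plan, !.data$constant)
  X <- expand_indicator_matrix(cube, live)
  m <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  m[is.na(m)] <- 0
  diag(m) <- 1
  spec$correlations <- check_target_repairable((m + t(m)) / 2, pd_floor)
  spec
}

# numeric matrix of expanded columns from a raw table, per plan rows
expand_indicator_matrix <- function(df, plan) {
  cols <- purrr::map(seq_len(nrow(plan)), function(i) {
    v <- df[[plan$feature[i]]]
    if (plan$type[i] == "categorical") {
      as.numeric(as.character(v) == plan$level[i])
    } else {
      as.numeric(v)
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- plan$column
  m
}

# ---- iterative rank-substitution synthesis ---------------------------------

# Materialize a sampling pool for one expanded column.
column_pool <- function(f, level, n) {
  pool_size <- max(10L * n, 10000L)
  if (!is.null(f$pool)) {
    if (f$type == "categorical") {
      return(as.numeric(as.character(f$pool) == level))
    }
    return(as.numeric(f$pool))
  }
  if (f$type == "continuous") {
    return(marginal_quantile_fun(f$dist)(stats::ppoints(pool_size)))
  }
  p <- if (f$type == "binary") f$p else f$probs[match(level, f$levels)]
  n1 <- round(p * pool_size)
  rep(c(1, 0), c(n1, pool_size - n1))
}

#' Synthesize correlated non-normal patient features
#'
#' Implements an iterative rank-substitution algorithm: standard normal
#' deviates are drawn under a working ("intermediate") correlation matrix,
#' each column is replaced by a bootstrap resample of its marginal pool
#' matched by rank, the realized correlation of the substituted data is
#' compared with the target, and the intermediate matrix is nudged by the
#' residual (then repaired to positive definiteness). The intermediate
#' matrix achieving the smallest root-mean-square residual (RMSR) against
#' the target is kept and used to generate the returned matrix. Marginals
#' are therefore reproduced exactly up to resampling, with no normality
#' assumption, while correlations converge to the target.
#'
#' Categorical features are synthesized through their indicator columns and
#' decoded to a single level per patient by the indicator/latent-rank
#' argmax. Rank matching operates on the continuous normal deviates, where
#' ties occur with probability zero; the discrete (tied) marginal values
#' land on the deviates' order statistics.
#'
#' @param spec A [feature_spec()].
#' @param n Number of patients (>= 2).
#' @param seed Master seed; draws use the `"features"` substream.
#' @return A tibble of `n` rows with one column per declared feature, typed
#'   per the spec. Attributes: `rmsr` (best RMSR attained), `iterations`
#'   (iterations run), `scaling` (per expanded model column, the centering /
#'   scaling constants of the generating pool), `target_corr` and
#'   `expanded_names`.
#' @export
simulate_features <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "feature_spec"), n >= 2)
  with_substream(seed, "features", {
    plan <- expansion_plan(spec)
    live <- dplyr::filter(plan, !.data$constant)
    target <- target_corr_matrix(spec)
    defs <- stats::setNames(spec$features,
                            vapply(spec$features, `[[`, "", "name"))
    pools <- purrr::map(seq_len(nrow(live)), function(i) {
      column_pool(defs[[live$feature[i]]], live$level[i], n)
    })
    names(pools) <- live$column

    fit <- ruscio_loop(pools, target, n, spec$controls)

    # decode expanded columns back to declared features
    out <- decode_features(spec, plan, fit$values, fit$latent, pools)
    attr(out, "rmsr") <- fit$rmsr
    attr(out, "iterations") <- fit$iterations
    attr(out, "target_corr") <- target
    attr(out, "expanded_names") <- live$column
    attr(out, "scaling") <- pool_scaling(live, pools)
    out
  })
}

ruscio_loop <- function(pools, target, n, controls) {
  k <- length(pools)
  # a sorted bootstrap resample of a 0/1 pool is fully described by its
  # count of ones; drawing it directly avoids an O(n log n) sort
  binary_pool <- vapply(pools, function(p) all(p %in% c(0, 1)), TRUE)
  pool_p1 <- vapply(pools, mean, 0)
  substitute_cols <- function(z) {
    s <- z
    for (j in seq_len(k)) {
      sp <- if (binary_pool[j]) {
        n1 <- stats::rbinom(1L, n, pool_p1[j])
        rep(c(0, 1), c(n - n1, n1))
      } else {
        sort(sample(pools[[j]], n, replace = TRUE))
      }
      # substitution by rank of the normal deviates; the deviates are
      # continuous so ties occur with probability zero
      s[order(z[, j]), j] <- sp
    }
    s
  }
  draw_latent <- function(interm) {
    matrix(stats::rnorm(n * k), n, k) %*% chol(interm)
  }
  if (k == 1L) {
    z <- matrix(stats::rnorm(n), n, 1)
    s <- substitute_cols(z)
    colnames(s) <- colnames(z) <- names(pools)
    return(list(values = s, latent = z, rmsr = 0, iterations = 0L))
  }
  interm <- repair_pd(target, controls$pd_floor)
  best <- interm
  best_rmsr <- Inf
  stale <- 0L
  it <- 0L
  lower <- lower.tri(target)
  while (it < controls$max_iterations && stale < controls$patience) {
    it <- it + 1L
    z <- draw_latent(interm)
    s <- substitute_cols(z)
    realized <- suppressWarnings(stats::cor(s))
    resid <- target - realized
    resid[is.na(resid)] <- 0
    rmsr <- sqrt(mean(resid[lower]^2))
    if (rmsr < best_rmsr) {
      best <- interm
      best_rmsr <- rmsr
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    interm <- repair_pd(interm + resid, controls$pd_floor)
  }
  z <- draw_latent(best)
  s <- substitute_cols(z)
  colnames(s) <- colnames(z) <- names(pools)
  list(values = s, latent = z, rmsr = best_rmsr, iterations = it)
}

decode_features <- function(spec, plan, values, latent, pools) {
  cols <- purrr::map(spec$features, function(f) {
    rows <- plan[plan$feature == f$name, ]
    if (rows$constant[1]) {
      return(rep(f$pool[!is.na(f$pool)][1], nrow(values)))
    }
    if (f$type != "categorical") {
      return(as.numeric(values[, rows$column]))
    }
    thr <- stats::qnorm(1 - vapply(rows$column, function(cn) mean(pools[[cn]]), 0))
    z <- latent[, rows$column, drop = FALSE]
    ind <- values[, rows$column, drop = FALSE]
    # prefer indicators set to 1; break ties by threshold-shifted latent rank
    score <- ind * 1000 + sweep(z, 2, thr)
    rows$level[max.col(score, ties.method = "first")]
  })
  names(cols) <- vapply(spec$features, `[[`, "", "name")
  tibble::as_tibble(cols)
}

pool_scaling <- function(live, pools) {
  purrr::map_dfr(seq_len(nrow(live)), function(i) {
    if (live$type[i] == "continuous") {
      tibble::tibble(column = live$column[i],
                     center = mean(pools[[i]]), scale = stats::sd(pools[[i]]))
    } else {
      tibble::tibble(column = live$column[i], center = 0, scale = 1)
    }
  })
}

# ---- reference cube I/O and synthetic stand-in ------------------------------

#' Read / write a reference data cube
#'
#' Cube CSVs carry a typed header: each column name is `name:type` with
#' `type` one of `continuous`, `binary`, `categorical`. `read_cube()`
#' returns a tibble with plain column names and a `"feature_types"`
#' attribute; plain headers are accepted, with types inferred from the
#' values.
#'
#' @param path File path.
#' @return `read_cube()`: a tibble. `write_cube()`: `path`, invisibly.
#' @export
read_cube <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  typed <- grepl(":", nm, fixed = TRUE)
  types <- ifelse(typed, sub("^.*:", "", nm), NA)
  names(df) <- sub(":[^:]*$", "", nm)
  out <- tibble::as_tibble(df)
  if (any(typed)) {
    tv <- stats::setNames(types[typed], names(df)[typed])
    bad <- setdiff(tv, c("continuous", "binary", "categorical"))
    if (length(bad)) stop("unknown cube column type(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    attr(out, "feature_types") <- tv
  }
  out
}

#' @rdname read_cube
#' @param cube A data frame; a `"feature_types"` attribute, if present, is
#'   written into the typed header.
#' @export
write_cube <- function(cube, path) {
  types <- attr(cube, "feature_types")
  df <- as.data.frame(cube)
  if (!is.null(types)) {
    idx <- match(names(types), names(df))
    names(df)[idx] <- paste(names(types), types, sep = ":")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic 35-feature reference cube
#'
#' A fully synthetic stand-in for an EHR-derived ICU data cube, usable as a
#' reference for [spec_from_cube()]. It contains 20 continuous features
#' (vital signs, laboratory values and lengths of stay; several right-skewed
#' via lognormal and gamma marginals) and 15 binary features (demographics,
#' comorbidities and interventions), generated from a Gaussian copula with a
#' documented block correlation structure (vitals inter-correlated, renal
#' markers tied to kidney disease, sepsis tied to lactate, pressors and
#' ventilation, age tied to chronic disease). No real patient data enters
#' its construction.
#'
#' @param n Number of rows.
#' @param seed Seed for the `"cube"` substream.
#' @return A tibble with 35 typed columns and a `"feature_types"` attribute.
#' @export
make_reference_cube <- function(n = 10000, seed = 1L) {
  cont <- tibble::tribble(
    ~name,          ~family,     ~a,     ~b,
    "age",          "snorm",     62,     16,
    "bmi",          "lnorm",     log(29), 0.22,
    "heart_rate",   "norm",      88,     16,
    "sbp",          "norm",      121,    19,
    "dbp",          "norm",      64,     13,
    "resp_rate",    "gamma",     40,     2,
    "temp_c",       "norm",      36.9,   0.7,
    "spo2",         "rbeta",     18,     1.2,
    "creatinine",   "lnorm",     0.1,    0.55,
    "bun",          "lnorm",     3.0,    0.55,
    "sodium",       "norm",      139,    4.5,
    "potassium",    "norm",      4.1,    0.5,
    "glucose",      "lnorm",     4.9,    0.33,
    "hematocrit",   "norm",      31,     5,
    "wbc",          "lnorm",     2.35,   0.45,
    "platelets",    "gamma",     6,      0.028,
    "lactate",      "lnorm",     0.55,   0.6,
    "bilirubin",    "lnorm",     -0.45,  0.9,
    "albumin",      "norm",      3.1,    0.65,
    "icu_los_days", "lnorm",     1.05,   0.8
  )
  bin <- tibble::tribble(
    ~name,            ~p,
    "male",           0.56,
    "diabetes",       0.27,
    "chf",            0.22,
    "copd",           0.14,
    "ckd",            0.12,
    "cancer",         0.13,
    "hypertension",   0.48,
    "afib",           0.21,
    "sepsis",         0.18,
    "vasopressor",    0.24,
    "mech_vent",      0.38,
    "dialysis",       0.05,
    "stroke",         0.07,
    "prior_mi",       0.11,
    "smoker",         0.30
  )
  nm <- c(cont$name, bin$name)
  R <- diag(length(nm))
  dimnames(R) <- list(nm, nm)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("sbp", "dbp", 0.6); set_r("heart_rate", "resp_rate", 0.30)
  set_r("heart_rate", "temp_c", 0.22); set_r("heart_rate", "sepsis", 0.20)
  set_r("creatinine", "bun", 0.62); set_r("creatinine", "ckd", 0.45)
  set_r("bun", "ckd", 0.38); set_r("creatinine", "dialysis", 0.35)
  set_r("ckd", "dialysis", 0.40); set_r("lactate", "sepsis", 0.40)
  set_r("lactate", "vasopressor", 0.30); set_r("sepsis", "vasopressor", 0.45)
  set_r("vasopressor", "mech_vent", 0.38); set_r("sepsis", "wbc", 0.28)
  set_r("sepsis", "icu_los_days", 0.25); set_r("mech_vent", "icu_los_days", 0.30)
  set_r("age", "ckd", 0.25); set_r("age", "afib", 0.32)
  set_r("age", "hypertension", 0.30); set_r("age", "heart_rate", -0.10)
  set_r("age", "icu_los_days", 0.10); set_r("bmi", "diabetes", 0.32)
  set_r("diabetes", "ckd", 0.25); set_r("diabetes", "hypertension", 0.28)
  set_r("chf", "afib", 0.28); set_r("chf", "bun", 0.20)
  set_r("copd", "smoker", 0.35); set_r("copd", "mech_vent", 0.18)
  set_r("bilirubin", "albumin", -0.25); set_r("albumin", "icu_los_days", -0.18)
  set_r("prior_mi", "chf", 0.25); set_r("spo2", "mech_vent", -0.15)
  set_r("glucose", "diabetes", 0.35); set_r("sbp", "hypertension", 0.20)
  set_r("cancer", "albumin", -0.15); set_r("stroke", "afib", 0.20)
  R <- repair_pd(R)

  with_substream(seed, "cube", {
    z <- matrix(stats::rnorm(n * length(nm)), n) %*% chol(R)
    colnames(z) <- nm
    u <- stats::pnorm(z)
    cols <- list()
    for (i in seq_len(nrow(cont))) {
      ci <- cont[i, ]
      cols[[ci$name]] <- switch(ci$family,
        norm = stats::qnorm(u[, ci$name], ci$a, ci$b),
        snorm = ci$a + ci$b * stats::qnorm(u[, ci$name]) -
          4 * (1 - u[, ci$name])^2, # mild left tail
        lnorm = stats::qlnorm(u[, ci$name], ci$a, ci$b),
        gamma = stats::qgamma(u[, ci$name], shape = ci$a, rate = ci$b),
        rbeta = 100 - 8 * stats::qbeta(1 - u[, ci$name], ci$a, ci$b)
      )
    }
    for (i in seq_len(nrow(bin))) {
      cols[[bin$name[i]]] <- as.numeric(u[, bin$name[i]] > 1 - bin$p[i])
    }
    out <- tibble::as_tibble(cols)[, nm]
    attr(out, "feature_types") <-
      stats::setNames(c(rep("continuous", nrow(cont)), rep("binary", nrow(bin))), nm)
    out
  })
}

# ---- (de)serialization of parametric specs ---------------------------------

feature_spec_from_list <- function(x) {
  feats <- purrr::map(x$features, function(f) {
    def <- list(name = f$name, type = f$type)
    if (!is.null(f$dist)) def$dist <- f$dist
    if (!is.null(f$p)) def$p <- f$p
    if (!is.null(f$levels)) {
      def$levels <- unlist(f$levels)
      def$probs <- unlist(f$probs)
    }
    def
  })
  ctrl <- x$controls %||% list()
  corr <- purrr::map(x$correlations %||% list(), function(tr) {
    list(tr[[1]], tr[[2]], as.numeric(tr[[3]]))
  })
  feature_spec(
    feats, correlations = if (length(corr)) corr else NULL,
    max_iterations = ctrl$max_iterations %||% 50,
    patience = ctrl$patience %||% 10,
    pd_floor = ctrl$pd_floor %||% 1e-6
  )
}

feature_spec_to_list <- function(spec) {
  has_pool <- any(vapply(spec$features, function(f) !is.null(f$pool), TRUE))
  if (has_pool) {
    stop("cube-derived feature specs are not serialized inline; reference the cube path in the config instead",
         call. = FALSE)
  }
  list(
    features = purrr::map(spec$features, function(f) {
      out <- list(name = f$name, type = f$type)
      if (!is.null(f$dist)) out$dist <- f$dist
      if (!is.null(f$p)) out$p <- f$p
      if (!is.null(f$levels)) {
        out$levels <- as.list(f$levels)
        out$probs <- as.list(f$probs)
      }
      out
    }),
    correlations = purrr::map(spec$correlations %||% list(), function(tr) {
      list(tr[[1]], tr[[2]], tr[[3]])
    }),
    controls = spec$controls
  )
}
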