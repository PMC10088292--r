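#' Flip outcome labels for a fixed fraction of patients
#'
#' Random label noise: a uniformly chosen subset of exactly
#' `round(fraction * n)` patients has their outcome flipped (adverse to
#' non-adverse and vice versa). With `exact_counts = FALSE`, each patient
#' is flipped independently with probability `fraction` instead.
#'
#' @param outcomes Binary vector.
#' @param fraction Fraction of labels to flip, in \[0, 1\].
#' @param seed Master seed; selection uses the `"noise"` substream.
#' @param exact_counts Exact-count (default) vs per-patient Bernoulli
#'   selection.
#' @return Binary vector with flips applied.
#' @export
apply_noise <- function(outcomes, fraction, seed = 1L, exact_counts = TRUE) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(outcomes)
  n <- length(outcomes)
  with_substream(seed, "noise", {
    idx <- if (exact_counts) {
      sample.int(n, round(fraction * n))
    } else {
      which(stats::runif(n) < fraction)
    }
    outcomes[idx] <- 1L - outcomes[idx]
    outcomes
  })
}

#' Mask feature cells completely at random
#'
#' Masks exactly `round(fraction * n * k)` cells of the feature block
#' (uniformly, without replacement) to `NA`; identifiers, treatment and
#' outcome are never masked, and masking is independent of every observed
#' and latent value (MCAR).
#'
#' @param features Tibble of feature columns only.
#' @param fraction Fraction of cells to mask, in \[0, 1\].
#' @param seed Master seed; selection uses the `"missingness"` substream.
#' @param exact_counts Exact-count (default) vs per-cell Bernoulli
#'   selection.
#' @return The tibble with masked cells set to `NA`.
#' @export
apply_missingness <- function(features, fraction, seed = 1L,
                              exact_counts = TRUE) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0 || ncol(features) == 0) return(features)
  n <- nrow(features)
  k <- ncol(features)
  with_substream(seed, "missingness", {
    cells <- if (exact_counts) {
      sample.int(n * k, round(fraction * n * k))
    } else {
      which(stats::runif(n * k) < fraction)
    }
    row <- ((cells - 1) %% n) + 1
    col <- ((cells - 1) %/% n) + 1
    for (j in unique(col)) {
      features[[j]][row[col == j]] <- NA
    }
    features
  })
}

#' Drop omitted features from a public dataset
#'
#' @param features Tibble of feature columns.
#' @param names Feature names to drop; unknown names are an error.
#' @return The tibble without the named columns.
#' @export
drop_omitted <- function(features, names) {
  bad <- setdiff(names, colnames(features))
  if (length(bad)) {
    stop("unknown omitted feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dplyr::select(features, -dplyr::all_of(names))
}
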