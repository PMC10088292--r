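# Seeded substreams: every pipeline stage draws from its own deterministically
# derived seed, so stages are independently reproducible -- e.g. changing the
# finalization options can never perturb treatment assignment.

.stage_offsets <- c(
  roster      = 1L,
  features    = 2L,
  treatment   = 3L,
  shuffle     = 4L,
  outcome     = 5L,
  noise       = 6L,
  missingness = 7L,
  cube        = 8L,
  evaluation  = 9L
)

#' Derive the seed of a named pipeline substream
#'
#' One master seed drives a whole simulation; each stage (roster building,
#' feature synthesis, treatment assignment, within-year shuffling, outcome
#' draws, label noise, missingness masking) receives its own derived seed.
#' The derivation is a fixed affine map modulo a Mersenne prime, so a given
#' `(seed, stage)` pair always yields the same substream and distinct stages
#' yield distinct streams.
#'
#' @param seed Master integer seed.
#' @param stage One of `"roster"`, `"features"`, `"treatment"`, `"shuffle"`,
#'   `"outcome"`, `"noise"`, `"missingness"`, `"cube"`, `"evaluation"`.
#' @return A single integer seed below 2^31.
#' @export
substream_seed <- function(seed, stage) {
  stage <- match.arg(stage, names(.stage_offsets))
  s <- (abs(as.double(seed)) * 48271 + .stage_offsets[[stage]] * 2654435) %%
    2147483647
  as.integer(s)
}

#' Evaluate an expression under a named substream
#'
#' Sets the RNG to the substream's derived seed for the duration of `expr`
#' and restores the caller's RNG state afterwards.
#'
#' @inheritParams substream_seed
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_substream <- function(seed, stage, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stage))
  expr
}

#' Derive the master seed of one replicate
#'
#' Multi-replicate runs give each replicate its own master seed by a fixed
#' affine map; results stay below 2^31.
#'
#' @param seed Master integer seed.
#' @param replicate Replicate index (>= 1).
#' @return A single integer seed.
#' @export
replicate_seed <- function(seed, replicate) {
  as.integer((abs(as.double(seed)) + (replicate - 1) * 1000003) %% 2147483647)
}
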