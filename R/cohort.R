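#' Build the provider roster
#'
#' Instantiates institutions and providers from a [cohort_config()]. Each
#' institution receives a provider count from the provider mix
#' (largest-remainder apportionment over institutions, so an even split is
#' exact whenever the counts divide); each provider draws a volume class
#' from the volume mix and then, independently for every active year, an
#' integer annual volume uniformly from that class's inclusive range. Entry
#' years follow the entry mode: under `"single"` entry every provider is
#' active from year 1; under `"annual"` entry, `ceiling(P/2)` of an
#' institution's providers start in year 1 and the remainder are spread
#' round-robin over years 2..`n_years` (earliest years get the extras).
#' Volumes are zero before a provider's entry year.
#'
#' @param cohort A [cohort_config()].
#' @param seed Master seed; draws use the `"roster"` substream.
#' @return A tibble with one row per provider: `provider_id`,
#'   `institution_id`, `entry_year`, and volume columns `volume_y1` ..
#'   `volume_y<n_years>`.
#' @export
build_roster <- function(cohort, seed = 1L) {
  validate_cohort_config(cohort)
  with_substream(seed, "roster", {
    n_inst <- cohort$n_institutions
    counts <- largest_remainder(cohort$provider_mix$fraction, n_inst)
    prov_per_inst <- rep(cohort$provider_mix$providers, counts)
    # shuffle which institution is large/small
    prov_per_inst <- prov_per_inst[sample.int(n_inst)]

    roster <- tibble::tibble(
      institution_id = rep(seq_len(n_inst), prov_per_inst)
    )
    p <- nrow(roster)
    roster$provider_id <- seq_len(p)

    # entry years
    roster$entry_year <- 1L
    if (cohort$entry_mode == "annual" && cohort$n_years > 1) {
      roster <- dplyr::group_by(roster, .data$institution_id)
      roster <- dplyr::mutate(roster, entry_year = entry_schedule(
        dplyr::n(), cohort$n_years
      ))
      roster <- dplyr::ungroup(roster)
    }

    # volume class per provider, annual volume redrawn per active year
    vm <- cohort$volume_mix
    cls <- sample.int(nrow(vm), p, replace = TRUE, prob = vm$fraction)
    vols <- matrix(0L, p, cohort$n_years)
    for (y in seq_len(cohort$n_years)) {
      active <- roster$entry_year <= y
      lo <- vm$lo[cls[active]]
      hi <- vm$hi[cls[active]]
      vols[active, y] <- lo + floor(stats::runif(sum(active)) * (hi - lo + 1))
    }
    colnames(vols) <- paste0("volume_y", seq_len(cohort$n_years))
    roster$volume_class <- cls
    dplyr::bind_cols(
      roster[, c("provider_id", "institution_id", "entry_year", "volume_class")],
      tibble::as_tibble(vols)
    )
  })
}

# integer apportionment of n units to fractions, largest remainder
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# year-1 gets ceiling(P/2); the rest round-robin over years 2..n_years
entry_schedule <- function(p, n_years) {
  first <- ceiling(p / 2)
  rest <- p - first
  later <- if (rest > 0) {
    rep(seq(2L, n_years), length.out = rest)
  } else {
    integer(0)
  }
  c(rep(1L, first), sort(later))
}

#' Total patient sample size implied by a roster
#'
#' The simulation's sample size is not set directly: it is the sum of every
#' provider's annual volumes over their active years.
#'
#' @param roster A roster tibble from [build_roster()].
#' @return Integer patient count.
#' @export
total_sample_size <- function(roster) {
  vols <- dplyr::select(roster, dplyr::starts_with("volume_y"))
  as.integer(sum(as.matrix(vols)))
}

#' Expand a roster into a patient ledger skeleton
#'
#' Creates exactly `volume_y` patients for each (provider, year) cell;
#' patients inherit their provider's institution. Feature columns,
#' treatment, case-series indices and outcomes are attached by later
#' pipeline stages.
#'
#' @param roster A roster tibble from [build_roster()].
#' @return A tibble with `patient_id`, `provider_id`, `institution_id`,
#'   `year`; one row per patient, `nrow` equal to [total_sample_size()].
#' @export
assign_patients <- function(roster) {
  vols <- as.matrix(dplyr::select(roster, dplyr::starts_with("volume_y")))
  n_years <- ncol(vols)
  cells <- tidyr::expand_grid(
    i = seq_len(nrow(roster)),
    year = seq_len(n_years)
  )
  cells$count <- vols[cbind(cells$i, cells$year)]
  cells <- cells[cells$count > 0, ]
  out <- tibble::tibble(
    provider_id = rep(roster$provider_id[cells$i], cells$count),
    institution_id = rep(roster$institution_id[cells$i], cells$count),
    year = rep(cells$year, cells$count)
  )
  out <- dplyr::arrange(out, .data$year, .data$provider_id)
  out$patient_id <- seq_len(nrow(out))
  dplyr::select(out, "patient_id", "provider_id", "institution_id", "year")
}
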