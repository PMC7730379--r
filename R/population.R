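# Time-of-day windows (hours) for the daily exposure patterns. The fixed
# slots draw uniformly within their window each day; "random" patterns draw
# uniformly over waking hours.
EXPOSURE_WINDOWS <- list(
  morning = c(7, 10),
  afternoon = c(12, 15),
  evening = c(18, 22),
  waking = c(7, 23)
)

events_per_day <- function(pattern) {
  switch(pattern,
    once_random = 1L, once_evening = 1L,
    twice_random = 2L, twice_morning_afternoon = 2L,
    thrice_random = 3L, thrice_morning_afternoon_evening = 3L,
    stop(sprintf("Unknown exposure pattern \"%s\".", pattern), call. = FALSE)
  )
}

runif_window <- function(n, window) stats::runif(n, window[1], window[2])

# One day's exposure times-of-day (hours, sorted). Random-slot patterns draw
# independently then sort; coincident draws are re-drawn.
draw_day_times <- function(pattern) {
  w <- EXPOSURE_WINDOWS
  switch(pattern,
    once_random = runif_window(1L, w$waking),
    once_evening = runif_window(1L, w$evening),
    twice_morning_afternoon = c(runif_window(1L, w$morning),
                                runif_window(1L, w$afternoon)),
    thrice_morning_afternoon_evening = c(runif_window(1L, w$morning),
                                         runif_window(1L, w$afternoon),
                                         runif_window(1L, w$evening)),
    twice_random = ,
    thrice_random = {
      k <- events_per_day(pattern)
      repeat {
        t <- sort(runif_window(k, w$waking))
        if (!anyDuplicated(t)) break
      }
      t
    }
  )
}

#' Sample per-individual exposure parameters
#'
#' Each individual receives a geometric-mean dose drawn from a log-normal
#' distribution with geometric mean 1 and the scenario's between-person GSD,
#' and an elimination half-life drawn log-normally around the chemical's
#' biological half-life with the half-life GSD. A GSD of 1 yields the
#' degenerate (constant) distribution.
#'
#' Draws use one derived seed per individual, so individual `i`'s parameters
#' do not depend on `n_individuals`.
#'
#' @param config A [scenario()].
#' @param seed Root seed; defaults to the scenario's.
#' @return A tibble with columns `individual`, `gm_dose`, `half_life`.
#' @export
sample_individuals <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "urine_scenario"))
  n <- config$n_individuals
  gm <- numeric(n)
  hl <- numeric(n)
  sd_b <- log(config$between_gsd)
  sd_h <- log(config$half_life_gsd)
  for (i in seq_len(n)) {
    draws <- with_seed(derive_seed(seed, i, STAGE$person),
                       stats::rnorm(2L))
    gm[i] <- exp(draws[1] * sd_b)
    hl[i] <- config$biological_half_life * exp(draws[2] * sd_h)
  }
  tibble::tibble(individual = seq_len(n), gm_dose = gm, half_life = hl)
}

# Exposure events for one individual: `n_days` days of the scenario pattern,
# per-event dose log-normal around the individual's geometric-mean dose with
# the within-person GSD. Times are hours from simulation start.
exposure_events_one <- function(gm_dose, config, n_days = config$total_days) {
  k <- events_per_day(config$exposure_pattern)
  tod <- unlist(lapply(seq_len(n_days), function(d) draw_day_times(config$exposure_pattern)))
  time_h <- rep(24 * (seq_len(n_days) - 1L), each = k) + tod
  dose <- stats::rlnorm(n_days * k, meanlog = log(gm_dose),
                        sdlog = log(config$within_gsd))
  tibble::tibble(day = rep(seq_len(n_days), each = k), time_h = time_h,
                 dose = dose)
}

#' Generate timed oral exposure events for a population
#'
#' Events cover every simulated day (accumulation plus exposure window) with
#' 1-3 events per day according to the scenario's exposure pattern. Fixed
#' slots (morning 07:00-10:00, afternoon 12:00-15:00, evening 18:00-22:00)
#' draw a uniform time within their window each day; "random" patterns draw
#' uniformly over waking hours (07:00-23:00) and sort within the day.
#'
#' @param individuals A tibble from [sample_individuals()] (columns
#'   `individual`, `gm_dose`).
#' @param config A [scenario()].
#' @param seed Root seed; defaults to the scenario's. Each individual's
#'   events derive from their own substream.
#' @param n_days Number of simulated days; defaults to accumulation + window.
#' @return A tibble with columns `individual`, `day`, `time_h`, `dose`,
#'   strictly time-ordered within each individual.
#' @export
generate_exposure_events <- function(individuals, config,
                                     seed = config$seed,
                                     n_days = config$total_days) {
  stopifnot(inherits(config, "urine_scenario"),
            all(c("individual", "gm_dose") %in% names(individuals)))
  if (n_days < 1L) stop("`n_days` must be >= 1.", call. = FALSE)
  out <- purrr::map2(individuals$individual, individuals$gm_dose,
    function(i, gm) {
      ev <- with_seed(derive_seed(seed, i, STAGE$events),
                      exposure_events_one(gm, config, n_days))
      ev$individual <- i
      ev
    })
  dplyr::bind_rows(out)[, c("individual", "day", "time_h", "dose")]
}
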