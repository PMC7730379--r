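# Which voids are "collected" and how samples pool.

#' Sampling days within the exposure window
#'
#' Picks the `max_samples` window days on which a sample is collected
#' (day indices 1..`window_days`). The default spreads them evenly:
#' `1 + round(j (W-1)/(m-1))`, `j = 0..m-1`; a single sample lands on the
#' window's midpoint day. `mode = "random"` draws days uniformly without
#' replacement using the current RNG state.
#'
#' @param window_days Length of the exposure window in days.
#' @param max_samples Number of sampling days (<= `window_days`).
#' @param mode `"even"` or `"random"`.
#' @return Sorted integer vector of day indices.
#' @export
sampling_days <- function(window_days, max_samples, mode = "even") {
  if (max_samples > window_days) {
    stop("`max_samples` cannot exceed `window_days` (one sample per day).",
         call. = FALSE)
  }
  if (mode == "random") {
    return(sort(sample.int(window_days, max_samples)))
  }
  if (max_samples == 1L) return(as.integer(round((window_days + 1) / 2)))
  j <- seq_len(max_samples) - 1L
  as.integer(1L + round(j * (window_days - 1) / (max_samples - 1L)))
}

# Concentration column per standardization mode.
conc_column <- function(standardization) {
  switch(standardization,
    none = "conc_raw",
    creatinine = "conc_creatinine",
    specific_gravity = "conc_sg",
    stop(sprintf("Unknown standardization \"%s\".", standardization),
         call. = FALSE)
  )
}

# One day's collected value from that day's voids (a list of aligned
# vectors, already carrying conc_raw/conc_creatinine/conc_sg). The
# whole-day scheme forms the 24-h composite first (volume-weighted analyte,
# creatinine and SG - 1, exactly what a lab would measure on an equal
# pooling of the full voids) and standardizes the composite; spot schemes
# pick one void and read off its standardized value.
collect_day <- function(day_voids, sample_timing, standardization,
                        sg_ref = 1.020) {
  nv <- length(day_voids$time_h)
  if (nv == 0L) {
    stop("Sampling day has no voids; schedules must provide daily voids.",
         call. = FALSE)
  }
  if (sample_timing == "whole_day_volume_weighted") {
    v <- day_voids$volume_L
    craw <- sum(day_voids$conc_raw * v) / sum(v)
    switch(standardization,
      none = craw,
      creatinine = craw / (sum(day_voids$creatinine_gL * v) / sum(v)),
      specific_gravity = {
        sg_comp <- 1 + sum((day_voids$specific_gravity - 1) * v) / sum(v)
        craw * (sg_ref - 1) / (sg_comp - 1)
      }
    )
  } else {
    tod <- day_voids$time_h %% 24
    pick <- switch(sample_timing,
      random_void = sample.int(nv, 1L),
      first_morning = 1L,
      first_evening = {
        evening <- which(tod >= 18)
        if (length(evening)) evening[1L] else nv
      },
      stop(sprintf("Unknown sample timing \"%s\".", sample_timing),
           call. = FALSE)
    )
    day_voids[[conc_column(standardization)]][pick]
  }
}

#' Collect urine samples for one individual
#'
#' Applies the scenario's sampling design to one individual's
#' concentration-annotated voids (from [void_concentrations()]): at most one
#' sample per day on the scenario's sampling days, selected as a random
#' void, the day's first void, the first void at or after 18:00 (falling
#' back to the day's last void), or the whole-day volume-weighted
#' composite. Random choices (random voids, random sampling days) use the
#' current RNG state.
#'
#' @param voids One individual's voids with a `day` column (absolute
#'   simulation day) and concentration columns.
#' @param config A [scenario()].
#' @param days Optional integer vector of window day indices to sample;
#'   default [sampling_days()] under the scenario.
#' @return A tibble with one row per sample: `sample` (chronological
#'   order), `window_day`, `day` (absolute), `concentration`.
#' @export
select_samples <- function(voids, config, days = NULL) {
  stopifnot(inherits(config, "urine_scenario"))
  if (is.null(days)) {
    days <- sampling_days(config$window_days, config$max_samples,
                          config$sampling_day_mode)
  }
  abs_days <- config$accum_days_sim + days
  cols <- c("time_h", "volume_L", "creatinine_gL", "specific_gravity",
            "conc_raw", "conc_creatinine", "conc_sg")
  by_day <- split(seq_len(nrow(voids)), voids$day)
  conc <- vapply(abs_days, function(d) {
    idx <- by_day[[as.character(d)]]
    day_voids <- lapply(cols, function(cl) voids[[cl]][idx]) |>
      stats::setNames(cols)
    collect_day(day_voids, config$sample_timing, config$standardization)
  }, numeric(1))
  tibble::tibble(sample = seq_along(days), window_day = as.integer(days),
                 day = as.integer(abs_days), concentration = conc)
}

#' Equal-volume pooling of collected samples
#'
#' Pooling equal volumes of `n` samples yields the unweighted arithmetic
#' mean of their concentrations, regardless of the underlying void volumes.
#' Pools are nested: the pool of size `n` uses the first `n` samples in
#' chronological order, so the reliability-vs-n curves reflect successively
#' adding samples.
#'
#' `pool_samples()` returns a single pooled value; `pool_curve()` returns
#' the whole nested-pool sequence.
#'
#' @param samples A tibble from [select_samples()] (columns `sample`,
#'   `concentration`).
#' @param n Pool size, between 1 and the number of samples.
#' @return `pool_samples()`: one number. `pool_curve()`: a tibble with
#'   columns `n`, `pooled`.
#' @export
pool_samples <- function(samples, n) {
  if (n < 1L || n > nrow(samples)) {
    stop(sprintf("Pool size n = %d out of range 1..%d.", n, nrow(samples)),
         call. = FALSE)
  }
  s <- samples[order(samples$sample), ]
  mean(s$concentration[seq_len(n)])
}

#' @rdname pool_samples
#' @export
pool_curve <- function(samples) {
  s <- samples[order(samples$sample), ]
  tibble::tibble(n = seq_len(nrow(s)),
                 pooled = cumsum(s$concentration) / seq_len(nrow(s)))
}
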