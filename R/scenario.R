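#' Exposure-pattern and sampling-scheme vocabularies
#'
#' `exposure_patterns()` and `sample_timings()` return the labels accepted by
#' [scenario()] for the daily exposure pattern and the timing of urine-sample
#' collection; `standardizations()` returns the urine-dilution adjustment modes.
#'
#' @return A character vector of valid labels.
#' @export
exposure_patterns <- function() {
  c(
    "once_random", "once_evening",
    "twice_random", "twice_morning_afternoon",
    "thrice_random", "thrice_morning_afternoon_evening"
  )
}

#' @rdname exposure_patterns
#' @export
sample_timings <- function() {
  c("random_void", "first_morning", "first_evening", "whole_day_volume_weighted")
}

#' @rdname exposure_patterns
#' @export
standardizations <- function() {
  c("none", "creatinine", "specific_gravity")
}

#' Default accumulation period before the exposure window
#'
#' The simulation runs an accumulation (burn-in) period of exposure before the
#' exposure period of interest so internal levels reach their long-run regime.
#' The default is seven biological half-lives, with a floor of 14 days.
#'
#' @param biological_half_life Elimination half-life in hours; must be > 0.
#' @return The accumulation period in days (not rounded).
#' @examples
#' default_accumulation_days(4)   # 14 (floor)
#' default_accumulation_days(96)  # 28
#' @export
default_accumulation_days <- function(biological_half_life) {
  if (!is.numeric(biological_half_life) || length(biological_half_life) != 1L ||
      !is.finite(biological_half_life) || biological_half_life <= 0) {
    stop("`biological_half_life` must be a single positive number of hours.",
         call. = FALSE)
  }
  max(14, 7 * biological_half_life / 24)
}

#' Define a simulation scenario
#'
#' A scenario bundles every input of the simulator: the chemical's
#' pharmacokinetics (elimination half-life and its population variability,
#' oral absorption half-life), the exposure pattern and its within- and
#' between-person log-normal variability, the exposure period of interest,
#' the urine-sampling design (number, timing, dilution standardization), the
#' population size, the accumulation period, and the seed.
#'
#' All durations given in days are also carried in hours internally
#' (simulation time is hours from midnight of day 1). A maximum of one
#' collected sample per day is allowed, so `max_samples <= window_days`.
#'
#' @param biological_half_life Elimination half-life, hours.
#' @param half_life_gsd Geometric standard deviation of the between-person
#'   half-life distribution (GSD >= 1; 1 means no variability). Default 1.3.
#' @param absorption_half_life Oral absorption half-life, hours. Default 0.4.
#' @param exposure_pattern One of [exposure_patterns()]. Default
#'   `"once_random"`.
#' @param within_gsd Within-person GSD of event doses (>= 1). Default 3.
#' @param between_gsd Between-person GSD of geometric-mean doses (>= 1).
#'   Default 2.
#' @param window_days Exposure period of interest, whole days (>= 1).
#'   Default 7.
#' @param max_samples Maximum number of urine samples collected per
#'   individual (1..`window_days`). Default 7.
#' @param sample_timing One of [sample_timings()]. Default `"random_void"`.
#' @param standardization One of [standardizations()]. Default `"none"`.
#' @param n_individuals Number of simulated individuals (>= 2). Default 3000.
#' @param accumulation_days Accumulation period in days; default
#'   [default_accumulation_days()] of the half-life. May be fractional; the
#'   simulated burn-in is rounded up to whole days so urination schedules
#'   align to calendar days.
#' @param fe Fraction of eliminated chemical excreted in urine as the
#'   measured analyte (0 < fe <= 1). Default 1. Reliability statistics are
#'   invariant to `fe`.
#' @param sampling_day_mode `"even"` spreads the sampling days evenly over
#'   the window (default); `"random"` draws them uniformly without
#'   replacement.
#' @param seed Integer root seed; every stochastic draw of a run derives
#'   from it. Default 1.
#' @return An object of class `urine_scenario`: a named list of validated
#'   fields plus derived hour quantities (`window_start_h`, `window_end_h`,
#'   `total_days`).
#' @examples
#' sc <- scenario(biological_half_life = 4)
#' sc$accumulation_days  # 14
#' @export
scenario <- function(biological_half_life,
                     half_life_gsd = 1.3,
                     absorption_half_life = 0.4,
                     exposure_pattern = "once_random",
                     within_gsd = 3,
                     between_gsd = 2,
                     window_days = 7L,
                     max_samples = 7L,
                     sample_timing = "random_void",
                     standardization = "none",
                     n_individuals = 3000L,
                     accumulation_days = NULL,
                     fe = 1,
                     sampling_day_mode = "even",
                     seed = 1L) {
  if (missing(biological_half_life)) {
    stop("`biological_half_life` is required (hours).", call. = FALSE)
  }
  if (is.null(accumulation_days)) {
    accumulation_days <- default_accumulation_days(biological_half_life)
  }
  cfg <- list(
    biological_half_life = as.numeric(biological_half_life),
    half_life_gsd = as.numeric(half_life_gsd),
    absorption_half_life = as.numeric(absorption_half_life),
    exposure_pattern = as.character(exposure_pattern),
    within_gsd = as.numeric(within_gsd),
    between_gsd = as.numeric(between_gsd),
    window_days = as.integer(window_days),
    max_samples = as.integer(max_samples),
    sample_timing = as.character(sample_timing),
    standardization = as.character(standardization),
    n_individuals = as.integer(n_individuals),
    accumulation_days = as.numeric(accumulation_days),
    fe = as.numeric(fe),
    sampling_day_mode = as.character(sampling_day_mode),
    seed = as.integer(seed)
  )
  validate_scenario(cfg)
}

# Field-by-field validation; returns the scenario with derived fields attached.
validate_scenario <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("Invalid scenario field `%s`: %s", field, msg), call. = FALSE)
  }
  pos <- function(field) {
    x <- cfg[[field]]
    if (length(x) != 1L || !is.finite(x) || x <= 0) {
      fail(field, "must be a single positive finite number")
    }
  }
  pos("biological_half_life")
  pos("absorption_half_life")
  pos("accumulation_days")
  for (f in c("half_life_gsd", "within_gsd", "between_gsd")) {
    x <- cfg[[f]]
    if (length(x) != 1L || !is.finite(x) || x < 1) {
      fail(f, "a geometric standard deviation must be >= 1")
    }
  }
  if (is.na(cfg$window_days) || cfg$window_days < 1L) {
    fail("window_days", "must be an integer >= 1")
  }
  if (is.na(cfg$max_samples) || cfg$max_samples < 1L) {
    fail("max_samples", "must be an integer >= 1")
  }
  if (cfg$max_samples > cfg$window_days) {
    fail("max_samples",
         sprintf("at most one sample per day is allowed, so max_samples (%d) cannot exceed window_days (%d)",
                 cfg$max_samples, cfg$window_days))
  }
  if (is.na(cfg$n_individuals) || cfg$n_individuals < 2L) {
    fail("n_individuals", "must be an integer >= 2")
  }
  if (!cfg$exposure_pattern %in% exposure_patterns()) {
    fail("exposure_pattern",
         sprintf("unknown label \"%s\"; valid: %s", cfg$exposure_pattern,
                 paste(exposure_patterns(), collapse = ", ")))
  }
  if (!cfg$sample_timing %in% sample_timings()) {
    fail("sample_timing",
         sprintf("unknown label \"%s\"; valid: %s", cfg$sample_timing,
                 paste(sample_timings(), collapse = ", ")))
  }
  if (!cfg$standardization %in% standardizations()) {
    fail("standardization",
         sprintf("unknown label \"%s\"; valid: %s", cfg$standardization,
                 paste(standardizations(), collapse = ", ")))
  }
  if (!cfg$sampling_day_mode %in% c("even", "random")) {
    fail("sampling_day_mode", "must be \"even\" or \"random\"")
  }
  if (length(cfg$fe) != 1L || !is.finite(cfg$fe) || cfg$fe <= 0 || cfg$fe > 1) {
    fail("fe", "must be in (0, 1]")
  }
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  if (cfg$absorption_half_life == cfg$biological_half_life) {
    fail("absorption_half_life",
         "absorption and elimination half-lives must differ (degenerate kinetics)")
  }
  # derived: hours from t = 0 at midnight of day 1
  cfg$accum_days_sim <- as.integer(ceiling(cfg$accumulation_days))
  cfg$total_days <- cfg$accum_days_sim + cfg$window_days
  cfg$window_start_h <- 24 * cfg$accum_days_sim
  cfg$window_end_h <- 24 * cfg$total_days
  structure(cfg, class = "urine_scenario")
}

#' @export
print.urine_scenario <- function(x, ...) {
  cat("<urine_scenario>\n")
  cat(sprintf("  chemical : t1/2 elim %g h (GSD %g), t1/2 abs %g h, fe %g\n",
              x$biological_half_life, x$half_life_gsd,
              x$absorption_half_life, x$fe))
  cat(sprintf("  exposure : %s, within GSD %g, between GSD %g\n",
              x$exposure_pattern, x$within_gsd, x$between_gsd))
  cat(sprintf("  design   : window %d d, accumulation %.2f d (%d simulated), %d samples (%s, %s days)\n",
              x$window_days, x$accumulation_days, x$accum_days_sim,
              x$max_samples, x$sample_timing, x$sampling_day_mode))
  cat(sprintf("  dilution : %s\n", x$standardization))
  cat(sprintf("  run      : %d individuals, seed %d\n", x$n_individuals, x$seed))
  invisible(x)
}

# Scenario fields that round-trip through the YAML file (derived fields are
# recomputed on load).
scenario_file_fields <- function() {
  c("biological_half_life", "half_life_gsd", "absorption_half_life",
    "exposure_pattern", "within_gsd", "between_gsd", "window_days",
    "max_samples", "sample_timing", "standardization", "n_individuals",
    "accumulation_days", "fe", "sampling_day_mode", "seed")
}

#' Read and write scenario files
#'
#' Scenarios are stored as YAML: one flat mapping with the fields of
#' [scenario()]. Absent fields take the documented defaults; unknown fields
#' are an error. JSON files are rejected with a pointer to the YAML format
#' (a single configuration dialect keeps runs reproducible from one file).
#'
#' @param path Path to a `.yml`/`.yaml` scenario file.
#' @return `read_scenario()` returns a validated `urine_scenario`;
#'   `write_scenario()` writes `x` and invisibly returns `path`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("Scenario file not found: %s", path), call. = FALSE)
  }
  first <- trimws(readLines(path, n = 1L, warn = FALSE))
  if (grepl("\\.json$", path, ignore.case = TRUE) ||
      (length(first) && startsWith(first, "{"))) {
    stop("Scenario files are YAML, not JSON; write a flat YAML mapping of scenario fields.",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) {
    stop("Scenario file must be a YAML mapping of field: value pairs.",
         call. = FALSE)
  }
  unknown <- setdiff(names(raw), scenario_file_fields())
  if (length(unknown)) {
    stop(sprintf("Unknown scenario field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!"biological_half_life" %in% names(raw)) {
    stop("Scenario file is missing required field `biological_half_life`.",
         call. = FALSE)
  }
  do.call(scenario, raw)
}

#' @rdname read_scenario
#' @param x A `urine_scenario`.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "urine_scenario"))
  yaml::write_yaml(unclass(x)[scenario_file_fields()], path)
  invisible(path)
}
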