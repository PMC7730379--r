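# End-to-end Monte Carlo run: population -> exposure events -> void
# schedules -> urinary profiles -> collected samples -> reliability report.

# Simulate one individual. `indrow` is one row of sample_individuals();
# every stochastic stage draws from its own seed derived from (root seed,
# individual index, stage), so results are independent of population size
# and of which other individuals are simulated.
simulate_individual <- function(indrow, bank, config, seed = config$seed) {
  i <- indrow$individual
  events <- with_seed(derive_seed(seed, i, STAGE$events),
                      exposure_events_one(indrow$gm_dose, config))
  voids <- with_seed(derive_seed(seed, i, STAGE$schedule),
                     assign_schedule_one(bank, config$total_days))
  params <- pk_params(config$absorption_half_life, indrow$half_life,
                      config$fe)
  voids <- void_concentrations(voids, events, params)
  auc <- window_auc(events, params, config$window_start_h,
                    config$window_end_h)
  samples <- with_seed(derive_seed(seed, i, STAGE$sampling),
                       select_samples(voids, config))
  list(events = events, voids = voids, samples = samples, auc = auc,
       template_id = attr(voids, "template_id"))
}

#' Run the full reliability simulation
#'
#' Simulates the scenario's population: draws per-person geometric-mean
#' doses and half-lives, generates timed oral exposures over the
#' accumulation period plus the exposure window, assigns synthetic (or
#' user-supplied) void schedules, computes internal kinetics and
#' void-by-void urinary concentrations analytically, collects and pools
#' samples, and assembles the reliability report.
#'
#' The run is a pure function of the scenario (including its seed): two
#' invocations give identical reports.
#'
#' @param config A [scenario()].
#' @param bank Optional void-schedule bank (e.g. from [read_schedules()]);
#'   by default a synthetic bank derived from the scenario seed.
#' @param keep_profiles Keep every individual's exposure events and
#'   concentration-annotated voids in the report (`$profiles`); off by
#'   default to bound memory at large populations.
#' @param quiet Suppress per-stage progress messages.
#' @return A `reliability_report` (see [build_report()]) with additional
#'   elements `individuals` (parameters and AUC per person), `manifest`
#'   (seed, package version, timestamps), and optionally `profiles`.
#' @examples
#' \donttest{
#' sc <- scenario(biological_half_life = 4, n_individuals = 100, seed = 7)
#' rep <- run_scenario(sc)
#' rep$curves
#' }
#' @export
run_scenario <- function(config, bank = NULL, keep_profiles = FALSE,
                         quiet = TRUE) {
  stopifnot(inherits(config, "urine_scenario"))
  started <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(bank)) {
    bank <- build_template_bank(seed = config$seed)
  }
  bank <- bank_index(bank)
  say("population: sampling %d individuals", config$n_individuals)
  individuals <- sample_individuals(config)
  n <- nrow(individuals)
  aucs <- numeric(n)
  tids <- integer(n)
  sample_rows <- vector("list", n)
  profiles <- if (keep_profiles) vector("list", n) else NULL
  say("simulation: %d days per individual", config$total_days)
  for (i in seq_len(n)) {
    sim <- tryCatch(
      simulate_individual(individuals[i, ], bank, config),
      error = function(e) {
        stop(sprintf("Simulation failed for individual %d: %s", i,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    aucs[i] <- sim$auc
    tids[i] <- sim$template_id
    s <- sim$samples
    s$individual <- individuals$individual[i]
    sample_rows[[i]] <- s
    if (keep_profiles) profiles[[i]] <- sim[c("events", "voids")]
  }
  individuals$template_id <- tids
  individuals$auc <- aucs
  samples <- dplyr::bind_rows(sample_rows)[, c("individual", "sample",
                                               "window_day", "day",
                                               "concentration")]
  say("report: reliability metrics for n = 1..%d", config$max_samples)
  report <- build_report(individuals[, c("individual", "auc")], samples,
                         config)
  report$individuals <- individuals
  report$samples <- samples
  if (keep_profiles) report$profiles <- profiles
  report$manifest <- list(
    seed = config$seed,
    version = as.character(utils::packageVersion("spoturine")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  report
}

#' Export one individual's temporal-variation series
#'
#' Recomputes a simulated individual's intake events and void-by-void
#' urinary concentrations (deterministic given the scenario seed) and
#' writes them as two CSVs: `individual_<i>_intake.csv` (`time_h`, `dose`)
#' and `individual_<i>_urine.csv` (`time_h`, raw and standardized
#' concentrations).
#'
#' @param x A `reliability_report` or a [scenario()].
#' @param individual Individual index, 1..`n_individuals`.
#' @param dir Output directory (created if needed).
#' @param bank Optional schedule bank; default as in [run_scenario()].
#' @return Invisibly, the two file paths.
#' @export
export_temporal <- function(x, individual, dir, bank = NULL) {
  config <- if (inherits(x, "reliability_report")) x$config else x
  stopifnot(inherits(config, "urine_scenario"))
  if (individual < 1L || individual > config$n_individuals) {
    stop(sprintf("`individual` must be in 1..%d.", config$n_individuals),
         call. = FALSE)
  }
  if (is.null(bank)) bank <- build_template_bank(seed = config$seed)
  indrow <- sample_individuals(config)[individual, ]
  sim <- simulate_individual(indrow, bank, config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  intake <- file.path(dir, sprintf("individual_%d_intake.csv", individual))
  urine <- file.path(dir, sprintf("individual_%d_urine.csv", individual))
  readr::write_csv(sim$events[, c("time_h", "dose")], intake)
  readr::write_csv(
    dplyr::rename(
      sim$voids[, c("time_h", "conc_raw", "conc_creatinine", "conc_sg")],
      concentration_raw = "conc_raw",
      concentration_creatinine = "conc_creatinine",
      concentration_sg = "conc_sg"
    ), urine)
  invisible(c(intake, urine))
}

#' Write a reliability report to disk
#'
#' Emits the report's tables as CSV (`r2_by_n.csv`, `accuracy_by_n.csv`,
#' `scatter_max_n.csv`), the ICC as `icc.txt`, the scenario as
#' `scenario.yml`, and `manifest.json` recording the seed, package version,
#' timestamps and an MD5 inventory of the written files.
#'
#' @param report A `reliability_report` from [run_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "reliability_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    r2 = file.path(dir, "r2_by_n.csv"),
    acc = file.path(dir, "accuracy_by_n.csv"),
    scatter = file.path(dir, "scatter_max_n.csv"),
    icc = file.path(dir, "icc.txt"),
    scenario = file.path(dir, "scenario.yml")
  )
  readr::write_csv(report$curves[, c("n", "r2")], paths[["r2"]])
  readr::write_csv(report$curves[, c("n", "tertile_accuracy",
                                     "quartile_accuracy")], paths[["acc"]])
  readr::write_csv(report$scatter, paths[["scatter"]])
  writeLines(c(
    sprintf("ICC (one-way ANOVA, log scale, k = %d): %s", report$icc$k,
            format(report$icc$icc, digits = 6)),
    sprintf("raw (unclipped) estimate: %s",
            format(report$icc$icc_raw, digits = 6)),
    sprintf("MSB = %s, MSW = %s", format(report$icc$msb, digits = 6),
            format(report$icc$msw, digits = 6))
  ), paths[["icc"]])
  write_scenario(report$config, paths[["scenario"]])
  manifest <- c(report$manifest %||% list(), list(
    files = lapply(as.list(paths), function(p) {
      list(name = basename(p), md5 = unname(tools::md5sum(p)))
    })
  ))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, manifest = manifest_path))
}
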