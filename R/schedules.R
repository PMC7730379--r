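# Synthetic urination-schedule bank.
#
# The simulator needs realistic per-person void schedules (times, volumes,
# creatinine, specific gravity). The defaults below are explicit, replaceable
# generating rules chosen to resemble healthy adults: 4-9 voids/day, 24-h
# urine volume log-normal (GM 1.5 L, GSD 1.4), near-constant daily creatinine
# excretion per person (normal, mean 1.2 g/day, SD 0.25, truncated > 0.4),
# and specific gravity tied linearly to creatinine concentration. Real void
# data can be supplied instead via read_schedules().

SG_SLOPE <- 0.0075 / 0.45   # (SG - 1) per g/L creatinine
SG_RANGE <- c(1.002, 1.035)

# One synthetic day for a template with daily creatinine excretion `creat_day`
# (g/day). The first (overnight) void falls in 05:00-09:00 and carries double
# Dirichlet weight, the last (pre-bed) void in 21:00-23:00 as in adult
# voiding diaries, interior voids in between. The first void's solute
# interval reaches back to the previous day's last void, assuming the day
# pattern tiles a 24-h cycle, so per-void creatinine mass sums exactly to
# `creat_day`.
synth_day <- function(creat_day, void_counts = 4:9,
                      volume_gm = 1.5, volume_gsd = 1.4) {
  n <- sample(void_counts, 1L)
  total_vol <- stats::rlnorm(1L, log(volume_gm), log(volume_gsd))
  first <- stats::runif(1L, 5, 9)
  last <- stats::runif(1L, 21, 23)  # pre-bed void
  repeat {
    mid <- sort(stats::runif(n - 2L, first, last))
    tod <- c(first, mid, last)
    if (!anyDuplicated(tod)) break
  }
  w <- stats::rgamma(n, shape = c(8, rep(4, n - 1L)))
  vol <- total_vol * w / sum(w)
  gaps <- c(tod[1] + 24 - tod[n], diff(tod))
  creat <- creat_day * (gaps / 24) / vol
  sg <- pmin(pmax(1 + SG_SLOPE * creat, SG_RANGE[1]), SG_RANGE[2])
  tibble::tibble(void = seq_len(n), time_of_day_h = tod, volume_L = vol,
                 creatinine_gL = creat, specific_gravity = sg)
}

#' Build a synthetic bank of urination-schedule templates
#'
#' A template plays the role of one donor: a small set of single-day void
#' sequences that simulated individuals resample day by day. The default
#' bank mirrors a panel of 8 donors observed for 6 days each.
#'
#' @param n_templates Number of templates (donors). Default 8.
#' @param days_per_template Day patterns per template. Default 6.
#' @param seed Optional seed; when given, the bank is a pure function of it.
#' @param void_counts Integer vector of admissible voids per day.
#' @param volume_gm,volume_gsd Geometric mean (L) and GSD of 24-h urine
#'   volume.
#' @param creat_mean,creat_sd Mean and SD (g/day) of per-template daily
#'   creatinine excretion (normal, truncated below `creat_min`).
#' @param creat_min Lower truncation for daily creatinine excretion (g/day).
#' @return A tibble with columns `template_id`, `day`, `void`,
#'   `time_of_day_h`, `volume_L`, `creatinine_gL`, `specific_gravity`, and a
#'   `creat_day` attribute (g/day per template).
#' @export
build_template_bank <- function(n_templates = 8L, days_per_template = 6L,
                                seed = NULL, void_counts = 4:9,
                                volume_gm = 1.5, volume_gsd = 1.4,
                                creat_mean = 1.2, creat_sd = 0.25,
                                creat_min = 0.4) {
  if (n_templates < 1L || days_per_template < 1L) {
    stop("`n_templates` and `days_per_template` must be >= 1.", call. = FALSE)
  }
  build <- function() {
    creat_day <- numeric(n_templates)
    rows <- vector("list", n_templates * days_per_template)
    k <- 0L
    for (t in seq_len(n_templates)) {
      repeat {
        e <- stats::rnorm(1L, creat_mean, creat_sd)
        if (e > creat_min) break
      }
      creat_day[t] <- e
      for (d in seq_len(days_per_template)) {
        day <- synth_day(e, void_counts, volume_gm, volume_gsd)
        day$template_id <- t
        day$day <- d
        k <- k + 1L
        rows[[k]] <- day
      }
    }
    bank <- dplyr::bind_rows(rows)[, c("template_id", "day", "void",
                                       "time_of_day_h", "volume_L",
                                       "creatinine_gL", "specific_gravity")]
    attr(bank, "creat_day") <- creat_day
    bank
  }
  if (is.null(seed)) build() else {
    with_seed(derive_seed(seed, 0L, STAGE$bank), build())
  }
}

# Pre-index a bank tibble into plain per-template, per-day column vectors
# (one conversion per run instead of one per individual).
bank_index <- function(bank) {
  if (inherits(bank, "schedule_bank_index")) return(bank)
  cols <- c("time_of_day_h", "volume_L", "creatinine_gL", "specific_gravity")
  ids <- unique(bank$template_id)
  templates <- lapply(ids, function(tid) {
    tpl <- bank[bank$template_id == tid, ]
    lapply(split(seq_len(nrow(tpl)), tpl$day), function(idx) {
      lapply(cols, function(cl) tpl[[cl]][idx]) |> stats::setNames(cols)
    })
  })
  structure(list(ids = ids, templates = templates),
            class = "schedule_bank_index")
}

# Void schedule for one individual using the current RNG state: one template
# chosen uniformly (fixed for the whole simulation), then one of its day
# patterns per simulated day, with replacement. Times become absolute hours.
assign_schedule_one <- function(bank, n_days) {
  if (n_days <= 0L) stop("`n_days` must be positive.", call. = FALSE)
  idx <- bank_index(bank)
  ti <- sample.int(length(idx$ids), 1L)
  days <- idx$templates[[ti]]
  picks <- sample.int(length(days), n_days, replace = TRUE)
  parts <- days[picks]
  nv <- vapply(parts, function(p) length(p$time_of_day_h), integer(1))
  day <- rep(seq_len(n_days), nv)
  pull <- function(col) unlist(lapply(parts, `[[`, col), use.names = FALSE)
  out <- tibble::tibble(
    day = day,
    time_h = 24 * (day - 1L) + pull("time_of_day_h"),
    volume_L = pull("volume_L"),
    creatinine_gL = pull("creatinine_gL"),
    specific_gravity = pull("specific_gravity")
  )
  attr(out, "template_id") <- idx$ids[ti]
  out
}

#' Assign void schedules to a population
#'
#' Each individual draws one template from the bank (kept for the whole
#' simulation) and, for every simulated day, one of that template's day
#' patterns uniformly with replacement. Per-individual derived seeds make
#' each individual's schedule independent of the population size.
#'
#' @param individuals Tibble with an `individual` column.
#' @param bank A template bank from [build_template_bank()] or
#'   [read_schedules()].
#' @param n_days Number of simulated days.
#' @param seed Root seed.
#' @return A tibble of void events: `individual`, `template_id`, `day`,
#'   `time_h` (absolute hours), `volume_L`, `creatinine_gL`,
#'   `specific_gravity`; strictly time-ordered within each individual.
#' @export
assign_schedules <- function(individuals, bank, n_days, seed = 1L) {
  out <- purrr::map(individuals$individual, function(i) {
    v <- with_seed(derive_seed(seed, i, STAGE$schedule),
                   assign_schedule_one(bank, n_days))
    v$individual <- i
    v$template_id <- attr(v, "template_id")
    v
  })
  dplyr::bind_rows(out)[, c("individual", "template_id", "day", "time_h",
                            "volume_L", "creatinine_gL", "specific_gravity")]
}

#' Read and write void-schedule banks as CSV
#'
#' The CSV carries one row per void with columns `template_id`, `day`,
#' `time_of_day_h`, `volume_L`, `creatinine_gL`, `specific_gravity`, letting
#' users substitute real diary data for the synthetic bank. Rows violating
#' the void invariants (non-positive volume or creatinine, specific gravity
#' at or below 1, non-increasing times within a template-day) are reported
#' with their row numbers.
#'
#' @param path CSV file path.
#' @return `read_schedules()` returns a bank tibble as in
#'   [build_template_bank()]; `write_schedules()` invisibly returns `path`.
#' @export
read_schedules <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("Schedule file not found: %s", path), call. = FALSE)
  }
  req <- c("template_id", "day", "time_of_day_h", "volume_L",
           "creatinine_gL", "specific_gravity")
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop(sprintf("Schedule CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  row <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("Schedule CSV: %s at line(s) %s", what,
                   paste(utils::head(row[cond], 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad(!is.finite(df$volume_L) | df$volume_L <= 0, "non-positive volume")
  bad(!is.finite(df$creatinine_gL) | df$creatinine_gL <= 0,
      "non-positive creatinine")
  bad(!is.finite(df$specific_gravity) | df$specific_gravity <= 1,
      "specific gravity must exceed 1")
  bad(!is.finite(df$time_of_day_h) | df$time_of_day_h < 0 |
        df$time_of_day_h >= 24, "time of day outside [0, 24)")
  df <- dplyr::arrange(df, .data$template_id, .data$day)
  grp <- paste(df$template_id, df$day)
  for (g in unique(grp)) {
    t <- df$time_of_day_h[grp == g]
    if (any(diff(t) <= 0)) {
      stop(sprintf("Schedule CSV: void times not strictly increasing in template %s, day %s",
                   sub(" .*", "", g), sub(".* ", "", g)), call. = FALSE)
    }
  }
  df$void <- stats::ave(df$time_of_day_h, grp, FUN = seq_along)
  df[, c("template_id", "day", "void", "time_of_day_h", "volume_L",
         "creatinine_gL", "specific_gravity")]
}

#' @rdname read_schedules
#' @param bank A bank tibble.
#' @export
write_schedules <- function(bank, path) {
  cols <- c("template_id", "day", "time_of_day_h", "volume_L",
            "creatinine_gL", "specific_gravity")
  readr::write_csv(bank[, cols], path)
  invisible(path)
}
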