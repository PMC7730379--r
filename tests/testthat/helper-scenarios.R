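# Small scenario factory for fast tests; overridable per call.
tiny_scenario <- function(...) {
  args <- utils::modifyList(
    list(biological_half_life = 4, n_individuals = 30L, window_days = 7L,
         max_samples = 7L, seed = 42L),
    list(...)
  )
  do.call(scenario, args)
}

# Hand-built voids for one individual on absolute days, with concentration
# columns filled directly (bypasses the PK layer).
toy_voids <- function(day, time_of_day, conc, vol,
                      creat = rep(1, length(conc)),
                      sg = rep(1.015, length(conc))) {
  tibble::tibble(
    day = as.integer(day),
    time_h = 24 * (day - 1) + time_of_day,
    volume_L = vol, creatinine_gL = creat, specific_gravity = sg,
    conc_raw = conc, conc_creatinine = conc / creat,
    conc_sg = conc * (1.020 - 1) / (sg - 1)
  )
}

# Independent trapezoidal AUC oracle on a fine grid hitting both endpoints.
trapz_auc <- function(events, params, from, to, dt = 0.01) {
  t <- seq(from, to, length.out = ceiling((to - from) / dt) + 1L)
  a <- internal_amount(events, params, t)
  sum((a[-1] + a[-length(a)]) / 2 * diff(t))
}

# Independent event-count table for the exposure patterns.
events_per_day_oracle <- function(p) {
  c(once_random = 1L, once_evening = 1L, twice_random = 2L,
    twice_morning_afternoon = 2L, thrice_random = 3L,
    thrice_morning_afternoon_evening = 3L)[[p]]
}

# Run expr under a seed without touching the session RNG afterwards.
with_seed_local <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
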