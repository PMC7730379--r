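# One-compartment first-order absorption/elimination kinetics, solved
# analytically per exposure event and superposed. The volume of distribution
# is fixed at 1 so "amount in the central compartment" and "internal
# concentration" coincide; all reliability statistics are invariant to this
# constant and to the urinary excretion fraction fe.

#' Pharmacokinetic parameters
#'
#' Converts half-lives into first-order rate constants: `ka = ln 2 /
#' absorption half-life`, `ke = ln 2 / elimination half-life`. Absorption
#' must be faster than elimination (`ka > ke`); equal rates give the
#' degenerate limit of the two-exponential solution and are rejected.
#'
#' @param absorption_half_life Oral absorption half-life, hours.
#' @param elimination_half_life Elimination (biological) half-life, hours.
#' @param fe Fraction of elimination excreted in urine as the measured
#'   analyte (0 < fe <= 1).
#' @return A list with class `pk_params`: `ka`, `ke` (1/h) and `fe`.
#' @examples
#' pk_params(0.4, 4)
#' @export
pk_params <- function(absorption_half_life, elimination_half_life, fe = 1) {
  if (absorption_half_life <= 0 || elimination_half_life <= 0) {
    stop("Half-lives must be positive.", call. = FALSE)
  }
  if (absorption_half_life >= elimination_half_life) {
    stop("Absorption half-life must be shorter than the elimination half-life (ka > ke required).",
         call. = FALSE)
  }
  if (fe <= 0 || fe > 1) stop("`fe` must be in (0, 1].", call. = FALSE)
  structure(list(ka = log(2) / absorption_half_life,
                 ke = log(2) / elimination_half_life,
                 fe = fe),
            class = "pk_params")
}

# Columns `time_h` and `dose` are required of every event table.
check_events <- function(events) {
  if (!all(c("time_h", "dose") %in% names(events))) {
    stop("`events` needs columns `time_h` and `dose`.", call. = FALSE)
  }
  invisible(events)
}

#' Amount of chemical in the central compartment
#'
#' Superposes the two-exponential (first-order absorption, first-order
#' elimination) solution over all exposure events at or before each
#' evaluation time: each event of dose D taken at time t0 contributes
#' `D ka/(ka-ke) (exp(-ke tau) - exp(-ka tau))` with `tau = t - t0`.
#'
#' @param events Tibble of exposure events (`time_h`, `dose`).
#' @param params A [pk_params()].
#' @param t Vector of evaluation times, hours.
#' @return Numeric vector of internal amounts at `t`.
#' @export
internal_amount <- function(events, params, t) {
  check_events(events)
  if (nrow(events) == 0L) return(numeric(length(t)))
  tau <- pmax(outer(t, events$time_h, "-"), 0)
  with(params, {
    contrib <- (ka / (ka - ke)) * (exp(-ke * tau) - exp(-ka * tau))
    as.numeric(contrib %*% events$dose)
  })
}

#' Cumulative mass of analyte excreted in urine
#'
#' The urinary elimination flux is `fe * ke * A(t)`; integrating the
#' superposed solution gives, per event,
#' `fe D [1 - (ka exp(-ke tau) - ke exp(-ka tau)) / (ka - ke)]`.
#' The result is non-decreasing in `t` and tends to `fe` times the total
#' dose.
#'
#' @inheritParams internal_amount
#' @return Numeric vector of cumulative excreted mass at `t`.
#' @export
cumulative_urinary_mass <- function(events, params, t) {
  check_events(events)
  if (nrow(events) == 0L) return(numeric(length(t)))
  tau <- pmax(outer(t, events$time_h, "-"), 0)
  with(params, {
    contrib <- 1 - (ka * exp(-ke * tau) - ke * exp(-ka * tau)) / (ka - ke)
    fe * as.numeric(contrib %*% events$dose)
  })
}

#' Area under the internal amount curve over a time window
#'
#' Closed-form integral of the superposed solution over
#' `[window_start, window_end]`; events after the window end contribute
#' nothing, events inside it contribute from their own time.
#'
#' @inheritParams internal_amount
#' @param window_start,window_end Window bounds in hours,
#'   `window_start < window_end`.
#' @return The AUC in amount x hours.
#' @export
window_auc <- function(events, params, window_start, window_end) {
  check_events(events)
  if (!(window_start < window_end)) {
    stop("`window_start` must be strictly before `window_end`.", call. = FALSE)
  }
  if (nrow(events) == 0L) return(0)
  keep <- events$time_h < window_end
  if (!any(keep)) return(0)
  t0 <- events$time_h[keep]
  d <- events$dose[keep]
  a <- pmax(window_start, t0) - t0
  b <- window_end - t0
  with(params, {
    piece <- (exp(-ke * a) - exp(-ke * b)) / ke -
             (exp(-ka * a) - exp(-ka * b)) / ka
    sum(d * (ka / (ka - ke)) * piece)
  })
}

#' Void-by-void urinary concentrations
#'
#' Bladder accounting: the analyte mass in a void is everything eliminated
#' in urine since the previous void (the first void drains from t = 0).
#' The raw concentration is that mass over the void volume. Two
#' dilution-standardized variants are attached: per gram creatinine
#' (`conc_creatinine = conc_raw / creatinine`) and specific-gravity
#' standardized (`conc_sg = conc_raw * (sg_ref - 1) / (SG - 1)`).
#'
#' @param voids Tibble of one individual's voids (`time_h`, `volume_L`,
#'   `creatinine_gL`, `specific_gravity`), strictly time-ordered.
#' @param events Tibble of the same individual's exposure events.
#' @param params A [pk_params()].
#' @param sg_ref Reference specific gravity for standardization.
#' @return `voids` with columns `conc_raw`, `conc_creatinine`, `conc_sg`
#'   added.
#' @export
void_concentrations <- function(voids, events, params, sg_ref = 1.020) {
  req <- c("time_h", "volume_L", "creatinine_gL", "specific_gravity")
  if (!all(req %in% names(voids))) {
    stop(sprintf("`voids` needs columns %s.", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  if (is.unsorted(voids$time_h, strictly = TRUE)) {
    stop("Void times must be strictly increasing.", call. = FALSE)
  }
  if (any(voids$volume_L <= 0)) {
    stop("Void volumes must be positive.", call. = FALSE)
  }
  m <- cumulative_urinary_mass(events, params, voids$time_h)
  dm <- diff(c(0, m))
  voids$conc_raw <- dm / voids$volume_L
  voids$conc_creatinine <- voids$conc_raw / voids$creatinine_gL
  voids$conc_sg <- voids$conc_raw * (sg_ref - 1) / (voids$specific_gravity - 1)
  voids
}
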