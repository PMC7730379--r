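params_default <- function() pk_params(0.4, 4)

test_that("rate constants derive from half-lives and degenerate kinetics are rejected", {
  p <- params_default()
  expect_equal(p$ka, log(2) / 0.4)
  expect_equal(p$ke, log(2) / 4)
  expect_error(pk_params(4, 4), "half-life")
  expect_error(pk_params(5, 4), "half-life")   # absorption slower than elimination
  expect_error(pk_params(-1, 4), "positive")
  expect_error(pk_params(0.4, 4, fe = 0), "fe")
  expect_error(pk_params(0.4, 4, fe = 1.2), "fe")
})

test_that("internal amount matches the closed form and an ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- params_default()
  ev <- tibble::tibble(time_h = 0, dose = 1)
  # closed form at t = 1 h: (10/9) (2^-0.25 - 2^-2.5)
  expect_equal(internal_amount(ev, p, 1), (10 / 9) * (2^-0.25 - 2^-2.5),
               tolerance = 1e-12)
  # independent oracle: numeric integration of the gut/central ODE system
  ode_fun <- function(t, y, parms) {
    list(c(-parms$ka * y[1], parms$ka * y[1] - parms$ke * y[2]))
  }
  sol <- deSolve::ode(y = c(gut = 1, central = 0), times = seq(0, 24, 0.25),
                      func = ode_fun, parms = p, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(internal_amount(ev, p, sol[, "time"]),
               unname(sol[, "central"]), tolerance = 1e-7)
})

test_that("no exposure events give identically zero outputs", {
  p <- params_default()
  none <- tibble::tibble(time_h = numeric(), dose = numeric())
  t <- c(0, 1, 10, 100)
  expect_equal(internal_amount(none, p, t), rep(0, 4))
  expect_equal(cumulative_urinary_mass(none, p, t), rep(0, 4))
  expect_equal(window_auc(none, p, 0, 100), 0)
})

test_that("cumulative urinary mass matches quadrature and conserves dose", {
  p <- params_default()
  ev <- tibble::tibble(time_h = 0, dose = 1)
  # closed form at t = 4 h (one elimination half-life)
  m4 <- with(p, 1 - (ka * 2^-1 - ke * 2^-10) / (ka - ke))
  expect_equal(cumulative_urinary_mass(ev, p, 4), m4, tolerance = 1e-12)
  # oracle: numerical quadrature of the urinary flux ke * A(s)
  quad <- stats::integrate(function(s) p$ke * internal_amount(ev, p, s),
                           0, 4, rel.tol = 1e-10)
  expect_equal(m4, quad$value, tolerance = 1e-8)
  # essentially all of the dose is excreted by 20 elimination half-lives:
  # exact residual is ka/(ka-ke) * 2^-20 - (tiny ka term) = 1.06e-6
  expect_equal(cumulative_urinary_mass(ev, p, 20 * 4), 1, tolerance = 1e-4)
  expect_gte(cumulative_urinary_mass(ev, p, 20 * 4), 1 - 1.2e-6)
  expect_equal(cumulative_urinary_mass(ev, p, 0), 0)
  # non-decreasing in t, and scales with fe
  t <- seq(0, 48, by = 0.5)
  expect_true(all(diff(cumulative_urinary_mass(ev, p, t)) >= 0))
  p5 <- pk_params(0.4, 4, fe = 0.5)
  expect_equal(cumulative_urinary_mass(ev, p5, t),
               0.5 * cumulative_urinary_mass(ev, p, t))
})

test_that("mass balance holds for random multi-event histories", {
  p <- params_default()
  set.seed(31)
  for (rep in 1:5) {
    ev <- tibble::tibble(time_h = sort(runif(10, 0, 72)),
                         dose = rlnorm(10, 0, 1))
    t_end <- max(ev$time_h) + 20 * 4
    expect_equal(cumulative_urinary_mass(ev, p, t_end), sum(ev$dose),
                 tolerance = 1e-4)
  }
})

test_that("window AUC agrees with the infinite-horizon value and trapezoids", {
  p <- params_default()
  ev <- tibble::tibble(time_h = 0, dose = 1)
  auc <- window_auc(ev, p, 0, 20 * 4)
  expect_equal(auc, 1 / p$ke, tolerance = 1e-4)   # D / ke = 4 / ln 2
  expect_equal(auc, trapz_auc(ev, p, 0, 80), tolerance = 1e-4)
  expect_error(window_auc(ev, p, 5, 5), "strictly before")
})

test_that("window AUC matches trapezoidal integration on random event sets", {
  p <- params_default()
  set.seed(77)
  for (rep in 1:5) {
    ev <- tibble::tibble(time_h = sort(runif(8, 0, 48)),
                         dose = rlnorm(8, 0, 1))
    w <- sort(runif(2, 0, 96))
    if (diff(w) < 1) w[2] <- w[1] + 1
    expect_equal(window_auc(ev, p, w[1], w[2]),
                 trapz_auc(ev, p, w[1], w[2], dt = 0.005),
                 tolerance = 1e-4)
  }
})

test_that("all PK outputs are linear in dose", {
  p <- params_default()
  set.seed(19)
  ev <- tibble::tibble(time_h = sort(runif(6, 0, 24)), dose = rlnorm(6))
  ev2 <- dplyr::mutate(ev, dose = 2 * dose)
  t <- seq(0, 48, by = 1)
  expect_equal(internal_amount(ev2, p, t), 2 * internal_amount(ev, p, t))
  expect_equal(cumulative_urinary_mass(ev2, p, t),
               2 * cumulative_urinary_mass(ev, p, t))
  expect_equal(window_auc(ev2, p, 0, 48), 2 * window_auc(ev, p, 0, 48))
})

test_that("void concentrations implement bladder accounting and standardization", {
  p <- params_default()
  ev <- tibble::tibble(time_h = c(8, 32), dose = c(1, 2))
  voids <- tibble::tibble(
    time_h = c(7, 12, 20, 30, 44),
    volume_L = c(0.3, 0.2, 0.4, 0.25, 0.35),
    creatinine_gL = c(1.2, 0.8, 1.0, 1.5, 0.9),
    specific_gravity = c(1.018, 1.010, 1.015, 1.022, 1.012)
  )
  out <- void_concentrations(voids, ev, p)
  m <- cumulative_urinary_mass(ev, p, voids$time_h)
  expect_equal(out$conc_raw, diff(c(0, m)) / voids$volume_L)
  # excreted mass is fully recovered across the voids
  expect_equal(sum(out$conc_raw * out$volume_L), m[5], tolerance = 1e-12)
  # standardizations are simple rescalings of the raw concentration
  expect_equal(out$conc_creatinine, out$conc_raw / voids$creatinine_gL)
  expect_equal(out$conc_sg,
               out$conc_raw * 0.020 / (voids$specific_gravity - 1))
  # raw 10 units/L with creatinine 1 g/L is 10 units/g; SG 1.010 doubles it
  m10 <- cumulative_urinary_mass(ev, p, 10)
  one <- void_concentrations(
    tibble::tibble(time_h = 10, volume_L = m10 / 10,
                   creatinine_gL = 1, specific_gravity = 1.010),
    ev, p)
  expect_equal(one$conc_raw, 10)
  expect_equal(one$conc_creatinine, 10)
  expect_equal(one$conc_sg, 20)
})

test_that("splitting a void interval conserves excreted mass", {
  p <- params_default()
  ev <- tibble::tibble(time_h = c(8, 32), dose = c(1, 2))
  voids <- tibble::tibble(time_h = c(12, 36), volume_L = c(0.5, 0.5),
                          creatinine_gL = 1, specific_gravity = 1.015)
  split2 <- tibble::tibble(time_h = c(12, 24, 36),
                           volume_L = c(0.5, 0.2, 0.3),
                           creatinine_gL = 1, specific_gravity = 1.015)
  a <- void_concentrations(voids, ev, p)
  b <- void_concentrations(split2, ev, p)
  expect_equal(sum(a$conc_raw * a$volume_L), sum(b$conc_raw * b$volume_L),
               tolerance = 1e-12)
  expect_equal(a$conc_raw[1], b$conc_raw[1])

  expect_error(void_concentrations(dplyr::mutate(voids, volume_L = 0), ev, p),
               "positive")
  expect_error(void_concentrations(voids[c(2, 1), ], ev, p), "increasing")
})
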