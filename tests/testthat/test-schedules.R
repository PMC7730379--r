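test_that("default bank has 8 templates of 6 day patterns with valid voids", {
  bank <- build_template_bank(seed = 1)
  expect_setequal(unique(bank$template_id), 1:8)
  counts <- dplyr::count(bank, template_id, day)
  expect_equal(nrow(counts), 48L)
  expect_true(all(counts$n >= 4 & counts$n <= 9))
  expect_true(all(bank$volume_L > 0))
  expect_true(all(bank$creatinine_gL > 0))
  expect_true(all(bank$specific_gravity >= 1.002 &
                    bank$specific_gravity <= 1.035))
  firsts <- bank |> dplyr::group_by(template_id, day) |>
    dplyr::summarise(first = min(time_of_day_h),
                     mono = !is.unsorted(time_of_day_h, strictly = TRUE),
                     .groups = "drop")
  expect_true(all(firsts$first >= 5 & firsts$first <= 9))
  expect_true(all(firsts$mono))
})

test_that("daily creatinine mass balances the template's excretion rate", {
  bank <- build_template_bank(seed = 2)
  e <- attr(bank, "creat_day")
  daily <- bank |> dplyr::group_by(template_id, day) |>
    dplyr::summarise(mass = sum(creatinine_gL * volume_L), .groups = "drop")
  expect_equal(daily$mass, e[daily$template_id], tolerance = 1e-9)
  # near-constant per person, plausible population spread
  expect_true(all(e > 0.4))
})

test_that("synthetic days reproduce the stated generating distributions", {
  # 1000 days in total across many templates
  bank <- build_template_bank(n_templates = 100, days_per_template = 10,
                              seed = 33)
  daily <- bank |> dplyr::group_by(template_id, day) |>
    dplyr::summarise(vol24 = sum(volume_L), .groups = "drop")
  expect_gte(nrow(daily), 1000L)
  expect_gt(stats::median(daily$vol24), 1.2)
  expect_lt(stats::median(daily$vol24), 1.9)

  # oracle: direct simulation of the generating rules, independent of the
  # package's implementation
  oracle_sg <- with_seed_local(99, {
    sims <- replicate(2000, {
      repeat {
        e <- rnorm(1, 1.2, 0.25)
        if (e > 0.4) break
      }
      n <- sample(4:9, 1)
      v24 <- rlnorm(1, log(1.5), log(1.4))
      tod <- c(runif(1, 5, 9), sort(runif(n - 2, 9, 21)), runif(1, 21, 23))
      w <- rgamma(n, shape = c(8, rep(4, n - 1)))
      vol <- v24 * w / sum(w)
      gaps <- c(tod[1] + 24 - tod[n], diff(tod))
      creat <- e * (gaps / 24) / vol
      pmin(pmax(1 + 0.0075 * creat / 0.45, 1.002), 1.035)
    })
    stats::median(unlist(sims))
  })
  med_sg <- stats::median(bank$specific_gravity)
  expect_equal(med_sg, oracle_sg, tolerance = 2e-3)
  # plausible dilute-to-concentrated adult spot-urine range
  expect_gt(med_sg, 1.005)
  expect_lt(med_sg, 1.030)
})

test_that("assigned schedules resample one template's days with replacement", {
  bank <- build_template_bank(seed = 4)
  ind <- tibble::tibble(individual = 1:5)
  voids <- assign_schedules(ind, bank, n_days = 14, seed = 10)
  counts <- dplyr::count(voids, individual)
  expect_true(all(counts$n >= 14 * 4 & counts$n <= 14 * 9))
  expect_equal(dplyr::n_distinct(voids$day), 14L)
  # one template per individual, held fixed
  tpl <- voids |> dplyr::group_by(individual) |>
    dplyr::summarise(k = dplyr::n_distinct(template_id))
  expect_true(all(tpl$k == 1L))
  # strictly increasing absolute times within individuals
  mono <- voids |> dplyr::group_by(individual) |>
    dplyr::summarise(ok = !is.unsorted(time_h, strictly = TRUE))
  expect_true(all(mono$ok))
  # determinism and independence from the rest of the population
  again <- assign_schedules(ind, bank, n_days = 14, seed = 10)
  expect_identical(voids, again)
  sub <- assign_schedules(ind[1:2, ], bank, n_days = 14, seed = 10)
  expect_identical(sub, voids[voids$individual <= 2, ])
  expect_error(assign_schedules(ind, bank, n_days = 0, seed = 1), "positive")
})

test_that("two individuals on the same template draw different day sequences", {
  # one-template bank forces a shared template; day picks still differ
  bank <- build_template_bank(n_templates = 1, seed = 6)
  ind <- tibble::tibble(individual = 1:2)
  voids <- assign_schedules(ind, bank, n_days = 14, seed = 3)
  key <- voids |> dplyr::group_by(individual, day) |>
    dplyr::summarise(sig = paste(round(volume_L, 9), collapse = ","),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = individual, values_from = sig)
  expect_false(all(key[[2]] == key[[3]]))
})

test_that("schedule CSVs round-trip and invalid rows are addressed", {
  bank <- build_template_bank(n_templates = 2, days_per_template = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedules(bank, path)
  back <- read_schedules(path)
  expect_equal(dplyr::n_distinct(back$template_id), 2L)
  expect_equal(back$volume_L, bank$volume_L, tolerance = 1e-12)

  df <- readr::read_csv(path, show_col_types = FALSE)
  df$volume_L[3] <- 0
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, bad)
  expect_error(read_schedules(bad), "line\\(s\\) 4")  # header + row 3

  df2 <- readr::read_csv(path, show_col_types = FALSE)
  df2$time_of_day_h[2] <- df2$time_of_day_h[1] - 1
  bad2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df2, bad2)
  expect_error(read_schedules(bad2), "not strictly increasing")

  df3 <- readr::read_csv(path, show_col_types = FALSE)
  df3$specific_gravity[1] <- 0.999
  bad3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df3, bad3)
  expect_error(read_schedules(bad3), "specific gravity")
})
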