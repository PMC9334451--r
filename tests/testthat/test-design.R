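test_that("the syncopated schedule satisfies every structural constraint", {
  sch <- build_schedule(8, seed = 1)
  tests <- schedule_tests(sch)
  spans <- schedule_spans(sch)

  # per subject: 6 reading tests, 21 videos, spans {3,3,3,6,6}
  per_subj <- dplyr::count(tests, subject)
  expect_true(all(per_subj$n == 6))
  vids <- sch |> dplyr::filter(has_video) |> dplyr::count(subject)
  expect_true(all(vids$n == 21))
  span_sets <- spans |>
    dplyr::group_by(subject) |>
    dplyr::summarise(set = paste(sort(n_videos), collapse = ","))
  expect_true(all(span_sets$set == "3,3,3,6,6"))
  # 3*(#short) + 6*(#long) accounts for all 21 videos
  tot <- spans |> dplyr::group_by(subject) |>
    dplyr::summarise(v = sum(n_videos))
  expect_true(all(tot$v == 21))

  # population: first/last positions full, intermediates 5 or 6, 48 tests
  pop <- dplyr::count(tests, position)
  expect_equal(pop$n[pop$position == 1], 8)
  expect_equal(pop$n[pop$position == 8], 8)
  expect_true(all(pop$n[pop$position %in% 2:7] %in% 5:6))
  expect_equal(nrow(tests), 48)

  # determinism and sensitivity to seed
  expect_identical(as.data.frame(build_schedule(8, seed = 1)),
                   as.data.frame(sch))
  expect_error(build_schedule(1, seed = 1))
})

test_that("the shipped synthetic schedule fixture satisfies the same constraints", {
  path <- system.file("extdata", "syncopated_schedule_synthetic.csv",
                      package = "phosvpl")
  sch <- read_schedule(path)
  spans <- schedule_spans(sch)
  span_sets <- spans |>
    dplyr::group_by(subject) |>
    dplyr::summarise(set = paste(sort(n_videos), collapse = ","))
  expect_true(all(span_sets$set == "3,3,3,6,6"))
  pop <- dplyr::count(schedule_tests(sch), position)
  expect_true(all(pop$n[pop$position %in% c(1, 8)] == 8))
  expect_true(all(pop$n[pop$position %in% 2:7] %in% 5:6))
})

test_that("span extraction matches direct subtraction over the schedule", {
  sch <- build_schedule(8, seed = 2)
  tests <- schedule_tests(sch)

  # constant series: all deltas zero
  const <- dplyr::mutate(tests, acuity_logmar = 1.2)
  sp <- extract_spans(const, sch)
  expect_true(all(sp$delta_logmar == 0))
  expect_equal(nrow(sp), 40)  # 5 spans x 8 subjects
  expect_equal(sum(sp$kind == "short"), 24)
  expect_equal(sum(sp$kind == "long"), 16)

  # uniform improvement of 0.01 per session-effect: the latent bookkeeping
  # says a short span spans 1 R + 3 v effects, a long span 1 R + 6 v
  cfg <- cohort_config(beta_R = -0.01, beta_V = -0.01, noise_sd = 0,
                       baseline_sd = 0)
  ac <- gen_acuity_series(cfg, sch, seed = 1)
  sp <- extract_spans(ac, sch)
  expect_equal(sp$delta_logmar[sp$kind == "short"],
               rep(-0.04, 24), tolerance = 1e-12)
  expect_equal(sp$delta_logmar[sp$kind == "long"],
               rep(-0.07, 16), tolerance = 1e-12)

  # brute-force subtraction oracle on an arbitrary series
  arb <- dplyr::mutate(tests,
                       acuity_logmar = 1.3 - 0.01 * position +
                         0.005 * subject %% 3)
  sp <- extract_spans(arb, sch)
  for (k in sample(nrow(sp), 10)) {
    row <- sp[k, ]
    a_from <- arb$acuity_logmar[arb$subject == row$subject &
                                  arb$position == row$from_position]
    a_to <- arb$acuity_logmar[arb$subject == row$subject &
                                arb$position == row$to_position]
    expect_equal(row$delta_logmar, a_to - a_from)
  }
})

test_that("censored acuities drop their adjacent spans with a warning", {
  sch <- build_schedule(8, seed = 2)
  tests <- schedule_tests(sch)
  # censor subject 1's second test -> its two adjacent spans drop
  pos2 <- sort(tests$position[tests$subject == 1])[2]
  ac <- dplyr::mutate(tests, acuity_logmar = 1.2,
                      censored = dplyr::if_else(
                        subject == 1 & position == pos2, "low", "none"))
  expect_warning(sp <- extract_spans(ac, sch), "2 span")
  expect_equal(nrow(sp), 38)
})

test_that("decode_rates inverts the span model exactly", {
  r <- decode_rates(-0.025, -0.035)
  expect_equal(r$beta_R, -0.015)
  expect_equal(round(r$beta_V, 3), -0.003)

  # no-video-effect case: y1 = y2 = c decodes to beta_V = 0, beta_R = c
  r0 <- decode_rates(-0.02, -0.02)
  expect_equal(r0$beta_V, 0)
  expect_equal(r0$beta_R, -0.02)

  # forward-substitution identity on random pairs
  withr::with_seed(123, {
    y1 <- rnorm(1000, 0, 0.05); y2 <- rnorm(1000, 0, 0.05)
    for (k in seq_len(20)) {
      r <- decode_rates(y1[k], y2[k])
      ys <- encode_spans(r$beta_R, r$beta_V)
      expect_equal(unname(ys), c(y1[k], y2[k]), tolerance = 1e-14)
    }
    # vectorised check across all 1000
    bR <- 2 * y1 - y2; bV <- (y2 - y1) / 3
    expect_equal(3 * bV + bR, y1, tolerance = 1e-14)
    expect_equal(6 * bV + bR, y2, tolerance = 1e-14)
  })
})

test_that("decoding a spans table pools means and optionally decodes per subject", {
  sch <- build_schedule(8, seed = 3)
  cfg <- cohort_config(noise_sd = 0, baseline_sd = 0)
  ac <- gen_acuity_series(cfg, sch, seed = 1)
  r <- decode_rates(extract_spans(ac, sch), per_subject = TRUE)
  # noiseless additive dynamics: exact recovery
  expect_equal(r$beta_R, cfg$beta_R, tolerance = 1e-12)
  expect_equal(r$beta_V, cfg$beta_V, tolerance = 1e-12)
  expect_equal(r$n_short, 24)
  expect_equal(r$n_long, 16)
  expect_equal(nrow(r$per_subject), 8)
  expect_equal(r$per_subject$beta_R, rep(cfg$beta_R, 8), tolerance = 1e-12)

  td <- tidy(r)
  expect_equal(td$estimate, c(r$beta_R, r$beta_V))
})

test_that("the regression cross-check recovers constructed exact fits", {
  # acuity exactly linear in video minutes only
  withr::with_seed(9, {
    df <- tibble::tibble(
      cum_video_min = seq(0, 500, length.out = 24),
      cum_reading_min = runif(24, 0, 70),
      acuity_logmar = 1.3 - 2e-4 * cum_video_min
    )
  })
  reg <- rates_from_regression(df)
  video_row <- dplyr::filter(reg, predictors == "video")
  expect_equal(video_row$r_squared, 1)
  expect_equal(video_row$slope_video, -2e-4, tolerance = 1e-10)
  both_row <- dplyr::filter(reg, predictors == "both")
  expect_lte(both_row$reading_lo, 0)
  expect_gte(both_row$reading_hi, 0)

  # duplicate rows leave OLS slopes unchanged
  reg2 <- rates_from_regression(dplyr::bind_rows(df, df))
  expect_equal(dplyr::filter(reg2, predictors == "both")$slope_video,
               both_row$slope_video, tolerance = 1e-12)

  # exactly dependent predictors raise the collinearity error
  bad <- dplyr::mutate(df, cum_reading_min = 2 * cum_video_min)
  expect_error(rates_from_regression(bad), "collinear")
})

test_that("per-minute slopes times session lengths agree with the span decoder", {
  sch <- build_schedule(8, seed = 4)
  cfg <- cohort_config(noise_sd = 0, baseline_sd = 0)
  ac <- gen_acuity_series(cfg, sch, seed = 6)
  tests <- schedule_tests(sch) |>
    dplyr::group_by(subject) |>
    dplyr::mutate(order = dplyr::row_number()) |>
    dplyr::ungroup()
  # cumulative exposure before each measurement under the mean session
  # lengths; prior reading exposure counts only tests this subject took
  expos <- dplyr::left_join(ac, tests, by = c("subject", "position")) |>
    dplyr::mutate(
      cum_reading_min = 13.6 * (order - 1),
      cum_video_min = 24.7 * 3 * (position - 1)
    )
  reg <- rates_from_regression(expos)
  per <- rates_per_session(reg)
  # noiseless additive dynamics are exactly linear in both exposures, so
  # slope x session length reproduces the per-session rates, matching the
  # span decoder
  dec <- decode_rates(extract_spans(ac, sch))
  expect_equal(per$beta_R_prime, dec$beta_R, tolerance = 1e-8)
  expect_equal(per$beta_V_prime, dec$beta_V, tolerance = 1e-8)
  expect_equal(per$beta_R_prime, cfg$beta_R, tolerance = 1e-8)
  expect_equal(per$beta_V_prime, cfg$beta_V, tolerance = 1e-8)
})

test_that("gain attribution multiplies rates by session counts and splits the total", {
  g <- attribute_gains(decode_rates(-0.025, -0.035))
  expect_equal(g$gain_logmar[g$task == "reading"], -0.075)
  expect_lt(abs(g$gain_logmar[g$task == "reading"] - (-0.08)), 0.01)
  expect_equal(g$gain_logmar[g$task == "video"], -0.07, tolerance = 1e-6)
  # brute-force percent split
  expect_equal(g$pct_of_total,
               100 * g$gain_logmar / sum(g$gain_logmar))
  expect_equal(sum(g$pct_of_total), 100)

  z <- attribute_gains(0, 0)
  expect_true(attr(z, "undefined_split"))
  expect_true(all(is.na(z$pct_of_total)))
  expect_true(all(z$gain_logmar == 0))
})

test_that("exposure bookkeeping reproduces the 1:6.8 ratio and 13% reading share", {
  e <- exposure_summary(4483, 30389)
  expect_equal(round(e$ratio_video_per_reading, 1), 6.8)
  expect_equal(e$ratio_label, "1:6.8")
  expect_equal(round(e$reading_fraction_pct), 13)
  expect_error(exposure_summary(0, 100))
})

test_that("the longitudinal summary reports the population endpoint change", {
  path <- system.file("extdata", "endpoint_acuity_synthetic.csv",
                      package = "phosvpl")
  endpoints <- readr::read_csv(path, show_col_types = FALSE)
  s <- longitudinal_summary(endpoints)
  expect_equal(s$first_mean, 1.28)
  expect_equal(s$last_mean, 1.13)
  expect_equal(round(s$change_mean, 2), -0.15)
  expect_lt(s$p_value, 0.001)
})
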