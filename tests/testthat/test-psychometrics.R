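test_that("score_trial uses case-insensitive, punctuation-stripped positional matching", {
  truth <- "We will climb only to be better able to give a helping hand"
  expect_equal(score_trial(truth, truth), 13)
  expect_equal(score_trial("", truth), 0)
  expect_equal(score_trial("we climb will", "we will climb"), 1)
  expect_equal(score_trial("WE, will... climb!", "we will climb"), 3)
  expect_equal(score_trial(c("we", "will"), "we will climb"), 2)
  # extra trailing words never score
  expect_equal(score_trial("we will climb high up", "we will climb"), 3)
  expect_error(score_trial("anything", ""), "at least one word")
})

test_that("accuracy and speed follow the percent-correct and WPM formulas", {
  out <- accuracy_and_speed(tibble::tibble(
    words_correct = c(10, 0, 7), words_total = c(10, 12, 13),
    duration_s = c(30, 20, 52)
  ))
  expect_equal(out$accuracy_pct, c(100, 0, 100 * 7 / 13))
  expect_equal(out$speed_wpm, c(20, 0, 7 / (52 / 60)))
  expect_equal(round(out$accuracy_pct[3], 2), 53.85)
  expect_equal(round(out$speed_wpm[3], 2), 8.08)
  expect_error(accuracy_and_speed(tibble::tibble(
    words_correct = 5, words_total = 10, duration_s = 0)))
  expect_error(accuracy_and_speed(tibble::tibble(
    words_correct = 11, words_total = 10, duration_s = 10)))
})

test_that("Snellen fractions convert to logMAR", {
  expect_equal(round(logmar_from_snellen(20, 500), 2), 1.40)
  expect_equal(round(logmar_from_snellen(20, 160), 2), 0.90)
  expect_equal(logmar_from_snellen(20, 20), 0)
  expect_error(logmar_from_snellen(0, 20))
  expect_error(logmar_from_snellen(20, -5))
})

logistic_trials <- function(mid, slope = 15, fonts = seq(0.9, 1.4, 0.1),
                            n_words = 24, exact = TRUE, seed = NULL) {
  p <- plogis(slope * (fonts - mid))
  correct <- if (exact) n_words * p else {
    withr::with_seed(seed, rbinom(length(fonts), n_words, p))
  }
  tibble::tibble(font_logmar = fonts, words_total = n_words,
                 words_correct = correct)
}

test_that("noiseless logistic data recover the generating midpoint exactly", {
  fit <- fit_acuity(logistic_trials(1.2))
  expect_equal(fit$acuity_logmar, 1.2, tolerance = 1e-8)
  expect_equal(fit$slope, 15, tolerance = 1e-6)
  expect_equal(fit$censored, "none")
  expect_false(fit$extrapolated)
  # midpoint sits at 50% predicted accuracy
  expect_equal(predict(fit, fit$acuity_logmar), 50)
})

test_that("degenerate profiles are censored, not errors", {
  all_right <- tibble::tibble(font_logmar = seq(0.9, 1.4, 0.1),
                              words_total = 24, words_correct = 24)
  f <- fit_acuity(all_right)
  expect_equal(f$censored, "low")
  expect_equal(f$bound, 0.9)
  expect_true(f$extrapolated)
  expect_true(is.na(f$acuity_logmar))
  expect_equal(predict(f, c(0.9, 1.4)), c(100, 100))

  none_right <- dplyr::mutate(all_right, words_correct = 0)
  g <- fit_acuity(none_right)
  expect_equal(g$censored, "high")
  expect_equal(g$bound, 1.4)

  expect_error(fit_acuity(all_right[1:2, ]), "3 distinct font sizes")
})

test_that("midpoints outside the tested range raise the extrapolation flag", {
  fit <- fit_acuity(logistic_trials(1.55))
  expect_true(fit$extrapolated)
  expect_equal(fit$acuity_logmar, 1.55, tolerance = 1e-6)
})

test_that("Bernoulli word noise leaves the fit unbiased and matching the grid oracle", {
  true_mid <- 1.25
  fonts <- seq(0.9, 1.4, 0.1)
  # 2 sentences x 12 words per font, 500 replicates
  mids <- purrr::map_dbl(seq_len(500), function(r) {
    tr <- logistic_trials(true_mid, n_words = 24, exact = FALSE,
                          seed = 5000 + r)
    f <- fit_acuity(tr)
    if (f$censored != "none") NA_real_ else f$acuity_logmar
  })
  expect_lt(mean(is.na(mids)), 0.02)
  expect_lt(abs(mean(mids, na.rm = TRUE) - true_mid), 0.02)

  # a handful of datasets against dense grid-search likelihood maximisation
  for (r in 1:3) {
    tr <- logistic_trials(true_mid, n_words = 24, exact = FALSE,
                          seed = 900 + r)
    f <- fit_acuity(tr)
    expect_equal(f$acuity_logmar, oracle_grid_mid(tr), tolerance = 0.01)
  }
})

test_that("improving every accuracy weakly improves the fitted acuity", {
  for (s in 1:5) {
    tr <- logistic_trials(1.2, n_words = 24, exact = FALSE, seed = 40 + s)
    if (sum(tr$words_correct) == 0) next
    better <- dplyr::mutate(tr, words_correct = pmin(words_total,
                                                     words_correct + 2))
    f0 <- fit_acuity(tr); f1 <- fit_acuity(better)
    if (f0$censored != "none" || f1$censored != "none") next
    expect_lte(f1$acuity_logmar, f0$acuity_logmar + 1e-8)
  }
})

test_that("refitting the fitted curve's predictions is idempotent", {
  tr <- logistic_trials(1.18, n_words = 24, exact = FALSE, seed = 77)
  f <- fit_acuity(tr)
  refit <- fit_acuity(tibble::tibble(
    font_logmar = tr$font_logmar, words_total = tr$words_total,
    words_correct = tr$words_total *
      predict(f, tr$font_logmar) / 100
  ))
  expect_equal(refit$acuity_logmar, f$acuity_logmar, tolerance = 1e-6)
})

test_that("pooled accuracy is the unweighted mean over fonts", {
  tr <- tibble::tibble(
    font_logmar = rep(c(0.9, 1.0, 1.1), each = 2),
    words_correct = c(0, 1, 5, 6, 10, 12),
    words_total = 12, duration_s = 30
  )
  pooled <- pooled_profile(tr)
  by_font <- reading_profile(tr)
  expect_equal(pooled$accuracy_pct, mean(by_font$accuracy_pct))
  expect_equal(pooled$accuracy_pct,
               mean(100 * c(1 / 24, 11 / 24, 22 / 24)))
})

test_that("an all-correct natural-view control pins accuracy at 100% with censored acuity", {
  tr <- tibble::tibble(
    font_logmar = rep(seq(0.9, 1.4, 0.1), each = 2),
    words_correct = 12, words_total = 12, duration_s = 6
  )
  expect_true(all(reading_profile(tr)$accuracy_pct == 100))
  expect_equal(fit_acuity(tr)$censored, "low")
})

test_that("the bootstrap CI is seeded, reproducible and brackets the estimate", {
  tr <- dplyr::bind_rows(
    logistic_trials(1.2, n_words = 12, exact = FALSE, seed = 1),
    logistic_trials(1.2, n_words = 12, exact = FALSE, seed = 2)
  )
  f1 <- fit_acuity(tr, boot = 200, seed = 99)
  f2 <- fit_acuity(tr, boot = 200, seed = 99)
  expect_equal(f1$ci_lo, f2$ci_lo)
  expect_equal(f1$ci_hi, f2$ci_hi)
  expect_lt(f1$ci_lo, f1$ci_hi)
  expect_gte(f1$acuity_logmar, f1$ci_lo - 0.15)
  expect_lte(f1$acuity_logmar, f1$ci_hi + 0.15)
  expect_error(fit_acuity(tr, boot = 10), "seed")
})

test_that("tidy and glance summarise an acuity fit", {
  f <- fit_acuity(logistic_trials(1.2))
  td <- tidy(f)
  expect_equal(td$acuity_logmar, 1.2, tolerance = 1e-6)
  gl <- glance(f)
  expect_equal(gl$n_fonts, 6)
  expect_equal(gl$font_max, 1.4)
})
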