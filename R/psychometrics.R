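#' Score a read-aloud response against the true sentence
#'
#' Deterministic stand-in for experimenter scoring: both token streams are
#' lower-cased, stripped of punctuation and split on whitespace, then matched
#' *positionally* — word `k` of the response scores only if it equals word
#' `k` of the truth. Transposed words therefore do not score, mirroring
#' strict left-to-right reading.
#'
#' @param response Character: the subject's response (one string or a token
#'   vector).
#' @param truth Character: the true sentence; must contain at least one word.
#' @return Integer count of correctly read words.
#' @examples
#' score_trial("We will climb", "we will climb")    # 3
#' score_trial("we climb will", "we will climb")    # 1
#' @export
score_trial <- function(response, truth) {
  truth_tok <- tokenize_words(truth)
  if (length(truth_tok) == 0) abort("`truth` must contain at least one word.")
  resp_tok <- tokenize_words(response)
  k <- min(length(resp_tok), length(truth_tok))
  if (k == 0) return(0L)
  sum(resp_tok[seq_len(k)] == truth_tok[seq_len(k)])
}

tokenize_words <- function(x) {
  x <- tolower(paste(x, collapse = " "))
  x <- gsub("[^a-z0-9' ]+", " ", x)
  tok <- strsplit(trimws(x), "\\s+")[[1]]
  tok[nzchar(tok)]
}

#' Reading accuracy and speed for a trial
#'
#' Accuracy is the percentage of words read correctly; speed is correctly
#' read words per minute (WPM).
#'
#' @param trials Data frame with columns `words_correct`, `words_total`,
#'   `duration_s` (one row per trial; extra columns pass through).
#' @return The input tibble with `accuracy_pct` and `speed_wpm` added.
#' @examples
#' accuracy_and_speed(tibble::tibble(
#'   words_correct = 7, words_total = 13, duration_s = 52))
#' @export
accuracy_and_speed <- function(trials) {
  trials <- tibble::as_tibble(trials)
  stopifnot(all(c("words_correct", "words_total", "duration_s") %in%
                  names(trials)))
  if (any(trials$duration_s <= 0)) abort("`duration_s` must be positive.")
  if (any(trials$words_correct < 0 | trials$words_correct > trials$words_total)) {
    abort("`words_correct` must lie in [0, words_total].")
  }
  dplyr::mutate(
    trials,
    accuracy_pct = 100 * .data$words_correct / .data$words_total,
    speed_wpm = .data$words_correct / (.data$duration_s / 60)
  )
}

#' Per-font reading profile
#'
#' Aggregates trials into per-font accuracy (percent of words read
#' correctly) and speed (correct words per minute), plus the pooled values:
#' unweighted means over font sizes, matching the equal-trials-per-font
#' design.
#'
#' @param trials Data frame with `font_logmar`, `words_correct`,
#'   `words_total`, `duration_s`; any grouping already applied is respected.
#' @return A list-free tibble with one row per font plus attributes; see
#'   also [pooled_profile()].
#' @export
reading_profile <- function(trials) {
  trials <- tibble::as_tibble(trials)
  dplyr::summarise(
    dplyr::group_by(trials, .data$font_logmar),
    words_correct = sum(.data$words_correct),
    words_total = sum(.data$words_total),
    duration_s = sum(.data$duration_s),
    .groups = "drop"
  ) |>
    dplyr::mutate(
      accuracy_pct = 100 * .data$words_correct / .data$words_total,
      speed_wpm = .data$words_correct / (.data$duration_s / 60)
    ) |>
    dplyr::arrange(.data$font_logmar)
}

#' @rdname reading_profile
#' @return `pooled_profile()`: a one-row tibble with `accuracy_pct` and
#'   `speed_wpm` as unweighted means over fonts.
#' @export
pooled_profile <- function(trials) {
  prof <- reading_profile(trials)
  tibble::tibble(
    accuracy_pct = mean(prof$accuracy_pct),
    speed_wpm = mean(prof$speed_wpm),
    n_fonts = nrow(prof)
  )
}

#' Convert Snellen acuity to logMAR
#'
#' `logMAR = log10(denominator / numerator)`; Snellen 20/20 is 0.0 logMAR,
#' 20/160 is 0.90 and 20/500 is 1.40.
#'
#' @param numerator,denominator Snellen fraction in feet (e.g. 20 and 500).
#' @return logMAR value(s).
#' @examples
#' logmar_from_snellen(20, 500)
#' @export
logmar_from_snellen <- function(numerator, denominator) {
  if (any(numerator <= 0) || any(denominator <= 0)) {
    abort("Snellen numerator and denominator must be positive.")
  }
  log10(denominator / numerator)
}

#' Fit the reading-acuity psychometric function
#'
#' Fits a logistic curve to word-level correctness as a function of font
#' size (logMAR), with asymptotes fixed at 0 and 100%; the font size at
#' which the curve crosses 50% is the *equivalent acuity*. Fitting is
#' maximum likelihood on word counts, via a weighted quasibinomial GLM on
#' per-font proportions (point estimates identical to binomial ML, and
#' tolerant of non-integer inputs such as noiseless expected counts).
#'
#' Degenerate data do not error: if every word is correct the acuity is
#' censored below the smallest tested font (`censored = "low"`), if every
#' word is wrong it is censored above the largest (`censored = "high"`); in
#' both cases `acuity_logmar` is `NA` and `bound` carries the limit. A
#' midpoint landing outside the tested font range sets `extrapolated`.
#'
#' @param trials Data frame with `font_logmar`, `words_correct`,
#'   `words_total` (one or more rows per font; rows are sentences, the
#'   bootstrap resampling unit).
#' @param boot Number of bootstrap resamples (over sentences) for a
#'   percentile CI on the acuity; 0 (default) skips the bootstrap, 1000 is
#'   the recommended value when a CI is wanted.
#' @param conf_level CI level for the bootstrap.
#' @param seed Seed for the bootstrap; required when `boot > 0`.
#' @return An object of class `acuity_fit`: list with `acuity_logmar`,
#'   `slope`, `censored` (`"none"`, `"low"`, `"high"`), `bound`,
#'   `extrapolated`, `converged`, `ci_lo`/`ci_hi` (if bootstrapped),
#'   `font_range`, `data`, `model`.
#' @examples
#' tr <- tibble::tibble(
#'   font_logmar = seq(0.9, 1.4, 0.1),
#'   words_total = 24,
#'   words_correct = round(24 * plogis(15 * (font_logmar - 1.2)))
#' )
#' fit <- fit_acuity(tr)
#' fit$acuity_logmar
#' @export
fit_acuity <- function(trials, boot = 0, conf_level = 0.95, seed = NULL) {
  trials <- tibble::as_tibble(trials)
  stopifnot(all(c("font_logmar", "words_correct", "words_total") %in%
                  names(trials)))
  if (dplyr::n_distinct(trials$font_logmar) < 3) {
    abort("need data at >= 3 distinct font sizes to fit a psychometric curve.")
  }
  font_range <- range(trials$font_logmar)

  total_correct <- sum(trials$words_correct)
  total_words <- sum(trials$words_total)
  if (total_correct >= total_words) {
    return(new_acuity_fit(NA_real_, NA_real_, censored = "low",
                          bound = font_range[1], extrapolated = TRUE,
                          converged = TRUE, font_range = font_range,
                          data = trials))
  }
  if (total_correct <= 0) {
    return(new_acuity_fit(NA_real_, NA_real_, censored = "high",
                          bound = font_range[2], extrapolated = TRUE,
                          converged = TRUE, font_range = font_range,
                          data = trials))
  }

  fit <- acuity_glm(trials)
  mid <- fit$mid
  out <- new_acuity_fit(mid, fit$slope, censored = "none", bound = NA_real_,
                        extrapolated = mid < font_range[1] | mid > font_range[2],
                        converged = fit$converged, font_range = font_range,
                        data = trials, model = fit$model)

  if (boot > 0) {
    if (is.null(seed)) abort("`seed` is required when `boot > 0`.")
    mids <- withr::with_seed(seed, {
      purrr::map_dbl(seq_len(boot), function(b) {
        res <- trials[sample.int(nrow(trials), replace = TRUE), , drop = FALSE]
        if (dplyr::n_distinct(res$font_logmar) < 3) return(NA_real_)
        kc <- sum(res$words_correct); kt <- sum(res$words_total)
        if (kc >= kt || kc <= 0) return(NA_real_)
        acuity_glm(res)$mid
      })
    })
    alpha <- (1 - conf_level) / 2
    ci <- quantile(mids, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    out$ci_lo <- ci[1]
    out$ci_hi <- ci[2]
    out$boot <- boot
  }
  out
}

# Logistic ML fit on per-font proportions, weighted by word counts.
# glm.fit on the aggregated 1-row-per-font design keeps bulk fitting fast.
acuity_glm <- function(trials) {
  k <- rowsum(trials$words_correct, trials$font_logmar)[, 1]
  n <- rowsum(trials$words_total, trials$font_logmar)[, 1]
  f <- as.numeric(names(k))
  m <- suppressWarnings(stats::glm.fit(
    x = cbind(`(Intercept)` = 1, font_logmar = f), y = k / n, weights = n,
    family = stats::quasibinomial()
  ))
  b <- m$coefficients
  list(mid = unname(-b[1] / b[2]), slope = unname(b[2]),
       converged = isTRUE(m$converged), model = m)
}

new_acuity_fit <- function(acuity, slope, censored, bound, extrapolated,
                           converged, font_range, data, model = NULL) {
  structure(
    list(acuity_logmar = acuity, slope = slope, censored = censored,
         bound = bound, extrapolated = extrapolated, converged = converged,
         ci_lo = NA_real_, ci_hi = NA_real_, boot = 0L,
         font_range = font_range, data = data, model = model),
    class = "acuity_fit"
  )
}

#' @export
print.acuity_fit <- function(x, ...) {
  if (x$censored == "none") {
    cat(sprintf("<acuity_fit> equivalent acuity %.2f logMAR (slope %.1f/logMAR)%s\n",
                x$acuity_logmar, x$slope,
                if (x$extrapolated) " [extrapolated]" else ""))
    if (x$boot > 0) {
      cat(sprintf("  bootstrap CI [%.2f, %.2f] (%d resamples)\n",
                  x$ci_lo, x$ci_hi, x$boot))
    }
  } else {
    cat(sprintf("<acuity_fit> censored: acuity %s %.2f logMAR\n",
                if (x$censored == "low") "<" else ">", x$bound))
  }
  invisible(x)
}

#' Predicted accuracy from a psychometric fit
#'
#' @param object An `acuity_fit`.
#' @param font_logmar Font sizes at which to predict.
#' @param ... Unused.
#' @return Predicted accuracy in percent.
#' @export
predict.acuity_fit <- function(object, font_logmar, ...) {
  if (object$censored == "low") return(rep(100, length(font_logmar)))
  if (object$censored == "high") return(rep(0, length(font_logmar)))
  100 * plogis(object$slope * (font_logmar - object$acuity_logmar))
}

#' Fit acuity for every subject/session in a trials table
#'
#' Convenience wrapper: groups a long trials table by subject and session,
#' fits each group with [fit_acuity()], and returns one row per fit.
#'
#' @param trials Data frame with `subject`, `session`, `font_logmar`,
#'   `words_correct`, `words_total` (a `condition` column, if present, is
#'   filtered to `"P1000"`).
#' @return Tibble: `subject`, `session`, `acuity_logmar`, `slope`,
#'   `censored`, `extrapolated`.
#' @export
fit_acuity_all <- function(trials) {
  trials <- tibble::as_tibble(trials)
  if ("condition" %in% names(trials)) {
    trials <- dplyr::filter(trials, .data$condition == "P1000")
  }
  trials |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_acuity(df)
      tibble::tibble(acuity_logmar = f$acuity_logmar, slope = f$slope,
                     censored = f$censored, extrapolated = f$extrapolated)
    }) |>
    dplyr::ungroup()
}
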