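#' Reading-test positions in the 23-session schedule
#'
#' Session 1 is the Snellen intake; videos run daily from session 2 through
#' 22 (21 videos); reading-test positions fall every three video sessions —
#' sessions 2, 5, 8, ..., 20 — with a final, video-free test on session 23.
#' Eight potential positions in all. Reading tests precede the video on
#' shared days, so the videos influencing a test are exactly those between
#' it and the previous test.
#'
#' @return Tibble with `position` (1..8) and `session`.
#' @export
test_positions <- function() {
  tibble::tibble(position = 1:8, session = c(seq(2L, 20L, by = 3L), 23L))
}

#' Build a syncopated reading/video schedule
#'
#' Each subject attends 23 sessions: Snellen intake, 21 video sessions, and
#' 6 reading tests taken at 6 of the 8 potential positions. Every subject
#' keeps the first and last positions and skips two *non-adjacent*
#' intermediate positions, which yields spans between consecutive tests of
#' exactly three videos (RvvvR, three per subject) and six videos
#' (RvvvvvvR, two per subject). Skips are balanced across the population so
#' each intermediate position is populated by 5 or 6 subjects (with the
#' default 8 subjects) while the first and last positions are fully
#' populated.
#'
#' @param n_subjects Number of subjects (default 8; minimum 2).
#' @param seed Integer seed; the assignment is deterministic per seed.
#' @return Tibble of class `vpl_schedule`: one row per subject x session
#'   with `subject`, `session`, `has_snellen`, `has_reading_test`,
#'   `has_video`, `position` (NA when no test).
#' @examples
#' sched <- build_schedule(8, seed = 1)
#' dplyr::count(schedule_tests(sched), subject)
#' @export
build_schedule <- function(n_subjects = 8, seed) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.")
  if (missing(seed)) abort("`seed` is required.")

  # candidate skip patterns: unordered non-adjacent pairs from positions 2..7
  pairs <- t(utils::combn(2:7, 2))
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= 2, , drop = FALSE]  # 10 patterns

  target_lo <- floor(2 * n_subjects / 6)   # per-position skip bounds that
  target_hi <- ceiling(2 * n_subjects / 6) # spread 2*n skips over 6 positions
  assignment <- withr::with_seed(seed, {
    for (attempt in 1:10000) {
      idx <- if (n_subjects <= nrow(pairs)) {
        sample.int(nrow(pairs), n_subjects)
      } else {
        sample.int(nrow(pairs), n_subjects, replace = TRUE)
      }
      counts <- tabulate(pairs[idx, ], nbins = 7)[2:7]
      if (all(counts >= target_lo) && all(counts <= target_hi)) break
      idx <- NULL
    }
    idx
  })
  if (is.null(assignment)) {
    abort("could not balance skip positions for this `n_subjects`; infeasible constraint set.")
  }

  pos <- test_positions()
  grid <- tidyr::expand_grid(subject = seq_len(n_subjects), session = 1:23)
  skips <- purrr::map(seq_len(n_subjects),
                      function(s) pairs[assignment[s], ])
  grid <- grid |>
    dplyr::left_join(pos, by = "session") |>
    dplyr::mutate(
      has_snellen = .data$session == 1,
      has_video = .data$session >= 2 & .data$session <= 22,
      skipped = purrr::map2_lgl(.data$subject, .data$position,
                                function(s, p) !is.na(p) && p %in% skips[[s]]),
      has_reading_test = !is.na(.data$position) & !.data$skipped,
      position = dplyr::if_else(.data$has_reading_test, .data$position,
                                NA_integer_)
    ) |>
    dplyr::select("subject", "session", "has_snellen", "has_reading_test",
                  "has_video", "position")
  tibble::new_tibble(grid, n_subjects = n_subjects, seed = seed,
                     class = "vpl_schedule")
}

#' @rdname build_schedule
#' @param schedule A `vpl_schedule` (or compatible data frame).
#' @return `schedule_tests()`: tibble `subject`, `position`, `session` of
#'   administered reading tests, ordered within subject.
#' @export
schedule_tests <- function(schedule) {
  schedule |>
    dplyr::filter(.data$has_reading_test) |>
    dplyr::select("subject", "position", "session") |>
    dplyr::arrange(.data$subject, .data$position)
}

#' @rdname build_schedule
#' @return `schedule_spans()`: tibble of consecutive-test spans with
#'   `subject`, `from_position`, `to_position`, `n_videos` (3 or 6), `kind`
#'   (`"short"`/`"long"`).
#' @export
schedule_spans <- function(schedule) {
  schedule_tests(schedule) |>
    dplyr::group_by(.data$subject) |>
    dplyr::reframe(
      from_position = head(.data$position, -1),
      to_position = tail(.data$position, -1)
    ) |>
    dplyr::mutate(
      n_videos = 3L * (.data$to_position - .data$from_position),
      kind = dplyr::if_else(.data$n_videos == 3L, "short", "long")
    )
}

#' Read or write a schedule as CSV
#'
#' Plain-text interchange format: columns `subject`, `session`,
#' `has_snellen`, `has_reading_test`, `has_video`, `position`.
#'
#' @param schedule A `vpl_schedule`.
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(as.data.frame(schedule), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(),
                        progress = FALSE, show_col_types = FALSE)
  df$position <- as.integer(df$position)
  tibble::new_tibble(df, n_subjects = dplyr::n_distinct(df$subject),
                     class = "vpl_schedule")
}

#' Span improvements from an acuity series
#'
#' Pairs each subject's consecutive reading-test acuities and records the
#' change (later minus earlier; negative = improvement) labelled by the
#' number of intervening video sessions: short spans (RvvvR, 3 videos)
#' carry `y1`-type improvements, long spans (RvvvvvvR, 6 videos) carry
#' `y2`-type. Censored or missing acuities drop their adjacent spans with a
#' warning giving the count.
#'
#' @param acuities Tibble with `subject`, `position`, `acuity_logmar`
#'   (optionally `censored`, values other than `"none"` mark unusable fits).
#' @param schedule A [build_schedule()] result.
#' @return Tibble of class `span_improvements`: `subject`, `from_position`,
#'   `to_position`, `n_videos`, `kind`, `delta_logmar`.
#' @export
extract_spans <- function(acuities, schedule) {
  acuities <- tibble::as_tibble(acuities)
  stopifnot(all(c("subject", "position", "acuity_logmar") %in% names(acuities)))
  tests <- schedule_tests(schedule)
  joined <- dplyr::left_join(tests, acuities, by = c("subject", "position"))
  if (anyNA(joined$acuity_logmar) && !"censored" %in% names(joined)) {
    joined$censored <- dplyr::if_else(is.na(joined$acuity_logmar), "missing",
                                      "none")
  }
  if (!"censored" %in% names(joined)) joined$censored <- "none"
  joined$usable <- !is.na(joined$acuity_logmar) & joined$censored == "none"

  spans <- joined |>
    dplyr::group_by(.data$subject) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::reframe(
      from_position = head(.data$position, -1),
      to_position = tail(.data$position, -1),
      delta_logmar = diff(.data$acuity_logmar),
      usable = head(.data$usable, -1) & tail(.data$usable, -1)
    ) |>
    dplyr::mutate(
      n_videos = 3L * (.data$to_position - .data$from_position),
      kind = dplyr::if_else(.data$n_videos == 3L, "short", "long")
    )
  n_drop <- sum(!spans$usable)
  if (n_drop > 0) {
    warn(sprintf("dropping %d span(s) adjacent to censored or missing acuities.",
                 n_drop))
    spans <- dplyr::filter(spans, .data$usable)
  }
  out <- dplyr::select(spans, "subject", "from_position", "to_position",
                       "n_videos", "kind", "delta_logmar")
  tibble::new_tibble(out, class = "span_improvements")
}

#' Decode per-session learning rates from span improvements
#'
#' The additive model says a short span changes acuity by
#' `y1 = 3*beta_V + beta_R` (one influencing reading session plus three
#' videos) and a long span by `y2 = 6*beta_V + beta_R` — the closing reading
#' test measures, but does not yet influence, its own span. Solving the two
#' linear equations decodes the per-session rates:
#' `beta_V = (y2 - y1) / 3` and `beta_R = 2*y1 - y2`.
#'
#' `decode_rates()` accepts either the two mean improvements directly, or a
#' [extract_spans()] table, in which case `y1`/`y2` are the means of the
#' short- and long-span improvements (optionally per subject).
#'
#' @param y1 Mean short-span (RvvvR) acuity change, logMAR; or a
#'   `span_improvements` data frame.
#' @param y2 Mean long-span (RvvvvvvR) acuity change, logMAR (when `y1` is
#'   numeric).
#' @param per_subject When decoding a spans table: also decode each
#'   subject's `(mean y1, mean y2)` pair and attach the distribution.
#' @param ... Passed between methods.
#' @return Object of class `learning_rates`: `beta_R`, `beta_V` (logMAR per
#'   session), `y1_mean`, `y2_mean`, `n_short`, `n_long`, and optionally
#'   `per_subject` (tibble of per-subject decodes).
#' @examples
#' decode_rates(-0.025, -0.035)
#' @export
decode_rates <- function(y1, ...) UseMethod("decode_rates")

#' @rdname decode_rates
#' @export
decode_rates.numeric <- function(y1, y2, ...) {
  new_learning_rates(beta_R = 2 * y1 - y2, beta_V = (y2 - y1) / 3,
                     y1_mean = y1, y2_mean = y2,
                     n_short = NA_integer_, n_long = NA_integer_)
}

#' @rdname decode_rates
#' @export
decode_rates.data.frame <- function(y1, per_subject = FALSE, ...) {
  spans <- y1
  stopifnot(all(c("kind", "delta_logmar", "subject") %in% names(spans)))
  y1_mean <- mean(spans$delta_logmar[spans$kind == "short"])
  y2_mean <- mean(spans$delta_logmar[spans$kind == "long"])
  out <- new_learning_rates(
    beta_R = 2 * y1_mean - y2_mean, beta_V = (y2_mean - y1_mean) / 3,
    y1_mean = y1_mean, y2_mean = y2_mean,
    n_short = sum(spans$kind == "short"), n_long = sum(spans$kind == "long")
  )
  if (per_subject) {
    out$per_subject <- spans |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(
        y1 = mean(.data$delta_logmar[.data$kind == "short"]),
        y2 = mean(.data$delta_logmar[.data$kind == "long"]),
        .groups = "drop"
      ) |>
      dplyr::mutate(beta_R = 2 * .data$y1 - .data$y2,
                    beta_V = (.data$y2 - .data$y1) / 3)
  }
  out
}

new_learning_rates <- function(beta_R, beta_V, y1_mean, y2_mean,
                               n_short, n_long) {
  structure(
    list(beta_R = beta_R, beta_V = beta_V, y1_mean = y1_mean,
         y2_mean = y2_mean, n_short = n_short, n_long = n_long,
         per_subject = NULL),
    class = "learning_rates"
  )
}

#' @export
print.learning_rates <- function(x, ...) {
  cat(sprintf("<learning_rates> beta_R = %.3f, beta_V = %.3f logMAR/session\n",
              x$beta_R, x$beta_V))
  cat(sprintf("  from y1 = %.3f (n=%s short spans), y2 = %.3f (n=%s long spans)\n",
              x$y1_mean, x$n_short, x$y2_mean, x$n_long))
  if (!is.null(x$per_subject)) {
    cat(sprintf("  per-subject decodes attached (%d subjects)\n",
                nrow(x$per_subject)))
  }
  invisible(x)
}

#' Re-encode rates into span improvements
#'
#' Forward model used by the decoder's identity check: given per-session
#' rates, the expected short- and long-span improvements.
#'
#' @param beta_R,beta_V Per-session rates, logMAR.
#' @return Named vector `c(y1, y2)`.
#' @export
encode_spans <- function(beta_R, beta_V) {
  c(y1 = 3 * beta_V + beta_R, y2 = 6 * beta_V + beta_R)
}

#' Regression cross-check of the learning rates
#'
#' Ordinary least squares of acuity on cumulative minutes spent in each
#' task, fitted three ways (reading only, video only, both), as a
#' model-free validation of the span decoder. Slopes from the joint model,
#' multiplied by mean session lengths, give per-session rates comparable to
#' [decode_rates()].
#'
#' @param data Tibble with `acuity_logmar`, `cum_reading_min`,
#'   `cum_video_min`, one row per acuity measurement.
#' @return Tibble of class `exposure_regression`: one row per predictor set
#'   with slopes, 95% CIs and R-squared; fitted `lm` objects in attribute
#'   `models`.
#' @export
rates_from_regression <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("acuity_logmar", "cum_reading_min", "cum_video_min") %in%
                  names(data)))
  if (nrow(data) < 3) abort("need >= 3 acuity measurements.")
  forms <- list(
    reading = acuity_logmar ~ cum_reading_min,
    video = acuity_logmar ~ cum_video_min,
    both = acuity_logmar ~ cum_reading_min + cum_video_min
  )
  models <- purrr::map(forms, lm, data = data)
  if (anyNA(coef(models$both))) {
    abort("collinear predictors: cumulative reading and video minutes are linearly dependent.")
  }
  row_for <- function(m, name) {
    # noiseless inputs produce zero-residual fits; the "essentially perfect
    # fit" warning is expected there, not actionable
    ci <- suppressWarnings(suppressMessages(confint(m)))
    pick <- function(term) {
      if (term %in% rownames(ci)) {
        c(coef(m)[term], ci[term, 1], ci[term, 2])
      } else {
        c(NA_real_, NA_real_, NA_real_)
      }
    }
    r <- pick("cum_reading_min"); v <- pick("cum_video_min")
    tibble::tibble(
      predictors = name,
      slope_reading = unname(r[1]), reading_lo = r[2], reading_hi = r[3],
      slope_video = unname(v[1]), video_lo = v[2], video_hi = v[3],
      r_squared = suppressWarnings(summary(m))$r.squared
    )
  }
  out <- dplyr::bind_rows(purrr::imap(models, row_for))
  tibble::new_tibble(out, models = models, class = "exposure_regression")
}

#' Per-session rates from regression slopes
#'
#' Converts per-minute slopes (joint model) into per-session rates using
#' mean session lengths (defaults: 13.6 min reading, 24.7 min video).
#'
#' @param reg A [rates_from_regression()] result.
#' @param t_reading,t_video Mean session lengths in minutes.
#' @return Tibble with `beta_R_prime`, `beta_V_prime` (logMAR/session).
#' @export
rates_per_session <- function(reg, t_reading = 13.6, t_video = 24.7) {
  both <- dplyr::filter(reg, .data$predictors == "both")
  tibble::tibble(
    beta_R_prime = both$slope_reading * t_reading,
    beta_V_prime = both$slope_video * t_video,
    t_reading = t_reading, t_video = t_video
  )
}

#' Attribute the overall acuity gain to reading vs video
#'
#' Multiplies each per-session rate by the number of sessions of that type
#' that could influence measurements and reports the split. With 6 reading
#' tests the final test influences nothing later, so 5 reading sessions
#' count by default, against 21 videos.
#'
#' @param rates A `learning_rates` object, or a numeric `beta_R`.
#' @param beta_V Ignored when `rates` is a `learning_rates`.
#' @param n_reading,n_video Session counts (influencing measurements).
#' @return Tibble: one row per task with `rate`, `n_sessions`,
#'   `gain_logmar`, `pct_of_total`; attribute `undefined_split` set when the
#'   total gain is zero.
#' @examples
#' attribute_gains(decode_rates(-0.025, -0.035))
#' @export
attribute_gains <- function(rates, beta_V = NULL, n_reading = 5, n_video = 21) {
  if (inherits(rates, "learning_rates")) {
    beta_R <- rates$beta_R
    beta_V <- rates$beta_V
  } else {
    beta_R <- rates
    if (is.null(beta_V)) abort("supply `beta_V` when `rates` is numeric.")
  }
  if (n_reading < 0 || n_video < 0) abort("session counts must be >= 0.")
  gains <- c(reading = beta_R * n_reading, video = beta_V * n_video)
  total <- sum(gains)
  undefined <- total == 0
  pct <- if (undefined) c(NA_real_, NA_real_) else 100 * gains / total
  out <- tibble::tibble(
    task = names(gains),
    rate = c(beta_R, beta_V),
    n_sessions = c(n_reading, n_video),
    gain_logmar = unname(gains),
    pct_of_total = unname(pct)
  )
  attr(out, "undefined_split") <- undefined
  out
}

#' Phosphene-exposure bookkeeping
#'
#' Summarises time spent in each task: mean seconds, the reading fraction of
#' total exposure (percent), and the reading:video ratio written `1:x`.
#'
#' @param reading_s,video_s Per-subject exposure in seconds (vectors or
#'   scalars).
#' @return One-row tibble: `t_reading_s`, `t_video_s`,
#'   `reading_fraction_pct`, `ratio_video_per_reading`, `ratio_label`.
#' @examples
#' exposure_summary(4483, 30389)
#' @export
exposure_summary <- function(reading_s, video_s) {
  if (any(reading_s <= 0) || any(video_s <= 0)) {
    abort("exposures must be positive.")
  }
  r <- mean(reading_s); v <- mean(video_s)
  frac <- if (length(reading_s) > 1) {
    mean(100 * reading_s / (reading_s + video_s))
  } else {
    100 * r / (r + v)
  }
  tibble::tibble(
    t_reading_s = r,
    t_video_s = v,
    reading_fraction_pct = frac,
    ratio_video_per_reading = v / r,
    ratio_label = sprintf("1:%.1f", v / r)
  )
}

#' Population change in acuity over the experiment
#'
#' Takes each subject's first and last equivalent acuities and reports the
#' population means, the mean paired change (negative = improvement), its
#' SD, and a paired t-test.
#'
#' @param endpoints Tibble with `subject`, `first_acuity`, `last_acuity`
#'   (logMAR).
#' @return One-row tibble: `first_mean`, `first_sd`, `last_mean`, `last_sd`,
#'   `change_mean`, `change_sd`, `p_value`.
#' @export
longitudinal_summary <- function(endpoints) {
  endpoints <- tibble::as_tibble(endpoints)
  stopifnot(all(c("first_acuity", "last_acuity") %in% names(endpoints)))
  d <- endpoints$last_acuity - endpoints$first_acuity
  p <- if (length(d) >= 2 && sd(d) > 0) t.test(d)$p.value else NA_real_
  tibble::tibble(
    first_mean = mean(endpoints$first_acuity),
    first_sd = sd(endpoints$first_acuity),
    last_mean = mean(endpoints$last_acuity),
    last_sd = sd(endpoints$last_acuity),
    change_mean = mean(d),
    change_sd = sd(d),
    p_value = p
  )
}
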