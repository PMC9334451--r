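#' Configuration for a synthetic cohort
#'
#' Collects the generating parameters of the synthetic study: per-subject
#' baseline acuities, additive per-session learning rates for reading
#' (`beta_R`) and video (`beta_V`) sessions, session-level measurement
#' noise, and the word-level psychometric model used to turn a latent
#' acuity into reading responses. Defaults anchor to the study conditions
#' this package models: 8 subjects starting at 1.28 +/- 0.04 logMAR,
#' `beta_R = -0.015` and `beta_V = -0.00333` logMAR/session, measurement
#' noise 0.04 logMAR, psychometric slope 15 per logMAR, six font sizes
#' (logMAR 0.9-1.4), two sentences per font per test, 12 words per
#' sentence.
#'
#' @param n_subjects Number of subjects.
#' @param baseline_mean,baseline_sd Baseline equivalent acuity (logMAR).
#' @param beta_R,beta_V Per-session acuity change (logMAR; negative =
#'   improvement) for reading-test and video sessions.
#' @param noise_sd Session-level additive measurement noise on the latent
#'   acuity at each reading test (logMAR); word-level Bernoulli sampling
#'   adds further, binomial noise on top.
#' @param slope Psychometric slope (per logMAR).
#' @param fonts Tested font sizes (logMAR).
#' @param sentences_per_font Sentences per font per reading test.
#' @param words_per_sentence Words per sentence.
#' @param mean_word_time_s,word_time_shape Gamma reading-time model: mean
#'   seconds per word and shape; chosen so pooled phosphene-view speeds sit
#'   near single-digit WPM.
#' @param latent_model `"additive"` (default; constant per-session effects)
#'   or `"saturating"` (effects shrink as total improvement approaches
#'   `sat_scale`, for model-misspecification experiments).
#' @param sat_scale Saturation scale (logMAR) for the `"saturating"`
#'   variant.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8,
                          baseline_mean = 1.28, baseline_sd = 0.04,
                          beta_R = -0.015, beta_V = -1 / 300,
                          noise_sd = 0.04,
                          slope = 15,
                          fonts = seq(0.9, 1.4, by = 0.1),
                          sentences_per_font = 2,
                          words_per_sentence = 12,
                          mean_word_time_s = 2.5,
                          word_time_shape = 4,
                          latent_model = c("additive", "saturating"),
                          sat_scale = 0.3) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.")
  if (baseline_sd < 0 || noise_sd < 0) abort("standard deviations must be >= 0.")
  structure(
    list(n_subjects = n_subjects, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, beta_R = beta_R, beta_V = beta_V,
         noise_sd = noise_sd, slope = slope, fonts = fonts,
         sentences_per_font = sentences_per_font,
         words_per_sentence = words_per_sentence,
         mean_word_time_s = mean_word_time_s,
         word_time_shape = word_time_shape,
         latent_model = match.arg(latent_model), sat_scale = sat_scale),
    class = "cohort_config"
  )
}

# latent per-session update
apply_session_effect <- function(acuity, beta, config) {
  if (config$latent_model == "additive") {
    acuity + beta
  } else {
    progress <- config$baseline_mean - acuity
    acuity + beta * exp(-max(progress, 0) / config$sat_scale)
  }
}

#' Generate a synthetic cohort
#'
#' Walks each subject through the schedule: the latent acuity starts at a
#' drawn baseline and changes by `beta_R` after each reading test and
#' `beta_V` after each video session (reading tests precede same-day
#' videos, and a test never influences its own measurement). At each
#' scheduled test the measured acuity is the latent value plus
#' `N(0, noise_sd)` session jitter, and every word of every sentence is an
#' independent Bernoulli draw from the logistic psychometric at that
#' measured latent value; sentence durations come from the gamma
#' reading-time model. Fully deterministic for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param schedule A [build_schedule()] result with matching `n_subjects`.
#' @param seed Integer seed.
#' @return List with `trajectory` (tibble: `subject`, `session`,
#'   `true_acuity`), `trials` (tibble: `subject`, `session`, `position`,
#'   `condition`, `font_logmar`, `sentence`, `words_total`,
#'   `words_correct`, `duration_s`), and `truth` (generating parameters).
#' @examples
#' cfg <- cohort_config(n_subjects = 2)
#' sch <- build_schedule(2, seed = 1)
#' sim <- gen_cohort(cfg, sch, seed = 1)
#' head(sim$trials)
#' @export
gen_cohort <- function(config, schedule, seed) {
  stopifnot(inherits(config, "cohort_config"))
  n_sched <- dplyr::n_distinct(schedule$subject)
  if (n_sched != config$n_subjects) {
    abort("`schedule` and `config` disagree on the number of subjects.")
  }
  withr::with_seed(seed, gen_cohort_impl(config, schedule))
}

gen_cohort_impl <- function(config, schedule) {
  baselines <- rnorm(config$n_subjects, config$baseline_mean,
                     config$baseline_sd)
  traj <- latent_trajectory(config, schedule, baselines)

  tests <- traj[traj$is_test, , drop = FALSE]
  a_meas <- tests$true_acuity + rnorm(nrow(tests), 0, config$noise_sd)

  # one row per subject x test x font x sentence
  grid <- tidyr::expand_grid(
    test = seq_len(nrow(tests)),
    font_logmar = config$fonts,
    sentence = seq_len(config$sentences_per_font)
  )
  p <- plogis(config$slope * (grid$font_logmar - a_meas[grid$test]))
  n <- config$words_per_sentence
  trials <- tibble::tibble(
    subject = tests$subject[grid$test],
    session = tests$session[grid$test],
    position = tests$position[grid$test],
    condition = "P1000",
    font_logmar = grid$font_logmar,
    sentence = grid$sentence,
    words_total = n,
    words_correct = rbinom(nrow(grid), n, p),
    # sum of n iid Gamma(shape, shape/mu) per-word reading times
    duration_s = rgamma(nrow(grid), shape = n * config$word_time_shape,
                        rate = config$word_time_shape / config$mean_word_time_s)
  )
  list(
    trajectory = traj[, c("subject", "session", "true_acuity")],
    trials = trials,
    truth = list(beta_R = config$beta_R, beta_V = config$beta_V,
                 baselines = baselines, config = config)
  )
}

# true acuity at the start of each session (a session's own test/video
# effects apply only after it); deterministic given baselines
latent_trajectory <- function(config, schedule, baselines) {
  sched <- dplyr::arrange(tibble::as_tibble(schedule), .data$subject,
                          .data$session)
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sub <- sched[sched$subject == s, , drop = FALSE]
    if (config$latent_model == "additive") {
      prior_R <- dplyr::lag(cumsum(sub$has_reading_test), default = 0L)
      prior_v <- dplyr::lag(cumsum(sub$has_video), default = 0L)
      acuity <- baselines[s] + config$beta_R * prior_R +
        config$beta_V * prior_v
    } else {
      acuity <- numeric(nrow(sub))
      a <- baselines[s]
      for (i in seq_len(nrow(sub))) {
        acuity[i] <- a
        if (sub$has_reading_test[i]) {
          a <- apply_session_effect(a, config$beta_R, config)
        }
        if (sub$has_video[i]) {
          a <- apply_session_effect(a, config$beta_V, config)
        }
      }
    }
    out[[s]] <- tibble::tibble(subject = s, session = sub$session,
                               position = sub$position,
                               is_test = sub$has_reading_test,
                               true_acuity = acuity)
  }
  dplyr::bind_rows(out)
}

#' Direct acuity series from the latent model
#'
#' Fast variant that skips word-level sampling: measured acuity at each test
#' is the latent value plus additive `N(0, noise_sd)` noise. Useful for
#' studying the span decoder in isolation.
#'
#' @inheritParams gen_cohort
#' @return Tibble: `subject`, `position`, `acuity_logmar`, `true_acuity`.
#' @export
gen_acuity_series <- function(config, schedule, seed) {
  sim <- gen_cohort_acuity_only(config, schedule, seed)
  sim
}

gen_cohort_acuity_only <- function(config, schedule, seed) {
  withr::with_seed(seed, {
    baselines <- rnorm(config$n_subjects, config$baseline_mean,
                       config$baseline_sd)
    traj <- latent_trajectory(config, schedule, baselines)
    tests <- traj[traj$is_test, , drop = FALSE]
    tibble::tibble(
      subject = tests$subject, position = tests$position,
      acuity_logmar = tests$true_acuity +
        rnorm(nrow(tests), 0, config$noise_sd),
      true_acuity = tests$true_acuity
    )
  })
}

#' Fit measured acuities for a synthetic cohort
#'
#' Runs [fit_acuity()] on each reading test of a [gen_cohort()] result.
#'
#' @param sim A [gen_cohort()] result (or its `trials` tibble).
#' @return Tibble: `subject`, `position`, `acuity_logmar`, `slope`,
#'   `censored`.
#' @export
fit_cohort_acuities <- function(sim) {
  trials <- if (is.list(sim) && !is.data.frame(sim)) sim$trials else sim
  groups <- split(
    trials[c("font_logmar", "words_correct", "words_total")],
    list(trials$subject, trials$position), drop = TRUE, sep = "\r"
  )
  keys <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  fits <- purrr::map(groups, fit_acuity)
  tibble::tibble(
    subject = as.integer(keys[, 1]),
    position = as.integer(keys[, 2]),
    acuity_logmar = purrr::map_dbl(fits, "acuity_logmar"),
    slope = purrr::map_dbl(fits, "slope"),
    censored = purrr::map_chr(fits, "censored")
  ) |>
    dplyr::arrange(.data$subject, .data$position)
}

#' Parameter-recovery experiment
#'
#' Monte-Carlo validation of the full pipeline: for each replicate,
#' generate a cohort, fit the per-test psychometric acuities, sort span
#' improvements, and decode `beta_R`/`beta_V`. Reports estimator bias,
#' RMSE, empirical coverage of the nominal 95% t-interval built from
#' per-subject decodes, and how often the decoded rates recover the
#' `|beta_R| > |beta_V|` ordering.
#'
#' @param config A [cohort_config()].
#' @param n_replicates Number of replicates.
#' @param seed Integer seed; replicate `r` uses `seed + r`.
#' @param schedule Optional fixed schedule; defaults to
#'   `build_schedule(config$n_subjects, seed)`.
#' @param acuity_only Use the fast additive-noise acuity series instead of
#'   word-level sampling + psychometric fitting.
#' @return List of class `recovery_report`: `summary` (one row per
#'   parameter with truth, mean estimate, bias, SE of the mean, RMSE,
#'   CI coverage), `replicates` (per-replicate decodes), `ordering_rate`,
#'   `n_failed`.
#' @export
recovery_experiment <- function(config, n_replicates, seed, schedule = NULL,
                                acuity_only = FALSE) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (is.null(schedule)) schedule <- build_schedule(config$n_subjects, seed)

  one <- function(r) {
    acuities <- if (acuity_only) {
      gen_acuity_series(config, schedule, seed + r)
    } else {
      fit_cohort_acuities(gen_cohort(config, schedule, seed + r))
    }
    spans <- suppressWarnings(extract_spans(acuities, schedule))
    rates <- decode_rates(spans, per_subject = TRUE)
    ps <- rates$per_subject
    ci_R <- t_ci(ps$beta_R); ci_V <- t_ci(ps$beta_V)
    cens <- if ("censored" %in% names(acuities)) acuities$censored else "none"
    tibble::tibble(
      replicate = r,
      beta_R_hat = rates$beta_R, beta_V_hat = rates$beta_V,
      y1_mean = rates$y1_mean, y2_mean = rates$y2_mean,
      cover_R = ci_R[1] <= config$beta_R & config$beta_R <= ci_R[2],
      cover_V = ci_V[1] <= config$beta_V & config$beta_V <= ci_V[2],
      ordered = abs(rates$beta_R) > abs(rates$beta_V),
      n_censored = sum(cens != "none", na.rm = TRUE)
    )
  }
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    tryCatch(one(r), error = function(e) NULL)
  })
  n_failed <- sum(purrr::map_lgl(reps, is.null))
  reps <- dplyr::bind_rows(reps)
  if (nrow(reps) == 0) abort("all replicates failed.")

  summarise_param <- function(hat, truth, cover, name) {
    tibble::tibble(
      parameter = name, truth = truth,
      mean_estimate = mean(hat), bias = mean(hat) - truth,
      se_mean = sd(hat) / sqrt(length(hat)),
      rmse = sqrt(mean((hat - truth)^2)),
      ci_coverage = mean(cover)
    )
  }
  summary <- dplyr::bind_rows(
    summarise_param(reps$beta_R_hat, config$beta_R, reps$cover_R, "beta_R"),
    summarise_param(reps$beta_V_hat, config$beta_V, reps$cover_V, "beta_V")
  )
  structure(
    list(summary = summary, replicates = reps,
         ordering_rate = mean(reps$ordered), n_failed = n_failed,
         config = config),
    class = "recovery_report"
  )
}

t_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x); s <- sd(x) / sqrt(n)
  q <- qt(1 - (1 - level) / 2, df = n - 1)
  c(m - q * s, m + q * s)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates (%d failed)\n",
              nrow(x$replicates), x$n_failed))
  print(x$summary)
  cat(sprintf("|beta_R| > |beta_V| recovered in %.1f%% of replicates\n",
              100 * x$ordering_rate))
  invisible(x)
}

# small built-in vocabulary for MNREAD-like synthetic sentences
synth_vocabulary <- function() {
  c("we", "will", "climb", "only", "to", "be", "better", "able", "give",
    "a", "helping", "hand", "the", "boy", "ran", "home", "after", "school",
    "my", "mother", "made", "bread", "for", "us", "all", "dog", "sat",
    "near", "old", "tree", "and", "watched", "birds", "fly", "over", "lake",
    "she", "found", "her", "lost", "keys", "under", "big", "red", "chair",
    "they", "walked", "down", "long", "road", "before", "dark", "came")
}

#' Generate MNREAD-like synthetic sentences
#'
#' Simple three-line sentences with a controlled word count, drawn from a
#' small built-in vocabulary. These are structural stand-ins (word count and
#' layout), not meaningful prose.
#'
#' @param n Number of sentences.
#' @param words_per_sentence Words per sentence (split over 3 lines).
#' @param seed Integer seed.
#' @return Tibble: `sentence_id`, `text`, `n_words`, `lines` (list of 3
#'   character lines).
#' @export
gen_sentences <- function(n, words_per_sentence = 12, seed) {
  if (n < 1 || words_per_sentence < 3) {
    abort("need n >= 1 and words_per_sentence >= 3 (three lines).")
  }
  vocab <- synth_vocabulary()
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      w <- sample(vocab, words_per_sentence, replace = TRUE)
      cut <- sort(sample(seq_len(words_per_sentence - 1), 2))
      lines <- c(paste(w[1:cut[1]], collapse = " "),
                 paste(w[(cut[1] + 1):cut[2]], collapse = " "),
                 paste(w[(cut[2] + 1):words_per_sentence], collapse = " "))
      tibble::tibble(sentence_id = i, text = paste(w, collapse = " "),
                     n_words = words_per_sentence, lines = list(lines))
    }) |> dplyr::bind_rows()
  })
}

#' Generate a synthetic gaze trace
#'
#' Reading traces follow the three-line MNREAD layout: three monotone
#' left-to-right sweeps at increasing line heights, joined by fast return
#' saccades, plus small fixational jitter. Video traces are a mean-
#' reverting random walk about screen centre. A small fraction of samples
#' is marked invalid in short runs, emulating blinks.
#'
#' @param task `"reading"` or `"video"`.
#' @param duration_s Trace duration in seconds.
#' @param screen A [screen_geometry()].
#' @param sample_rate_hz Sampling rate (traces are emitted downsampled;
#'   default 100 Hz).
#' @param blink_rate_hz Expected blinks per second.
#' @param seed Integer seed.
#' @return Tibble: `t_ms`, `x_px`, `y_px`, `valid`.
#' @export
gen_gaze <- function(task = c("reading", "video"), duration_s,
                     screen = screen_geometry(), sample_rate_hz = 100,
                     blink_rate_hz = 0.2, seed) {
  task <- match.arg(task)
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  n <- max(2L, round(duration_s * sample_rate_hz))
  t_ms <- (seq_len(n) - 1) * 1000 / sample_rate_hz
  withr::with_seed(seed, {
    if (task == "reading") {
      # three equal-time sweeps; short return saccade closes each line
      phase <- (seq_len(n) - 1) / n * 3          # 0..3, one unit per line
      line <- pmin(floor(phase), 2)
      frac <- phase - line
      sweep <- pmin(frac / 0.95, 1)              # last 5% = return saccade
      x <- 0.1 * screen$width_px + 0.8 * screen$width_px * sweep
      x[frac > 0.95 & line < 2] <- 0.1 * screen$width_px
      y <- screen$height_px * (0.3 + 0.2 * line)
    } else {
      step_sd <- 0.01 * screen$width_px
      x <- numeric(n); y <- numeric(n)
      x[1] <- screen$width_px / 2; y[1] <- screen$height_px / 2
      for (i in 2:n) {
        x[i] <- x[i - 1] + 0.05 * (screen$width_px / 2 - x[i - 1]) +
          rnorm(1, 0, step_sd)
        y[i] <- y[i - 1] + 0.05 * (screen$height_px / 2 - y[i - 1]) +
          rnorm(1, 0, step_sd)
      }
    }
    x <- x + rnorm(n, 0, 0.002 * screen$width_px)
    y <- y + rnorm(n, 0, 0.002 * screen$width_px)
    valid <- rep(TRUE, n)
    n_blinks <- rbinom(1, max(1, round(duration_s)), min(1, blink_rate_hz))
    if (n_blinks > 0) {
      starts <- sample.int(n, n_blinks)
      len <- pmax(1, round(0.1 * sample_rate_hz))
      for (b in starts) valid[b:min(n, b + len)] <- FALSE
    }
    # keep endpoints valid so traces always have >= 2 valid samples
    valid[c(1, n)] <- TRUE
    tibble::tibble(t_ms = t_ms, x_px = x, y_px = y, valid = valid)
  })
}

#' Generate toy video frames
#'
#' Synthetic luminance frames for exercising the renderer: a drifting
#' oblique grating with a moving bright Gaussian blob, values in `[0, 1]`.
#'
#' @param n_frames Number of frames.
#' @param screen A [screen_geometry()] (frames match its resolution).
#' @param drift_px Per-frame drift of the pattern in pixels.
#' @param static Freeze the scene (all frames identical).
#' @param seed Integer seed (random grating phase/orientation).
#' @return List of `n_frames` matrices.
#' @export
gen_frames <- function(n_frames, screen = screen_geometry(160, 90, 0.25),
                       drift_px = 2, static = FALSE, seed = 1) {
  if (n_frames < 1) abort("`n_frames` must be >= 1.")
  w <- screen$width_px; h <- screen$height_px
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  withr::with_seed(seed, {
    theta <- runif(1, 0, pi)
    phase0 <- runif(1, 0, 2 * pi)
    freq <- 2 * pi / (0.25 * w)
    purrr::map(seq_len(n_frames), function(k) {
      shift <- if (static) 0 else (k - 1) * drift_px
      g <- 0.5 + 0.3 * sin(freq * (xs * cos(theta) + ys * sin(theta) - shift) +
                             phase0)
      bx <- w * (0.3 + if (static) 0 else 0.4 * (k - 1) / max(1, n_frames - 1))
      by <- h * 0.5
      blob <- 0.4 * exp(-((xs - bx)^2 + (ys - by)^2) / (2 * (0.08 * w)^2))
      pmin(pmax(g + blob, 0), 1)
    })
  })
}
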