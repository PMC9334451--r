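# Independent brute-force oracles used across the suite. These deliberately
# use naive double loops / exhaustive enumeration, not the package's
# vectorised code paths.

# per-pixel Gaussian-sum renderer: loops every pixel for every phosphene
oracle_render <- function(image, field, gaze, screen) {
  out <- matrix(0, nrow(image), ncol(image))
  for (k in seq_len(nrow(field))) {
    cx <- gaze[1] + field$x_deg[k] / screen$deg_per_px
    cy <- gaze[2] + field$y_deg[k] / screen$deg_per_px
    sigma <- field$sigma_deg[k] / screen$deg_per_px
    wsum <- 0; lsum <- 0
    for (i in seq_len(nrow(image))) {
      for (j in seq_len(ncol(image))) {
        d2 <- (j - 0.5 - cx)^2 + (i - 0.5 - cy)^2
        if (d2 <= (3 * sigma)^2) {
          w <- exp(-d2 / (2 * sigma^2))
          wsum <- wsum + w
          lsum <- lsum + w * image[i, j]
        }
      }
    }
    if (wsum == 0) next
    lum <- lsum / wsum
    for (i in seq_len(nrow(image))) {
      for (j in seq_len(ncol(image))) {
        d2 <- (j - 0.5 - cx)^2 + (i - 0.5 - cy)^2
        if (d2 <= (3 * sigma)^2) {
          out[i, j] <- out[i, j] + lum * exp(-d2 / (2 * sigma^2))
        }
      }
    }
  }
  pmin(pmax(out, 0), 1)
}

# pixel-exhaustive Gaussian-weighted mean luminance for one phosphene
oracle_luminance <- function(image, cx, cy, sigma) {
  wsum <- 0; lsum <- 0
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      d2 <- (j - 0.5 - cx)^2 + (i - 0.5 - cy)^2
      if (d2 <= (3 * sigma)^2) {
        w <- exp(-d2 / (2 * sigma^2))
        wsum <- wsum + w
        lsum <- lsum + w * image[i, j]
      }
    }
  }
  if (wsum == 0) 0 else lsum / wsum
}

# step-by-step accumulator simulation of the frame scheduler
oracle_schedule <- function(video_fps, monitor_hz, n_frames) {
  r <- monitor_hz / video_fps
  total <- 0
  reps <- integer(n_frames)
  for (i in seq_len(n_frames)) {
    want <- i * r
    reps[i] <- round(want - total)
    total <- total + reps[i]
  }
  reps
}

# dense grid-search ML for the psychometric midpoint (word-count Bernoulli
# likelihood, asymptotes 0/1)
oracle_grid_mid <- function(trials, mids = seq(0.6, 1.8, by = 0.002),
                            slopes = seq(4, 40, by = 0.5)) {
  best <- -Inf; best_mid <- NA_real_
  for (s in slopes) {
    for (m in mids) {
      p <- plogis(s * (trials$font_logmar - m))
      ll <- sum(dbinom(trials$words_correct, trials$words_total, p,
                       log = TRUE))
      if (ll > best) { best <- ll; best_mid <- m }
    }
  }
  best_mid
}

# direct pairwise summation of a gaze trace (valid samples only, no gap
# handling: for use on gap-free traces)
oracle_path_length <- function(trace, width_px) {
  v <- trace[as.logical(trace$valid), ]
  total <- 0
  for (i in 2:nrow(v)) {
    total <- total + sqrt((v$x_px[i] - v$x_px[i - 1])^2 +
                            (v$y_px[i] - v$y_px[i - 1])^2)
  }
  total / width_px
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small screen for renderer tests
toy_screen <- function(w = 40, h = 30) screen_geometry(w, h, deg_per_px = 0.5)
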