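#' Veridical-encoding renderer
#'
#' In veridical encoding each phosphene plays two roles: a *filter* that
#' measures the mean image luminance under its footprint at its
#' gaze-translated screen position, and a *display* element drawn as a 2D
#' Gaussian at that matched luminance. The rendered frame is the sum of the
#' per-phosphene Gaussians (unit peak, scaled by sampled luminance), clipped
#' to `[0, 1]`. Because the whole field is translated rigidly to the current
#' gaze point, shifting gaze shifts the rendered pattern in rigid concert.
#'
#' Images are numeric matrices with values in `[0, 1]`, indexed
#' `[row = y, col = x]`; the centre of pixel `(i, j)` sits at screen
#' coordinates `(j - 0.5, i - 0.5)`. Gaussians are truncated at `3 * sigma`.
#'
#' @param image Numeric matrix, luminance in `[0, 1]`.
#' @param field A [generate_field()] result.
#' @param gaze_px Length-2 gaze position in pixels.
#' @param screen A [screen_geometry()]; must match `dim(image)`.
#' @param footprint Sampling footprint for the luminance filter:
#'   `"gaussian"` (Gaussian-weighted mean, same sigma as the display
#'   Gaussian, truncated at 3 sigma) or `"disc"` (uniform disc of radius
#'   2 sigma).
#' @return `render_frame()`: a matrix of the same dimensions as `image`, in
#'   `[0, 1]`, with attributes `gaze_px` and `gaze_held` (TRUE when an
#'   invalid gaze sample forced hold-last-value).
#' @examples
#' scr <- screen_geometry(160, 90, deg_per_px = 0.25)
#' f <- generate_field(n = 50, field_span = 30, seed = 3)
#' img <- matrix(runif(90 * 160), 90, 160)
#' out <- render_frame(img, f, c(80, 45), scr)
#' range(out)
#' @export
render_frame <- function(image, field, gaze_px, screen = screen_geometry(),
                         footprint = c("gaussian", "disc")) {
  footprint <- match.arg(footprint)
  check_image(image, screen)
  px <- field_to_screen(field, gaze_px, screen)
  out <- matrix(0, nrow(image), ncol(image))
  for (k in seq_len(nrow(field))) {
    blob <- gaussian_patch(image, px$x[k], px$y[k], px$sigma[k])
    if (is.null(blob)) next
    lum <- patch_luminance(image, px$x[k], px$y[k], px$sigma[k], footprint)
    if (lum > 0) {
      out[blob$rows, blob$cols] <- out[blob$rows, blob$cols] + lum * blob$w
    }
  }
  out <- pmin(pmax(out, 0), 1)
  attr(out, "gaze_px") <- gaze_px
  attr(out, "gaze_held") <- FALSE
  out
}

#' Sample mean image luminance under one phosphene
#'
#' The filter half of veridical encoding: the mean luminance of the image
#' under the phosphene's footprint once the field has been translated to the
#' gaze point. Returns 0 when the footprint misses the image entirely.
#'
#' @param phosphene One-row data frame (or list) with `x_deg`, `y_deg`,
#'   `sigma_deg`.
#' @inheritParams render_frame
#' @return Luminance in `[0, 1]`.
#' @export
sample_luminance <- function(image, phosphene, gaze_px,
                             screen = screen_geometry(),
                             footprint = c("gaussian", "disc")) {
  footprint <- match.arg(footprint)
  check_image(image, screen)
  cx <- gaze_px[1] + phosphene$x_deg[1] / screen$deg_per_px
  cy <- gaze_px[2] + phosphene$y_deg[1] / screen$deg_per_px
  patch_luminance(image, cx, cy, phosphene$sigma_deg[1] / screen$deg_per_px,
                  footprint)
}

check_image <- function(image, screen) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.")
  }
  if (nrow(image) != screen$height_px || ncol(image) != screen$width_px) {
    abort(sprintf(
      "`image` is %d x %d but `screen` declares %d x %d (rows x cols).",
      nrow(image), ncol(image), screen$height_px, screen$width_px
    ))
  }
  if (any(image < 0 | image > 1)) abort("`image` values must lie in [0, 1].")
  invisible(TRUE)
}

# Pixel window within `radius` of (cx, cy); NULL if it misses the image.
pixel_window <- function(image, cx, cy, radius) {
  cols <- max(1L, floor(cx - radius + 0.5)):min(ncol(image), ceiling(cx + radius + 0.5))
  rows <- max(1L, floor(cy - radius + 0.5)):min(nrow(image), ceiling(cy + radius + 0.5))
  if (cols[1] > ncol(image) || cols[length(cols)] < 1 ||
      rows[1] > nrow(image) || rows[length(rows)] < 1 ||
      cx + radius < 0 || cx - radius > ncol(image) ||
      cy + radius < 0 || cy - radius > nrow(image)) {
    return(NULL)
  }
  list(rows = rows, cols = cols)
}

# Unit-peak Gaussian weights over the 3-sigma pixel window.
gaussian_patch <- function(image, cx, cy, sigma) {
  win <- pixel_window(image, cx, cy, 3 * sigma)
  if (is.null(win)) return(NULL)
  dx <- (win$cols - 0.5) - cx
  dy <- (win$rows - 0.5) - cy
  d2 <- outer(dy^2, dx^2, `+`)
  w <- exp(-d2 / (2 * sigma^2))
  w[d2 > (3 * sigma)^2] <- 0
  list(rows = win$rows, cols = win$cols, w = w)
}

patch_luminance <- function(image, cx, cy, sigma, footprint) {
  if (footprint == "gaussian") {
    blob <- gaussian_patch(image, cx, cy, sigma)
    if (is.null(blob) || sum(blob$w) == 0) return(0)
    sum(blob$w * image[blob$rows, blob$cols]) / sum(blob$w)
  } else {
    win <- pixel_window(image, cx, cy, 2 * sigma)
    if (is.null(win)) return(0)
    dx <- (win$cols - 0.5) - cx
    dy <- (win$rows - 0.5) - cy
    inside <- outer(dy^2, dx^2, `+`) <= (2 * sigma)^2
    if (!any(inside)) return(0)
    mean(image[win$rows, win$cols][inside])
  }
}

#' Render an image sequence against a gaze trace
#'
#' Offline renderer: one output frame per input frame, each rendered at the
#' most recent valid gaze sample at or before the frame's timestamp
#' (hold-last-value, no interpolation). Frames whose gaze was held because
#' the current sample was invalid or missing are flagged.
#'
#' @param frames List of luminance matrices.
#' @param gaze A data frame with columns `t_ms`, `x_px`, `y_px`, `valid`.
#' @param frame_times_ms Timestamps of the frames; defaults to frame index
#'   spaced by `1000 / video_fps`.
#' @param video_fps Frame rate used for default timestamps.
#' @inheritParams render_frame
#' @return List with `frames` (rendered matrices) and `gaze_used` (tibble:
#'   `frame`, `t_ms`, `x_px`, `y_px`, `held`).
#' @export
render_sequence <- function(frames, gaze, field, screen = screen_geometry(),
                            video_fps = 23.96, frame_times_ms = NULL,
                            footprint = "gaussian") {
  stopifnot(is.list(frames), length(frames) >= 1)
  if (is.null(frame_times_ms)) {
    frame_times_ms <- (seq_along(frames) - 1) * 1000 / video_fps
  }
  valid <- gaze[as.logical(gaze$valid), , drop = FALSE]
  if (nrow(valid) == 0) abort("gaze trace contains no valid samples.")
  out <- vector("list", length(frames))
  used <- vector("list", length(frames))
  last <- c(valid$x_px[1], valid$y_px[1])
  for (i in seq_along(frames)) {
    t <- frame_times_ms[i]
    idx_all <- which(gaze$t_ms <= t)
    idx_ok <- which(valid$t_ms <= t)
    held <- length(idx_ok) == 0 ||
      (length(idx_all) > 0 &&
         !as.logical(gaze$valid[max(idx_all)]))
    if (length(idx_ok) > 0) {
      last <- c(valid$x_px[max(idx_ok)], valid$y_px[max(idx_ok)])
    }
    out[[i]] <- render_frame(frames[[i]], field, last, screen,
                             footprint = footprint)
    attr(out[[i]], "gaze_held") <- held
    used[[i]] <- tibble::tibble(frame = i, t_ms = t, x_px = last[1],
                                y_px = last[2], held = held)
  }
  list(frames = out, gaze_used = dplyr::bind_rows(used))
}

#' Schedule video frames onto monitor refreshes
#'
#' When the monitor refresh rate is not an integer multiple of the video
#' frame rate, an accumulator decides how many refreshes each video frame
#' occupies: frame `i` is shown for `round(i * r) - round((i - 1) * r)`
#' refreshes, where `r = monitor_hz / video_fps`. Repetitions are therefore
#' always `floor(r)` or `ceiling(r)`, and the running total tracks real time
#' exactly. At 144 Hz over 23.96 fps (`r = 6.01`) frames repeat 6 times with
#' a 7-repeat roughly every 4 s to resynchronize.
#'
#' @param video_fps Video frame rate (Hz); must not exceed `monitor_hz`.
#' @param monitor_hz Monitor refresh rate (Hz).
#' @param n_frames Number of video frames to schedule.
#' @return A tibble of class `frame_schedule` with columns `frame`,
#'   `repeats`; attribute `ratio` holds `monitor_hz / video_fps`.
#' @examples
#' sched <- schedule_frames(23.96, 144, 240)
#' table(sched$repeats)
#' @export
schedule_frames <- function(video_fps, monitor_hz, n_frames) {
  if (video_fps <= 0 || monitor_hz <= 0) abort("rates must be positive.")
  if (video_fps > monitor_hz) {
    abort("unsupported configuration: `video_fps` exceeds `monitor_hz`.")
  }
  if (n_frames < 1) abort("`n_frames` must be >= 1.")
  r <- monitor_hz / video_fps
  i <- seq_len(n_frames)
  reps <- round(i * r) - round((i - 1) * r)
  tibble::new_tibble(
    tibble::tibble(frame = i, repeats = as.integer(reps)),
    ratio = r, monitor_hz = monitor_hz, video_fps = video_fps,
    class = "frame_schedule"
  )
}
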