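#' Scan-path length of a gaze trace
#'
#' Sums Euclidean distances between consecutive valid gaze samples and
#' normalises by the screen width in pixels, giving path length in *screen
#' widths*. Invalid samples (blinks, track loss) are dropped, and the trace
#' is not bridged across a gap: whenever consecutive valid samples are
#' separated by dropped samples or by more than `max_gap_ms`, that segment
#' contributes zero distance and increments the gap count.
#'
#' @param trace Data frame with `t_ms`, `x_px`, `y_px`, `valid`; timestamps
#'   strictly increasing.
#' @param screen A [screen_geometry()] (only `width_px` is used).
#' @param max_gap_ms Longest inter-sample interval (ms) that is still
#'   summed; larger intervals are treated as gaps.
#' @return One-row tibble: `path_length_sw`, `n_valid`, `n_gaps`.
#' @examples
#' tr <- tibble::tibble(t_ms = c(0, 10), x_px = c(0, 1600),
#'                      y_px = c(0, 900), valid = TRUE)
#' path_length(tr)  # the 16:9 diagonal, ~1.147 screen widths
#' @export
path_length <- function(trace, screen = screen_geometry(), max_gap_ms = 100) {
  trace <- tibble::as_tibble(trace)
  stopifnot(all(c("t_ms", "x_px", "y_px", "valid") %in% names(trace)))
  if (is.unsorted(trace$t_ms, strictly = TRUE)) {
    abort("`t_ms` must be strictly increasing.")
  }
  v <- trace[as.logical(trace$valid), , drop = FALSE]
  if (nrow(v) < 2) abort("need >= 2 valid gaze samples.")

  # a segment is a gap if samples were dropped between its endpoints or the
  # time difference exceeds the threshold
  idx <- which(as.logical(trace$valid))
  dropped_between <- diff(idx) > 1
  dt <- diff(v$t_ms)
  is_gap <- dropped_between | dt > max_gap_ms

  seg <- sqrt(diff(v$x_px)^2 + diff(v$y_px)^2)
  tibble::tibble(
    path_length_sw = sum(seg[!is_gap]) / screen$width_px,
    n_valid = nrow(v),
    n_gaps = sum(is_gap)
  )
}

#' Scan-path summaries for a table of traces
#'
#' @param traces Data frame of gaze samples with identifying columns
#'   (e.g. `subject`, `session`, `task`) plus `t_ms`, `x_px`, `y_px`,
#'   `valid`.
#' @param by Character vector of identifying columns.
#' @inheritParams path_length
#' @return Tibble: one row per group with `path_length_sw`, `n_valid`,
#'   `n_gaps`.
#' @export
path_length_by <- function(traces, by = c("subject", "session", "task"),
                           screen = screen_geometry(), max_gap_ms = 100) {
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ path_length(.x, screen, max_gap_ms)) |>
    dplyr::ungroup()
}

#' Per-subject-mean-corrected correlation between paired scan paths
#'
#' Removes each subject's mean from both series (so stable between-subject
#' differences cannot drive the correlation), then computes the Pearson
#' correlation on the pooled residual pairs with `df = n - 2`. A session-
#' by-session latent factor shared by the two tasks (e.g. motivation)
#' surfaces as a positive residual correlation.
#'
#' @param pairs Tibble with `subject` and the two paired measurements per
#'   session, in columns named by `x` and `y`.
#' @param x,y Column names of the paired series (default `"reading"`,
#'   `"video"`).
#' @return One-row tibble: `r`, `df`, `p_value`, `n_pairs`; `r` is `NA`
#'   with a warning when a residual series has zero variance.
#' @export
demeaned_correlation <- function(pairs, x = "reading", y = "video") {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("subject", x, y) %in% names(pairs)))
  if (nrow(pairs) < 3) abort("need >= 3 paired observations.")
  res <- pairs |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(
      rx = .data[[x]] - mean(.data[[x]]),
      ry = .data[[y]] - mean(.data[[y]])
    ) |>
    dplyr::ungroup()
  if (sd(res$rx) == 0 || sd(res$ry) == 0) {
    warn("zero-variance residuals; correlation undefined.")
    return(tibble::tibble(r = NA_real_, df = nrow(res) - 2L,
                          p_value = NA_real_, n_pairs = nrow(res)))
  }
  ct <- cor.test(res$rx, res$ry)
  tibble::tibble(
    r = unname(ct$estimate),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    n_pairs = nrow(res)
  )
}
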