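#' Plot a phosphene field
#'
#' Phosphene centres in degree coordinates, point size scaled by sigma;
#' the centre-weighted layout reads directly off the plot.
#'
#' @param object A [generate_field()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phosphene_field <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$x_deg, .data$y_deg,
                               size = .data$sigma_deg)) +
    ggplot2::geom_point(alpha = 0.5, colour = "grey20") +
    ggplot2::scale_size_continuous(range = c(0.1, 3)) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", size = expression(sigma),
                  title = sprintf("%d-phosphene center-weighted field",
                                  nrow(object))) +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit
#'
#' Per-font observed accuracy with the fitted logistic curve; the dashed
#' lines mark the 50% crossing, i.e. the equivalent acuity.
#'
#' @param object An [fit_acuity()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acuity_fit <- function(object, ...) {
  obs <- object$data |>
    dplyr::group_by(.data$font_logmar) |>
    dplyr::summarise(
      accuracy_pct = 100 * sum(.data$words_correct) / sum(.data$words_total),
      .groups = "drop"
    )
  xx <- seq(object$font_range[1] - 0.1, object$font_range[2] + 0.1,
            length.out = 200)
  curve <- tibble::tibble(font_logmar = xx,
                          accuracy_pct = predict(object, xx))
  p <- ggplot2::ggplot(obs, ggplot2::aes(.data$font_logmar,
                                         .data$accuracy_pct)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "font size (logMAR)", y = "reading accuracy (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if (object$censored == "none") {
    p <- p +
      ggplot2::geom_vline(xintercept = object$acuity_logmar,
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
      ggplot2::labs(title = sprintf("equivalent acuity %.2f logMAR",
                                    object$acuity_logmar))
  }
  p
}

#' Plot span improvements
#'
#' Short-span (RvvvR) and long-span (RvvvvvvR) acuity changes per subject
#' with the group means, the quantities `y1` and `y2` that the decoder
#' consumes.
#'
#' @param object An [extract_spans()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.span_improvements <- function(object, ...) {
  df <- tibble::as_tibble(object)
  means <- df |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(delta_logmar = mean(.data$delta_logmar),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$kind, .data$delta_logmar)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6, shape = 1) +
    ggplot2::geom_point(data = means, shape = 95, size = 12,
                        colour = "black") +
    ggplot2::scale_x_discrete(limits = c("short", "long"),
                              labels = c(short = "RvvvR (y1)",
                                         long = "RvvvvvvR (y2)")) +
    ggplot2::labs(x = NULL, y = "acuity change (logMAR)") +
    ggplot2::theme_minimal()
}

#' Plot a recovery report
#'
#' Distributions of the decoded per-session rates across replicates with
#' the generating values marked.
#'
#' @param object A [recovery_experiment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_report <- function(object, ...) {
  reps <- object$replicates |>
    tidyr::pivot_longer(c("beta_R_hat", "beta_V_hat"),
                        names_to = "parameter", values_to = "estimate") |>
    dplyr::mutate(parameter = sub("_hat$", "", .data$parameter))
  truths <- tibble::tibble(
    parameter = c("beta_R", "beta_V"),
    truth = c(object$config$beta_R, object$config$beta_V)
  )
  ggplot2::ggplot(reps, ggplot2::aes(.data$estimate)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(data = truths,
                        ggplot2::aes(xintercept = .data$truth),
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "decoded rate (logMAR/session)", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Acuity trajectories over test positions
#'
#' One line per subject; falling lines mean improving acuity.
#'
#' @param acuities Tibble with `subject`, `position`, `acuity_logmar`.
#' @return A ggplot.
#' @export
plot_acuity_trajectories <- function(acuities) {
  ggplot2::ggplot(tibble::as_tibble(acuities),
                  ggplot2::aes(.data$position, .data$acuity_logmar,
                               group = .data$subject,
                               colour = factor(.data$subject))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "measurement position", y = "equivalent acuity (logMAR)",
                  colour = "subject") +
    ggplot2::theme_minimal()
}
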