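#' Tidy an acuity psychometric fit
#'
#' @param x An [fit_acuity()] result.
#' @param ... Unused.
#' @return One-row tibble: `acuity_logmar`, `slope`, `censored`, `bound`,
#'   `extrapolated`, `ci_lo`, `ci_hi`.
#' @export
tidy.acuity_fit <- function(x, ...) {
  tibble::tibble(
    acuity_logmar = x$acuity_logmar, slope = x$slope, censored = x$censored,
    bound = x$bound, extrapolated = x$extrapolated,
    ci_lo = x$ci_lo, ci_hi = x$ci_hi
  )
}

#' @rdname tidy.acuity_fit
#' @return `glance()`: one-row tibble with `converged`, `n_fonts`,
#'   `n_words`, `font_min`, `font_max`, `boot`.
#' @export
glance.acuity_fit <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    n_fonts = dplyr::n_distinct(x$data$font_logmar),
    n_words = sum(x$data$words_total),
    font_min = x$font_range[1], font_max = x$font_range[2],
    boot = x$boot
  )
}

#' Tidy decoded learning rates
#'
#' @param x A [decode_rates()] result.
#' @param ... Unused.
#' @return Tibble with one row per rate (`beta_R`, `beta_V`), the mean span
#'   improvements they were decoded from, and span counts.
#' @export
tidy.learning_rates <- function(x, ...) {
  tibble::tibble(
    term = c("beta_R", "beta_V"),
    estimate = c(x$beta_R, x$beta_V),
    unit = "logMAR/session"
  )
}

#' @rdname tidy.learning_rates
#' @export
glance.learning_rates <- function(x, ...) {
  tibble::tibble(
    y1_mean = x$y1_mean, y2_mean = x$y2_mean,
    n_short = x$n_short, n_long = x$n_long,
    per_subject = !is.null(x$per_subject)
  )
}

#' Tidy a recovery report
#'
#' @param x A [recovery_experiment()] result.
#' @param ... Unused.
#' @return The per-parameter summary tibble (truth, mean estimate, bias,
#'   RMSE, CI coverage).
#' @export
tidy.recovery_report <- function(x, ...) x$summary

#' @rdname tidy.recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(
    n_replicates = nrow(x$replicates), n_failed = x$n_failed,
    ordering_rate = x$ordering_rate
  )
}
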