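#' Screen geometry descriptor
#'
#' Describes the stimulus monitor in both pixel and visual-degree units.
#' Pixel origin is the top-left corner, x rightward, y downward; visual-field
#' coordinates are centred on the point of regard with the same axis
#' directions. `deg_per_px` is an explicit calibration value, never inferred
#' from a viewing distance; the default makes a 1600-px-wide panel subtend
#' 40 degrees.
#'
#' @param width_px,height_px Monitor resolution in pixels.
#' @param deg_per_px Degrees of visual angle per pixel.
#' @return An object of class `screen_geometry`.
#' @examples
#' screen_geometry()
#' @export
screen_geometry <- function(width_px = 1600, height_px = 900,
                            deg_per_px = 40 / 1600) {
  if (width_px <= 0 || height_px <= 0 || deg_per_px <= 0) {
    abort("width_px, height_px and deg_per_px must all be positive.")
  }
  structure(
    list(width_px = width_px, height_px = height_px, deg_per_px = deg_per_px),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px, %.4f deg/px (%.1f x %.1f deg)\n",
    x$width_px, x$height_px, x$deg_per_px,
    x$width_px * x$deg_per_px, x$height_px * x$deg_per_px
  ))
  invisible(x)
}

# Radial density profile: phosphenes per unit area ~ 1/(e + e2), a
# cortical-magnification-style falloff. e2 (deg) controls how fast size and
# spacing grow with eccentricity.
field_density <- function(e, e2) 1 / (e + e2)

#' Generate a center-weighted phosphene field
#'
#' Places `n` phosphenes over a disc of diameter `field_span` degrees with
#' local density proportional to \eqn{M(e) = 1/(e + e_2)}, so phosphenes are
#' smaller and denser toward the point of regard and sparser in the
#' periphery. Radii are drawn by seeded rejection sampling against the
#' density profile; angles are uniform. Each phosphene's Gaussian radius
#' `sigma_deg` is a fixed fraction of the expected local nearest-neighbour
#' spacing \eqn{0.5/\sqrt{density}}, which makes sigma deterministic and
#' monotone non-decreasing in eccentricity.
#'
#' @param n Number of phosphenes (default 1000).
#' @param field_span Full extent of the field in degrees (disc diameter).
#' @param e2 Eccentricity (deg) at which density has halved relative to an
#'   extrapolated foveal value; smaller values concentrate phosphenes
#'   centrally.
#' @param sigma_frac Sigma as a fraction of the expected local
#'   nearest-neighbour spacing.
#' @param seed Integer seed; required so maps are reproducible.
#' @return A tibble of class `phosphene_field` with columns `x_deg`, `y_deg`,
#'   `sigma_deg` and attributes `field_span`, `e2`, `sigma_frac`, `seed`.
#' @examples
#' field <- generate_field(n = 200, seed = 1)
#' field
#' @export
generate_field <- function(n = 1000, field_span = 80, e2 = 2,
                           sigma_frac = 0.4, seed) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a single count >= 1.")
  }
  if (field_span <= 0) abort("`field_span` must be positive.")
  if (e2 <= 0) abort("`e2` must be positive.")
  if (missing(seed)) abort("`seed` is required for a reproducible field.")
  n <- as.integer(n)
  r_max <- field_span / 2

  if (n == 1L) {
    ecc <- 0
  } else {
    ecc <- withr::with_seed(seed, sample_eccentricities(n, r_max, e2))
  }
  theta <- withr::with_seed(seed + 1L, runif(n, 0, 2 * pi))
  if (n == 1L) theta <- 0

  # Normalising constant: integral of 2*pi*e/(e+e2) over [0, r_max]
  total <- 2 * pi * (r_max - e2 * log1p(r_max / e2))
  dens <- n * field_density(ecc, e2) / total     # phosphenes per deg^2
  spacing <- 0.5 / sqrt(dens)                    # expected NN distance (Poisson)

  field <- tibble::tibble(
    x_deg = ecc * cos(theta),
    y_deg = ecc * sin(theta),
    sigma_deg = sigma_frac * spacing
  )
  new_phosphene_field(field, field_span = field_span, e2 = e2,
                      sigma_frac = sigma_frac, seed = seed)
}

# Rejection sampler for eccentricity with radial pdf ~ e/(e + e2) on [0, r_max]
sample_eccentricities <- function(n, r_max, e2) {
  out <- numeric(0)
  # acceptance ratio bounded below by r_max/(r_max+e2); batch generously
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * (1 + e2 / r_max) * 1.2) + 50
    e <- runif(m, 0, r_max)
    keep <- runif(m) < (e / (e + e2)) * ((r_max + e2) / r_max)
    out <- c(out, e[keep])
  }
  out[seq_len(n)]
}

new_phosphene_field <- function(df, field_span, e2 = NA_real_,
                                sigma_frac = NA_real_, seed = NA_integer_) {
  tibble::new_tibble(
    df,
    field_span = field_span, e2 = e2, sigma_frac = sigma_frac, seed = seed,
    class = "phosphene_field"
  )
}

#' Count phosphenes landing on the monitor
#'
#' Translates the field so that its centre sits at the current gaze point and
#' counts phosphene centres inside the monitor area. With gaze near a screen
#' edge much of the field hangs off-screen, so the count varies with gaze.
#'
#' @param field A [generate_field()] result (or any data frame with `x_deg`,
#'   `y_deg`).
#' @param gaze_px Length-2 numeric, gaze position in pixels (x, y).
#' @param screen A [screen_geometry()].
#' @return Integer count.
#' @examples
#' f <- generate_field(n = 500, seed = 2)
#' phosphenes_on_screen(f, c(800, 450), screen_geometry())
#' @export
phosphenes_on_screen <- function(field, gaze_px, screen = screen_geometry()) {
  stopifnot(length(gaze_px) == 2)
  px <- field_to_screen(field, gaze_px, screen)
  sum(px$x >= 0 & px$x <= screen$width_px &
        px$y >= 0 & px$y <= screen$height_px)
}

# degree-space field -> pixel-space centres at the given gaze point
field_to_screen <- function(field, gaze_px, screen) {
  list(
    x = gaze_px[1] + field$x_deg / screen$deg_per_px,
    y = gaze_px[2] + field$y_deg / screen$deg_per_px,
    sigma = field$sigma_deg / screen$deg_per_px
  )
}

#' Read / write phosphene map files
#'
#' The on-disk map format is a CSV with header `x_deg,y_deg,sigma_deg`, one
#' row per phosphene. The JSON variant wraps the same table in a metadata
#' block (`n`, `field_span`, `e2`, `sigma_frac`, `seed`). Coordinates are
#' written with enough digits to round-trip doubles exactly.
#'
#' @param field A `phosphene_field`.
#' @param path Output file; `.json` extension selects the JSON variant.
#' @return `write_phosphene_map()` returns `path` invisibly;
#'   `read_phosphene_map()` returns a `phosphene_field`.
#' @export
write_phosphene_map <- function(field, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      metadata = list(
        n = nrow(field),
        field_span = attr(field, "field_span"),
        e2 = attr(field, "e2"),
        sigma_frac = attr(field, "sigma_frac"),
        seed = attr(field, "seed")
      ),
      phosphenes = as.data.frame(field)
    )
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  } else {
    readr::write_csv(as.data.frame(field), path)
  }
  invisible(path)
}

#' @rdname write_phosphene_map
#' @export
read_phosphene_map <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    md <- payload$metadata
    new_phosphene_field(
      tibble::as_tibble(payload$phosphenes),
      field_span = md$field_span, e2 = md$e2 %||% NA_real_,
      sigma_frac = md$sigma_frac %||% NA_real_,
      seed = md$seed %||% NA_integer_
    )
  } else {
    df <- readr::read_csv(path, col_types = "ddd", progress = FALSE)
    span <- 2 * max(sqrt(df$x_deg^2 + df$y_deg^2))
    new_phosphene_field(df, field_span = span)
  }
}
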