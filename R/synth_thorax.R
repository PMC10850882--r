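#' Generate intercostal transmitter candidate positions
#'
#' Places 1-3 candidate transmitter entry points on an idealized chest wall
#' anterolateral to the LV, one per available intercostal space (ICS 4-6 at
#' decreasing height along the long axis). The per-patient number of
#' available spaces follows the cohort distribution (default 36 % one, 37 %
#' two, 27 % three). Each beam axis points from the skin entry towards a
#' jittered point in the basal inferolateral region, so candidates differ in
#' angle and depth to any given segment.
#'
#' @param geom An [lv_geometry()].
#' @param params The `thorax` block of [plan_config()].
#' @param seed Integer seed.
#' @param n_candidates Optional fixed number of spaces (1-3) overriding the
#'   cohort draw; 0 or less is an error.
#' @return A tibble of class `thorax_model` with one row per candidate:
#'   `ics_id`, `entry_x/y/z` (mm), `axis_x/y/z` (unit vector).
#' @export
generate_thorax <- function(geom, params = plan_config()$thorax, seed = 1L,
                            n_candidates = NULL) {
  set.seed(as.integer(seed))
  if (is.null(n_candidates)) {
    probs <- c(params$p_one_ics, params$p_two_ics, params$p_three_ics)
    n_candidates <- sample(1:3, 1, prob = probs / sum(probs))
  }
  if (n_candidates < 1) stop("at least one candidate intercostal space is required")
  if (n_candidates > 3) stop("at most 3 intercostal spaces are modeled")

  ics_ids <- sort(sample(4:6, n_candidates))
  base_z <- sum((geom$base_centroid - geom$apex_point) * geom$long_axis)
  # heights of ICS 4/5/6 along the axis (upper spaces more basal)
  z_at <- stats::setNames(base_z * c(0.85, 0.65, 0.45), c("4", "5", "6"))

  aim <- segment_centroid(geom, 5L) # basal inferolateral neighbourhood
  rows <- purrr::map(ics_ids, function(ics) {
    az <- stats::runif(1, -35, 35) * pi / 180 # around the lateral direction
    entry <- c(
      params$chest_radius_mm * cos(az),
      params$chest_radius_mm * sin(az),
      z_at[[as.character(ics)]] + stats::rnorm(1, 0, 4)
    )
    target <- aim + stats::rnorm(3, 0, 8)
    axis <- target - entry
    axis <- axis / sqrt(sum(axis^2))
    tibble::tibble(
      ics_id = ics,
      entry_x = entry[1], entry_y = entry[2], entry_z = entry[3],
      axis_x = axis[1], axis_y = axis[2], axis_z = axis[3]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("thorax_model", class(out))
  out
}
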