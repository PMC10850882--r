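#' Bull's-eye plot of per-segment values
#'
#' Standard AHA-16 polar display: basal ring outermost, apical innermost,
#' anterior wall at the top, septum on the left. Zero values are drawn white
#' (no coverage, as in acoustic-intensity maps); missing values are drawn in
#' grey and listed in the subtitle.
#'
#' @param values Numeric vector of exactly 16 per-segment values (NA
#'   allowed), ordered by AHA id.
#' @param title,fill_label Plot annotations.
#' @param zero_as_white Render exact zeros as white "no coverage" sectors
#'   (default TRUE).
#' @return A ggplot object.
#' @export
plot_bullseye <- function(values, title = NULL, fill_label = "value",
                          zero_as_white = TRUE) {
  if (length(values) != 16) stop("exactly 16 per-segment values are required")
  segs <- aha_segments()
  radii <- c(basal = 4, mid = 3, apical = 2) # outer radius per ring; inner = outer - 1
  poly <- purrr::map(1:16, function(i) {
    r_out <- radii[[segs$ring[i]]]
    r_in <- r_out - 1
    # display angle equals the canonical azimuth: 0 = lateral (right),
    # 90 = anterior (top), 180 = septal (left)
    ang <- seq(segs$sector_start_deg[i], segs$sector_end_deg[i], length.out = 20) * pi / 180
    tibble::tibble(
      id = i,
      x = c(r_out * cos(ang), r_in * cos(rev(ang))),
      y = c(r_out * sin(ang), r_in * sin(rev(ang)))
    )
  }) |> dplyr::bind_rows()
  poly$value <- values[poly$id]
  poly$status <- dplyr::case_when(
    is.na(poly$value) ~ "missing",
    zero_as_white & poly$value == 0 ~ "zero",
    TRUE ~ "value"
  )
  missing_ids <- which(is.na(values))

  p <- ggplot2::ggplot(poly, ggplot2::aes(x = .data$x, y = .data$y, group = .data$id)) +
    ggplot2::geom_polygon(
      data = ~ dplyr::filter(.x, .data$status == "value"),
      ggplot2::aes(fill = .data$value), colour = "grey20"
    ) +
    ggplot2::geom_polygon(
      data = ~ dplyr::filter(.x, .data$status == "zero"),
      fill = "white", colour = "grey20"
    ) +
    ggplot2::geom_polygon(
      data = ~ dplyr::filter(.x, .data$status == "missing"),
      fill = "grey80", colour = "grey20", linetype = "22"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = title, fill = fill_label,
      subtitle = if (length(missing_ids)) {
        paste("missing:", paste(missing_ids, collapse = ", "))
      }
    )
  p
}

#' @rdname plot_bullseye
#' @param object A `transmitter_ranking` from [rank_transmitter_sites()].
#' @param ... Unused.
#' @export
autoplot.transmitter_ranking <- function(object, ...) {
  maps <- object$acoustic_map |>
    dplyr::arrange(.data$ics_id, .data$id)
  plots <- lapply(split(maps, maps$ics_id), function(df) {
    plot_bullseye(df$intensity[order(df$id)],
                  title = paste("ICS", df$ics_id[1]),
                  fill_label = "intensity")
  })
  if (length(plots) > 1 && requireNamespace("patchwork", quietly = TRUE)) {
    return(patchwork::wrap_plots(plots, nrow = 1))
  }
  plots[[1]]
}

#' C-arm viewing geometry
#'
#' @param rao_lao_deg Right/left anterior oblique angle (deg, RAO positive,
#'   within \[-90, 90\]).
#' @param cranial_caudal_deg Cranial (positive) / caudal angulation (deg,
#'   within \[-90, 90\]).
#' @param source_to_detector_mm,source_to_isocenter_mm C-arm distances (mm).
#' @param detector_mm Detector side length (mm).
#' @return A list of class `carm_view`.
#' @export
carm_view <- function(rao_lao_deg = 0, cranial_caudal_deg = 0,
                      source_to_detector_mm = 1200,
                      source_to_isocenter_mm = 600, detector_mm = 300) {
  if (abs(rao_lao_deg) > 90 || abs(cranial_caudal_deg) > 90) {
    stop("angles must lie within [-90, 90] degrees")
  }
  if (source_to_detector_mm <= 0 || source_to_isocenter_mm <= 0 ||
      detector_mm <= 0) {
    stop("distances must be positive")
  }
  structure(
    list(rao_lao_deg = rao_lao_deg, cranial_caudal_deg = cranial_caudal_deg,
         source_to_detector_mm = source_to_detector_mm,
         source_to_isocenter_mm = source_to_isocenter_mm,
         detector_mm = detector_mm),
    class = "carm_view"
  )
}

#' Project target-segment boundaries onto a fluoroscopic detector
#'
#' Point-source (pinhole) perspective projection of the boundary polylines
#' of the chosen target segments onto the detector plane of a C-arm view,
#' in detector millimetres. The isocenter is the endocardial centroid; at
#' the isocenter the magnification is `source_to_detector /
#' source_to_isocenter`.
#'
#' @param geom An [lv_geometry()].
#' @param target_ids AHA ids whose boundaries to project.
#' @param view A [carm_view()].
#' @return A tibble of ordered contour points: `id`, `point` (order along
#'   the loop), `u_mm`, `v_mm` (detector coordinates, v vertical).
#' @export
project_overlay <- function(geom, target_ids, view = carm_view()) {
  stopifnot(inherits(view, "carm_view"))
  iso <- colMeans(geom$endo_vertices)
  a <- view$rao_lao_deg * pi / 180
  b <- view$cranial_caudal_deg * pi / 180
  # beam direction (source -> detector): AP beam (posterior-directed -y),
  # rotated RAO about the long axis then cranially about the rotated lateral axis
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  beam0 <- c(0, -1, 0)
  lat0 <- c(1, 0, 0)
  beam1 <- as.vector(rz %*% beam0)
  u_axis <- as.vector(rz %*% lat0)
  rot_about <- function(v, axis, ang) {
    v * cos(ang) + cross3(axis, v) * sin(ang) + axis * sum(axis * v) * (1 - cos(ang))
  }
  beam <- rot_about(beam1, u_axis, b)
  v_axis <- cross3(beam, u_axis)
  source <- iso - view$source_to_isocenter_mm * beam

  project <- function(pts) {
    w <- pts - matrix(source, nrow(pts), 3, byrow = TRUE)
    depth <- as.vector(w %*% beam)
    if (any(depth <= 0)) stop("segment lies behind the source plane")
    s <- view$source_to_detector_mm / depth
    tibble::tibble(u_mm = as.vector(w %*% u_axis) * s,
                   v_mm = as.vector(w %*% v_axis) * s)
  }

  out <- purrr::map(target_ids, function(id) {
    loop <- segment_boundary_loop(geom, id)
    proj <- project(geom$endo_vertices[loop, , drop = FALSE])
    proj |> dplyr::mutate(id = id, point = dplyr::row_number(), .before = 1)
  })
  dplyr::bind_rows(out)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# ordered vertex loop around a segment's boundary (edges with exactly one
# incident face inside the segment, chained into a closed walk)
segment_boundary_loop <- function(geom, id) {
  ed <- mesh_edges(geom$endo_faces)
  ed$inside <- geom$segment_labels[ed$face] == id
  per_edge <- ed |>
    dplyr::group_by(.data$edge, .data$v1, .data$v2) |>
    dplyr::summarise(n_in = sum(.data$inside), n_tot = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_in == 1)
  if (!nrow(per_edge)) stop("segment ", id, " has no boundary edges")
  # chain edges greedily from an arbitrary start
  remaining <- per_edge[, c("v1", "v2")]
  loop <- c(remaining$v1[1], remaining$v2[1])
  remaining <- remaining[-1, ]
  while (nrow(remaining)) {
    head <- loop[length(loop)]
    nxt <- which(remaining$v1 == head | remaining$v2 == head)[1]
    if (is.na(nxt)) break
    loop <- c(loop, if (remaining$v1[nxt] == head) remaining$v2[nxt] else remaining$v1[nxt])
    remaining <- remaining[-nxt, ]
  }
  if (loop[1] == loop[length(loop)]) loop <- loop[-length(loop)]
  loop
}
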