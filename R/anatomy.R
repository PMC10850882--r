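#' AHA-16 parcellation of an LV endocardial mesh
#'
#' Labels every endocardial face with an AHA segment id using the geometry's
#' landmarks: the normalized long-axis coordinate (apex 0, base 1) splits the
#' surface into apical/mid/basal thirds, and the azimuth around the long axis
#' -- anchored to the geometry's septal-direction landmark, or synthesized
#' from the RV pacing site when no landmark is stored (which assumes that
#' site lies mid-septal) -- splits each ring into 6/6/4 circumferential
#' sectors. Invariant under rigid motion applied jointly to the mesh and its
#' landmarks.
#'
#' @param geom An [lv_geometry()] (its stored labels are ignored;
#'   this recomputes them from landmarks).
#' @return Integer vector of AHA ids (1-16), one per endocardial face.
#' @export
parcellate_aha <- function(geom) {
  if (is.null(geom$apex_point) || is.null(geom$base_centroid)) {
    stop("apex and base landmarks are required")
  }
  if (is.null(geom$long_axis)) stop("long axis is required")
  sept <- geom$septal_dir
  if (is.null(sept)) {
    sept <- geom$rv_pacing_site - geom$apex_point
    sept <- sept - sum(sept * geom$long_axis) * geom$long_axis
    if (sqrt(sum(sept^2)) < 1e-9) {
      stop("RV pacing site does not define a septal direction")
    }
    sept <- sept / sqrt(sum(sept^2))
  }
  parcellate_frame(
    geom$endo_vertices, geom$endo_faces, geom$apex_point, geom$base_centroid,
    geom$long_axis, septal_dir = sept
  )
}

# Frame-based labelling shared with the generator. `septal_dir` is a unit
# vector (perpendicular component already taken) pointing at the mid-septum;
# the lateral reference (azimuth 0) is its opposite, and anterior (+90 deg) is
# long_axis x lateral (right-handed).
parcellate_frame <- function(vertices, faces, apex_point, base_centroid,
                             long_axis, septal_dir) {
  axis <- long_axis / sqrt(sum(long_axis^2))
  lat <- -septal_dir
  lat <- lat - sum(lat * axis) * axis
  lat <- lat / sqrt(sum(lat^2))
  ant <- c(
    axis[2] * lat[3] - axis[3] * lat[2],
    axis[3] * lat[1] - axis[1] * lat[3],
    axis[1] * lat[2] - axis[2] * lat[1]
  )
  cent <- mesh_face_centroids(vertices, faces)
  rel <- cent - matrix(apex_point, nrow(cent), 3, byrow = TRUE)
  h <- as.vector(rel %*% axis) / sum((base_centroid - apex_point) * axis)
  h <- pmin(pmax(h, 0), 1 - 1e-12)
  az <- (atan2(rel %*% ant, rel %*% lat) * 180 / pi) %% 360
  ring <- cut(h, c(-Inf, 1 / 3, 2 / 3, Inf), labels = c("apical", "mid", "basal"))
  out <- integer(nrow(cent))
  for (r in c("basal", "mid", "apical")) {
    sel <- ring == r
    if (any(sel)) out[sel] <- aha_sector_of(az[sel], r)
  }
  out
}

#' Wall thickness by normal ray casting
#'
#' For every endocardial vertex, casts a ray along the outward endocardial
#' normal and takes the distance to the nearest epicardial triangle hit.
#' Vertices whose rays miss the epicardium (open basal rim) are excluded from
#' the per-segment summary with a warning. Per-segment summary thickness is
#' the median (robust to basal-rim artifacts; `summary = "min"` available for
#' conservative screening) and a segment is flagged thin when the summary is
#' strictly below `thin_mm`.
#'
#' @param geom An [lv_geometry()].
#' @param thin_mm Thin threshold in mm (strict `<`; default 5).
#' @param summary `"median"` (default) or `"min"`.
#' @param min_valid Minimum number of valid vertices a segment needs
#'   (default 10); fewer is an error.
#' @return A tibble with one row per segment: `id`, `thickness_mm`,
#'   `n_valid`, `thin`. Per-vertex thickness (NA where the ray missed) is
#'   attached as attribute `"vertex_thickness"`.
#' @export
#' @examples
#' pat <- generate_lv_geometry(seed = 2)
#' compute_wall_thickness(pat$geometry)
compute_wall_thickness <- function(geom, thin_mm = 5, summary = c("median", "min"),
                                   min_valid = 10L) {
  summary <- match.arg(summary)
  vn <- mesh_vertex_normals(geom$endo_vertices, geom$endo_faces)
  d <- raycast_distance(geom$endo_vertices, vn, geom$epi_vertices, geom$epi_faces)
  d[d < 0] <- NA_real_
  n_miss <- sum(is.na(d))
  if (n_miss > 0) {
    warning(n_miss, " endocardial vertices had no epicardial intersection; excluded")
  }
  labels <- geom$segment_labels
  # vertex -> segments via incident faces
  vert_seg <- tibble::tibble(
    vertex = as.vector(geom$endo_faces),
    id = rep(labels, 3)
  ) |> dplyr::distinct()
  stat_fun <- if (summary == "median") stats::median else min
  res <- vert_seg |>
    dplyr::mutate(thickness = d[.data$vertex]) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_valid = sum(!is.na(.data$thickness)),
      thickness_mm = if (sum(!is.na(.data$thickness)) > 0) {
        stat_fun(.data$thickness[!is.na(.data$thickness)])
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$id)
  bad <- res$id[res$n_valid < min_valid]
  if (length(bad)) {
    stop("segment(s) ", paste(bad, collapse = ", "), " have fewer than ",
         min_valid, " valid thickness vertices")
  }
  out <- res |>
    dplyr::mutate(thin = .data$thickness_mm < thin_mm) |>
    dplyr::select("id", "thickness_mm", "n_valid", "thin")
  attr(out, "vertex_thickness") <- d
  out
}
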