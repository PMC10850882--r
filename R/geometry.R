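#' Left-ventricular geometry object
#'
#' Container for an LV endocardial/epicardial triangle-mesh anatomy in the
#' canonical frame (long axis = +z, apex at the origin, millimetres).
#' Vertices are `n x 3` numeric matrices, faces `m x 3` integer matrices of
#' 1-based vertex indices with consistent outward winding. Every endocardial
#' face carries exactly one AHA segment label in 1..16.
#'
#' @param endo_vertices,endo_faces Endocardial surface (mm; triangle indices).
#' @param epi_vertices,epi_faces Epicardial surface.
#' @param apex_point,base_centroid Landmarks (mm).
#' @param long_axis Unit vector, apex-to-base direction.
#' @param rv_pacing_site Septal endocardial point (mm); must lie on a face
#'   labelled septal (segments 2, 3, 8 or 9).
#' @param segment_labels Integer AHA id (1-16) per endocardial face.
#' @param septal_dir Optional unit vector (perpendicular to the long axis)
#'   pointing at the mid-septum: the circumferential anchor of the AHA
#'   parcellation. When absent, [parcellate_aha()] synthesizes the anchor
#'   from the RV pacing site, which assumes that site lies mid-septal.
#' @return An object of class `lv_geometry`.
#' @export
lv_geometry <- function(endo_vertices, endo_faces, epi_vertices, epi_faces,
                        apex_point, base_centroid, long_axis, rv_pacing_site,
                        segment_labels, septal_dir = NULL) {
  endo_vertices <- as.matrix(endo_vertices)
  epi_vertices <- as.matrix(epi_vertices)
  endo_faces <- matrix(as.integer(endo_faces), ncol = 3)
  epi_faces <- matrix(as.integer(epi_faces), ncol = 3)
  stopifnot(
    ncol(endo_vertices) == 3, ncol(epi_vertices) == 3,
    all(is.finite(endo_vertices)), all(is.finite(epi_vertices)),
    length(segment_labels) == nrow(endo_faces),
    all(segment_labels %in% 1:16)
  )
  axis_len <- sqrt(sum((base_centroid - apex_point)^2))
  if (!(axis_len > 0)) stop("apex-to-base distance must be positive")
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  if (!is.null(septal_dir)) {
    septal_dir <- septal_dir - sum(septal_dir * long_axis) * long_axis
    septal_dir <- septal_dir / sqrt(sum(septal_dir^2))
  }
  geom <- structure(
    list(
      endo_vertices = endo_vertices, endo_faces = endo_faces,
      epi_vertices = epi_vertices, epi_faces = epi_faces,
      apex_point = as.numeric(apex_point),
      base_centroid = as.numeric(base_centroid),
      long_axis = as.numeric(long_axis),
      rv_pacing_site = as.numeric(rv_pacing_site),
      segment_labels = as.integer(segment_labels),
      septal_dir = if (is.null(septal_dir)) NULL else as.numeric(septal_dir)
    ),
    class = "lv_geometry"
  )
  # RV pacing site must sit on (near) a septal-labelled face
  septal <- geom$segment_labels %in% c(2L, 3L, 8L, 9L)
  cent <- mesh_face_centroids(endo_vertices, endo_faces)
  d2 <- rowSums((cent - matrix(geom$rv_pacing_site, nrow(cent), 3, byrow = TRUE))^2)
  if (!septal[which.min(d2)]) {
    stop("rv_pacing_site does not lie on a septal-labelled face (segments 2,3,8,9)")
  }
  geom
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat(
    "<lv_geometry> ", nrow(x$endo_vertices), " endo vertices / ",
    nrow(x$endo_faces), " faces; ", nrow(x$epi_vertices),
    " epi vertices; apex-base ",
    round(sqrt(sum((x$base_centroid - x$apex_point)^2)), 1), " mm\n",
    sep = ""
  )
  invisible(x)
}

# ---- mesh primitives -------------------------------------------------------

#' Triangle areas of a mesh
#' @param vertices `n x 3` matrix (mm).
#' @param faces `m x 3` integer matrix.
#' @return Numeric vector of face areas (mm^2).
#' @export
mesh_face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Face centroids
#' @inheritParams mesh_face_areas
#' @return `m x 3` matrix of centroids.
#' @export
mesh_face_centroids <- function(vertices, faces) {
  (vertices[faces[, 1], , drop = FALSE] +
    vertices[faces[, 2], , drop = FALSE] +
    vertices[faces[, 3], , drop = FALSE]) / 3
}

# Unit face normals (right-hand winding).
mesh_face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  n <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
}

# Area-weighted unit vertex normals.
mesh_vertex_normals <- function(vertices, faces) {
  fn <- mesh_face_normals(vertices, faces)
  fa <- mesh_face_areas(vertices, faces)
  vn <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    idx <- faces[, k]
    for (d in 1:3) {
      vn[, d] <- vn[, d] + tabulate_weighted(idx, fn[, d] * fa, nrow(vertices))
    }
  }
  vn / pmax(sqrt(rowSums(vn^2)), .Machine$double.eps)
}

# rowsum() wrapper returning a dense vector over 1..n
tabulate_weighted <- function(index, weights, n) {
  out <- numeric(n)
  s <- rowsum(weights, index)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Unique undirected edge list of a triangle mesh: tibble with vertex ids and
# the 1-2 incident faces.
mesh_edges <- function(faces) {
  m <- nrow(faces)
  e <- rbind(
    cbind(faces[, 1], faces[, 2], seq_len(m)),
    cbind(faces[, 2], faces[, 3], seq_len(m)),
    cbind(faces[, 3], faces[, 1], seq_len(m))
  )
  key_a <- pmin(e[, 1], e[, 2])
  key_b <- pmax(e[, 1], e[, 2])
  ord <- order(key_a, key_b)
  key_a <- key_a[ord]; key_b <- key_b[ord]; face <- e[ord, 3]
  grp <- cumsum(c(TRUE, diff(key_a) != 0 | diff(key_b) != 0))
  tibble::tibble(v1 = key_a, v2 = key_b, face = face, edge = grp)
}

# Per-vertex mean of a per-face quantity (membership-weighted).
face_to_vertex <- function(values, faces, n_vertices) {
  num <- numeric(n_vertices)
  den <- numeric(n_vertices)
  for (k in 1:3) {
    idx <- faces[, k]
    num <- num + tabulate_weighted(idx, values, n_vertices)
    den <- den + tabulate_weighted(idx, rep(1, length(idx)), n_vertices)
  }
  num / pmax(den, 1)
}

#' Area-weighted centroid of an AHA segment's endocardial faces
#'
#' @param geom An [lv_geometry()].
#' @param id AHA segment id.
#' @return Length-3 numeric (mm).
#' @export
segment_centroid <- function(geom, id) {
  sel <- geom$segment_labels == id
  if (!any(sel)) stop("segment ", id, " has no faces")
  cent <- mesh_face_centroids(geom$endo_vertices, geom$endo_faces)[sel, , drop = FALSE]
  w <- mesh_face_areas(geom$endo_vertices, geom$endo_faces)[sel]
  colSums(cent * w) / sum(w)
}

# ---- parametric shells -----------------------------------------------------

# Truncated prolate-ellipsoid open shell: semi-axes (a, a, c), apex (south
# pole) at origin, long axis +z, truncated at z_base = trunc_frac * 2c.
# Returns vertices, faces (outward winding), plus the polar/azimuth grid used.
ellipsoid_shell <- function(a, c_ax, trunc_frac = 0.7,
                            n_phi = 36L, n_u = 14L,
                            radial_offset = NULL) {
  stopifnot(a > 0, c_ax > 0, trunc_frac > 0, trunc_frac <= 1)
  z_base <- trunc_frac * 2 * c_ax
  theta_base <- acos(pmin(1, (z_base - c_ax) / c_ax))
  theta <- seq(pi, theta_base, length.out = n_u + 1L)[-1L] # exclude exact apex
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  grid <- expand.grid(phi = phi, theta = theta)
  r_xy <- a * sin(grid$theta)
  v <- cbind(
    x = r_xy * cos(grid$phi),
    y = r_xy * sin(grid$phi),
    z = c_ax + c_ax * cos(grid$theta)
  )
  apex <- c(0, 0, 0)
  vertices <- rbind(apex, v)
  apex_id <- 1L
  ring_id <- function(j, i) 1L + (j - 1L) * n_phi + ((i - 1L) %% n_phi) + 1L

  faces <- list()
  # apex fan (ring j = 1); outward normal points away from axis/down
  f_fan <- cbind(
    apex_id,
    ring_id(1L, seq_len(n_phi) + 1L),
    ring_id(1L, seq_len(n_phi))
  )
  faces[[1]] <- f_fan
  for (j in seq_len(n_u - 1L)) {
    i <- seq_len(n_phi)
    lo1 <- ring_id(j, i); lo2 <- ring_id(j, i + 1L)
    hi1 <- ring_id(j + 1L, i); hi2 <- ring_id(j + 1L, i + 1L)
    faces[[length(faces) + 1L]] <- cbind(lo1, hi2, hi1)
    faces[[length(faces) + 1L]] <- cbind(lo1, lo2, hi2)
  }
  faces <- do.call(rbind, faces)
  storage.mode(faces) <- "integer"

  # ensure outward winding: flip faces whose normal points inward (towards axis)
  fn <- mesh_face_normals(vertices, faces)
  cent <- mesh_face_centroids(vertices, faces)
  outward <- cbind(cent[, 1], cent[, 2], 0)
  nrm <- sqrt(rowSums(outward^2))
  use <- nrm > 1e-9
  flip <- rep(FALSE, nrow(faces))
  flip[use] <- rowSums(fn[use, , drop = FALSE] * outward[use, , drop = FALSE]) < 0
  flip[!use] <- fn[!use, 3] > 0 # apex fan: outward is -z
  faces[flip, ] <- faces[flip, c(1, 3, 2)]

  list(vertices = vertices, faces = faces, n_phi = n_phi, n_u = n_u,
       z_base = z_base, apex_id = apex_id)
}

# Closed UV-sphere used in tests (thickness and activation oracles).
sphere_mesh <- function(radius = 30, n_phi = 36L, n_theta = 18L,
                        center = c(0, 0, 0)) {
  theta <- seq(pi, 0, length.out = n_theta + 1L)
  theta <- theta[-c(1L, n_theta + 1L)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  grid <- expand.grid(phi = phi, theta = theta)
  v <- cbind(
    radius * sin(grid$theta) * cos(grid$phi),
    radius * sin(grid$theta) * sin(grid$phi),
    radius * cos(grid$theta)
  )
  south <- c(0, 0, -radius); north <- c(0, 0, radius)
  vertices <- rbind(south, v, north)
  south_id <- 1L
  north_id <- nrow(vertices)
  ring_id <- function(j, i) 1L + (j - 1L) * n_phi + ((i - 1L) %% n_phi) + 1L
  nr <- n_theta - 1L
  faces <- list(cbind(south_id, ring_id(1L, seq_len(n_phi) + 1L), ring_id(1L, seq_len(n_phi))))
  for (j in seq_len(nr - 1L)) {
    i <- seq_len(n_phi)
    faces[[length(faces) + 1L]] <- cbind(ring_id(j, i), ring_id(j + 1L, i + 1L), ring_id(j + 1L, i))
    faces[[length(faces) + 1L]] <- cbind(ring_id(j, i), ring_id(j, i + 1L), ring_id(j + 1L, i + 1L))
  }
  faces[[length(faces) + 1L]] <- cbind(north_id, ring_id(nr, seq_len(n_phi)), ring_id(nr, seq_len(n_phi) + 1L))
  faces <- do.call(rbind, faces)
  storage.mode(faces) <- "integer"
  fn <- mesh_face_normals(vertices, faces)
  cent <- mesh_face_centroids(vertices, faces)
  flip <- rowSums(fn * cent) < 0
  faces[flip, ] <- faces[flip, c(1, 3, 2)]
  vertices <- vertices + matrix(center, nrow(vertices), 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}
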