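# Shared fixtures, all built in code.

# regular flat strip in the z = 0 plane; grid spacing `dx` mm
flat_strip_mesh <- function(nx = 30, ny = 10, dx = 2) {
  g <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1)) * dx
  v <- cbind(g$x, g$y, 0)
  id <- function(i, j) (j - 1) * nx + i
  f <- list()
  for (j in 1:(ny - 1)) {
    for (i in 1:(nx - 1)) {
      f[[length(f) + 1]] <- rbind(
        c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
        c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
      )
    }
  }
  list(vertices = v, faces = do.call(rbind, f))
}

# bare-bones geometry object (bypasses lv_geometry() validation) for solver
# tests that do not need a ventricle
as_geom <- function(vertices, faces, labels = rep(1L, nrow(faces)), ...) {
  structure(
    c(list(endo_vertices = vertices, endo_faces = faces,
           segment_labels = as.integer(labels)), list(...)),
    class = "lv_geometry"
  )
}

# concentric-sphere "ventricle": endo radius r_in, epi r_out, AHA-like labels
# from the standard parcellation rule so per-segment summaries work
concentric_sphere_geom <- function(r_in = 30, r_out = 40,
                                   n_phi = 48L, n_theta = 24L) {
  endo <- wiseplan:::sphere_mesh(r_in, n_phi, n_theta)
  epi <- wiseplan:::sphere_mesh(r_out, n_phi, n_theta)
  labels <- wiseplan:::parcellate_frame(
    endo$vertices, endo$faces,
    apex_point = c(0, 0, -r_in), base_centroid = c(0, 0, r_in),
    long_axis = c(0, 0, 1), septal_dir = c(-1, 0, 0)
  )
  as_geom(endo$vertices, endo$faces, labels,
          epi_vertices = epi$vertices, epi_faces = epi$faces,
          apex_point = c(0, 0, -r_in), base_centroid = c(0, 0, r_in),
          long_axis = c(0, 0, 1))
}

# light-weight cohort configuration for smoke tests (coarser mesh, fewer
# patients); thin-flag recovery is not asserted at this resolution
fast_cfg <- function(seed = 7L, n_patients = 2L, anatomy = list(), ...) {
  anatomy <- utils::modifyList(list(n_phi = 36L, n_u = 14L), anatomy)
  plan_config(seed = seed, n_patients = n_patients, anatomy = anatomy, ...)
}

# even-odd ray-crossing point-in-polygon (test-local oracle)
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((py[i] > y) != (py[j] > y)) &&
        (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# synthetic 16-segment feature table for planner tests
make_feature_table <- function(ttp = rep(0.3, 16), act = rep(80, 16),
                               thin = integer(0), scar = integer(0),
                               flat = integer(0)) {
  tab <- tibble::tibble(
    id = 1:16,
    thickness_mm = ifelse(1:16 %in% thin, 4, 8),
    thin = 1:16 %in% thin,
    hypoperfused = 1:16 %in% scar,
    late_enhancement = FALSE,
    ttp_phase = ifelse(1:16 %in% flat, NA_real_, ttp),
    ttp_ms = ifelse(1:16 %in% flat, NA_real_, ttp * 857),
    activation_ms = act
  )
  dplyr::mutate(tab, viable = !thin & !hypoperfused, target = FALSE)
}
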