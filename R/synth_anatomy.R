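#' Generate a synthetic LV anatomy with ground truth
#'
#' Builds a truncated prolate-ellipsoid endocardial surface (default semi-axes
#' 25 x 25 x 80 mm, base truncation at 70 % of the long axis), parcellates it
#' into AHA-16 segments, draws a per-segment wall thickness such that the
#' expected number of thin (<5 mm) segments follows the configured
#' distribution (default mean 4.8, SD 3.5, clipped to 0..16), and offsets the
#' epicardial surface accordingly. Ischemic-phenotype patients (default
#' probability 6/11) receive a contiguous scar territory of 2-4 segments with
#' reduced true myocardial blood flow; thin-segment sampling prefers scar
#' segments so scar territories present as thinned, matching the ischemic
#' phenotype. A ground-truth record (thin set, scar set, true MBF, target
#' pair, per-segment response class) is returned alongside for recovery
#' testing.
#'
#' @param params The `anatomy` block of [plan_config()].
#' @param seed Integer seed; identical `(params, seed)` give byte-identical
#'   output.
#' @param perf_params Optional `perfusion` block (for true-MBF draws);
#'   defaults to the standard block.
#' @return A list with elements `geometry` ([lv_geometry()]) and `truth`
#'   (list: `thin_segments`, `scar_segments`, `ischemic`, `true_mbf`,
#'   `true_target_segments`, `ahr_class`, `thickness_mm`).
#' @export
#' @examples
#' pat <- generate_lv_geometry(seed = 1)
#' pat$truth$thin_segments
generate_lv_geometry <- function(params = plan_config()$anatomy, seed = 1L,
                                 perf_params = plan_config()$perfusion) {
  if (params$endo_a <= 0 || params$endo_c <= 0) stop("axis lengths must be positive")
  if (params$thin_thickness_min <= 0) stop("wall thickness bounds must be positive")
  set.seed(as.integer(seed))

  # ---- thin count and scar territory ---------------------------------------
  n_thin <- if (params$thin_sd == 0) {
    round(params$thin_mean)
  } else {
    round(stats::rnorm(1, params$thin_mean, params$thin_sd))
  }
  n_thin <- max(0L, min(16L, as.integer(n_thin)))

  ischemic <- stats::runif(1) < params$ischemic_prob
  scar <- integer(0)
  if (ischemic) {
    n_scar <- sample(params$scar_size_min:params$scar_size_max, 1)
    scar <- grow_contiguous_segments(n_scar)
  }

  # thin sampling prefers scar segments; count stays the calibrated draw
  thin <- integer(0)
  if (n_thin > 0) {
    from_scar <- sample_int(scar, min(n_thin, length(scar)))
    rest <- setdiff(1:16, from_scar)
    thin <- sort(c(from_scar, sample_int(rest, n_thin - length(from_scar))))
  }

  # ---- target pair: adjacent viable segments, lateral preference -----------
  viable <- setdiff(1:16, union(thin, scar))
  targets <- draw_target_pair(viable)

  # ---- thickness draw ------------------------------------------------------
  thickness <- stats::runif(16, params$normal_thickness_min, params$normal_thickness_max)
  if (length(thin)) {
    thickness[thin] <- stats::runif(
      length(thin), params$thin_thickness_min, params$thin_thickness_max
    )
  }

  # ---- surfaces ------------------------------------------------------------
  shell <- ellipsoid_shell(params$endo_a, params$endo_c, params$trunc_frac,
                           n_phi = params$n_phi, n_u = params$n_u)
  apex_point <- c(0, 0, 0)
  base_centroid <- c(0, 0, shell$z_base)
  long_axis <- c(0, 0, 1)
  labels <- parcellate_frame(
    shell$vertices, shell$faces, apex_point, base_centroid, long_axis,
    septal_dir = c(-1, 0, 0)
  )

  vtx_thick <- face_to_vertex(thickness[labels], shell$faces, nrow(shell$vertices))
  vn <- mesh_vertex_normals(shell$vertices, shell$faces)
  epi_vertices <- shell$vertices + vn * vtx_thick

  # RV pacing site: septal segment farthest from the primary target
  sept_ids <- c(2L, 3L, 8L, 9L)
  ref <- if (length(targets)) {
    seg_centroid_raw(shell$vertices, shell$faces, labels, targets[1])
  } else {
    c(params$endo_a, 0, shell$z_base / 2)
  }
  sept_cents <- t(vapply(
    sept_ids, function(s) seg_centroid_raw(shell$vertices, shell$faces, labels, s),
    numeric(3)
  ))
  rv_seg <- sept_ids[which.max(rowSums((sept_cents - matrix(ref, 4, 3, byrow = TRUE))^2))]
  rv_cent <- sept_cents[match(rv_seg, sept_ids), ]
  d2 <- rowSums((shell$vertices - matrix(rv_cent, nrow(shell$vertices), 3, byrow = TRUE))^2)
  # snap to a vertex of a face in the chosen septal segment
  cand <- unique(as.vector(shell$faces[labels == rv_seg, ]))
  rv_site <- shell$vertices[cand[which.min(d2[cand])], ]

  geom <- lv_geometry(
    endo_vertices = shell$vertices, endo_faces = shell$faces,
    epi_vertices = epi_vertices, epi_faces = shell$faces,
    apex_point = apex_point, base_centroid = base_centroid,
    long_axis = long_axis, rv_pacing_site = rv_site,
    segment_labels = labels, septal_dir = c(-1, 0, 0)
  )

  true_mbf <- stats::rnorm(16, perf_params$mbf_healthy_mean, perf_params$mbf_healthy_sd)
  true_mbf <- pmax(true_mbf, 1)
  true_mbf[scar] <- true_mbf[scar] * perf_params$scar_flow_fraction

  ahr_class <- rep("nontarget_viable", 16)
  ahr_class[scar] <- "scarred"
  ahr_class[targets] <- "target"

  truth <- list(
    thin_segments = thin,
    scar_segments = scar,
    ischemic = ischemic,
    true_mbf = true_mbf,
    true_ttp = rep(NA_real_, 16), # filled by generate_motion()
    true_target_segments = targets,
    ahr_class = ahr_class,
    thickness_mm = thickness
  )
  list(geometry = geom, truth = truth)
}

# sample() without the length-1 surprise
sample_int <- function(x, size) {
  if (size <= 0 || length(x) == 0) return(integer(0))
  x[sample.int(length(x), min(size, length(x)))]
}

# random contiguous segment set grown on the AHA adjacency graph
grow_contiguous_segments <- function(n) {
  seg <- sample.int(16, 1)
  set <- seg
  while (length(set) < n) {
    frontier <- setdiff(unlist(lapply(set, aha_neighbors)), set)
    if (!length(frontier)) break
    set <- c(set, sample_int(frontier, 1))
  }
  sort(as.integer(set))
}

# target pair: primary drawn from viable lateral-wall segments (weights
# reflecting the typical implant distribution), secondary = preferred viable
# neighbour; falls back to the global preference order, or empty when no
# adjacent viable pair exists.
draw_target_pair <- function(viable) {
  lateral <- c(5L, 6L, 11L, 12L)
  w <- c(0.40, 0.15, 0.25, 0.20)
  has_viable_neighbor <- function(s) length(intersect(aha_neighbors(s), viable)) > 0
  cand <- lateral[lateral %in% viable]
  cand <- cand[vapply(cand, has_viable_neighbor, logical(1))]
  primary <- if (length(cand)) {
    if (length(cand) == 1L) cand else sample(cand, 1, prob = w[match(cand, lateral)])
  } else {
    pool <- aha_preference_order(viable)
    pool <- pool[vapply(pool, has_viable_neighbor, logical(1))]
    if (!length(pool)) return(integer(0))
    pool[1]
  }
  second <- aha_preference_order(intersect(aha_neighbors(primary), viable))[1]
  c(primary, second) # primary first (receives the latest time-to-peak)
}

# raw-array segment centroid (before lv_geometry construction)
seg_centroid_raw <- function(vertices, faces, labels, id) {
  sel <- labels == id
  cent <- mesh_face_centroids(vertices, faces)[sel, , drop = FALSE]
  w <- mesh_face_areas(vertices, faces)[sel]
  colSums(cent * w) / sum(w)
}
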