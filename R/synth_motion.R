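#' Generate a cyclic endocardial motion sequence
#'
#' Displaces each vertex radially towards the long axis with a smooth
#' single-peak contraction envelope -- a baseline-shifted Gaussian bump,
#' symmetric about its peak -- whose peak phase is the segment's
#' ground-truth time-to-peak. Viable segments draw a contraction amplitude
#' from the configured range; scarred segments are akinetic (amplitude below
#' the flat-curve threshold). Target segments receive the two latest peak
#' phases (primary latest), so the mechanical lateness the planner relies on
#' is present by construction. The truth record is returned updated with the
#' drawn `true_ttp` and `amplitude`.
#'
#' @param geom An [lv_geometry()].
#' @param truth Ground-truth list from [generate_lv_geometry()].
#' @param params The `mechanics` block of [plan_config()].
#' @param seed Integer seed.
#' @return A list: `sequence` (class `mesh_sequence`: `phases`, `positions`
#'   list of vertex matrices, `cycle_length_ms`) and `truth` (updated).
#' @export
generate_motion <- function(geom, truth, params = plan_config()$mechanics,
                            seed = 1L) {
  if (params$amp_viable_min < 0 || params$amp_viable_max > 0.5) {
    stop("contraction amplitudes must lie in [0, 0.5]")
  }
  set.seed(as.integer(seed))

  amp <- stats::runif(16, params$amp_viable_min, params$amp_viable_max)
  amp[truth$scar_segments] <- params$amp_scar

  ttp <- stats::runif(16, params$ttp_other_min, params$ttp_other_max)
  tg <- truth$true_target_segments
  if (length(tg) >= 1) ttp[tg[1]] <- stats::runif(1, params$ttp_primary_min, params$ttp_primary_max)
  if (length(tg) >= 2) ttp[tg[2]] <- stats::runif(1, params$ttp_secondary_min, params$ttp_secondary_max)
  stopifnot(all(ttp > 0 & ttp < 1))

  truth$true_ttp <- ttp
  truth$true_ttp[truth$scar_segments] <- NA_real_ # akinetic: no meaningful peak
  truth$amplitude <- amp

  phases <- seq(0, 1, length.out = params$n_phases + 1L)[seq_len(params$n_phases)]
  n_v <- nrow(geom$endo_vertices)

  # Each vertex blends the envelopes of the segments its incident faces
  # belong to, with cubed-count weights so boundary vertices are dominated
  # by their own segment while the displacement field stays smooth at the
  # mesh scale (hard per-vertex assignment shears boundary faces by more
  # than their own size). Residual cross-boundary blending pulls a
  # segment's measured area-curve peak towards its neighbours' phases; the
  # narrow symmetric envelope (see contraction_wave) makes that pull
  # negligible at the frame resolution.
  gamma <- vertex_segment_weights(geom$endo_faces, geom$segment_labels, n_v,
                                  power = 3)

  axis <- geom$long_axis
  rel <- geom$endo_vertices - matrix(geom$apex_point, n_v, 3, byrow = TRUE)
  ax_comp <- as.vector(rel %*% axis)
  radial <- rel - outer(ax_comp, axis)

  positions <- vector("list", length(phases))
  for (p in seq_along(phases)) {
    w <- contraction_wave(phases[p], ttp) # length 16
    v_amp <- as.vector(gamma %*% (amp * w))
    positions[[p]] <- matrix(geom$apex_point, n_v, 3, byrow = TRUE) +
      outer(ax_comp, axis) + radial * (1 - v_amp)
  }
  # phase 0 must equal the static geometry exactly
  positions[[1]] <- geom$endo_vertices

  seq_out <- structure(
    list(phases = phases, positions = positions,
         cycle_length_ms = params$cycle_length_ms),
    class = "mesh_sequence"
  )
  list(sequence = seq_out, truth = truth)
}

# n_vertices x 16 row-stochastic weight matrix: incident-face counts per
# segment raised to `power` and normalized (power > 1 sharpens a boundary
# vertex towards its own segment while keeping the field smooth)
vertex_segment_weights <- function(faces, labels, n_vertices, power = 3) {
  tab <- matrix(0, n_vertices, 16)
  for (k in 1:3) {
    for (s in 1:16) {
      sel <- labels == s
      if (any(sel)) tab[, s] <- tab[, s] + tabulate(faces[sel, k], nbins = n_vertices)
    }
  }
  tab <- tab^power
  tab / pmax(rowSums(tab), 1)
}

# Contraction envelope: baseline-shifted Gaussian bump, zero at phase 0,
# single peak of height 1 exactly at `ttp`, and -- crucially -- symmetric
# about the peak. An asymmetric envelope (e.g. piecewise raised cosine with
# a slow relaxation limb) skews the sampled area-change curve so that both
# the discrete argmin and its quadratic refinement land up to a full frame
# late of the nominal peak. Vectorized over ttp.
contraction_wave <- function(phase, ttp, sigma = 0.05) {
  g <- exp(-(phase - ttp)^2 / (2 * sigma^2))
  g0 <- exp(-ttp^2 / (2 * sigma^2))
  pmax(0, (g - g0) / (1 - g0))
}

#' @export
print.mesh_sequence <- function(x, ...) {
  cat("<mesh_sequence> ", length(x$phases), " phases, ",
      nrow(x$positions[[1]]), " vertices, cycle ", x$cycle_length_ms, " ms\n",
      sep = "")
  invisible(x)
}
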