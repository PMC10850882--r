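#' Per-segment strain and area-change curves over the cardiac cycle
#'
#' With vertex correspondence across phases given (generator or registration
#' upstream), computes for every AHA segment and phase: local area change
#' (segment surface area relative to phase 0, minus 1), and circumferential
#' and longitudinal strain from mean relative edge-length change, edges
#' binned by their reference orientation to the long axis (|cosine| <= 0.5 is
#' circumferential, > 0.5 longitudinal). All curves are zero at phase 0 by
#' construction.
#'
#' @param seq A `mesh_sequence` from [generate_motion()].
#' @param geom The [lv_geometry()] the sequence animates (supplies faces,
#'   labels and the long axis).
#' @param labels Optional per-face AHA labels overriding `geom$segment_labels`.
#' @return An object of class `strain_curves`: list with `curves` (tibble:
#'   `id`, `phase`, `area_change`, `circ_strain`, `long_strain`) and
#'   `cycle_length_ms`.
#' @export
compute_strain_curves <- function(seq, geom, labels = geom$segment_labels) {
  stopifnot(inherits(seq, "mesh_sequence"))
  if (length(seq$phases) < 10) stop("at least 10 phases are required")
  faces <- geom$endo_faces
  if (length(labels) != nrow(faces)) stop("labels must cover all endocardial faces")

  ref <- seq$positions[[1]]
  ref_area <- mesh_face_areas(ref, faces)
  seg_ref_area <- as.vector(rowsum(ref_area, labels))
  seg_ids <- sort(unique(labels))
  if (any(seg_ref_area <= 0)) {
    stop("degenerate (zero-area) segment(s): ",
         paste(seg_ids[seg_ref_area <= 0], collapse = ", "))
  }

  # unique edges with a representative face (for the segment assignment) and
  # reference orientation bin
  ed <- mesh_edges(faces)
  ed1 <- ed |> dplyr::distinct(.data$edge, .keep_all = TRUE)
  evec <- ref[ed1$v2, , drop = FALSE] - ref[ed1$v1, , drop = FALSE]
  elen0 <- sqrt(rowSums(evec^2))
  cosl <- abs(as.vector(evec %*% geom$long_axis)) / pmax(elen0, 1e-12)
  # an edge contributes to every segment whose faces contain it
  edge_seg <- ed |> dplyr::mutate(id = labels[.data$face]) |>
    dplyr::distinct(.data$edge, .data$id)
  edge_info <- edge_seg |>
    dplyr::left_join(
      tibble::tibble(edge = ed1$edge, v1 = ed1$v1, v2 = ed1$v2,
                     len0 = elen0, circ = cosl <= 0.5),
      by = "edge"
    )

  out <- vector("list", length(seq$phases))
  for (p in seq_along(seq$phases)) {
    pos <- seq$positions[[p]]
    area_p <- as.vector(rowsum(mesh_face_areas(pos, faces), labels))
    dv <- pos[edge_info$v2, , drop = FALSE] - pos[edge_info$v1, , drop = FALSE]
    rel_len <- sqrt(rowSums(dv^2)) / edge_info$len0 - 1
    strains <- tibble::tibble(
      id = edge_info$id, circ = edge_info$circ, rel = rel_len
    ) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(
        circ_strain = mean_or_zero(.data$rel[.data$circ]),
        long_strain = mean_or_zero(.data$rel[!.data$circ]),
        .groups = "drop"
      )
    out[[p]] <- strains |>
      dplyr::mutate(
        phase = seq$phases[p],
        area_change = area_p / seg_ref_area - 1,
        .before = 1
      )
  }
  curves <- dplyr::bind_rows(out) |>
    dplyr::select("id", "phase", "area_change", "circ_strain", "long_strain") |>
    dplyr::arrange(.data$id, .data$phase)
  structure(
    list(curves = curves, cycle_length_ms = seq$cycle_length_ms),
    class = "strain_curves"
  )
}

mean_or_zero <- function(x) if (length(x)) mean(x) else 0

# sub-step peak localization: quadratic interpolation through the discrete
# minimum and its neighbours (plain argmin errs by up to a full phase step
# for asymmetric contraction waveforms)
refine_argmin <- function(x, y) {
  i <- which.min(y)
  if (i == 1 || i == length(y)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  offset <- if (abs(denom) < 1e-15) 0 else 0.5 * (y[i - 1] - y[i + 1]) / denom
  x[i] + max(-0.5, min(0.5, offset)) * (x[2] - x[1])
}

#' Time-to-peak contraction with flat-curve exclusion
#'
#' The time-to-peak (TTP) of a segment is the phase of its most negative
#' local area change (maximal shortening). Segments whose area-change curves
#' are flat -- peak-to-peak excursion below `flat_threshold` -- are excluded,
#' mirroring the exclusion of akinetic/scarred segments. The latest
#' mechanically activating segment is the non-flat segment with the largest
#' TTP; ties resolve basal-then-lateral.
#'
#' @param curves A `strain_curves` object from [compute_strain_curves()].
#' @param flat_threshold Peak-to-peak area-change fraction below which a
#'   segment is flagged flat (default 0.05).
#' @return A tibble with one row per segment: `id`, `ttp_phase`, `ttp_ms`
#'   (via the cycle length), `peak_amplitude` (peak-to-peak area change) and
#'   `flat`. TTP columns are NA for flat segments. The latest mechanical
#'   segment id is attached as attribute `"latest_segment"`.
#' @export
time_to_peak <- function(curves, flat_threshold = 0.05) {
  stopifnot(inherits(curves, "strain_curves"), flat_threshold > 0)
  res <- curves$curves |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      ttp_phase = refine_argmin(.data$phase, .data$area_change),
      peak_amplitude = max(.data$area_change) - min(.data$area_change),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      flat = .data$peak_amplitude < flat_threshold,
      ttp_phase = ifelse(.data$flat, NA_real_, .data$ttp_phase),
      ttp_ms = .data$ttp_phase * curves$cycle_length_ms
    ) |>
    dplyr::select("id", "ttp_phase", "ttp_ms", "peak_amplitude", "flat") |>
    dplyr::arrange(.data$id)
  if (all(res$flat)) stop("no mechanical signal: all segments flat")
  latest <- res |> dplyr::filter(!.data$flat)
  cand <- latest$id[latest$ttp_phase == max(latest$ttp_phase)]
  attr(res, "latest_segment") <- aha_preference_order(cand)[1]
  res
}
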