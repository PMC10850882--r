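#' Join per-segment features into the planner's feature table
#'
#' One row per AHA segment combining wall thickness, perfusion, mechanics
#' and activation. A segment is `viable` when it is neither thin nor
#' hypoperfused. Flat (excluded) segments keep their row with missing TTP so
#' the table always covers all 16 segments.
#'
#' @param thickness Tibble from [compute_wall_thickness()].
#' @param perfusion Tibble from [classify_hypoperfusion()]; may carry a
#'   `late_enhancement` column.
#' @param mechanics Tibble from [time_to_peak()].
#' @param activation An `activation_map` from [simulate_activation()] (or
#'   its `per_segment` tibble).
#' @return A tibble with columns `id`, `thickness_mm`, `thin`,
#'   `hypoperfused`, `late_enhancement`, `ttp_phase`, `ttp_ms`,
#'   `activation_ms`, `viable`, `target` (initialized `FALSE`; see
#'   [select_target_segments()]).
#' @export
build_feature_table <- function(thickness, perfusion, mechanics, activation) {
  act <- if (inherits(activation, "activation_map")) activation$per_segment else activation
  parts <- list(thickness = thickness, perfusion = perfusion,
                mechanics = mechanics, activation = act)
  for (nm in names(parts)) {
    ids <- sort(parts[[nm]]$id)
    if (!identical(as.integer(ids), 1:16)) {
      stop("'", nm, "' does not cover segments 1..16 exactly (has: ",
           paste(ids, collapse = ","), ")")
    }
  }
  le <- if ("late_enhancement" %in% names(perfusion)) {
    perfusion$late_enhancement[order(perfusion$id)]
  } else {
    rep(NA, 16)
  }
  tab <- tibble::tibble(
    id = 1:16,
    thickness_mm = thickness$thickness_mm[order(thickness$id)],
    thin = thickness$thin[order(thickness$id)],
    hypoperfused = perfusion$hypoperfused[order(perfusion$id)],
    late_enhancement = le,
    ttp_phase = mechanics$ttp_phase[order(mechanics$id)],
    ttp_ms = mechanics$ttp_ms[order(mechanics$id)],
    activation_ms = act$mean_ms[order(act$id)]
  )
  tab |>
    dplyr::mutate(
      viable = !.data$thin & !isTRUE_vec(.data$hypoperfused),
      target = FALSE
    )
}

#' Select the two adjacent target segments for electrode implantation
#'
#' Implements the targeting rule: the latest mechanically and electrically
#' activating segments outside the thin or scar segments. Every viable
#' segment with a defined time-to-peak is scored by the sum of its lateness
#' ranks across the mechanical (TTP) and electrical (activation time) maps;
#' the primary target is the best-scoring segment and the second target its
#' best-scoring viable neighbour on the AHA adjacency graph, so the pair is
#' always adjacent. Ties resolve basal-then-lateral. `fusion` can restrict
#' the score to one map.
#'
#' @param table Feature table from [build_feature_table()].
#' @param fusion `"rank_sum"` (default), `"mechanical"` or `"electrical"`.
#' @return Integer vector of 2 AHA ids (primary first). Errors with
#'   "no viable target pair" when fewer than 2 qualifying segments exist or
#'   no viable segment has a viable neighbour.
#' @export
select_target_segments <- function(table,
                                   fusion = c("rank_sum", "mechanical", "electrical")) {
  fusion <- match.arg(fusion)
  cand <- table |>
    dplyr::filter(.data$viable, !is.na(.data$ttp_phase), is.finite(.data$activation_ms))
  if (nrow(cand) < 2) stop("no viable target pair")

  mech_rank <- rank(-cand$ttp_phase, ties.method = "min")
  elec_rank <- rank(-cand$activation_ms, ties.method = "min")
  score <- switch(fusion,
    rank_sum = mech_rank + elec_rank,
    mechanical = mech_rank,
    electrical = elec_rank
  )
  ord <- order(score, aha_segments()$preference[cand$id])
  for (k in ord) {
    primary <- cand$id[k]
    nb <- intersect(aha_neighbors(primary), cand$id)
    if (length(nb)) {
      nb_score <- score[match(nb, cand$id)]
      best <- nb[nb_score == min(nb_score)]
      second <- aha_preference_order(best)[1]
      return(c(primary, second))
    }
  }
  stop("no viable target pair")
}

#' Acoustic intensity of a transmitter candidate at a segment
#'
#' Point-source surrogate for the delivered ultrasound intensity, based on
#' the depth and angle between transmitter and target:
#' `I = cos(theta) * exp(-mu * d)`, normalized to 1 at zero angle and depth,
#' with hard admissibility cutoffs at `theta >= 30` degrees or `d >= 12` cm
#' (the acoustic-window bounds). `theta` is measured at the skin entry point
#' between the beam axis and the entry-to-segment line; `d` is the Euclidean
#' entry-to-segment distance.
#'
#' @param entry_point Skin entry point (mm).
#' @param beam_axis Unit beam direction.
#' @param segment_point Target segment centroid (mm).
#' @param mu Attenuation coefficient (1/cm, default 0.1).
#' @param angle_max_deg,depth_max_cm Admissibility cutoffs (default 30 / 12).
#' @return A one-row tibble: `depth_cm`, `angle_deg`, `intensity`, `covered`.
#' @export
acoustic_intensity <- function(entry_point, beam_axis, segment_point,
                               mu = 0.1, angle_max_deg = 30, depth_max_cm = 12) {
  stopifnot(all(is.finite(segment_point)))
  nb <- sqrt(sum(beam_axis^2))
  if (nb < 1e-12) stop("beam axis has zero length")
  beam_axis <- beam_axis / nb
  dvec <- segment_point - entry_point
  d_mm <- sqrt(sum(dvec^2))
  if (d_mm < 1e-9) {
    return(tibble::tibble(depth_cm = 0, angle_deg = 0, intensity = 1, covered = TRUE))
  }
  d_cm <- d_mm / 10
  cosang <- sum(beam_axis * dvec) / d_mm
  theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  # strict bounds with a hair of tolerance so a beam built exactly on the
  # admissibility cone is excluded regardless of rounding direction
  admissible <- theta < angle_max_deg - 1e-9 && d_cm < depth_max_cm - 1e-12
  intensity <- if (admissible) cos(theta * pi / 180) * exp(-mu * d_cm) else 0
  tibble::tibble(depth_cm = d_cm, angle_deg = theta,
                 intensity = intensity, covered = intensity > 0)
}

#' Rank transmitter intercostal sites by acoustic intensity at the targets
#'
#' Scores every candidate by its mean acoustic intensity over the two target
#' segment centroids and returns the candidates sorted best-first (stable;
#' `ics_id` breaks ties). A full 16-segment acoustic map (the bull's-eye of
#' Figure-style coverage reports) is computed per candidate. When no
#' candidate covers either target the ranking is still returned with
#' `adequate_coverage = FALSE`.
#'
#' @param thorax A `thorax_model` tibble from [generate_thorax()].
#' @param targets Integer vector of 2 AHA target ids.
#' @param geom The [lv_geometry()].
#' @param mu,angle_max_deg,depth_max_cm Passed to [acoustic_intensity()].
#' @return A list of class `transmitter_ranking`: `ranking` (tibble:
#'   `rank`, `ics_id`, `mean_target_intensity`, `covers_targets`),
#'   `acoustic_map` (tibble per (ics_id, segment): `id`, `depth_cm`,
#'   `angle_deg`, `intensity`, `covered`), `adequate_coverage`.
#' @export
rank_transmitter_sites <- function(thorax, targets, geom,
                                   mu = 0.1, angle_max_deg = 30, depth_max_cm = 12) {
  stopifnot(nrow(thorax) >= 1, length(targets) >= 1)
  cents <- t(vapply(1:16, function(s) segment_centroid(geom, s), numeric(3)))

  amap <- purrr::map(seq_len(nrow(thorax)), function(i) {
    entry <- c(thorax$entry_x[i], thorax$entry_y[i], thorax$entry_z[i])
    axis <- c(thorax$axis_x[i], thorax$axis_y[i], thorax$axis_z[i])
    purrr::map(1:16, function(s) {
      acoustic_intensity(entry, axis, cents[s, ], mu, angle_max_deg, depth_max_cm) |>
        dplyr::mutate(ics_id = thorax$ics_id[i], id = s, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  ranking <- amap |>
    dplyr::filter(.data$id %in% targets) |>
    dplyr::group_by(.data$ics_id) |>
    dplyr::summarise(
      mean_target_intensity = mean(.data$intensity),
      covers_targets = all(.data$covered),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_target_intensity), .data$ics_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)

  structure(
    list(
      ranking = ranking, acoustic_map = amap,
      targets = targets,
      adequate_coverage = any(ranking$mean_target_intensity > 0)
    ),
    class = "transmitter_ranking"
  )
}

#' @export
print.transmitter_ranking <- function(x, ...) {
  cat("<transmitter_ranking> targets ", paste(x$targets, collapse = ", "),
      if (!x$adequate_coverage) " [no adequate coverage]", "\n", sep = "")
  print(x$ranking)
  invisible(x)
}
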