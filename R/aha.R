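#' AHA 16-segment model: segment table
#'
#' The standard American Heart Association left-ventricular parcellation with
#' the apical cap excluded: three longitudinal rings (basal, mid, apical) of
#' circumferential sectors (6/6/4). Angles are azimuths in the short-axis
#' plane of the canonical frame used throughout the package: the LV long axis
#' is +z with the apex at the origin, 0 deg points at the centre of the
#' lateral free wall, 90 deg at the centre of the anterior wall, and 180 deg
#' at the mid septum. Sectors are half-open `[start, end)` intervals.
#'
#' @return A tibble with one row per segment: `id` (1-16), `name`, `ring`
#'   (`"basal"`, `"mid"`, `"apical"`), `sector_start_deg`, `sector_end_deg`,
#'   `center_deg`, and `preference` — the deterministic tie-break order used
#'   everywhere a "latest" segment must be unique (lower is preferred; more
#'   basal first, then more lateral, inferolateral before anterolateral).
#' @export
#' @examples
#' aha_segments()
aha_segments <- function() {
  tibble::tibble(
    id = 1:16,
    name = c(
      "basal anterior", "basal anteroseptal", "basal inferoseptal",
      "basal inferior", "basal inferolateral", "basal anterolateral",
      "mid anterior", "mid anteroseptal", "mid inferoseptal",
      "mid inferior", "mid inferolateral", "mid anterolateral",
      "apical anterior", "apical septal", "apical inferior", "apical lateral"
    ),
    ring = rep(c("basal", "mid", "apical"), c(6L, 6L, 4L)),
    sector_start_deg = c(
      60, 120, 180, 240, 300, 0,
      60, 120, 180, 240, 300, 0,
      45, 135, 225, 315
    ),
    sector_end_deg = c(
      120, 180, 240, 300, 360, 60,
      120, 180, 240, 300, 360, 60,
      135, 225, 315, 360 + 45
    ),
    center_deg = ((sector_start_deg + sector_end_deg) / 2) %% 360,
    preference = c(
      4L, 6L, 5L, 3L, 1L, 2L,
      10L, 12L, 11L, 9L, 7L, 8L,
      15L, 16L, 14L, 13L
    )
  )
}

#' AHA 16-segment adjacency graph
#'
#' Edges of the segment adjacency graph on the bull's-eye layout:
#' within-ring neighbours plus longitudinal neighbours, the latter defined by
#' angular-sector overlap between rings (the 6-sector basal/mid rings against
#' the 4-sector apical ring). Shipped as a plain CSV under `extdata` so the
#' graph is version-controlled data, and unit-tested against the overlap rule.
#'
#' @return A tibble with columns `from`, `to` (AHA ids, each undirected edge
#'   listed once).
#' @export
aha_adjacency <- function() {
  path <- system.file("extdata", "aha16_adjacency.csv", package = "wiseplan")
  utils::read.csv(path, colClasses = "integer") |> tibble::as_tibble()
}

#' Neighbours of an AHA segment
#'
#' @param id AHA segment id (1-16).
#' @return Integer vector of adjacent segment ids, sorted.
#' @export
aha_neighbors <- function(id) {
  stopifnot(length(id) == 1L, id %in% 1:16)
  adj <- aha_adjacency()
  sort(unique(c(adj$to[adj$from == id], adj$from[adj$to == id])))
}

#' Order segments by the basal-then-lateral tie-break convention
#'
#' Used to resolve ties in "latest segment" queries: more basal ring first,
#' then more lateral within a ring (inferolateral preferred over
#' anterolateral, matching the usual posterolateral implant preference).
#'
#' @param ids AHA segment ids.
#' @return `ids` reordered, most preferred first.
#' @export
aha_preference_order <- function(ids) {
  pref <- aha_segments()$preference
  ids[order(pref[ids])]
}

# Assign sector ids for a ring given azimuths (deg, canonical anchored frame).
aha_sector_of <- function(azimuth_deg, ring) {
  segs <- aha_segments() |> dplyr::filter(.data$ring == !!ring)
  az <- azimuth_deg %% 360
  out <- integer(length(az))
  for (i in seq_len(nrow(segs))) {
    lo <- segs$sector_start_deg[i]
    hi <- segs$sector_end_deg[i]
    hit <- if (hi > 360) (az >= lo | az < (hi - 360)) else (az >= lo & az < hi)
    out[hit] <- segs$id[i]
  }
  out
}
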