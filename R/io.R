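#' Write a triangle mesh as legacy-ASCII VTK polydata
#'
#' Minimal legacy VTK 2.0 writer: POINTS, POLYGONS and optional scalar
#' POINT_DATA / CELL_DATA arrays (one SCALARS block per named element).
#'
#' @param vertices `n x 3` matrix (mm).
#' @param faces `m x 3` integer matrix (1-based; written 0-based).
#' @param path Output file.
#' @param point_data,cell_data Named lists of numeric vectors (length `n` /
#'   `m`).
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(vertices, faces, path,
                               point_data = list(), cell_data = list()) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 2.0", "wiseplan mesh", "ASCII", "DATASET POLYDATA",
    paste("POINTS", nrow(vertices), "double")
  ), con)
  writeLines(apply(format(vertices, trim = TRUE, digits = 10), 1, paste, collapse = " "), con)
  writeLines(paste("POLYGONS", nrow(faces), nrow(faces) * 4L), con)
  writeLines(paste(3L, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  write_vtk_data <- function(block, keyword, n) {
    if (!length(block)) return(invisible())
    writeLines(paste(keyword, n), con)
    for (nm in names(block)) {
      stopifnot(length(block[[nm]]) == n)
      writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
      writeLines(format(block[[nm]], trim = TRUE, digits = 10), con)
    }
  }
  write_vtk_data(point_data, "POINT_DATA", nrow(vertices))
  write_vtk_data(cell_data, "CELL_DATA", nrow(faces))
  invisible(path)
}

#' Read legacy-ASCII VTK polydata written by [write_vtk_polydata()]
#'
#' @param path File path.
#' @return A list: `vertices`, `faces` (1-based), `point_data`, `cell_data`.
#' @export
read_vtk_polydata <- function(path) {
  lines <- readLines(path)
  pt_i <- grep("^POINTS", lines)[1]
  n_pts <- as.integer(strsplit(lines[pt_i], "\\s+")[[1]][2])
  vertices <- matrix(
    scan(text = lines[(pt_i + 1):(pt_i + n_pts)], quiet = TRUE),
    ncol = 3, byrow = TRUE
  )
  pg_i <- grep("^POLYGONS", lines)[1]
  n_fc <- as.integer(strsplit(lines[pg_i], "\\s+")[[1]][2])
  fc <- matrix(
    as.integer(scan(text = lines[(pg_i + 1):(pg_i + n_fc)], quiet = TRUE)),
    ncol = 4, byrow = TRUE
  )
  stopifnot(all(fc[, 1] == 3L))
  faces <- fc[, 2:4, drop = FALSE] + 1L

  read_block <- function(keyword, n) {
    k_i <- grep(paste0("^", keyword), lines)
    out <- list()
    if (!length(k_i)) return(out)
    i <- k_i[1] + 1L
    while (i <= length(lines) && grepl("^SCALARS", lines[i])) {
      nm <- strsplit(lines[i], "\\s+")[[1]][2]
      vals <- scan(text = lines[(i + 2):(i + 1 + n)], quiet = TRUE)
      out[[nm]] <- vals
      i <- i + 2L + n
    }
    out
  }
  list(
    vertices = vertices, faces = faces,
    point_data = read_block("POINT_DATA", n_pts),
    cell_data = read_block("CELL_DATA", n_fc)
  )
}

#' Write / read a triangle mesh in OFF format
#'
#' @param vertices,faces Mesh arrays (faces 1-based).
#' @param path File path.
#' @return `write_off` returns `path` invisibly; `read_off` a list with
#'   `vertices` and `faces`.
#' @export
write_off <- function(vertices, faces, path) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(vertices), nrow(faces), 0L), con)
  writeLines(apply(format(vertices, trim = TRUE, digits = 10), 1, paste, collapse = " "), con)
  writeLines(paste(3L, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  stopifnot(trimws(lines[1]) == "OFF")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  n_v <- counts[1]; n_f <- counts[2]
  vertices <- matrix(scan(text = lines[3:(2 + n_v)], quiet = TRUE),
                     ncol = 3, byrow = TRUE)
  fc <- matrix(as.integer(scan(text = lines[(3 + n_v):(2 + n_v + n_f)], quiet = TRUE)),
               ncol = 4, byrow = TRUE)
  list(vertices = vertices, faces = fc[, 2:4, drop = FALSE] + 1L)
}

#' Write / read a time-attenuation curve set as CSV
#'
#' The interchange layout: columns `time_s`, `aif_hu`, `seg01_hu` ..
#' `seg16_hu`; the pre-contrast baseline travels in a `baseline_hu` column
#' (constant) so the file is self-contained.
#'
#' @param tac TAC tibble from [generate_tacs()].
#' @param path File path.
#' @return `write_tac_csv` returns `path` invisibly; `read_tac_csv` the TAC
#'   tibble with its `baseline_hu` attribute restored.
#' @export
write_tac_csv <- function(tac, path) {
  df <- as.data.frame(tac)
  df$baseline_hu <- attr(tac, "baseline_hu") %||% df$aif_hu[1]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  baseline <- df$baseline_hu[1]
  df$baseline_hu <- NULL
  out <- tibble::as_tibble(df)
  attr(out, "baseline_hu") <- baseline
  out
}
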