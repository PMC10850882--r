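#' Ray/mesh nearest-hit distances
#'
#' Casts one ray per row of `origins`/`dirs` against a triangle mesh and
#' returns the distance to the nearest intersection, or -1 for a miss.
#' Directions need not be unit length; distances are reported in units of the
#' direction norm, so pass unit vectors for metric distances.
#'
#' @param origins,dirs `n x 3` matrices of ray origins and directions.
#' @param vertices,faces Target mesh (mm; 1-based triangle indices).
#' @param eps Minimum hit distance (guards against self-hits at the origin).
#' @return Numeric vector of length `n`.
#' @export
raycast_distance <- function(origins, dirs, vertices, faces, eps = 1e-6) {
  origins <- as.matrix(origins); dirs <- as.matrix(dirs)
  stopifnot(ncol(origins) == 3, ncol(dirs) == 3, nrow(origins) == nrow(dirs))
  .raycast_distance_cpp(origins, dirs, as.matrix(vertices),
                        matrix(as.integer(faces), ncol = 3), eps)
}
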