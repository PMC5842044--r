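#' Correspondence map between a canonical mesh and a target surface
#'
#' One entry per canonical vertex: the face of the target mesh the vertex
#' corresponds to plus barycentric coordinates within that face. This is the
#' output of every registration algorithm in the package.
#'
#' @param face integer vector of 1-based target face indices.
#' @param bary numeric n x 3 matrix of barycentric coordinates (non-negative,
#'   rows summing to 1).
#' @param target optional [triangle_mesh()] the entries lie on; if supplied
#'   the entries are validated against it and 3D points can be recovered with
#'   [correspondence_points()].
#' @return object of class `correspondence_map`.
#' @export
correspondence_map <- function(face, bary, target = NULL) {
  face <- as.integer(face)
  bary <- as.matrix(bary)
  if (nrow(bary) != length(face) || ncol(bary) != 3L)
    stop("`bary` must be an n x 3 matrix matching `face`")
  if (any(bary < -1e-9) || any(abs(rowSums(bary) - 1) > 1e-9))
    stop("barycentric coordinates must be non-negative and sum to 1")
  if (!is.null(target)) {
    if (any(face < 1L | face > nrow(target$faces)))
      stop("correspondence face index out of range for target mesh")
  }
  structure(list(face = face, bary = bary), class = "correspondence_map")
}

#' 3D points of a correspondence map on its target mesh
#' @param map a [correspondence_map()].
#' @param target the target [triangle_mesh()].
#' @return n x 3 matrix of points (mm).
#' @export
correspondence_points <- function(map, target) {
  barycentric_points(target, map$face, map$bary)
}

#' Identity correspondence map of a mesh onto itself
#'
#' Each vertex maps to itself (corner barycentric coordinates of an incident
#' face).
#' @param mesh a [triangle_mesh()].
#' @return a [correspondence_map()].
#' @export
identity_correspondence <- function(mesh) {
  vb <- vertex_as_barycentric(mesh)
  correspondence_map(vb$face, vb$bary, target = mesh)
}

#' @export
print.correspondence_map <- function(x, ...) {
  cat(sprintf("correspondence_map: %d entries\n", length(x$face)))
  invisible(x)
}

#' Write / read a correspondence map as CSV
#'
#' Columns `canonical_vertex,target_face,b0,b1,b2`; indices are written
#' 0-based (file-format convention, like PLY), and converted back to R's
#' 1-based indexing on read.
#' @param map a [correspondence_map()].
#' @param path file path.
#' @return `write_correspondence`: the path, invisibly;
#'   `read_correspondence`: a [correspondence_map()].
#' @export
write_correspondence <- function(map, path) {
  df <- data.frame(canonical_vertex = seq_along(map$face) - 1L,
                   target_face = map$face - 1L,
                   b0 = map$bary[, 1], b1 = map$bary[, 2], b2 = map$bary[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correspondence
#' @export
read_correspondence <- function(path) {
  df <- read.csv(path)
  df <- df[order(df$canonical_vertex), , drop = FALSE]
  correspondence_map(df$target_face + 1L, cbind(df$b0, df$b1, df$b2))
}
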