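#' Typed landmark set on a surface
#'
#' Landmarks come in three kinds, following the sliding-semilandmark
#' tradition: `point` landmarks are homologous anatomical points and never
#' slide; `curve` landmarks lie on a named curve and may slide tangentially
#' along it (1D); `surface` landmarks are otherwise undistinguished points
#' that may slide within the local tangent plane (2D). Locations are stored
#' intrinsically as a face index plus barycentric coordinates on the owning
#' mesh.
#'
#' @param kind character vector in `point`, `curve`, `surface`.
#' @param face integer vector of 1-based face indices.
#' @param bary n x 3 barycentric coordinates.
#' @param curve_id integer curve identifier (`NA` unless kind is `curve`).
#' @param order integer position along the curve (strictly increasing within
#'   each curve; `NA` unless kind is `curve`).
#' @param mesh the owning [triangle_mesh()].
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(kind, face, bary, curve_id = NA_integer_,
                         order = NA_integer_, mesh = NULL) {
  kind <- as.character(kind)
  n <- length(kind)
  if (!all(kind %in% c("point", "curve", "surface")))
    stop("landmark kind must be point, curve or surface")
  face <- as.integer(face)
  bary <- as.matrix(bary)
  curve_id <- rep_len(as.integer(curve_id), n)
  order <- rep_len(as.integer(order), n)
  if (any(bary < -1e-9) || any(abs(rowSums(bary) - 1) > 1e-9))
    stop("landmark barycentric coordinates must be non-negative and sum to 1")
  is_c <- kind == "curve"
  if (any(is_c & is.na(curve_id)))
    stop("curve landmarks need a curve_id")
  for (cid in unique(curve_id[is_c])) {
    o <- order[is_c & curve_id == cid]
    if (anyNA(o) || any(diff(sort(o)) == 0L))
      stop(sprintf("curve %d: order must be strictly increasing", cid))
  }
  structure(list(kind = kind, face = face, bary = bary,
                 curve_id = curve_id, order = order, mesh = mesh),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  tab <- table(x$kind)
  cat(sprintf("landmark_set: %d entries (%s)\n", length(x$kind),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Number of landmarks in a set
#' @param x a [landmark_set()].
#' @return integer count.
#' @export
length.landmark_set <- function(x) length(x$kind)

#' 3D coordinates of a landmark set
#' @param lms a [landmark_set()].
#' @param mesh mesh to evaluate on; defaults to the owning mesh.
#' @return n x 3 matrix (mm).
#' @export
landmark_points <- function(lms, mesh = NULL) {
  if (is.null(mesh)) mesh <- lms$mesh
  if (is.null(mesh)) stop("landmark set has no owning mesh; supply `mesh`")
  barycentric_points(mesh, lms$face, lms$bary)
}

# subset a landmark set
subset_landmarks <- function(lms, sel) {
  landmark_set(lms$kind[sel], lms$face[sel], lms$bary[sel, , drop = FALSE],
               lms$curve_id[sel], lms$order[sel], mesh = lms$mesh)
}

#' Concatenate two landmark sets on the same owning mesh
#' @param a,b [landmark_set()] objects sharing an owning mesh.
#' @return the combined [landmark_set()].
#' @export
combine_landmarks <- function(a, b) {
  landmark_set(c(a$kind, b$kind), c(a$face, b$face), rbind(a$bary, b$bary),
               c(a$curve_id, b$curve_id), c(a$order, b$order), mesh = a$mesh)
}

# snap arbitrary 3D points onto a mesh and build a landmark set
landmarks_from_points <- function(mesh, pts, kind, curve_id = NA_integer_,
                                  order = NA_integer_) {
  cp <- closest_surface_point(mesh, pts)
  landmark_set(rep_len(kind, nrow(pts)), cp$face, cp$bary,
               curve_id = curve_id, order = order, mesh = mesh)
}

#' Read and write landmark files
#'
#' CSV dialect with header `kind,curve_id,order,face,b0,b1,b2`; `kind` is one
#' of `point`/`curve`/`surface` and `face` is written 0-based on disk
#' (file-format convention) and converted to 1-based indexing in memory.
#'
#' @param lms a [landmark_set()].
#' @param path file path.
#' @param mesh owning mesh to attach on read (optional).
#' @return `write_landmarks`: the path, invisibly; `read_landmarks`: a
#'   [landmark_set()].
#' @export
write_landmarks <- function(lms, path) {
  df <- data.frame(kind = lms$kind, curve_id = lms$curve_id,
                   order = lms$order, face = lms$face - 1L,
                   b0 = lms$bary[, 1], b1 = lms$bary[, 2], b2 = lms$bary[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path, mesh = NULL) {
  df <- read.csv(path)
  need <- c("kind", "curve_id", "order", "face", "b0", "b1", "b2")
  if (!all(need %in% names(df)))
    stop("landmark file must have columns kind,curve_id,order,face,b0,b1,b2")
  landmark_set(df$kind, df$face + 1L, cbind(df$b0, df$b1, df$b2),
               df$curve_id, df$order, mesh = mesh)
}
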