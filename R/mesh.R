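#' Triangular surface mesh
#'
#' Constructs a validated triangular mesh: vertex coordinates in millimetres
#' (right-handed frame) and 1-based face indices with counter-clockwise
#' orientation. Validation enforces the structural invariants every other
#' operation in the package relies on: indices in range, no degenerate face,
#' edge-manifoldness (each edge shared by at most two faces) and consistent
#' orientation (a shared edge is traversed in opposite directions by its two
#' faces).
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates (mm).
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @param validate check the structural invariants (default `TRUE`).
#' @return an object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("`faces` must be an F x 3 matrix")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate the structural invariants of a triangle mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return `mesh`, invisibly; errors describe the first offending record.
#' @export
validate_mesh <- function(mesh) {
  V <- nrow(mesh$vertices)
  f <- mesh$faces
  if (anyNA(mesh$vertices) || any(!is.finite(mesh$vertices)))
    stop("mesh vertices contain non-finite coordinates")
  bad <- which(f < 1L | f > V, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("face %d references vertex index %d (valid range 1..%d)",
                 bad[1, 1], f[bad[1, 1], bad[1, 2]], V))
  rep_v <- which(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])
  if (length(rep_v) > 0L)
    stop(sprintf("face %d repeats a vertex", rep_v[1]))
  # directed edges: consistent orientation means no directed edge repeats,
  # and each undirected edge appears at most twice
  de <- rbind(f[, c(1, 2), drop = FALSE],
              f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  key <- (as.numeric(de[, 1]) - 1) * V + (as.numeric(de[, 2]) - 1)
  if (anyDuplicated(key) > 0L)
    stop("inconsistent face orientation: a directed edge occurs twice")
  ukey <- (pmin(de[, 1], de[, 2]) - 1) * as.numeric(V) +
    (pmax(de[, 1], de[, 2]) - 1)
  tab <- tabulate(match(ukey, unique(ukey)))
  if (any(tab > 2L))
    stop("mesh is not edge-manifold: an edge is shared by more than 2 faces")
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  ext <- apply(x$vertices, 2, range)
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

#' Textured surface: a triangle mesh plus one scalar per vertex
#'
#' The scalar plays the role of a mapped cortical property such as cortical
#' mass surface density (thickness times mineral density, mg/cm^2), but any
#' finite per-vertex quantity is accepted.
#'
#' @param mesh a [triangle_mesh()].
#' @param texture numeric vector, one finite value per vertex. Defaults to
#'   zeros.
#' @return an object of class `textured_surface`.
#' @export
textured_surface <- function(mesh, texture = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- nrow(mesh$vertices)
  if (is.null(texture)) texture <- numeric(V)
  texture <- as.numeric(texture)
  if (length(texture) != V)
    stop(sprintf("texture length %d does not match vertex count %d",
                 length(texture), V))
  if (any(!is.finite(texture))) stop("texture contains non-finite values")
  structure(list(mesh = mesh, texture = texture), class = "textured_surface")
}

#' @export
print.textured_surface <- function(x, ...) {
  cat(sprintf("textured_surface: %d vertices, %d faces\n",
              nrow(x$mesh$vertices), nrow(x$mesh$faces)))
  cat(sprintf("  texture: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$texture), min(x$texture), max(x$texture)))
  invisible(x)
}

# Spatial acceleration structure, built lazily and cached in an environment
# keyed by the mesh object identity within a single computation.
mesh_grid <- function(mesh) {
  g <- attr(mesh, "gmia_grid")
  if (!is.null(g)) return(g)
  .cpp_grid_build(mesh$vertices, mesh$faces - 1L)
}

#' Attach a cached spatial index to a mesh
#'
#' Registration loops query the same target surface thousands of times;
#' attaching the index once avoids rebuilding it per call.
#' @param mesh a [triangle_mesh()].
#' @return the mesh with a spatial index attribute.
#' @keywords internal
#' @export
index_mesh <- function(mesh) {
  attr(mesh, "gmia_grid") <- .cpp_grid_build(mesh$vertices, mesh$faces - 1L)
  mesh
}

#' Closest point on a surface
#'
#' Finds, for each query point, the global minimiser of Euclidean distance to
#' the union of the mesh triangles (point-to-triangle, not point-to-vertex).
#'
#' @param mesh a [triangle_mesh()].
#' @param query numeric 3-vector or n x 3 matrix of query points (mm).
#' @return a list with `face` (1-based face index), `bary` (n x 3 barycentric
#'   coordinates within that face), `point` (n x 3 foot points) and
#'   `distance` (mm).
#' @export
closest_surface_point <- function(mesh, query) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  storage.mode(query) <- "double"
  .cpp_grid_closest(mesh_grid(mesh), query)
}

#' Euclidean vertex neighbourhood
#'
#' Returns the indices of all vertices within Euclidean distance `d` of vertex
#' `k` (including `k` itself). Distances are straight-line, measured on the
#' undeformed mesh; the locally affine registration freezes these
#' neighbourhoods across iterations.
#'
#' @param mesh a [triangle_mesh()].
#' @param k vertex index (1-based).
#' @param d radius in mm, positive.
#' @return integer vector of vertex indices.
#' @export
vertex_neighbourhood <- function(mesh, k, d) {
  stopifnot(d > 0)
  x <- mesh$vertices
  dx <- x[, 1] - x[k, 1]; dy <- x[, 2] - x[k, 2]; dz <- x[, 3] - x[k, 3]
  which(dx * dx + dy * dy + dz * dz <= d * d)
}

# all pairwise neighbourhoods + Gaussian proximity weights (sigma = d/3,
# truncated at d); returned as parallel lists of indices and weights.
# max_neighbours caps each neighbourhood by a deterministic
# distance-stratified subsample (vertex k itself always kept): with several
# hundred members the local rigid fit and transform blend are already
# saturated, so the cap trades nothing measurable for a large constant in
# the LAD inner loop.
lad_neighbourhoods <- function(mesh, d, max_neighbours = 300L) {
  x <- mesh$vertices
  V <- nrow(x)
  sigma <- d / 3
  nbrs <- vector("list", V)
  wts <- vector("list", V)
  # block the V x V distance computation to bound memory
  block <- max(1L, floor(2e7 / V))
  for (start in seq(1L, V, by = block)) {
    idx <- start:min(V, start + block - 1L)
    d2 <- outer(x[idx, 1], x[, 1], "-")^2 +
      outer(x[idx, 2], x[, 2], "-")^2 +
      outer(x[idx, 3], x[, 3], "-")^2
    for (r in seq_along(idx)) {
      k <- idx[r]
      sel <- which(d2[r, ] <= d * d)
      if (length(sel) > max_neighbours) {
        ord <- sel[order(d2[r, sel])]
        keep <- ord[unique(round(seq(1, length(ord),
                                     length.out = max_neighbours)))]
        sel <- sort(unique(c(k, keep)))
      }
      nbrs[[k]] <- as.integer(sel)
      wts[[k]] <- exp(-d2[r, sel] / (2 * sigma^2))
    }
  }
  list(nbrs = nbrs, wts = wts)
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [triangle_mesh()].
#' @return scalar area.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

# barycentric (one-third) vertex area shares
vertex_areas <- function(mesh) {
  A <- face_areas(mesh)
  va <- numeric(nrow(mesh$vertices))
  f <- mesh$faces
  for (j in 1:3) {
    acc <- tapply(A, f[, j], sum)
    va[as.integer(names(acc))] <- va[as.integer(names(acc))] + acc
  }
  va / 3
}

# cotangent (Voronoi) vertex areas: A_i = 1/8 sum over incident corners of
# cot(opposite angles) |edge|^2; falls back to the barycentric share where
# obtuse triangles make the Voronoi cell degenerate
vertex_areas_voronoi <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  V <- nrow(v)
  va <- numeric(V)
  bad <- rep(FALSE, V)
  for (j in 1:3) {
    i0 <- f[, j]                      # apex carrying the angle
    i1 <- f[, (j %% 3) + 1]
    i2 <- f[, ((j + 1) %% 3) + 1]
    e1 <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    e2 <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    cotan <- rowSums(e1 * e2) / pmax(sqrt(rowSums(cr^2)), 1e-300)
    l2 <- rowSums((v[i2, , drop = FALSE] - v[i1, , drop = FALSE])^2)
    # the angle at i0 contributes cot(angle)*|i1 i2|^2 / 8 to i1 and i2
    for (tgt in list(i1, i2)) {
      acc <- tapply(cotan * l2 / 8, tgt, sum)
      va[as.integer(names(acc))] <- va[as.integer(names(acc))] + acc
    }
    obt <- which(cotan < 0)
    if (length(obt)) bad[unique(c(i0[obt], i1[obt], i2[obt]))] <- TRUE
  }
  if (any(bad)) va[bad] <- vertex_areas(mesh)[bad]
  va
}

# outward unit normal of each face (CCW orientation)
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

# area-weighted vertex normals
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  f <- mesh$faces
  for (j in 1:3) {
    for (a in 1:3) {
      acc <- tapply(fn[, a], f[, j], sum)
      vn[as.integer(names(acc)), a] <- vn[as.integer(names(acc)), a] + acc
    }
  }
  vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
}

#' Discrete Gaussian curvature (angle deficit)
#'
#' Estimates Gaussian curvature at each vertex as the angle deficit (2*pi
#' minus the sum of incident face angles; pi minus the sum on boundary
#' vertices) normalised by the barycentric vertex area share. For a closed
#' mesh the unnormalised deficits sum to 2*pi times the Euler characteristic
#' (Gauss-Bonnet), which [make_femur_proxy()]'s tests use as a topology check.
#'
#' @param mesh a [triangle_mesh()].
#' @param normalized divide the deficits by the vertex area share (default
#'   `TRUE`; `FALSE` returns the raw deficits in radians).
#' @return per-vertex curvature (1/mm^2), or raw deficits.
#' @export
gaussian_curvature <- function(mesh, normalized = TRUE) {
  A <- face_areas(mesh)
  if (any(A <= 1e-12))
    stop(sprintf("degenerate (zero-area) faces: %s",
                 paste(head(which(A <= 1e-12), 10), collapse = ", ")))
  v <- mesh$vertices
  f <- mesh$faces
  V <- nrow(v)
  ang_sum <- numeric(V)
  for (j in 1:3) {
    i0 <- f[, j]
    i1 <- f[, (j %% 3) + 1]
    i2 <- f[, ((j + 1) %% 3) + 1]
    e1 <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    e2 <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      (sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang)))
    acc <- tapply(ang, i0, sum)
    ang_sum[as.integer(names(acc))] <- ang_sum[as.integer(names(acc))] + acc
  }
  # boundary vertices get deficit pi - angle sum
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ukey <- (pmin(de[, 1], de[, 2]) - 1) * as.numeric(V) +
    (pmax(de[, 1], de[, 2]) - 1)
  cnt <- table(ukey)
  bkeys <- as.numeric(names(cnt)[cnt == 1L])
  boundary <- rep(FALSE, V)
  if (length(bkeys) > 0) {
    bi <- floor(bkeys / V) + 1
    bj <- (bkeys %% V) + 1
    boundary[c(bi, bj)] <- TRUE
  }
  deficit <- ifelse(boundary, pi, 2 * pi) - ang_sum
  if (!normalized) return(deficit)
  deficit / vertex_areas_voronoi(mesh)   # Voronoi cells: unbiased on spheres
}

#' Euler characteristic of a mesh (V - E + F)
#' @param mesh a [triangle_mesh()].
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  V <- nrow(mesh$vertices)
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ukey <- (pmin(de[, 1], de[, 2]) - 1) * as.numeric(V) +
    (pmax(de[, 1], de[, 2]) - 1)
  E <- length(unique(ukey))
  V - E + nrow(f)
}

# 3D points of the (face, barycentric) locations `face`, `bary` on `mesh`
barycentric_points <- function(mesh, face, bary) {
  f <- mesh$faces[face, , drop = FALSE]
  v <- mesh$vertices
  bary[, 1] * v[f[, 1], , drop = FALSE] +
    bary[, 2] * v[f[, 2], , drop = FALSE] +
    bary[, 3] * v[f[, 3], , drop = FALSE]
}

# face containing each vertex, with corner barycentric coordinates
vertex_as_barycentric <- function(mesh) {
  V <- nrow(mesh$vertices)
  face <- integer(V)
  corner <- integer(V)
  f <- mesh$faces
  for (j in 3:1) {  # earliest face wins
    face[f[, j]] <- seq_len(nrow(f))
    corner[f[, j]] <- j
  }
  bary <- matrix(0, V, 3)
  bary[cbind(seq_len(V), corner)] <- 1
  list(face = face, bary = bary)
}
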