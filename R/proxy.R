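# Parametric femur proxy: a closed, manifold, femur-like mesh built by
# shrink-wrapping an icosphere onto the union of two convex primitives that
# share the hinge point (a capped shaft cylinder and a neck-head "round
# cone"), plus a fovea dimple and a trochanter bump applied along vertex
# normals. The proxy carries an internal two-bone armature (shaft bone and
# head bone hinged at the junction) so that neck-shaft angle can be varied by
# linear-blend skinning, and a full landmarking scheme: homologous points,
# boundary/rim/calcar curves and the two texture-effect patches.

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; a closed genus-0 mesh with
#' `20 * 4^subdiv` faces, used as the sampling topology for the femur proxy
#' and as a convenient closed test mesh.
#'
#' @param subdiv number of 4-to-1 subdivisions (0 gives the icosahedron).
#' @param radius sphere radius (mm).
#' @return a [triangle_mesh()].
#' @export
icosphere <- function(subdiv = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_id <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      edge_id[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  triangle_mesh(v * radius, f, validate = FALSE)
}

# smoothstep on [0,1]
.smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# proxy geometry constants (mm); the hinge point is the origin
.proxy_geom <- function() {
  alpha <- 50 * pi / 180              # neck axis angle from +z
  u_neck <- c(sin(alpha), 0, cos(alpha))
  v_inf <- c(cos(alpha), 0, -sin(alpha))   # inferior (calcar) side of neck
  list(
    u_shaft = c(0, 0, -1),
    shaft_top = c(0, 0, 8), shaft_len = 78, shaft_r = 13,
    u_neck = u_neck, v_inf = v_inf, v_sup = -v_inf,
    neck_len = 40, neck_r = 11,
    head_centre = 40 * u_neck, head_r = 19,
    blend_lo = 6, blend_hi = 22      # skinning blend band along the neck axis
  )
}

# inside tests for the two convex primitives (vectorised over point rows)
.inside_shaft <- function(P, g) {
  rel <- sweep(P, 2, g$shaft_top)
  a <- rel %*% g$u_shaft
  rad2 <- rowSums(rel^2) - a^2
  a >= 0 & a <= g$shaft_len & rad2 <= g$shaft_r^2
}

.inside_neckhead <- function(P, g) {
  # hull of sphere(origin, neck_r) and sphere(head_centre, head_r):
  # sphere-swept segment with linearly varying radius; the 1D objective
  # |x - t h| - r(t) is convex in t, minimised by ternary search
  h <- g$head_centre
  lo <- rep(0, nrow(P)); hi <- rep(1, nrow(P))
  for (i in 1:48) {
    m1 <- lo + (hi - lo) / 3
    m2 <- hi - (hi - lo) / 3
    f1 <- sqrt(rowSums((P - outer(m1, h))^2)) - (g$neck_r + m1 * (g$head_r - g$neck_r))
    f2 <- sqrt(rowSums((P - outer(m2, h))^2)) - (g$neck_r + m2 * (g$head_r - g$neck_r))
    sel <- f1 > f2
    lo[sel] <- m1[sel]
    hi[!sel] <- m2[!sel]
  }
  t <- 0.5 * (lo + hi)
  f <- sqrt(rowSums((P - outer(t, h))^2)) - (g$neck_r + t * (g$head_r - g$neck_r))
  f <= 0
}

# exit distance along unit directions from the origin for a convex primitive
# containing the origin (vectorised bisection)
.ray_exit <- function(dirs, inside, g, tmax = 200) {
  n <- nrow(dirs)
  lo <- rep(0, n); hi <- rep(tmax, n)
  has <- inside(dirs * 1e-9, g)  # origin inside => always TRUE
  for (i in 1:55) {
    mid <- 0.5 * (lo + hi)
    isin <- inside(dirs * mid, g)
    lo[isin] <- mid[isin]
    hi[!isin] <- mid[!isin]
  }
  out <- 0.5 * (lo + hi)
  out[!has] <- 0
  out
}

#' Build the synthetic femur proxy
#'
#' Constructs a closed, manifold femur-like mesh (capped shaft tube joined to
#' an angled neck flaring into a spherical head with a fovea dimple and a
#' lateral trochanter bump), its two-bone hinge armature with per-vertex
#' skinning weights, a landmarking scheme (three homologous points, the
#' head-neck boundary ring, the shaft truncation rim and a calcar curve along
#' the inferior neck) and the superior (S) and inferior (I) femoral-neck
#' texture patches.
#'
#' @param resolution target face count (>= 500); rounded up to the nearest
#'   icosphere subdivision level.
#' @param patch_radius patch radius in mm.
#' @return a list of class `femur_proxy` with elements `mesh`, `armature`
#'   (hinge point/axis and skinning `weights`), `landmarks` (a
#'   [landmark_set()]), `patches` (centres/radii of S and I) and `features`
#'   (named 3D anchor points used by the texture model).
#' @export
make_femur_proxy <- function(resolution = 5120, patch_radius = 9) {
  if (resolution < 500)
    stop("resolution too low to represent the proxy's features (need >= 500 faces)")
  subdiv <- max(3L, ceiling(log(resolution / 20) / log(4)))
  subdiv <- min(subdiv, 6L)
  g <- .proxy_geom()
  ico <- icosphere(subdiv, radius = 1)
  dirs <- ico$vertices
  r_shaft <- .ray_exit(dirs, .inside_shaft, g)
  r_nh <- .ray_exit(dirs, .inside_neckhead, g)
  r <- pmax(r_shaft, r_nh)
  mesh <- triangle_mesh(dirs * r, ico$faces, validate = FALSE)

  # fovea dimple: inward displacement along vertex normals near the fovea
  vn <- vertex_normals(mesh)
  u_f <- c(g$u_neck + c(0, 0.45, 0.25))
  u_f <- u_f / sqrt(sum(u_f^2))
  pf <- g$head_centre + g$head_r * u_f
  d_f <- sqrt(rowSums(sweep(mesh$vertices, 2, pf)^2))
  disp <- -2.5 * exp(-(d_f / 3.5)^2)
  # trochanter bump: outward displacement on the lateral junction
  u_t <- c(-1, 0, 0.15); u_t <- u_t / sqrt(sum(u_t^2))
  score <- (mesh$vertices %*% u_t) / pmax(sqrt(rowSums(mesh$vertices^2)), 1e-9)
  pt <- mesh$vertices[which.max(score), ]
  d_t <- sqrt(rowSums(sweep(mesh$vertices, 2, pt)^2))
  disp2 <- 4 * exp(-(d_t / 6)^2)
  mesh <- triangle_mesh(mesh$vertices + vn * (disp + disp2), ico$faces,
                        validate = FALSE)
  validate_mesh(mesh)
  mesh <- index_mesh(mesh)

  # skinning weights from the axial coordinate along the neck
  a <- as.numeric(mesh$vertices %*% g$u_neck)
  weights <- .smoothstep((a - g$blend_lo) / (g$blend_hi - g$blend_lo))
  armature <- list(hinge_point = c(0, 0, 0), hinge_axis = c(0, 1, 0),
                   weights = weights)

  # landmarks ---------------------------------------------------------------
  snap <- function(p) closest_surface_point(mesh, rbind(p))
  apex <- pt + 4 * u_t
  junction <- c(0, g$shaft_r, 0)
  pts_fixed <- rbind(pf, apex, junction)
  lm_points <- landmarks_from_points(mesh, pts_fixed, "point")

  ring_centre <- g$head_centre - 0.8 * g$head_r * g$u_neck
  e1 <- c(0, 1, 0)
  e2 <- c(g$u_neck[3], 0, -g$u_neck[1])  # u_neck x e1 direction in the x-z plane
  phi <- seq(0, 2 * pi, length.out = 25)[-25]
  ring <- t(vapply(phi, function(p)
    ring_centre + 0.65 * g$head_r * (cos(p) * e1 + sin(p) * e2), numeric(3)))
  lm_ring <- landmarks_from_points(mesh, ring, "curve", curve_id = 1L,
                                   order = seq_along(phi))
  rim_z <- g$shaft_top[3] - g$shaft_len
  rim <- cbind(g$shaft_r * cos(phi), g$shaft_r * sin(phi), rim_z)
  lm_rim <- landmarks_from_points(mesh, rim, "curve", curve_id = 2L,
                                  order = seq_along(phi))
  tt <- seq(0.10, 0.90, length.out = 12)
  calcar <- t(vapply(tt, function(t)
    t * g$neck_len * g$u_neck + 1.3 * g$neck_r * g$v_inf, numeric(3)))
  lm_calcar <- landmarks_from_points(mesh, calcar, "curve", curve_id = 3L,
                                     order = seq_along(tt))
  landmarks <- Reduce(combine_landmarks,
                      list(lm_points, lm_ring, lm_rim, lm_calcar))

  centre_S <- snap(0.55 * g$neck_len * g$u_neck + 1.25 * g$neck_r * g$v_sup)$point[1, ]
  centre_I <- snap(0.45 * g$neck_len * g$u_neck + 1.25 * g$neck_r * g$v_inf)$point[1, ]
  patches <- list(S = list(centre = centre_S, radius = patch_radius),
                  I = list(centre = centre_I, radius = patch_radius))

  features <- list(fovea = snap(pf)$point[1, ], trochanter = snap(apex)$point[1, ],
                   junction = snap(junction)$point[1, ],
                   calcar_mid = snap(calcar[6, ])$point[1, ],
                   head_centre = g$head_centre, geom = g)
  structure(list(mesh = mesh, armature = armature, landmarks = landmarks,
                 patches = patches, features = features, subdiv = subdiv),
            class = "femur_proxy")
}

#' @export
print.femur_proxy <- function(x, ...) {
  cat(sprintf("femur_proxy: %d vertices, %d faces, %d landmarks\n",
              nrow(x$mesh$vertices), nrow(x$mesh$faces), length(x$landmarks$kind)))
  invisible(x)
}

#' Bend a skinned mesh about its armature hinge
#'
#' Each vertex is rotated about the hinge axis (through the hinge point) by
#' its skinning weight times the bend angle: weight-0 vertices (shaft bone)
#' stay fixed, weight-1 vertices (head bone) rotate rigidly by the full
#' angle, and the blend band interpolates. Faces are unchanged, so the bent
#' mesh shares topology with the canonical proxy and the identity vertex map
#' is the ground-truth correspondence.
#'
#' @param mesh a [triangle_mesh()].
#' @param armature armature list with `hinge_point`, `hinge_axis`, `weights`.
#' @param theta bend angle in degrees, within \[-20, 20\].
#' @return the bent [triangle_mesh()].
#' @export
bend_mesh <- function(mesh, armature, theta) {
  if (abs(theta) > 20 + 1e-9) stop("bend angle must lie in [-20, 20] degrees")
  if (theta == 0) return(mesh)
  w <- armature$weights
  if (length(w) != nrow(mesh$vertices))
    stop("armature weights do not match the mesh")
  k <- armature$hinge_axis / sqrt(sum(armature$hinge_axis^2))
  p <- sweep(mesh$vertices, 2, armature$hinge_point)
  ang <- w * theta * pi / 180
  # Rodrigues rotation, vectorised over per-vertex angles
  kxp <- cbind(k[2] * p[, 3] - k[3] * p[, 2],
               k[3] * p[, 1] - k[1] * p[, 3],
               k[1] * p[, 2] - k[2] * p[, 1])
  kdp <- as.numeric(p %*% k)
  rot <- p * cos(ang) + kxp * sin(ang) + outer(kdp * (1 - cos(ang)), k)
  triangle_mesh(sweep(rot, 2, armature$hinge_point, "+"), mesh$faces,
                validate = FALSE)
}
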