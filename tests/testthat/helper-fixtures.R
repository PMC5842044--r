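# Shared fixtures: small meshes built in code, independent geometric oracles,
# and memoised expensive objects (proxy, cohort, full study) reused across
# test files.

# regular planar grid mesh in the z = 0 plane, spacing h, n x n vertices
planar_grid_mesh <- function(n = 15, h = 1, lift = NULL) {
  xs <- seq(0, (n - 1) * h, by = h) - (n - 1) * h / 2
  V <- as.matrix(expand.grid(x = xs, y = xs))
  z <- if (is.null(lift)) 0 else lift(V[, 1], V[, 2])
  V <- cbind(V, z)
  idx <- function(i, j) (j - 1L) * n + i
  fl <- matrix(0L, 2L * (n - 1L)^2, 3L)
  r <- 1L
  for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
    fl[r, ] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    fl[r + 1L, ] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    r <- r + 2L
  }
  triangle_mesh(V, fl)
}

# a valid closed tetrahedron (outward orientation)
tetrahedron_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f)
}

# independent exact point-to-triangle closest point: candidate enumeration
# (unconstrained plane foot, clamped edge projections, vertices)
oracle_point_triangle <- function(a, b, c, p) {
  cand <- list(a, b, c)
  for (ed in list(list(a, b), list(b, c), list(c, a))) {
    u <- ed[[2]] - ed[[1]]
    t <- sum((p - ed[[1]]) * u) / sum(u * u)
    cand[[length(cand) + 1]] <- ed[[1]] + min(1, max(0, t)) * u
  }
  e1 <- b - a; e2 <- c - a
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e2 * e1), sum(e2 * e2)))
  rhs <- c(sum((p - a) * e1), sum((p - a) * e2))
  st <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (!is.null(st) && st[1] >= 0 && st[2] >= 0 && sum(st) <= 1)
    cand[[length(cand) + 1]] <- a + st[1] * e1 + st[2] * e2
  d <- vapply(cand, function(q) sum((q - p)^2), numeric(1))
  sqrt(min(d))
}

oracle_closest_distance <- function(mesh, p) {
  f <- mesh$faces
  v <- mesh$vertices
  min(vapply(seq_len(nrow(f)), function(k)
    oracle_point_triangle(v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ], p),
    numeric(1)))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y)),
        c(2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x)),
        c(2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)))
}

# ---- memoised expensive fixtures -------------------------------------------
.gmia_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .gmia_cache))
    assign(name, force(expr), envir = .gmia_cache)
  get(name, envir = .gmia_cache)
}

# small proxy for cheap unit tests (642 vertices)
small_proxy <- function() cached("small_proxy", make_femur_proxy(1280))

# the study-condition proxy (default resolution, ~2500 vertices)
default_proxy <- function() cached("default_proxy", make_femur_proxy())

default_cohort <- function() cached(
  "default_cohort", make_cohort(cohort_spec(seed = 1), default_proxy()))

zero_noise_cohort_small <- function() cached(
  "zero_noise_small",
  make_cohort(cohort_spec(angles = c(-20, 0, 20), noise_rms = 0, seed = 1),
              small_proxy()))

# the full six-algorithm study all heavyweight acceptance checks share
acceptance_study <- function() cached(
  "acceptance_study",
  run_synthetic_study(cohort_spec(seed = 1), proxy = default_proxy(),
                      cohort = default_cohort(), seed = 1))
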