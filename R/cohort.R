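# Synthetic cohort generator: bent copies of the femur proxy carrying a
# smooth baseline texture modulated by two localized ground-truth effects (a
# gender effect at the inferior neck patch, a neck-shaft-angle effect at the
# superior neck patch) plus spatially smooth residual noise.

#' Baseline surface texture for the femur proxy
#'
#' A smooth, strictly positive per-vertex field standing in for a cohort-mean
#' cortical mass surface density map (synthetic; mean level 100 texture
#' units). It combines gentle large-scale variation with a dense band around
#' the mid-calcar and a denser inferior head region, so the field has local
#' extrema along the calcar curve — the structure that makes tangential
#' misregistration visible.
#'
#' @param proxy a [make_femur_proxy()] result.
#' @return per-vertex texture vector (positive).
#' @export
baseline_texture <- function(proxy) {
  v <- proxy$mesh$vertices
  cm <- proxy$features$calcar_mid
  hc <- proxy$features$head_centre
  d_cal <- sqrt(rowSums(sweep(v, 2, cm)^2))
  d_head <- sqrt(rowSums(sweep(v, 2, hc + c(0, 0, 12))^2))
  tex <- 100 * (1 +
    0.20 * sin(2 * pi * v[, 3] / 150 + 0.4) +
    0.15 * cos(2 * pi * v[, 1] / 110) +
    0.10 * sin(2 * pi * v[, 2] / 90 + 1.0)) +
    35 * exp(-(d_cal / 9)^2) +
    20 * exp(-(d_head / 12)^2)
  stopifnot(all(tex > 0))
  tex
}

#' Cohort specification
#'
#' The study conditions for the synthetic experiment: 41 neck-shaft angles
#' from -20 to +20 degrees at 1-degree intervals, each realised once per
#' group ("male"/"female", 82 specimens in all); a +/-10 percent
#' multiplicative gender effect at the inferior patch; a -1 percent-per-degree
#' shape-coupled effect at the superior patch; and smooth residual noise of
#' 10 percent RMS (of the mean baseline) at 10 mm FWHM.
#'
#' @param angles neck-shaft bend angles in degrees.
#' @param groups group labels; the first is coded +1, the second -1.
#' @param group_effect fractional texture modulation at the inferior patch.
#' @param shape_effect fractional modulation per degree at the superior patch.
#' @param noise_rms residual noise RMS as a percentage of the mean baseline.
#' @param noise_fwhm residual noise smoothness (mm full width half maximum).
#' @param seed integer seed for the noise fields.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(angles = seq(-20, 20, by = 1),
                        groups = c("male", "female"),
                        group_effect = 0.10, shape_effect = 0.01,
                        noise_rms = 10, noise_fwhm = 10, seed = 1L) {
  stopifnot(length(groups) == 2L, noise_rms >= 0, noise_fwhm >= 0)
  structure(list(angles = angles, groups = groups,
                 group_effect = group_effect, shape_effect = shape_effect,
                 noise_rms = noise_rms, noise_fwhm = noise_fwhm,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# cosine taper: 1 inside 80% of the radius, smooth to 0 at the rim
patch_taper <- function(dist, radius) {
  inner <- 0.8 * radius
  w <- numeric(length(dist))
  w[dist <= inner] <- 1
  ramp <- dist > inner & dist < radius
  w[ramp] <- 0.5 * (1 + cos(pi * (dist[ramp] - inner) / (radius - inner)))
  w
}

# vertex indices within frac * radius of a patch centre
patch_vertices <- function(mesh, patch, frac = 1) {
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, patch$centre)^2))
  which(d <= frac * patch$radius)
}

#' Smooth random noise field on a mesh
#'
#' White Gaussian noise per vertex, diffused to the requested full width half
#' maximum, centred, and rescaled so its root mean square equals
#' `rms_pct * reference_mean / 100` exactly. Identical seeds give identical
#' fields.
#'
#' @param mesh a [triangle_mesh()].
#' @param rms_pct target RMS as a percentage of `reference_mean`.
#' @param fwhm smoothness in mm.
#' @param seed integer seed.
#' @param reference_mean reference texture level (default 1).
#' @param lap optional precomputed [mesh_laplacian] for reuse.
#' @return per-vertex noise vector.
#' @export
make_noise_field <- function(mesh, rms_pct, fwhm, seed,
                             reference_mean = 1, lap = NULL) {
  stopifnot(rms_pct >= 0)
  V <- nrow(mesh$vertices)
  if (rms_pct == 0) return(numeric(V))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  eps <- rnorm(V)
  if (fwhm > 0)
    eps <- smooth_texture(textured_surface(mesh, eps), fwhm, lap = lap)
  eps <- eps - mean(eps)
  target <- rms_pct * reference_mean / 100
  eps * target / sqrt(mean(eps^2))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate the synthetic textured-femur cohort
#'
#' For every (angle, group) pair the canonical proxy is bent about its
#' armature hinge and textured as
#' `baseline * (1 + g * group_effect * taper_I) * (1 - shape_effect * angle *
#' taper_S) + noise`, where `g` is +1/-1 group coding and the tapers fall
#' smoothly from 1 at each patch core to 0 at the patch rim. Ground-truth
#' correspondences (the identity vertex map) and the covariate table are
#' recorded alongside.
#'
#' @param spec a [cohort_spec()].
#' @param proxy a [make_femur_proxy()] result.
#' @return a list of class `cohort`: `surfaces` (list of
#'   [textured_surface()]), `covariates` (data frame `id`, `group`, `angle`,
#'   `group_code`), `canonical` (the proxy textured with the baseline),
#'   `proxy`, `spec`, and per-vertex `taper_S`/`taper_I` effect supports.
#' @export
make_cohort <- function(spec = cohort_spec(), proxy = make_femur_proxy()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(proxy, "femur_proxy"))
  mesh <- proxy$mesh
  base <- baseline_texture(proxy)
  dS <- sqrt(rowSums(sweep(mesh$vertices, 2, proxy$patches$S$centre)^2))
  dI <- sqrt(rowSums(sweep(mesh$vertices, 2, proxy$patches$I$centre)^2))
  taper_S <- patch_taper(dS, proxy$patches$S$radius)
  taper_I <- patch_taper(dI, proxy$patches$I$radius)
  if (any(taper_S > 0 & taper_I > 0))
    stop("patches S and I overlap: the two texture effects must be separable")
  grid <- expand.grid(angle = spec$angles, group = spec$groups,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  lap <- mesh_laplacian(mesh)
  surfaces <- vector("list", n)
  ids <- character(n)
  gcode <- ifelse(grid$group == spec$groups[1], 1, -1)
  for (i in seq_len(n)) {
    th <- grid$angle[i]
    bent <- bend_mesh(mesh, proxy$armature, th)
    noise <- make_noise_field(mesh, spec$noise_rms, spec$noise_fwhm,
                              seed = spec$seed + i,
                              reference_mean = mean(base), lap = lap)
    tex <- base * (1 + gcode[i] * spec$group_effect * taper_I) *
      (1 - spec$shape_effect * th * taper_S) + noise
    surfaces[[i]] <- textured_surface(bent, tex)
    ids[i] <- sprintf("%s_%+03d", substr(grid$group[i], 1, 1), th)
  }
  covariates <- data.frame(id = ids, group = grid$group, angle = grid$angle,
                           group_code = gcode, stringsAsFactors = FALSE)
  structure(list(surfaces = surfaces, covariates = covariates,
                 canonical = textured_surface(mesh, base), proxy = proxy,
                 spec = spec, taper_S = taper_S, taper_I = taper_I),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d specimens (%d angles x %d groups), %d vertices\n",
              nrow(x$covariates), length(x$spec$angles),
              length(x$spec$groups), nrow(x$canonical$mesh$vertices)))
  invisible(x)
}

#' Evenly spaced surface semilandmarks
#'
#' Distributes `n` surface-sliding semilandmarks over the mesh by
#' farthest-point (maximin) sampling of the vertices, which guarantees a
#' minimum pairwise spacing comparable to the ideal packing distance
#' `sqrt(area / n)`.
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of semilandmarks (default 476).
#' @param seed seed choosing the starting vertex.
#' @return a [landmark_set()] of `n` surface-kind entries.
#' @export
place_semilandmarks <- function(mesh, n = 476, seed = 1L) {
  V <- nrow(mesh$vertices)
  if (n > V) stop("more semilandmarks requested than mesh vertices")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sel <- integer(n)
  sel[1] <- sample.int(V, 1)
  v <- mesh$vertices
  mind <- rowSums(sweep(v, 2, v[sel[1], ])^2)
  if (n > 1) {
    for (i in 2:n) {
      sel[i] <- which.max(mind)
      mind <- pmin(mind, rowSums(sweep(v, 2, v[sel[i], ])^2))
    }
  }
  vb <- vertex_as_barycentric(mesh)
  landmark_set(rep("surface", n), vb$face[sel], vb$bary[sel, , drop = FALSE],
               mesh = mesh)
}
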