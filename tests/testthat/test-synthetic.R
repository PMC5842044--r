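# Synthetic-data generators: ribbon population, femur proxy, armature
# bending, cohort texture effects, noise model and semilandmark placement.

test_that("ribbon population: size, identity warp, fixed ends, monotonicity", {
  pop <- make_ribbon_population()
  expect_equal(pop$n, 201)
  expect_equal(nrow(pop$textures), 201)
  mid <- which.min(abs(pop$s))
  expect_lt(abs(pop$s[mid]), 1e-12)
  expect_equal(pop$textures[mid, ],
               gmia:::ribbon_profile_default(pop$positions), tolerance = 1e-9)
  # ends fixed for every individual
  expect_equal(pop$textures[, 1],
               rep(gmia:::ribbon_profile_default(0), 201), tolerance = 1e-9)
  expect_equal(pop$textures[, ncol(pop$textures)],
               rep(gmia:::ribbon_profile_default(1), 201), tolerance = 1e-9)
  expect_true(all(apply(pop$warped, 1, function(w) all(diff(w) > 0))))
  expect_error(make_ribbon_population(s_range = 1), "non-monotone")
})

test_that("ribbon mode counts: one shape mode, several texture modes, zero for a degenerate population", {
  counts <- ribbon_mode_counts(make_ribbon_population(), 0.99)
  expect_identical(counts$shape_modes, 1L)
  expect_gt(counts$texture_modes, 1L)
  flat <- make_ribbon_population(s_range = 0)
  c0 <- ribbon_mode_counts(flat, 0.99)
  expect_identical(c0$shape_modes, 0L)
  expect_identical(c0$texture_modes, 0L)
})

test_that("femur proxy is a closed, manifold, genus-0 mesh with valid landmarks and patches", {
  proxy <- default_proxy()
  expect_silent(validate_mesh(proxy$mesh))
  expect_identical(euler_characteristic(proxy$mesh), 2L)
  expect_equal(sum(gaussian_curvature(proxy$mesh, normalized = FALSE)),
               4 * pi, tolerance = 1e-9)
  lms <- proxy$landmarks
  expect_true(all(lms$bary >= -1e-9))
  expect_equal(rowSums(lms$bary), rep(1, length(lms$kind)), tolerance = 1e-9)
  expect_setequal(unique(lms$kind), c("point", "curve", "surface")[1:2])
  # landmark locations lie on the surface
  pts <- landmark_points(lms)
  cp <- closest_surface_point(proxy$mesh, pts)
  expect_lt(max(cp$distance), 1e-9)
  # skinning weights: 0 at the distal shaft, 1 at the head apex
  z <- proxy$mesh$vertices[, 3]
  expect_equal(max(proxy$armature$weights[z < -50]), 0)
  apex <- which.max(proxy$mesh$vertices %*% proxy$features$geom$u_neck)
  expect_equal(proxy$armature$weights[apex], 1)
  expect_error(make_femur_proxy(200), "resolution too low")
})

test_that("bend_mesh: identity at 0, exact rotation oracle on the head, invertible on rigid parts", {
  proxy <- small_proxy()
  mesh <- proxy$mesh
  expect_identical(bend_mesh(mesh, proxy$armature, 0)$vertices, mesh$vertices)
  theta <- 13
  bent <- bend_mesh(mesh, proxy$armature, theta)
  w1 <- which(proxy$armature$weights == 1)
  ang <- theta * pi / 180
  Ry <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0), c(-sin(ang), 0, cos(ang)))
  # independent rotation-matrix application about the hinge axis (0,1,0)
  expected <- mesh$vertices[w1, , drop = FALSE] %*% t(Ry)
  expect_equal(bent$vertices[w1, ], expected, tolerance = 1e-9)
  back <- bend_mesh(bent, proxy$armature, -theta)
  keep <- proxy$armature$weights %in% c(0, 1)
  expect_lt(max(abs(back$vertices[keep, ] - mesh$vertices[keep, ])), 1e-9)
  expect_error(bend_mesh(mesh, proxy$armature, 25), "\\[-20, 20\\]")
})

test_that("cohort: 82 specimens by default, exact multiplicative patch effects, effects confined to patches", {
  co <- default_cohort()
  expect_identical(nrow(co$covariates), 82L)
  expect_identical(length(co$surfaces), 82L)
  expect_identical(sum(co$covariates$group == "male"), 41L)
  zn <- zero_noise_cohort_small()
  proxy <- small_proxy()
  base <- baseline_texture(proxy)
  core_I <- which(zn$taper_I == 1)
  core_S <- which(zn$taper_S == 1)
  expect_gt(length(core_I), 0)
  expect_gt(length(core_S), 0)
  cv <- zn$covariates
  m0 <- which(cv$group == "male" & cv$angle == 0)
  f0 <- which(cv$group == "female" & cv$angle == 0)
  p20 <- which(cv$angle == 20 & cv$group == "male")
  # male/female ratio 1.1/0.9 at the inferior patch core
  expect_equal(zn$surfaces[[m0]]$texture[core_I] /
                 zn$surfaces[[f0]]$texture[core_I],
               rep(1.1 / 0.9, length(core_I)), tolerance = 1e-12)
  # +20 degrees: 20% less than canonical at the superior patch core
  expect_equal(zn$surfaces[[p20]]$texture[core_S], 0.8 * base[core_S],
               tolerance = 1e-12)
  # outside both patches the texture is exactly the baseline (zero noise)
  out <- which(zn$taper_I == 0 & zn$taper_S == 0)
  expect_equal(zn$surfaces[[p20]]$texture[out], base[out], tolerance = 1e-12)
  # overlap guard
  pr <- small_proxy()
  pr$patches$S$centre <- pr$patches$I$centre
  expect_error(make_cohort(cohort_spec(angles = 0), pr), "overlap")
})

test_that("noise field: zeros at 0%, deterministic in the seed, exact RMS", {
  mesh <- small_proxy()$mesh
  expect_identical(make_noise_field(mesh, 0, 10, seed = 1),
                   rep(0, nrow(mesh$vertices)))
  n1 <- make_noise_field(mesh, 10, 10, seed = 5, reference_mean = 120)
  n2 <- make_noise_field(mesh, 10, 10, seed = 5, reference_mean = 120)
  n3 <- make_noise_field(mesh, 10, 10, seed = 6, reference_mean = 120)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  expect_equal(sqrt(mean(n1^2)), 12, tolerance = 1e-6)
  expect_equal(mean(n1), 0, tolerance = 1e-9)
})

test_that("cohort generation is reproducible from its seed", {
  spec <- cohort_spec(angles = c(-10, 10), seed = 33)
  proxy <- small_proxy()
  a <- make_cohort(spec, proxy)
  b <- make_cohort(spec, proxy)
  expect_identical(a$surfaces[[3]]$texture, b$surfaces[[3]]$texture)
  expect_identical(a$covariates, b$covariates)
})

test_that("semilandmark placement: counts, surface kind, spacing bound", {
  proxy <- default_proxy()
  one <- place_semilandmarks(proxy$mesh, 1, seed = 2)
  expect_length(one$kind, 1)
  expect_identical(one$kind, "surface")
  area <- mesh_area(proxy$mesh)
  for (n in c(100, 476)) {
    lm <- place_semilandmarks(proxy$mesh, n, seed = 2)
    expect_length(lm$kind, n)
    pts <- landmark_points(lm)
    dm <- as.matrix(dist(pts)); diag(dm) <- Inf
    expect_gte(min(dm), 0.5 * sqrt(area / n))
  }
  expect_error(place_semilandmarks(proxy$mesh, 1e6), "more semilandmarks")
})
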