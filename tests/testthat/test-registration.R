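# Registration algorithms: rigid/similarity fits, ICP, LAD and LAD-TEX,
# thin-plate splines, sliding semilandmarks and the ground-truth oracle.

test_that("fit_rigid: self-alignment, synthetic recovery, reflection rejection", {
  set.seed(31)
  P <- matrix(rnorm(45), 15, 3)
  id <- fit_rigid(P, P)
  expect_equal(id$R, diag(3), tolerance = 1e-9)
  expect_equal(id$t, c(0, 0, 0), tolerance = 1e-9)
  for (rep in 1:5) {
    R0 <- random_rotation()
    t0 <- rnorm(3)
    fit <- fit_rigid(P, sweep(P %*% t(R0), 2, t0, "+"),
                     weights = runif(15, 0.5, 2))
    expect_equal(fit$R, R0, tolerance = 1e-9)
    expect_equal(fit$t, t0, tolerance = 1e-9)
  }
  # reflected targets: the fit stays a proper rotation with larger residual
  Q <- P %*% diag(c(-1, 1, 1))
  fit <- fit_rigid(P, Q)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
  res <- sum((apply_transform(fit, P) - Q)^2)
  expect_gt(res, 1e-3)
  expect_error(fit_rigid(P[1:2, ], P[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(fit_rigid(line, line), "collinear")
})

test_that("icp_similarity recovers a synthetic similarity transform and flags self-registration", {
  proxy <- small_proxy()
  tr <- icp_similarity(proxy$mesh, proxy$mesh)
  expect_true(attr(tr, "converged"))
  expect_equal(tr$scale, 1, tolerance = 1e-3)
  expect_equal(tr$R, diag(3), tolerance = 1e-3)
  set.seed(32)
  ang <- 8 * pi / 180
  R0 <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  M2 <- triangle_mesh(sweep(1.2 * proxy$mesh$vertices %*% t(R0), 2,
                            c(3, -2, 5), "+"), proxy$mesh$faces,
                      validate = FALSE)
  fit <- icp_similarity(proxy$mesh, M2)
  expect_lt(abs(fit$scale - 1.2) / 1.2, 0.01)
  rot_err <- acos(pmin(1, (sum(diag(t(fit$R) %*% R0)) - 1) / 2)) * 180 / pi
  expect_lt(rot_err, 1)
})

test_that("icp residuals stay near the noise floor under vertex jitter", {
  set.seed(33)
  proxy <- small_proxy()
  scale <- mean(sqrt(rowSums(proxy$mesh$vertices^2)))
  jit <- 0.01 * scale
  M2 <- triangle_mesh(proxy$mesh$vertices + matrix(rnorm(3 * nrow(proxy$mesh$vertices), sd = jit), ncol = 3),
                      proxy$mesh$faces, validate = FALSE)
  fit <- icp_similarity(proxy$mesh, M2)
  cp <- closest_surface_point(M2, apply_transform(fit, proxy$mesh$vertices))
  expect_lt(sqrt(mean(cp$distance^2)), 2 * jit)
})

test_that("LAD: self-registration is trivial and rigid motion is recovered", {
  proxy <- small_proxy()
  r <- lad_register(proxy$mesh, proxy$mesh, d = 15)
  expect_lt(max(sqrt(rowSums((r$deformed - proxy$mesh$vertices)^2))), 0.05)
  set.seed(34)
  R0 <- random_rotation()
  M2 <- triangle_mesh(sweep(proxy$mesh$vertices %*% t(R0), 2, c(5, 1, -4), "+"),
                      proxy$mesh$faces, validate = FALSE)
  r2 <- lad_register(proxy$mesh, M2, d = 15)
  cp <- closest_surface_point(M2, r2$deformed)
  expect_lt(mean(cp$distance), 0.01 * 15)
  # correspondences lie on the target: valid barycentric entries
  expect_true(all(r2$correspondence$bary >= -1e-9))
  expect_equal(rowSums(r2$correspondence$bary),
               rep(1, nrow(r2$correspondence$bary)), tolerance = 1e-9)
})

test_that("shape-driven registrations are independent of the textures supplied", {
  proxy <- small_proxy()
  co <- zero_noise_cohort_small()
  tgt <- co$surfaces[[2]]
  set.seed(35)
  perm <- textured_surface(tgt$mesh, sample(tgt$texture))
  r1 <- lad_register(co$canonical, tgt, d = 15)
  r2 <- lad_register(co$canonical, perm, d = 15)
  expect_identical(r1$correspondence$face, r2$correspondence$face)
  expect_identical(r1$correspondence$bary, r2$correspondence$bary)
})

test_that("LAD-TEX equals LAD on identical textured surfaces and follows a displaced texture step", {
  proxy <- small_proxy()
  base <- baseline_texture(proxy)
  surf <- textured_surface(proxy$mesh, base)
  r_lad <- lad_register(surf, surf, d = 15)
  r_tex <- lad_tex_register(surf, surf, d = 15)
  expect_lt(max(sqrt(rowSums((r_tex$deformed - r_lad$deformed)^2))), 0.1)
  expect_lte(r_tex$discrepancy, r_lad$discrepancy + 1e-6)
  # flat geometry with a tangentially displaced texture step: texture pairing
  # shifts correspondences toward texture alignment and lowers discrepancy
  mesh <- planar_grid_mesh(21, 1)
  step1 <- textured_surface(mesh, as.numeric(mesh$vertices[, 1] > 0))
  step2 <- textured_surface(mesh, as.numeric(mesh$vertices[, 1] > 2))
  r0 <- lad_register(step1, step2, d = 6)
  r1 <- lad_tex_register(step1, step2, d = 6)
  expect_lt(r1$discrepancy, r0$discrepancy)
})

test_that("tps_fit interpolates exactly, is affine-exact with zero energy, and validates controls", {
  set.seed(36)
  C <- matrix(rnorm(60), 20, 3)
  Y <- C + 0.3 * matrix(rnorm(60), 20, 3)
  w <- tps_fit(C, Y)
  expect_lt(max(abs(predict(w, C) - Y)) / max(abs(Y)), 1e-9)
  expect_gte(tps_bending_energy(w), 0)
  # kernel weights satisfy the polynomial orthogonality conditions
  expect_lt(max(abs(colSums(w$W))), 1e-8)
  expect_lt(max(abs(t(C) %*% w$W)), 1e-7)
  # energy equals the kernel quadratic form computed independently
  Km <- as.matrix(dist(C))
  expect_equal(tps_bending_energy(w), -sum(diag(t(w$W) %*% Km %*% w$W)),
               tolerance = 1e-6)
  A <- matrix(rnorm(9), 3); b <- rnorm(3)
  wa <- tps_fit(C, sweep(C %*% t(A), 2, b, "+"))
  expect_lt(tps_bending_energy(wa), 1e-10)
  expect_lt(max(abs(wa$W)), 1e-9)
  wid <- tps_fit(C, C)
  expect_lt(tps_bending_energy(wid), 1e-10)
  expect_error(tps_fit(C[1:3, ], Y[1:3, ]), "at least 4")
  expect_error(tps_fit(rbind(C, C[1, ]), rbind(Y, Y[1, ])), "duplicate")
  flat <- cbind(C[, 1:2], 0)
  expect_error(tps_fit(flat, Y), "coplanar")
})

test_that("tps bending energy is invariant under joint rigid motion", {
  set.seed(37)
  C <- matrix(rnorm(45), 15, 3)
  Y <- C + 0.5 * matrix(rnorm(45), 15, 3)
  e0 <- tps_bending_energy(tps_fit(C, Y))
  for (rep in 1:5) {
    R0 <- random_rotation(); t0 <- rnorm(3, sd = 10)
    e1 <- tps_bending_energy(tps_fit(sweep(C %*% t(R0), 2, t0, "+"),
                                     sweep(Y %*% t(R0), 2, t0, "+")))
    expect_equal(e1, e0, tolerance = 1e-6)
  }
})

test_that("sliding semilandmarks: fixed points stay put, zero-bending configurations do not move, energy is monotone", {
  proxy <- small_proxy()
  mesh <- proxy$mesh
  # all point-kind landmarks: nothing slides
  pts <- place_semilandmarks(mesh, 30, seed = 4)
  fixed <- landmark_set(rep("point", 30), pts$face, pts$bary, mesh = mesh)
  out <- slide_semilandmarks(fixed, fixed, mesh)
  expect_identical(out$face, fixed$face)
  expect_equal(out$bary, fixed$bary, tolerance = 1e-12, ignore_attr = TRUE)
  # rigid copy with correctly transferred landmarks: already minimal
  set.seed(38)
  R0 <- random_rotation()
  M2 <- triangle_mesh(sweep(mesh$vertices %*% t(R0), 2, c(2, -1, 3), "+"),
                      mesh$faces, validate = FALSE)
  semis <- place_semilandmarks(mesh, 60, seed = 5)
  tar <- landmark_set(semis$kind, semis$face, semis$bary, mesh = M2)
  slid <- slide_semilandmarks(semis, tar, M2)
  moved <- sqrt(rowSums((landmark_points(slid, M2) -
                           landmark_points(tar, M2))^2))
  expect_lt(max(moved), 0.5)
  # perturbed initialisations: energy trace non-increasing, final <= initial
  co <- zero_noise_cohort_small()
  bent <- co$surfaces[[3]]$mesh
  tar0 <- landmark_set(semis$kind, semis$face, semis$bary, mesh = bent)
  for (rep in 1:5) {
    set.seed(100 + rep)
    jitter_pts <- landmark_points(tar0, bent) + matrix(rnorm(180, sd = 2), ncol = 3)
    cp <- closest_surface_point(bent, jitter_pts)
    tarj <- landmark_set(semis$kind, cp$face, cp$bary, mesh = bent)
    out <- slide_semilandmarks(semis, tarj, bent, max_iter = 8)
    tr <- attr(out, "energy_trace")
    expect_true(all(diff(tr) <= 1e-9))
    expect_lte(tr[length(tr)], tr[1] + 1e-12)
  }
})

test_that("tps_register: self-registration is the identity; affine pairs have negligible bending energy", {
  proxy <- small_proxy()
  mesh <- proxy$mesh
  lms <- combine_landmarks(proxy$landmarks,
                           place_semilandmarks(mesh, 120, seed = 6))
  r <- tps_register(mesh, mesh, lms, use_homologous = FALSE)
  expect_lt(max(sqrt(rowSums((r$deformed - mesh$vertices)^2))), 0.05)
  # pure affine deformation with consistently transferred semilandmarks
  A <- diag(3) + matrix(c(0, 0.05, 0, 0.02, 0, 0, 0, 0, -0.03), 3)
  M2 <- triangle_mesh(mesh$vertices %*% t(A), mesh$faces, validate = FALSE)
  r2 <- tps_register(mesh, M2, lms, use_homologous = FALSE)
  expect_lt(tps_bending_energy(r2$warp), 1e-4)
  expect_error(tps_register(mesh, mesh, gmia:::subset_landmarks(lms, 1:3)),
               "surface semilandmarks|at least 4")
})

test_that("TPS-LM tracks the ground-truth bend better than homology-free TPS", {
  co <- zero_noise_cohort_small()
  proxy <- small_proxy()
  tgt <- co$surfaces[[3]]   # +20 degrees
  lms <- combine_landmarks(proxy$landmarks,
                           place_semilandmarks(proxy$mesh, 200, seed = 7))
  tlms <- landmark_set(lms$kind, lms$face, lms$bary, lms$curve_id,
                       lms$order, mesh = tgt$mesh)
  r_tps <- tps_register(co$canonical, tgt, lms, use_homologous = FALSE)
  r_lm <- tps_register(co$canonical, tgt, lms, target_lms = tlms,
                       use_homologous = TRUE)
  err <- function(r) mean(sqrt(rowSums((r$deformed - tgt$mesh$vertices)^2)))
  expect_lt(err(r_lm), err(r_tps))
})

test_that("perfect_register returns the stored bijection with zero error", {
  co <- zero_noise_cohort_small()
  r <- perfect_register(co, 3)
  expect_identical(r$deformed, co$surfaces[[3]]$mesh$vertices)
  expect_error(perfect_register(co, 99), "unknown specimen")
  expect_error(perfect_register(co, "nope"), "unknown specimen")
  # zero-noise cohort: discrepancy vanishes at patch-free vertices
  cmap <- r$correspondence
  mapped <- transfer_texture(co$surfaces[[3]], cmap)
  base <- co$canonical$texture
  out <- which(co$taper_I == 0 & co$taper_S == 0)
  expect_equal(mapped[out], base[out], tolerance = 1e-12)
})

test_that("perfect registration discrepancy matches the analytic generative RMS", {
  co <- default_cohort()
  disc <- vapply(seq_len(82), function(i) perfect_register(co, i)$discrepancy,
                 numeric(1))
  # analytic: deterministic patch effects + independent noise of exact RMS
  base <- co$canonical$texture
  mb <- mean(base)
  cv <- co$covariates
  det2 <- vapply(seq_len(82), function(i) {
    det <- base * (1 + cv$group_code[i] * 0.10 * co$taper_I) *
      (1 - 0.01 * cv$angle[i] * co$taper_S) - base
    mean(det^2)
  }, numeric(1))
  expected <- 100 * sqrt(mean(det2) + (0.10 * mb)^2) / mb
  expect_lt(abs(mean(disc) - expected), 0.05 * expected)
  expect_true(all(disc > 0))
})
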