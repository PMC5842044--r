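# Mesh data model, geometric queries, texture transfer/smoothing and the
# discrepancy metric.

test_that("mesh validation catches out-of-range, degenerate and non-manifold faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(triangle_mesh(v, rbind(c(1, 2, 5))), "references vertex index 5")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 2))), "repeats a vertex")
  # same directed edge twice = inconsistent orientation
  expect_error(triangle_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4))),
               "orientation")
  expect_silent(validate_mesh(tetrahedron_mesh()))
})

test_that("textured_surface enforces texture length and finiteness", {
  m <- tetrahedron_mesh()
  expect_error(textured_surface(m, 1:3), "does not match vertex count")
  expect_error(textured_surface(m, c(1, 2, NA, 4)), "non-finite")
  expect_equal(textured_surface(m)$texture, rep(0, 4))
})

test_that("closest_surface_point handles on-surface and orthogonal queries", {
  m <- tetrahedron_mesh()
  hit <- closest_surface_point(m, m$vertices[3, ])
  expect_equal(hit$distance, 0, tolerance = 1e-12)
  expect_equal(hit$point[1, ], m$vertices[3, ], tolerance = 1e-12)
  # isolated unit triangle, query at unit height above its centroid
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)), validate = FALSE)
  centroid <- colMeans(tri$vertices)
  hit <- closest_surface_point(tri, centroid + c(0, 0, 1))
  expect_equal(hit$distance, 1, tolerance = 1e-12)
  expect_equal(hit$point[1, ], centroid, tolerance = 1e-12)
  expect_equal(hit$bary[1, ], rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("closest_surface_point agrees with the exhaustive per-triangle oracle", {
  set.seed(11)
  mesh <- planar_grid_mesh(11, 1, lift = function(x, y) 0.4 * sin(x) * cos(y))
  Q <- cbind(runif(100, -7, 7), runif(100, -7, 7), runif(100, -3, 3))
  got <- closest_surface_point(mesh, Q)
  for (k in seq_len(nrow(Q))) {
    expect_equal(got$distance[k], oracle_closest_distance(mesh, Q[k, ]),
                 tolerance = 1e-9)
  }
  # returned points actually lie on the named faces
  pts <- gmia:::barycentric_points(mesh, got$face, got$bary)
  expect_lt(max(abs(pts - got$point)), 1e-9)
})

test_that("vertex_neighbourhood matches a brute-force distance filter", {
  mesh <- small_proxy()$mesh
  expect_error(vertex_neighbourhood(mesh, 1, 0), "d > 0")
  # tiny d isolates the vertex, huge d returns everything
  emin <- min(sqrt(rowSums((mesh$vertices[mesh$faces[, 1], ] -
                              mesh$vertices[mesh$faces[, 2], ])^2)))
  expect_identical(vertex_neighbourhood(mesh, 5, emin * 0.5), 5L)
  expect_length(vertex_neighbourhood(mesh, 5, 1e4), nrow(mesh$vertices))
  set.seed(3)
  for (k in sample(nrow(mesh$vertices), 5)) {
    d2 <- rowSums(sweep(mesh$vertices, 2, mesh$vertices[k, ])^2)
    expect_identical(vertex_neighbourhood(mesh, k, 15), which(d2 <= 225))
  }
})

test_that("transfer_texture is the identity under identity correspondences and exact for linear fields", {
  set.seed(4)
  surf <- textured_surface(small_proxy()$mesh,
                           runif(nrow(small_proxy()$mesh$vertices)))
  idmap <- identity_correspondence(surf$mesh)
  expect_equal(transfer_texture(surf, idmap), surf$texture)
  # linear field is reproduced exactly at arbitrary surface points
  a <- c(0.3, -1.2, 0.7)
  lin <- textured_surface(surf$mesh, as.numeric(surf$mesh$vertices %*% a) + 5)
  Q <- sweep(matrix(rnorm(60, sd = 30), 20, 3), 2, c(10, 0, -20), "+")
  cp <- closest_surface_point(surf$mesh, Q)
  cmap <- correspondence_map(cp$face, cp$bary, target = surf$mesh)
  expect_equal(transfer_texture(lin, cmap),
               as.numeric(cp$point %*% a) + 5, tolerance = 1e-9)
  # random correspondences match an independent per-face evaluation
  vals <- transfer_texture(surf, cmap)
  for (i in seq_len(nrow(Q))) {
    fv <- surf$mesh$faces[cp$face[i], ]
    expect_equal(vals[i], sum(cp$bary[i, ] * surf$texture[fv]),
                 tolerance = 1e-12)
  }
})

test_that("smooth_texture: fixed points, no-op at fwhm 0, and planar Gaussian kernel", {
  mesh <- planar_grid_mesh(41, 1)
  const <- textured_surface(mesh, rep(3.7, nrow(mesh$vertices)))
  expect_equal(smooth_texture(const, 10), const$texture, tolerance = 1e-9)
  imp <- numeric(nrow(mesh$vertices))
  centre <- which(mesh$vertices[, 1] == 0 & mesh$vertices[, 2] == 0)
  imp[centre] <- 1
  surf <- textured_surface(mesh, imp)
  expect_identical(smooth_texture(surf, 0), imp)
  expect_error(smooth_texture(surf, -1), "non-negative")
  sm <- smooth_texture(surf, 10)
  # heat kernel at t = FWHM^2/(16 log 2) is a Gaussian of that FWHM
  r2 <- mesh$vertices[, 1]^2 + mesh$vertices[, 2]^2
  sigma2 <- 2 * 10^2 / (16 * log(2))
  gauss <- exp(-r2 / (2 * sigma2))
  gauss <- gauss * sum(sm) / sum(gauss)
  sel <- r2 < 15^2
  expect_lt(sqrt(mean((sm[sel] - gauss[sel])^2)) / max(gauss), 0.10)
  # discrete maximum principle on a non-obtuse triangulation
  expect_gte(min(sm), min(imp) - 1e-12)
  expect_lte(max(sm), max(imp) + 1e-12)
})

test_that("smoothing preserves the area-weighted mean on a closed mesh", {
  mesh <- icosphere(3, 10)
  set.seed(8)
  tex <- rnorm(nrow(mesh$vertices), mean = 100, sd = 20)
  sm <- smooth_texture(textured_surface(mesh, tex), 8)
  a <- gmia:::vertex_areas(mesh)
  expect_equal(sum(a * sm) / sum(a), sum(a * tex) / sum(a),
               tolerance = 1e-3)
})

test_that("gaussian_curvature: flat interior, sphere value, Gauss-Bonnet", {
  grid <- planar_grid_mesh(9, 1)
  K <- gaussian_curvature(grid)
  interior <- which(abs(grid$vertices[, 1]) < 3 & abs(grid$vertices[, 2]) < 3)
  expect_lt(max(abs(K[interior])), 1e-9)
  ic <- icosphere(3, 10)
  Ks <- gaussian_curvature(ic)
  expect_lt(max(abs(Ks - 0.01)) / 0.01, 0.05)
  # Gauss-Bonnet: deficits sum to 2 pi chi on closed meshes
  expect_equal(sum(gaussian_curvature(ic, normalized = FALSE)), 4 * pi,
               tolerance = 1e-9)
  expect_equal(sum(gaussian_curvature(tetrahedron_mesh(),
                                      normalized = FALSE)), 4 * pi,
               tolerance = 1e-9)
  degen <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         rbind(c(1, 2, 3)), validate = FALSE)
  expect_error(gaussian_curvature(degen), "degenerate")
})

test_that("rms_texture_discrepancy implements 100 RMS(a-b)/mean", {
  expect_equal(rms_texture_discrepancy(1:5, 1:5, 10), 0)
  a <- runif(50)
  expect_equal(rms_texture_discrepancy(a, a + 3, 12), 100 * 3 / 12)
  set.seed(9)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_equal(rms_texture_discrepancy(x, y, 7),
               100 * sqrt(mean((x - y)^2)) / 7)
  expect_error(rms_texture_discrepancy(1:3, 1:4, 1), "length")
  expect_error(rms_texture_discrepancy(1:3, 1:3, 0), "positive")
})
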