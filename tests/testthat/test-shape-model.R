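# Procrustes standardisation and the PCA shape model.

test_that("procrustes_align: self, rotated and scaled specimens behave as specified", {
  proxy <- small_proxy()
  ref <- proxy$mesh
  V <- nrow(ref$vertices)
  ref_c <- sweep(ref$vertices, 2, colMeans(ref$vertices))
  # self-alignment: centred reference, identity rotation
  pr <- procrustes_align(list(ref$vertices), ref)
  expect_equal(matrix(pr$aligned[1, ], V, 3), ref_c, tolerance = 1e-9)
  expect_equal(pr$rotations[[1]], diag(3), tolerance = 1e-9)
  # arbitrary rigid motion: identical output (invariance)
  set.seed(41)
  for (rep in 1:3) {
    R0 <- random_rotation()
    moved <- sweep(ref$vertices %*% t(R0), 2, rnorm(3, sd = 20), "+")
    pr2 <- procrustes_align(list(moved), ref)
    expect_equal(pr2$aligned[1, ], pr$aligned[1, ], tolerance = 1e-6)
  }
  # pure scaling: unit-size stage identical, output exactly scaled
  pr3 <- procrustes_align(list(2 * ref$vertices), ref)
  expect_equal(pr3$aligned[1, ], 2 * pr$aligned[1, ], tolerance = 1e-9)
  expect_equal(pr3$sizes[1], 2 * pr$sizes[1], tolerance = 1e-9)
  # the fitted rotation solves the orthogonal Procrustes problem: residual
  # no larger than random alternatives
  Xu <- matrix(pr2$aligned[1, ], V, 3) / pr2$sizes[1]
  ref_u <- ref_c / sqrt(sum(ref_c^2))
  best <- sum((Xu - ref_u)^2)
  for (rep in 1:5) {
    expect_gte(sum((Xu %*% random_rotation() - ref_u)^2), best - 1e-12)
  }
  expect_error(procrustes_align(list(matrix(1, V, 3)), ref), "degenerate")
})

test_that("a 5580-vertex specimen yields a 16740-element coordinate vector", {
  set.seed(42)
  ref <- matrix(rnorm(5580 * 3), 5580, 3)
  pr <- procrustes_align(list(ref + 0.01), ref)
  expect_identical(ncol(pr$aligned), 16740L)
})

test_that("two-specimen PCA matches the closed-form solution", {
  set.seed(43)
  x1 <- rnorm(30); x2 <- rnorm(30)
  model <- build_shape_model(rbind(x1, x2))
  expect_length(model$eigenvalues, 1)
  # closed form: lambda_1 = |x1 - x2|^2 / 2 for n = 2 (n-1 normalisation)
  expect_equal(model$eigenvalues[1], sum((x1 - x2)^2) / 2, tolerance = 1e-9)
  expect_equal(abs(model$scores[, 1]),
               rep(sqrt(sum((x1 - x2)^2)) / 2, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # direct covariance eigendecomposition agrees
  X <- rbind(x1, x2)
  C <- crossprod(sweep(X, 2, colMeans(X)))
  expect_equal(model$eigenvalues[1], eigen(C, symmetric = TRUE,
                                           only.values = TRUE)$values[1],
               tolerance = 1e-9)
})

test_that("shape model invariants: orthonormal modes, descending eigenvalues, exact reconstruction, trace conservation", {
  set.seed(44)
  n <- 12; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  model <- build_shape_model(X)
  M <- model$modes
  expect_equal(t(M) %*% M, diag(ncol(M)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(model$eigenvalues) <= 1e-9))
  expect_true(all(model$eigenvalues >= 0))
  # full-mode reconstruction of every training specimen
  for (i in seq_len(n)) {
    rec <- reconstruct_shape(model, as.numeric(model$scores[i, ]))
    expect_lt(max(abs(rec - X[i, ])) / max(abs(X[i, ])), 1e-6)
  }
  # trace conservation
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(model$eigenvalues), sum(Xc^2) / (n - 1), tolerance = 1e-9)
  expect_error(build_shape_model(X[1, , drop = FALSE]), "at least 2")
})

test_that("cumulative_variance is non-decreasing and complete; project_shape works", {
  set.seed(45)
  X <- matrix(rnorm(300), 10, 30)
  model <- build_shape_model(X)
  cv <- cumulative_variance(model)
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[length(cv)], 1, tolerance = 1e-9)
  expect_error(cumulative_variance(model, 100), "exceeds")
  expect_equal(project_shape(model, model$mean, 3), rep(0, 3),
               tolerance = 1e-9)
  spec <- model$mean + 2.5 * model$modes[, 2]
  expect_equal(project_shape(model, spec, 4), c(0, 2.5, 0, 0),
               tolerance = 1e-9)
  expect_error(project_shape(model, model$mean, 100), "exceeds")
})

test_that("on the perfectly registered cohort one mode dominates and tracks the bend angle", {
  rep <- acceptance_study()
  perf <- rep$per_algorithm$perfect
  expect_gte(perf$mode1_variance_fraction, 0.99)
  expect_gte(abs(perf$mode1_angle_correlation), 0.99)
  # scores are monotone in angle within each group
  co_angles <- rep$covariates$angle
  s1 <- perf$scores[, 1]
  male <- rep$covariates$group == "male"
  ord <- order(co_angles[male])
  expect_true(all(diff(s1[male][ord]) > 0) || all(diff(s1[male][ord]) < 0))
})
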