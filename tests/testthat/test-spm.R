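# Vertex-wise GLM, effect maps and permutation cluster inference.

test_that("fit_glm recovers exact linear data and validates its inputs", {
  n <- 10; V <- 7
  x <- seq(-2, 2.5, length.out = n)
  Y <- matrix(rep(3 + 2 * x, V), n, V)
  glm <- fit_glm(Y, design_matrix(x = x))
  expect_equal(unname(glm$coefficients["(Intercept)", ]), rep(3, V),
               tolerance = 1e-9)
  expect_equal(unname(glm$coefficients["x", ]), rep(2, V), tolerance = 1e-9)
  expect_error(fit_glm(Y, design_matrix(x = x, x2 = 2 * x)),
               "rank deficient.*x2")
  expect_error(fit_glm(Y[1:2, ], design_matrix(x = x[1:2])), "more specimens")
})

test_that("single-vertex fit matches an independent least-squares oracle", {
  y <- c(4.1, 5.3, 2.2, 6.8, 5.0, 3.9, 7.1, 4.4)
  x <- c(-1.2, 0.3, -2.0, 1.5, 0.2, -0.7, 2.1, 0.1)
  glm <- fit_glm(matrix(y, ncol = 1), design_matrix(x = x))
  ref <- summary(lm(y ~ x))
  expect_equal(unname(glm$coefficients[, 1]), unname(coef(ref)[, 1]),
               tolerance = 1e-9)
  expect_equal(unname(glm$se[, 1]), unname(coef(ref)[, 2]), tolerance = 1e-9)
  expect_equal(unname(glm$t[, 1]), unname(coef(ref)[, 3]), tolerance = 1e-9)
  expect_identical(glm$df, ref$df[2])
})

test_that("residuals are orthogonal to the design and fitted + residual reconstructs the data", {
  set.seed(51)
  n <- 20; V <- 40
  Y <- matrix(rnorm(n * V), n, V)
  X <- design_matrix(g = rep(c(1, -1), n / 2), z = rnorm(n))
  glm <- fit_glm(Y, X)
  expect_lt(max(abs(t(glm$residuals) %*% X)), 1e-9)
  expect_equal(glm$fitted + glm$residuals, Y, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("null p-values are uniform across repeated simulations", {
  set.seed(52)
  pvals <- replicate(500, {
    y <- rnorm(12)
    x <- rnorm(12)
    glm <- fit_glm(matrix(y, ncol = 1), design_matrix(x = x))
    2 * pt(-abs(glm$t["x", 1]), glm$df)
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("effect_map scales coefficients per unit and per SD of the regressor", {
  set.seed(53)
  n <- 30; V <- 5
  g <- rep(c(1, -1), n / 2)
  base <- 200
  Y <- matrix(base, n, V) + outer(g, rep(10, V)) + matrix(rnorm(n * V), n, V)
  glm <- fit_glm(Y, design_matrix(Gender = g))
  mt <- colMeans(Y)
  eff <- effect_map(glm, "Gender", mt, "per-unit", unit = 2)
  # male-female difference is ~20 texture units on a ~200 mean: ~10%
  expect_equal(mean(eff), 100 * 20 / base, tolerance = 0.5)
  per_sd <- effect_map(glm, "Gender", mt, "per-SD")
  expect_equal(per_sd, eff * sd(g) / 2, tolerance = 1e-9)
  expect_equal(effect_map(glm, "Gender", mt, unit = 0), rep(0, V))
  expect_error(effect_map(glm, "Age", mt), "Age")
  expect_error(effect_map(glm, "Gender", rep(0, V)), "positive")
})

test_that("cluster_inference: sub-threshold maps give an empty mask; clusters are mesh components", {
  set.seed(54)
  mesh <- icosphere(2, 30)
  V <- nrow(mesh$vertices)
  n <- 16
  g <- rep(c(1, -1), n / 2)
  Y <- matrix(rnorm(n * V), n, V)
  glm <- fit_glm(Y, design_matrix(Group = g))
  inf <- cluster_inference(glm, "Group", mesh, n_perm = 120, seed = 3)
  if (nrow(inf$clusters) == 0) {
    expect_false(any(inf$mask))
  }
  # an implanted strong localized effect yields one significant cluster
  centre <- mesh$vertices[1, ]
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, centre)^2))
  bump <- as.numeric(d < 12)
  Y2 <- Y + outer(g, 4 * bump)
  glm2 <- fit_glm(Y2, design_matrix(Group = g))
  inf2 <- cluster_inference(glm2, "Group", mesh, n_perm = 200, seed = 3)
  expect_true(any(inf2$clusters$p_corrected < 0.05))
  expect_true(inf2$mask[1])
  # cluster sizes equal connected-component sizes of the masked set
  labs <- inf2$labels
  expect_identical(sort(unname(inf2$clusters$size)),
                   sort(unname(tabulate(labs[labs > 0]))))
  expect_error(cluster_inference(glm2, "Group", mesh, n_perm = 10),
               "at least 100")
})

test_that("corrected p-values are stable across permutation seeds to Monte-Carlo error", {
  set.seed(55)
  mesh <- icosphere(2, 30)
  V <- nrow(mesh$vertices)
  n <- 16
  g <- rep(c(1, -1), n / 2)
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, mesh$vertices[5, ])^2))
  Y <- matrix(rnorm(n * V), n, V) + outer(g, 1.5 * as.numeric(d < 15))
  glm <- fit_glm(Y, design_matrix(Group = g))
  p1 <- cluster_inference(glm, "Group", mesh, n_perm = 400, seed = 1)$clusters
  p2 <- cluster_inference(glm, "Group", mesh, n_perm = 400, seed = 99)$clusters
  if (nrow(p1) > 0 && nrow(p2) > 0) {
    expect_equal(p1$p_corrected, p2$p_corrected,
                 tolerance = 3 / sqrt(400) + 1e-12)
  }
})

test_that("classify_polarity distinguishes none, monopolar and bipolar regions", {
  eff <- c(1, 2, -3, 4, 0)
  expect_identical(classify_polarity(eff, rep(FALSE, 5), 1:5), "none")
  expect_identical(classify_polarity(eff, c(TRUE, TRUE, FALSE, TRUE, FALSE), 1:5),
                   "monopolar_positive")
  expect_identical(classify_polarity(-eff, c(TRUE, TRUE, FALSE, TRUE, FALSE), 1:5),
                   "monopolar_negative")
  expect_identical(classify_polarity(eff, rep(TRUE, 5), 1:5), "bipolar")
  expect_identical(classify_polarity(eff, rep(TRUE, 5), 1:2),
                   "monopolar_positive")
  expect_error(classify_polarity(eff, rep(TRUE, 5), integer(0)), "empty")
})
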