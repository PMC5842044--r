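# End-to-end experiment drivers.

test_that("ribbon study reports the ambiguity and handles the degenerate population", {
  rep <- run_ribbon_study()
  expect_identical(rep$shape_modes, 1L)
  expect_gt(rep$texture_modes, 1L)
  rep0 <- run_ribbon_study(s_range = 0)
  expect_identical(rep0$shape_modes, 0L)
  expect_identical(rep0$texture_modes, 0L)
})

test_that("patch_centre_summary averages over the patch core", {
  proxy <- small_proxy()
  vals <- numeric(nrow(proxy$mesh$vertices))
  core <- gmia:::patch_vertices(proxy$mesh, proxy$patches$I, 0.5)
  vals[core] <- 7
  expect_equal(patch_centre_summary(vals, proxy$mesh, proxy$patches$I), 7)
})

test_that("study reports are reproducible from (config, seed)", {
  spec <- cohort_spec(angles = c(-20, 0, 20), seed = 9)
  proxy <- small_proxy()
  a <- run_synthetic_study(spec, proxy = proxy, algorithms = c("perfect", "lad"),
                           n_semilandmarks = 60, seed = 2)
  b <- run_synthetic_study(spec, proxy = proxy, algorithms = c("perfect", "lad"),
                           n_semilandmarks = 60, seed = 2)
  expect_identical(a$per_algorithm$perfect$gender_patch_I,
                   b$per_algorithm$perfect$gender_patch_I)
  expect_identical(a$per_algorithm$lad$discrepancies,
                   b$per_algorithm$lad$discrepancies)
  expect_identical(a$per_algorithm$lad$cumulative_variance,
                   b$per_algorithm$lad$cumulative_variance)
})

test_that("gender effect localises to the inferior patch under perfect registration", {
  rep <- acceptance_study()
  proxy <- default_proxy()
  mesh <- proxy$mesh
  glm <- rep$per_algorithm$perfect$glm
  inf <- cluster_inference(glm, "Gender", mesh, n_perm = 300, seed = 1)
  centre_I <- gmia:::patch_vertices(mesh, proxy$patches$I, 0.1)
  centre_S <- gmia:::patch_vertices(mesh, proxy$patches$S, 0.1)
  expect_true(any(inf$mask[centre_I]))
  expect_false(any(inf$mask[centre_S]))
})

test_that("LAD-TEX attenuates the gender effect relative to shape-driven registration", {
  rep <- acceptance_study()
  expect_lt(abs(rep$per_algorithm$`lad-tex-15`$gender_patch_I),
            abs(rep$per_algorithm$perfect$gender_patch_I))
  # shape-driven algorithms agree on the patch-centre gender estimate
  ests <- vapply(c("perfect", "tps", "tps-lm", "lad"), function(a)
    rep$per_algorithm[[a]]$gender_patch_I, numeric(1))
  expect_lt(max(ests) - min(ests), 5)
})

test_that("misregistration sensitivity responds linearly and classifies polarity", {
  proxy <- small_proxy()
  rep <- run_misregistration_sensitivity(proxy, n_perm = 200,
                                         n_semilandmarks = 150, seed = 1)
  expect_identical(rep$polarity, "bipolar")
  rep_half <- run_misregistration_sensitivity(
    proxy, displacements = seq(-1.5, 1.5, length.out = 41), n_perm = 200,
    n_semilandmarks = 150, seed = 1)
  m_full <- mean(rep$effect[rep$region])
  m_half <- mean(rep_half$effect[rep_half$region])
  expect_lt(abs(m_full - m_half) / abs(m_full), 0.10)
  expect_error(run_misregistration_sensitivity(
    proxy, displacements = rep(100, 5), n_perm = 200, seed = 1),
    "beyond the curve extent")
})
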