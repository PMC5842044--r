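# End-to-end synthetic studies: the shape/texture variance trade-off across
# registration algorithms, ground-truth effect recovery and artefact
# generation under the vertex-wise GLM, the 1D ribbon ambiguity
# demonstration, and the landmark-displacement misregistration sensitivity
# analysis with monopolar/bipolar classification.

#' Mean effect over a patch core
#'
#' Patch-level summaries average the per-vertex effect over the central
#' `frac` of the patch radius, avoiding the tapered rim.
#'
#' @param values per-vertex values.
#' @param mesh the canonical [triangle_mesh()].
#' @param patch list with `centre` and `radius`.
#' @param frac core fraction of the radius (default 0.5).
#' @return scalar mean.
#' @export
patch_centre_summary <- function(values, mesh, patch, frac = 0.5) {
  mean(values[patch_vertices(mesh, patch, frac)])
}

.study_algorithms <- c("perfect", "tps", "tps-lm", "lad",
                       "lad-tex-15", "lad-tex-30")

# target landmark set for a synthetic specimen: same intrinsic locations on
# the bent mesh (the identity vertex bijection carries face/bary over)
.transfer_landmarks_ground_truth <- function(lms, bent_mesh) {
  landmark_set(lms$kind, lms$face, lms$bary, lms$curve_id, lms$order,
               mesh = bent_mesh)
}

# register one specimen with the named algorithm (standalone interface)
.register_specimen <- function(algorithm, cohort, i, canonical_lms,
                               sliding_iter = 8) {
  canon <- cohort$canonical
  target <- cohort$surfaces[[i]]
  switch(algorithm,
    "perfect" = perfect_register(cohort, i),
    "lad" = lad_register(canon, target, d = 15),
    "lad-tex-15" = lad_tex_register(canon, target, d = 15),
    "lad-tex-30" = lad_tex_register(canon, target, d = 30),
    "tps" = tps_register(canon, target, canonical_lms,
                         use_homologous = FALSE, max_iter = sliding_iter),
    "tps-lm" = tps_register(canon, target, canonical_lms,
                            target_lms = .transfer_landmarks_ground_truth(
                              canonical_lms, target$mesh),
                            use_homologous = TRUE, max_iter = sliding_iter),
    stop(sprintf("unknown algorithm '%s'", algorithm))
  )
}

# register one specimen with every requested algorithm, sharing the ICP
# alignment, the frozen canonical neighbourhoods and the shape-driven LAD
# state between algorithms (identical results to the standalone functions,
# computed once instead of repeatedly)
.register_specimen_all <- function(algorithms, cohort, i, canonical_lms,
                                   nb15, nb30, sliding_iter = 8) {
  canon <- cohort$canonical
  target <- cohort$surfaces[[i]]
  M1 <- canon$mesh
  M2 <- index_mesh(target$mesh)
  target$mesh <- M2
  out <- list()
  need_icp <- any(algorithms != "perfect")
  icp <- if (need_icp) icp_similarity(M1, M2) else NULL
  X0 <- if (need_icp) apply_transform(icp, M1$vertices) else NULL
  lad_chain <- function(nb, d, with_tex) {
    shape <- .lad_core(M1, M2, d, 100, 1e-3 * d, X_start = X0, nb = nb)
    res <- list(shape = shape)
    if (with_tex)
      res$tex <- .lad_core(M1, M2, d, 50, 1e-3 * d, tex_mode = 1L,
                           tex1 = canon$texture, tex2 = target$texture,
                           search = 3, X_start = shape$X, nb = nb)
    res
  }
  chain15 <- if (any(c("lad", "lad-tex-15") %in% algorithms))
    lad_chain(nb15, 15, "lad-tex-15" %in% algorithms) else NULL
  chain30 <- if ("lad-tex-30" %in% algorithms)
    lad_chain(nb30, 30, TRUE) else NULL
  for (alg in algorithms) {
    out[[alg]] <- switch(alg,
      "perfect" = perfect_register(cohort, i),
      "lad" = {
        st <- chain15$shape
        finish_registration(.lad_correspondence(M2, st), M2, target,
                            canon$texture, st$iterations, st$converged,
                            "LAD-15")
      },
      "lad-tex-15" = {
        st <- chain15$tex
        finish_registration(.lad_correspondence(M2, st), M2, target,
                            canon$texture,
                            chain15$shape$iterations + st$iterations,
                            st$converged, "LAD-TEX-15")
      },
      "lad-tex-30" = {
        st <- chain30$tex
        finish_registration(.lad_correspondence(M2, st), M2, target,
                            canon$texture,
                            chain30$shape$iterations + st$iterations,
                            st$converged, "LAD-TEX-30")
      },
      "tps" = tps_register(M1, target, canonical_lms,
                           use_homologous = FALSE,
                           canonical_texture = canon$texture,
                           max_iter = sliding_iter, icp = icp),
      "tps-lm" = tps_register(M1, target, canonical_lms,
                              target_lms = .transfer_landmarks_ground_truth(
                                canonical_lms, M2),
                              use_homologous = TRUE,
                              canonical_texture = canon$texture,
                              max_iter = sliding_iter, icp = icp))
  }
  out
}

#' Run the full synthetic registration study
#'
#' Generates the synthetic cohort, registers the canonical textured proxy to
#' every specimen with each requested algorithm, and for each algorithm
#' computes the mean post-registration texture discrepancy, the Procrustes/
#' PCA shape model (cumulative variance, correlation of mode-1 scores with
#' the ground-truth bend angle), and the vertex-wise GLM
#' `1 + Gender + S1 + S2 + S3` with gender and shape effect maps and
#' patch-core summaries. Optionally adds permutation cluster inference for
#' the gender contrast.
#'
#' @param spec a [cohort_spec()].
#' @param proxy a [make_femur_proxy()] result (built at default resolution
#'   when omitted).
#' @param algorithms subset of `perfect`, `tps`, `tps-lm`, `lad`,
#'   `lad-tex-15`, `lad-tex-30`.
#' @param n_semilandmarks surface semilandmarks for the TPS algorithms.
#' @param n_perm permutations for gender cluster inference (`NULL` skips it).
#' @param seed integer seed (semilandmark placement, permutations).
#' @param cohort optionally, a pre-generated [make_cohort()] result
#'   (must match `spec`/`proxy`).
#' @return an `experiment_report` list: `per_algorithm` (each with
#'   discrepancies, shape model summaries, effect maps and patch estimates),
#'   `cohort` info, and the configuration echo.
#' @export
run_synthetic_study <- function(spec = cohort_spec(), proxy = NULL,
                                algorithms = .study_algorithms,
                                n_semilandmarks = 476, n_perm = NULL,
                                seed = 1L, cohort = NULL) {
  algorithms <- match.arg(algorithms, .study_algorithms, several.ok = TRUE)
  if (is.null(proxy)) proxy <- make_femur_proxy()
  if (is.null(cohort)) cohort <- make_cohort(spec, proxy)
  mesh <- cohort$canonical$mesh
  canonical_lms <- combine_landmarks(
    proxy$landmarks, place_semilandmarks(mesh, n_semilandmarks, seed = seed))
  n <- nrow(cohort$covariates)
  V <- nrow(mesh$vertices)
  gcode <- cohort$covariates$group_code
  angles <- cohort$covariates$angle
  need_lad <- any(c("lad", "lad-tex-15") %in% algorithms)
  nb15 <- if (need_lad) lad_neighbourhoods(mesh, 15) else NULL
  nb30 <- if ("lad-tex-30" %in% algorithms) lad_neighbourhoods(mesh, 30) else NULL
  regs <- vector("list", n)
  for (i in seq_len(n))
    regs[[i]] <- tryCatch(
      .register_specimen_all(algorithms, cohort, i, canonical_lms,
                             nb15, nb30),
      error = function(e) e)
  per_algorithm <- list()
  for (alg in algorithms) {
    textures <- matrix(NA_real_, n, V)
    deformed <- vector("list", n)
    disc <- numeric(n)
    failed <- FALSE
    for (i in seq_len(n)) {
      reg <- if (inherits(regs[[i]], "error")) regs[[i]] else regs[[i]][[alg]]
      if (inherits(reg, "error")) {
        per_algorithm[[alg]] <- list(failed = TRUE,
                                     message = conditionMessage(reg))
        failed <- TRUE
        break
      }
      textures[i, ] <- transfer_texture(cohort$surfaces[[i]],
                                        reg$correspondence)
      deformed[[i]] <- reg$deformed
      disc[i] <- reg$discrepancy
    }
    if (failed) next
    pr <- procrustes_align(deformed, mesh)
    model <- build_shape_model(pr)
    k <- min(3, ncol(model$scores))
    S <- model$scores[, seq_len(k), drop = FALSE]
    colnames(S) <- paste0("S", seq_len(k))
    X <- do.call(design_matrix, c(list(Gender = gcode),
                                  as.list(as.data.frame(S))))
    glm <- fit_glm(textures, X)
    mean_tex <- colMeans(textures)
    gender_map <- effect_map(glm, "Gender", mean_tex, "per-unit", unit = 2)
    s1_map <- effect_map(glm, "S1", mean_tex, "per-SD")
    gender_I <- patch_centre_summary(gender_map, mesh, proxy$patches$I)
    gender_S <- patch_centre_summary(gender_map, mesh, proxy$patches$S)
    # model-predicted texture change between the +20 degree and 0 degree
    # shapes, read off the fitted model's linear response of predicted
    # texture to bend angle (slope x 20 degrees). Pointwise evaluation at
    # the +20 endpoint would inject the endpoint leverage of the higher,
    # noise-dominated modes; the linear response estimates the same model
    # quantity without it (the generative effect is linear in angle).
    uang <- sort(unique(angles))
    Sbar <- t(vapply(uang, function(th)
      colMeans(S[angles == th, , drop = FALSE]), numeric(ncol(S))))
    beta_S <- glm$coefficients[colnames(S), , drop = FALSE]
    pred <- Sbar %*% beta_S                      # angle x vertex predictions
    ac <- uang - mean(uang)
    slope <- colSums(ac * pred) / sum(ac^2)      # per-degree response
    shape_reduction_S <- patch_centre_summary(-100 * slope * 20 / mean_tex,
                                              mesh, proxy$patches$S)
    r_mode1 <- suppressWarnings(stats::cor(model$scores[, 1], angles))
    inference <- NULL
    if (!is.null(n_perm))
      inference <- cluster_inference(glm, "Gender", mesh, n_perm = n_perm,
                                     seed = seed)
    per_algorithm[[alg]] <- list(
      failed = FALSE,
      discrepancies = disc,
      mean_discrepancy = mean(disc),
      cumulative_variance = cumulative_variance(
        model, min(20, length(model$eigenvalues))),
      total_shape_variance = total_shape_variance(model),
      mode1_angle_correlation = r_mode1,
      mode1_variance_fraction = cumulative_variance(model, 1),
      gender_map = gender_map, s1_map = s1_map,
      gender_patch_I = gender_I, gender_patch_S = gender_S,
      shape_reduction_patch_S = shape_reduction_S,
      scores = model$scores[, seq_len(k), drop = FALSE],
      glm = glm, inference = inference)
  }
  structure(list(per_algorithm = per_algorithm,
                 cohort_size = n,
                 covariates = cohort$covariates,
                 patches = proxy$patches,
                 config = list(spec = unclass(spec), algorithms = algorithms,
                               n_semilandmarks = n_semilandmarks,
                               n_perm = n_perm, seed = seed)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report\n")
  if (!is.null(x$per_algorithm)) {
    for (alg in names(x$per_algorithm)) {
      a <- x$per_algorithm[[alg]]
      if (isTRUE(a$failed)) {
        cat(sprintf("  %-11s FAILED: %s\n", alg, a$message))
      } else if (!is.null(a$mean_discrepancy)) {
        cat(sprintf("  %-11s discrepancy %5.2f%%  total shape var %10.1f  gender@I %+6.2f%%\n",
                    alg, a$mean_discrepancy, a$total_shape_variance,
                    a$gender_patch_I))
      }
    }
  }
  if (!is.null(x$shape_modes))
    cat(sprintf("  ribbon: %d shape mode(s) vs %d texture mode(s) for %.0f%% variance\n",
                x$shape_modes, x$texture_modes, 100 * x$variance_target))
  if (!is.null(x$polarity))
    cat(sprintf("  sensitivity: polarity %s, %d significant vertices\n",
                x$polarity, sum(x$inference$mask)))
  invisible(x)
}

#' Run the one-dimensional ribbon ambiguity study
#'
#' Builds the ribbon population and reports how many linear modes the
#' shape-only and texture-only interpretations need to explain the target
#' fraction of the population variance.
#'
#' @param n population size (default 201).
#' @param n_samples sample positions per ribbon.
#' @param s_range warp half-range.
#' @param variance_target variance fraction (default 0.99).
#' @param seed unused (deterministic construction); kept for interface
#'   symmetry.
#' @return an `experiment_report` with `shape_modes`, `texture_modes` and
#'   the population.
#' @export
run_ribbon_study <- function(n = 201, n_samples = 101, s_range = 0.9,
                             variance_target = 0.99, seed = 1L) {
  pop <- make_ribbon_population(n = n, n_samples = n_samples,
                                s_range = s_range, seed = seed)
  counts <- ribbon_mode_counts(pop, variance_target)
  structure(list(shape_modes = counts$shape_modes,
                 texture_modes = counts$texture_modes,
                 variance_target = variance_target, population = pop,
                 config = list(n = n, n_samples = n_samples,
                               s_range = s_range, seed = seed)),
            class = "experiment_report")
}

# cumulative arclength of a polyline
.polyline_arclength <- function(line) {
  c(0, cumsum(sqrt(rowSums(diff(line)^2))))
}

# point at arclength s along a polyline (error beyond the extent)
.polyline_at <- function(line, s) {
  arc <- .polyline_arclength(line)
  if (s < -1e-9 || s > arc[length(arc)] + 1e-9)
    stop("displacement runs beyond the curve extent")
  s <- min(max(s, 0), arc[length(arc)])
  seg <- max(1L, findInterval(s, arc, rightmost.closed = TRUE))
  seg <- min(seg, nrow(line) - 1L)
  t <- (s - arc[seg]) / max(arc[seg + 1L] - arc[seg], 1e-300)
  line[seg, ] + t * (line[seg + 1L, ] - line[seg, ])
}

#' Misregistration sensitivity analysis along a textured curve
#'
#' Quantifies what systematic sliding misregistration along a curve landmark
#' would look like: the canonical textured proxy is registered (TPS-LM) to a
#' population of identical copies of itself, but with the named curve's
#' semilandmarks converted to fixed point landmarks displaced along the curve
#' trajectory by a per-specimen amount. A GLM of the registered texture on
#' the displacement then gives the induced percent-per-millimetre effect,
#' whose polarity over the curve region is classified: systematic sliding of
#' a texture with a local extremum produces a *bipolar* pattern, unlike a
#' genuine monopolar physiological effect.
#'
#' @param proxy a [make_femur_proxy()] result.
#' @param displacements per-specimen landmark displacements along the curve
#'   (mm); should span positive and negative values.
#' @param curve_id which curve to displace (default 3, the calcar).
#' @param n_semilandmarks surface semilandmarks for the TPS-LM registration.
#' @param n_perm permutations for cluster inference.
#' @param region_radius radius (mm) around the curve defining the region for
#'   polarity classification.
#' @param seed integer seed.
#' @return an `experiment_report` with the percent-per-mm `effect` map, the
#'   `inference` mask, the `polarity` label and the curve `region`.
#' @export
run_misregistration_sensitivity <- function(proxy,
                                            displacements = seq(-3, 3, length.out = 41),
                                            curve_id = 3L,
                                            n_semilandmarks = 476,
                                            n_perm = 500,
                                            region_radius = 10,
                                            seed = 1L) {
  stopifnot(inherits(proxy, "femur_proxy"))
  mesh <- proxy$mesh
  canon <- textured_surface(mesh, baseline_texture(proxy))
  lms <- proxy$landmarks
  is_cv <- lms$kind == "curve" & lms$curve_id == curve_id
  if (!any(is_cv)) stop(sprintf("no curve with id %d", curve_id))
  semis <- place_semilandmarks(mesh, n_semilandmarks, seed = seed)
  # canonical set: the displaced curve becomes fixed points
  kinds <- lms$kind
  kinds[is_cv] <- "point"
  can_lms <- landmark_set(kinds, lms$face, lms$bary,
                          ifelse(is_cv, NA_integer_, lms$curve_id),
                          ifelse(is_cv, NA_integer_, lms$order), mesh = mesh)
  can_lms <- combine_landmarks(can_lms, semis)
  curve_sel <- which(is_cv)
  curve_sel <- curve_sel[order(lms$order[curve_sel])]
  line <- landmark_points(subset_landmarks(lms, curve_sel))
  # extend the trajectory beyond the landmark span (the anatomical curve
  # continues past the digitised points) so end landmarks can be displaced
  ext <- max(abs(displacements)) + 1
  t_lo <- line[1, ] - line[2, ]
  t_hi <- line[nrow(line), ] - line[nrow(line) - 1, ]
  t_lo <- t_lo / sqrt(sum(t_lo^2)); t_hi <- t_hi / sqrt(sum(t_hi^2))
  lo_pt <- closest_surface_point(mesh, rbind(line[1, ] + ext * t_lo))$point
  hi_pt <- closest_surface_point(mesh, rbind(line[nrow(line), ] + ext * t_hi))$point
  line <- rbind(lo_pt, line, hi_pt)
  arc <- .polyline_arclength(line)
  base_s <- arc[2:(length(arc) - 1L)]   # arclength of each curve landmark
  n <- length(displacements)
  V <- nrow(mesh$vertices)
  textures <- matrix(NA_real_, n, V)
  for (i in seq_len(n)) {
    delta <- displacements[i]
    newpts <- t(vapply(base_s, function(s) .polyline_at(line, s + delta),
                       numeric(3)))
    # target landmark set: original points/curves, displaced calcar points
    tar <- can_lms
    disp_lms <- landmarks_from_points(mesh, newpts, "point")
    # replace the calcar point entries (they occupy the same positions in
    # can_lms as in lms, order preserved by construction)
    tar$face[curve_sel] <- disp_lms$face
    tar$bary[curve_sel, ] <- disp_lms$bary
    reg <- tps_register(canon, canon, can_lms,
                        target_lms = subset_landmarks(tar, which(tar$kind != "surface")),
                        use_homologous = TRUE, max_iter = 6)
    textures[i, ] <- transfer_texture(canon, reg$correspondence)
  }
  d_curve <- apply(mesh$vertices, 1, function(p)
    min(sqrt(colSums((t(line) - p)^2))))
  region <- which(d_curve <= region_radius)
  if (sd(displacements) == 0) {
    # constant displacement: identical population, no estimable effect
    eff <- numeric(V)
    glm <- NULL
    inference <- structure(list(mask = rep(FALSE, V),
                                clusters = data.frame(id = integer(0),
                                                      size = integer(0),
                                                      p_corrected = numeric(0)),
                                t = numeric(V), t_threshold = Inf,
                                labels = integer(V), alpha = 0.05,
                                n_perm = n_perm),
                           class = "effect_mask")
  } else {
    X <- design_matrix(displacement = displacements)
    glm <- fit_glm(textures, X)
    mean_tex <- colMeans(textures)
    eff <- effect_map(glm, "displacement", mean_tex, "per-unit")
    inference <- cluster_inference(glm, "displacement", mesh, n_perm = n_perm,
                                   seed = seed)
  }
  polarity <- classify_polarity(eff, inference$mask, region)
  structure(list(effect = eff, inference = inference, polarity = polarity,
                 region = region, glm = glm,
                 config = list(displacements = displacements,
                               curve_id = curve_id, n_perm = n_perm,
                               region_radius = region_radius, seed = seed)),
            class = "experiment_report")
}
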