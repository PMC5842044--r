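# Locally affine deformation (LAD) registration and its texture-driven
# variant. After a global ICP similarity alignment, every canonical vertex is
# repeatedly (1) paired with its closest point on the target surface, (2)
# given a local rigid transform fitted over its frozen Euclidean
# neighbourhood N_k (radius d on the undeformed canonical mesh), and (3)
# moved to the proximity-weighted average of its images under the
# neighbourhood's transforms. The single parameter d regularises the
# deformation: small d allows more deformation, large d favours smooth
# displacement fields. The texture-driven variant continues iterating with
# vertices paired instead to the target *vertex* of most similar texture
# within a small search range.

new_registration_result <- function(correspondence, deformed, iterations,
                                    converged, discrepancy = NA_real_,
                                    method = "unknown", extra = list()) {
  structure(c(list(correspondence = correspondence, deformed = deformed,
                   iterations = iterations, converged = converged,
                   discrepancy = discrepancy, method = method), extra),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result [%s]: %d vertices, %d iterations%s\n",
              x$method, nrow(x$deformed), x$iterations,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  if (is.finite(x$discrepancy))
    cat(sprintf("  texture discrepancy: %.2f%%\n", x$discrepancy))
  invisible(x)
}

# shared LAD driver; tex_mode 0 = closest point, 1 = texture similarity
.lad_core <- function(M1, M2, d, max_iter, tol, tex_mode = 0L,
                      tex1 = NULL, tex2 = NULL, search = 3,
                      X_start = NULL, nb = NULL) {
  grid <- mesh_grid(M2)
  if (is.null(nb)) nb <- lad_neighbourhoods(M1, d)
  if (is.null(X_start)) {
    icp <- icp_similarity(M1, M2)
    X_start <- apply_transform(icp, M1$vertices)
  }
  if (is.null(tex1)) tex1 <- numeric(nrow(M1$vertices))
  if (is.null(tex2)) tex2 <- numeric(nrow(M2$vertices))
  out <- .cpp_lad_run(grid, X_start, nb$nbrs, nb$wts,
                      as.integer(max_iter), tol, as.integer(tex_mode),
                      tex1, tex2, search)
  out$nb <- nb
  out
}

# final correspondence for a LAD state: closest points for shape-driven
# pairing, paired-vertex corners for texture pairing
.lad_correspondence <- function(M2, out) {
  cp <- .cpp_grid_closest(mesh_grid(M2), out$X)
  if (any(out$pair_vertex >= 0L)) {
    vb <- vertex_as_barycentric(M2)
    sel <- which(out$pair_vertex >= 0L)
    vid <- out$pair_vertex[sel] + 1L
    cp$face[sel] <- vb$face[vid]
    cp$bary[sel, ] <- vb$bary[vid, , drop = FALSE]
    cp$point[sel, ] <- M2$vertices[vid, , drop = FALSE]
  }
  correspondence_map(cp$face, pmax(cp$bary, 0) / rowSums(pmax(cp$bary, 0)),
                     target = M2)
}

#' Locally affine deformation (LAD) registration
#'
#' Shape-driven nonrigid registration of the canonical mesh `M1` onto the
#' target surface `M2`; see the package vignette for the algorithm. Starts
#' from an internal ICP similarity alignment. Near-collinear neighbourhoods
#' fall back to a pure translation for that vertex (counted in
#' `n_fallback`).
#'
#' @param M1 canonical [triangle_mesh()] (or [textured_surface()]).
#' @param M2 target [triangle_mesh()] (or [textured_surface()]).
#' @param d neighbourhood radius in mm (default 15).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence threshold on the mean vertex update; defaults to
#'   `1e-3 * d` mm.
#' @param canonical_texture optional canonical texture used to report the
#'   final texture discrepancy when `M2` carries a texture.
#' @return a `registration_result`: correspondences onto `M2`, deformed
#'   canonical vertices (on the target surface), iteration count,
#'   convergence flag and (when textures are available) the final
#'   discrepancy in percent.
#' @export
lad_register <- function(M1, M2, d = 15, max_iter = 100, tol = NULL,
                         canonical_texture = NULL) {
  surf2 <- if (inherits(M2, "textured_surface")) M2 else NULL
  if (inherits(M1, "textured_surface")) {
    if (is.null(canonical_texture)) canonical_texture <- M1$texture
    M1 <- M1$mesh
  }
  if (inherits(M2, "textured_surface")) M2 <- M2$mesh
  stopifnot(d > 0)
  if (is.null(tol)) tol <- 1e-3 * d
  out <- .lad_core(M1, M2, d, max_iter, tol)
  cmap <- .lad_correspondence(M2, out)
  finish_registration(cmap, M2, surf2, canonical_texture, out$iterations,
                      out$converged, method = sprintf("LAD-%g", d),
                      extra = list(n_fallback = out$n_fallback))
}

#' Texture-driven LAD registration (LAD-TEX)
#'
#' Runs [lad_register()] to convergence, then continues iterating with
#' texture-similarity pairing: each canonical vertex is paired with the
#' target *vertex*, within `search` mm of its current position, whose texture
#' value is most similar (ties broken by distance); vertices with no
#' candidate in range keep closest-point pairing. Reduces the post-
#' registration texture discrepancy at the cost of extra tangential
#' deformation.
#'
#' @param M1 canonical [textured_surface()].
#' @param M2 target [textured_surface()].
#' @param d neighbourhood radius in mm (15 or 30 in the standard variants).
#' @param search texture search range in mm (default 3).
#' @param max_iter cap for the initial shape-driven phase.
#' @param tex_iter cap for the texture-driven continuation (default 50).
#' @param tol convergence threshold (defaults to `1e-3 * d`).
#' @return a `registration_result` (see [lad_register()]).
#' @export
lad_tex_register <- function(M1, M2, d = 15, search = 3, max_iter = 100,
                             tex_iter = 50, tol = NULL) {
  stopifnot(inherits(M1, "textured_surface"),
            inherits(M2, "textured_surface"))
  if (is.null(tol)) tol <- 1e-3 * d
  mesh1 <- M1$mesh; mesh2 <- M2$mesh
  shape <- .lad_core(mesh1, mesh2, d, max_iter, tol)
  tex <- .lad_core(mesh1, mesh2, d, tex_iter, tol, tex_mode = 1L,
                   tex1 = M1$texture, tex2 = M2$texture, search = search,
                   X_start = shape$X, nb = shape$nb)
  cmap <- .lad_correspondence(mesh2, tex)
  finish_registration(cmap, mesh2, M2, M1$texture,
                      shape$iterations + tex$iterations, tex$converged,
                      method = sprintf("LAD-TEX-%g", d),
                      extra = list(n_fallback = tex$n_fallback,
                                   n_empty_search = tex$n_empty_search))
}

# assemble a registration_result, computing the discrepancy when possible
finish_registration <- function(cmap, target_mesh, target_surface,
                                canonical_texture, iterations, converged,
                                method, extra = list()) {
  deformed <- correspondence_points(cmap, target_mesh)
  disc <- NA_real_
  if (!is.null(target_surface) && !is.null(canonical_texture)) {
    mapped <- transfer_texture(target_surface, cmap)
    disc <- rms_texture_discrepancy(mapped, canonical_texture,
                                    mean(canonical_texture))
  }
  new_registration_result(cmap, deformed, iterations, converged, disc,
                          method, extra)
}

#' Ground-truth ("perfect") registration of a synthetic specimen
#'
#' Returns the stored bijective vertex correspondences of a cohort specimen:
#' canonical vertex i corresponds to vertex i of the bent mesh. The oracle
#' against which every real registration algorithm is compared.
#'
#' @param cohort a [make_cohort()] result.
#' @param specimen specimen index or id.
#' @return a `registration_result`.
#' @export
perfect_register <- function(cohort, specimen) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.character(specimen))
    specimen <- match(specimen, cohort$covariates$id)
  if (is.na(specimen) || specimen < 1 || specimen > length(cohort$surfaces))
    stop("unknown specimen")
  surf <- cohort$surfaces[[specimen]]
  cmap <- identity_correspondence(surf$mesh)
  finish_registration(cmap, surf$mesh, surf, cohort$canonical$texture,
                      iterations = 0L, converged = TRUE, method = "perfect")
}
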