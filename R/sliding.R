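# Sliding-semilandmark registration. Homologous point landmarks stay fixed;
# curve semilandmarks slide tangentially along their curve (1D) and surface
# semilandmarks within the local tangent plane (2D), so as to minimise the
# bending energy of the thin-plate spline that carries the canonical
# landmarks onto the target's. Each iteration takes the closed-form
# generalised-least-squares sliding step and re-projects the slid points
# onto the target surface (surface kind) or curve polyline (curve kind);
# steps that fail to reduce the energy are rejected, so the energy trace is
# non-increasing.

# closest point on a polyline to each row of P
.polyline_project <- function(P, line) {
  n <- nrow(P)
  out <- matrix(0, n, 3)
  nseg <- nrow(line) - 1L
  for (i in seq_len(n)) {
    best <- Inf
    for (s in seq_len(nseg)) {
      a <- line[s, ]; b <- line[s + 1L, ]
      ab <- b - a
      t <- sum((P[i, ] - a) * ab) / max(sum(ab^2), 1e-300)
      t <- min(1, max(0, t))
      q <- a + t * ab
      d <- sum((P[i, ] - q)^2)
      if (d < best) { best <- d; out[i, ] <- q }
    }
  }
  out
}

# curve tangents by central differences along ordered points (one-sided at
# the endpoints)
.curve_tangents <- function(Y) {
  n <- nrow(Y)
  Tn <- matrix(0, n, 3)
  if (n == 1) { Tn[1, ] <- c(1, 0, 0); return(Tn) }
  Tn[1, ] <- Y[2, ] - Y[1, ]
  Tn[n, ] <- Y[n, ] - Y[n - 1, ]
  if (n > 2)
    Tn[2:(n - 1), ] <- Y[3:n, , drop = FALSE] - Y[1:(n - 2), , drop = FALSE]
  Tn / pmax(sqrt(rowSums(Tn^2)), 1e-300)
}

# orthonormal tangent-plane basis vectors for unit normals (n x 3)
.tangent_basis <- function(normals) {
  ref <- matrix(rep(c(1, 0, 0), each = nrow(normals)), ncol = 3)
  alt <- abs(normals[, 1]) > 0.9
  ref[alt, ] <- matrix(rep(c(0, 1, 0), each = sum(alt)), ncol = 3)
  u <- cbind(normals[, 2] * ref[, 3] - normals[, 3] * ref[, 2],
             normals[, 3] * ref[, 1] - normals[, 1] * ref[, 3],
             normals[, 1] * ref[, 2] - normals[, 2] * ref[, 1])
  u <- u / pmax(sqrt(rowSums(u^2)), 1e-300)
  v <- cbind(normals[, 2] * u[, 3] - normals[, 3] * u[, 2],
             normals[, 3] * u[, 1] - normals[, 1] * u[, 3],
             normals[, 1] * u[, 2] - normals[, 2] * u[, 1])
  list(u = u, v = v)
}

#' Slide semilandmarks to minimise thin-plate-spline bending energy
#'
#' Reconfigures the target's semilandmarks (curve kind sliding in 1D along
#' their curve, surface kind in 2D within the tangent plane; point kind
#' fixed) so that the TPS warping the canonical landmarks onto them has
#' minimal bending energy. Iterates a closed-form generalised-least-squares
#' sliding step with re-projection onto the target geometry; the bending
#' energy is non-increasing across iterations.
#'
#' @param canonical_lms [landmark_set()] on the canonical mesh.
#' @param target_lms matching [landmark_set()] on the target mesh (same
#'   kinds, curve ids and ordering).
#' @param M2 the target [triangle_mesh()].
#' @param max_iter iteration cap (default 10).
#' @param tol relative energy-decrease threshold (default 1e-4).
#' @return the updated target [landmark_set()], with attributes
#'   `energy_trace` (bending energy per iteration, non-increasing) and
#'   `converged`.
#' @export
slide_semilandmarks <- function(canonical_lms, target_lms, M2,
                                max_iter = 10, tol = 1e-4) {
  stopifnot(inherits(canonical_lms, "landmark_set"),
            inherits(target_lms, "landmark_set"))
  K <- length(canonical_lms$kind)
  if (length(target_lms$kind) != K ||
      !all(canonical_lms$kind == target_lms$kind))
    stop("canonical and target landmark sets must match one-to-one by kind")
  X <- landmark_points(canonical_lms)
  Y <- landmark_points(target_lms, M2)
  Bm <- tps_energy_matrix(X)
  energy_of <- function(Y) sum(Y * (Bm %*% Y))
  kinds <- canonical_lms$kind
  is_curve <- kinds == "curve"
  is_surf <- kinds == "surface"
  # fixed curve polylines from the initial target configuration
  polylines <- list()
  for (cid in unique(target_lms$curve_id[is_curve])) {
    sel <- which(is_curve & target_lms$curve_id == cid)
    sel <- sel[order(target_lms$order[sel])]
    polylines[[as.character(cid)]] <- Y[sel, , drop = FALSE]
  }
  fnorm <- face_normals(M2)
  cur_face <- target_lms$face
  cur_bary <- target_lms$bary
  e <- energy_of(Y)
  trace <- e
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (e <= 1e-12 * max(1, sum(Y^2))) { converged <- TRUE; break }
    # assemble sliding directions
    lmidx <- integer(0)
    U <- matrix(0, 0, 3)
    for (cid in names(polylines)) {
      sel <- which(is_curve & target_lms$curve_id == as.integer(cid))
      sel <- sel[order(target_lms$order[sel])]
      Tn <- .curve_tangents(Y[sel, , drop = FALSE])
      lmidx <- c(lmidx, sel)
      U <- rbind(U, Tn)
    }
    if (any(is_surf)) {
      sel <- which(is_surf)
      tb <- .tangent_basis(fnorm[cur_face[sel], , drop = FALSE])
      lmidx <- c(lmidx, sel, sel)
      U <- rbind(U, tb$u, tb$v)
    }
    if (length(lmidx) == 0L) { converged <- TRUE; break }
    M <- Bm[lmidx, lmidx, drop = FALSE] * (U %*% t(U))
    G <- Bm %*% Y
    b <- rowSums(U * G[lmidx, , drop = FALSE])
    diag(M) <- diag(M) + 1e-10 * max(diag(M), 1e-300)
    tpar <- tryCatch(solve(M, -b), error = function(e) NULL)
    if (is.null(tpar)) break
    dY <- matrix(0, K, 3)
    for (q in seq_along(lmidx))
      dY[lmidx[q], ] <- dY[lmidx[q], ] + tpar[q] * U[q, ]
    Ynew <- Y + dY
    # re-project onto the target geometry
    new_face <- cur_face
    new_bary <- cur_bary
    for (cid in names(polylines)) {
      sel <- which(is_curve & target_lms$curve_id == as.integer(cid))
      sel <- sel[order(target_lms$order[sel])]
      Ynew[sel, ] <- .polyline_project(Ynew[sel, , drop = FALSE],
                                       polylines[[cid]])
      cp <- closest_surface_point(M2, Ynew[sel, , drop = FALSE])
      new_face[sel] <- cp$face
      new_bary[sel, ] <- cp$bary
      Ynew[sel, ] <- cp$point
    }
    if (any(is_surf)) {
      sel <- which(is_surf)
      cp <- closest_surface_point(M2, Ynew[sel, , drop = FALSE])
      new_face[sel] <- cp$face
      new_bary[sel, ] <- cp$bary
      Ynew[sel, ] <- cp$point
    }
    enew <- energy_of(Ynew)
    if (enew >= e) break   # projection undid the gain: keep the previous state
    rel <- (e - enew) / max(e, 1e-300)
    Y <- Ynew
    cur_face <- new_face
    cur_bary <- new_bary
    e <- enew
    trace <- c(trace, e)
    if (rel < tol) { converged <- TRUE; break }
  }
  out <- landmark_set(target_lms$kind, cur_face, cur_bary,
                      target_lms$curve_id, target_lms$order, mesh = M2)
  attr(out, "energy_trace") <- trace
  attr(out, "converged") <- converged
  out
}

#' Thin-plate-spline semilandmark registration (TPS / TPS-LM)
#'
#' Registers the canonical mesh onto a target surface with the sliding
#' semilandmark machinery. With `use_homologous = FALSE` ("TPS") only the
#' automatically placed surface semilandmarks constrain the warp; with
#' `use_homologous = TRUE` ("TPS-LM") the homologous point landmarks and
#' curve semilandmarks are added, anchoring the registration to features
#' whose placement does not depend on gross shape. Surface semilandmarks on
#' the target are initialised by ICP similarity transfer; point and curve
#' landmarks must be supplied on the target (they are expert knowledge, not
#' derivable from geometry). After sliding, the final TPS warps every
#' canonical vertex and the result is projected onto the target surface.
#'
#' @param M1 canonical [triangle_mesh()] or [textured_surface()].
#' @param M2 target [triangle_mesh()] or [textured_surface()].
#' @param canonical_lms [landmark_set()] on the canonical mesh (surface
#'   semilandmarks, plus point/curve landmarks for TPS-LM).
#' @param target_lms [landmark_set()] on the target carrying the homologous
#'   point/curve entries (required when `use_homologous = TRUE`).
#' @param use_homologous include point/curve landmarks (TPS-LM) or not (TPS).
#' @param canonical_texture optional canonical texture for the discrepancy
#'   report.
#' @param max_iter,tol sliding controls, see [slide_semilandmarks()].
#' @param icp optional precomputed [icp_similarity()] transform (reused by
#'   the study driver).
#' @return a `registration_result`.
#' @export
tps_register <- function(M1, M2, canonical_lms, target_lms = NULL,
                         use_homologous = FALSE, canonical_texture = NULL,
                         max_iter = 10, tol = 1e-4, icp = NULL) {
  surf2 <- if (inherits(M2, "textured_surface")) M2 else NULL
  if (inherits(M1, "textured_surface")) {
    if (is.null(canonical_texture)) canonical_texture <- M1$texture
    M1 <- M1$mesh
  }
  if (inherits(M2, "textured_surface")) M2 <- M2$mesh
  kinds <- canonical_lms$kind
  if (!any(kinds == "surface"))
    stop("surface semilandmarks are required")
  sel <- if (use_homologous) seq_along(kinds) else which(kinds == "surface")
  can <- subset_landmarks(canonical_lms, sel)
  if (length(can$kind) < 4)
    stop("need at least 4 landmarks for a thin-plate-spline registration")
  # initial target configuration
  if (is.null(icp)) icp <- icp_similarity(M1, M2)
  Xpts <- landmark_points(can)
  init_face <- integer(length(can$kind))
  init_bary <- matrix(0, length(can$kind), 3)
  surf_sel <- which(can$kind == "surface")
  cp <- closest_surface_point(M2, apply_transform(icp, Xpts[surf_sel, , drop = FALSE]))
  init_face[surf_sel] <- cp$face
  init_bary[surf_sel, ] <- cp$bary
  hom_sel <- which(can$kind != "surface")
  if (length(hom_sel) > 0) {
    if (is.null(target_lms))
      stop("target point/curve landmarks are required when use_homologous = TRUE")
    # curve entries match by (curve_id, order); point entries by occurrence
    key_can <- paste(can$kind[hom_sel], can$curve_id[hom_sel], can$order[hom_sel])
    key_tar <- paste(target_lms$kind, target_lms$curve_id, target_lms$order)
    m <- match(key_can, key_tar)
    pts_c <- which(can$kind[hom_sel] == "point")
    pts_t <- which(target_lms$kind == "point")
    if (length(pts_c) > length(pts_t))
      stop("target landmark set lacks matching point landmarks")
    m[pts_c] <- pts_t[seq_along(pts_c)]
    if (anyNA(m))
      stop("target landmark set does not match the canonical point/curve landmarks")
    init_face[hom_sel] <- target_lms$face[m]
    init_bary[hom_sel, ] <- target_lms$bary[m, , drop = FALSE]
  }
  tar0 <- landmark_set(can$kind, init_face, init_bary, can$curve_id,
                       can$order, mesh = M2)
  slid <- slide_semilandmarks(can, tar0, M2, max_iter = max_iter, tol = tol)
  warp <- tps_fit(Xpts, landmark_points(slid, M2))
  warped <- predict(warp, M1$vertices)
  cp <- closest_surface_point(M2, warped)
  cmap <- correspondence_map(cp$face, cp$bary, target = M2)
  finish_registration(cmap, M2, surf2, canonical_texture,
                      iterations = length(attr(slid, "energy_trace")),
                      converged = isTRUE(attr(slid, "converged")),
                      method = if (use_homologous) "TPS-LM" else "TPS",
                      extra = list(warp = warp,
                                   energy_trace = attr(slid, "energy_trace")))
}
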