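# Thin-plate splines in 3D with kernel U(r) = r. The interpolating warp maps
# K control points exactly onto K targets; its affine part is free (affine
# maps incur no bending energy) and the kernel weights satisfy the polynomial
# orthogonality conditions. Because U(r) = r is conditionally negative
# definite, the (non-negative) bending energy is -sum_d w_d' K w_d.

.tps_kernel_matrix <- function(A, B) {
  # |a_i - b_j| distance matrix
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

.tps_check_controls <- function(controls) {
  K <- nrow(controls)
  if (K < 4) stop("need at least 4 control points for a 3D thin-plate spline")
  D <- .tps_kernel_matrix(controls, controls)
  diag(D) <- Inf
  if (min(D) < 1e-9)
    stop("duplicate control points (closer than 1e-9 mm)")
  sv <- svd(scale(controls, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1e-300))
    stop("control points are coplanar: the affine part is not determined")
  invisible(K)
}

#' Fit an interpolating 3D thin-plate-spline warp
#'
#' Solves the standard TPS linear system with kernel `U(r) = r` so that the
#' warp maps each control point exactly onto its target (no regularisation).
#'
#' @param controls K x 3 control points (no duplicates, not coplanar).
#' @param targets K x 3 target points.
#' @return object of class `tps_warp` with the affine part, kernel weights
#'   and bending energy; evaluate with [predict.tps_warp()].
#' @export
tps_fit <- function(controls, targets) {
  controls <- as.matrix(controls); targets <- as.matrix(targets)
  K <- .tps_check_controls(controls)
  stopifnot(nrow(targets) == K, ncol(targets) == 3)
  Km <- .tps_kernel_matrix(controls, controls)
  P <- cbind(1, controls)
  L <- rbind(cbind(Km, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(targets, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  W <- sol[1:K, , drop = FALSE]
  A <- sol[(K + 1):(K + 4), , drop = FALSE]
  energy <- max(0, -sum(W * (Km %*% W)))
  structure(list(controls = controls, targets = targets, W = W, A = A,
                 energy = energy),
            class = "tps_warp")
}

#' Evaluate a thin-plate-spline warp
#' @param object a [tps_fit()] result.
#' @param newdata n x 3 matrix of points to warp.
#' @param ... unused.
#' @return warped n x 3 matrix.
#' @export
predict.tps_warp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  U <- .tps_kernel_matrix(newdata, object$controls)
  cbind(1, newdata) %*% object$A + U %*% object$W
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("tps_warp: %d controls, bending energy %.4g\n",
              nrow(x$controls), x$energy))
  invisible(x)
}

#' Bending energy of a thin-plate-spline warp
#'
#' The TPS roughness functional: zero exactly for affine maps, positive
#' otherwise, and invariant under joint rigid motion of controls and targets.
#'
#' @param warp a [tps_fit()] result.
#' @return non-negative scalar.
#' @export
tps_bending_energy <- function(warp) {
  stopifnot(inherits(warp, "tps_warp"))
  warp$energy
}

# bending-energy matrix of a control configuration: the matrix Bm such that
# the energy of targets Y is sum_d y_d' Bm y_d (Bm is minus the upper-left
# block of L^{-1}, positive semi-definite)
tps_energy_matrix <- function(controls) {
  controls <- as.matrix(controls)
  K <- .tps_check_controls(controls)
  Km <- .tps_kernel_matrix(controls, controls)
  P <- cbind(1, controls)
  L <- rbind(cbind(Km, P), cbind(t(P), matrix(0, 4, 4)))
  Li <- solve(L)
  Bm <- -Li[1:K, 1:K, drop = FALSE]
  0.5 * (Bm + t(Bm))
}
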