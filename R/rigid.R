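#' Weighted least-squares rigid transform (Kabsch)
#'
#' Finds the rotation + translation minimising the weighted sum of squared
#' distances between transformed points `P` and targets `Q`. Reflections are
#' excluded: the returned rotation always has determinant +1.
#'
#' @param P,Q K x 3 matrices of paired points.
#' @param weights K non-negative weights (default uniform).
#' @return list of class `rigid_transform` with `R` (3 x 3 rotation) and `t`
#'   (translation); apply as `x %*% t(R) + t`.
#' @export
fit_rigid <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  K <- nrow(P)
  if (K < 3) stop("need at least 3 point pairs for a rigid fit")
  if (is.null(weights)) weights <- rep(1, K)
  w <- weights / sum(weights)
  pc <- colSums(P * w); qc <- colSums(Q * w)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("points are collinear: rigid rotation is not determined")
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  structure(list(R = R, t = as.numeric(qc - R %*% pc)), class = "rigid_transform")
}

#' Apply a rigid or similarity transform to points
#' @param transform a `rigid_transform` or `similarity_transform`.
#' @param X n x 3 matrix of points.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, X) {
  s <- if (is.null(transform$scale)) 1 else transform$scale
  sweep(s * as.matrix(X) %*% t(transform$R), 2, transform$t, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.2f deg, |t| = %.3f mm\n",
              ang, sqrt(sum(x$t^2))))
  invisible(x)
}

# weighted Umeyama similarity fit (rotation, translation, isotropic scale)
fit_similarity <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  K <- nrow(P)
  if (is.null(weights)) weights <- rep(1, K)
  w <- weights / sum(weights)
  pc <- colSums(P * w); qc <- colSums(Q * w)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  d3 <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d3))
  R <- sv$v %*% D %*% t(sv$u)
  varP <- sum(w * rowSums(Pc^2))
  s <- sum(sv$d * c(1, 1, d3)) / varP
  structure(list(R = R, t = as.numeric(qc - s * R %*% pc), scale = s),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("similarity_transform: rotation %.2f deg, scale %.4f, |t| = %.3f mm\n",
              ang, x$scale, sqrt(sum(x$t^2))))
  invisible(x)
}

#' Iterative-closest-point similarity alignment
#'
#' Alternates closest-point pairing of the source vertices against the target
#' surface with a weighted similarity fit (rotation, translation, isotropic
#' scale) until the mean vertex motion per iteration drops below `tol`. The
#' global alignment every nonrigid registration in the package starts from.
#'
#' @param M1 source [triangle_mesh()] (the canonical mesh).
#' @param M2 target [triangle_mesh()].
#' @param max_iter iteration cap.
#' @param tol convergence threshold on mean vertex motion (mm).
#' @param n_sample subsample size for the pairing (the fitted transform is
#'   insensitive to using every vertex; `Inf` disables subsampling).
#' @return a `similarity_transform` with attributes `iterations` and
#'   `converged` (non-convergence flags the result rather than erroring).
#' @export
icp_similarity <- function(M1, M2, max_iter = 50, tol = 0.01,
                           n_sample = 800) {
  if (nrow(M1$faces) == 0L || nrow(M2$faces) == 0L) stop("empty mesh")
  grid <- mesh_grid(M2)
  X <- M1$vertices
  if (is.finite(n_sample) && nrow(X) > n_sample)
    X <- X[round(seq(1, nrow(X), length.out = n_sample)), , drop = FALSE]
  cur <- structure(list(R = diag(3), t = c(0, 0, 0), scale = 1),
                   class = "similarity_transform")
  converged <- FALSE
  it <- 0L
  Xc <- X
  for (it in seq_len(max_iter)) {
    cp <- .cpp_grid_closest(grid, Xc)
    fit <- fit_similarity(X, cp$point)
    Xn <- apply_transform(fit, X)
    motion <- mean(sqrt(rowSums((Xn - Xc)^2)))
    Xc <- Xn
    cur <- fit
    if (motion < tol) { converged <- TRUE; break }
  }
  attr(cur, "iterations") <- it
  attr(cur, "converged") <- converged
  cur
}
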