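# Procrustes standardisation against the canonical mesh and PCA shape
# modelling. Each registered specimen (a set of deformed canonical vertices)
# is translated to a common origin, scaled to unit centroid size and rotated
# onto the undeformed canonical mesh by orthogonal Procrustes; its
# coordinates are then rescaled by its centroid size, so that overall size
# remains part of the shape model. PCA of the resulting coordinate vectors
# yields the mean shape, orthonormal modes, eigenvalues and per-specimen
# shape coefficients.

centroid_size <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sqrt(sum(Xc^2))
}

#' Procrustes alignment of registered specimens to the canonical mesh
#'
#' @param specimens list of V x 3 matrices (deformed canonical vertices, one
#'   per specimen), or a single matrix.
#' @param reference the canonical [triangle_mesh()] (or a V x 3 matrix).
#' @return object of class `procrustes_result`: `aligned` (n x 3V matrix of
#'   concatenated coordinates, x-block then y then z), `sizes` (centroid
#'   sizes), `rotations`, `V`.
#' @export
procrustes_align <- function(specimens, reference) {
  if (is.matrix(specimens)) specimens <- list(specimens)
  ref <- if (inherits(reference, "triangle_mesh")) reference$vertices else reference
  V <- nrow(ref)
  ref_c <- sweep(ref, 2, colMeans(ref))
  ref_u <- ref_c / sqrt(sum(ref_c^2))
  n <- length(specimens)
  aligned <- matrix(0, n, 3 * V)
  sizes <- numeric(n)
  rotations <- vector("list", n)
  for (i in seq_len(n)) {
    X <- as.matrix(specimens[[i]])
    if (nrow(X) != V) stop("specimen vertex count does not match reference")
    Xc <- sweep(X, 2, colMeans(X))
    s <- sqrt(sum(Xc^2))
    if (s < 1e-12) stop("degenerate specimen: zero centroid size")
    Xu <- Xc / s
    # orthogonal Procrustes: rotation (det +1) minimising |Xu R - ref_u|
    sv <- svd(t(Xu) %*% ref_u)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$u %*% D %*% t(sv$v)
    Xa <- (Xu %*% R) * s   # rescale by centroid size: size stays in the model
    aligned[i, ] <- as.vector(Xa)
    sizes[i] <- s
    rotations[[i]] <- R
  }
  structure(list(aligned = aligned, sizes = sizes, rotations = rotations,
                 V = V),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("procrustes_result: %d specimens, %d vertices\n",
              nrow(x$aligned), x$V))
  invisible(x)
}

#' Build a statistical shape model by PCA
#'
#' Principal component analysis of the Procrustes-aligned coordinate vectors:
#' the mean shape, orthonormal modes (eigenvectors of the (n-1)-normalised
#' sample covariance), descending eigenvalues and per-specimen shape
#' coefficients S_i (projections of the centred specimens onto the modes).
#' Mode signs are fixed so each mode's largest-magnitude entry is positive.
#'
#' @param aligned a [procrustes_align()] result (or an n x 3V matrix).
#' @return object of class `shape_model` with `mean`, `modes` (3V x k),
#'   `eigenvalues`, `scores` (n x k coefficients), `V`.
#' @export
build_shape_model <- function(aligned) {
  X <- if (inherits(aligned, "procrustes_result")) aligned$aligned else as.matrix(aligned)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 specimens for a shape model")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  keep <- which(sv$d > 1e-9 * max(sv$d[1], 1e-300))
  d <- sv$d[keep]
  modes <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|entry| of each mode positive
  for (j in seq_along(keep)) {
    imax <- which.max(abs(modes[, j]))
    if (modes[imax, j] < 0) modes[, j] <- -modes[, j]
  }
  scores <- Xc %*% modes
  structure(list(mean = mu, modes = modes, eigenvalues = d^2 / (n - 1),
                 scores = scores, V = length(mu) / 3, n = n),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d specimens, %d vertices, %d modes\n",
              x$n, x$V, length(x$eigenvalues)))
  cv <- cumsum(x$eigenvalues) / sum(x$eigenvalues)
  k <- min(3, length(cv))
  cat(sprintf("  variance explained by first %d mode(s): %s\n", k,
              paste(sprintf("%.1f%%", 100 * cv[1:k]), collapse = ", ")))
  invisible(x)
}

#' @export
summary.shape_model <- function(object, ...) {
  lam <- object$eigenvalues
  data.frame(mode = seq_along(lam), eigenvalue = lam,
             proportion = lam / sum(lam),
             cumulative = cumsum(lam) / sum(lam))
}

#' Cumulative shape variance of the leading modes
#'
#' @param model a [build_shape_model()] result.
#' @param k number of modes (default all).
#' @return non-decreasing vector of cumulative eigenvalue fractions of the
#'   total variance.
#' @export
cumulative_variance <- function(model, k = length(model$eigenvalues)) {
  if (k > length(model$eigenvalues)) stop("k exceeds the number of modes")
  lam <- model$eigenvalues
  cumsum(lam)[seq_len(k)] / sum(lam)
}

#' Total shape variance embodied in a model
#' @param model a [build_shape_model()] result.
#' @return sum of the eigenvalues (trace of the sample covariance).
#' @export
total_shape_variance <- function(model) sum(model$eigenvalues)

#' Project an aligned specimen onto the leading shape modes
#'
#' @param model a [build_shape_model()] result.
#' @param specimen a 3V coordinate vector aligned by the same Procrustes
#'   pipeline (or a V x 3 matrix).
#' @param k number of shape coefficients.
#' @return numeric vector of k shape coefficients.
#' @export
project_shape <- function(model, specimen, k = 3) {
  if (k > ncol(model$modes)) stop("k exceeds the number of modes")
  x <- as.vector(as.matrix(specimen))
  if (length(x) != length(model$mean)) stop("specimen length mismatch")
  as.numeric(t(model$modes[, seq_len(k), drop = FALSE]) %*% (x - model$mean))
}

#' Reconstruct a specimen from shape coefficients
#' @param model a [build_shape_model()] result.
#' @param scores coefficient vector (length <= number of modes).
#' @return 3V coordinate vector.
#' @export
reconstruct_shape <- function(model, scores) {
  k <- length(scores)
  model$mean + as.numeric(model$modes[, seq_len(k), drop = FALSE] %*% scores)
}
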