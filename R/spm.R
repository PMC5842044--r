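# Statistical parametric mapping on meshes: a general linear model fitted
# independently at every vertex of the canonical mesh, effect maps expressed
# as a percentage of the cohort mean texture, and cluster-extent significance
# testing by Freedman-Lane permutation of reduced-model residuals (the
# permutation analogue of random-field cluster inference: clusters of
# |t| above an uncorrected-p threshold are measured against the permutation
# null distribution of the maximum cluster extent).

#' Design matrix for vertex-wise texture models
#'
#' Builds an intercept-plus-covariates design, e.g. `1 + Gender + S1 + S2 +
#' S3`. Group factors should be supplied already coded (+1/-1).
#'
#' @param ... named numeric regressors of equal length.
#' @return matrix of class `design_matrix` with an `(Intercept)` first
#'   column.
#' @export
design_matrix <- function(...) {
  args <- list(...)
  if (is.null(names(args)) || any(names(args) == ""))
    stop("all regressors must be named")
  X <- cbind(`(Intercept)` = 1, do.call(cbind, args))
  colnames(X) <- c("(Intercept)", names(args))
  class(X) <- c("design_matrix", class(X))
  X
}

#' Fit a vertex-wise general linear model
#'
#' Ordinary least squares of the registered textures on the design,
#' independently at each vertex: `y_j = beta_0j + sum_i beta_ij x_i + eps_j`.
#' Residuals are orthogonal to every design column and fitted + residual
#' reconstructs the data exactly.
#'
#' @param textures n x V matrix (specimens by vertices) of registered
#'   textures.
#' @param design n x p design matrix with an intercept first column (see
#'   [design_matrix()]).
#' @return object of class `mesh_glm`: `coefficients` (p x V), `t` (p x V
#'   per-coefficient t statistics), `se`, `sigma2` (residual variance per
#'   vertex), `df`, `residuals`, `fitted`, `design`.
#' @export
fit_glm <- function(textures, design) {
  Y <- as.matrix(textures)
  X <- as.matrix(design)
  n <- nrow(Y); p <- ncol(X)
  if (nrow(X) != n) stop("design and texture matrix disagree on n")
  if (n <= p) stop("need more specimens than design columns")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(sprintf("design matrix is rank deficient (collinear: %s)",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrX, Y)
  fitted <- X %*% beta
  res <- Y - fitted
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  tstat <- beta / se
  tstat[se == 0] <- 0   # zero-variance vertices carry no evidence
  rownames(beta) <- rownames(tstat) <- rownames(se) <- colnames(X)
  structure(list(coefficients = beta, t = tstat, se = se, sigma2 = sigma2,
                 df = df, residuals = res, fitted = fitted, design = X),
            class = "mesh_glm")
}

#' @export
print.mesh_glm <- function(x, ...) {
  cat(sprintf("mesh_glm: %d specimens, %d vertices, %d regressors (df = %d)\n",
              nrow(x$design), ncol(x$coefficients), nrow(x$coefficients), x$df))
  invisible(x)
}

#' Effect map in percent of the mean texture
#'
#' Converts a fitted coefficient into the map the field reports: the
#' percentage change in texture per unit (or per standard deviation) of a
#' regressor, relative to the cohort mean texture at each vertex. For a
#' +1/-1 coded group, use `unit = 2` to express the between-group difference
#' (e.g. male versus female).
#'
#' @param glm a [fit_glm()] result.
#' @param regressor design column name.
#' @param mean_texture per-vertex cohort mean texture (positive).
#' @param scale `"per-unit"` or `"per-SD"` (sample SD of the regressor).
#' @param unit contrast size in regressor units for `"per-unit"` scaling.
#' @return per-vertex percentage effect vector.
#' @export
effect_map <- function(glm, regressor, mean_texture,
                       scale = c("per-unit", "per-SD"), unit = 1) {
  scale <- match.arg(scale)
  if (!regressor %in% rownames(glm$coefficients))
    stop(sprintf("no regressor named '%s'", regressor))
  if (any(mean_texture <= 0)) stop("mean texture must be positive")
  beta <- glm$coefficients[regressor, ]
  mult <- if (scale == "per-SD") sd(glm$design[, regressor]) else unit
  100 * beta * mult / mean_texture
}

# connected components of a vertex subset on the mesh edge graph
mesh_clusters <- function(mesh, members) {
  if (!any(members)) return(integer(0))
  ids <- which(members)
  f <- mesh$faces
  keep <- members[f[, 1]] | members[f[, 2]] | members[f[, 3]]
  e <- rbind(f[keep, c(1, 2), drop = FALSE], f[keep, c(2, 3), drop = FALSE],
             f[keep, c(3, 1), drop = FALSE])
  e <- e[members[e[, 1]] & members[e[, 2]], , drop = FALSE]
  out <- integer(nrow(mesh$vertices))
  if (nrow(e) == 0L) {           # isolated member vertices only
    out[ids] <- seq_along(ids)
    return(out)
  }
  idx <- match(e, ids)
  g <- igraph::graph_from_edgelist(matrix(idx, ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out[ids] <- comp
  out
}

# largest supra-threshold cluster extent of a |t| map
.max_cluster_extent <- function(mesh, tstat, thr) {
  members <- abs(tstat) > thr
  if (!any(members)) return(0L)
  cl <- mesh_clusters(mesh, members)
  max(tabulate(cl[cl > 0L]))
}

#' Cluster-extent significance by permutation
#'
#' Two-sided cluster-extent inference for one regressor: vertices with |t|
#' above the cluster-defining threshold (uncorrected p < `cluster_p`) are
#' grouped into connected clusters on the mesh edge graph, and each cluster's
#' extent is referred to the permutation null distribution of the *maximum*
#' cluster extent, built by Freedman-Lane permutation of reduced-model
#' residuals. Clusters with familywise-corrected p below `alpha` form the
#' significance mask.
#'
#' @param glm a [fit_glm()] result.
#' @param contrast design column to test.
#' @param mesh the canonical [triangle_mesh()] (defines vertex adjacency).
#' @param cluster_p uncorrected cluster-defining p threshold (default 0.001).
#' @param alpha familywise significance level (default 0.05).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed for the permutations.
#' @return object of class `effect_mask`: logical `mask`, `clusters`
#'   (data frame id, size, p_corrected), `t` (observed t map), `t_threshold`,
#'   `labels` (per-vertex cluster id, 0 outside).
#' @export
cluster_inference <- function(glm, contrast, mesh, cluster_p = 0.001,
                              alpha = 0.05, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("use at least 100 permutations")
  if (!contrast %in% rownames(glm$coefficients))
    stop(sprintf("no regressor named '%s'", contrast))
  thr <- qt(1 - cluster_p / 2, glm$df)
  tobs <- glm$t[contrast, ]
  members <- abs(tobs) > thr & is.finite(tobs)
  labels <- mesh_clusters(mesh, members)
  sizes <- if (any(members)) tabulate(labels[labels > 0L]) else integer(0)

  X <- glm$design
  j <- match(contrast, colnames(X))
  Xr <- X[, -j, drop = FALSE]
  qr_r <- qr(Xr)
  fit_r <- qr.fitted(qr_r, glm$residuals + glm$fitted)
  res_r <- (glm$residuals + glm$fitted) - fit_r
  n <- nrow(X)
  # precompute pieces of the full-model t statistic for permuted data
  qrX <- qr(X)
  xtx_inv_jj <- chol2inv(qr.R(qrX))[j, j]
  df <- glm$df
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    Yb <- fit_r + res_r[sample.int(n), , drop = FALSE]
    beta_b <- qr.coef(qrX, Yb)
    res_b <- Yb - X %*% beta_b
    s2 <- colSums(res_b^2) / df
    tb <- beta_b[j, ] / sqrt(xtx_inv_jj * s2)
    tb[!is.finite(tb)] <- 0
    null_max[b] <- .max_cluster_extent(mesh, tb, thr)
  }
  p_corr <- vapply(sizes, function(sz)
    (1 + sum(null_max >= sz)) / (n_perm + 1), numeric(1))
  signif_ids <- which(p_corr < alpha)
  mask <- labels > 0L & labels %in% signif_ids
  clusters <- data.frame(id = seq_along(sizes), size = sizes,
                         p_corrected = p_corr)
  structure(list(mask = mask, clusters = clusters, t = tobs,
                 t_threshold = thr, labels = labels, alpha = alpha,
                 n_perm = n_perm),
            class = "effect_mask")
}

#' @export
print.effect_mask <- function(x, ...) {
  sig <- sum(x$clusters$p_corrected < x$alpha)
  cat(sprintf("effect_mask: %d cluster(s), %d significant at alpha = %g; %d masked vertices\n",
              nrow(x$clusters), sig, x$alpha, sum(x$mask)))
  invisible(x)
}

#' Classify the polarity of a masked effect over a region
#'
#' A significant region whose masked effects all share one sign is
#' "monopolar"; a mix of signs is "bipolar" — the signature of tangential
#' (sliding) misregistration along a textured feature.
#'
#' @param effect per-vertex effect values (e.g. from [effect_map()]).
#' @param mask logical significance mask (e.g. from [cluster_inference()]).
#' @param region vertex indices of the region to examine.
#' @return one of `"none"`, `"monopolar_positive"`, `"monopolar_negative"`,
#'   `"bipolar"`.
#' @export
classify_polarity <- function(effect, mask, region) {
  if (length(region) == 0) stop("empty region")
  vals <- effect[region][mask[region]]
  vals <- vals[vals != 0]
  if (length(vals) == 0) return("none")
  if (all(vals > 0)) return("monopolar_positive")
  if (all(vals < 0)) return("monopolar_negative")
  "bipolar"
}
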