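# Multivariate conventions shared across the analyses: unit-variance PCA
# with iterative SVD imputation, bivariate-normal prediction ellipses, and
# correlation-distance / average-linkage hierarchical clustering.

scale_rows <- function(x, drop_zero_var = TRUE) {
  rv <- apply(x, 1, stats::var, na.rm = TRUE)
  zero <- !is.finite(rv) | rv < 1e-24
  if (any(zero)) {
    if (!drop_zero_var) stopf("zero-variance row(s): %s",
                              paste(rownames(x)[zero], collapse = ", "))
    warnf("dropping %d zero-variance row(s)", sum(zero))
    x <- x[!zero, , drop = FALSE]
  }
  t(scale(t(x)))
}

#' Unit-variance PCA with iterative SVD imputation
#'
#' Rows (features) are centred and scaled to unit variance; missing entries
#' are filled by iterative low-rank SVD imputation (rank
#' `min(rank, dims - 1)`, relative tolerance `tol`); principal components
#' are then obtained from the SVD of the completed, scaled matrix.
#' Observation scores are orthogonal across components and explained
#' variance fractions sum to at most 1.
#'
#' @param x numeric matrix, features in rows, observations in columns
#'   (missing values as NA).
#' @param n_components number of components to return.
#' @param rank imputation rank (default 5, capped at dims - 1).
#' @param tol relative convergence tolerance of the imputation.
#' @param max_iter imputation iteration cap.
#' @return a `uv_pca`: list with `scores` (observations x components),
#'   `loadings` (features x components), `explained_variance` (fractions),
#'   `imputed` (logical matrix of filled cells), `iterations`.
#' @export
pca_unit_variance <- function(x, n_components = 2, rank = 5,
                              tol = 1e-6, max_iter = 500) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stopf("need at least 2 observations (columns)")
  xs <- scale_rows(x)
  miss <- is.na(xs)
  iterations <- 0L
  if (any(miss)) {
    r <- min(rank, nrow(xs) - 1, ncol(xs) - 1)
    if (r < 1) stopf("matrix too small for SVD imputation")
    filled <- xs
    filled[miss] <- 0
    repeat {
      iterations <- iterations + 1L
      sv <- svd(filled, nu = r, nv = r)
      recon <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
      new <- filled
      new[miss] <- recon[miss]
      delta <- sqrt(sum((new - filled)^2)) / max(sqrt(sum(filled^2)), 1e-12)
      filled <- new
      if (delta < tol || iterations >= max_iter) break
    }
    xs <- filled
  }
  k <- min(n_components, nrow(xs) - 1, ncol(xs) - 1)
  sv <- svd(xs)
  ev <- sv$d^2 / sum(sv$d^2)
  scores <- sv$v[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(k)))
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(rownames(xs), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(k)],
                 imputed = miss, iterations = iterations),
            class = "uv_pca")
}

#' @export
print.uv_pca <- function(x, ...) {
  cat(sprintf("<uv_pca> %d observations, %d components (%s explained)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  if (any(x$imputed)) {
    cat(sprintf("  %d missing cells imputed in %d SVD iterations\n",
                sum(x$imputed), x$iterations))
  }
  invisible(x)
}

#' Bivariate-normal prediction ellipse for a group of scores
#'
#' The prediction (not confidence) ellipse: with the stated probability, a
#' new observation from the same group falls inside it. The radius uses the
#' small-sample F-based factor
#' \eqn{r^2 = 2 (n+1)(n-1) / (n (n-2)) \; F_{coverage; 2, n-2}} applied to
#' the sample mean and covariance.
#'
#' @param group_scores numeric matrix/data.frame with >= 3 rows and 2
#'   columns (e.g. PC1/PC2 scores of one group).
#' @param coverage prediction coverage (default 0.95).
#' @return a `prediction_ellipse`: list with `center`, `cov`, `radius2`,
#'   `axes` (semi-axis lengths, major first), `angle_deg` (major-axis
#'   direction), `coverage`, `degenerate` (TRUE when the covariance is
#'   singular).
#' @export
prediction_ellipse <- function(group_scores, coverage = 0.95) {
  s <- as.matrix(group_scores)
  if (ncol(s) != 2) stopf("`group_scores` must have exactly 2 columns")
  n <- nrow(s)
  if (n < 3) stopf("need >= 3 observations for a prediction ellipse")
  check_scalar(coverage, "coverage", lower = 1e-6, upper = 1 - 1e-9)
  center <- colMeans(s)
  S <- stats::cov(s)
  radius2 <- 2 * (n + 1) * (n - 1) / (n * (n - 2)) *
    stats::qf(coverage, 2, n - 2)
  eig <- eigen(S, symmetric = TRUE)
  degenerate <- eig$values[2] <= 1e-12 * max(eig$values[1], 1e-300)
  axes <- sqrt(pmax(eig$values, 0) * radius2)
  angle <- atan2(eig$vectors[2, 1], eig$vectors[1, 1]) * 180 / pi
  structure(list(center = center, cov = S, radius2 = radius2,
                 axes = axes, angle_deg = wrap_axial(angle),
                 coverage = coverage, degenerate = degenerate),
            class = "prediction_ellipse")
}

#' Is a point inside a prediction ellipse?
#'
#' @param ellipse a [prediction_ellipse()].
#' @param points matrix/data.frame of 2D points (rows).
#' @return logical vector: squared Mahalanobis distance <= ellipse radius.
#' @export
in_ellipse <- function(ellipse, points) {
  stopifnot(inherits(ellipse, "prediction_ellipse"))
  p <- as.matrix(points)
  stats::mahalanobis(p, ellipse$center, ellipse$cov) <= ellipse$radius2
}

#' Boundary points of a prediction ellipse (for plotting)
#'
#' @param ellipse a [prediction_ellipse()].
#' @param n number of boundary points.
#' @return n x 2 matrix tracing the ellipse.
#' @export
ellipse_points <- function(ellipse, n = 180) {
  stopifnot(inherits(ellipse, "prediction_ellipse"))
  theta <- seq(0, 2 * pi, length.out = n)
  eig <- eigen(ellipse$cov, symmetric = TRUE)
  circ <- rbind(ellipse$axes[1] * cos(theta), ellipse$axes[2] * sin(theta))
  pts <- t(eig$vectors %*% circ) +
    matrix(ellipse$center, n, 2, byrow = TRUE)
  colnames(pts) <- names(ellipse$center)
  pts
}

#' Correlation-distance, average-linkage hierarchical clustering
#'
#' Rows are centred and unit-variance scaled (zero-variance rows dropped
#' with a warning); pairwise distance is `1 - Pearson correlation`; the
#' merge tree uses average linkage (UPGMA). Columns are clustered the same
#' way on the scaled matrix. Inputs are ordered lexicographically by label
#' before clustering so leaf order is deterministic under ties.
#'
#' @param x numeric matrix with row and column names.
#' @param cluster_cols also cluster columns (default TRUE).
#' @return a `cluster_result`: list with `row_order`, `col_order` (label
#'   permutations), `row_hclust`, `col_hclust`, and the scaled matrix
#'   `scaled`.
#' @export
hierarchical_cluster <- function(x, cluster_cols = TRUE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("r%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("c%03d", seq_len(ncol(x)))
  x <- x[order(rownames(x)), order(colnames(x)), drop = FALSE]
  xs <- scale_rows(x)
  if (nrow(xs) < 2) stopf("need >= 2 rows after dropping degenerate ones")
  d_row <- stats::as.dist(1 - stats::cor(t(xs)))
  hr <- stats::hclust(d_row, method = "average")
  out <- list(row_order = rownames(xs)[hr$order], row_hclust = hr,
              scaled = xs)
  if (cluster_cols) {
    if (ncol(xs) < 2) stopf("need >= 2 columns to cluster columns")
    d_col <- stats::as.dist(1 - stats::cor(xs))
    hc <- stats::hclust(d_col, method = "average")
    out$col_order <- colnames(xs)[hc$order]
    out$col_hclust <- hc
  }
  structure(out, class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d rows%s, correlation distance, average linkage\n",
              length(x$row_order),
              if (!is.null(x$col_order)) {
                sprintf(", %d columns", length(x$col_order))
              } else ""))
  invisible(x)
}
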