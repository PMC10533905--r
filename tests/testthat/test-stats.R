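# Shared statistics: PCA with SVD imputation, prediction ellipses,
# clustering, Spearman, ANOVA/Tukey, normality gate.

test_that("unit-variance PCA hits its exact special cases", {
  # perfectly collinear data after scaling: PC1 explains everything
  obs <- seq(-2, 2, length.out = 6)
  x <- rbind(a = obs, b = 3 * obs + 1, c = -2 * obs + 5)
  p <- pca_unit_variance(x, n_components = 2)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  # no missing values: imputation is a no-op, scores orthogonal
  set.seed(2)
  y <- matrix(rnorm(8 * 10), 8)
  rownames(y) <- letters[1:8]
  p2 <- pca_unit_variance(y, n_components = 3)
  expect_equal(p2$iterations, 0)
  g <- crossprod(p2$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-9)
  expect_lte(sum(p2$explained_variance), 1)
  # row reordering leaves scores unchanged up to sign
  p3 <- pca_unit_variance(y[sample(8), ], n_components = 3)
  for (k in 1:3) {
    expect_equal(abs(p3$scores[, k]), abs(p2$scores[, k]), tolerance = 1e-9)
  }
  # zero-variance rows are dropped with a warning
  y2 <- rbind(y, flat = rep(1, 10))
  expect_warning(pca_unit_variance(y2), "zero-variance")
})

test_that("SVD imputation reconstructs a low-rank matrix", {
  set.seed(4)
  u <- matrix(rnorm(30 * 2), 30); v <- matrix(rnorm(12 * 2), 12)
  x <- u %*% t(v) + matrix(rnorm(30 * 12, 0, 0.01), 30)
  rownames(x) <- sprintf("f%02d", 1:30)
  miss <- matrix(runif(30 * 12) < 0.1, 30)
  xm <- x; xm[miss] <- NA
  p <- pca_unit_variance(xm, n_components = 2, rank = 2)
  expect_equal(dim(p$loadings), c(30L, 2L))
  expect_gt(p$iterations, 0)
  # rank-2 structure: two components carry almost all variance
  expect_gt(sum(p$explained_variance), 0.95)
})

test_that("prediction ellipses cover ~95% of new draws and are equivariant", {
  set.seed(6)
  mu <- c(1, -2)
  A <- matrix(c(2, 0.8, 0.8, 1), 2)
  train <- MASS::mvrnorm(200, mu, A)
  ell <- prediction_ellipse(train)
  fresh <- MASS::mvrnorm(4000, mu, A)
  cover <- mean(in_ellipse(ell, fresh))
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / 4000) + 0.01)
  # isotropic data: near-equal axes
  iso <- MASS::mvrnorm(2000, c(0, 0), diag(2))
  ei <- prediction_ellipse(iso)
  expect_lt(abs(ei$axes[1] / ei$axes[2] - 1), 0.1)
  # rotating the data rotates the ellipse angle identically
  th <- 35 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  er <- prediction_ellipse(train %*% t(R))
  expect_lt(abs(wrap_diff(er$angle_deg, ell$angle_deg + 35)), 2)
  # boundary points lie exactly on the Mahalanobis shell
  pts <- ellipse_points(ell, 50)
  d2 <- mahalanobis(pts, ell$center, ell$cov)
  expect_equal(d2, rep(ell$radius2, 50), tolerance = 1e-9)
  expect_error(prediction_ellipse(train[1:2, ]), ">= 3")
})

test_that("hierarchical clustering follows correlation distance + UPGMA", {
  set.seed(8)
  x <- matrix(rnorm(6 * 10), 6)
  rownames(x) <- sprintf("r%d", 1:6)
  colnames(x) <- sprintf("c%02d", 1:10)
  cl <- hierarchical_cluster(x)
  expect_setequal(cl$row_order, rownames(x))
  expect_setequal(cl$col_order, colnames(x))
  # identical rows merge first at height 0
  x2 <- x; x2[2, ] <- x2[1, ] * 2 + 3  # perfectly correlated
  cl2 <- hierarchical_cluster(x2)
  expect_lt(cl2$row_hclust$height[1], 1e-12)
  first_pair <- abs(cl2$row_hclust$merge[1, ])
  expect_setequal(rownames(x2)[sort(first_pair)], c("r1", "r2"))
  # merge heights equal the brute-force UPGMA oracle
  for (rep in 1:10) {
    y <- matrix(rnorm(6 * 8), 6)
    rownames(y) <- sprintf("r%d", 1:6); colnames(y) <- sprintf("c%d", 1:8)
    cy <- hierarchical_cluster(y, cluster_cols = FALSE)
    ys <- t(scale(t(y)))
    expect_equal(sort(cy$row_hclust$height),
                 oracle_upgma_heights(1 - cor(t(ys))),
                 tolerance = 1e-9)
  }
  # anti-correlated rows sit at distance 2 and merge last among three
  z <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8.5), c = c(4, 3, 2, 1))
  colnames(z) <- sprintf("c%d", 1:4)
  cz <- hierarchical_cluster(z, cluster_cols = FALSE)
  expect_equal(max(cz$row_hclust$height), 2, tolerance = 0.05)
  expect_error(hierarchical_cluster(z[1, , drop = FALSE]), ">= 2 rows")
})

test_that("Spearman matches full enumeration and is monotone invariant", {
  s <- spearman_cor(1:6, (1:6)^3)
  expect_equal(s$rho, 1)
  expect_equal(s$method, "exact")
  sd_ <- spearman_cor(1:6, -(1:6))
  expect_equal(sd_$rho, -1)
  # tied 6-point example against a full 720-permutation oracle
  x <- c(1, 2, 2, 3, 4, 5); y <- c(2.5, 1, 4, 4, 3, 6)
  s2 <- spearman_cor(x, y)
  perms <- oracle_perms(6)
  rx <- rank(x); ry <- rank(y)
  rho_all <- apply(perms, 1, function(pm) cor(rx, ry[pm]))
  expect_equal(s2$rho, cor(rx, ry), tolerance = 1e-12)
  expect_equal(s2$p, mean(abs(rho_all) >= abs(s2$rho) - 1e-12),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms
  set.seed(10)
  a <- rnorm(30); b <- rnorm(30)
  s_ab <- spearman_cor(a, b)
  s_tr <- spearman_cor(exp(a), 2 * atan(b) + 5)
  expect_equal(s_tr$rho, s_ab$rho, tolerance = 1e-12)
  expect_equal(s_tr$p, s_ab$p, tolerance = 1e-12)
  expect_equal(s_ab$method, "t")
  # constant input: undefined flag
  expect_equal(spearman_cor(rep(1, 5), 1:5)$method, "undefined")
})

test_that("ANOVA/Tukey: identities, degeneracies, and p ordering", {
  # identical groups
  eq <- anova_tukey(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
  expect_true(all(eq$tukey$p_adj == 1))
  # two groups: F = t^2, same p
  set.seed(12)
  g1 <- rnorm(8); g2 <- rnorm(8, 0.5)
  at <- anova_tukey(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(at$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(at$p, tt$p.value, tolerance = 1e-10)
  # Tukey adjusted p >= the unadjusted pairwise p computed on the same
  # pooled error (the studentized-range adjustment can only raise it)
  g3 <- rnorm(8, 1)
  groups <- list(a = g1, b = g2, c = g3)
  at3 <- anova_tukey(groups)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (24 - 3)
  for (k in seq_len(nrow(at3$tukey))) {
    pair <- strsplit(at3$tukey$comparison[k], "-")[[1]]
    dif <- mean(groups[[pair[1]]]) - mean(groups[[pair[2]]])
    t_pool <- dif / sqrt(mse * (1 / 8 + 1 / 8))
    praw <- 2 * pt(-abs(t_pool), 24 - 3)
    expect_gte(at3$tukey$p_adj[k], praw - 1e-10)
  }
  expect_true(all(at3$tukey$p_adj >= 0 & at3$tukey$p_adj <= 1))
})

test_that("Tukey family-wise error is near 0.05 under a 4-group null", {
  set.seed(14)
  n_rep <- 600
  fwe <- mean(replicate(n_rep, {
    res <- anova_tukey(list(a = rnorm(5), b = rnorm(5), c = rnorm(5),
                            d = rnorm(5)))
    any(res$tukey$p_adj < 0.05)
  }))
  expect_lt(abs(fwe - 0.05), 2 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("the normality gate recommends sensibly and guards edge cases", {
  set.seed(16)
  para <- mean(vapply(1:100, function(i) {
    normality_gate(rnorm(200))$recommendation == "parametric"
  }, logical(1)))
  expect_gte(para, 0.9)
  skewed <- normality_gate(exp(rnorm(100, 0, 1)))
  expect_equal(skewed$recommendation, "nonparametric")
  expect_lt(skewed$p, 0.05)
  expect_equal(normality_gate(rnorm(5))$recommendation, "abstain")
  expect_error(normality_gate(rep(2, 20)), "constant")
})
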