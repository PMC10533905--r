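# Texture module: segmentation, density, GLCM, structure tensor.

test_that("segmentation handles flat, binary and synthetic images", {
  expect_warning(m <- segment_collagen(matrix(0, 16, 16)), "flat")
  expect_false(any(m))
  bin <- matrix(0, 16, 16); bin[5:8, ] <- 255
  seg <- segment_collagen(bin)
  expect_equal(seg, bin > 0, ignore_attr = TRUE)
  img <- sim_fiber_image(image_size = 128, target_coverage = 0.3, seed = 3)
  dens <- collagen_density(segment_collagen(img)) / 100
  expect_lt(abs(dens - img$truth$coverage), 0.05)
})

test_that("collagen density is the percent of tissue covered", {
  m <- matrix(FALSE, 8, 8); m[1:2, ] <- TRUE
  expect_equal(collagen_density(m), 25)
  expect_equal(collagen_density(matrix(TRUE, 4, 4)), 100)
  tissue <- matrix(c(TRUE, FALSE), 8, 8)
  expect_equal(collagen_density(m & tissue, tissue), 25)
  expect_error(collagen_density(m, matrix(FALSE, 8, 8)), "empty")
  # density from a relative (quantile) threshold is scale invariant
  img <- sim_fiber_image(image_size = 64, n_fibers = 10, seed = 4)
  d1 <- collagen_density(segment_collagen(img$pixels, "quantile"))
  d2 <- collagen_density(segment_collagen(img$pixels * 7.5, "quantile"))
  expect_equal(d1, d2)
  # random mask at known coverage
  set.seed(1)
  rm <- matrix(runif(100 * 100) < 0.4, 100)
  expect_lt(abs(collagen_density(rm) - 40), 3 * 100 * sqrt(0.4 * 0.6 / 1e4))
})

test_that("GLCM matches hand enumeration on the 2x2 case", {
  m <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  g <- compute_glcm(m, n_levels = 2, angles = 0)
  expect_equal(g$p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(sum(g$p), 1)
})

test_that("GLCM respects the tissue mask and probability axioms", {
  set.seed(7)
  px <- matrix(runif(12 * 12), 12)
  mask <- matrix(TRUE, 12, 12); mask[, 7:12] <- FALSE
  g <- compute_glcm(px, n_levels = 8, mask = mask)
  gl <- compute_glcm(px[, 1:6], n_levels = 8)
  # masking the right half must equal analysing the left half alone,
  # because pairs with either pixel out of mask are excluded
  expect_equal(g$n_pairs, gl$n_pairs)
  expect_equal(sum(g$p), 1, tolerance = 1e-12)
  expect_true(all(g$p >= 0))
  expect_lt(max(abs(g$p - t(g$p))), 1e-12)  # symmetric config
})

test_that("GLCM level-count validation rejects unrepresentable requests", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(compute_glcm(m, n_levels = 4), "representable")
})

test_that("features hit their closed-form limits", {
  g <- compute_glcm(matrix(5, 8, 8), n_levels = 16)  # constant image
  f <- glcm_features(g)
  expect_equal(f$asm, 1)
  expect_equal(f$entropy, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$idm, 1)
  expect_true(is.na(f$correlation))
  expect_false(attr(f, "correlation_defined"))
  # uniform 2-level symmetric matrix: direct evaluation of the four sums
  gu <- structure(list(p = matrix(0.25, 2, 2), mu_i = 0.5, mu_j = 0.5,
                       sd_i = 0.5, sd_j = 0.5, n_pairs = 4,
                       config = list(n_levels = 2L, distances = 1,
                                     angles = 0, symmetric = TRUE)),
                  class = "glcm")
  fu <- glcm_features(gu)
  expect_equal(fu$entropy, 2)
  expect_equal(fu$asm, 0.25)
  expect_equal(fu$contrast, 0.5)
  expect_equal(fu$idm, 0.75)
  expect_equal(fu$correlation, 0)
})

test_that("GLCM features equal the brute-force oracle on random images", {
  set.seed(123)
  for (rep in 1:25) {
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    n_levels <- sample(2:6, 1)
    px <- matrix(sample(0:(n_levels - 1), nr * nc, replace = TRUE), nr, nc)
    if (max(px) == min(px)) px[1, 1] <- px[1, 1] + 1
    angles <- sample(c(0, 45, 90, 135), sample(1:4, 1))
    sym <- sample(c(TRUE, FALSE), 1)
    g <- compute_glcm(px, n_levels = max(px) - min(px) + 1, angles = angles,
                      symmetric = sym)
    f <- glcm_features(g)
    o <- oracle_glcm(px, n_levels = max(px) - min(px) + 1, angles = angles,
                     symmetric = sym)
    expect_equal(g$p, o$p, tolerance = 1e-12)
    expect_equal(f$contrast, o$contrast, tolerance = 1e-10)
    expect_equal(f$entropy, o$entropy, tolerance = 1e-10)
    expect_equal(f$idm, o$idm, tolerance = 1e-10)
    expect_equal(f$asm, o$asm, tolerance = 1e-10)
    if (!is.na(o$correlation)) {
      expect_equal(f$correlation, o$correlation, tolerance = 1e-10)
    }
  }
})

test_that("structure tensor reads stripe orientation and is equivariant", {
  st <- structure_tensor_coherency(make_stripes(fibre_deg = 90))
  expect_gt(st$coherency, 0.95)
  expect_lt(abs(st$orientation_deg - 90), 1)
  base <- structure_tensor_coherency(make_stripes(fibre_deg = 60))
  for (rot in c(15, 30, 45)) {
    st_r <- structure_tensor_coherency(make_stripes(fibre_deg = 60 - rot))
    expect_lt(abs(wrap_diff(st_r$orientation_deg, 60 - rot)), 3)
    expect_lt(abs(st_r$coherency - base$coherency), 0.05)
  }
})

test_that("flat images give zero coherency with undefined orientation", {
  st <- structure_tensor_coherency(matrix(3, 32, 32))
  expect_equal(st$coherency, 0)
  expect_false(st$orientation_defined)
  expect_true(is.na(st$orientation_deg))
})

test_that("isotropic fields are incoherent, concentrated fields coherent", {
  coh0 <- mean(vapply(1:8, function(s) {
    img <- sim_fiber_image(image_size = 96, n_fibers = 60,
                           orientation_kappa = 0, seed = s)
    structure_tensor_coherency(img)$coherency
  }, numeric(1)))
  imgk <- sim_fiber_image(image_size = 96, n_fibers = 60,
                          orientation_kappa = 8, mean_orientation = 30,
                          seed = 1)
  cohk <- structure_tensor_coherency(imgk)$coherency
  expect_lt(coh0, 0.2)
  expect_gt(cohk, coh0 + 0.3)
})

test_that("the feature panel is reproducible and tracks the generator", {
  img <- sim_fiber_image(image_size = 96, target_coverage = 0.2, seed = 8)
  expect_identical(image_feature_panel(img), image_feature_panel(img))
  dense <- sim_fiber_image(image_size = 96, target_coverage = 0.45, seed = 8)
  expect_gt(image_feature_panel(dense)$density_pct,
            image_feature_panel(img)$density_pct)
  # coherency rises monotonically (Spearman) with orientation concentration
  kappas <- c(0, 0.5, 1, 2, 3, 4, 6, 8, 12, 16)
  coh <- vapply(seq_along(kappas), function(i) {
    im <- sim_fiber_image(image_size = 96, n_fibers = 50,
                          orientation_kappa = kappas[i],
                          mean_orientation = 20, seed = 100 + i)
    structure_tensor_coherency(im)$coherency
  }, numeric(1))
  expect_gt(spearman_cor(kappas, coh)$rho, 0.8)
})
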