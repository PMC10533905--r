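# Collagen segmentation, density, and structure-tensor coherency.

as_pixels <- function(image) {
  px <- if (inherits(image, "fibrous_image")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px) || any(!is.finite(px))) {
    stopf("image must be a finite numeric matrix or fibrous_image")
  }
  px
}

image_tissue_mask <- function(image, px) {
  m <- if (inherits(image, "fibrous_image")) image$tissue_mask else NULL
  if (is.null(m)) m <- matrix(TRUE, nrow(px), ncol(px))
  if (!identical(dim(m), dim(px))) stopf("tissue mask shape must match image")
  m
}

#' Segment collagen-positive pixels
#'
#' Thresholds the image within the tissue mask. `method = "otsu"` uses
#' Otsu's criterion on the in-mask intensities (via EBImage); `method =
#' "quantile"` uses a fixed relative quantile of the in-mask intensities,
#' which makes the resulting density invariant to global intensity
#' rescaling.
#'
#' @param image a `fibrous_image` or numeric matrix.
#' @param method `"otsu"` (default) or `"quantile"`.
#' @param quantile quantile used when `method = "quantile"`.
#' @return logical matrix of collagen-positive pixels (FALSE outside the
#'   tissue mask); attributes `threshold` and `method` record provenance.
#'   An all-flat image yields an empty mask with a warning.
#' @export
segment_collagen <- function(image, method = c("otsu", "quantile"),
                             quantile = 0.75) {
  method <- match.arg(method)
  px <- as_pixels(image)
  tissue <- image_tissue_mask(image, px)
  vals <- px[tissue]
  if (!length(vals)) stopf("tissue mask is empty")
  if (max(vals) <= min(vals)) {
    warnf("image is flat within the tissue mask; returning empty mask")
    out <- matrix(FALSE, nrow(px), ncol(px))
    return(structure(out, threshold = Inf, method = method))
  }
  if (method == "otsu") {
    rng <- range(vals)
    scaled <- (vals - rng[1]) / (rng[2] - rng[1])
    thr01 <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)),
                           range = c(0, 1), levels = 256)
    threshold <- rng[1] + thr01 * (rng[2] - rng[1])
  } else {
    threshold <- stats::quantile(vals, quantile, names = FALSE)
  }
  out <- px > threshold & tissue
  structure(out, threshold = threshold, method = method)
}

#' Collagen density: percent of tissue covered
#'
#' `100 * |mask AND tissue| / |tissue|`.
#'
#' @param mask logical matrix of collagen-positive pixels.
#' @param tissue_mask optional logical tissue mask (default: whole frame).
#' @return density in percent.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, ] <- TRUE
#' collagen_density(m)  # 25
#' @export
collagen_density <- function(mask, tissue_mask = NULL) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stopf("`mask` must be a logical matrix")
  }
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, nrow(mask), ncol(mask))
  if (!identical(dim(tissue_mask), dim(mask))) {
    stopf("`tissue_mask` shape must match `mask`")
  }
  n_tissue <- sum(tissue_mask)
  if (n_tissue == 0) stopf("tissue mask is empty")
  100 * sum(mask & tissue_mask) / n_tissue
}

#' Structure-tensor coherency and dominant fibre orientation
#'
#' The image is smoothed with a Gaussian of sd `gradient_sigma`, gradients
#' are taken by central differences, and the structure tensor
#' \eqn{J = [<f_x^2>, <f_x f_y>; <f_x f_y>, <f_y^2>]} is averaged over the
#' tissue mask (optionally with an additional Gaussian window of sd
#' `window_sigma` before averaging). Coherency is the normalised tensor
#' anisotropy \eqn{(\lambda_{max}-\lambda_{min}) /
#' (\lambda_{max}+\lambda_{min})} in [0, 1]. The dominant fibre direction is
#' perpendicular to the dominant gradient direction and is reported in
#' degrees from the image x-axis (columns), y pointing down, in (-90, 90].
#'
#' @param image a `fibrous_image` or numeric matrix.
#' @param gradient_sigma Gaussian sd (pixels) applied before
#'   differentiation.
#' @param window_sigma optional Gaussian sd (pixels) applied to the tensor
#'   component maps before mask-averaging; `NULL` for plain averaging.
#' @param mask optional logical tissue mask.
#' @return list with `coherency`, `orientation_deg`, and
#'   `orientation_defined` (FALSE for a flat image, where coherency is 0 by
#'   convention and orientation is NA).
#' @examples
#' stripes <- matrix(rep(c(0, 0, 255, 255), 16), 32, 64)[, 1:32]
#' @export
structure_tensor_coherency <- function(image, gradient_sigma = 1,
                                       window_sigma = NULL, mask = NULL) {
  px <- as_pixels(image)
  if (min(dim(px)) < 8) stopf("image smaller than the smoothing kernels")
  if (is.null(mask)) mask <- image_tissue_mask(image, px)
  if (gradient_sigma > 0) {
    px <- EBImage::gblur(px, sigma = gradient_sigma)
  }
  nr <- nrow(px); nc <- ncol(px)
  # x = column index, y = row index (down); central differences
  fx <- matrix(0, nr, nc)
  fy <- matrix(0, nr, nc)
  fx[, 2:(nc - 1)] <- (px[, 3:nc] - px[, 1:(nc - 2)]) / 2
  fy[2:(nr - 1), ] <- (px[3:nr, ] - px[1:(nr - 2), ]) / 2
  jxx <- fx * fx; jyy <- fy * fy; jxy <- fx * fy
  if (!is.null(window_sigma) && window_sigma > 0) {
    jxx <- EBImage::gblur(jxx, sigma = window_sigma)
    jyy <- EBImage::gblur(jyy, sigma = window_sigma)
    jxy <- EBImage::gblur(jxy, sigma = window_sigma)
  }
  # drop the one-pixel border where the differences are one-sided
  inner <- mask
  inner[c(1, nr), ] <- FALSE
  inner[, c(1, nc)] <- FALSE
  Jxx <- mean(jxx[inner]); Jyy <- mean(jyy[inner]); Jxy <- mean(jxy[inner])
  trace <- Jxx + Jyy
  if (!is.finite(trace) || trace <= .Machine$double.eps) {
    return(list(coherency = 0, orientation_deg = NA_real_,
                orientation_defined = FALSE))
  }
  coherency <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / trace
  grad_deg <- 0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi
  list(coherency = min(coherency, 1),
       orientation_deg = wrap_axial(grad_deg + 90),
       orientation_defined = TRUE)
}

#' One-row texture feature panel for an image
#'
#' Combines collagen density, mean in-tissue intensity, the five GLCM
#' features and the structure-tensor coherency/orientation into a single
#' data.frame row, with provenance columns recording the configuration, as
#' input for region-level PCA and correlation analyses.
#'
#' @param image a `fibrous_image` or numeric matrix.
#' @param n_levels,distances,angles,symmetric passed to [compute_glcm()].
#' @param gradient_sigma,window_sigma passed to
#'   [structure_tensor_coherency()].
#' @param threshold_method passed to [segment_collagen()].
#' @return one-row data.frame with columns `density_pct`, `mean_intensity`,
#'   `contrast`, `entropy`, `correlation`, `idm`, `asm`, `coherency`,
#'   `orientation_deg` plus provenance columns.
#' @export
image_feature_panel <- function(image, n_levels = 64, distances = 1,
                                angles = c(0, 45, 90, 135), symmetric = TRUE,
                                gradient_sigma = 1, window_sigma = NULL,
                                threshold_method = c("otsu", "quantile")) {
  threshold_method <- match.arg(threshold_method)
  px <- as_pixels(image)
  tissue <- image_tissue_mask(image, px)
  seg <- segment_collagen(image, method = threshold_method)
  dens <- collagen_density(seg, tissue)
  g <- compute_glcm(image, n_levels = n_levels, distances = distances,
                    angles = angles, symmetric = symmetric, mask = tissue)
  feats <- glcm_features(g)
  st <- structure_tensor_coherency(image, gradient_sigma = gradient_sigma,
                                   window_sigma = window_sigma, mask = tissue)
  data.frame(density_pct = dens,
             mean_intensity = mean(px[tissue]),
             contrast = feats$contrast, entropy = feats$entropy,
             correlation = feats$correlation, idm = feats$idm,
             asm = feats$asm,
             coherency = st$coherency,
             orientation_deg = st$orientation_deg,
             threshold_method = threshold_method,
             glcm_levels = n_levels,
             glcm_distances = paste(distances, collapse = ";"),
             glcm_angles = paste(angles, collapse = ";"),
             entropy_base = 2,
             stringsAsFactors = FALSE)
}
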