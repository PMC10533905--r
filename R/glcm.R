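# Grey-level co-occurrence matrices and Haralick-style texture features.
#
# Conventions: quantization is min-max within the tissue mask to `n_levels`
# grey levels; offsets default to distance 1 at 0/45/90/135 degrees,
# symmetrised and averaged over directions; pixel pairs with either member
# outside the tissue mask are excluded (not zero-coded). Entropy is in bits.

glcm_offset <- function(distance, angle) {
  # standard GLCM direction convention (image rows increase downwards):
  # 0 deg -> (0, +d); 45 -> (-d, +d); 90 -> (-d, 0); 135 -> (-d, -d)
  a <- angle %% 180
  if (a == 0) c(0L, distance)
  else if (a == 45) c(-distance, distance)
  else if (a == 90) c(-distance, 0L)
  else if (a == 135) c(-distance, -distance)
  else stopf("unsupported GLCM angle %s (use 0, 45, 90, 135)", angle)
}

#' Compute a grey-level co-occurrence matrix
#'
#' Intensities are quantized min-max within the tissue mask to `n_levels`
#' levels; co-occurrence counts are accumulated over every configured
#' (distance, angle) offset, optionally symmetrised, then normalised to
#' joint probabilities p(i, j). Pairs with either pixel outside the tissue
#' mask are excluded from the counts.
#'
#' @param image a `fibrous_image` or numeric matrix.
#' @param n_levels grey levels after quantization (>= 2).
#' @param distances integer pixel offsets (>= 1).
#' @param angles directions in degrees, drawn from 0, 45, 90, 135.
#' @param symmetric count each pair in both orders (default TRUE).
#' @param mask optional logical matrix restricting the analysis; defaults to
#'   the image's `tissue_mask` or the whole frame.
#' @return a `glcm` object: list with `p` (n_levels x n_levels probability
#'   matrix), marginal means/sds `mu_i`, `mu_j`, `sd_i`, `sd_j`, `n_pairs`
#'   and the configuration used.
#' @examples
#' m <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
#' g <- compute_glcm(m, n_levels = 2, angles = 0)
#' g$p
#' @export
compute_glcm <- function(image, n_levels = 64, distances = 1,
                         angles = c(0, 45, 90, 135), symmetric = TRUE,
                         mask = NULL) {
  px <- if (inherits(image, "fibrous_image")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px) || any(!is.finite(px))) {
    stopf("image must be a finite numeric matrix")
  }
  if (is.null(mask) && inherits(image, "fibrous_image")) {
    mask <- image$tissue_mask
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  if (!identical(dim(mask), dim(px))) stopf("mask shape must match image")
  if (!is_scalar_num(n_levels) || n_levels < 2 ||
      n_levels != round(n_levels)) {
    stopf("`n_levels` must be an integer >= 2")
  }
  if (any(distances < 1)) stopf("`distances` must be >= 1")

  vals <- px[mask]
  if (!length(vals)) stopf("tissue mask is empty")
  lo <- min(vals); hi <- max(vals)
  if (hi > lo) {
    # integer-valued images can represent at most range+1 distinct levels
    if (all(vals == round(vals)) && n_levels > hi - lo + 1) {
      stopf("n_levels = %d exceeds the %d representable levels of this image",
            n_levels, as.integer(hi - lo + 1))
    }
    quant <- pmin(floor((px - lo) / (hi - lo) * n_levels), n_levels - 1)
  } else {
    quant <- matrix(0, nrow(px), ncol(px))  # constant image: single level
  }
  n_levels <- as.integer(n_levels)

  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(px); nc <- ncol(px)
  for (d in distances) {
    for (a in angles) {
      off <- glcm_offset(as.integer(d), a)
      dr <- off[1]; dc <- off[2]
      r1 <- max(1, 1 - dr):min(nr, nr - dr)
      c1 <- max(1, 1 - dc):min(nc, nc - dc)
      if (!length(r1) || !length(c1)) next
      ok <- mask[r1, c1, drop = FALSE] &
        mask[r1 + dr, c1 + dc, drop = FALSE]
      i <- quant[r1, c1, drop = FALSE][ok]
      j <- quant[r1 + dr, c1 + dc, drop = FALSE][ok]
      if (!length(i)) next
      tab <- tabulate(i * n_levels + j + 1, nbins = n_levels^2)
      counts <- counts + matrix(tab, n_levels, n_levels, byrow = TRUE)
    }
  }
  if (symmetric) counts <- counts + t(counts)
  n_pairs <- sum(counts)
  if (n_pairs == 0) stopf("no in-mask pixel pairs at the requested offsets")
  p <- counts / n_pairs

  lev <- seq_len(n_levels) - 1
  p_i <- rowSums(p); p_j <- colSums(p)
  mu_i <- sum(lev * p_i); mu_j <- sum(lev * p_j)
  structure(list(p = p,
                 mu_i = mu_i, mu_j = mu_j,
                 sd_i = sqrt(sum((lev - mu_i)^2 * p_i)),
                 sd_j = sqrt(sum((lev - mu_j)^2 * p_j)),
                 n_pairs = n_pairs,
                 config = list(n_levels = n_levels, distances = distances,
                               angles = angles, symmetric = symmetric)),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d levels, distances {%s}, angles {%s}, %s, %d pairs\n",
              x$config$n_levels,
              paste(x$config$distances, collapse = ","),
              paste(x$config$angles, collapse = ","),
              if (x$config$symmetric) "symmetric" else "asymmetric",
              x$n_pairs))
  invisible(x)
}

#' Haralick-style features of a co-occurrence matrix
#'
#' The five second-order statistics used for collagen texture scoring:
#' \describe{
#'   \item{contrast}{\eqn{\sum (i-j)^2 p(i,j)}}
#'   \item{entropy}{\eqn{-\sum p \log_2 p} over p > 0, in bits}
#'   \item{correlation}{\eqn{\sum (i-\mu_i)(j-\mu_j) p / (\sigma_i \sigma_j)};
#'     `NA` with attribute `correlation_defined = FALSE` when either marginal
#'     sd is zero (e.g. a constant image)}
#'   \item{idm}{inverse difference moment \eqn{\sum p / (1 + (i-j)^2)}}
#'   \item{asm}{angular second moment \eqn{\sum p^2}}
#' }
#'
#' @param glcm a `glcm` from [compute_glcm()].
#' @return named list with `contrast`, `entropy`, `correlation`, `idm`,
#'   `asm`; attribute `correlation_defined` flags degenerate marginals.
#' @export
glcm_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  p <- glcm$p
  n <- nrow(p)
  lev <- seq_len(n) - 1
  i <- matrix(lev, n, n)        # row level index
  j <- t(i)
  contrast <- sum((i - j)^2 * p)
  pp <- p[p > 0]
  entropy <- -sum(pp * log2(pp))
  idm <- sum(p / (1 + (i - j)^2))
  asm <- sum(p^2)
  denom <- glcm$sd_i * glcm$sd_j
  if (denom > 0) {
    correlation <- sum((i - glcm$mu_i) * (j - glcm$mu_j) * p) / denom
    defined <- TRUE
  } else {
    correlation <- NA_real_
    defined <- FALSE
  }
  structure(list(contrast = contrast, entropy = entropy,
                 correlation = correlation, idm = idm, asm = asm),
            correlation_defined = defined)
}
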