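# Synthetic fibrous-image generator: anti-aliased straight fibres with
# von Mises-distributed orientations over a noisy background, with exact
# ground-truth coverage. Emulates the statistical structure of SHG collagen
# images (aligned vs isotropic fibre fields at controlled density).

#' Sample axial fibre orientations from a von Mises distribution
#'
#' Orientations are axial (period 180 degrees): a sample is drawn from a
#' von Mises distribution on the doubled angle and halved, the standard
#' construction for axial data. `kappa = 0` gives isotropic orientations.
#'
#' @param n number of samples.
#' @param mean_deg mean orientation in degrees, in (-90, 90].
#' @param kappa concentration parameter, >= 0.
#' @return numeric vector of orientations in degrees, wrapped to (-90, 90].
#' @examples
#' with_axial <- rvonmises_axial(5, mean_deg = 30, kappa = 8)
#' @export
rvonmises_axial <- function(n, mean_deg, kappa) {
  check_scalar(kappa, "kappa", lower = 0)
  mu2 <- 2 * mean_deg * pi / 180
  th2 <- rvonmises(n, mu2, kappa)
  wrap_axial(th2 / 2 * 180 / pi)
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution on
# (-pi, pi]. Reduces to uniform sampling at very small kappa.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) {
    return (((runif(n, -pi, pi) + mu + pi) %% (2 * pi)) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        out[i] <- mu + sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

#' Generate a synthetic fibrous image with known ground truth
#'
#' Renders `n_fibers` anti-aliased straight fibres (chords through the field)
#' whose orientations follow a von Mises distribution, over Gaussian
#' background noise. Fibre intensity is additive with clipping at
#' `fiber_intensity`, so overlapping fibres do not double-count coverage.
#' The returned ground truth records the exact fraction of pixels whose
#' noiseless fibre signal exceeds half `fiber_intensity`.
#'
#' Coordinates follow the image convention: x is the column index, y the row
#' index with y increasing downwards; orientations are degrees from the
#' x-axis in (-90, 90].
#'
#' Each fibre draws from its own deterministic RNG sub-stream, so increasing
#' `n_fibers` reproduces the earlier fibres exactly.
#'
#' @param image_size side of the square image in pixels (>= 32).
#' @param n_fibers number of fibres; ignored when `target_coverage` is given.
#' @param fiber_width fibre width in pixels.
#' @param mean_orientation mean fibre orientation in degrees, (-90, 90].
#' @param orientation_kappa von Mises concentration; 0 = isotropic.
#' @param fiber_intensity grey value of a fibre core.
#' @param background_noise_sd standard deviation of the Gaussian background.
#' @param target_coverage optional coverage fraction in [0, 1); when given,
#'   fibres are added until the ground-truth coverage reaches it.
#' @param pixel_size physical pixel size in micrometres.
#' @param seed integer seed; the generator is a pure function of its inputs.
#' @return a `fibrous_image`: list with `pixels` (matrix), `pixel_size`,
#'   `tissue_mask` (NULL here) and `truth` (coverage, mean_orientation,
#'   orientation_kappa, n_fibers).
#' @examples
#' img <- sim_fiber_image(image_size = 64, n_fibers = 10, seed = 1)
#' img$truth$coverage
#' @export
sim_fiber_image <- function(image_size = 256, n_fibers = 60, fiber_width = 3,
                            mean_orientation = 0, orientation_kappa = 0,
                            fiber_intensity = 200, background_noise_sd = 5,
                            target_coverage = NULL, pixel_size = 1,
                            seed = 1L) {
  check_scalar(image_size, "image_size", lower = 32)
  check_scalar(orientation_kappa, "orientation_kappa", lower = 0)
  check_scalar(fiber_width, "fiber_width", lower = 0.5)
  check_scalar(fiber_intensity, "fiber_intensity", lower = 1)
  check_scalar(background_noise_sd, "background_noise_sd", lower = 0)
  if (!is.null(target_coverage)) {
    check_scalar(target_coverage, "target_coverage", lower = 0, upper = 1)
    if (target_coverage >= 0.995) {
      stopf("target_coverage %.3f is not achievable with finite fibres",
            target_coverage)
    }
  } else {
    check_scalar(n_fibers, "n_fibers", lower = 0)
  }

  sz <- as.integer(image_size)
  xs <- matrix(rep(seq_len(sz), each = sz), nrow = sz)   # column index
  ys <- matrix(rep(seq_len(sz), times = sz), nrow = sz)  # row index
  signal <- matrix(0, sz, sz)

  render_fiber <- function(i) {
    with_seed(substream_seed(seed, i), {
      cx <- runif(1, 1, sz)
      cy <- runif(1, 1, sz)
      theta <- rvonmises_axial(1, mean_orientation, orientation_kappa) *
        pi / 180
      # perpendicular distance to the line through (cx, cy), direction theta
      d <- abs((xs - cx) * sin(theta) - (ys - cy) * cos(theta))
      pmin(1, pmax(0, fiber_width / 2 + 0.5 - d))
    })
  }

  if (is.null(target_coverage)) {
    for (i in seq_len(n_fibers)) {
      signal <- pmin(signal + fiber_intensity * render_fiber(i),
                     fiber_intensity)
    }
    n_used <- as.integer(n_fibers)
  } else {
    max_fibers <- 50000L
    n_used <- 0L
    repeat {
      cov_now <- mean(signal > fiber_intensity / 2)
      if (cov_now >= target_coverage) break
      if (n_used >= max_fibers) {
        stopf("target_coverage %.3f not reached after %d fibres",
              target_coverage, max_fibers)
      }
      n_used <- n_used + 1L
      signal <- pmin(signal + fiber_intensity * render_fiber(n_used),
                     fiber_intensity)
    }
  }

  coverage <- mean(signal > fiber_intensity / 2)
  noise <- with_seed(substream_seed(seed, 0L), {
    matrix(rnorm(sz * sz, 0, background_noise_sd), sz, sz)
  })
  pixels <- pmax(signal + noise, 0)

  structure(
    list(pixels = pixels, pixel_size = pixel_size, tissue_mask = NULL,
         truth = list(coverage = coverage,
                      mean_orientation = mean_orientation,
                      orientation_kappa = orientation_kappa,
                      n_fibers = n_used)),
    class = "fibrous_image")
}

#' @export
print.fibrous_image <- function(x, ...) {
  cat(sprintf("<fibrous_image> %d x %d px (%.3g um/px)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  cat(sprintf("  ground truth: coverage %.3f, orientation %.1f deg, kappa %.2f, %d fibres\n",
              x$truth$coverage, x$truth$mean_orientation,
              x$truth$orientation_kappa, x$truth$n_fibers))
  invisible(x)
}

#' Write / read a fibrous image as single-channel TIFF with YAML ground truth
#'
#' The image is stored as 16-bit greyscale TIFF; ground truth and pixel size
#' go to a `.yaml` sidecar next to the image.
#'
#' @param image a `fibrous_image`.
#' @param path output TIFF path.
#' @param max_value grey value mapped to the TIFF white point.
#' @return `write_fiber_image()` the path, invisibly; `read_fiber_image()` a
#'   `fibrous_image` (truth restored from the sidecar when present).
#' @export
write_fiber_image <- function(image, path, max_value = 255) {
  stopifnot(inherits(image, "fibrous_image"))
  px <- pmin(pmax(image$pixels / max_value, 0), 1)
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
  yaml::write_yaml(c(image$truth,
                     list(pixel_size = image$pixel_size,
                          max_value = max_value)), sidecar)
  invisible(path)
}

#' @rdname write_fiber_image
#' @export
read_fiber_image <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
  truth <- NULL
  pixel_size <- 1
  max_value <- 255
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    pixel_size <- meta$pixel_size %||% 1
    max_value <- meta$max_value %||% 255
    truth <- meta[setdiff(names(meta), c("pixel_size", "max_value"))]
  }
  structure(list(pixels = px * max_value, pixel_size = pixel_size,
                 tissue_mask = NULL, truth = truth),
            class = "fibrous_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
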