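# Independent brute-force oracles used to pin down the vectorised
# implementations. Each is written as a plain double loop over the
# definition, sharing only the stated conventions (quantization formula,
# offset table).

# Brute-force GLCM: loop over every pixel and every offset, then evaluate
# the five features by explicit double sums over (i, j).
oracle_glcm <- function(px, n_levels, distances = 1,
                        angles = c(0, 45, 90, 135), symmetric = TRUE,
                        mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  lo <- min(px[mask]); hi <- max(px[mask])
  q <- if (hi > lo) {
    pmin(floor((px - lo) / (hi - lo) * n_levels), n_levels - 1)
  } else {
    matrix(0, nrow(px), ncol(px))
  }
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  counts <- matrix(0, n_levels, n_levels)
  for (d in distances) {
    for (a in angles) {
      o <- offs[[as.character(a)]] * d
      for (r in seq_len(nrow(px))) {
        for (cc in seq_len(ncol(px))) {
          r2 <- r + o[1]; c2 <- cc + o[2]
          if (r2 >= 1 && r2 <= nrow(px) && c2 >= 1 && c2 <= ncol(px) &&
              mask[r, cc] && mask[r2, c2]) {
            counts[q[r, cc] + 1, q[r2, c2] + 1] <-
              counts[q[r, cc] + 1, q[r2, c2] + 1] + 1
          }
        }
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  p <- counts / sum(counts)
  contrast <- 0; entropy <- 0; idm <- 0; asm <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:n_levels) for (j in 1:n_levels) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  s_i <- 0; s_j <- 0; num <- 0
  for (i in 1:n_levels) for (j in 1:n_levels) {
    pij <- p[i, j]
    contrast <- contrast + (i - j)^2 * pij
    if (pij > 0) entropy <- entropy - pij * log2(pij)
    idm <- idm + pij / (1 + (i - j)^2)
    asm <- asm + pij^2
    s_i <- s_i + (i - 1 - mu_i)^2 * pij
    s_j <- s_j + (j - 1 - mu_j)^2 * pij
    num <- num + (i - 1 - mu_i) * (j - 1 - mu_j) * pij
  }
  correlation <- if (s_i > 0 && s_j > 0) num / sqrt(s_i * s_j) else NA_real_
  list(p = p, contrast = contrast, entropy = entropy,
       correlation = correlation, idm = idm, asm = asm)
}

# Textbook BH step-up, straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Brute-force track filter: literal re-statement of the three rules.
oracle_filter <- function(df, min_frames, max_speed, full_frames) {
  keep <- character()
  rules <- character()
  for (id in unique(df$track_id)) {
    tr <- df[df$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) <= min_frames) { rules <- c(rules, "min_frames"); next }
    if (!all(full_frames %in% tr$frame)) {
      rules <- c(rules, "full_duration"); next
    }
    ok <- TRUE
    for (k in 2:nrow(tr)) {
      step <- sqrt((tr$x_um[k] - tr$x_um[k - 1])^2 +
                   (tr$y_um[k] - tr$y_um[k - 1])^2)
      if (step / ((tr$t_min[k] - tr$t_min[k - 1]) * 60) > max_speed) {
        ok <- FALSE; break
      }
    }
    if (ok) keep <- c(keep, id) else rules <- c(rules, "max_speed")
  }
  keep
}

# Brute-force motility labels from the printed thresholds.
oracle_classes <- function(disp) {
  vapply(disp, function(d) {
    if (d < 30) "sessile" else if (d <= 90) "motile" else "highly_motile"
  }, character(1))
}

# All permutations of 1..n, built recursively (independent of
# e1071::permutations used inside the package).
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# UPGMA merge heights by direct agglomeration on a distance matrix.
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i < j && d[active[i], active[j]] < bestd) {
          bestd <- d[active[i], active[j]]
          best <- c(active[i], active[j])
        }
      }
    }
    heights <- c(heights, bestd)
    a <- best[1]; b <- best[2]
    for (k in setdiff(active, best)) {
      newd <- (sizes[a] * d[a, k] + sizes[b] * d[b, k]) /
        (sizes[a] + sizes[b])
      d[a, k] <- newd; d[k, a] <- newd
    }
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  sort(heights)
}

# Smallest axial (period-180) difference between two orientations.
wrap_diff <- function(a, b) {
  d <- (a - b + 90) %% 180 - 90
  d
}

# Periodic stripe pattern with a chosen fibre orientation (degrees from the
# x-axis, y down); the intensity gradient is perpendicular to the fibres.
make_stripes <- function(n = 64, fibre_deg = 90, period = 8) {
  g <- (fibre_deg + 90) * pi / 180
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- matrix(rep(seq_len(n), n), n)
  127.5 * (1 + cos(2 * pi / period * (xs * cos(g) + ys * sin(g))))
}

# Pure 2D Brownian tracks with diffusivity D (um^2/min).
make_brownian_tracks <- function(n_tracks, n_points, dt, D, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    s <- matrix(rnorm(2 * (n_points - 1), 0, sqrt(2 * D * dt)), ncol = 2)
    data.frame(track_id = sprintf("bm%04d", i),
               frame = seq_len(n_points) - 1L,
               t_min = (seq_len(n_points) - 1L) * dt,
               x_um = c(0, cumsum(s[, 1])), y_um = c(0, cumsum(s[, 2])))
  }))
}
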