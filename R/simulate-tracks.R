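# Synthetic cell-track generator: a labelled mixture of confined
# ("sessile", oscillating around a fixed position) and persistent-random-walk
# movers, sampled at a uniform frame interval with additive positional noise.

#' Simulate a mixture of sessile and persistent-random-walk cell tracks
#'
#' Sessile movers follow a positional Ornstein-Uhlenbeck process (harmonic
#' pull towards their origin) whose stationary root-mean-square radial
#' distance equals `confinement_radius`. Motile and highly motile movers
#' follow a persistent random walk: an Ornstein-Uhlenbeck velocity process
#' with root-mean-square speed `prw_speed` (for highly motile movers;
#' motile movers are scaled by `motile_speed_factor`) and persistence time
#' `prw_persistence`, whose ensemble MSD follows the Fuerth form
#' \eqn{2 S^2 P (\tau - P (1 - e^{-\tau/P}))}.
#'
#' Every track spans the full duration. Each track draws from its own
#' deterministic RNG sub-stream, so increasing `n_tracks` reproduces earlier
#' tracks exactly.
#'
#' @param n_tracks number of tracks.
#' @param class_proportions named or unnamed triplet (sessile, motile,
#'   highly_motile) of nonnegative values summing to 1.
#' @param frame_interval minutes between frames.
#' @param duration experiment duration in hours; `duration * 60 /
#'   frame_interval` must be an integer.
#' @param prw_speed root-mean-square speed of highly motile movers, um/min.
#' @param prw_persistence persistence time, minutes.
#' @param motile_speed_factor speed multiplier for the intermediate
#'   "motile" class.
#' @param confinement_radius stationary RMS radial distance of sessile
#'   movers, um.
#' @param positional_noise_sd additive Gaussian localisation noise, um.
#' @param field_size side of the square field in which track origins are
#'   placed uniformly, um.
#' @param seed integer seed.
#' @return a `track_set`: data.frame with columns `track_id`, `frame`,
#'   `t_min`, `x_um`, `y_um`; attribute `truth` holds the per-track true
#'   class, attribute `frame_interval` the sampling interval in minutes.
#' @examples
#' ts <- sim_tracks(n_tracks = 5, duration = 1, frame_interval = 5, seed = 1)
#' head(ts)
#' attr(ts, "truth")
#' @export
sim_tracks <- function(n_tracks = 100,
                       class_proportions = c(sessile = 0.5, motile = 0.3,
                                             highly_motile = 0.2),
                       frame_interval = 5, duration = 12,
                       prw_speed = 1, prw_persistence = 20,
                       motile_speed_factor = 0.3,
                       confinement_radius = 10,
                       positional_noise_sd = 0.2,
                       field_size = 500, seed = 1L) {
  check_scalar(n_tracks, "n_tracks", lower = 1)
  if (length(class_proportions) != 3L || any(class_proportions < 0)) {
    stopf("`class_proportions` must be 3 nonnegative values")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stopf("`class_proportions` must sum to 1 (got %.12f)",
          sum(class_proportions))
  }
  check_scalar(frame_interval, "frame_interval", lower = 1e-6)
  check_scalar(duration, "duration", lower = 1e-6)
  n_steps <- duration * 60 / frame_interval
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stopf("duration %g h at %g-min intervals gives a non-integer frame count",
          duration, frame_interval)
  }
  n_steps <- as.integer(round(n_steps))
  check_scalar(prw_speed, "prw_speed", lower = 0)
  check_scalar(prw_persistence, "prw_persistence", lower = 1e-6)
  check_scalar(confinement_radius, "confinement_radius", lower = 0)
  check_scalar(positional_noise_sd, "positional_noise_sd", lower = 0)

  classes <- c("sessile", "motile", "highly_motile")
  cum_p <- cumsum(as.numeric(class_proportions))
  dt <- frame_interval
  n_pts <- n_steps + 1L

  sim_one <- function(i) {
    with_seed(substream_seed(seed, i), {
      cls <- classes[findInterval(runif(1), cum_p, left.open = TRUE) + 1L]
      x0 <- runif(2, 0, field_size)
      if (cls == "sessile") {
        # positional OU, per-component sd r/sqrt(2), relaxation 30 min
        sdc <- confinement_radius / sqrt(2)
        rho <- exp(-dt / 30)
        pos <- matrix(0, n_pts, 2)
        p <- sdc * rnorm(2)
        pos[1, ] <- p
        for (k in 2:n_pts) {
          p <- rho * p + sdc * sqrt(1 - rho^2) * rnorm(2)
          pos[k, ] <- p
        }
        pos <- sweep(pos, 2, x0, "+")
      } else {
        s <- prw_speed * if (cls == "motile") motile_speed_factor else 1
        sigma <- s / sqrt(2)  # per-component stationary velocity sd
        nsub <- 10L
        h <- dt / nsub
        v <- sigma * rnorm(2)
        pos <- matrix(0, n_pts, 2)
        pos[1, ] <- x0
        p <- x0
        for (k in 2:n_pts) {
          for (j in seq_len(nsub)) {
            p <- p + v * h
            v <- v * (1 - h / prw_persistence) +
              sigma * sqrt(2 * h / prw_persistence) * rnorm(2)
          }
          pos[k, ] <- p
        }
      }
      if (positional_noise_sd > 0) {
        pos <- pos + matrix(rnorm(2 * n_pts, 0, positional_noise_sd),
                            n_pts, 2)
      }
      list(cls = cls,
           df = data.frame(track_id = sprintf("track_%04d", i),
                           frame = seq_len(n_pts) - 1L,
                           t_min = (seq_len(n_pts) - 1L) * dt,
                           x_um = pos[, 1], y_um = pos[, 2]))
    })
  }

  sims <- lapply(seq_len(n_tracks), sim_one)
  out <- do.call(rbind, lapply(sims, `[[`, "df"))
  rownames(out) <- NULL
  truth <- data.frame(track_id = sprintf("track_%04d", seq_len(n_tracks)),
                      class = vapply(sims, `[[`, character(1), "cls"))
  structure(out, truth = truth, frame_interval = dt,
            class = c("track_set", "data.frame"))
}

#' Write a track set to CSV
#'
#' Columns `track_id,frame,t_min,x_um,y_um`; the true class labels, when
#' present, go to a YAML sidecar.
#'
#' @param tracks a `track_set` or data.frame with the track columns.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @seealso [read_tracks()]
#' @export
write_tracks <- function(tracks, path) {
  cols <- c("track_id", "frame", "t_min", "x_um", "y_um")
  if (!all(cols %in% names(tracks))) {
    stopf("tracks must have columns %s", paste(cols, collapse = ", "))
  }
  write.csv(as.data.frame(tracks)[, cols], path, row.names = FALSE)
  truth <- attr(tracks, "truth")
  if (!is.null(truth)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".yaml")
    yaml::write_yaml(list(class = as.list(setNames(truth$class,
                                                   truth$track_id))),
                     sidecar)
  }
  invisible(path)
}
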