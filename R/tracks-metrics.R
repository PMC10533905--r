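# Per-track migration metrics, ensemble MSD, motility classification,
# contingency testing, PRW fitting, and SuperPlot-style summaries.

#' Per-track migration metrics
#'
#' For each track: path length (sum of step lengths), displacement
#' (straight-line start-to-end distance), mean track speed (path length
#' divided by the elapsed time between first and last timestamps, um/min),
#' and straightness (directionality) ratio (displacement / path length; a
#' straight trajectory gives 1, a trajectory returning to its origin gives
#' 0; defined as 0 when the path length is 0).
#'
#' @param tracks a `track_set` or conforming data.frame (one or many
#'   tracks).
#' @return data.frame with one row per track: `track_id`, `n_points`,
#'   `duration_min`, `path_length_um`, `displacement_um`,
#'   `mean_track_speed_um_min`, `straightness_ratio`.
#' @examples
#' tr <- data.frame(track_id = "a", frame = 0:2, t_min = c(0, 5, 10),
#'                  x_um = c(0, 10, 20), y_um = 0)
#' track_metrics(tr)
#' @export
track_metrics <- function(tracks) {
  df <- as.data.frame(tracks)
  if (!nrow(df)) {
    return(data.frame(track_id = character(), n_points = integer(),
                      duration_min = numeric(), path_length_um = numeric(),
                      displacement_um = numeric(),
                      mean_track_speed_um_min = numeric(),
                      straightness_ratio = numeric()))
  }
  one <- function(tr) {
    if (nrow(tr) < 2) {
      stopf("track %s has a single point; metrics undefined", tr$track_id[1])
    }
    tr <- tr[order(tr$frame), , drop = FALSE]
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    path <- sum(steps)
    disp <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                 (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    elapsed <- tr$t_min[nrow(tr)] - tr$t_min[1]
    if (elapsed <= 0) stopf("track %s has non-positive duration",
                            tr$track_id[1])
    data.frame(track_id = tr$track_id[1], n_points = nrow(tr),
               duration_min = elapsed, path_length_um = path,
               displacement_um = disp,
               mean_track_speed_um_min = path / elapsed,
               straightness_ratio = if (path > 0) disp / path else 0)
  }
  out <- do.call(rbind, lapply(split(df, df$track_id), one))
  rownames(out) <- NULL
  out
}

#' Ensemble mean squared displacement
#'
#' The default estimator is from the track origin (matching trackers that
#' report MSD as squared distances from the beginning of the track):
#' \eqn{MSD(\tau) = mean_i |r_i(t_0+\tau) - r_i(t_0)|^2}. The overlapping
#' time-averaged estimator is available as `method = "time_averaged"` but
#' is not the default.
#'
#' @param tracks a `track_set`; all tracks must share one frame interval.
#' @param max_lag largest lag in frames (default: longest track).
#' @param method `"origin"` (default) or `"time_averaged"`.
#' @return an `msd_curve` data.frame: `lag_min`, `msd_um2`, `sem_um2`,
#'   `n_tracks`; the zero-lag row is included with MSD 0.
#' @export
ensemble_msd <- function(tracks, max_lag = NULL,
                         method = c("origin", "time_averaged")) {
  method <- match.arg(method)
  df <- as.data.frame(tracks)
  if (!nrow(df)) stopf("no tracks")
  trs <- lapply(split(df, df$track_id),
                function(tr) tr[order(tr$frame), , drop = FALSE])
  dts <- unlist(lapply(trs, function(tr) diff(tr$t_min)))
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-6 * max(dt, 1))) {
    stopf("tracks do not share a single frame interval")
  }
  n_max <- max(vapply(trs, nrow, integer(1))) - 1L
  if (is.null(max_lag)) max_lag <- n_max
  max_lag <- min(max_lag, n_max)
  lags <- 0:max_lag
  per_lag <- lapply(lags, function(k) {
    if (k == 0) return(list(vals = 0, n = length(trs)))
    vals <- unlist(lapply(trs, function(tr) {
      n <- nrow(tr)
      if (n <= k) return(NULL)
      if (method == "origin") {
        (tr$x_um[1 + k] - tr$x_um[1])^2 + (tr$y_um[1 + k] - tr$y_um[1])^2
      } else {
        mean((tr$x_um[(1 + k):n] - tr$x_um[1:(n - k)])^2 +
             (tr$y_um[(1 + k):n] - tr$y_um[1:(n - k)])^2)
      }
    }))
    list(vals = vals, n = length(vals))
  })
  msd <- vapply(per_lag, function(z) mean(z$vals), numeric(1))
  n_tr <- vapply(per_lag, function(z) z$n, numeric(1))
  sem <- vapply(per_lag, function(z) {
    if (z$n > 1) stats::sd(z$vals) / sqrt(z$n) else NA_real_
  }, numeric(1))
  out <- data.frame(lag_min = lags * dt, msd_um2 = msd, sem_um2 = sem,
                    n_tracks = n_tr)
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "method") <- method
  out
}

#' Classify motility from 12-h displacement
#'
#' Cells moving less than `t_low` (two average cell lengths, 30 um) are
#' sessile; cells moving up to `t_high` (90 um, inclusive) are motile; cells
#' moving further are highly motile.
#'
#' @param metrics output of [track_metrics()], or a numeric vector of
#'   displacements in um.
#' @param t_low,t_high class boundaries in um (defaults 30 and 90).
#' @return factor with levels `sessile`, `motile`, `highly_motile`.
#' @examples
#' classify_motility(c(25, 90, 95))
#' @export
classify_motility <- function(metrics, t_low = 30, t_high = 90) {
  if (t_low >= t_high) stopf("`t_low` must be below `t_high`")
  disp <- if (is.data.frame(metrics)) metrics$displacement_um else metrics
  lab <- ifelse(disp < t_low, "sessile",
                ifelse(disp <= t_high, "motile", "highly_motile"))
  factor(lab, levels = c("sessile", "motile", "highly_motile"))
}

#' Chi-squared contingency test of motility class proportions
#'
#' Pearson chi-squared (no continuity correction) on the condition x class
#' count table. Sessile cells can be excluded so the comparison is motile
#' vs highly motile only.
#'
#' @param classes_by_condition a counts matrix/table (conditions x classes),
#'   or a data.frame with columns `condition` and `class`.
#' @param drop_sessile exclude the `sessile` column before testing.
#' @return list with `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
motility_contingency <- function(classes_by_condition, drop_sessile = FALSE) {
  if (is.data.frame(classes_by_condition)) {
    tab <- table(classes_by_condition$condition, classes_by_condition$class)
  } else {
    tab <- as.table(as.matrix(classes_by_condition))
  }
  if (drop_sessile && "sessile" %in% colnames(tab)) {
    tab <- tab[, colnames(tab) != "sessile", drop = FALSE]
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stopf("contingency test needs >= 2 conditions and >= 2 classes with nonzero margins")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), observed = ct$observed,
       expected = ct$expected)
}

#' Fit the Fuerth persistent-random-walk model to an MSD curve
#'
#' Least-squares fit of \eqn{MSD(\tau) = 2 S^2 P (\tau - P (1 -
#' e^{-\tau/P}))} (the 2D Fuerth equation), estimating the speed scale S
#' (um/min) and persistence time P (min). Points are weighted by
#' \eqn{1/MSD^2} (relative least squares), since the sampling error of an
#' ensemble MSD scales with its magnitude; with exact Fuerth input the fit
#' reproduces (S, P) to numerical precision regardless of weighting.
#'
#' @param msd_curve an `msd_curve` from [ensemble_msd()] (or a data.frame
#'   with `lag_min` and `msd_um2`), with at least 5 positive lags.
#' @return a `prw_fit` with components `S`, `P`, `rss`, `fitted`,
#'   `ballistic` (TRUE when the fitted P exceeds the observation window,
#'   i.e. the data never leave the ballistic regime) and the underlying
#'   `nls` object. `coef()` and `predict()` methods are provided.
#' @examples
#' tau <- seq(5, 200, by = 5)
#' msd <- data.frame(lag_min = tau,
#'                   msd_um2 = 2 * 4 * 10 * (tau - 10 * (1 - exp(-tau / 10))))
#' coef(fit_prw(msd))
#' @export
fit_prw <- function(msd_curve) {
  df <- as.data.frame(msd_curve)
  df <- df[df$lag_min > 0 & is.finite(df$msd_um2), , drop = FALSE]
  if (nrow(df) < 5) stopf("need at least 5 positive lags to fit the PRW model")
  tau_max <- max(df$lag_min)
  p0 <- tau_max / 4
  slope <- df$msd_um2[nrow(df)] / df$lag_min[nrow(df)]
  s0 <- sqrt(max(slope, 1e-12) / (2 * p0))
  w <- 1 / pmax(df$msd_um2, 1e-12)^2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      msd_um2 ~ 2 * S^2 * P * (lag_min - P * (1 - exp(-lag_min / P))),
      data = df, start = list(S = s0, P = p0), weights = w,
      lower = c(S = 0, P = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stopf("PRW fit did not converge: %s", conditionMessage(e)))
  est <- coef(fit)
  structure(list(S = unname(est["S"]), P = unname(est["P"]),
                 rss = sum(residuals(fit)^2),
                 fitted = fitted(fit),
                 ballistic = unname(est["P"]) > tau_max,
                 tau_max = tau_max, nls = fit),
            class = "prw_fit")
}

#' @export
print.prw_fit <- function(x, ...) {
  cat(sprintf("<prw_fit> S = %.4g um/min, P = %.4g min (RSS %.4g)\n",
              x$S, x$P, x$rss))
  if (x$ballistic) {
    cat(sprintf("  note: P exceeds the observation window (%.4g min); data are ballistic\n",
                x$tau_max))
  }
  invisible(x)
}

#' @export
coef.prw_fit <- function(object, ...) c(S = object$S, P = object$P)

#' @export
predict.prw_fit <- function(object, lag_min, ...) {
  if (missing(lag_min)) return(object$fitted)
  S <- object$S; P <- object$P
  2 * S^2 * P * (lag_min - P * (1 - exp(-lag_min / P)))
}

#' SuperPlot-style donor-level summary
#'
#' Cell-level values are averaged per biological replicate (donor), and
#' inference runs on the donor means, never on pooled cells: the one-way
#' ANOVA with Tukey's multiple-comparison test (see [anova_tukey()]) is
#' applied to the per-donor means across conditions.
#'
#' @param values numeric cell-level measurements.
#' @param donor_ids biological replicate (donor) for each value.
#' @param condition_ids condition for each value.
#' @return list with `donor_means` (data.frame `condition`, `donor`, `mean`,
#'   `n_cells`) and `anova` (an [anova_tukey()] result, or NULL with a
#'   warning when any condition has < 2 donors).
#' @export
superplot_summary <- function(values, donor_ids, condition_ids) {
  if (length(values) != length(donor_ids) ||
      length(values) != length(condition_ids)) {
    stopf("values, donor_ids and condition_ids must have equal length")
  }
  key <- data.frame(condition = as.character(condition_ids),
                    donor = as.character(donor_ids), value = values)
  agg <- stats::aggregate(value ~ condition + donor, key, mean)
  ncell <- stats::aggregate(value ~ condition + donor, key, length)
  donor_means <- data.frame(condition = agg$condition, donor = agg$donor,
                            mean = agg$value, n_cells = ncell$value)
  donor_means <- donor_means[order(donor_means$condition, donor_means$donor), ]
  rownames(donor_means) <- NULL
  n_donors <- table(donor_means$condition)
  if (any(n_donors < 2)) {
    warnf("condition(s) with < 2 donors (%s); ANOVA on donor means skipped",
          paste(names(n_donors)[n_donors < 2], collapse = ", "))
    anova <- NULL
  } else {
    anova <- anova_tukey(split(donor_means$mean, donor_means$condition))
  }
  list(donor_means = donor_means, anova = anova)
}
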