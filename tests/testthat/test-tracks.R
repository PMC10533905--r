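# Track analytics: IO, gap closing, filtering, metrics, MSD, classes,
# contingency, PRW fit, SuperPlot summaries.

straight_track <- function(n = 13, step = 10, dt = 5, id = "s") {
  data.frame(track_id = id, frame = seq_len(n) - 1L,
             t_min = (seq_len(n) - 1L) * dt,
             x_um = (seq_len(n) - 1L) * step, y_um = 0)
}

test_that("track CSV IO round-trips and rejects malformed input", {
  ts <- sim_tracks(n_tracks = 3, duration = 1, frame_interval = 5, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts, path)
  back <- read_tracks(path)
  expect_equal(as.data.frame(back), as.data.frame(ts)[names(back)],
               tolerance = 1e-12, ignore_attr = TRUE)
  # duplicated (track_id, frame)
  df <- as.data.frame(ts)
  write.csv(rbind(df, df[1, ]), path, row.names = FALSE)
  expect_error(read_tracks(path), "duplicated")
  # missing column
  write.csv(df[, -3], path, row.names = FALSE)
  expect_error(read_tracks(path), "t_min")
  # empty file with header is fine
  write.csv(df[0, ], path, row.names = FALSE)
  expect_equal(nrow(read_tracks(path)), 0)
})

test_that("gap closing interpolates linearly and splits oversized gaps", {
  tr <- data.frame(track_id = "g", frame = c(4L, 6L), t_min = c(20, 30),
                   x_um = c(0, 2), y_um = c(0, 2))
  out <- close_gaps(tr)
  mid <- out[out$frame == 5, ]
  expect_equal(c(mid$x_um, mid$y_um, mid$t_min), c(1, 1, 25))
  expect_true(mid$interpolated)
  expect_false(any(out$interpolated[out$frame != 5]))
  # no gaps: unchanged
  st <- straight_track()
  expect_equal(as.data.frame(close_gaps(st))[, names(st)], st)
  # gap of 4 missing frames with max_gap 3: split in two
  tr2 <- data.frame(track_id = "h", frame = c(0:2, 7:9),
                    t_min = c(0:2, 7:9) * 5,
                    x_um = 0:5, y_um = 0)
  out2 <- close_gaps(tr2, max_gap = 3)
  expect_equal(length(unique(out2$track_id)), 2)
  expect_error(close_gaps(tr2, max_gap = 3, on_exceed = "error"), "gap")
})

test_that("the published filter rules remove the right tracks", {
  dt <- 5
  mk <- function(id, n, speed_um_min = 2, start_frame = 0) {
    data.frame(track_id = id, frame = start_frame + seq_len(n) - 1L,
               t_min = (start_frame + seq_len(n) - 1L) * dt,
               x_um = (seq_len(n) - 1L) * speed_um_min * dt, y_um = 0)
  }
  full_n <- 30L
  set <- rbind(mk("ok", full_n),
               mk("short13", 12),              # 12 points -> deleted
               mk("partial", 20, start_frame = 5),
               mk("fast", full_n, speed_um_min = 101 * 60))  # >100 um/s
  filt <- filter_tracks(as_set <- structure(set, class = c("track_set", "data.frame")),
                        track_filter_rules(),
                        experiment_frames = 0:(full_n - 1))
  expect_equal(unique(filt$track_id), "ok")
  rej <- attr(filt, "rejections")
  expect_equal(rej$rule[rej$track_id == "short13"], "min_frames")
  expect_equal(rej$rule[rej$track_id == "partial"], "full_duration")
  expect_equal(rej$rule[rej$track_id == "fast"], "max_speed")
  # boundary: 13 points survive the "12 or less" rule (given full window)
  tr13 <- mk("b13", 13)
  f13 <- filter_tracks(structure(tr13, class = c("track_set", "data.frame")),
                       track_filter_rules(require_full_duration = FALSE))
  expect_equal(unique(f13$track_id), "b13")
})

test_that("filtering equals a brute-force rule application on random sets", {
  set.seed(99)
  for (rep in 1:20) {
    n_tr <- sample(3:12, 1)
    dt <- 5
    full <- 0:19
    df <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
      n <- sample(c(5, 13, 20), 1)
      start <- sample(c(0, 0, 3), 1)
      frames <- start + seq_len(min(n, 20 - start)) - 1
      sp <- sample(c(1, 50000), 1, prob = c(0.8, 0.2))  # um/min
      data.frame(track_id = sprintf("t%02d", i), frame = frames,
                 t_min = frames * dt,
                 x_um = cumsum(c(0, runif(length(frames) - 1, 0, sp * dt))),
                 y_um = 0)
    }))
    ts <- structure(df, class = c("track_set", "data.frame"))
    filt <- filter_tracks(ts, track_filter_rules(), experiment_frames = full)
    expect_setequal(unique(filt$track_id),
                    oracle_filter(df, 12, 100, full))
  }
})

test_that("metrics match hand geometry", {
  m <- track_metrics(straight_track())
  expect_equal(m$path_length_um, 120)
  expect_equal(m$displacement_um, 120)
  expect_equal(m$mean_track_speed_um_min, 2)
  expect_equal(m$straightness_ratio, 1)
  # closed square loop: displacement and straightness 0
  sq <- data.frame(track_id = "sq", frame = 0:4, t_min = (0:4) * 5,
                   x_um = c(0, 30, 30, 0, 0), y_um = c(0, 0, 30, 30, 0))
  msq <- track_metrics(sq)
  expect_equal(msq$displacement_um, 0)
  expect_equal(msq$straightness_ratio, 0)
  expect_equal(msq$path_length_um, 120)
  # L-path: Pythagoras by hand
  lp <- data.frame(track_id = "L", frame = 0:2, t_min = (0:2) * 5,
                   x_um = c(0, 30, 30), y_um = c(0, 0, 40))
  ml <- track_metrics(lp)
  expect_equal(ml$displacement_um, 50)
  expect_equal(ml$path_length_um, 70)
  expect_equal(ml$straightness_ratio, 5 / 7)
  expect_error(track_metrics(straight_track(n = 1)), "single point")
})

test_that("displacement never exceeds path length over simulations", {
  ts <- sim_tracks(n_tracks = 40, duration = 2, frame_interval = 5, seed = 31)
  m <- track_metrics(ts)
  expect_true(all(m$displacement_um <= m$path_length_um + 1e-9))
  expect_true(all(m$straightness_ratio >= 0 & m$straightness_ratio <= 1))
})

test_that("MSD obeys closed forms and internal consistency", {
  # ballistic: msd(tau) = (v tau)^2
  st <- straight_track(n = 25, step = 10, dt = 5)  # v = 2 um/min
  msd <- ensemble_msd(st)
  expect_equal(msd$msd_um2, (2 * msd$lag_min)^2, tolerance = 1e-12)
  # stationary: identically zero
  still <- data.frame(track_id = "z", frame = 0:9, t_min = (0:9) * 5,
                      x_um = 1, y_um = 2)
  expect_true(all(ensemble_msd(still)$msd_um2 == 0))
  # from-origin MSD at the final lag equals the mean squared displacement
  ts <- sim_tracks(n_tracks = 25, duration = 2, frame_interval = 5, seed = 13)
  msd2 <- ensemble_msd(ts)
  m2 <- track_metrics(ts)
  expect_equal(msd2$msd_um2[nrow(msd2)], mean(m2$displacement_um^2),
               tolerance = 1e-9)
  # mixed frame intervals fail
  bad <- rbind(straight_track(id = "a"),
               within(straight_track(id = "b"), t_min <- t_min * 2))
  expect_error(ensemble_msd(bad), "frame interval")
})

test_that("Brownian simulation recovers the diffusion slope", {
  D <- 2
  bt <- make_brownian_tracks(500, 73, dt = 5, D = D, seed = 51)
  msd <- ensemble_msd(bt)
  last <- msd[nrow(msd), ]
  D_hat <- last$msd_um2 / (4 * last$lag_min)
  se <- last$sem_um2 / (4 * last$lag_min)
  expect_lt(abs(D_hat - D), 3 * se)
})

test_that("motility classes follow the printed displacement thresholds", {
  expect_equal(as.character(classify_motility(c(25, 29.999, 30, 90, 90.001, 95))),
               c("sessile", "sessile", "motile", "motile",
                 "highly_motile", "highly_motile"))
  set.seed(5)
  disp <- runif(200, 0, 150)
  expect_equal(as.character(classify_motility(disp)), oracle_classes(disp))
})

test_that("confined movers classify sessile; class mixtures are recovered", {
  ts <- sim_tracks(n_tracks = 60, class_proportions = c(1, 0, 0),
                   confinement_radius = 10, seed = 17)
  cls <- classify_motility(track_metrics(ts))
  expect_gte(mean(cls == "sessile"), 0.9)
  # well-separated regime: confinement far below 30 um, fast movers far
  # beyond 90 um, so measured proportions recover the mixture weights
  mix <- sim_tracks(n_tracks = 150, class_proportions = c(0.4, 0, 0.6),
                    prw_speed = 3, seed = 23)
  mm <- track_metrics(mix)
  cls_hat <- classify_motility(mm)
  expect_lt(abs(mean(cls_hat == "sessile") - 0.4),
            3 * sqrt(0.4 * 0.6 / 150) + 0.05)
  expect_lt(abs(mean(cls_hat == "highly_motile") - 0.6),
            3 * sqrt(0.6 * 0.4 / 150) + 0.05)
  # generator label agreement in this regime
  truth <- attr(mix, "truth")
  agree <- mean(as.character(cls_hat) ==
                  truth$class[match(mm$track_id, truth$track_id)])
  expect_gt(agree, 0.85)
})

test_that("contingency test matches hand chi-square and handles guards", {
  eq <- motility_contingency(matrix(c(10, 10, 10, 10), 2))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  hand <- motility_contingency(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(hand$statistic, 20 / 3, tolerance = 1e-10)  # sum (O-E)^2/E
  expect_equal(hand$df, 1)
  expect_error(motility_contingency(matrix(c(5, 5, 0, 0), 2)),
               "nonzero margins")
  # drop_sessile restricts to motile vs highly motile
  df <- data.frame(condition = rep(c("a", "b"), each = 30),
                   class = factor(rep(c("sessile", "motile", "highly_motile"),
                                      20),
                                  levels = c("sessile", "motile",
                                             "highly_motile")))
  full <- motility_contingency(df)
  red <- motility_contingency(df, drop_sessile = TRUE)
  expect_equal(sum(red$observed), 40)
  expect_equal(red$df, 1)
  expect_equal(full$df, 2)
})

test_that("chi-square null rejection rate is near alpha", {
  set.seed(77)
  rej <- mean(replicate(400, {
    cls <- sample(c("motile", "highly_motile"), 120, replace = TRUE)
    cond <- rep(c("a", "b"), each = 60)
    motility_contingency(data.frame(condition = cond, class = cls))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.02)
})

test_that("PRW fit is exact on Fuerth input and flags ballistic data", {
  tau <- seq(5, 300, by = 5)
  S <- 2; P <- 10
  exact <- data.frame(lag_min = tau,
                      msd_um2 = 2 * S^2 * P * (tau - P * (1 - exp(-tau / P))))
  fit <- fit_prw(exact)
  expect_equal(unname(coef(fit)), c(2, 10), tolerance = 1e-6)
  expect_false(fit$ballistic)
  expect_equal(predict(fit, tau), exact$msd_um2, tolerance = 1e-6)
  # ballistic limit: msd = (v tau)^2 has P far beyond the window
  bal <- data.frame(lag_min = tau[1:20], msd_um2 = (1.5 * tau[1:20])^2)
  bfit <- fit_prw(bal)
  expect_true(bfit$ballistic)
  expect_error(fit_prw(exact[1:3, ]), "at least 5")
})

test_that("SuperPlot inference runs on donor means, not pooled cells", {
  set.seed(3)
  donors <- rep(sprintf("d%d", 1:6), each = 40)
  cond <- rep(c("ctrl", "ipf"), each = 120)
  vals <- rnorm(240) + (cond == "ipf") * 0.1
  sp <- superplot_summary(vals, donors, cond)
  expect_equal(nrow(sp$donor_means), 6)    # donor-level n, not 240
  expect_equal(sp$donor_means$n_cells, rep(40, 6))
  expect_equal(sp$anova$df_between + sp$anova$df_within + 1, 6)
  # identical donor means across conditions -> Tukey p ~ 1
  flat <- superplot_summary(rep(1, 240), donors, cond)
  expect_true(all(flat$anova$tukey$p_adj > 1 - 1e-9))
  # strong separation is detected
  sep <- superplot_summary(vals + (cond == "ipf") * 50, donors, cond)
  expect_lt(sep$anova$p, 0.01)
  expect_warning(superplot_summary(1:10, rep("d1", 10),
                                   rep(c("a", "b"), 5)),
                 "< 2 donors")
})
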