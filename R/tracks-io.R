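# Track IO, gap closing, and the published filtering rules.

track_cols <- c("track_id", "frame", "t_min", "x_um", "y_um")

as_track_set <- function(df, frame_interval = NULL) {
  df <- as.data.frame(df)[, intersect(c(track_cols, "interpolated"),
                                      names(df))]
  if (is.null(frame_interval) && nrow(df)) {
    dts <- unlist(tapply(df$t_min, df$track_id,
                         function(t) diff(sort(t)), simplify = FALSE))
    frame_interval <- if (length(dts)) stats::median(dts) else NA_real_
  }
  structure(df, frame_interval = frame_interval,
            class = c("track_set", "data.frame"))
}

#' @export
print.track_set <- function(x, ...) {
  ids <- unique(x$track_id)
  cat(sprintf("<track_set> %d tracks, %d points, frame interval %s min\n",
              length(ids), nrow(x),
              format(attr(x, "frame_interval"))))
  invisible(x)
}

#' Read cell tracks from CSV
#'
#' Expects columns `track_id,frame,t_min,x_um,y_um`. Rows are grouped by
#' track and sorted by frame. Malformed rows (non-finite coordinates or
#' frames) and duplicate `(track_id, frame)` pairs are reported with their
#' line numbers.
#'
#' @param path CSV path.
#' @return a `track_set`. An empty file with a valid header yields an empty
#'   track set.
#' @seealso [write_tracks()]
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(track_cols, names(df))
  if (length(missing)) {
    stopf("track file %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(as_track_set(df))
  bad <- !is.finite(df$frame) | !is.finite(df$t_min) |
    !is.finite(df$x_um) | !is.finite(df$y_um)
  if (any(bad)) {
    stopf("malformed track rows at line(s): %s",
          paste(which(bad) + 1L, collapse = ", "))  # +1 for the header
  }
  dup <- duplicated(df[, c("track_id", "frame")])
  if (any(dup)) {
    d <- df[dup, , drop = FALSE][1, ]
    stopf("duplicated (track_id, frame) = (%s, %d) at line %d",
          d$track_id, d$frame, which(dup)[1] + 1L)
  }
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  as_track_set(df)
}

#' Close small frame gaps by linear interpolation
#'
#' Missing frames inside a track are filled by linear interpolation of
#' position (and time); interpolated points carry `interpolated = TRUE`.
#' A gap larger than `max_gap` missing frames either splits the track into
#' independent sub-tracks (suffix `.2`, `.3`, ...) or fails, per
#' `on_exceed`.
#'
#' @param tracks a `track_set` or conforming data.frame.
#' @param max_gap largest number of consecutive missing frames to
#'   interpolate (default 3, the published tracking setting).
#' @param on_exceed `"split"` (default) or `"error"`.
#' @return a `track_set` with an `interpolated` logical column.
#' @export
close_gaps <- function(tracks, max_gap = 3, on_exceed = c("split", "error")) {
  on_exceed <- match.arg(on_exceed)
  df <- as.data.frame(tracks)
  if (!nrow(df)) return(as_track_set(df))
  if (!"interpolated" %in% names(df)) df$interpolated <- FALSE

  fix_one <- function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    gaps <- diff(tr$frame) - 1L
    if (any(gaps < 0)) stopf("non-monotone frames in track %s", tr$track_id[1])
    # split where the gap exceeds max_gap
    if (any(gaps > max_gap)) {
      if (on_exceed == "error") {
        stopf("track %s has a gap of %d frames (max_gap = %d)",
              tr$track_id[1], max(gaps), max_gap)
      }
      seg <- cumsum(c(0L, as.integer(gaps > max_gap)))
      pieces <- split(tr, seg)
      pieces <- Map(function(p, k) {
        if (k > 1) p$track_id <- paste0(p$track_id, ".", k)
        p
      }, pieces, seq_along(pieces))
      return(do.call(rbind, lapply(pieces, fix_one)))
    }
    full <- seq(tr$frame[1], tr$frame[nrow(tr)])
    if (length(full) == nrow(tr)) return(tr)
    out <- data.frame(track_id = tr$track_id[1], frame = full,
                      t_min = stats::approx(tr$frame, tr$t_min, full)$y,
                      x_um = stats::approx(tr$frame, tr$x_um, full)$y,
                      y_um = stats::approx(tr$frame, tr$y_um, full)$y,
                      interpolated = !(full %in% tr$frame))
    out$interpolated <- out$interpolated | full %in% tr$frame[tr$interpolated]
    out
  }

  pieces <- lapply(split(df, df$track_id), fix_one)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  as_track_set(out, frame_interval = attr(tracks, "frame_interval"))
}

#' Track filtering rules
#'
#' Defaults follow the published tracking pipeline: tracks with 12 or fewer
#' frames are deleted, only cells tracked for the entire experiment are
#' kept, and any instantaneous step faster than 100 um/s (floating debris)
#' rejects the track.
#'
#' @param require_full_duration keep only tracks present at every frame of
#'   the experiment window.
#' @param min_frames tracks with this many points or fewer are deleted.
#' @param max_speed maximum instantaneous (per-step) speed in um/s.
#' @param max_gap largest closable gap, in frames (see [close_gaps()]).
#' @return a `track_filter_rules` list.
#' @export
track_filter_rules <- function(require_full_duration = TRUE,
                               min_frames = 12, max_speed = 100,
                               max_gap = 3) {
  check_flag(require_full_duration, "require_full_duration")
  check_scalar(min_frames, "min_frames", lower = 0)
  check_scalar(max_speed, "max_speed", lower = 1e-12)
  check_scalar(max_gap, "max_gap", lower = 0)
  structure(list(require_full_duration = require_full_duration,
                 min_frames = min_frames, max_speed = max_speed,
                 max_gap = max_gap),
            class = "track_filter_rules")
}

#' Apply the track filtering rules
#'
#' Removes tracks with `<= min_frames` points, tracks not spanning every
#' frame of the experiment window (when `require_full_duration`), and
#' tracks containing any step faster than `max_speed` um/s. The rejection
#' log names the rule responsible for each removal.
#'
#' @param tracks a `track_set`.
#' @param rules a [track_filter_rules()] object.
#' @param experiment_frames integer vector of frames defining the window;
#'   default `min(frame):max(frame)` over the whole set.
#' @return the surviving `track_set`; attribute `rejections` is a
#'   data.frame (`track_id`, `rule`).
#' @export
filter_tracks <- function(tracks, rules = track_filter_rules(),
                          experiment_frames = NULL) {
  stopifnot(inherits(rules, "track_filter_rules"))
  df <- as.data.frame(tracks)
  if (!nrow(df)) {
    out <- as_track_set(df)
    attr(out, "rejections") <- data.frame(track_id = character(),
                                          rule = character())
    return(out)
  }
  if (is.null(experiment_frames)) {
    experiment_frames <- seq(min(df$frame), max(df$frame))
  }
  rej <- list()
  keep_one <- function(tr) {
    id <- tr$track_id[1]
    if (nrow(tr) <= rules$min_frames) return(c(id, "min_frames"))
    if (rules$require_full_duration &&
        !all(experiment_frames %in% tr$frame)) {
      return(c(id, "full_duration"))
    }
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) >= 2) {
      step <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
      dt_s <- diff(tr$t_min) * 60
      if (any(step / dt_s > rules$max_speed)) return(c(id, "max_speed"))
    }
    NULL
  }
  verdicts <- lapply(split(df, df$track_id), keep_one)
  rejected <- do.call(rbind, verdicts[!vapply(verdicts, is.null, logical(1))])
  rej_df <- if (is.null(rejected)) {
    data.frame(track_id = character(), rule = character())
  } else {
    data.frame(track_id = rejected[, 1], rule = rejected[, 2],
               row.names = NULL)
  }
  out <- df[!df$track_id %in% rej_df$track_id, , drop = FALSE]
  rownames(out) <- NULL
  out <- as_track_set(out, frame_interval = attr(tracks, "frame_interval"))
  attr(out, "rejections") <- rej_df
  out
}
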