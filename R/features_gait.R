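# Stand-up-and-walk (SAW): segmentation into stand-up / walk / turn and
# spatio-temporal gait features.

#' SAW segmentation thresholds
#'
#' @param v_su pelvis speed threshold marking stand-up effort, in normalized
#'   units per second (default 0.3).
#' @param v_walk horizontal pelvis speed below which the subject is not
#'   walking (default 0.2 normalized units/s).
#' @param su_settle_s pelvis speed must stay below `v_su` this long (with
#'   pelvis height at the standing plateau) to end the stand-up segment
#'   (default 0.25 s).
#' @param tu_min_s minimum duration of a low-speed interval with a walking
#'   direction reversal to count as a turn (default 0.2 s).
#' @param boundary_pad_s step extrema closer than this to a detected turn
#'   segment are discarded (default 0.2 s; the detected turn already extends
#'   into the gait deceleration, so a wider guard starts consuming genuine
#'   edge steps).
#' @param min_walk_s walk segments shorter than this are dropped
#'   (default 0.5 s).
#' @return An object of class `saw_config`.
#' @export
saw_config <- function(v_su = 0.3, v_walk = 0.2, su_settle_s = 0.25,
                       tu_min_s = 0.2, boundary_pad_s = 0.2,
                       min_walk_s = 0.5) {
  structure(list(v_su = v_su, v_walk = v_walk, su_settle_s = su_settle_s,
                 tu_min_s = tu_min_s, boundary_pad_s = boundary_pad_s,
                 min_walk_s = min_walk_s), class = "saw_config")
}

# Centered moving average with edges held at the nearest full-window value.
moving_avg <- function(v, k) {
  if (k < 2L) return(v)
  f <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  zoo::na.fill(f, fill = "extend")
}

# Maximal runs of TRUE in a logical vector: matrix of (start, end), 1-based.
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Segment a SAW recording into stand-up, walk and turn intervals
#'
#' Works on the smoothed global pelvis track. The stand-up (SU) segment runs
#' from the onset of the first pelvis-speed burst above `v_su` (walked back
#' to near-zero speed) until speed falls back below `v_su` for
#' `su_settle_s` with the pelvis height within 5% of the standing plateau;
#' its duration is the time to stand. Turns (TU) are low-horizontal-speed
#' intervals (at least `tu_min_s` long) across which the walking direction
#' reverses. Walk (W) segments are the sustained-motion intervals between
#' those boundaries.
#'
#' @param pelvis a [pose_sequence()] holding the global 2D pelvis track
#'   (`B2`, side `"center"`), pre-processed.
#' @param cfg a [saw_config()].
#' @return An object of class `saw_segments`: `segments` (data.frame with
#'   columns `kind` in SU/W/TU, `start`, `end` frame indices),
#'   `time_to_stand` (s), `turning_times` (s), `fps`.
#' @export
segment_saw <- function(pelvis, cfg = saw_config()) {
  fps <- pelvis$fps
  p <- joint_track(pelvis, "pelvis")
  n <- nrow(p)
  if (n < 5 * fps)
    nk_stop("SAW segmentation needs at least 5 s of pelvis track",
            "neurokin_segmentation_error")
  # thresholding acts on smoothed velocities: frame-level differentiation
  # amplifies keypoint noise far above the v_su / v_walk scales
  k <- odd_window(0.15 * fps)
  vx <- moving_avg(derivative(signal1d(p[, 1L], fps), 1L)$values, k)
  vy <- moving_avg(derivative(signal1d(p[, 2L], fps), 1L)$values, k)
  speed <- sqrt(vx^2 + vy^2)

  ## ---- stand-up ----
  cross <- which(speed > cfg$v_su)
  if (length(cross) == 0L)
    nk_stop("no stand-up effort found (pelvis speed never exceeds v_su)",
            "neurokin_segmentation_error")
  cross <- cross[1L]
  onset <- cross
  while (onset > 1L && speed[onset - 1L] > 0.2 * cfg$v_su) onset <- onset - 1L
  y <- p[, 2L]
  y_stand <- stats::median(y[y >= stats::quantile(y, 0.8, na.rm = TRUE)], na.rm = TRUE)
  rise <- y_stand - min(y, na.rm = TRUE)
  settle <- max(1L, as.integer(round(cfg$su_settle_s * fps)))
  su_end <- NA_integer_
  for (j in cross:(n - settle)) {
    if (all(speed[j:(j + settle)] < cfg$v_su) &&
        abs(y[j] - y_stand) <= 0.05 * rise) { su_end <- j; break }
  }
  if (is.na(su_end))
    nk_stop("stand-up never settles to a standing plateau",
            "neurokin_segmentation_error")
  time_to_stand <- (su_end - onset) / fps

  ## ---- turns and walks after stand-up ----
  after <- su_end:n
  low <- abs(vx) < cfg$v_walk
  runs <- true_runs(low)
  runs <- runs[runs[, "end"] > su_end, , drop = FALSE]
  if (nrow(runs)) runs[, "start"] <- pmax(runs[, "start"], su_end)
  tu <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  win <- max(1L, as.integer(round(0.3 * fps)))
  for (r in seq_len(nrow(runs))) {
    s <- runs[r, "start"]; e <- runs[r, "end"]
    if ((e - s + 1L) / fps < cfg$tu_min_s) next
    # a turn is bounded by sustained walking in opposite directions
    if (s - win < 1L || e + win > n) next
    before <- mean(vx[(s - win):(s - 1L)])
    after <- mean(vx[(e + 1L):(e + win)])
    if (abs(before) > cfg$v_walk && abs(after) > cfg$v_walk &&
        sign(before) != sign(after))
      tu <- rbind(tu, c(s, e))
  }
  # walking means sustained horizontal motion: isolated above-threshold
  # velocity samples (noise excursions while standing) do not qualify
  mv_runs <- true_runs(abs(vx) >= cfg$v_walk)
  mv_runs <- mv_runs[(mv_runs[, "end"] - mv_runs[, "start"] + 1L) / fps >=
                       cfg$min_walk_s, , drop = FALSE]
  moving <- unlist(lapply(seq_len(nrow(mv_runs)), function(r)
    mv_runs[r, "start"]:mv_runs[r, "end"]))
  moving <- moving[moving > su_end]
  if (length(moving) == 0L)
    nk_stop("no walking motion found after stand-up", "neurokin_segmentation_error")
  bounds <- c(su_end, as.vector(t(tu)), max(moving))
  w <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  starts <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
  ends <- bounds[seq(2L, length(bounds), by = 2L)]
  for (i in seq_along(starts)) {
    s <- starts[i] + 1L; e <- ends[i] - if (i < length(starts)) 1L else 0L
    if (e <= s) next
    # clip to the sustained-motion core of the interval
    mv <- moving[moving >= s & moving <= e]
    if (length(mv) == 0L) next
    s <- min(mv); e <- max(mv)
    if ((e - s + 1L) / fps < cfg$min_walk_s) next
    w <- rbind(w, c(s, e))
  }
  if (nrow(w) == 0L)
    nk_stop("no walk segment found", "neurokin_segmentation_error")
  seg <- rbind(
    data.frame(kind = "SU", start = onset, end = su_end),
    data.frame(kind = "W", start = w[, "start"], end = w[, "end"]),
    if (nrow(tu)) data.frame(kind = "TU", start = tu[, "start"], end = tu[, "end"])
  )
  seg <- seg[order(seg$start), ]
  rownames(seg) <- NULL
  structure(list(segments = seg, time_to_stand = time_to_stand,
                 turning_times = (tu[, "end"] - tu[, "start"] + 1L) / fps,
                 fps = fps), class = "saw_segments")
}

#' @export
print.saw_segments <- function(x, ...) {
  cat(sprintf("<saw_segments> time_to_stand=%.2fs, %d turn(s)\n",
              x$time_to_stand, length(x$turning_times)))
  print(x$segments)
  invisible(x)
}

#' Distance between the two feet
#'
#' Per-frame Euclidean distance between the right and left foot keypoints of
#' the 3D body pose -- the primary gait signal, whose maxima mark steps
#' (step length) and minima mark feet-together instants (step width).
#'
#' @param rec a pre-processed SAW [recording()] with `B3` sequences.
#' @return a [signal1d()] in normalized length units.
#' @export
feet_distance_series <- function(rec) {
  r <- joint_track(get_sequence(rec, "B3", "right"), "foot")
  l <- joint_track(get_sequence(rec, "B3", "left"), "foot")
  signal1d(row_norms(r - l), rec$fps, "normalized-length")
}

# Step events (feet-distance extrema) inside each walk segment, with extrema
# within boundary_pad_s of a turn segment discarded (steps blur into the turn
# there). Returns a list per W of list(maxima, minima) as absolute frame
# indices.
saw_step_events <- function(dsaw, segs, kin = kinematics_config(),
                            cfg = saw_config()) {
  w <- segs$segments[segs$segments$kind == "W", , drop = FALSE]
  tu <- segs$segments[segs$segments$kind == "TU", , drop = FALSE]
  pad <- as.integer(round(cfg$boundary_pad_s * dsaw$fps))
  near_turn <- function(idx) {
    if (nrow(tu) == 0L || length(idx) == 0L) return(rep(FALSE, length(idx)))
    vapply(idx, function(i) {
      any(pmax(0L, tu$start - i, i - tu$end) < pad)
    }, logical(1))
  }
  lapply(seq_len(nrow(w)), function(i) {
    s <- w$start[i]; e <- w$end[i]
    seg <- signal1d(dsaw$values[s:e], dsaw$fps, dsaw$units)
    cs <- detect_cycles(seg, kin$min_prominence_frac, kin$min_period_gait_s,
                        boundary = "maxima")
    keep <- function(idx) {
      idx <- idx + s - 1L
      idx[!near_turn(idx)]
    }
    list(maxima = keep(cs$maxima_idx), minima = keep(cs$minima_idx),
         start = s, end = e)
  })
}

#' Spatio-temporal step features
#'
#' From the feet-distance extrema within walk segments: step time (interval
#' between consecutive maxima within one walk segment), step length (maxima
#' values) and step width (minima values), each summarized by mean/SD/median.
#' Turning segments are excluded and extrema too close to a segment boundary
#' are discarded.
#'
#' @param dsaw the [feet_distance_series()].
#' @param segs a [segment_saw()] result.
#' @param kin a [kinematics_config()].
#' @param cfg a [saw_config()].
#' @return list of `summary_stats` for `step_time`, `step_length`,
#'   `step_width`.
#' @export
step_features <- function(dsaw, segs, kin = kinematics_config(),
                          cfg = saw_config()) {
  ev <- saw_step_events(dsaw, segs, kin, cfg)
  step_time <- unlist(lapply(ev, function(e)
    if (length(e$maxima) >= 2L) diff(e$maxima) / dsaw$fps else numeric(0)))
  step_length <- dsaw$values[unlist(lapply(ev, `[[`, "maxima"))]
  step_width <- dsaw$values[unlist(lapply(ev, `[[`, "minima"))]
  list(step_time = summary_stats(step_time),
       step_length = summary_stats(step_length),
       step_width = summary_stats(step_width))
}

#' Cadence and walking speed
#'
#' Per walk segment: cadence is the number of steps (feet-distance maxima)
#' divided by the segment duration; walking speed is the total traveled
#' distance of the pelvis divided by the segment duration. Both are
#' summarized across walk segments.
#'
#' @param pelvis the global 2D pelvis [pose_sequence()].
#' @param dsaw the [feet_distance_series()].
#' @param segs a [segment_saw()] result.
#' @param kin a [kinematics_config()].
#' @param cfg a [saw_config()].
#' @return list of `summary_stats` for `cadence` and `walking_speed`.
#' @export
gait_global_features <- function(pelvis, dsaw, segs, kin = kinematics_config(),
                                 cfg = saw_config()) {
  ev <- saw_step_events(dsaw, segs, kin, cfg)
  p <- joint_track(pelvis, "pelvis")
  cad <- vapply(ev, function(e)
    length(e$maxima) / ((e$end - e$start + 1L) / dsaw$fps), numeric(1))
  spd <- vapply(ev, function(e)
    polyline_length(p[e$start:e$end, , drop = FALSE]) /
      ((e$end - e$start + 1L) / dsaw$fps), numeric(1))
  list(cadence = summary_stats(cad), walking_speed = summary_stats(spd))
}

#' Knee angle series
#'
#' Per-frame angle at the knee between the knee-to-hip and knee-to-foot
#' vectors of the 3D leg, in `[0, pi]` radians (`pi` = straight leg). Frames
#' with a zero-length limb vector are `NA`.
#'
#' @param rec a pre-processed SAW [recording()] with `B3` sequences.
#' @param side `"right"` or `"left"`.
#' @return a [signal1d()] in radians.
#' @export
knee_angle_series <- function(rec, side = c("right", "left")) {
  side <- match.arg(side)
  s <- get_sequence(rec, "B3", side)
  hip <- joint_track(s, "hip"); knee <- joint_track(s, "knee")
  foot <- joint_track(s, "foot")
  u <- hip - knee; v <- foot - knee
  nu <- row_norms(u); nv <- row_norms(v)
  cosang <- rowSums(u * v) / (nu * nv)
  cosang[nu == 0 | nv == 0] <- NA_real_
  signal1d(acos(pmin(1, pmax(-1, cosang))), s$fps, "radians")
}

#' Right/left gait symmetries
#'
#' A gait cycle (stride) spans two consecutive steps, i.e. the interval
#' between feet-distance maxima two apart. For each stride the right and
#' left knee-angle series (and, separately, the right and left horizontal
#' foot positions) are resampled to a common length and aligned by the lag --
#' up to half a stride, absorbing the physiologic right/left phase offset --
#' that maximizes their correlation; the aligned correlations are summarized
#' across strides.
#'
#' @param rec a pre-processed SAW [recording()].
#' @param segs a [segment_saw()] result.
#' @param kin a [kinematics_config()].
#' @param cfg a [saw_config()].
#' @return list of `summary_stats` for `knee_angle_symmetry` and
#'   `step_symmetry`.
#' @export
gait_symmetries <- function(rec, segs, kin = kinematics_config(),
                            cfg = saw_config()) {
  dsaw <- feet_distance_series(rec)
  ev <- saw_step_events(dsaw, segs, kin, cfg)
  knee <- list(right = knee_angle_series(rec, "right")$values,
               left = knee_angle_series(rec, "left")$values)
  foot_x <- list(right = joint_track(get_sequence(rec, "B3", "right"), "foot")[, 1L],
                 left = joint_track(get_sequence(rec, "B3", "left"), "foot")[, 1L])
  knee_cc <- c(); step_cc <- c()
  for (e in ev) {
    m <- e$maxima
    if (length(m) < 3L) next
    for (i in seq_len(length(m) - 2L)) {
      idx <- m[i]:m[i + 2L]
      cc_of <- function(tr) {
        r <- resample_cycle(tr$right[idx], kin$resample_len)
        l <- resample_cycle(tr$left[idx], kin$resample_len)
        align_and_cc(r, l, kin$max_lag_frac, circular = TRUE)$cc
      }
      knee_cc <- c(knee_cc, cc_of(knee))
      step_cc <- c(step_cc, cc_of(foot_x))
    }
  }
  list(knee_angle_symmetry = summary_stats(knee_cc),
       step_symmetry = summary_stats(step_cc))
}

#' Extract stand-up-and-walk features
#'
#' Runs [segment_saw()] on the global pelvis track, then assembles the gait
#' feature set: knee-angle and step symmetries, step length/width/time,
#' time to stand, turning time, walking speed and cadence.
#'
#' @param rec a pre-processed SAW [recording()].
#' @param cfg a [kinematics_config()].
#' @param saw a [saw_config()].
#' @return an `nk_features` object.
#' @export
extract_saw <- function(rec, cfg = kinematics_config(), saw = saw_config()) {
  pelvis <- get_sequence(rec, "B2", "center")
  segs <- segment_saw(pelvis, saw)
  dsaw <- feet_distance_series(rec)
  st <- step_features(dsaw, segs, cfg, saw)
  gl <- gait_global_features(pelvis, dsaw, segs, cfg, saw)
  sy <- gait_symmetries(rec, segs, cfg, saw)
  out <- c(
    stats_entries("saw.knee_sym", sy$knee_angle_symmetry),
    stats_entries("saw.step_sym", sy$step_symmetry),
    stats_entries("saw.step_length", st$step_length),
    stats_entries("saw.step_width", st$step_width),
    stats_entries("saw.step_time", st$step_time),
    saw.time_to_stand = segs$time_to_stand,
    stats_entries("saw.turn_time", summary_stats(segs$turning_times)),
    stats_entries("saw.walk_speed", gl$walking_speed, stats = c("mean", "std")),
    stats_entries("saw.cadence", gl$cadence, stats = c("mean", "std")))
  nk_features("SAW", out, rec)
}
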