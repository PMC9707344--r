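# Test-specific feature extraction: finger tapping (FT), finger-to-finger
# (FTF), forearm roll (FR).

#' Kinematics thresholds
#'
#' @param min_prominence_frac extremum prominence as a fraction of the
#'   signal's global range (default 0.2).
#' @param min_period_upper_s minimum cycle period for upper-limb tests
#'   (default 0.15 s, i.e. movement up to ~6.7 Hz).
#' @param min_period_gait_s minimum step period for gait (default 0.3 s).
#' @param resample_len common length cycles are resampled to before pairwise
#'   correlation (default 100).
#' @param max_lag_frac lag search window for gait cycle alignment, as a
#'   fraction of the resampled length (default 0.5, i.e. up to half a
#'   stride).
#' @return An object of class `kinematics_config`.
#' @export
kinematics_config <- function(min_prominence_frac = 0.2,
                              min_period_upper_s = 0.15,
                              min_period_gait_s = 0.3,
                              resample_len = 100L,
                              max_lag_frac = 0.5) {
  structure(list(min_prominence_frac = min_prominence_frac,
                 min_period_upper_s = min_period_upper_s,
                 min_period_gait_s = min_period_gait_s,
                 resample_len = as.integer(resample_len),
                 max_lag_frac = max_lag_frac),
            class = "kinematics_config")
}

# Feature-set container shared by all tests.
nk_features <- function(test, values, rec) {
  structure(list(test = test, values = values,
                 subject_id = rec$subject_id, label = rec$label,
                 device = rec$device,
                 recording_id = rec$recording_id %||%
                   paste(rec$subject_id, rec$test, rec$label, rec$device,
                         sep = "_")),
            class = "nk_features")
}

#' @export
print.nk_features <- function(x, ...) {
  cat(sprintf("<%s features> %s (%s, %s): %d features\n", x$test,
              x$recording_id, x$label, x$device, length(x$values)))
  print(utils::head(round(x$values, 4), 12))
  invisible(x)
}

side_suffix <- c(right = "r", left = "l")

# Unwrapped velocity-angle series atan2(vy, vx) of one cycle. The velocity
# direction is undefined where the motion (nearly) stops -- at the turning
# points of a cycle, where the true angle flips by exactly pi with no
# preferred sign. Low-speed samples are masked, each moving run is unwrapped,
# and runs are stitched across the gaps: a gap whose wrapped angle change is
# near zero is a slow spot (continuation), one near +/- pi is a motion
# reversal, resolved to +pi by convention so the series is reproducible
# across cycles.
velocity_angle <- function(vx, vy, low_speed_frac = 0.1, smooth_k = 5L) {
  # a short moving average stabilizes the direction estimate at low speeds,
  # where frame noise would otherwise cause 2*pi unwrapping slips
  if (smooth_k > 1L) {
    vx <- moving_avg(vx, smooth_k)
    vy <- moving_avg(vy, smooth_k)
  }
  sp <- sqrt(vx^2 + vy^2)
  mx <- max(sp)
  if (!is.finite(mx) || mx == 0) return(rep(NA_real_, length(vx)))
  moving <- sp >= low_speed_frac * mx
  th <- rep(NA_real_, length(vx))
  runs <- true_runs(moving)
  prev_end <- NULL
  prev_idx <- NULL
  for (r in seq_len(nrow(runs))) {
    idx <- runs[r, "start"]:runs[r, "end"]
    seg <- unwrap_angle(atan2(vy[idx], vx[idx]))
    if (!is.null(prev_end)) {
      # reversal or slow spot? judge from mean velocity vectors over a few
      # samples on each side of the gap, where speed (hence direction) is
      # more reliable than at the single edge samples
      nb <- min(5L, length(prev_idx)); na <- min(5L, length(idx))
      vb <- c(mean(vx[utils::tail(prev_idx, nb)]), mean(vy[utils::tail(prev_idx, nb)]))
      va <- c(mean(vx[idx[seq_len(na)]]), mean(vy[idx[seq_len(na)]]))
      target <- if (sum(vb * va) < 0) pi else 0
      step <- seg[1L] - prev_end
      seg <- seg + 2 * pi * round((target - step) / (2 * pi))
    }
    th[idx] <- seg
    prev_end <- seg[length(seg)]
    prev_idx <- idx
  }
  th <- zoo::na.approx(th, na.rm = FALSE)
  zoo::na.fill(th, fill = "extend")
}

# Expand summary_stats into named feature entries <prefix>.<stat>[.<side>].
stats_entries <- function(prefix, st, side = NULL, stats = c("mean", "std", "median")) {
  sfx <- if (is.null(side)) "" else paste0(".", side_suffix[[side]])
  setNames(unlist(st[stats]), paste0(prefix, ".", stats, sfx))
}

# Per-frame stability ratio of a paired joint (wrist/elbow): the distance
# between the right and left joints divided by the pelvis-anchored magnitude
# of the right joint. Anchoring the origin at the pelvis makes the
# denominator a body-relative magnitude, invariant to where the subject
# stands in the image.
stability_series <- function(rec, joint) {
  r <- get_sequence(rec, "B2", "right")
  l <- get_sequence(rec, "B2", "left")
  pr <- joint_track(r, "pelvis")
  num <- row_norms(joint_track(r, joint) - joint_track(l, joint))
  den <- row_norms(joint_track(r, joint) - pr)
  ratio <- num / den
  ratio[!is.finite(ratio)] <- NA_real_
  ratio
}

#' Fingertip separation series for finger tapping
#'
#' Per-frame Euclidean distance between the thumb tip and the index fingertip
#' of one hand -- the primary kinematic signal of the FT test.
#'
#' @param rec a pre-processed [recording()] with `H2` sequences.
#' @param side `"right"` or `"left"`.
#' @return a [signal1d()] in normalized length units.
#' @export
ft_distance_series <- function(rec, side = c("right", "left")) {
  side <- match.arg(side)
  h <- get_sequence(rec, "H2", side)
  d <- row_norms(joint_track(h, "thumb_tip") - joint_track(h, "index_tip"))
  signal1d(d, h$fps, "normalized-length")
}

# Cycle-derived summaries shared by FT and FR: period, frequency, amplitude
# per cycle, per-cycle max |velocity| and |acceleration|, and cycle rate.
cycle_kinematics <- function(sig, cs, amplitude_minmax = FALSE) {
  duration <- length(sig$values) / sig$fps
  if (cs$too_few) {
    na <- summary_stats(numeric(0))
    return(list(period = na, freq = na, amp = na, vmax = na, amax = na,
                rate = NA_real_, n_cycles = cs$n_cycles))
  }
  v <- derivative(sig, 1L)$values
  a <- derivative(sig, 2L)$values
  per_cycle <- function(x, f) vapply(seq_len(nrow(cs$cycles)), function(i)
    f(x[cs$cycles[i, 1L]:cs$cycles[i, 2L]]), numeric(1))
  amp <- if (amplitude_minmax) {
    vapply(seq_len(nrow(cs$cycles)), function(i) {
      idx <- cs$cycles[i, 1L]:cs$cycles[i, 2L]
      half <- refine_half(length(idx))
      refine_extremum_value(sig$values, idx[which.max(sig$values[idx])], half) -
        refine_extremum_value(sig$values, idx[which.min(sig$values[idx])], half)
    }, numeric(1))
  } else cs$amplitude
  list(period = summary_stats(cs$period),
       freq = summary_stats(1 / cs$period),
       amp = summary_stats(amp),
       vmax = summary_stats(per_cycle(abs(v), max)),
       amax = summary_stats(per_cycle(abs(a), max)),
       rate = cs$n_cycles / duration,
       n_cycles = cs$n_cycles,
       amp_per_cycle = amp)
}

#' Extract finger-tapping features
#'
#' Detects tapping cycles on the fingertip separation series of each hand and
#' summarizes amplitude, period, frequency, per-cycle maximum speed and
#' acceleration, tapping rate, their right/left asymmetries
#' ([asymmetry()] of the per-side means), and wrist/elbow stability (the mean,
#' SD and median over frames of the right-left joint distance relative to the
#' pelvis-anchored right-joint magnitude). Cycle-based fields are `NA` when
#' fewer than 2 cycles are detected on a side.
#'
#' @param rec a pre-processed FT [recording()].
#' @param cfg a [kinematics_config()].
#' @return an `nk_features` object.
#' @export
extract_ft <- function(rec, cfg = kinematics_config()) {
  out <- numeric()
  per_side <- list()
  for (side in c("right", "left")) {
    d <- ft_distance_series(rec, side)
    cs <- detect_cycles(d, cfg$min_prominence_frac, cfg$min_period_upper_s)
    ck <- cycle_kinematics(d, cs)
    per_side[[side]] <- ck
    out <- c(out,
      stats_entries("ft.amplitude", ck$amp, side),
      stats_entries("ft.period", ck$period, side),
      stats_entries("ft.frequency", ck$freq, side),
      stats_entries("ft.max_speed", ck$vmax, side, stats = "mean"),
      stats_entries("ft.max_accel", ck$amax, side),
      setNames(ck$rate, paste0("ft.tap_rate.", side_suffix[[side]])))
  }
  asym_of <- function(field) asymmetry(per_side$right[[field]]$mean,
                                       per_side$left[[field]]$mean)
  out <- c(out,
    ft.amplitude.asym = asym_of("amp"),
    ft.period.asym = asym_of("period"),
    ft.frequency.asym = asym_of("freq"),
    ft.max_speed.asym = asym_of("vmax"),
    ft.max_accel.asym = asym_of("amax"),
    stats_entries("ft.wrist_stability", summary_stats(stability_series(rec, "wrist"))),
    stats_entries("ft.elbow_stability", summary_stats(stability_series(rec, "elbow"))))
  nk_features("FT", out, rec)
}

#' Horizontal and vertical mirror symmetry of finger-to-finger motion
#'
#' In a normal FTF performance the two index fingers travel mirrored paths:
#' the left x-trajectory equals the negated right x-trajectory. The
#' symmetries are the correlations `Sx = CC(x_l, -x_r)` and
#' `Sy = CC(y_l, -y_r)` of the mid-index-finger joint trajectories
#' (correlation centers each series internally, so the vertical symmetry
#' compares mirrored *excursions* about the mean).
#'
#' @param rec a pre-processed FTF [recording()].
#' @return list with `sym_x` and `sym_y` in `[-1, 1]` (`NA` for constant
#'   trajectories).
#' @export
ftf_symmetries <- function(rec) {
  r <- joint_track(get_sequence(rec, "H2", "right"), "index_mid")
  l <- joint_track(get_sequence(rec, "H2", "left"), "index_mid")
  list(sym_x = pearson_cc(l[, 1L], -r[, 1L]),
       sym_y = pearson_cc(l[, 2L], -r[, 2L]))
}

#' Extract finger-to-finger features
#'
#' Cycles (one up-meet-up excursion) are segmented on the vertical coordinate
#' of the mid-index joint of the dominant hand (the one with the larger
#' vertical excursion); both hands are sliced on the same boundaries. Per
#' cycle and side the features are: period; average speed (trajectory path
#' length within each half-cycle divided by that half's duration); path
#' smoothness of each half-cycle ([path_smoothness()]); and the unwrapped
#' velocity-angle series `atan2(dy/dt, dx/dt)`, resampled to a common length,
#' whose all-pairs correlations across cycles measure cycle-to-cycle
#' consistency. Mirror symmetries come from [ftf_symmetries()].
#'
#' @param rec a pre-processed FTF [recording()].
#' @param cfg a [kinematics_config()].
#' @return an `nk_features` object.
#' @export
extract_ftf <- function(rec, cfg = kinematics_config()) {
  tracks <- list(right = joint_track(get_sequence(rec, "H2", "right"), "index_mid"),
                 left = joint_track(get_sequence(rec, "H2", "left"), "index_mid"))
  fps <- rec$fps
  excursion <- vapply(tracks, function(m) diff(range(m[, 2L], na.rm = TRUE)),
                      numeric(1))
  dominant <- names(which.max(excursion))
  ys <- signal1d(tracks[[dominant]][, 2L], fps, "normalized-length")
  cs <- detect_cycles(ys, cfg$min_prominence_frac, cfg$min_period_upper_s,
                      boundary = "maxima")
  out <- numeric()
  sym <- ftf_symmetries(rec)
  out <- c(out, ftf.sym_x = sym$sym_x, ftf.sym_y = sym$sym_y)
  for (side in c("right", "left")) {
    m <- tracks[[side]]
    if (cs$n_cycles >= 1L) {
      speeds <- c(); ps <- c(); thetas <- list()
      vx <- derivative(signal1d(m[, 1L], fps), 1L)$values
      vy <- derivative(signal1d(m[, 2L], fps), 1L)$values
      for (i in seq_len(nrow(cs$cycles))) {
        i0 <- cs$cycles[i, 1L]; i1 <- cs$cycles[i, 2L]
        seg <- m[i0:i1, , drop = FALSE]
        # the meet point (lowest vertical position) splits the cycle in half
        mid <- i0 + which.min(m[i0:i1, 2L]) - 1L
        for (h in list(i0:mid, mid:i1)) {
          if (length(h) < 3L) next
          dur <- (length(h) - 1L) / fps
          speeds <- c(speeds, polyline_length(m[h, , drop = FALSE]) / dur)
          ps <- c(ps, path_smoothness(m[h, , drop = FALSE]))
        }
        th <- velocity_angle(vx[i0:i1], vy[i0:i1])
        if (anyNA(th)) next
        thetas[[length(thetas) + 1L]] <- resample_cycle(th, cfg$resample_len)
      }
      vcc <- c()
      if (length(thetas) >= 2L) {
        pairs <- utils::combn(length(thetas), 2L)
        vcc <- vapply(seq_len(ncol(pairs)), function(j)
          pearson_cc(thetas[[pairs[1L, j]]], thetas[[pairs[2L, j]]]), numeric(1))
      }
      period_st <- if (cs$too_few) summary_stats(numeric(0)) else summary_stats(cs$period)
      out <- c(out,
        stats_entries("ftf.period", period_st, side, stats = c("mean", "std")),
        stats_entries("ftf.avg_speed", summary_stats(speeds), side, stats = c("mean", "std")),
        stats_entries("ftf.path_smoothness", summary_stats(ps), side, stats = c("mean", "std")),
        stats_entries("ftf.velangle_sym", summary_stats(vcc), side, stats = c("mean", "std")))
    } else {
      na <- summary_stats(numeric(0))
      out <- c(out,
        stats_entries("ftf.period", na, side, stats = c("mean", "std")),
        stats_entries("ftf.avg_speed", na, side, stats = c("mean", "std")),
        stats_entries("ftf.path_smoothness", na, side, stats = c("mean", "std")),
        stats_entries("ftf.velangle_sym", na, side, stats = c("mean", "std")))
    }
  }
  nk_features("FTF", out, rec)
}

#' Extract forearm-roll features
#'
#' Rolling cycles are detected on the vertical coordinate of each wrist. Per
#' side the features are: amplitude (per-cycle vertical range), period and
#' their summaries with right/left asymmetries; per-cycle maximum speed and
#' acceleration of the vertical wrist motion; rolling speed (amplitude
#' divided by half the period, per cycle); rolling rate (cycles per second);
#' and elbow stability (as in [extract_ft()]).
#'
#' @param rec a pre-processed FR [recording()].
#' @param cfg a [kinematics_config()].
#' @return an `nk_features` object.
#' @export
extract_fr <- function(rec, cfg = kinematics_config()) {
  out <- numeric()
  per_side <- list()
  for (side in c("right", "left")) {
    w <- joint_track(get_sequence(rec, "B2", side), "wrist")
    ysig <- signal1d(w[, 2L], rec$fps, "normalized-length")
    cs <- detect_cycles(ysig, cfg$min_prominence_frac, cfg$min_period_upper_s)
    ck <- cycle_kinematics(ysig, cs, amplitude_minmax = TRUE)
    roll_speed <- if (cs$too_few) summary_stats(numeric(0)) else
      summary_stats(ck$amp_per_cycle / (cs$period / 2))
    per_side[[side]] <- ck
    out <- c(out,
      stats_entries("fr.amplitude", ck$amp, side),
      stats_entries("fr.period", ck$period, side),
      stats_entries("fr.max_speed", ck$vmax, side),
      stats_entries("fr.max_accel", ck$amax, side),
      stats_entries("fr.roll_speed", roll_speed, side),
      setNames(ck$rate, paste0("fr.roll_rate.", side_suffix[[side]])))
  }
  asym_of <- function(field) asymmetry(per_side$right[[field]]$mean,
                                       per_side$left[[field]]$mean)
  out <- c(out,
    fr.amplitude.asym = asym_of("amp"),
    fr.period.asym = asym_of("period"),
    fr.max_speed.asym = asym_of("vmax"),
    fr.max_accel.asym = asym_of("amax"),
    stats_entries("fr.elbow_stability", summary_stats(stability_series(rec, "elbow"))))
  nk_features("FR", out, rec)
}

#' Extract the feature set matching a recording's test
#'
#' Dispatches to [extract_ft()], [extract_ftf()], [extract_fr()] or
#' [extract_saw()] according to `rec$test`.
#'
#' @param rec a pre-processed [recording()].
#' @param cfg a [kinematics_config()].
#' @return an `nk_features` object.
#' @export
extract_features <- function(rec, cfg = kinematics_config()) {
  switch(rec$test,
         FT = extract_ft(rec, cfg),
         FTF = extract_ftf(rec, cfg),
         FR = extract_fr(rec, cfg),
         SAW = extract_saw(rec, cfg))
}

#' Pre-process and extract features in one step
#' @param rec a raw [recording()].
#' @param pre a [preprocess_config()].
#' @param cfg a [kinematics_config()].
#' @return an `nk_features` object.
#' @export
analyze_recording <- function(rec, pre = preprocess_config(),
                              cfg = kinematics_config()) {
  extract_features(preprocess_recording(rec, pre), cfg)
}
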