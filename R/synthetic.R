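# Seeded synthetic pose generators for all four tests, with ground-truth
# motion parameters, emulating the study's impairment manipulations (rubber
# band, wrist brace, knee brace, mimicked tremor).

# Raw-unit scale of the synthetic rigs: the forearm (upper-limb tests) and
# the pelvis-neck distance (SAW) are this many raw units long, so commanded
# normalized-unit parameters translate to raw coordinates as value * REF.
.REF_UPPER <- 120
.REF_SAW <- 100

#' Synthetic motion specification
#'
#' Ground-truth parameters for one synthetic recording. Defaults reproduce
#' the study conditions: 15 s upper-limb tests / 45 s SAW at 60 fps; finger
#' tapping at 2 Hz with unit (forearm-length) amplitude; forearm roll at
#' 1.5 Hz with 0.3 orbit radius; gait with 0.55-unit step length and 0.55 s
#' step time over 3 walking passes. The `"abnormal"` presets quantify the
#' physical impairment manipulations as parameter changes: FT -- one hand's
#' amplitude x0.4 and frequency x0.6 (rubber band); FTF -- a 6 Hz tremor of
#' 0.05 units superimposed on the finger path (mimicked tremor); FR -- both
#' frequencies x0.6 and the braced (left) radius x0.5 (wrist brace); SAW --
#' the braced knee's flexion capped at half its range and step length x0.7
#' (knee brace).
#'
#' @param test `"FT"`, `"FTF"`, `"FR"` or `"SAW"`.
#' @param preset `"normal"` or `"abnormal"`.
#' @param fps frames per second (default 60).
#' @param duration_s recording length (default 15 s; 45 s for SAW).
#' @param keypoint_noise_sd isotropic keypoint noise, in normalized units
#'   (default 0.01).
#' @param seed RNG seed for the recording.
#' @param ... named overrides of any test-specific field: `freq`, `amp`
#'   (named right/left pairs), `tremor_freq`, `tremor_amp`, `phase_delay_l`,
#'   `step_length`, `step_time`, `step_width`, `knee_range`,
#'   `knee_restriction`, `time_to_stand`, `sit_s`, `pause_s`, `n_passes`,
#'   `steps_per_pass`, `turn_s`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(test = c("FT", "FTF", "FR", "SAW"),
                           preset = c("normal", "abnormal"),
                           fps = 60, duration_s = NULL,
                           keypoint_noise_sd = 0.01, seed = 1L, ...) {
  test <- match.arg(test)
  preset <- match.arg(preset)
  duration_s <- duration_s %||% if (test == "SAW") 45 else 15
  base <- switch(test,
    FT = list(freq = c(right = 2, left = 2), amp = c(right = 1, left = 1),
              contact_gap = 0.05),
    FTF = list(freq = c(right = 1, left = 1), amp = c(right = 1, left = 1),
               tremor_freq = 6, tremor_amp = 0, tremor_phase_jitter = 0.15,
               phase_delay_l = 0),
    FR = list(freq = c(right = 1.5, left = 1.5), amp = c(right = 0.3, left = 0.3)),
    SAW = list(step_length = 0.55, step_time = 0.55, step_width = 0.12,
               knee_range = pi - 2.27, knee_restriction = 0,
               time_to_stand = 1.5, sit_s = 2, pause_s = 0.5,
               n_passes = 3L, steps_per_pass = 8L, turn_s = 1))
  if (preset == "abnormal") {
    base <- switch(test,
      FT = { base$amp[["left"]] <- base$amp[["left"]] * 0.4
             base$freq[["left"]] <- base$freq[["left"]] * 0.6; base },
      FTF = { base$tremor_amp <- 0.05; base },
      FR = { base$freq <- base$freq * 0.6
             base$amp[["left"]] <- base$amp[["left"]] * 0.5; base },
      SAW = { base$knee_restriction <- 0.5
              base$step_length <- base$step_length * 0.7; base })
  }
  ov <- list(...)
  for (nm in names(ov)) base[[nm]] <- ov[[nm]]
  sp <- c(list(test = test, preset = preset, fps = fps,
               duration_s = duration_s,
               keypoint_noise_sd = keypoint_noise_sd, seed = as.integer(seed)),
          base)
  if (!is.null(sp$freq)) {
    if (any(sp$freq <= 0.3 | sp$freq >= 8))
      nk_stop("frequencies must lie in (0.3, 8) Hz", "neurokin_format_error")
    if (duration_s * min(sp$freq) < 3)
      nk_stop("recording too short for 3 movement cycles", "neurokin_format_error")
  }
  if (!is.null(sp$amp) && any(sp$amp < 0))
    nk_stop("amplitudes must be non-negative", "neurokin_format_error")
  structure(sp, class = "synthetic_spec")
}

# Static upper-body B2 rig (raw units, y-up): pelvis at the origin, neck one
# torso up, elbows/wrists placed so the forearm is exactly .REF_UPPER long.
upper_body_rig <- function(side) {
  sx <- if (side == "right") 1 else -1
  list(pelvis = c(0, 0), neck = c(0, 240), nose = c(0, 280),
       eye = c(sx * 10, 290), ear = c(sx * 25, 285),
       shoulder = c(sx * 80, 220), elbow = c(sx * 150, 120),
       wrist = c(sx * 150, 240))
}

# Assemble a pose_sequence from a named list of N x D joint tracks (raw
# units), adding iid keypoint noise.
build_sequence <- function(tree_id, side, tracks, n, fps, noise_sd_raw) {
  spec <- skeleton_spec(tree_id)
  coords <- array(NA_real_, c(n, spec$n_joints, spec$ndim))
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    if (is.null(dim(tr))) tr <- matrix(tr, nrow = n, ncol = length(tr), byrow = TRUE)
    k <- joint_index(spec, nm) + 1L
    coords[, k, ] <- tr + matrix(stats::rnorm(length(tr), 0, noise_sd_raw),
                                 nrow = n)
  }
  pose_sequence(spec, side, coords, fps = fps)
}

#' Generate a synthetic finger-tapping recording
#'
#' Each hand's fingertip separation follows
#' `d(t) = (A/2) * (1 - cos(2 pi f t + phase))` along a fixed opening axis:
#' the thumb tip stays at the hand anchor while the index tip opens and
#' closes, over a static wrist/elbow/pelvis rig whose forearm provides the
#' normalization reference. Isotropic keypoint noise is added everywhere.
#'
#' @param spec a [synthetic_spec()] with `test = "FT"`.
#' @return list with elements `recording` and `spec`.
#' @export
gen_ft <- function(spec = synthetic_spec("FT")) {
  stopifnot(spec$test == "FT")
  set.seed(spec$seed)
  n <- as.integer(round(spec$duration_s * spec$fps))
  t <- seq_len(n) / spec$fps
  noise <- spec$keypoint_noise_sd * .REF_UPPER
  seqs <- list()
  for (side in c("right", "left")) {
    sx <- if (side == "right") 1 else -1
    phase <- stats::runif(1, 0, 2 * pi)
    # contact_gap: fingertip keypoints sit on the finger pads and never
    # coincide; a zero true separation would also bias the measured
    # (noisy, non-negative) distance upward at contact
    d <- spec$contact_gap +
      (spec$amp[[side]] / 2) * (1 - cos(2 * pi * spec$freq[[side]] * t + phase))
    anchor <- c(sx * 150, 250)
    axis <- c(sx * cos(pi / 3), sin(pi / 3))   # fingers open up and outward
    open <- outer(d * .REF_UPPER, axis)
    hand <- list(
      wrist = c(sx * 150, 240), thumb_base = anchor + c(sx * 8, -14),
      thumb_mid = anchor + c(sx * 5, -7), thumb_tip = anchor,
      index_base = anchor + c(sx * -6, -10),
      index_mid = sweep(open / 2, 2L, anchor + c(sx * -3, -5), "+"),
      index_tip = sweep(open, 2L, anchor, "+"))
    seqs[[seq_key("H2", side)]] <-
      build_sequence("H2", side, hand, n, spec$fps, noise)
    seqs[[seq_key("B2", side)]] <-
      build_sequence("B2", side, upper_body_rig(side), n, spec$fps, noise)
  }
  rec <- recording("synthetic", "FT", seqs,
                   label = if (spec$preset == "normal") "normal" else "abnormal")
  list(recording = rec, spec = spec)
}

# Quadratic Bezier arc between an "up" and a "meet" position, with an outward
# control point; returns position and tangent at parameter u in [0, 1].
ftf_arc <- function(u, up, meet, ctrl) {
  b <- cbind((1 - u)^2, 2 * u * (1 - u), u^2)
  pts <- b %*% rbind(up, ctrl, meet)
  db <- cbind(-2 * (1 - u), 2 - 4 * u, 2 * u)
  tan <- db %*% rbind(up, ctrl, meet)
  list(pos = pts, tangent = tan)
}

#' Generate a synthetic finger-to-finger recording
#'
#' The mid-index joint of each hand travels a mirrored quadratic arc between
#' a raised "up" position and a "meet" position in front of the chest, cycled
#' at the commanded frequency. A tremor term adds a sinusoid of amplitude
#' `tremor_amp` perpendicular to the local path tangent; `phase_delay_l`
#' delays the left hand by a fraction of a cycle (decorrelating the mirror
#' symmetry).
#'
#' @param spec a [synthetic_spec()] with `test = "FTF"`.
#' @return list with elements `recording` and `spec`.
#' @export
gen_ftf <- function(spec = synthetic_spec("FTF")) {
  stopifnot(spec$test == "FTF")
  set.seed(spec$seed)
  n <- as.integer(round(spec$duration_s * spec$fps))
  t <- seq_len(n) / spec$fps
  noise <- spec$keypoint_noise_sd * .REF_UPPER
  phase0 <- stats::runif(1, 0, 2 * pi)
  seqs <- list()
  for (side in c("right", "left")) {
    sx <- if (side == "right") 1 else -1
    delay <- if (side == "left") spec$phase_delay_l * 2 * pi else 0
    u <- (1 - cos(2 * pi * spec$freq[[side]] * t + phase0 + delay)) / 2
    up <- c(sx * 0.9, 1.6) * .REF_UPPER
    meet <- c(sx * 0.1, 0.8) * .REF_UPPER
    ctrl <- (up + meet) / 2 + c(sx * 0.35, 0.1) * .REF_UPPER
    arc <- ftf_arc(u, up, meet, ctrl)
    pos <- arc$pos
    if (spec$tremor_amp > 0) {
      nrm <- cbind(-arc$tangent[, 2L], arc$tangent[, 1L])
      nrm <- nrm / pmax(row_norms(nrm), 1e-9)
      # physiological tremor is quasi-periodic, not phase-locked to the
      # movement: let the tremor phase drift as a random walk
      drift <- cumsum(stats::rnorm(n, 0, spec$tremor_phase_jitter))
      pos <- pos + nrm * (spec$tremor_amp * .REF_UPPER *
                            sin(2 * pi * spec$tremor_freq * t + drift))
    }
    hand <- list(
      index_mid = pos,
      index_tip = sweep(pos, 2L, c(sx * 4, 12), "+"),
      index_base = sweep(pos, 2L, c(sx * 2, -12), "+"),
      wrist = sweep(pos, 2L, c(sx * 6, -40), "+"),
      thumb_base = sweep(pos, 2L, c(sx * 12, -30), "+"),
      thumb_mid = sweep(pos, 2L, c(sx * 14, -22), "+"),
      thumb_tip = sweep(pos, 2L, c(sx * 16, -16), "+"))
    seqs[[seq_key("H2", side)]] <-
      build_sequence("H2", side, hand, n, spec$fps, noise)
    seqs[[seq_key("B2", side)]] <-
      build_sequence("B2", side, upper_body_rig(side), n, spec$fps, noise)
  }
  rec <- recording("synthetic", "FTF", seqs,
                   label = if (spec$preset == "normal") "normal" else "abnormal")
  list(recording = rec, spec = spec)
}

#' Generate a synthetic forearm-roll recording
#'
#' The two wrists orbit in antiphase: vertical coordinates
#' `y(t) = c + R * cos(2 pi f t)` (left offset by pi), with per-side radii.
#' Elbows are static, so the median forearm length stays at the reference.
#'
#' @param spec a [synthetic_spec()] with `test = "FR"`.
#' @return list with elements `recording` and `spec`.
#' @export
gen_fr <- function(spec = synthetic_spec("FR")) {
  stopifnot(spec$test == "FR")
  set.seed(spec$seed)
  n <- as.integer(round(spec$duration_s * spec$fps))
  t <- seq_len(n) / spec$fps
  noise <- spec$keypoint_noise_sd * .REF_UPPER
  phase0 <- stats::runif(1, 0, 2 * pi)
  seqs <- list()
  for (side in c("right", "left")) {
    sx <- if (side == "right") 1 else -1
    ph <- phase0 + if (side == "left") pi else 0
    r <- spec$amp[[side]] * .REF_UPPER
    rig <- upper_body_rig(side)
    # the horizontal wobble is kept small: it lengthens the apparent forearm
    # (quadratically) and would bias the normalization reference
    wrist <- cbind(sx * 110 + 0.1 * r * sin(2 * pi * spec$freq[[side]] * t + ph),
                   240 + r * cos(2 * pi * spec$freq[[side]] * t + ph))
    rig$wrist <- wrist
    rig$elbow <- c(sx * 110, 120)
    seqs[[seq_key("B2", side)]] <-
      build_sequence("B2", side, rig, n, spec$fps, noise)
  }
  rec <- recording("synthetic", "FR", seqs,
                   label = if (spec$preset == "normal") "normal" else "abnormal")
  list(recording = rec, spec = spec)
}

# Piecewise-linear motion with short smoothing ramps: returns cumulative
# position for a velocity profile that ramps 0 -> v over `ramp` s, holds, and
# ramps back to 0, covering `dist` in `dur` s.
trapezoid_motion <- function(t_local, dur, dist, ramp = 0.08) {
  v <- dist / (dur - ramp)           # plateau speed
  pos <- numeric(length(t_local))
  for (i in seq_along(t_local)) {
    tt <- min(max(t_local[i], 0), dur)
    pos[i] <-
      if (tt < ramp) v * tt^2 / (2 * ramp)
      else if (tt < dur - ramp) v * ramp / 2 + v * (tt - ramp)
      else dist - v * (dur - tt)^2 / (2 * ramp)
  }
  pos
}

# Raised-cosine bump of width w centered at c (phase in [0, 1)).
phase_bump <- function(phi, c, w) {
  d <- phi - c
  ifelse(abs(d) < w / 2, cos(pi * d / w)^2, 0)
}

#' Generate a synthetic stand-up-and-walk recording
#'
#' Builds a global 2D pelvis track (sit, a near-linear rise over the
#' commanded time to stand, a standing pause, then back-and-forth walking
#' passes separated by stationary turns, padded with quiet standing to the
#' recording duration) plus pelvis-relative 3D legs: foot positions alternate
#' in antiphase so the feet-distance maxima equal the commanded step length
#' and occur every commanded step time, and each knee follows a double-bump
#' flexion profile per stride (half-stride right/left offset). The knee-brace
#' manipulation caps the braced (left) knee's flexion at
#' `(1 - knee_restriction)` of its range -- flattening the waveform rather
#' than merely scaling it, as a rigid brace does.
#'
#' @param spec a [synthetic_spec()] with `test = "SAW"`.
#' @return list with elements `recording` and `spec`.
#' @export
gen_saw <- function(spec = synthetic_spec("SAW")) {
  stopifnot(spec$test == "SAW")
  set.seed(spec$seed)
  fps <- spec$fps
  stride_s <- 2 * spec$step_time
  walk_s <- spec$steps_per_pass * spec$step_time
  events_end <- spec$sit_s + spec$time_to_stand + spec$pause_s +
    spec$n_passes * walk_s + (spec$n_passes - 1L) * spec$turn_s + 1
  dur <- max(spec$duration_s, events_end)
  n <- as.integer(round(dur * fps))
  t <- seq_len(n) / fps
  rise_h <- 0.6                                   # pelvis rise, normalized units
  noise_b2 <- spec$keypoint_noise_sd * .REF_SAW

  ## ---- global pelvis track (normalized units, converted to raw below) ----
  x <- numeric(n); y <- numeric(n)
  y_sit <- 0; y_stand <- rise_h
  t_rise <- spec$sit_s
  t_pause <- t_rise + spec$time_to_stand
  y <- y_sit + trapezoid_motion(t - t_rise, spec$time_to_stand, rise_h)
  x[] <- 0
  phase <- rep(NA_real_, n)    # stride phase while walking, NA elsewhere
  t0 <- t_pause + spec$pause_s
  dir <- 1
  for (p in seq_len(spec$n_passes)) {
    inpass <- t >= t0 & t < t0 + walk_s
    x[t >= t0] <- x[t >= t0][1L] +
      dir * trapezoid_motion(t[t >= t0] - t0, walk_s,
                             spec$steps_per_pass * spec$step_length, ramp = 0.15)
    phase[inpass] <- ((t[inpass] - t0) / stride_s) %% 1
    t0 <- t0 + walk_s + spec$turn_s
    dir <- -dir
  }
  pelvis <- cbind(x, y + 1.0)    # pelvis rides ~1 unit above the seat origin
  b2 <- list(pelvis = pelvis * .REF_SAW,
             neck = cbind(pelvis[, 1L], pelvis[, 2L] + 1.0) * .REF_SAW)
  seq_b2 <- build_sequence("B2", "center", b2, n, fps, noise_b2)

  ## ---- pelvis-relative 3D legs ----
  sw <- spec$step_width
  ax <- sqrt(max(spec$step_length^2 - sw^2, 0)) / 2
  walk <- !is.na(phase)
  seqs <- list(`B2.center` = seq_b2)
  for (side in c("right", "left")) {
    sz <- if (side == "right") 1 else -1
    ph <- ifelse(walk, (phase + if (side == "left") 0.5 else 0) %% 1, NA_real_)
    # antiphase feet: the left foot mirrors the right foot's fore-aft swing
    foot_x <- ifelse(walk, ax * sin(2 * pi * phase) * (if (side == "right") 1 else -1), 0)
    foot <- cbind(foot_x, -1.6, sz * sw / 2)
    hip <- cbind(rep(0, n), -0.1, sz * sw / 2)
    # knee flexion: double-bump per stride (swing + loading). A brace on the
    # left knee caps flexion at (1 - restriction) of the range, widens and
    # delays the swing bump (the leg is swung stiffly) and suppresses the
    # loading-response flexion.
    r_eff <- if (side == "left") spec$knee_restriction else 0
    flex <- numeric(n)
    flex[walk] <- spec$knee_range *
      (phase_bump(ph[walk], 0.75 + 0.1 * r_eff, 0.5 * (1 + 0.8 * r_eff)) +
         0.25 * (1 - r_eff) * phase_bump(ph[walk], 0.15, 0.3))
    sitting <- t < t_rise
    rising <- t >= t_rise & t < t_pause
    flex[sitting] <- spec$knee_range * 0.9
    flex[rising] <- spec$knee_range * 0.9 *
      (1 - (t[rising] - t_rise) / spec$time_to_stand)
    if (r_eff > 0) flex <- pmin(flex, spec$knee_range * (1 - r_eff))
    theta <- pi - flex
    # place the knee so the hip-knee-foot angle equals theta exactly:
    # isoceles construction in the sagittal plane
    u <- foot - hip
    d <- row_norms(u)
    h_off <- (d / 2) / tan(theta / 2)
    nrm <- cbind(-u[, 2L], u[, 1L], 0)           # forward-facing in-plane normal
    nrm <- nrm / pmax(row_norms(nrm), 1e-12)
    knee <- (hip + foot) / 2 + nrm * h_off
    tracks <- list(pelvis = matrix(0, n, 3L),
                   spine = matrix(rep(c(0, 0.5, 0), each = n), n, 3L),
                   hip = hip, knee = knee, foot = foot)
    tracks <- lapply(tracks, function(m) m * .REF_SAW)
    seqs[[seq_key("B3", side)]] <-
      build_sequence("B3", side, tracks, n, fps,
                     spec$keypoint_noise_sd * .REF_SAW)
  }
  rec <- recording("synthetic", "SAW", seqs,
                   label = if (spec$preset == "normal") "normal" else "abnormal",
                   view = "sagittal")
  list(recording = rec, spec = spec)
}

#' Generate one synthetic recording of any test
#' @param spec a [synthetic_spec()].
#' @return list with elements `recording` and `spec`.
#' @export
gen_recording <- function(spec) {
  switch(spec$test, FT = gen_ft(spec), FTF = gen_ftf(spec), FR = gen_fr(spec),
         SAW = gen_saw(spec))
}

# Apply subject/device multipliers to a spec's kinematic parameters.
scale_spec <- function(spec, f_mult, a_mult) {
  if (!is.null(spec$freq)) spec$freq <- pmin(spec$freq * f_mult, 7.9)
  if (!is.null(spec$amp)) spec$amp <- spec$amp * a_mult
  if (!is.null(spec$tremor_amp)) spec$tremor_amp <- spec$tremor_amp * a_mult
  if (spec$test == "SAW") {
    spec$step_length <- spec$step_length * a_mult
    spec$step_time <- spec$step_time / f_mult
    spec$time_to_stand <- spec$time_to_stand / f_mult
  }
  spec
}

#' Generate a synthetic study cohort
#'
#' Emulates the study design: every subject performs the test normally and
#' with the simulated impairment, each captured on two devices, giving four
#' recordings per subject. Per-subject lognormal random effects (sd
#' `subject_sd`) on speed and amplitude apply to both the normal and abnormal
#' specs (the abnormal manipulation is relative to the subject's own
#' baseline); smaller per-device lognormal jitter (sd `device_jitter_sd`)
#' perturbs each device's capture independently.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param test `"FT"`, `"FTF"`, `"FR"` or `"SAW"`.
#' @param normal_spec,abnormal_spec base [synthetic_spec()]s; defaults are
#'   the test's presets.
#' @param devices character vector of device tags (default tablet/phone).
#' @param subject_sd sd of the per-subject lognormal multipliers (default 0.1).
#' @param device_jitter_sd sd of the per-device lognormal multipliers
#'   (default 0.02).
#' @param seed cohort seed; every recording's seed derives from it.
#' @return list of entries, each `list(recording, spec, subject_id, label,
#'   device)`.
#' @export
gen_cohort <- function(n_subjects, test,
                       normal_spec = synthetic_spec(test, "normal"),
                       abnormal_spec = synthetic_spec(test, "abnormal"),
                       devices = c("tablet", "phone"),
                       subject_sd = 0.1, device_jitter_sd = 0.02, seed = 1L) {
  stopifnot(n_subjects >= 2)
  out <- list()
  for (s in seq_len(n_subjects)) {
    set.seed(derive_seed(seed, s))
    f_mult <- stats::rlnorm(1, 0, subject_sd)
    a_mult <- stats::rlnorm(1, 0, subject_sd)
    subject_id <- sprintf("S%02d", s)
    for (label_i in 1:2) {
      base <- if (label_i == 1L) normal_spec else abnormal_spec
      for (d in seq_along(devices)) {
        set.seed(derive_seed(seed, s, label_i, d))
        fj <- stats::rlnorm(1, 0, device_jitter_sd)
        aj <- stats::rlnorm(1, 0, device_jitter_sd)
        sp <- scale_spec(base, f_mult * fj, a_mult * aj)
        sp$seed <- derive_seed(seed, s, label_i, d, 99)
        g <- gen_recording(sp)
        rec <- g$recording
        rec$subject_id <- subject_id
        rec$device <- devices[d]
        rec$recording_id <- paste(subject_id, test, rec$label, devices[d],
                                  sep = "_")
        out[[length(out) + 1L]] <- list(recording = rec, spec = g$spec,
                                        subject_id = subject_id,
                                        label = rec$label,
                                        device = devices[d])
      }
    }
  }
  out
}
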