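saw_quick <- function(seed, ...) {
  g <- gen_saw(synthetic_spec("SAW", seed = seed, ...))
  preprocess_recording(g$recording)
}

test_that("a standard recording segments into one stand-up, three walks, two turns", {
  rec <- saw_quick(101)
  segs <- segment_saw(get_sequence(rec, "B2", "center"))
  kinds <- table(factor(segs$segments$kind, c("SU", "W", "TU")))
  expect_equal(unname(kinds[["SU"]]), 1L)
  expect_equal(unname(kinds[["W"]]), 3L)
  expect_equal(unname(kinds[["TU"]]), 2L)
  expect_lt(abs(segs$time_to_stand - 1.5), 0.1)
  expect_true(all(abs(segs$turning_times - 1.0) < 0.15))
  # segments are ordered, non-overlapping and inside the recording
  s <- segs$segments
  expect_true(all(s$start <= s$end))
  expect_true(all(diff(s$start) > 0))
  expect_true(all(s$end[-nrow(s)] <= s$start[-1]))
  expect_lte(sum(s$end - s$start + 1) / segs$fps,
             n_frames(get_sequence(rec, "B2", "center")) / segs$fps)
})

test_that("monotone walking yields one walk segment and no turns", {
  rec <- saw_quick(102, n_passes = 1L)
  segs <- segment_saw(get_sequence(rec, "B2", "center"))
  expect_equal(sum(segs$segments$kind == "W"), 1L)
  expect_equal(sum(segs$segments$kind == "TU"), 0L)
})

test_that("a static pelvis track is a segmentation error", {
  pelvis <- mk_seq("B2", "center",
                   list(pelvis = c(0, 100), neck = c(0, 200)), n = 600)
  expect_error(segment_saw(pelvis), class = "neurokin_segmentation_error")
})

test_that("the feet-distance series is a plain 3D distance", {
  n <- 60
  rec <- recording("T01", "SAW", list(
    B3.right = mk_seq("B3", "right", list(foot = c(0.15, 0, 0),
                                          knee = c(0, -1, 0.1),
                                          hip = c(0, -0.1, 0.1),
                                          pelvis = c(0, 0, 0)), n),
    B3.left = mk_seq("B3", "left", list(foot = c(-0.15, 0, 0),
                                        knee = c(0, -1, -0.1),
                                        hip = c(0, -0.1, -0.1),
                                        pelvis = c(0, 0, 0)), n),
    B2.center = mk_seq("B2", "center", list(pelvis = c(0, 100),
                                            neck = c(0, 200)), n)))
  expect_equal(feet_distance_series(rec)$values, rep(0.3, n))
})

test_that("step features recover commanded step length and time", {
  rec <- saw_quick(103)
  segs <- segment_saw(get_sequence(rec, "B2", "center"))
  st <- step_features(feet_distance_series(rec), segs)
  expect_lt(abs(st$step_length$mean - 0.55) / 0.55, 0.05)
  expect_lt(abs(st$step_time$mean - 0.55) / 0.55, 0.05)
  expect_lt(st$step_width$mean, st$step_length$mean)  # widths are the minima
})

test_that("a commanded step-length reduction is recovered proportionally", {
  v1 <- extract_saw(saw_quick(104))$values
  v2 <- extract_saw(saw_quick(104, step_length = 0.55 * 0.7))$values
  ratio <- v2[["saw.step_length.mean"]] / v1[["saw.step_length.mean"]]
  expect_lt(abs(ratio - 0.7), 0.05 * 0.7)
})

test_that("a single step leaves step time and spread undefined", {
  fps <- 60
  v <- 0.1 + 0.4 * exp(-((seq_len(150) - 80) / 12)^2)
  dsaw <- signal1d(v, fps, "normalized-length")
  segs <- structure(list(
    segments = data.frame(kind = c("SU", "W"), start = c(1L, 10L),
                          end = c(9L, 150L)),
    time_to_stand = 0.5, turning_times = numeric(0), fps = fps),
    class = "saw_segments")
  st <- step_features(dsaw, segs)
  expect_true(is.na(st$step_time$mean))
  expect_equal(st$step_length$mean, max(v), tolerance = 0.01)
  expect_true(is.na(st$step_length$std))
})

test_that("cadence and walking speed follow the walk-segment arithmetic", {
  rec <- saw_quick(105)
  pelvis <- get_sequence(rec, "B2", "center")
  segs <- segment_saw(pelvis)
  dsaw <- feet_distance_series(rec)
  gl <- gait_global_features(pelvis, dsaw, segs)
  # commanded: 8 steps of 0.55 s per pass; detection trims boundary steps
  expect_gt(gl$cadence$mean, 1 / 0.55 * 0.75)
  expect_lt(gl$cadence$mean, 1 / 0.55 * 1.05)
  expect_lt(abs(gl$walking_speed$mean - 1.0), 0.1)  # 0.55 units / 0.55 s
  expect_lt(gl$cadence$std, 0.2)
})

test_that("knee angles follow the vector geometry", {
  n <- 10
  straight <- mk_seq("B3", "right", list(hip = c(0, 1, 0), knee = c(0, 0, 0),
                                         foot = c(0, -1, 0), pelvis = c(0, 1.1, 0)), n)
  rec <- recording("T01", "SAW", list(B3.right = straight), check = FALSE)
  expect_equal(knee_angle_series(rec, "right")$values, rep(pi, n))
  bent <- mk_seq("B3", "right", list(hip = c(0, 1, 0), knee = c(0, 0, 0),
                                     foot = c(1, 0, 0), pelvis = c(0, 1.1, 0)), n)
  rec2 <- recording("T01", "SAW", list(B3.right = bent), check = FALSE)
  expect_equal(knee_angle_series(rec2, "right")$values, rep(pi / 2, n))
  # generator knee-range contract
  full <- saw_quick(106)
  ka <- knee_angle_series(full, "right")$values
  segs <- segment_saw(get_sequence(full, "B2", "center"))
  w <- segs$segments[segs$segments$kind == "W", ][1, ]
  ww <- ka[(w$start + 10):(w$end - 10)]
  expect_lt(abs(min(ww) - 2.27), 0.03)
  expect_lt(abs(max(ww) - pi), 0.03)
})

test_that("gait symmetries are high for symmetric gait and drop under restriction", {
  rec <- saw_quick(107)
  segs <- segment_saw(get_sequence(rec, "B2", "center"))
  sy <- gait_symmetries(rec, segs)
  expect_gt(sy$knee_angle_symmetry$mean, 0.98)
  expect_gt(sy$step_symmetry$mean, 0.98)
  for (s in 108:110) {
    v0 <- extract_saw(saw_quick(s))$values
    v1 <- extract_saw(saw_quick(s, knee_restriction = 0.5))$values
    expect_lt(v1[["saw.knee_sym.mean"]], v0[["saw.knee_sym.mean"]] - 0.1)
  }
})

test_that("swapping legs leaves the symmetry features unchanged", {
  rec <- saw_quick(111, knee_restriction = 0.4)
  segs <- segment_saw(get_sequence(rec, "B2", "center"))
  sy <- gait_symmetries(rec, segs)
  sw <- rec
  sw$sequences[c("B3.right", "B3.left")] <- rec$sequences[c("B3.left", "B3.right")]
  sw$sequences$B3.right$side <- "right"; sw$sequences$B3.left$side <- "left"
  sy2 <- gait_symmetries(sw, segs)
  expect_equal(sy2$knee_angle_symmetry$mean, sy$knee_angle_symmetry$mean,
               tolerance = 1e-9)
})

test_that("segmentation and step features are invariant to mirroring the walk direction", {
  g <- gen_saw(synthetic_spec("SAW", seed = 112))
  rec <- g$recording
  mir <- rec
  mir$sequences <- lapply(mir$sequences, function(s) {
    s$coords[, , 1] <- -s$coords[, , 1]; s })
  v <- extract_saw(preprocess_recording(rec))$values
  vm <- extract_saw(preprocess_recording(mir))$values
  expect_equal(vm[["saw.step_length.mean"]], v[["saw.step_length.mean"]],
               tolerance = 1e-6)
  expect_equal(vm[["saw.time_to_stand"]], v[["saw.time_to_stand"]],
               tolerance = 1e-6)
  expect_equal(vm[["saw.cadence.mean"]], v[["saw.cadence.mean"]], tolerance = 1e-6)
})

test_that("step counts per walk segment match the commanded count within one", {
  for (s in 113:118) {
    rec <- saw_quick(s)
    segs <- segment_saw(get_sequence(rec, "B2", "center"))
    dsaw <- feet_distance_series(rec)
    ev <- neurokin:::saw_step_events(dsaw, segs)
    for (e in ev) expect_lte(abs(length(e$maxima) - 8L), 1L)
  }
})
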