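test_that("skeleton specs resolve the joints every feature needs", {
  h2 <- skeleton_spec("H2")
  expect_equal(joint_index(h2, "thumb_tip"), 3L)
  expect_equal(joint_index(h2, "index_mid"), 5L)
  expect_equal(joint_index(h2, "index_tip"), 6L)
  b2 <- skeleton_spec("B2")
  expect_equal(joint_index(b2, "pelvis"), 0L)
  expect_equal(joint_index(b2, "elbow"), 6L)
  expect_equal(joint_index(b2, "wrist"), 7L)
  b3 <- skeleton_spec("B3")
  expect_equal(unname(b3$name_to_index[c("foot", "knee", "hip", "pelvis")]),
               c(2L, 3L, 4L, 0L))
  expect_error(joint_index(h2, "nose"), class = "neurokin_format_error")
})

test_that("malformed skeletons are rejected", {
  expect_error(skeleton_spec("H2", name_to_index = c(a = 1L, b = 1L)),
               class = "neurokin_format_error")
  expect_error(
    skeleton_spec("B3", edges = rbind(c(0L, 1L), c(1L, 2L), c(2L, 0L))),
    class = "neurokin_format_error")
})

test_that("pose sequences enforce shape, fps and dimension invariants", {
  sp <- skeleton_spec("H2")
  good <- array(0, c(5, sp$n_joints, 2))
  expect_s3_class(pose_sequence(sp, "right", good, fps = 60), "pose_sequence")
  expect_error(pose_sequence(sp, "right", array(0, c(1, sp$n_joints, 2)), fps = 60),
               class = "neurokin_empty_input")
  expect_error(pose_sequence(sp, "right", array(0, c(5, sp$n_joints, 3)), fps = 60),
               class = "neurokin_format_error")
  expect_error(pose_sequence(sp, "right", good, fps = 0),
               class = "neurokin_format_error")
  s <- pose_sequence(sp, "right", good, fps = 50)
  expect_equal(seq_times(s), (1:5) / 50)
})

write_op_frame <- function(dir, i, hand_r, body = NULL, hand_l = NULL) {
  doc <- list(people = list(c(
    list(hand_right_keypoints_2d = hand_r),
    if (!is.null(body)) list(pose_keypoints_2d = body),
    if (!is.null(hand_l)) list(hand_left_keypoints_2d = hand_l))))
  jsonlite::write_json(doc, file.path(dir, sprintf("frame_%03d.json", i)),
                       auto_unbox = TRUE, digits = NA)
}

test_that("the per-frame keypoint JSON reader maps, flips and flags", {
  dir <- withr::local_tempdir()
  hand <- as.numeric(rbind(matrix(rnorm(42), 2, 21), 0.9))  # x,y rows + conf
  for (i in 1:3) write_op_frame(dir, i, hand)
  rec <- read_openpose_frames(dir, fps = 60, test = "FT")
  s <- rec$sequences$H2.right
  expect_equal(n_frames(s), 3L)
  expect_equal(dim(s$coords)[3], 2L)
  # index 4 of the flat array is the thumb tip; image y flips to math y-up
  expect_equal(joint_track(s, "thumb_tip")[1, 2], -hand[3 * 4 + 2])
  # a low-confidence keypoint becomes missing coordinates
  hand_low <- hand; hand_low[3 * 8 + 3] <- 0.01   # index_tip confidence
  dir2 <- withr::local_tempdir()
  write_op_frame(dir2, 1, hand_low); write_op_frame(dir2, 2, hand)
  rec2 <- read_openpose_frames(dir2, fps = 60, test = "FT")
  expect_true(is.na(joint_track(rec2$sequences$H2.right, "index_tip")[1, 1]))
  expect_false(anyNA(joint_track(rec2$sequences$H2.right, "index_tip")[2, ]))
})

test_that("the JSON reader is total: malformed inputs raise typed errors", {
  dir <- withr::local_tempdir()
  expect_error(read_openpose_frames(dir, fps = 60), class = "neurokin_empty_input")
  hand21 <- rep(c(1, 2, 0.9), 21)
  hand20 <- rep(c(1, 2, 0.9), 20)
  write_op_frame(dir, 1, hand21); write_op_frame(dir, 2, hand20)
  expect_error(read_openpose_frames(dir, fps = 60),
               class = "neurokin_format_error")
})

test_that("pose tables round-trip recordings bit-exactly", {
  g <- gen_ft(synthetic_spec("FT", seed = 3, duration_s = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_table(g$recording, f)
  r2 <- read_pose_table(f)
  for (k in names(g$recording$sequences)) {
    expect_identical(g$recording$sequences[[k]]$coords, r2$sequences[[k]]$coords)
    expect_identical(g$recording$sequences[[k]]$confidence,
                     r2$sequences[[k]]$confidence)
  }
  expect_identical(r2$test, "FT")
  expect_identical(r2$label, g$recording$label)
  expect_identical(r2$fps, g$recording$fps)
})

test_that("pose table reading rejects malformed tables", {
  g <- gen_ft(synthetic_spec("FT", seed = 4, duration_s = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_table(g$recording, f)
  dt <- data.table::fread(f)
  # duplicate rows
  f_dup <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(rbind(dt, dt[1, ]), f_dup)
  expect_error(read_pose_table(f_dup), class = "neurokin_format_error")
  # empty input
  f_empty <- withr::local_tempfile(fileext = ".csv")
  file.create(f_empty)
  expect_error(read_pose_table(f_empty), class = "neurokin_empty_input")
  # a 3D tree without z
  gs <- gen_saw(synthetic_spec("SAW", seed = 4, duration_s = 1, n_passes = 1L,
                               steps_per_pass = 4L))
  f_saw <- withr::local_tempfile(fileext = ".csv")
  write_pose_table(gs$recording, f_saw)
  ds <- data.table::fread(f_saw)
  ds$z <- NA_real_
  f_noz <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(ds, f_noz)
  expect_error(read_pose_table(f_noz), class = "neurokin_format_error")
})

test_that("feature tables keep undefined features missing, never zero", {
  g1 <- analyze_recording(gen_ft(synthetic_spec("FT", seed = 1, duration_s = 5))$recording)
  g2 <- analyze_recording(gen_ft(synthetic_spec("FT", seed = 2, duration_s = 5))$recording)
  g2$values[["ft.amplitude.mean.r"]] <- NA_real_
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(list(g1, g2), f)
  tbl <- read_feature_table(f)
  expect_equal(nrow(tbl), 2L)
  expect_true(is.na(tbl$ft.amplitude.mean.r[2]))
  expect_false(is.na(tbl$ft.amplitude.mean.r[1]))
  # mixed test types refuse to combine
  g3 <- analyze_recording(gen_fr(synthetic_spec("FR", seed = 1, duration_s = 5))$recording)
  expect_error(features_to_table(list(g1, g3)), class = "neurokin_format_error")
  # empty collection: header-only file
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(list(), f2)
  expect_equal(nrow(read_feature_table(f2)), 0L)
})

test_that("recordings validate their per-test sequence inventory", {
  g <- gen_saw(synthetic_spec("SAW", seed = 1, duration_s = 1, n_passes = 1L,
                              steps_per_pass = 4L))
  rec <- g$recording
  rec$sequences$B3.left <- NULL
  expect_error(validate_recording(rec), class = "neurokin_format_error")
})
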