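test_that("the fingertip separation series is a plain Euclidean distance", {
  n <- 60
  rec <- mk_ft_rec(thumb_r = c(0, 0), index_r = c(3, 4), n = n)
  d <- ft_distance_series(rec, "right")
  expect_equal(d$values, rep(5, n))   # 3-4-5 triangle
  rec0 <- mk_ft_rec(thumb_r = c(7, 7), index_r = c(7, 7), n = n)
  expect_equal(ft_distance_series(rec0, "right")$values, rep(0, n))
})

test_that("finger-tapping features recover symmetric ground truth", {
  g <- gen_ft(synthetic_spec("FT", seed = 21))
  v <- analyze_recording(g$recording)$values
  for (s in c("r", "l")) {
    expect_lt(abs(v[[paste0("ft.frequency.mean.", s)]] - 2), 0.05)
    # period * frequency consistency within 5%
    expect_lt(abs(v[[paste0("ft.frequency.mean.", s)]] *
                    v[[paste0("ft.period.mean.", s)]] - 1), 0.05)
  }
  expect_lt(v[["ft.amplitude.asym"]], 0.03)
  expect_lt(v[["ft.frequency.asym"]], 0.02)
  expect_gt(v[["ft.tap_rate.r"]], 1.8)
})

test_that("the rubber-band preset shows the asymmetries implied by its parameters", {
  g <- gen_ft(synthetic_spec("FT", "abnormal", seed = 22))
  v <- analyze_recording(g$recording)$values
  # direct evaluation of the asymmetry form on the commanded parameters
  expect_lt(abs(v[["ft.frequency.asym"]] - abs(2 - 1.2) / (2 + 1.2)), 0.02)
  expect_lt(abs(v[["ft.amplitude.asym"]] - abs(1 - 0.4) / (1 + 0.4)), 0.03)
})

test_that("static hands leave cycle features undefined but stability finite", {
  rec <- mk_ft_rec(thumb_r = c(150, 250), index_r = c(160, 260), n = 400)
  v <- extract_ft(preprocess_recording(rec))$values
  expect_true(is.na(v[["ft.amplitude.mean.r"]]))
  expect_true(is.na(v[["ft.tap_rate.r"]]))
  expect_true(is.finite(v[["ft.wrist_stability.mean"]]))
})

test_that("swapping sides swaps per-side features and fixes asymmetries", {
  g <- gen_ft(synthetic_spec("FT", "abnormal", seed = 23))
  rec <- g$recording
  sw <- rec
  sw$sequences[c("H2.right", "H2.left")] <- rec$sequences[c("H2.left", "H2.right")]
  sw$sequences$H2.right$side <- "right"; sw$sequences$H2.left$side <- "left"
  v <- analyze_recording(rec)$values
  vs <- analyze_recording(sw)$values
  for (f in c("ft.amplitude.mean", "ft.period.mean", "ft.frequency.mean",
              "ft.tap_rate")) {
    expect_equal(vs[[paste0(f, ".r")]], v[[paste0(f, ".l")]])
    expect_equal(vs[[paste0(f, ".l")]], v[[paste0(f, ".r")]])
  }
  for (f in c("ft.amplitude.asym", "ft.period.asym", "ft.frequency.asym"))
    expect_equal(vs[[f]], v[[f]])
})

test_that("mirror symmetries behave as their definitions dictate", {
  n <- 300; fps <- 60; t <- (1:n) / fps
  xr <- 150 + 40 * sin(2 * pi * t); y <- 250 + 30 * cos(2 * pi * t)
  mk <- function(xl) recording("T01", "FTF", list(
    H2.right = mk_seq("H2", "right", list(index_mid = cbind(xr, y)), n),
    H2.left = mk_seq("H2", "left", list(index_mid = cbind(xl, y)), n),
    B2.right = mk_b2("right", n), B2.left = mk_b2("left", n)))
  mirrored <- ftf_symmetries(mk(-xr))
  expect_equal(mirrored$sym_x, 1, tolerance = 1e-9)
  same_dir <- ftf_symmetries(mk(xr))
  expect_equal(same_dir$sym_x, -1, tolerance = 1e-9)
  # mirrored motion plus independent 10%-of-range noise stays near 1
  set.seed(9)
  vals <- replicate(25, {
    noisy <- mk(-xr + rnorm(n, 0, 8))
    noisy$sequences$H2.right$coords[, 6, 1] <-
      noisy$sequences$H2.right$coords[, 6, 1] + rnorm(n, 0, 8)
    ftf_symmetries(noisy)$sym_x
  })
  expect_true(all(vals > 0.9 & vals <= 1))
})

test_that("finger-to-finger features separate clean from tremulous motion", {
  v0 <- analyze_recording(gen_ftf(synthetic_spec("FTF", seed = 31))$recording)$values
  expect_gt(v0[["ftf.velangle_sym.mean.r"]], 0.95)
  expect_lt(v0[["ftf.path_smoothness.mean.r"]], 1.01)
  expect_gt(v0[["ftf.sym_x"]], 0.99)
  v1 <- analyze_recording(gen_ftf(synthetic_spec("FTF", "abnormal", seed = 31))$recording)$values
  expect_gt(v1[["ftf.path_smoothness.mean.r"]], 1.05)
  expect_lt(v1[["ftf.velangle_sym.mean.r"]], v0[["ftf.velangle_sym.mean.r"]])
})

test_that("a single cycle yields no velocity-angle pairs but other features", {
  g <- gen_ftf(synthetic_spec("FTF", seed = 32))
  # locate the first two up-position maxima, then truncate around them so the
  # recording contains exactly one complete cycle
  pre <- preprocess_recording(g$recording)
  y <- joint_track(get_sequence(pre, "H2", "right"), "index_mid")[, 2]
  cs <- detect_cycles(signal1d(y, pre$fps), boundary = "maxima")
  m <- cs$maxima_idx
  short <- truncate_recording(g$recording, max(m[1] - 4, 0), m[2] + 4)
  v <- extract_ftf(preprocess_recording(short))$values
  expect_true(is.na(v[["ftf.velangle_sym.mean.r"]]))
  expect_false(is.na(v[["ftf.avg_speed.mean.r"]]))
})

test_that("forearm-roll features recover antiphase rolling ground truth", {
  v <- analyze_recording(gen_fr(synthetic_spec("FR", seed = 41))$recording)$values
  for (s in c("r", "l")) {
    expect_lt(abs(v[[paste0("fr.period.mean.", s)]] - 1 / 1.5), 0.02)
    expect_lt(abs(v[[paste0("fr.amplitude.mean.", s)]] - 0.6), 0.02)
  }
  expect_lt(v[["fr.period.asym"]], 0.02)
  expect_gt(v[["fr.roll_rate.r"]], 1.3)
  va <- analyze_recording(gen_fr(synthetic_spec("FR", "abnormal", seed = 41))$recording)$values
  expect_lt(abs(va[["fr.amplitude.asym"]] - abs(0.3 - 0.15) / (0.3 + 0.15)), 0.03)
  # static wrists: undefined cycle features
  g0 <- gen_fr(synthetic_spec("FR", seed = 41, amp = c(right = 0, left = 0.3)))
  v0 <- analyze_recording(g0$recording)$values
  expect_true(is.na(v0[["fr.amplitude.mean.r"]]))
  expect_false(is.na(v0[["fr.amplitude.mean.l"]]))
})

test_that("frequency recovery stays within the frame-quantization bound", {
  for (f in c(1, 2, 3)) {
    g <- gen_ft(synthetic_spec("FT", seed = 42, freq = c(right = f, left = f)))
    v <- analyze_recording(g$recording)$values
    bound <- (1 / 60) / (1 / f)^2    # one frame of quantization: fps^-1 / T^2
    expect_lt(abs(v[["ft.frequency.mean.r"]] - f), bound + 1e-9)
  }
})
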