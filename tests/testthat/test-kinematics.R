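test_that("the asymmetry metric matches its closed form and is scale-free", {
  expect_equal(asymmetry(2, 2), 0)
  expect_equal(asymmetry(3, 1), abs(3 - 1) / (3 + 1))  # 0.5 by direct evaluation
  expect_equal(asymmetry(1, 0), 1)
  expect_true(is.na(asymmetry(0, 0)))
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5); c <- runif(1, 0.01, 100)
    expect_equal(asymmetry(c * a, c * b), asymmetry(a, b), tolerance = 1e-12)
  }
})

test_that("the correlation coefficient matches hand evaluation and base R", {
  x <- rnorm(50)
  expect_equal(pearson_cc(x, 2 * x + 5), 1)
  expect_equal(pearson_cc(x, -x), -1)
  # centered dot product by hand: cov 1, norms sqrt(2) * sqrt(2)
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_true(is.na(pearson_cc(rep(1, 10), rnorm(10))))
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30)
    expect_equal(pearson_cc(a, b), cor(a, b), tolerance = 1e-12)  # oracle: stats::cor
    expect_equal(pearson_cc(3 * a + 1, b), pearson_cc(a, b), tolerance = 1e-12)
    expect_equal(pearson_cc(-a, b), -pearson_cc(a, b), tolerance = 1e-12)
  }
})

test_that("cycles of an analytic sinusoid are detected with correct period and amplitude", {
  fps <- 60; t <- (1:(15 * fps)) / fps
  sig <- signal1d(0.5 * (1 - cos(2 * pi * 2 * t)), fps, "normalized-length")
  cs <- detect_cycles(sig)
  expect_gte(cs$n_cycles, 28); expect_lte(cs$n_cycles, 30)
  expect_true(all(abs(cs$period - 0.5) <= 1 / fps + 1e-9))
  expect_true(all(abs(cs$amplitude - 1) <= 0.02))
  # constant signal: no cycles
  expect_true(detect_cycles(signal1d(rep(1, 100), fps))$too_few)
  # small high-frequency ripple does not create spurious cycles: the
  # extrema-based frequency still matches the FFT oracle within 2%
  ripple <- signal1d(0.5 * (1 - cos(2 * pi * 2 * t)) + 0.02 * sin(2 * pi * 20 * t),
                     fps, "normalized-length")
  cs2 <- detect_cycles(ripple, min_prominence_frac = 0.1)
  expect_lte(abs(cs2$n_cycles - cs$n_cycles), 2L)
  f_ext <- 1 / mean(cs2$period)
  expect_lt(abs(f_ext - fft_dominant_freq(ripple$values, fps)) / 2, 0.02)
})

test_that("extrema-based frequency agrees with the FFT oracle on clean periodic signals", {
  fps <- 60
  set.seed(11)
  for (i in 1:10) {
    f <- runif(1, 1, 4); amp <- runif(1, 0.5, 2); ph <- runif(1, 0, 2 * pi)
    t <- (1:(15 * fps)) / fps
    sig <- signal1d(amp * (1 - cos(2 * pi * f * t + ph)) / 2, fps)
    cs <- detect_cycles(sig)
    f_ext <- 1 / mean(cs$period)
    f_fft <- fft_dominant_freq(sig$values, fps)
    expect_lt(abs(f_ext - f_fft) / f_fft, 0.02)
  }
})

test_that("derivatives are central differences with correct units and magnitudes", {
  fps <- 60; t <- (1:300) / fps
  ramp <- signal1d(3 * t, fps, "normalized-length")
  d1 <- derivative(ramp, 1L)
  expect_equal(d1$values[5:295], rep(3, 291), tolerance = 1e-9)
  expect_equal(d1$units, "normalized-length/s")
  sine <- signal1d(0.5 * (1 - cos(2 * pi * 2 * t)), fps)
  expect_lt(abs(max(abs(derivative(sine, 1L)$values)) - 2 * pi) / (2 * pi), 0.02)
  expect_equal(derivative(signal1d(rep(2, 50), fps), 1L)$values, rep(0, 50))
  const2 <- derivative(signal1d(rep(2, 50), fps), 2L)
  expect_equal(const2$values, rep(0, 50))
  expect_equal(const2$units, "unitless/s^2")
})

test_that("cycle resampling interpolates linearly and preserves shape", {
  expect_equal(resample_cycle(c(0, 1), 3), c(0, 0.5, 1))
  v <- rnorm(37)
  expect_equal(resample_cycle(v, 37), v)
  t <- seq(0, 2 * pi, length.out = 80)
  expect_gt(pearson_cc(resample_cycle(sin(t), 100),
                       resample_cycle(sin(t), 100)), 1 - 1e-6)
})

test_that("lag search recovers shifts (verified against brute force) and bounds hold", {
  same <- sin(seq(0, 4 * pi, length.out = 100))
  r0 <- align_and_cc(same, same, 0.25)
  expect_equal(r0$lag, 0L); expect_equal(r0$cc, 1)
  shifted <- c(rep(same[1], 10), same[1:90])
  r <- align_and_cc(same, shifted, 0.25)
  expect_equal(abs(r$lag), 10L)
  expect_gt(r$cc, 0.999)
  # brute force over admissible lags confirms the maximum
  brute <- max(sapply(-25:25, function(l) {
    ia <- max(1, 1 + l):min(100, 100 + l)
    suppressWarnings(cor(same[ia], shifted[ia - l]))
  }), na.rm = TRUE)
  expect_equal(r$cc, brute, tolerance = 1e-12)
  set.seed(3)
  rn <- align_and_cc(rnorm(100), rnorm(100), 0.25)
  expect_lte(abs(rn$lag), 25L)
  # circular alignment of a rotated copy is exact
  rot <- c(same[41:100], same[1:40])
  rc <- align_and_cc(same, rot, 0.5, circular = TRUE)
  expect_gt(rc$cc, 1 - 1e-9)
})

test_that("path smoothness is 1 on smooth quadratics and grows with zig-zag", {
  u <- seq(0, 1, length.out = 60)
  line <- cbind(u, 2 * u)
  expect_equal(path_smoothness(line), 1, tolerance = 1e-9)
  parab <- cbind(2 * u, 1 + u - 2 * u^2)
  expect_equal(path_smoothness(parab), 1, tolerance = 1e-6)
  # oracle: the arc-length ratio computed from the generator geometry.
  # perpendicular zig-zag of +/-0.05 adds sqrt(dl^2 + (2*0.05)^2) per step.
  zig <- parab + outer(rep(c(0.05, -0.05), 30), c(0, 1))
  ps <- path_smoothness(zig)
  seg <- sqrt(rowSums(diff(parab)^2))
  lower_bound <- sum(sqrt(pmax(seg^2, 0) + 0.1^2 * 0.5)) / (sum(seg) * 1.02)
  expect_gt(ps, 1.05)
  expect_gt(ps, lower_bound * 0.9)
  expect_true(is.na(path_smoothness(matrix(1, 10, 2))))
  # floor: never below 1
  set.seed(5)
  for (i in 1:20) {
    pts <- cbind(cumsum(rnorm(30)), cumsum(rnorm(30)))
    expect_gte(path_smoothness(pts), 1)
  }
})

test_that("summary statistics respect undefined-value rules", {
  s <- summary_stats(c(1, 2, 3, NA))
  expect_equal(s$mean, 2); expect_equal(s$n, 3L)
  s1 <- summary_stats(5)
  expect_equal(s1$median, 5); expect_true(is.na(s1$std))
  s0 <- summary_stats(numeric(0))
  expect_true(is.na(s0$mean) && is.na(s0$median))
})
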