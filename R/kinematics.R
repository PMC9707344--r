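# Shared signal primitives: asymmetry, correlation, cycle detection,
# derivatives, cycle alignment/resampling, path smoothness.

#' Construct a 1-D kinematic signal
#'
#' @param values numeric vector, length >= 2, uniformly sampled.
#' @param fps sampling rate in Hz.
#' @param units one of `"normalized-length"`, `"radians"`, `"unitless"`, or a
#'   derived unit string such as `"normalized-length/s"`.
#' @return An object of class `nk_signal`.
#' @export
signal1d <- function(values, fps, units = "unitless") {
  stopifnot(length(values) >= 2L, fps > 0)
  structure(list(values = as.numeric(values), fps = fps, units = units),
            class = "nk_signal")
}

sig_values <- function(x) if (inherits(x, "nk_signal")) x$values else as.numeric(x)

#' Summary statistics of a per-cycle feature
#'
#' @param x numeric vector (NAs dropped).
#' @return list with `mean`, `std`, `median`, `n`. `mean`/`median` are `NA`
#'   when no finite value exists; `std` is `NA` when fewer than 2 exist.
#' @export
summary_stats <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  list(mean = if (n >= 1L) mean(x) else NA_real_,
       std = if (n >= 2L) stats::sd(x) else NA_real_,
       median = if (n >= 1L) stats::median(x) else NA_real_,
       n = n)
}

#' Left-right asymmetry metric
#'
#' `Asym(fr, fl) = |fr - fl| / (fr + fl)`: a scale-free measure of the
#' difference between a right-side and a left-side feature, 0 for perfect
#' symmetry and 1 when one side is entirely absent. Undefined (NA) when both
#' features are zero.
#'
#' @param fr,fl non-negative right/left feature values.
#' @return scalar in `[0, 1]`, or `NA` if undefined.
#' @export
#' @examples
#' asymmetry(3, 1)  # 0.5
asymmetry <- function(fr, fl) {
  if (!is.finite(fr) || !is.finite(fl)) return(NA_real_)
  s <- fr + fl
  if (s == 0) return(NA_real_)
  abs(fr - fl) / s
}

#' Pearson correlation coefficient of two series
#'
#' The centered dot product of the two series divided by the product of their
#' centered norms. Returns `NA` (undefined) if either series is constant.
#' Incomplete pairs (NA in either series) are dropped.
#'
#' @param x1,x2 numeric vectors or [signal1d()] objects of equal length >= 2.
#' @return scalar in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_cc <- function(x1, x2) {
  x1 <- sig_values(x1); x2 <- sig_values(x2)
  if (length(x1) != length(x2))
    nk_stop("series must have equal length", "neurokin_format_error")
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (length(x1) < 2L) return(NA_real_)
  c1 <- x1 - mean(x1); c2 <- x2 - mean(x2)
  n1 <- sqrt(sum(c1^2)); n2 <- sqrt(sum(c2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  sum(c1 * c2) / (n1 * n2)
}

# All strictly alternating local extrema of v. Plateaus contribute their
# midpoint. Returns data.frame(idx, type) with type +1 (max) / -1 (min).
local_extrema <- function(v) {
  n <- length(v)
  dv <- diff(v)
  s <- sign(dv)
  # carry the previous non-zero slope through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  idx <- integer(); type <- integer()
  run_start <- 1L
  for (i in seq_len(n - 2L)) {
    if (s[i] != 0 && s[i + 1L] != 0 && s[i] != s[i + 1L]) {
      # slope change at position i+1; locate plateau midpoint
      j <- i + 1L
      k <- j
      while (k > 1L && v[k - 1L] == v[j]) k <- k - 1L
      idx <- c(idx, as.integer(round((k + j) / 2)))
      type <- c(type, if (s[i] > 0) 1L else -1L)
    }
  }
  data.frame(idx = idx, type = type)
}

# Fit half-width for extremum refinement: ~10% of the cycle, so the quadratic
# approximation of the peak stays valid at high movement frequencies.
refine_half <- function(cycle_len) as.integer(min(6L, max(2L, round(0.1 * cycle_len))))

# Sub-frame refinement of an extremum's value: quadratic fit over +/- `half`
# frames around the detected extremum. Compensates the value lost to frame
# quantization (the sampled peak sits up to half a frame off the true peak)
# and averages frame noise at the extremum.
refine_extremum_value <- function(v, idx, half = 3L) {
  i0 <- max(1L, idx - half); i1 <- min(length(v), idx + half)
  if (i1 - i0 < 4L) return(v[idx])
  x <- (i0:i1) - idx
  fit <- stats::lm.fit(cbind(1, x, x^2), v[i0:i1])
  b <- fit$coefficients
  if (!is.finite(b[3L]) || b[3L] == 0) return(v[idx])
  xv <- -b[2L] / (2 * b[3L])
  if (abs(xv) > half) return(v[idx])   # fit vertex outside window: distrust
  b[1L] + b[2L] * xv + b[3L] * xv^2
}

# Prune alternating extrema whose rise/fall is below `thresh`, smallest first.
# Removing an adjacent (min,max) pair preserves alternation.
prune_extrema <- function(ex, v, thresh) {
  while (nrow(ex) >= 2L) {
    dv <- abs(diff(v[ex$idx]))
    m <- which.min(dv)
    if (dv[m] >= thresh) break
    ex <- ex[-c(m, m + 1L), , drop = FALSE]
  }
  ex
}

# Enforce minimum spacing between consecutive same-type extrema: drop the
# weaker of the violating pair plus the opposite-type extremum between them.
enforce_spacing <- function(ex, v, min_gap) {
  repeat {
    if (nrow(ex) < 3L) break
    same <- seq_len(nrow(ex) - 2L)
    gaps <- ex$idx[same + 2L] - ex$idx[same]
    bad <- which(gaps < min_gap)
    if (length(bad) == 0L) break
    i <- bad[1L]
    a <- ex$idx[i]; b <- ex$idx[i + 2L]; ty <- ex$type[i]
    weaker <- if (ty == 1L) { if (v[a] >= v[b]) i + 2L else i }
              else          { if (v[a] <= v[b]) i + 2L else i }
    ex <- ex[-c(weaker, i + 1L), , drop = FALSE]
  }
  ex
}

#' Detect movement cycles in a periodic 1-D signal
#'
#' Finds local minima and maxima whose excursion exceeds
#' `min_prominence_frac` of the signal's global range and whose spacing
#' respects `min_period_s`, enforcing strict min/max alternation (of two
#' same-type neighbors the more extreme one is kept). Cycles are delimited by
#' consecutive boundary extrema (minima by default); the per-cycle period is
#' the time between them and the per-cycle amplitude is the difference
#' between the cycle's opposite-type extremum and its starting boundary value
#' (min-to-next-max by default).
#'
#' @param sig a [signal1d()] (or numeric vector with `fps` supplied).
#' @param min_prominence_frac extrema below this fraction of the global range
#'   are treated as ripple (default 0.2).
#' @param min_period_s minimum admissible cycle period in seconds (default
#'   0.15, suited to upper-limb movement; use ~0.3 for gait).
#' @param boundary which extrema delimit a cycle: `"minima"` (default) or
#'   `"maxima"`.
#' @param min_range signals whose global range falls below this absolute
#'   value carry no movement (a static limb shows only residual keypoint
#'   noise, whose extrema would otherwise pass the scale-free prominence
#'   rule); default 0.05 signal units.
#' @param fps sampling rate, required if `sig` is a bare vector.
#' @return An object of class `cycle_set`: `minima_idx`, `maxima_idx`,
#'   `cycles` (two-column matrix of boundary frame indices), `period` and
#'   `amplitude` per cycle, `n_cycles`, and `too_few` (TRUE when fewer than 2
#'   cycles were found, in which case cycle-based fields are `NA`).
#' @export
detect_cycles <- function(sig, min_prominence_frac = 0.2, min_period_s = 0.15,
                          boundary = c("minima", "maxima"), min_range = 0.05,
                          fps = NULL) {
  boundary <- match.arg(boundary)
  if (inherits(sig, "nk_signal")) { v <- sig$values; fps <- sig$fps }
  else { v <- as.numeric(sig); if (is.null(fps)) nk_stop("fps required", "neurokin_format_error") }
  empty <- structure(list(minima_idx = integer(), maxima_idx = integer(),
                          cycles = matrix(integer(), 0L, 2L),
                          period = NA_real_, amplitude = NA_real_,
                          n_cycles = 0L, too_few = TRUE, fps = fps,
                          boundary = boundary), class = "cycle_set")
  rng <- diff(range(v, na.rm = TRUE))
  if (!is.finite(rng) || rng < min_range) return(empty)
  ex <- local_extrema(v)
  if (nrow(ex) < 2L) {
    out <- empty
    out$minima_idx <- ex$idx[ex$type == -1L]
    out$maxima_idx <- ex$idx[ex$type == 1L]
    return(out)
  }
  ex <- prune_extrema(ex, v, min_prominence_frac * rng)
  ex <- enforce_spacing(ex, v, min_period_s * fps)
  minima <- ex$idx[ex$type == -1L]
  maxima <- ex$idx[ex$type == 1L]
  bidx <- if (boundary == "minima") minima else maxima
  if (length(bidx) < 2L) {
    out <- empty
    out$minima_idx <- minima; out$maxima_idx <- maxima
    return(out)
  }
  cycles <- cbind(start = bidx[-length(bidx)], end = bidx[-1L])
  period <- diff(bidx) / fps
  amplitude <- vapply(seq_len(nrow(cycles)), function(i) {
    idx <- cycles[i, 1L]:cycles[i, 2L]
    half <- refine_half(length(idx))
    opp <- if (boundary == "minima") idx[which.max(v[idx])] else idx[which.min(v[idx])]
    a <- refine_extremum_value(v, opp, half) -
      refine_extremum_value(v, cycles[i, 1L], half)
    if (boundary == "minima") a else -a
  }, numeric(1))
  structure(list(minima_idx = minima, maxima_idx = maxima, cycles = cycles,
                 period = period, amplitude = amplitude,
                 n_cycles = nrow(cycles), too_few = nrow(cycles) < 2L,
                 fps = fps, boundary = boundary), class = "cycle_set")
}

#' Time derivative of a signal
#'
#' Central differences scaled by the frame rate, one-sided at the edges.
#' Units gain a `/s` per order.
#'
#' @param sig a [signal1d()].
#' @param order 1 (velocity) or 2 (acceleration, central difference applied
#'   twice).
#' @return a [signal1d()] of the same length.
#' @export
derivative <- function(sig, order = 1L) {
  stopifnot(inherits(sig, "nk_signal"), order %in% c(1L, 2L))
  v <- sig$values
  n <- length(v)
  if (n < 3L) nk_stop("derivative needs at least 3 samples", "neurokin_empty_input")
  d1 <- function(v) {
    dv <- numeric(n)
    dv[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / 2
    dv[1L] <- v[2L] - v[1L]
    dv[n] <- v[n] - v[n - 1L]
    dv * sig$fps
  }
  v <- d1(v)
  if (order == 2L) v <- d1(v)
  units <- paste0(sig$units, if (order == 1L) "/s" else "/s^2")
  signal1d(v, sig$fps, units)
}

#' Resample a cycle segment to a fixed length
#'
#' Linear interpolation of the segment onto `L` uniformly spaced points over
#' its time span, so cycles of different frame counts can be compared
#' point-wise (e.g. pairwise correlation of velocity-angle series).
#'
#' @param segment numeric vector (length >= 2) or [signal1d()].
#' @param L target length.
#' @return numeric vector of length `L`.
#' @export
resample_cycle <- function(segment, L = 100L) {
  v <- sig_values(segment)
  n <- length(v)
  if (n < 2L) nk_stop("segment too short to resample", "neurokin_empty_input")
  stats::approx(seq_len(n), v, xout = seq(1, n, length.out = L))$y
}

#' Best-lag alignment of two series by correlation
#'
#' Searches integer lags within `max_lag_frac` of the series length for the
#' lag maximizing the Pearson correlation of the overlapping parts (used to
#' remove the physiologic right/left phase offset before comparing gait
#' cycles). Ties resolve to the smallest absolute lag.
#'
#' @param a,b numeric vectors or [signal1d()] of equal length.
#' @param max_lag_frac maximum |lag| as a fraction of length, in `[0, 0.5]`.
#' @param circular if `TRUE`, treat the series as one period of a cyclic
#'   signal and rotate `b` instead of shifting it, so the correlation always
#'   uses the full length (appropriate for gait strides); if `FALSE`
#'   (default), correlate the overlapping parts only.
#' @return list with `lag` (samples; positive means `b` is delayed relative
#'   to `a`) and `cc` (the maximized correlation; `NA` if every admissible
#'   overlap is shorter than 4 samples or degenerate).
#' @export
align_and_cc <- function(a, b, max_lag_frac = 0.5, circular = FALSE) {
  a <- sig_values(a); b <- sig_values(b)
  if (length(a) != length(b))
    nk_stop("series must have equal length", "neurokin_format_error")
  stopifnot(max_lag_frac >= 0, max_lag_frac <= 0.5)
  L <- length(a)
  max_lag <- as.integer(floor(max_lag_frac * L))
  best <- list(lag = NA_integer_, cc = NA_real_)
  for (lag in -max_lag:max_lag) {
    if (circular) {
      ia <- seq_len(L)
      ib <- ((ia - 1L - lag) %% L) + 1L
    } else {
      ia <- max(1L, 1L + lag):min(L, L + lag)
      ib <- ia - lag
    }
    if (length(ia) < 4L) next
    cc <- pearson_cc(a[ia], b[ib])
    if (is.na(cc)) next
    if (is.na(best$cc) || cc > best$cc + 1e-12 ||
        (abs(cc - best$cc) <= 1e-12 && abs(lag) < abs(best$lag))) {
      best <- list(lag = lag, cc = cc)
    }
  }
  best
}

#' Path smoothness of a trajectory segment
#'
#' Fits the x and y coordinates separately as quadratic polynomials of the
#' normalized chord-length parameter and returns the ratio of the actual
#' polyline arc length to the arc length of the fitted curve sampled at the
#' same parameter values. Smooth (near-parabolic) motion gives values near 1;
#' tremor superimposed on the path inflates the numerator and pushes the
#' ratio above 1. The ratio is floored at 1 (see the source note): sub-1
#' values carry no signal, arising only from parameterization error of the
#' reference fit.
#'
#' @param points ordered two-column matrix of 2D positions along one cycle
#'   (>= 5 rows).
#' @return scalar >= 1, or `NA` for degenerate input (all points
#'   coincident).
#' @export
path_smoothness <- function(points) {
  points <- as.matrix(points)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 5L) return(NA_real_)
  seg <- sqrt(rowSums(diff(points)^2))
  total <- sum(seg)
  if (total == 0) return(NA_real_)
  u <- c(0, cumsum(seg)) / total
  beta <- qr.solve(cbind(1, u, u^2), points)  # least squares per axis
  fitted <- cbind(1, u, u^2) %*% beta
  lf <- polyline_length(fitted)
  if (lf == 0) return(NA_real_)
  # The ratio is floored at 1: the smooth reference cannot meaningfully be
  # longer than the measured path, and values below 1 arise only from the
  # chord-length parameter mismatching the curve's own parameterization.
  max(1, total / lf)
}

#' Unwrap a phase-angle series
#'
#' Removes 2*pi jumps so the velocity-angle series is continuous within a
#' cycle before resampling and correlation.
#'
#' @param theta numeric vector of angles in radians.
#' @return unwrapped numeric vector.
#' @export
unwrap_angle <- function(theta) {
  ok <- is.finite(theta)
  if (!any(ok)) return(theta)
  theta[ok] <- signal::unwrap(theta[ok])
  theta
}
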