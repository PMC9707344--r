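# Pre-processing: truncation, reference-length normalization, gap
# interpolation, median + Savitzky-Golay smoothing.

#' Pre-processing configuration
#'
#' Filter windows are specified in seconds and converted to odd frame counts
#' at the recording's frame rate, so the same configuration behaves
#' consistently across capture devices. At 60 fps the defaults give a
#' 3-frame running median, a 7-frame Savitzky-Golay window of order 3 and a
#' 6-frame maximum interpolation gap. The windows are deliberately short: a
#' running median attenuates the peaks of a periodic signal by roughly
#' `1 - cos(pi f (k-1) / fs)` at movement frequency `f`, and amplitude
#' features read peak-to-trough excursions, so wider windows (e.g. a 5-frame
#' median) already bias amplitudes by ~5% at 3 Hz while adding little extra
#' robustness beyond single-frame spike rejection.
#'
#' @param median_window_s running-median window in seconds (default 0.05 s).
#' @param sg_window_s Savitzky-Golay window in seconds (default 0.117 s).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @param max_gap_s longest invalid-keypoint gap bridged by linear
#'   interpolation, in seconds (default 0.1 s); longer gaps flag the sequence
#'   unreliable.
#' @param start_frame,end_frame optional truncation bounds (0-based,
#'   half-open) applied by [preprocess_recording()].
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(median_window_s = 0.05, sg_window_s = 0.117,
                              sg_order = 3L, max_gap_s = 0.1,
                              start_frame = NULL, end_frame = NULL) {
  stopifnot(median_window_s > 0, sg_window_s > 0, sg_order >= 1, max_gap_s >= 0)
  structure(list(median_window_s = median_window_s, sg_window_s = sg_window_s,
                 sg_order = as.integer(sg_order), max_gap_s = max_gap_s,
                 start_frame = start_frame, end_frame = end_frame),
            class = "preprocess_config")
}

#' Truncate a recording to a frame window
#'
#' Restricts every sequence to frames `[start, end)` (0-based, half-open),
#' keeping fps and updating each sequence's frame offset.
#'
#' @param rec a [recording()].
#' @param start first frame kept (0-based).
#' @param end first frame dropped; `start < end <= N`.
#' @return the truncated [recording()].
#' @export
truncate_recording <- function(rec, start, end) {
  n <- n_frames(rec$sequences[[1L]])
  if (!(start >= 0 && start < end && end <= n))
    nk_stop("truncation window must satisfy 0 <= start < end <= N",
            "neurokin_empty_input")
  idx <- (start + 1L):end
  map_sequences(rec, function(s) {
    s$coords <- s$coords[idx, , , drop = FALSE]
    s$confidence <- s$confidence[idx, , drop = FALSE]
    s$frame_offset <- s$frame_offset + as.integer(start)
    s
  })
}

# Median over frames of the distance between two named joints of a sequence.
median_joint_distance <- function(seq, a, b) {
  d <- row_norms(joint_track(seq, a) - joint_track(seq, b))
  d <- d[is.finite(d)]
  if (length(d) == 0L)
    nk_stop("no valid frames to measure a reference length", "neurokin_degenerate")
  stats::median(d)
}

#' Reference length of a recording
#'
#' The scale used to normalize coordinates: for the upper-limb tests (FT,
#' FTF, FR) the forearm length -- the per-frame wrist-elbow distance,
#' median over frames, averaged over the right and left arms; for SAW the
#' median pelvis-neck distance of the global body track. Using the median
#' makes the reference robust to sporadic pose-estimation errors.
#'
#' @param rec a [recording()].
#' @return strictly positive scalar in raw coordinate units.
#' @export
reference_length <- function(rec) {
  ref <- if (rec$test == "SAW") {
    median_joint_distance(get_sequence(rec, "B2", "center"), "pelvis", "neck")
  } else {
    mean(c(
      median_joint_distance(get_sequence(rec, "B2", "right"), "wrist", "elbow"),
      median_joint_distance(get_sequence(rec, "B2", "left"), "wrist", "elbow")
    ))
  }
  if (!is.finite(ref) || ref <= 0)
    nk_stop("degenerate pose: reference length is zero", "neurokin_degenerate")
  ref
}

#' Normalize a recording by a reference length
#'
#' Divides every coordinate of every sequence by `ref`, converting raw
#' image/world units into normalized length units so that features are
#' comparable across subjects and camera distances. Applying the function
#' twice with a freshly computed reference is the identity (the second
#' reference is 1).
#'
#' @param rec a [recording()].
#' @param ref positive scalar, typically [reference_length()].
#' @return the normalized [recording()].
#' @export
normalize_recording <- function(rec, ref = reference_length(rec)) {
  if (!is.finite(ref) || ref <= 0)
    nk_stop("reference length must be positive", "neurokin_degenerate")
  map_sequences(rec, function(s) { s$coords <- s$coords / ref; s })
}

# Smooth a single 1-D track: bridge short NA gaps, running median, then
# Savitzky-Golay. Returns list(values, reliable).
smooth_track <- function(v, fps, cfg) {
  n <- length(v)
  reliable <- TRUE
  if (anyNA(v)) {
    max_gap <- max(1L, as.integer(round(cfg$max_gap_s * fps)))
    runs <- rle(is.na(v))
    if (any(runs$values & runs$lengths > max_gap)) reliable <- FALSE
    v <- zoo::na.approx(v, na.rm = FALSE, maxgap = max_gap)
    v <- zoo::na.fill(v, fill = "extend")  # edge gaps held at nearest value
    if (anyNA(v)) { reliable <- FALSE; v <- zoo::na.fill(v, fill = "extend") }
    if (anyNA(v)) return(list(values = v, reliable = FALSE))
  }
  mk <- odd_window(cfg$median_window_s * fps)
  if (n >= mk) v <- stats::runmed(v, mk, endrule = "median")
  sw <- odd_window(cfg$sg_window_s * fps)
  if (n >= sw && cfg$sg_order < sw)
    v <- signal::sgolayfilt(v, p = cfg$sg_order, n = sw)
  list(values = v, reliable = reliable)
}

#' Smooth a recording
#'
#' Per keypoint and axis: linear interpolation across invalid-keypoint gaps up
#' to the configured maximum, a running median to reject single-frame pose
#' spikes, then a Savitzky-Golay filter to suppress frame-to-frame jitter
#' while preserving local polynomial structure (derivatives in particular).
#' Sequence length, fps and units are unchanged. Sequences containing a gap
#' longer than the configured maximum are flagged via attribute
#' `"unreliable"` on the returned recording (a character vector of sequence
#' keys), mirroring the practice of excluding recordings whose estimated pose
#' is too unreliable to analyze.
#'
#' @param rec a [recording()].
#' @param cfg a [preprocess_config()].
#' @return the smoothed [recording()], with attribute `"unreliable"`.
#' @export
smooth_recording <- function(rec, cfg = preprocess_config()) {
  unreliable <- character()
  rec$sequences <- lapply(setNames(names(rec$sequences), names(rec$sequences)),
    function(key) {
      s <- rec$sequences[[key]]
      ok <- TRUE
      for (k in (s$tree$name_to_index + 1L)) {
        for (d in seq_len(dim(s$coords)[3L])) {
          v <- s$coords[, k, d]
          if (all(is.na(v))) next  # joint absent throughout: leave as missing
          sm <- smooth_track(v, s$fps, cfg)
          s$coords[, k, d] <- sm$values
          ok <- ok && sm$reliable
        }
      }
      if (!ok) unreliable <<- c(unreliable, key)
      s
    })
  attr(rec, "unreliable") <- unreliable
  rec
}

#' Full pre-processing pipeline
#'
#' Optional truncation, then reference-length normalization, then smoothing
#' ([smooth_recording()]). Downstream features computed on the result are
#' invariant to the subject's distance from the camera (uniform coordinate
#' rescaling) and to global translation wherever the feature definition is
#' relative.
#'
#' @param rec a [recording()].
#' @param cfg a [preprocess_config()].
#' @return the pre-processed [recording()], with attribute `"unreliable"`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  if (!is.null(cfg$start_frame) || !is.null(cfg$end_frame)) {
    n <- n_frames(rec$sequences[[1L]])
    rec <- truncate_recording(rec, cfg$start_frame %||% 0L, cfg$end_frame %||% n)
  }
  rec <- normalize_recording(rec)
  smooth_recording(rec, cfg)
}
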