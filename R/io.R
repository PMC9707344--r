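# Readers and writers for the pose formats the pipeline touches.

# Maps from this package's semantic joint names to keypoint indices of the
# OpenPose-style flat arrays (BODY_25 body, 21-keypoint hand). Right/left body
# joints live at different BODY_25 indices; hands come in separate arrays.
openpose_body25_map <- function(side) {
  if (side == "right")
    c(pelvis = 8L, neck = 1L, nose = 0L, eye = 15L, ear = 17L,
      shoulder = 2L, elbow = 3L, wrist = 4L)
  else
    c(pelvis = 8L, neck = 1L, nose = 0L, eye = 16L, ear = 18L,
      shoulder = 5L, elbow = 6L, wrist = 7L)
}

openpose_hand21_map <- c(wrist = 0L, thumb_base = 2L, thumb_mid = 3L,
                         thumb_tip = 4L, index_base = 5L, index_mid = 6L,
                         index_tip = 8L)

# Pull (x, y, conf) for a set of source indices out of a flat [x,y,c]*K array.
flat_to_xyc <- function(flat, src_idx) {
  x <- flat[3L * src_idx + 1L]
  y <- flat[3L * src_idx + 2L]
  conf <- flat[3L * src_idx + 3L]
  cbind(x = x, y = y, conf = conf)
}

#' Read per-frame OpenPose-style keypoint JSON
#'
#' Reads a directory of per-frame JSON documents (one file per frame, ordered
#' by file name) holding flat `[x, y, confidence] * K` keypoint arrays under
#' the usual keys (`pose_keypoints_2d`, `hand_right_keypoints_2d`,
#' `hand_left_keypoints_2d`, either at top level or inside the first element
#' of `people`). Image y-coordinates (downward-positive) are flipped to
#' mathematical y-up on load, so vertical positions and amplitudes increase
#' upward everywhere downstream. Keypoints with detector confidence below
#' `confidence_min` (or absent) are marked invalid: coordinates `NA`,
#' later bridged by pre-processing interpolation.
#'
#' @param path directory containing one `.json` file per frame.
#' @param fps capture frame rate in Hz.
#' @param subject_id,test,label,device,view recording metadata, see
#'   [recording()].
#' @param confidence_min keypoints below this confidence are treated as
#'   missing (default 0.1).
#' @return A [recording()] with one [pose_sequence()] per detected
#'   (tree, side).
#' @export
read_openpose_frames <- function(path, fps, subject_id = "unknown",
                                 test = c("FT", "FTF", "FR", "SAW"),
                                 label = "unknown", device = "unknown",
                                 view = "frontal", confidence_min = 0.1) {
  test <- match.arg(test)
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L)
    nk_stop("no frame JSON files found", "neurokin_empty_input")
  docs <- lapply(files, function(f) {
    doc <- jsonlite::fromJSON(f, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    if (!is.null(doc$people)) doc$people[[1L]] else doc
  })
  keys <- c(body = "pose_keypoints_2d",
            hand_right = "hand_right_keypoints_2d",
            hand_left = "hand_left_keypoints_2d")
  present <- names(keys)[vapply(keys, function(k)
    any(vapply(docs, function(d) !is.null(d[[k]]), logical(1))), logical(1))]
  n <- length(docs)
  grab <- function(key) {
    lens <- vapply(docs, function(d) length(unlist(d[[key]])), integer(1))
    kset <- unique(lens[lens > 0L])
    if (length(kset) != 1L)
      nk_stop(sprintf("inconsistent keypoint count across frames for %s", key),
              "neurokin_format_error")
    lapply(docs, function(d) {
      v <- unlist(d[[key]])
      if (length(v) == 0L) rep(NA_real_, kset) else as.numeric(v)
    })
  }
  build_seq <- function(tree_id, side, flat_list, src_map) {
    spec <- skeleton_spec(tree_id)
    k_use <- spec$name_to_index[names(src_map)] + 1L
    coords <- array(NA_real_, c(n, spec$n_joints, 2L))
    conf <- matrix(0, n, spec$n_joints)
    for (i in seq_len(n)) {
      xyc <- flat_to_xyc(flat_list[[i]], src_map)
      bad <- is.na(xyc[, "conf"]) | xyc[, "conf"] < confidence_min
      xyc[bad, c("x", "y")] <- NA_real_
      coords[i, k_use, 1L] <- xyc[, "x"]
      coords[i, k_use, 2L] <- -xyc[, "y"]  # image y-down -> math y-up
      conf[i, k_use] <- ifelse(is.na(xyc[, "conf"]), 0, xyc[, "conf"])
    }
    pose_sequence(spec, side, coords, conf, fps)
  }
  seqs <- list()
  if ("body" %in% present) {
    body <- grab("pose_keypoints_2d")
    seqs[["B2.right"]] <- build_seq("B2", "right", body, openpose_body25_map("right"))
    seqs[["B2.left"]]  <- build_seq("B2", "left",  body, openpose_body25_map("left"))
  }
  if ("hand_right" %in% present)
    seqs[["H2.right"]] <- build_seq("H2", "right", grab("hand_right_keypoints_2d"),
                                    openpose_hand21_map)
  if ("hand_left" %in% present)
    seqs[["H2.left"]] <- build_seq("H2", "left", grab("hand_left_keypoints_2d"),
                                   openpose_hand21_map)
  if (length(seqs) == 0L)
    nk_stop("no keypoint arrays found in frame JSON", "neurokin_format_error")
  recording(subject_id, test, seqs, label = label, device = device, view = view,
            check = FALSE)
}

#' Write a recording to a flat pose table
#'
#' One row per (sequence, joint, frame) with columns `subject`, `test`,
#' `label`, `device`, `view`, `fps`, `tree`, `side`, `joint`, `frame`, `x`,
#' `y`, `z`, `confidence`. Coordinates are written at full precision so that
#' [read_pose_table()] round-trips bit-exactly for finite values. `frame` is
#' the absolute (offset-adjusted) 0-based frame index.
#'
#' @param rec a [recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(rec, path) {
  # 17 significant digits guarantee the shortest exact decimal representation
  # of a double, so read_pose_table restores coordinates bit-exactly
  full <- function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  rows <- lapply(names(rec$sequences), function(key) {
    s <- rec$sequences[[key]]
    nm <- names(s$tree$name_to_index)
    kk <- s$tree$name_to_index + 1L
    n <- n_frames(s)
    data.table::data.table(
      subject = rec$subject_id, test = rec$test, label = rec$label,
      device = rec$device, view = rec$view, fps = s$fps,
      tree = s$tree$tree_id, side = s$side,
      joint = rep(nm, each = n),
      frame = rep(s$frame_offset + seq_len(n) - 1L, times = length(nm)),
      x = full(as.vector(s$coords[, kk, 1L])),
      y = full(as.vector(s$coords[, kk, 2L])),
      z = if (s$tree$ndim == 3L) full(as.vector(s$coords[, kk, 3L]))
          else NA_character_,
      confidence = full(as.vector(s$confidence[, kk]))
    )
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a flat pose table
#'
#' Inverse of [write_pose_table()]. Raises a format error on duplicate
#' (tree, side, joint, frame) rows, non-contiguous frame indices, or a B3
#' tree whose finite keypoints lack a z coordinate; an empty file raises an
#' empty-input error.
#'
#' @param path CSV path written by [write_pose_table()] (or equivalent).
#' @return A [recording()].
#' @export
read_pose_table <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L)
    nk_stop("pose table file is empty or missing", "neurokin_empty_input")
  dt <- data.table::fread(path)
  if (nrow(dt) == 0L) nk_stop("pose table has no rows", "neurokin_empty_input")
  need <- c("subject", "test", "label", "device", "view", "fps", "tree",
            "side", "joint", "frame", "x", "y", "confidence")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    nk_stop(paste("pose table missing columns:", paste(miss, collapse = ", ")),
            "neurokin_format_error")
  if (anyDuplicated(dt, by = c("tree", "side", "joint", "frame")))
    nk_stop("duplicate (tree, side, joint, frame) rows", "neurokin_format_error")
  if (!"z" %in% names(dt)) dt$z <- NA_real_
  for (col in c("x", "y", "z", "confidence")) dt[[col]] <- as.numeric(dt[[col]])
  keys <- unique(dt[, c("tree", "side")])
  seqs <- list()
  for (r in seq_len(nrow(keys))) {
    tree_id <- keys$tree[r]; side <- keys$side[r]
    sub <- dt[dt$tree == tree_id & dt$side == side, ]
    spec <- skeleton_spec(tree_id)
    if (spec$ndim == 3L && any(is.na(sub$z) & !is.na(sub$x)))
      nk_stop("B3 tree rows must carry a z coordinate", "neurokin_format_error")
    frames <- sort(unique(sub$frame))
    if (!all(diff(frames) == 1L))
      nk_stop("frame indices must be contiguous", "neurokin_format_error")
    n <- length(frames)
    coords <- array(NA_real_, c(n, spec$n_joints, spec$ndim))
    conf <- matrix(0, n, spec$n_joints)
    i <- sub$frame - frames[1L] + 1L
    k <- spec$name_to_index[sub$joint] + 1L
    if (anyNA(k))
      nk_stop("pose table references joints unknown to the skeleton spec",
              "neurokin_format_error")
    coords[cbind(i, k, 1L)] <- sub$x
    coords[cbind(i, k, 2L)] <- sub$y
    if (spec$ndim == 3L) coords[cbind(i, k, 3L)] <- sub$z
    conf[cbind(i, k)] <- sub$confidence
    seqs[[seq_key(tree_id, side)]] <-
      pose_sequence(spec, side, coords, conf, fps = sub$fps[1L],
                    frame_offset = frames[1L])
  }
  recording(dt$subject[1L], dt$test[1L], seqs, label = dt$label[1L],
            device = dt$device[1L], view = dt$view[1L], check = FALSE)
}

#' Write extracted features to a tabular file
#'
#' One row per recording, one column per named feature, in a stable column
#' order (union of feature names in first-seen order). Undefined features
#' (e.g. too few detected cycles) are written as empty cells, never as 0.
#'
#' @param features list of feature sets from [extract_features()] (all from
#'   the same test).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  tbl <- features_to_table(features)
  data.table::fwrite(tbl, path)
  invisible(path)
}

#' Assemble feature sets into a classification-ready table
#' @param features list of feature sets from [extract_features()].
#' @return A `data.frame` with metadata columns (`recording_id`, `subject`,
#'   `label`, `device`, `test`) followed by one numeric column per feature.
#' @export
features_to_table <- function(features) {
  if (length(features) == 0L)
    return(data.frame(recording_id = character(), subject = character(),
                      label = character(), device = character(),
                      test = character()))
  tests <- unique(vapply(features, function(f) f$test, character(1)))
  if (length(tests) > 1L)
    nk_stop("feature sets mix test types", "neurokin_format_error")
  all_names <- unique(unlist(lapply(features, function(f) names(f$values))))
  rows <- lapply(features, function(f) {
    v <- setNames(rep(NA_real_, length(all_names)), all_names)
    v[names(f$values)] <- f$values
    cbind(data.frame(recording_id = f$recording_id %||% NA_character_,
                     subject = f$subject_id %||% NA_character_,
                     label = f$label %||% "unknown",
                     device = f$device %||% "unknown",
                     test = f$test, stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  do.call(rbind, rows)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return A `data.frame` as produced by [features_to_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L)
    nk_stop("feature table file is empty or missing", "neurokin_empty_input")
  as.data.frame(data.table::fread(path))
}
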