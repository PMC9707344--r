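# Data model: skeleton trees, pose sequences, recordings.

#' Skeleton specifications
#'
#' A skeleton spec names the keypoints of one of the three skeleton trees used
#' by the analysis -- `H2` (2D hand), `B2` (2D body) and `B3` (3D body) -- and
#' maps each semantic joint name to its integer keypoint index. Feature code
#' never hard-codes indices; every joint is resolved through the spec, so
#' alternative pose estimators can be accommodated by supplying a different
#' `name_to_index` map.
#'
#' Default indexing: `H2` uses wrist=0, thumb chain 1-3 (thumb_tip=3), index
#' chain 4-6 (index_mid=5, index_tip=6). `B2` uses pelvis=0, neck=1, nose=2,
#' eye=3, ear=4, shoulder=5, elbow=6, wrist=7. `B3` uses pelvis=0, spine=1,
#' foot=2, knee=3, hip=4.
#'
#' @param tree_id one of `"H2"`, `"B2"`, `"B3"`.
#' @param name_to_index optional named integer vector overriding the default
#'   joint-name to 0-based keypoint-index map.
#' @param edges optional two-column integer matrix of (parent, child) keypoint
#'   indices; must form a tree (no cycles).
#' @return An object of class `skeleton_spec` with fields `tree_id`,
#'   `name_to_index`, `edges`, `n_joints` and `ndim` (2 or 3).
#' @export
#' @examples
#' sp <- skeleton_spec("H2")
#' sp$name_to_index[["thumb_tip"]]
skeleton_spec <- function(tree_id = c("H2", "B2", "B3"),
                          name_to_index = NULL, edges = NULL) {
  tree_id <- match.arg(tree_id)
  defaults <- switch(tree_id,
    H2 = list(
      map = c(wrist = 0L, thumb_base = 1L, thumb_mid = 2L, thumb_tip = 3L,
              index_base = 4L, index_mid = 5L, index_tip = 6L),
      edges = rbind(c(0L, 1L), c(1L, 2L), c(2L, 3L),
                    c(0L, 4L), c(4L, 5L), c(5L, 6L))
    ),
    B2 = list(
      map = c(pelvis = 0L, neck = 1L, nose = 2L, eye = 3L, ear = 4L,
              shoulder = 5L, elbow = 6L, wrist = 7L),
      edges = rbind(c(0L, 1L), c(1L, 2L), c(2L, 3L), c(3L, 4L),
                    c(1L, 5L), c(5L, 6L), c(6L, 7L))
    ),
    B3 = list(
      map = c(pelvis = 0L, spine = 1L, foot = 2L, knee = 3L, hip = 4L),
      edges = rbind(c(0L, 1L), c(0L, 4L), c(4L, 3L), c(3L, 2L))
    )
  )
  map <- name_to_index %||% defaults$map
  map <- vapply(map, as.integer, integer(1))
  edges <- edges %||% defaults$edges
  storage.mode(edges) <- "integer"
  if (anyDuplicated(map))
    nk_stop("keypoint indices must be unique within a tree", "neurokin_format_error")
  # edges must form a tree: connected would require all nodes; we check acyclic
  # via |E| = |V| - #components using a union-find pass.
  nodes <- sort(unique(c(edges)))
  parent <- seq_along(nodes)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(edges))) {
    a <- findp(match(edges[r, 1L], nodes)); b <- findp(match(edges[r, 2L], nodes))
    if (a == b) nk_stop("skeleton edges contain a cycle", "neurokin_format_error")
    parent[a] <- b
  }
  structure(list(
    tree_id = tree_id,
    name_to_index = map,
    edges = edges,
    n_joints = max(map) + 1L,
    ndim = if (tree_id == "B3") 3L else 2L
  ), class = "skeleton_spec")
}

#' Resolve a joint name to a 0-based keypoint index
#' @param spec a [skeleton_spec()].
#' @param name semantic joint name.
#' @return integer 0-based keypoint index.
#' @export
joint_index <- function(spec, name) {
  if (!name %in% names(spec$name_to_index))
    nk_stop(sprintf("joint '%s' not defined in tree %s", name, spec$tree_id),
            "neurokin_format_error")
  spec$name_to_index[[name]]
}

#' Construct a pose sequence
#'
#' A pose sequence is the time-indexed track of all keypoints of one skeleton
#' (one side, for paired limbs) in one recording. Frame `i` occurs at time
#' `i / fps` seconds relative to the (possibly truncated) recording start.
#' Coordinates are in image/world units before pre-processing and in
#' normalized length units (multiples of the reference length) afterwards.
#' Coordinates of invalid keypoints (low detector confidence, dropped frames)
#' are `NA` and their confidence is 0.
#'
#' @param tree a [skeleton_spec()].
#' @param side `"right"`, `"left"` or `"center"`.
#' @param coords numeric array of dimension N x K x D (frames x keypoints x
#'   coordinate dimension). D must be 2 for H2/B2 and 3 for B3.
#' @param confidence optional N x K matrix in `[0, 1]`; defaults to all ones
#'   (zero where coordinates are `NA`).
#' @param fps frames per second, > 0.
#' @param frame_offset integer index of the first frame within the original
#'   (untruncated) recording.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(tree, side = c("right", "left", "center"), coords,
                          confidence = NULL, fps, frame_offset = 0L) {
  side <- match.arg(side)
  stopifnot(inherits(tree, "skeleton_spec"))
  if (length(dim(coords)) != 3L)
    nk_stop("coords must be an N x K x D array", "neurokin_format_error")
  d <- dim(coords)
  if (d[1] < 2L) nk_stop("a pose sequence needs at least 2 frames", "neurokin_empty_input")
  if (d[3] != tree$ndim)
    nk_stop(sprintf("tree %s requires D = %d coordinates, got %d",
                    tree$tree_id, tree$ndim, d[3]), "neurokin_format_error")
  if (d[2] < tree$n_joints)
    nk_stop("coords has fewer keypoints than the skeleton spec declares",
            "neurokin_format_error")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    nk_stop("fps must be a positive scalar", "neurokin_format_error")
  if (is.null(confidence)) {
    confidence <- matrix(1, d[1], d[2])
    confidence[is.na(coords[, , 1L])] <- 0
  }
  structure(list(
    tree = tree, side = side, coords = coords,
    confidence = confidence, fps = fps,
    frame_offset = as.integer(frame_offset)
  ), class = "pose_sequence")
}

#' Number of frames in a pose sequence
#' @param seq a [pose_sequence()].
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$coords)[1L]

#' Frame times of a pose sequence
#' @param seq a [pose_sequence()].
#' @return numeric vector of times in seconds, `i / fps`.
#' @export
seq_times <- function(seq) seq_len(n_frames(seq)) / seq$fps

#' Extract the track of one named joint
#' @param seq a [pose_sequence()].
#' @param name semantic joint name resolved through the sequence's skeleton
#'   spec.
#' @return N x D numeric matrix of coordinates (may contain `NA`).
#' @export
joint_track <- function(seq, name) {
  k <- joint_index(seq$tree, name) + 1L
  m <- seq$coords[, k, , drop = FALSE]
  dim(m) <- dim(m)[c(1L, 3L)]
  m
}

seq_key <- function(tree_id, side) paste(tree_id, side, sep = ".")

#' Construct a recording
#'
#' A recording bundles the pose sequences of one test performance with its
#' metadata. The sequences required per test are: FT/FTF -- `H2` right+left
#' and `B2` right+left; FR -- `B2` right+left; SAW -- `B3` right+left and a
#' `B2` center (pelvis/neck) track providing global position.
#'
#' @param subject_id subject identifier string.
#' @param test one of `"FT"`, `"FTF"`, `"FR"`, `"SAW"`.
#' @param sequences named list of [pose_sequence()] keyed `"<tree>.<side>"`,
#'   e.g. `"H2.right"`.
#' @param label `"normal"`, `"abnormal"` or `"unknown"`.
#' @param device free-text capture device tag.
#' @param view `"frontal"` or `"sagittal"`.
#' @param check validate that the sequences required for `test` are present.
#' @return An object of class `recording`.
#' @export
recording <- function(subject_id, test = c("FT", "FTF", "FR", "SAW"),
                      sequences, label = c("unknown", "normal", "abnormal"),
                      device = "unknown", view = c("frontal", "sagittal"),
                      check = TRUE) {
  test <- match.arg(test)
  label <- match.arg(label)
  view <- match.arg(view)
  stopifnot(is.list(sequences))
  fps <- unique(vapply(sequences, function(s) s$fps, numeric(1)))
  if (length(fps) != 1L)
    nk_stop("all sequences of a recording must share one fps", "neurokin_format_error")
  rec <- structure(list(
    subject_id = as.character(subject_id), test = test, label = label,
    device = device, view = view, sequences = sequences, fps = fps
  ), class = "recording")
  if (check) validate_recording(rec)
  rec
}

required_sequences <- function(test) {
  switch(test,
    FT  = c("H2.right", "H2.left", "B2.right", "B2.left"),
    FTF = c("H2.right", "H2.left", "B2.right", "B2.left"),
    FR  = c("B2.right", "B2.left"),
    SAW = c("B3.right", "B3.left", "B2.center")
  )
}

#' Validate a recording's sequence inventory
#' @param rec a [recording()].
#' @return `rec`, invisibly; raises a format error if a required sequence is
#'   missing.
#' @export
validate_recording <- function(rec) {
  need <- required_sequences(rec$test)
  miss <- setdiff(need, names(rec$sequences))
  if (length(miss))
    nk_stop(sprintf("%s recording is missing sequence(s): %s",
                    rec$test, paste(miss, collapse = ", ")),
            "neurokin_format_error")
  invisible(rec)
}

#' Fetch one sequence of a recording
#' @param rec a [recording()].
#' @param tree_id `"H2"`, `"B2"` or `"B3"`.
#' @param side `"right"`, `"left"` or `"center"`.
#' @return the requested [pose_sequence()].
#' @export
get_sequence <- function(rec, tree_id, side) {
  key <- seq_key(tree_id, side)
  s <- rec$sequences[[key]]
  if (is.null(s))
    nk_stop(sprintf("recording has no %s sequence", key), "neurokin_format_error")
  s
}

# Apply a function to the coords of every sequence, preserving structure.
map_sequences <- function(rec, f) {
  rec$sequences <- lapply(rec$sequences, f)
  rec
}

#' @export
print.recording <- function(x, ...) {
  ns <- vapply(x$sequences, n_frames, integer(1))
  cat(sprintf("<recording> test=%s subject=%s label=%s device=%s view=%s fps=%g\n",
              x$test, x$subject_id, x$label, x$device, x$view, x$fps))
  cat(sprintf("  sequences: %s\n",
              paste(sprintf("%s[N=%d]", names(x$sequences), ns), collapse = " ")))
  invisible(x)
}

#' @export
print.pose_sequence <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<pose_sequence> %s.%s N=%d K=%d D=%d fps=%g offset=%d\n",
              x$tree$tree_id, x$side, d[1], d[2], d[3], x$fps, x$frame_offset))
  invisible(x)
}
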