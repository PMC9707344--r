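# Shared fixtures and independent oracles.

# Build one noise-free pose sequence from named joint tracks. Tracks may be a
# length-D constant or an N x D matrix; unnamed joints stay missing.
mk_seq <- function(tree_id, side, joints, n, fps = 60) {
  spec <- skeleton_spec(tree_id)
  coords <- array(NA_real_, c(n, spec$n_joints, spec$ndim))
  for (nm in names(joints)) {
    tr <- joints[[nm]]
    if (is.null(dim(tr))) tr <- matrix(tr, n, length(tr), byrow = TRUE)
    coords[, spec$name_to_index[[nm]] + 1L, ] <- tr
  }
  pose_sequence(spec, side, coords, fps = fps)
}

# Static upper-body rig with forearm length exactly `forearm` raw units.
mk_b2 <- function(side, n, fps = 60, forearm = 120, wrist = NULL) {
  sx <- if (side == "right") 1 else -1
  mk_seq("B2", side, list(
    pelvis = c(0, 0), neck = c(0, 240), shoulder = c(sx * 80, 220),
    elbow = c(sx * 150, 120),
    wrist = wrist %||% c(sx * 150, 120 + forearm)), n, fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal FT recording from explicit fingertip tracks.
mk_ft_rec <- function(thumb_r, index_r, thumb_l = thumb_r * c(-1, 1),
                      index_l = index_r * c(-1, 1), n, fps = 60) {
  flip <- function(tr) if (is.null(dim(tr))) tr else tr %*% diag(c(-1, 1))
  recording("T01", "FT", list(
    H2.right = mk_seq("H2", "right", list(thumb_tip = thumb_r, index_tip = index_r,
                                          wrist = c(150, 240)), n, fps),
    H2.left = mk_seq("H2", "left", list(thumb_tip = thumb_l, index_tip = index_l,
                                        wrist = c(-150, 240)), n, fps),
    B2.right = mk_b2("right", n, fps),
    B2.left = mk_b2("left", n, fps)))
}

# FFT oracle: dominant frequency of a uniformly sampled signal. Zero-padding
# refines the frequency grid well below the comparison tolerance.
fft_dominant_freq <- function(v, fps) {
  v <- v - mean(v)
  n <- length(v)
  nfft <- 2^ceiling(log2(n * 32))
  sp <- Mod(stats::fft(c(v, rep(0, nfft - n))))[2:floor(nfft / 2)]
  which.max(sp) * fps / nfft
}

# Mean silhouette of a 2-class labelling in a points matrix.
silhouette_mean <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  sil <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own]); b <- mean(d[i, !own & seq_len(nrow(x)) != i])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# Small synthetic feature table for classifier tests. The first
# `n_informative` features shift by `shift` for abnormal recordings (noise sd
# `inf_sd`); the rest are standard-normal noise.
mk_feature_table <- function(n_subjects = 10, informative = TRUE, seed = 1,
                             n_informative = 1, shift = 1, inf_sd = 0.05,
                             n_features = 6) {
  set.seed(seed)
  rows <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                      label = c("normal", "abnormal"),
                      device = c("tablet", "phone"),
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  x <- data.frame(
    recording_id = paste(rows$subject, rows$label, rows$device, sep = "_"),
    subject = rows$subject, label = rows$label, device = rows$device,
    test = "FT", stringsAsFactors = FALSE)
  for (j in seq_len(n_features)) {
    x[[paste0("f", j)]] <- if (informative && j <= n_informative)
      ifelse(rows$label == "abnormal", shift, 0) + rnorm(n, 0, inf_sd)
    else rnorm(n)
  }
  x
}
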