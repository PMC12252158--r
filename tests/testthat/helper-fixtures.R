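# Shared fixtures: a deterministic standing stick figure and small
# random feature maps.

# A standing figure around x = 100, hips at y = 200, head at y ~ 60.
test_frame <- function(dx = 0, dy = 0, frame_index = 0, timestamp = 0,
                       margin = 3) {
  base <- data.frame(
    name = c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
             "left_shoulder", "right_shoulder", "left_elbow",
             "right_elbow", "left_wrist", "right_wrist",
             "left_hip", "right_hip", "left_knee", "right_knee",
             "left_ankle", "right_ankle"),
    x = c(100, 98, 102, 96, 104, 85, 115, 80, 120, 78, 122,
          93, 107, 92, 108, 91, 109),
    y = c(70, 67, 67, 69, 69, 110, 110, 145, 145, 180, 180,
          200, 200, 250, 250, 300, 300),
    confidence = 1, visible = TRUE, stringsAsFactors = FALSE)
  base$x <- base$x + dx
  base$y <- base$y + dy
  box <- bbox(min(base$x) - margin, min(base$y) - margin,
              max(base$x) + margin, max(base$y) + margin)
  pose_frame(frame_index, timestamp, box, base)
}

# Track whose centroid drops `per_frame` px each frame, no other motion.
dropping_track <- function(n = 60, per_frame = 6, fps = 60) {
  frames <- lapply(seq_len(n) - 1L, function(i)
    test_frame(dy = per_frame * i, frame_index = i, timestamp = i / fps))
  track_sequence(frames, fps)
}

rand_fmap <- function(C, H, W, seed = 1) {
  set.seed(seed)
  array(rnorm(C * H * W), c(C, H, W))
}

# Independent trunk-angle oracle: atan2 folded into [0, 180].
angle_oracle <- function(z) abs(atan2(z[2], z[1]) * 180 / pi)

# Independent brute-force max filter (stride 1, same padding).
maxfilter_oracle <- function(mat, k) {
  h <- nrow(mat); w <- ncol(mat); r <- (k - 1) / 2
  out <- matrix(-Inf, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- max(1, i - r):min(h, i + r)
      ci <- max(1, j - r):min(w, j + r)
      out[i, j] <- max(mat[ri, ci])
    }
  }
  out
}
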