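# Synthetic keypoint-trajectory simulator.
#
# Generates labelled walking / lying / falling tracks whose kinematic
# signatures match the assumptions of the rule engine: walking shows a
# periodic bounding-box aspect-ratio oscillation; lying is a slow postural
# transition with a gentle centroid drop; falling is a fast (~0.5 s)
# centroid drop with a concentrated trunk rotation.  Keypoints are placed
# on a consistent stick-figure model; the bounding box is the tight hull
# of the visible keypoints plus a margin.

# Stick-figure proportions in body frame (origin at hip centre, y up,
# units of total body height L).
SKELETON_PROPORTIONS <- local({
  m <- matrix(c(
     0.00, 0.43,   # nose
    -0.02, 0.46,   0.02, 0.46,    # eyes
    -0.04, 0.45,   0.04, 0.45,    # ears
    -0.11, 0.30,   0.11, 0.30,    # shoulders
    -0.13, 0.18,   0.13, 0.18,    # elbows
    -0.14, 0.04,   0.14, 0.04,    # wrists
    -0.06, 0.00,   0.06, 0.00,    # hips
    -0.07, -0.25,  0.07, -0.25,   # knees
    -0.08, -0.48,  0.08, -0.48    # ankles
  ), ncol = 2, byrow = TRUE)
  rownames(m) <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
                   "left_shoulder", "right_shoulder", "left_elbow",
                   "right_elbow", "left_wrist", "right_wrist",
                   "left_hip", "right_hip", "left_knee", "right_knee",
                   "left_ankle", "right_ankle")
  colnames(m) <- c("x", "y")
  m
})

#' Behaviour parameters for the trajectory simulator
#'
#' Defines one simulated behaviour episode.  Defaults emulate the
#' calibration conditions of the rule engine: 60 fps, 65-frame sequences
#' (lying uses 4 s so its slow transition can span at least 3 s), a
#' 15-frame walking gait period with aspect ratio inside (1.6, 2.4), a
#' fall whose peak per-0.25-s centroid drop is 120 px (480 px/s) with a
#' 90-degree trunk rotation, and a lying transition peaking at 30 px per
#' 0.25 s (120 px/s) with an 85-degree rotation over 3 s.
#'
#' @param behavior `"walking"`, `"lying"` or `"falling"`.
#' @param fps Frames per second (> 0).
#' @param duration_s Episode length in seconds; default 65 frames for
#'   walking/falling and 4 s for lying.
#' @param gait_period Walking gait period in frames.
#' @param A_band Walking aspect-ratio oscillation range.
#' @param peak_drop Peak centroid drop per 0.25 s window, pixels
#'   (falling default 120, lying default 30).
#' @param rotation_total Total trunk rotation in degrees (falling default
#'   90, lying default 85).
#' @param noise_sd Isotropic Gaussian keypoint noise, pixels.
#' @param occlusion_prob Per-keypoint probability of being marked
#'   invisible.
#' @param seed Integer RNG seed; identical params + seed give identical
#'   tracks.
#' @param body_height Stick-figure height in pixels.
#' @param canvas `c(width, height)` of the virtual image in pixels;
#'   thresholds are pixel-scale dependent, so this fixes the scale.
#' @param onset_frame 0-based frame at which the fall/lying transition
#'   starts (defaults: 15 for falling -- one sample interval in -- and
#'   0.5 s worth of frames for lying).
#' @param transition_s Length of the postural transition in seconds
#'   (falling default 0.5, lying default 3).
#' @param margin Bounding-box margin around the keypoint hull, pixels.
#' @return An object of class `"behavior_params"`.
#' @examples
#' behavior_params("falling")
#' @export
behavior_params <- function(behavior = c("walking", "lying", "falling"),
                            fps = 60, duration_s = NULL, gait_period = 15L,
                            A_band = c(1.6, 2.4), peak_drop = NULL,
                            rotation_total = NULL, noise_sd = 0.5,
                            occlusion_prob = 0, seed = 1L,
                            body_height = 300, canvas = c(640, 480),
                            onset_frame = NULL, transition_s = NULL,
                            margin = 3) {
  behavior <- match.arg(behavior)
  if (is.null(duration_s)) {
    duration_s <- if (behavior == "lying") 4.0 else 65 / fps
  }
  if (is.null(peak_drop)) {
    peak_drop <- switch(behavior, falling = 120, lying = 30, walking = 0)
  }
  if (is.null(rotation_total)) {
    rotation_total <- switch(behavior, falling = 90, lying = 85, walking = 0)
  }
  if (is.null(transition_s)) {
    transition_s <- switch(behavior, falling = 0.5, lying = 3, walking = 0)
  }
  if (is.null(onset_frame)) {
    onset_frame <- switch(behavior, falling = 15L,
                          lying = as.integer(round(0.5 * fps)), walking = 0L)
  }
  stopifnot(fps > 0, duration_s > 0, gait_period >= 2,
            length(A_band) == 2, A_band[1] < A_band[2],
            noise_sd >= 0, occlusion_prob >= 0, occlusion_prob <= 1,
            body_height > 0, length(canvas) == 2, all(canvas > 0),
            margin >= 0)
  if (behavior != "walking" && transition_s <= 0) {
    stop("transition_s must be > 0 for lying/falling", call. = FALSE)
  }
  structure(list(behavior = behavior, fps = fps, duration_s = duration_s,
                 gait_period = as.integer(gait_period), A_band = A_band,
                 peak_drop = peak_drop, rotation_total = rotation_total,
                 noise_sd = noise_sd, occlusion_prob = occlusion_prob,
                 seed = as.integer(seed), body_height = body_height,
                 canvas = canvas, onset_frame = as.integer(onset_frame),
                 transition_s = transition_s, margin = margin),
            class = "behavior_params")
}

#' @export
print.behavior_params <- function(x, ...) {
  cat(sprintf("<behavior_params: %s, %g fps, %.2f s, seed %d>\n",
              x$behavior, x$fps, x$duration_s, x$seed))
  invisible(x)
}

# Place the stick figure: rotate body-frame points by phi degrees
# (clockwise in image coords, i.e. toward +x) about the hip centre, flip y
# to image coordinates, and translate so the torso centroid (mean of
# shoulders and hips) lands at (cx, cy).
place_skeleton <- function(phi_deg, cx, cy, L, ankle_half_spread = NULL) {
  pts <- SKELETON_PROPORTIONS * L
  if (!is.null(ankle_half_spread)) {
    pts["left_ankle", "x"] <- -ankle_half_spread
    pts["right_ankle", "x"] <- ankle_half_spread
    kneespread <- ankle_half_spread * 0.55
    pts["left_knee", "x"] <- -kneespread
    pts["right_knee", "x"] <- kneespread
  }
  phi <- phi_deg * pi / 180
  # rotation toward +x in image coords = clockwise in body frame
  R <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2, byrow = TRUE)
  rot <- t(R %*% t(pts))
  img <- cbind(x = rot[, 1], y = -rot[, 2])  # y flip to image coords
  torso <- c("left_shoulder", "right_shoulder", "left_hip", "right_hip")
  ctr <- colMeans(img[torso, , drop = FALSE])
  img[, "x"] <- img[, "x"] - ctr["x"] + cx
  img[, "y"] <- img[, "y"] - ctr["y"] + cy
  img
}

skeleton_to_frame <- function(pts, frame_index, timestamp, noise_sd,
                              margin, track_id = 1L) {
  if (noise_sd > 0) {
    pts <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd),
                        ncol = 2, dimnames = dimnames(pts))
  }
  kps <- data.frame(name = rownames(pts), x = pts[, "x"], y = pts[, "y"],
                    confidence = 1, visible = TRUE,
                    stringsAsFactors = FALSE)
  rownames(kps) <- NULL
  box <- bbox(min(pts[, "x"]) - margin, min(pts[, "y"]) - margin,
              max(pts[, "x"]) + margin, max(pts[, "y"]) + margin)
  pose_frame(frame_index, timestamp, box, kps, track_id = track_id)
}

# Fraction of the total transition drop completed at local progress u in
# [0, 1]: constant-acceleration profile.
drop_profile <- function(u) clamp(u, 0, 1)^2

# Fraction of the total trunk rotation completed at local progress u:
# flat until 40% of the transition, then smoothstep to 1, so most of the
# rotation concentrates in a single sampled interval.
rotation_profile <- function(u) smoothstep((clamp(u, 0, 1) - 0.4) / 0.6)

# Total drop D such that the peak drop over an aligned 0.25 s window is
# peak_drop, under the constant-acceleration profile over T seconds.
total_drop <- function(peak_drop, transition_s) {
  Tn <- max(transition_s, 0.25)
  frac <- 1 - (1 - 0.25 / Tn)^2
  peak_drop / frac
}

#' Simulate a labelled behaviour track
#'
#' Generates one keypoint track for the requested behaviour.  Walking
#' oscillates the bounding-box aspect ratio sinusoidally inside `A_band`
#' with period `gait_period` (via leg spread) while the centroid stays
#' nearly level; lying and falling rotate the trunk by `rotation_total`
#' degrees and drop the centroid with a constant-acceleration profile
#' scaled so the largest sample-aligned 0.25-s window drop equals
#' `peak_drop` pixels.  Deterministic given `seed`.
#'
#' @param params A [behavior_params()].
#' @return A `labeled_track`: list with `track` (a [track_sequence()]),
#'   `label`, and `event_frame` (fall onset; `NULL` unless falling).
#' @examples
#' lt <- simulate_track(behavior_params("walking", seed = 3))
#' lt$label
#' @export
simulate_track <- function(params) {
  stopifnot(inherits(params, "behavior_params"))
  p <- params
  n <- as.integer(round(p$duration_s * p$fps))
  if (n < 1) stop("invalid parameters: zero-length track", call. = FALSE)
  L <- p$body_height
  floor_y <- p$canvas[2] - 20
  cx0 <- p$canvas[1] / 2
  cy0 <- floor_y - 0.63 * L     # standing torso-centroid height
  frames <- with_seed(p$seed, {
    out <- vector("list", n)
    if (p$behavior == "walking") {
      A_mid <- mean(p$A_band)
      A_amp <- diff(p$A_band) / 2
      hull_h <- 0.94 * L
      for (i in seq_len(n)) {
        tt <- (i - 1) / p$fps
        A_t <- A_mid + A_amp * sin(2 * pi * (i - 1) / p$gait_period)
        box_h <- hull_h + 2 * p$margin
        half_w <- (box_h / A_t - 2 * p$margin) / 2
        cx <- cx0 - 40 + 40 * tt                # slow forward drift
        cy <- cy0 + 2 * sin(4 * pi * (i - 1) / p$gait_period)  # gait bob
        pts <- place_skeleton(0, cx, cy, L, ankle_half_spread = half_w)
        out[[i]] <- skeleton_to_frame(pts, i - 1L, tt, p$noise_sd, p$margin)
      }
    } else {
      Tn <- p$transition_s
      D <- total_drop(p$peak_drop, Tn)
      for (i in seq_len(n)) {
        tt <- (i - 1) / p$fps
        u <- (i - 1 - p$onset_frame) / (Tn * p$fps)
        phi <- p$rotation_total * rotation_profile(u)
        cy <- cy0 + D * drop_profile(u)
        pts <- place_skeleton(phi, cx0, cy, L)
        out[[i]] <- skeleton_to_frame(pts, i - 1L, tt, p$noise_sd, p$margin)
      }
    }
    out
  })
  lt <- structure(list(track = track_sequence(frames, p$fps),
                       label = p$behavior,
                       event_frame = if (p$behavior == "falling")
                         p$onset_frame else NULL,
                       params = p),
                  class = "labeled_track")
  if (p$occlusion_prob > 0) {
    lt <- occlude_track(lt, p$occlusion_prob, seed = p$seed + 104729L)
  }
  lt
}

#' @export
print.labeled_track <- function(x, ...) {
  cat(sprintf("<labeled_track: %s, %d frames @ %g fps%s>\n", x$label,
              length(x$track$frames), x$track$fps,
              if (!is.null(x$event_frame))
                sprintf(", event at frame %d", x$event_frame) else ""))
  invisible(x)
}

#' Randomly occlude keypoints along a track
#'
#' Marks each keypoint of each frame invisible independently with the
#' given probability; coordinates are retained.  Deterministic given
#' `seed`.
#'
#' @param labeled A `labeled_track` (or a bare [track_sequence()]).
#' @param occlusion_prob Probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Object of the same type with visibilities updated.
#' @export
occlude_track <- function(labeled, occlusion_prob, seed = 1L) {
  stopifnot(occlusion_prob >= 0, occlusion_prob <= 1)
  is_lab <- inherits(labeled, "labeled_track")
  track <- if (is_lab) labeled$track else labeled
  stopifnot(inherits(track, "track_sequence"))
  track$frames <- with_seed(seed, lapply(track$frames, function(f) {
    hide <- stats::runif(nrow(f$keypoints)) < occlusion_prob
    f$keypoints$visible <- f$keypoints$visible & !hide
    f
  }))
  if (is_lab) {
    labeled$track <- track
    labeled
  } else {
    track
  }
}

#' Render a pose frame as a stick-figure raster
#'
#' Draws the skeleton limbs (between mutually visible keypoints) as white
#' lines on a black canvas; used to build deterministic raster fixtures
#' for the erasing augmentation.  Keypoints must lie inside the canvas.
#'
#' @param frame A [pose_frame()].
#' @param canvas `c(width, height)` in pixels.
#' @param line_width Stroke width in pixels.
#' @return Numeric array `[height, width, 3]` with values in `[0, 255]`.
#' @export
render_fixture <- function(frame, canvas = c(640, 480), line_width = 2) {
  w <- as.integer(canvas[1]); h <- as.integer(canvas[2])
  img <- array(0, dim = c(h, w, 3))
  kps <- frame$keypoints
  vis <- kps[kps$visible, , drop = FALSE]
  if (nrow(vis) == 0) return(img)
  if (any(vis$x < 0) || any(vis$x > w - 1) ||
      any(vis$y < 0) || any(vis$y > h - 1)) {
    stop("keypoints fall outside the canvas", call. = FALSE)
  }
  half <- floor((line_width - 1) / 2)
  draw_seg <- function(img, p, q) {
    len <- max(abs(p - q))
    nsteps <- max(2L, as.integer(ceiling(len)) * 2L)
    xs <- round(seq(p[1], q[1], length.out = nsteps)) + 1L
    ys <- round(seq(p[2], q[2], length.out = nsteps)) + 1L
    for (dx in -half:(line_width - 1 - half)) {
      for (dy in -half:(line_width - 1 - half)) {
        xi <- clamp(xs + dx, 1L, w)
        yi <- clamp(ys + dy, 1L, h)
        for (ch in 1:3) img[cbind(yi, xi, ch)] <- 255
      }
    }
    img
  }
  for (k in seq_len(nrow(COCO_SKELETON))) {
    a <- kps[kps$name == COCO_SKELETON[k, 1], ]
    b <- kps[kps$name == COCO_SKELETON[k, 2], ]
    if (a$visible && b$visible) {
      img <- draw_seg(img, c(a$x, a$y), c(b$x, b$y))
    }
  }
  img
}
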