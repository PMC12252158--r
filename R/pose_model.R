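#' @keywords internal
"_PACKAGE"

# Canonical COCO-17 keypoint order.  All keypoint tables in the package use
# this ordering; readers enforce it.
COCO_KEYPOINTS <- c(
  "nose", "left_eye", "right_eye", "left_ear", "right_ear",
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle"
)

# Derived (non-COCO) landmark names.  They are stored separately from the 17
# base keypoints so the data model is robust to 17- or 18-point inputs.
DERIVED_KEYPOINTS <- c("neck", "centroid", "ground_proj")

# Limb connectivity used by the stick-figure renderer.
COCO_SKELETON <- matrix(c(
  "left_ankle", "left_knee",    "left_knee", "left_hip",
  "right_ankle", "right_knee",  "right_knee", "right_hip",
  "left_hip", "right_hip",
  "left_shoulder", "left_hip",  "right_shoulder", "right_hip",
  "left_shoulder", "right_shoulder",
  "left_shoulder", "left_elbow",  "left_elbow", "left_wrist",
  "right_shoulder", "right_elbow", "right_elbow", "right_wrist",
  "nose", "left_eye", "nose", "right_eye",
  "left_eye", "left_ear", "right_eye", "right_ear",
  "left_shoulder", "nose", "right_shoulder", "nose"
), ncol = 2, byrow = TRUE)

#' Construct a single keypoint
#'
#' A keypoint is a named 2D body landmark in pixel image coordinates
#' (origin top-left, y increasing downward, sub-pixel positions allowed)
#' with a detection confidence and a visibility flag.
#'
#' @param name Semantic label: one of the 17 COCO part names or
#'   `"neck"`, `"centroid"`, `"ground_proj"`.
#' @param x,y Pixel coordinates; must be finite.
#' @param confidence Unitless confidence in `[0, 1]`.
#' @param visible Logical visibility flag.
#' @return A one-row `data.frame` with columns `name`, `x`, `y`,
#'   `confidence`, `visible`.
#' @examples
#' keypoint("nose", 12.5, 40, confidence = 0.98)
#' @export
keypoint <- function(name, x, y, confidence = 1, visible = TRUE) {
  name <- match.arg(name, c(COCO_KEYPOINTS, DERIVED_KEYPOINTS))
  if (!is.finite(x) || !is.finite(y)) {
    stop("keypoint coordinates must be finite", call. = FALSE)
  }
  if (!is.finite(confidence) || confidence < 0 || confidence > 1) {
    stop("keypoint confidence must lie in [0, 1]", call. = FALSE)
  }
  data.frame(name = name, x = as.numeric(x), y = as.numeric(y),
             confidence = as.numeric(confidence),
             visible = as.logical(visible),
             stringsAsFactors = FALSE)
}

#' Construct a bounding box
#'
#' @param xmin,ymin,xmax,ymax Corner coordinates in pixels; `xmax > xmin`
#'   and `ymax > ymin`.
#' @return An object of class `"bbox"` (named numeric vector).
#' @examples
#' bbox(0, 0, 40, 80)
#' @export
bbox <- function(xmin, ymin, xmax, ymax) {
  v <- c(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  if (any(!is.finite(v))) stop("bbox coordinates must be finite", call. = FALSE)
  if (v["xmax"] <= v["xmin"] || v["ymax"] <= v["ymin"]) {
    stop("degenerate bbox: require xmax > xmin and ymax > ymin", call. = FALSE)
  }
  structure(v, class = "bbox")
}

#' Construct a per-frame pose observation
#'
#' A `pose_frame` bundles the bounding box and the 17 COCO keypoints
#' observed for one person in one video frame, plus (optionally) the
#' derived landmarks computed by [derive_points()].
#'
#' @param frame_index Integer frame index, 0-based.
#' @param timestamp Time of the frame in seconds.
#' @param bbox A [bbox()].
#' @param keypoints A 17-row keypoint `data.frame` in canonical COCO order
#'   (see [keypoint()]), or a list of single keypoints.
#' @param derived Optional keypoint `data.frame` of derived landmarks.
#' @param track_id Integer id of the person track this frame belongs to.
#' @return An object of class `"pose_frame"`.
#' @export
pose_frame <- function(frame_index, timestamp, bbox, keypoints,
                       derived = NULL, track_id = 1L) {
  if (is.list(keypoints) && !is.data.frame(keypoints)) {
    keypoints <- do.call(rbind, keypoints)
  }
  stopifnot(is.data.frame(keypoints))
  if (nrow(keypoints) != 17L) {
    stop("pose_frame requires exactly 17 base keypoints, got ",
         nrow(keypoints), call. = FALSE)
  }
  ord <- match(COCO_KEYPOINTS, keypoints$name)
  if (anyNA(ord)) {
    stop("keypoints must contain each of the 17 COCO parts exactly once",
         call. = FALSE)
  }
  keypoints <- keypoints[ord, , drop = FALSE]
  rownames(keypoints) <- NULL
  if (frame_index < 0) stop("frame_index must be >= 0", call. = FALSE)
  structure(list(
    frame_index = as.integer(frame_index),
    timestamp = as.numeric(timestamp),
    bbox = bbox,
    keypoints = keypoints,
    derived = derived,
    track_id = as.integer(track_id)
  ), class = "pose_frame")
}

#' @export
print.pose_frame <- function(x, ...) {
  cat(sprintf("<pose_frame #%d t=%.3fs track=%d bbox=[%.1f,%.1f,%.1f,%.1f]>\n",
              x$frame_index, x$timestamp, x$track_id,
              x$bbox["xmin"], x$bbox["ymin"], x$bbox["xmax"], x$bbox["ymax"]))
  vis <- sum(x$keypoints$visible)
  cat(sprintf("  %d/17 keypoints visible; derived: %s\n", vis,
              if (is.null(x$derived)) "none" else
                paste(x$derived$name, collapse = ", ")))
  invisible(x)
}

#' Construct a time-ordered track of pose frames
#'
#' @param frames List of [pose_frame()] objects with strictly increasing
#'   timestamps.
#' @param fps Frame rate of the source video (frames per second, > 0).
#' @return An object of class `"track_sequence"`.
#' @export
track_sequence <- function(frames, fps) {
  stopifnot(is.list(frames))
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (length(frames)) {
    ts <- vapply(frames, function(f) f$timestamp, numeric(1))
    if (any(diff(ts) <= 0)) {
      stop("timestamps must strictly increase along a track", call. = FALSE)
    }
  }
  structure(list(frames = frames, fps = as.numeric(fps)),
            class = "track_sequence")
}

#' @export
print.track_sequence <- function(x, ...) {
  cat(sprintf("<track_sequence: %d frames @ %g fps>\n",
              length(x$frames), x$fps))
  invisible(x)
}

#' @export
length.track_sequence <- function(x) length(x$frames)

kp_row <- function(frame, name, source = c("base", "derived")) {
  source <- match.arg(source)
  tab <- if (source == "base") frame$keypoints else frame$derived
  if (is.null(tab)) return(NULL)
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L) NULL else row
}

#' Derive the neck landmark from the shoulders
#'
#' The neck is not part of the COCO-17 set; it is taken as the midpoint of
#' the two shoulders, with confidence equal to the smaller of the two
#' shoulder confidences.
#'
#' @param frame A [pose_frame()].
#' @return A one-row keypoint `data.frame` named `"neck"`.
#' @examples
#' \dontrun{derive_neck(frame)}
#' @export
derive_neck <- function(frame) {
  ls <- kp_row(frame, "left_shoulder")
  rs <- kp_row(frame, "right_shoulder")
  ok <- function(k) !is.null(k) && k$visible && k$confidence > 0
  if (!ok(ls) || !ok(rs)) {
    stop("missing shoulder: both shoulders must be visible with confidence > 0",
         call. = FALSE)
  }
  keypoint("neck", (ls$x + rs$x) / 2, (ls$y + rs$y) / 2,
           confidence = min(ls$confidence, rs$confidence))
}

#' Derive the body centroid from the torso keypoints
#'
#' The centroid is the mean of the four torso keypoints (both shoulders
#' and both hips); its confidence is the minimum over the four.
#'
#' @param frame A [pose_frame()].
#' @return A one-row keypoint `data.frame` named `"centroid"`.
#' @export
derive_centroid <- function(frame) {
  parts <- c("left_shoulder", "right_shoulder", "left_hip", "right_hip")
  rows <- lapply(parts, kp_row, frame = frame)
  ok <- vapply(rows, function(k) !is.null(k) && k$visible && k$confidence > 0,
               logical(1))
  if (!all(ok)) {
    stop("missing torso keypoint: shoulders and hips must be visible (",
         paste(parts[!ok], collapse = ", "), ")", call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  keypoint("centroid", mean(tab$x), mean(tab$y),
           confidence = min(tab$confidence))
}

#' Derive the ground projection of the torso centroid
#'
#' Vertical projection of the centroid onto the bottom edge of the
#' person's bounding box: `(x_centroid, ymax)`.
#'
#' @param frame A [pose_frame()].
#' @return A one-row keypoint `data.frame` named `"ground_proj"`.
#' @export
derive_ground_projection <- function(frame) {
  ctr <- derive_centroid(frame)
  keypoint("ground_proj", ctr$x, unname(frame$bbox["ymax"]),
           confidence = ctr$confidence)
}

#' Attach all derived landmarks to a frame
#'
#' Computes neck, centroid and ground projection and stores them in the
#' frame's `derived` slot. Frames whose torso keypoints are occluded raise
#' an error; callers that tolerate gaps should wrap in `tryCatch()`.
#'
#' @param frame A [pose_frame()].
#' @return The frame with `derived` filled in.
#' @export
derive_points <- function(frame) {
  frame$derived <- rbind(derive_neck(frame), derive_centroid(frame),
                         derive_ground_projection(frame))
  frame
}

#' Keypoint grouping schemes
#'
#' Returns a named partition of the 17 COCO keypoints under one of the
#' three supported grouping schemes used for grouped training:
#' the whole body as one group, an upper/lower split, or the four-way
#' head/arms/body/legs split.
#'
#' @param scheme One of `"whole_body"`, `"upper_lower"`,
#'   `"head_arm_body_leg"`.
#' @return A named list of character vectors partitioning the 17 parts;
#'   class `"keypoint_grouping"`.
#' @examples
#' group_keypoints("head_arm_body_leg")
#' @export
group_keypoints <- function(scheme = c("head_arm_body_leg", "whole_body",
                                       "upper_lower")) {
  if (!is.character(scheme) || length(scheme) != 1L ||
      !scheme[1] %in% c("head_arm_body_leg", "whole_body", "upper_lower")) {
    stop("unknown grouping scheme: ",
         paste(utils::head(scheme, 1), collapse = ""), call. = FALSE)
  }
  head_parts <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear")
  arm_parts <- c("left_shoulder", "right_shoulder", "left_elbow",
                 "right_elbow", "left_wrist", "right_wrist")
  body_parts <- c("left_hip", "right_hip")
  leg_parts <- c("left_knee", "right_knee", "left_ankle", "right_ankle")
  g <- switch(scheme,
    whole_body = list(whole_body = COCO_KEYPOINTS),
    upper_lower = list(upper = c(head_parts, arm_parts),
                       lower = c(body_parts, leg_parts)),
    head_arm_body_leg = list(head = head_parts, arms = arm_parts,
                             body = body_parts, legs = leg_parts)
  )
  structure(g, class = "keypoint_grouping", scheme = scheme)
}

#' @export
print.keypoint_grouping <- function(x, ...) {
  cat(sprintf("<keypoint_grouping '%s': %d group(s)>\n",
              attr(x, "scheme"), length(x)))
  for (nm in names(x)) cat(" ", nm, ":", paste(x[[nm]], collapse = " "), "\n")
  invisible(x)
}
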