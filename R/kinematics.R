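# Kinematic fall discriminants: aspect ratio A, centroid descent speed V,
# trunk-ground angle theta and its change rate Omega.

#' Bounding-box aspect ratio
#'
#' Height-to-width ratio `A = (ymax - ymin) / (xmax - xmin)` of a person's
#' bounding box.  An upright person has `A` well above 1; a horizontal
#' body drops below 1.
#'
#' @param box A [bbox()].
#' @return Strictly positive unitless ratio.
#' @examples
#' aspect_ratio(bbox(0, 0, 40, 80))  # 2
#' @export
aspect_ratio <- function(box) {
  w <- unname(box["xmax"] - box["xmin"])
  h <- unname(box["ymax"] - box["ymin"])
  if (!is.finite(w) || w <= 0) {
    stop("degenerate bbox: width must be > 0", call. = FALSE)
  }
  h / w
}

#' Centroid descent speed
#'
#' Rate of vertical motion of the body centroid over an interval `dt`,
#' in pixels/second.  Image coordinates have y increasing downward, so the
#' speed is defined as `(y_end - y_initial) / dt`: downward motion
#' (a drop) is positive, upward motion negative.
#'
#' @param y_initial Centroid y at the start of the interval (pixels).
#' @param y_end Centroid y at the end of the interval (pixels).
#' @param dt Interval length in seconds, > 0.
#' @return Signed speed in pixels/second (positive = descending).
#' @examples
#' centroid_descent_speed(100, 190, 0.25)  # 360 px/s downward
#' @export
centroid_descent_speed <- function(y_initial, y_end, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  (y_end - y_initial) / dt
}

#' Trunk-ground angle
#'
#' Angle in degrees between a trunk vector `Z` and the image x-axis
#' direction `x' = (1, 0)` (the ground direction), computed as
#' `acos(<x', Z> / |Z|)` and therefore lying in `[0, 180]`.
#'
#' @param z Numeric 2-vector (trunk vector in pixels), nonzero.
#' @return Angle in degrees in `[0, 180]`.
#' @examples
#' trunk_angle(c(0, 40))  # 90: perpendicular to the ground axis
#' @export
trunk_angle <- function(z) {
  stopifnot(length(z) == 2, all(is.finite(z)))
  n <- sqrt(sum(z^2))
  if (n == 0) stop("zero trunk vector has no angle", call. = FALSE)
  acos(pmin(1, pmax(-1, z[1] / n))) * 180 / pi
}

#' Angular change rate of the trunk
#'
#' Absolute change in the trunk-ground angle over an interval, divided by
#' the interval length: `|theta_curr - theta_prev| / dt` in degrees/second.
#'
#' @param theta_prev,theta_curr Angles in degrees.
#' @param dt Interval in seconds, > 0.
#' @return Nonnegative rate in degrees/second.
#' @examples
#' angular_rate(90, 0, 0.5)  # 180 deg/s
#' @export
angular_rate <- function(theta_prev, theta_curr, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  abs(theta_curr - theta_prev) / dt
}

#' Trunk vectors of a pose frame
#'
#' `Z1 = centroid - neck` and `Z2 = centroid - ground projection`, both in
#' pixels.  Derived landmarks are computed on demand if absent.
#'
#' @param frame A [pose_frame()].
#' @return List with numeric 2-vectors `Z1` and `Z2`.
#' @export
trunk_vectors <- function(frame) {
  if (is.null(frame$derived)) frame <- derive_points(frame)
  neck <- kp_row(frame, "neck", "derived")
  ctr <- kp_row(frame, "centroid", "derived")
  gp <- kp_row(frame, "ground_proj", "derived")
  if (is.null(neck) || is.null(ctr) || is.null(gp)) {
    stop("derived landmarks unavailable for trunk vectors", call. = FALSE)
  }
  list(Z1 = c(ctr$x - neck$x, ctr$y - neck$y),
       Z2 = c(ctr$x - gp$x, ctr$y - gp$y))
}

frame_angles <- function(frame) {
  zv <- trunk_vectors(frame)
  th1 <- if (sqrt(sum(zv$Z1^2)) > 0) trunk_angle(zv$Z1) else NA_real_
  th2 <- if (sqrt(sum(zv$Z2^2)) > 0) trunk_angle(zv$Z2) else NA_real_
  c(theta1 = th1, theta2 = th2)
}

# Fast per-frame measurement used by the judge and the series computation:
# centroid y and both trunk angles as plain numerics, NULL when the torso
# keypoints are underivable.  Relies on the canonical keypoint order
# enforced by pose_frame(); equivalent to derive_points() + frame_angles().
TORSO_IDX <- c(ls = 6L, rs = 7L, lh = 12L, rh = 13L)

frame_measurements <- function(frame) {
  kp <- frame$keypoints
  i <- TORSO_IDX
  if (!all(kp$visible[i]) || any(kp$confidence[i] <= 0)) return(NULL)
  nx <- (kp$x[i["ls"]] + kp$x[i["rs"]]) / 2
  ny <- (kp$y[i["ls"]] + kp$y[i["rs"]]) / 2
  cx <- mean(kp$x[i]); cy <- mean(kp$y[i])
  ang <- function(zx, zy) {
    n <- sqrt(zx^2 + zy^2)
    if (n == 0) return(NA_real_)
    acos(min(1, max(-1, zx / n))) * 180 / pi
  }
  list(cy = cy,
       th1 = ang(cx - nx, cy - ny),
       th2 = ang(0, cy - unname(frame$bbox["ymax"])),
       t = frame$timestamp)
}

#' Per-frame kinematic series of a track
#'
#' Computes, for every frame of a track, the aspect ratio `A`, and --
#' against the frame one sampling interval `dt` earlier -- the centroid
#' descent speed `V` and the trunk angular change rate `omega`
#' (the larger of the two trunk-vector rates).  Frames earlier than one
#' interval from the start carry `V = 0`, `omega = 0`.  Frames whose torso
#' keypoints cannot be derived are flagged as gaps (`gap = TRUE`) with
#' `NA` kinematics and are skipped as reference frames.
#'
#' @param track A [track_sequence()].
#' @param dt Sampling interval in seconds (default 0.25).
#' @return A `data.frame` with columns `frame_index`, `t`, `A`, `V`,
#'   `theta1`, `theta2`, `omega`, `gap`.
#' @export
kinematics_series <- function(track, dt = 0.25) {
  stopifnot(inherits(track, "track_sequence"))
  n <- length(track$frames)
  if (n == 0) stop("empty track", call. = FALSE)
  stride <- max(1L, as.integer(round(dt * track$fps)))
  rows <- vector("list", n)
  # per-frame state: centroid y + angles, NA when underivable
  cy <- rep(NA_real_, n); th1 <- rep(NA_real_, n); th2 <- rep(NA_real_, n)
  A <- rep(NA_real_, n); tt <- numeric(n); idx <- integer(n)
  gap <- logical(n)
  for (i in seq_len(n)) {
    f <- track$frames[[i]]
    idx[i] <- f$frame_index
    tt[i] <- f$timestamp
    A[i] <- tryCatch(aspect_ratio(f$bbox), error = function(e) NA_real_)
    meas <- frame_measurements(f)
    if (!is.null(meas)) {
      cy[i] <- meas$cy
      th1[i] <- meas$th1; th2[i] <- meas$th2
    }
    gap[i] <- is.null(meas) || is.na(A[i])
  }
  V <- numeric(n); omega <- numeric(n)
  for (i in seq_len(n)) {
    j <- i - stride
    if (j < 1 || gap[i] || gap[j]) next
    dtt <- tt[i] - tt[j]
    if (dtt <= 0) next
    V[i] <- centroid_descent_speed(cy[j], cy[i], dtt)
    r1 <- if (!is.na(th1[i]) && !is.na(th1[j])) abs(th1[i] - th1[j]) else NA
    r2 <- if (!is.na(th2[i]) && !is.na(th2[j])) abs(th2[i] - th2[j]) else NA
    dth <- suppressWarnings(max(r1, r2, na.rm = TRUE))
    omega[i] <- if (is.finite(dth)) dth / dtt else 0
  }
  V[gap] <- NA_real_; omega[gap] <- NA_real_
  data.frame(frame_index = idx, t = tt, A = A, V = V,
             theta1 = th1, theta2 = th2, omega = omega, gap = gap)
}

#' Write a kinematic series to CSV
#'
#' @param series Output of [kinematics_series()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}
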