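# Rule-based fall judgment: walking / lying / fall classification of a
# keypoint track, with a latched alert on fall.
#
# Every frame contributes an aspect-ratio reading; every sample_stride-th
# frame additionally evaluates the centroid descent speed V and the trunk
# angular change dTheta against thresholds.  A sample with
# A < lying_fall_A, V > v_threshold and dTheta > omega_threshold latches a
# fall.  Otherwise the last max_judgments samples resolve to walking (all
# inside the walking aspect-ratio band) or lying, re-evaluated as a
# sliding window so continuous video keeps being monitored.

#' Fall judgment configuration
#'
#' Thresholds and sampling parameters of the fall judgment rule engine.
#' Defaults are the calibrated operating point: centroid speed gate
#' 350 pixels/second, trunk angular change gate 75 degrees per sampled
#' interval, evaluation every 15 frames (0.25 s at 60 fps), walking
#' aspect-ratio band (1.5, 2.5) and horizontal-body cutoff A < 1.
#'
#' @param v_threshold Centroid descent speed gate, pixels/second.
#' @param omega_threshold Trunk angle change gate. In `omega_mode =
#'   "change"` (default) it is degrees per sampled interval; in
#'   `"rate"` it is degrees/second.
#' @param sample_stride Frames between sampled evaluations.
#' @param walking_band Open interval of aspect ratios treated as upright
#'   walking.
#' @param lying_fall_A Aspect-ratio cutoff below which the body is
#'   considered horizontal.
#' @param max_judgments Number of sampled evaluations per judgment window.
#' @param dt Seconds per sampled interval; `NULL` (default) means
#'   `sample_stride / fps`, resolved when a track is judged.
#' @param omega_mode `"change"` compares the angle change over one sampled
#'   interval against `omega_threshold` (degrees); `"rate"` compares the
#'   change divided by the interval (degrees/second).
#' @param signed_v If `FALSE`, use `abs(V)` in the fall gate instead of the
#'   signed downward speed.
#' @return An object of class `"fall_config"`.
#' @examples
#' fall_config()
#' @export
fall_config <- function(v_threshold = 350, omega_threshold = 75,
                        sample_stride = 15L, walking_band = c(1.5, 2.5),
                        lying_fall_A = 1.0, max_judgments = 3L, dt = NULL,
                        omega_mode = c("change", "rate"), signed_v = TRUE) {
  omega_mode <- match.arg(omega_mode)
  stopifnot(v_threshold > 0, omega_threshold > 0, sample_stride >= 1,
            length(walking_band) == 2, walking_band[1] < walking_band[2],
            lying_fall_A > 0, max_judgments >= 1)
  if (!is.null(dt)) stopifnot(dt > 0)
  structure(list(v_threshold = v_threshold,
                 omega_threshold = omega_threshold,
                 sample_stride = as.integer(sample_stride),
                 walking_band = as.numeric(walking_band),
                 lying_fall_A = lying_fall_A,
                 max_judgments = as.integer(max_judgments),
                 dt = dt, omega_mode = omega_mode, signed_v = signed_v),
            class = "fall_config")
}

#' @export
print.fall_config <- function(x, ...) {
  cat(sprintf(paste0("<fall_config: V>%g px/s, dTheta>%g deg (%s), ",
                     "stride %d, walking A in (%g,%g), lying/fall A<%g, ",
                     "window %d>\n"),
              x$v_threshold, x$omega_threshold, x$omega_mode,
              x$sample_stride, x$walking_band[1], x$walking_band[2],
              x$lying_fall_A, x$max_judgments))
  invisible(x)
}

#' Classify a single sampled observation
#'
#' The per-sample decision rule: a *fall* requires the conjunction
#' `A < lying_fall_A` AND `V > v_threshold` AND
#' `dTheta > omega_threshold`; an aspect ratio inside the open walking
#' band yields a *walking* candidate; anything else is a *lying*
#' (ambiguous) candidate.
#'
#' @param A Aspect ratio (unitless).
#' @param V Centroid descent speed, pixels/second (positive = down).
#' @param dTheta Trunk angle change over the sampled interval, degrees
#'   (or degrees/second under `omega_mode = "rate"`).
#' @param config A [fall_config()].
#' @return One of `"fall"`, `"walking"`, `"lying"`.
#' @examples
#' evaluate_sample(0.8, 400, 85, fall_config())  # "fall"
#' @export
evaluate_sample <- function(A, V, dTheta, config = fall_config()) {
  stopifnot(is.finite(A), is.finite(V), is.finite(dTheta))
  v_eff <- if (config$signed_v) V else abs(V)
  if (A < config$lying_fall_A && v_eff > config$v_threshold &&
      dTheta > config$omega_threshold) {
    return("fall")
  }
  if (A > config$walking_band[1] && A < config$walking_band[2]) {
    return("walking")
  }
  "lying"
}

new_judgment_state <- function() {
  list(status = "unknown", judgment_count = 0L,
       previous_A_values = numeric(0), fall_frame = NULL,
       n_frames = 0L, n_gaps = 0L,
       samples = data.frame(frame_index = integer(0), t = numeric(0),
                            A = numeric(0), V = numeric(0),
                            dTheta = numeric(0), label = character(0)))
}

#' Online (streaming) fall judge
#'
#' Creates an incremental judge that consumes pose frames one at a time
#' and maintains the same judgment state as the batch [judge_sequence()].
#' Frames must arrive in increasing frame-index order.
#'
#' @param config A [fall_config()].
#' @param fps Frame rate of the incoming stream (frames/second).
#' @param inquiry_hook Optional callback `function(state)` invoked exactly
#'   once, when (and only when) a fall latches -- the pluggable stand-in
#'   for a voice-inquiry / alerting subsystem.
#' @return An object of class `"stream_judge"`: a list of closures
#'   `push(frame)`, `finalize()`, and `state()`.
#' @examples
#' sj <- stream_judge(fall_config(), fps = 60)
#' @export
stream_judge <- function(config = fall_config(), fps, inquiry_hook = NULL) {
  stopifnot(inherits(config, "fall_config"), fps > 0)
  env <- new.env(parent = emptyenv())
  env$st <- new_judgment_state()
  env$seen <- 0L            # frames consumed
  env$last_index <- -1L
  env$ref <- NULL           # reference (cy, th1, th2, t) for V / dTheta
  env$window <- character(0)  # labels of the last samples (sliding)
  env$latched <- FALSE

  eval_frame <- function(frame) {
    if (env$latched) return(env$st$status)
    if (!inherits(frame, "pose_frame")) stop("push() expects a pose_frame",
                                             call. = FALSE)
    if (frame$frame_index <= env$last_index) {
      stop("out-of-order frame: index ", frame$frame_index,
           " after ", env$last_index, call. = FALSE)
    }
    env$last_index <- frame$frame_index
    env$seen <- env$seen + 1L
    env$st$n_frames <- env$st$n_frames + 1L
    A <- tryCatch(aspect_ratio(frame$bbox), error = function(e) NA_real_)
    meas <- frame_measurements(frame)
    if (is.null(meas) || is.na(A)) {
      env$st$n_gaps <- env$st$n_gaps + 1L
      return(env$st$status)
    }
    sampled <- env$seen %% config$sample_stride == 0L
    if (is.null(env$ref)) {
      env$ref <- meas   # first derivable frame anchors the first interval
      if (!sampled) return(env$st$status)
    }
    if (!sampled) return(env$st$status)
    dt_nom <- if (is.null(config$dt)) config$sample_stride / fps else config$dt
    dtt <- meas$t - env$ref$t
    if (dtt <= 0) dtt <- dt_nom
    V <- centroid_descent_speed(env$ref$cy, meas$cy, dtt)
    d1 <- abs(meas$th1 - env$ref$th1)
    d2 <- abs(meas$th2 - env$ref$th2)
    dTheta <- max(d1, d2, na.rm = TRUE)
    if (!is.finite(dTheta)) dTheta <- 0
    if (config$omega_mode == "rate") dTheta <- dTheta / dtt
    env$ref <- meas
    label <- evaluate_sample(A, V, dTheta, config)
    env$st$judgment_count <- env$st$judgment_count + 1L
    env$st$previous_A_values <- c(env$st$previous_A_values, A)
    env$st$samples <- rbind(env$st$samples, data.frame(
      frame_index = frame$frame_index, t = frame$timestamp, A = A, V = V,
      dTheta = dTheta, label = label))
    if (label == "fall") {
      env$latched <- TRUE
      env$st$status <- "fall"
      env$st$fall_frame <- frame$frame_index
      if (is.function(inquiry_hook)) inquiry_hook(env$st)
      return(env$st$status)
    }
    env$window <- utils::tail(c(env$window, label), config$max_judgments)
    if (length(env$window) >= config$max_judgments) {
      env$st$status <- if (all(env$window == "walking")) "walking" else "lying"
    }
    env$st$status
  }

  finalize <- function() {
    st <- env$st
    if (!env$latched && st$status == "unknown" && length(env$window) > 0) {
      st$status <- if (all(env$window == "walking")) "walking" else "lying"
    }
    structure(st, class = "fall_judgment")
  }

  structure(list(push = eval_frame, finalize = finalize,
                 state = function() structure(env$st,
                                              class = "fall_judgment")),
            class = "stream_judge")
}

#' Judge a complete track
#'
#' Batch fall judgment: computes the aspect ratio on every frame,
#' evaluates centroid speed and trunk angle change at every
#' `sample_stride`-th frame, and classifies the track as `"walking"`,
#' `"lying"`, `"fall"` (latched on the first sample that passes the fall
#' conjunction) or `"unknown"`.  Internally replays the track through the
#' streaming judge, so online and batch results agree by construction.
#'
#' @param track A [track_sequence()].
#' @param config A [fall_config()].
#' @param inquiry_hook Optional callback invoked only when a fall latches.
#' @return An object of class `"fall_judgment"`: status, fall frame (if
#'   any), per-sample kinematics, gap count.
#' @examples
#' \dontrun{judge_sequence(simulate_track(behavior_params("falling"))$track)}
#' @export
judge_sequence <- function(track, config = fall_config(),
                           inquiry_hook = NULL) {
  stopifnot(inherits(track, "track_sequence"))
  if (length(track$frames) == 0) stop("empty track", call. = FALSE)
  sj <- stream_judge(config, fps = track$fps, inquiry_hook = inquiry_hook)
  for (f in track$frames) sj$push(f)
  sj$finalize()
}

#' @export
print.fall_judgment <- function(x, ...) {
  cat(sprintf("<fall_judgment: status=%s, %d frame(s), %d sample(s), %d gap(s)%s>\n",
              x$status, x$n_frames, x$judgment_count, x$n_gaps,
              if (!is.null(x$fall_frame))
                sprintf(", fall at frame %d", x$fall_frame) else ""))
  invisible(x)
}
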