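# Readers and writers for the formats the toolkit touches: COCO-keypoints
# JSON, JSONL track streams, YOLO-style normalized bbox text, YAML
# configuration, and PNG rasters.

TRACK_SCHEMA <- "fallwatch-track"
TRACK_SCHEMA_VERSION <- 1L

kp_df_to_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) list(
    name = df$name[i], x = df$x[i], y = df$y[i],
    confidence = df$confidence[i], visible = df$visible[i]))
}

kp_list_to_df <- function(lst) {
  do.call(rbind, lapply(lst, function(k)
    data.frame(name = k$name, x = as.numeric(k$x), y = as.numeric(k$y),
               confidence = as.numeric(k$confidence),
               visible = as.logical(k$visible), stringsAsFactors = FALSE)))
}

#' Save a track as a JSONL stream
#'
#' One JSON object per line: a schema/version/fps header followed by one
#' frame per line.  The round trip through [load_track_stream()] is
#' lossless, including derived landmarks.
#'
#' @param track A [track_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_track_stream <- function(track, path) {
  stopifnot(inherits(track, "track_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- list(schema = TRACK_SCHEMA, version = TRACK_SCHEMA_VERSION,
              fps = track$fps)
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA), con)
  for (f in track$frames) {
    rec <- list(frame_index = f$frame_index, timestamp = f$timestamp,
                track_id = f$track_id,
                bbox = as.numeric(f$bbox),
                keypoints = kp_df_to_list(f$keypoints))
    if (!is.null(f$derived)) rec$derived <- kp_df_to_list(f$derived)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Load a JSONL track stream
#'
#' @param path File written by [save_track_stream()].
#' @return A [track_sequence()].
#' @export
load_track_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty track file: ", path, call. = FALSE)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
             error = function(e) {
               stop("malformed track stream at line ", i,
                    " (last good line: ", i - 1L, ")", call. = FALSE)
             })
  }
  hdr <- parse_line(1)
  if (!identical(hdr$schema, TRACK_SCHEMA)) {
    stop("not a ", TRACK_SCHEMA, " stream: ", path, call. = FALSE)
  }
  if (!identical(as.integer(hdr$version), TRACK_SCHEMA_VERSION)) {
    stop("track stream version mismatch: file has ", hdr$version,
         ", reader supports ", TRACK_SCHEMA_VERSION, call. = FALSE)
  }
  if (length(lines) == 1) stop("empty track: no frames in ", path,
                               call. = FALSE)
  frames <- lapply(seq.int(2, length(lines)), function(i) {
    rec <- parse_line(i)
    b <- as.numeric(unlist(rec$bbox))
    pose_frame(rec$frame_index, rec$timestamp,
               bbox(b[1], b[2], b[3], b[4]),
               kp_list_to_df(rec$keypoints),
               derived = if (!is.null(rec$derived))
                 kp_list_to_df(rec$derived) else NULL,
               track_id = rec$track_id)
  })
  track_sequence(frames, fps = as.numeric(hdr$fps))
}

#' Read COCO-keypoints annotations as pose frames
#'
#' Parses a COCO-style keypoints JSON file (annotation records carrying a
#' flat `17 x 3` keypoints list of `x, y, v`).  The canonical part order
#' is enforced; the v-flag maps to visibility/confidence
#' (`2` visible/1.0, `1` labelled-occluded/0.5, `0` unlabelled/0.0 --
#' unlabelled points are invisible and excluded from derived-landmark
#' computation).  The bounding box comes from the annotation `bbox`
#' (`x, y, w, h`) or, if absent, the hull of labelled keypoints.
#'
#' @param path COCO JSON file.
#' @param fps Nominal frame rate used to derive timestamps from the frame
#'   order (default 60).
#' @return List of [pose_frame()] objects, ordered by image id.
#' @export
read_coco_keypoints <- function(path, fps = 60) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed COCO file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  anns <- doc$annotations
  if (is.null(anns)) stop("malformed COCO file: no 'annotations' in ",
                          path, call. = FALSE)
  ids <- vapply(anns, function(a)
    as.numeric(a$image_id %||% a$id %||% 0), numeric(1))
  anns <- anns[order(ids)]
  lapply(seq_along(anns), function(i) {
    a <- anns[[i]]
    kp <- as.numeric(unlist(a$keypoints))
    if (length(kp) != 51) {
      stop("annotation ", i, " in ", path, ": expected 17x3 = 51 keypoint ",
           "values, got ", length(kp), call. = FALSE)
    }
    m <- matrix(kp, ncol = 3, byrow = TRUE)
    v <- m[, 3]
    kps <- data.frame(name = COCO_KEYPOINTS, x = m[, 1], y = m[, 2],
                      confidence = c(0, 0.5, 1)[v + 1],
                      visible = v == 2, stringsAsFactors = FALSE)
    box <- if (!is.null(a$bbox)) {
      b <- as.numeric(unlist(a$bbox))
      bbox(b[1], b[2], b[1] + b[3], b[2] + b[4])
    } else {
      lab <- m[v > 0, , drop = FALSE]
      if (nrow(lab) < 2) stop("annotation ", i, ": no bbox and too few ",
                              "labelled keypoints", call. = FALSE)
      bbox(min(lab[, 1]) - 3, min(lab[, 2]) - 3,
           max(lab[, 1]) + 3, max(lab[, 2]) + 3)
    }
    pose_frame(i - 1L, (i - 1L) / fps, box, kps,
               track_id = as.integer(a$track_id %||% 1L))
  })
}

#' Write pose frames as COCO-keypoints JSON
#'
#' @param frames List of [pose_frame()] objects.
#' @param path Output path.
#' @param image_size `c(width, height)` recorded in the image records.
#' @return `path`, invisibly.
#' @export
write_coco_keypoints <- function(frames, path, image_size = c(640, 480)) {
  v_of <- function(k) ifelse(k$visible, 2L, ifelse(k$confidence > 0, 1L, 0L))
  anns <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    kp <- f$keypoints
    flat <- as.vector(t(cbind(kp$x, kp$y, v_of(kp))))
    b <- f$bbox
    list(id = i, image_id = f$frame_index,
         category_id = 1L, track_id = f$track_id,
         keypoints = flat, num_keypoints = sum(kp$visible),
         bbox = c(b["xmin"], b["ymin"], b["xmax"] - b["xmin"],
                  b["ymax"] - b["ymin"]))
  })
  doc <- list(
    images = lapply(seq_along(frames), function(i) list(
      id = frames[[i]]$frame_index, width = image_size[1],
      height = image_size[2],
      file_name = sprintf("frame_%06d.png", frames[[i]]$frame_index))),
    annotations = anns,
    categories = list(list(id = 1L, name = "person",
                           keypoints = COCO_KEYPOINTS)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read YOLO-style normalized bounding boxes
#'
#' Text lines of `class cx cy w h` with coordinates normalized to
#' `[0, 1]`; converted to pixel-space [bbox()] objects.
#'
#' @param path Text file.
#' @param image_w,image_h Image size in pixels.
#' @return A `data.frame` with `class` and `xmin/ymin/xmax/ymax` columns.
#' @export
read_yolo_bbox <- function(path, image_w, image_h) {
  m <- utils::read.table(path, col.names = c("class", "cx", "cy", "w", "h"))
  data.frame(class = m$class,
             xmin = (m$cx - m$w / 2) * image_w,
             ymin = (m$cy - m$h / 2) * image_h,
             xmax = (m$cx + m$w / 2) * image_w,
             ymax = (m$cy + m$h / 2) * image_h)
}

#' Toolkit configuration
#'
#' Bundles the defaults of the rule engine, the eraser, the simulator and
#' the model assemblies; round-trips losslessly through YAML via
#' [write_toolkit_config()] / [read_toolkit_config()].
#'
#' @param fall A [fall_config()].
#' @param erase An [erase_spec()].
#' @param sim A [behavior_params()].
#' @param model List of model settings (HRNet base width, backbone stage
#'   widths, SPPF scales, SA groups).
#' @param logging Logging level string.
#' @return An object of class `"toolkit_config"`.
#' @export
toolkit_config <- function(fall = fall_config(), erase = erase_spec(),
                           sim = behavior_params("walking"),
                           model = list(hrnet_width = 32L,
                                        detector_widths =
                                          c(24L, 116L, 232L, 464L),
                                        sppf_scales = c(5L, 9L, 13L),
                                        sa_groups = 2L),
                           logging = "info") {
  structure(list(fall = fall, erase = erase, sim = sim, model = model,
                 logging = logging), class = "toolkit_config")
}

#' @rdname toolkit_config
#' @param config A `toolkit_config`.
#' @param path YAML file path.
#' @export
write_toolkit_config <- function(config, path) {
  stopifnot(inherits(config, "toolkit_config"))
  raw <- list(fall = unclass(config$fall), erase = unclass(config$erase),
              sim = unclass(config$sim), model = config$model,
              logging = config$logging)
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' @rdname toolkit_config
#' @export
read_toolkit_config <- function(path) {
  raw <- yaml::read_yaml(path)
  toolkit_config(
    fall = do.call(fall_config, raw$fall[!vapply(raw$fall, is.null,
                                                 logical(1))]),
    erase = do.call(erase_spec, raw$erase),
    sim = do.call(behavior_params, raw$sim),
    model = raw$model,
    logging = raw$logging %||% "info")
}

#' Read / write PNG rasters
#'
#' Images are numeric arrays `[H, W, 3]` with values in `[0, 255]`.
#' Grayscale and RGBA files are promoted/truncated to RGB on read.
#'
#' @param path PNG file path.
#' @return `read_image_png`: the image array.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2) img <- array(rep(img[, , 1], 3),
                                     c(dim(img)[1:2], 3))
  img * 255
}

#' @rdname read_image_png
#' @param image Array `[H, W, 3]`, values in `[0, 255]`.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp(image / 255, 0, 1), path)
  invisible(path)
}
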