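# Random-erasing occlusion augmentation in three modes:
#   ire  -- one mean-filled rectangle anywhere on the image
#   kre  -- one rectangle inside the person bounding box (keypoint region)
#   ikre -- both
# Erased pixels are set exactly to the fill colour (default: the ImageNet
# channel means in 8-bit RGB); all other pixels are untouched.

IMAGENET_MEAN_RGB <- c(124, 116, 104)

#' Random-erasing specification
#'
#' @param mode `"ire"`, `"kre"` or `"ikre"`.
#' @param ratio Erased-area fraction of the target region, in `(0, 1]`
#'   (default 0.5, the empirically best-performing occlusion ratio).
#' @param fill RGB fill triple in 8-bit space (default the ImageNet
#'   channel means `c(124, 116, 104)`).
#' @param seed Integer seed; identical spec + seed give identical
#'   rectangles.
#' @param aspect_range Range of rectangle aspect ratios (width/height)
#'   sampled log-uniformly.
#' @param count Rectangles per mode per image (default 1).
#' @param keypoint_bias In `kre`/`ikre`, centre the box rectangle on a
#'   randomly chosen visible keypoint when keypoints are supplied.
#' @return An object of class `"erase_spec"`.
#' @examples
#' erase_spec("ire", ratio = 0.3, seed = 7)
#' @export
erase_spec <- function(mode = c("ire", "kre", "ikre"), ratio = 0.5,
                       fill = IMAGENET_MEAN_RGB, seed = 1L,
                       aspect_range = c(1 / 3, 3), count = 1L,
                       keypoint_bias = TRUE) {
  mode <- match.arg(mode)
  stopifnot(ratio > 0, ratio <= 1, length(fill) == 3, all(fill >= 0),
            length(aspect_range) == 2, all(aspect_range > 0),
            aspect_range[1] <= aspect_range[2], count >= 1)
  structure(list(mode = mode, ratio = ratio, fill = as.numeric(fill),
                 seed = as.integer(seed),
                 aspect_range = as.numeric(aspect_range),
                 count = as.integer(count),
                 keypoint_bias = isTRUE(keypoint_bias)),
            class = "erase_spec")
}

#' @export
print.erase_spec <- function(x, ...) {
  cat(sprintf("<erase_spec: %s, ratio %.2f, fill (%g,%g,%g), seed %d>\n",
              x$mode, x$ratio, x$fill[1], x$fill[2], x$fill[3], x$seed))
  invisible(x)
}

#' Sample an erasing rectangle
#'
#' Draws a rectangle of area `ratio * region_w * region_h` (to within
#' whole-pixel rounding) with a log-uniform aspect ratio, placed
#' uniformly among feasible positions inside the region.  Aspect ratios
#' that cannot fit are clamped to the feasible range.  Uses the current
#' RNG state; seed externally for determinism.
#'
#' @param region_w,region_h Region size in pixels (> 0).
#' @param ratio Area fraction in `(0, 1]`.
#' @param aspect_range Width/height aspect-ratio range.
#' @return Integer vector `c(x, y, w, h)`, 0-based offsets within the
#'   region.
#' @export
sample_erase_rect <- function(region_w, region_h, ratio,
                              aspect_range = c(1 / 3, 3)) {
  stopifnot(region_w >= 1, region_h >= 1, ratio > 0, ratio <= 1)
  W <- as.integer(floor(region_w)); H <- as.integer(floor(region_h))
  area <- ratio * W * H
  if (ratio >= 1) {
    return(c(x = 0L, y = 0L, w = W, h = H))
  }
  # feasible aspect interval given w <= W, h <= H
  lo <- max(aspect_range[1], area / H^2)
  hi <- min(aspect_range[2], W^2 / area)
  if (lo > hi) {          # clamp to the nearest feasible aspect
    a <- if (area / H^2 > aspect_range[2]) area / H^2 else W^2 / area
    a <- max(min(a, W^2 / area), area / H^2)
  } else {
    a <- exp(stats::runif(1, log(lo), log(hi)))
  }
  h <- as.integer(clamp(round(sqrt(area / a)), 1, H))
  w <- as.integer(clamp(round(area / h), 1, W))
  x <- if (W - w > 0) sample.int(W - w + 1L, 1L) - 1L else 0L
  y <- if (H - h > 0) sample.int(H - h + 1L, 1L) - 1L else 0L
  c(x = x, y = y, w = w, h = h)
}

fill_rect <- function(image, rect, fill, x0 = 0, y0 = 0) {
  rows <- y0 + rect["y"] + seq_len(rect["h"])
  cols <- x0 + rect["x"] + seq_len(rect["w"])
  for (ch in 1:3) image[rows, cols, ch] <- fill[ch]
  image
}

#' Apply random erasing to an image
#'
#' Erases rectangle(s) according to the spec's mode: `ire` over the whole
#' image, `kre` inside the person bounding box (optionally centred on a
#' visible keypoint), `ikre` both.  Erased pixels equal the fill colour
#' exactly; every other pixel is unchanged.  Deterministic given
#' `spec$seed`.
#'
#' @param image Numeric array `[H, W, 3]`, values in `[0, 255]`.
#' @param spec An [erase_spec()].
#' @param box Optional [bbox()]; required for `kre` and `ikre`.
#' @param keypoints Optional keypoint `data.frame` (columns `x`, `y`,
#'   `visible`) used for keypoint-biased placement.
#' @return An object of class `"erase_result"`: `$image` and `$rects`
#'   (a `data.frame` with columns `x`, `y`, `w`, `h`, `region`,
#'   coordinates in whole-image pixels, 0-based).
#' @export
apply_random_erasing <- function(image, spec, box = NULL,
                                 keypoints = NULL) {
  stopifnot(inherits(spec, "erase_spec"), is.array(image),
            length(dim(image)) == 3, dim(image)[3] == 3)
  H <- dim(image)[1]; W <- dim(image)[2]
  needs_box <- spec$mode %in% c("kre", "ikre")
  if (needs_box && is.null(box)) {
    stop("mode '", spec$mode, "' requires a bounding box", call. = FALSE)
  }
  rects <- list()
  with_seed(spec$seed, {
    if (spec$mode %in% c("ire", "ikre")) {
      for (k in seq_len(spec$count)) {
        r <- sample_erase_rect(W, H, spec$ratio, spec$aspect_range)
        image <- fill_rect(image, r, spec$fill)
        rects[[length(rects) + 1]] <- c(r, region = "image")
      }
    }
    if (needs_box) {
      bx0 <- max(0L, as.integer(floor(box["xmin"])))
      by0 <- max(0L, as.integer(floor(box["ymin"])))
      bx1 <- min(W, as.integer(ceiling(box["xmax"])))
      by1 <- min(H, as.integer(ceiling(box["ymax"])))
      bw <- bx1 - bx0; bh <- by1 - by0
      if (bw < 1 || bh < 1) {
        stop("bounding box lies outside the image", call. = FALSE)
      }
      for (k in seq_len(spec$count)) {
        r <- sample_erase_rect(bw, bh, spec$ratio, spec$aspect_range)
        if (spec$keypoint_bias && !is.null(keypoints)) {
          vis <- keypoints[keypoints$visible, , drop = FALSE]
          if (nrow(vis) > 0) {
            pick <- vis[sample.int(nrow(vis), 1L), ]
            r["x"] <- as.integer(clamp(round(pick$x - bx0 - r["w"] / 2),
                                       0, bw - r["w"]))
            r["y"] <- as.integer(clamp(round(pick$y - by0 - r["h"] / 2),
                                       0, bh - r["h"]))
          }
        }
        image <- fill_rect(image, r, spec$fill, x0 = bx0, y0 = by0)
        abs_r <- r
        abs_r["x"] <- r["x"] + bx0
        abs_r["y"] <- r["y"] + by0
        rects[[length(rects) + 1]] <- c(abs_r, region = "bbox")
      }
    }
  })
  rect_df <- do.call(rbind, lapply(rects, function(r)
    data.frame(x = as.integer(r["x"]), y = as.integer(r["y"]),
               w = as.integer(r["w"]), h = as.integer(r["h"]),
               region = unname(r["region"]))))
  structure(list(image = image, rects = rect_df), class = "erase_result")
}

#' @export
print.erase_result <- function(x, ...) {
  cat(sprintf("<erase_result: %d rect(s)>\n", nrow(x$rects)))
  print(x$rects)
  invisible(x)
}
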