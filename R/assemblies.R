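# Untrained network assemblies: the high-resolution keypoint network with
# bottleneck attention (BAM) on the non-top branches, and the lightweight
# shuffle-backbone detector with SPPF and shuffle attention.  Both are
# forward-only, randomly initialized, and exist to verify the printed
# shape/width contracts end to end.

# Residual basic block: two 3x3 convs with BN, identity shortcut.
hr_basic_block <- function(channels) {
  a <- cbr(channels, channels, 3, act = "relu")
  cv <- make_conv(channels, channels, 3)
  bn <- make_bn(channels)
  list(fn = function(x) relu_arr(x + apply_bn(bn, apply_conv(cv, a$fn(x)))),
       n_params = a$n_params + cv$n_params + bn$n_params)
}

# Residual bottleneck: 1x1 reduce, 3x3, 1x1 expand, projected shortcut.
hr_bottleneck <- function(in_c, mid_c, out_c) {
  a <- cbr(in_c, mid_c, 1)
  b <- cbr(mid_c, mid_c, 3)
  cv <- make_conv(mid_c, out_c, 1)
  bn <- make_bn(out_c)
  proj <- if (in_c != out_c) cbr(in_c, out_c, 1, act = "none") else NULL
  n <- a$n_params + b$n_params + cv$n_params + bn$n_params +
    if (is.null(proj)) 0 else proj$n_params
  list(fn = function(x) {
    sc <- if (is.null(proj)) x else proj$fn(x)
    relu_arr(sc + apply_bn(bn, apply_conv(cv, b$fn(a$fn(x)))))
  }, n_params = n)
}

seq_blocks <- function(blocks) {
  list(fn = function(x) {
    for (b in blocks) x <- b$fn(x)
    x
  }, n_params = sum(vapply(blocks, `[[`, numeric(1), "n_params")))
}

#' Assemble the attention-augmented high-resolution keypoint network
#'
#' Builds the untrained keypoint network: a stride-4 two-convolution stem,
#' a bottleneck stage, then three transition/stage rounds growing one
#' branch each (branch `i` at `width * 2^(i-1)` channels and 1/2^(i-1) of
#' the stem resolution), with four basic blocks per branch and multi-scale
#' fusion per stage.  A BAM block refines every branch except the
#' highest-resolution one after each fusion.  A final upsample fusion and
#' a 1x1 head emit one heatmap per keypoint at stem resolution.
#'
#' @param width Channel count of the highest-resolution branch
#'   (default 32).
#' @param input_size `c(height, width)` of the input image; both must be
#'   divisible by 32 (default `c(256, 192)`).
#' @param n_keypoints Number of output heatmaps (default 17).
#' @param seed Seed for the random weight initialization.
#' @return An object of class `"bam_hrnet"`: `$forward(x)` takes a
#'   `[3, H, W]` array and returns `list(branches = <4 maps>, heatmaps)`;
#'   also `$n_params`, `$bam_count`, `$branch_specs`.
#' @examples
#' \dontrun{net <- assemble_bam_hrnet(); out <- net$forward(array(0, c(3, 256, 192)))}
#' @export
assemble_bam_hrnet <- function(width = 32, input_size = c(256, 192),
                               n_keypoints = 17, seed = 1L) {
  if (any(input_size %% 32 != 0)) {
    stop("input size must be divisible by 32", call. = FALSE)
  }
  with_seed(seed, {
    n_branches <- 4L
    widths <- width * 2^(seq_len(n_branches) - 1)
    stem1 <- cbr(3, 64, 3, stride = 2)
    stem2 <- cbr(64, 64, 3, stride = 2)
    layer1 <- seq_blocks(c(list(hr_bottleneck(64, 64, 256)),
                           lapply(1:3, function(i)
                             hr_bottleneck(256, 64, 256))))
    # transition k grows branch k+1; branch 1..k pass through (branch
    # widths fixed from the start, so only new-branch convs are needed
    # except the first transition which maps 256 -> width)
    trans1_a <- cbr(256, widths[1], 3)
    trans1_b <- cbr(256, widths[2], 3, stride = 2)
    trans2 <- cbr(widths[2], widths[3], 3, stride = 2)
    trans3 <- cbr(widths[3], widths[4], 3, stride = 2)
    stages <- vector("list", 3)
    bam_count <- 0L
    for (s in 1:3) {
      nb <- s + 1L
      branch_blocks <- lapply(seq_len(nb), function(b)
        seq_blocks(lapply(1:4, function(k) hr_basic_block(widths[b]))))
      fuse <- multiscale_fusion(fusion_config(nb, nb, width))
      bams <- lapply(seq_len(nb), function(b) {
        if (b == 1) return(NULL)   # highest-resolution path unaltered
        # dilation clamped so the dilated 3x3 footprint fits the branch
        sp <- min(input_size / 4 / 2^(b - 1))
        bam_module(widths[b], r = 16,
                   dilation = max(1, min(4, (sp - 1) %/% 2)))
      })
      bam_count <- bam_count + (nb - 1L)
      stages[[s]] <- list(blocks = branch_blocks, fuse = fuse, bams = bams)
    }
    final_up <- lapply(2:4, function(b)
      cbr(widths[b], widths[1], 1))
    head_cv <- make_conv(widths[1], n_keypoints, 1)
    n_params <- stem1$n_params + stem2$n_params + layer1$n_params +
      trans1_a$n_params + trans1_b$n_params + trans2$n_params +
      trans3$n_params + length(head_cv$w) +
      sum(vapply(final_up, `[[`, numeric(1), "n_params")) +
      sum(vapply(stages, function(st) {
        sum(vapply(st$blocks, `[[`, numeric(1), "n_params")) +
          st$fuse$n_params +
          sum(vapply(st$bams, function(b)
            if (is.null(b)) 0 else b$n_params, numeric(1)))
      }, numeric(1)))

    forward <- function(x) {
      x <- as_fmap(x)
      if (any(dim(x)[2:3] %% 32 != 0)) {
        stop("input size must be divisible by 32", call. = FALSE)
      }
      y <- stem2$fn(stem1$fn(x))
      y <- layer1$fn(y)
      branches <- list(trans1_a$fn(y), trans1_b$fn(y))
      for (s in 1:3) {
        if (s == 2) branches[[3]] <- trans2$fn(branches[[2]])
        if (s == 3) branches[[4]] <- trans3$fn(branches[[3]])
        st <- stages[[s]]
        nb <- length(st$blocks)
        for (b in seq_len(nb)) {
          branches[[b]] <- st$blocks[[b]]$fn(branches[[b]])
        }
        branches[seq_len(nb)] <- st$fuse$forward(branches[seq_len(nb)])
        for (b in seq_len(nb)) {
          if (!is.null(st$bams[[b]])) {
            branches[[b]] <- st$bams[[b]]$forward(branches[[b]])
          }
        }
      }
      fusedtop <- branches[[1]]
      for (b in 2:4) {
        fusedtop <- fusedtop + upsample_nearest(
          final_up[[b - 1]]$fn(branches[[b]]), 2^(b - 1))
      }
      fusedtop <- relu_arr(fusedtop)
      heat <- conv2d_arr(fusedtop, head_cv$w)
      list(branches = branches, heatmaps = heat)
    }
    structure(list(forward = forward, n_params = n_params,
                   bam_count = bam_count, width = width,
                   input_size = input_size, n_keypoints = n_keypoints,
                   branch_specs = lapply(seq_len(4), function(b)
                     c(channels = widths[b],
                       height = input_size[1] / 4 / 2^(b - 1),
                       width = input_size[2] / 4 / 2^(b - 1)))),
              class = "bam_hrnet")
  })
}

#' @export
print.bam_hrnet <- function(x, ...) {
  cat(sprintf("<bam_hrnet: width %d, input %dx%d, %d BAM blocks, %s params>\n",
              x$width, x$input_size[1], x$input_size[2], x$bam_count,
              format(x$n_params, big.mark = ",")))
  for (b in seq_along(x$branch_specs)) {
    sp <- x$branch_specs[[b]]
    cat(sprintf("  branch %d: (%d, %d, %d)\n", b, sp["channels"],
                sp["height"], sp["width"]))
  }
  invisible(x)
}

# Cross-stage block: 1x1 expand, chained half-width 3x3 blocks, concat,
# 1x1 fuse.
c2f_block <- function(in_c, out_c, n = 1) {
  stopifnot(out_c %% 2 == 0)
  h <- out_c / 2
  cv1 <- cbr(in_c, out_c, 1)
  inner <- lapply(seq_len(n), function(i) cbr(h, h, 3))
  cv2 <- cbr((2 + n) * h, out_c, 1)
  list(fn = function(x) {
    y <- cv1$fn(x)
    parts <- list(y[seq_len(h), , , drop = FALSE],
                  y[h + seq_len(h), , , drop = FALSE])
    for (blk in inner) {
      parts[[length(parts) + 1]] <- blk$fn(parts[[length(parts)]])
    }
    cv2$fn(concat_channels(parts))
  }, n_params = cv1$n_params + cv2$n_params +
    sum(vapply(inner, `[[`, numeric(1), "n_params")))
}

#' Assemble the lightweight shuffle-backbone detector
#'
#' Builds the untrained person detector: a shuffle-unit backbone with
#' stage widths 24/116/232/464 (stride-2 stem conv + max pool, then three
#' stages of one down-sampling unit plus 3/7/3 basic units), serial
#' spatial pyramid pooling (scales 5/9/13) on the deepest 20x20 map, a
#' three-scale feature-pyramid neck of cross-stage blocks with a shuffle
#' attention block per neck stage, and per-scale heads emitting 4 box
#' coordinates plus class scores.
#'
#' @param input_size Square input size in pixels (default 640).
#' @param widths Backbone stage widths.
#' @param n_classes Number of object classes (default 1: person).
#' @param seed Seed for random weight initialization.
#' @return An object of class `"shuffle_detector"`: `$forward(x)` maps a
#'   `[3, S, S]` array to `list(backbone, pre_sppf_size, outputs)` where
#'   `outputs` holds the three head maps; also `$n_params`.
#' @export
assemble_detector <- function(input_size = 640,
                              widths = c(24, 116, 232, 464),
                              n_classes = 1, seed = 1L) {
  stopifnot(length(widths) == 4)
  with_seed(seed, {
    stem <- cbr(3, widths[1], 3, stride = 2)
    mk_stage <- function(in_c, out_c, n_basic) {
      units <- c(list(shuffle_unit_down(in_c, out_c)),
                 lapply(seq_len(n_basic), function(i)
                   shuffle_unit_basic(out_c)))
      list(fn = function(x) {
        for (u in units) x <- u$forward(x)
        x
      }, n_params = sum(vapply(units, `[[`, numeric(1), "n_params")))
    }
    st2 <- mk_stage(widths[1], widths[2], 3)
    st3 <- mk_stage(widths[2], widths[3], 7)
    st4 <- mk_stage(widths[3], widths[4], 3)
    spp <- sppf(widths[4], widths[4], scales = c(5, 9, 13))
    # neck: top-down then bottom-up, SA per stage
    td4 <- c2f_block(widths[4] + widths[3], widths[3])
    sa4 <- sa_block(widths[3])
    td3 <- c2f_block(widths[3] + widths[2], widths[2])
    sa3 <- sa_block(widths[2])
    dn3 <- cbr(widths[2], widths[2], 3, stride = 2)
    bu4 <- c2f_block(widths[2] + widths[3], widths[3])
    sa4b <- sa_block(widths[3])
    dn4 <- cbr(widths[3], widths[3], 3, stride = 2)
    bu5 <- c2f_block(widths[3] + widths[4], widths[4])
    sa5 <- sa_block(widths[4])
    heads <- lapply(c(widths[2], widths[3], widths[4]), function(cw)
      make_conv(cw, 4 + n_classes, 1))
    n_params <- stem$n_params + st2$n_params + st3$n_params +
      st4$n_params + spp$n_params + td4$n_params + sa4$n_params +
      td3$n_params + sa3$n_params + dn3$n_params + bu4$n_params +
      sa4b$n_params + dn4$n_params + bu5$n_params + sa5$n_params +
      sum(vapply(heads, function(h) h$n_params, numeric(1)))
    forward <- function(x) {
      x <- as_fmap(x)
      if (any(dim(x)[2:3] != input_size)) {
        stop("detector expects a ", input_size, "x", input_size,
             " input", call. = FALSE)
      }
      y <- maxpool_stride(stem$fn(x))          # widths[1] @ S/4
      p3 <- st2$fn(y)                          # widths[2] @ S/8
      p4 <- st3$fn(p3)                         # widths[3] @ S/16
      p5_pre <- st4$fn(p4)                     # widths[4] @ S/32
      p5 <- spp$forward(p5_pre)
      n4 <- sa4$forward(td4$fn(concat_channels(upsample_nearest(p5, 2), p4)))
      n3 <- sa3$forward(td3$fn(concat_channels(upsample_nearest(n4, 2), p3)))
      n4b <- sa4b$forward(bu4$fn(concat_channels(dn3$fn(n3), n4)))
      n5 <- sa5$forward(bu5$fn(concat_channels(dn4$fn(n4b), p5)))
      outs <- list(conv2d_arr(n3, heads[[1]]$w),
                   conv2d_arr(n4b, heads[[2]]$w),
                   conv2d_arr(n5, heads[[3]]$w))
      list(backbone = list(p3 = p3, p4 = p4, p5 = p5_pre),
           pre_sppf_size = dim(p5_pre)[2:3], outputs = outs)
    }
    structure(list(forward = forward, n_params = n_params,
                   widths = widths, input_size = input_size,
                   n_classes = n_classes),
              class = "shuffle_detector")
  })
}

#' @export
print.shuffle_detector <- function(x, ...) {
  cat(sprintf(
    "<shuffle_detector: input %dx%d, widths %s, %s params>\n",
    x$input_size, x$input_size, paste(x$widths, collapse = "/"),
    format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Per-stage shape summary of an assembly
#'
#' @param model A `"bam_hrnet"` or `"shuffle_detector"`.
#' @return A `data.frame` of stage names, output shapes, and the total
#'   parameter count as an attribute.
#' @export
model_summary <- function(model) {
  if (inherits(model, "bam_hrnet")) {
    rows <- do.call(rbind, lapply(seq_along(model$branch_specs),
      function(b) {
        sp <- model$branch_specs[[b]]
        data.frame(stage = sprintf("branch%d", b),
                   shape = sprintf("(%d, %d, %d)", sp["channels"],
                                   sp["height"], sp["width"]))
      }))
    rows <- rbind(rows, data.frame(
      stage = "heatmaps",
      shape = sprintf("(%d, %d, %d)", model$n_keypoints,
                      model$input_size[1] / 4, model$input_size[2] / 4)))
  } else if (inherits(model, "shuffle_detector")) {
    s <- model$input_size
    rows <- data.frame(
      stage = c("stage2", "stage3", "stage4", "sppf"),
      shape = sprintf("(%d, %d, %d)", model$widths[2:4][c(1, 2, 3, 3)],
                      s / c(8, 16, 32, 32), s / c(8, 16, 32, 32)))
  } else {
    stop("model_summary expects a bam_hrnet or shuffle_detector",
         call. = FALSE)
  }
  attr(rows, "n_params") <- model$n_params
  rows
}
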