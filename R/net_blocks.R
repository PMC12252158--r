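# Network building blocks: channel shuffle, ShuffleNetV2 units, serial
# spatial pyramid pooling (SPPF), shuffle attention (SA), the bottleneck
# attention module (BAM), and multi-scale feature fusion.  All blocks are
# untrained, shape- and value-contract components operating on [C, H, W]
# arrays.

new_nb_module <- function(forward, n_params, name, ...) {
  structure(list(forward = forward, n_params = n_params, name = name, ...),
            class = "nb_module")
}

#' @export
print.nb_module <- function(x, ...) {
  cat(sprintf("<nb_module %s: %s parameters>\n", x$name,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Channel shuffle
#'
#' The fixed reshape-transpose permutation that mixes information across
#' channel groups: channels are viewed as a `groups x (C/groups)` grid and
#' read out transposed.  Values are untouched; only channel order changes.
#'
#' @param x Feature map array `[C, H, W]`.
#' @param groups Number of groups `G`; `C` must be divisible by `G`.
#' @return Array of the same shape with permuted channels.
#' @examples
#' x <- array(1:16, c(4, 2, 2))
#' channel_shuffle(x, 2)
#' @export
channel_shuffle <- function(x, groups) {
  x <- as_fmap(x)
  C <- dim(x)[1]
  if (C %% groups != 0) {
    stop("channels (", C, ") not divisible by groups (", groups, ")",
         call. = FALSE)
  }
  idx <- as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
  x[idx, , , drop = FALSE]
}

# The permutation applied by channel_shuffle, as an index vector.
channel_shuffle_perm <- function(C, groups) {
  as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
}

#' Basic (stride-1) channel-split shuffle unit
#'
#' The lightweight backbone's basic unit: channels split into two halves,
#' one passed through unchanged, the other through 1x1 conv + 3x3
#' depthwise + 1x1 conv (each with batch norm), then concatenated and
#' channel-shuffled.  Spatial size and channel count are preserved.
#'
#' @param channels Input (= output) channel count; must be even.
#' @param init Weight initialization: `"he"` (random) or `"identity"`
#'   (all convolutions pass channels through unchanged; for contract
#'   tests).
#' @return An `nb_module` with `$forward(x)` and `$n_params`.
#' @export
shuffle_unit_basic <- function(channels, init = c("he", "identity")) {
  init <- match.arg(init)
  if (channels %% 2 != 0) {
    stop("shuffle_unit_basic requires an even channel count", call. = FALSE)
  }
  h <- channels / 2
  c1 <- make_conv(h, h, 1, init = init); b1 <- make_bn(h)
  dw <- make_dw(h, 3, stride = 1, init = init); b2 <- make_bn(h)
  c2 <- make_conv(h, h, 1, init = init); b3 <- make_bn(h)
  fwd <- function(x) {
    x <- as_fmap(x)
    stopifnot(dim(x)[1] == channels)
    x1 <- x[seq_len(h), , , drop = FALSE]
    x2 <- x[h + seq_len(h), , , drop = FALSE]
    y <- relu_arr(apply_bn(b1, apply_conv(c1, x2)))
    y <- apply_bn(b2, apply_dw(dw, y))
    y <- relu_arr(apply_bn(b3, apply_conv(c2, y)))
    channel_shuffle(concat_channels(x1, y), 2)
  }
  n <- c1$n_params + b1$n_params + dw$n_params + b2$n_params +
    c2$n_params + b3$n_params
  new_nb_module(fwd, n, sprintf("S_Unit(1) %dch", channels))
}

#' Down-sampling shuffle unit
#'
#' The stride-2 unit: both branches see the full input; each halves the
#' spatial size (3x3 depthwise, stride 2) and produces `out_channels / 2`
#' channels; concatenation plus channel shuffle doubles the width by
#' default.
#'
#' @param in_channels Input channels.
#' @param out_channels Output channels (even; default `2 * in_channels`).
#' @param init `"he"` or `"identity"` weight init.
#' @return An `nb_module`; `$forward` maps `[C, H, W]` (H, W even) to
#'   `[out_channels, H/2, W/2]`.
#' @export
shuffle_unit_down <- function(in_channels, out_channels = 2 * in_channels,
                              init = c("he", "identity")) {
  init <- match.arg(init)
  if (out_channels %% 2 != 0) {
    stop("out_channels must be even", call. = FALSE)
  }
  h <- out_channels / 2
  # branch 1: dw s2 -> 1x1
  dwa <- make_dw(in_channels, 3, stride = 2,
                 init = if (init == "identity") "identity" else "he")
  ba1 <- make_bn(in_channels)
  ca <- make_conv(in_channels, h, 1,
                  init = if (init == "identity" && in_channels == h)
                    "identity" else "he")
  ba2 <- make_bn(h)
  # branch 2: 1x1 -> dw s2 -> 1x1
  cb1 <- make_conv(in_channels, h, 1,
                   init = if (init == "identity" && in_channels == h)
                     "identity" else "he")
  bb1 <- make_bn(h)
  dwb <- make_dw(h, 3, stride = 2,
                 init = if (init == "identity") "identity" else "he")
  bb2 <- make_bn(h)
  cb2 <- make_conv(h, h, 1, init = init)
  bb3 <- make_bn(h)
  fwd <- function(x) {
    x <- as_fmap(x)
    d <- dim(x)
    stopifnot(d[1] == in_channels)
    if (d[2] %% 2 != 0 || d[3] %% 2 != 0) {
      stop("spatial size must be even for the down-sampling unit",
           call. = FALSE)
    }
    y1 <- relu_arr(apply_bn(ba2, apply_conv(ca, apply_bn(ba1,
      apply_dw(dwa, x)))))
    y2 <- relu_arr(apply_bn(bb1, apply_conv(cb1, x)))
    y2 <- apply_bn(bb2, apply_dw(dwb, y2))
    y2 <- relu_arr(apply_bn(bb3, apply_conv(cb2, y2)))
    channel_shuffle(concat_channels(y1, y2), 2)
  }
  n <- dwa$n_params + ba1$n_params + ca$n_params + ba2$n_params +
    cb1$n_params + bb1$n_params + dwb$n_params + bb2$n_params +
    cb2$n_params + bb3$n_params
  new_nb_module(fwd, n, sprintf("S_Unit(2) %d->%dch", in_channels,
                                out_channels))
}

#' Serial spatial pyramid pooling (SPPF)
#'
#' Cascaded stride-1 same-padding max pools with the given odd, ascending
#' kernel scales; the input (after a 1x1 reduction) and the three pooled
#' maps are concatenated along channels and fused to `out_channels` by a
#' final 1x1 convolution.  Spatial size is preserved.
#'
#' @param channels Input channel count.
#' @param out_channels Output channel count (default `channels`).
#' @param scales Odd ascending pooling kernel sizes, default `c(5, 9, 13)`.
#' @return An `nb_module`.
#' @export
sppf <- function(channels, out_channels = channels, scales = c(5, 9, 13)) {
  if (any(scales %% 2 == 0)) {
    stop("SPPF scales must be odd", call. = FALSE)
  }
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("SPPF scales must be ascending", call. = FALSE)
  }
  h <- max(1L, channels %/% 2L)
  red <- cbr(channels, h, 1)
  fuse <- cbr(h * (length(scales) + 1), out_channels, 1)
  fwd <- function(x) {
    x <- as_fmap(x)
    stopifnot(dim(x)[1] == channels)
    y <- red$fn(x)
    pools <- vector("list", length(scales) + 1)
    pools[[1]] <- y
    for (i in seq_along(scales)) {
      pools[[i + 1]] <- maxpool_same(pools[[i]], scales[i])
    }
    fuse$fn(concat_channels(pools))
  }
  new_nb_module(fwd, red$n_params + fuse$n_params,
                sprintf("SPPF(%s) %dch", paste(scales, collapse = ","),
                        channels), scales = scales)
}

# Group normalization over one sub-branch (unit affine).
group_norm_arr <- function(x, eps = 1e-5) {
  mu <- mean(x)
  (x - mu) / sqrt(mean((x - mu)^2) + eps)
}

#' Shuffle attention block
#'
#' Grouped mixed attention: the input is split into `groups` groups; each
#' group is split into a channel-attention sub-branch (per-channel global
#' pooling with a learnable scale/shift feeding a sigmoid gate) and a
#' spatial-attention sub-branch (group-normalized map with a learnable
#' scale/shift feeding a sigmoid gate).  Branches are recombined and a
#' final channel shuffle mixes the groups.  Output shape equals input
#' shape.
#'
#' @param channels Input channel count; must be divisible by
#'   `2 * groups` (so divisible by 4 at the default `groups = 2`).
#' @param groups Number of groups `G` (default 2).
#' @param init `"default"` (unit scale, zero shift) or `"zero"` (all gate
#'   parameters zero, so every gate is exactly 0.5; for contract tests).
#' @return An `nb_module`.
#' @export
sa_block <- function(channels, groups = 2, init = c("default", "zero")) {
  init <- match.arg(init)
  if (channels %% (2 * groups) != 0) {
    stop("channels must be divisible by 2 * groups", call. = FALSE)
  }
  sub <- channels / (2 * groups)   # channels per sub-branch
  g0 <- if (init == "zero") 0 else 1
  pars <- lapply(seq_len(groups), function(g) {
    list(cw = rep(g0, sub), cb = rep(0, sub),
         sw = rep(g0, sub), sb = rep(0, sub))
  })
  fwd <- function(x) {
    x <- as_fmap(x)
    stopifnot(dim(x)[1] == channels)
    per <- channels / groups
    outs <- vector("list", groups)
    for (g in seq_len(groups)) {
      xg <- x[(g - 1) * per + seq_len(per), , , drop = FALSE]
      xc <- xg[seq_len(sub), , , drop = FALSE]
      xs <- xg[sub + seq_len(sub), , , drop = FALSE]
      pg <- pars[[g]]
      s <- global_avg_pool(xc)
      cgate <- sigmoid_arr(pg$cw * s + pg$cb)       # per channel
      yc <- xc * cgate
      gn <- group_norm_arr(xs)
      sgate <- sigmoid_arr(gn * pg$sw + pg$sb)      # elementwise
      ys <- xs * sgate
      outs[[g]] <- concat_channels(yc, ys)
    }
    channel_shuffle(concat_channels(outs), 2)
  }
  new_nb_module(fwd, groups * 4 * sub, sprintf("SA(G=%d) %dch", groups,
                                               channels))
}

#' Bottleneck attention configuration and weights
#'
#' Builds the parameters of a BAM block: a channel branch (global average
#' pooling, a reduction MLP `W1(W0(.) + b0) + b1` with hidden width
#' `C / r`, batch norm) and a spatial branch (1x1 reduction, two 3x3
#' dilated convolutions, 1x1 collapse to one channel, batch norm).
#'
#' @param channels Input channel count `C`; must be divisible by `r`.
#' @param r Reduction ratio (default 16).
#' @param dilation Dilation of the two 3x3 convolutions (default 4).
#' @param init `"he"` random weights or `"zero"` (all-zero weights and
#'   biases; both branches then output exactly zero).
#' @return A list of class `"bam_config"` holding the weights.
#' @export
bam_config <- function(channels, r = 16, dilation = 4,
                       init = c("he", "zero")) {
  init <- match.arg(init)
  if (channels %% r != 0) {
    stop("channels must be divisible by the reduction ratio r",
         call. = FALSE)
  }
  h <- channels / r
  rnd <- function(nr, nc) {
    m <- matrix(0, nr, nc)
    if (init == "he") m[] <- he_init(nr * nc, nc)
    m
  }
  cv <- function(o, i, k, dil = 1) {
    make_conv(i, o, k, dilation = dil, init = if (init == "he") "he" else
      "zero")
  }
  structure(list(
    channels = channels, r = r, dilation = dilation,
    W0 = rnd(h, channels), b0 = rep(0, h),
    W1 = rnd(channels, h), b1 = rep(0, channels),
    bn_c = make_bn(channels),
    c0 = cv(h, channels, 1), c1 = cv(h, h, 3, dilation),
    c2 = cv(h, h, 3, dilation), c3 = cv(1, h, 1),
    bn_s = make_bn(1)
  ), class = "bam_config")
}

#' BAM channel attention branch
#'
#' `BN(W1 (W0 AvgPool(x) + b0) + b1)`: one attention value per channel.
#'
#' @param x Feature map `[C, H, W]`.
#' @param cfg A [bam_config()].
#' @return Numeric vector of length `C`.
#' @export
bam_channel_branch <- function(x, cfg) {
  x <- as_fmap(x)
  stopifnot(dim(x)[1] == cfg$channels)
  v <- global_avg_pool(x)
  hid <- relu_arr(as.vector(cfg$W0 %*% v + cfg$b0))
  out <- as.vector(cfg$W1 %*% hid + cfg$b1)
  as.vector(apply_bn(cfg$bn_c, out))
}

#' BAM spatial attention branch
#'
#' 1x1 channel reduction, two 3x3 dilated convolutions, 1x1 collapse to a
#' single channel, batch norm.  Spatial size is preserved.
#'
#' @param x Feature map `[C, H, W]`; spatial size must cover the dilated
#'   3x3 footprint `(k - 1) * dilation + 1`.
#' @param cfg A [bam_config()].
#' @return Array `[1, H, W]`.
#' @export
bam_spatial_branch <- function(x, cfg) {
  x <- as_fmap(x)
  stopifnot(dim(x)[1] == cfg$channels)
  foot <- 2 * cfg$dilation + 1
  if (dim(x)[2] < foot || dim(x)[3] < foot) {
    stop("input smaller than the dilated receptive footprint (",
         foot, " px)", call. = FALSE)
  }
  y <- relu_arr(apply_conv(cfg$c0, x))
  y <- relu_arr(apply_conv(cfg$c1, y))
  y <- relu_arr(apply_conv(cfg$c2, y))
  y <- apply_conv(cfg$c3, y)
  apply_bn(cfg$bn_s, y)
}

#' BAM refinement
#'
#' Combines the channel and spatial attention maps by broadcast addition,
#' squashes through a sigmoid, and refines the input with a residual
#' gating: `x + x * sigmoid(channel + spatial)`.
#'
#' @param x Input feature map `[C, H, W]`.
#' @param channel_map Length-`C` vector (or `[C, 1, 1]` array).
#' @param spatial_map `[1, H, W]` array.
#' @return Refined feature map, same shape as `x`.
#' @export
bam_refine <- function(x, channel_map, spatial_map) {
  x <- as_fmap(x)
  d <- dim(x)
  cm <- as.vector(channel_map)
  if (length(cm) != d[1]) {
    stop("channel map length must equal the channel count", call. = FALSE)
  }
  sm <- as_fmap(spatial_map)
  if (dim(sm)[1] != 1 || any(dim(sm)[2:3] != d[2:3])) {
    stop("spatial map must be [1, H, W] matching the input", call. = FALSE)
  }
  att <- array(cm, d)                       # broadcast over H, W
  att <- att + array(rep(sm[1, , ], each = d[1]), d)
  x + x * sigmoid_arr(att)
}

#' Complete BAM block as a module
#'
#' @param channels,r,dilation,init Passed to [bam_config()].
#' @return An `nb_module` whose `$forward` applies both branches and
#'   [bam_refine()].
#' @export
bam_module <- function(channels, r = 16, dilation = 4, init = "he") {
  cfg <- bam_config(channels, r, dilation, init)
  n <- length(cfg$W0) + length(cfg$b0) + length(cfg$W1) + length(cfg$b1) +
    cfg$bn_c$n_params + cfg$c0$n_params + cfg$c1$n_params +
    cfg$c2$n_params + cfg$c3$n_params + cfg$bn_s$n_params
  fwd <- function(x) {
    bam_refine(x, bam_channel_branch(x, cfg), bam_spatial_branch(x, cfg))
  }
  new_nb_module(fwd, n, sprintf("BAM(r=%d,d=%d) %dch", r, dilation,
                                channels), config = cfg)
}

#' Multi-scale fusion configuration
#'
#' @param input_branches,output_branches Branch counts (>= 1).
#' @param c Channel count of the highest-resolution branch; branch `i`
#'   (0-based) carries `c * 2^i` channels at half the spatial size of
#'   branch `i - 1`.
#' @return A list of class `"fusion_config"`.
#' @export
fusion_config <- function(input_branches, output_branches, c = 32) {
  stopifnot(input_branches >= 1, output_branches >= 1, c >= 1)
  structure(list(input_branches = as.integer(input_branches),
                 output_branches = as.integer(output_branches),
                 c = as.integer(c)), class = "fusion_config")
}

#' Multi-scale feature fusion layer
#'
#' High-resolution-network style fusion: output branch `i` sums an
#' identity path from input branch `i`, upsampling paths (1x1 conv + BN +
#' nearest-neighbor x2^(j-i)) from lower-resolution branches `j > i`, and
#' stride-2 3x3 convolution chains from higher-resolution branches
#' `j < i` (the final conv in each chain maps to branch `i`'s channel
#' count), followed by a ReLU.
#'
#' @param cfg A [fusion_config()].
#' @param init `"he"` or `"zero"` (all conv weights zero, so each output
#'   reduces to `relu(identity path)`; for contract tests).
#' @return An `nb_module` whose `$forward` maps a list of branch maps to
#'   a list of fused branch maps.
#' @export
multiscale_fusion <- function(cfg, init = c("he", "zero")) {
  init <- match.arg(init)
  stopifnot(inherits(cfg, "fusion_config"))
  conv_init <- if (init == "zero") "zero" else "he"
  n_params <- 0
  paths <- vector("list", cfg$output_branches)
  for (i in seq_len(cfg$output_branches) - 1L) {
    paths[[i + 1]] <- vector("list", cfg$input_branches)
    for (j in seq_len(cfg$input_branches) - 1L) {
      ci <- cfg$c * 2^i; cj <- cfg$c * 2^j
      if (i == j) {
        paths[[i + 1]][[j + 1]] <- list(kind = "identity")
      } else if (i < j) {
        cv <- make_conv(cj, ci, 1, init = conv_init)
        bn <- make_bn(ci)
        n_params <- n_params + cv$n_params + bn$n_params
        paths[[i + 1]][[j + 1]] <- list(kind = "up", cv = cv, bn = bn,
                                        factor = 2^(j - i))
      } else {
        chain <- list()
        cin <- cj
        for (s in seq_len(i - j)) {
          cout <- if (s == i - j) ci else cin
          cv <- make_conv(cin, cout, 3, stride = 2, init = conv_init)
          bn <- make_bn(cout)
          n_params <- n_params + cv$n_params + bn$n_params
          chain[[s]] <- list(cv = cv, bn = bn, last = s == i - j)
          cin <- cout
        }
        paths[[i + 1]][[j + 1]] <- list(kind = "down", chain = chain)
      }
    }
  }
  fwd <- function(branch_maps) {
    stopifnot(is.list(branch_maps),
              length(branch_maps) == cfg$input_branches)
    for (j in seq_len(cfg$input_branches)) {
      d <- dim(as_fmap(branch_maps[[j]]))
      if (d[1] != cfg$c * 2^(j - 1)) {
        stop("branch ", j - 1, " has ", d[1], " channels; expected ",
             cfg$c * 2^(j - 1), call. = FALSE)
      }
      if (j > 1) {
        dprev <- dim(branch_maps[[j - 1]])
        if (any(dprev[2:3] != 2 * d[2:3])) {
          stop("inconsistent branch shapes: spatial size must halve per ",
               "branch", call. = FALSE)
        }
      }
    }
    out <- vector("list", cfg$output_branches)
    for (i in seq_len(cfg$output_branches)) {
      acc <- NULL
      for (j in seq_len(cfg$input_branches)) {
        p <- paths[[i]][[j]]
        y <- switch(p$kind,
          identity = branch_maps[[j]],
          up = upsample_nearest(apply_bn(p$bn,
            apply_conv(p$cv, branch_maps[[j]])), p$factor),
          down = {
            z <- branch_maps[[j]]
            for (st in p$chain) {
              z <- apply_bn(st$bn, apply_conv(st$cv, z))
              if (!st$last) z <- relu_arr(z)
            }
            z
          })
        acc <- if (is.null(acc)) y else acc + y
      }
      out[[i]] <- relu_arr(acc)
    }
    out
  }
  new_nb_module(fwd, n_params,
                sprintf("fuse(%d->%d, c=%d)", cfg$input_branches,
                        cfg$output_branches, cfg$c))
}

#' Multi-scale fusion as a single call
#'
#' Convenience wrapper constructing a [multiscale_fusion()] layer and
#' applying it to the given branch maps.
#'
#' @param branch_maps List of `[c * 2^i, H_i, W_i]` arrays.
#' @param cfg A [fusion_config()]; inferred from the maps when `NULL`.
#' @param init Weight init passed to [multiscale_fusion()].
#' @return List of fused branch maps.
#' @export
fuse_multiscale <- function(branch_maps, cfg = NULL, init = "he") {
  if (is.null(cfg)) {
    cfg <- fusion_config(length(branch_maps), length(branch_maps),
                         c = dim(as_fmap(branch_maps[[1]]))[1])
  }
  multiscale_fusion(cfg, init = init)$forward(branch_maps)
}
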