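# Array primitives for the network building blocks.
#
# Feature maps are numeric arrays [C, H, W] (batch handled by lists).
# Convolutions use im2col + matrix multiply so the heavy lifting is BLAS;
# batch normalization is inference-mode (running statistics).  These
# primitives exist to make the block contracts (shapes, forced values,
# small-instance oracles) checkable; no training is involved.

as_fmap <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3)
  x
}

fmap_spec <- function(x) {
  d <- dim(as_fmap(x))
  c(channels = d[1], height = d[2], width = d[3])
}

pad_fmap <- function(x, pad, value = 0) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3])] <- x
  xp
}

# Dense 2D convolution, weights w[O, C, kh, kw] (square kernel).
conv2d_arr <- function(x, w, bias = NULL, stride = 1, pad = 0,
                       dilation = 1) {
  x <- as_fmap(x)
  d <- dim(x); C <- d[1]
  O <- dim(w)[1]; k <- dim(w)[3]
  stopifnot(dim(w)[2] == C, dim(w)[4] == k)
  xp <- pad_fmap(x, pad)
  eff <- (k - 1) * dilation + 1
  Ho <- (dim(xp)[2] - eff) %/% stride + 1
  Wo <- (dim(xp)[3] - eff) %/% stride + 1
  if (Ho < 1 || Wo < 1) {
    stop("input too small for kernel/dilation footprint", call. = FALSE)
  }
  cols <- matrix(0, C * k * k, Ho * Wo)
  for (ki in seq_len(k)) {
    ri <- (ki - 1) * dilation + seq(1, by = stride, length.out = Ho)
    for (kj in seq_len(k)) {
      ci <- (kj - 1) * dilation + seq(1, by = stride, length.out = Wo)
      block <- ((ki - 1) * k + (kj - 1)) * C
      cols[block + seq_len(C), ] <- matrix(xp[, ri, ci, drop = FALSE],
                                           C, Ho * Wo)
    }
  }
  wm <- matrix(aperm(w, c(1, 2, 4, 3)), nrow = O)
  out <- wm %*% cols
  if (!is.null(bias)) out <- out + bias
  array(out, c(O, Ho, Wo))
}

# Depthwise convolution, weights w[C, k, k].
depthwise_arr <- function(x, w, stride = 1, pad = 0, dilation = 1) {
  x <- as_fmap(x)
  C <- dim(x)[1]; k <- dim(w)[2]
  stopifnot(dim(w)[1] == C)
  xp <- pad_fmap(x, pad)
  eff <- (k - 1) * dilation + 1
  Ho <- (dim(xp)[2] - eff) %/% stride + 1
  Wo <- (dim(xp)[3] - eff) %/% stride + 1
  if (Ho < 1 || Wo < 1) {
    stop("input too small for kernel footprint", call. = FALSE)
  }
  out <- array(0, c(C, Ho, Wo))
  for (ki in seq_len(k)) {
    ri <- (ki - 1) * dilation + seq(1, by = stride, length.out = Ho)
    for (kj in seq_len(k)) {
      ci <- (kj - 1) * dilation + seq(1, by = stride, length.out = Wo)
      out <- out + xp[, ri, ci, drop = FALSE] * w[, ki, kj]
    }
  }
  out
}

# Max pooling, stride 1, same padding (odd kernel).
maxpool_same <- function(x, k) {
  if (k %% 2 == 0) stop("max-pool kernel must be odd", call. = FALSE)
  x <- as_fmap(x)
  pad <- (k - 1) / 2
  xp <- pad_fmap(x, pad, value = -Inf)
  d <- dim(x)
  out <- array(-Inf, d)
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      out <- pmax(out, xp[, (ki - 1) + seq_len(d[2]),
                          (kj - 1) + seq_len(d[3]), drop = FALSE])
    }
  }
  out
}

# Max pooling with kernel k, stride s (used by the detector stem).
maxpool_stride <- function(x, k = 3, stride = 2, pad = 1) {
  x <- as_fmap(x)
  xp <- pad_fmap(x, pad, value = -Inf)
  Ho <- (dim(xp)[2] - k) %/% stride + 1
  Wo <- (dim(xp)[3] - k) %/% stride + 1
  out <- array(-Inf, c(dim(x)[1], Ho, Wo))
  for (ki in seq_len(k)) {
    ri <- (ki - 1) + seq(1, by = stride, length.out = Ho)
    for (kj in seq_len(k)) {
      ci <- (kj - 1) + seq(1, by = stride, length.out = Wo)
      out <- pmax(out, xp[, ri, ci, drop = FALSE])
    }
  }
  out
}

upsample_nearest <- function(x, factor) {
  x <- as_fmap(x)
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = factor),
    rep(seq_len(d[3]), each = factor), drop = FALSE]
}

relu_arr <- function(x) pmax(x, 0)
sigmoid_arr <- function(x) 1 / (1 + exp(-x))

global_avg_pool <- function(x) {
  x <- as_fmap(x)
  apply(x, 1, mean)
}

concat_channels <- function(...) {
  maps <- list(...)
  if (length(maps) == 1 && is.list(maps[[1]]) && !is.array(maps[[1]])) {
    maps <- maps[[1]]
  }
  d <- dim(maps[[1]])
  for (m in maps) stopifnot(all(dim(m)[2:3] == d[2:3]))
  C <- sum(vapply(maps, function(m) dim(m)[1], numeric(1)))
  out <- array(0, c(C, d[2], d[3]))
  at <- 0
  for (m in maps) {
    cm <- dim(m)[1]
    out[at + seq_len(cm), , ] <- m
    at <- at + cm
  }
  out
}

# ---- parameterized primitive layers -------------------------------------

he_init <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))

make_conv <- function(in_c, out_c, k = 1, stride = 1, dilation = 1,
                      init = c("he", "identity", "zero")) {
  init <- match.arg(init)
  w <- array(0, c(out_c, in_c, k, k))
  if (init == "he") {
    w[] <- he_init(length(w), in_c * k * k)
  } else if (init == "identity") {
    stopifnot(in_c == out_c)
    mid <- (k + 1) / 2
    for (c in seq_len(in_c)) w[c, c, mid, mid] <- 1
  }
  pad <- ((k - 1) * dilation) / 2
  stopifnot(pad == floor(pad))
  list(kind = "conv", w = w, stride = stride, pad = pad,
       dilation = dilation, n_params = length(w))
}

make_bn <- function(c, eps = 1e-5) {
  list(kind = "bn", gamma = rep(1, c), beta = rep(0, c),
       mean = rep(0, c), var = rep(1, c), eps = eps, n_params = 2 * c)
}

make_dw <- function(c, k = 3, stride = 1, dilation = 1,
                    init = c("he", "identity", "zero")) {
  init <- match.arg(init)
  w <- array(0, c(c, k, k))
  if (init == "he") {
    w[] <- he_init(length(w), k * k)
  } else if (init == "identity") {
    w[, (k + 1) / 2, (k + 1) / 2] <- 1
  }
  pad <- ((k - 1) * dilation) / 2
  list(kind = "dw", w = w, stride = stride, pad = pad, dilation = dilation,
       n_params = length(w))
}

apply_conv <- function(layer, x) {
  conv2d_arr(x, layer$w, stride = layer$stride, pad = layer$pad,
             dilation = layer$dilation)
}

apply_dw <- function(layer, x) {
  depthwise_arr(x, layer$w, stride = layer$stride, pad = layer$pad,
                dilation = layer$dilation)
}

apply_bn <- function(layer, x) {
  scale <- layer$gamma / sqrt(layer$var + layer$eps)
  shift <- layer$beta - layer$mean * scale
  x * scale + shift   # recycles along the channel (first) dimension
}

# conv + BN (+ activation) composite; returns fn + parameter count
cbr <- function(in_c, out_c, k = 1, stride = 1, dilation = 1,
                act = c("relu", "none"), init = "he") {
  act <- match.arg(act)
  cv <- make_conv(in_c, out_c, k, stride, dilation, init = init)
  bn <- make_bn(out_c)
  fn <- function(x) {
    y <- apply_bn(bn, apply_conv(cv, x))
    if (act == "relu") relu_arr(y) else y
  }
  list(fn = fn, n_params = cv$n_params + bn$n_params)
}
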