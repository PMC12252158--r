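# Network blocks: permutation, shape and forced-value contracts, with
# independent small-instance oracles.

test_that("channel shuffle is the reshape-transpose permutation", {
  x <- array(0, c(4, 2, 2))
  for (c in 1:4) x[c, , ] <- c
  y <- channel_shuffle(x, 2)
  expect_equal(y[, 1, 1], c(1, 3, 2, 4))   # [0,2,1,3] in 0-based labels
  # independent oracle: split channels into G consecutive groups, then
  # interleave (first member of each group, second of each group, ...)
  for (C in c(6, 8, 12)) {
    for (G in c(2, 3)) {
      if (C %% G != 0) next
      grps <- split(seq_len(C), rep(seq_len(G), each = C / G))
      oracle <- unlist(lapply(seq_len(C / G), function(k)
        vapply(grps, `[`, numeric(1), k)), use.names = FALSE)
      xi <- array(rep(seq_len(C), 4), c(C, 2, 2))
      expect_equal(channel_shuffle(xi, G)[, 1, 1], oracle)
    }
  }
  # G = 1 is the identity; shuffle then inverse permutation is identity
  x6 <- rand_fmap(6, 3, 3)
  expect_identical(channel_shuffle(x6, 1), x6)
  y6 <- channel_shuffle(x6, 3)
  perm <- channel_shuffle(array(seq_len(6), c(6, 1, 1)), 3)[, 1, 1]
  inv <- order(perm)
  expect_identical(y6[inv, , ], x6)
  expect_error(channel_shuffle(x6, 4), "divisible")
})

test_that("basic shuffle unit preserves shape and identity weights permute", {
  u <- shuffle_unit_basic(116)
  x <- rand_fmap(116, 40, 40)
  y <- u$forward(x)
  expect_equal(dim(y), c(116, 40, 40))
  expect_true(all(is.finite(y)))
  expect_error(shuffle_unit_basic(7), "even")

  uid <- shuffle_unit_basic(8, init = "identity")
  xp <- abs(rand_fmap(8, 5, 5, seed = 3))   # nonnegative, ReLU-transparent
  yp <- uid$forward(xp)
  # output channels are a permutation of input channels (BN eps-level tol)
  sums_in <- sort(apply(xp, 1, sum))
  sums_out <- sort(apply(yp, 1, sum))
  expect_equal(sums_out, sums_in, tolerance = 1e-4)
})

test_that("down-sampling unit halves space and doubles channels", {
  d <- shuffle_unit_down(24)
  y <- d$forward(rand_fmap(24, 160, 160))
  expect_equal(dim(y), c(48, 80, 80))
  d2 <- shuffle_unit_down(116, 232)
  expect_equal(dim(d2$forward(rand_fmap(116, 40, 40))), c(232, 20, 20))
  # applying twice: (4C, H/4, W/4)
  da <- shuffle_unit_down(8); db <- shuffle_unit_down(16)
  expect_equal(dim(db$forward(da$forward(rand_fmap(8, 16, 16)))),
               c(32, 4, 4))
  expect_error(d$forward(rand_fmap(24, 15, 16)), "even")
})

test_that("SPPF preserves space, pools serially, and validates scales", {
  s <- sppf(32, 32)
  x <- rand_fmap(32, 12, 12)
  expect_equal(dim(s$forward(x)), c(32, 12, 12))
  # spatially constant input stays spatially constant through max pools
  xc <- array(rep(rnorm(32), 9 * 9), c(32, 9, 9))
  yc <- s$forward(xc)
  expect_lt(max(apply(yc, 1, function(m) diff(range(m)))), 1e-10)
  expect_error(sppf(32, scales = c(4, 9, 13)), "odd")
  expect_error(sppf(32, scales = c(9, 5, 13)), "ascending")
})

test_that("serial max pooling matches a brute-force max filter", {
  set.seed(4)
  m <- matrix(rnorm(81), 9, 9)
  x <- array(m, c(1, 9, 9))
  p5 <- fallwatch:::maxpool_same(x, 5)
  expect_equal(p5[1, , ], maxfilter_oracle(m, 5))
  p9 <- fallwatch:::maxpool_same(p5, 9)
  expect_equal(p9[1, , ], maxfilter_oracle(maxfilter_oracle(m, 5), 9))
  # single bright pixel: support grows with kernel size
  imp <- array(0, c(1, 9, 9)); imp[1, 5, 5] <- 1
  expect_equal(sum(fallwatch:::maxpool_same(imp, 5) > 0), 25)
  expect_equal(sum(fallwatch:::maxpool_same(imp, 9) > 0), 81)
})

test_that("shuffle attention keeps shape; zero gates halve the shuffle", {
  sa <- sa_block(64)
  x <- rand_fmap(64, 20, 20)
  expect_equal(dim(sa$forward(x)), c(64, 20, 20))
  expect_error(sa_block(6), "divisible")

  saz <- sa_block(16, init = "zero")
  xz <- rand_fmap(16, 4, 4, seed = 8)
  expect_equal(saz$forward(xz), 0.5 * channel_shuffle(xz, 2),
               tolerance = 1e-12)
})

test_that("BAM channel branch: forced zero, constant pooling, hand arithmetic", {
  cfgz <- bam_config(32, r = 16, init = "zero")
  xz <- rand_fmap(32, 8, 8)
  expect_true(all(bam_channel_branch(xz, cfgz) == 0))

  # hand-computed 2-channel, r = 2 instance
  cfg <- bam_config(2, r = 2, init = "zero")
  cfg$W0 <- matrix(c(1, 2), 1, 2)
  cfg$b0 <- 0.5
  cfg$W1 <- matrix(c(3, -1), 2, 1)
  cfg$b1 <- c(0.1, 0.2)
  cfg$bn_c$eps <- 0
  m1 <- 0.7; m2 <- -0.2   # constant per-channel input
  xc <- array(c(m1, m2), c(2, 4, 4))
  hid <- max(0, 1 * m1 + 2 * m2 + 0.5)
  expect_equal(bam_channel_branch(xc, cfg),
               c(3 * hid + 0.1, -1 * hid + 0.2))
})

test_that("BAM spatial branch: shape, forced zero, dilated footprint", {
  cfg <- bam_config(32, r = 16, dilation = 4)
  x <- rand_fmap(32, 16, 12)
  sm <- bam_spatial_branch(x, cfg)
  expect_equal(dim(sm), c(1, 16, 12))
  expect_true(all(bam_spatial_branch(x, bam_config(32, 16, 4,
                                                   init = "zero")) == 0))
  expect_error(bam_spatial_branch(rand_fmap(32, 6, 6), cfg), "footprint")

  # an impulse through the two dilated 3x3 convs spans (k-1)*d+1 = 9 px
  # per conv; with center-only second conv the support is exactly 9x9
  c2 <- bam_config(2, r = 2, dilation = 4, init = "zero")
  c2$c0$w[] <- 1
  c2$c1$w[] <- 1
  c2$c2$w[1, 1, 2, 2] <- 1
  c2$c3$w[] <- 1
  imp <- array(0, c(2, 21, 21)); imp[, 11, 11] <- 1
  out <- bam_spatial_branch(imp, c2)
  nz <- which(out[1, , ] != 0, arr.ind = TRUE)
  expect_equal(max(nz[, 1]) - min(nz[, 1]) + 1, 9)
  expect_equal(max(nz[, 2]) - min(nz[, 2]) + 1, 9)
})

test_that("BAM refinement matches limits and a scalar loop oracle", {
  x <- rand_fmap(2, 3, 3, seed = 5)
  zero_c <- rep(0, 2); zero_s <- array(0, c(1, 3, 3))
  expect_equal(bam_refine(x, zero_c, zero_s), 1.5 * x)
  big <- 50
  expect_equal(bam_refine(x, rep(big, 2), zero_s), 2 * x, tolerance = 1e-10)
  expect_equal(bam_refine(x, rep(-big, 2), zero_s), x, tolerance = 1e-10)

  cm <- rnorm(2); sm <- array(rnorm(9), c(1, 3, 3))
  got <- bam_refine(x, cm, sm)
  oracle <- array(0, dim(x))
  for (c in 1:2) for (i in 1:3) for (j in 1:3) {
    g <- 1 / (1 + exp(-(cm[c] + sm[1, i, j])))
    oracle[c, i, j] <- x[c, i, j] + x[c, i, j] * g
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(bam_refine(x, rnorm(3), sm), "channel")
})

test_that("multi-scale fusion honours shapes, identity path and factors", {
  # one branch in/out: identity path only
  x <- rand_fmap(16, 8, 8)
  out1 <- fuse_multiscale(list(x), init = "zero")
  expect_equal(out1[[1]], pmax(x, 0))
  # two branches at the published sizes keep their shapes
  maps <- list(rand_fmap(32, 64, 48), rand_fmap(64, 32, 24, seed = 2))
  fz <- multiscale_fusion(fusion_config(2, 2, 32))
  out <- fz$forward(maps)
  expect_equal(dim(out[[1]]), c(32, 64, 48))
  expect_equal(dim(out[[2]]), c(64, 32, 24))
  # zero-init convs: diagonal identity reproduces relu(input)
  f0 <- multiscale_fusion(fusion_config(2, 2, 32), init = "zero")
  out0 <- f0$forward(maps)
  expect_equal(out0[[1]], pmax(maps[[1]], 0))
  expect_equal(out0[[2]], pmax(maps[[2]], 0))
  # three branches: the j=2 -> i=0 path upsamples by 2^(j-i) = 4
  maps3 <- list(rand_fmap(8, 16, 16), rand_fmap(16, 8, 8),
                rand_fmap(32, 4, 4))
  out3 <- fuse_multiscale(maps3, fusion_config(3, 3, 8))
  expect_equal(dim(out3[[1]]), c(8, 16, 16))
  # inconsistent branch shapes are rejected
  bad <- list(rand_fmap(8, 16, 16), rand_fmap(16, 9, 8))
  expect_error(fuse_multiscale(bad, fusion_config(2, 2, 8)),
               "inconsistent|halve")
})

test_that("blocks are batch-independent", {
  sa <- sa_block(16)
  xs <- list(rand_fmap(16, 6, 6, seed = 1), rand_fmap(16, 6, 6, seed = 2))
  ys <- lapply(xs, sa$forward)
  ys_perm <- lapply(rev(xs), sa$forward)
  expect_identical(ys[[1]], ys_perm[[2]])
  expect_identical(ys[[2]], ys_perm[[1]])
})
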