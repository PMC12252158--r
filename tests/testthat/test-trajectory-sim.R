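# Trajectory simulator: signatures, determinism, occlusion, rendering.

test_that("walking tracks oscillate at the gait period inside the A band", {
  lt <- simulate_track(behavior_params("walking", seed = 1, noise_sd = 0))
  A <- vapply(lt$track$frames, function(f) aspect_ratio(f$bbox), numeric(1))
  expect_equal(dominant_period(A), 15)
  expect_true(all(A > 1.5 & A < 2.5))
  # and never crosses the fall V-gate
  ks <- kinematics_series(lt$track)
  expect_true(all(abs(ks$V) < 350, na.rm = TRUE))
})

test_that("falling tracks hit the designed peak descent speed", {
  lt <- simulate_track(behavior_params("falling", seed = 1, noise_sd = 0))
  ks <- kinematics_series(lt$track, dt = 0.25)
  expect_equal(max(ks$V, na.rm = TRUE), 480, tolerance = 1e-6)
  expect_identical(lt$label, "falling")
  expect_equal(lt$event_frame, 15L)
})

test_that("lying tracks stay under both gates and are judged lying", {
  hits <- 0L
  lt <- simulate_track(behavior_params("lying", seed = 3))
  res <- judge_sequence(lt$track,
                        inquiry_hook = function(st) hits <<- hits + 1L)
  expect_identical(res$status, "lying")
  expect_equal(hits, 0L)
  ks <- kinematics_series(lt$track)
  expect_lt(max(ks$V, na.rm = TRUE), 350)
  # the body does end up horizontal
  A <- vapply(lt$track$frames, function(f) aspect_ratio(f$bbox), numeric(1))
  expect_lt(tail(A, 1), 1)
})

test_that("tracks are deterministic given seed and differ across seeds", {
  a <- simulate_track(behavior_params("falling", seed = 11))
  b <- simulate_track(behavior_params("falling", seed = 11))
  cc <- simulate_track(behavior_params("falling", seed = 12))
  xa <- vapply(a$track$frames, function(f) f$keypoints$x[1], numeric(1))
  xb <- vapply(b$track$frames, function(f) f$keypoints$x[1], numeric(1))
  xc <- vapply(cc$track$frames, function(f) f$keypoints$x[1], numeric(1))
  expect_identical(xa, xb)
  expect_false(identical(xa, xc))
})

test_that("occlusion marks the expected fraction of keypoints invisible", {
  lt <- simulate_track(behavior_params("walking", seed = 5))
  expect_identical(occlude_track(lt, 0, seed = 9)$track$frames[[3]]$keypoints,
                   lt$track$frames[[3]]$keypoints)
  all_hidden <- occlude_track(lt, 1, seed = 9)
  expect_true(all(!vapply(all_hidden$track$frames, function(f)
    any(f$keypoints$visible), logical(1))))
  # binomial check on ~10000 draws
  p <- 0.3
  lts <- lapply(1:9, function(s)
    occlude_track(simulate_track(behavior_params("walking", seed = s)),
                  p, seed = s))
  vis <- unlist(lapply(lts, function(l)
    lapply(l$track$frames, function(f) !f$keypoints$visible)))
  n <- length(vis)
  expect_gte(n, 9000)
  expect_lt(abs(mean(vis) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("rendered fixtures are deterministic and hug the frame bbox", {
  f <- simulate_track(behavior_params("walking", seed = 2))$track$frames[[1]]
  img1 <- render_fixture(f)
  img2 <- render_fixture(f)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(480, 640, 3))
  nz <- which(img1[, , 1] > 0, arr.ind = TRUE)
  tol <- f$params
  # tight hull of drawn pixels vs declared bbox (margin 3 + line width 2)
  expect_lt(abs(min(nz[, 2]) - 1 - f$bbox["xmin"]), 6)
  expect_lt(abs(max(nz[, 2]) - 1 - f$bbox["xmax"]), 6)
  expect_lt(abs(min(nz[, 1]) - 1 - f$bbox["ymin"]), 6)
  expect_lt(abs(max(nz[, 1]) - 1 - f$bbox["ymax"]), 6)

  # fully occluded pose draws nothing
  blank <- f
  blank$keypoints$visible <- FALSE
  expect_true(all(render_fixture(blank) == 0))
})
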