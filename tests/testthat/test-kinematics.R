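# Kinematic discriminants: A, V, theta, Omega and the per-track series.

test_that("aspect ratio follows height over width", {
  expect_equal(aspect_ratio(bbox(0, 0, 10, 10)), 1.0)
  expect_equal(aspect_ratio(bbox(0, 0, 40, 80)), 2.0)
  expect_equal(aspect_ratio(bbox(5, 5, 105, 30)), 0.25)
  expect_error(bbox(5, 0, 5, 10), "degenerate")
})

test_that("centroid descent speed is signed, positive downward", {
  expect_equal(centroid_descent_speed(100, 100, 0.25), 0)
  expect_equal(centroid_descent_speed(100, 190, 0.25), 360)
  expect_equal(centroid_descent_speed(200, 150, 0.5), -100)
  expect_error(centroid_descent_speed(0, 1, 0), "dt")
})

test_that("trunk angle matches closed forms and the atan2 oracle", {
  expect_equal(trunk_angle(c(1, 0)), 0)
  expect_equal(trunk_angle(c(0, 40)), 90)
  expect_equal(trunk_angle(c(1, 1)), 45)
  expect_error(trunk_angle(c(0, 0)), "zero")
  # brute-force oracle over a grid of directions and magnitudes
  for (phi in seq(-175, 180, by = 5)) {
    for (r in c(0.5, 7, 300)) {
      z <- r * c(cos(phi * pi / 180), sin(phi * pi / 180))
      expect_equal(trunk_angle(z), angle_oracle(z), tolerance = 1e-10)
    }
  }
})

test_that("angular rate is absolute change over time", {
  expect_equal(angular_rate(90, 90, 0.25), 0)
  expect_equal(angular_rate(90, 0, 0.5), 180)
  expect_equal(angular_rate(30, 75, 0.25), 180)
})

test_that("A and theta are scale-invariant while V scales linearly", {
  f <- test_frame()
  zv <- trunk_vectors(f)
  for (s in c(0.5, 2, 13)) {
    box <- f$bbox
    sbox <- bbox(s * box["xmin"], s * box["ymin"],
                 s * box["xmax"], s * box["ymax"])
    expect_equal(aspect_ratio(sbox), aspect_ratio(box))
    expect_equal(trunk_angle(s * zv$Z1), trunk_angle(zv$Z1))
    expect_equal(centroid_descent_speed(s * 100, s * 190, 0.25),
                 s * centroid_descent_speed(100, 190, 0.25))
  }
  # translation leaves A unchanged
  tbox <- bbox(f$bbox["xmin"] + 11, f$bbox["ymin"] - 7,
               f$bbox["xmax"] + 11, f$bbox["ymax"] - 7)
  expect_equal(aspect_ratio(tbox), aspect_ratio(f$bbox))
})

test_that("kinematics series reports stationary, dropping and single-frame tracks", {
  # constant pose: all V = 0, omega = 0
  const <- track_sequence(lapply(0:29, function(i)
    test_frame(frame_index = i, timestamp = i / 60)), 60)
  ks <- kinematics_series(const, dt = 0.25)
  expect_true(all(ks$V == 0))
  expect_true(all(ks$omega == 0))
  expect_false(any(ks$gap))

  # centroid dropping 90 px per 0.25 s -> V = 360 beyond the first window
  drop <- dropping_track(n = 60, per_frame = 6, fps = 60)
  ks <- kinematics_series(drop, dt = 0.25)
  expect_true(all(abs(ks$V[16:60] - 360) < 1e-9))
  expect_true(all(ks$V[1:15] == 0))

  # single frame
  one <- track_sequence(list(test_frame()), 60)
  ks1 <- kinematics_series(one)
  expect_equal(nrow(ks1), 1)
  expect_equal(ks1$V, 0)
  expect_equal(ks1$omega, 0)
})

test_that("frames with occluded torsos become flagged gaps", {
  frames <- lapply(0:29, function(i)
    test_frame(frame_index = i, timestamp = i / 60))
  frames[[10]]$keypoints$visible[
    frames[[10]]$keypoints$name == "left_hip"] <- FALSE
  ks <- kinematics_series(track_sequence(frames, 60))
  expect_true(ks$gap[10])
  expect_true(is.na(ks$V[10]))
  expect_equal(sum(ks$gap), 1)
})
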