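# Pose data model: derived landmarks and keypoint grouping.

frame_with <- function(edits) {
  f <- test_frame()
  for (nm in names(edits)) {
    i <- which(f$keypoints$name == nm)
    f$keypoints$x[i] <- edits[[nm]][1]
    f$keypoints$y[i] <- edits[[nm]][2]
    if (length(edits[[nm]]) > 2) f$keypoints$confidence[i] <- edits[[nm]][3]
  }
  f
}

test_that("neck is the shoulder midpoint with min confidence", {
  f <- frame_with(list(left_shoulder = c(10, 20), right_shoulder = c(30, 20)))
  n <- derive_neck(f)
  expect_equal(c(n$x, n$y), c(20, 20))

  f <- frame_with(list(left_shoulder = c(5, 5), right_shoulder = c(5, 5)))
  n <- derive_neck(f)
  expect_equal(c(n$x, n$y), c(5, 5))

  f <- frame_with(list(left_shoulder = c(0, 0, 0.9),
                       right_shoulder = c(4, 2, 0.3)))
  n <- derive_neck(f)
  expect_equal(c(n$x, n$y, n$confidence), c(2, 1, 0.3))
})

test_that("neck derivation fails when a shoulder is occluded", {
  f <- test_frame()
  f$keypoints$visible[f$keypoints$name == "left_shoulder"] <- FALSE
  expect_error(derive_neck(f), "shoulder")
})

test_that("centroid is the mean of the four torso keypoints", {
  f <- frame_with(list(left_shoulder = c(0, 0), right_shoulder = c(2, 0),
                       left_hip = c(0, 4), right_hip = c(2, 4)))
  ctr <- derive_centroid(f)
  expect_equal(c(ctr$x, ctr$y), c(1, 2))

  f <- frame_with(list(left_shoulder = c(7, 7), right_shoulder = c(7, 7),
                       left_hip = c(7, 7), right_hip = c(7, 7)))
  expect_equal(c(derive_centroid(f)$x, derive_centroid(f)$y), c(7, 7))

  f <- frame_with(list(left_shoulder = c(1, 1), right_shoulder = c(3, 1),
                       left_hip = c(1, 9), right_hip = c(5, 9)))
  ctr <- derive_centroid(f)
  expect_equal(c(ctr$x, ctr$y), c(2.5, 5))

  f$keypoints$visible[f$keypoints$name == "right_hip"] <- FALSE
  expect_error(derive_centroid(f), "torso")
})

test_that("ground projection drops the centroid onto the bbox bottom", {
  f <- test_frame()
  ctr <- derive_centroid(f)
  gp <- derive_ground_projection(f)
  expect_equal(gp$x, ctr$x)
  expect_equal(gp$y, unname(f$bbox["ymax"]))

  # explicit numbers: centroid (2.5, 5) in a (0,0,6,12) box -> (2.5, 12)
  f2 <- frame_with(list(left_shoulder = c(1, 1), right_shoulder = c(3, 1),
                        left_hip = c(1, 9), right_hip = c(5, 9)))
  f2$bbox <- bbox(0, 0, 6, 12)
  gp2 <- derive_ground_projection(f2)
  expect_equal(c(gp2$x, gp2$y), c(2.5, 12))
})

test_that("derived points are translation-equivariant and deterministic", {
  set.seed(42)
  for (k in 1:10) {
    dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
    f0 <- derive_points(test_frame())
    f1 <- derive_points(test_frame(dx = dx, dy = dy))
    expect_equal(f1$derived$x, f0$derived$x + dx)
    expect_equal(f1$derived$y, f0$derived$y + dy)
  }
  expect_identical(derive_points(test_frame())$derived,
                   derive_points(test_frame())$derived)
})

test_that("every grouping scheme partitions the 17 keypoints", {
  all_parts <- test_frame()$keypoints$name
  for (scheme in c("whole_body", "upper_lower", "head_arm_body_leg")) {
    g <- group_keypoints(scheme)
    members <- unlist(g, use.names = FALSE)
    expect_length(members, 17)
    expect_setequal(members, all_parts)
    expect_false(any(duplicated(members)))
  }
  expect_length(group_keypoints("whole_body"), 1)
  expect_length(group_keypoints("upper_lower"), 2)
  g4 <- group_keypoints("head_arm_body_leg")
  expect_named(g4, c("head", "arms", "body", "legs"))
  expect_setequal(g4$legs, c("left_knee", "right_knee",
                             "left_ankle", "right_ankle"))
  expect_error(group_keypoints("torso_only"), "unknown")
})

test_that("constructors validate their invariants", {
  expect_error(bbox(10, 0, 10, 5), "degenerate")
  expect_error(keypoint("nose", Inf, 0), "finite")
  expect_error(keypoint("nose", 0, 0, confidence = 1.2), "confidence")
  f <- test_frame()
  expect_error(pose_frame(0, 0, f$bbox, f$keypoints[-1, ]), "17")
})
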