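# Fall judgment rule engine: per-sample rule, latch, streaming judge.

test_that("per-sample rule matches the threshold conjunction on a 3^3 grid", {
  cfg <- fall_config()
  for (A in c(0.8, 2.0, 3.0)) {
    for (V in c(200, 340, 420)) {
      for (dTh in c(40, 70, 95)) {
        expected <- if (A < 1 && V > 350 && dTh > 75) "fall"
          else if (A > 1.5 && A < 2.5) "walking" else "lying"
        expect_identical(evaluate_sample(A, V, dTh, cfg), expected,
                         info = sprintf("A=%g V=%g dTheta=%g", A, V, dTh))
      }
    }
  }
})

test_that("spec-level examples of the sample rule hold", {
  cfg <- fall_config()
  expect_identical(evaluate_sample(2.0, 10, 3, cfg), "walking")
  expect_identical(evaluate_sample(0.8, 400, 85, cfg), "fall")
  expect_identical(evaluate_sample(0.8, 400, 60, cfg), "lying")
})

test_that("fall verdicts are monotone in V and dTheta", {
  cfg <- fall_config()
  set.seed(7)
  for (k in 1:200) {
    A <- runif(1, 0.2, 3.5)
    V <- runif(1, 0, 700)
    dTh <- runif(1, 0, 160)
    if (evaluate_sample(A, V, dTh, cfg) == "fall") {
      expect_identical(evaluate_sample(A, V + runif(1, 0, 300), dTh, cfg),
                       "fall")
      expect_identical(evaluate_sample(A, V, dTh + runif(1, 0, 90), cfg),
                       "fall")
    }
  }
})

test_that("simulated behaviours are classified correctly", {
  for (seed in 1:5) {
    expect_identical(
      judge_sequence(simulate_track(behavior_params("falling",
                                                    seed = seed))$track)$status,
      "fall")
    expect_identical(
      judge_sequence(simulate_track(behavior_params("lying",
                                                    seed = seed))$track)$status,
      "lying")
    expect_identical(
      judge_sequence(simulate_track(behavior_params("walking",
                                                    seed = seed))$track)$status,
      "walking")
  }
})

test_that("a latched fall persists and reports its frame", {
  lt <- simulate_track(behavior_params("falling", seed = 2))
  res <- judge_sequence(lt$track)
  expect_identical(res$status, "fall")
  expect_false(is.null(res$fall_frame))
  expect_gte(res$fall_frame, lt$event_frame)
  # stream cut immediately after the latch retains the fall
  sj <- stream_judge(fall_config(), fps = lt$track$fps)
  for (f in lt$track$frames) {
    sj$push(f)
    if (sj$state()$status == "fall") break
  }
  expect_identical(sj$finalize()$status, "fall")
  # pushing further frames cannot unset it
  sj2 <- stream_judge(fall_config(), fps = lt$track$fps)
  for (f in lt$track$frames) sj2$push(f)
  expect_identical(sj2$finalize()$status, "fall")
  expect_equal(sj2$finalize()$fall_frame, res$fall_frame)
})

test_that("online and batch judging agree on every simulated track", {
  for (behavior in c("walking", "lying", "falling")) {
    for (seed in 1:10) {
      lt <- simulate_track(behavior_params(behavior, seed = seed))
      batch <- judge_sequence(lt$track)
      sj <- stream_judge(fall_config(), fps = lt$track$fps)
      for (f in lt$track$frames) sj$push(f)
      online <- sj$finalize()
      expect_identical(online$status, batch$status)
      expect_equal(online$judgment_count, batch$judgment_count)
    }
  }
})

test_that("the inquiry hook fires only on falls, exactly once", {
  hits <- 0L
  hook <- function(st) hits <<- hits + 1L
  judge_sequence(simulate_track(behavior_params("walking", seed = 1))$track,
                 inquiry_hook = hook)
  judge_sequence(simulate_track(behavior_params("lying", seed = 1))$track,
                 inquiry_hook = hook)
  expect_equal(hits, 0L)
  judge_sequence(simulate_track(behavior_params("falling", seed = 1))$track,
                 inquiry_hook = hook)
  expect_equal(hits, 1L)
})

test_that("stream judge rejects disorder and empty input resolves unknown", {
  sj <- stream_judge(fall_config(), fps = 60)
  expect_identical(sj$finalize()$status, "unknown")
  sj$push(test_frame(frame_index = 5, timestamp = 5 / 60))
  expect_error(sj$push(test_frame(frame_index = 4, timestamp = 4 / 60)),
               "out-of-order")
  expect_error(judge_sequence(track_sequence(list(), 60)), "empty")
})

test_that("gap frames are skipped but counted", {
  lt <- simulate_track(behavior_params("walking", seed = 4,
                                       occlusion_prob = 0.35))
  res <- judge_sequence(lt$track)
  expect_gt(res$n_gaps, 0)
  expect_equal(res$n_frames, length(lt$track$frames))
})
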