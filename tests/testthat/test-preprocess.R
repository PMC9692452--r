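test_that("paa reproduces hand-computed segment means and fixed points", {
  expect_equal(paa(c(5, 5, 5, 5), 2), c(5, 5))
  expect_equal(paa(c(1, 2, 3, 4, 5, 6), 3), c(1.5, 3.5, 5.5))
  expect_equal(paa(c(1, 2, 3, 4), 4), c(1, 2, 3, 4))
  expect_error(paa(c(1, 2), 3), "N")
  expect_error(paa(numeric(0), 1), "empty")
})

test_that("paa preserves the global mean when n is divisible by N", {
  set.seed(11)
  for (rep in 1:20) {
    N <- sample(1:6, 1)
    n <- N * sample(1:5, 1)
    x <- stats::rnorm(n)
    expect_equal(mean(paa(x, N)), mean(x), tolerance = 1e-12)
    expect_equal(paa(x, 1), mean(x))
    expect_equal(paa(x, n), x)
  }
})

test_that("paa excludes nulls from means and propagates all-null segments", {
  expect_equal(paa(c(1, NA, 3, 4), 2), c(1, 3.5))
  expect_equal(paa(c(NA, NA, 3, 5), 2), c(NA, 4))
  # non-divisible split: half-open windows [0,2) [2,4) [4,5) -> 2, 2, 1
  expect_equal(paa(c(10, 1, 3, 6, 8), 3), c(5.5, 4.5, 8))
})

test_that("resampling a constant pose yields identical frames on the 20 Hz grid", {
  pf <- make_posture_frames(posture_spec(duration = 1))
  st <- new_stream_for_test(pf$body, 30, "body")
  out <- resample_stream(st, 20)
  expect_equal(nrow(out$frames), 20)
  expect_equal(diff(out$frames$timestamp), rep(0.05, 19), tolerance = 1e-9)
  expect_true(all(abs(out$frames$j08_x - pf$body$j08_x[1]) < 1e-9))
  expect_error(resample_stream(out, 30), "upsampling")
})

test_that("resampling a linear ramp gives window-midpoint means", {
  n <- 30
  fr <- data.frame(timestamp = (0:(n - 1)) / 30, v_x = 0:(n - 1),
                   v_y = 0, v_z = 0)
  st <- new_stream_for_test(fr, 30, "body")
  out <- resample_stream(st, 20)
  # windows of 1.5 samples alternate {1,2}-sample blocks; check exact means
  expect_equal(nrow(out$frames), 20)
  starts <- ceiling((0:19) * 30 / 20)
  ends <- ceiling((1:20) * 30 / 20) - 1
  expected <- (starts + ends) / 2
  expect_equal(out$frames$v_x, expected)
})

test_that("a 3.2 s hand stream at 64 Hz resamples to 64 frames", {
  pf <- make_posture_frames(posture_spec(duration = 3.2), hand_rate = 64)
  st <- new_stream_for_test(pf$hand, 64, "hand")
  out <- resample_stream(st, 20)
  expect_equal(nrow(out$frames), 64)
})

test_that("fusion joins by nearest grid timestamp within half a step", {
  pf <- make_posture_frames(posture_spec(duration = 1))
  b <- resample_stream(new_stream_for_test(pf$body, 30, "body"), 20)
  h <- resample_stream(new_stream_for_test(pf$hand, 64, "hand"), 20)
  fused <- fuse(b, h, NULL, 20)
  expect_equal(nrow(fused), 20)
  # a 10 ms sensor offset still joins 1:1 (offset < 25 ms)
  h2 <- h; h2$frames$timestamp <- h2$frames$timestamp + 0.010
  expect_equal(nrow(fuse(b, h2, NULL, 20)), 20)
  # hand covering only the first half restricts fusion to the overlap
  h3 <- h; h3$frames <- h3$frames[1:10, ]
  f3 <- fuse(b, h3, NULL, 20)
  expect_equal(nrow(f3), 10)
  expect_equal(unname(attr(f3, "dropped")["body"]), 10)
  h4 <- h; h4$frames$timestamp <- h4$frames$timestamp + 100
  expect_error(fuse(b, h4, NULL, 20), "disjoint")
})

test_that("labels attach by interval containment", {
  pf <- make_posture_frames(posture_spec(duration = 1))
  b <- resample_stream(new_stream_for_test(pf$body, 30, "body"), 20)
  h <- resample_stream(new_stream_for_test(pf$hand, 64, "hand"), 20)
  labels <- data.frame(timestamp = c(0, 0.5),
                       high = c("assemble side panel", "integrate panel"),
                       middle = "m", low = c("grasp", "assemble"))
  fused <- fuse(b, h, labels, 20)
  expect_equal(sum(fused$high == "assemble side panel"), 10)
  expect_equal(sum(fused$high == "integrate panel"), 10)
})

test_that("null-row removal is driven by the scoring joint registry", {
  pf <- make_posture_frames(posture_spec(duration = 1))
  b <- resample_stream(new_stream_for_test(pf$body, 30, "body"), 20)
  h <- resample_stream(new_stream_for_test(pf$hand, 64, "hand"), 20)
  fused <- fuse(b, h, NULL, 20)
  expect_equal(nrow(drop_null_rows(fused)), 20)
  # joint 07 (right shoulder) is referenced: frame dropped
  f2 <- fused
  f2[3, c("j07_x", "j07_y", "j07_z")] <- NA
  expect_equal(nrow(drop_null_rows(f2)), 19)
  expect_equal(attr(drop_null_rows(f2), "removed"), 1)
  # joint 15 (right foot) is not referenced by any formula: frame kept
  f3 <- fused
  f3[3, c("j15_x", "j15_y", "j15_z")] <- NA
  expect_equal(nrow(drop_null_rows(f3)), 20)
  # unused finger joint: kept; scoring finger joint: dropped
  f4 <- fused
  f4[5, c("R07_x", "R07_y", "R07_z")] <- NA
  expect_equal(nrow(drop_null_rows(f4)), 20)
  f5 <- fused
  f5[5, c("R13_x", "R13_y", "R13_z")] <- NA
  expect_equal(nrow(drop_null_rows(f5)), 19)
})

test_that("the resample-fuse-drop pipeline never fabricates frames", {
  set.seed(3)
  for (dur in c(0.5, 1.3)) {
    pf <- make_posture_frames(posture_spec(duration = dur, null_rate = 0.05))
    b <- resample_stream(new_stream_for_test(pf$body, 30, "body"), 20)
    h <- resample_stream(new_stream_for_test(pf$hand, 64, "hand"), 20)
    out <- drop_null_rows(fuse(b, h, NULL, 20))
    expect_lte(nrow(out), min(nrow(b$frames), nrow(h$frames)))
  }
})
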