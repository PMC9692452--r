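test_that("upper-arm bands recover across generated fixtures", {
  cases <- list(list(t = 0, s = 1L), list(t = 10, s = 1L),
                list(t = -30, s = 2L), list(t = 30, s = 2L),
                list(t = 60, s = 3L), list(t = 120, s = 4L))
  for (cs in cases) {
    fr <- posture_frame(upper_arm = cs$t, neck_side_bend = NA)
    sc <- upper_arm_score(fr, "right")
    expect_equal(sc$angles$position, cs$t, tolerance = 1e-6)
    expect_equal(sc$base, cs$s)
    expect_equal(sc$score, cs$s)  # raise/abduction inactive by default
    scl <- upper_arm_score(fr, "left")
    expect_equal(scl$score, cs$s)
  }
})

test_that("shoulder raise and abduction add their increments and cap at 6", {
  fr <- posture_frame(upper_arm = 30, shoulder_raise = 95,
                      neck_side_bend = NA)
  sc <- upper_arm_score(fr, "right")
  expect_equal(sc$components$shoulder_raised, 1L)
  expect_equal(sc$score, 3L)  # base 2 + raise
  fr2 <- posture_frame(upper_arm = 40, abduction = 30, neck_side_bend = NA)
  sc2 <- upper_arm_score(fr2, "right")
  expect_equal(sc2$angles$abduction, 30, tolerance = 1e-6)
  expect_equal(sc2$components$abducted, 1L)
  expect_equal(sc2$score, 3L)  # base 2 + abducted
  fr3 <- posture_frame(upper_arm = 120, shoulder_raise = 95, abduction = 35,
                       neck_side_bend = NA)
  sc3 <- upper_arm_score(fr3, "right")
  expect_equal(sc3$score, 6L)  # 4 + 1 + 1, at the cap
})

test_that("lower-arm bands and adjustments follow the printed criteria", {
  for (cs in list(list(t = 80, s = 1L), list(t = 65, s = 1L),
                  list(t = 30, s = 2L), list(t = 120, s = 2L))) {
    fr <- posture_frame(lower_arm = cs$t)
    sc <- lower_arm_score(fr, "right")
    expect_equal(sc$angles$position, cs$t, tolerance = 1e-6)
    expect_equal(sc$base, cs$s)
  }
  # with the arm explicitly clear of the midline the score equals the base
  fr <- posture_frame(lower_arm = 80, across_midline = 60)
  expect_equal(lower_arm_score(fr, "right")$score, 1L)
  # across the midline: chain angle through the torso above 90
  fr <- posture_frame(lower_arm = 80, across_midline = 100)
  sc <- lower_arm_score(fr, "right")
  expect_equal(sc$components$across_midline, 1L)
  expect_equal(sc$score, 2L)
  # out to the side: the printed formula reuses the upper-arm angle (> 30)
  fr2 <- posture_frame(upper_arm = 40, lower_arm = 80, across_midline = NA)
  sc2 <- lower_arm_score(fr2, "right")
  expect_equal(sc2$components$out_to_side, 1L)
})

test_that("neck bands include the extension branch and side-bend increment", {
  for (cs in list(list(t = 5, s = 1L), list(t = 15, s = 2L),
                  list(t = 30, s = 3L), list(t = -10, s = 4L))) {
    fr <- posture_frame(neck = cs$t, neck_side_bend = NA, trunk = NA)
    sc <- neck_score(fr)
    expect_equal(sc$angles$position, cs$t, tolerance = 1e-6)
    expect_equal(sc$score, cs$s)
  }
  fr <- posture_frame(neck = 25, neck_side_bend = 24, trunk = NA)
  sc <- neck_score(fr)
  expect_equal(sc$angles$side_bending, 24, tolerance = 1e-6)
  expect_equal(sc$score, 4L)  # base 3 + side bend
})

test_that("trunk bands, neutral band and side-bend increment", {
  for (cs in list(list(t = 0, s = 1L), list(t = 10, s = 2L),
                  list(t = 40, s = 3L), list(t = 70, s = 4L))) {
    fr <- posture_frame(trunk = cs$t)
    sc <- trunk_score(fr)
    expect_equal(sc$angles$position, cs$t, tolerance = 1e-5)
    expect_equal(sc$score, cs$s)
  }
  fr <- posture_frame(trunk = 40, trunk_side_bend = 25)
  sc <- trunk_score(fr)
  expect_equal(sc$angles$side_bending, 25, tolerance = 1e-6)
  expect_equal(sc$score, 4L)  # base 3 + side bend
})

test_that("legs score is the protocol constant", {
  expect_equal(legs_score(TRUE)$score, 2L)
  expect_equal(legs_score(FALSE)$score, 1L)
})

test_that("segment scores stay in their RULA codomains on random valid poses", {
  set.seed(9)
  for (rep in 1:25) {
    fr <- posture_frame(
      upper_arm = stats::runif(1, -40, 130),
      lower_arm = stats::runif(1, 10, 150),
      neck = stats::runif(1, -20, 40), neck_side_bend = NA,
      trunk = NA,
      wrist_fe = stats::runif(1, -40, 40),
      wrist_ru = stats::runif(1, 0, 30),
      wrist_ps = NA,
      across_midline = NA)
    expect_true(upper_arm_score(fr, "right")$score %in% 1:6)
    expect_true(upper_arm_score(fr, "left")$score %in% 1:6)
    expect_true(lower_arm_score(fr, "right")$score %in% 1:3)
    expect_true(neck_score(fr)$score %in% 1:6)
    expect_true(trunk_score(fr)$score %in% 1:6)
  }
})

test_that("missing scoring joints make a segment unscorable, not an error", {
  fr <- posture_frame()
  fr[, c("j08_x", "j08_y", "j08_z")] <- NA
  expect_true(is.na(upper_arm_score(fr, "right")$score))
  expect_false(is.na(upper_arm_score(fr, "left")$score))
  fr2 <- posture_frame()
  fr2[, c("j01_x", "j01_y", "j01_z")] <- NA
  expect_true(is.na(neck_score(fr2)$score))
  expect_true(is.na(trunk_score(fr2)$score))
})
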