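test_that("calibration uses the first valid frame and names a missing side", {
  pf <- make_posture_frames(posture_spec(duration = 0.1), hand_rate = 64)
  hf <- pf$hand
  cal <- calibrate(hf)
  expect_equal(cal$right$frame, 1L)
  expect_equal(cal$left$frame, 1L)
  expect_equal(cal$right$neutral_ru, 90, tolerance = 1e-9)
  # dropout of R24 in frame 1 pushes the right side to frame 2
  hf2 <- hf
  hf2[1, c("R24_x", "R24_y", "R24_z")] <- NA
  cal2 <- calibrate(hf2)
  expect_equal(cal2$right$frame, 2L)
  expect_equal(cal2$left$frame, 1L)
  # left hand missing everywhere
  hf3 <- hf
  hf3[, grep("^L", names(hf3))] <- NA
  expect_error(calibrate(hf3), "left")
  # forced frame policy
  cal4 <- calibrate(hf, policy = "frame:3")
  expect_equal(cal4$right$frame, 3L)
})

test_that("flexion-extension matches the literal two-point formula", {
  fr <- frame_from_joints(right = list("13" = c(0, 1, 1), "14" = c(0, 1, 0),
                                       "04" = c(1, 1, 0), "24" = c(-1, 1, 0),
                                       "05" = c(1, 2, 0), "00" = c(0, 0, 0)))
  expect_equal(flexion_extension(fr, "right"), 45, tolerance = 1e-9)
  # collinear position vectors read 0
  fr0 <- frame_from_joints(right = list("13" = c(0, 2, 0), "14" = c(0, 1, 0),
                                        "04" = c(1, 1, 0), "24" = c(-1, 1, 0),
                                        "05" = c(1, 2, 0), "00" = c(0, 0, 0)))
  expect_equal(flexion_extension(fr0, "right"), 0, tolerance = 1e-9)
  # recentered mode: straight chain through the wrist reference reads 0
  frc <- frame_from_joints(right = list("13" = c(5, 3, 0), "14" = c(5, 2, 0),
                                        "04" = c(6, 1, 0), "24" = c(4, 1, 0),
                                        "05" = c(6, 2, 0), "00" = c(5, 1, 0)))
  cfg <- rula_config(wrist = list(mode = "recentered"))
  expect_equal(flexion_extension(frc, "right", config = cfg), 0,
               tolerance = 1e-9)
  # missing joint makes the frame unscorable, not an error
  frm <- fr
  frm[, c("R13_x", "R13_y", "R13_z")] <- NA
  expect_true(is.na(flexion_extension(frm, "right")))
})

test_that("signed flexion-extension and deviation recover generator targets", {
  cal <- neutral_cal()
  for (fe in c(-25, -8, 0, 8, 25)) {
    fr <- posture_frame(wrist_fe = fe)
    expect_equal(flexion_extension(fr, "right", cal), fe, tolerance = 1e-6)
    expect_equal(flexion_extension(fr, "left", cal), fe, tolerance = 1e-6)
  }
  for (ru in c(0, 5, 20)) {
    fr <- posture_frame(wrist_ru = ru)
    expect_equal(radial_ulnar(fr, "right", cal), ru, tolerance = 1e-6)
  }
})

test_that("pronation-supination recovers known rotations and folds at 180", {
  cal <- neutral_cal()
  for (ps in c(0, 45, 90, 130, 165)) {
    fr <- posture_frame(wrist_ps = ps)
    expect_equal(pronation_supination(fr, cal, "right"), ps,
                 tolerance = 1e-6)
  }
  # a 200-degree physical rotation folds to 160 through the arccos range:
  # rotate the neutral right hand rigidly about the forearm axis
  pf <- make_posture_frames(posture_spec())
  h <- pf$joints$hands$right
  R <- rotation_matrix(c(0, 1, 0), 200)
  rot <- lapply(h, function(p) as.vector(R %*% p))
  fr <- frame_from_joints(right = rot)
  expect_equal(pronation_supination(fr, cal, "right"), 160,
               tolerance = 1e-6)
})

test_that("wrist angles are invariant to rigid translation; twist to shared rotation", {
  cal <- neutral_cal()
  fr <- posture_frame(wrist_fe = 12, wrist_ru = 10, wrist_ps = 40)
  pf <- make_posture_frames(posture_spec(wrist_fe = 12, wrist_ru = 10,
                                         wrist_ps = 40))
  h <- pf$joints$hands$right
  shift <- c(31, -12, 7)
  fr_t <- frame_from_joints(right = lapply(h, function(p) p + shift))
  expect_equal(radial_ulnar(fr_t, "right", cal),
               radial_ulnar(fr, "right", cal), tolerance = 1e-9)
  expect_equal(pronation_supination(fr_t, cal, "right"),
               pronation_supination(fr, cal, "right"), tolerance = 1e-9)
  # a rotation applied to BOTH calibration and current hand cancels in ps
  R <- random_rotation()
  hn <- make_posture_frames(posture_spec())$joints$hands$right
  rot <- function(js) lapply(js, function(p) as.vector(R %*% p))
  cal_r <- calibrate(frame_from_joints(right = rot(hn),
                                       left = make_posture_frames(posture_spec())$joints$hands$left))
  fr_r <- frame_from_joints(right = rot(h))
  expect_equal(pronation_supination(fr_r, cal_r, "right"),
               pronation_supination(fr, cal, "right"), tolerance = 1e-6)
})

test_that("wrist position score follows the printed bands with the bend adjustment", {
  expect_equal(wrist_position_score(0, 0), 1L)
  expect_equal(wrist_position_score(10, 0), 2L)
  expect_equal(wrist_position_score(-10, 0), 2L)
  expect_equal(wrist_position_score(25, 0), 3L)
  expect_equal(wrist_position_score(-25, 0), 3L)
  expect_equal(wrist_position_score(25, 20), 4L)
  expect_equal(wrist_position_score(0, 20), 2L)
  expect_equal(wrist_position_score(25, 14.9), 3L)
  expect_equal(wrist_position_score(25, 15), 4L)  # "15 degrees or more"
  # cap at 4 and monotonicity in both arguments
  expect_equal(wrist_position_score(90, 90), 4L)
  fes <- c(0, 5, 14, 16, 40); rus <- c(0, 10, 15, 30)
  for (i in seq_along(fes)[-1]) for (j in seq_along(rus)[-1]) {
    expect_gte(wrist_position_score(fes[i], rus[j]),
               wrist_position_score(fes[i - 1], rus[j]))
    expect_gte(wrist_position_score(fes[i], rus[j]),
               wrist_position_score(fes[i], rus[j - 1]))
  }
})

test_that("wrist twist score is a single step at 105 degrees", {
  expect_equal(wrist_twist_score(0), 1L)
  expect_equal(wrist_twist_score(90), 1L)
  expect_equal(wrist_twist_score(105), 1L)
  expect_equal(wrist_twist_score(105.001), 2L)
  expect_equal(wrist_twist_score(130), 2L)
  expect_equal(wrist_twist_score(170), 2L)
  expect_error(wrist_twist_score(200), "0, 180")
})
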