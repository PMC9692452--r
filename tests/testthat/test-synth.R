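test_that("the same seed reproduces bit-identical streams", {
  sp <- posture_spec(duration = 0.5, jitter_sd = 1, null_rate = 0.05)
  a <- make_posture_frames(sp, seed = 99)
  b <- make_posture_frames(sp, seed = 99)
  expect_identical(a$body, b$body)
  expect_identical(a$hand, b$hand)
  c_ <- make_posture_frames(sp, seed = 100)
  expect_false(identical(a$body, c_$body))
})

test_that("frame counts follow rate times duration", {
  pf <- make_posture_frames(posture_spec(duration = 10))
  expect_equal(nrow(pf$body), 300)
  expect_equal(nrow(pf$hand), 640)
  pf2 <- make_posture_frames(posture_spec(duration = 2),
                             body_rate = 15, hand_rate = 32)
  expect_equal(nrow(pf2$body), 30)
  expect_equal(nrow(pf2$hand), 64)
})

test_that("the neutral pose realises every default target to 1e-6 degrees", {
  pf <- make_posture_frames(posture_spec())
  tr <- pf$truth
  expect_equal(tr$upper_arm_right, 10, tolerance = 1e-6)
  expect_equal(tr$lower_arm_left, 70, tolerance = 1e-6)
  expect_equal(tr$shoulder_raise_right, 90, tolerance = 1e-6)
  expect_equal(tr$neck, 5, tolerance = 1e-6)
  expect_equal(tr$neck_side_bend, 0, tolerance = 1e-6)
  expect_equal(tr$trunk, 0, tolerance = 1e-6)
  expect_equal(tr$trunk_side_bend, 0, tolerance = 1e-6)
  expect_equal(tr$wrist_fe_right, 0, tolerance = 1e-6)
  expect_equal(tr$wrist_ru_right, 0, tolerance = 1e-6)
  expect_equal(tr$wrist_ps_right, 0, tolerance = 1e-6)
})

test_that("conflicting or degenerate targets raise feasibility errors", {
  expect_error(make_posture_frames(posture_spec(upper_arm = 0, abduction = 40)),
               "feasibility")
  expect_error(make_posture_frames(posture_spec(upper_arm = 10,
                                                abduction = 60)),
               "feasibility")
  sp <- posture_spec()
  sp$trunk_twist <- 25
  expect_error(make_posture_frames(sp), "trunk-twist")
  expect_error(make_posture_frames(posture_spec(neck = 0,
                                                neck_side_bend = 10)),
               "side bend")
})

test_that("the empirical dropout fraction matches the requested null rate", {
  rate <- 0.05
  pf <- make_posture_frames(posture_spec(duration = 6, null_rate = rate),
                            seed = 17)
  cols <- grep("_x$", names(pf$body), value = TRUE)
  frac <- mean(is.na(as.matrix(pf$body[, cols])))
  n <- nrow(pf$body) * length(cols)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(frac - rate), 3 * se)
})

test_that("jitter perturbs angles but preserves limb lengths", {
  pf <- make_posture_frames(posture_spec(duration = 0.2, jitter_sd = 2),
                            seed = 4)
  clean <- make_posture_frames(posture_spec(duration = 0.2))
  # limb length shoulder-elbow is invariant under the rotational jitter
  len <- function(df, i) sqrt((df$j08_x[i] - df$j07_x[i])^2 +
                                (df$j08_y[i] - df$j07_y[i])^2 +
                                (df$j08_z[i] - df$j07_z[i])^2)
  ref <- len(clean$body, 1)
  for (i in seq_len(nrow(pf$body)))
    expect_equal(len(pf$body, i), ref, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(pf$body$j08_x, clean$body$j08_x)))
})

test_that("sessions write all four CSVs with labelled strata", {
  dir <- withr::local_tempdir()
  segs <- lapply(activity_levels(), function(a)
    list(posture = posture_spec(duration = 0.25), high = a, low = "grasp"))
  paths <- make_session(session_spec(segs, calibration_lead = 0),
                        dir, seed = 2)
  expect_true(all(file.exists(unlist(paths[c("body", "hand", "labels",
                                             "truth")]))))
  labs <- read_labels(paths$labels)
  expect_equal(nrow(labs), 5)
  expect_setequal(labs$high, activity_levels())
  truth <- utils::read.csv(paths$truth)
  expect_equal(nrow(truth), 5 * 0.25 * 20)
  expect_true(all(c("grand_general", "upper_arm_right", "wrist_fe_right")
                  %in% names(truth)))
})

test_that("expert files respect stride and the perturbation domains", {
  sc <- data.frame(timestamp = (1:100 - 0.5) / 20,
                   upper_arm_right = 1L, upper_arm_left = 1L,
                   lower_arm_right = 1L, lower_arm_left = 1L,
                   wrist_position_right = 1L, wrist_position_left = 1L,
                   wrist_twist_right = 1L, wrist_twist_left = 1L,
                   neck = 1L, trunk = 1L, legs = 2L,
                   A_right = 1L, A_left = 1L, A_max = 1L, B = 3L,
                   grand_right = 3L, grand_left = 3L, grand_general = 3L)
  p <- withr::local_tempfile(fileext = ".csv")
  make_expert_file(sc, p, stride = 10, disagreement_rate = 0)
  ex <- read_expert_file(p)
  expect_equal(length(unique(ex$timestamp)), 10)
  expect_equal(ex$score[ex$segment == "legs"], rep(2L, 10))
  # full disagreement still stays inside each score's domain
  make_expert_file(sc, p, stride = 5, disagreement_rate = 1, seed = 3)
  ex2 <- read_expert_file(p)
  wt <- ex2$score[ex2$segment == "wrist_twist"]
  expect_true(all(wt %in% 1:2))
  ua <- ex2$score[ex2$segment == "upper_arm"]
  expect_true(all(ua %in% 1:6))
  expect_true(any(ex2$score != 1L))
})

test_that("band recovery: generated fixtures score their intended band", {
  # all printed base bands of the wrist and body tables, mid-band targets
  cal <- neutral_cal()
  wrist_cases <- list(list(fe = 0, s = 1L), list(fe = 8, s = 2L),
                      list(fe = -8, s = 2L), list(fe = 25, s = 3L),
                      list(fe = -25, s = 3L))
  for (cs in wrist_cases) {
    fr <- posture_frame(wrist_fe = cs$fe)
    w <- wrist_assess(fr, "right", cal)
    expect_equal(w$position_score, cs$s)
  }
  twist_cases <- list(list(ps = 20, s = 1L), list(ps = 90, s = 1L),
                      list(ps = 130, s = 2L), list(ps = 170, s = 2L))
  for (cs in twist_cases) {
    fr <- posture_frame(wrist_ps = cs$ps)
    expect_equal(wrist_assess(fr, "right", cal)$twist_score, cs$s)
  }
})
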