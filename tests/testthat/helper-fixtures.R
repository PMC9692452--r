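# Shared fixture builders: everything is generated in code at test time.

# a wide frame row from body + hand joint lists
frame_from_joints <- function(body = NULL, left = NULL, right = NULL,
                              timestamp = 0) {
  vals <- list(timestamp = timestamp)
  add <- function(joints, pre) {
    for (nm in names(joints)) {
      p <- joints[[nm]]
      vals[[paste0(pre, nm, "_x")]] <<- p[1]
      vals[[paste0(pre, nm, "_y")]] <<- p[2]
      vals[[paste0(pre, nm, "_z")]] <<- p[3]
    }
  }
  if (!is.null(body)) add(body, "j")
  if (!is.null(left)) add(left, "L")
  if (!is.null(right)) add(right, "R")
  as.data.frame(vals)
}

# clean single-posture frame (body + both hands) realising the given targets
posture_frame <- function(...) {
  pf <- make_posture_frames(posture_spec(...))
  frame_from_joints(pf$joints$body, pf$joints$hands$left,
                    pf$joints$hands$right)
}

# calibration taken from the neutral template hands
neutral_cal <- function() {
  pf <- make_posture_frames(posture_spec())
  hf <- frame_from_joints(left = pf$joints$hands$left,
                          right = pf$joints$hands$right)
  calibrate(hf)
}

# write a small body-stream CSV with n frames of a constant neutral pose
write_body_csv <- function(path, n = 3, rate = 30) {
  pf <- make_posture_frames(posture_spec(duration = n / rate),
                            body_rate = rate)
  utils::write.csv(pf$body, path, row.names = FALSE, na = "")
  invisible(pf$body)
}

write_hand_csv <- function(path, n = 64, rate = 64) {
  pf <- make_posture_frames(posture_spec(duration = n / rate),
                            hand_rate = rate)
  utils::write.csv(pf$hand, path, row.names = FALSE, na = "")
  invisible(pf$hand)
}

# in-memory stream container without a round trip through disk
new_stream_for_test <- function(frames, rate, kind) {
  ergorula:::new_stream(frames, rate, kind)
}

# independent brute-force angle between two vectors (no shared code path)
bf_angle <- function(a, b) {
  cross <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
  atan2(sqrt(sum(cross^2)), sum(a * b)) * 180 / pi
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_matrix(ax, stats::runif(1, 0, 360))
}
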