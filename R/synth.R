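#' @title Synthetic skeleton fixtures with known ground-truth angles
#' @name synth-fixtures
#' @description
#' Generates body- and hand-tracking streams whose joints are placed by
#' forward construction so that every targeted scoring formula evaluates
#' to its target angle exactly (to 1e-6 degrees) before noise. The
#' canonical skeleton is a stick figure with fixed limb lengths; since all
#' scoring is angle-based, the lengths are arbitrary constants. Angular
#' jitter is applied as small random rotations of each joint about its
#' parent (preserving limb lengths), dropouts as per-joint Bernoulli
#' nulls, and the two streams are sampled at the body- and hand-sensor
#' rates (30 and 64 Hz by default).
NULL

.unit <- function(v) v / sqrt(sum(v * v))
.deg <- 180 / pi

# canonical body template: subject frame x = right, y = anterior, z = up.
# Hips sit level with the waist so that the lateral trunk measures read
# exactly 0 in the neutral stance.
body_template <- function() {
  list("01" = c(0, 0, 1610), "02" = c(0, 0, 1450), "03" = c(0, 0, 1200),
       "04" = c(0, 0, 1000), "05" = c(90, 0, 1000), "06" = c(-90, 0, 1000),
       "07" = c(180, 0, 1420), "08" = c(185, 10, 1150),
       "09" = c(190, 20, 910), "10" = c(-180, 0, 1420),
       "11" = c(-185, 10, 1150), "12" = c(-190, 20, 910),
       "13" = c(90, 0, 520), "14" = c(-90, 0, 520),
       "15" = c(90, 40, 40), "16" = c(-90, 40, 40))
}

#' Posture specification for the fixture generator
#'
#' Target angles for every scoring formula; `NA` leaves a measure free
#' (the generator picks a natural pose and records the achieved value as
#' ground truth). Angles in degrees; `upper_arm` and `neck` are signed
#' (positive = anterior). The neutral defaults describe a relaxed
#' standing pose: arms hanging about 10 degrees off the trunk with a
#' softly flexed elbow, head 5 degrees forward, upright trunk, wrists in
#' the neutral handshake position. The free (`NA`) defaults for
#' abduction, across-midline and pronation-supination let the generator
#' pick the natural value (for the across-midline angle, the azimuth that
#' keeps the forearm clearest of the midline) and record it as truth.
#'
#' @param upper_arm,lower_arm,shoulder_raise,abduction,across_midline
#'   per-side targets; scalars are recycled to both sides, or give
#'   `c(right = , left = )`.
#' @param neck,neck_side_bend,trunk,trunk_side_bend central targets.
#' @param wrist_fe,wrist_ru,wrist_ps per-side wrist targets
#'   (flexion-extension signed, radial-ulnar deviation >= 0,
#'   pronation-supination in [0, 180] or NA for free).
#' @param duration segment duration in seconds.
#' @param jitter_sd angular jitter standard deviation in degrees.
#' @param null_rate per-joint per-frame dropout probability in [0, 1).
#' @return a list of class `posture_spec`.
#' @export
posture_spec <- function(upper_arm = 10, lower_arm = 70,
                         shoulder_raise = 90, abduction = NA,
                         across_midline = NA,
                         neck = 5, neck_side_bend = 0,
                         trunk = 0, trunk_side_bend = 0,
                         wrist_fe = 0, wrist_ru = 0, wrist_ps = NA,
                         duration = 1, jitter_sd = 0, null_rate = 0) {
  two <- function(x) {
    if (length(x) == 1L) c(right = unname(x), left = unname(x))
    else c(right = unname(x[["right"]]), left = unname(x[["left"]]))
  }
  stopifnot(duration > 0, jitter_sd >= 0, null_rate >= 0, null_rate < 1)
  ru <- two(wrist_ru)
  if (any(!is.na(ru) & ru < 0))
    stop("posture_spec: wrist_ru must be >= 0", call. = FALSE)
  structure(list(upper_arm = two(upper_arm), lower_arm = two(lower_arm),
                 shoulder_raise = two(shoulder_raise),
                 abduction = two(abduction),
                 across_midline = two(across_midline),
                 neck = neck, neck_side_bend = neck_side_bend,
                 trunk = trunk, trunk_side_bend = trunk_side_bend,
                 trunk_twist = 0,
                 wrist_fe = two(wrist_fe), wrist_ru = ru,
                 wrist_ps = two(wrist_ps),
                 duration = duration, jitter_sd = jitter_sd,
                 null_rate = null_rate),
            class = "posture_spec")
}

# bracket a root of f on a grid and polish with uniroot; targets at the
# boundary of the achievable set (tangencies, e.g. an unsigned angle
# hitting 0) are recovered by minimising |f|
.solve_angle <- function(f, lo, hi, what, grid = 121L) {
  xs <- seq(lo, hi, length.out = grid)
  ys <- vapply(xs, f, numeric(1))
  k <- which(ys[-1] * ys[-grid] <= 0)
  if (length(k))
    return(stats::uniroot(f, c(xs[k[1]], xs[k[1] + 1L]), tol = 1e-12)$root)
  j <- which.min(abs(ys))
  span <- c(xs[max(1L, j - 1L)], xs[min(grid, j + 1L)])
  op <- stats::optimize(function(x) abs(f(x)), span, tol = 1e-14)
  if (abs(op$objective) < 1e-7) return(op$minimum)
  stop("feasibility error: cannot realise target for ", what,
       " (achievable values stay ", round(min(abs(ys)), 3), "..",
       round(max(abs(ys)), 3), " degrees away from the target)",
       call. = FALSE)
}

# place the head on a cone of half-angle |neck| about the up-trunk axis,
# solving the azimuth for the side-bend target
.place_head <- function(neck02, waist, shoulder_l, neck, side_bend,
                        anterior, head_len = 160) {
  u <- .unit(neck02 - waist)
  if (abs(neck) < 1e-12) {
    if (!is.na(side_bend) && abs(side_bend) > 1e-9)
      stop("feasibility error: cannot realise target for neck side bend ",
           "with a zero neck angle", call. = FALSE)
    return(neck02 + head_len * u)
  }
  ea <- anterior - sum(anterior * u) * u
  if (sqrt(sum(ea^2)) < 1e-9)
    stop("feasibility error: anterior axis parallel to trunk", call. = FALSE)
  ea <- .unit(ea)
  el <- c(u[2] * ea[3] - u[3] * ea[2], u[3] * ea[1] - u[1] * ea[3],
          u[1] * ea[2] - u[2] * ea[1])
  nu <- abs(neck) * pi / 180
  sgn <- if (neck >= 0) 1 else -1
  head_at <- function(psi) {
    h <- cos(nu) * u + sin(nu) * (cos(psi) * sgn * ea + sin(psi) * el)
    neck02 + head_len * h
  }
  if (is.na(side_bend)) return(head_at(0))
  f <- function(psi) {
    h01 <- head_at(psi)
    (90 - three_point_angle(shoulder_l, neck02, h01)) - side_bend
  }
  psi <- .solve_angle(f, -pi / 2 + 1e-6, pi / 2 - 1e-6, "neck side bend")
  head_at(psi)
}

# one arm: elbow on the (upper-arm angle, abduction) cone intersection,
# wrist on the elbow-flexion cone with azimuth solved for across-midline
.place_arm <- function(joints, side, targets, anterior) {
  sh <- if (side == "right") joints[["07"]] else joints[["10"]]
  hip <- if (side == "right") joints[["05"]] else joints[["06"]]
  nk <- joints[["02"]]
  th <- targets$upper_arm[[side]]
  ab <- targets$abduction[[side]]
  e1 <- .unit(hip - sh)
  w <- .unit(sh - nk)
  fperp <- w - sum(w * e1) * e1
  e2 <- .unit(fperp)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  if (sum(e3 * anterior) < 0) e3 <- -e3
  tha <- abs(th) * pi / 180
  if (tha < 1e-12) {
    d <- e1
    if (!is.na(ab)) {
      ach <- abs(vector_angle(d, w) - 90)
      if (abs(ach - ab) > 1e-6)
        stop("feasibility error: cannot realise target for abduction with ",
             "a zero upper-arm angle (conflicting targets)", call. = FALSE)
    }
  } else if (is.na(ab)) {
    sphi <- if (th >= 0) 1 else -1
    d <- cos(tha) * e1 + sin(tha) * sphi * e3
  } else {
    c1 <- sum(w * e1); c2 <- sqrt(sum(fperp^2))
    cands <- c()
    for (tgt in c(90 - ab, 90 + ab)) {
      cphi <- (cos(tgt * pi / 180) - cos(tha) * c1) / (sin(tha) * c2)
      if (abs(cphi) <= 1) cands <- c(cands, cphi)
    }
    if (!length(cands))
      stop("feasibility error: cannot realise target for abduction ",
           ab, " at upper-arm angle ", th, " (conflicting targets)",
           call. = FALSE)
    cphi <- cands[1]
    sphi <- sqrt(max(0, 1 - cphi^2)) * (if (th >= 0) 1 else -1)
    d <- cos(tha) * e1 + sin(tha) * (cphi * e2 + sphi * e3)
  }
  elbow <- sh + 280 * d
  # forearm cone about the upper-arm axis: flexion fixed, azimuth free
  fl <- targets$lower_arm[[side]] * pi / 180
  b1 <- d
  ref <- anterior
  if (abs(sum(ref * b1)) > 0.99) ref <- .unit(nk - sh)
  b2 <- .unit(ref - sum(ref * b1) * b1)
  b3 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  wrist_at <- function(zeta) {
    g <- cos(fl) * b1 + sin(fl) * (cos(zeta) * b2 + sin(zeta) * b3)
    elbow + 250 * g
  }
  am <- targets$across_midline[[side]]
  if (is.na(am)) {
    # free azimuth: keep the forearm clear of the midline where possible
    tor <- joints[["03"]]
    op <- stats::optimize(function(z) three_point_angle(sh, tor, wrist_at(z)),
                          c(-pi, pi), tol = 1e-10)
    wr <- wrist_at(op$minimum)
  } else {
    tor <- joints[["03"]]
    f <- function(z) three_point_angle(sh, tor, wrist_at(z)) - am
    zeta <- .solve_angle(f, -pi, pi, paste(side, "across-midline angle"))
    wr <- wrist_at(zeta)
  }
  if (side == "right") {
    joints[["08"]] <- elbow; joints[["09"]] <- wr
  } else {
    joints[["11"]] <- elbow; joints[["12"]] <- wr
  }
  joints
}

# full body pose realising the targets; exact to the uniroot tolerance
build_body_pose <- function(spec) {
  if (!is.null(spec$trunk_twist) && abs(spec$trunk_twist) > 1e-9)
    stop("feasibility error: the trunk-twist formula is insensitive to ",
         "axial rotation of this skeleton; nonzero trunk-twist targets ",
         "cannot be realised", call. = FALSE)
  tpl <- body_template()
  waist <- tpl[["04"]]
  upper <- c("01", "02", "03", "07", "10")
  pose_at <- function(phi) {
    Rs <- rotation_matrix(c(0, 1, 0), spec$trunk_side_bend)
    Rf <- rotation_matrix(c(1, 0, 0), -phi)
    M <- Rf %*% Rs
    j <- tpl
    for (tk in c("02", "03")) j[[tk]] <- waist + as.vector(M %*% (tpl[[tk]] - waist))
    u <- .unit(j[["02"]] - waist)
    anterior <- as.vector(M %*% c(0, 1, 0))
    elat <- as.vector(M %*% c(1, 0, 0))
    # shoulders: raise angle has the closed form 90 + elevation
    for (side in c("right", "left")) {
      chi <- (spec$shoulder_raise[[side]] - 90) * pi / 180
      lat <- if (side == "right") elat else -elat
      wdir <- cos(chi) * lat + sin(chi) * u
      tk <- if (side == "right") "07" else "10"
      j[[tk]] <- j[["02"]] + 182 * wdir
    }
    j[["01"]] <- .place_head(j[["02"]], waist, j[["10"]], spec$neck,
                             spec$neck_side_bend, anterior)
    list(joints = j, anterior = anterior,
         trunk_val = 180 - vector_angle(waist - j[["01"]], c(0, 0, 1)))
  }
  phi <- if (is.na(spec$trunk)) 0
  else .solve_angle(function(p) pose_at(p)$trunk_val - spec$trunk,
                    -80, 100, "trunk position")
  pose <- pose_at(phi)
  j <- pose$joints
  for (side in c("right", "left"))
    j <- .place_arm(j, side, spec, pose$anterior)
  j
}

# canonical right-hand template; the left hand is its x-mirror.
# Palm in the z = 0 plane, middle finger along +y, wrist at the origin.
hand_template_points <- function() {
  list(p00 = c(0, 0, 0), p14 = c(0, 90, 0), p13 = c(0, 130, 0),
       p04 = c(40, 55, 0), p24 = c(-35, 50, 0))
}

# one hand pose realising (fe, ru deviation, ps); returns all 25 joints.
# fe displaces x13 along the calibration normal; ru rotates the index
# direction within the palm plane; ps rotates the whole hand about the
# forearm axis (y), solved so the plane-normal angle hits the target.
build_hand_pose <- function(side, fe, ru_dev, ps, neutral_ru = 90) {
  tp <- hand_template_points()
  mir <- if (side == "left") c(-1, 1, 1) else c(1, 1, 1)
  m <- function(p) p * mir
  p00 <- m(tp$p00); p14 <- m(tp$p14); p04 <- m(tp$p04); p24 <- m(tp$p24)
  p13n <- m(tp$p13)
  n0 <- normal_vector(p13n, p04, p24)
  n0u <- .unit(n0)
  fe_r <- fe * pi / 180
  # radial-ulnar: index direction at (neutral_ru + dev) to the pinky chord
  v2 <- p24 - p04
  q <- as.vector(rotation_matrix(n0u, neutral_ru + ru_dev) %*% .unit(v2))
  p05 <- p04 - 60 * q
  # flexion-extension: angle between the x13 and x14 position vectors,
  # signed by the component along the calibration normal. A large
  # pronation-supination rotation can carry x13 across the calibration
  # plane and flip the sign, so try both displacement sides.
  build <- function(flip) {
    p13 <- 130 * (cos(abs(fe_r)) * .unit(p14) +
                    sin(abs(fe_r)) * sign(fe_r + (fe_r == 0)) * flip * n0u)
    pts <- list(p00 = p00, p04 = p04, p05 = p05, p13 = p13, p14 = p14,
                p24 = p24)
    if (!is.na(ps)) {
      f <- function(beta) {
        R <- rotation_matrix(c(0, 1, 0), beta)
        plane_angle(normal_vector(as.vector(R %*% p13), as.vector(R %*% p04),
                                  as.vector(R %*% p24)), n0) - ps
      }
      beta <- .solve_angle(f, -180, 180, paste(side, "pronation-supination"))
      R <- rotation_matrix(c(0, 1, 0), beta)
      pts <- lapply(pts, function(p) as.vector(R %*% p))
    }
    pts
  }
  pts <- build(1)
  achieved_sign <- sign(sum(pts$p13 * n0))
  if (abs(fe_r) > 1e-12 && achieved_sign != sign(fe_r))
    pts <- tryCatch(build(-1), error = function(e) pts)
  # fill the remaining 19 joints as rigid finger points (unused by scoring);
  # anchored on the rotated key points so the whole hand moves rigidly
  out <- vector("list", 25L)
  names(out) <- sprintf("%02d", 0:24)
  out[["00"]] <- pts$p00; out[["04"]] <- pts$p04; out[["05"]] <- pts$p05
  out[["13"]] <- pts$p13; out[["14"]] <- pts$p14; out[["24"]] <- pts$p24
  filler <- setdiff(names(out), c("00", "04", "05", "13", "14", "24"))
  base <- .unit(pts$p14 - pts$p00)
  lat <- .unit(pts$p04 - pts$p24)
  for (i in seq_along(filler)) {
    k <- as.integer(filler[i])
    out[[filler[i]]] <- pts$p00 + (30 + 5 * k) * base +
      ((k %% 5) - 2) * 12 * lat
  }
  out
}

# apply per-joint angular jitter about the parent joint, propagating down
# the kinematic chain (parents first) so every limb length is preserved
.jitter_joints <- function(points, parents, sd_deg) {
  if (sd_deg <= 0) return(points)
  old <- points
  for (nm in names(parents)) {
    par <- parents[[nm]]
    off <- old[[nm]] - old[[par]]
    R <- rotation_matrix(stats::rnorm(3), stats::rnorm(1, 0, sd_deg))
    points[[nm]] <- points[[par]] + as.vector(R %*% off)
  }
  points
}

# topological order: every joint's parent precedes it (04 is the root)
.body_parents <- c("03" = "04", "02" = "03", "01" = "02", "05" = "04",
                   "06" = "04", "07" = "02", "08" = "07", "09" = "08",
                   "10" = "02", "11" = "10", "12" = "11", "13" = "05",
                   "14" = "06", "15" = "13", "16" = "14")

# flatten a joint list into one wide row given a column prefix scheme
.row_from_joints <- function(joints, prefix_fun) {
  vals <- list()
  for (nm in names(joints)) {
    p <- joints[[nm]]
    cols <- prefix_fun(nm)
    vals[[cols[1]]] <- p[1]; vals[[cols[2]]] <- p[2]; vals[[cols[3]]] <- p[3]
  }
  vals
}

#' Generate body and hand frame sequences for one posture
#'
#' Places joints by forward construction so every targeted formula
#' evaluates to its target within 1e-6 degrees (verified; conflicting
#' targets raise a feasibility error), then samples the posture at the
#' two sensor rates with optional seeded jitter and dropouts.
#'
#' @param spec a [posture_spec()].
#' @param body_rate,hand_rate sampling rates in Hz (defaults 30 and 64).
#' @param t0 first timestamp in seconds.
#' @param seed integer seed for jitter/dropouts (`NULL` = leave RNG state).
#' @return list with `body` and `hand` frame data.frames, the clean
#'   `joints` (body list, per-side hand lists) and `truth` (achieved
#'   angles per targeted formula).
#' @export
make_posture_frames <- function(spec, body_rate = 30, hand_rate = 64,
                                t0 = 0, seed = NULL) {
  stopifnot(inherits(spec, "posture_spec"))
  if (!is.null(seed)) set.seed(seed)
  bj <- build_body_pose(spec)
  hands <- list(
    right = build_hand_pose("right", spec$wrist_fe[["right"]],
                            spec$wrist_ru[["right"]], spec$wrist_ps[["right"]]),
    left = build_hand_pose("left", spec$wrist_fe[["left"]],
                           spec$wrist_ru[["left"]], spec$wrist_ps[["left"]]))
  truth <- .verify_pose(bj, hands, spec)

  nb <- max(1L, round(spec$duration * body_rate))
  nh <- max(1L, round(spec$duration * hand_rate))
  body_rows <- vector("list", nb)
  for (i in seq_len(nb)) {
    jj <- .jitter_joints(bj, .body_parents, spec$jitter_sd)
    if (spec$null_rate > 0)
      for (nm in names(jj))
        if (stats::runif(1) < spec$null_rate) jj[[nm]] <- c(NA, NA, NA)
    row <- .row_from_joints(jj, function(nm) paste0("j", nm, "_", c("x", "y", "z")))
    body_rows[[i]] <- as.data.frame(c(list(timestamp = t0 + (i - 1) / body_rate),
                                      row))
  }
  hand_rows <- vector("list", nh)
  hp_par <- stats::setNames(rep("00", 24), sprintf("%02d", 1:24))
  for (i in seq_len(nh)) {
    vals <- list(timestamp = t0 + (i - 1) / hand_rate)
    for (side in c("left", "right")) {
      pre <- if (side == "left") "L" else "R"
      jj <- .jitter_joints(hands[[side]], hp_par, spec$jitter_sd)
      if (spec$null_rate > 0)
        for (nm in names(jj))
          if (stats::runif(1) < spec$null_rate) jj[[nm]] <- c(NA, NA, NA)
      vals <- c(vals, .row_from_joints(jj, function(nm)
        paste0(pre, nm, "_", c("x", "y", "z"))))
    }
    hand_rows[[i]] <- as.data.frame(vals)
  }
  list(body = do.call(rbind, body_rows),
       hand = do.call(rbind, hand_rows),
       joints = list(body = bj, hands = hands), truth = truth)
}

# compare achieved formula values against targets; 1e-6 degree tolerance
.verify_pose <- function(bj, hands, spec, tol = 1e-6) {
  frame <- as.data.frame(c(
    list(timestamp = 0),
    .row_from_joints(bj, function(nm) paste0("j", nm, "_", c("x", "y", "z"))),
    .row_from_joints(hands$left, function(nm) paste0("L", nm, "_", c("x", "y", "z"))),
    .row_from_joints(hands$right, function(nm) paste0("R", nm, "_", c("x", "y", "z")))))
  cal <- .neutral_calibration()
  ach <- list()
  conflicts <- character(0)
  chk <- function(name, achieved, target) {
    ach[[name]] <<- achieved
    if (!is.na(target) && (is.na(achieved) || abs(achieved - target) > tol))
      conflicts <<- c(conflicts, sprintf("%s: target %.6g achieved %.6g",
                                         name, target, achieved))
  }
  cfg <- rula_config()
  for (side in c("right", "left")) {
    ua <- upper_arm_score(frame, side, config = cfg)
    la <- lower_arm_score(frame, side, config = cfg)
    chk(paste0("upper_arm_", side), ua$angles$position,
        spec$upper_arm[[side]])
    chk(paste0("shoulder_raise_", side), ua$angles$shoulder_raise,
        spec$shoulder_raise[[side]])
    chk(paste0("abduction_", side), ua$angles$abduction,
        spec$abduction[[side]])
    chk(paste0("lower_arm_", side), la$angles$position,
        spec$lower_arm[[side]])
    chk(paste0("across_midline_", side), la$angles$across_midline,
        spec$across_midline[[side]])
    chk(paste0("wrist_fe_", side),
        flexion_extension(frame, side, cal, cfg), spec$wrist_fe[[side]])
    chk(paste0("wrist_ru_", side), radial_ulnar(frame, side, cal),
        spec$wrist_ru[[side]])
    chk(paste0("wrist_ps_", side),
        pronation_supination(frame, cal, side), spec$wrist_ps[[side]])
  }
  nk <- neck_score(frame, config = cfg)
  tr <- trunk_score(frame, config = cfg)
  chk("neck", nk$angles$position, spec$neck)
  chk("neck_side_bend", nk$angles$side_bending, spec$neck_side_bend)
  chk("trunk", tr$angles$position, spec$trunk)
  chk("trunk_side_bend", tr$angles$side_bending, spec$trunk_side_bend)
  chk("trunk_twist", tr$angles$twist, spec$trunk_twist)
  if (length(conflicts))
    stop("feasibility error: conflicting targets\n  ",
         paste(conflicts, collapse = "\n  "), call. = FALSE)
  ach
}

# calibration object of the neutral hand templates (used for ground truth)
.neutral_calibration <- function() {
  out <- list()
  for (side in c("left", "right")) {
    h <- build_hand_pose(side, 0, 0, NA)
    out[[side]] <- list(
      normal = normal_vector(h[["13"]], h[["04"]], h[["24"]]),
      neutral_ru = three_point_angle(h[["05"]], h[["04"]], h[["24"]]),
      frame = 0L)
  }
  structure(out, class = "wrist_calibration")
}

#' Session specification: an ordered sequence of labelled postures
#'
#' @param segments list of `list(posture = posture_spec, high = , middle = ,
#'   low = )` entries; low-level labels must be Therbligs.
#' @param body_rate,hand_rate sensor rates in Hz.
#' @param subject subject identifier.
#' @param handedness `"right"` or `"left"`.
#' @param calibration_lead seconds of neutral handshake pose prepended so
#'   the pipeline's first-valid-frame calibration sees a neutral wrist
#'   (default 0.5).
#' @return a list of class `session_spec`.
#' @export
session_spec <- function(segments, body_rate = 30, hand_rate = 64,
                         subject = "S1", handedness = "right",
                         calibration_lead = 0.5) {
  stopifnot(length(segments) > 0)
  for (s in segments) {
    stopifnot(inherits(s$posture, "posture_spec"))
    if (!is.null(s$low) && !s$low %in% therblig_levels())
      stop("session_spec: low-level label must be a Therblig: ", s$low,
           call. = FALSE)
  }
  structure(list(segments = segments, body_rate = body_rate,
                 hand_rate = hand_rate, subject = subject,
                 handedness = handedness,
                 calibration_lead = calibration_lead),
            class = "session_spec")
}

#' Generate a full synthetic session on disk
#'
#' Writes four CSVs: the body stream, the hand stream, the activity
#' labels and a ground-truth table holding, per fused-grid frame, the
#' true angles and true scores of the clean (noise-free) posture.
#'
#' @param spec a [session_spec()].
#' @param dir output directory (created if needed).
#' @param seed integer seed; all jitter and dropout randomness flows from
#'   it.
#' @return named list of file paths (`body`, `hand`, `labels`, `truth`)
#'   plus the in-memory `truth` data.frame.
#' @export
make_session <- function(spec, dir, seed = 1L) {
  stopifnot(inherits(spec, "session_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  segments <- spec$segments
  if (spec$calibration_lead > 0) {
    lead <- list(posture = posture_spec(duration = spec$calibration_lead),
                 high = segments[[1]]$high, middle = segments[[1]]$middle,
                 low = segments[[1]]$low)
    segments <- c(list(lead), segments)
  }
  t0 <- 0
  body_all <- list(); hand_all <- list(); labels <- list(); truth <- list()
  cfg <- rula_config()
  cal <- .neutral_calibration()
  for (si in seq_along(segments)) {
    sg <- segments[[si]]
    pf <- make_posture_frames(sg$posture, spec$body_rate, spec$hand_rate,
                              t0 = t0, seed = NULL)
    body_all[[si]] <- pf$body
    hand_all[[si]] <- pf$hand
    labels[[si]] <- data.frame(timestamp = t0,
                               high = sg$high %||% activity_levels()[1],
                               middle = sg$middle %||% "step",
                               low = sg$low %||% "assemble")
    # per-fused-frame truth: score the clean pose once, replicate on grid
    clean <- as.data.frame(c(
      list(timestamp = 0),
      .row_from_joints(pf$joints$body,
                       function(nm) paste0("j", nm, "_", c("x", "y", "z"))),
      .row_from_joints(pf$joints$hands$left,
                       function(nm) paste0("L", nm, "_", c("x", "y", "z"))),
      .row_from_joints(pf$joints$hands$right,
                       function(nm) paste0("R", nm, "_", c("x", "y", "z")))))
    sc <- score_frame(clean, cal, config = cfg)
    nfused <- round(sg$posture$duration * cfg$target_rate)
    if (nfused > 0) {
      ts <- t0 + (seq_len(nfused) - 0.5) / cfg$target_rate
      tr <- sc[rep(1L, nfused), , drop = FALSE]
      tr$timestamp <- ts
      ang <- as.data.frame(pf$truth)
      truth[[si]] <- cbind(tr, ang[rep(1L, nfused), , drop = FALSE],
                           segment_index = si)
    }
    t0 <- t0 + sg$posture$duration
  }
  body <- do.call(rbind, body_all)
  hand <- do.call(rbind, hand_all)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  paths <- list(body = file.path(dir, "body.csv"),
                hand = file.path(dir, "hand.csv"),
                labels = file.path(dir, "labels.csv"),
                truth = file.path(dir, "ground_truth.csv"))
  utils::write.csv(body, paths$body, row.names = FALSE, na = "")
  utils::write.csv(hand, paths$hand, row.names = FALSE, na = "")
  utils::write.csv(do.call(rbind, labels), paths$labels, row.names = FALSE)
  utils::write.csv(truth, paths$truth, row.names = FALSE, na = "")
  c(paths, list(truth_df = truth))
}

#' Derive an expert-label file from a score table
#'
#' Copies every `stride`-th scored frame into the long expert format;
#' with probability `disagreement_rate` a copied score is perturbed by
#' plus or minus 1, clipped to its RULA domain, emulating imperfect
#' expert agreement.
#'
#' @param scores a `rula_scores` object or score data.frame.
#' @param path output CSV path.
#' @param stride labelling cadence in fused frames (default 10 = 0.5 s).
#' @param disagreement_rate probability of a unit perturbation per label.
#' @param seed integer seed.
#' @return `path`, invisibly.
#' @export
make_expert_file <- function(scores, path, stride = 10,
                             disagreement_rate = 0, seed = 1L) {
  df <- as.data.frame(scores)
  set.seed(seed)
  keep <- df[seq(1L, nrow(df), by = stride), , drop = FALSE]
  domains <- list(
    upper_arm = c(1, 6), lower_arm = c(1, 3), wrist_position = c(1, 4),
    wrist_twist = c(1, 2), neck = c(1, 6), trunk = c(1, 6), legs = c(1, 2),
    A = c(1, 9), B = c(1, 9), grand = c(1, 7))
  cols <- list(
    c("upper_arm", "right", "upper_arm_right"),
    c("upper_arm", "left", "upper_arm_left"),
    c("lower_arm", "right", "lower_arm_right"),
    c("lower_arm", "left", "lower_arm_left"),
    c("wrist_position", "right", "wrist_position_right"),
    c("wrist_position", "left", "wrist_position_left"),
    c("wrist_twist", "right", "wrist_twist_right"),
    c("wrist_twist", "left", "wrist_twist_left"),
    c("neck", "center", "neck"), c("trunk", "center", "trunk"),
    c("legs", "center", "legs"),
    c("A", "right", "A_right"), c("A", "left", "A_left"),
    c("A", "max", "A_max"), c("B", "center", "B"),
    c("grand", "right", "grand_right"), c("grand", "left", "grand_left"),
    c("grand", "general", "grand_general"))
  rows <- list()
  for (i in seq_len(nrow(keep))) {
    for (cc in cols) {
      sc <- keep[i, cc[3]]
      if (is.na(sc)) next
      if (disagreement_rate > 0 && stats::runif(1) < disagreement_rate) {
        dom <- domains[[cc[1]]]
        sc <- min(max(sc + sample(c(-1L, 1L), 1L), dom[1]), dom[2])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        timestamp = keep$timestamp[i], segment = cc[1], side = cc[2],
        score = as.integer(sc))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
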