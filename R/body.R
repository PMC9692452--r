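#' @title Body-segment angles and RULA posture scores
#' @name body-posture
#' @description
#' All body-segment angles are computed from the 16-joint body stream by
#' vector geometry. The angle convention per formula is the one that makes
#' the published band edges meaningful (documented in the methods
#' vignette): the upper-arm position and the shoulder-raise test use the
#' interior angle at the middle joint; the lower-arm, neck and
#' across-midline tests use the chain angle (straight chain reads 0); the
#' lateral adjustments (abduction, trunk side-bending) are deviations of
#' the chain angle from 90 degrees, mirroring the printed
#' `90 - (angle(10, 02, 01))` neck side-bend form. Signs for the upper-arm
#' and neck flexion bands come from projecting the distal joint onto the
#' body's anterior axis, estimated from the hip and spine joints.
NULL

# extract one body joint from a wide frame row; NULL when missing
body_joint <- function(frame, token, registry = body_registry()) {
  token <- resolve_joint(registry, token)
  cols <- paste0("j", token, "_", c("x", "y", "z"))
  if (!all(cols %in% names(frame))) return(NULL)
  v <- as.numeric(frame[1, cols])
  if (anyNA(v)) NULL else v
}

# anterior (front-facing) unit axis of the body, from the configured
# up (waist -> neck) and right-lateral (left hip -> right hip) joint pairs
anterior_axis <- function(frame, registry = body_registry(),
                          config = rula_config()) {
  af <- config$body$anterior_from
  up <- body_joint(frame, af[["up_to"]], registry)
  lo <- body_joint(frame, af[["up_from"]], registry)
  lr <- body_joint(frame, af[["lat_to"]], registry)
  ll <- body_joint(frame, af[["lat_from"]], registry)
  if (is.null(up) || is.null(lo) || is.null(lr) || is.null(ll)) return(NULL)
  u <- up - lo; l <- lr - ll
  a <- c(u[2] * l[3] - u[3] * l[2],
         u[3] * l[1] - u[1] * l[3],
         u[1] * l[2] - u[2] * l[1])
  n <- sqrt(sum(a^2))
  if (n <= 0) return(NULL)
  a / n
}

.ba <- function(frame, reg, t1, t2, t3, fun = three_point_angle) {
  a <- body_joint(frame, t1, reg); b <- body_joint(frame, t2, reg)
  c_ <- body_joint(frame, t3, reg)
  if (is.null(a) || is.null(b) || is.null(c_)) return(NA_real_)
  tryCatch(fun(a, b, c_), error = function(e) NA_real_)
}

new_segment_score <- function(segment, side, base, components, angles, cap) {
  if (is.na(base)) score <- NA_integer_
  else score <- min(base + sum(unlist(components)), cap)
  structure(list(segment = segment, side = side, score = score,
                 base = base, components = components, angles = angles),
            class = "segment_score")
}

#' @export
print.segment_score <- function(x, ...) {
  comp <- paste(sprintf("%s=%+d", names(x$components),
                        unlist(x$components)), collapse = " ")
  cat(sprintf("%s (%s): score %s (base %s%s)\n", x$segment, x$side,
              x$score, x$base, if (nzchar(comp)) paste0(", ", comp) else ""))
  invisible(x)
}

#' Upper-arm RULA score
#'
#' Base score from the signed upper-arm position angle (interior angle at
#' the shoulder between the elbow and hip directions; elbow anterior to
#' the frontal plane gives a positive sign): 1 for [-20, 20), 2 below -20
#' or for [20, 45), 3 for [45, 90), 4 from 90 up. +1 when the shoulder is
#' raised (waist-shoulder interior angle at the neck above 90) and +1 when
#' the arm is abducted (chain-angle deviation from 90 above 20). Capped
#' at 6.
#'
#' @param frame one body/fused frame row.
#' @param side `"left"` or `"right"`.
#' @param registry a [body_registry()].
#' @param config a [rula_config()].
#' @return a `segment_score`.
#' @export
upper_arm_score <- function(frame, side, registry = body_registry(),
                            config = rula_config()) {
  j <- if (identical(side, "right")) {
    list(elbow = "08", shoulder = "07", hip = "05", abd_mid = "07", abd_el = "08",
         raise_sh = "07")
  } else {
    list(elbow = "11", shoulder = "10", hip = "06", abd_mid = "10", abd_el = "11",
         raise_sh = "10")
  }
  pos <- .ba(frame, registry, j$elbow, j$shoulder, j$hip, interior_angle)
  ant <- anterior_axis(frame, registry, config)
  sgn <- 1
  if (!is.na(pos) && !is.null(ant)) {
    el <- body_joint(frame, j$elbow, registry)
    sh <- body_joint(frame, j$shoulder, registry)
    if (sum((el - sh) * ant) < 0) sgn <- -1
  }
  spos <- if (is.na(pos)) NA_real_ else sgn * pos
  raise <- .ba(frame, registry, "04", "02", j$raise_sh, interior_angle)
  abd_raw <- .ba(frame, registry, "02", j$abd_mid, j$abd_el)
  abd <- if (is.na(abd_raw)) NA_real_ else abs(abd_raw - 90)
  base <- if (is.na(spos)) NA_integer_
  else if (spos < -20) 2L
  else if (spos < 20) 1L
  else if (spos < 45) 2L
  else if (spos < 90) 3L
  else 4L
  comp <- list(shoulder_raised = if (!is.na(raise) && raise > 90) 1L else 0L,
               abducted = if (!is.na(abd) && abd > 20) 1L else 0L)
  new_segment_score("upper_arm", side, base, comp,
                    list(position = spos, shoulder_raise = raise,
                         abduction = abd), 6L)
}

#' Lower-arm RULA score
#'
#' Base score from the elbow chain angle (flexion from a straight arm):
#' 1 for [60, 100), 2 for [0, 60) and from 100 up. +1 when the arm works
#' across the midline (chain angle through the torso above 90) and +1
#' when the arm is out to the side of the body (the printed criterion
#' reuses the upper-arm position joints with a 30 degree edge). Capped
#' at 3.
#'
#' @inheritParams upper_arm_score
#' @return a `segment_score`.
#' @export
lower_arm_score <- function(frame, side, registry = body_registry(),
                            config = rula_config()) {
  j <- if (identical(side, "right")) {
    list(wrist = "09", elbow = "08", shoulder = "07", hip = "05")
  } else {
    list(wrist = "12", elbow = "11", shoulder = "10", hip = "06")
  }
  pos <- .ba(frame, registry, j$wrist, j$elbow, j$shoulder)
  across <- .ba(frame, registry, j$shoulder, "03", j$wrist)
  out <- .ba(frame, registry, j$elbow, j$shoulder, j$hip, interior_angle)
  base <- if (is.na(pos)) NA_integer_
  else if (pos < 60) 2L
  else if (pos < 100) 1L
  else 2L
  comp <- list(across_midline = if (!is.na(across) && across > 90) 1L else 0L,
               out_to_side = if (!is.na(out) && out > 30) 1L else 0L)
  new_segment_score("lower_arm", side, base, comp,
                    list(position = pos, across_midline = across,
                         out_to_side = out), 3L)
}

#' Neck RULA score
#'
#' Base score from the signed neck chain angle through head, neck and
#' waist (0 when the head continues the trunk line; anterior flexion
#' positive): 1 for [0, 10), 2 for [10, 20), 3 from 20 up, 4 for any
#' extension (negative angle). +1 when the head is side-bending
#' (`90 - angle(10, 02, 01)` beyond 20 in magnitude). Neck twist is not
#' assessed. Capped at 6.
#'
#' @inheritParams upper_arm_score
#' @return a `segment_score`.
#' @export
neck_score <- function(frame, registry = body_registry(),
                       config = rula_config()) {
  pos <- .ba(frame, registry, "01", "02", "04")
  ant <- anterior_axis(frame, registry, config)
  sgn <- 1
  if (!is.na(pos) && !is.null(ant)) {
    h <- body_joint(frame, "01", registry); nk <- body_joint(frame, "02", registry)
    if (sum((h - nk) * ant) < 0) sgn <- -1
  }
  spos <- if (is.na(pos)) NA_real_ else sgn * pos
  sb_raw <- .ba(frame, registry, "10", "02", "01")
  sb <- if (is.na(sb_raw)) NA_real_ else 90 - sb_raw
  nb <- config$body$neutral_band_deg
  base <- if (is.na(spos)) NA_integer_
  else if (spos < -nb) 4L
  else if (abs(spos) <= nb || spos < 10) 1L
  else if (spos < 20) 2L
  else 3L
  comp <- list(side_bending = if (!is.na(sb) && abs(sb) > 20) 1L else 0L)
  new_segment_score("neck", "center", base, comp,
                    list(position = spos, side_bending = sb), 6L)
}

#' Trunk RULA score
#'
#' Base score from the trunk position `180 - angle(waist -> head segment,
#' vertical axis)` (0 when standing upright): 1 inside the neutral band
#' around 0, 2 up to 20, 3 for [20, 60), 4 from 60 up. +1 when the trunk
#' is twisted (deviation of the waist-hip vector from the neck/hips plane
#' normal's 90 degree neutral above 20) and +1 when the trunk is
#' side-bending (chain-angle deviation from 90 above 20, either side).
#' Capped at 6.
#'
#' @inheritParams upper_arm_score
#' @return a `segment_score`.
#' @export
trunk_score <- function(frame, registry = body_registry(),
                        config = rula_config()) {
  head <- body_joint(frame, "01", registry)
  waist <- body_joint(frame, "04", registry)
  va <- config$body$vertical_axis
  pos <- if (is.null(head) || is.null(waist)) NA_real_
  else tryCatch(180 - vector_angle(waist - head, va), error = function(e) NA_real_)
  # twist: angle between (left hip -> waist) and the neck/hips plane normal,
  # measured as deviation from the 90-degree neutral
  tw <- NA_real_
  n2 <- body_joint(frame, "02", registry)
  h5 <- body_joint(frame, "05", registry); h6 <- body_joint(frame, "06", registry)
  if (!is.null(waist) && !is.null(n2) && !is.null(h5) && !is.null(h6)) {
    nv <- tryCatch(normal_vector(n2, h5, h6), error = function(e) NULL)
    if (!is.null(nv))
      tw <- tryCatch(abs(vector_angle(waist - h6, nv) - 90),
                     error = function(e) NA_real_)
  }
  sbr_raw <- .ba(frame, registry, "02", "04", "05")
  sbl_raw <- .ba(frame, registry, "02", "04", "06")
  sb <- suppressWarnings(max(abs(sbr_raw - 90), abs(sbl_raw - 90), na.rm = TRUE))
  if (!is.finite(sb)) sb <- NA_real_
  nb <- config$body$neutral_band_deg
  base <- if (is.na(pos)) NA_integer_
  else if (abs(pos) < nb) 1L
  else if (pos < 20) 2L
  else if (pos < 60) 3L
  else 4L
  comp <- list(twisted = if (!is.na(tw) && tw > 20) 1L else 0L,
               side_bending = if (!is.na(sb) && sb > 20) 1L else 0L)
  new_segment_score("trunk", "center", base, comp,
                    list(position = pos, twist = tw, side_bending = sb), 6L)
}

#' Legs RULA score
#'
#' The assembly protocol has subjects standing without support, so the
#' legs score is the constant 2; a supported-and-balanced configuration
#' scores 1.
#'
#' @param standing_unsupported logical flag (default TRUE).
#' @return a `segment_score` with score 2 (unsupported) or 1.
#' @export
legs_score <- function(standing_unsupported = TRUE) {
  new_segment_score("legs", "center",
                    if (isTRUE(standing_unsupported)) 2L else 1L,
                    list(), list(), 2L)
}

#' All body-segment angles of one frame
#'
#' Raw degrees for every body formula, keyed by (segment, measure, side);
#' useful for auditing against ground truth.
#'
#' @inheritParams upper_arm_score
#' @return data.frame with columns segment, measure, side, degrees.
#' @export
body_angles <- function(frame, registry = body_registry(),
                        config = rula_config()) {
  rows <- list()
  for (side in c("right", "left")) {
    ua <- upper_arm_score(frame, side, registry, config)
    la <- lower_arm_score(frame, side, registry, config)
    rows[[length(rows) + 1L]] <- data.frame(
      segment = c("upper_arm", "upper_arm", "upper_arm",
                  "lower_arm", "lower_arm", "lower_arm"),
      measure = c("position", "shoulder_raise", "abduction",
                  "position", "across_midline", "out_to_side"),
      side = side,
      degrees = c(ua$angles$position, ua$angles$shoulder_raise,
                  ua$angles$abduction, la$angles$position,
                  la$angles$across_midline, la$angles$out_to_side))
  }
  nk <- neck_score(frame, registry, config)
  tr <- trunk_score(frame, registry, config)
  rows[[length(rows) + 1L]] <- data.frame(
    segment = c("neck", "neck", "trunk", "trunk", "trunk"),
    measure = c("position", "side_bending", "position", "twist",
                "side_bending"),
    side = "center",
    degrees = c(nk$angles$position, nk$angles$side_bending,
                tr$angles$position, tr$angles$twist, tr$angles$side_bending))
  do.call(rbind, rows)
}
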