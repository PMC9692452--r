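#' @title Wrist kinematics and wrist scoring
#' @name wrist-kinematics
#' @description
#' The wrist is scored from the hand-tracking joints alone. Three
#' kinematic quantities are measured per side: flexion-extension (signed;
#' positive = extension/up), radial-ulnar deviation (unsigned, relative to
#' the neutral chain angle captured at calibration) and
#' pronation-supination (angle between the current palm-plane normal and
#' the calibration palm-plane normal, folded into [0, 180]).
NULL

# extract one hand joint from a wide frame row; returns c(x,y,z) or NULL
hand_joint <- function(frame, side, index, registry = hand_registry()) {
  pre <- if (identical(side, "left")) "L" else "R"
  if (index %in% names(registry$roles)) index <- registry$roles[[index]]
  cols <- paste0(pre, index, "_", c("x", "y", "z"))
  if (!all(cols %in% names(frame))) return(NULL)
  v <- as.numeric(frame[1, cols])
  if (anyNA(v)) NULL else v
}

#' Capture the calibration (neutral) hand pose
#'
#' Stores, per side, the palm-plane normal `NV(x13, x04, x24)` of the
#' initial neutral (handshake) position and the neutral radial-ulnar chain
#' angle; both anchor the per-frame wrist measurements.
#'
#' @param hand_stream a hand `skel_stream` (or its frames data.frame).
#' @param registry a [hand_registry()].
#' @param policy `"first_valid"` (default) or `"frame:<k>"` to force frame
#'   k (1-based).
#' @return object of class `wrist_calibration`: per side a list with
#'   `normal`, `neutral_ru` and `frame` (the frame index used).
#' @export
calibrate <- function(hand_stream, registry = hand_registry(),
                      policy = "first_valid") {
  frames <- if (inherits(hand_stream, "skel_stream")) hand_stream$frames
            else as.data.frame(hand_stream)
  forced <- NULL
  if (grepl("^frame:", policy))
    forced <- as.integer(sub("^frame:", "", policy))
  out <- list()
  for (side in c("left", "right")) {
    found <- NULL
    rows <- if (is.null(forced)) seq_len(nrow(frames)) else forced
    for (i in rows) {
      p13 <- hand_joint(frames[i, ], side, "middle_pp_end", registry)
      p04 <- hand_joint(frames[i, ], side, "thumb_mc_end", registry)
      p24 <- hand_joint(frames[i, ], side, "pinky_mc_end", registry)
      p05 <- hand_joint(frames[i, ], side, "index_dp_start", registry)
      if (is.null(p13) || is.null(p04) || is.null(p24) || is.null(p05)) next
      nv <- tryCatch(normal_vector(p13, p04, p24), error = function(e) NULL)
      ru <- tryCatch(three_point_angle(p05, p04, p24), error = function(e) NULL)
      if (is.null(nv) || is.null(ru)) next
      found <- list(normal = nv, neutral_ru = ru, frame = i)
      break
    }
    if (is.null(found))
      stop("calibration error: no valid frame for ", side, " side",
           call. = FALSE)
    out[[side]] <- found
  }
  structure(out, class = "wrist_calibration")
}

#' Wrist flexion-extension angle
#'
#' Default mode `"literal"` measures the angle between the position vectors
#' of the middle-finger proximal-phalanx endpoint (x13) and the
#' middle-finger metacarpal endpoint (x14) taken from the configured
#' origin; mode `"recentered"` first translates both points so the wrist
#' reference joint (x00) is the origin, which makes the measure invariant
#' to where the hand sits in the sensor frame. The up/down sign is taken
#' from the component of x13 along the calibration palm-plane normal
#' (positive = extension).
#'
#' @param frame one row of a hand stream / fused frame.
#' @param side `"left"` or `"right"`.
#' @param calibration a `wrist_calibration` (needed for the sign; unsigned
#'   magnitude is returned when omitted).
#' @param config a [rula_config()].
#' @param registry a [hand_registry()].
#' @return signed degrees, or `NA` when the frame is unscorable.
#' @export
flexion_extension <- function(frame, side, calibration = NULL,
                              config = rula_config(),
                              registry = hand_registry()) {
  p13 <- hand_joint(frame, side, "middle_pp_end", registry)
  p14 <- hand_joint(frame, side, "middle_mc_end", registry)
  if (is.null(p13) || is.null(p14)) return(NA_real_)
  if (identical(config$wrist$mode, "recentered")) {
    ref <- hand_joint(frame, side, "wrist_ref", registry)
    if (is.null(ref)) return(NA_real_)
    a <- p13 - ref; b <- p14 - ref
  } else {
    a <- p13; b <- p14
  }
  ang <- tryCatch(vector_angle(a, b), error = function(e) NA_real_)
  if (is.na(ang) || is.null(calibration)) return(ang)
  s <- sum(a * calibration[[side]]$normal)
  if (s < 0) -ang else ang
}

#' Wrist radial-ulnar deviation
#'
#' Unsigned deviation of the chain angle through the index distal-phalanx
#' start (x05), the thumb metacarpal endpoint (x04) and the pinky
#' metacarpal endpoint (x24) from the neutral value of the same angle
#' captured at calibration. Scored against the 15 degree
#' bent-from-midline threshold.
#'
#' @inheritParams flexion_extension
#' @return degrees >= 0, or `NA` when the frame is unscorable.
#' @export
radial_ulnar <- function(frame, side, calibration,
                         registry = hand_registry()) {
  p05 <- hand_joint(frame, side, "index_dp_start", registry)
  p04 <- hand_joint(frame, side, "thumb_mc_end", registry)
  p24 <- hand_joint(frame, side, "pinky_mc_end", registry)
  if (is.null(p05) || is.null(p04) || is.null(p24)) return(NA_real_)
  ang <- tryCatch(three_point_angle(p05, p04, p24),
                  error = function(e) NA_real_)
  if (is.na(ang)) return(NA_real_)
  abs(ang - calibration[[side]]$neutral_ru)
}

#' Forearm pronation-supination (wrist twist) angle
#'
#' Angle between the current palm-plane normal `NV(x13, x04, x24)` and the
#' calibration palm-plane normal. The arccosine folds rotations beyond
#' 180 degrees back into [0, 180].
#'
#' @inheritParams flexion_extension
#' @return degrees in [0, 180], or `NA` when the frame is unscorable.
#' @export
pronation_supination <- function(frame, calibration, side,
                                 registry = hand_registry()) {
  p13 <- hand_joint(frame, side, "middle_pp_end", registry)
  p04 <- hand_joint(frame, side, "thumb_mc_end", registry)
  p24 <- hand_joint(frame, side, "pinky_mc_end", registry)
  if (is.null(p13) || is.null(p04) || is.null(p24)) return(NA_real_)
  nv <- tryCatch(normal_vector(p13, p04, p24), error = function(e) NULL)
  if (is.null(nv)) return(NA_real_)
  plane_angle(nv, calibration[[side]]$normal)
}

#' RULA wrist position score
#'
#' Base score from the signed flexion-extension angle: 1 within the
#' neutral band around 0, 2 up to 15 degrees up or down, 3 beyond
#' 15 degrees; +1 when the radial-ulnar deviation reaches the
#' bent-from-midline threshold (15 degrees). Capped at 4.
#'
#' @param fe signed flexion-extension in degrees.
#' @param ru radial-ulnar deviation in degrees (>= 0).
#' @param config a [rula_config()].
#' @return integer score in 1..4, `NA` if either input is `NA`.
#' @export
wrist_position_score <- function(fe, ru, config = rula_config()) {
  if (is.na(fe) || is.na(ru)) return(NA_integer_)
  nb <- config$wrist$neutral_band_deg
  base <- if (abs(fe) < nb) 1L else if (abs(fe) <= 15) 2L else 3L
  adj <- if (ru >= config$wrist$bend_threshold_deg) 1L else 0L
  min(base + adj, 4L)
}

#' RULA wrist twist score
#'
#' 1 while the pronation-supination angle stays in mid-range, 2 once it
#' passes the 105 degree end-of-range boundary. Values outside the printed
#' 75-165 degree bands map to the nearest band, keeping the published
#' {1, 2} codomain total over [0, 180].
#'
#' @param ps pronation-supination angle in degrees, [0, 180].
#' @param config a [rula_config()].
#' @return integer 1 or 2, `NA` for `NA` input.
#' @export
wrist_twist_score <- function(ps, config = rula_config()) {
  if (is.na(ps)) return(NA_integer_)
  if (ps < 0 || ps > 180)
    stop("wrist_twist_score: angle outside [0, 180]", call. = FALSE)
  if (ps > config$wrist$twist_band_deg) 2L else 1L
}

#' All wrist kinematics and scores for one frame and side
#'
#' @inheritParams flexion_extension
#' @return list with `flexion_extension`, `radial_ulnar`,
#'   `pronation_supination`, `position_score`, `twist_score`.
#' @export
wrist_assess <- function(frame, side, calibration, config = rula_config(),
                         registry = hand_registry()) {
  fe <- flexion_extension(frame, side, calibration, config, registry)
  ru <- radial_ulnar(frame, side, calibration, registry)
  ps <- pronation_supination(frame, calibration, side, registry)
  list(flexion_extension = fe, radial_ulnar = ru, pronation_supination = ps,
       position_score = wrist_position_score(fe, ru, config),
       twist_score = if (is.na(ps)) NA_integer_
                     else wrist_twist_score(ps, config))
}
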