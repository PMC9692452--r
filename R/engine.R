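#' @title Per-frame RULA scoring engine
#' @name rula-engine
#' @description
#' Combines the wrist scores (hand sensor) with the arm scores (body
#' sensor) into section A per side, computes section B once per frame, and
#' produces three grand scores: left, right and general. The general score
#' follows the Max-score rule: the per-component maxima of the left and
#' right segment scores enter the Table A lookup (Max applied upstream of
#' the table, which guarantees the general grand score dominates both
#' sides under table monotonicity); `max_mode = "per_A"` instead takes the
#' maximum of the two looked-up section A scores.
NULL

score_frame <- function(frame, calibration, body_reg = body_registry(),
                        hand_reg = hand_registry(), config = rula_config()) {
  ua_r <- upper_arm_score(frame, "right", body_reg, config)
  ua_l <- upper_arm_score(frame, "left", body_reg, config)
  la_r <- lower_arm_score(frame, "right", body_reg, config)
  la_l <- lower_arm_score(frame, "left", body_reg, config)
  nk <- neck_score(frame, body_reg, config)
  tr <- trunk_score(frame, body_reg, config)
  lg <- legs_score(config$legs$standing_unsupported)
  w_r <- wrist_assess(frame, "right", calibration, config, hand_reg)
  w_l <- wrist_assess(frame, "left", calibration, config, hand_reg)

  A_r <- score_A(ua_r$score, la_r$score, w_r$position_score, w_r$twist_score,
                 config)
  A_l <- score_A(ua_l$score, la_l$score, w_l$position_score, w_l$twist_score,
                 config)
  if (identical(config$engine$max_mode, "per_A")) {
    A_max <- if (is.na(A_r) || is.na(A_l)) NA_integer_ else max(A_r, A_l)
  } else {
    A_max <- score_A(max(ua_r$score, ua_l$score),
                     max(la_r$score, la_l$score),
                     max(w_r$position_score, w_l$position_score),
                     max(w_r$twist_score, w_l$twist_score), config)
  }
  B <- score_B(nk$score, tr$score, lg$score, config)
  g_r <- grand_score(A_r, B); g_l <- grand_score(A_l, B)
  g_g <- grand_score(A_max, B)
  data.frame(
    timestamp = frame$timestamp,
    upper_arm_right = ua_r$score, upper_arm_left = ua_l$score,
    lower_arm_right = la_r$score, lower_arm_left = la_l$score,
    wrist_position_right = w_r$position_score,
    wrist_position_left = w_l$position_score,
    wrist_twist_right = w_r$twist_score, wrist_twist_left = w_l$twist_score,
    neck = nk$score, trunk = tr$score, legs = lg$score,
    A_right = A_r, A_left = A_l, A_max = A_max, B = B,
    grand_right = g_r, grand_left = g_l, grand_general = g_g,
    risk_right = risk_level(g_r), risk_left = risk_level(g_l),
    risk_general = risk_level(g_g),
    fe_right = w_r$flexion_extension, fe_left = w_l$flexion_extension,
    ru_right = w_r$radial_ulnar, ru_left = w_l$radial_ulnar,
    ps_right = w_r$pronation_supination, ps_left = w_l$pronation_supination,
    stringsAsFactors = FALSE)
}

#' Score a fused frame sequence with RULA
#'
#' The central scorer: runs the wrist and body assessments on every fused
#' frame, combines them through the RULA tables and returns a classed
#' per-frame score table. Frames with an unscorable segment are skipped
#' and counted.
#'
#' @param fused a `fused_frames` data.frame from [preprocess()] / [fuse()].
#' @param calibration a `wrist_calibration` from [calibrate()].
#' @param config a [rula_config()].
#' @param body_reg,hand_reg joint registries.
#' @return an object of class `rula_scores`: a data.frame with one row per
#'   scored frame (timestamp, segment scores, section scores A
#'   left/right/max and B, grand scores left/right/general, risk levels
#'   and raw wrist kinematics), carrying activity labels and skip counts
#'   as attributes.
#' @export
rula <- function(fused, calibration, config = rula_config(),
                 body_reg = body_registry(), hand_reg = hand_registry()) {
  fused <- as.data.frame(fused)
  if (!nrow(fused)) stop("rula: no frames to score", call. = FALSE)
  rows <- lapply(seq_len(nrow(fused)), function(i)
    score_frame(fused[i, ], calibration, body_reg, hand_reg, config))
  out <- do.call(rbind, rows)
  scored <- stats::complete.cases(
    out[, c("grand_right", "grand_left", "grand_general")])
  skipped <- sum(!scored)
  labels <- NULL
  if (all(c("high", "middle", "low") %in% names(fused)))
    labels <- fused[scored, c("high", "middle", "low"), drop = FALSE]
  res <- out[scored, , drop = FALSE]
  if (!is.null(labels)) res <- cbind(res, labels)
  rownames(res) <- NULL
  structure(res, skipped = skipped, config = config,
            class = c("rula_scores", "data.frame"))
}

#' @export
print.rula_scores <- function(x, ...) {
  cat(sprintf("RULA scores: %d frames (%d skipped as unscorable)\n",
              nrow(x), attr(x, "skipped") %||% 0L))
  if (nrow(x)) {
    cat(sprintf("  grand general: median %d, range %d-%d\n",
                as.integer(stats::median(x$grand_general)),
                min(x$grand_general), max(x$grand_general)))
    tab <- table(factor(x$risk_general,
                        levels = c("negligible", "low", "medium", "high")))
    cat("  risk (general): ",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.rula_scores <- function(object, ...) {
  segs <- c("upper_arm_right", "upper_arm_left", "lower_arm_right",
            "lower_arm_left", "wrist_position_right", "wrist_position_left",
            "wrist_twist_right", "wrist_twist_left", "neck", "trunk", "legs",
            "A_right", "A_left", "A_max", "B",
            "grand_right", "grand_left", "grand_general")
  s <- data.frame(
    score = segs,
    min = vapply(segs, function(k) min(object[[k]]), numeric(1)),
    median = vapply(segs, function(k) stats::median(object[[k]]), numeric(1)),
    max = vapply(segs, function(k) max(object[[k]]), numeric(1)),
    row.names = NULL)
  structure(list(n = nrow(object), skipped = attr(object, "skipped") %||% 0L,
                 table = s,
                 risk = table(factor(object$risk_general,
                                     levels = c("negligible", "low",
                                                "medium", "high")))),
            class = "summary.rula_scores")
}

#' @export
print.summary.rula_scores <- function(x, ...) {
  cat(sprintf("RULA scoring summary: %d frames (%d skipped)\n", x$n,
              x$skipped))
  print(x$table, row.names = FALSE)
  cat("risk levels (general): ",
      paste(sprintf("%s %d", names(x$risk), x$risk), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.rula_scores <- function(x, which = "grand_general", ...) {
  graphics::plot(x$timestamp, x[[which]], type = "s",
                 xlab = "time [s]", ylab = which,
                 ylim = c(1, 7), ...)
  graphics::abline(h = c(2.5, 4.5, 6.5), lty = 3, col = "grey50")
  invisible(x)
}

#' @export
as.data.frame.rula_scores <- function(x, ...) {
  class(x) <- "data.frame"
  attr(x, "skipped") <- NULL; attr(x, "config") <- NULL
  x
}
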