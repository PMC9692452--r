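#' @title Agreement with expert labels and across-subject comparison
#' @name evaluation
#' @description
#' System scores are validated against per-segment expert labels with a
#' numeric similarity statistic, stratified by high-level activity, and
#' subjects are compared with a one-way ANOVA on the general grand score
#' followed by all pairwise two-sample t-tests.
NULL

#' Numeric similarity between an expert and a system score
#'
#' \eqn{numSim(es, ss) = 1 - |es - ss| / (es + ss)}. Symmetric, in (0, 1]
#' for positive scores, and exactly 1 iff the scores agree.
#'
#' @param es,ss scores >= 1 (vectorised).
#' @return similarity in (0, 1].
#' @examples
#' num_sim(3, 3) # 1
#' num_sim(1, 3) # 0.5
#' @export
num_sim <- function(es, ss) {
  if (any(es < 1, na.rm = TRUE) || any(ss < 1, na.rm = TRUE))
    stop("domain error: scores must be >= 1", call. = FALSE)
  1 - abs(es - ss) / (es + ss)
}

#' Mean similarity of an aligned score series
#'
#' The mean of [num_sim()] over aligned (expert, system) score pairs.
#'
#' @param es,ss equal-length numeric vectors of aligned scores.
#' @return mean similarity in (0, 1].
#' @export
tsim <- function(es, ss) {
  if (length(es) == 0L || length(es) != length(ss))
    stop("domain error: aligned non-empty series required", call. = FALSE)
  mean(num_sim(es, ss))
}

# map the expert file's (segment, side) naming onto score-table columns
.expert_column <- function(segment, side) {
  key <- paste(segment, side, sep = "|")
  map <- c("upper_arm|right" = "upper_arm_right", "upper_arm|left" = "upper_arm_left",
           "lower_arm|right" = "lower_arm_right", "lower_arm|left" = "lower_arm_left",
           "wrist_position|right" = "wrist_position_right",
           "wrist_position|left" = "wrist_position_left",
           "wrist_twist|right" = "wrist_twist_right",
           "wrist_twist|left" = "wrist_twist_left",
           "neck|center" = "neck", "trunk|center" = "trunk",
           "legs|center" = "legs",
           "A|right" = "A_right", "A|left" = "A_left", "A|max" = "A_max",
           "B|center" = "B",
           "grand|right" = "grand_right", "grand|left" = "grand_left",
           "grand|general" = "grand_general")
  unname(map[key])
}

#' Similarity report between system scores and expert labels
#'
#' Joins the expert rows to the system scores by exact fused-frame
#' timestamp and computes the mean similarity per (segment, side,
#' high-level activity) stratum plus a per-(segment, side) overall row
#' (activity `"all"`). Strata with no labelled rows are absent from the
#' report, not fabricated as zero.
#'
#' @param expert data.frame from [read_expert_file()] (columns timestamp,
#'   segment, side, score).
#' @param scores a `rula_scores` object or score data.frame with a `high`
#'   activity column (when absent, only the overall stratum is reported).
#' @param tol timestamp matching tolerance in seconds (default 1e-6).
#' @return data.frame of class `similarity_report`: segment, side,
#'   activity, n, tsim.
#' @export
similarity_report <- function(expert, scores, tol = 1e-6) {
  scores <- as.data.frame(scores)
  idx <- vapply(expert$timestamp, function(t) {
    k <- which.min(abs(scores$timestamp - t))
    if (length(k) && abs(scores$timestamp[k] - t) <= tol) k else NA_integer_
  }, integer(1))
  if (anyNA(idx))
    stop("alignment error: expert rows with no matching fused timestamp: ",
         paste(utils::head(expert$timestamp[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  cols <- .expert_column(expert$segment, expert$side)
  if (anyNA(cols))
    stop("unknown expert (segment, side) pair(s): ",
         paste(unique(paste(expert$segment[is.na(cols)],
                            expert$side[is.na(cols)])), collapse = ", "),
         call. = FALSE)
  ss <- vapply(seq_along(idx), function(i) scores[idx[i], cols[i]], numeric(1))
  act <- if ("high" %in% names(scores)) scores$high[idx]
         else rep("all", length(idx))
  d <- data.frame(segment = expert$segment, side = expert$side,
                  activity = act, es = expert$score, ss = ss,
                  stringsAsFactors = FALSE)
  strata <- unique(d[, c("segment", "side", "activity")])
  per_act <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sub <- d[d$segment == strata$segment[i] & d$side == strata$side[i] &
               d$activity == strata$activity[i], ]
    data.frame(segment = strata$segment[i], side = strata$side[i],
               activity = strata$activity[i], n = nrow(sub),
               tsim = tsim(sub$es, sub$ss), stringsAsFactors = FALSE)
  }))
  seg_side <- unique(d[, c("segment", "side")])
  overall <- do.call(rbind, lapply(seq_len(nrow(seg_side)), function(i) {
    sub <- d[d$segment == seg_side$segment[i] & d$side == seg_side$side[i], ]
    data.frame(segment = seg_side$segment[i], side = seg_side$side[i],
               activity = "all", n = nrow(sub), tsim = tsim(sub$es, sub$ss),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(per_act, overall)
  rownames(out) <- NULL
  structure(out, class = c("similarity_report", "data.frame"))
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("Similarity to expert labels (tsim)\n")
  print.data.frame(cbind(x[, 1:4], tsim = round(x$tsim, 4)),
                   row.names = FALSE)
  invisible(x)
}

#' Across-subject comparison of grand scores
#'
#' One-way ANOVA on the general grand score grouped by subject, followed
#' by all pairwise two-sided two-sample t-tests (Student's equal-variance
#' by default, Welch via `var_equal = FALSE`). Subjects with fewer than
#' two frames or zero variance are excluded with a warning. Pairs of
#' identical samples are reported with p = 1.
#'
#' @param scores_by_subject named list of numeric grand-score vectors, or
#'   a data.frame with columns `subject` and `score`.
#' @param alpha significance level for the flags (default 0.05).
#' @param var_equal use the pooled-variance t-test (default TRUE).
#' @param p_adjust multiplicity correction for the pairwise matrix
#'   (`"none"` by default; any `stats::p.adjust` method).
#' @return object of class `subject_comparison`: `anova_F`, `anova_p`,
#'   symmetric `p_matrix` with unit diagonal, logical `significant`
#'   matrix, `alpha`, group sizes `n`.
#' @export
subject_comparison <- function(scores_by_subject, alpha = 0.05,
                               var_equal = TRUE, p_adjust = "none") {
  if (is.data.frame(scores_by_subject))
    scores_by_subject <- split(scores_by_subject$score,
                               scores_by_subject$subject)
  keep <- vapply(scores_by_subject, function(v) length(v) >= 2L, logical(1))
  if (any(!keep))
    warning("excluding subject(s) with n < 2: ",
            paste(names(scores_by_subject)[!keep], collapse = ", "),
            call. = FALSE)
  g <- scores_by_subject[keep]
  if (length(g) < 2L)
    stop("subject_comparison: need at least two subjects", call. = FALSE)
  subj <- rep(names(g), lengths(g))
  val <- unlist(g, use.names = FALSE)
  fit <- stats::aov(val ~ factor(subj))
  av <- summary(fit)[[1]]
  Fv <- av[["F value"]][1]; pv <- av[["Pr(>F)"]][1]
  s <- names(g)
  pm <- matrix(1, length(s), length(s), dimnames = list(s, s))
  for (i in seq_along(s)) for (j in seq_along(s)) {
    if (j <= i) next
    a <- g[[i]]; b <- g[[j]]
    p <- if (length(a) == length(b) && all(sort(a) == sort(b)) &&
             stats::var(a) == 0) 1
    else if (stats::var(a) == 0 && stats::var(b) == 0)
      if (a[1] == b[1]) 1 else 0
    else tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
                  error = function(e) NA_real_)
    pm[i, j] <- pm[j, i] <- p
  }
  if (!identical(p_adjust, "none")) {
    up <- pm[upper.tri(pm)]
    pm[upper.tri(pm)] <- stats::p.adjust(up, method = p_adjust)
    pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
  }
  structure(list(anova_F = Fv, anova_p = pv, p_matrix = pm,
                 significant = pm < alpha & row(pm) != col(pm),
                 alpha = alpha, n = lengths(g)),
            class = "subject_comparison")
}

#' @export
print.subject_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (alpha = %g)\n",
              x$anova_F, x$anova_p, x$alpha))
  cat("Pairwise t-test p-values:\n")
  print(signif(x$p_matrix, 3))
  invisible(x)
}
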