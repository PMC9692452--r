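#' Run the full assessment pipeline on stream files
#'
#' Chains reading, PAA rate-balancing, fusion, null-row removal, wrist
#' calibration, per-frame RULA scoring, and (when an expert file is
#' given) the similarity evaluation. This is the function behind the
#' command-line entry point.
#'
#' @param body_path,hand_path input stream CSVs.
#' @param labels_path optional activity-label CSV.
#' @param expert_path optional expert-label CSV.
#' @param out_dir output directory; written artifacts are `fused.csv`,
#'   `scores.csv` and, with an expert file, `similarity.csv`.
#' @param config a [rula_config()].
#' @param quiet suppress per-stage frame-count messages.
#' @return invisible list with `fused`, `scores` (a `rula_scores`) and
#'   optionally `similarity`.
#' @export
run_pipeline <- function(body_path, hand_path, labels_path = NULL,
                         expert_path = NULL, out_dir = ".",
                         config = rula_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  body <- read_body_stream(body_path)
  hand <- read_hand_stream(hand_path)
  labels <- if (!is.null(labels_path)) read_labels(labels_path) else NULL
  say(sprintf("read: %d body frames (%.3g Hz), %d hand frames (%.3g Hz)",
              nrow(body$frames), body$nominal_rate,
              nrow(hand$frames), hand$nominal_rate))
  fused <- preprocess(body, hand, labels, config)
  say(sprintf("fused: %d frames at %g Hz (%d removed as null rows)",
              nrow(fused), config$target_rate, attr(fused, "removed")))
  cal <- calibrate(hand, policy = config$wrist$calibration)
  scores <- rula(fused, cal, config)
  say(sprintf("scored: %d frames (%d skipped)", nrow(scores),
              attr(scores, "skipped")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(fused), file.path(out_dir, "fused.csv"),
                   row.names = FALSE, na = "")
  write_scores(scores, file.path(out_dir, "scores.csv"))
  out <- list(fused = fused, scores = scores)
  if (!is.null(expert_path)) {
    expert <- read_expert_file(expert_path)
    rep <- similarity_report(expert, scores)
    utils::write.csv(as.data.frame(rep),
                     file.path(out_dir, "similarity.csv"), row.names = FALSE)
    out$similarity <- rep
    say(sprintf("similarity: %d strata, overall mean tsim %.4f",
                nrow(rep), mean(rep$tsim[rep$activity == "all"])))
  }
  invisible(out)
}
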