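#' @title Skeleton stream containers and delimited-text IO
#' @name stream-io
#' @description
#' Streams are stored wide: one row per frame, one `<joint>_x/_y/_z` column
#' triple per joint, plus a `timestamp` column in seconds. A joint is null
#' in a frame when its three coordinates are all `NA`; readers coerce any
#' unparseable or partially missing triple to a fully null joint so the
#' "all present or all null" invariant holds everywhere downstream.
#' The CSV dialect is fixed: comma separator, header row, UTF-8, "."
#' decimal, empty cell for null.
NULL

body_columns <- function(registry = body_registry()) {
  as.vector(t(outer(paste0("j", registry$tokens), c("x", "y", "z"),
                    function(a, b) paste(a, b, sep = "_"))))
}

hand_columns <- function(registry = hand_registry()) {
  labs <- as.vector(t(outer(registry$sides, registry$indices, paste0)))
  as.vector(t(outer(labs, c("x", "y", "z"), function(a, b) paste(a, b, sep = "_"))))
}

new_stream <- function(frames, nominal_rate, kind,
                       subject = NA_character_, handedness = "right") {
  stopifnot(is.data.frame(frames), nominal_rate > 0)
  structure(list(frames = frames, nominal_rate = nominal_rate, kind = kind,
                 subject = subject, handedness = handedness),
            class = "skel_stream")
}

#' @export
print.skel_stream <- function(x, ...) {
  cat(sprintf("<%s stream> %d frames @ %.6g Hz, subject %s\n",
              x$kind, nrow(x$frames), x$nominal_rate,
              ifelse(is.na(x$subject), "?", x$subject)))
  invisible(x)
}

infer_rate <- function(ts) {
  if (length(ts) < 2L) return(1)
  1 / stats::median(diff(ts))
}

# shared reader core: column check, null-joint coercion, monotone timestamps
read_stream_csv <- function(path, cols, kind, registry, nominal_rate = NULL,
                            subject = NA_character_, handedness = "right") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("timestamp", cols)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, need, drop = FALSE]
  for (nm in need) df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  ts <- df$timestamp
  if (anyNA(ts)) stop("validation error: unparseable timestamps", call. = FALSE)
  if (nrow(df) > 1L && any(diff(ts) <= 0))
    stop("validation error: timestamps must be strictly increasing",
         call. = FALSE)
  # a joint with any unparseable/missing coordinate becomes fully null
  joints <- unique(sub("_[xyz]$", "", cols))
  for (j in joints) {
    trip <- paste(j, c("x", "y", "z"), sep = "_")
    bad <- !stats::complete.cases(df[, trip, drop = FALSE])
    if (any(bad)) df[bad, trip] <- NA_real_
  }
  rate <- if (is.null(nominal_rate)) infer_rate(ts) else nominal_rate
  new_stream(df, rate, kind, subject, handedness)
}

#' Read a body-tracking stream from CSV
#'
#' Expected header: `timestamp,j01_x,j01_y,j01_z,...,j16_z` (tokens per the
#' registry). Row count is preserved; cells that fail to parse become null
#' joints rather than dropped rows.
#'
#' @param path CSV file path.
#' @param registry a [body_registry()].
#' @param nominal_rate optional sampling rate in Hz; inferred from the
#'   median timestamp step when omitted.
#' @param subject,handedness session metadata carried on the stream.
#' @return a `skel_stream` of kind `"body"`.
#' @export
read_body_stream <- function(path, registry = body_registry(),
                             nominal_rate = NULL, subject = NA_character_,
                             handedness = "right") {
  read_stream_csv(path, body_columns(registry), "body", registry,
                  nominal_rate, subject, handedness)
}

#' Read a hand-tracking stream from CSV
#'
#' Expected header: `timestamp,L00_x,...,L24_z,R00_x,...,R24_z`.
#'
#' @inheritParams read_body_stream
#' @param registry a [hand_registry()].
#' @return a `skel_stream` of kind `"hand"`.
#' @export
read_hand_stream <- function(path, registry = hand_registry(),
                             nominal_rate = NULL, subject = NA_character_,
                             handedness = "right") {
  read_stream_csv(path, hand_columns(registry), "hand", registry,
                  nominal_rate, subject, handedness)
}

#' Write a skeleton stream to CSV
#'
#' Inverse of the stream readers up to floating-point text formatting.
#'
#' @param stream a `skel_stream`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "skel_stream"))
  utils::write.csv(stream$frames, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an activity-label CSV
#'
#' Header `timestamp,high,middle,low`; each row labels the interval from
#' its timestamp to the next row's timestamp. The low level must use the
#' six Therblig motions relevant to assembly work.
#'
#' @param path CSV path.
#' @param validate_low enforce the six-Therblig vocabulary (default TRUE).
#' @return data.frame with columns timestamp, high, middle, low.
#' @export
read_labels <- function(path, validate_low = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("timestamp", "high", "middle", "low")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$timestamp <- as.numeric(df$timestamp)
  if (validate_low) {
    bad <- setdiff(unique(df$low), c(therblig_levels(), NA, "")) # nolint
    if (length(bad))
      stop("validation error: low-level labels outside the Therblig ",
           "vocabulary: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df[order(df$timestamp), need]
}

#' The six Therblig low-level activity labels
#' @return character vector of the six motions.
#' @export
therblig_levels <- function() {
  c("grasp", "transport loaded", "assemble", "inspect", "position",
    "release load")
}

#' High-level assembly activity labels
#' @return character vector of the five assembly steps.
#' @export
activity_levels <- function() {
  c("assemble side panel", "assemble main panel", "integrate panel",
    "prepare the workspace", "slide the mid-panel")
}

#' Write per-frame RULA results to CSV
#'
#' One row per scored frame, in timestamp order regardless of input order:
#' timestamp, per-segment scores (left/right where sided), section scores
#' A-left/A-right/A-max and B, the three grand scores and risk levels.
#'
#' @param results a `rula_scores` object or its data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(results, path) {
  df <- as.data.frame(results)
  if (nrow(df) == 0L) stop("write_scores: no results to write", call. = FALSE)
  df <- df[order(df$timestamp), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-frame RULA score CSV written by [write_scores()]
#'
#' @param path CSV path.
#' @return data.frame of per-frame scores.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"timestamp" %in% names(df))
    stop("format error: missing required column(s): timestamp", call. = FALSE)
  df
}

#' Read an expert-label CSV
#'
#' Long format, header `timestamp,segment,side,score`: one row per labelled
#' (segment, side) pair at each labelled frame (the labelling cadence is
#' every k-th fused frame, 0.5 s at the default stride of 10).
#'
#' @param path CSV path.
#' @return data.frame with columns timestamp, segment, side, score.
#' @export
read_expert_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(timestamp = "numeric",
                                       segment = "character",
                                       side = "character",
                                       score = "integer"))
  need <- c("timestamp", "segment", "side", "score")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df[, need]
}
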