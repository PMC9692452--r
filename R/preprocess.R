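#' Piecewise Aggregate Approximation of a univariate series
#'
#' Divides a length-`n` series into `N` equal-length segments and replaces
#' each segment by its mean. When `n` is not divisible by `N`, segments are
#' the half-open index windows \eqn{[\lceil (i-1)n/N \rceil, \lceil in/N \rceil)},
#' which reduces to the textbook equal-block definition in the divisible
#' case. `NA` values are excluded from a segment's mean; a segment that is
#' entirely `NA` yields `NA` so that downstream null-row removal still sees
#' the dropout.
#'
#' @param series numeric vector (may contain `NA`).
#' @param N number of segments, `1 <= N <= length(series)`.
#' @return numeric vector of length `N` of segment means.
#' @examples
#' paa(c(1, 2, 3, 4, 5, 6), 3) # 1.5 3.5 5.5
#' paa(c(5, 5, 5, 5), 2)       # 5 5  (constant series is a fixed point)
#' @export
paa <- function(series, N) {
  n <- length(series)
  if (n == 0L) stop("paa: empty series", call. = FALSE)
  N <- as.integer(N)
  if (is.na(N) || N < 1L || N > n)
    stop("paa: need 1 <= N <= length(series)", call. = FALSE)
  if (N == n) return(as.numeric(series))
  starts <- ceiling((seq_len(N) - 1L) * n / N) + 1L
  ends <- ceiling(seq_len(N) * n / N)
  vapply(seq_len(N), function(i) {
    seg <- series[starts[i]:ends[i]]
    if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
  }, numeric(1))
}

#' Rate-balance a skeleton stream with PAA
#'
#' Applies [paa()] independently to every coordinate channel (each joint's
#' x, y and z is one univariate series) to reduce the stream to
#' `target_rate`. The number of output frames is
#' `N = round(duration * target_rate)` with `duration = n / nominal_rate`,
#' and output timestamps are segment-center times on the uniform grid
#' anchored at the first input timestamp.
#'
#' @param stream a `skel_stream` with `nominal_rate >= target_rate`.
#' @param target_rate output rate in Hz (default 20).
#' @return a `skel_stream` at `target_rate`.
#' @export
resample_stream <- function(stream, target_rate = 20) {
  stopifnot(inherits(stream, "skel_stream"))
  if (stream$nominal_rate < target_rate - 1e-9)
    stop("resample_stream: upsampling from ",
         format(stream$nominal_rate), " Hz to ", format(target_rate),
         " Hz is not supported", call. = FALSE)
  fr <- stream$frames
  n <- nrow(fr)
  duration <- n / stream$nominal_rate
  N <- max(1L, as.integer(round(duration * target_rate)))
  if (N > n) N <- n
  t0 <- fr$timestamp[1]
  out <- data.frame(timestamp = t0 + (seq_len(N) - 0.5) / target_rate)
  for (nm in setdiff(names(fr), "timestamp")) out[[nm]] <- paa(fr[[nm]], N)
  # PAA averages coordinates independently; re-impose the all-or-null joint
  # invariant on the output frames
  joints <- unique(sub("_[xyz]$", "", setdiff(names(fr), "timestamp")))
  for (j in joints) {
    trip <- paste(j, c("x", "y", "z"), sep = "_")
    bad <- !stats::complete.cases(out[, trip, drop = FALSE])
    if (any(bad)) out[bad, trip] <- NA_real_
  }
  new_stream(out, target_rate, stream$kind, stream$subject, stream$handedness)
}

#' Fuse rate-balanced body and hand streams
#'
#' Joins frames of the two streams by nearest grid timestamp (maximum
#' offset strictly less than half a grid step), attaches activity labels by
#' timestamp-interval containment, and reports how many frames were dropped
#' as unmatched.
#'
#' @param body20,hand20 `skel_stream`s already at the common target rate.
#' @param labels optional data.frame from [read_labels()].
#' @param target_rate the common grid rate in Hz.
#' @return a data.frame of fused frames (class `fused_frames`): timestamp,
#'   all body joint columns, all hand joint columns, and label columns
#'   `high`, `middle`, `low` when labels are given. Attribute `dropped`
#'   holds the per-stream unmatched frame counts.
#' @export
fuse <- function(body20, hand20, labels = NULL, target_rate = 20) {
  stopifnot(inherits(body20, "skel_stream"), inherits(hand20, "skel_stream"))
  if (abs(body20$nominal_rate - target_rate) > 1e-6 ||
      abs(hand20$nominal_rate - target_rate) > 1e-6)
    stop("fuse: both streams must already be at the target rate", call. = FALSE)
  bt <- body20$frames$timestamp
  ht <- hand20$frames$timestamp
  if (min(bt) > max(ht) || min(ht) > max(bt))
    stop("validation error: disjoint time ranges between streams",
         call. = FALSE)
  step <- 1 / target_rate
  # nearest-neighbour join body -> hand with offset < step / 2
  idx <- vapply(bt, function(t) {
    k <- which.min(abs(ht - t))
    if (abs(ht[k] - t) < step / 2) k else NA_integer_
  }, integer(1))
  keep <- !is.na(idx)
  dropped <- c(body = sum(!keep), hand = nrow(hand20$frames) - length(unique(idx[keep])))
  fused <- cbind(body20$frames[keep, , drop = FALSE],
                 hand20$frames[idx[keep], setdiff(names(hand20$frames), "timestamp"),
                               drop = FALSE])
  rownames(fused) <- NULL
  if (!is.null(labels) && nrow(labels)) {
    bins <- findInterval(fused$timestamp, labels$timestamp)
    fused$high <- ifelse(bins >= 1, labels$high[pmax(bins, 1L)], NA_character_)
    fused$middle <- ifelse(bins >= 1, labels$middle[pmax(bins, 1L)], NA_character_)
    fused$low <- ifelse(bins >= 1, labels$low[pmax(bins, 1L)], NA_character_)
  }
  structure(fused, dropped = dropped,
            class = c("fused_frames", "data.frame"))
}

#' Remove frames with null scoring joints
#'
#' Drops every fused frame in which any joint dereferenced by a scoring
#' formula is null. Joints that no formula touches (knees, feet, unused
#' finger joints) do not cause removal.
#'
#' @param fused a `fused_frames` data.frame from [fuse()].
#' @param body_reg a [body_registry()].
#' @param hand_reg a [hand_registry()].
#' @param config a [rula_config()] (the `recentered` wrist mode additionally
#'   requires the wrist reference joint).
#' @return the filtered `fused_frames`; attribute `removed` holds the
#'   number of frames removed.
#' @export
drop_null_rows <- function(fused, body_reg = body_registry(),
                           hand_reg = hand_registry(),
                           config = rula_config()) {
  need_body <- paste0("j", required_body_tokens(body_reg))
  roles <- hand_reg$roles[required_hand_roles(config)]
  need_hand <- as.vector(outer(c("L", "R"), roles, paste0))
  cols <- as.vector(t(outer(c(need_body, need_hand), c("x", "y", "z"),
                            function(a, b) paste(a, b, sep = "_"))))
  cols <- intersect(cols, names(fused))
  ok <- stats::complete.cases(fused[, cols, drop = FALSE])
  out <- fused[ok, , drop = FALSE]
  rownames(out) <- NULL
  if (!any(ok)) warning("drop_null_rows: all frames removed", call. = FALSE)
  structure(out, removed = sum(!ok), dropped = attr(fused, "dropped"),
            class = c("fused_frames", "data.frame"))
}

#' Preprocess raw streams into fused frames
#'
#' Convenience wrapper chaining [resample_stream()] on both streams,
#' [fuse()] and [drop_null_rows()].
#'
#' @param body,hand raw `skel_stream`s.
#' @param labels optional label data.frame.
#' @param config a [rula_config()].
#' @param body_reg,hand_reg joint registries.
#' @return a `fused_frames` data.frame.
#' @export
preprocess <- function(body, hand, labels = NULL, config = rula_config(),
                       body_reg = body_registry(), hand_reg = hand_registry()) {
  b <- resample_stream(body, config$target_rate)
  h <- resample_stream(hand, config$target_rate)
  drop_null_rows(fuse(b, h, labels, config$target_rate),
                 body_reg, hand_reg, config)
}
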