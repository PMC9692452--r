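#' Body joint registry
#'
#' Maps the two-digit body-joint index tokens used by the scoring formulas
#' to anatomical names and to column positions in the body stream. The body
#' sensor reports 16 physical joints; token "19" (referenced only by the
#' left shoulder-raise formula) is an alias that must resolve to one of the
#' physical joints. The default mapping is a documented, provisional
#' interpretation (the sensor vendor's joint table is not public):
#' 01 head, 02 neck, 03 torso, 04 waist, 05/06 right/left hip,
#' 07-09 right shoulder/elbow/wrist, 10-12 left shoulder/elbow/wrist,
#' 13-16 knees and feet, alias 19 -> left shoulder.
#'
#' @param names named character vector overriding token -> anatomical name.
#' @param aliases named character vector mapping alias tokens to physical
#'   tokens (default `c("19" = "10")`).
#' @param vertical_axis unit vector of the body-sensor frame's vertical
#'   (default `c(0, 0, 1)`).
#' @return an object of class `body_registry`.
#' @export
body_registry <- function(names = NULL, aliases = c("19" = "10"),
                          vertical_axis = c(0, 0, 1)) {
  default <- c("01" = "head", "02" = "neck", "03" = "torso", "04" = "waist",
               "05" = "hip_right", "06" = "hip_left",
               "07" = "shoulder_right", "08" = "elbow_right", "09" = "wrist_right",
               "10" = "shoulder_left", "11" = "elbow_left", "12" = "wrist_left",
               "13" = "knee_right", "14" = "knee_left",
               "15" = "foot_right", "16" = "foot_left")
  if (!is.null(names)) default[base::names(names)] <- names
  if (length(default) != 16L)
    stop("body_registry: exactly 16 physical joints required", call. = FALSE)
  va <- as.numeric(vertical_axis)
  if (abs(sqrt(sum(va^2)) - 1) > 1e-9)
    stop("body_registry: vertical axis must have unit norm", call. = FALSE)
  reg <- list(tokens = base::names(default), names = default,
              aliases = aliases, vertical_axis = va)
  class(reg) <- "body_registry"
  # every token referenced by a scoring formula must resolve
  need <- c(sprintf("%02d", 1:12), "19")
  bad <- need[!vapply(need, function(tk) !is.null(tryCatch(
    resolve_joint(reg, tk), error = function(e) NULL)), logical(1))]
  if (length(bad))
    stop("body_registry: unresolved formula tokens: ",
         paste(bad, collapse = ", "), call. = FALSE)
  reg
}

#' Resolve a body-joint token to its physical token
#'
#' @param registry a [body_registry()].
#' @param token two-digit token, possibly an alias (e.g. "19").
#' @return the physical token (character).
#' @export
resolve_joint <- function(registry, token) {
  token <- as.character(token)
  if (token %in% names(registry$aliases)) token <- registry$aliases[[token]]
  if (!token %in% registry$tokens)
    stop("unregistered body joint token: ", token, call. = FALSE)
  token
}

#' Hand joint registry
#'
#' Each hand has 25 joints labelled L00-L24 / R00-R24. Five joints carry
#' scoring roles: the thumb metacarpal endpoint (04), the index-finger
#' distal-phalanx start (05), the middle-finger proximal-phalanx endpoint
#' (13), the middle-finger metacarpal endpoint (14) and the pinky
#' metacarpal endpoint (24). Joint 00 is the wrist/palm reference used by
#' the `recentered` flexion-extension mode.
#'
#' @param roles named character vector overriding role -> joint index
#'   (indices "00".."24").
#' @return an object of class `hand_registry`.
#' @export
hand_registry <- function(roles = NULL) {
  default_roles <- c(wrist_ref = "00", thumb_mc_end = "04",
                     index_dp_start = "05", middle_pp_end = "13",
                     middle_mc_end = "14", pinky_mc_end = "24")
  if (!is.null(roles)) default_roles[names(roles)] <- roles
  idx <- sprintf("%02d", 0:24)
  if (!all(default_roles %in% idx))
    stop("hand_registry: role indices must lie in 00..24", call. = FALSE)
  reg <- list(indices = idx, roles = default_roles,
              sides = c("L", "R"))
  class(reg) <- "hand_registry"
  reg
}

#' Default pipeline configuration
#'
#' All scoring thresholds, band edges, calibration policy and axis
#' conventions in one auditable list. The shipped defaults are the
#' published RULA thresholds (15 degrees wrist bend, 75/105/165 degree
#' twist bands, the Table-4 body bands) together with the package's
#' documented interpretation choices.
#'
#' @param ... named overrides of top-level or nested keys, e.g.
#'   `wrist = list(mode = "recentered")`. Unknown keys are rejected.
#' @return a nested list of class `rula_config`.
#' @export
rula_config <- function(...) {
  cfg <- list(
    target_rate = 20,              # Hz of the fused grid
    grid_alignment = "center",     # PAA segment-center timestamps
    wrist = list(
      mode = "literal",            # "literal" or "recentered" flexion-extension
      neutral_band_deg = 1,        # half-width of the "exactly 0" band
      bend_threshold_deg = 15,     # radial-ulnar adjustment threshold
      twist_band_deg = 105,        # mid-range / end-of-range split
      calibration = "first_valid"  # or "frame:<k>"
    ),
    body = list(
      neutral_band_deg = 1,
      vertical_axis = c(0, 0, 1),
      anterior_from = c(up_from = "04", up_to = "02",
                        lat_from = "06", lat_to = "05")
    ),
    legs = list(standing_unsupported = TRUE),
    engine = list(max_mode = "per_component",  # or "per_A"
                  muscle = 0, force = 0),
    evaluation = list(stride = 10, alpha = 0.05,
                      var_equal = TRUE, p_adjust = "none")
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad))
      stop("rula_config: unknown keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (k in names(ov)) {
      if (is.list(cfg[[k]]) && is.list(ov[[k]])) {
        bad2 <- setdiff(names(ov[[k]]), names(cfg[[k]]))
        if (length(bad2))
          stop("rula_config: unknown keys under '", k, "': ",
               paste(bad2, collapse = ", "), call. = FALSE)
        cfg[[k]][names(ov[[k]])] <- ov[[k]]
      } else cfg[[k]] <- ov[[k]]
    }
  }
  class(cfg) <- c("rula_config", "list")
  cfg
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' @param path file path to a YAML (requires the `yaml` package) or JSON
#'   configuration whose keys mirror [rula_config()].
#' @return a `rula_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    # minimal JSON via yaml-compatible parse is not safe; use base scan of
    # key: value lines only when yaml is unavailable
    if (requireNamespace("yaml", quietly = TRUE)) yaml::read_yaml(path)
    else stop("unsupported config format: ", path, call. = FALSE)
  }
  do.call(rula_config, raw)
}

# Joint tokens that any scoring formula dereferences; frames where one of
# these is null are dropped before scoring (see drop_null_rows).
required_body_tokens <- function(registry = body_registry()) {
  unique(vapply(c(sprintf("%02d", 1:12), "19"),
                function(tk) resolve_joint(registry, tk), character(1)))
}

required_hand_roles <- function(config = rula_config()) {
  roles <- c("thumb_mc_end", "index_dp_start", "middle_pp_end",
             "middle_mc_end", "pinky_mc_end")
  if (identical(config$wrist$mode, "recentered")) roles <- c(roles, "wrist_ref")
  roles
}
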