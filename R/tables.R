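#' @title RULA lookup tables and score combination
#' @name rula-tables
#' @description
#' The three published RULA lookup matrices, transcribed from the standard
#' RULA employee assessment worksheet (McAtamney & Corlett): Table A maps
#' (upper arm, lower arm, wrist position, wrist twist) to the arm/wrist
#' posture score, Table B maps (neck, trunk, legs) to the neck/trunk/legs
#' posture score, and Table C maps the two section scores (after the
#' muscle-use and force additions, both fixed at 0 here) to the 1-7 grand
#' score. The matrices are fixed published constants; an audit at load
#' time checks their checksums and verifies monotone non-decrease along
#' every argument.
NULL

# Table A: dim = upper arm 1..6, lower arm 1..3, wrist 1..4, twist 1..2
.rula_table_A <- local({
  raw <- c(
    # ua=1
    1,2, 2,2, 2,3, 3,3,   2,2, 2,2, 3,3, 3,3,   2,3, 3,3, 3,3, 4,4,
    # ua=2
    2,3, 3,3, 3,4, 4,4,   3,3, 3,3, 3,4, 4,4,   3,4, 4,4, 4,4, 5,5,
    # ua=3
    3,3, 4,4, 4,4, 5,5,   3,4, 4,4, 4,4, 5,5,   4,4, 4,4, 4,5, 5,5,
    # ua=4
    4,4, 4,4, 4,5, 5,5,   4,4, 4,4, 4,5, 5,5,   4,4, 4,5, 5,5, 6,6,
    # ua=5
    5,5, 5,5, 5,6, 6,7,   5,6, 6,6, 6,7, 7,7,   6,6, 6,7, 7,7, 7,8,
    # ua=6
    7,7, 7,7, 7,8, 8,9,   8,8, 8,8, 8,9, 9,9,   9,9, 9,9, 9,9, 9,9)
  a <- array(NA_integer_, c(6, 3, 4, 2))
  k <- 1L
  for (ua in 1:6) for (la in 1:3) for (w in 1:4) for (tw in 1:2) {
    a[ua, la, w, tw] <- as.integer(raw[k]); k <- k + 1L
  }
  a
})

# Table B: dim = neck 1..6, trunk 1..6, legs 1..2
.rula_table_B <- local({
  raw <- c(
    1,3, 2,3, 3,4, 5,5, 6,6, 7,7,
    2,3, 2,3, 4,5, 5,5, 6,7, 7,7,
    3,3, 3,4, 4,5, 5,6, 6,7, 7,7,
    5,5, 5,6, 6,7, 7,7, 7,7, 8,8,
    7,7, 7,7, 7,8, 8,8, 8,8, 8,8,
    8,8, 8,8, 8,8, 8,9, 9,9, 9,9)
  b <- array(NA_integer_, c(6, 6, 2))
  k <- 1L
  for (nk in 1:6) for (tr in 1:6) for (lg in 1:2) {
    b[nk, tr, lg] <- as.integer(raw[k]); k <- k + 1L
  }
  b
})

# Table C: dim = section A score 1..8 (capped), section B score 1..7 (capped)
.rula_table_C <- matrix(as.integer(c(
  1, 2, 3, 3, 4, 5, 5,
  2, 2, 3, 4, 4, 5, 5,
  3, 3, 3, 4, 4, 5, 6,
  3, 3, 3, 4, 5, 6, 6,
  4, 4, 4, 5, 6, 7, 7,
  4, 4, 5, 6, 6, 7, 7,
  5, 5, 6, 6, 7, 7, 7,
  5, 5, 6, 7, 7, 7, 7)), nrow = 8, byrow = TRUE)

# exhaustive monotonicity audit over the full (small) domains, plus simple
# checksums of the transcriptions; runs once at package load
audit_rula_tables <- function() {
  stopifnot(sum(.rula_table_A) == 705L, sum(.rula_table_B) == 438L,
            sum(.rula_table_C) == 269L)
  non_decreasing_along <- function(a, dim_i) {
    d <- dim(a)
    idx <- expand.grid(lapply(d, seq_len))
    for (r in seq_len(nrow(idx))) {
      i <- as.integer(idx[r, ])
      if (i[dim_i] < d[dim_i]) {
        j <- i; j[dim_i] <- j[dim_i] + 1L
        if (a[matrix(j, 1)] < a[matrix(i, 1)]) return(FALSE)
      }
    }
    TRUE
  }
  for (k in 1:4) stopifnot(non_decreasing_along(.rula_table_A, k))
  for (k in 1:3) stopifnot(non_decreasing_along(.rula_table_B, k))
  for (k in 1:2) stopifnot(non_decreasing_along(.rula_table_C, k))
  invisible(TRUE)
}

.onLoad <- function(libname, pkgname) audit_rula_tables()

#' Checksums of the embedded RULA tables
#' @return named integer vector of element sums for tables A, B and C.
#' @export
rula_table_checksums <- function() {
  c(table_A = sum(.rula_table_A), table_B = sum(.rula_table_B),
    table_C = sum(.rula_table_C))
}

check_domain <- function(value, name, lo, hi) {
  if (is.na(value)) return(NA_integer_)
  v <- as.integer(value)
  if (v < lo || v > hi)
    stop("domain error: ", name, " score ", value, " outside ", lo, "..", hi,
         call. = FALSE)
  v
}

#' RULA section A (arm and wrist) score
#'
#' Table A lookup over the four arm/wrist segment scores, plus the
#' muscle-use and force additions (both 0 under the assembly protocol).
#'
#' @param upper upper-arm score 1..6.
#' @param lower lower-arm score 1..3.
#' @param wrist_position wrist position score 1..4.
#' @param wrist_twist wrist twist score 1..2.
#' @param config a [rula_config()].
#' @return integer section A score (`NA` if any input is `NA`).
#' @export
score_A <- function(upper, lower, wrist_position, wrist_twist,
                    config = rula_config()) {
  ua <- check_domain(upper, "upper arm", 1L, 6L)
  la <- check_domain(lower, "lower arm", 1L, 3L)
  wp <- check_domain(wrist_position, "wrist position", 1L, 4L)
  wt <- check_domain(wrist_twist, "wrist twist", 1L, 2L)
  if (anyNA(c(ua, la, wp, wt))) return(NA_integer_)
  .rula_table_A[ua, la, wp, wt] + as.integer(config$engine$muscle) +
    as.integer(config$engine$force)
}

#' RULA section B (neck, trunk, legs) score
#'
#' @param neck neck score 1..6.
#' @param trunk trunk score 1..6.
#' @param legs legs score 1..2.
#' @param config a [rula_config()].
#' @return integer section B score (`NA` if any input is `NA`).
#' @export
score_B <- function(neck, trunk, legs, config = rula_config()) {
  nk <- check_domain(neck, "neck", 1L, 6L)
  tr <- check_domain(trunk, "trunk", 1L, 6L)
  lg <- check_domain(legs, "legs", 1L, 2L)
  if (anyNA(c(nk, tr, lg))) return(NA_integer_)
  .rula_table_B[nk, tr, lg] + as.integer(config$engine$muscle) +
    as.integer(config$engine$force)
}

#' RULA grand score
#'
#' Table C lookup of the section A and B scores; inputs above the table's
#' last row/column are capped there, so the result is always in 1..7.
#'
#' @param A section A score (>= 1).
#' @param B section B score (>= 1).
#' @return integer grand score 1..7 (`NA` for `NA` input).
#' @export
grand_score <- function(A, B) {
  if (is.na(A) || is.na(B)) return(NA_integer_)
  if (A < 1 || B < 1) stop("domain error: section scores must be >= 1",
                           call. = FALSE)
  .rula_table_C[min(as.integer(A), 8L), min(as.integer(B), 7L)]
}

#' RULA risk level
#'
#' Grand scores 1-2 are negligible risk, 3-4 low (further investigation
#' and change may be needed), 5-6 medium (investigation and change
#' required soon), 7 high (investigation and change required
#' immediately).
#'
#' @param grand integer grand score in 1..7.
#' @return one of `"negligible"`, `"low"`, `"medium"`, `"high"`.
#' @export
risk_level <- function(grand) {
  if (is.na(grand)) return(NA_character_)
  g <- as.integer(grand)
  if (g < 1L || g > 7L)
    stop("domain error: grand score ", grand, " outside 1..7", call. = FALSE)
  c("negligible", "negligible", "low", "low", "medium", "medium",
    "high")[g]
}
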