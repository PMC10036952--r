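#' Random disambiguation sequences
#'
#' Each prime trial carries one independent disambiguation strength per
#' segment, drawn from the flat 21-level grid \{-1.0, -0.9, ..., 0.9, 1.0\}.
#' To keep the 0.1-step grid exact, sequences are represented throughout the
#' package as *integer tenths* (-10L..10L); [tenths_to_strength()] and
#' [strength_to_tenths()] convert between the two encodings.
#'
#' The sign of a stored sequence is absolute: positive values cue the rotation
#' direction labelled "right". The analysis-relative sign (positive = same
#' direction as the preceding probe's report) is applied later by
#' [align_sign()].
#'
#' @param schedule a [kde_schedule()].
#' @param n number of sequences to draw.
#' @return For `n = 1` an integer vector of length `schedule$n_segments`; for
#'   `n > 1` an `n` x `n_segments` integer matrix. Values are tenths in
#'   `-10:10`, i.i.d. uniform over the 21 grid levels. Uses the current RNG
#'   stream, so results are reproducible under `set.seed()`.
#' @examples
#' set.seed(1)
#' generate_sequence(kde_schedule("onset_only"))
#' @export
generate_sequence <- function(schedule, n = 1) {
  validate_schedule(schedule)
  stopifnot(length(n) == 1L, n >= 1)
  vals <- sample(-10L:10L, n * schedule$n_segments, replace = TRUE)
  if (n == 1) {
    return(vals)
  }
  matrix(vals, nrow = n, ncol = schedule$n_segments, byrow = TRUE)
}

#' Convert between integer-tenths and strength encodings
#'
#' @param tenths integer values in `-10:10` (vector or matrix).
#' @param strength numeric disambiguation strengths on the 0.1-step grid in
#'   \[-1, 1\].
#' @return `tenths_to_strength()` returns `tenths / 10`;
#'   `strength_to_tenths()` returns the integer-tenths encoding and errors for
#'   values off the grid.
#' @examples
#' strength_to_tenths(c(-1, 0.3, 0))
#' tenths_to_strength(-10:10)
#' @export
tenths_to_strength <- function(tenths) {
  check_tenths(tenths)
  tenths / 10
}

#' @rdname tenths_to_strength
#' @export
strength_to_tenths <- function(strength) {
  t10 <- round(strength * 10)
  bad <- is.na(strength) | abs(strength * 10 - t10) > 1e-8 | abs(t10) > 10
  if (any(bad)) {
    stop(
      "disambiguation strengths must lie on the 0.1-step grid in [-1, 1]; ",
      "offending value(s): ", paste(strength[bad], collapse = ", "),
      call. = FALSE
    )
  }
  storage.mode(t10) <- "integer"
  t10
}

check_tenths <- function(tenths) {
  bad <- is.na(tenths) | tenths != round(tenths) | abs(tenths) > 10
  if (any(bad)) {
    stop("integer-tenths values must be whole numbers in -10:10", call. = FALSE)
  }
  invisible(tenths)
}

#' Map a disambiguation strength magnitude to front/back dot sizes
#'
#' The rotation direction of the KDE sphere is cued by a dot-size contrast
#' between the front and back surfaces. A fully ambiguous display
#' (magnitude 0) uses 0.2 dva dots everywhere; maximal disambiguation
#' (magnitude 1) uses 0.4 dva front dots and vanishing back dots. The map is
#' linear between these anchors:
#' `front = 0.2 * (1 + m)`, `back = 0.2 * (1 - m)`, so `front + back = 0.4`
#' for every magnitude.
#'
#' @param magnitude unsigned disambiguation strength(s) in \[0, 1\].
#' @return A data frame with columns `front_dva` and `back_dva` (degrees of
#'   visual angle), one row per input magnitude.
#' @examples
#' strength_to_dot_sizes(c(0, 0.5, 1))
#' @export
strength_to_dot_sizes <- function(magnitude) {
  if (length(magnitude) == 0 || any(!is.finite(magnitude)) ||
      any(magnitude < 0 | magnitude > 1)) {
    stop("'magnitude' must be in [0, 1]", call. = FALSE)
  }
  data.frame(
    front_dva = 0.2 * (1 + magnitude),
    back_dva = 0.2 * (1 - magnitude)
  )
}
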