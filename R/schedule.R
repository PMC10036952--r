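#' Disambiguation schedules
#'
#' A schedule describes when, within a prime presentation, the random
#' disambiguation segments are shown. Three variants are supported, matching
#' the three experimental designs the pipeline analyses:
#'
#' \describe{
#'   \item{`onset_only`}{10 segments of 30 ms covering the first 300 ms of an
#'     800 ms presentation; the remaining 500 ms are fully ambiguous.}
#'   \item{`full`}{10 segments of 30 ms covering an entire 300 ms
#'     presentation.}
#'   \item{`onset_offset`}{20 segments of 30 ms; segments 1-10 cover the first
#'     300 ms and segments 11-20 the last 300 ms of a 1000 ms presentation,
#'     with a fully ambiguous 400 ms gap in between.}
#' }
#'
#' `n_segments` and `segment_ms` may be overridden (e.g. for small test
#' problems); presentation time is then recomputed keeping the variant's
#' layout: `onset_only` keeps a 500 ms ambiguous tail, `full` has none, and
#' `onset_offset` keeps a 400 ms ambiguous gap between its two halves (and
#' requires an even `n_segments`).
#'
#' @param variant schedule variant, one of `"onset_only"`, `"full"`,
#'   `"onset_offset"`.
#' @param n_segments number of independent disambiguation segments.
#' @param segment_ms duration of one segment in milliseconds.
#'
#' @return An object of class `kde_schedule`: a list with elements `variant`,
#'   `n_segments`, `segment_ms`, `presentation_ms` and `segment_onsets_ms`.
#' @examples
#' kde_schedule("onset_only")
#' segment_onset_times(kde_schedule("onset_offset"))
#' @export
kde_schedule <- function(variant = c("onset_only", "full", "onset_offset"),
                         n_segments = NULL, segment_ms = NULL) {
  variant <- match.arg(variant)
  segment_ms <- as.numeric(segment_ms %||% 30)
  n_segments <- as.integer(n_segments %||% if (variant == "onset_offset") 20L else 10L)
  if (length(n_segments) != 1L || is.na(n_segments) || n_segments < 1L) {
    stop("'n_segments' must be a single positive integer", call. = FALSE)
  }
  if (length(segment_ms) != 1L || !is.finite(segment_ms) || segment_ms <= 0) {
    stop("'segment_ms' must be a single positive duration in ms", call. = FALSE)
  }

  if (variant == "onset_only") {
    onsets <- (seq_len(n_segments) - 1) * segment_ms
    presentation_ms <- n_segments * segment_ms + 500
  } else if (variant == "full") {
    onsets <- (seq_len(n_segments) - 1) * segment_ms
    presentation_ms <- n_segments * segment_ms
  } else {
    if (n_segments %% 2L != 0L) {
      stop("'onset_offset' schedules need an even number of segments", call. = FALSE)
    }
    half <- n_segments %/% 2L
    presentation_ms <- n_segments * segment_ms + 400
    onsets <- c(
      (seq_len(half) - 1) * segment_ms,
      presentation_ms - half * segment_ms + (seq_len(half) - 1) * segment_ms
    )
  }

  out <- structure(
    list(
      variant = variant,
      n_segments = n_segments,
      segment_ms = segment_ms,
      presentation_ms = presentation_ms,
      segment_onsets_ms = onsets
    ),
    class = "kde_schedule"
  )
  validate_schedule(out)
  out
}

validate_schedule <- function(schedule) {
  if (!inherits(schedule, "kde_schedule")) {
    stop("expected a 'kde_schedule' object", call. = FALSE)
  }
  ons <- schedule$segment_onsets_ms
  stopifnot(
    length(ons) == schedule$n_segments,
    !is.unsorted(ons, strictly = TRUE),
    all(ons + schedule$segment_ms <= schedule$presentation_ms + 1e-9)
  )
  invisible(schedule)
}

#' @export
print.kde_schedule <- function(x, ...) {
  cat(sprintf(
    "<kde_schedule '%s'>: %d segments x %g ms within %g ms presentation\n",
    x$variant, x$n_segments, x$segment_ms, x$presentation_ms
  ))
  cat("onsets (ms):", paste(x$segment_onsets_ms, collapse = ", "), "\n")
  invisible(x)
}

#' Segment onset times
#'
#' @param schedule a [kde_schedule()].
#' @return Numeric vector of onset times in milliseconds, one per segment,
#'   strictly increasing.
#' @examples
#' segment_onset_times(kde_schedule("onset_only"))
#' @export
segment_onset_times <- function(schedule) {
  validate_schedule(schedule)
  schedule$segment_onsets_ms
}
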