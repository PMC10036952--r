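#' Align a disambiguation sequence to the preceding probe's report
#'
#' Stored sequences use an absolute sign convention (positive = cues the
#' rotation direction "right"). The analysis works with strengths relative to
#' the *expected* direction -- the direction reported on the leading probe --
#' so that positive values bias toward the same percept and negative values
#' against it. Aligning negates the sequence iff the leading report is
#' `"left"`; applying the same alignment twice returns the input.
#'
#' @param raw_sequence numeric or integer vector (or matrix, one sequence per
#'   row) of signed strengths in the absolute convention.
#' @param leading_probe_report `"left"` or `"right"` (vector of one per row
#'   for matrix input). Missing reports are an error.
#' @return The sequence(s) in the probe-relative sign convention.
#' @examples
#' align_sign(c(0.5, -0.2), "left")
#' @export
align_sign <- function(raw_sequence, leading_probe_report) {
  if (any(is.na(leading_probe_report)) ||
      !all(leading_probe_report %in% c("left", "right"))) {
    stop("leading probe report must be 'left' or 'right' (not missing)",
         call. = FALSE)
  }
  sgn <- ifelse(leading_probe_report == "right", 1, -1)
  if (is.matrix(raw_sequence)) {
    stopifnot(length(sgn) %in% c(1L, nrow(raw_sequence)))
    return(raw_sequence * sgn)
  }
  stopifnot(length(sgn) == 1L)
  raw_sequence * sgn
}

#' Classify a probe-prime-probe triplet's perceptual outcome
#'
#' The prime's perception counts as changed iff its report differs from the
#' leading probe's report; perceptual memory counts as changed iff the
#' trailing probe's report differs from the leading probe's report. The 2 x 2
#' combination gives four outcome classes.
#'
#' @param leading,prime,trailing reports (`"left"`/`"right"`), vectorised.
#' @return A factor with levels `both_changed`, `prime_only`, `memory_only`,
#'   `no_change`.
#' @examples
#' classify_outcome("left", "right", "right") # both_changed
#' @export
classify_outcome <- function(leading, prime, trailing) {
  ok <- c("left", "right")
  if (!all(leading %in% ok) || !all(prime %in% ok) || !all(trailing %in% ok)) {
    stop("all three reports must be 'left' or 'right'", call. = FALSE)
  }
  prime_chg <- prime != leading
  mem_chg <- trailing != leading
  lab <- ifelse(prime_chg & mem_chg, "both_changed",
         ifelse(prime_chg, "prime_only",
         ifelse(mem_chg, "memory_only", "no_change")))
  factor(lab, levels = c("both_changed", "prime_only", "memory_only", "no_change"))
}

#' Build probe-prime-probe triplets from a session
#'
#' Walks each participant's trials in order and forms one triplet per prime
#' whose own report and both flanking probes' reports are valid. Sequences are
#' converted to strengths and sign-aligned to the leading probe's report. With
#' `overlap = "sliding"` (default) a probe may serve as the trailing probe of
#' one triplet and the leading probe of the next; `"disjoint"` greedily drops
#' triplets that would reuse a probe.
#'
#' @param session a `kde_session` data frame ([simulate_session()],
#'   [read_trial_log()]), possibly spanning several participants.
#' @param overlap `"sliding"` or `"disjoint"`.
#' @return A data frame of class `kde_triplets` with columns `participant`,
#'   `prime_trial_index`, `report_lead`, `report_prime`, `report_trail`,
#'   `outcome` (see [classify_outcome()]) and sign-aligned strength columns
#'   `seg_01 ...`. May have zero rows. The schedule travels along as attribute
#'   `"schedule"`.
#' @export
build_triplets <- function(session, overlap = c("sliding", "disjoint")) {
  overlap <- match.arg(overlap)
  schedule <- attr(session, "schedule")
  if (is.null(schedule)) {
    stop("'session' must carry a schedule attribute", call. = FALSE)
  }
  nseg <- schedule$n_segments
  seg_cols <- sprintf("seg_%02d", seq_len(nseg))
  stopifnot(all(seg_cols %in% names(session)))

  one_participant <- function(df) {
    df <- df[order(df$trial_index), , drop = FALSE]
    n <- nrow(df)
    keep <- integer(0)
    last_trail <- -1L
    for (j in seq_len(n)) {
      if (df$trial_type[j] != "prime") next
      if (j == 1L || j == n) next
      if (df$trial_type[j - 1L] != "probe" || df$trial_type[j + 1L] != "probe") next
      reps <- df$report[c(j - 1L, j, j + 1L)]
      if (any(reps == "missing")) next
      if (overlap == "disjoint" && (j - 1L) == last_trail) next
      keep <- c(keep, j)
      last_trail <- j + 1L
    }
    if (length(keep) == 0L) {
      return(NULL)
    }
    raw <- as.matrix(df[keep, seg_cols, drop = FALSE]) / 10
    lead <- df$report[keep - 1L]
    out <- data.frame(
      participant = df$participant[keep],
      prime_trial_index = df$trial_index[keep],
      report_lead = lead,
      report_prime = df$report[keep],
      report_trail = df$report[keep + 1L],
      stringsAsFactors = FALSE
    )
    out$outcome <- classify_outcome(out$report_lead, out$report_prime, out$report_trail)
    aligned <- as.data.frame(align_sign(raw, lead))
    names(aligned) <- seg_cols
    rownames(aligned) <- NULL
    cbind(out, aligned)
  }

  pieces <- lapply(split(as.data.frame(session), session$participant), one_participant)
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  out <- if (length(pieces) == 0L) {
    empty <- data.frame(
      participant = character(0), prime_trial_index = integer(0),
      report_lead = character(0), report_prime = character(0),
      report_trail = character(0),
      outcome = factor(character(0),
                       levels = c("both_changed", "prime_only", "memory_only", "no_change")),
      stringsAsFactors = FALSE
    )
    for (cl in seg_cols) empty[[cl]] <- numeric(0)
    empty
  } else {
    do.call(rbind, pieces)
  }
  rownames(out) <- NULL
  structure(out, schedule = schedule, overlap = overlap,
            class = c("kde_triplets", "data.frame"))
}

# outcome classes entering each selection set
selection_outcomes <- function(selection = c("prime_changed", "memory_changed")) {
  selection <- match.arg(selection)
  if (selection == "prime_changed") {
    c("both_changed", "prime_only")
  } else {
    c("both_changed", "memory_only")
  }
}

select_triplets <- function(triplets, selection) {
  stopifnot(inherits(triplets, "kde_triplets"))
  triplets[triplets$outcome %in% selection_outcomes(selection), , drop = FALSE]
}

triplet_seg_matrix <- function(triplets) {
  schedule <- attr(triplets, "schedule")
  seg_cols <- sprintf("seg_%02d", seq_len(schedule$n_segments))
  as.matrix(triplets[, seg_cols, drop = FALSE])
}
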