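#' Reverse-correlation average of selected disambiguation sequences
#'
#' Averages the sign-aligned sequences of the triplets in a selection set:
#' `"prime_changed"` pools the `both_changed` and `prime_only` outcome classes
#' (sequences that altered the perception of the prime itself);
#' `"memory_changed"` pools `both_changed` and `memory_only` (sequences that
#' altered the memory read out by the trailing probe).
#'
#' @param triplets a `kde_triplets` data frame ([build_triplets()]); pass a
#'   single participant's rows for an individual average, or all rows for a
#'   pooled one.
#' @param selection `"prime_changed"` or `"memory_changed"`.
#' @return An object of class `rc_estimate`: a data frame with one row per
#'   segment (`segment_index`, `onset_ms`, `mean`, `n_trials`). When no
#'   triplet qualifies the means are `NA`, `n_trials` is 0 and the attribute
#'   `"empty"` is `TRUE` -- an explicit "no qualifying trials" result rather
#'   than a silent zero.
#' @export
average_sequence <- function(triplets, selection = c("prime_changed", "memory_changed")) {
  selection <- match.arg(selection)
  sel <- select_triplets(triplets, selection)
  schedule <- attr(triplets, "schedule")
  n <- nrow(sel)
  means <- if (n == 0L) rep(NA_real_, schedule$n_segments) else colMeans(triplet_seg_matrix(sel))
  out <- data.frame(
    segment_index = seq_len(schedule$n_segments),
    onset_ms = schedule$segment_onsets_ms,
    mean = unname(means),
    n_trials = n
  )
  structure(out, selection = selection, schedule = schedule, empty = n == 0L,
            class = c("rc_estimate", "data.frame"))
}

#' Per-participant bootstrap confidence intervals for segment averages
#'
#' For each participant and each disambiguation segment separately, resamples
#' the selected triplets' aligned strengths with replacement `n_iterations`
#' times and takes the equal-tailed percentile interval of the resampled means
#' at mass `interval_mass`.
#'
#' @inheritParams average_sequence
#' @param n_iterations bootstrap iterations (default 2000).
#' @param interval_mass central interval mass (default 0.97).
#' @param seed optional integer seed; when given, the caller's RNG stream is
#'   left untouched.
#' @return An `rc_estimate` data frame with one row per participant x segment:
#'   `participant`, `segment_index`, `onset_ms`, `mean`, `ci_lo`, `ci_hi`,
#'   `n_trials`.
#' @export
bootstrap_individual <- function(triplets,
                                 selection = c("prime_changed", "memory_changed"),
                                 n_iterations = 2000, interval_mass = 0.97,
                                 seed = NULL) {
  selection <- match.arg(selection)
  check_bootstrap_config(n_iterations, interval_mass)
  sel <- select_triplets(triplets, selection)
  if (nrow(sel) == 0L) {
    stop("no qualifying trials for selection '", selection, "'", call. = FALSE)
  }
  schedule <- attr(triplets, "schedule")
  probs <- c((1 - interval_mass) / 2, 1 - (1 - interval_mass) / 2)

  with_seed(seed, {
    pieces <- lapply(split(sel, sel$participant, drop = TRUE), function(df) {
      m <- triplet_seg_matrix(df)
      n <- nrow(m)
      ci <- apply(m, 2, function(v) {
        bm <- colMeans(matrix(sample(v, n * n_iterations, replace = TRUE),
                              nrow = n, ncol = n_iterations))
        quantile(bm, probs, names = FALSE)
      })
      data.frame(
        participant = df$participant[1L],
        segment_index = seq_len(schedule$n_segments),
        onset_ms = schedule$segment_onsets_ms,
        mean = unname(colMeans(m)),
        ci_lo = ci[1L, ],
        ci_hi = ci[2L, ],
        n_trials = n,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    structure(out, selection = selection, schedule = schedule,
              interval_mass = interval_mass, level = "individual",
              class = c("rc_estimate", "data.frame"))
  })
}

#' Group-level bootstrap confidence intervals for segment averages
#'
#' Each bootstrap iteration resamples, per segment, every participant's
#' selected strengths with replacement within that participant, computes
#' participant means, and averages them (unweighted) into a group mean; the
#' interval is the percentile interval of those group means. The reported
#' `mean` is the unweighted mean of participant means.
#'
#' @inheritParams bootstrap_individual
#' @return An `rc_estimate` data frame with one row per segment and
#'   `participant = "group"`; `n_trials` is the total number of selected
#'   triplets across participants.
#' @export
bootstrap_group <- function(triplets,
                            selection = c("prime_changed", "memory_changed"),
                            n_iterations = 2000, interval_mass = 0.97,
                            seed = NULL) {
  selection <- match.arg(selection)
  check_bootstrap_config(n_iterations, interval_mass)
  sel <- select_triplets(triplets, selection)
  parts <- split(sel, sel$participant, drop = TRUE)
  if (length(parts) < 2L) {
    stop("group bootstrap needs >= 2 participants with qualifying triplets",
         call. = FALSE)
  }
  schedule <- attr(triplets, "schedule")
  nseg <- schedule$n_segments
  probs <- c((1 - interval_mass) / 2, 1 - (1 - interval_mass) / 2)
  mats <- lapply(parts, triplet_seg_matrix)

  with_seed(seed, {
    group_means <- matrix(0, nrow = n_iterations, ncol = nseg)
    point <- rep(0, nseg)
    for (m in mats) {
      n <- nrow(m)
      point <- point + colMeans(m) / length(mats)
      for (s in seq_len(nseg)) {
        bm <- colMeans(matrix(sample(m[, s], n * n_iterations, replace = TRUE),
                              nrow = n, ncol = n_iterations))
        group_means[, s] <- group_means[, s] + bm / length(mats)
      }
    }
    ci <- apply(group_means, 2, quantile, probs = probs, names = FALSE)
    out <- data.frame(
      participant = "group",
      segment_index = seq_len(nseg),
      onset_ms = schedule$segment_onsets_ms,
      mean = unname(point),
      ci_lo = ci[1L, ],
      ci_hi = ci[2L, ],
      n_trials = nrow(sel),
      stringsAsFactors = FALSE
    )
    structure(out, selection = selection, schedule = schedule,
              interval_mass = interval_mass, level = "group",
              class = c("rc_estimate", "data.frame"))
  })
}

check_bootstrap_config <- function(n_iterations, interval_mass) {
  if (length(n_iterations) != 1L || n_iterations < 1) {
    stop("'n_iterations' must be >= 1", call. = FALSE)
  }
  if (length(interval_mass) != 1L || interval_mass <= 0 || interval_mass >= 1) {
    stop("'interval_mass' must be in (0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.rc_estimate <- function(x, digits = 3, ...) {
  sel <- attr(x, "selection")
  if (isTRUE(attr(x, "empty"))) {
    cat(sprintf("<rc_estimate '%s'>: no qualifying trials\n", sel))
    return(invisible(x))
  }
  lvl <- attr(x, "level") %||% "average"
  cat(sprintf("<rc_estimate '%s', %s level>\n", sel, lvl))
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot a reverse-correlation estimate
#'
#' Per-segment means against onset time, with confidence-interval error bars
#' when present; one panel per participant.
#'
#' @param x an `rc_estimate`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rc_estimate <- function(x, ...) {
  df <- as.data.frame(x)
  if (isTRUE(attr(x, "empty"))) {
    stop("nothing to plot: no qualifying trials", call. = FALSE)
  }
  parts <- if ("participant" %in% names(df)) unique(df$participant) else "all"
  if (length(parts) > 1L) {
    old <- par(mfrow = c(1, length(parts)))
    on.exit(par(old), add = TRUE)
  }
  for (p in parts) {
    d <- if ("participant" %in% names(df)) df[df$participant == p, ] else df
    ylim <- range(0, d$mean, d$ci_lo, d$ci_hi, na.rm = TRUE)
    plot(d$onset_ms, d$mean,
         xlab = "segment onset (ms)", ylab = "disambiguation strength",
         main = p, ylim = ylim, pch = 19, ...)
    abline(h = 0, lty = 3)
    if (!is.null(d$ci_lo)) {
      arrows(d$onset_ms, d$ci_lo, d$onset_ms, d$ci_hi,
             angle = 90, code = 3, length = 0.03)
    }
  }
  invisible(x)
}
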