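#' Synthetic bistable observer
#'
#' A generative stand-in for a human participant in the probe-prime-probe
#' design. The observer carries its perceptual-memory state between trials as
#' the previous probe's (drawn) report. A prime's sign-aligned disambiguation
#' sequence is pooled linearly through a temporal kernel into a scalar drive
#' `d` ([drive()]), and both the prime's own report and the next probe's
#' report are Bernoulli draws whose "same direction as the preceding probe"
#' probability is a lapse-mixed logistic in `d` ([response_probabilities()]).
#'
#' The kernel `kappa` is the observer's per-segment sensitivity to
#' disambiguation *supporting the currently dominant direction*: positive
#' entries mean that same-direction disambiguation in that segment stabilises
#' perception and memory. Consequently the reverse-correlation average over
#' *changed* trials recovers the change-directed profile `-kappa` (a negative
#' early bump for the default kernel), which is the shape the analysis is
#' designed to estimate. The default kernel, `default_kernel()`, is a bump
#' `0.6 * exp(-(k - 2)^2 / 4)` over segments 1-5 (peak at segment 2, i.e.
#' 30-60 ms after onset) and exactly zero afterwards, so that late segments
#' are genuinely uninformative and serve as a built-in null region.
#'
#' @param kernel numeric kernel, one weight per schedule segment; defaults to
#'   `default_kernel(n_segments)` when a schedule is supplied to
#'   [simulate_session()].
#' @param gain_perception,gain_memory non-negative logistic gains applied to
#'   the drive for the prime report and the following probe report. The
#'   defaults (1 and 0.5) encode the empirical regime in which perceptual
#'   memory is altered by weaker disambiguation than prime perception, so the
#'   memory-changed reverse-correlation curve has roughly half the amplitude
#'   of the perception-changed curve.
#' @param baseline_perception,baseline_memory logistic baselines (log-odds of
#'   reporting the same direction as the preceding probe at zero drive);
#'   the default of 2 gives about 88\% persistence.
#' @param lapse probability of a uniformly random report, in \[0, 0.2\].
#' @param p_miss probability that a response is missing, in \[0, 0.2\].
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(kernel = default_kernel(10))
#' @export
observer_params <- function(kernel = NULL,
                            gain_perception = 1,
                            gain_memory = 0.5,
                            baseline_perception = 2,
                            baseline_memory = 2,
                            lapse = 0.05,
                            p_miss = 0.02) {
  stopifnot(
    length(gain_perception) == 1L, is.finite(gain_perception), gain_perception >= 0,
    length(gain_memory) == 1L, is.finite(gain_memory), gain_memory >= 0,
    length(baseline_perception) == 1L, is.finite(baseline_perception),
    length(baseline_memory) == 1L, is.finite(baseline_memory)
  )
  if (length(lapse) != 1L || !is.finite(lapse) || lapse < 0 || lapse > 0.2) {
    stop("'lapse' must be in [0, 0.2]", call. = FALSE)
  }
  if (length(p_miss) != 1L || !is.finite(p_miss) || p_miss < 0 || p_miss > 0.2) {
    stop("'p_miss' must be in [0, 0.2]", call. = FALSE)
  }
  if (!is.null(kernel) && any(!is.finite(kernel))) {
    stop("'kernel' must be finite", call. = FALSE)
  }
  structure(
    list(
      kernel = kernel,
      gain_perception = gain_perception,
      gain_memory = gain_memory,
      baseline_perception = baseline_perception,
      baseline_memory = baseline_memory,
      lapse = lapse,
      p_miss = p_miss
    ),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf(
    "  gains (perception/memory): %g / %g; baselines: %g / %g\n",
    x$gain_perception, x$gain_memory, x$baseline_perception, x$baseline_memory
  ))
  cat(sprintf("  lapse: %g; p_miss: %g\n", x$lapse, x$p_miss))
  if (is.null(x$kernel)) {
    cat("  kernel: default (set from the schedule at simulation time)\n")
  } else {
    cat("  kernel:", paste(signif(x$kernel, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname observer_params
#' @param n_segments number of segments the kernel should cover.
#' @export
default_kernel <- function(n_segments) {
  k <- seq_len(n_segments)
  kappa <- 0.6 * exp(-(k - 2)^2 / 4)
  kappa[k > 5] <- 0
  kappa
}

#' Linear evidence pooling of a disambiguation sequence
#'
#' @param sequence_rel numeric sign-aligned strengths (positive = same
#'   direction as the preceding probe's report).
#' @param kernel numeric kernel of the same length.
#' @return The scalar drive `sum(kernel * sequence_rel)`.
#' @examples
#' drive(c(1, 0, 0), c(0.5, 0.2, 0.1))
#' @export
drive <- function(sequence_rel, kernel) {
  if (length(sequence_rel) != length(kernel)) {
    stop("'sequence_rel' and 'kernel' must have the same length", call. = FALSE)
  }
  sum(kernel * sequence_rel)
}

#' Report probabilities given a drive
#'
#' Probability that the prime report, and the following probe report, have the
#' same direction as the preceding probe's report:
#' `p = lapse/2 + (1 - lapse) * plogis(baseline + gain * d)`, with the
#' perception channel (`gain_perception`, `baseline_perception`) for the prime
#' and the memory channel for the following probe. Lapses are split evenly
#' between the two directions so they introduce no direction bias.
#'
#' @param d scalar drive(s) from [drive()].
#' @param params an [observer_params()] object.
#' @return A data frame with columns `p_prime_same` and `p_probe_next_same`,
#'   one row per element of `d`. Both are nondecreasing in `d`.
#' @examples
#' response_probabilities(0, observer_params(lapse = 0))
#' @export
response_probabilities <- function(d, params) {
  stopifnot(inherits(params, "observer_params"), all(is.finite(d)))
  lam <- params$lapse
  data.frame(
    p_prime_same = lam / 2 +
      (1 - lam) * plogis(params$baseline_perception + params$gain_perception * d),
    p_probe_next_same = lam / 2 +
      (1 - lam) * plogis(params$baseline_memory + params$gain_memory * d)
  )
}

flip_dir <- function(dir) ifelse(dir == "right", "left", "right")

#' Simulate a probe-prime-probe session
#'
#' Generates one participant's session: an alternating sequence of fully
#' ambiguous probes and randomly disambiguated primes, ending with a trailing
#' probe after the final prime. A prime is presented only after a probe with a
#' valid (non-missing) report; after any missing report the next trial is a
#' probe. Missing responses are injected independently with probability
#' `p_miss`; when a report is missing the internally drawn percept still
#' updates the memory state, only the record shows `"missing"`.
#'
#' @param params an [observer_params()]; a `NULL` kernel is replaced by
#'   `default_kernel(schedule$n_segments)`.
#' @param schedule a [kde_schedule()].
#' @param n_primes number of prime trials to present (>= 1).
#' @param participant participant identifier.
#' @return A data frame of class `kde_session` with columns `participant`,
#'   `trial_index`, `trial_type` (`"probe"`/`"prime"`), `report` (`"left"`,
#'   `"right"`, `"missing"`) and `seg_01 ...` integer-tenths disambiguation
#'   columns (`NA` on probes; absolute sign, positive = cues "right"). The
#'   schedule is attached as attribute `"schedule"`. Uses the current RNG
#'   stream.
#' @examples
#' set.seed(8)
#' sess <- simulate_session(observer_params(p_miss = 0),
#'                          kde_schedule("onset_only"), n_primes = 5)
#' table(sess$trial_type)
#' @export
simulate_session <- function(params, schedule, n_primes, participant = "obs01") {
  stopifnot(inherits(params, "observer_params"))
  validate_schedule(schedule)
  if (length(n_primes) != 1L || n_primes < 1) {
    stop("'n_primes' must be >= 1", call. = FALSE)
  }
  nseg <- schedule$n_segments
  kernel <- params$kernel %||% default_kernel(nseg)
  if (length(kernel) != nseg) {
    stop("kernel length must match the schedule's number of segments", call. = FALSE)
  }

  n_max <- 2L * n_primes + 2L + stats::qbinom(1 - 1e-9, 4L * n_primes, params$p_miss)
  trial_type <- character(n_max)
  report <- character(n_max)
  seqs <- matrix(NA_integer_, n_max, nseg)

  lam <- params$lapse
  p_persist_probe <- lam / 2 + (1 - lam) * plogis(params$baseline_memory)

  ti <- 0L
  k_prime <- 0L
  mem_dir <- NA_character_ # most recent probe percept (memory state)
  last_valid <- FALSE      # previous trial had a valid report
  pending_d <- NA_real_    # drive of the last prime, not yet read out

  repeat {
    ti <- ti + 1L
    if (ti > n_max) { # extremely miss-heavy runs; grow storage
      trial_type <- c(trial_type, character(n_max))
      report <- c(report, character(n_max))
      seqs <- rbind(seqs, matrix(NA_integer_, n_max, nseg))
      n_max <- 2L * n_max
    }
    if (last_valid && trial_type[ti - 1L] == "probe" && k_prime < n_primes) {
      # prime trial
      k_prime <- k_prime + 1L
      raw <- generate_sequence(schedule)
      seqs[ti, ] <- raw
      d <- drive(align_sign(raw / 10, mem_dir), kernel)
      p <- response_probabilities(d, params)
      if (runif(1) < params$p_miss) {
        report[ti] <- "missing"
      } else {
        same <- runif(1) < p$p_prime_same
        report[ti] <- if (same) mem_dir else flip_dir(mem_dir)
      }
      trial_type[ti] <- "prime"
      pending_d <- d
    } else {
      # probe trial
      trial_type[ti] <- "probe"
      if (is.na(mem_dir)) {
        percept <- if (runif(1) < 0.5) "right" else "left"
      } else {
        p_same <- if (is.na(pending_d)) {
          p_persist_probe
        } else {
          response_probabilities(pending_d, params)$p_probe_next_same
        }
        percept <- if (runif(1) < p_same) mem_dir else flip_dir(mem_dir)
      }
      pending_d <- NA_real_
      mem_dir <- percept
      report[ti] <- if (runif(1) < params$p_miss) "missing" else percept
    }
    last_valid <- report[ti] != "missing"
    if (k_prime == n_primes && trial_type[ti] == "probe") {
      break
    }
  }

  out <- data.frame(
    participant = rep(participant, ti),
    trial_index = seq_len(ti),
    trial_type = trial_type[seq_len(ti)],
    report = report[seq_len(ti)],
    stringsAsFactors = FALSE
  )
  segs <- as.data.frame(seqs[seq_len(ti), , drop = FALSE])
  names(segs) <- sprintf("seg_%02d", seq_len(nseg))
  out <- cbind(out, segs)
  structure(out, schedule = schedule, class = c("kde_session", "data.frame"))
}

#' Simulate a multi-participant experiment
#'
#' @inheritParams simulate_session
#' @param n_participants number of participants.
#' @param participants participant identifiers (defaults to
#'   `obs01, obs02, ...`).
#' @param params a single [observer_params()] shared by all participants, or a
#'   list with one `observer_params` per participant.
#' @return A `kde_session` data frame with all participants' trials stacked.
#' @export
simulate_experiment <- function(params, schedule, n_participants, n_primes,
                                participants = sprintf("obs%02d", seq_len(n_participants))) {
  stopifnot(n_participants >= 1, length(participants) == n_participants)
  if (inherits(params, "observer_params")) {
    params <- rep(list(params), n_participants)
  }
  stopifnot(length(params) == n_participants)
  sessions <- lapply(seq_len(n_participants), function(i) {
    simulate_session(params[[i]], schedule, n_primes, participant = participants[i])
  })
  out <- do.call(rbind, lapply(sessions, as.data.frame))
  structure(out, schedule = schedule, class = c("kde_session", "data.frame"))
}
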