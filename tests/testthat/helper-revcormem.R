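# shared fixtures and independent oracles ------------------------------------

# construct a kde_triplets object directly (bypassing session building) so the
# averaging/bootstrap operations can be tested on hand-chosen values
make_triplets <- function(values, participant = "p1",
                          outcome = "memory_only",
                          schedule = NULL) {
  values <- as.matrix(values)
  if (is.null(schedule)) {
    schedule <- kde_schedule("full", n_segments = ncol(values))
  }
  n <- nrow(values)
  df <- data.frame(
    participant = rep_len(participant, n),
    prime_trial_index = seq_len(n) * 2L,
    report_lead = "right",
    report_prime = "left",
    report_trail = "left",
    outcome = factor(rep_len(outcome, n),
                     levels = c("both_changed", "prime_only", "memory_only", "no_change")),
    stringsAsFactors = FALSE
  )
  segs <- as.data.frame(values)
  names(segs) <- sprintf("seg_%02d", seq_len(ncol(values)))
  out <- cbind(df, segs)
  structure(out, schedule = schedule, overlap = "sliding",
            class = c("kde_triplets", "data.frame"))
}

# hand-build a kde_session from trial types / reports / sequences (tenths)
make_session <- function(trial_type, report, seqs = NULL, participant = "p1",
                         schedule = kde_schedule("full", n_segments = 2)) {
  n <- length(trial_type)
  nseg <- schedule$n_segments
  m <- matrix(NA_integer_, n, nseg)
  if (!is.null(seqs)) {
    for (i in seq_along(seqs)) {
      if (!is.null(seqs[[i]])) m[i, ] <- seqs[[i]]
    }
  } else {
    m[trial_type == "prime", ] <- 1L
  }
  df <- data.frame(
    participant = rep_len(participant, n),
    trial_index = seq_len(n),
    trial_type = trial_type,
    report = report,
    stringsAsFactors = FALSE
  )
  segs <- as.data.frame(m)
  names(segs) <- sprintf("seg_%02d", seq_len(nseg))
  out <- cbind(df, segs)
  structure(out, schedule = schedule, class = c("kde_session", "data.frame"))
}

# Cox-de Boor recursion, written independently of splines::splineDesign, as
# the oracle for the B-spline basis
deboor_basis <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  b0 <- function(i, t) {
    # zero-degree: indicator of [knots[i], knots[i+1]), closed at the far end
    as.numeric((t >= knots[i] & t < knots[i + 1]) |
                 (t == knots[length(knots)] & knots[i + 1] == knots[length(knots)] &
                    knots[i] < knots[i + 1]))
  }
  bspl <- function(i, d, t) {
    if (d == 0) {
      return(b0(i, t))
    }
    left <- 0
    den1 <- knots[i + d] - knots[i]
    if (den1 > 0) {
      left <- (t - knots[i]) / den1 * bspl(i, d - 1L, t)
    }
    right <- 0
    den2 <- knots[i + d + 1] - knots[i + 1]
    if (den2 > 0) {
      right <- (knots[i + d + 1] - t) / den2 * bspl(i + 1L, d - 1L, t)
    }
    left + right
  }
  vapply(seq_len(nb), function(i) bspl(i, degree, x), numeric(length(x)))
}

# exact leave-one-out log predictive densities for the conjugate model
# y ~ N(theta, s2_known), theta ~ N(mu0, tau0^2)
exact_loo_normal <- function(y, s2, mu0, tau02) {
  vapply(seq_along(y), function(i) {
    yi <- y[-i]
    post_prec <- 1 / tau02 + length(yi) / s2
    post_mean <- (mu0 / tau02 + sum(yi) / s2) / post_prec
    dnorm(y[i], post_mean, sqrt(1 / post_prec + s2), log = TRUE)
  }, 0)
}
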