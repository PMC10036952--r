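# column-extraction helpers for rc_fit draw matrices -------------------------

fit_is_dual <- function(fit) startsWith(fit$model, "dual_")

# posterior draws of mu for a subset of observations; S x length(idx)
mu_draws <- function(fit, idx = seq_along(fit$obs$bias)) {
  d <- fit$draws
  P <- fit$obs$P[idx]
  seg <- fit$obs$seg[idx]
  if (fit$model == "linear") {
    a <- d[, sprintf("a_p[%d]", P), drop = FALSE]
    b <- d[, sprintf("b_p[%d]", P), drop = FALSE]
    a + sweep(b, 2, seg - 1, `*`)
  } else if (fit$model == "additive") {
    d[, sprintf("curve[%d]", seg), drop = FALSE] *
      d[, sprintf("w_p[%d]", P), drop = FALSE]
  } else {
    cond <- fit$obs$cond[idx]
    d[, sprintf("curve[%d,%d]", seg, cond), drop = FALSE] *
      d[, sprintf("w_p[%d,%d]", P, cond), drop = FALSE]
  }
}

# residual-sd draws per observation subset; S x length(idx)
sigma_draws <- function(fit, idx = seq_along(fit$obs$bias)) {
  if (fit_is_dual(fit)) {
    fit$draws[, sprintf("sigma[%d]", fit$obs$cond[idx]), drop = FALSE]
  } else {
    matrix(fit$draws[, "sigma"], nrow = nrow(fit$draws), ncol = length(idx))
  }
}

# pointwise log-likelihood, S x length(idx)
pointwise_loglik <- function(fit, idx = seq_along(fit$obs$bias)) {
  mu <- mu_draws(fit, idx)
  sdm <- sigma_draws(fit, idx)
  y <- matrix(fit$obs$bias[idx], nrow = nrow(mu), ncol = length(idx), byrow = TRUE)
  dnorm(y, mu, sdm, log = TRUE)
}

# ---------------------------------------------------------------------------

#' @export
print.rc_fit <- function(x, ...) {
  cat(sprintf("<rc_fit '%s'>\n", x$model))
  cat(sprintf("  %d observations, %d participants, %d segments\n",
              length(x$obs$bias), length(x$participants), x$obs$n_segments))
  cat(sprintf("  %d chains x %d draws (warmup %d); sampled in %.1f s\n",
              x$chains, x$iter, x$warmup, x$elapsed))
  rh <- x$summary$rhat
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f\n",
              max(rh[is.finite(rh)]), min(x$summary$ess, na.rm = TRUE)))
  print(utils::head(x$summary[, c("parameter", "mean", "ci_lo", "ci_hi", "rhat")], 8),
        digits = 3, row.names = FALSE)
  if (nrow(x$summary) > 8) cat("  ... use summary() for all parameters\n")
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param object an `rc_fit`.
#' @param ... unused.
#' @return The per-parameter posterior summary data frame: mean, sd, median,
#'   97\% percentile credible interval, 97\% HPD interval, split-Rhat and
#'   effective sample size.
#' @export
summary.rc_fit <- function(object, ...) {
  object$summary
}

#' @export
coef.rc_fit <- function(object, ...) {
  pars <- object$summary$parameter
  keep <- !grepl("^(a_p|b_p|w_p|curve)\\[", pars)
  setNames(object$summary$mean[keep], pars[keep])
}

#' @export
fitted.rc_fit <- function(object, ...) {
  n <- length(object$obs$bias)
  out <- numeric(n)
  for (idx in split(seq_len(n), ceiling(seq_len(n) / 5000))) {
    out[idx] <- colMeans(mu_draws(object, idx))
  }
  out
}

#' @export
residuals.rc_fit <- function(object, ...) {
  object$obs$bias - fitted(object)
}

#' Posterior predicted disambiguation curves
#'
#' Summarises the posterior of the model's mean curve over segment index,
#' either per participant (including the participant's scaling weight or
#' random effects) or at the population level.
#'
#' @param object an `rc_fit`.
#' @param level `"participant"` or `"population"`.
#' @param mass credible-interval mass (default 0.97).
#' @param ... unused.
#' @return A data frame with `participant` (or `"population"`), `condition`
#'   (dual models only), `segment_index`, `estimate`, `lo`, `hi`.
#' @export
predict.rc_fit <- function(object, level = c("participant", "population"),
                           mass = 0.97, ...) {
  level <- match.arg(level)
  d <- object$draws
  nseg <- object$obs$n_segments
  segs <- seq_len(nseg)
  conds <- if (fit_is_dual(object)) c("perception", "memory") else NA_character_

  curve_draws <- function(ci) {
    if (object$model == "linear") {
      stop("internal", call. = FALSE) # handled below
    }
    if (fit_is_dual(object)) {
      d[, sprintf("curve[%d,%d]", segs, ci), drop = FALSE]
    } else {
      d[, sprintf("curve[%d]", segs), drop = FALSE]
    }
  }

  rows <- list()
  groups <- if (level == "participant") seq_along(object$participants) else 0L
  for (g in groups) {
    for (ci in seq_along(conds)) {
      mu <- if (object$model == "linear") {
        a <- if (g == 0L) d[, "alpha"] else d[, sprintf("a_p[%d]", g)]
        b <- if (g == 0L) d[, "beta"] else d[, sprintf("b_p[%d]", g)]
        outer(a, segs - 1, function(ai, s) ai) + outer(b, segs - 1)
      } else {
        cd <- curve_draws(ci)
        w <- if (g == 0L) {
          1
        } else if (fit_is_dual(object)) {
          d[, sprintf("w_p[%d,%d]", g, ci)]
        } else {
          d[, sprintf("w_p[%d]", g)]
        }
        cd * w
      }
      ci_mat <- apply(mu, 2, percentile_ci, mass = mass)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = if (g == 0L) "population" else object$participants[g],
        condition = conds[ci],
        segment_index = segs,
        estimate = unname(colMeans(mu)),
        lo = ci_mat[1L, ],
        hi = ci_mat[2L, ],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!fit_is_dual(object)) {
    out$condition <- NULL
  }
  rownames(out) <- NULL
  out
}

#' Per-participant contrast of condition scaling weights
#'
#' For a dual-condition fit, the fraction of posterior draws in which the
#' participant's memory-condition scaling weight is smaller than their
#' perception-condition scaling weight. Values near 1 reproduce the finding
#' that perceptual memory is altered by weaker disambiguation than prime
#' perception.
#'
#' @param fit a dual-condition `rc_fit`.
#' @return Named numeric vector, one fraction per participant.
#' @export
scaling_weight_contrast <- function(fit) {
  stopifnot(inherits(fit, "rc_fit"))
  if (!fit_is_dual(fit)) {
    stop("scaling_weight_contrast() needs a dual-condition fit", call. = FALSE)
  }
  np <- length(fit$participants)
  out <- vapply(seq_len(np), function(p) {
    mean(fit$draws[, sprintf("w_p[%d,2]", p)] < fit$draws[, sprintf("w_p[%d,1]", p)])
  }, 0)
  setNames(out, fit$participants)
}

#' Simulate replicated observations from the posterior predictive
#'
#' @param object an `rc_fit`.
#' @param nsim number of replicated data sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns, each a posterior predictive
#'   replicate of the observed `bias` vector (one posterior draw per
#'   replicate).
#' @export
simulate.rc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    n <- length(object$obs$bias)
    mu <- mu_draws(object)
    sdm <- sigma_draws(object)
    s_idx <- sample.int(nrow(mu), nsim, replace = nsim > nrow(mu))
    reps <- vapply(s_idx, function(s) rnorm(n, mu[s, ], sdm[s, ]), numeric(n))
    as.data.frame(reps, col.names = paste0("sim_", seq_len(nsim)))
  })
}
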