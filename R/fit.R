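#' Long-format segment observations for model fitting
#'
#' Expands a selection set of triplets into one row per (triplet, segment):
#' the response `bias` is the sign-aligned disambiguation strength, the
#' covariate `segment_index` is the 1-based segment number, and `participant`
#' identifies the random-effect group. `dual_segment_observations()` stacks
#' the two selection sets with a `condition` factor (`"perception"` for the
#' prime-changed set, `"memory"` for the memory-changed set); note that
#' `both_changed` triplets legitimately appear in both conditions.
#'
#' @inheritParams average_sequence
#' @return A data frame with columns `participant`, `segment_index`, `bias`
#'   (and `condition` for the dual version).
#' @export
segment_observations <- function(triplets, selection = c("prime_changed", "memory_changed")) {
  selection <- match.arg(selection)
  sel <- select_triplets(triplets, selection)
  schedule <- attr(triplets, "schedule")
  nseg <- schedule$n_segments
  m <- triplet_seg_matrix(sel)
  out <- data.frame(
    participant = rep(sel$participant, times = nseg),
    segment_index = rep(seq_len(nseg), each = nrow(sel)),
    bias = as.vector(m),
    stringsAsFactors = FALSE
  )
  attr(out, "n_segments") <- nseg
  out
}

#' @rdname segment_observations
#' @export
dual_segment_observations <- function(triplets) {
  per <- segment_observations(triplets, "prime_changed")
  mem <- segment_observations(triplets, "memory_changed")
  per$condition <- "perception"
  mem$condition <- "memory"
  out <- rbind(per, mem)
  out$condition <- factor(out$condition, levels = c("perception", "memory"))
  attr(out, "n_segments") <- attr(per, "n_segments")
  out
}

jags_model_string <- function(model) {
  # Correlated random intercepts/slopes in the centered parameterization:
  # with a Gibbs backend the centered form is the convergence-motivated
  # (and mathematically identical) counterpart of the Cholesky/noncentered
  # form used with Hamiltonian samplers.
  linear <- "
model {
  for (i in 1:N) {
    mu[i] <- a_p[P[i]] + b_p[P[i]] * (seg[i] - 1)
    bias[i] ~ dnorm(mu[i], tau)
  }
  for (p in 1:NP) {
    ab_p[p, 1:2] ~ dmnorm(mu_ab, Omega)
    a_p[p] <- ab_p[p, 1]
    b_p[p] <- ab_p[p, 2]
  }
  mu_ab[1] <- alpha
  mu_ab[2] <- beta
  S[1, 1] <- sigma_a * sigma_a
  S[1, 2] <- rho * sigma_a * sigma_b
  S[2, 1] <- S[1, 2]
  S[2, 2] <- sigma_b * sigma_b
  Omega <- inverse(S)
  alpha ~ dnorm(0, 1)
  beta ~ dnorm(0, 1)
  sigma_a ~ dexp(1)
  sigma_b ~ dexp(1)
  sigma ~ dexp(1)
  tau <- pow(sigma, -2)
  # rho = 2*Beta(2,2) - 1 is exactly the LKJ(2) marginal for a 2x2 matrix
  rho_raw ~ dbeta(2, 2)
  rho <- 2 * rho_raw - 1
}"

  additive <- "
model {
  for (i in 1:N) {
    mu[i] <- curve[seg[i]] * w_p[P[i]]
    bias[i] ~ dnorm(mu[i], tau)
  }
  for (k in 1:NSEG) {
    curve[k] <- inprod(B[k, ], w_spline)
  }
  for (j in 1:NS) {
    w_spline[j] ~ dnorm(0, 1)
  }
  # strictly positive participant scaling weights, noncentered log-normal
  for (p in 1:NP) {
    z_p[p] ~ dnorm(0, 1)
    w_p[p] <- exp(sigma_p * z_p[p])
  }
  sigma_p ~ dexp(10)
  sigma ~ dexp(1)
  tau <- pow(sigma, -2)
}"

  dual_head <- "
model {
  for (i in 1:N) {
    mu[i] <- curve[seg[i], cond[i]] * w_p[P[i], cond[i]]
    bias[i] ~ dnorm(mu[i], tau[cond[i]])
  }
  for (c in 1:2) {
    for (p in 1:NP) {
      z_p[p, c] ~ dnorm(0, 1)
      w_p[p, c] <- exp(sigma_p[c] * z_p[p, c])
    }
    sigma_p[c] ~ dexp(10)
    sigma[c] ~ dexp(1)
    tau[c] <- pow(sigma[c], -2)
  }
"
  dual_tail <- "}"

  dual_weights <- switch(
    model,
    dual_independent = "
  for (c in 1:2) {
    for (k in 1:NSEG) {
      curve[k, c] <- inprod(B[k, ], w_spline[, c])
    }
    for (j in 1:NS) {
      w_spline[j, c] ~ dnorm(0, 1)
    }
  }
",
    dual_correlated = "
  for (c in 1:2) {
    for (k in 1:NSEG) {
      curve[k, c] <- inprod(B[k, ], w_spline[, c])
    }
  }
  # pairwise-correlated standard-normal weights; centered bivariate form
  # (block-updated by the Gibbs sampler), correlation prior LKJ(2)
  for (j in 1:NS) {
    w_spline[j, 1:2] ~ dmnorm(zero2, Omega_w)
  }
  zero2[1] <- 0
  zero2[2] <- 0
  S_w[1, 1] <- 1
  S_w[1, 2] <- rho
  S_w[2, 1] <- rho
  S_w[2, 2] <- 1
  Omega_w <- inverse(S_w)
  rho_raw ~ dbeta(2, 2)
  rho <- 2 * rho_raw - 1
",
    dual_identical = "
  for (k in 1:NSEG) {
    curve_shared[k] <- inprod(B[k, ], w_spline)
    curve[k, 1] <- curve_shared[k]
    curve[k, 2] <- curve_shared[k]
  }
  for (j in 1:NS) {
    w_spline[j] ~ dnorm(0, 1)
  }
",
    NULL
  )

  switch(model,
    linear = linear,
    additive = additive,
    paste0(dual_head, dual_weights, dual_tail)
  )
}

#' Fit a hierarchical Bayesian model of disambiguation strength
#'
#' Fits one of five hierarchical models of sign-aligned disambiguation
#' strength (`bias`) against segment index, with participants as groups, by
#' MCMC (JAGS, Gibbs sampling; the correlation structures use noncentered
#' parameterizations via the Cholesky factor of the 2 x 2 correlation
#' matrix):
#'
#' \describe{
#'   \item{`linear`}{`bias_i ~ Normal(alpha_P + beta_P * (segment - 1),
#'     sigma)` with correlated random intercepts and slopes; priors
#'     `alpha, beta ~ Normal(0, 1)`, `sigma_a, sigma_b, sigma ~
#'     Exponential(1)`, correlation `R ~ LKJ(2)`.}
#'   \item{`additive`}{`bias_i ~ Normal(curve[segment] * w_P, sigma)` with
#'     `curve = B w_spline` a weighted sum of cubic B-splines and strictly
#'     positive participant scaling weights; priors `w_spline ~ Normal(0,1)`,
#'     `log w_P ~ Normal(0, sigma_P)`, `sigma_P ~ Exponential(10)`,
#'     `sigma ~ Exponential(1)`.}
#'   \item{`dual_independent`, `dual_correlated`, `dual_identical`}{the
#'     additive model duplicated across two conditions (all parameters per
#'     condition) with spline weights that are independent, pairwise
#'     correlated with `rho ~ LKJ(2)`, or shared.}
#' }
#'
#' @param data a data frame with columns `bias`, `segment_index`,
#'   `participant` (and `condition` with levels `perception`/`memory` for the
#'   dual models); see [segment_observations()].
#' @param model one of `"linear"`, `"additive"`, `"dual_independent"`,
#'   `"dual_correlated"`, `"dual_identical"`.
#' @param basis a [spline_basis()] whose evaluation points match the number
#'   of segments (additive/dual models); built automatically when `NULL`.
#' @param chains,iter,warmup,adapt MCMC settings: number of chains, kept
#'   draws per chain, burn-in iterations, and JAGS adaptation iterations.
#' @param seed integer seed controlling both the chain RNGs and nothing else;
#'   `NULL` draws chain seeds from the caller's RNG stream.
#' @param quiet suppress JAGS progress output.
#' @return An object of class `rc_fit` with components `model`, `draws`
#'   (matrix of kept draws, chains stacked, one column per monitored
#'   parameter), `summary` (per-parameter posterior summary incl. 97\%
#'   percentile and HPD intervals, split-Rhat and effective sample size),
#'   `data`, `basis`, and the MCMC settings. A warning is raised when any
#'   split-Rhat exceeds 1.01.
#' @seealso [summary.rc_fit()], [predict.rc_fit()], [loo_elpd()],
#'   [compare_models()], [scaling_weight_contrast()]
#' @export
fit_bias_model <- function(data,
                           model = c("linear", "additive", "dual_independent",
                                     "dual_correlated", "dual_identical"),
                           basis = NULL,
                           chains = 4, iter = 1000, warmup = 1000, adapt = 500,
                           seed = NULL, quiet = TRUE) {
  model <- match.arg(model)
  dual <- startsWith(model, "dual_")

  required <- c("bias", "segment_index", "participant", if (dual) "condition")
  missing_cols <- setdiff(required, names(data))
  if (nrow(data) == 0L) {
    stop("'data' has no observations", call. = FALSE)
  }
  if (length(missing_cols) > 0L) {
    stop("'data' is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(data$bias))) {
    stop("'bias' must be finite", call. = FALSE)
  }

  participant <- factor(data$participant)
  if (nlevels(participant) < 2L) {
    stop("at least 2 participants are required (random effects are not ",
         "identifiable from one)", call. = FALSE)
  }
  seg <- as.integer(data$segment_index)
  nseg <- max(seg)
  if (min(seg) < 1L || length(unique(seg)) < 2L) {
    stop("'segment_index' must be 1-based with at least 2 distinct segments",
         call. = FALSE)
  }

  jags_data <- list(
    N = nrow(data),
    P = as.integer(participant),
    NP = nlevels(participant),
    seg = seg,
    bias = as.numeric(data$bias)
  )

  if (model != "linear") {
    if (is.null(basis)) {
      basis <- spline_basis(nseg)
    }
    stopifnot(inherits(basis, "spline_basis"))
    if (basis$n_points != nseg) {
      stop("basis/segment mismatch: basis has ", basis$n_points,
           " evaluation points but the data span ", nseg, " segments",
           call. = FALSE)
    }
    jags_data$B <- basis$B
    jags_data$NSEG <- nseg
    jags_data$NS <- basis$n_splines
  } else {
    basis <- NULL
  }

  cond <- NULL
  if (dual) {
    cond <- factor(data$condition, levels = c("perception", "memory"))
    if (any(is.na(cond)) || nlevels(droplevels(cond)) < 2L) {
      stop("dual models need a 'condition' column with both levels ",
           "'perception' and 'memory'", call. = FALSE)
    }
    jags_data$cond <- as.integer(cond)
  }

  monitors <- switch(model,
    linear = c("alpha", "beta", "sigma_a", "sigma_b", "sigma", "rho", "a_p", "b_p"),
    additive = c("w_spline", "w_p", "sigma_p", "sigma", "curve"),
    dual_independent = c("w_spline", "w_p", "sigma_p", "sigma", "curve"),
    dual_correlated = c("w_spline", "w_p", "sigma_p", "sigma", "curve", "rho"),
    dual_identical = c("w_spline", "w_p", "sigma_p", "sigma", "curve")
  )

  chain_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, chains))
  inits <- lapply(chain_seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })

  t0 <- Sys.time()
  run <- function() {
    jm <- rjags::jags.model(
      textConnection(jags_model_string(model)),
      data = jags_data, inits = inits, n.chains = chains,
      n.adapt = adapt, quiet = quiet
    )
    update(jm, n.iter = warmup, progress.bar = "none")
    rjags::coda.samples(jm, variable.names = monitors, n.iter = iter,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  draws <- do.call(rbind, lapply(samples, as.matrix))
  summ <- posterior_summary_table(samples)

  fit <- structure(
    list(
      model = model,
      draws = draws,
      chains = chains,
      iter = iter,
      warmup = warmup,
      adapt = adapt,
      seed = seed,
      summary = summ,
      participants = levels(participant),
      obs = list(
        bias = jags_data$bias, P = jags_data$P, seg = seg,
        cond = if (dual) as.integer(cond) else NULL,
        n_segments = nseg
      ),
      basis = basis,
      elapsed = elapsed
    ),
    class = "rc_fit"
  )

  bad <- summ$parameter[is.finite(summ$rhat) & summ$rhat > 1.01]
  if (length(bad) > 0L) {
    warning("split-Rhat above 1.01 for: ", paste(bad, collapse = ", "),
            "; consider more iterations", call. = FALSE)
  }
  fit
}

# split-Rhat and summary table from a coda mcmc.list
posterior_summary_table <- function(samples) {
  mats <- lapply(samples, as.matrix)
  pars <- colnames(mats[[1L]])
  all_draws <- do.call(rbind, mats)
  ess <- tryCatch(coda::effectiveSize(samples), error = function(e) NULL)

  rows <- lapply(seq_along(pars), function(j) {
    x <- all_draws[, j]
    chains_j <- lapply(mats, function(m) m[, j])
    pci <- percentile_ci(x, 0.97)
    hpd <- hpdi(x, 0.97)
    data.frame(
      parameter = pars[j],
      mean = mean(x),
      sd = sd(x),
      median = median(x),
      ci_lo = pci[1L], ci_hi = pci[2L],
      hpdi_lo = hpd[1L], hpdi_hi = hpd[2L],
      rhat = split_rhat(chains_j),
      ess = if (is.null(ess)) NA_real_ else unname(ess[pars[j]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# classic split-Rhat: each chain halved, potential scale reduction across the
# resulting 2*chains sequences
split_rhat <- function(chains_list) {
  halves <- unlist(lapply(chains_list, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[seq_len(n) + (length(x) - n)])
  }), recursive = FALSE)
  n <- min(lengths(halves))
  if (n < 2L) {
    return(NA_real_)
  }
  halves <- lapply(halves, function(x) x[seq_len(n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  w <- mean(vars)
  b <- n * var(means)
  if (!is.finite(w) || w <= 0) {
    return(if (b <= 1e-12 || !is.finite(b)) 1 else Inf)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}
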