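# Generalized Pareto fit to exceedances by the Zhang & Stephens (2009)
# profile-likelihood/quasi-Bayes estimator, in the parameterization
# F(x) = 1 - (1 - k x / sigma)^(1/k); heavy tails have k < 0, and the
# Pareto shape reported as a diagnostic is xi = -k.
gpd_fit <- function(x) {
  n <- length(x)
  x <- sort.int(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_of <- function(t) -mean(log1p(-t * x))
  l_theta <- vapply(theta, function(t) {
    k <- k_of(t)
    n * (log(t / k) + k - 1)
  }, 0)
  w <- 1 / vapply(jj, function(j) sum(exp(l_theta - l_theta[j])), 0)
  theta_hat <- sum(theta * w)
  k_hat <- k_of(theta_hat)
  sigma_hat <- k_hat / theta_hat
  xi <- -k_hat
  # weak prior toward xi = 0.5 stabilises small tails
  xi_reg <- (n * xi + 5) / (n + 10)
  list(sigma = sigma_hat, xi = xi, xi_reg = xi_reg)
}

# quantile of the fitted GPD (exceedance scale)
gpd_quantile <- function(p, sigma, xi) {
  k <- -xi
  if (abs(k) < 1e-12) {
    return(-sigma * log1p(-p))
  }
  sigma / k * (1 - (1 - p)^k)
}

# Pareto-smoothed importance weights for one observation.
# lr: log importance ratios (log 1/p(y_i | theta_s)). Returns normalized log
# weights and the (regularised) Pareto shape diagnostic.
psis_weights <- function(lr) {
  s <- length(lr)
  lr <- lr - max(lr)
  m <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  k <- NA_real_
  if (m >= 5L) {
    ord <- order(lr)
    tail_idx <- ord[seq.int(s - m + 1L, s)]
    u <- exp(lr[ord[s - m]])
    x <- exp(lr[tail_idx]) - u
    if (max(x) > 0 && length(unique(x)) >= 2L) {
      fit <- gpd_fit(x)
      if (is.finite(fit$xi) && is.finite(fit$sigma) && fit$sigma > 0) {
        qq <- (seq_len(m) - 0.5) / m
        smoothed <- u + gpd_quantile(qq, fit$sigma, fit$xi)
        smoothed <- pmin(smoothed, 1) # never above the raw maximum weight
        lr[tail_idx] <- log(smoothed)
        k <- fit$xi_reg
      }
    }
  }
  list(log_weights = lr - log_sum_exp(lr), pareto_k = k)
}

#' PSIS-LOO expected log predictive density
#'
#' Estimates the leave-one-out expected log pointwise predictive density
#' (ELPD) from posterior draws by Pareto-smoothed importance sampling: for
#' each observation the importance ratios `1 / p(y_i | theta)` are
#' tail-smoothed with a generalized Pareto fit before computing the
#' importance-weighted predictive density. The standard error is
#' `sqrt(n * var(pointwise))`; Pareto shape diagnostics above about 0.7 flag
#' unreliable observations.
#'
#' @param x an [fit_bias_model()] result (the pointwise log-likelihood is
#'   reconstructed from the stored draws in blocks), or a draws x
#'   observations matrix of pointwise log-likelihoods.
#' @return An object of class `rc_loo`: list with `elpd`, `se`, `pointwise`
#'   (per-observation ELPD contributions), `pareto_k`, `n_obs`, `n_draws`.
#' @export
loo_elpd <- function(x) {
  if (inherits(x, "rc_fit")) {
    n <- length(x$obs$bias)
    pointwise <- numeric(n)
    pareto_k <- numeric(n)
    for (idx in split(seq_len(n), ceiling(seq_len(n) / 2000))) {
      ll <- pointwise_loglik(x, idx)
      res <- psis_elpd_matrix(ll)
      pointwise[idx] <- res$pointwise
      pareto_k[idx] <- res$pareto_k
    }
    n_draws <- nrow(x$draws)
    data_id <- c(n, mean(x$obs$bias), var(x$obs$bias))
    model <- x$model
  } else {
    ll <- as.matrix(x)
    if (any(!is.finite(ll))) {
      stop("pointwise log-likelihoods must be finite", call. = FALSE)
    }
    res <- psis_elpd_matrix(ll)
    pointwise <- res$pointwise
    pareto_k <- res$pareto_k
    n <- ncol(ll)
    n_draws <- nrow(ll)
    data_id <- NULL
    model <- "loglik_matrix"
  }
  structure(
    list(
      elpd = sum(pointwise),
      se = sqrt(n * var(pointwise)),
      pointwise = pointwise,
      pareto_k = pareto_k,
      n_obs = n,
      n_draws = n_draws,
      model = model,
      data_id = data_id
    ),
    class = "rc_loo"
  )
}

psis_elpd_matrix <- function(ll) {
  if (any(!is.finite(ll))) {
    stop("pointwise log-likelihoods must be finite", call. = FALSE)
  }
  n <- ncol(ll)
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    w <- psis_weights(-ll[, i])
    pointwise[i] <- log_sum_exp(w$log_weights + ll[, i])
    pareto_k[i] <- w$pareto_k
  }
  list(pointwise = pointwise, pareto_k = pareto_k)
}

#' @export
print.rc_loo <- function(x, ...) {
  cat(sprintf("<rc_loo%s>: elpd = %.1f (se %.1f), %d observations, %d draws\n",
              if (x$model == "loglik_matrix") "" else paste0(" '", x$model, "'"),
              x$elpd, x$se, x$n_obs, x$n_draws))
  kk <- x$pareto_k[is.finite(x$pareto_k)]
  if (length(kk) > 0L) {
    cat(sprintf("  Pareto k: max %.2f, %d observation(s) above 0.7\n",
                max(kk), sum(kk > 0.7)))
  }
  invisible(x)
}

#' Compare fitted models by ELPD
#'
#' Ranks models by PSIS-LOO ELPD, reporting the difference to the best model
#' with the standard error of that difference (computed from the pointwise
#' ELPD differences over the shared observations) and a relative weight per
#' model. Weights are the softmax of the ELPDs (pseudo-BMA) by default;
#' `weights = "stacking"` instead maximises the stacked log predictive
#' density over the simplex.
#'
#' @param ... two or more `rc_fit` or `rc_loo` objects fitted to the same
#'   observations, optionally named.
#' @param weights `"pseudobma"` or `"stacking"`.
#' @return An object of class `rc_model_comparison`: a data frame with one
#'   row per model (`model`, `elpd`, `se`, `delta_elpd`, `delta_se`,
#'   `weight`), ordered best first; the best row has `delta_elpd = 0` and the
#'   weights sum to 1.
#' @export
compare_models <- function(..., weights = c("pseudobma", "stacking")) {
  weights <- match.arg(weights)
  objs <- list(...)
  if (length(objs) == 1L && is.list(objs[[1L]]) && !inherits(objs[[1L]], c("rc_fit", "rc_loo"))) {
    objs <- objs[[1L]]
  }
  if (length(objs) < 2L) {
    stop("need at least two models to compare", call. = FALSE)
  }
  nms <- names(objs)
  if (is.null(nms)) {
    nms <- rep("", length(objs))
  }
  loos <- lapply(seq_along(objs), function(i) {
    o <- objs[[i]]
    if (inherits(o, "rc_fit")) {
      l <- loo_elpd(o)
    } else if (inherits(o, "rc_loo")) {
      l <- o
    } else {
      stop("arguments must be 'rc_fit' or 'rc_loo' objects", call. = FALSE)
    }
    if (nms[i] == "") {
      nms[i] <<- if (l$model == "loglik_matrix") paste0("model", i) else l$model
    }
    l
  })
  n_obs <- vapply(loos, function(l) l$n_obs, 0)
  if (length(unique(n_obs)) != 1L) {
    stop("models were fitted to different observation sets", call. = FALSE)
  }
  ids <- lapply(loos, function(l) l$data_id)
  ids <- ids[!vapply(ids, is.null, TRUE)]
  if (length(ids) > 1L &&
      !all(vapply(ids[-1L], function(d) isTRUE(all.equal(d, ids[[1L]])), TRUE))) {
    stop("models were fitted to different observation sets", call. = FALSE)
  }

  elpd <- vapply(loos, function(l) l$elpd, 0)
  se <- vapply(loos, function(l) l$se, 0)
  best <- which.max(elpd)
  delta <- elpd - elpd[best]
  delta_se <- vapply(seq_along(loos), function(i) {
    if (i == best) {
      return(0)
    }
    dpt <- loos[[i]]$pointwise - loos[[best]]$pointwise
    sqrt(length(dpt) * var(dpt))
  }, 0)

  w <- if (weights == "pseudobma") {
    ew <- exp(elpd - max(elpd))
    ew / sum(ew)
  } else {
    stacking_weights(do.call(cbind, lapply(loos, function(l) l$pointwise)))
  }

  out <- data.frame(
    model = nms, elpd = elpd, se = se,
    delta_elpd = delta, delta_se = delta_se, weight = w,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$elpd), ]
  rownames(out) <- NULL
  structure(out, weights_method = weights,
            class = c("rc_model_comparison", "data.frame"))
}

# stacking of predictive distributions: maximise sum_i log sum_k w_k
# exp(lpd_ik) over the simplex (optimised on unconstrained logits)
stacking_weights <- function(lpd) {
  k <- ncol(lpd)
  if (k == 1L) {
    return(1)
  }
  obj <- function(eta) {
    w <- exp(c(eta, 0))
    w <- w / sum(w)
    lw <- sweep(lpd, 2, log(w), `+`)
    -sum(apply(lw, 1, log_sum_exp))
  }
  opt <- optim(rep(0, k - 1L), obj, method = "BFGS")
  w <- exp(c(opt$par, 0))
  unname(w / sum(w))
}

#' @export
print.rc_model_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("<rc_model_comparison> (%s weights)\n", attr(x, "weights_method")))
  df <- as.data.frame(x)
  df$weight <- signif(df$weight, 4)
  print.data.frame(df, digits = digits + 2, row.names = FALSE)
  invisible(x)
}
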