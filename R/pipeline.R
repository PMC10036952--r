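#' Run the full reverse-correlation pipeline
#'
#' Executes the complete analysis for one configuration: simulate sessions,
#' build triplets, compute individual and group reverse-correlation estimates
#' for both selection sets, fit the five hierarchical models (linear and
#' additive to the prime-changed observations; the three dual-condition
#' variants to both selection sets), and compare them by PSIS-LOO ELPD.
#' Every output is regenerable from the trial log plus the configuration
#' alone; all randomness is governed by the three explicit seeds.
#'
#' Files written to `out_dir`: `trials.csv` (trial log), `triplets.csv`,
#' `estimates_individual.csv`, `estimates_group.csv`, per-model
#' `summary_<model>.csv`, `draws_<model>.csv` (columns parameter, chain,
#' draw, value), `loo_<model>.csv` (pointwise ELPD contributions),
#' `model_comparison.csv` and `run_log.txt`.
#'
#' @param config an [rc_config][read_run_config()] list or a path to a YAML
#'   configuration.
#' @param out_dir output directory (defaults to `config$output_dir`).
#' @return Invisibly, a list with the fitted models, comparisons and the
#'   output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- read_run_config(config)
  }
  if (!inherits(config, "rc_config")) {
    config <- validate_run_config(config)
  }
  out_dir <- out_dir %||% config$output_dir
  if (is.null(out_dir)) {
    stop("no output directory: set 'output_dir' in the config or pass 'out_dir'",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log_lines <- c(
    sprintf("revcormem %s on R %s.%s", packageVersion("revcormem"),
            R.version$major, R.version$minor),
    sprintf("started %s", format(Sys.time())),
    sprintf("experiment=%s n_participants=%d n_primes=%d",
            config$experiment, config$n_participants, config$n_primes),
    sprintf("seeds: simulation=%d bootstrap=%d mcmc=%d",
            config$seeds$simulation, config$seeds$bootstrap, config$seeds$mcmc)
  )
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf(
      "stage %-10s ok (%.1f s)", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ))
    res
  }

  session <- stage("simulate", {
    s <- with_seed(config$seeds$simulation,
                   simulate_experiment(config$observer, config$schedule,
                                       config$n_participants, config$n_primes))
    write_trial_log(s, file.path(out_dir, "trials.csv"))
    s
  })

  triplets <- stage("triplets", {
    tr <- build_triplets(session)
    write.csv(as.data.frame(tr), file.path(out_dir, "triplets.csv"),
              row.names = FALSE)
    tr
  })

  estimates <- stage("revcorr", {
    sels <- c("prime_changed", "memory_changed")
    indiv <- do.call(rbind, lapply(seq_along(sels), function(i) {
      e <- bootstrap_individual(triplets, sels[i],
                                n_iterations = config$bootstrap$n_iterations,
                                interval_mass = config$bootstrap$interval_mass,
                                seed = config$seeds$bootstrap + i)
      cbind(selection = sels[i], as.data.frame(e))
    }))
    grp <- do.call(rbind, lapply(seq_along(sels), function(i) {
      e <- bootstrap_group(triplets, sels[i],
                           n_iterations = config$bootstrap$n_iterations,
                           interval_mass = config$bootstrap$interval_mass,
                           seed = config$seeds$bootstrap + 100 + i)
      cbind(selection = sels[i], as.data.frame(e))
    }))
    write.csv(indiv, file.path(out_dir, "estimates_individual.csv"), row.names = FALSE)
    write.csv(grp, file.path(out_dir, "estimates_group.csv"), row.names = FALSE)
    list(individual = indiv, group = grp)
  })

  fits <- stage("fit", {
    obs_single <- segment_observations(triplets, "prime_changed")
    obs_dual <- dual_segment_observations(triplets)
    basis <- spline_basis(config$schedule$n_segments)
    models <- c("linear", "additive", "dual_independent", "dual_correlated",
                "dual_identical")
    out <- list()
    for (i in seq_along(models)) {
      m <- models[i]
      fit <- fit_bias_model(
        if (startsWith(m, "dual_")) obs_dual else obs_single,
        model = m, basis = if (m == "linear") NULL else basis,
        chains = config$mcmc$chains, iter = config$mcmc$iter,
        warmup = config$mcmc$warmup, adapt = config$mcmc$adapt,
        seed = config$seeds$mcmc + i
      )
      write.csv(fit$summary, file.path(out_dir, sprintf("summary_%s.csv", m)),
                row.names = FALSE)
      dr <- fit$draws
      long <- data.frame(
        parameter = rep(colnames(dr), each = nrow(dr)),
        chain = rep(rep(seq_len(fit$chains), each = fit$iter), ncol(dr)),
        draw = rep(rep(seq_len(fit$iter), fit$chains), ncol(dr)),
        value = as.vector(dr)
      )
      write.csv(long, file.path(out_dir, sprintf("draws_%s.csv", m)),
                row.names = FALSE)
      l <- loo_elpd(fit)
      write.csv(
        data.frame(observation = seq_along(l$pointwise),
                   elpd_pointwise = l$pointwise, pareto_k = l$pareto_k),
        file.path(out_dir, sprintf("loo_%s.csv", m)), row.names = FALSE
      )
      out[[m]] <- fit
    }
    out
  })

  comparisons <- stage("compare", {
    cmp_single <- compare_models(linear = fits$linear, additive = fits$additive)
    cmp_dual <- compare_models(independent = fits$dual_independent,
                               correlated = fits$dual_correlated,
                               identical = fits$dual_identical)
    tab <- rbind(
      cbind(family = "single_condition", as.data.frame(cmp_single)),
      cbind(family = "dual_condition", as.data.frame(cmp_dual))
    )
    write.csv(tab, file.path(out_dir, "model_comparison.csv"), row.names = FALSE)
    list(single = cmp_single, dual = cmp_dual)
  })

  log_lines <- c(log_lines, sprintf("finished %s", format(Sys.time())))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(
    out_dir = out_dir,
    session = session,
    triplets = triplets,
    estimates = estimates,
    fits = fits,
    comparisons = comparisons
  ))
}
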