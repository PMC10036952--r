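#' Write and read trial logs
#'
#' The trial-log CSV is the package's on-disk session format: one row per
#' trial with columns `participant`, `experiment` (schedule variant),
#' `trial_index`, `trial_type` (`probe`/`prime`), `report`
#' (`left`/`right`/`missing`) and `seg_01 ...` disambiguation strengths in
#' *integer tenths* (empty on probe rows), which keeps the 0.1-step grid
#' exact in text form.
#'
#' @param session a `kde_session` data frame.
#' @param path file path.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   returns a validated `kde_session` (rows ordered by participant and trial
#'   index, schedule rebuilt from the `experiment` column and the number of
#'   segment columns). Malformed rows are reported with their line numbers.
#' @export
write_trial_log <- function(session, path) {
  schedule <- attr(session, "schedule")
  stopifnot(!is.null(schedule))
  df <- as.data.frame(session)
  df <- cbind(
    df[, "participant", drop = FALSE],
    experiment = schedule$variant,
    df[, setdiff(names(df), "participant"), drop = FALSE]
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) {
    stop("trial log not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant", "experiment", "trial_index", "trial_type", "report")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("trial log is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  seg_cols <- grep("^seg_[0-9]+$", names(df), value = TRUE)
  if (length(seg_cols) == 0L) {
    stop("trial log has no segment columns (seg_01 ...)", call. = FALSE)
  }
  seg_cols <- sort(seg_cols)
  variant <- unique(df$experiment)
  if (length(variant) != 1L) {
    stop("trial log mixes experiment variants: ", paste(variant, collapse = ", "),
         call. = FALSE)
  }
  schedule <- kde_schedule(variant, n_segments = length(seg_cols))

  # data-frame row i is file line i + 1 (header)
  line_of <- function(i) i + 1L
  fail_rows <- function(bad, what) {
    if (any(bad)) {
      stop(sprintf("trial log %s: %s at line(s) %s", path, what,
                   paste(line_of(which(bad)), collapse = ", ")), call. = FALSE)
    }
  }

  fail_rows(!df$trial_type %in% c("probe", "prime"), "invalid trial_type")
  fail_rows(!df$report %in% c("left", "right", "missing"), "invalid report")

  seg <- as.matrix(df[, seg_cols, drop = FALSE])
  if (!is.numeric(seg)) {
    storage.mode(seg) <- "double"
  }
  is_prime <- df$trial_type == "prime"
  fail_rows(!is_prime & rowSums(!is.na(seg)) > 0,
            "probe rows must have empty segment values")
  fail_rows(is_prime & rowSums(is.na(seg)) > 0,
            "prime rows must have all segment values")
  off_grid <- rowSums(!is.na(seg) &
                        (seg != round(seg) | abs(seg) > 10)) > 0
  fail_rows(off_grid, "segment strengths off the 0.1 grid (integer tenths -10..10)")

  dup <- duplicated(df[, c("participant", "trial_index")])
  fail_rows(dup, "duplicate (participant, trial_index)")

  df <- df[order(df$participant, df$trial_index), , drop = FALSE]
  out <- df[, c("participant", "trial_index", "trial_type", "report", seg_cols)]
  for (cl in seg_cols) {
    out[[cl]] <- as.integer(out[[cl]])
  }
  rownames(out) <- NULL
  structure(out, schedule = schedule, class = c("kde_session", "data.frame"))
}

config_spec <- list(
  experiment = NULL,
  n_segments = NULL,
  segment_ms = NULL,
  n_participants = NULL,
  n_primes = NULL,
  observer = c("kernel", "gain_perception", "gain_memory",
               "baseline_perception", "baseline_memory", "lapse", "p_miss"),
  bootstrap = c("n_iterations", "interval_mass"),
  mcmc = c("chains", "iter", "warmup", "adapt"),
  seeds = c("simulation", "bootstrap", "mcmc"),
  output_dir = NULL
)

#' Read and validate a pipeline run configuration
#'
#' Configurations are plain YAML with the sections `experiment` (schedule
#' variant, with optional `n_segments`/`segment_ms` overrides for scaled-down
#' runs), `n_participants`, `n_primes`, `observer` (see
#' [observer_params()]; `kernel: default` uses [default_kernel()]),
#' `bootstrap`, `mcmc`, `seeds` (all three of `simulation`, `bootstrap`,
#' `mcmc` are mandatory, so every randomness source is explicit) and
#' `output_dir`. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated configuration list of class `rc_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a configuration list (as from [yaml::read_yaml()]).
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), names(config_spec))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (section in c("observer", "bootstrap", "mcmc", "seeds")) {
    extra <- setdiff(names(config[[section]]), config_spec[[section]])
    if (length(extra) > 0L) {
      stop("unknown config key(s) in '", section, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  for (key in c("experiment", "n_participants", "n_primes")) {
    if (is.null(config[[key]])) {
      stop("config is missing '", key, "'", call. = FALSE)
    }
  }
  seeds <- config$seeds
  missing_seeds <- setdiff(config_spec$seeds, names(seeds))
  if (length(missing_seeds) > 0L) {
    stop("config must set explicit seeds: missing ",
         paste(missing_seeds, collapse = ", "), call. = FALSE)
  }

  obs <- config$observer %||% list()
  kernel <- obs$kernel
  if (is.null(kernel) || identical(kernel, "default")) {
    kernel <- NULL
  } else {
    kernel <- as.numeric(unlist(kernel))
  }
  config$observer <- observer_params(
    kernel = kernel,
    gain_perception = obs$gain_perception %||% 1,
    gain_memory = obs$gain_memory %||% 0.5,
    baseline_perception = obs$baseline_perception %||% 2,
    baseline_memory = obs$baseline_memory %||% 2,
    lapse = obs$lapse %||% 0.05,
    p_miss = obs$p_miss %||% 0.02
  )
  config$bootstrap <- list(
    n_iterations = config$bootstrap$n_iterations %||% 2000,
    interval_mass = config$bootstrap$interval_mass %||% 0.97
  )
  config$mcmc <- list(
    chains = config$mcmc$chains %||% 4,
    iter = config$mcmc$iter %||% 1000,
    warmup = config$mcmc$warmup %||% 1000,
    adapt = config$mcmc$adapt %||% 500
  )
  config$schedule <- kde_schedule(config$experiment,
                                  n_segments = config$n_segments,
                                  segment_ms = config$segment_ms)
  structure(config, class = c("rc_config", "list"))
}
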