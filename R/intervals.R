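#' Equal-tailed percentile interval
#'
#' The central interval at quantiles `(1 - mass)/2` and `1 - (1 - mass)/2`
#' (linear-interpolation quantiles, R type 7). Used both for bootstrap
#' confidence intervals and for percentile credible intervals of posterior
#' draws.
#'
#' @param samples numeric vector (>= 2 values).
#' @param mass interval probability mass in (0, 1); default 0.97.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' percentile_ci(1:100, mass = 0.5)
#' @export
percentile_ci <- function(samples, mass = 0.97) {
  stopifnot(length(samples) >= 2L, all(is.finite(samples)),
            length(mass) == 1L, mass > 0, mass < 1)
  unname(quantile(samples, c((1 - mass) / 2, 1 - (1 - mass) / 2)))
}

#' Highest posterior density interval
#'
#' The narrowest contiguous window of the sorted sample containing
#' `ceiling(mass * n)` draws. For skewed posteriors (e.g. correlation
#' parameters) it is narrower than the equal-tailed interval and always
#' contains the densest region of the sample.
#'
#' @param samples numeric vector of at least 50 draws.
#' @param mass probability mass in (0, 1); default 0.97.
#' @return Numeric vector `c(lower, upper)`; zero-width for constant samples.
#' @examples
#' set.seed(1)
#' hpdi(rnorm(1000))
#' @export
hpdi <- function(samples, mass = 0.97) {
  stopifnot(all(is.finite(samples)), length(mass) == 1L, mass > 0, mass < 1)
  n <- length(samples)
  if (n < 50L) {
    stop("'hpdi' needs at least 50 samples", call. = FALSE)
  }
  xs <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) {
    return(c(xs[1L], xs[n]))
  }
  starts <- seq_len(n - m + 1L)
  widths <- xs[starts + m - 1L] - xs[starts]
  i <- which.min(widths)
  c(xs[i], xs[i + m - 1L])
}
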