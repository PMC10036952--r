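#' Clamped cubic B-spline basis over segment index
#'
#' Builds the spline basis used by the additive models: `n_splines` clamped
#' (open-uniform) cubic B-splines evaluated at the segment indices
#' `1 ... n_points`, with interior knots evenly spaced between the first and
#' last index. The columns form a partition of unity (each row of the basis
#' matrix sums to 1), every entry lies in `[0, 1]`, each basis function has a
#' single contiguous support, and the construction is fully deterministic.
#'
#' @param n_points number of evaluation points (segment indices); must be at
#'   least `n_splines`.
#' @param n_splines number of basis functions (default 6); must be at least
#'   `degree + 1`.
#' @param degree polynomial degree (default 3, cubic).
#' @return An object of class `spline_basis`: list with the `n_points` x
#'   `n_splines` matrix `B`, the full `knots` vector, `degree`, `n_points`
#'   and `n_splines`.
#' @examples
#' b <- spline_basis(10)
#' rowSums(b$B) # all 1
#' @export
spline_basis <- function(n_points, n_splines = 6, degree = 3) {
  stopifnot(length(n_points) == 1L, length(n_splines) == 1L, length(degree) == 1L)
  n_points <- as.integer(n_points)
  n_splines <- as.integer(n_splines)
  if (n_splines < degree + 1L) {
    stop("'n_splines' must be at least degree + 1", call. = FALSE)
  }
  if (n_points < n_splines) {
    stop("'n_points' must be at least 'n_splines'", call. = FALSE)
  }
  n_interior <- n_splines - degree - 1L
  interior <- if (n_interior > 0L) {
    seq(1, n_points, length.out = n_interior + 2L)[seq_len(n_interior) + 1L]
  } else {
    numeric(0)
  }
  knots <- c(rep(1, degree + 1L), interior, rep(n_points, degree + 1L))
  B <- splines::splineDesign(knots, x = seq_len(n_points), ord = degree + 1L)
  dimnames(B) <- list(NULL, sprintf("s%d", seq_len(n_splines)))
  structure(
    list(B = B, knots = knots, degree = degree,
         n_points = n_points, n_splines = n_splines),
    class = "spline_basis"
  )
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("<spline_basis>: %d degree-%d B-splines at %d points\n",
              x$n_splines, x$degree, x$n_points))
  cat("knots:", paste(signif(x$knots, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Weighted sum of spline basis functions
#'
#' @param basis a [spline_basis()].
#' @param w numeric weight vector, one weight per basis function.
#' @return Numeric curve of length `basis$n_points`, `B %*% w`.
#' @examples
#' synthesize_curve(spline_basis(10), rep(1, 6)) # constant 1
#' @export
synthesize_curve <- function(basis, w) {
  stopifnot(inherits(basis, "spline_basis"))
  if (length(w) != basis$n_splines) {
    stop("'w' must have one weight per basis function (",
         basis$n_splines, ")", call. = FALSE)
  }
  drop(basis$B %*% w)
}

#' Least-squares spline weights for a target curve
#'
#' Convenience helper for approximating a known shape with the basis (used,
#' for example, to check that the basis reproduces straight lines exactly and
#' bell shapes closely).
#'
#' @inheritParams synthesize_curve
#' @param target numeric target values at the basis' evaluation points.
#' @return Weight vector of length `basis$n_splines`.
#' @export
fit_curve_weights <- function(basis, target) {
  stopifnot(inherits(basis, "spline_basis"), length(target) == basis$n_points)
  qr.solve(basis$B, target)
}
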