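#' Activity-potential distributions
#'
#' In the activity-driven model each individual carries an activity potential
#' \eqn{a \in (0,1]}, the per-step probability of becoming active and creating
#' \eqn{m} links, drawn once from a density \eqn{f(a)}. These constructors
#' build the distribution families used throughout the package; every family
#' exposes an exact (or quadrature-free) moment \eqn{\langle a^k \rangle},
#' its density, and an i.i.d. sampler.
#'
#' Supported families:
#' \describe{
#'   \item{uniform}{constant density \eqn{1/(b - a_0)} on \eqn{[a_0, b]},
#'     e.g. the benchmark \eqn{f(a) = 1000/999} on \eqn{[0.001, 1]}.}
#'   \item{point mass}{all individuals share the same activity \eqn{a_0}.}
#'   \item{tabulated}{piecewise-linear density on a grid of support points,
#'     renormalized to integrate to 1; moments by exact integration of the
#'     linear pieces.}
#' }
#'
#' @param min,max support endpoints of the uniform density, within (0, 1].
#' @param a0 location of the point mass, in (0, 1].
#' @param a grid of support points (increasing, within (0, 1]).
#' @param f non-negative density values at `a` (rescaled to integrate to 1).
#' @return An object of class `activity_dist`.
#' @examples
#' d <- activity_uniform(0.001, 1)
#' activity_moment(d, 1)            # <a> = 0.5005
#' activity_density(d, 0.3)         # 1000/999
#' @name activity_dist
NULL

new_activity_dist <- function(family, params, support) {
  structure(list(family = family, params = params, support = support),
            class = "activity_dist")
}

check_support <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo > hi)
    stop("invalid support: need lower <= upper, got [", lo, ", ", hi, "]")
  if (lo <= 0)
    stop("invalid support: activity potentials must be > 0, lower bound ",
         lo, " violates a > 0")
  if (hi > 1)
    stop("invalid support: activity potentials must be <= 1, upper bound ",
         hi, " violates a <= 1")
}

#' @rdname activity_dist
#' @export
activity_uniform <- function(min = 0.001, max = 1) {
  check_support(min, max)
  if (min >= max) stop("uniform family needs min < max")
  new_activity_dist("uniform", c(min = min, max = max), c(min, max))
}

#' @rdname activity_dist
#' @export
activity_point <- function(a0) {
  check_support(a0, a0)
  new_activity_dist("point-mass", c(a0 = a0), c(a0, a0))
}

#' @rdname activity_dist
#' @export
activity_tabulated <- function(a, f) {
  if (length(a) != length(f) || length(a) < 2L)
    stop("tabulated family needs matching grids of length >= 2")
  if (is.unsorted(a, strictly = TRUE)) stop("grid 'a' must be increasing")
  check_support(a[1L], a[length(a)])
  if (any(f < 0)) stop("density values must be non-negative")
  z <- sum(diff(a) * (utils::head(f, -1L) + utils::tail(f, -1L)) / 2)
  if (z <= 0) stop("density must have positive mass")
  d <- new_activity_dist("tabulated", list(a = a, f = f / z),
                         c(a[1L], a[length(a)]))
  d
}

#' @export
print.activity_dist <- function(x, ...) {
  cat("activity distribution [", x$family, "] on (",
      x$support[1L], ", ", x$support[2L], "]  <a> = ",
      format(activity_moment(x, 1), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Moments of an activity distribution
#'
#' Returns \eqn{\langle a^k \rangle = \int a^k f(a)\,da}, the k-th raw moment
#' of the activity potential. Closed form for the uniform and point-mass
#' families; exact piecewise-polynomial integration for tabulated densities.
#'
#' @param dist an [activity_dist] object.
#' @param k non-negative integer order (vectorized).
#' @return numeric vector of moments, one per entry of `k`.
#' @export
activity_moment <- function(dist, k) {
  stopifnot(inherits(dist, "activity_dist"), all(k >= 0), all(k == round(k)))
  vapply(k, function(kk) moment1(dist, kk), numeric(1))
}

moment1 <- function(dist, k) {
  if (k == 0) return(1)
  switch(dist$family,
    "uniform" = {
      lo <- dist$params[["min"]]; hi <- dist$params[["max"]]
      (hi^(k + 1) - lo^(k + 1)) / ((k + 1) * (hi - lo))
    },
    "point-mass" = dist$params[["a0"]]^k,
    "tabulated" = {
      a <- dist$params$a; f <- dist$params$f
      # integrate a^k * (linear interpolant of f) exactly on each panel
      tot <- 0
      for (i in seq_len(length(a) - 1L)) {
        a1 <- a[i]; a2 <- a[i + 1L]; f1 <- f[i]; f2 <- f[i + 1L]
        slope <- (f2 - f1) / (a2 - a1)
        icpt <- f1 - slope * a1
        tot <- tot + icpt * (a2^(k + 1) - a1^(k + 1)) / (k + 1) +
          slope * (a2^(k + 2) - a1^(k + 2)) / (k + 2)
      }
      tot
    },
    stop("unknown family: ", dist$family))
}

#' Density of an activity distribution
#'
#' @param dist an [activity_dist] object.
#' @param a evaluation points.
#' @return density values f(a) (0 outside the support).
#' @export
activity_density <- function(dist, a) {
  lo <- dist$support[1L]; hi <- dist$support[2L]
  inside <- a >= lo & a <= hi
  out <- numeric(length(a))
  if (dist$family == "uniform") {
    out[inside] <- 1 / (hi - lo)
  } else if (dist$family == "point-mass") {
    stop("point-mass distribution has no density; use activity_moment()")
  } else {
    out[inside] <- stats::approx(dist$params$a, dist$params$f,
                                 xout = a[inside])$y
  }
  out
}

#' Sample activity potentials
#'
#' Draws N i.i.d. activity potentials from f(a). Deterministic given `seed`.
#'
#' @param dist an [activity_dist] object.
#' @param N number of individuals (>= 1).
#' @param seed optional integer seed (set with [set.seed()] internally).
#' @return numeric vector of length N with values in (0, 1].
#' @export
sample_activities <- function(dist, N, seed = NULL) {
  stopifnot(inherits(dist, "activity_dist"), N >= 1)
  if (!is.null(seed)) set.seed(seed)
  switch(dist$family,
    "uniform" = stats::runif(N, dist$params[["min"]], dist$params[["max"]]),
    "point-mass" = rep(dist$params[["a0"]], N),
    "tabulated" = {
      # inverse-CDF on the piecewise-linear density via a fine grid
      a <- dist$params$a; f <- dist$params$f
      grid <- seq(a[1L], a[length(a)], length.out = 2048L)
      fg <- stats::approx(a, f, xout = grid)$y
      cdf <- cumsum(c(0, diff(grid) * (utils::head(fg, -1L) +
                                         utils::tail(fg, -1L)) / 2))
      cdf <- cdf / cdf[length(cdf)]
      ok <- !duplicated(cdf)
      stats::approx(cdf[ok], grid[ok], xout = stats::runif(N))$y
    })
}

#' Read an activity distribution from a YAML/JSON config block
#'
#' The block has fields `family` (one of `uniform`, `point-mass`,
#' `tabulated`), `params`, and optionally `support`.
#'
#' @param x a named list as parsed from YAML/JSON.
#' @return an [activity_dist] object.
#' @export
activity_dist_from_config <- function(x) {
  if (is.null(x$family)) stop("distribution config needs a 'family' field")
  p <- x$params
  switch(as.character(x$family),
    "uniform" = activity_uniform(p$min %||% p[[1L]], p$max %||% p[[2L]]),
    "point-mass" = activity_point(p$a0 %||% p[[1L]]),
    "tabulated" = activity_tabulated(unlist(p$a), unlist(p$f)),
    stop("unknown distribution family: ", x$family))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
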