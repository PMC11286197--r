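#' Deterministic replicator-type dynamics
#'
#' The same functional form covers the classical replicator equations
#' (M = A, well-mixed) and the replicator-like equations on activity-driven
#' temporal networks (M = A' = alpha1 A + alpha2 B):
#' \deqn{\dot x_i = x_i\,(e_i \cdot M x - x \cdot M x).}
#' Velocities sum to zero, so the simplex is invariant; positive rescaling
#' of M only rescales time, leaving phase portraits unchanged.
#'
#' @name dynamics
NULL

#' Replicator right-hand side
#'
#' @param M n x n payoff (or transformed payoff) matrix.
#' @param x frequency vector on the simplex.
#' @return velocity vector (components sum to 0).
#' @export
replicator_rhs <- function(M, x) {
  M <- unclass(as_payoff(M))
  if (length(x) != nrow(M))
    stop("state length ", length(x), " does not match matrix dimension ",
         nrow(M))
  fit <- as.vector(M %*% x)
  x * (fit - sum(x * fit))
}

#' Analytic Jacobian of the replicator right-hand side
#'
#' J_ij = delta_ij (e_i.Mx - phi) + x_i (M_ij - (Mx)_j - (M'x)_j) with
#' phi = x.Mx; used (after tangent-space projection) for fixed-point
#' classification.
#'
#' @inheritParams replicator_rhs
#' @return n x n Jacobian matrix.
#' @export
replicator_jacobian <- function(M, x) {
  M <- unclass(as_payoff(M))
  n <- nrow(M)
  fit <- as.vector(M %*% x)
  fitT <- as.vector(crossprod(M, x))
  phi <- sum(x * fit)
  J <- x * (M - matrix(fit + fitT, n, n, byrow = TRUE))
  diag(J) <- diag(J) + (fit - phi)
  J
}

#' Integrate a replicator trajectory
#'
#' Adaptive integration (deSolve, lsoda) with tight tolerances. Output
#' states are clipped at 0 and renormalized onto the simplex; the largest
#' per-step simplex drift |sum(x) - 1| observed before renormalization is
#' reported, and an absorption event is logged when a trajectory comes
#' within `vertex_tol` of a vertex. An optional uniform mutation rate adds
#' eps * (1/n - x_i) to each component (used only as a stress test for
#' boundary-supported attractors).
#'
#' @param M payoff matrix driving the dynamics.
#' @param x0 initial frequencies on the simplex.
#' @param t_end final time.
#' @param n_out number of sample times (including 0 and t_end).
#' @param rtol,atol integrator tolerances.
#' @param mutation uniform mutation rate eps (default 0).
#' @param vertex_tol absorption distance to a vertex.
#' @return list of class `replicator_trajectory`: `times`, `x`
#'   (n_out x n matrix), `terminal`, `max_drift`, `events`
#'   (data frame of vertex-absorption events).
#' @export
integrate_trajectory <- function(M, x0, t_end, n_out = 201L,
                                 rtol = 1e-10, atol = 1e-12,
                                 mutation = 0, vertex_tol = 1e-6) {
  M <- unclass(as_payoff(M))
  n <- nrow(M)
  stopifnot(length(x0) == n, all(x0 >= 0))
  if (abs(sum(x0) - 1) > 1e-8) stop("x0 must lie on the simplex")
  times <- seq(0, t_end, length.out = n_out)
  rhs <- function(t, x, parms) {
    v <- replicator_rhs(M, x)
    if (mutation > 0) v <- v + mutation * (1 / n - x)
    list(v)
  }
  sol <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("integrator failed to meet the requested tolerance (istate = ",
         attr(sol, "istate")[1L], ")")
  X <- unname(sol[, -1L, drop = FALSE])
  drift <- max(abs(rowSums(X) - 1))
  X[X < 0] <- 0
  X <- X / rowSums(X)
  # vertex absorption events
  ev <- NULL
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((X - rep(diag(n)[i, ], each = nrow(X)))^2))
    hit <- which(d < vertex_tol)
    if (length(hit))
      ev <- rbind(ev, data.frame(vertex = i, t = times[hit[1L]]))
  }
  structure(list(times = times, x = X, terminal = X[nrow(X), ],
                 max_drift = drift,
                 events = if (is.null(ev))
                   data.frame(vertex = integer(), t = numeric()) else ev),
            class = "replicator_trajectory")
}

#' @export
print.replicator_trajectory <- function(x, ...) {
  cat("replicator trajectory: t in [0,", max(x$times), "], terminal x = (",
      paste(format(x$terminal, digits = 4), collapse = ", "),
      ")\n  max simplex drift", format(x$max_drift, digits = 3), "\n")
  invisible(x)
}

#' Classify a fixed point of the replicator dynamics
#'
#' Projects the analytic Jacobian onto the (n-1)-dimensional tangent space
#' of the simplex (orthogonal complement of the all-ones vector) and
#' classifies by the real parts of its eigenvalues: all < -tol stable; all
#' > tol unstable; mixed signs saddle; exactly one eigenvalue inside the
#' tol band with the rest negative marks a non-isolated rest point with a
#' neutral direction (e.g. a line of fixed points); anything else is
#' reported undecided.
#'
#' @param M payoff matrix driving the dynamics.
#' @param x_star candidate fixed point (simplex vector).
#' @param tol residual / eigenvalue tolerance.
#' @return list of class `fixed_point_report`: `location`, `eigenvalues`
#'   (tangent-space, complex), `classification`, `residual`.
#' @export
classify_fixed_point <- function(M, x_star, tol = 1e-7) {
  M <- unclass(as_payoff(M))
  n <- nrow(M)
  stopifnot(length(x_star) == n)
  res <- sqrt(sum(replicator_rhs(M, x_star)^2))
  if (res > max(tol, 1e-8))
    stop("not a fixed point: residual norm ", format(res, digits = 4),
         " exceeds tolerance")
  J <- replicator_jacobian(M, x_star)
  Tb <- qr.Q(qr(cbind(rep(1, n))), complete = TRUE)[, -1L, drop = FALSE]
  Jt <- crossprod(Tb, J %*% Tb)
  ev <- eigen(Jt, only.values = TRUE)$values
  re <- Re(ev)
  cls <- if (all(re < -tol)) "stable"
  else if (all(re > tol)) "unstable"
  else if (any(re > tol) && any(re < -tol) && !any(abs(re) <= tol)) "saddle"
  else if (sum(abs(re) <= tol) == 1L && all(re[abs(re) > tol] < 0))
    "non-isolated/neutral-direction"
  else if (any(re > tol)) "unstable"
  else "undecided"
  structure(list(location = x_star, eigenvalues = ev, classification = cls,
                 residual = res),
            class = "fixed_point_report")
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat("fixed point (", paste(format(x$location, digits = 4), collapse = ", "),
      "): ", x$classification, "\n  tangent eigenvalues: ",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
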