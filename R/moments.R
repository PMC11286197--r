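#' Activity-moment hierarchy and slow manifold
#'
#' The mean-field description of the ABM tracks, per strategy si, the
#' moments I^k_si(t) = integral of x_{a,si}(t) a^k da. At neutrality the
#' hierarchy is linear,
#' \deqn{\dot I^k = \tfrac12(-I^{k+1} - \langle a\rangle I^k +
#'   \langle a^k\rangle I^1 + \langle a^{k+1}\rangle I^0),}
#' and relaxes fast (independently of beta) onto the slow manifold
#' I^k = <a^k> I^0, while the frequencies I^0 move only at O(beta). The
#' O(beta) selection terms come from the four-term gain/loss balance of
#' the imitation process, with the expected payoff of an activity-a player
#' E(P_{a,si}) = ((a + <a>) m delta - 1) * (A I^0)_si + a_{si,sj} (the last
#' term being the focal interaction with the imitation partner, strategy
#' sj); the Fermi factor is expanded to first order in beta inside the
#' pairing integrals. On the slow manifold this selection term reduces
#' exactly to the replicator-like equations with A' = alpha1 A + alpha2 B.
#'
#' @name moment_hierarchy
NULL

#' Slow-manifold moment values
#'
#' I^k_si = <a^k> x_si: the equilibrium the higher-order variables relax to
#' while the frequencies are (nearly) frozen.
#'
#' @param x frequency vector.
#' @param dist an [activity_dist].
#' @param k_max highest order.
#' @return matrix n x (k_max + 1); column k + 1 holds order k.
#' @export
slow_manifold_moments <- function(x, dist, k_max) {
  stopifnot(all(x >= 0), abs(sum(x) - 1) < 1e-8, k_max >= 0)
  mu <- activity_moment(dist, 0:k_max)
  out <- outer(x, mu)
  dimnames(out) <- list(names(x), paste0("k", 0:k_max))
  out
}

# extend an n x (K+1) moment table to orders K+1, K+2 under a closure
extend_moments <- function(I, mu, closure) {
  K <- ncol(I) - 1L
  ext <- matrix(0, nrow(I), 2)
  if (closure == "slow-manifold-top") {
    # recursion I^{k+1} = -<a> I^k + <a^k> I^1 + <a^{k+1}> I^0 (the
    # stationarity identity of the neutral hierarchy), applied twice
    ext[, 1] <- -mu[2] * I[, K + 1] + mu[K + 1] * I[, 2] + mu[K + 2] * I[, 1]
    ext[, 2] <- -mu[2] * ext[, 1] + mu[K + 2] * I[, 2] + mu[K + 3] * I[, 1]
  } else if (closure != "truncate-top") {
    stop("unknown closure: ", closure,
         " (use 'slow-manifold-top' or 'truncate-top')")
  }
  cbind(I, ext)
}

#' Right-hand side of the moment hierarchy
#'
#' Time derivative of the moment table I (rows: strategies, columns:
#' orders 0..k_max). The neutral part follows the linear hierarchy above;
#' with `selection = TRUE` the O(beta) four-term imitation balance is
#' added. Orders k_max + 1, k_max + 2 (needed by the top rows) are supplied
#' by the closure.
#'
#' @param I n x (k_max + 1) moment matrix.
#' @param game n x n payoff matrix.
#' @param dist an [activity_dist].
#' @param beta selection intensity.
#' @param m,delta network parameters.
#' @param closure `"slow-manifold-top"` (default) or `"truncate-top"`.
#' @param selection include the O(beta) terms?
#' @return matrix of the same shape as `I`.
#' @export
moment_hierarchy_rhs <- function(I, game, dist, beta, m, delta,
                                 closure = "slow-manifold-top",
                                 selection = TRUE) {
  game <- unclass(as_payoff(game))
  n <- nrow(game)
  stopifnot(nrow(I) == n, ncol(I) >= 2)
  K <- ncol(I) - 1L
  mu <- activity_moment(dist, 0:(K + 2))   # mu[k+1] = <a^k>
  Ie <- extend_moments(I, mu, closure)
  md <- m * delta
  dI <- matrix(0, n, K + 1)
  # neutral linear hierarchy (identically 0 at k = 0)
  for (k in 0:K) {
    dI[, k + 1] <- 0.5 * (-Ie[, k + 2] - mu[2] * I[, k + 1] +
                            mu[k + 1] * I[, 2] + mu[k + 2] * I[, 1])
  }
  if (selection && beta > 0) {
    B <- game - t(game)
    pii <- as.vector(game %*% I[, 1])          # pi_i = (A I^0)_i
    D <- (mu[2] * md - 1) * outer(pii, pii, "-") + B   # d_ij
    S0 <- sum(I[, 1]); S1 <- sum(I[, 2])
    Tp <- colSums(Ie)                          # T^k = sum_j I^k_j
    Tpi <- as.vector(crossprod(Ie, pii))       # sum_j pi_j I^k_j
    DI0 <- as.vector(D %*% I[, 1])
    DI1 <- as.vector(D %*% I[, 2])
    for (k in 0:K) {
      Ik <- Ie[, k + 1]; Ik1 <- Ie[, k + 2]; Ik2 <- Ie[, k + 3]
      sel <- Ik1 * DI0 - md * Ik1 * Tpi[2] + md * pii * Ik2 * S0 +
        Ik * DI1 - md * Ik * Tpi[3] + md * pii * Ik1 * S1 +
        I[, 1] * as.vector(D %*% Ik1) + md * pii * I[, 2] * Tp[k + 2] -
        I[, 1] * Tpi[k + 3] * md +
        I[, 2] * as.vector(D %*% Ik) + md * pii * I[, 3] * Tp[k + 1] -
        I[, 2] * Tpi[k + 2] * md
      dI[, k + 1] <- dI[, k + 1] + (beta / 4) * sel
    }
  }
  dimnames(dI) <- dimnames(I)
  dI
}

#' Integrate the moment hierarchy
#'
#' Direct forward integration of the truncated ladder. Note that the
#' truncation is delicate: although the untruncated hierarchy (equivalently
#' the joint activity-strategy density dynamics) relaxes to the slow
#' manifold, closing the ladder at a finite k_max introduces spurious
#' weakly unstable modes (growth rates of order 0.1 for k_max around 8),
#' so residuals grow again on long horizons. For quantitative long-time
#' work use [integrate_activity_density()], which integrates the
#' untruncated hierarchy exactly in its density representation.
#'
#' @param I0 initial n x (k_max + 1) moment matrix.
#' @inheritParams moment_hierarchy_rhs
#' @param t_end final time.
#' @param n_out number of output times.
#' @param rtol,atol integrator tolerances.
#' @return list: `times`, `I` (array n_out x n x (k_max + 1)).
#' @export
integrate_moment_hierarchy <- function(I0, game, dist, beta, m, delta,
                                       t_end, n_out = 101L,
                                       closure = "slow-manifold-top",
                                       selection = TRUE,
                                       rtol = 1e-10, atol = 1e-12) {
  n <- nrow(I0); K <- ncol(I0) - 1L
  times <- seq(0, t_end, length.out = n_out)
  rhs <- function(t, y, parms) {
    list(as.vector(moment_hierarchy_rhs(matrix(y, n, K + 1), game, dist,
                                        beta, m, delta, closure, selection)))
  }
  sol <- deSolve::ode(y = as.vector(I0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("moment-hierarchy integration failed (istate = ",
         attr(sol, "istate")[1L], ")")
  arr <- array(unname(sol[, -1L]), c(length(times), n, K + 1))
  list(times = times, I = arr)
}

#' Discretize an activity distribution into atoms
#'
#' Represents f(a) as a discrete measure (atoms `a`, masses `p`), used by
#' the density-representation integrator. A point mass keeps its single
#' atom; a tabulated density uses its own grid; a uniform density is
#' sampled on an equispaced grid with masses proportional to f.
#'
#' @param dist an [activity_dist].
#' @param n_atoms number of atoms for continuous families.
#' @return list with `a`, `p` (masses summing to 1) and
#'   `moment(k)` giving the discrete moments (vectorized in k).
#' @export
discretize_activity <- function(dist, n_atoms = 201L) {
  if (dist$family == "point-mass") {
    a <- dist$params[["a0"]]; p <- 1
  } else if (dist$family == "tabulated") {
    a <- dist$params$a; p <- dist$params$f
    p <- p / sum(p)
  } else {
    a <- seq(dist$support[1L], dist$support[2L], length.out = n_atoms)
    p <- rep(1 / n_atoms, n_atoms)
  }
  list(a = a, p = p,
       moment = function(k) vapply(k, function(kk) sum(p * a^kk), numeric(1)))
}

#' Integrate the untruncated moment hierarchy (density representation)
#'
#' Evolves the joint activity-strategy density z_{i,g} (strategy i, activity
#' atom g) under the mean-field imitation dynamics whose k-th moments obey
#' the full hierarchy for every k simultaneously -- no truncation or
#' closure. The gain/loss kernel pairs a focal player and a role model
#' with combined activation weight (a + a') and the Fermi factor expanded
#' to first order in beta. The activity marginal is conserved exactly; at
#' neutrality the density relaxes onto z_{i,g} = x_i p_g (the slow
#' manifold), and with selection the induced frequency dynamics matches
#' the replicator-like equations with A' = alpha1 A + alpha2 B up to
#' O(beta^2).
#'
#' @param Z0 initial n x G density matrix (column sums = activity masses
#'   `disc$p`), e.g. `outer(x0, disc$p)` for an uncorrelated start.
#' @param disc a discrete activity measure from [discretize_activity()].
#' @param game n x n payoff matrix.
#' @param beta selection intensity.
#' @param m,delta network parameters.
#' @param t_end final time.
#' @param n_out number of output times.
#' @param rtol,atol integrator tolerances.
#' @return list: `times`, `Z` (array n_out x n x G), and `moments(k_max)`
#'   returning the array n_out x n x (k_max + 1) of moments.
#' @export
integrate_activity_density <- function(Z0, disc, game, beta, m, delta,
                                       t_end, n_out = 101L,
                                       rtol = 1e-10, atol = 1e-12) {
  game <- unclass(as_payoff(game))
  n <- nrow(game)
  G <- length(disc$a)
  stopifnot(nrow(Z0) == n, ncol(Z0) == G)
  a <- disc$a
  md <- m * delta
  mu1 <- sum(disc$p * a)
  B <- game - t(game)
  rhs <- function(t, y, parms) {
    Z <- matrix(y, n, G)
    I0 <- as.vector(Z %*% rep(1, G))
    I1 <- as.vector(Z %*% a)
    I2 <- as.vector(Z %*% a^2)
    pii <- as.vector(game %*% I0)
    D <- (mu1 * md - 1) * outer(pii, pii, "-") + B  # d_ij
    dZ <- matrix(0, n, G)
    for (i in seq_len(n)) {
      gain <- numeric(G); loss <- numeric(G)
      for (j in seq_len(n)) {
        # role model strategy i (gain): focal j at atom a_g adopts i
        Fij0 <- 0.5 + (beta / 4) * (D[i, j] - md * pii[j] * a)
        gain <- gain + Z[j, ] *
          (a * (Fij0 * I0[i] + (beta / 4) * md * pii[i] * I1[i]) +
             (Fij0 * I1[i] + (beta / 4) * md * pii[i] * I2[i]))
        # focal i at atom a_g adopts j (loss)
        Fji0 <- 0.5 + (beta / 4) * (D[j, i] - md * pii[i] * a)
        loss <- loss + (a * (Fji0 * I0[j] + (beta / 4) * md * pii[j] * I1[j]) +
                          (Fji0 * I1[j] + (beta / 4) * md * pii[j] * I2[j]))
      }
      dZ[i, ] <- gain - Z[i, ] * loss
    }
    list(as.vector(dZ))
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = as.vector(Z0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("density integration failed (istate = ", attr(sol, "istate")[1L], ")")
  Zarr <- array(unname(sol[, -1L]), c(length(times), n, G))
  list(times = times, Z = Zarr,
       moments = function(k_max) {
         out <- array(0, c(length(times), n, k_max + 1))
         for (k in 0:k_max)
           for (tt in seq_along(times))
             out[tt, , k + 1] <- matrix(Zarr[tt, , ], n, G) %*% a^k
         out
       })
}
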