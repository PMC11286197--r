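#' Agent-based Monte Carlo simulation
#'
#' One evolutionary step has a game phase and an updating phase. In the game
#' phase every individual accumulates payoff by playing the pairwise game
#' with all its neighbours on the integrated network G_delta(t). In the
#' updating phase every individual with at least one neighbour picks one
#' uniformly at random and imitates its strategy with the Fermi probability
#' F(P_v - P_u) = 1 / (1 + exp(-beta (P_v - P_u))). All decisions are taken
#' synchronously from the pre-update state (an asynchronous random-order
#' variant is available as a sensitivity switch). Isolated nodes keep their
#' strategy and payoff 0.
#'
#' @name abm
NULL

#' Fermi imitation probability
#'
#' `1 / (1 + exp(-beta * dP))`, saturating to 0/1 for large |beta * dP|.
#' For weak selection this is 1/2 + beta * dP / 4 + O(beta^2).
#'
#' @param dP payoff difference P_v - P_u (role model minus focal).
#' @param beta selection intensity (>= 0).
#' @return imitation probability in [0, 1] (vectorized).
#' @export
fermi_prob <- function(dP, beta) {
  stopifnot(beta >= 0)
  stats::plogis(beta * dP)
}

#' Accumulated payoffs on an integrated graph
#'
#' P_u = sum over neighbours v of A[s_u, s_v]; isolated nodes get 0.
#'
#' @param graph an `activity_graph` over the same node set.
#' @param strategies integer vector (values in 1..n).
#' @param game n x n payoff matrix.
#' @return numeric payoff vector of length N.
#' @export
accumulate_payoffs <- function(graph, strategies, game) {
  game <- as_payoff(game)
  N <- graph$N
  if (length(strategies) != N)
    stop("strategies (", length(strategies), ") must align with graph nodes (",
         N, ")")
  if (any(strategies < 1 | strategies > nrow(game)))
    stop("strategy index out of range 1..", nrow(game))
  cpp_accumulate_payoffs(graph$edges, as.integer(strategies),
                         unclass(game), as.integer(N))
}

#' One synchronous (or asynchronous) Fermi imitation sweep
#'
#' @param graph the integrated graph the payoffs were computed on.
#' @param strategies pre-update strategy vector.
#' @param payoffs payoff vector from [accumulate_payoffs()].
#' @param beta selection intensity.
#' @param seed optional integer seed.
#' @param scheme `"synchronous"` (default: all nodes decide from the
#'   pre-update state) or `"asynchronous"` (random order, frozen payoffs).
#' @return updated strategy vector.
#' @export
update_strategies <- function(graph, strategies, payoffs, beta, seed = NULL,
                              scheme = c("synchronous", "asynchronous")) {
  scheme <- match.arg(scheme)
  stopifnot(length(strategies) == graph$N, length(payoffs) == graph$N)
  if (!is.null(seed)) set.seed(seed)
  cpp_update_strategies(graph$edges, as.integer(strategies),
                        as.numeric(payoffs), beta,
                        scheme == "synchronous")
}

#' Empirical activity moments by strategy
#'
#' I^k_si = (1/N) * sum over carriers u of strategy si of a_u^k. The
#' zeroth order I^0_si is the strategy frequency x_si.
#'
#' @param activities activity vector.
#' @param strategies strategy vector (1..n).
#' @param n_strategies number of strategies n.
#' @param k_max highest order recorded.
#' @return numeric matrix `n_strategies x (k_max + 1)`; column k + 1 holds
#'   order k. Rows are labelled by strategy, columns `k0..k<k_max>`.
#' @export
empirical_moments <- function(activities, strategies, n_strategies, k_max) {
  N <- length(activities)
  stopifnot(length(strategies) == N, k_max >= 0)
  out <- matrix(0, n_strategies, k_max + 1,
                dimnames = list(paste0("s", seq_len(n_strategies)),
                                paste0("k", 0:k_max)))
  for (i in seq_len(n_strategies)) {
    au <- activities[strategies == i]
    out[i, ] <- vapply(0:k_max, function(k) sum(au^k) / N, numeric(1))
  }
  out
}

#' Run the agent-based evolutionary game simulation
#'
#' Per step: build G_delta(t), accumulate payoffs, synchronously update by
#' the Fermi rule, and record the strategy frequencies x_si(t) and the
#' activity moments I^k_si(t) for k up to `k_max`. Stationary moments are
#' time-averaged over the final `record_steps` steps (after a relaxation
#' window of `steps - record_steps` steps), for each of `replicates`
#' independent initial conditions.
#'
#' @param game n x n payoff matrix.
#' @param dist an [activity_dist] for the activity potentials.
#' @param N population size.
#' @param m links per activation.
#' @param delta window length.
#' @param beta selection intensity.
#' @param init_freq initial strategy frequencies (length n, sums to 1);
#'   each replicate assigns strategies i.i.d. with these probabilities.
#' @param steps total evolutionary steps per replicate (default 1000).
#' @param record_steps final steps averaged into the stationary moments
#'   (default 250, i.e. 750 relaxation steps at the default `steps`).
#' @param k_max highest moment order recorded (default 8).
#' @param replicates number of independent initial conditions.
#' @param seed master seed; per-replicate streams are split from it.
#' @param freeze_activities if TRUE all replicates reuse one activity draw.
#' @param scheme update scheme, see [update_strategies()].
#' @return list of class `abm_result`:
#'   `stationary` (array replicates x n x (k_max+1) of time-averaged
#'   moments), `freq` (steps x n frequency trajectory of the last
#'   replicate), `moments_last` (recorded per-step moment matrix of the
#'   last replicate), and the parameters.
#' @export
run_abm <- function(game, dist, N, m, delta, beta, init_freq,
                    steps = 1000L, record_steps = 250L, k_max = 8L,
                    replicates = 1L, seed = NULL,
                    freeze_activities = FALSE,
                    scheme = c("synchronous", "asynchronous")) {
  scheme <- match.arg(scheme)
  game <- as_payoff(game)
  n <- nrow(game)
  if (n < 2) stop("need at least 2 strategies")
  if (length(init_freq) != n || any(init_freq < 0) ||
      abs(sum(init_freq) - 1) > 1e-8)
    stop("init_freq must be a probability vector of length ", n)
  check_net_args(N, m)
  stopifnot(delta >= 1, steps >= 1, record_steps >= 1, record_steps <= steps,
            beta >= 0, k_max >= 0)
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^30))
  stationary <- array(NA_real_, c(replicates, n, k_max + 1))
  freq <- NULL; moments_last <- NULL
  act <- NULL
  for (r in seq_len(replicates)) {
    set.seed(split_seed(seed, r))
    if (is.null(act) || !freeze_activities)
      act <- sample_activities(dist, N)
    s0 <- sample.int(n, N, replace = TRUE, prob = init_freq)
    res <- cpp_run_abm(act, as.integer(s0), unclass(game), beta,
                       as.integer(m), as.integer(delta), as.integer(steps),
                       as.integer(k_max),
                       as.integer(steps - record_steps + 1L),
                       scheme == "synchronous")
    mom <- res$moments   # record_steps x (n * (k_max + 1))
    avg <- colMeans(mom)
    stationary[r, , ] <- matrix(avg, n, k_max + 1, byrow = TRUE)
    if (r == replicates) {
      freq <- res$freq
      moments_last <- mom
    }
  }
  structure(list(stationary = stationary, freq = freq,
                 moments_last = moments_last,
                 params = list(N = N, m = m, delta = delta, beta = beta,
                               steps = steps, record_steps = record_steps,
                               k_max = k_max, replicates = replicates,
                               seed = seed, scheme = scheme,
                               labels = rownames(game))),
            class = "abm_result")
}

#' @export
print.abm_result <- function(x, ...) {
  p <- x$params
  cat("ABM run: N =", p$N, " m =", p$m, " delta =", p$delta,
      " beta =", p$beta, "\n ", p$replicates, "replicate(s) x", p$steps,
      "steps;", p$record_steps, "recorded\n")
  xbar <- apply(x$stationary[, , 1, drop = FALSE], 2, mean)
  cat("  stationary frequencies:",
      paste(p$labels, format(xbar, digits = 4), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

# deterministic counter-based seed splitting, kept below 2^31
split_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 1000003) %% 2147483647)
}
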