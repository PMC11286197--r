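# shared fixtures: small games and random generators used across tests

coord_game <- function() payoff_matrix(matrix(c(1, 0, 0, 0.5), 2, 2,
                                              byrow = TRUE))

pd_game <- function(b = 3, c = 1) {
  # prisoner's dilemma with T > R > P > S
  payoff_matrix(rbind(c(b - c, -c), c(b, 0)), labels = c("C", "D"))
}

random_game <- function(n) payoff_matrix(matrix(stats::rnorm(n * n), n, n))

random_simplex_point <- function(n) {
  e <- -log(stats::runif(n))
  e / sum(e)
}

uniform_dist <- function() activity_uniform(0.001, 1)

# exact expected strategy indicator after one synchronous Fermi sweep,
# by direct enumeration of every node's neighbour choice and coin flip
expected_freq_after_sweep <- function(graph, s, P, beta, n_strat) {
  N <- graph$N
  adj <- vector("list", N)
  for (e in seq_len(nrow(graph$edges))) {
    u <- graph$edges[e, 1]; v <- graph$edges[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  pr <- matrix(0, N, n_strat)     # pr[u, i] = P(s'(u) = i)
  for (u in seq_len(N)) {
    if (is.null(adj[[u]])) { pr[u, s[u]] <- 1; next }
    du <- length(adj[[u]])
    for (v in adj[[u]]) {
      f <- fermi_prob(P[v] - P[u], beta)
      pr[u, s[v]] <- pr[u, s[v]] + f / du
      pr[u, s[u]] <- pr[u, s[u]] + (1 - f) / du
    }
  }
  colSums(pr) / N
}
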