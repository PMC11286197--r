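test_that("Fermi probability has the right symmetry and weak limit", {
  expect_equal(fermi_prob(0, 5), 0.5)
  expect_equal(fermi_prob(c(-3, 0, 7), 0), rep(0.5, 3))
  # weak-selection linearization: 1/2 + beta dP / 4 with O(beta^2) error
  expect_equal(fermi_prob(4, 1e-6), 0.5 + 1e-6, tolerance = 1e-12)
  # saturation without overflow
  expect_equal(fermi_prob(1e6, 10), 1)
  expect_equal(fermi_prob(-1e6, 10), 0)
})

test_that("payoff accumulation sums the game over neighbourhoods", {
  A <- coord_game()
  empty <- integrate_window(rep(0, 6), m = 1, delta = 1, seed = 1)
  expect_equal(accumulate_payoffs(empty, rep(1, 6), A), rep(0, 6))
  # single edge, both strategy 1, a_{s1,s1} = 1
  g <- structure(list(edges = rbind(c(1L, 2L)), N = 2), class = "activity_graph")
  expect_equal(accumulate_payoffs(g, c(1, 1), A), c(1, 1))
  # star: centre s1, three leaves s2; a_{s1,s2} = a_{s2,s1} = 0
  star <- structure(list(edges = rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)),
                         N = 4), class = "activity_graph")
  expect_equal(accumulate_payoffs(star, c(1, 2, 2, 2), A), rep(0, 4))
  # mixed game sanity on the same star with the off-diagonals nonzero
  M <- payoff_matrix(rbind(c(1, 2), c(5, 0.5)))
  expect_equal(accumulate_payoffs(star, c(1, 2, 2, 2), M),
               c(3 * 2, 5, 5, 5))
  expect_error(accumulate_payoffs(star, c(1, 2, 3, 2), A), "out of range")
  expect_error(accumulate_payoffs(star, c(1, 2), A), "align")
})

test_that("imitation cannot create strategies and respects the Fermi coin", {
  A <- coord_game()
  g <- integrate_window(rep(0.8, 40), m = 2, delta = 2, seed = 2)
  s <- rep(2L, 40)
  P <- accumulate_payoffs(g, s, A)
  expect_identical(update_strategies(g, s, P, beta = 5, seed = 3), s)
  # two-node graph with equal payoffs: adoption probability is exactly 1/2
  g2 <- structure(list(edges = rbind(c(1L, 2L)), N = 2),
                  class = "activity_graph")
  set.seed(4)
  flips <- replicate(4000, update_strategies(g2, c(1L, 2L), c(0, 0),
                                             beta = 1)[1] == 2L)
  expect_lt(abs(mean(flips) - 0.5), 3 * 0.5 / sqrt(4000))
})

test_that("one synchronous sweep matches its exact expectation", {
  # enumeration oracle: per-node law of the uniformly chosen neighbour and
  # Fermi coin, against the Monte-Carlo mean of update_strategies
  A <- payoff_matrix(rbind(c(1, 0.2), c(1.4, 0.5)))
  set.seed(5)
  a <- stats::runif(12, 0.3, 1)
  g <- integrate_window(a, m = 2, delta = 2, seed = 6)
  s <- sample(1:2, 12, replace = TRUE)
  P <- accumulate_payoffs(g, s, A)
  beta <- 0.8
  exp_freq <- expected_freq_after_sweep(g, s, P, beta, 2)
  reps <- 4000
  set.seed(7)
  f1 <- replicate(reps, mean(update_strategies(g, s, P, beta) == 1))
  se <- stats::sd(f1) / sqrt(reps)
  expect_lt(abs(mean(f1) - exp_freq[1]), 3 * se + 1e-4)
})

test_that("neutral imitation is a martingale over the graph ensemble", {
  # on a single frozen graph E[dx] need not vanish (degree-strategy
  # correlations enter through the uniform-neighbour choice); averaging
  # over the activity-driven graph ensemble restores the martingale
  A <- coord_game()
  set.seed(8)
  a <- stats::runif(100, 0.2, 1)
  s <- rep(c(1L, 2L), 50)   # strategies independent of activities
  reps <- 1500
  dx <- replicate(reps, {
    g <- integrate_window(a, m = 2, delta = 2)
    P <- accumulate_payoffs(g, s, A)
    mean(update_strategies(g, s, P, beta = 0) == 1) - mean(s == 1)
  })
  expect_lt(abs(mean(dx)), 3 * stats::sd(dx) / sqrt(reps) + 1e-4)
})

test_that("empirical moments aggregate a^k by strategy", {
  m <- empirical_moments(rep(0.1, 5), rep(1L, 5), 2, 2)
  expect_equal(m[1, "k2"], 0.01)
  expect_equal(m[2, ], c(k0 = 0, k1 = 0, k2 = 0))
  # k = 0 row sums to 1
  set.seed(10)
  a <- stats::runif(1000, 0.001, 1)
  s <- sample(1:3, 1000, replace = TRUE)
  mm <- empirical_moments(a, s, 3, 4)
  expect_equal(sum(mm[, "k0"]), 1)
  # independence of strategy and activity at initialization
  a2 <- sample_activities(uniform_dist(), 1e5, seed = 11)
  s2 <- sample(1:2, 1e5, replace = TRUE)
  m2 <- empirical_moments(a2, s2, 2, 1)
  expect_lt(abs(m2[1, "k1"] - 0.5 * 0.5005), 3 * 0.3 / sqrt(1e5))
})

test_that("run_abm conserves moment-table structure every recorded step", {
  res <- run_abm(coord_game(), uniform_dist(), N = 400, m = 3, delta = 2,
                 beta = 0.02, init_freq = c(0.5, 0.5), steps = 60,
                 record_steps = 60, k_max = 6, replicates = 1, seed = 13)
  mom <- res$moments_last   # steps x (n * (k+1))
  I1 <- mom[, 1:7]; I2 <- mom[, 8:14]
  expect_equal(unname(I1[, 1] + I2[, 1]), rep(1, nrow(mom)), tolerance = 1e-12)
  expect_true(all(diff(t(I1)) <= 1e-12))   # I^{k+1} <= I^k per step
  expect_true(all(diff(t(I2)) <= 1e-12))
  expect_true(all(I1 >= 0 & I2 >= 0))
})

test_that("monomorphic populations are absorbing states", {
  res <- run_abm(coord_game(), uniform_dist(), N = 300, m = 3, delta = 2,
                 beta = 0.1, init_freq = c(1, 0), steps = 10,
                 record_steps = 10, k_max = 2, replicates = 1, seed = 14)
  expect_equal(unname(res$freq[, 1]), rep(1, 10))
  # once extinct, never resurrected (no mutation): strong drift run
  res2 <- run_abm(coord_game(), uniform_dist(), N = 60, m = 4, delta = 2,
                  beta = 0, init_freq = c(0.5, 0.5), steps = 400,
                  record_steps = 400, k_max = 0, replicates = 1, seed = 15)
  x1 <- res2$freq[, 1]
  hit0 <- which(x1 == 0)[1]; hit1 <- which(x1 == 1)[1]
  if (!is.na(hit0)) expect_true(all(x1[hit0:length(x1)] == 0))
  if (!is.na(hit1)) expect_true(all(x1[hit1:length(x1)] == 1))
})

test_that("neutral drift keeps the mean frequency at its start", {
  res <- run_abm(coord_game(), uniform_dist(), N = 1000, m = 4, delta = 2,
                 beta = 0, init_freq = c(0.5, 0.5), steps = 50,
                 record_steps = 1, k_max = 0, replicates = 40, seed = 16)
  xT <- res$stationary[, 1, 1]
  expect_lt(abs(mean(xT) - 0.5), 3 * stats::sd(xT) / sqrt(length(xT)) + 0.005)
})

test_that("run_abm is reproducible and validates its inputs", {
  r1 <- run_abm(coord_game(), uniform_dist(), N = 200, m = 2, delta = 2,
                beta = 1e-3, init_freq = c(0.3, 0.7), steps = 20,
                record_steps = 5, k_max = 3, replicates = 2, seed = 17)
  r2 <- run_abm(coord_game(), uniform_dist(), N = 200, m = 2, delta = 2,
                beta = 1e-3, init_freq = c(0.3, 0.7), steps = 20,
                record_steps = 5, k_max = 3, replicates = 2, seed = 17)
  expect_identical(r1$stationary, r2$stationary)
  expect_error(run_abm(coord_game(), uniform_dist(), N = 200, m = 2,
                       delta = 2, beta = 1e-3, init_freq = c(0.5, 0.4),
                       steps = 5, record_steps = 5, seed = 1),
               "probability vector")
})
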