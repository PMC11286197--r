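test_that("critical offer threshold and its limits", {
  expect_equal(critical_offer(1, 0), 0)
  expect_equal(critical_offer(1, 2), 0.4)
  expect_equal(critical_offer(1e-12, 2), 0.5, tolerance = 1e-9)
  expect_error(critical_offer(2, -1), "degenerate")
})

test_that("closed-form edge fixed points are exact RHS roots", {
  for (p in list(c(0.3, 0.2), c(0.45, 0.2), c(0.45, 0.42), c(0.35, 0.05))) {
    h <- p[1]; l <- p[2]
    Ap <- transformed_matrix(mug_matrix(h, l), 1, 2)$A_prime
    fps <- edge_fixed_points(h, l, 1, 2, classify = FALSE)
    for (fp in fps) {
      if (!fp$exists) next
      expect_lt(sqrt(sum(replicator_rhs(Ap, fp$location)^2)), 1e-12)
      expect_equal(sum(fp$location), 1, tolerance = 1e-12)
    }
  }
})

test_that("edge fixed points match their closed-form examples", {
  # R-F at h = 0.45, alpha = (1, 2): [0.75, 0, 0.25, 0]
  fps <- edge_fixed_points(0.45, 0.2, 1, 2)
  rf <- fps[[1]]
  expect_true(rf$exists)
  expect_equal(rf$location, c(0.75, 0, 0.25, 0))
  # G-I at (0.3, 0.2): [0, 0.5, 0, 0.5], exists since h - l < 1/5
  gi <- edge_fixed_points(0.3, 0.2, 1, 2)[[2]]
  expect_true(gi$exists)
  expect_equal(gi$location, c(0, 0.5, 0, 0.5))
  # R-F does not exist below the critical h
  expect_false(edge_fixed_points(0.3, 0.2, 1, 2)[[1]]$exists)
  # well-mixed limit alpha2 = 0: [1 - h, 0, h, 0]
  rf0 <- edge_fixed_points(0.3, 0.2, 1, 0)[[1]]
  expect_equal(rf0$location, c(0.7, 0, 0.3, 0))
  # well-mixed G-F endpoint: [0, (1-h)/(1-l), (h-l)/(1-l), 0]
  gf0 <- edge_fixed_points(0.3, 0.2, 1, 0)[[3]]
  expect_equal(gf0$location, c(0, 0.7 / 0.8, 0.1 / 0.8, 0))
})

test_that("existence flags are equivalent to the analytic inequalities", {
  set.seed(51)
  for (i in 1:200) {
    l <- stats::runif(1, 0.01, 0.45)
    h <- stats::runif(1, l + 0.01, 0.499)
    a1 <- stats::runif(1, 0.1, 3)
    a2 <- stats::runif(1, 0, 3)
    fps <- edge_fixed_points(h, l, a1, a2, classify = FALSE)
    expect_identical(fps[[1]]$exists, h > a2 / (a1 + 2 * a2))
    expect_identical(fps[[2]]$exists, h - l < a1 / (a1 + 2 * a2))
    expect_true(fps[[3]]$exists)  # the G-F endpoint is always interior
  }
})

test_that("R-F and G-I edge points are unstable as the portrait requires", {
  rf <- edge_fixed_points(0.45, 0.2, 1, 2)[[1]]
  expect_gt(max(Re(rf$stability$eigenvalues)), 1e-6)
  gi <- edge_fixed_points(0.3, 0.2, 1, 2)[[2]]
  expect_gt(max(Re(gi$stability$eigenvalues)), 1e-6)
})

test_that("the G-F line splits into stable and unstable segments at the
           computed endpoint", {
  h <- 0.3; l <- 0.2
  Ap <- transformed_matrix(mug_matrix(h, l), 1, 2)$A_prime
  xg_end <- edge_fixed_points(h, l, 1, 2)[[3]]$location[2]
  gf_point <- function(xg) c(0, xg, 1 - xg, 0)
  for (xg in seq(0.05, xg_end - 0.05, length.out = 5)) {
    fp <- classify_fixed_point(Ap, gf_point(xg), tol = 1e-7)
    expect_identical(fp$classification, "non-isolated/neutral-direction")
    # transverse eigenvalues non-positive
    expect_lt(sort(Re(fp$eigenvalues), decreasing = TRUE)[2], 0)
  }
  for (xg in seq(xg_end + 0.05, 0.95, length.out = 5)) {
    fp <- classify_fixed_point(Ap, gf_point(xg), tol = 1e-7)
    expect_gt(max(Re(fp$eigenvalues)), 1e-7)
  }
})

test_that("constant of motion: arithmetic and invariance along trajectories", {
  expect_equal(constant_of_motion(rep(0.25, 4)), 1)
  expect_equal(constant_of_motion(c(0.4, 0.2, 0.1, 0.3)), 2 / 3)
  expect_error(constant_of_motion(c(0.5, 0.5, 0, 0)), "boundary")
  Ap <- transformed_matrix(mug_matrix(0.3, 0.2), 1, 2)$A_prime
  set.seed(52)
  for (i in 1:5) {
    x0 <- random_simplex_point(4)
    tr <- integrate_trajectory(Ap, x0, t_end = 25, n_out = 51)
    K <- apply(tr$x, 1, constant_of_motion)
    expect_lt(max(abs(log(K) - log(K[1]))), 1e-6)
  }
})

test_that("payoff and gradient identities hold on the transformed game", {
  set.seed(53)
  for (i in 1:50) {
    l <- stats::runif(1, 0.05, 0.4)
    h <- stats::runif(1, l + 0.02, 0.49)
    a1 <- stats::runif(1, 0.2, 3)
    a2 <- stats::runif(1, 0, 3)
    Ap <- transformed_matrix(mug_matrix(h, l), a1, a2)$A_prime
    # row identity a'(s,R) + a'(s,F) = a'(s,G) + a'(s,I)
    expect_lt(max(abs(Ap[, 1] + Ap[, 3] - Ap[, 2] - Ap[, 4])), 1e-12)
    # gradient identity on random interior states
    x <- random_simplex_point(4)
    EP <- as.vector(Ap %*% x)
    rhs <- ((a1 + 2 * a2) * l - a2) * (x[1] + x[4])
    expect_lt(abs((EP[1] - EP[4]) - rhs), 1e-12)
    expect_lt(abs((EP[2] - EP[3]) - rhs), 1e-12)
  }
})

test_that("no interior fixed point exists for the temporal dynamics", {
  Ap <- transformed_matrix(mug_matrix(0.3, 0.2), 1, 2)$A_prime
  # multistart minimization of |rhs|^2 over the open simplex (softmax
  # parametrization keeps iterates interior)
  set.seed(54)
  for (i in 1:25) {
    z0 <- stats::rnorm(4)
    obj <- function(z) {
      x <- exp(z - max(z)); x <- x / sum(x)
      sum(replicator_rhs(Ap, x)^2)
    }
    opt <- stats::optim(z0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    x <- exp(opt$par - max(opt$par)); x <- x / sum(x)
    # every numerical root is a boundary point (some component ~ 0)
    if (opt$value < 1e-16) expect_lt(min(x), 1e-4)
  }
})

test_that("phase diagram flips exactly at l = alpha2/(alpha1 + 2 alpha2)", {
  pd <- phase_diagram(alpha_ratio = 10^seq(-2, 2, length.out = 21),
                      l = seq(0.025, 0.475, length.out = 19))
  expect_identical(nrow(pd), 21L * 19L)
  mis <- sum((pd$l < pd$threshold & pd$verdict != "R-unstable") |
               (pd$l > pd$threshold & pd$verdict != "R-stable"))
  expect_identical(mis, 0L)
  # named regimes from the temporal phase portraits
  expect_identical(as.character(
    phase_diagram(2, 0.2)$verdict), "R-unstable")
  expect_identical(as.character(
    phase_diagram(2, 0.42)$verdict), "R-stable")
  # l -> 0+ is always unstable
  expect_identical(as.character(
    phase_diagram(c(0.05, 1, 50), 0.001)$verdict), rep("R-unstable", 3))
})

test_that("trajectory bundles converge as the portraits dictate", {
  # (0.3, 0.2): fairness wins; I goes extinct from interior starts
  Ap <- transformed_matrix(mug_matrix(0.3, 0.2), 1, 2)$A_prime
  set.seed(55)
  for (i in 1:5) {
    x0 <- random_simplex_point(4)
    tr <- integrate_trajectory(Ap, x0, t_end = 400, n_out = 41)
    term <- tr$terminal
    expect_lt(term[4], 1e-3)             # immoral strategy extinct
    expect_lt(term[1], 1e-3)             # reasonable strategy extinct
    xg_end <- edge_fixed_points(0.3, 0.2, 1, 2)[[3]]$location[2]
    expect_lt(term[2], xg_end + 1e-3)    # lands on the stable G-F segment
  }
  # (0.45, 0.42): R attracts a positive-measure set under mutation stress
  Ap3 <- transformed_matrix(mug_matrix(0.45, 0.42), 1, 2)$A_prime
  tr3 <- integrate_trajectory(Ap3, c(0.9, 0.04, 0.03, 0.03), t_end = 2000,
                              mutation = 1e-6)
  expect_gt(tr3$terminal[1], 0.99)
})
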