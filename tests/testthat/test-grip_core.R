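# Objective, resolvent, gradient, projection, oracles.

test_that("compute_M: identity at u = 0, Woodbury equals direct inversion,
           and the large-rho limit", {
  set.seed(1)
  m <- 6
  n <- 4
  X <- matrix(rnorm(m * n), m, n)
  expect_equal(compute_M(rep(0, n), X, rho = 1), diag(m))

  for (i in 1:25) {
    u <- runif(n)                      # fractional selectors included
    if (i %% 2 == 0) u <- round(u)
    rho <- 10^runif(1, -1, 1)
    Md <- compute_M(u, X, rho, method = "direct")
    Mw <- compute_M(u, X, rho, method = "woodbury")
    expect_lt(max(abs(Md - Mw)), 1e-10)
  }

  u <- runif(n)
  rho <- 1e8
  M <- compute_M(u, X, rho)
  bound <- max(abs(tcrossprod(sweep(X, 2, u, `*`), X))) / rho
  expect_lt(max(abs(M - diag(m))), bound * 1.01 + 1e-12)

  expect_error(compute_M(c(1, NA, 0, 0), X, 1), "non-finite")
})

test_that("objective_G reproduces the hand-computed toy value and the
           no-selection baseline", {
  X <- diag(2)
  y <- c(1, 1)
  S <- matrix(c(0, 2, 2, 0), 2)
  p <- regulation_problem(y, X, S = S, rho = 1, lam = 1, k = 2)
  # u = (1,1): y^T (XX^T + I)^{-1} y + 1 * u^T S u = 1 + 4
  expect_equal(objective_G(c(1, 1), p), 5, tolerance = 1e-12)
  expect_equal(objective_G(c(0, 0), p), sum(y^2), tolerance = 1e-12)
  expect_error(objective_G(c(1, 0, 0), p), "expected")
})

test_that("Boolean objective at lambda = 0 equals the closed-form ridge on
           the support", {
  set.seed(2)
  for (i in 1:40) {
    m <- sample(5:20, 1)
    n <- sample(2:8, 1)
    X <- matrix(rnorm(m * n), m, n)
    y <- rnorm(m)
    rho <- 10^runif(1, -1, 1)
    p <- regulation_problem(y, X, S = matrix(0, n, n), rho = rho, lam = 0,
                            k = n)
    u <- rbinom(n, 1, 0.5)
    expect_equal(objective_G(u, p), ridge_oracle(which(u == 1), X, y, rho),
                 tolerance = 1e-8)
  }
  # orthonormal columns: value = ||y||^2 - sum (x_i' y)^2 / (1 + rho)
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))
  y <- rnorm(30)
  rho <- 0.7
  val <- ridge_oracle(c(1, 3), Q, y, rho)
  ref <- sum(y^2) - sum((crossprod(Q, y)[c(1, 3)])^2) / (1 + rho)
  expect_equal(val, ref, tolerance = 1e-10)
  expect_equal(ridge_oracle(integer(0), Q, y, rho), sum(y^2))
})

test_that("gradient_G matches central finite differences and its closed
           special cases", {
  set.seed(4)
  m <- 8
  n <- 5
  X <- matrix(rnorm(m * n), m, n)
  y <- rnorm(m)
  S <- abs(matrix(rnorm(n * n), n))
  S <- (S + t(S)) / 2
  diag(S) <- 0
  p <- regulation_problem(y, X, S = S, rho = 1.3, lam = 0.2, k = 3)
  for (i in 1:10) {
    u <- runif(n, 0.05, 0.95)
    g <- gradient_G(u, p)
    fd <- fd_gradient(u, p)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-6)), 1e-5)
  }
  # u = 0, lambda = 0: gradient is -(1/rho)(X'y)^2 elementwise
  p0 <- regulation_problem(y, X, S = S, rho = 2, lam = 0, k = 3)
  expect_equal(gradient_G(rep(0, n), p0),
               -drop(crossprod(X, y))^2 / 2, tolerance = 1e-12)
  # X = 0: gradient reduces to the proximity term
  pz <- regulation_problem(y, matrix(0, m, n), S = S, rho = 1, lam = 0.5,
                           k = 3)
  u <- runif(n)
  expect_equal(gradient_G(u, pz), drop(S %*% u), tolerance = 1e-12)
})

test_that("capped-simplex projection solves its KKT system", {
  expect_equal(project_capped_simplex(c(0.2, 0.3), 1), c(0.2, 0.3))
  expect_equal(project_capped_simplex(c(2, 2), 1), c(0.5, 0.5))
  expect_equal(project_capped_simplex(c(10, 0.2, -3), 1), c(1, 0, 0))
  expect_error(project_capped_simplex(c(1, 2), 0), "k must be")

  # exhaustive KKT enumeration oracle on small vectors
  set.seed(5)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    v <- rnorm(n, sd = 2)
    k <- runif(1, 0.5, n)
    u <- project_capped_simplex(v, k)
    ref <- proj_kkt_enum(v, k)
    expect_equal(u, ref, tolerance = 1e-8)
  }

  # bisection oracle on large vectors + feasibility + idempotence
  set.seed(6)
  for (i in 1:30) {
    n <- sample(c(50, 200, 1000), 1)
    v <- rnorm(n, sd = 3)
    k <- sample(1:20, 1)
    u <- project_capped_simplex(v, k)
    expect_true(all(u >= 0) && all(u <= 1))
    expect_lte(sum(u), k + 1e-8)
    expect_lt(max(abs(u - proj_bisect(v, k))), 1e-6)
    expect_equal(project_capped_simplex(u, k), u, tolerance = 1e-12)
  }
})

test_that("brute-force oracle enumerates correctly and a dominant proximity
           penalty forces near-singleton supports", {
  set.seed(7)
  # n = 1: only two candidate supports
  X <- matrix(rnorm(10), 10, 1)
  y <- drop(X) + rnorm(10, sd = 0.1)
  p1 <- regulation_problem(y, X, S = matrix(0, 1, 1), rho = 1, lam = 0, k = 1)
  bf <- brute_force_oracle(p1)
  expect_equal(bf$support, 1L)
  expect_equal(bf$objective,
               min(objective_G(0, p1), objective_G(1, p1)))

  # huge off-diagonal S and large lambda: any pair is too expensive
  n <- 6
  X <- matrix(rnorm(30 * n), 30, n)
  y <- rnorm(30)
  S <- matrix(1e4, n, n)
  diag(S) <- 0
  pb <- regulation_problem(y, X, S = S, rho = 1, lam = 10, k = 3)
  bfb <- brute_force_oracle(pb)
  expect_lte(length(bfb$support), 1)

  expect_error(brute_force_oracle(random_problem(10, 19, 1, k = 10),
                                  max_evals = 100), "budget")
})

test_that("randomized rounding: Boolean passthrough, unbiased draws, and
           budget repair", {
  prob <- random_problem(20, 5, seed = 8, k = 2)
  ub <- c(1, 0, 1, 0, 0)
  r <- randomized_rounding(ub, prob, n_samples = 5, seed = 1)
  expect_equal(r$u_tilde, as.integer(ub))

  u_half <- c(0.5, 0.5, 0, 0, 0)
  r2 <- randomized_rounding(u_half, prob, n_samples = 10000, seed = 2)
  se <- sqrt(0.25 / 10000)
  expect_true(all(abs(r2$draw_mean[1:2] - 0.5) <= 3 * se))
  expect_true(all(r2$draw_mean[3:5] == 0))

  prob3 <- random_problem(20, 3, seed = 9, k = 1)
  r3 <- randomized_rounding(c(0.9, 0.05, 0.05), prob3, n_samples = 200,
                            seed = 3)
  expect_lte(length(r3$support), 1)
  expect_lte(r3$objective, objective_G(c(0, 0, 0), prob3) + 1e-12)
  expect_error(randomized_rounding(c(0.5, 0.5, 0.5), prob3, n_samples = 0),
               "n_samples")
})

test_that("problem construction validates dimensions and S structure", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  S_ok <- matrix(c(0, 1, 1, 0), 2)
  expect_s3_class(regulation_problem(y, X, S = S_ok, rho = 1, lam = 0, k = 1),
                  "regulation_problem")
  expect_error(regulation_problem(y, X, S = matrix(1, 2, 2), rho = 1,
                                  lam = 0, k = 1), "diagonal")
  expect_error(regulation_problem(y, X, S = S_ok, rho = 0, lam = 0, k = 1),
               "rho")
  expect_error(regulation_problem(y, X, S = S_ok, rho = 1, lam = 0, k = 3),
               "k must be")
  expect_error(regulation_problem(y[1:5], X, S = S_ok, rho = 1, lam = 0,
                                  k = 1), "length")
  # the minimum-eigenvalue diagnostic and the optional convexifying shift
  expect_lt(s_min_eigenvalue(S_ok), 0)
  ps <- regulation_problem(y, X, S = S_ok, rho = 1, lam = 0, k = 1,
                           s_shift = 2)
  expect_equal(diag(ps$S), c(2, 2))
})
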