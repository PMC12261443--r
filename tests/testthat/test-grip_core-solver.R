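# Relaxation solver, exactness certificate, cross-validation, and the
# end-to-end single-TG inference path.

# Orthonormal design with well-separated coefficient tiers. Separation
# matters: the relaxed fit term is separable with marginal value
# c_i^2 rho/(rho+u_i)^2, so the relaxation is Boolean only when the selected
# and unselected squared correlations differ by more than (1+1/rho)^2 --
# near-tied tiers water-fill into fractional solutions.
orthonormal_problem <- function(m, n, seed, k, lam = 0, S = NULL,
                                rho = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(m * n), m, n)))
  beta <- c(seq(3, 2.2, length.out = k), seq(0.3, 0.1, length.out = n - k))
  y <- drop(Q %*% beta) + rnorm(m, sd = 0.02)
  if (is.null(S)) S <- matrix(0, n, n)
  regulation_problem(y, Q, S = S, rho = rho, lam = lam, k = k)
}

test_that("solver concentrates mass on the strongest orthonormal columns
           and matches the enumeration optimum", {
  p <- orthonormal_problem(40, 5, seed = 10, k = 2)
  sol <- solve_relaxation(p)
  expect_true(sol$converged)
  corr <- drop(crossprod(p$X, p$y))^2
  top2 <- order(corr, decreasing = TRUE)[1:2]
  expect_equal(sort(order(sol$u_hat, decreasing = TRUE)[1:2]), sort(top2))
  rr <- randomized_rounding(sol$u_hat, p, 50, seed = 1)
  bf <- brute_force_oracle(p)
  expect_equal(sort(rr$support), sort(bf$support))
  expect_equal(rr$objective, bf$objective, tolerance = 1e-10)
})

test_that("with k = n and a beneficial design the all-ones selector is
           optimal", {
  p <- orthonormal_problem(30, 4, seed = 11, k = 4)
  sol <- solve_relaxation(p)
  expect_true(sol$converged)
  expect_equal(sol$u_hat, rep(1, 4), tolerance = 1e-4)
  # enumeration over all Boolean vectors confirms global optimality
  for (bits in 0:15) {
    u <- as.integer(intToBits(bits)[1:4])
    expect_lte(sol$objective, objective_G(u, p) + 1e-8)
  }
})

test_that("solver is deterministic and monotonically decreasing", {
  p <- random_problem(40, 10, seed = 12, lam = 0.2, k = 3)
  s1 <- solve_relaxation(p)
  s2 <- solve_relaxation(p)
  expect_identical(s1$u_hat, s2$u_hat)
  expect_identical(s1$objective_trace, s2$objective_trace)
  expect_true(all(diff(s1$objective_trace) <= 0))
  expect_true(all(s1$u_hat >= 0 & s1$u_hat <= 1))
  expect_lte(sum(s1$u_hat), p$k + 1e-8)
})

test_that("solver honours init choices and validates configuration", {
  p <- random_problem(30, 8, seed = 13, lam = 0.1, k = 3)
  sz <- solve_relaxation(p, solver_config(init = "zeros"))
  expect_true(sz$converged)
  sw <- solve_relaxation(p, solver_config(init = "warm",
                                          warm_start = rep(0.5, 8)))
  expect_true(sw$converged)
  expect_error(solve_relaxation(p, solver_config(init = "warm")),
               "warm_start")
  expect_error(solver_config(grad_tol = 0), "grad_tol")
  expect_error(solver_config(max_iter = 0), "max_iter")
})

test_that("certificate separates scores for an exactly-Boolean optimum and
           orders orthonormal scores by squared correlation", {
  p <- orthonormal_problem(40, 5, seed = 14, k = 2)
  sol <- solve_relaxation(p)
  tight <- check_tightness(sol, p)
  corr <- drop(crossprod(p$X, p$y))^2
  expect_true(tight$xi_exists)
  expect_equal(sort(tight$support),
               sort(order(corr, decreasing = TRUE)[1:2]))
  # at lambda = 0 the scores are the squared correlations at M(u_hat)
  expect_equal(order(tight$scores), order(corr))
  # certified exactness backed by enumeration
  bf <- brute_force_oracle(p)
  rr <- randomized_rounding(sol$u_hat, p, 50, seed = 2)
  expect_equal(rr$objective, bf$objective, tolerance = 1e-10)
})

test_that("two exactly tied scores straddling the budget yield a fractional
           uncertified solution", {
  set.seed(15)
  m <- 30
  x <- rnorm(m)
  z <- rnorm(m) * 0.1
  X <- cbind(x, x, z)       # duplicated column forces the tie
  y <- x + rnorm(m, sd = 0.05)
  p <- regulation_problem(y, X, S = matrix(0, 3, 3), rho = 1, lam = 0, k = 1)
  sol <- solve_relaxation(p)
  tight <- check_tightness(sol, p)
  expect_equal(sol$u_hat[1], sol$u_hat[2], tolerance = 1e-6)
  expect_equal(sol$u_hat[1], 0.5, tolerance = 1e-3)
  expect_false(tight$xi_exists)
})

test_that("cross-validation is deterministic, reduces to the pure sparse
           model at lambda = 0, and nails a noiseless planted instance", {
  inst <- generate_instance(synthetic_spec(n_tfs = 10, m_cells = 60,
                                           noise_sd = 0, seed = 16))
  p <- inst$problem
  cfg <- solver_config(seed = 5)
  cv1 <- cross_validate(p$X, p$y, p$S, rho_grid = c(0.1, 1),
                        lambda_grid = c(0, 0.1), k_grid = c(3, 5),
                        n_folds = 5, seed = 5, config = cfg)
  cv2 <- cross_validate(p$X, p$y, p$S, rho_grid = c(0.1, 1),
                        lambda_grid = c(0, 0.1), k_grid = c(3, 5),
                        n_folds = 5, seed = 5, config = cfg)
  expect_identical(cv1$best, cv2$best)
  expect_identical(cv1$scores$score, cv2$scores$score)
  expect_gte(cv1$best$k, 3)
  best_score <- cv1$scores$score[cv1$scores$rho == cv1$best$rho &
                                 cv1$scores$lam == cv1$best$lam &
                                 cv1$scores$k == cv1$best$k]
  expect_lt(best_score, 0.05)  # noiseless: held-out MSE collapses

  # lambda = 0 with an arbitrary S equals the model with no proximity term
  f_zero <- infer_regulators(p$X, p$y, p$tf_ids, S = p$S, rho = 1, lam = 0,
                             k = 3, config = cfg)
  f_null <- infer_regulators(p$X, p$y, p$tf_ids,
                             S = matrix(0, p$n, p$n), rho = 1, lam = 0,
                             k = 3, config = cfg)
  expect_equal(f_zero$relaxed$u_hat, f_null$relaxed$u_hat, tolerance = 1e-10)
  expect_identical(f_zero$boolean$support, f_null$boolean$support)

  expect_error(cross_validate(p$X, p$y, p$S, n_folds = 1), "n_folds")
  expect_error(cross_validate(p$X[1:4, ], p$y[1:4], p$S, n_folds = 4),
               "fold with")
})

test_that("infer_regulators recovers a planted noiseless support and ranks
           all TFs when k = n", {
  inst <- generate_instance(synthetic_spec(n_tfs = 10, m_cells = 80,
                                           noise_sd = 0, seed = 17),
                            lam = 0.05)
  p <- inst$problem
  fit <- infer_regulators(p$X, p$y, p$tf_ids, S = p$S, rho = 1, lam = 0.05,
                          k = 3, config = solver_config(seed = 1))
  expect_setequal(fit$ranked_tfs$tf[fit$ranked_tfs$selected == 1],
                  inst$true_tfs)
  bf <- brute_force_oracle(p)
  expect_setequal(fit$boolean$support, bf$support)

  fit_all <- infer_regulators(p$X, p$y, p$tf_ids, S = p$S, rho = 1, lam = 0,
                              k = p$n, config = solver_config(seed = 1))
  expect_equal(nrow(fit_all$ranked_tfs), p$n)
  expect_equal(fit_all$ranked_tfs$u_hat, sort(fit_all$relaxed$u_hat,
                                              decreasing = TRUE))
})

test_that("a proximity-weighted fit excludes network-distant decoys that
           the pure sparse model admits", {
  spec <- synthetic_spec(n_tfs = 30, m_cells = 200, seed = 12,
                         decoy = list(enabled = TRUE))
  inst <- generate_instance(spec)
  p <- inst$problem
  cfg <- solver_config(seed = 12)
  f0 <- infer_regulators(p$X, p$y, p$tf_ids, S = p$S, rho = 1, lam = 0,
                         k = 3, config = cfg)
  f1 <- infer_regulators(p$X, p$y, p$tf_ids, S = p$S, rho = 1, lam = 1,
                         k = 3, config = cfg)
  sel0 <- f0$ranked_tfs$tf[f0$ranked_tfs$selected == 1]
  sel1 <- f1$ranked_tfs$tf[f1$ranked_tfs$selected == 1]
  expect_gt(length(intersect(sel0, inst$decoy_tfs)), 0)
  expect_equal(length(intersect(sel1, inst$decoy_tfs)), 0)
  expect_gt(recovery_f1(sel1, inst$true_tfs),
            recovery_f1(sel0, inst$true_tfs))
})
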