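#' Construct a single-target regulator-selection problem
#'
#' Bundles everything needed to select at most \code{k} transcription factors
#' (TFs) for one target gene (TG): the centered TG expression \code{y}, the
#' standardized candidate-TF expression matrix \code{X}, a symmetric
#' network-distance matrix \code{S} between the candidates (typically a
#' diffusion state distance submatrix, see \code{\link{distance_submatrix}}),
#' the ridge weight \code{rho}, the proximity weight \code{lam}, and the
#' sparsity budget \code{k}.
#'
#' The model minimized over Boolean selectors \code{u} is
#' \deqn{G(u) = y^T (\tfrac{1}{\rho} X D(u) X^T + I)^{-1} y + \lambda u^T S u,
#'       \quad \sum_i u_i \le k,}
#' the first term being the partially minimized L0-constrained ridge fit and
#' the second the pooled pairwise network distance of the selected TFs.
#'
#' No preprocessing is applied here: callers are expected to center \code{y}
#' and standardize the columns of \code{X} (\code{\link{assemble_problem}}
#' does both).
#'
#' @param y numeric response vector (length m, one entry per cell).
#' @param X numeric m x n matrix of candidate-TF expression, one column per TF.
#' @param tf_ids character vector of n TF symbols (defaults to column names).
#' @param S symmetric n x n non-negative distance matrix with zero diagonal.
#' @param rho ridge weight, > 0.
#' @param lam proximity weight, >= 0.
#' @param k sparsity budget, integer in [1, n].
#' @param s_shift optional non-negative ridge added to the off-diagonal term as
#'   \code{S + s_shift * I}; default 0 (distances are used as-is). A strictly
#'   positive shift can be used to convexify \code{u^T S u} when the minimum
#'   eigenvalue of \code{S} (see \code{\link{s_min_eigenvalue}}) is negative.
#' @return an object of class \code{"regulation_problem"}.
#' @seealso \code{\link{solve_relaxation}}, \code{\link{infer_regulators}}
#' @export
regulation_problem <- function(y, X, tf_ids = colnames(X), S, rho, lam, k,
                               s_shift = 0) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  S <- as.matrix(S)
  m <- length(y)
  n <- ncol(X)
  if (nrow(X) != m) stopf("nrow(X) = %d but length(y) = %d", nrow(X), m)
  if (is.null(tf_ids)) tf_ids <- paste0("TF", seq_len(n))
  tf_ids <- as.character(tf_ids)
  if (length(tf_ids) != n) stopf("tf_ids has length %d, expected %d",
                                 length(tf_ids), n)
  if (!all(dim(S) == c(n, n))) stopf("S must be %d x %d", n, n)
  if (!all(is.finite(y)) || !all(is.finite(X)) || !all(is.finite(S)))
    stopf("non-finite values in problem inputs")
  if (max(abs(S - t(S))) > 1e-8) stopf("S must be symmetric")
  if (any(diag(S) != 0)) stopf("S must have a zero diagonal")
  if (any(S < 0)) stopf("S must be non-negative")
  if (!is_scalar_number(rho) || rho <= 0) stopf("rho must be a positive number")
  if (!is_scalar_number(lam) || lam < 0) stopf("lam must be >= 0")
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n)
    stopf("k must be an integer in [1, %d]", n)
  if (!is_scalar_number(s_shift) || s_shift < 0)
    stopf("s_shift must be >= 0")
  S <- (S + t(S)) / 2
  if (s_shift > 0) S <- S + diag(s_shift, n)
  structure(list(y = y, X = X, tf_ids = tf_ids, S = S,
                 rho = rho, lam = lam, k = k, m = m, n = n),
            class = "regulation_problem")
}

#' @export
print.regulation_problem <- function(x, ...) {
  cat(sprintf(
    "regulation_problem: m = %d cells, n = %d candidate TFs, k = %d, rho = %g, lambda = %g\n",
    x$m, x$n, x$k, x$rho, x$lam))
  invisible(x)
}

#' Minimum eigenvalue of the distance matrix
#'
#' Distance matrices are not positive semidefinite in general, so the
#' proximity term \code{u^T S u} need not be convex. This diagnostic reports
#' the smallest eigenvalue of \code{S} so users can judge how far from
#' convexity a given instance is (and, if desired, pass a compensating
#' \code{s_shift} to \code{\link{regulation_problem}}).
#'
#' @param S symmetric matrix (or a \code{regulation_problem}).
#' @return smallest eigenvalue, a single number.
#' @export
s_min_eigenvalue <- function(S) {
  if (inherits(S, "regulation_problem")) S <- S$S
  min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# M y and related quantities without forming M when n < m.
# M = (X D(u) X^T / rho + I)^{-1}; the Woodbury route factors through
# Xs = X diag(sqrt(u)) and the n x n capacitance matrix
# C = I + Xs^T Xs / rho, valid for any u >= 0 including fractional u.
M_times_y <- function(u, X, rho, y, method = c("auto", "direct", "woodbury")) {
  method <- match.arg(method)
  m <- nrow(X)
  n <- ncol(X)
  if (method == "auto") method <- if (n < m) "woodbury" else "direct"
  if (method == "direct") {
    A <- tcrossprod(sweep(X, 2, u, `*`), X) / rho + diag(m)
    return(drop(solve(A, y)))
  }
  su <- sqrt(pmax(u, 0))
  Xs <- sweep(X, 2, su, `*`)
  C <- diag(n) + crossprod(Xs) / rho
  drop(y - Xs %*% solve(C, crossprod(Xs, y)) / rho)
}

#' Resolvent matrix of the selected design
#'
#' Computes \eqn{M = (\tfrac{1}{\rho} X D(u) X^T + I)^{-1}}, the m x m matrix
#' through which the partially minimized ridge objective is evaluated. Two
#' algebraically identical execution paths are provided: a direct m x m
#' inversion, and a Woodbury low-rank path
#' \deqn{M = I - \tfrac{1}{\rho} X D(u)^{1/2}
#'   (I + \tfrac{1}{\rho} D(u)^{1/2} X^T X D(u)^{1/2})^{-1} D(u)^{1/2} X^T}
#' that only inverts an n x n matrix and is preferred when the number of
#' candidates n is smaller than the number of cells m. The square-root form
#' keeps the identity valid for fractional selectors \code{u} in [0,1].
#'
#' @param u selector vector in \code{[0,1]^n}.
#' @param X m x n design matrix.
#' @param rho ridge weight, > 0.
#' @param method \code{"auto"} (default; Woodbury when n < m), \code{"direct"},
#'   or \code{"woodbury"}.
#' @return the m x m matrix M.
#' @export
compute_M <- function(u, X, rho, method = c("auto", "direct", "woodbury")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  u <- as.numeric(u)
  if (length(u) != ncol(X)) stopf("length(u) = %d, expected %d", length(u), ncol(X))
  if (!all(is.finite(u)) || !all(is.finite(X)) || !is_scalar_number(rho) || rho <= 0)
    stopf("non-finite inputs to compute_M")
  m <- nrow(X)
  n <- ncol(X)
  if (method == "auto") method <- if (n < m) "woodbury" else "direct"
  if (method == "direct") {
    A <- tcrossprod(sweep(X, 2, u, `*`), X) / rho + diag(m)
    return(solve(A))
  }
  su <- sqrt(pmax(u, 0))
  Xs <- sweep(X, 2, su, `*`)
  C <- diag(n) + crossprod(Xs) / rho
  diag(m) - Xs %*% solve(C, t(Xs)) / rho
}

#' Relaxed selection objective G(u)
#'
#' Evaluates \eqn{G(u) = y^T M(u) y + \lambda u^T S u} for a selector vector
#' \code{u} in \code{[0,1]^n}. At Boolean \code{u} with \code{lam = 0} this
#' equals the L0-constrained ridge value on the support of \code{u}
#' (see \code{\link{ridge_oracle}}).
#'
#' @param u selector vector in \code{[0,1]^n}.
#' @param problem a \code{\link{regulation_problem}}.
#' @return the objective value, a single number.
#' @export
objective_G <- function(u, problem) {
  u <- as.numeric(u)
  if (length(u) != problem$n)
    stopf("length(u) = %d, expected %d", length(u), problem$n)
  My <- M_times_y(u, problem$X, problem$rho, problem$y)
  fit <- sum(problem$y * My)
  prox <- if (problem$lam > 0) problem$lam * drop(u %*% problem$S %*% u) else 0
  fit + prox
}

#' Closed-form ridge value on a fixed support
#'
#' Returns \eqn{\min_\beta \|y - X_A \beta\|_2^2 + \rho \|\beta\|_2^2} for the
#' column subset \code{A = support}, via the normal equations. By the matrix
#' inversion lemma this equals \eqn{y^T M y} evaluated at the Boolean
#' indicator of the support, which is what makes the Boolean reformulation of
#' the sparse ridge model exact; the identity is exercised in the test suite.
#'
#' @param support integer indices of the selected columns (may be empty).
#' @param X m x n design matrix.
#' @param y response vector.
#' @param rho ridge weight, > 0.
#' @return the penalized residual value, a single number.
#' @export
ridge_oracle <- function(support, X, y, rho) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  support <- as.integer(support)
  if (length(support) > 0 &&
      (min(support) < 1L || max(support) > ncol(X)))
    stopf("support indices out of range")
  if (length(support) == 0L) return(sum(y^2))
  Xa <- X[, support, drop = FALSE]
  beta <- solve(crossprod(Xa) + diag(rho, length(support)), crossprod(Xa, y))
  r <- y - Xa %*% beta
  sum(r^2) + rho * sum(beta^2)
}

#' Gradient of the relaxed objective
#'
#' \deqn{\nabla G(u) = -\tfrac{1}{\rho} (X^T M y) \odot (X^T M y)
#'   + 2 \lambda S u}
#' with \eqn{M} evaluated at the given \code{u} and \eqn{\odot} the
#' elementwise product.
#'
#' @inheritParams objective_G
#' @return numeric gradient vector of length n.
#' @export
gradient_G <- function(u, problem) {
  u <- as.numeric(u)
  if (length(u) != problem$n)
    stopf("length(u) = %d, expected %d", length(u), problem$n)
  My <- M_times_y(u, problem$X, problem$rho, problem$y)
  c_vec <- drop(crossprod(problem$X, My))
  g <- -(c_vec * c_vec) / problem$rho
  if (problem$lam > 0) g <- g + 2 * problem$lam * drop(problem$S %*% u)
  g
}

#' Euclidean projection onto the capped simplex
#'
#' Projects \code{v} onto \eqn{\{u : \sum_i u_i \le k,\ 0 \le u_i \le 1\}},
#' the feasible set of the relaxed selector. If the box clip of \code{v}
#' already satisfies the budget it is returned unchanged; otherwise the
#' unique projection is \eqn{u_i = \mathrm{clip}(v_i - \theta, 0, 1)} with the
#' threshold \eqn{\theta > 0} located exactly by sorting the 2n breakpoints
#' of the piecewise-linear budget function (O(n log n)).
#'
#' @param v numeric vector.
#' @param k positive budget (need not be integer).
#' @return the projected vector, same length as \code{v}.
#' @export
project_capped_simplex <- function(v, k) {
  if (!is_scalar_number(k) || k <= 0) stopf("k must be > 0")
  v <- as.numeric(v)
  w <- pmin(pmax(v, 0), 1)
  s <- sum(w)
  if (s <= k) return(w)
  # sum(clip(v - theta, 0, 1)) is continuous, piecewise linear and
  # non-increasing in theta with kinks at v_i - 1 and v_i.
  bp <- sort(unique(c(v, v - 1)))
  budget_at <- function(th) sum(pmin(pmax(v - th, 0), 1))
  lo <- 1L
  hi <- length(bp)
  # invariant: budget_at(bp[lo]) >= k >= budget_at(bp[hi])
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (budget_at(bp[mid]) >= k) lo <- mid else hi <- mid
  }
  th_lo <- bp[lo]
  # on (bp[lo], bp[hi]) the active set is fixed; solve the linear equation
  ones <- sum(v - th_lo > 1 + 1e-15)
  act <- which(v - th_lo > 1e-15 & v - th_lo <= 1 + 1e-15)
  # recompute actives against the open interval midpoint for robustness
  mid_th <- (th_lo + bp[hi]) / 2
  ones <- sum(v - mid_th >= 1)
  act <- which(v - mid_th > 0 & v - mid_th < 1)
  if (length(act) == 0L) {
    theta <- th_lo
  } else {
    theta <- (sum(v[act]) + ones - k) / length(act)
    theta <- min(max(theta, th_lo), bp[hi])
  }
  pmin(pmax(v - theta, 0), 1)
}

#' Solver settings for the projected quasi-Newton method
#'
#' @param init \code{"uniform"} (the feasible interior point (k/n) 1, default),
#'   \code{"zeros"}, or \code{"warm"} with \code{warm_start} supplied.
#' @param warm_start optional starting vector used when \code{init = "warm"}.
#' @param max_iter maximum outer iterations.
#' @param grad_tol stopping tolerance on the infinity norm of the projected
#'   gradient step \code{u - P(u - grad)}.
#' @param lbfgs_memory number of curvature pairs retained.
#' @param newton_limit largest candidate count n for which the exact-curvature
#'   active-set direction is attempted (the Hessian of the fit term has the
#'   closed form \eqn{(2/\rho^2)(cc^T) \odot (X^T M X)} with
#'   \eqn{c = X^T M y}, an O(n^2 m + n^3) computation); beyond it the solver
#'   uses only limited-memory directions.
#' @param n_rounding_samples Bernoulli draws used by
#'   \code{\link{randomized_rounding}}.
#' @param seed integer seed for all downstream randomness.
#' @return a \code{"solver_config"} list.
#' @export
solver_config <- function(init = c("uniform", "zeros", "warm"),
                          warm_start = NULL,
                          max_iter = 500L, grad_tol = 1e-6,
                          lbfgs_memory = 10L, newton_limit = 500L,
                          n_rounding_samples = 100L,
                          seed = 1L) {
  init <- match.arg(init)
  if (max_iter < 1L) stopf("max_iter must be >= 1")
  if (!is_scalar_number(grad_tol) || grad_tol <= 0) stopf("grad_tol must be > 0")
  if (n_rounding_samples < 1L) stopf("n_rounding_samples must be >= 1")
  structure(list(init = init, warm_start = warm_start,
                 max_iter = as.integer(max_iter), grad_tol = grad_tol,
                 lbfgs_memory = as.integer(lbfgs_memory),
                 newton_limit = as.integer(newton_limit),
                 n_rounding_samples = as.integer(n_rounding_samples),
                 seed = as.integer(seed)),
            class = "solver_config")
}

# Precomputed Gram quantities: with C(u) = I + (1/rho) D^{1/2} X^T X D^{1/2}
# every solver quantity is expressible in n-space:
#   y^T M y = y^T y - (1/rho) b^T C^{-1} b,          b = D^{1/2} X^T y
#   X^T M y = X^T y - (1/rho) (X^T X D^{1/2}) C^{-1} b
#   X^T M X = X^T X - (1/rho) (X^T X D^{1/2}) C^{-1} (D^{1/2} X^T X)
# so iterations cost O(n^3) regardless of the number of cells m.
solver_cache <- function(problem) {
  list(XtX = crossprod(problem$X),
       Xty = drop(crossprod(problem$X, problem$y)),
       yty = sum(problem$y^2))
}

cached_objective <- function(u, cache, problem) {
  su <- sqrt(pmax(u, 0))
  n <- problem$n
  Cm <- diag(n) + (su %o% su) * cache$XtX / problem$rho
  b <- su * cache$Xty
  fit <- cache$yty - sum(b * solve(Cm, b)) / problem$rho
  if (problem$lam > 0) fit <- fit + problem$lam * drop(u %*% problem$S %*% u)
  fit
}

cached_gradient <- function(u, cache, problem) {
  su <- sqrt(pmax(u, 0))
  n <- problem$n
  rho <- problem$rho
  Cm <- diag(n) + (su %o% su) * cache$XtX / rho
  a <- solve(Cm, su * cache$Xty)
  c_vec <- cache$Xty - drop(cache$XtX %*% (su * a)) / rho
  g <- -(c_vec * c_vec) / rho
  if (problem$lam > 0) g <- g + 2 * problem$lam * drop(problem$S %*% u)
  g
}

# Exact-curvature direction restricted to the estimated free set
# (two-metric projection): coordinates pressed against their bound by the
# gradient move along -g; the free block takes a Newton step, with the
# budget constraint, when active, eliminated through its multiplier.
newton_direction <- function(u, g, pgnorm, problem, cache) {
  n <- problem$n
  rho <- problem$rho
  su <- sqrt(pmax(u, 0))
  Cm <- diag(n) + (su %o% su) * cache$XtX / rho
  Cinv_b <- solve(Cm, su * cache$Xty)
  cv <- cache$Xty - drop(cache$XtX %*% (su * Cinv_b)) / rho
  B <- cache$XtX -
    sweep(cache$XtX, 2, su, `*`) %*% solve(Cm, su * cache$XtX) / rho
  H <- (2 / rho^2) * (cv %o% cv) * B
  if (problem$lam > 0) H <- H + 2 * problem$lam * problem$S
  eps <- min(1e-3, pgnorm)
  at_low <- u <= eps & g > 0
  at_high <- u >= 1 - eps & g < 0
  free <- which(!(at_low | at_high))
  if (length(free) == 0L) return(NULL)
  d <- -g
  HFF <- H[free, free, drop = FALSE]
  ev <- eigen(HFF, symmetric = TRUE, only.values = TRUE)$values
  # positive-definite modification; the relative term guards against
  # numerically singular blocks from strongly collinear candidates
  HFF <- HFF + diag(max(0, -min(ev)) + 1e-7 * max(abs(ev), 1) + 1e-10,
                    length(free))
  ok <- TRUE
  if (sum(u) < problem$k - 1e-9) {
    d[free] <- tryCatch(-solve(HFF, g[free]),
                        error = function(e) {
                          ok <<- FALSE
                          NULL
                        })
  } else {
    hi <- tryCatch(solve(HFF, cbind(g[free], rep(1, length(free)))),
                   error = function(e) {
                     ok <<- FALSE
                     NULL
                   })
    if (ok) {
      mu <- sum(hi[, 1L]) / sum(hi[, 2L])
      d[free] <- -(hi[, 1L] - mu * hi[, 2L])
    }
  }
  if (!ok) return(NULL)
  # the selector lives in [0,1]^n, so any direction component beyond a few
  # box widths is ill-conditioning noise; capping keeps the unit step of
  # the line search meaningful on degenerate flats
  dmax <- max(abs(d))
  if (dmax > 4) d <- d * (4 / dmax)
  d
}

# L-BFGS two-loop recursion; S_mem/Y_mem are lists of recent (s, y) pairs.
lbfgs_direction <- function(g, S_mem, Y_mem) {
  q <- g
  nmem <- length(S_mem)
  if (nmem == 0L) return(-g)
  alpha <- numeric(nmem)
  rho_m <- numeric(nmem)
  for (i in nmem:1) {
    rho_m[i] <- 1 / sum(Y_mem[[i]] * S_mem[[i]])
    alpha[i] <- rho_m[i] * sum(S_mem[[i]] * q)
    q <- q - alpha[i] * Y_mem[[i]]
  }
  gamma <- sum(S_mem[[nmem]] * Y_mem[[nmem]]) / sum(Y_mem[[nmem]]^2)
  r <- gamma * q
  for (i in 1:nmem) {
    beta <- rho_m[i] * sum(Y_mem[[i]] * r)
    r <- r + (alpha[i] - beta) * S_mem[[i]]
  }
  -r
}

#' Solve the capped-simplex relaxation by projected quasi-Newton
#'
#' Minimizes \code{G(u)} over the capped simplex. Each iteration tries, in
#' order, (i) an exact-curvature active-set (two-metric) Newton direction --
#' affordable because the fit term's Hessian has a closed form and the
#' candidate count n is small in this problem class -- (ii) a limited-memory
#' L-BFGS direction, and (iii) a Barzilai-Borwein-scaled projected gradient
#' step; the first direction passing an Armijo sufficient-decrease test along
#' the projected arc (\code{\link{project_capped_simplex}}) is accepted.
#' Accepted iterates are strictly non-increasing in objective. Convergence is
#' declared when the projected gradient step \code{u - P(u - grad)} drops
#' below \code{grad_tol} in the infinity norm, or when no further decrease is
#' numerically attainable and that norm is already below
#' \code{sqrt(grad_tol)}. The algorithm is fully deterministic.
#'
#' @param problem a \code{\link{regulation_problem}}.
#' @param config a \code{\link{solver_config}}.
#' @return an object of class \code{"relaxed_solution"}: fields \code{u_hat},
#'   \code{objective}, \code{n_iterations}, \code{converged},
#'   \code{projected_gradient_norm}, and \code{objective_trace}.
#' @export
solve_relaxation <- function(problem, config = solver_config()) {
  stopifnot(inherits(problem, "regulation_problem"))
  n <- problem$n
  k <- problem$k
  u <- switch(config$init,
    uniform = rep(k / n, n),
    zeros = rep(0, n),
    warm = {
      if (is.null(config$warm_start)) stopf("init = 'warm' needs warm_start")
      project_capped_simplex(as.numeric(config$warm_start), k)
    })
  cache <- solver_cache(problem)
  f <- cached_objective(u, cache, problem)
  if (!is.finite(f)) stopf("non-finite objective at the starting point")
  g <- cached_gradient(u, cache, problem)
  S_mem <- list()
  Y_mem <- list()
  alpha_bb <- 1 / max(max(abs(g)), 1e-12)
  trace <- f
  converged <- FALSE
  pgnorm <- Inf
  it <- 0L
  c1 <- 1e-4
  drop_window <- 15L
  for (it in seq_len(config$max_iter)) {
    pg <- u - project_capped_simplex(u - g, k)
    pgnorm <- max(abs(pg))
    if (pgnorm <= config$grad_tol) {
      converged <- TRUE
      it <- it - 1L
      break
    }
    # numerically stationary: the recent decrease is negligible against
    # both the objective scale and the total decrease so far, while the
    # projected gradient is already small -- typical of degenerate flat
    # faces (e.g. blocks of near-collinear candidates), where first-order
    # wandering redistributes selector mass without changing anything
    # downstream
    nt <- length(trace)
    if (nt > drop_window &&
        trace[nt - drop_window] - trace[nt] <=
          max(1e-10, 1e-12 * abs(f), 1e-5 * (trace[1L] - f)) &&
        pgnorm <= sqrt(config$grad_tol)) {
      converged <- TRUE
      it <- it - 1L
      break
    }
    moved <- FALSE
    for (dir_kind in c("newton", "lbfgs", "bb_gradient")) {
      if (dir_kind == "newton") {
        if (n > config$newton_limit) next
        d <- newton_direction(u, g, pgnorm, problem, cache)
        if (is.null(d)) next
        alpha <- 1
        n_bt <- 15L
      } else if (dir_kind == "lbfgs") {
        if (length(S_mem) == 0L) next
        d <- lbfgs_direction(g, S_mem, Y_mem)
        alpha <- 1
        n_bt <- 20L
      } else {
        d <- -g
        alpha <- alpha_bb
        n_bt <- 50L
      }
      for (ls in seq_len(n_bt)) {
        u_try <- project_capped_simplex(u + alpha * d, k)
        step <- u_try - u
        if (max(abs(step)) == 0) break
        f_try <- cached_objective(u_try, cache, problem)
        if (!is.finite(f_try)) stopf("non-finite objective during line search")
        gd <- sum(g * step)
        if (f_try <= f + c1 * min(gd, 0) && f_try <= f) {
          g_new <- cached_gradient(u_try, cache, problem)
          yv <- g_new - g
          sy <- sum(yv * step)
          if (sy > 1e-10) {
            S_mem <- c(S_mem, list(step))
            Y_mem <- c(Y_mem, list(yv))
            if (length(S_mem) > config$lbfgs_memory) {
              S_mem <- S_mem[-1]
              Y_mem <- Y_mem[-1]
            }
            alpha_bb <- min(max(sum(step * step) / sy, 1e-10), 1e10)
          } else {
            alpha_bb <- min(alpha * 2, 1e10)
          }
          u <- u_try
          f <- f_try
          g <- g_new
          moved <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (moved) break
    }
    trace <- c(trace, f)
    if (!moved) {
      # no numerically productive step in either direction: accept as
      # converged if the projected gradient is already small, otherwise
      # flag a likely gradient inconsistency
      if (pgnorm <= sqrt(config$grad_tol)) {
        converged <- TRUE
        break
      }
      stopf(paste("line search failed to decrease the objective",
                  "(projected gradient norm %.3g); gradient inconsistency?"),
            pgnorm)
    }
  }
  if (!converged) {
    pg <- u - project_capped_simplex(u - g, k)
    pgnorm <- max(abs(pg))
    if (pgnorm <= config$grad_tol) converged <- TRUE
  }
  structure(list(u_hat = pmin(pmax(u, 0), 1), objective = f,
                 n_iterations = it, converged = converged,
                 projected_gradient_norm = pgnorm,
                 objective_trace = trace),
            class = "relaxed_solution")
}

#' @export
print.relaxed_solution <- function(x, ...) {
  cat(sprintf(
    "relaxed_solution: G = %.6g after %d iterations (%s, |pg| = %.2e)\n",
    x$objective, x$n_iterations,
    if (x$converged) "converged" else "max_iter reached",
    x$projected_gradient_norm))
  invisible(x)
}

#' Score-separation certificate for relaxation exactness
#'
#' The Boolean relaxation is exact (its optimum is attained at a Boolean
#' vector, hence equals the combinatorial optimum) if and only if a threshold
#' \eqn{\xi} separates the selection scores
#' \deqn{v_i = (x_i^T M y)^2 + 2 \lambda \sum_j S_{ij} u_j}
#' of the supported coordinates from the rest. This function evaluates the
#' scores at the computed relaxed solution \code{u_hat} (with \code{M} at
#' \code{u_hat}), takes the support as \code{u_hat > support_tol}, and reports
#' whether the separating interval \code{(max_out, min_in]} is non-empty.
#' Trivial supports (empty or full) are certified by convention.
#'
#' @param u_star a \code{"relaxed_solution"} (or a bare numeric vector).
#' @param problem the \code{\link{regulation_problem}} it solves.
#' @param support_tol threshold above which a coordinate counts as supported.
#' @return an object of class \code{"tightness_report"} with fields
#'   \code{scores}, \code{support}, \code{min_in}, \code{max_out},
#'   \code{xi_exists}.
#' @export
check_tightness <- function(u_star, problem, support_tol = 1e-4) {
  u <- if (inherits(u_star, "relaxed_solution")) u_star$u_hat else as.numeric(u_star)
  if (length(u) != problem$n) stopf("selector length mismatch")
  My <- M_times_y(u, problem$X, problem$rho, problem$y)
  c_vec <- drop(crossprod(problem$X, My))
  scores <- c_vec^2 + 2 * problem$lam * drop(problem$S %*% u)
  support <- which(u > support_tol)
  n_in <- length(support)
  if (n_in == 0L || n_in == problem$n) {
    min_in <- if (n_in == 0L) NA_real_ else min(scores)
    max_out <- if (n_in == 0L) max(scores) else NA_real_
    xi_exists <- TRUE
  } else {
    min_in <- min(scores[support])
    max_out <- max(scores[-support])
    # a support larger than the budget cannot be the support of a Boolean
    # optimum, however well separated its scores are (e.g. two tied
    # candidates straddling the budget force a fractional solution)
    xi_exists <- (n_in <= problem$k) && (min_in > max_out)
  }
  structure(list(scores = scores, support = support,
                 min_in = min_in, max_out = max_out,
                 xi_exists = xi_exists, support_tol = support_tol),
            class = "tightness_report")
}

#' @export
print.tightness_report <- function(x, ...) {
  cat(sprintf(
    "tightness_report: |support| = %d, separating interval (%.4g, %.4g], exact = %s\n",
    length(x$support), x$max_out, x$min_in, x$xi_exists))
  invisible(x)
}

#' Randomized rounding of a fractional selector
#'
#' Draws \code{n_samples} Boolean vectors with independent coordinates
#' \eqn{P[\tilde u_i = 1] = \hat u_i}; a draw exceeding the budget is repaired
#' by keeping the k drawn coordinates with the largest \eqn{\hat u_i}. The
#' deterministic top-k-of-\eqn{\hat u} candidate is always added to the pool,
#' so the result is never worse than plain thresholding. Among the feasible
#' candidates the one with minimal \code{\link{objective_G}} is returned
#' (first-seen on ties, which makes the output deterministic given the seed).
#'
#' @param u_hat fractional selector in \code{[0,1]^n}.
#' @param problem the \code{\link{regulation_problem}}.
#' @param n_samples number of Bernoulli draws, >= 1.
#' @param seed integer seed (local to this call).
#' @return an object of class \code{"boolean_solution"}: fields
#'   \code{u_tilde}, \code{support}, \code{objective}, and \code{draw_mean}
#'   (the pre-repair empirical coordinate mean of the draws).
#' @export
randomized_rounding <- function(u_hat, problem, n_samples = 100L, seed = 1L) {
  u_hat <- as.numeric(u_hat)
  n <- problem$n
  k <- problem$k
  if (length(u_hat) != n) stopf("u_hat length mismatch")
  if (any(u_hat < -1e-9) || any(u_hat > 1 + 1e-9)) stopf("u_hat outside [0,1]")
  u_hat <- pmin(pmax(u_hat, 0), 1)
  if (n_samples < 1L) stopf("n_samples must be >= 1")
  # deterministic top-k candidate (ties broken by index order)
  topk <- integer(n)
  topk[order(u_hat, decreasing = TRUE)[seq_len(k)]] <- 1L
  topk[u_hat == 0] <- 0L
  draws <- local_seed(seed, {
    matrix(stats::runif(n_samples * n), nrow = n_samples) <
      matrix(u_hat, nrow = n_samples, ncol = n, byrow = TRUE)
  })
  storage.mode(draws) <- "integer"
  draw_mean <- colMeans(draws)
  repair <- function(b) {
    if (sum(b) <= k) return(b)
    keep <- which(b == 1L)
    keep <- keep[order(u_hat[keep], decreasing = TRUE)[seq_len(k)]]
    out <- integer(n)
    out[keep] <- 1L
    out
  }
  pool <- vector("list", n_samples + 1L)
  pool[[1L]] <- topk
  for (i in seq_len(n_samples)) pool[[i + 1L]] <- repair(draws[i, ])
  keys <- vapply(pool, paste, character(1), collapse = "")
  pool <- pool[!duplicated(keys)]
  cache <- solver_cache(problem)
  objs <- vapply(pool, cached_objective, numeric(1), cache = cache,
                 problem = problem)
  best <- which.min(objs)
  u_tilde <- pool[[best]]
  structure(list(u_tilde = u_tilde, support = which(u_tilde == 1L),
                 objective = objs[best], draw_mean = draw_mean,
                 n_samples = n_samples),
            class = "boolean_solution")
}

#' @export
print.boolean_solution <- function(x, ...) {
  cat(sprintf("boolean_solution: |support| = %d, G = %.6g\n",
              length(x$support), x$objective))
  invisible(x)
}

#' Exhaustive Boolean optimum for small instances
#'
#' Enumerates every support of size 0..k, evaluates \code{\link{objective_G}}
#' at its indicator, and returns the minimizer. Ties are broken by size then
#' lexicographic order of the support, which is the enumeration order.
#' Intended as an independent optimum for testing and certification on small
#' problems; refuses instances whose enumeration would be too large.
#'
#' @param problem the \code{\link{regulation_problem}}; requires n <= 20.
#' @param max_evals guard on the number of enumerated supports.
#' @return a \code{"boolean_solution"} (without rounding-draw fields).
#' @export
brute_force_oracle <- function(problem, max_evals = 2e5) {
  n <- problem$n
  k <- problem$k
  if (n > 20L) stopf("brute_force_oracle requires n <= 20 (got %d)", n)
  total <- sum(vapply(0:k, function(s) choose(n, s), numeric(1)))
  if (total > max_evals) stopf("enumeration budget exceeded (%g supports)", total)
  best_obj <- Inf
  best_sup <- integer(0)
  cache <- solver_cache(problem)
  for (size in 0:k) {
    subsets <- if (size == 0L) list(integer(0)) else
      utils::combn(n, size, simplify = FALSE)
    for (sub in subsets) {
      u <- numeric(n)
      u[sub] <- 1
      val <- cached_objective(u, cache, problem)
      if (val < best_obj) {
        best_obj <- val
        best_sup <- sub
      }
    }
  }
  u <- integer(n)
  u[best_sup] <- 1L
  structure(list(u_tilde = u, support = best_sup, objective = best_obj),
            class = "boolean_solution")
}

#' Cross-validated hyper-parameter selection
#'
#' Grid search over \code{(rho, lambda, k)} with k-fold cross-validation:
#' for each grid point and fold, the selector is fit (relaxation + rounding)
#' on the training cells and scored by the held-out mean squared error of the
#' closed-form ridge fit restricted to the selected support. The grid point
#' with the smallest mean score wins; ties break deterministically toward
#' smaller k, then smaller lambda, then smaller rho.
#'
#' @param X,y,S as in \code{\link{regulation_problem}}.
#' @param rho_grid,lambda_grid,k_grid numeric grids; \code{lambda_grid} should
#'   include 0 so the pure sparse model is always a candidate.
#' @param n_folds number of folds, >= 2.
#' @param seed integer seed controlling the fold shuffle and rounding.
#' @param config solver settings applied at every grid point. Fold-level
#'   fits run with a loosened gradient tolerance (1e-4): the CV score is the
#'   held-out error of a ridge refit on the *selected support*, which is
#'   insensitive to late-stage polishing of the fractional selector.
#' @return list with \code{best} (named list rho/lam/k), \code{scores}
#'   (data.frame of per-point mean CV MSE), and \code{fold_scores}.
#' @export
cross_validate <- function(X, y, S,
                           rho_grid = c(0.1, 1, 10),
                           lambda_grid = c(0, 0.01, 0.1, 1),
                           k_grid = c(3, 5, 10),
                           n_folds = 5L, seed = 1L,
                           config = solver_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  m <- length(y)
  n <- ncol(X)
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  if (length(rho_grid) == 0 || length(lambda_grid) == 0 || length(k_grid) == 0)
    stopf("empty hyper-parameter grid")
  k_grid <- unique(pmin(as.integer(k_grid), n))
  perm <- local_seed(derive_seed(seed, 1L), sample.int(m))
  fold_id <- rep(seq_len(n_folds), length.out = m)[order(perm)]
  if (min(table(fold_id)) < 2L) stopf("fold with < 2 samples")
  grid <- expand.grid(rho = rho_grid, lam = lambda_grid, k = k_grid,
                      KEEP.OUT.ATTRS = FALSE)
  fold_cfg <- config
  fold_cfg$grad_tol <- max(config$grad_tol, 1e-4)
  fold_cfg$max_iter <- min(config$max_iter, 100L)
  fold_scores <- matrix(NA_real_, nrow(grid), n_folds)
  # within each (rho, k, fold), walk the lambda grid from large to small
  # with warm starts (regularization-path style); strongly penalized
  # problems converge fastest and their solutions seed the flatter ones
  for (fold in seq_len(n_folds)) {
    te <- fold_id == fold
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y[!te]
    for (rho_v in rho_grid) {
      for (k_v in k_grid) {
        warm <- NULL
        for (lam_v in sort(unique(lambda_grid), decreasing = TRUE)) {
          gi <- which(grid$rho == rho_v & grid$lam == lam_v & grid$k == k_v)
          prob <- regulation_problem(ytr, Xtr, tf_ids = colnames(X), S = S,
                                     rho = rho_v, lam = lam_v, k = k_v)
          cfg_i <- fold_cfg
          if (!is.null(warm)) {
            cfg_i$init <- "warm"
            cfg_i$warm_start <- warm
          }
          rel <- solve_relaxation(prob, cfg_i)
          warm <- rel$u_hat
          rnd <- randomized_rounding(
            rel$u_hat, prob, n_samples = config$n_rounding_samples,
            seed = derive_seed(seed, 100L + gi * n_folds + fold))
          sup <- rnd$support
          if (length(sup) == 0L) {
            pred <- rep(0, sum(te))
          } else {
            Xa <- Xtr[, sup, drop = FALSE]
            beta <- solve(crossprod(Xa) + diag(rho_v, length(sup)),
                          crossprod(Xa, ytr))
            pred <- drop(X[te, sup, drop = FALSE] %*% beta)
          }
          fold_scores[gi, fold] <- mean((y[te] - pred)^2)
        }
      }
    }
  }
  grid$score <- rowMeans(fold_scores)
  ord <- order(grid$score, grid$k, grid$lam, grid$rho)
  best <- grid[ord[1L], ]
  list(best = list(rho = best$rho, lam = best$lam, k = best$k),
       scores = grid, fold_scores = fold_scores)
}

#' Infer the regulators of one target gene
#'
#' End-to-end selection for one TG: solve the capped-simplex relaxation,
#' evaluate the exactness certificate, recover a Boolean support by
#' randomized rounding (skipped when the relaxed solution is already Boolean
#' to within 1e-6), and rank the selected TFs by their relaxed selector value.
#'
#' @param X m x n standardized candidate-TF expression matrix.
#' @param y centered TG expression vector.
#' @param tf_ids candidate TF symbols.
#' @param S candidate-TF distance matrix.
#' @param rho,lam,k hyper-parameters; alternatively set \code{cv = TRUE} to
#'   select them by \code{\link{cross_validate}} over the supplied grids.
#' @param config a \code{\link{solver_config}}.
#' @param cv logical; run cross-validation first.
#' @param rho_grid,lambda_grid,k_grid grids used when \code{cv = TRUE}.
#' @param n_folds folds used when \code{cv = TRUE}.
#' @return an object of class \code{"grip_fit"}: \code{ranked_tfs}
#'   (data.frame tf/u_hat/selected/rank), \code{relaxed}, \code{boolean},
#'   \code{tightness}, \code{problem}, and \code{hyperparams}.
#' @export
infer_regulators <- function(X, y, tf_ids = colnames(X), S,
                             rho = 1, lam = 0.1, k = 3,
                             config = solver_config(),
                             cv = FALSE,
                             rho_grid = c(0.1, 1, 10),
                             lambda_grid = c(0, 0.01, 0.1, 1),
                             k_grid = c(3, 5, 10),
                             n_folds = 5L) {
  if (cv) {
    sel <- cross_validate(X, y, S, rho_grid, lambda_grid, k_grid,
                          n_folds = n_folds, seed = config$seed,
                          config = config)
    rho <- sel$best$rho
    lam <- sel$best$lam
    k <- sel$best$k
  }
  problem <- regulation_problem(y, X, tf_ids = tf_ids, S = S,
                                rho = rho, lam = lam, k = k)
  rel <- solve_relaxation(problem, config)
  tight <- check_tightness(rel, problem)
  near_bool <- all(pmin(rel$u_hat, 1 - rel$u_hat) < 1e-6)
  if (near_bool) {
    u_tilde <- as.integer(rel$u_hat > 0.5)
    bool <- structure(list(u_tilde = u_tilde, support = which(u_tilde == 1L),
                           objective = objective_G(u_tilde, problem),
                           draw_mean = NULL, n_samples = 0L),
                      class = "boolean_solution")
  } else {
    bool <- randomized_rounding(rel$u_hat, problem,
                                n_samples = config$n_rounding_samples,
                                seed = derive_seed(config$seed, 7L))
  }
  sel_idx <- bool$support
  ord <- order(rel$u_hat, decreasing = TRUE)
  ranked <- data.frame(tf = problem$tf_ids[ord],
                       u_hat = rel$u_hat[ord],
                       selected = as.integer(ord %in% sel_idx),
                       stringsAsFactors = FALSE)
  ranked$rank <- seq_len(nrow(ranked))
  structure(list(ranked_tfs = ranked, relaxed = rel, boolean = bool,
                 tightness = tight, problem = problem,
                 hyperparams = list(rho = rho, lam = lam, k = k)),
            class = "grip_fit")
}

#' @export
print.grip_fit <- function(x, ...) {
  sel <- x$ranked_tfs$tf[x$ranked_tfs$selected == 1L]
  cat(sprintf(
    "grip_fit: %d/%d TFs selected (rho = %g, lambda = %g, k = %d), relaxation %s\n",
    length(sel), x$problem$n, x$hyperparams$rho, x$hyperparams$lam,
    x$hyperparams$k,
    if (x$tightness$xi_exists) "certified exact" else "fractional"))
  if (length(sel)) cat("  selected:", paste(sel, collapse = ", "), "\n")
  invisible(x)
}
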