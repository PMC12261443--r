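# Independent oracles used by the tests. These deliberately use different
# algorithms (and where possible different libraries) than the package code
# they check.

# all-pairs shortest paths by Floyd-Warshall on an adjacency matrix
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], nd)
    }
  }
  dimnames(d) <- dimnames(adj)
  d
}

# capped-simplex projection by bisection on the dual threshold
proj_bisect <- function(v, k, tol = 1e-12) {
  w <- pmin(pmax(v, 0), 1)
  if (sum(w) <= k) return(w)
  lo <- min(v) - 1
  hi <- max(v)
  for (i in 1:200) {
    th <- (lo + hi) / 2
    if (sum(pmin(pmax(v - th, 0), 1)) > k) lo <- th else hi <- th
    if (hi - lo < tol) break
  }
  pmin(pmax(v - hi, 0), 1)
}

# capped-simplex projection by exhaustive KKT pattern enumeration (small n):
# assign each coordinate to {lower, free, upper}, solve for the multiplier,
# keep KKT-consistent candidates, return the feasible minimizer of ||u - v||
proj_kkt_enum <- function(v, k) {
  n <- length(v)
  best <- NULL
  best_val <- Inf
  consider <- function(u) {
    if (any(u < -1e-9) || any(u > 1 + 1e-9) || sum(u) > k + 1e-9) return()
    val <- sum((u - v)^2)
    if (val < best_val - 1e-12) {
      best_val <<- val
      best <<- u
    }
  }
  consider(pmin(pmax(v, 0), 1))  # budget-inactive candidate
  patterns <- expand.grid(rep(list(c("z", "f", "o")), n),
                          stringsAsFactors = FALSE)
  for (pi in seq_len(nrow(patterns))) {
    pat <- unlist(patterns[pi, ])
    fr <- pat == "f"
    on <- pat == "o"
    nf <- sum(fr)
    rhs <- k - sum(on)
    if (rhs < -1e-9) next
    if (nf == 0L) {
      if (abs(sum(on) - k) > 1e-9 && sum(on) > k) next
      u <- numeric(n)
      u[on] <- 1
      consider(u)
      next
    }
    th <- (sum(v[fr]) - rhs) / nf
    if (th < -1e-9) next  # multiplier must be >= 0 when budget binds
    u <- numeric(n)
    u[on] <- 1
    u[fr] <- v[fr] - th
    if (any(u[fr] < -1e-9) || any(u[fr] > 1 + 1e-9)) next
    consider(u)
  }
  best
}

# central finite-difference gradient of objective_G
fd_gradient <- function(u, problem, h = 1e-6) {
  n <- length(u)
  vapply(seq_len(n), function(i) {
    e <- numeric(n)
    e[i] <- h
    (objective_G(u + e, problem) - objective_G(u - e, problem)) / (2 * h)
  }, numeric(1))
}

# random dense problem with S taken from the DSD of a random connected graph
random_problem <- function(m, n, seed, rho = 1, lam = 0.1, k = 3,
                           sigma = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(m * n), m, n)
  beta <- numeric(n)
  sup <- sample.int(n, min(k, n))
  beta[sup] <- runif(length(sup), 0.5, 1.5)
  y <- drop(X %*% beta) + rnorm(m, sd = sigma)
  g <- igraph::sample_gnp(n, 0.3)
  comps <- igraph::components(g)
  if (comps$no > 1) {
    for (ci in 2:comps$no)
      g <- igraph::add_edges(g, c(which(comps$membership == 1)[1],
                                  which(comps$membership == ci)[1]))
  }
  igraph::V(g)$name <- sprintf("TF%02d", seq_len(n))
  dsd <- dsd_matrix(ppi_network(igraph::simplify(g)), n_steps = 5)
  S <- dsd$D
  regulation_problem(y - mean(y), scale(X), tf_ids = igraph::V(g)$name,
                     S = S, rho = rho, lam = lam, k = min(k, n))
}
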