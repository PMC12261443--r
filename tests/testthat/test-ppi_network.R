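make_net <- function(edges_chr) {
  # edges_chr: character vector like c("A-B", "B-C")
  parts <- do.call(rbind, strsplit(edges_chr, "-", fixed = TRUE))
  load_ppi(data.frame(symbol_a = parts[, 1], symbol_b = parts[, 2],
                      interaction_type = "physical"))
}

test_that("load_ppi filters to physical interactions and simplifies", {
  net <- load_ppi(data.frame(a = c("A", "A", "A"), b = c("B", "B", "A"),
                             type = "physical"))
  expect_equal(igraph::ecount(net$graph), 1)
  expect_setequal(igraph::V(net$graph)$name, c("A", "B"))

  expect_error(load_ppi(data.frame(a = "A", b = "B", type = "genetic")),
               "no physical interactions")

  net2 <- load_ppi(data.frame(a = c("A", "B"), b = c("B", "C"),
                              type = c("Physical", "physical")))
  expect_equal(igraph::vcount(net2$graph), 3)
  expect_equal(igraph::ecount(net2$graph), 2)
  expect_equal(unname(shortest_path_distances(net2, "A")[1, "C"]), 2)

  # symbols are cleaned and case-collapsed; malformed rows are reported
  net3 <- load_ppi(data.frame(a = c(" tp53", "TP53"), b = c("MDM2 ", "mdm2"),
                              type = "physical"))
  expect_equal(igraph::ecount(net3$graph), 1)
  expect_error(load_ppi(data.frame(a = c("A", ""), b = c("B", "C"),
                                   type = "physical")),
               "row")
})

test_that("shortest-path distances agree with Floyd-Warshall and mark
           unreachable pairs as missing", {
  net <- make_net(c("A-B", "B-C", "X-Y"))
  d <- shortest_path_distances(net, c("A", "X"))
  expect_equal(unname(d["A", "A"]), 0)
  expect_equal(unname(d["A", "C"]), 2)
  expect_true(is.na(d["A", "X"]))
  expect_error(shortest_path_distances(net, "ZZZ"), "ZZZ")

  set.seed(7)
  g <- igraph::sample_gnp(25, 0.15)
  igraph::V(g)$name <- sprintf("N%02d", 1:25)
  net2 <- ppi_network(igraph::simplify(g))
  adj <- as.matrix(igraph::as_adjacency_matrix(net2$graph, sparse = FALSE))
  ref <- floyd_warshall(adj)
  ref[is.infinite(ref)] <- NA
  got <- shortest_path_distances(net2, rownames(adj))
  expect_equal(got[rownames(ref), colnames(ref)], ref)
})

test_that("DSD matches hand-computed walk sums on a 3-node path", {
  net <- make_net(c("A-B", "B-C"))
  dsd <- dsd_matrix(net, n_steps = 1)
  # independent computation: H = I + P from the explicit transition matrix
  P <- matrix(c(0, 1, 0,
                0.5, 0, 0.5,
                0, 1, 0), 3, 3, byrow = TRUE)
  H <- diag(3) + P
  ref <- as.matrix(dist(H, method = "manhattan"))
  ids <- c("A", "B", "C")
  dimnames(ref) <- list(ids, ids)
  expect_equal(dsd$D[ids, ids], ref, tolerance = 1e-12)
  expect_equal(unname(diag(dsd$D)), rep(0, 3))
})

test_that("DSD satisfies the metric axioms on a random graph", {
  set.seed(11)
  g <- igraph::sample_gnp(20, 0.2)
  comps <- igraph::components(g)
  if (comps$no > 1)
    for (ci in 2:comps$no)
      g <- igraph::add_edges(g, c(1, which(comps$membership == ci)[1]))
  igraph::V(g)$name <- sprintf("N%02d", 1:20)
  net <- ppi_network(igraph::simplify(g))
  D <- dsd_matrix(net, n_steps = 7)$D
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  # exhaustive triangle inequality over all ordered triples
  n <- nrow(D)
  viol <- 0
  for (a in 1:n) for (b in 1:n) for (cc in 1:n)
    if (D[a, cc] > D[a, b] + D[b, cc] + 1e-9) viol <- viol + 1
  expect_equal(viol, 0)
})

test_that("DSD increments shrink with the walk horizon and approach the
           converged variant", {
  net <- make_net(c("A-B", "B-C", "C-D", "D-A", "A-C", "D-E"))
  Ds <- lapply(1:8, function(t) dsd_matrix(net, n_steps = t)$D)
  inc <- vapply(1:7, function(t) max(abs(Ds[[t + 1]] - Ds[[t]])), numeric(1))
  expect_true(all(diff(inc) <= 1e-9))
  Dinf <- dsd_matrix(net, converged = TRUE)$D
  D_long <- dsd_matrix(net, n_steps = 300)$D
  expect_equal(D_long, Dinf, tolerance = 1e-6)
})

test_that("dsd_matrix validates its input", {
  net <- make_net(c("A-B", "X-Y"))
  expect_error(dsd_matrix(net), "disconnected")
  big <- dsd_matrix(net, component = "largest")
  expect_equal(sort(big$node_ids), c("A", "B"))
  expect_error(dsd_matrix(make_net("A-B"), n_steps = 0), "n_steps")
})

test_that("distance_submatrix slices, fills, and drops per policy", {
  net <- make_net(c("A-B", "B-C", "C-D"))
  dsd <- dsd_matrix(net, n_steps = 3)
  sub <- distance_submatrix(dsd, c("B", "D", "A"), "error")
  expect_equal(rownames(sub$S), c("B", "D", "A"))
  expect_identical(sub$S, t(sub$S))
  expect_true(all(diag(sub$S) == 0))
  expect_equal(sub$S["B", "D"], dsd$D["B", "D"])

  expect_error(distance_submatrix(dsd, c("A", "ZZ"), "error"), "ZZ")

  dr <- distance_submatrix(dsd, c("A", "ZZ", "C"), "drop")
  expect_equal(dr$tf_ids, c("A", "C"))
  expect_equal(dr$dropped, "ZZ")
  expect_equal(dim(dr$S), c(2, 2))

  mf <- distance_submatrix(dsd, c("A", "ZZ", "C"), "max_fill")
  expect_equal(dim(mf$S), c(3, 3))
  expect_equal(unname(mf$S["ZZ", "A"]), max(dsd$D))
  expect_equal(unname(mf$S["ZZ", "ZZ"]), 0)
})

test_that("Mann-Whitney U handles the documented small cases", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 1 / 6, tolerance = 1e-12)  # exact enumeration path
  expect_lt(r$p_value, 0.5)

  same <- mann_whitney_u(c(5, 1, 3), c(3, 5, 1))
  expect_equal(same$z_score, 0)
  expect_equal(same$p_value, 0.5)

  # midranks: pooled [1,1,1,2,2,2] -> ranks 2,2,2,5,5,5; R_a = 9, U = 3
  tied <- mann_whitney_u(c(1, 1, 2), c(1, 2, 2))
  expect_equal(tied$u_statistic, 3)
  sigma2 <- (9 / 12) * (7 - 48 / (6 * 5))
  expect_equal(tied$z_score, (3 - 4.5) / sqrt(sigma2), tolerance = 1e-12)

  expect_error(mann_whitney_u(c(2, 2), c(2, 2, 2)), "all ties")
})

test_that("exact Mann-Whitney p equals the permutation distribution and the
           tie-corrected z matches wilcox.test", {
  set.seed(3)
  for (i in 1:20) {
    na <- sample(2:4, 1)
    nb <- sample(2:4, 1)
    a <- sample(seq(1, 40), na)  # tie-free integers
    b <- sample(setdiff(seq(1, 40), a), nb)
    r <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, alternative = "less", exact = TRUE)
    expect_equal(r$u_statistic, unname(ref$statistic))
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  }
  # tied, large: normal approximation cross-checked against wilcox.test
  set.seed(4)
  a <- sample(1:6, 30, replace = TRUE)
  b <- sample(2:8, 35, replace = TRUE)
  r <- mann_whitney_u(a, b, exact = "never")
  ref <- wilcox.test(a, b, alternative = "less", exact = FALSE,
                     correct = FALSE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("proximity test ranks a tight regulon below a distant background", {
  # regulon pair at hop distance 1; the only background pair is at 3
  net <- make_net(c("A-B", "B-C", "C-D", "D-E", "E-F"))
  r <- proximity_test(list(TG1 = c("A", "B")), background_tfs = c("C", "F"),
                      metric = "shortest_path", net = net)
  expect_equal(r$u_statistic, 0)
  expect_equal(r$n_regulon_pairs, 1)
  expect_equal(r$n_background_pairs, 1)
  expect_lte(r$p_value, 0.5)  # one pair per sample: U = 0 is half the space

  expect_error(proximity_test(list(TG1 = "A"), c("C", "F"),
                              metric = "shortest_path", net = net),
               "mappable")
})

test_that("planted regulons are significantly proximal; null regulons are
           not", {
  tc <- generate_proximity_testcase(seed = 5)
  planted <- proximity_test(tc$regulons, tc$background,
                            metric = "shortest_path", net = tc$network)
  expect_lt(planted$p_value, 0.05)

  ps <- vapply(1:40, function(sd) {
    tc <- generate_proximity_testcase(seed = 500 + sd)
    null_regs <- local({
      set.seed(sd)
      lapply(1:5, function(i) sample(tc$background, 3))
    })
    proximity_test(null_regs, tc$background,
                   metric = "shortest_path", net = tc$network)$p_value
  }, numeric(1))
  expect_gt(median(ps), 0.25)
  expect_lt(median(ps), 0.75)
})

test_that("degree-preserving randomization keeps the degree multiset", {
  tc <- generate_proximity_testcase(seed = 9)
  rnd <- degree_preserving_randomization(tc$network, seed = 2)
  expect_equal(sort(igraph::degree(rnd$graph)),
               sort(igraph::degree(tc$network$graph)))
  # same seed reproduces, different seed (generically) differs
  rnd2 <- degree_preserving_randomization(tc$network, seed = 2)
  expect_identical(igraph::as_edgelist(rnd$graph),
                   igraph::as_edgelist(rnd2$graph))
})

test_that("DSD matrices round-trip through TSV", {
  net <- make_net(c("A-B", "B-C", "C-A", "C-D"))
  dsd <- dsd_matrix(net, n_steps = 4)
  path <- tempfile(fileext = ".tsv")
  write_dsd(dsd, path)
  back <- read_dsd(path)
  expect_equal(back$node_ids, dsd$node_ids)
  expect_equal(back$D, dsd$D, tolerance = 1e-12)
})
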