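#' Build a physical PPI network from an edge table
#'
#' Reads a BioGRID-style edge table (a data frame or a headered TSV file with
#' columns \code{symbol_a}, \code{symbol_b}, \code{interaction_type}; extra
#' columns are ignored) and keeps only rows whose interaction type equals
#' \code{"physical"} (case-insensitively). Gene symbols are uppercased and
#' whitespace-stripped; self-loops and duplicate edges are dropped, so the
#' result is a simple undirected graph.
#'
#' @param edge_table data frame with at least three columns, or path to a TSV.
#' @return an object of class \code{"ppi_network"} wrapping an igraph graph.
#' @examples
#' net <- load_ppi(data.frame(symbol_a = c("a", "A", "B"),
#'                            symbol_b = c("B", "B", "C"),
#'                            interaction_type = "physical"))
#' igraph::vcount(net$graph)
#' @export
load_ppi <- function(edge_table) {
  if (is.character(edge_table) && length(edge_table) == 1L) {
    if (!file.exists(edge_table)) stopf("edge table not found: %s", edge_table)
    edge_table <- utils::read.delim(edge_table, stringsAsFactors = FALSE)
  }
  edge_table <- as.data.frame(edge_table)
  if (ncol(edge_table) < 3L)
    stopf("edge table needs >= 3 columns (symbol_a, symbol_b, interaction_type)")
  a <- clean_symbols(edge_table[[1L]])
  b <- clean_symbols(edge_table[[2L]])
  typ <- tolower(trimws(as.character(edge_table[[3L]])))
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "" | a == "NA" | b == "NA")
  if (length(bad) > 0)
    stopf("malformed edge table row(s): %s", paste(bad, collapse = ", "))
  keep <- typ == "physical"
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0L) stopf("no physical interactions")
  drop_loop <- a == b
  a <- a[!drop_loop]
  b <- b[!drop_loop]
  if (length(a) == 0L) stopf("no physical interactions")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]
  hi <- hi[!dup]
  g <- igraph::graph_from_data_frame(data.frame(from = lo, to = hi),
                                     directed = FALSE)
  igraph::E(g)$interaction_type <- "physical"
  structure(list(graph = g), class = "ppi_network")
}

#' Wrap an igraph graph as a PPI network
#'
#' Utility used by the synthetic generator; validates that the graph is
#' simple and undirected.
#'
#' @param g an igraph undirected simple graph with named vertices.
#' @return a \code{"ppi_network"}.
#' @export
ppi_network <- function(g) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::is_directed(g)) stopf("PPI network must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    stopf("PPI network must be a simple graph")
  if (is.null(igraph::V(g)$name)) stopf("vertices must be named gene symbols")
  structure(list(graph = g), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d physical interactions\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Unweighted shortest-path (hop) distances
#'
#' Breadth-first hop counts from each source protein to every protein in the
#' network. Pairs in different connected components are reported as
#' \code{NA} (missing), not as a numeric infinity.
#'
#' @param net a \code{"ppi_network"}.
#' @param sources character vector of source symbols; must all be present.
#' @return numeric matrix, rows = sources, columns = all nodes; entries are
#'   hop counts or \code{NA}.
#' @export
shortest_path_distances <- function(net, sources) {
  stopifnot(inherits(net, "ppi_network"))
  sources <- clean_symbols(sources)
  nodes <- igraph::V(net$graph)$name
  missing <- setdiff(sources, nodes)
  if (length(missing) > 0)
    stopf("source not in graph: %s", paste(missing, collapse = ", "))
  d <- igraph::distances(net$graph, v = sources, mode = "all")
  d[is.infinite(d)] <- NA_real_
  d
}

#' Diffusion state distance matrix
#'
#' Computes the diffusion state distance (DSD) between all protein pairs of a
#' connected PPI network. With the random-walk transition matrix \eqn{P}
#' (rows of the adjacency matrix normalized by degree), the t-step diffusion
#' state of node v is \eqn{He^t(v) = \sum_{i=0}^{t} e_v^T P^i}, and
#' \eqn{D[u,v] = \|He^t(u) - He^t(v)\|_1}. The converged variant replaces the
#' finite sum by its limit with the stationary-distribution correction:
#' \eqn{D[u,v] = \|(e_u - e_v)^T (I - P + W)^{-1}\|_1} where every row of
#' \eqn{W} is the stationary distribution \eqn{\pi \propto} degree. Being an
#' L1 distance between node embeddings, DSD is symmetric, non-negative, has a
#' zero diagonal, and satisfies the triangle inequality by construction.
#'
#' @param net a \code{"ppi_network"}.
#' @param n_steps walk horizon t, >= 1 (default 7); ignored when
#'   \code{converged = TRUE}.
#' @param converged use the infinite-horizon form.
#' @param component \code{"error"} (default: refuse disconnected input) or
#'   \code{"largest"} (restrict to the largest connected component).
#' @return an object of class \code{"dsd_matrix"} with fields
#'   \code{node_ids}, \code{D}, \code{n_steps}, \code{converged}.
#' @export
dsd_matrix <- function(net, n_steps = 7L, converged = FALSE,
                       component = c("error", "largest")) {
  stopifnot(inherits(net, "ppi_network"))
  component <- match.arg(component)
  g <- net$graph
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    if (component == "error")
      stopf("network is disconnected (%d components); use component = 'largest'",
            comps$no)
    keep <- which(comps$membership == which.max(comps$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  if (!converged) {
    n_steps <- as.integer(n_steps)
    if (is.na(n_steps) || n_steps < 1L) stopf("n_steps must be >= 1")
  }
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  deg <- rowSums(A)
  if (any(deg == 0)) stopf("isolated node in the selected component")
  P <- A / deg
  nv <- nrow(A)
  if (converged) {
    pi_stat <- deg / sum(deg)
    W <- matrix(pi_stat, nrow = nv, ncol = nv, byrow = TRUE)
    H <- solve(diag(nv) - P + W)
  } else {
    H <- diag(nv)
    Pi <- diag(nv)
    for (i in seq_len(n_steps)) {
      Pi <- Pi %*% P
      H <- H + Pi
    }
  }
  D <- as.matrix(stats::dist(H, method = "manhattan"))
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  structure(list(node_ids = igraph::V(g)$name, D = D,
                 n_steps = if (converged) NA_integer_ else n_steps,
                 converged = converged),
            class = "dsd_matrix")
}

#' @export
print.dsd_matrix <- function(x, ...) {
  cat(sprintf("dsd_matrix: %d nodes, %s\n", length(x$node_ids),
              if (x$converged) "converged walk" else
                sprintf("%d-step walk", x$n_steps)))
  invisible(x)
}

#' Slice a TF-by-TF distance submatrix
#'
#' Extracts the pairwise-distance matrix \code{S} between the requested TFs,
#' aligned to \code{tf_ids}. TFs absent from the DSD matrix are handled per
#' \code{missing_policy}: \code{"error"} refuses and names them,
#' \code{"max_fill"} fills their row/column with the largest observed DSD
#' value (diagonal stays 0), \code{"drop"} removes them and reports them.
#'
#' @param dsd a \code{"dsd_matrix"}.
#' @param tf_ids character vector of TF symbols.
#' @param missing_policy one of \code{"error"}, \code{"max_fill"},
#'   \code{"drop"}.
#' @return list with \code{S} (symmetric matrix with dimnames),
#'   \code{tf_ids} (retained order), \code{dropped} (symbols removed under
#'   \code{"drop"}), \code{filled} (symbols filled under \code{"max_fill"}).
#' @export
distance_submatrix <- function(dsd, tf_ids,
                               missing_policy = c("error", "max_fill", "drop")) {
  stopifnot(inherits(dsd, "dsd_matrix"))
  missing_policy <- match.arg(missing_policy)
  tf_ids <- clean_symbols(tf_ids)
  if (anyDuplicated(tf_ids)) stopf("duplicate TF symbols in tf_ids")
  absent <- setdiff(tf_ids, dsd$node_ids)
  dropped <- character(0)
  filled <- character(0)
  if (length(absent) > 0) {
    if (missing_policy == "error") {
      stopf("TF(s) missing from the DSD matrix: %s",
            paste(absent, collapse = ", "))
    } else if (missing_policy == "drop") {
      dropped <- absent
      tf_ids <- setdiff(tf_ids, absent)
      if (length(tf_ids) == 0L) stopf("all TFs missing from the DSD matrix")
    } else {
      filled <- absent
    }
  }
  n <- length(tf_ids)
  S <- matrix(0, n, n, dimnames = list(tf_ids, tf_ids))
  present <- intersect(tf_ids, dsd$node_ids)
  S[present, present] <- dsd$D[present, present]
  if (length(filled) > 0) {
    fill_val <- max(dsd$D)
    S[filled, ] <- fill_val
    S[, filled] <- fill_val
    diag(S) <- 0
  }
  list(S = S, tf_ids = tf_ids, dropped = dropped, filled = filled)
}

#' Mann-Whitney U test with tie correction
#'
#' Rank-sum test that sample \code{a} is stochastically smaller than sample
#' \code{b} (default), with midranks for ties. The p-value uses the exact
#' permutation distribution when both samples are small and tie-free
#' (\code{n_a + n_b <= exact_limit}), and otherwise the normal approximation
#' with the tie-corrected variance
#' \deqn{\sigma_U^2 = \frac{n_a n_b}{12}\Big[(N+1) -
#'   \frac{\sum_t (t^3 - t)}{N(N-1)}\Big].}
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param alternative \code{"less"} (a stochastically smaller than b,
#'   default), \code{"greater"}, or \code{"two.sided"}.
#' @param exact \code{"auto"} (default), \code{"never"}, or \code{"always"}
#'   (refuses if ties are present).
#' @param exact_limit maximum \code{n_a + n_b} for the exact enumeration.
#' @return an object of class \code{"mwu_test"}: \code{u_statistic} (U for
#'   sample a), \code{z_score} (tie-corrected), \code{p_value}, \code{n_a},
#'   \code{n_b}, \code{method}.
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           alternative = c("less", "greater", "two.sided"),
                           exact = c("auto", "never", "always"),
                           exact_limit = 10L) {
  alternative <- match.arg(alternative)
  exact <- match.arg(exact)
  a <- as.numeric(sample_a)
  b <- as.numeric(sample_b)
  if (length(a) == 0L || length(b) == 0L) stopf("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stopf("missing values in samples")
  na <- length(a)
  nb <- length(b)
  N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  Ra <- sum(r[seq_len(na)])
  U <- Ra - na * (na + 1) / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  if (tie_term >= N^3 - N) stopf("degenerate (all ties)")
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- (U - mu) / sqrt(sigma2)
  has_ties <- any(tie_tab > 1)
  use_exact <- switch(exact,
    never = FALSE,
    always = {
      if (has_ties) stopf("exact p-value requested but ties are present")
      TRUE
    },
    auto = !has_ties && N <= exact_limit)
  if (use_exact) {
    # enumerate all rank assignments of sample a among 1..N
    combos <- utils::combn(N, na)
    us <- colSums(combos) - na * (na + 1) / 2
    p <- switch(alternative,
      less = mean(us <= U),
      greater = mean(us >= U),
      two.sided = min(1, 2 * min(mean(us <= U), mean(us >= U))))
    method <- "exact permutation"
  } else {
    p <- switch(alternative,
      less = stats::pnorm(z),
      greater = stats::pnorm(z, lower.tail = FALSE),
      two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation, tie-corrected"
  }
  structure(list(u_statistic = U, z_score = z, p_value = p,
                 n_a = na, n_b = nb, alternative = alternative,
                 method = method),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d), z = %.3f, p (%s) = %.4g [%s]\n",
              x$u_statistic, x$n_a, x$n_b, x$z_score, x$alternative,
              x$p_value, x$method))
  invisible(x)
}

# pooled pairwise distances among a symbol set, from a hop matrix or DSD
pairwise_distances <- function(ids, lookup) {
  n <- length(ids)
  if (n < 2L) return(numeric(0))
  idx <- utils::combn(n, 2L)
  vals <- lookup[cbind(ids[idx[1L, ]], ids[idx[2L, ]])]
  vals[!is.na(vals)]
}

#' Test whether co-regulating TFs are closer than random TFs
#'
#' Tests the proximity hypothesis: pooled pairwise network distances within
#' each regulon (the TF set of one TG) against pairwise distances among a
#' caller-supplied background TF universe, one-sided for "regulon pairs are
#' smaller". Distances are either BFS hop counts or diffusion state
#' distances. Pairs that are unreachable under the hop metric are dropped.
#'
#' @param regulon_sets named list, one character vector of TF symbols per TG.
#' @param background_tfs character vector of background TF symbols.
#' @param metric \code{"dsd"} or \code{"shortest_path"}.
#' @param net a \code{"ppi_network"} (required for \code{"shortest_path"};
#'   for \code{"dsd"} either supply \code{net} or a precomputed \code{dsd}).
#' @param dsd optional precomputed \code{"dsd_matrix"}.
#' @param n_steps walk horizon when DSD is computed here.
#' @return an object of class \code{"proximity_test_result"}: the
#'   \code{"mwu_test"} fields plus \code{n_regulon_pairs},
#'   \code{n_background_pairs}, \code{n_regulons_used}.
#' @export
proximity_test <- function(regulon_sets, background_tfs,
                           metric = c("dsd", "shortest_path"),
                           net = NULL, dsd = NULL, n_steps = 7L) {
  metric <- match.arg(metric)
  if (metric == "dsd") {
    if (is.null(dsd)) {
      if (is.null(net)) stopf("supply net or dsd for the DSD metric")
      dsd <- dsd_matrix(net, n_steps = n_steps, component = "largest")
    }
    lookup <- dsd$D
    universe <- dsd$node_ids
  } else {
    if (is.null(net)) stopf("supply net for the shortest-path metric")
    universe <- igraph::V(net$graph)$name
    bg_clean <- intersect(clean_symbols(background_tfs), universe)
    all_ids <- unique(c(unlist(lapply(regulon_sets, clean_symbols)), bg_clean))
    all_ids <- intersect(all_ids, universe)
    lookup <- shortest_path_distances(net, all_ids)[, all_ids, drop = FALSE]
  }
  sample_a <- numeric(0)
  used <- 0L
  for (reg in regulon_sets) {
    ids <- intersect(clean_symbols(reg), rownames(lookup))
    if (length(ids) >= 2L) {
      sample_a <- c(sample_a, pairwise_distances(ids, lookup))
      used <- used + 1L
    }
  }
  if (used == 0L) stopf("no regulon with >= 2 mappable TFs")
  bg <- intersect(clean_symbols(background_tfs), rownames(lookup))
  if (length(bg) < 2L) stopf("fewer than 2 mappable background TFs")
  sample_b <- pairwise_distances(bg, lookup)
  res <- mann_whitney_u(sample_a, sample_b, alternative = "less")
  out <- c(unclass(res),
           list(n_regulon_pairs = length(sample_a),
                n_background_pairs = length(sample_b),
                n_regulons_used = used, metric = metric))
  class(out) <- c("proximity_test_result", "mwu_test")
  out
}

#' Degree-preserving network randomization
#'
#' Null model used to ask whether results depend on the network's wiring
#' rather than its degree sequence: edges are rewired by seeded double-edge
#' swaps (default 10 x |E| swap attempts), which preserves every node's
#' degree exactly.
#'
#' @param net a \code{"ppi_network"}.
#' @param n_swaps number of swap attempts (default \code{10 * ecount}).
#' @param seed integer seed (local to this call).
#' @return a rewired \code{"ppi_network"} with the identical degree multiset.
#' @export
degree_preserving_randomization <- function(net, n_swaps = NULL, seed = 1L) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  if (is.null(n_swaps)) n_swaps <- 10L * igraph::ecount(g)
  g2 <- local_seed(seed,
                   igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps)))
  ppi_network(g2)
}

#' Write / read a DSD matrix as symbol-headered TSV
#'
#' @param dsd a \code{"dsd_matrix"}.
#' @param path output TSV path (first column and header row carry symbols).
#' @return \code{write_dsd} returns \code{path} invisibly; \code{read_dsd}
#'   returns a \code{"dsd_matrix"} (walk metadata is not persisted).
#' @export
write_dsd <- function(dsd, path) {
  stopifnot(inherits(dsd, "dsd_matrix"))
  df <- data.frame(symbol = dsd$node_ids, dsd$D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dsd
#' @export
read_dsd <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- clean_symbols(df[[1L]])
  D <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(D) <- list(ids, clean_symbols(colnames(D)))
  D <- D[ids, ids]
  structure(list(node_ids = ids, D = D, n_steps = NA_integer_,
                 converged = NA),
            class = "dsd_matrix")
}
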