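#' Specification of a synthetic regulator-inference instance
#'
#' Defines the generative conditions for a fully self-contained test
#' instance: a PPI graph over the candidate TFs with the true regulators
#' planted as a mutually adjacent set (a clique by default), expression
#' following the linear model \eqn{y = X \beta^* + \epsilon}, and, when
#' decoys are enabled, additional candidate TFs whose expression tracks the
#' target's regulatory signal but which sit far from the true regulators in
#' the network.
#'
#' Decoy columns are correlated with the noise-free regulatory signal
#' \eqn{X \beta^*} (not with the realized \eqn{y}): biologically they emulate
#' TFs driven by the same upstream program as the target, which co-express
#' with it without regulating it. Their default correlation (0.98) is chosen
#' so that expression alone barely distinguishes decoys from true regulators
#' -- the regime the network-proximity term is designed to resolve.
#'
#' @param n_tfs number of candidate TFs (network nodes), default 30.
#' @param m_cells number of cells, default 200.
#' @param k_true number of true regulators, default 3.
#' @param graph_model \code{"erdos_renyi"} (default), \code{"barabasi_albert"}
#'   or \code{"geometric"}.
#' @param graph_params list of model parameters (\code{p} for Erdos-Renyi,
#'   default 0.15; \code{m} edges per step for Barabasi-Albert; \code{radius}
#'   for the geometric model).
#' @param beta_star coefficients on the planted support; default
#'   \code{seq(1, 0.5, length.out = k_true)} (regulators of graded strength).
#' @param noise_sd standard deviation of \eqn{\epsilon}, default 0.5.
#' @param decoy list: \code{enabled} (default FALSE), \code{n_decoys}
#'   (default 6), \code{correlation} with the regulatory signal (default
#'   0.98, must be in (-1, 1)), \code{min_distance} hops from every true
#'   regulator (default 4).
#' @param seed integer seed.
#' @return a \code{"synthetic_spec"} list.
#' @export
synthetic_spec <- function(n_tfs = 30L, m_cells = 200L, k_true = 3L,
                           graph_model = c("erdos_renyi", "barabasi_albert",
                                           "geometric"),
                           graph_params = list(p = 0.15),
                           beta_star = NULL, noise_sd = 0.5,
                           decoy = list(enabled = FALSE),
                           seed = 1L) {
  graph_model <- match.arg(graph_model)
  n_tfs <- as.integer(n_tfs)
  m_cells <- as.integer(m_cells)
  k_true <- as.integer(k_true)
  if (k_true > n_tfs) stopf("k_true must be <= n_tfs")
  if (is.null(beta_star)) beta_star <- seq(1, 0.5, length.out = k_true)
  beta_star <- as.numeric(beta_star)
  if (length(beta_star) != k_true || any(beta_star == 0))
    stopf("beta_star must have k_true nonzero entries")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stopf("noise_sd must be >= 0")
  decoy_defaults <- list(enabled = FALSE, n_decoys = 6L, correlation = 0.98,
                         min_distance = 4L)
  decoy <- utils::modifyList(decoy_defaults, decoy)
  if (isTRUE(decoy$enabled)) {
    if (abs(decoy$correlation) >= 1)
      stopf("infeasible decoy correlation (|rho_decoy| >= 1)")
    if (k_true + decoy$n_decoys + decoy$min_distance > n_tfs)
      stopf("n_tfs too small for the requested decoy placement")
  }
  structure(list(n_tfs = n_tfs, m_cells = m_cells, k_true = k_true,
                 graph_model = graph_model, graph_params = graph_params,
                 beta_star = beta_star, noise_sd = noise_sd,
                 decoy = decoy, seed = as.integer(seed)),
            class = "synthetic_spec")
}

tf_names <- function(n) sprintf("TF%02d", seq_len(n))

# one connected random graph on the given vertex names; if the raw draw is
# disconnected, successive components are joined by one random edge each
# (keeps the edge density of the model essentially unchanged)
random_component <- function(names, model, params) {
  nv <- length(names)
  if (nv == 1L) {
    g0 <- igraph::make_empty_graph(1, directed = FALSE)
    return(igraph::set_vertex_attr(g0, "name", value = names))
  }
  g <- switch(model,
    erdos_renyi = igraph::sample_gnp(nv, p = params$p %||% 0.15),
    barabasi_albert = igraph::sample_pa(nv, m = params$m %||% 2L,
                                        directed = FALSE),
    geometric = igraph::sample_grg(nv, radius = params$radius %||% 0.4))
  igraph::V(g)$name <- names
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    for (ci in 2:comps$no) {
      a <- sample(which(comps$membership == 1L), 1L)
      b <- sample(which(comps$membership == ci), 1L)
      g <- igraph::add_edges(g, c(a, b))
    }
  }
  igraph::simplify(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a PPI network with planted proximal regulators
#'
#' Builds the candidate-TF graph of a \code{\link{synthetic_spec}}: the true
#' regulators are made mutually adjacent (a planted clique), the remaining
#' nodes follow the requested random-graph model, and the whole graph is
#' regenerated (bounded retries) until connected. When decoys are enabled,
#' the graph is built as two random lobes joined by a path of null TFs, with
#' the true regulators in one lobe and the decoys in the other, and the
#' decoy-to-regulator hop distance is verified to be at least
#' \code{decoy$min_distance} by BFS.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param max_retries bound on regeneration attempts.
#' @return list with \code{network} (a \code{"ppi_network"}),
#'   \code{true_tfs}, \code{decoy_tfs}, and \code{tf_ids} (node order).
#' @export
generate_network <- function(spec, max_retries = 100L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ids <- tf_names(spec$n_tfs)
  true_tfs <- ids[seq_len(spec$k_true)]
  dec <- spec$decoy
  decoy_tfs <- if (isTRUE(dec$enabled))
    ids[spec$k_true + seq_len(dec$n_decoys)] else character(0)
  nulls <- setdiff(ids, c(true_tfs, decoy_tfs))
  for (attempt in seq_len(max_retries)) {
    g <- local_seed(derive_seed(spec$seed, attempt), {
      if (!isTRUE(dec$enabled)) {
        g1 <- random_component(ids, spec$graph_model, spec$graph_params)
        if (spec$k_true >= 2L)
          g1 <- igraph::add_edges(g1,
                                  as.vector(utils::combn(true_tfs, 2L)))
        igraph::simplify(g1)
      } else {
        # two random lobes joined by a chain of null TFs enforce decoy
        # remoteness from the true clique; each decoy hangs as a pendant on
        # its own far-lobe anchor, so decoys are also mutually scattered
        # (pairwise hop distance >= 3) rather than forming a second planted
        # proximal set
        n_bridge <- max(dec$min_distance - 3L, 1L)
        need <- spec$k_true + dec$n_decoys * 2L + n_bridge + 1L
        if (spec$n_tfs < need)
          stopf("n_tfs too small for the decoy construction (need >= %d)",
                need)
        bridge <- nulls[seq_len(n_bridge)]
        rest <- setdiff(nulls, bridge)
        half <- max(ceiling(length(rest) / 2), 1L)
        lobe_a <- c(true_tfs, rest[seq_len(half)])
        nulls_b <- rest[-seq_len(half)]
        ga <- random_component(lobe_a, spec$graph_model, spec$graph_params)
        gb <- random_component(nulls_b, spec$graph_model, spec$graph_params)
        if (spec$k_true >= 2L)
          ga <- igraph::add_edges(
            ga, match(as.vector(utils::combn(true_tfs, 2L)),
                      igraph::V(ga)$name))
        ga <- igraph::simplify(ga)
        g1 <- igraph::disjoint_union(ga, gb)
        g1 <- igraph::add_vertices(g1, length(bridge) + dec$n_decoys,
                                   name = c(bridge, decoy_tfs))
        chain <- c(lobe_a[length(lobe_a)], bridge, nulls_b[1L])
        anchors <- sample(nulls_b, dec$n_decoys)
        new_edges <- c(
          unlist(lapply(seq_len(length(chain) - 1L),
                        function(i) chain[i + 0:1])),
          as.vector(rbind(decoy_tfs, anchors)))
        igraph::simplify(igraph::add_edges(
          g1, match(new_edges, igraph::V(g1)$name)))
      }
    })
    if (is.null(g)) next
    if (!igraph::is_connected(g)) next
    net <- ppi_network(g)
    if (isTRUE(dec$enabled)) {
      d <- shortest_path_distances(net, true_tfs)[, decoy_tfs, drop = FALSE]
      if (any(is.na(d)) || min(d) < dec$min_distance) next
      dd <- shortest_path_distances(net, decoy_tfs)[, decoy_tfs, drop = FALSE]
      if (any(dd[upper.tri(dd)] < 3)) next
    }
    return(list(network = net, true_tfs = true_tfs, decoy_tfs = decoy_tfs,
                tf_ids = ids))
  }
  stopf("could not generate a connected planted network in %d retries",
        max_retries)
}

#' Generate a complete synthetic inference instance
#'
#' Draws expression under the linear model of the spec, computes the DSD
#' matrix of the planted network, and constructs toy genomic tables (ATAC
#' peaks, motif hits, promoter-capture links) consistent with the planted
#' structure: every candidate TF has a motif hit in a peak inside the
#' target's 250 kb window, and the promoter-capture links cover exactly the
#' peaks hit by the true regulators. Columns of \code{X} are standardized and
#' \code{y} is centered, matching what \code{\link{assemble_problem}} would
#' produce from raw tables.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param rho,lam,k hyper-parameters stored in the embedded
#'   \code{\link{regulation_problem}} (defaults 1, 0.1, \code{k_true}).
#' @param n_steps DSD walk horizon.
#' @return an object of class \code{"synthetic_instance"}: fields
#'   \code{problem}, \code{true_support} (indices), \code{true_tfs},
#'   \code{decoy_tfs}, \code{network}, \code{dsd}, \code{expr} (cells x
#'   genes matrix incl. the target column \code{"TG1"}), \code{gene},
#'   \code{peaks}, \code{motif_hits}, \code{links}, \code{spec}.
#' @export
generate_instance <- function(spec, rho = 1, lam = 0.1, k = NULL,
                              n_steps = 7L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(k)) k <- spec$k_true
  netgen <- generate_network(spec)
  net <- netgen$network
  ids <- netgen$tf_ids
  n <- spec$n_tfs
  m <- spec$m_cells
  true_idx <- match(netgen$true_tfs, ids)
  decoy_idx <- match(netgen$decoy_tfs, ids)
  dat <- local_seed(derive_seed(spec$seed, 9901L), {
    X <- matrix(stats::rnorm(m * n), m, n, dimnames = list(NULL, ids))
    signal <- drop(X[, true_idx, drop = FALSE] %*% spec$beta_star)
    eps <- if (spec$noise_sd > 0) stats::rnorm(m, sd = spec$noise_sd) else
      numeric(m)
    y <- signal + eps
    if (length(decoy_idx) > 0) {
      rho_d <- spec$decoy$correlation
      s_unit <- signal / sqrt(sum(signal^2))
      for (j in decoy_idx) {
        z <- stats::rnorm(m)
        X[, j] <- rho_d * s_unit * sqrt(m) + sqrt(1 - rho_d^2) * z
      }
    }
    list(X = X, y = y)
  })
  X <- scale(dat$X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  y <- dat$y - mean(dat$y)
  dsd <- dsd_matrix(net, n_steps = n_steps)
  S <- distance_submatrix(dsd, ids, missing_policy = "error")$S
  problem <- regulation_problem(y, X, tf_ids = ids, S = S,
                                rho = rho, lam = lam, k = k)
  # toy genomics: TG promoter at 500 kb; one peak and one motif hit per TF
  tss <- 500000L
  gene <- list(gene_id = "TG1", chrom = "chr1", tss = tss, strand = "+")
  peak_start <- tss + 5000L + 1000L * (seq_len(n) - 1L)  # distal, within 250 kb
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = peak_start + 1L, end = peak_start + 400L))
  names(peaks) <- sprintf("peak_%s", ids)
  motif_hits <- data.frame(tf_id = ids, chrom = "chr1",
                           start = peak_start + 50L, end = peak_start + 60L,
                           stringsAsFactors = FALSE)
  links <- data.frame(tg = "TG1", chrom = "chr1",
                      start = peak_start[true_idx],
                      end = peak_start[true_idx] + 400L,
                      stringsAsFactors = FALSE)
  structure(list(problem = problem, true_support = true_idx,
                 true_tfs = netgen$true_tfs, decoy_tfs = netgen$decoy_tfs,
                 network = net, dsd = dsd,
                 expr = cbind(dat$X, TG1 = dat$y),
                 gene = gene, peaks = peaks, motif_hits = motif_hits,
                 links = links, spec = spec),
            class = "synthetic_instance")
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "synthetic_instance: %d cells x %d TFs, %d true regulators (%s)%s\n",
    x$spec$m_cells, x$spec$n_tfs, length(x$true_support),
    paste(x$true_tfs, collapse = ", "),
    if (length(x$decoy_tfs)) sprintf(", %d decoys", length(x$decoy_tfs)) else ""))
  invisible(x)
}

#' Support-recovery F1 score
#'
#' F1 overlap between a selected TF set and the planted truth:
#' \eqn{2 |sel \cap truth| / (|sel| + |truth|)}.
#'
#' @param selected,truth index or character vectors.
#' @return F1 in [0, 1].
#' @export
recovery_f1 <- function(selected, truth) {
  if (length(selected) + length(truth) == 0L) return(0)
  2 * length(intersect(selected, truth)) / (length(selected) + length(truth))
}

#' Write a synthetic instance to plain-text fixture files
#'
#' Emits the files a real analysis would start from: \code{expression.tsv}
#' (cells x genes, incl. the target column), \code{edges.tsv} (physical PPI
#' edge list), \code{peaks.bed}, \code{tss.tsv}, \code{motif_hits.tsv},
#' \code{links.tsv}, and \code{truth.json}.
#'
#' @param inst a \code{"synthetic_instance"}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_instance <- function(inst, dir) {
  stopifnot(inherits(inst, "synthetic_instance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- data.frame(cell = sprintf("cell%03d", seq_len(nrow(inst$expr))),
                     inst$expr, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  el <- igraph::as_edgelist(inst$network$graph)
  utils::write.table(
    data.frame(symbol_a = el[, 1], symbol_b = el[, 2],
               interaction_type = "physical"),
    file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  pk <- inst$peaks
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(pk)),
               start = GenomicRanges::start(pk) - 1L,
               end = GenomicRanges::end(pk)),
    file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(gene_id = inst$gene$gene_id, chrom = inst$gene$chrom,
               tss = inst$gene$tss + 1L, strand = inst$gene$strand),
    file.path(dir, "tss.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(inst$motif_hits, file.path(dir, "motif_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(inst$links, file.path(dir, "links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(true_tfs = inst$true_tfs, decoy_tfs = inst$decoy_tfs,
         beta_star = inst$spec$beta_star, noise_sd = inst$spec$noise_sd,
         seed = inst$spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Planted-regulon network for proximity-hypothesis experiments
#'
#' Generates a connected random network in which several disjoint regulons
#' are planted as cliques, for exercising \code{\link{proximity_test}}:
#' planted regulons should test significantly closer than background, and
#' regulons drawn at random from the background should not.
#'
#' @param n_tfs total TFs, default 40.
#' @param n_regulons number of planted regulons, default 5.
#' @param regulon_size TFs per regulon, default 3.
#' @param p Erdos-Renyi edge probability, default 0.15.
#' @param seed integer seed.
#' @param max_retries bound on regeneration attempts.
#' @return list with \code{network}, \code{regulons} (named list of TF sets),
#'   and \code{background} (all TF symbols).
#' @export
generate_proximity_testcase <- function(n_tfs = 40L, n_regulons = 5L,
                                        regulon_size = 3L, p = 0.15,
                                        seed = 1L, max_retries = 100L) {
  if (n_regulons * regulon_size > n_tfs)
    stopf("regulons do not fit into n_tfs")
  ids <- tf_names(n_tfs)
  regulons <- lapply(seq_len(n_regulons), function(i)
    ids[(i - 1L) * regulon_size + seq_len(regulon_size)])
  names(regulons) <- sprintf("TG%02d", seq_len(n_regulons))
  for (attempt in seq_len(max_retries)) {
    g <- local_seed(derive_seed(seed, 3000L + attempt), {
      g1 <- igraph::sample_gnp(n_tfs, p = p)
      igraph::V(g1)$name <- ids
      for (reg in regulons)
        g1 <- igraph::add_edges(g1, match(as.vector(utils::combn(reg, 2L)),
                                          ids))
      igraph::simplify(g1)
    })
    if (igraph::is_connected(g))
      return(list(network = ppi_network(g), regulons = regulons,
                  background = ids))
  }
  stopf("could not generate a connected regulon network in %d retries",
        max_retries)
}
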