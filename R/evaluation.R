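# Benchmark metrics: out-of-sample MSE of a small feed-forward predictor,
# average pairwise DSD distance of the inferred TFs, and F1 agreement with
# promoter-capture interaction links.

#' Out-of-sample MSE of a feed-forward TG-expression predictor
#'
#' Measures the predictive power of an inferred TF set for a target gene:
#' cells are split 90/10 by a seeded shuffle, a three-layer feed-forward
#' regressor with layer widths (number of TFs, 20, 1) -- a single hidden
#' layer of 20 logistic units with a linear output, trained by penalized
#' least squares -- is fit on the training cells, and the mean squared error
#' on the held-out cells is returned. The layer widths are fixed to keep the
#' predictor small; activation, weight decay and the epoch budget are
#' configurable through \code{net_spec}.
#'
#' @param expr cells x genes expression matrix.
#' @param tg target-gene column name.
#' @param tf_ids non-empty character vector of predictor columns.
#' @param split_frac training fraction, default 0.9.
#' @param seed integer seed controlling the split and the weight
#'   initialization (training is deterministic given the seed).
#' @param net_spec list: \code{hidden} (default 20), \code{epochs} (default
#'   200), \code{decay} (default 1e-4).
#' @return held-out mean squared error, a single non-negative number.
#' @export
oos_mse <- function(expr, tg, tf_ids, split_frac = 0.9, seed = 1L,
                    net_spec = list(hidden = 20L, epochs = 200L,
                                    decay = 1e-4)) {
  expr <- as.matrix(expr)
  colnames(expr) <- clean_symbols(colnames(expr))
  tg <- clean_symbols(tg)
  tf_ids <- clean_symbols(tf_ids)
  if (length(tf_ids) == 0L) stopf("tf_ids must be non-empty")
  missing <- setdiff(c(tg, tf_ids), colnames(expr))
  if (length(missing) > 0)
    stopf("absent from expression: %s", paste(missing, collapse = ", "))
  m <- nrow(expr)
  if (m < 10L) stopf("need >= 10 cells")
  spec <- utils::modifyList(list(hidden = 20L, epochs = 200L, decay = 1e-4),
                            net_spec)
  perm <- local_seed(derive_seed(seed, 11L), sample.int(m))
  n_train <- floor(split_frac * m)
  if (m - n_train < 2L) stopf("fewer than 2 test cells")
  tr <- perm[seq_len(n_train)]
  te <- perm[-seq_len(n_train)]
  Xtr <- expr[tr, tf_ids, drop = FALSE]
  Xte <- expr[te, tf_ids, drop = FALSE]
  ytr <- expr[tr, tg]
  yte <- expr[te, tg]
  # scale inputs/outputs on training statistics for stable optimization
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
  Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, `/`)
  ymu <- mean(ytr)
  ysd <- stats::sd(ytr)
  if (ysd == 0) ysd <- 1
  fit <- local_seed(derive_seed(seed, 12L),
    nnet::nnet(x = Xtr, y = (ytr - ymu) / ysd, size = spec$hidden,
               linout = TRUE, maxit = spec$epochs, decay = spec$decay,
               trace = FALSE, MaxNWts = 10000L))
  pred <- drop(stats::predict(fit, Xte)) * ysd + ymu
  mean((yte - pred)^2)
}

#' Average pairwise DSD distance of a TF set
#'
#' @param tf_ids character vector of >= 2 distinct TF symbols, all present in
#'   the DSD matrix.
#' @param dsd a \code{"dsd_matrix"}.
#' @return mean of D[i, j] over all unordered pairs.
#' @export
average_tf_distance <- function(tf_ids, dsd) {
  stopifnot(inherits(dsd, "dsd_matrix"))
  tf_ids <- clean_symbols(tf_ids)
  if (anyDuplicated(tf_ids)) stopf("duplicate TF symbols")
  tf_ids <- intersect(tf_ids, dsd$node_ids)
  if (length(tf_ids) < 2L)
    stopf("undefined for fewer than two TFs")
  idx <- utils::combn(length(tf_ids), 2L)
  mean(dsd$D[cbind(tf_ids[idx[1L, ]], tf_ids[idx[2L, ]])])
}

#' Read promoter-capture interaction links
#'
#' Expects a headered TSV with columns \code{tg}, \code{chrom}, \code{start},
#' \code{end} (0-based half-open), one row per region linked to the TG's
#' promoter.
#'
#' @param path TSV path.
#' @return data.frame with an attached row-aligned GRanges attribute
#'   \code{"granges"}.
#' @export
read_links <- function(path) {
  if (!file.exists(path)) stopf("links file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tg", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stopf("links file must have columns: %s", paste(need, collapse = ", "))
  df$tg <- clean_symbols(df$tg)
  attr(df, "granges") <- bed_to_granges(df$chrom, as.integer(df$start),
                                        as.integer(df$end))
  df
}

links_for_tg <- function(links, tg) {
  gr <- attr(links, "granges")
  if (is.null(gr)) gr <- bed_to_granges(links$chrom, as.integer(links$start),
                                        as.integer(links$end))
  gr[clean_symbols(links$tg) == clean_symbols(tg)]
}

#' F1 agreement between top-k inferred TFs and promoter-capture links
#'
#' For one TG, builds the set \eqn{\Omega} of unique candidate regions hit by
#' any of the top-k ranked TFs (from their motif hits), intersects it with
#' the linked-region set \eqn{\Lambda} to get \eqn{\Delta} (interval overlap
#' of at least one shared base), and returns precision
#' \eqn{|\Delta|/|\Omega|} (0 when \eqn{\Omega} is empty), recall
#' \eqn{|\Delta|/|\Lambda|}, and their harmonic mean (0 when both are 0).
#'
#' @param tg target-gene symbol.
#' @param ranked_tfs character vector of TFs, best first.
#' @param k number of top TFs to consider (default 3).
#' @param motif_hits data.frame from \code{\link{read_motif_hits}}.
#' @param candidate_regions GRanges of the TG's candidate regions
#'   (promoter + distal; \eqn{\Omega} is restricted to these).
#' @param links data.frame from \code{\link{read_links}}, or a GRanges of
#'   linked regions for this TG.
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{n_omega}, \code{n_delta}, \code{n_lambda}, \code{k_used}.
#' @export
f1_topk <- function(tg, ranked_tfs, k = 3L, motif_hits, candidate_regions,
                    links) {
  if (k < 1L) stopf("k must be >= 1")
  lambda <- if (inherits(links, "GRanges")) links else links_for_tg(links, tg)
  if (length(lambda) == 0L) stopf("TG has no PCHiC links")
  top <- utils::head(clean_symbols(ranked_tfs), k)
  hit_gr <- motif_hit_granges(motif_hits)
  tf_col <- clean_symbols(motif_hits$tf_id)
  top_hits <- hit_gr[tf_col %in% top]
  omega_idx <- sort(unique(S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(top_hits, candidate_regions))))
  omega <- candidate_regions[omega_idx]
  n_omega <- length(omega)
  n_delta <- sum(IRanges::overlapsAny(omega, lambda))
  precision <- if (n_omega == 0L) 0 else n_delta / n_omega
  recall <- n_delta / length(lambda)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_omega = n_omega, n_delta = n_delta, n_lambda = length(lambda),
       k_used = as.integer(k))
}

#' Paired one-sided location test
#'
#' Convenience wrapper used when comparing a metric between two methods over
#' a shared set of TGs: a paired t-test that \code{a} is smaller (or
#' greater) than \code{b}.
#'
#' @param a,b paired numeric vectors.
#' @param alternative \code{"less"} (default) or \code{"greater"}.
#' @return the \code{htest} object from \code{\link[stats]{t.test}}.
#' @export
paired_onesided_test <- function(a, b, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stats::t.test(a, b, paired = TRUE, alternative = alternative)
}
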