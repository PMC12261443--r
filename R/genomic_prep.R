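# Genomic coordinates use the BED convention (0-based, half-open) in all
# files; in memory regions are standard Bioconductor GRanges (1-based,
# closed). Conversion happens exactly once, at the I/O boundary.

bed_to_granges <- function(chrom, start0, end0) {
  if (any(start0 < 0) || any(end0 <= start0))
    stopf("invalid region: require 0 <= start < end")
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0))
}

granges_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read ATAC peaks from a BED3+ file
#'
#' @param path BED file (no header, >= 3 columns, 0-based half-open).
#' @return a GRanges of peaks.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stopf("peak file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stopf("BED file needs >= 3 columns")
  bed_to_granges(df[[1L]], as.integer(df[[2L]]), as.integer(df[[3L]]))
}

#' Read TSS annotations
#'
#' Expects a headered TSV with columns \code{gene_id}, \code{chrom},
#' \code{tss}, \code{strand}. Annotation TSS positions are 1-based by
#' convention and converted to 0-based on load.
#'
#' @param path TSV path.
#' @param one_based are the input positions 1-based (default TRUE)?
#' @return data.frame with columns gene_id, chrom, tss (0-based), strand.
#' @export
read_tss <- function(path, one_based = TRUE) {
  if (!file.exists(path)) stopf("TSS file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stopf("TSS file must have columns: %s", paste(need, collapse = ", "))
  df$gene_id <- clean_symbols(df$gene_id)
  df$tss <- as.integer(df$tss) - if (one_based) 1L else 0L
  if (any(df$tss < 0)) stopf("negative TSS after conversion")
  if (!all(df$strand %in% c("+", "-"))) stopf("strand must be + or -")
  df
}

#' Read TF motif hits
#'
#' Expects a headered TSV with columns \code{tf_id}, \code{chrom},
#' \code{start}, \code{end} (0-based half-open), as produced by reducing an
#' external motif scanner's output. Scanning itself is upstream of this
#' package; hits are consumed as given.
#'
#' @param path TSV path.
#' @return data.frame with a \code{regions} GRanges attached as attribute
#'   \code{"granges"} (row-aligned).
#' @export
read_motif_hits <- function(path) {
  if (!file.exists(path)) stopf("motif-hit file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stopf("motif-hit file must have columns: %s", paste(need, collapse = ", "))
  df$tf_id <- clean_symbols(df$tf_id)
  if (any(df$tf_id == "")) stopf("empty tf_id in motif hits")
  attr(df, "granges") <- bed_to_granges(df$chrom, as.integer(df$start),
                                        as.integer(df$end))
  df
}

motif_hit_granges <- function(motif_hits) {
  gr <- attr(motif_hits, "granges")
  if (is.null(gr))
    gr <- bed_to_granges(motif_hits$chrom, as.integer(motif_hits$start),
                         as.integer(motif_hits$end))
  gr
}

#' Read an expression table
#'
#' Either a headered TSV whose first column holds cell identifiers and whose
#' remaining columns are genes, or a MatrixMarket triplet (\code{.mtx} with
#' sibling \code{<stem>_rows.txt} / \code{<stem>_cols.txt} name files, rows =
#' cells, columns = genes).
#'
#' @param path TSV or .mtx path.
#' @return numeric matrix, cells x genes, with gene symbols as column names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rows <- readLines(paste0(stem, "_rows.txt"))
    cols <- readLines(paste0(stem, "_cols.txt"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m))
      stopf("row/col name files do not match matrix dimensions")
    dimnames(m) <- list(rows, clean_symbols(cols))
    return(m)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  colnames(m) <- clean_symbols(colnames(m))
  storage.mode(m) <- "double"
  m
}

#' Classify peaks as promoter or distal relative to one gene
#'
#' Follows the region convention used throughout the package: a peak
#' overlapping the strand-aware 500 bp window immediately upstream of the
#' TSS is a promoter peak; any other peak on the same chromosome overlapping
#' the +/- 250 kb window around the TSS is a distal candidate functional
#' region; everything else is dropped. Promoter takes precedence, so the two
#' classes partition the in-window peaks. Overlap of any shared base
#' suffices.
#'
#' @param peaks GRanges of ATAC peaks (any chromosomes).
#' @param gene list or single-row data.frame with \code{gene_id},
#'   \code{chrom}, \code{tss} (0-based), \code{strand}.
#' @param promoter_bp upstream promoter window, default 500.
#' @param window_bp distal window half-width, default 250000.
#' @return list with GRanges \code{promoter} and \code{distal}.
#' @export
classify_peaks <- function(peaks, gene, promoter_bp = 500L,
                           window_bp = 250000L) {
  if (promoter_bp < 0 || window_bp < 0) stopf("negative window")
  gene <- as.list(gene)
  tss <- as.integer(gene$tss)
  # promoter: 0-based half-open [tss - P, tss) on +, (tss, tss + P] on -
  prom <- if (gene$strand == "+") {
    bed_to_granges(gene$chrom, max(tss - promoter_bp, 0L), max(tss, 1L))
  } else {
    bed_to_granges(gene$chrom, tss + 1L, tss + promoter_bp + 1L)
  }
  win <- bed_to_granges(gene$chrom, max(tss - window_bp, 0L), tss + window_bp)
  is_prom <- IRanges::overlapsAny(peaks, prom)
  in_win <- IRanges::overlapsAny(peaks, win)
  list(promoter = peaks[is_prom],
       distal = peaks[in_win & !is_prom])
}

#' Assemble the candidate TF set for one target gene
#'
#' Classifies the peaks around the TG and collects every TF with at least
#' one motif hit overlapping the promoter or distal regions (or only the
#' distal regions when \code{include_promoter = FALSE}).
#'
#' @param tg target-gene symbol.
#' @param peaks GRanges of ATAC peaks.
#' @param gene the TG's annotation row (see \code{\link{classify_peaks}}).
#' @param motif_hits data.frame from \code{\link{read_motif_hits}}.
#' @param include_promoter include promoter-region hits (default TRUE).
#' @param promoter_bp,window_bp see \code{\link{classify_peaks}}.
#' @return an object of class \code{"candidate_set"}: \code{tg},
#'   \code{promoter_regions}, \code{distal_regions}, \code{candidate_tfs},
#'   \code{tf_to_regions} (named list of GRanges).
#' @export
build_candidate_set <- function(tg, peaks, gene, motif_hits,
                                include_promoter = TRUE,
                                promoter_bp = 500L, window_bp = 250000L) {
  cls <- classify_peaks(peaks, gene, promoter_bp, window_bp)
  regions <- if (include_promoter) c(cls$promoter, cls$distal) else cls$distal
  hit_gr <- motif_hit_granges(motif_hits)
  tfs <- clean_symbols(motif_hits$tf_id)
  ov <- GenomicRanges::findOverlaps(hit_gr, regions)
  hit_tf <- tfs[S4Vectors::queryHits(ov)]
  hit_region <- S4Vectors::subjectHits(ov)
  candidate_tfs <- sort(unique(hit_tf))
  tf_to_regions <- lapply(candidate_tfs, function(tf)
    regions[sort(unique(hit_region[hit_tf == tf]))])
  names(tf_to_regions) <- candidate_tfs
  structure(list(tg = clean_symbols(tg),
                 promoter_regions = cls$promoter,
                 distal_regions = cls$distal,
                 candidate_tfs = candidate_tfs,
                 tf_to_regions = tf_to_regions),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "candidate_set for %s: %d promoter + %d distal regions, %d candidate TFs\n",
    x$tg, length(x$promoter_regions), length(x$distal_regions),
    length(x$candidate_tfs)))
  invisible(x)
}

#' Write / read a candidate set as JSON
#'
#' Round-trip persistence for \code{"candidate_set"} objects; coordinates are
#' stored 0-based half-open.
#'
#' @param cs a \code{"candidate_set"}.
#' @param path JSON path.
#' @export
write_candidate_set <- function(cs, path) {
  stopifnot(inherits(cs, "candidate_set"))
  ser <- list(tg = cs$tg,
              promoter_regions = granges_to_bed(cs$promoter_regions),
              distal_regions = granges_to_bed(cs$distal_regions),
              candidate_tfs = cs$candidate_tfs,
              tf_to_regions = lapply(cs$tf_to_regions, granges_to_bed))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_candidate_set
#' @export
read_candidate_set <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_bed <- function(df) {
    if (is.null(df) || NROW(df) == 0)
      return(GenomicRanges::GRanges())
    bed_to_granges(df$chrom, as.integer(df$start), as.integer(df$end))
  }
  tfr <- lapply(ser$tf_to_regions, from_bed)
  structure(list(tg = ser$tg,
                 promoter_regions = from_bed(ser$promoter_regions),
                 distal_regions = from_bed(ser$distal_regions),
                 candidate_tfs = as.character(ser$candidate_tfs),
                 tf_to_regions = tfr),
            class = "candidate_set")
}

#' Assemble a regulation problem from expression, candidates and distances
#'
#' Centers the TG expression, standardizes the candidate-TF expression
#' columns (zero-variance columns are dropped with a warning), slices the
#' DSD submatrix over the retained TFs per \code{missing_policy}, and
#' returns a ready-to-solve \code{\link{regulation_problem}} whose
#' \code{tf_ids} ordering is identical across \code{X} columns and \code{S}
#' rows/columns.
#'
#' @param tg target-gene symbol (must be a column of \code{expr}).
#' @param expr cells x genes expression matrix (see
#'   \code{\link{read_expression}}).
#' @param candidates a \code{"candidate_set"} (or a character vector of
#'   candidate TF symbols).
#' @param dsd a \code{"dsd_matrix"}.
#' @param rho,lam,k hyper-parameters (k is capped at the number of retained
#'   TFs).
#' @param missing_policy policy for TFs absent from expression or the DSD
#'   matrix: \code{"drop"} (default), \code{"error"}, or \code{"max_fill"}
#'   (DSD only; TFs absent from expression are always dropped or an error).
#' @return a \code{\link{regulation_problem}} with attribute
#'   \code{"dropped"} listing removed TFs and why.
#' @export
assemble_problem <- function(tg, expr, candidates, dsd, rho = 1, lam = 0.1,
                             k = 3L, missing_policy = c("drop", "error",
                                                        "max_fill")) {
  missing_policy <- match.arg(missing_policy)
  tg <- clean_symbols(tg)
  expr <- as.matrix(expr)
  colnames(expr) <- clean_symbols(colnames(expr))
  if (!(tg %in% colnames(expr))) stopf("target gene %s absent from expression", tg)
  tf_ids <- if (inherits(candidates, "candidate_set"))
    candidates$candidate_tfs else clean_symbols(candidates)
  tf_ids <- setdiff(unique(tf_ids), tg)
  dropped <- list()
  no_expr <- setdiff(tf_ids, colnames(expr))
  if (length(no_expr) > 0) {
    if (missing_policy == "error")
      stopf("candidate TF(s) absent from expression: %s",
            paste(no_expr, collapse = ", "))
    dropped$no_expression <- no_expr
    tf_ids <- setdiff(tf_ids, no_expr)
  }
  if (length(tf_ids) == 0L) stopf("no candidate TF retained")
  Xr <- expr[, tf_ids, drop = FALSE]
  sds <- apply(Xr, 2, stats::sd)
  const <- tf_ids[sds == 0 | !is.finite(sds)]
  if (length(const) > 0) {
    warnf("dropping constant-expression TF(s): %s",
          paste(const, collapse = ", "))
    dropped$constant <- const
    tf_ids <- setdiff(tf_ids, const)
    if (length(tf_ids) == 0L) stopf("no candidate TF retained")
    Xr <- expr[, tf_ids, drop = FALSE]
  }
  sub_policy <- if (missing_policy == "drop") "drop" else missing_policy
  sub <- distance_submatrix(dsd, tf_ids, missing_policy = sub_policy)
  if (length(sub$dropped) > 0) {
    dropped$no_dsd <- sub$dropped
    tf_ids <- sub$tf_ids
    Xr <- expr[, tf_ids, drop = FALSE]
  }
  X <- scale(Xr)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  y <- expr[, tg] - mean(expr[, tg])
  prob <- regulation_problem(y, X, tf_ids = tf_ids, S = sub$S,
                             rho = rho, lam = lam,
                             k = min(as.integer(k), length(tf_ids)))
  attr(prob, "dropped") <- dropped
  prob
}
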