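#' Per-species TPM normalization
#'
#' `TPM_{g,s} = 1e6 * (c_{g,s} / l_g) / sum_h (c_{h,s} / l_h)`, computed on
#' one organism's counts at a time.  Because the denominator runs over that
#' organism's genes only, the result is invariant to the fraction of the
#' library the other species consumed — this is what makes per-species TPM
#' the right representation for mixed-species xenograft samples.
#'
#' @param counts A [count_matrix()] for a single organism, carrying per-gene
#'   effective lengths.
#' @return An [expression_matrix()] tagged `"TPM"`; columns sum to 1e6.
#'   All-zero input columns stay all-zero and are listed in the
#'   `zero_columns` attribute.
#' @export
tpm <- function(counts) {
  if (!inherits(counts, "count_matrix"))
    stop("tpm() expects a count_matrix (per-species counts with lengths)")
  lens <- attr(counts, "lengths")
  rate <- unclass(counts) / lens
  denom <- colSums(rate)
  zero_cols <- colnames(counts)[denom == 0]
  denom[denom == 0] <- 1  # keep all-zero columns all-zero
  out <- sweep(rate, 2L, denom, "/") * 1e6
  res <- expression_matrix(out, attr(counts, "organism"), "TPM")
  attr(res, "zero_columns") <- zero_cols
  res
}

#' Log2 transform of TPM values
#'
#' `value -> log2(value + 1)`; the pseudocount keeps zeros at zero.
#'
#' @param expr An [expression_matrix()] tagged `"TPM"`.
#' @return The matrix tagged `c("TPM", "log2TPM")`.
#' @export
log_transform <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  tags <- transforms_of(expr)
  if (length(tags) == 0L || tags[length(tags)] != "TPM")
    stop("log_transform() expects a matrix whose last transform is 'TPM'")
  if (any(expr < 0)) stop("negative values cannot be log-transformed")
  with_transform(expr, log2(unclass(expr) + 1), "log2TPM")
}

#' Remove genes that are zero across all samples
#'
#' @param expr An [expression_matrix()] (any transform state).
#' @return The matrix with exactly the all-zero rows removed; row order
#'   otherwise preserved.  Dropped gene ids are recorded in the
#'   `dropped_genes` attribute.
#' @export
drop_all_zero_genes <- function(expr) {
  stopifnot(is.matrix(expr))
  keep <- rowSums(unclass(expr) != 0) > 0
  out <- expr[keep, , drop = FALSE]
  attr(out, "dropped_genes") <- rownames(expr)[!keep]
  out
}

#' Expression prefilter ahead of differential testing
#'
#' Keeps a gene iff (a) its expression exceeds `min_expr` in at least
#' `ceiling(min_frac * n_samples)` samples, and (b) its max/min intensity
#' ratio exceeds `ratio_threshold`, with 1 added to the minimum only when
#' the minimum is zero (division guard).  The literal `> 0.5` ratio clause
#' is almost always satisfied; it is kept as printed with the threshold
#' exposed.
#'
#' @param counts Matrix of expression values (counts or TPM).
#' @param min_expr Expression threshold (default 0.5).
#' @param min_frac Fraction of samples that must exceed it (default 0.10).
#' @param ratio_threshold Max/min ratio threshold (default 0.5).
#' @return The filtered matrix; dropped gene ids in the `dropped_genes`
#'   attribute.
#' @export
de_prefilter <- function(counts, min_expr = 0.5, min_frac = 0.10,
                         ratio_threshold = 0.5) {
  stopifnot(min_expr > 0, min_frac > 0, ratio_threshold > 0)
  m <- unclass(counts)
  need <- ceiling(min_frac * ncol(m))
  expressed <- rowSums(m > min_expr) >= need
  rmin <- apply(m, 1L, min); rmax <- apply(m, 1L, max)
  ratio <- rmax / (rmin + (rmin == 0))
  keep <- expressed & ratio > ratio_threshold
  out <- counts[keep, , drop = FALSE]
  attr(out, "dropped_genes") <- rownames(m)[!keep]
  out
}

#' Upper-quantile normalization (log scale)
#'
#' Shifts each column additively on the log scale so that its 75th
#' percentile, computed over the genes nonzero in that column, equals the
#' cross-column mean of those percentiles.  Zero entries (undetected genes)
#' are left at zero, which makes the operation idempotent.  An additive
#' shift on the log scale is a scaling on the linear scale.
#'
#' @param expr Log-scale [expression_matrix()].
#' @param p Quantile to align (default 0.75).
#' @return The matrix tagged `"uq_normalized"`.
#' @export
upper_quantile_normalize <- function(expr, p = 0.75) {
  m <- unclass(expr)
  q <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j][m[, j] != 0]
    if (!length(v)) NA_real_ else quantile(v, p, names = FALSE)
  }, numeric(1))
  if (anyNA(q)) {
    warning("all-zero column(s) skipped: ",
            paste(colnames(m)[is.na(q)], collapse = ", "))
  }
  target <- mean(q, na.rm = TRUE)
  for (j in seq_len(ncol(m))) {
    if (is.na(q[j])) next
    nz <- m[, j] != 0
    m[nz, j] <- m[nz, j] - q[j] + target
  }
  if (inherits(expr, "expression_matrix"))
    with_transform(expr, m, "uq_normalized")
  else m
}

#' Center every row at its median
#'
#' @param expr Matrix or [expression_matrix()].
#' @return The row-median-centered matrix (tag `"median_centered"` when the
#'   input carries transforms).
#' @export
median_center_rows <- function(expr) {
  m <- unclass(expr)
  m <- m - apply(m, 1L, median)
  if (inherits(expr, "expression_matrix"))
    with_transform(expr, m, "median_centered")
  else m
}

#' Top variable genes
#'
#' The `n` genes with the largest sample variances; ties broken by gene id
#' lexicographically for a deterministic result.
#'
#' @param expr Genes-by-samples matrix.
#' @param n Number of genes to return (default 2000).
#' @return Character vector of gene ids, highest variance first.
#' @export
top_variable_genes <- function(expr, n = 2000L) {
  m <- unclass(expr)
  if (n > nrow(m)) stop("n exceeds the number of genes")
  v <- apply(m, 1L, var)
  ord <- order(-v, rownames(m))
  rownames(m)[ord][seq_len(n)]
}

#' Correlation-based label-swap quality control
#'
#' Infers each sample's profile line as the line whose labelled samples
#' have the highest *median* Pearson correlation with it (the median makes
#' the inference robust to the mislabelled samples themselves — a single
#' swapped neighbour cannot drag its whole line along).  Samples whose
#' inferred line differs from their labelled line are flagged; a pair of
#' flagged samples whose labels resolve each other (each one's inferred
#' line is the other's label) is reported as a suspected physical swap.
#'
#' @param expr Genes-by-samples expression matrix (log2 TPM recommended).
#' @param metadata Data frame with `sample_id` and `line_id`.
#' @return Data frame of flagged samples (`sample_id`, `labeled_line`,
#'   `inferred_line`, `median_cor`, `mutual`); zero rows when nothing is
#'   flagged or fewer than two samples are supplied.
#' @export
correlation_qc <- function(expr, metadata) {
  empty <- data.frame(sample_id = character(), labeled_line = character(),
                      inferred_line = character(), median_cor = numeric(),
                      mutual = logical(), stringsAsFactors = FALSE)
  m <- unclass(expr)
  if (ncol(m) < 2L) return(empty)
  line_of <- setNames(metadata$line_id, metadata$sample_id)[colnames(m)]
  lines <- sort(unique(line_of))
  if (length(lines) < 2L) return(empty)
  cc <- cor(m)
  # per sample, per line: median correlation to that line's labelled
  # samples, excluding the sample itself
  med_cor <- vapply(lines, function(l) {
    vapply(colnames(m), function(s) {
      grp <- setdiff(colnames(m)[line_of == l], s)
      if (!length(grp)) return(-Inf)
      median(cc[s, grp])
    }, numeric(1))
  }, numeric(ncol(m)))
  inferred <- lines[apply(med_cor, 1L, which.max)]
  names(inferred) <- colnames(m)
  flagged <- colnames(m)[inferred != line_of]
  if (!length(flagged)) return(empty)
  mutual <- vapply(flagged, function(a) {
    any(vapply(setdiff(flagged, a), function(b)
      line_of[[a]] == inferred[[b]] && line_of[[b]] == inferred[[a]],
      logical(1)))
  }, logical(1))
  data.frame(
    sample_id = flagged,
    labeled_line = unname(line_of[flagged]),
    inferred_line = unname(inferred[flagged]),
    median_cor = vapply(flagged, function(s)
      med_cor[match(s, colnames(m)), match(inferred[[s]], lines)],
      numeric(1)),
    mutual = unname(mutual),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Hierarchical clustering with Pearson distance and Ward linkage
#'
#' Distance `1 - r` between sample columns, agglomerated with `ward.D2`.
#'
#' @param expr Genes-by-samples matrix.
#' @return An `hclust` object (over samples).
#' @export
hcluster <- function(expr) {
  m <- unclass(expr)
  d <- stats::as.dist(1 - cor(m))
  hclust(d, method = "ward.D2")
}

#' PCA sample scores
#'
#' Rows (genes) are centered and unit-scaled before decomposition;
#' zero-variance rows are dropped.  Component signs are fixed by making the
#' largest-magnitude loading of each component positive.
#'
#' @param expr Genes-by-samples matrix.
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components), `loadings`,
#'   `variance_explained` (fraction per component).
#' @export
pca_scores <- function(expr, n_components = 2L) {
  m <- unclass(expr)
  keep <- apply(m, 1L, var) > 0
  m <- m[keep, , drop = FALSE]
  pc <- prcomp(t(m), center = TRUE, scale. = TRUE)
  n_components <- min(n_components, ncol(pc$x))
  flip <- vapply(seq_len(n_components), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2L, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(n_components), drop = FALSE],
                    2L, flip, "*")
  list(scores = scores, loadings = loadings,
       variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[
         seq_len(n_components)])
}

#' Merge two expression cohorts on a shared gene namespace
#'
#' Column-wise concatenation restricted to `gene_subset` intersected with
#' the genes present in both matrices (e.g. merging a PDX cohort with an
#' external cohort on a signature gene list).  Values pass through
#' untransformed.
#'
#' @param expr_a,expr_b Genes-by-samples matrices.
#' @param gene_subset Character vector of genes to keep (default: all
#'   shared genes).
#' @return Matrix over the common genes; attributes `origin` (per-column
#'   cohort label) and `missing_genes` (requested genes absent from either
#'   input).
#' @export
merge_cohorts <- function(expr_a, expr_b,
                          gene_subset = intersect(rownames(expr_a),
                                                  rownames(expr_b))) {
  shared <- intersect(intersect(gene_subset, rownames(expr_a)),
                      rownames(expr_b))
  missing <- setdiff(gene_subset, shared)
  a <- unclass(expr_a)[shared, , drop = FALSE]
  b <- unclass(expr_b)[shared, , drop = FALSE]
  out <- cbind(a, b)
  attr(out, "origin") <- c(rep("a", ncol(a)), rep("b", ncol(b)))
  attr(out, "missing_genes") <- missing
  out
}

#' Filter samples by mapped read count
#'
#' Keeps samples with strictly more than `min_reads` mapped reads of the
#' focal organism (default 10 million, the subtyping depth threshold).
#'
#' @param metadata Data frame with `sample_id` and a mapped-read-count
#'   column.
#' @param min_reads Strict lower bound (default 1e7).
#' @param column Name of the mapped-read-count column.
#' @return Character vector of retained sample ids.
#' @export
filter_by_mapped_reads <- function(metadata, min_reads = 1e7,
                                   column = "human_mapped_reads") {
  stopifnot(column %in% names(metadata) || nrow(metadata) == 0L)
  if (nrow(metadata) == 0L) return(character(0))
  metadata$sample_id[metadata[[column]] > min_reads]
}

#' Nearest-centroid classification
#'
#' Assigns each sample the class of the user-supplied centroid it
#' correlates best with (Spearman by default).  A generic stand-in for
#' trained subtype classifiers: the centroid matrix is an input, not a
#' shipped model.
#'
#' @param expr Genes-by-samples matrix.
#' @param centroid_matrix Genes-by-classes matrix of centroids (shared gene
#'   namespace with `expr`).
#' @param method Correlation method (default `"spearman"`).
#' @return Data frame `sample_id`, `class` (ties give `"unclassified"`),
#'   `score` (best correlation).
#' @export
nearest_centroid <- function(expr, centroid_matrix, method = "spearman") {
  shared <- intersect(rownames(expr), rownames(centroid_matrix))
  if (!length(shared)) stop("no shared genes with the centroid matrix")
  e <- unclass(expr)[shared, , drop = FALSE]
  ce <- unclass(centroid_matrix)[shared, , drop = FALSE]
  cc <- cor(e, ce, method = method)
  best <- apply(cc, 1L, function(r) {
    top <- max(r)
    hits <- colnames(ce)[r == top]
    c(class = if (length(hits) == 1L) hits else "unclassified",
      score = top)
  })
  data.frame(sample_id = colnames(e), class = unname(best["class", ]),
             score = as.numeric(best["score", ]),
             stringsAsFactors = FALSE, row.names = NULL)
}
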