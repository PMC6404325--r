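#' Parse a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member genes.
#' Duplicate members within a set are collapsed; empty sets and malformed
#' lines (< 3 fields) are rejected with the offending line number.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids; the `description`
#'   attribute keeps each set's description field.
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields")
  nms <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ", nms[duplicated(nms)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  empty <- which(vapply(sets, length, integer(1)) == 0L)
  if (length(empty))
    stop("empty gene set at line ", empty[1])
  names(sets) <- nms
  attr(sets, "description") <- setNames(
    vapply(fields, `[`, character(1), 2L), nms)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(collection, path, description = "na") {
  description <- rep_len(description, length(collection))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], description[i], collection[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# positions (in the descending-expression ordering, ties broken by gene id)
# of each gene; shared by the score and matrix forms
rank_positions <- function(values, gene_ids) {
  order(-values, gene_ids)
}

# single-sample enrichment score from ordered membership.
# With genes ranked 1..N by descending expression, rank weight
# r_i = N - i + 1, in-set weight w_i = r_i^alpha:
#   ES = sum_i [P_in(i) - P_out(i)]
# which collapses to a closed form over member positions (each gene's step
# persists for the N - pos + 1 positions at and after it).
es_from_positions <- function(member_pos, n, alpha) {
  n_in <- length(member_pos)
  if (n_in == 0L) stop("undefined score: no gene-set member present")
  if (n_in == n) return(0)
  w <- (n - member_pos + 1)^alpha
  persist <- n - member_pos + 1
  sum_p_in <- sum(w * persist) / sum(w)
  sum_p_out <- (n * (n + 1) / 2 - sum(persist)) / (n - n_in)
  sum_p_in - sum_p_out
}

#' Single-sample GSEA enrichment score
#'
#' Ranks the sample's genes by descending expression (ties broken by gene
#' id), weights in-set genes by `rank^alpha`, and accumulates the running
#' difference between the normalized in-set weight CDF and the uniform
#' out-of-set CDF; the score is the sum of that difference over all
#' positions.
#'
#' @param values Named numeric expression vector for one sample.
#' @param gene_set Character vector of member gene ids.
#' @param alpha Rank-weight exponent (default 0.25).
#' @return Numeric enrichment score.
#' @export
ssgsea_score <- function(values, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(values)))
  ord <- rank_positions(values, names(values))
  member <- names(values)[ord] %in% gene_set
  es_from_positions(which(member), length(values), alpha)
}

#' ssGSEA scores for a whole collection
#'
#' One enrichment score per gene set per sample, on an expression matrix
#' the caller has already restricted to samples dominated by the focal
#' organism (see [sample_fraction_filter()]).  With `normalize = TRUE` all
#' scores are divided by the range (max - min) of the whole matrix.
#'
#' @param expr Genes-by-samples matrix (log2 TPM recommended: scores are
#'   rank-based, so any monotone per-sample transform gives the same
#'   result).
#' @param collection Named list of gene-id vectors.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Divide by the matrix-wide score range (default TRUE).
#' @return Sets-by-samples numeric matrix.
#' @export
ssgsea_matrix <- function(expr, collection, alpha = 0.25,
                          normalize = TRUE) {
  if (length(collection) == 0L) stop("empty gene-set collection")
  m <- unclass(expr)
  genes <- rownames(m)
  es <- matrix(NA_real_, length(collection), ncol(m),
               dimnames = list(names(collection), colnames(m)))
  member_idx <- lapply(collection, function(s) which(genes %in% s))
  if (any(vapply(member_idx, length, integer(1)) == 0L))
    stop("undefined score: gene set(s) with no member present: ",
         paste(names(collection)[
           vapply(member_idx, length, integer(1)) == 0L][1:1],
           collapse = ", "))
  for (j in seq_len(ncol(m))) {
    ord <- rank_positions(m[, j], genes)
    pos_of <- integer(length(genes))
    pos_of[ord] <- seq_along(ord)
    for (k in seq_along(collection))
      es[k, j] <- es_from_positions(sort(pos_of[member_idx[[k]]]),
                                    length(genes), alpha)
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  es
}

#' Per-line tumor-vs-metastasis enrichment-score differences
#'
#' For every gene set and PDX line: mean enrichment score over that line's
#' metastasis samples minus the mean over its mammary-tumor samples.
#'
#' @param es Sets-by-samples enrichment matrix from [ssgsea_matrix()].
#' @param metadata Data frame with `sample_id`, `line_id` and the grouping
#'   column.
#' @param group_col Metadata column holding the group labels (default
#'   `"tissue"`).
#' @param met_values Labels counting as metastasis (default the `met_*`
#'   tissues).
#' @param tumor_values Labels counting as mammary tumor (default `"MGT"`).
#' @return Sets-by-lines matrix of differences (only lines with at least
#'   one sample in each group).
#' @export
es_group_difference <- function(es, metadata, group_col = "tissue",
                                met_values = c("met_liver", "met_lung",
                                               "met_brain"),
                                tumor_values = "MGT") {
  meta <- metadata[match(colnames(es), metadata$sample_id), ]
  lines <- unique(meta$line_id)
  cols <- lapply(lines, function(l) {
    met <- which(meta$line_id == l & meta[[group_col]] %in% met_values)
    tum <- which(meta$line_id == l & meta[[group_col]] %in% tumor_values)
    if (!length(met) || !length(tum)) return(NULL)
    rowMeans(es[, met, drop = FALSE]) - rowMeans(es[, tum, drop = FALSE])
  })
  keep <- !vapply(cols, is.null, logical(1))
  out <- do.call(cbind, cols[keep])
  colnames(out) <- lines[keep]
  out
}

#' Cross-line sum-of-enrichment-scores ranking
#'
#' Sums the per-line (metastasis - tumor) enrichment-score differences
#' across PDX lines and ranks gene sets by the descending sum: the ranking
#' that surfaces programs commonly activated in metastases across lines.
#'
#' @param differences Sets-by-lines matrix from [es_group_difference()].
#' @return Data frame: `set`, one column per line, `sum`, `rank`
#'   (rank 1 = largest sum; ties broken by set name).
#' @export
sum_es_ranking <- function(differences) {
  stopifnot(is.matrix(differences))
  sums <- rowSums(differences)
  ord <- order(-sums, rownames(differences))
  out <- data.frame(set = rownames(differences)[ord],
                    differences[ord, , drop = FALSE],
                    sum = sums[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  attr(out, "n_lines") <- ncol(differences)
  out
}

#' Mean signature score
#'
#' Unweighted per-sample mean of the listed genes' expression values, over
#' the genes present in the matrix.  Missing genes are reported in the
#' `missing_genes` attribute; if none of the listed genes is present the
#' call errors.
#'
#' @param expr Genes-by-samples matrix.
#' @param genes Character vector of signature gene ids.
#' @return Named numeric vector of per-sample scores.
#' @export
mean_signature_score <- function(expr, genes) {
  m <- unclass(expr)
  present <- intersect(genes, rownames(m))
  if (!length(present))
    stop("none of the signature genes is present in the matrix")
  out <- colMeans(m[present, , drop = FALSE])
  attr(out, "missing_genes") <- setdiff(genes, present)
  out
}

# one-way two-group ANOVA (equal-variance F test); handles the degenerate
# zero-residual-variance case explicitly
anova_two_group <- function(x, idx_a, idx_b) {
  a <- x[idx_a]; b <- x[idx_b]
  n <- length(a) + length(b)
  grand <- mean(c(a, b))
  ss_between <- length(a) * (mean(a) - grand)^2 +
    length(b) * (mean(b) - grand)^2
  ss_within <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  if (ss_within == 0) {
    p <- if (ss_between == 0) 1 else 0
    return(c(F = if (ss_between == 0) 0 else Inf, p = p))
  }
  f <- (ss_between / 1) / (ss_within / (n - 2))
  c(F = f, p = pf(f, 1, n - 2, lower.tail = FALSE))
}

#' Attribute signature genes to the host compartment by ANOVA
#'
#' Tests each candidate gene of a human-derived metastasis signature in the
#' host (mouse) expression matrix: one-way ANOVA between `group_a` (e.g.
#' livers bearing metastases) and `group_b` (e.g. normal livers).  Genes
#' significant at `p_threshold` and higher in `group_a` are attributed to
#' the host microenvironment response rather than to the cancer cells.
#'
#' Candidates are mapped into the host gene namespace by case-insensitive
#' symbol equality unless an explicit two-column `gene_map` is given.
#'
#' @param candidate_genes Character vector of signature gene ids (human
#'   namespace).
#' @param host_expr Mouse genes-by-samples expression matrix.
#' @param group_a,group_b Character vectors of sample ids (>= 2 each).
#' @param p_threshold ANOVA p-value cutoff (default 0.05).
#' @param direction `"up_in_a"` (default) or `"up_in_b"`.
#' @param gene_map Optional data frame with columns `from` (candidate id)
#'   and `to` (host id), overriding the symbol-equality mapping.
#' @return Data frame `gene`, `host_gene`, `F`, `p`, `mean_a`, `mean_b`,
#'   `retained`; candidates absent from the host matrix are reported in
#'   the `missing_genes` attribute.
#' @export
anova_origin_filter <- function(candidate_genes, host_expr, group_a,
                                group_b, p_threshold = 0.05,
                                direction = c("up_in_a", "up_in_b"),
                                gene_map = NULL) {
  direction <- match.arg(direction)
  m <- unclass(host_expr)
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L,
            all(c(group_a, group_b) %in% colnames(m)))
  if (is.null(gene_map)) {
    host <- rownames(m)[match(toupper(candidate_genes),
                              toupper(rownames(m)))]
  } else {
    stopifnot(all(c("from", "to") %in% names(gene_map)))
    host <- gene_map$to[match(candidate_genes, gene_map$from)]
    host[!host %in% rownames(m)] <- NA
  }
  found <- !is.na(host)
  idx_a <- match(group_a, colnames(m)); idx_b <- match(group_b, colnames(m))
  res <- t(vapply(host[found], function(g)
    anova_two_group(m[g, ], idx_a, idx_b), numeric(2)))
  mean_a <- vapply(host[found], function(g) mean(m[g, idx_a]), numeric(1))
  mean_b <- vapply(host[found], function(g) mean(m[g, idx_b]), numeric(1))
  up <- if (direction == "up_in_a") mean_a > mean_b else mean_b > mean_a
  out <- data.frame(gene = candidate_genes[found], host_gene = host[found],
                    F = res[, "F"], p = res[, "p"],
                    mean_a = mean_a, mean_b = mean_b,
                    retained = res[, "p"] < p_threshold & up,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "missing_genes") <- candidate_genes[!found]
  out
}

#' Filter samples by species read percentage
#'
#' Keeps samples whose percentage of reads from the focal organism is
#' strictly above `min_pct` (default 50): the rule used to decide which
#' samples have enough of a compartment's signal to score.
#'
#' @param metadata Data frame with `sample_id` and per-organism percentage
#'   columns (`human_pct`, `mouse_pct`, ...).
#' @param organism `"human"` or `"mouse"` (selects the column).
#' @param min_pct Strict lower bound (default 50).
#' @return Character vector of retained sample ids.
#' @export
sample_fraction_filter <- function(metadata, organism = "human",
                                   min_pct = 50) {
  col <- paste0(organism, "_pct")
  stopifnot(col %in% names(metadata) || nrow(metadata) == 0L)
  if (nrow(metadata) == 0L) return(character(0))
  metadata$sample_id[metadata[[col]] > min_pct]
}
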