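#' Median-of-ratios size factors
#'
#' `factor_s = median over genes g of c_{g,s} / geomean_g`, taken over genes
#' whose geometric mean across samples is positive, then rescaled so the
#' geometric mean of the factors is 1.  Falls back to library-size ratios
#' (with a warning) when no gene is nonzero in every sample.
#'
#' @param counts Genes-by-samples count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- unclass(counts)
  logm <- log(m)
  loggeo <- rowMeans(logm)
  use <- is.finite(loggeo)
  if (!any(use)) {
    warning("no gene is nonzero in every sample; ",
            "falling back to library-size ratios")
    sf <- colSums(m)
    if (any(sf == 0)) stop("sample(s) with zero total counts")
  } else {
    sf <- apply(logm[use, , drop = FALSE], 2L, function(lc)
      exp(median(lc - loggeo[use])))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

#' Per-gene method-of-moments NB dispersion
#'
#' On size-factor-normalized counts, `alpha_g = max((s^2 - mu) / mu^2,
#' floor)`.  When `groups` is supplied the moments are taken within each
#' group and combined as a df-weighted average, so planted condition
#' effects do not inflate the estimate.
#'
#' With few samples the per-gene estimate is very noisy, and genes whose
#' sample variance fluctuates low receive overconfident tests downstream.
#' `prior_df > 0` moderates each estimate toward the cross-gene median
#' `alpha_0` with `prior_df` pseudo-degrees of freedom:
#' `alpha_g <- (prior_df * alpha_0 + df_g * alpha_g) / (prior_df + df_g)`.
#' The default 0 is the bare per-gene estimator; [run_de()] uses
#' `prior_df = 10`.
#'
#' @param counts Genes-by-samples count matrix.
#' @param sf Size factors from [size_factors()].
#' @param groups Optional factor of condition labels per sample.
#' @param floor Lower bound on the estimate (default 1e-8).
#' @param prior_df Moderation weight toward the cross-gene median
#'   (default 0 = none).
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, sf, groups = NULL, floor = 1e-8,
                                prior_df = 0) {
  norm <- sweep(unclass(counts), 2L, sf, "/")
  mom <- function(x) {
    mu <- mean(x)
    if (mu <= 0) return(NA_real_)
    (var(x) - mu) / mu^2
  }
  if (is.null(groups)) {
    a <- apply(norm, 1L, mom)
    df <- ncol(norm) - 1L
  } else {
    groups <- as.factor(groups)
    idx <- split(seq_along(groups), groups)
    idx <- idx[vapply(idx, length, integer(1)) >= 2L]
    w <- vapply(idx, length, integer(1)) - 1L
    a <- apply(norm, 1L, function(x) {
      est <- vapply(idx, function(i) mom(x[i]), numeric(1))
      ok <- !is.na(est)
      if (!any(ok)) return(NA_real_)
      sum(est[ok] * w[ok]) / sum(w[ok])
    })
    df <- sum(w)
  }
  if (prior_df > 0 && sum(!is.na(a)) >= 2L) {
    alpha0 <- median(pmax(a, floor), na.rm = TRUE)
    a <- (prior_df * alpha0 + df * a) / (prior_df + df)
  }
  a[is.na(a)] <- floor
  setNames(pmax(a, floor), rownames(counts))
}

#' Differential-expression design with composition covariate
#'
#' Encodes the model `log mu = b0 + b1 * percent + sum b_c [condition = c]`
#' with the species read percentage as the nuisance covariate that absorbs
#' mixing variation across xenograft samples (the focal organism's percent:
#' mouse percent for the mouse matrix, human percent for the human matrix).
#'
#' @param percent Numeric per-sample percentage in \[0, 100\].
#' @param condition Character or factor of condition labels (e.g. MGT, Met,
#'   Normal).
#' @param contrast Length-2 character vector `c(B, A)`: test condition B
#'   versus reference A.
#' @param use_percent Include the percent covariate in the model matrix
#'   (`FALSE` gives the condition-only design used for comparison runs).
#' @return Object of class `de_design`.
#' @export
de_design <- function(percent, condition, contrast,
                      use_percent = TRUE) {
  stopifnot(length(percent) == length(condition),
            all(percent >= 0 & percent <= 100),
            length(contrast) == 2L,
            all(contrast %in% condition))
  condition <- stats::relevel(factor(condition), ref = contrast[2])
  tab <- table(condition)
  if (any(tab[contrast] < 2L))
    stop("each contrasted condition needs at least 2 samples")
  structure(list(percent = percent, condition = condition,
                 contrast = contrast, use_percent = use_percent),
            class = "de_design")
}

# model matrix for a de_design; drops the percent column when constant
design_matrix <- function(design) {
  pc <- design$percent - mean(design$percent)
  if (!isTRUE(design$use_percent) || var(pc) == 0) {
    if (isTRUE(design$use_percent))
      warning("percent covariate is constant; dropping it from the design")
    X <- stats::model.matrix(~ condition,
                             data = list(condition = design$condition))
  } else {
    X <- stats::model.matrix(~ pc + condition,
                             data = list(pc = pc,
                                         condition = design$condition))
  }
  X
}

#' Fit the per-gene negative-binomial GLM
#'
#' NB log-link GLM with `log(size_factor)` offset and the dispersion held
#' fixed, fitted by iteratively reweighted least squares (relative
#' tolerance 1e-8, at most 100 iterations).  Coefficients and standard
#' errors are reported on the log2 scale.
#'
#' @param y Integer count vector for one gene.
#' @param design A [de_design()].
#' @param sf Size factors.
#' @param dispersion The gene's NB dispersion.
#' @return List: `coefficients` and `se` (log2 scale, named), `converged`,
#'   `contrast_coef` (name of the tested coefficient).
#' @export
fit_gene_glm <- function(y, design, sf, dispersion) {
  X <- design_matrix(design)
  theta <- 1 / max(dispersion, 1e-8)
  fam <- MASS::negative.binomial(theta = theta, link = "log")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = log(sf),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100L)))
  p <- fit$rank
  pivot <- fit$qr$pivot[seq_len(p)]
  covmat <- tryCatch(
    chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]),
    error = function(e) matrix(NA_real_, p, p))
  se <- rep(NA_real_, ncol(X))
  se[pivot] <- sqrt(diag(covmat))
  names(se) <- colnames(X)
  list(coefficients = fit$coefficients / log(2),
       se = se / log(2),
       converged = isTRUE(fit$converged) && p == ncol(X),
       contrast_coef = paste0("condition", design$contrast[1]))
}

#' Wald test
#'
#' Two-sided normal test of `z = estimate / se`.
#'
#' @param estimate,se Numeric vectors (same length).
#' @return List with `stat` (z) and `pvalue`.
#' @export
wald_test <- function(estimate, se) {
  z <- estimate / se
  list(stat = z, pvalue = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotonicity
#' enforced).
#'
#' @param pvalues Numeric vector of p-values (NAs passed through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) p.adjust(pvalues, method = "BH")

# log2 fold change of group means on normalized counts (pseudocount guards
# empty means); used by the outlier heuristic, not by the GLM
lfc_of_means <- function(norm_row, idx_b, idx_a, pseudo = 0.5) {
  log2((mean(norm_row[idx_b]) + pseudo) / (mean(norm_row[idx_a]) + pseudo))
}

# flag genes whose apparent effect (>= 2-fold) vanishes in sign when one
# contrast sample is left out: a single-sample-driven call
outlier_flags <- function(norm, idx_a, idx_b) {
  both <- c(idx_a, idx_b)
  apply(norm, 1L, function(x) {
    full <- lfc_of_means(x, idx_b, idx_a)
    if (abs(full) < 1) return(FALSE)
    for (drop in both) {
      ia <- setdiff(idx_a, drop); ib <- setdiff(idx_b, drop)
      if (!length(ia) || !length(ib)) next
      if (sign(lfc_of_means(x, ib, ia)) != sign(full)) return(TRUE)
    }
    FALSE
  })
}

#' Composition-adjusted differential expression
#'
#' The full per-species DE stage: median-of-ratios size factors, per-gene
#' method-of-moments dispersion (within condition groups), NB GLM with the
#' design `~ percent + condition`, Wald test on the contrast coefficient,
#' independent filtering on the base mean, the NA-padj convention for
#' filtered and outlier-flagged genes, and Benjamini-Hochberg adjustment of
#' the rest.
#'
#' @param counts Genes-by-samples count matrix (already prefiltered with
#'   [de_prefilter()]).
#' @param metadata Data frame with `sample_id`, the condition column and
#'   the percent column; rows matched to count columns by `sample_id`.
#' @param contrast Length-2 character vector `c(B, A)`: condition B vs. A.
#' @param condition_col,percent_col Metadata column names (defaults
#'   `"tissue"`, `"human_pct"`; use `"mouse_pct"` for the mouse matrix).
#' @param alpha BH significance threshold used by independent filtering
#'   (default 0.05).
#' @param independent_filtering Scan 20 base-mean quantile cutoffs and keep
#'   the one maximizing rejections; genes below it get `padj = NA`.
#' @param outlier_flagging Give `padj = NA` to genes whose apparent fold
#'   change is driven by a single sample (see Details in the vignette).
#' @param use_covariate Include the percent covariate (set `FALSE` only for
#'   comparison runs).
#' @param prior_df Dispersion-moderation weight passed to
#'   [estimate_dispersion()] (default 10).
#' @return Data frame with columns `gene_id`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`; attributes
#'   `filter_threshold` (base-mean cutoff used) and `n_outliers`.
#' @export
run_de <- function(counts, metadata, contrast,
                   condition_col = "tissue", percent_col = "human_pct",
                   alpha = 0.05, independent_filtering = TRUE,
                   outlier_flagging = TRUE, use_covariate = TRUE,
                   prior_df = 10) {
  m <- unclass(counts)
  stopifnot(all(colnames(m) %in% metadata$sample_id))
  meta <- metadata[match(colnames(m), metadata$sample_id), ]
  condition <- meta[[condition_col]]
  design <- de_design(meta[[percent_col]], condition, contrast,
                      use_percent = use_covariate)

  sf <- size_factors(m)
  disp <- estimate_dispersion(m, sf, groups = design$condition,
                              prior_df = prior_df)
  norm <- sweep(m, 2L, sf, "/")
  idx_a <- which(design$condition == contrast[2])
  idx_b <- which(design$condition == contrast[1])
  base_mean <- rowMeans(norm[, c(idx_a, idx_b), drop = FALSE])

  n_genes <- nrow(m)
  lfc <- se <- stat <- pval <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    fit <- fit_gene_glm(m[g, ], design, sf, disp[g])
    if (!fit$converged) next
    b <- fit$coefficients[fit$contrast_coef]
    s <- fit$se[fit$contrast_coef]
    if (is.na(b) || is.na(s) || s <= 0) next
    lfc[g] <- b; se[g] <- s
    wt <- wald_test(b, s)
    stat[g] <- wt$stat; pval[g] <- wt$pvalue
  }

  outlier <- if (outlier_flagging) outlier_flags(norm, idx_a, idx_b)
             else rep(FALSE, n_genes)
  testable <- !is.na(pval) & !outlier

  padj <- rep(NA_real_, n_genes)
  threshold <- 0
  if (independent_filtering && sum(testable) > 0L) {
    cuts <- quantile(base_mean[testable], probs = seq(0, 0.95, length.out = 20),
                     names = FALSE)
    rejections <- vapply(cuts, function(ct) {
      sel <- testable & base_mean >= ct
      sum(bh_adjust(pval[sel]) <= alpha, na.rm = TRUE)
    }, numeric(1))
    threshold <- cuts[which.max(rejections)]  # ties: lowest cutoff wins
    sel <- testable & base_mean >= threshold
    padj[sel] <- bh_adjust(pval[sel])
  } else {
    padj[testable] <- bh_adjust(pval[testable])
  }

  out <- data.frame(gene_id = rownames(m), baseMean = base_mean,
                    log2FoldChange = lfc, lfcSE = se, stat = stat,
                    pvalue = pval, padj = padj,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "filter_threshold") <- threshold
  attr(out, "n_outliers") <- sum(outlier)
  out
}

#' Recurrent differential genes across PDX lines
#'
#' Keeps a gene when its direction-signed fold change meets
#' `fold_threshold` in at least `min_lines` of the per-line DE tables, and
#' (when `require_fdr`) `padj < fdr_threshold` in those same tables.
#' Mirrors the cross-line recurrence rules used for metastasis and
#' host-response gene lists (e.g. 2-fold in 6 of 7 lines at FDR < 0.05 for
#' the mouse liver response).
#'
#' @param de_tables Named list of [run_de()] result tables, one per PDX
#'   line.
#' @param fold_threshold Linear-scale fold-change threshold (default 2).
#' @param min_lines Minimum number of supporting lines.
#' @param direction `"up"` or `"down"`.
#' @param require_fdr Additionally require `padj < fdr_threshold` in the
#'   supporting lines.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return Data frame `gene_id`, `n_lines`, `mean_fold` sorted by support
#'   then mean fold change.
#' @export
recurrent_genes <- function(de_tables, fold_threshold = 2, min_lines,
                            direction = c("up", "down"),
                            require_fdr = FALSE, fdr_threshold = 0.05) {
  direction <- match.arg(direction)
  stopifnot(length(de_tables) >= 1L)
  genes <- sort(unique(unlist(lapply(de_tables, `[[`, "gene_id"))))
  sgn <- if (direction == "up") 1 else -1
  support <- matrix(FALSE, length(genes), length(de_tables),
                    dimnames = list(genes, names(de_tables)))
  fold <- matrix(NA_real_, length(genes), length(de_tables))
  rownames(fold) <- genes
  for (i in seq_along(de_tables)) {
    tab <- de_tables[[i]]
    f <- 2^(sgn * tab$log2FoldChange)
    ok <- !is.na(f) & f >= fold_threshold
    if (require_fdr)
      ok <- ok & !is.na(tab$padj) & tab$padj < fdr_threshold
    support[tab$gene_id, i] <- ok
    fold[tab$gene_id, i] <- f
  }
  n_lines <- rowSums(support)
  keep <- n_lines >= min_lines
  mean_fold <- vapply(which(keep), function(g)
    mean(fold[g, support[g, ]]), numeric(1))
  out <- data.frame(gene_id = genes[keep], n_lines = n_lines[keep],
                    mean_fold = mean_fold, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$n_lines, -out$mean_fold, out$gene_id), , drop = FALSE]
}
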