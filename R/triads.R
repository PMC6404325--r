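#' Define a sample triad
#'
#' A matched triple of sample groups from one PDX line: parental mammary
#' tumors, metastases derived from them, and mammary tumors regrown from
#' those metastases.  Comparing the three separates reversible
#' (microenvironment-induced) from heritable (metastasis-selected)
#' expression changes.
#'
#' @param line_id PDX line identifier.
#' @param parental_MGT,metastasis,MGT_from_met Character vectors of sample
#'   ids (>= 1 each).
#' @return Object of class `triad`.
#' @export
triad <- function(line_id, parental_MGT, metastasis, MGT_from_met) {
  groups <- list(parental_MGT = parental_MGT, metastasis = metastasis,
                 MGT_from_met = MGT_from_met)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("invalid triad: every passage role needs at least one sample")
  if (anyDuplicated(unlist(groups)))
    stop("invalid triad: a sample appears in more than one role")
  structure(c(list(line_id = line_id), groups), class = "triad")
}

#' Extract triads from sample metadata
#'
#' Groups samples by `line_id` and `passage_role` and builds a [triad()]
#' for every line carrying all three roles.
#'
#' @param metadata Data frame with `sample_id`, `line_id`, `passage_role`.
#' @return Named list of `triad` objects (possibly empty).
#' @export
triads_from_metadata <- function(metadata) {
  out <- list()
  for (l in unique(metadata$line_id)) {
    sub <- metadata[metadata$line_id == l, ]
    by_role <- split(sub$sample_id, sub$passage_role)
    roles <- c("parental_MGT", "metastasis", "MGT_from_met")
    if (all(roles %in% names(by_role)))
      out[[l]] <- triad(l, by_role$parental_MGT, by_role$metastasis,
                        by_role$MGT_from_met)
  }
  out
}

#' Per-gene fold changes within a triad
#'
#' On linear-scale expression (TPM), computes for every gene
#' `FC1 = (mean_met + c) / (mean_MGT + c)` and
#' `FC2 = (mean_regrown + c) / (mean_MGT + c)`, with group means over
#' replicate samples and pseudocount `c` guarding zeros.
#'
#' @param expr Linear-scale genes-by-samples matrix containing all triad
#'   samples.
#' @param triad A [triad()].
#' @param pseudocount Positive pseudocount (default 1).
#' @return Data frame `gene_id`, `fc_met`, `fc_regrown`.
#' @export
triad_fold_changes <- function(expr, triad, pseudocount = 1) {
  stopifnot(inherits(triad, "triad"), pseudocount > 0)
  m <- unclass(expr)
  missing <- setdiff(unlist(triad[c("parental_MGT", "metastasis",
                                    "MGT_from_met")]), colnames(m))
  if (length(missing))
    stop("invalid triad: sample(s) absent from the matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  gm <- function(ids) rowMeans(m[, ids, drop = FALSE])
  mgt <- gm(triad$parental_MGT)
  data.frame(gene_id = rownames(m),
             fc_met = (gm(triad$metastasis) + pseudocount) /
               (mgt + pseudocount),
             fc_regrown = (gm(triad$MGT_from_met) + pseudocount) /
               (mgt + pseudocount),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify genes as transient or selected
#'
#' Twofold-cutoff rules on the triad fold-change pair:
#' * `transient` — up at least `threshold`-fold in metastases
#'   (`fc_met >= threshold`) but reverted in the regrown tumor
#'   (`fc_regrown < threshold`): a microenvironment-induced change;
#' * `selected` — up in metastases and still up after regrowth
#'   (`fc_regrown >= threshold`): evidence of clonal selection;
#' * `down_transient` / `down_selected` — the mirrored classes for
#'   `fc_met <= 1/threshold`;
#' * `unchanged` — everything else.
#'
#' @param fc_pairs Data frame from [triad_fold_changes()].
#' @param threshold Fold-change cutoff > 1 (default 2).
#' @return The input with a `class` factor column appended; every gene
#'   receives exactly one class.
#' @export
classify_genes <- function(fc_pairs, threshold = 2) {
  stopifnot(threshold > 1,
            all(c("gene_id", "fc_met", "fc_regrown") %in% names(fc_pairs)))
  cls <- rep("unchanged", nrow(fc_pairs))
  up <- fc_pairs$fc_met >= threshold
  dn <- fc_pairs$fc_met <= 1 / threshold
  cls[up & fc_pairs$fc_regrown < threshold] <- "transient"
  cls[up & fc_pairs$fc_regrown >= threshold] <- "selected"
  cls[dn & fc_pairs$fc_regrown > 1 / threshold] <- "down_transient"
  cls[dn & fc_pairs$fc_regrown <= 1 / threshold] <- "down_selected"
  fc_pairs$class <- factor(cls, levels = c("transient", "selected",
                                           "down_transient",
                                           "down_selected", "unchanged"))
  fc_pairs
}

#' Summarize triad classifications across PDX lines
#'
#' @param classifications Named list (by line) of [classify_genes()]
#'   outputs.
#' @return List with `counts` (lines x classes table of gene counts) and
#'   `overlap` (data frame of gene/class pairs shared by >= 2 lines, with
#'   the supporting lines).
#' @export
summarize_triads <- function(classifications) {
  stopifnot(length(classifications) >= 1L)
  classes <- levels(classifications[[1]]$class)
  counts <- t(vapply(classifications, function(cl)
    table(cl$class)[classes], numeric(length(classes))))
  colnames(counts) <- classes
  long <- do.call(rbind, lapply(names(classifications), function(l) {
    cl <- classifications[[l]]
    keep <- cl$class != "unchanged"
    data.frame(line = l, gene_id = cl$gene_id[keep],
               class = as.character(cl$class)[keep],
               stringsAsFactors = FALSE)
  }))
  overlap <- data.frame(gene_id = character(), class = character(),
                        n_lines = integer(), lines = character(),
                        stringsAsFactors = FALSE)
  if (!is.null(long) && nrow(long)) {
    key <- paste(long$gene_id, long$class, sep = "\r")
    tab <- table(key)
    shared <- names(tab)[tab >= 2L]
    if (length(shared)) {
      parts <- strsplit(shared, "\r", fixed = TRUE)
      overlap <- data.frame(
        gene_id = vapply(parts, `[`, character(1), 1L),
        class = vapply(parts, `[`, character(1), 2L),
        n_lines = as.integer(tab[shared]),
        lines = vapply(shared, function(k)
          paste(sort(long$line[key == k]), collapse = ","), character(1)),
        stringsAsFactors = FALSE, row.names = NULL)
      overlap <- overlap[order(overlap$gene_id, overlap$class), ,
                         drop = FALSE]
    }
  }
  list(counts = counts, overlap = overlap)
}
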