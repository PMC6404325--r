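#' Build an organism-unique k-mer index over species references
#'
#' Stores every canonical k-mer (lexicographic minimum of the k-mer and its
#' reverse complement) of every transcript of every reference.  A k-mer
#' occurring in more than one organism is marked *shared* and carries no
#' species information; an organism-unique k-mer additionally remembers the
#' gene it occurs in (or that it occurs in several genes of its organism).
#' This plays the role of indexing a prefix-labelled concatenated genome for
#' unique alignment.
#'
#' @param references List of [species_reference()] objects (>= 1; >= 2 for
#'   classification to be meaningful).
#' @param k Odd k-mer length, 11 <= k <= 63.  Default 31, standard for
#'   species-level discrimination.
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(references, k = 31L) {
  k <- as.integer(k)
  if (k %% 2L != 1L || k < 11L || k > 63L)
    stop("k must be an odd integer in [11, 63]")
  refs <- if (inherits(references, "species_reference")) list(references)
          else references
  stopifnot(length(refs) >= 1L,
            all(vapply(refs, inherits, logical(1), "species_reference")))
  organisms <- vapply(refs, `[[`, character(1), "organism")
  if (anyDuplicated(organisms)) stop("duplicate organism prefixes")
  seqs <- character(0); org_idx <- integer(0); gene_ids <- character(0)
  for (i in seq_along(refs)) {
    r <- refs[[i]]
    short <- r$transcripts$transcript_id[r$transcripts$length < k]
    if (length(short))
      stop("transcript(s) shorter than k=", k, ": ",
           paste(utils::head(short, 3), collapse = ", "))
    seqs <- c(seqs, unname(r$sequences))
    org_idx <- c(org_idx, rep(i - 1L, length(r$sequences)))
    gene_ids <- c(gene_ids, r$transcripts$gene_id)
  }
  genes <- unique(gene_ids)
  gene_idx <- match(gene_ids, genes) - 1L
  ptr <- kmer_index_build_cpp(seqs, org_idx, gene_idx, organisms, genes, k)
  structure(list(ptr = ptr, k = k, organisms = organisms, genes = genes),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  s <- kmer_index_stats_cpp(x$ptr)
  cat("kmer_index: k =", s$k, "|", format(s$n_kmers, big.mark = ","),
      "k-mers (", s$n_shared, "shared )\n")
  print(s$n_unique)
  invisible(x)
}

#' Inspect a k-mer index
#'
#' `kmer_index_stats()` returns counts of stored, shared and
#' organism-unique k-mers; `kmer_index_query()` looks up canonical forms of
#' the supplied k-mers; `kmer_index_kmers()` returns every stored canonical
#' k-mer (small indexes only — intended for tests).
#'
#' @param index A `kmer_index`.
#' @rdname kmer_index_inspect
#' @export
kmer_index_stats <- function(index) kmer_index_stats_cpp(index$ptr)

#' @param kmers Character vector of k-mers to look up.
#' @rdname kmer_index_inspect
#' @export
kmer_index_query <- function(index, kmers) {
  res <- kmer_index_query_cpp(index$ptr, toupper(kmers))
  data.frame(kmer = kmers, organism = res$organism, gene = res$gene,
             stringsAsFactors = FALSE)
}

#' @rdname kmer_index_inspect
#' @export
kmer_index_kmers <- function(index) sort(kmer_index_keys_cpp(index$ptr))

#' Classify reads by organism-unique k-mer content
#'
#' Counts informative (organism-unique) k-mer hits per organism for each
#' read and applies uniqueness semantics: exactly one organism with at least
#' `min_informative` hits and no hits elsewhere assigns the read to that
#' organism; informative hits in two or more organisms discard the read as
#' `ambiguous`; no informative hits (including reads shorter than k) leave
#' it `unmapped`.
#'
#' @param reads Character vector of read sequences.
#' @param index A `kmer_index` built by [build_kmer_index()].
#' @param min_informative Minimum organism-unique k-mer hits required for an
#'   assignment (default 2, suppressing single-k-mer false hits under
#'   sequencing error).
#' @return Factor of labels with levels `organisms..., ambiguous, unmapped`.
#' @export
classify_read <- function(reads, index, min_informative = 2L) {
  stopifnot(inherits(index, "kmer_index"), min_informative >= 1L)
  res <- classify_reads_cpp(index$ptr, reads, as.integer(min_informative))
  labs <- c(index$organisms, "ambiguous", "unmapped")
  code <- res$label
  code[code == 0L] <- length(index$organisms) + 2L
  code[code == -1L] <- length(index$organisms) + 1L
  factor(labs[code], levels = labs)
}

#' Partition a read set by species
#'
#' Applies [classify_read()] to every read and aggregates per-class read
#' counts and per-organism gene-level counts.  A read's gene-level count
#' goes to the gene owning the plurality of its informative k-mer hits;
#' plurality ties are counted at the organism level only.
#'
#' @inheritParams classify_read
#' @return An object of class `partition_result`: `labels` (per-read
#'   factor), `class_counts` (named integer vector over organisms +
#'   ambiguous + unmapped), `gene_counts` (named list per organism of named
#'   integer vectors over that organism's genes with nonzero counts).
#' @export
partition_readset <- function(reads, index, min_informative = 2L) {
  stopifnot(inherits(index, "kmer_index"), min_informative >= 1L)
  if (length(index$organisms) < 2L)
    warning("index built over a single organism; ",
            "every mapped read will be assigned to it")
  labs <- c(index$organisms, "ambiguous", "unmapped")
  if (length(reads) == 0L) {
    return(structure(list(
      labels = factor(character(0), levels = labs),
      class_counts = setNames(integer(length(labs)), labs),
      gene_counts = setNames(
        rep(list(setNames(integer(0), character(0))),
            length(index$organisms)), index$organisms),
      n_reads = 0L),
      class = "partition_result"))
  }
  res <- classify_reads_cpp(index$ptr, reads, as.integer(min_informative))
  code <- res$label
  idx <- code
  idx[code == 0L] <- length(index$organisms) + 2L
  idx[code == -1L] <- length(index$organisms) + 1L
  labels <- factor(labs[idx], levels = labs)
  class_counts <- setNames(as.integer(table(labels)), labs)
  gene_counts <- lapply(seq_along(index$organisms), function(o) {
    sel <- which(code == o & !is.na(res$gene))
    tab <- table(index$genes[res$gene[sel]])
    setNames(as.integer(tab), names(tab))
  })
  names(gene_counts) <- index$organisms
  structure(list(labels = labels, class_counts = class_counts,
                 gene_counts = gene_counts, n_reads = length(reads)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("partition_result:", x$n_reads, "reads\n")
  print(x$class_counts)
  invisible(x)
}

#' Merge two partition results additively
#'
#' Models merging re-sequenced runs of the same library: class counts and
#' gene-level counts add; per-read labels are concatenated.
#'
#' @param a,b `partition_result` objects over the same organisms.
#' @return A merged `partition_result`.
#' @export
merge_partitions <- function(a, b) {
  stopifnot(inherits(a, "partition_result"),
            inherits(b, "partition_result"),
            identical(names(a$class_counts), names(b$class_counts)))
  add_named <- function(x, y) {
    all_n <- union(names(x), names(y))
    out <- setNames(integer(length(all_n)), all_n)
    out[names(x)] <- out[names(x)] + x
    out[names(y)] <- out[names(y)] + y
    out
  }
  structure(list(
    labels = factor(c(as.character(a$labels), as.character(b$labels)),
                    levels = levels(a$labels)),
    class_counts = a$class_counts + b$class_counts,
    gene_counts = setNames(lapply(names(a$gene_counts), function(o)
      add_named(a$gene_counts[[o]], b$gene_counts[[o]])),
      names(a$gene_counts)),
    n_reads = a$n_reads + b$n_reads),
    class = "partition_result")
}

#' Per-sample species composition
#'
#' Percentage of classified reads per retained organism:
#' `100 * organism reads / sum of retained organism reads`.  Ambiguous and
#' unmapped reads never enter the denominator, nor do organisms listed in
#' `exclude` (e.g. a viral reference).
#'
#' @param partition A `partition_result`.
#' @param exclude Character vector of organism labels to drop from the
#'   denominator.
#' @return Data frame with columns `organism`, `reads`, `pct`; attribute
#'   `reads_used` records the denominator.
#' @export
composition_stats <- function(partition, exclude = character()) {
  stopifnot(inherits(partition, "partition_result"))
  organisms <- setdiff(names(partition$class_counts),
                       c("ambiguous", "unmapped"))
  if (length(bad <- setdiff(exclude, organisms)))
    stop("exclude names organisms not present: ",
         paste(bad, collapse = ", "))
  keep <- setdiff(organisms, exclude)
  counts <- partition$class_counts[keep]
  total <- sum(counts)
  if (total == 0L)
    stop("undefined composition: zero retained classified reads")
  out <- data.frame(organism = keep, reads = as.integer(counts),
                    pct = 100 * as.numeric(counts) / total,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "reads_used") <- total
  out
}

#' Classify mate pairs
#'
#' Mates are classified independently; the fragment label is their agreement
#' when both mates agree, `ambiguous` when they name different organisms,
#' and the informative mate's label when the other is unmapped.
#'
#' @param mate1,mate2 Character vectors of mate sequences (parallel).
#' @inheritParams classify_read
#' @return Factor of fragment labels.
#' @export
classify_fragments <- function(mate1, mate2, index, min_informative = 2L) {
  stopifnot(length(mate1) == length(mate2))
  l1 <- classify_read(mate1, index, min_informative)
  l2 <- classify_read(mate2, index, min_informative)
  o1 <- as.character(l1); o2 <- as.character(l2)
  organism1 <- !(o1 %in% c("ambiguous", "unmapped"))
  organism2 <- !(o2 %in% c("ambiguous", "unmapped"))
  out <- o1
  # an unmapped mate defers to the informative one
  out[!organism1 & o1 == "unmapped"] <- o2[!organism1 & o1 == "unmapped"]
  # conflicting organism evidence, or any ambiguous mate, discards the pair
  out[organism1 & organism2 & o1 != o2] <- "ambiguous"
  out[o1 == "ambiguous" | o2 == "ambiguous"] <- "ambiguous"
  factor(out, levels = levels(l1))
}

#' Write a composition table as TSV
#'
#' One row per sample with per-organism percentage columns
#' (`human_pct`, `mouse_pct`, ...).
#'
#' @param compositions Named list of [composition_stats()] results, one per
#'   sample.
#' @param path Output TSV path.
#' @export
write_composition_tsv <- function(compositions, path) {
  rows <- lapply(names(compositions), function(s) {
    comp <- compositions[[s]]
    vals <- setNames(as.list(comp$pct), paste0(comp$organism, "_pct"))
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          as.data.frame(vals))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
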