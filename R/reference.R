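#' Species reference transcriptome
#'
#' A minimal transcriptome reference for one organism: a set of transcript
#' sequences with a transcript-to-gene map, every sequence name carrying an
#' organism-specific prefix.  Two such references play the role of the
#' prefix-labelled concatenated genome used to separate xenograft reads by
#' species.
#'
#' @param organism Short organism prefix (e.g. `"hs"`, `"mm"`); prepended to
#'   every transcript and gene identifier.
#' @param sequences Named character vector of nucleotide sequences; names are
#'   transcript identifiers.
#' @param gene_ids Character vector, same length as `sequences`: the gene each
#'   transcript belongs to.
#' @param ortholog_map Optional data frame with columns `gene_a`, `gene_b`
#'   pairing genes of this reference with genes of a partner reference;
#'   must be one-to-one.
#' @return An object of class `species_reference` with fields `organism`,
#'   `sequences`, `transcripts` (data frame: `transcript_id`, `gene_id`,
#'   `length`) and `ortholog_map`.
#' @export
species_reference <- function(organism, sequences, gene_ids,
                              ortholog_map = NULL) {
  stopifnot(is.character(organism), length(organism) == 1L, nzchar(organism),
            is.character(sequences), length(sequences) >= 1L,
            length(gene_ids) == length(sequences))
  tx_ids <- names(sequences)
  if (is.null(tx_ids) || anyDuplicated(tx_ids))
    stop("sequences must be uniquely named by transcript_id")
  if (!all(startsWith(tx_ids, organism)))
    stop("all transcript names must carry the organism prefix '",
         organism, "'")
  if (!is.null(ortholog_map)) {
    stopifnot(is.data.frame(ortholog_map),
              all(c("gene_a", "gene_b") %in% names(ortholog_map)))
    if (anyDuplicated(ortholog_map$gene_a) ||
        anyDuplicated(ortholog_map$gene_b))
      stop("ortholog_map must be one-to-one")
  }
  structure(list(
    organism = organism,
    sequences = sequences,
    transcripts = data.frame(
      transcript_id = tx_ids,
      gene_id = gene_ids,
      length = nchar(sequences),
      stringsAsFactors = FALSE, row.names = NULL),
    ortholog_map = ortholog_map
  ), class = "species_reference")
}

#' @export
print.species_reference <- function(x, ...) {
  cat("species_reference:", x$organism, "-", nrow(x$transcripts),
      "transcripts,", length(unique(x$transcripts$gene_id)), "genes\n")
  invisible(x)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Substitute each position independently with probability `rate`, always to a
# different base.  Used for the optional sequencing-error model.
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  hit <- which(runif(nchar(seq)) < rate)
  substitute_bases(seq, hit)
}

substitute_bases <- function(seq, positions) {
  if (!length(positions)) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  bases[positions] <- vapply(bases[positions],
                             function(b) sample(alt[[b]], 1L), character(1L))
  paste(bases, collapse = "")
}

#' Generate a pair of divergent species references
#'
#' Builds two single-transcript-per-gene references with distinct organism
#' prefixes.  The first `n_orthologs` gene pairs are orthologs: the second
#' organism's sequence is the first's with independent per-base substitutions
#' at rate `divergence` (binomially sampled positions, substitution always to
#' a different base).  All remaining sequences are independent uniform-random
#' nucleotides.  Deterministic for a fixed `seed`.
#'
#' @param n_genes Number of genes per organism (single transcript each).
#' @param n_orthologs Number of ortholog pairs; `<= n_genes`.
#' @param divergence Per-base substitution fraction between ortholog pairs,
#'   in (0, 1).
#' @param transcript_length Transcript length in bases.
#' @param seed Optional integer seed.
#' @param organisms Length-2 character vector of organism prefixes.
#' @return List of two `species_reference` objects; each carries the
#'   ortholog map (`gene_a` = first organism, `gene_b` = second).
#' @examples
#' refs <- generate_reference(20, n_orthologs = 5, divergence = 0.1,
#'                            transcript_length = 300, seed = 1)
#' refs$a
#' @export
generate_reference <- function(n_genes, n_orthologs = 0L, divergence = 0.10,
                               transcript_length = 1000L, seed = NULL,
                               organisms = c("hs", "mm")) {
  stopifnot(n_genes >= 1L, length(organisms) == 2L,
            organisms[1] != organisms[2])
  if (n_orthologs > n_genes)
    stop("n_orthologs must not exceed n_genes")
  if (n_orthologs > 0L && (divergence <= 0 || divergence >= 1))
    stop("divergence must lie strictly between 0 and 1")
  if (transcript_length < 2L)
    stop("transcript_length too short to be informative")
  if (!is.null(seed)) set.seed(seed)

  ids <- function(org) sprintf("%s_g%04d", org, seq_len(n_genes))
  gene_a <- ids(organisms[1]); gene_b <- ids(organisms[2])
  seq_a <- vapply(seq_len(n_genes), function(i) random_dna(transcript_length),
                  character(1L))
  seq_b <- character(n_genes)
  if (n_orthologs > 0L) {
    for (i in seq_len(n_orthologs)) {
      n_sub <- rbinom(1L, transcript_length, divergence)
      pos <- sample.int(transcript_length, n_sub)
      seq_b[i] <- substitute_bases(seq_a[i], pos)
    }
  }
  for (i in seq(from = n_orthologs + 1L, length.out = n_genes - n_orthologs))
    seq_b[i] <- random_dna(transcript_length)

  omap <- if (n_orthologs > 0L)
    data.frame(gene_a = gene_a[seq_len(n_orthologs)],
               gene_b = gene_b[seq_len(n_orthologs)],
               stringsAsFactors = FALSE)
  else NULL

  names(seq_a) <- paste0(gene_a, "_t1")
  names(seq_b) <- paste0(gene_b, "_t1")
  list(a = species_reference(organisms[1], seq_a, gene_a, omap),
       b = species_reference(organisms[2], seq_b, gene_b, omap))
}

#' Write / read a species reference as FASTA
#'
#' Sequence headers are `transcript_id gene_id`; the organism prefix on the
#' identifiers preserves species labelling through round trips.
#'
#' @param ref A `species_reference`.
#' @param path Output (input) FASTA path.
#' @rdname reference_fasta
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "species_reference"))
  x <- Biostrings::DNAStringSet(ref$sequences)
  names(x) <- paste(ref$transcripts$transcript_id, ref$transcripts$gene_id)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @param organism Organism prefix of the reference being read.
#' @rdname reference_fasta
#' @export
read_reference_fasta <- function(path, organism) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), " ", fixed = TRUE)
  tx <- vapply(parts, `[`, character(1L), 1L)
  gene <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else p[1L],
                 character(1L))
  seqs <- as.character(x)
  names(seqs) <- tx
  species_reference(organism, seqs, gene)
}
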