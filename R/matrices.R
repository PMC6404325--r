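#' Count and expression matrix containers
#'
#' Thin wrappers around a numeric `genes x samples` matrix.  A
#' `count_matrix` carries the organism label and per-gene effective lengths
#' (needed for TPM); an `expression_matrix` carries the organism label and an
#' append-only chain of applied transforms (`"TPM"`, `"log2TPM"`,
#' `"uq_normalized"`, `"median_centered"`).
#'
#' @param x Numeric matrix with unique rownames (gene ids) and colnames
#'   (sample ids).
#' @param organism Organism label (e.g. `"human"`).
#' @param lengths Named numeric vector of per-gene effective lengths in
#'   bases; names must cover rownames of `x`.
#' @return The matrix with class `count_matrix` prepended.
#' @export
count_matrix <- function(x, organism, lengths) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)),
            !anyDuplicated(rownames(x)), !anyDuplicated(colnames(x)))
  if (any(x < 0)) stop("counts must be non-negative")
  if (!all(rownames(x) %in% names(lengths)))
    stop("missing length for gene(s): ",
         paste(utils::head(setdiff(rownames(x), names(lengths)), 5),
               collapse = ", "))
  lengths <- lengths[rownames(x)]
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  structure(x, organism = organism, lengths = lengths,
            class = c("count_matrix", class(x)))
}

#' @param transforms Character vector of transform tags already applied.
#' @rdname count_matrix
#' @export
expression_matrix <- function(x, organism, transforms = character()) {
  stopifnot(is.matrix(x), !is.null(colnames(x)),
            !anyDuplicated(colnames(x)))
  if (nrow(x) > 0L)  # R drops rownames entirely on empty selections
    stopifnot(!is.null(rownames(x)), !anyDuplicated(rownames(x)))
  structure(x, organism = organism, transforms = transforms,
            class = c("expression_matrix", class(x)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix [", attr(x, "organism"), "]: ", nrow(x), " genes x ",
      ncol(x), " samples\n", sep = "")
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix [", attr(x, "organism"), "]: ", nrow(x),
      " genes x ", ncol(x), " samples; transforms: ",
      paste(attr(x, "transforms"), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

transforms_of <- function(x) attr(x, "transforms")

# rebuild an expression_matrix from a plain matrix, appending a tag
with_transform <- function(template, mat, tag) {
  expression_matrix(mat, organism = attr(template, "organism"),
                    transforms = c(transforms_of(template), tag))
}

# subsetting drops to plain matrix attributes; keep metadata when possible
#' @export
`[.count_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- count_matrix(out, attr(x, "organism"),
                        attr(x, "lengths")[rownames(out)])
  out
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- expression_matrix(out, attr(x, "organism"), transforms_of(x))
  out
}

#' Read and write genes-by-samples TSV matrices
#'
#' The on-disk layout is one header row of sample ids, a leading `gene_id`
#' column, and (for counts) an optional `length` column holding effective
#' gene lengths.
#'
#' @param x A `count_matrix` or `expression_matrix` (or plain matrix).
#' @param path TSV file path.
#' @rdname matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)[, ,
                   drop = FALSE]), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (inherits(x, "count_matrix"))
    df <- cbind(df[1], length = as.numeric(attr(x, "lengths")), df[-1])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param organism Organism label to attach on read.
#' @param counts Logical; read as `count_matrix` (expects a `length`
#'   column) rather than `expression_matrix`.
#' @rdname matrix_tsv
#' @export
read_matrix_tsv <- function(path, organism = "human", counts = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("gene_id" %in% names(df))
  genes <- df$gene_id
  if (counts) {
    stopifnot("length" %in% names(df))
    lens <- setNames(df$length, genes)
    m <- as.matrix(df[, setdiff(names(df), c("gene_id", "length")),
                      drop = FALSE])
    rownames(m) <- genes
    count_matrix(m, organism, lens)
  } else {
    m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
    rownames(m) <- genes
    expression_matrix(m, organism)
  }
}

#' Read / write sample metadata TSV
#'
#' One row per sample; expected columns include `sample_id`, `line_id`,
#' `tissue`, `passage_role`, `human_pct`, `mouse_pct`,
#' `human_mapped_reads`.
#'
#' @param metadata Data frame of sample annotations.
#' @param path TSV path.
#' @rdname metadata_tsv
#' @export
write_metadata_tsv <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

TISSUE_LEVELS <- c("MGT", "met_liver", "met_lung", "met_brain",
                   "normal_liver", "normal_lung", "normal_brain",
                   "human_control")
PASSAGE_ROLES <- c("parental_MGT", "metastasis", "MGT_from_met", "none")
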