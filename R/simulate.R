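#' Simulation design for a synthetic xenograft cohort
#'
#' Describes a cohort of mixed-species RNA-seq samples: how many genes each
#' organism contributes, the per-sample plan (PDX line, tissue, passage role,
#' true human read fraction, library size), the planted per-gene effects, and
#' the negative-binomial noise level.  Gene-level nuisance parameters (base
#' abundance, effective length, per-gene composition sensitivity, per-line
#' expression offsets) are drawn once at construction from `seed`, so a
#' design fully determines every downstream simulation.
#'
#' Planted effects are named log2 fold-change vectors over gene ids:
#' * `human_met` — applied to human genes in every metastasis sample
#'   (metastasis vs. mammary tumor program),
#' * `human_transient` — applied in metastases only; reverts in tumors
#'   regrown from metastases (microenvironment-induced),
#' * `human_selected` — applied in metastases *and* in regrown tumors
#'   (metastasis-selected),
#' * `mouse_met` — applied to mouse genes in `met_*` tissues relative to the
#'   matching normal organ (host response).
#'
#' The optional per-gene composition sensitivity makes a sample's expected
#' count scale as `fraction^gamma_g` with `gamma_g ~ N(1, sd)` instead of
#' exactly linearly in the species fraction; with `sd = 0` (default) the
#' fraction is a purely global column scaling.  A nonzero `sd` models the
#' gene-specific coupling between composition and measured expression
#' (mapping bleed-through, depth-dependent dropout) that the percent
#' covariate of the differential-expression stage exists to absorb.
#'
#' @param sample_plan Data frame with columns `sample_id`, `line_id`,
#'   `tissue` (one of `r paste(TISSUE_LEVELS, collapse=", ")`),
#'   `passage_role` (one of `r paste(PASSAGE_ROLES, collapse=", ")`),
#'   `human_fraction` in \[0, 1\], `library_size` (expected total reads).
#' @param n_genes Named integer vector `c(human = ..., mouse = ...)`.
#' @param effects List of named numeric log2 fold-change vectors (see
#'   Details); genes absent from a vector have effect 0.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   `0` gives Poisson noise.
#' @param fraction_sensitivity_sd SD of the per-gene composition-sensitivity
#'   exponent around 1; `0` disables.
#' @param line_effect_sd SD of per-line log2 baseline offsets on human genes;
#'   `0` disables (used to give PDX lines distinguishable profiles).
#' @param gene_sets Optional named list of gene-id character vectors
#'   (a planted gene-set collection for enrichment analyses).
#' @param seed Integer RNG seed; all gene-level parameters and all
#'   downstream simulations are deterministic given the design.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(sample_plan,
                       n_genes = c(human = 2000L, mouse = 500L),
                       effects = list(),
                       dispersion = 0.1,
                       fraction_sensitivity_sd = 0,
                       line_effect_sd = 0,
                       gene_sets = NULL,
                       seed = 1L) {
  need <- c("sample_id", "line_id", "tissue", "passage_role",
            "human_fraction", "library_size")
  stopifnot(is.data.frame(sample_plan), all(need %in% names(sample_plan)))
  if (nrow(sample_plan) == 0L) stop("sample plan is empty")
  if (anyDuplicated(sample_plan$sample_id)) stop("duplicate sample_id")
  if (!all(sample_plan$tissue %in% TISSUE_LEVELS))
    stop("unknown tissue in sample plan")
  if (!all(sample_plan$passage_role %in% PASSAGE_ROLES))
    stop("unknown passage_role in sample plan")
  if (any(sample_plan$human_fraction < 0 | sample_plan$human_fraction > 1))
    stop("human_fraction must lie in [0, 1]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  stopifnot(all(c("human", "mouse") %in% names(n_genes)))
  tr <- names(effects$human_transient); se <- names(effects$human_selected)
  if (length(intersect(tr, se)))
    stop("transient and selected gene sets must be disjoint")

  gene_ids <- list(
    human = sprintf("hs_g%04d", seq_len(n_genes[["human"]])),
    mouse = sprintf("mm_g%04d", seq_len(n_genes[["mouse"]])))
  universe <- unlist(gene_ids, use.names = FALSE)
  for (nm in names(effects)) {
    if (!all(names(effects[[nm]]) %in% universe))
      stop("effect table '", nm, "' names genes outside the gene universe")
  }
  if (!is.null(gene_sets) &&
      !all(unlist(gene_sets, use.names = FALSE) %in% universe))
    stop("planted gene sets must be subsets of the gene universe")

  set.seed(seed)
  gene_params <- lapply(c(human = "human", mouse = "mouse"), function(org) {
    n <- n_genes[[org]]
    data.frame(
      gene_id = gene_ids[[org]],
      length = pmax(200, round(stats::rlnorm(n, log(1500), 0.4))),
      base = {b <- stats::rlnorm(n, 0, 1.2); b / sum(b)},
      gamma = if (fraction_sensitivity_sd > 0)
        pmax(0.2, rnorm(n, 1, fraction_sensitivity_sd)) else rep(1, n),
      stringsAsFactors = FALSE)
  })
  lines <- unique(sample_plan$line_id)
  line_effects <- NULL
  if (line_effect_sd > 0) {
    line_effects <- sapply(lines, function(l)
      rnorm(n_genes[["human"]], 0, line_effect_sd))
    rownames(line_effects) <- gene_ids$human
  }

  structure(list(sample_plan = sample_plan, n_genes = n_genes,
                 gene_ids = gene_ids, gene_params = gene_params,
                 effects = effects, dispersion = dispersion,
                 fraction_sensitivity_sd = fraction_sensitivity_sd,
                 line_effects = line_effects, gene_sets = gene_sets,
                 seed = seed),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("sim_design:", nrow(x$sample_plan), "samples,",
      x$n_genes[["human"]], "human +", x$n_genes[["mouse"]],
      "mouse genes, dispersion", x$dispersion, "\n")
  invisible(x)
}

# log2 effect of condition on one organism's genes for one sample row
sample_log2_effect <- function(design, org, plan_row) {
  n <- design$n_genes[[org]]
  e <- numeric(n)
  names(e) <- design$gene_ids[[org]]
  add <- function(e, v) { if (length(v)) {
    keep <- intersect(names(v), names(e)); e[keep] <- e[keep] + v[keep] }
    e }
  is_met <- startsWith(plan_row$tissue, "met_")
  if (org == "human") {
    if (is_met) {
      e <- add(e, design$effects$human_met)
      e <- add(e, design$effects$human_transient)
      e <- add(e, design$effects$human_selected)
    } else if (plan_row$passage_role == "MGT_from_met") {
      e <- add(e, design$effects$human_selected)
    }
    if (!is.null(design$line_effects) &&
        plan_row$line_id %in% colnames(design$line_effects))
      e <- e + design$line_effects[, plan_row$line_id]
  } else if (org == "mouse" && is_met) {
    e <- add(e, design$effects$mouse_met)
  }
  e
}

# expected count vector for one organism in one sample
expected_counts <- function(design, org, plan_row) {
  gp <- design$gene_params[[org]]
  f <- if (org == "human") plan_row$human_fraction else
    1 - plan_row$human_fraction
  e <- sample_log2_effect(design, org, plan_row)
  gp$base * 2^e * (f ^ gp$gamma) * plan_row$library_size
}

#' Simulate per-species gene count matrices
#'
#' Draws `count ~ NB(mean = base_g * effect_{g, condition(s)} *
#' fraction_s(organism)^gamma_g * library_size_s, dispersion)` for every gene
#' and sample, separately per organism; the two count matrices share sample
#' columns.  Metadata records the realized species percentages (computed
#' from the simulated counts, mirroring what the read partitioner would
#' report) and the truth object records the design fractions and all planted
#' effects.
#'
#' @param design A [sim_design()].
#' @param noiseless If `TRUE`, return rounded expected counts instead of NB
#'   draws (used for exact-recovery fixtures).
#' @param seed Seed for the count noise draws; defaults to a seed derived
#'   from the design so repeated calls reproduce the same counts.  Pass
#'   different values to draw replicate noise realizations of one design.
#' @return List with elements `human` and `mouse` ([count_matrix()]s),
#'   `metadata` (data frame) and `truth`.
#' @export
simulate_counts <- function(design, noiseless = FALSE,
                            seed = design$seed + 1L) {
  stopifnot(inherits(design, "sim_design"))
  plan <- design$sample_plan
  set.seed(seed)
  draw <- function(mu) {
    if (noiseless) return(round(mu))
    if (design$dispersion < 1e-12) return(rpois(length(mu), mu))
    rnbinom(length(mu), mu = mu, size = 1 / design$dispersion)
  }
  mats <- lapply(c(human = "human", mouse = "mouse"), function(org) {
    n_g <- design$n_genes[[org]]
    m <- matrix(unlist(lapply(seq_len(nrow(plan)), function(i)
      draw(expected_counts(design, org, plan[i, ])))), nrow = n_g)
    dimnames(m) <- list(design$gene_ids[[org]], plan$sample_id)
    count_matrix(m, org,
                 setNames(design$gene_params[[org]]$length,
                          design$gene_ids[[org]]))
  })
  hum <- colSums(mats$human); mou <- colSums(mats$mouse)
  tot <- hum + mou
  metadata <- data.frame(
    sample_id = plan$sample_id, line_id = plan$line_id,
    tissue = plan$tissue, passage_role = plan$passage_role,
    human_pct = ifelse(tot > 0, 100 * hum / tot, NA_real_),
    mouse_pct = ifelse(tot > 0, 100 * mou / tot, NA_real_),
    human_mapped_reads = hum,
    stringsAsFactors = FALSE)
  truth <- list(fractions = setNames(plan$human_fraction, plan$sample_id),
                effects = design$effects,
                gene_sets = design$gene_sets,
                gene_params = design$gene_params)
  list(human = mats$human, mouse = mats$mouse, metadata = metadata,
       truth = truth)
}

#' Simulate mixed-species reads
#'
#' Each read is a uniform-random substring of a transcript: the organism is
#' drawn from the sample's true human fraction, the transcript proportional
#' to that sample's per-organism expected expression, and the start position
#' uniformly.  Read origin (organism and gene) is recorded in the truth
#' table.  In paired mode two mates are emitted per fragment, from the same
#' transcript in opposite orientations.
#'
#' @param design A [sim_design()]; `library_size` is the read count per
#'   sample.
#' @param references Pair of [species_reference()]s as returned by
#'   [generate_reference()] (`a` = human-side, `b` = mouse-side).
#' @param read_length Read length in bases; must not exceed the shortest
#'   transcript.
#' @param paired Emit mate pairs.
#' @param error_rate Uniform per-base substitution rate (default 0,
#'   error-free).
#' @return List with `reads`: per-sample character vector of read sequences
#'   (paired mode: list with `mate1`, `mate2`), and `truth`: data frame
#'   `read_id`, `sample_id`, `organism`, `gene_id`.
#' @export
simulate_reads <- function(design, references, read_length = 100L,
                           paired = FALSE, error_rate = 0) {
  stopifnot(inherits(design, "sim_design"))
  refs <- list(human = references$a, mouse = references$b)
  min_len <- min(vapply(refs, function(r) min(r$transcripts$length),
                        numeric(1)))
  if (read_length > min_len)
    stop("read_length exceeds the shortest transcript (", min_len, " bp)")
  set.seed(design$seed + 2L)
  plan <- design$sample_plan
  out_reads <- list(); truth <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    n <- row$library_size
    is_hum <- runif(n) < row$human_fraction
    orgs <- ifelse(is_hum, "human", "mouse")
    tx_idx <- integer(n); starts <- integer(n)
    seqs <- character(n)
    for (org in c("human", "mouse")) {
      sel <- which(orgs == org)
      if (!length(sel)) next
      ref <- refs[[org]]
      w <- design$gene_params[[org]]$base *
        2^sample_log2_effect(design, org, row)
      ti <- sample.int(nrow(ref$transcripts), length(sel), replace = TRUE,
                       prob = w)
      lens <- ref$transcripts$length[ti]
      st <- 1L + floor(runif(length(sel)) * (lens - read_length + 1L))
      seqs[sel] <- substring(ref$sequences[ti], st, st + read_length - 1L)
      tx_idx[sel] <- ti; starts[sel] <- st
    }
    if (error_rate > 0)
      seqs <- vapply(seqs, mutate_dna, character(1L), rate = error_rate,
                     USE.NAMES = FALSE)
    ids <- sprintf("%s_r%06d", row$sample_id, seq_len(n))
    names(seqs) <- ids
    gene_of <- ifelse(orgs == "human",
                      refs$human$transcripts$gene_id[tx_idx],
                      refs$mouse$transcripts$gene_id[tx_idx])
    if (paired) {
      mate2 <- character(n)
      for (org in c("human", "mouse")) {
        sel <- which(orgs == org)
        if (!length(sel)) next
        ref <- refs[[org]]
        lens <- ref$transcripts$length[tx_idx[sel]]
        fr_end <- pmin(starts[sel] + 2L * read_length - 1L, lens)
        m2 <- substring(ref$sequences[tx_idx[sel]],
                        fr_end - read_length + 1L, fr_end)
        mate2[sel] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(m2)))
      }
      if (error_rate > 0)
        mate2 <- vapply(mate2, mutate_dna, character(1L), rate = error_rate,
                        USE.NAMES = FALSE)
      names(mate2) <- ids
      out_reads[[row$sample_id]] <- list(mate1 = seqs, mate2 = mate2)
    } else {
      out_reads[[row$sample_id]] <- seqs
    }
    truth[[i]] <- data.frame(read_id = ids, sample_id = row$sample_id,
                             organism = orgs, gene_id = gene_of,
                             stringsAsFactors = FALSE)
  }
  list(reads = out_reads, truth = do.call(rbind, truth))
}

#' Write simulated reads to FASTQ
#'
#' Constant Phred-33 quality (`"I"`, Q40).
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(
    Biostrings::width(x), function(w) strrep("I", w), character(1L)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ path.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub(" .*", "", names(x)))
}

default_preset_seeds <- c(partition_demo = 101L, de_demo = 202L,
                          triad_demo = 303L, signature_demo = 404L)

#' Build a deterministic small synthetic cohort
#'
#' Four presets cover the pipeline's test surfaces:
#' * `partition_demo` — two divergent references (divergence 0.10) and four
#'   mixed samples with truth labels for every read; exercises the species
#'   partitioner.
#' * `de_demo` — 2000 human genes, 6 mammary tumors vs. 6 liver metastases
#'   of one PDX line with the human fraction systematically lower in
#'   metastases (the composition confound), 50 genes planted 4-fold up in
#'   metastases; exercises the composition-adjusted DE stage.
#' * `triad_demo` — three PDX lines, each with parental mammary tumors,
#'   liver metastases and tumors regrown from those metastases; 30 planted
#'   transient and 30 planted selected genes (disjoint).
#' * `signature_demo` — six PDX lines with tumors and metastases, one
#'   planted pan-line gene set shifted up in every line's metastases among
#'   100 decoy sets.
#'
#' @param preset One of `"partition_demo"`, `"de_demo"`, `"triad_demo"`,
#'   `"signature_demo"`.
#' @param seed Integer seed; defaults to a fixed documented seed per preset.
#' @param n_reads_per_sample Reads per sample (`partition_demo` only).
#' @param noise `triad_demo` only: draw NB counts (`TRUE`) or use exact
#'   expected counts (`FALSE`, default).
#' @param replicates `triad_demo` only: samples per passage role per line.
#' @param dispersion `triad_demo` only: NB dispersion when `noise = TRUE`.
#' @return A list; all presets include `design`, `metadata` and `truth`,
#'   plus preset-specific elements (`references`/`reads` for
#'   `partition_demo`; `human`/`mouse` count matrices otherwise;
#'   `gene_sets` for `signature_demo`).
#' @export
build_cohort_fixture <- function(preset, seed = NULL,
                                 n_reads_per_sample = 1e5L,
                                 noise = FALSE, replicates = 3L,
                                 dispersion = 0.05) {
  presets <- names(default_preset_seeds)
  if (!is.character(preset) || length(preset) != 1L ||
      !(preset %in% presets))
    stop("unknown preset; must be one of: ", paste(presets, collapse = ", "))
  if (is.null(seed)) seed <- default_preset_seeds[[preset]]
  switch(preset,
         partition_demo = fixture_partition_demo(seed, n_reads_per_sample),
         de_demo = fixture_de_demo(seed),
         triad_demo = fixture_triad_demo(seed, noise, replicates,
                                         dispersion),
         signature_demo = fixture_signature_demo(seed))
}

fixture_partition_demo <- function(seed, n_reads) {
  refs <- generate_reference(n_genes = 60L, n_orthologs = 20L,
                             divergence = 0.10, transcript_length = 500L,
                             seed = seed)
  plan <- data.frame(
    sample_id = sprintf("pd_s%d", 1:4),
    line_id = "HCI10",
    tissue = c("MGT", "met_liver", "met_brain", "MGT"),
    passage_role = c("parental_MGT", "metastasis", "metastasis",
                     "parental_MGT"),
    human_fraction = c(0.8, 0.5, 0.2, 0.95),
    library_size = n_reads,
    stringsAsFactors = FALSE)
  design <- sim_design(plan, n_genes = c(human = 60L, mouse = 60L),
                       dispersion = 0.1, seed = seed)
  sim <- simulate_reads(design, refs, read_length = 100L)
  list(design = design, references = refs, reads = sim$reads,
       truth = sim$truth, metadata = plan)
}

fixture_de_demo <- function(seed) {
  # fixed composition grids spanning the observed ranges: mammary tumors
  # narrow and human-rich, liver metastases wide and systematically lower
  plan <- data.frame(
    sample_id = sprintf("de_s%02d", 1:12),
    line_id = "HCI10",
    tissue = rep(c("MGT", "met_liver"), each = 6L),
    passage_role = rep(c("parental_MGT", "metastasis"), each = 6L),
    human_fraction = c(seq(0.72, 0.91, length.out = 6),
                       seq(0.25, 0.90, length.out = 6)),
    library_size = round(seq(1.6e6, 2.4e6, length.out = 12)),
    stringsAsFactors = FALSE)
  design <- sim_design(plan, n_genes = c(human = 2000L, mouse = 300L),
                       dispersion = 0.1, fraction_sensitivity_sd = 0.2,
                       seed = seed + 1L)
  # plant 4-fold up-in-metastasis genes among reasonably expressed genes
  gp <- design$gene_params$human
  eligible <- gp$gene_id[gp$base > quantile(gp$base, 0.30)]
  set.seed(seed + 2L)
  planted <- sort(sample(eligible, 50L))
  design$effects$human_met <- setNames(rep(2, 50L), planted)
  sim <- simulate_counts(design)
  sim$design <- design
  sim$truth$planted_up <- planted
  sim
}

fixture_triad_demo <- function(seed, noise, replicates, dispersion) {
  lines <- c("HCI01", "HCI09", "WHIM2")
  roles <- data.frame(
    passage_role = c("parental_MGT", "metastasis", "MGT_from_met"),
    tissue = c("MGT", "met_liver", "MGT"),
    human_fraction = c(0.85, 0.50, 0.85),
    stringsAsFactors = FALSE)
  plan <- do.call(rbind, lapply(lines, function(l) {
    do.call(rbind, lapply(seq_len(nrow(roles)), function(r) {
      data.frame(sample_id = sprintf("%s_%s_%d", l, roles$passage_role[r],
                                     seq_len(replicates)),
                 line_id = l, tissue = roles$tissue[r],
                 passage_role = roles$passage_role[r],
                 human_fraction = roles$human_fraction[r],
                 library_size = 2e6, stringsAsFactors = FALSE)
    }))
  }))
  design <- sim_design(plan, n_genes = c(human = 1000L, mouse = 200L),
                       dispersion = if (noise) dispersion else 0,
                       seed = seed)
  gp <- design$gene_params$human
  eligible <- gp$gene_id[gp$base > quantile(gp$base, 0.30)]
  set.seed(seed + 2L)
  picked <- sample(eligible, 60L)
  transient <- sort(picked[1:30]); selected <- sort(picked[31:60])
  design$effects$human_transient <- setNames(rep(2, 30L), transient)
  design$effects$human_selected <- setNames(rep(2, 30L), selected)
  sim <- simulate_counts(design, noiseless = !noise)
  sim$design <- design
  sim$truth$transient <- transient
  sim$truth$selected <- selected
  sim
}

fixture_signature_demo <- function(seed) {
  lines <- sprintf("PDX%02d", 1:6)
  plan <- do.call(rbind, lapply(lines, function(l) {
    data.frame(sample_id = sprintf("%s_%s_%d", l,
                                   rep(c("MGT", "met"), each = 2L), 1:2),
               line_id = l,
               tissue = rep(c("MGT", "met_liver"), each = 2L),
               passage_role = rep(c("parental_MGT", "metastasis"),
                                  each = 2L),
               human_fraction = rep(c(0.85, 0.55), each = 2L),
               library_size = 2e6, stringsAsFactors = FALSE)
  }))
  design <- sim_design(plan, n_genes = c(human = 1000L, mouse = 100L),
                       dispersion = 0.1, line_effect_sd = 0.4,
                       seed = seed)
  gp <- design$gene_params$human
  eligible <- gp$gene_id[gp$base > quantile(gp$base, 0.30)]
  set.seed(seed + 2L)
  planted_genes <- sort(sample(eligible, 20L))
  design$effects$human_met <- setNames(rep(1, 20L), planted_genes)
  sets <- c(list(PLANTED_MET_PROGRAM = planted_genes),
            setNames(lapply(1:100, function(i)
              sort(sample(gp$gene_id, 20L))),
              sprintf("DECOY_SET_%03d", 1:100)))
  design$gene_sets <- sets
  sim <- simulate_counts(design)
  sim$design <- design
  sim$gene_sets <- sets
  sim$truth$planted_set <- "PLANTED_MET_PROGRAM"
  sim
}
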