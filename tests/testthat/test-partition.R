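ref_from_seqs <- function(organism, seqs) {
  names(seqs) <- sprintf("%s_g%02d_t1", organism, seq_along(seqs))
  species_reference(organism, seqs,
                    sub("_t1$", "", names(seqs)))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

test_that("identical references yield only shared k-mers", {
  set.seed(1)
  s <- rand_seq(80)
  idx <- build_kmer_index(list(ref_from_seqs("aa", s),
                               ref_from_seqs("bb", s)), k = 11)
  st <- kmer_index_stats(idx)
  expect_equal(st$n_shared, st$n_kmers)
  expect_true(all(st$n_unique == 0))
})

test_that("references without common k-mers are fully organism-unique", {
  idx <- build_kmer_index(list(
    ref_from_seqs("aa", strrep("A", 40)),
    ref_from_seqs("bb", strrep("C", 40))), k = 11)
  st <- kmer_index_stats(idx)
  expect_equal(st$n_shared, 0)
  expect_true(all(st$n_unique > 0))
})

test_that("the index holds exactly the canonical k-mers of its input", {
  s <- "ACGTACGTACGTAC"  # 14 bp -> 4 k-mers at k = 11
  idx <- build_kmer_index(ref_from_seqs("aa", s), k = 11)
  kmers <- substring(s, 1:4, 11:14)
  canon <- vapply(kmers, function(km) {
    rc <- reverse_complement(km)
    if (rc < km) rc else km
  }, character(1), USE.NAMES = FALSE)
  expect_setequal(kmer_index_kmers(idx), unique(canon))
  q <- kmer_index_query(idx, kmers)
  expect_true(all(q$organism == "aa"))
})

test_that("transcripts shorter than k are rejected by name", {
  expect_error(build_kmer_index(ref_from_seqs("aa", "ACGTACGT"), k = 11),
               "aa_g01_t1")
  expect_error(build_kmer_index(ref_from_seqs("aa", rand_seq(40)),
                                k = 12), "odd")
})

test_that("read classification follows uniqueness semantics", {
  set.seed(2)
  a <- rand_seq(200); b <- rand_seq(200)
  idx <- build_kmer_index(list(ref_from_seqs("hs", a),
                               ref_from_seqs("mm", b)), k = 31)
  # verbatim copy of a human-unique region
  expect_equal(as.character(classify_read(substr(a, 20, 120), idx)), "hs")
  # chimeric read: half human, half mouse
  chim <- paste0(substr(a, 1, 60), substr(b, 1, 60))
  expect_equal(as.character(classify_read(chim, idx)), "ambiguous")
  # random sequence sharing no k-mer with either reference
  r <- rand_seq(100)
  hits <- kmer_index_query(idx, substring(r, 1:70, 31:100))
  expect_true(all(is.na(hits$organism)))
  expect_equal(as.character(classify_read(r, idx)), "unmapped")
  # shorter than k is unmapped, not an error
  expect_equal(as.character(classify_read("ACGT", idx)), "unmapped")
})

test_that("classification agrees with a brute-force substring oracle", {
  set.seed(3)
  refs <- generate_reference(4, n_orthologs = 2, divergence = 0.10,
                             transcript_length = 500, seed = 33)
  idx <- build_kmer_index(list(refs$a, refs$b), k = 31)
  plan <- data.frame(sample_id = "s1", line_id = "L1", tissue = "MGT",
                     passage_role = "parental_MGT", human_fraction = 0.5,
                     library_size = 40, stringsAsFactors = FALSE)
  des <- sim_design(plan, n_genes = c(human = 4L, mouse = 4L), seed = 33)
  reads <- simulate_reads(des, refs, read_length = 60)$reads[[1]]
  reads <- c(reads, vapply(1:10, function(i) rand_seq(60), character(1)))
  got <- as.character(classify_read(reads, idx, min_informative = 2))
  want <- vapply(reads, oracle_classify, character(1),
                 refs = list(refs$a, refs$b), k = 31, min_informative = 2,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("partitioning is accurate, conservative and deterministic", {
  fx <- build_cohort_fixture("partition_demo", n_reads_per_sample = 5000)
  idx <- build_kmer_index(list(fx$references$a, fx$references$b), k = 31)
  for (s in fx$metadata$sample_id[1:2]) {
    pr <- partition_readset(fx$reads[[s]], idx)
    truth <- fx$truth$organism[fx$truth$sample_id == s]
    got <- as.character(pr$labels)
    correct <- (truth == "human" & got == "hs") |
      (truth == "mouse" & got == "mm")
    wrong <- (truth == "human" & got == "mm") |
      (truth == "mouse" & got == "hs")
    expect_gte(mean(correct), 0.99)
    expect_equal(sum(wrong), 0)
    # label conservation
    expect_equal(sum(pr$class_counts), pr$n_reads)
    # gene-level counts never exceed the organism totals
    expect_lte(sum(pr$gene_counts$hs), pr$class_counts[["hs"]])
  }
  p1 <- partition_readset(fx$reads[[1]], idx)
  p2 <- partition_readset(fx$reads[[1]], idx)
  expect_identical(p1$class_counts, p2$class_counts)
})

test_that("gene-level counts go to the gene of origin", {
  fx <- build_cohort_fixture("partition_demo", n_reads_per_sample = 2000)
  idx <- build_kmer_index(list(fx$references$a, fx$references$b), k = 31)
  pr <- partition_readset(fx$reads[[1]], idx)
  truth <- fx$truth[fx$truth$sample_id == fx$metadata$sample_id[1], ]
  truth_tab <- table(truth$gene_id[truth$organism == "human"])
  common <- intersect(names(truth_tab), names(pr$gene_counts$hs))
  # nearly all human reads should land on their true gene
  expect_gt(sum(pmin(truth_tab[common], pr$gene_counts$hs[common])) /
              sum(truth_tab), 0.98)
})

test_that("empty read sets partition to all-zero counts", {
  set.seed(4)
  idx <- build_kmer_index(list(ref_from_seqs("hs", rand_seq(100)),
                               ref_from_seqs("mm", rand_seq(100))),
                          k = 31)
  pr <- partition_readset(character(0), idx)
  expect_equal(sum(pr$class_counts), 0)
  expect_equal(pr$n_reads, 0)
})

test_that("raising min_informative never rescues a read", {
  set.seed(5)
  refs <- generate_reference(6, 3, 0.10, 400, seed = 44)
  idx <- build_kmer_index(list(refs$a, refs$b), k = 31)
  des <- sim_design(data.frame(sample_id = "s1", line_id = "L1",
                               tissue = "MGT",
                               passage_role = "parental_MGT",
                               human_fraction = 0.5, library_size = 300,
                               stringsAsFactors = FALSE),
                    n_genes = c(human = 6L, mouse = 6L), seed = 44)
  reads <- simulate_reads(des, refs, read_length = 50,
                          error_rate = 0.08)$reads[[1]]
  prev <- as.character(classify_read(reads, idx, min_informative = 1))
  for (mi in 2:5) {
    cur <- as.character(classify_read(reads, idx, min_informative = mi))
    moved <- prev %in% c("ambiguous", "unmapped") &
      !(cur %in% c("ambiguous", "unmapped"))
    expect_false(any(moved))
    prev <- cur
  }
})

test_that("paired-end fragments are labelled by mate agreement", {
  set.seed(6)
  a <- rand_seq(200); b <- rand_seq(200)
  idx <- build_kmer_index(list(ref_from_seqs("hs", a),
                               ref_from_seqs("mm", b)), k = 31)
  m1 <- c(substr(a, 1, 80), substr(a, 1, 80), rand_seq(80),
          substr(a, 1, 80))
  m2 <- c(substr(a, 100, 180), substr(b, 1, 80), substr(b, 1, 80),
          rand_seq(80))
  labs <- as.character(classify_fragments(m1, m2, idx))
  expect_equal(labs, c("hs", "ambiguous", "mm", "hs"))
})

test_that("merging partitions adds counts", {
  fx <- build_cohort_fixture("partition_demo", n_reads_per_sample = 1000)
  idx <- build_kmer_index(list(fx$references$a, fx$references$b), k = 31)
  p1 <- partition_readset(fx$reads[[1]], idx)
  p2 <- partition_readset(fx$reads[[2]], idx)
  pm <- merge_partitions(p1, p2)
  expect_equal(pm$class_counts, p1$class_counts + p2$class_counts)
  expect_equal(pm$n_reads, 2000)
  g <- union(names(p1$gene_counts$hs), names(p2$gene_counts$hs))
  for (gene in g[1:5]) {
    a <- p1$gene_counts$hs[gene]; b <- p2$gene_counts$hs[gene]
    expect_equal(unname(pm$gene_counts$hs[gene]),
                 sum(a, b, na.rm = TRUE))
  }
})

test_that("composition percentages follow the exclusion rule", {
  pr <- structure(list(
    labels = factor(character(0),
                    levels = c("human", "mouse", "viral", "ambiguous",
                               "unmapped")),
    class_counts = c(human = 800L, mouse = 200L, viral = 50L,
                     ambiguous = 0L, unmapped = 100L),
    gene_counts = list(human = integer(0), mouse = integer(0),
                       viral = integer(0)),
    n_reads = 1150L), class = "partition_result")
  comp <- composition_stats(pr, exclude = "viral")
  expect_equal(comp$pct[comp$organism == "human"], 80)
  expect_equal(comp$pct[comp$organism == "mouse"], 20)
  expect_equal(attr(comp, "reads_used"), 1000L)

  pr$class_counts <- c(human = 0L, mouse = 500L, viral = 0L,
                       ambiguous = 0L, unmapped = 0L)
  comp <- composition_stats(pr, exclude = "viral")
  expect_equal(comp$pct, c(0, 100))

  pr$class_counts <- c(human = 0L, mouse = 0L, viral = 9L,
                       ambiguous = 1L, unmapped = 5L)
  expect_error(composition_stats(pr, exclude = "viral"),
               "undefined composition")
  expect_error(composition_stats(pr, exclude = "plants"), "not present")
})

test_that("composition recovers the true mixing fraction", {
  fx <- build_cohort_fixture("partition_demo", n_reads_per_sample = 5000)
  idx <- build_kmer_index(list(fx$references$a, fx$references$b), k = 31)
  pr <- partition_readset(fx$reads[["pd_s1"]], idx)
  comp <- composition_stats(pr)
  expect_lt(abs(comp$pct[comp$organism == "hs"] - 80), 2)
})
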