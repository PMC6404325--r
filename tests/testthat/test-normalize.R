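toy_counts <- function(m, lengths = NULL, organism = "human") {
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  if (is.null(lengths)) lengths <- setNames(rep(1000, nrow(m)),
                                            rownames(m))
  count_matrix(m, organism, lengths)
}

test_that("tpm matches the closed form and is scale invariant", {
  cm <- toy_counts(matrix(c(10, 10), 2, 1),
                   lengths = c(g01 = 1000, g02 = 2000))
  tp <- tpm(cm)
  expect_equal(as.numeric(tp), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  set.seed(1)
  m <- matrix(rpois(60, 50), 10, 6)
  cm <- toy_counts(m)
  expect_equal(unclass(tpm(cm)), unclass(tpm(toy_counts(m * 7L))))
  expect_equal(unname(colSums(unclass(tpm(cm)))), rep(1e6, 6))
})

test_that("tpm flags all-zero columns and keeps them zero", {
  m <- matrix(c(5, 3, 0, 0), 2, 2)
  tp <- tpm(toy_counts(m))
  expect_equal(attr(tp, "zero_columns"), "s02")
  expect_true(all(tp[, 2] == 0))
})

test_that("log transform is log2(x + 1) and guards its domain", {
  cm <- toy_counts(matrix(c(0, 1, 10), 3, 1))
  lt <- log_transform(tpm(cm))
  expect_equal(attr(lt, "transforms"), c("TPM", "log2TPM"))
  single <- log_transform(tpm(toy_counts(matrix(5, 1, 1))))
  expect_equal(as.numeric(single), log2(1e6 + 1), tolerance = 1e-9)
  em <- expression_matrix(matrix(1, 1, 1, dimnames = list("g", "s")),
                          "human", "log2TPM")
  expect_error(log_transform(em), "TPM")
})

test_that("all-zero gene rows are dropped exactly", {
  m <- matrix(1, 5, 3, dimnames = list(sprintf("g%d", 1:5),
                                       c("a", "b", "c")))
  m[3, ] <- 0
  em <- expression_matrix(m, "human", "TPM")
  out <- drop_all_zero_genes(em)
  expect_equal(rownames(out), c("g1", "g2", "g4", "g5"))
  expect_equal(attr(out, "dropped_genes"), "g3")
  expect_equal(nrow(drop_all_zero_genes(out)), 4)  # identity on clean input
  allz <- expression_matrix(matrix(0, 2, 3,
                                   dimnames = list(c("g1", "g2"),
                                                   c("a", "b", "c"))),
                            "human")
  out <- drop_all_zero_genes(allz)
  expect_equal(nrow(out), 0)
  expect_equal(colnames(out), c("a", "b", "c"))
})

test_that("the DE prefilter applies both clauses as printed", {
  m <- matrix(0, 3, 20, dimnames = list(c("zero", "sparse", "flat"),
                                        sprintf("s%02d", 1:20)))
  m["sparse", 1:2] <- 10          # > 0.5 in exactly 2 = ceiling(0.1 * 20)
  m["flat", ] <- 3                # constant positive: ratio 1 > 0.5
  out <- de_prefilter(m)
  expect_setequal(rownames(out), c("sparse", "flat"))
  expect_equal(attr(out, "dropped_genes"), "zero")
})

test_that("upper-quantile normalization aligns columns and is idempotent", {
  set.seed(2)
  m <- matrix(rexp(300), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("s%d", 1:6)))
  em <- expression_matrix(m, "human", c("TPM", "log2TPM"))
  out <- upper_quantile_normalize(em)
  q <- apply(unclass(out), 2, function(v) quantile(v[v != 0], 0.75))
  expect_lt(diff(range(q)), 1e-10)
  # a +1 log2 shift (2x linear) between otherwise identical columns
  m2 <- cbind(a = m[, 1], b = m[, 1] + 1)
  out2 <- upper_quantile_normalize(
    expression_matrix(m2, "human", "log2TPM"))
  expect_equal(as.numeric(unclass(out2)[, "a"]),
               as.numeric(unclass(out2)[, "b"]), tolerance = 1e-12)
  # idempotency
  twice <- upper_quantile_normalize(out)
  expect_equal(as.numeric(unclass(twice)), as.numeric(unclass(out)),
               tolerance = 1e-12)
})

test_that("row median centering matches hand-computed medians", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g", c("a", "b", "c")))
  expect_equal(as.numeric(median_center_rows(m)), c(-1, 0, 1))
  m4 <- matrix(c(1, 2, 3, 10), 1, 4,
               dimnames = list("g", sprintf("s%d", 1:4)))
  expect_equal(as.numeric(median_center_rows(m4)),
               c(-1.5, -0.5, 0.5, 7.5))
  centered <- median_center_rows(m4)
  expect_equal(median_center_rows(centered), centered)  # idempotent
})

test_that("top variable genes match a brute-force variance ranking", {
  set.seed(3)
  m <- matrix(rnorm(100), 10, 10,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  colnames(m) <- sprintf("s%02d", 1:10)
  m["g05", ] <- 0  # constant gene
  got <- top_variable_genes(m, 5)
  v <- apply(m, 1, var)
  want <- names(sort(v, decreasing = TRUE))[1:5]
  expect_setequal(got, want)
  expect_equal(got, rownames(m)[order(-v, rownames(m))][1:5])
  expect_equal(length(top_variable_genes(m, 10)), 10)
  expect_false("g05" %in% top_variable_genes(m, 9))
  expect_error(top_variable_genes(m, 11), "exceeds")
})

test_that("correlation QC flags a planted label swap as a mutual pair", {
  plan <- do.call(rbind, lapply(c("HCI01", "WHIM2"), function(l)
    data.frame(sample_id = sprintf("%s_s%d", l, 1:4), line_id = l,
               tissue = "MGT", passage_role = "parental_MGT",
               human_fraction = 0.85, library_size = 5e5,
               stringsAsFactors = FALSE)))
  des <- sim_design(plan, n_genes = c(human = 400L, mouse = 50L),
                    dispersion = 0.05, line_effect_sd = 0.8, seed = 21)
  sim <- simulate_counts(des)
  lt <- log_transform(tpm(sim$human))
  meta <- sim$metadata
  expect_equal(nrow(correlation_qc(lt, meta)), 0)  # no swap planted
  swapped <- meta
  swapped$line_id[swapped$sample_id == "HCI01_s1"] <- "WHIM2"
  swapped$line_id[swapped$sample_id == "WHIM2_s1"] <- "HCI01"
  flags <- correlation_qc(lt, swapped)
  expect_setequal(flags$sample_id[flags$mutual],
                  c("HCI01_s1", "WHIM2_s1"))
  expect_setequal(flags$sample_id, c("HCI01_s1", "WHIM2_s1"))
})

test_that("duplicate columns with the same label are not flagged", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("g%d", 1:10),
                              c("a1", "a2", "b1", "b2")))
  m[, "a2"] <- m[, "a1"]
  meta <- data.frame(sample_id = colnames(m),
                     line_id = c("A", "A", "B", "B"),
                     stringsAsFactors = FALSE)
  m[, "b2"] <- m[, "b1"] + rnorm(10, sd = 0.01)
  expect_equal(nrow(correlation_qc(m, meta)), 0)
  expect_equal(nrow(correlation_qc(m[, 1, drop = FALSE], meta[1, ])), 0)
})

test_that("hierarchical clustering merges by correlation structure", {
  set.seed(4)
  base <- rnorm(30)
  m <- cbind(a = base, b = base, c = rnorm(30), d = rnorm(30) * 2)
  rownames(m) <- sprintf("g%02d", 1:30)
  hc <- hcluster(m)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("a", "b"))  # identical samples merge first
  # three samples: the correlated pair merges before the third joins
  m3 <- cbind(x = base, y = base + rnorm(30, sd = 0.05), z = rnorm(30))
  hc3 <- hcluster(m3)
  expect_setequal(hc3$labels[-hc3$merge[1, ]], c("x", "y"))
})

test_that("merge order equals the O(n^3) Ward.D2 oracle", {
  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(rnorm(8 * 25), 25, 8,
                dimnames = list(NULL, sprintf("s%d", 1:8)))
    hc <- hcluster(m)
    d <- 1 - cor(m)
    orc <- oracle_ward2(d)
    expect_equal(hc$height, orc$heights, tolerance = 1e-8)
    expect_identical(hclust_partitions(hc, hc$labels), orc$partitions)
  }
})

test_that("PCA separates duplicated clusters with fixed signs", {
  set.seed(6)
  c1 <- rnorm(40); c2 <- rnorm(40)
  m <- cbind(a1 = c1, a2 = c1 + rnorm(40, sd = 0.01),
             b1 = c2, b2 = c2 + rnorm(40, sd = 0.01))
  rownames(m) <- sprintf("g%02d", 1:40)
  pc <- pca_scores(m, 3)
  s1 <- pc$scores[, 1]
  expect_true(max(s1[1:2]) < min(s1[3:4]) ||
                min(s1[1:2]) > max(s1[3:4]))
  expect_lt(abs(sum(pc$scores[, 1] * pc$scores[, 2])), 1e-8)
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)
  pc2 <- pca_scores(m, 3)
  expect_identical(pc$scores, pc2$scores)  # deterministic signs
})

test_that("cohort merging respects the shared gene namespace", {
  a <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"),
                                         c("a1", "a2")))
  b <- matrix(7:12, 3, 2, dimnames = list(c("g2", "g3", "g4"),
                                          c("b1", "b2")))
  out <- merge_cohorts(a, b, gene_subset = c("g2", "g3", "g9"))
  expect_equal(rownames(out), c("g2", "g3"))
  expect_equal(attr(out, "missing_genes"), "g9")
  expect_equal(out["g2", ], c(a1 = 2, a2 = 5, b1 = 7, b2 = 10))
  expect_equal(attr(out, "origin"), c("a", "a", "b", "b"))
  disj <- merge_cohorts(a, matrix(1, 1, 1, dimnames = list("zz", "c1")))
  expect_equal(nrow(disj), 0)
  self <- merge_cohorts(a, a)
  expect_equal(ncol(self), 4)
})

test_that("the mapped-read filter is a strict bound", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     human_mapped_reads = c(1e7, 1e7 + 1, 2e7),
                     stringsAsFactors = FALSE)
  expect_equal(filter_by_mapped_reads(meta), c("b", "c"))
  expect_equal(filter_by_mapped_reads(meta[0, ]), character(0))
})

test_that("nearest-centroid recovers simulated class structure", {
  set.seed(7)
  cen <- matrix(rnorm(50 * 3), 50, 3,
                dimnames = list(sprintf("g%02d", 1:50),
                                c("basal", "lumA", "her2")))
  truth <- sample(colnames(cen), 60, replace = TRUE)
  m <- cen[, truth] + rnorm(50 * 60, sd = 0.1)
  colnames(m) <- sprintf("s%02d", 1:60)
  res <- nearest_centroid(m, cen)
  expect_gte(mean(res$class == truth), 0.95)
  exact <- nearest_centroid(cen[, 1, drop = FALSE], cen)
  expect_equal(exact$class, "basal")
})
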