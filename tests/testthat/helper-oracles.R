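# Independent reference implementations used to cross-check the package.
# These deliberately use the most direct / brute-force formulation of each
# definition and share no code with the implementation under test.

# step-up Benjamini-Hochberg, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# ssGSEA running sum computed stepwise, position by position
oracle_ssgsea <- function(values, gene_set, alpha = 0.25) {
  ord <- order(-values, names(values))
  genes <- names(values)[ord]
  n <- length(genes)
  in_set <- genes %in% gene_set
  stopifnot(any(in_set))
  if (all(in_set)) return(0)
  w <- (n - seq_len(n) + 1)^alpha
  p_in <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
  p_out <- cumsum(!in_set) / sum(!in_set)
  sum(p_in - p_out)
}

# O(n^3) Ward.D2 agglomeration via the Lance-Williams update; returns merge
# heights and the partition after each merge (as sorted member strings)
oracle_ward2 <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(rownames(d))
  sizes <- rep(1L, n)
  act <- seq_len(n)
  heights <- numeric(0)
  partitions <- list()
  dd <- d
  diag(dd) <- Inf
  while (length(act) > 1L) {
    sub <- dd[act, act, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    i <- act[min(ij)]; j <- act[max(ij)]
    heights <- c(heights, dd[i, j])
    # Lance-Williams ward.D2 update for every other active cluster
    for (k in setdiff(act, c(i, j))) {
      nk <- sizes[k]; ni <- sizes[i]; nj <- sizes[j]
      dd[i, k] <- dd[k, i] <- sqrt(
        ((ni + nk) * dd[i, k]^2 + (nj + nk) * dd[j, k]^2 -
           nk * dd[i, j]^2) / (ni + nj + nk))
    }
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    sizes[i] <- sizes[i] + sizes[j]
    act <- setdiff(act, j)
    partitions[[length(partitions) + 1L]] <-
      sort(vapply(clusters[act], paste, character(1), collapse = "|"))
  }
  list(heights = heights, partitions = partitions)
}

# partition state of an hclust object after each merge step
hclust_partitions <- function(hc, labels) {
  merged <- list()
  get_members <- function(id) if (id < 0) labels[-id] else merged[[id]]
  alive <- as.list(-seq_along(labels))
  out <- list()
  for (s in seq_len(nrow(hc$merge))) {
    a <- hc$merge[s, 1]; b <- hc$merge[s, 2]
    merged[[s]] <- sort(c(get_members(a), get_members(b)))
    alive <- Filter(function(id) !(id %in% c(a, b)), alive)
    alive <- c(alive, s)
    out[[s]] <- sort(vapply(alive, function(id)
      paste(get_members(id), collapse = "|"), character(1)))
  }
  out
}

# direct median-of-ratios size factors (no shared code with the package)
oracle_size_factors <- function(m) {
  geo <- apply(m, 1, function(x) exp(mean(log(x))))
  keep <- geo > 0 & is.finite(geo)
  sf <- apply(m, 2, function(col) median(col[keep] / geo[keep]))
  sf / exp(mean(log(sf)))
}

reverse_complement <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# brute-force read classification by substring search over whole references
oracle_classify <- function(read, refs, k, min_informative) {
  orgs <- vapply(refs, `[[`, character(1), "organism")
  if (nchar(read) < k) return("unmapped")
  hits <- setNames(integer(length(refs)), orgs)
  for (pos in seq_len(nchar(read) - k + 1)) {
    km <- substr(read, pos, pos + k - 1)
    rc <- reverse_complement(km)
    present <- vapply(refs, function(r)
      any(grepl(km, r$sequences, fixed = TRUE) |
            grepl(rc, r$sequences, fixed = TRUE)), logical(1))
    if (sum(present) == 1L) hits[present] <- hits[present] + 1L
  }
  n_hit <- sum(hits > 0)
  if (n_hit >= 2L) return("ambiguous")
  if (n_hit == 0L || max(hits) < min_informative) return("unmapped")
  orgs[which.max(hits)]
}

# small helper: pairwise Hamming fraction between equal-length strings
hamming_fraction <- function(a, b) {
  mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
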