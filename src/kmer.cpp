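// Canonical k-mer index and read classifier.
//
// Emulates unique alignment against an organism-prefixed concatenated
// reference: a k-mer seen in more than one organism is "shared" and carries
// no species information; an organism-unique k-mer additionally remembers
// which gene it came from (or that it occurs in several genes of that
// organism).  Classification counts informative (organism-unique) k-mer hits
// per organism and applies uniqueness semantics: evidence for two organisms
// discards the read.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Occ {
  int org;   // organism index, -1 = shared across organisms
  int gene;  // gene index, -1 = multiple genes within the organism
};

struct KmerIndex {
  int k;
  std::vector<std::string> organisms;
  std::vector<std::string> genes;
  std::unordered_map<std::string, Occ> table;
};

inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;  // anything non-ACGT invalidates the k-mer
  }
}

// Write the canonical (lexicographic min of forward / reverse complement)
// k-mer starting at `pos` into `out`; returns false on non-ACGT content.
inline bool canonical_kmer(const std::string& seq, size_t pos, int k,
                           std::string& out) {
  out.assign(seq, pos, k);
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) {
    char cc = complement(out[i]);
    if (cc == 0) return false;
    rc[k - 1 - i] = cc;
  }
  if (rc < out) out.swap(rc);
  return true;
}

}  // namespace

// [[Rcpp::export]]
SEXP kmer_index_build_cpp(CharacterVector seqs, IntegerVector org_idx,
                          IntegerVector gene_idx, CharacterVector organisms,
                          CharacterVector genes, int k) {
  XPtr<KmerIndex> idx(new KmerIndex(), true);
  idx->k = k;
  idx->organisms = as<std::vector<std::string> >(organisms);
  idx->genes = as<std::vector<std::string> >(genes);
  std::string km;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const std::string seq = as<std::string>(seqs[s]);
    const int org = org_idx[s], gene = gene_idx[s];
    if (static_cast<int>(seq.size()) < k) continue;  // validated R-side
    for (size_t pos = 0; pos + k <= seq.size(); ++pos) {
      if (!canonical_kmer(seq, pos, k, km)) continue;
      std::unordered_map<std::string, Occ>::iterator it = idx->table.find(km);
      if (it == idx->table.end()) {
        Occ o; o.org = org; o.gene = gene;
        idx->table[km] = o;
      } else {
        if (it->second.org != org) { it->second.org = -1; it->second.gene = -1; }
        else if (it->second.gene != gene) it->second.gene = -1;
      }
    }
  }
  return idx;
}

// [[Rcpp::export]]
List kmer_index_stats_cpp(SEXP ptr) {
  XPtr<KmerIndex> idx(ptr);
  const int n_org = idx->organisms.size();
  IntegerVector unique_per_org(n_org);
  int shared = 0;
  for (std::unordered_map<std::string, Occ>::const_iterator it =
           idx->table.begin(); it != idx->table.end(); ++it) {
    if (it->second.org < 0) ++shared;
    else ++unique_per_org[it->second.org];
  }
  unique_per_org.names() = wrap(idx->organisms);
  return List::create(_["k"] = idx->k,
                      _["organisms"] = wrap(idx->organisms),
                      _["n_kmers"] = static_cast<double>(idx->table.size()),
                      _["n_shared"] = shared,
                      _["n_unique"] = unique_per_org);
}

// [[Rcpp::export]]
CharacterVector kmer_index_keys_cpp(SEXP ptr) {
  XPtr<KmerIndex> idx(ptr);
  CharacterVector out(idx->table.size());
  R_xlen_t i = 0;
  for (std::unordered_map<std::string, Occ>::const_iterator it =
           idx->table.begin(); it != idx->table.end(); ++it)
    out[i++] = it->first;
  return out;
}

// [[Rcpp::export]]
List kmer_index_query_cpp(SEXP ptr, CharacterVector kmers) {
  XPtr<KmerIndex> idx(ptr);
  const R_xlen_t n = kmers.size();
  CharacterVector org(n), gene(n);
  std::string km;
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string q = as<std::string>(kmers[i]);
    if (static_cast<int>(q.size()) != idx->k ||
        !canonical_kmer(q, 0, idx->k, km)) {
      org[i] = NA_STRING; gene[i] = NA_STRING;
      continue;
    }
    std::unordered_map<std::string, Occ>::const_iterator it =
        idx->table.find(km);
    if (it == idx->table.end()) {
      org[i] = NA_STRING; gene[i] = NA_STRING;
    } else if (it->second.org < 0) {
      org[i] = "shared"; gene[i] = NA_STRING;
    } else {
      org[i] = idx->organisms[it->second.org];
      gene[i] = it->second.gene < 0 ? NA_STRING
                                    : String(idx->genes[it->second.gene]);
    }
  }
  return List::create(_["organism"] = org, _["gene"] = gene);
}

// Per-read classification.  label: 1..n_org = organism, 0 = unmapped,
// -1 = ambiguous.  gene: 1-based index into the index's gene table for the
// plurality gene of the winning organism, NA on ties / no gene-level info.
// [[Rcpp::export]]
List classify_reads_cpp(SEXP ptr, CharacterVector reads, int min_informative) {
  XPtr<KmerIndex> idx(ptr);
  const int k = idx->k;
  const int n_org = idx->organisms.size();
  const R_xlen_t n = reads.size();
  IntegerVector label(n), gene(n);
  std::vector<int> hits(n_org);
  std::unordered_map<int, int> gene_hits;
  std::string km;
  for (R_xlen_t r = 0; r < n; ++r) {
    const std::string seq = as<std::string>(reads[r]);
    std::fill(hits.begin(), hits.end(), 0);
    gene_hits.clear();
    if (static_cast<int>(seq.size()) >= k) {
      for (size_t pos = 0; pos + k <= seq.size(); ++pos) {
        if (!canonical_kmer(seq, pos, k, km)) continue;
        std::unordered_map<std::string, Occ>::const_iterator it =
            idx->table.find(km);
        if (it == idx->table.end() || it->second.org < 0) continue;
        ++hits[it->second.org];
        if (it->second.gene >= 0) ++gene_hits[it->second.gene];
      }
    }
    int n_hit_org = 0, best = -1;
    for (int o = 0; o < n_org; ++o)
      if (hits[o] > 0) { ++n_hit_org; best = o; }
    if (n_hit_org >= 2) {
      label[r] = -1; gene[r] = NA_INTEGER;
    } else if (n_hit_org == 0 || hits[best] < min_informative) {
      label[r] = 0; gene[r] = NA_INTEGER;
    } else {
      label[r] = best + 1;
      int bg = -1, bc = 0; bool tie = false;
      for (std::unordered_map<int, int>::const_iterator it = gene_hits.begin();
           it != gene_hits.end(); ++it) {
        if (it->second > bc) { bg = it->first; bc = it->second; tie = false; }
        else if (it->second == bc) tie = true;
      }
      gene[r] = (bg >= 0 && !tie) ? bg + 1 : NA_INTEGER;
    }
  }
  return List::create(_["label"] = label, _["gene"] = gene);
}
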