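// Ungapped small-RNA read mapper: seed-and-verify against a k-mer index.
//
// For a read of length L mapped with <= m substitutions, the read is split
// into m+1 non-overlapping chunks of length k = L/(m+1); by pigeonhole at
// least one chunk matches the genome exactly (a chunk containing N cannot
// match but is itself guaranteed >= 1 mismatch, so the argument still
// holds while any alignment within budget exists). Candidate placements
// found through exact chunk hits are verified by Hamming count with early
// abort. N in read or genome never matches anything.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerMap;

// index all exact (N-free) k-mers of one contig
static void build_index(const std::string& g, int k, KmerMap& idx) {
  const int n = (int) g.size();
  if (n < k) return;
  uint64_t kmer = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0; // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int c = base_code(g[i]);
    if (c == 4) {
      valid = 0;
      kmer = 0;
      continue;
    }
    kmer = ((kmer << 2) | (uint64_t) c) & mask;
    if (++valid >= k) idx[kmer].push_back(i - k + 1);
  }
}

// Hamming verify of query q (already genome-oriented) at genome position
// start; returns total mismatches or max_mm+1 on abort. Positions of the
// mismatches (query coordinates) are appended to mmpos.
static int verify(const std::string& g, const std::string& q, int start,
                  int max_mm, std::vector<int>& mmpos) {
  mmpos.clear();
  const int L = (int) q.size();
  int mm = 0;
  for (int i = 0; i < L; ++i) {
    char a = q[i], b = g[start + i];
    int ca = base_code(a), cb = base_code(b);
    if (ca == 4 || cb == 4 || ca != cb) {
      if (++mm > max_mm) return max_mm + 1;
      mmpos.push_back(i);
    }
  }
  return mm;
}

// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector contigs,
                        int max_mismatch) {
  const int n_contig = contigs.size();
  std::vector<std::string> gs(n_contig);
  for (int c = 0; c < n_contig; ++c) gs[c] = as<std::string>(contigs[c]);

  // lazily built indexes: per contig, per k
  std::vector<std::unordered_map<int, KmerMap> > indexes(n_contig);

  std::vector<int> out_read, out_contig, out_start, out_int, out_tail, out_tot;
  std::vector<int> out_strand; // 1 = plus, 0 = minus

  const int s = max_mismatch + 1;
  std::vector<int> mmpos;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = (int) fwd.size();
    const int k = L / s;
    if (k < 1) continue;
    std::string rev(L, 'N');
    for (int i = 0; i < L; ++i) rev[L - 1 - i] = comp_base(fwd[i]);

    for (int c = 0; c < n_contig; ++c) {
      const std::string& g = gs[c];
      if ((int) g.size() < L) continue;
      std::unordered_map<int, KmerMap>& cidx = indexes[c];
      if (cidx.find(k) == cidx.end()) build_index(g, k, cidx[k]);
      KmerMap& idx = cidx[k];

      for (int strand = 1; strand >= 0; --strand) {
        const std::string& q = strand ? fwd : rev;
        std::unordered_set<int> seen;
        for (int chunk = 0; chunk < s; ++chunk) {
          const int off = chunk * k;
          uint64_t kmer = 0;
          bool ok = true;
          for (int i = 0; i < k; ++i) {
            int cb = base_code(q[off + i]);
            if (cb == 4) { ok = false; break; }
            kmer = (kmer << 2) | (uint64_t) cb;
          }
          if (!ok) continue;
          KmerMap::const_iterator it = idx.find(kmer);
          if (it == idx.end()) continue;
          for (size_t h = 0; h < it->second.size(); ++h) {
            int start = it->second[h] - off;
            if (start < 0 || start + L > (int) g.size()) continue;
            if (!seen.insert(start).second) continue;
            int mm = verify(g, q, start, max_mismatch, mmpos);
            if (mm > max_mismatch) continue;
            // read-orientation position of a query mismatch
            int tail = 0;
            for (size_t p = 0; p < mmpos.size(); ++p) {
              int read_pos = strand ? mmpos[p] : (L - 1 - mmpos[p]);
              if (read_pos >= L - 2) ++tail;
            }
            out_read.push_back(r + 1);
            out_contig.push_back(c + 1);
            out_start.push_back(start);
            out_strand.push_back(strand);
            out_int.push_back(mm - tail);
            out_tail.push_back(tail);
            out_tot.push_back(mm);
          }
        }
      }
    }
  }

  return DataFrame::create(
    _["read"] = out_read, _["contig"] = out_contig, _["start"] = out_start,
    _["plus"] = out_strand, _["mm_internal"] = out_int,
    _["mm_tail3"] = out_tail, _["mm_total"] = out_tot);
}
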