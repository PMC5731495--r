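// Compiled core of the canonical k-mer machinery.
//
// Both entry points slide a window of length k over every input
// sequence, skip windows containing non-ACGT characters, and tally
// windows under their canonical form (the lexicographically smaller of
// the window and its reverse complement). A window counts once toward
// its canonical form regardless of the strand it was read from.
//
// For k <= 31 a window is packed into a 64-bit word, two bits per base
// (A=0, C=1, G=2, T=3), with the first base in the highest bits; the
// numeric order of packed words then equals the lexicographic order of
// the strings, so canonicalization and sorting can stay in integer
// space, and both the forward and reverse-complement words are updated
// in a rolling fashion. Longer k falls back to a string-keyed table.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 0;
  }
}

// ---------------------------------------------------------------------
// packed path (k <= 31)

static void count_windows_packed(const CharacterVector &seqs, int k,
                                 std::unordered_map<uint64_t, int> &tab) {
  const int shift = 2 * (k - 1);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    SEXP el = STRING_ELT(seqs, s);
    if (el == NA_STRING) continue;
    const char *p = CHAR(el);
    int n = (int) LENGTH(el);
    if (n < k) continue;
    uint64_t fwd = 0, rc = 0;
    int run = 0; // valid bases accumulated
    for (int i = 0; i < n; ++i) {
      int code = base_code(p[i]);
      if (code < 0) { run = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) code) & mask;
      rc = (rc >> 2) | ((uint64_t) (3 - code) << shift);
      if (++run >= k) ++tab[fwd < rc ? fwd : rc];
    }
  }
}

static std::string decode_kmer(uint64_t x, int k) {
  static const char b[] = "ACGT";
  std::string s(k, 'A');
  for (int j = k - 1; j >= 0; --j) {
    s[j] = b[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// reverse complement of a packed k-mer
static inline uint64_t rc_packed(uint64_t x, int k) {
  uint64_t r = 0;
  for (int j = 0; j < k; ++j) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static inline uint64_t canon_packed(uint64_t x, int k) {
  uint64_t r = rc_packed(x, k);
  return x < r ? x : r;
}

static IntegerVector harvest_packed(
    const std::unordered_map<uint64_t, int> &tab, int k) {
  std::vector<std::pair<uint64_t, int>> items(tab.begin(), tab.end());
  std::sort(items.begin(), items.end());
  IntegerVector counts((R_xlen_t) items.size());
  CharacterVector names((R_xlen_t) items.size());
  for (R_xlen_t i = 0; i < (R_xlen_t) items.size(); ++i) {
    counts[i] = items[i].second;
    names[i] = decode_kmer(items[i].first, k);
  }
  counts.attr("names") = names;
  return counts;
}

// ---------------------------------------------------------------------
// string path (k > 31)

static inline void canonicalize_str(const char *w, int k, std::string &out) {
  int dir = 0; // <=0: forward is canonical
  for (int j = 0; j < k; ++j) {
    char f = w[j], r = comp_base(w[k - 1 - j]);
    if (f < r) { dir = -1; break; }
    if (f > r) { dir = 1; break; }
  }
  if (dir <= 0) {
    out.assign(w, k);
  } else {
    out.resize(k);
    for (int j = 0; j < k; ++j) out[j] = comp_base(w[k - 1 - j]);
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static void count_windows_str(const CharacterVector &seqs, int k,
                              std::unordered_map<std::string, int> &tab) {
  std::string can;
  can.reserve(k);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    SEXP el = STRING_ELT(seqs, s);
    if (el == NA_STRING) continue;
    const char *p = CHAR(el);
    int n = (int) LENGTH(el);
    if (n < k) continue;
    int last_bad = -1;
    for (int i = 0; i < n; ++i) {
      if (!valid_base(p[i])) last_bad = i;
      if (i >= k - 1 && last_bad < i - k + 1) {
        canonicalize_str(p + i - k + 1, k, can);
        ++tab[can];
      }
    }
  }
}

static IntegerVector harvest_str(
    const std::unordered_map<std::string, int> &tab) {
  std::vector<const std::pair<const std::string, int> *> items;
  items.reserve(tab.size());
  for (auto &kv : tab) items.push_back(&kv);
  std::sort(items.begin(), items.end(),
            [](const std::pair<const std::string, int> *a,
               const std::pair<const std::string, int> *b) {
              return a->first < b->first;
            });
  IntegerVector counts((R_xlen_t) items.size());
  CharacterVector names((R_xlen_t) items.size());
  for (R_xlen_t i = 0; i < (R_xlen_t) items.size(); ++i) {
    counts[i] = items[i]->second;
    names[i] = items[i]->first;
  }
  counts.attr("names") = names;
  return counts;
}

// ---------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector kmer_count_cpp(CharacterVector seqs, int k) {
  if (k <= 31) {
    std::unordered_map<uint64_t, int> tab;
    count_windows_packed(seqs, k, tab);
    return harvest_packed(tab, k);
  }
  std::unordered_map<std::string, int> tab;
  count_windows_str(seqs, k, tab);
  return harvest_str(tab);
}

// Canonical (k'+1)-mers of `seqs` whose k'-prefix, read in either
// orientation, is present among `prev` (the surviving canonical
// k'-mers). The reverse-orientation prefix of a (k'+1)-mer is the
// reverse complement of its k'-suffix, so membership is checked for the
// canonical forms of both the prefix and the suffix.
// [[Rcpp::export]]
IntegerVector kmer_extend_cpp(CharacterVector seqs, int k1,
                              CharacterVector prev) {
  const int kp = k1 - 1;
  if (k1 <= 31) {
    std::unordered_set<uint64_t> keep;
    keep.reserve((size_t) prev.size() * 2);
    for (R_xlen_t i = 0; i < prev.size(); ++i) {
      const char *p = CHAR(STRING_ELT(prev, i));
      uint64_t x = 0;
      for (int j = 0; j < kp; ++j) x = (x << 2) | (uint64_t) base_code(p[j]);
      keep.insert(x);
    }
    std::unordered_map<uint64_t, int> tab;
    count_windows_packed(seqs, k1, tab);
    const uint64_t pmask = (1ULL << (2 * kp)) - 1;
    for (auto it = tab.begin(); it != tab.end();) {
      uint64_t w = it->first;
      bool ok = keep.count(canon_packed(w >> 2, kp)) > 0 ||
                keep.count(canon_packed(w & pmask, kp)) > 0;
      if (ok) ++it; else it = tab.erase(it);
    }
    return harvest_packed(tab, k1);
  }
  std::unordered_set<std::string> keep;
  for (R_xlen_t i = 0; i < prev.size(); ++i) {
    keep.insert(std::string(CHAR(STRING_ELT(prev, i))));
  }
  std::unordered_map<std::string, int> tab;
  count_windows_str(seqs, k1, tab);
  std::string can;
  for (auto it = tab.begin(); it != tab.end();) {
    const std::string &w = it->first;
    canonicalize_str(w.c_str(), kp, can);
    bool ok = keep.count(can) > 0;
    if (!ok) {
      canonicalize_str(w.c_str() + 1, kp, can);
      ok = keep.count(can) > 0;
    }
    if (ok) ++it; else it = tab.erase(it);
  }
  return harvest_str(tab);
}
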