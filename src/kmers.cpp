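#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// 2-bit base encoding: A=0, C=1, G=2, T=3; -1 for anything else.
// Lowercase (soft-masked) bases encode as their uppercase equivalent.
static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// Append the codes of all valid k-windows of s to out. A window containing
// any non-ACGT character is skipped entirely. Canonical = min(fwd, revcomp).
static void collect_codes(const char *s, size_t n, int k, bool canonical,
                          std::vector<uint64_t> &out) {
  if (n < (size_t)k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;  // consecutive valid bases ending at current position
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++valid >= k) out.push_back(canonical ? std::min(fwd, rev) : fwd);
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
  if (k < 1 || k > 26) stop("k must be between 1 and 26");
  std::vector<uint64_t> codes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    collect_codes(s, LENGTH(STRING_ELT(seqs, i)), k, canonical, codes);
  }
  std::sort(codes.begin(), codes.end());
  // run-length encode the sorted code vector
  std::vector<double> uniq;
  std::vector<int> counts;
  size_t i = 0, n = codes.size();
  while (i < n) {
    size_t j = i;
    while (j < n && codes[j] == codes[i]) ++j;
    uniq.push_back((double)codes[i]);
    counts.push_back((int)(j - i));
    i = j;
  }
  return List::create(_["codes"] = NumericVector(uniq.begin(), uniq.end()),
                      _["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["total"] = (double)n);
}

// 0-based start positions of windows of `seq` whose canonical code is in the
// sorted code set. Each window position is reported at most once.
// [[Rcpp::export]]
IntegerVector cpp_match_positions(std::string seq, NumericVector sorted_codes,
                                  int k, bool canonical) {
  if (k < 1 || k > 26) stop("k must be between 1 and 26");
  std::vector<uint64_t> set(sorted_codes.size());
  for (R_xlen_t i = 0; i < sorted_codes.size(); ++i)
    set[i] = (uint64_t)sorted_codes[i];
  std::vector<int> hits;
  const size_t n = seq.size();
  if (n < (size_t)k || set.empty()) return IntegerVector(0);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++valid >= k) {
      uint64_t code = canonical ? std::min(fwd, rev) : fwd;
      if (std::binary_search(set.begin(), set.end(), code))
        hits.push_back((int)(i - k + 1));
    }
  }
  return IntegerVector(hits.begin(), hits.end());
}

// [[Rcpp::export]]
NumericVector cpp_encode_kmers(CharacterVector windows, bool canonical) {
  NumericVector out(windows.size());
  for (R_xlen_t w = 0; w < windows.size(); ++w) {
    const char *s = CHAR(STRING_ELT(windows, w));
    int k = LENGTH(STRING_ELT(windows, w));
    if (k < 1 || k > 26) stop("k-mer length must be between 1 and 26");
    const int shift = 2 * (k - 1);
    uint64_t fwd = 0, rev = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t)b;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    }
    if (!ok) { out[w] = NA_REAL; continue; }
    out[w] = (double)(canonical ? std::min(fwd, rev) : fwd);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(NumericVector codes, int k) {
  if (k < 1 || k > 26) stop("k must be between 1 and 26");
  CharacterVector out(codes.size());
  std::vector<char> buf(k + 1, '\0');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t code = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = BITS2BASE[code & 3ULL];
      code >>= 2;
    }
    out[i] = std::string(buf.data(), k);
  }
  return out;
}

// Effective length: total length minus N/n; when mask_aware also minus
// lowercase (soft-masked) a/c/g/t.
// [[Rcpp::export]]
IntegerVector cpp_effective_length(CharacterVector seqs, bool mask_aware) {
  IntegerVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int n = LENGTH(STRING_ELT(seqs, i));
    int eff = 0;
    for (int j = 0; j < n; ++j) {
      char c = s[j];
      if (c == 'N' || c == 'n') continue;
      if (mask_aware && (c == 'a' || c == 'c' || c == 'g' || c == 't')) continue;
      ++eff;
    }
    out[i] = eff;
  }
  return out;
}
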