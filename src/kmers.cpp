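#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else (N, lowercase handled
// upstream) interrupts the rolling window. Canonical form is the smaller of
// the k-mer code and its reverse-complement code. k <= 26 keeps codes below
// 2^52 so they round-trip exactly through R doubles.

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 11 || k > 26) stop("k must be in [11, 26]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::unordered_map<uint64_t, double> counts;
  counts.reserve(1 << 20);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (const char* p = str; *p; ++p) {
      int b = base2bit(*p);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = std::min(fwd, rev);
        counts[canon] += 1.0;
      }
    }
  }
  size_t n = counts.size();
  NumericVector codes(n);
  NumericVector cnt(n);
  size_t i = 0;
  for (auto& kv : counts) {
    codes[i] = (double)kv.first;
    cnt[i] = kv.second;
    ++i;
  }
  // sort by code for reproducible order and fast set operations in R
  std::vector<size_t> ord(n);
  for (size_t j = 0; j < n; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return codes[a] < codes[b];
  });
  NumericVector codes_s(n), cnt_s(n);
  for (size_t j = 0; j < n; ++j) {
    codes_s[j] = codes[ord[j]];
    cnt_s[j] = cnt[ord[j]];
  }
  return List::create(_["code"] = codes_s, _["count"] = cnt_s);
}

// [[Rcpp::export(name = ".decode_kmers_cpp")]]
CharacterVector decode_kmers_cpp(NumericVector codes, int k) {
  static const char bases[] = "ACGT";
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t code = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[code & 3ULL];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}
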