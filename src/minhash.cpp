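#include <Rcpp.h>
#include <set>
#include <cstdint>
using namespace Rcpp;

// Fixed-seed 64-bit mixer (splitmix64 finaliser); constant across platforms
// so sketches are bit-reproducible.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Bottom-s MinHash over canonical k-mers (lexicographic min of the strand
// pair under the A<C<G<T order, which equals numeric order of the 2-bit
// encoding). Hash values are truncated to 53 bits so they are exactly
// representable as doubles on the R side. Non-ACGT characters break the
// k-mer run. Returns the sorted distinct bottom-s hash values.
// [[Rcpp::export]]
NumericVector minhash_sketch_cpp(CharacterVector contigs, int k, int s) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  if (s < 1) stop("sketch size must be positive");
  std::set<uint64_t> keep;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int shift = 2 * (k - 1);
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    SEXP el = STRING_ELT(contigs, ci);
    const char* seq = CHAR(el);
    const int n = LENGTH(el);
    uint64_t f = 0, r = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      const int b = base2bit(seq[i]);
      if (b < 0) { run = 0; f = 0; r = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | (((uint64_t)(3 - b)) << shift);
      if (++run >= k) {
        const uint64_t canon = f < r ? f : r;
        const uint64_t h = mix64(canon) >> 11;  // 53-bit
        if ((int)keep.size() < s) {
          keep.insert(h);
        } else if (h < *keep.rbegin()) {
          if (keep.insert(h).second) keep.erase(std::prev(keep.end()));
        }
      }
    }
  }
  NumericVector out(keep.size());
  R_xlen_t i = 0;
  for (std::set<uint64_t>::const_iterator it = keep.begin(); it != keep.end(); ++it)
    out[i++] = (double)*it;
  return out;
}
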