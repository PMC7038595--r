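#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int b2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char compl_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

typedef std::unordered_map<uint64_t, std::vector<int64_t> > SeedIndex;

// Gap-free best-locus identity of one fragment against the indexed target.
// Seed k-mers vote for a (contig, diagonal) placement; the top-voted
// placements are scored by direct base comparison over the aligned overlap.
// Identity is computed over the overlap length; placements covering less
// than min_cov of the fragment (clipped at a contig end) are rejected, so
// scaffold fragmentation does not deflate identity.
static double best_identity(const char* frag, int flen,
                            const std::vector<std::string>& tg,
                            const SeedIndex& idx, int seed_k, int stride,
                            double min_cov) {
  const uint64_t mask = (1ULL << (2 * seed_k)) - 1ULL;
  std::unordered_map<int64_t, int> votes;
  uint64_t code = 0;
  int run = 0;
  for (int i = 0; i < flen; ++i) {
    const int b = b2(frag[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= seed_k) {
      const int q = i - seed_k + 1;
      if (q % stride != 0) continue;
      SeedIndex::const_iterator hit = idx.find(code);
      if (hit == idx.end()) continue;
      const std::vector<int64_t>& pos = hit->second;
      for (size_t j = 0; j < pos.size(); ++j) {
        const int64_t ci = pos[j] >> 40;
        const int64_t tp = pos[j] & ((1LL << 40) - 1);
        votes[(ci << 40) | (uint64_t)(tp - q + flen)]++;  // +flen keeps key >= 0
      }
    }
  }
  if (votes.empty()) return -1.0;
  // score the three best-voted diagonals
  std::vector<std::pair<int, int64_t> > ranked;
  ranked.reserve(votes.size());
  for (std::unordered_map<int64_t, int>::const_iterator it = votes.begin();
       it != votes.end(); ++it)
    ranked.push_back(std::make_pair(it->second, it->first));
  std::sort(ranked.begin(), ranked.end(),
            std::greater<std::pair<int, int64_t> >());
  const size_t ntry = std::min((size_t)3, ranked.size());
  double best = -1.0;
  for (size_t r = 0; r < ntry; ++r) {
    const int64_t key = ranked[r].second;
    const int64_t ci = key >> 40;
    const int64_t off = (key & ((1LL << 40) - 1)) - flen;
    const std::string& t = tg[(size_t)ci];
    int match = 0, overlap = 0;
    for (int i = 0; i < flen; ++i) {
      const int64_t tp = off + i;
      if (tp < 0 || tp >= (int64_t)t.size()) continue;
      ++overlap;
      if (frag[i] == t[(size_t)tp]) ++match;
    }
    if (overlap < min_cov * flen) continue;
    const double ident = 100.0 * match / overlap;
    if (ident > best) best = ident;
  }
  return best;
}

// Fragment-based ANI: the query is cut into non-overlapping fragments
// (trailing partial fragments dropped); each fragment is placed on its best
// target locus by seed voting on both strands and scored gap-free over the
// aligned overlap (which must cover at least min_cov of the fragment). ANI
// is the mean identity over fragments reaching min_ident;
// aligned_fraction is the percentage of fragments that qualify.
// [[Rcpp::export]]
List ani_fragments_cpp(CharacterVector query, CharacterVector target,
                       int fragment, int seed_k, int stride,
                       double min_ident, double min_cov) {
  if (seed_k < 4 || seed_k > 31) stop("seed_k must be between 4 and 31");
  if (stride < 1) stop("stride must be positive");
  if (fragment < seed_k) stop("fragment shorter than seed k-mer");
  std::vector<std::string> tg;
  for (R_xlen_t i = 0; i < target.size(); ++i)
    tg.push_back(std::string(CHAR(STRING_ELT(target, i))));
  // forward-strand seed index of the target
  SeedIndex idx;
  const uint64_t mask = (1ULL << (2 * seed_k)) - 1ULL;
  for (size_t ci = 0; ci < tg.size(); ++ci) {
    const std::string& t = tg[ci];
    uint64_t code = 0;
    int run = 0;
    for (size_t i = 0; i < t.size(); ++i) {
      const int b = b2(t[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= seed_k)
        idx[code].push_back(((int64_t)ci << 40) |
                            (int64_t)(i - seed_k + 1));
    }
  }
  int total = 0, qual = 0;
  double sum_ident = 0.0;
  std::vector<double> idents;
  std::string rc;
  for (R_xlen_t qi = 0; qi < query.size(); ++qi) {
    SEXP el = STRING_ELT(query, qi);
    const char* qs = CHAR(el);
    const int n = LENGTH(el);
    for (int start = 0; start + fragment <= n; start += fragment) {
      ++total;
      double best = best_identity(qs + start, fragment, tg, idx, seed_k,
                                  stride, min_cov);
      rc.assign((size_t)fragment, 'N');
      for (int i = 0; i < fragment; ++i)
        rc[(size_t)(fragment - 1 - i)] = compl_base(qs[start + i]);
      const double brc = best_identity(rc.c_str(), fragment, tg, idx,
                                       seed_k, stride, min_cov);
      if (brc > best) best = brc;
      if (best < 0) best = 0.0;
      idents.push_back(best);
      if (best >= min_ident) { sum_ident += best; ++qual; }
    }
  }
  const double ani = qual > 0 ? sum_ident / qual : NA_REAL;
  const double af = total > 0 ? 100.0 * qual / total : NA_REAL;
  return List::create(_["ani"] = ani,
                      _["aligned_fraction"] = af,
                      _["n_fragments"] = total,
                      _["fragment_identity"] = wrap(idents));
}
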