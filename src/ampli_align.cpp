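#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit sets over (A, C, G, T). Two symbols match
// when their sets intersect, so a degenerate primer base matches any read
// base it encodes.
static inline int iupac_bits(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1 | 4;   case 'Y': return 2 | 8;
    case 'S': return 2 | 4;   case 'W': return 1 | 8;
    case 'K': return 4 | 8;   case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8;  case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8;  case 'V': return 1 | 2 | 4;
    case 'N': return 1 | 2 | 4 | 8;
    default:  return 0;
  }
}

static std::vector<int> encode_iupac(const std::string& s, const char* what) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = iupac_bits(s[i]);
    if (b == 0)
      stop("non-nucleotide character '%c' in %s", s[i], what);
    out[i] = b;
  }
  return out;
}

// Global (end-to-end) edit distance with unit costs and IUPAC-aware match.
// [[Rcpp::export]]
int cpp_iupac_edit(std::string a, std::string b) {
  std::vector<int> pa = encode_iupac(a, "first sequence");
  std::vector<int> pb = encode_iupac(b, "second sequence");
  const size_t m = pa.size(), n = pb.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (size_t j = 0; j <= n; ++j) prev[j] = static_cast<int>(j);
  for (size_t i = 1; i <= m; ++i) {
    cur[0] = static_cast<int>(i);
    for (size_t j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + ((pa[i - 1] & pb[j - 1]) ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Semi-global search: align the whole pattern against the best-matching
// substring of the text (free start and end in the text). Returns
// c(distance, start, end), 1-based inclusive span in the text; start > end
// encodes an empty match (pattern fully deleted). Leftmost end, then
// leftmost start, breaks ties.
// [[Rcpp::export]]
IntegerVector cpp_iupac_find(std::string pattern, std::string text) {
  std::vector<int> pp = encode_iupac(pattern, "pattern");
  std::vector<int> pt = encode_iupac(text, "text");
  const size_t m = pp.size(), n = pt.size();
  if (m == 0) stop("empty pattern");
  // D[i][j]: best distance of pattern[0..i) vs a text substring ending at j;
  // S[i][j]: 1-based start of that substring.
  std::vector<int> dprev(n + 1), dcur(n + 1), sprev(n + 1), scur(n + 1);
  for (size_t j = 0; j <= n; ++j) { dprev[j] = 0; sprev[j] = static_cast<int>(j) + 1; }
  for (size_t i = 1; i <= m; ++i) {
    dcur[0] = static_cast<int>(i);
    scur[0] = 1;
    for (size_t j = 1; j <= n; ++j) {
      int sub = dprev[j - 1] + ((pp[i - 1] & pt[j - 1]) ? 0 : 1);
      int del = dprev[j] + 1;      // delete pattern char
      int ins = dcur[j - 1] + 1;   // insert text char
      int best = sub, st = sprev[j - 1];
      if (del < best || (del == best && sprev[j] < st)) { best = del; st = sprev[j]; }
      if (ins < best || (ins == best && scur[j - 1] < st)) { best = ins; st = scur[j - 1]; }
      dcur[j] = best;
      scur[j] = st;
    }
    std::swap(dprev, dcur);
    std::swap(sprev, scur);
  }
  int bestj = 0, bestd = dprev[0];
  for (size_t j = 1; j <= n; ++j)
    if (dprev[j] < bestd) { bestd = dprev[j]; bestj = static_cast<int>(j); }
  return IntegerVector::create(bestd, sprev[bestj], bestj);
}

static inline int max_run(const int* agree, const int* order, int nsite,
                          int npair, int p) {
  int best = 0, cur = 0;
  for (int s = 0; s < nsite; ++s) {
    if (agree[p + static_cast<size_t>(order[s]) * npair]) {
      if (++cur > best) best = cur;
    } else {
      cur = 0;
    }
  }
  return best;
}

// Longest run of agreement per pair under the identity site order.
// `agree` is an npair x nsite 0/1 matrix.
// [[Rcpp::export]]
IntegerVector cpp_max_runs(IntegerMatrix agree) {
  const int npair = agree.nrow(), nsite = agree.ncol();
  std::vector<int> id(nsite);
  for (int s = 0; s < nsite; ++s) id[s] = s;
  IntegerVector out(npair);
  for (int p = 0; p < npair; ++p)
    out[p] = max_run(agree.begin(), id.data(), nsite, npair, p);
  return out;
}

// Sorted (descending) agreement-run length profile of one pair under a
// site order; the primary fragment score is the leading element.
static void run_profile(const int* agree, const int* order, int nsite,
                        int npair, int p, std::vector<int>& out) {
  out.clear();
  int cur = 0;
  for (int s = 0; s < nsite; ++s) {
    if (agree[p + static_cast<size_t>(order[s]) * npair]) {
      ++cur;
    } else if (cur > 0) {
      out.push_back(cur);
      cur = 0;
    }
  }
  if (cur > 0) out.push_back(cur);
  std::sort(out.begin(), out.end(), std::greater<int>());
}

// Lexicographic comparison of run profiles (missing entries rank as 0).
static int profile_cmp(const std::vector<int>& a, const std::vector<int>& b) {
  const size_t n = std::max(a.size(), b.size());
  for (size_t i = 0; i < n; ++i) {
    int av = i < a.size() ? a[i] : 0;
    int bv = i < b.size() ? b[i] : 0;
    if (av != bv) return av < bv ? -1 : 1;
  }
  return 0;
}

// Permutation engine for the gene-conversion scan. `perms` holds 0-based
// site orders, one per row; the same order is applied to every pair (one
// column shuffle of the alignment per replicate). Replicates are ranked by
// the full run profile, and only strictly better replicates are counted,
// so ties favor the observed arrangement. Returns per-pair strictly-better
// counts, the observed max-run scores, and the count of replicates whose
// alignment-wide best profile strictly beats the observed one.
// [[Rcpp::export]]
List cpp_geneconv_perm(IntegerMatrix agree, IntegerMatrix perms) {
  const int npair = agree.nrow(), nsite = agree.ncol();
  const int nperm = perms.nrow();
  if (perms.ncol() != nsite) stop("permutation width mismatch");
  std::vector<int> id(nsite);
  for (int s = 0; s < nsite; ++s) id[s] = s;
  std::vector< std::vector<int> > obs(npair);
  std::vector<int> gbest;  // lexicographically best observed profile
  IntegerVector obs_score(npair);
  for (int p = 0; p < npair; ++p) {
    run_profile(agree.begin(), id.data(), nsite, npair, p, obs[p]);
    obs_score[p] = obs[p].empty() ? 0 : obs[p][0];
    if (p == 0 || profile_cmp(obs[p], gbest) > 0) gbest = obs[p];
  }
  IntegerVector counts(npair);
  int gcount = 0;
  std::vector<int> order(nsite), prof, permbest;
  for (int k = 0; k < nperm; ++k) {
    for (int s = 0; s < nsite; ++s) order[s] = perms(k, s);
    permbest.clear();
    for (int p = 0; p < npair; ++p) {
      run_profile(agree.begin(), order.data(), nsite, npair, p, prof);
      if (profile_cmp(prof, obs[p]) > 0) counts[p]++;
      if (p == 0 || profile_cmp(prof, permbest) > 0) permbest = prof;
    }
    if (profile_cmp(permbest, gbest) > 0) gcount++;
  }
  return List::create(_["counts"] = counts, _["observed_score"] = obs_score,
                      _["global_count"] = gcount);
}
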