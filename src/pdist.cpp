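// Ends-free global alignment ("overlap" alignment with free end gaps in
// BOTH sequences) used for p-distance: match +1, mismatch -1, interior
// gaps -2 per base, leading/trailing gaps in either sequence free.
// Along one optimal path we count mismatches and compared sites; columns
// holding a gap or an ambiguous base (anything outside A/C/G/T) in
// either sequence are excluded from both counts, per the p-distance
// convention.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N / IUPAC ambiguity: neutral, uncounted
  }
}

static const int GAP = -2;

struct AlignBuffers {
  std::vector<int> S;
  std::vector<signed char> tb;
  std::vector<int> ai, bi;
};

// counts[0] = mismatches, counts[1] = comparable sites
static void pdist_core(const std::string& a, const std::string& b,
                       int* counts, AlignBuffers& buf) {
  const int n = (int) a.size(), m = (int) b.size();
  std::vector<int>& ai = buf.ai;
  std::vector<int>& bi = buf.bi;
  ai.resize(n); bi.resize(m);
  for (int i = 0; i < n; ++i) ai[i] = base_code(a[i]);
  for (int j = 0; j < m; ++j) bi[j] = base_code(b[j]);

  const size_t W = (size_t) m + 1;
  std::vector<int>& S = buf.S;
  std::vector<signed char>& tb = buf.tb;
  const size_t need = (size_t)(n + 1) * W;
  if (S.size() < need) { S.resize(need); tb.resize(need); }
  for (int j = 0; j <= m; ++j) { S[j] = 0; tb[j] = 0; }
  for (int i = 1; i <= n; ++i) { S[i * W] = 0; tb[i * W] = 0; }
  static const int SUB[5][5] = {
    { 1, -1, -1, -1, 0 },
    { -1, 1, -1, -1, 0 },
    { -1, -1, 1, -1, 0 },
    { -1, -1, -1, 1, 0 },
    { 0, 0, 0, 0, 0 }
  };
  // S[i][0] = S[0][j] = 0: free leading end gaps
  for (int i = 1; i <= n; ++i) {
    const int* Sprev = &S[(size_t)(i - 1) * W];
    int* Scur = &S[(size_t) i * W];
    signed char* tcur = &tb[(size_t) i * W];
    const int* subrow = SUB[ai[i - 1]];
    const int* bp = bi.data();
    for (int j = 1; j <= m; ++j) {
      int best = Sprev[j - 1] + subrow[bp[j - 1]];
      signed char t = 1;                  // diagonal
      const int up = Sprev[j] + GAP;      // gap in b
      if (up > best) { best = up; t = 2; }
      const int left = Scur[j - 1] + GAP; // gap in a
      if (left > best) { best = left; t = 3; }
      Scur[j] = best;
      tcur[j] = t;
    }
  }
  // free trailing end gaps: best cell on last row or last column
  int bi_ = n, bj_ = m, bscore = S[(size_t) n * W + m];
  for (int j = 0; j <= m; ++j) {
    if (S[(size_t) n * W + j] > bscore) { bscore = S[(size_t) n * W + j]; bi_ = n; bj_ = j; }
  }
  for (int i = 0; i <= n; ++i) {
    if (S[(size_t) i * W + m] > bscore) { bscore = S[(size_t) i * W + m]; bi_ = i; bj_ = m; }
  }
  int mism = 0, sites = 0;
  int i = bi_, j = bj_;
  while (i > 0 && j > 0) {
    const signed char t = tb[(size_t) i * W + j];
    if (t == 1) {
      if (ai[i - 1] != 4 && bi[j - 1] != 4) {
        ++sites;
        if (ai[i - 1] != bi[j - 1]) ++mism;
      }
      --i; --j;
    } else if (t == 2) {
      --i;
    } else if (t == 3) {
      --j;
    } else {
      break;  // reached a free-end cell
    }
  }
  counts[0] = mism;
  counts[1] = sites;
}

// Local (Smith-Waterman) variant used for read-level screening: reads
// carry technical flanks (tags, primers) and cover only part of the
// barcode frame, so the homologous region is found locally and the
// counts are taken along its path. Same scoring as above.
static void pdist_local_core(const std::string& a, const std::string& b,
                             int* counts, AlignBuffers& buf) {
  const int n = (int) a.size(), m = (int) b.size();
  std::vector<int>& ai = buf.ai;
  std::vector<int>& bi = buf.bi;
  ai.resize(n); bi.resize(m);
  for (int i = 0; i < n; ++i) ai[i] = base_code(a[i]);
  for (int j = 0; j < m; ++j) bi[j] = base_code(b[j]);

  const size_t W = (size_t) m + 1;
  std::vector<int>& S = buf.S;
  std::vector<signed char>& tb = buf.tb;
  const size_t need = (size_t)(n + 1) * W;
  if (S.size() < need) { S.resize(need); tb.resize(need); }
  for (int j = 0; j <= m; ++j) { S[j] = 0; tb[j] = 0; }
  for (int i = 1; i <= n; ++i) { S[i * W] = 0; tb[i * W] = 0; }
  static const int SUB[5][5] = {
    { 1, -1, -1, -1, 0 },
    { -1, 1, -1, -1, 0 },
    { -1, -1, 1, -1, 0 },
    { -1, -1, -1, 1, 0 },
    { 0, 0, 0, 0, 0 }
  };
  int bscore = 0, bi_ = 0, bj_ = 0;
  for (int i = 1; i <= n; ++i) {
    const int* Sprev = &S[(size_t)(i - 1) * W];
    int* Scur = &S[(size_t) i * W];
    signed char* tcur = &tb[(size_t) i * W];
    const int* subrow = SUB[ai[i - 1]];
    const int* bp = bi.data();
    for (int j = 1; j <= m; ++j) {
      int best = Sprev[j - 1] + subrow[bp[j - 1]];
      signed char t = 1;
      const int up = Sprev[j] + GAP;
      if (up > best) { best = up; t = 2; }
      const int left = Scur[j - 1] + GAP;
      if (left > best) { best = left; t = 3; }
      if (best <= 0) { best = 0; t = 0; }
      Scur[j] = best;
      tcur[j] = t;
      if (best > bscore) { bscore = best; bi_ = i; bj_ = j; }
    }
  }
  int mism = 0, sites = 0;
  int i = bi_, j = bj_;
  while (i > 0 && j > 0) {
    const signed char t = tb[(size_t) i * W + j];
    if (t == 1) {
      if (ai[i - 1] != 4 && bi[j - 1] != 4) {
        ++sites;
        if (ai[i - 1] != bi[j - 1]) ++mism;
      }
      --i; --j;
    } else if (t == 2) {
      --i;
    } else if (t == 3) {
      --j;
    } else {
      break;
    }
  }
  counts[0] = mism;
  counts[1] = sites;
}

// [[Rcpp::export(name = ".pdist_local_batch")]]
IntegerMatrix pdist_local_batch(CharacterVector queries, std::string ref) {
  const int n = queries.size();
  IntegerMatrix out(n, 2);
  int counts[2];
  AlignBuffers buf;
  for (int k = 0; k < n; ++k) {
    pdist_local_core(as<std::string>(queries[k]), ref, counts, buf);
    out(k, 0) = counts[0];
    out(k, 1) = counts[1];
  }
  colnames(out) = CharacterVector::create("mismatches", "sites");
  return out;
}

// [[Rcpp::export(name = ".pdist_count")]]
IntegerVector pdist_count(std::string a, std::string b) {
  int counts[2];
  AlignBuffers buf;
  pdist_core(a, b, counts, buf);
  return IntegerVector::create(_["mismatches"] = counts[0],
                               _["sites"] = counts[1]);
}

// [[Rcpp::export(name = ".pdist_count_batch")]]
IntegerMatrix pdist_count_batch(CharacterVector queries, std::string ref) {
  const int n = queries.size();
  IntegerMatrix out(n, 2);
  int counts[2];
  AlignBuffers buf;
  for (int k = 0; k < n; ++k) {
    pdist_core(as<std::string>(queries[k]), ref, counts, buf);
    out(k, 0) = counts[0];
    out(k, 1) = counts[1];
  }
  colnames(out) = CharacterVector::create("mismatches", "sites");
  return out;
}
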