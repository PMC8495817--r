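// Semi-global (ends-free / overlap) pairwise alignment with affine gap costs.
//
// A gap run of length L inside the overlap region costs gap_open + L * gap_extend;
// terminal gap runs (leading/trailing, in either row) are free and are excluded
// from the identity denominator.  Optima are resolved lexicographically:
// maximal score, then minimal number of internal gap columns, then a fixed
// deterministic preference (substitution > gap-in-subject > gap-in-query;
// endpoints prefer the longest overlap).  Any symbol pair other than two equal
// bytes counts as a mismatch, so IUPAC ambiguity codes only match themselves.
//
// The lexicographic objective (score desc, gap columns asc) is packed into one
// 64-bit integer, v = score * 2^20 - gaps (gaps < 2^20 always holds at
// desk-scale lengths), so that v1 > v2 iff (score, gaps) is strictly better.
// Score rows roll; only byte-sized traceback pointers span the full matrix.

#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

const int64_t NEG = INT64_MIN / 4;
const int64_t SC = 1 << 20;  // score unit

struct AlnOut {
  std::string ga, gb;
  int score;
};

// state codes: 0 = free start, 1 = M (substitution), 2 = X (query residue over
// gap in subject), 3 = Y (gap in query over subject residue)
AlnOut align_core(const std::string& a, const std::string& b,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  const int W = n + 1;
  const int64_t vmatch = (int64_t)match * SC;
  const int64_t vmis = (int64_t)mismatch * SC;
  const int64_t vgoe = (int64_t)(gap_open + gap_extend) * SC - 1;  // open: score + 1 gap col
  const int64_t vge = (int64_t)gap_extend * SC - 1;                // extend: score + 1 gap col

  std::vector<int64_t> pM(W, NEG), pX(W, NEG), pY(W, NEG);
  std::vector<int64_t> cM(W, NEG), cX(W, NEG), cY(W, NEG);
  std::vector<unsigned char> PM((size_t)(m + 1) * W, 0), PX((size_t)(m + 1) * W, 0),
      PY((size_t)(m + 1) * W, 0);

  // endpoint bookkeeping: trailing terminal gaps are free; the degenerate
  // no-overlap alignment (score 0, no internal gaps) is always available
  int64_t bestV = 0;
  int bi = m, bj = 0;
  unsigned char bstate = 0;
  auto consider = [&](int i, int j, unsigned char st, int64_t v) {
    if (v <= NEG) return;
    bool take = false;
    if (v > bestV) {
      take = true;
    } else if (v == bestV && st != 0) {
      if (bstate == 0) take = true;
      else {
        int cur = bi + bj, cand = i + j;
        if (cand > cur) take = true;
        else if (cand == cur && i > bi) take = true;
        else if (cand == cur && i == bi && st < bstate) take = true;
      }
    }
    if (take) { bestV = v; bi = i; bj = j; bstate = st; }
  };

  for (int i = 1; i <= m; ++i) {
    cM[0] = cX[0] = cY[0] = NEG;
    const char ai = a[i - 1];
    const size_t row = (size_t)i * W;
    for (int j = 1; j <= n; ++j) {
      // --- M: diagonal from (i-1, j-1); ties keep the first of M, X, Y, start
      {
        int64_t bs = pM[j - 1];
        unsigned char bp = 1;
        if (pX[j - 1] > bs) { bs = pX[j - 1]; bp = 2; }
        if (pY[j - 1] > bs) { bs = pY[j - 1]; bp = 3; }
        if ((i == 1 || j == 1) && 0 > bs) { bs = 0; bp = 0; }
        if (bs > NEG) {
          cM[j] = bs + ((ai == b[j - 1]) ? vmatch : vmis);
          PM[row + j] = bp;
        } else {
          cM[j] = NEG;
        }
      }
      // --- X: from (i-1, j), query residue over gap in subject
      {
        int64_t bs = (pM[j] > NEG) ? pM[j] + vgoe : NEG;
        unsigned char bp = 1;
        if (pX[j] > NEG && pX[j] + vge > bs) { bs = pX[j] + vge; bp = 2; }
        if (pY[j] > NEG && pY[j] + vgoe > bs) { bs = pY[j] + vgoe; bp = 3; }
        if (i == 1 && vgoe > bs) { bs = vgoe; bp = 0; }
        cX[j] = bs;
        if (bs > NEG) PX[row + j] = bp;
      }
      // --- Y: from (i, j-1), gap in query over subject residue
      {
        int64_t bs = (cM[j - 1] > NEG) ? cM[j - 1] + vgoe : NEG;
        unsigned char bp = 1;
        if (cX[j - 1] > NEG && cX[j - 1] + vgoe > bs) { bs = cX[j - 1] + vgoe; bp = 2; }
        if (cY[j - 1] > NEG && cY[j - 1] + vge > bs) { bs = cY[j - 1] + vge; bp = 3; }
        if (j == 1 && vgoe > bs) { bs = vgoe; bp = 0; }
        cY[j] = bs;
        if (bs > NEG) PY[row + j] = bp;
      }
    }
    consider(i, n, 1, cM[n]);
    consider(i, n, 2, cX[n]);
    consider(i, n, 3, cY[n]);
    if (i == m) {
      for (int j = 1; j < n; ++j) {
        consider(m, j, 1, cM[j]);
        consider(m, j, 2, cX[j]);
        consider(m, j, 3, cY[j]);
      }
    }
    pM.swap(cM); pX.swap(cX); pY.swap(cY);
  }

  AlnOut out;
  // recover score from the packed objective: v = s * SC - g with 0 <= g < SC,
  // so s = ceil(v / SC); |v| < 2^40, exact in double
  out.score = (int)std::ceil((double)bestV / (double)SC);
  if (bstate == 0) {
    out.ga = a + std::string(n, '-');
    out.gb = std::string(m, '-') + b;
    return out;
  }

  std::string ra, rb;  // built backwards
  if (bj == n) {
    for (int i2 = m; i2 > bi; --i2) { ra.push_back(a[i2 - 1]); rb.push_back('-'); }
  } else {
    for (int j2 = n; j2 > bj; --j2) { ra.push_back('-'); rb.push_back(b[j2 - 1]); }
  }
  int i = bi, j = bj;
  unsigned char st = bstate;
  while (st != 0) {
    unsigned char pred;
    const size_t row = (size_t)i * W;
    if (st == 1) {
      pred = PM[row + j];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
    } else if (st == 2) {
      pred = PX[row + j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
    } else {
      pred = PY[row + j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
    }
    st = pred;
  }
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }

  out.ga.assign(ra.rbegin(), ra.rend());
  out.gb.assign(rb.rbegin(), rb.rend());
  return out;
}

struct Stats { int n_ident, n_denom, q_res; };

Stats stats_from_gapped(const std::string& ga, const std::string& gb) {
  const int L = (int)ga.size();
  int fa = -1, la = -1, fb = -1, lb = -1;
  for (int k = 0; k < L; ++k) {
    if (ga[k] != '-') { if (fa < 0) fa = k; la = k; }
    if (gb[k] != '-') { if (fb < 0) fb = k; lb = k; }
  }
  Stats s = {0, 0, 0};
  if (fa < 0 || fb < 0) return s;
  int lo = std::max(fa, fb), hi = std::min(la, lb);
  for (int k = lo; k <= hi; ++k) {
    ++s.n_denom;
    if (ga[k] != '-') ++s.q_res;
    if (ga[k] != '-' && ga[k] == gb[k]) ++s.n_ident;
  }
  return s;
}

}  // namespace

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b, int match, int mismatch,
                    int gap_open, int gap_extend) {
  AlnOut r = align_core(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(_["query"] = r.ga, _["subject"] = r.gb, _["score"] = r.score);
}

// [[Rcpp::export]]
IntegerVector pair_stats_cpp(std::string a, std::string b, int match, int mismatch,
                             int gap_open, int gap_extend) {
  AlnOut r = align_core(a, b, match, mismatch, gap_open, gap_extend);
  Stats s = stats_from_gapped(r.ga, r.gb);
  return IntegerVector::create(_["n_ident"] = s.n_ident, _["n_denom"] = s.n_denom,
                               _["q_res"] = s.q_res, _["score"] = r.score);
}

// all unordered pairs i < j; one row per pair with the query = sequence i
// [[Rcpp::export]]
IntegerMatrix all_pairs_stats_cpp(CharacterVector seqs, int match, int mismatch,
                                  int gap_open, int gap_extend) {
  const int n = seqs.size();
  const R_xlen_t np = (R_xlen_t)n * (n - 1) / 2;
  IntegerMatrix out(np, 6);
  colnames(out) = CharacterVector::create("i", "j", "n_ident", "n_denom", "q_res", "score");
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  R_xlen_t r = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j, ++r) {
      AlnOut a = align_core(ss[i], ss[j], match, mismatch, gap_open, gap_extend);
      Stats s = stats_from_gapped(a.ga, a.gb);
      out(r, 0) = i + 1;
      out(r, 1) = j + 1;
      out(r, 2) = s.n_ident;
      out(r, 3) = s.n_denom;
      out(r, 4) = s.q_res;
      out(r, 5) = a.score;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// one query against many subjects; one row per subject
// [[Rcpp::export]]
IntegerMatrix query_stats_cpp(std::string query, CharacterVector subjects, int match,
                              int mismatch, int gap_open, int gap_extend) {
  const int n = subjects.size();
  IntegerMatrix out(n, 4);
  colnames(out) = CharacterVector::create("n_ident", "n_denom", "q_res", "score");
  for (int j = 0; j < n; ++j) {
    AlnOut a = align_core(query, as<std::string>(subjects[j]), match, mismatch,
                          gap_open, gap_extend);
    Stats s = stats_from_gapped(a.ga, a.gb);
    out(j, 0) = s.n_ident;
    out(j, 1) = s.n_denom;
    out(j, 2) = s.q_res;
    out(j, 3) = a.score;
  }
  return out;
}
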