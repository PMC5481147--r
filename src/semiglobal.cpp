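// Semi-global (end-gap-free) affine-gap alignment.
//
// Convention: query `a`, reference `b`.  Leading and trailing gaps on either
// sequence are free; an alignment may only terminate at a sequence end.
// A gap of length g costs gap_open + g * gap_extend (open <= 0, extend <= 0).
// CIGAR is reported relative to the query: M consumes both, I consumes query
// only, D consumes reference only.  Coordinates are 0-based half-open.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

// state codes used in traceback matrices
enum { ST_M = 0, ST_I = 1, ST_D = 2, ST_START = 3 };

struct AlnResult {
  int score;
  std::string cigar;
  int a_start, a_end, b_start, b_end;
  int matches, columns;
  bool found;
};

static List result_to_list(const AlnResult& r) {
  return List::create(
    _["score"] = r.score,
    _["cigar"] = r.cigar,
    _["a_start"] = r.a_start, _["a_end"] = r.a_end,
    _["b_start"] = r.b_start, _["b_end"] = r.b_end,
    _["matches"] = r.matches, _["columns"] = r.columns,
    _["found"] = r.found);
}

static void append_cigar(std::string& out, char op, int n) {
  if (n <= 0) return;
  out += std::to_string(n);
  out += op;
}

// Full-rectangle DP.  Memory: 3 traceback bytes per cell, rolling score rows.
static AlnResult semiglobal_full(const std::string& a, const std::string& b,
                                 int match, int mismatch,
                                 int gap_open, int gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  const size_t row = (size_t)n + 1;
  std::vector<int> M0(row), I0(row), D0(row), M1(row), I1(row), D1(row);
  // packed traceback: bits 0-1 M-pred, 2-3 I-pred, 4-5 D-pred
  std::vector<unsigned char> tb((size_t)(m + 1) * row,
                                (unsigned char)(ST_START | (ST_START << 2) | (ST_START << 4)));

  // row 0: boundary, M = 0 (free leading gap in a), I/D unreachable
  for (int j = 0; j <= n; ++j) { M0[j] = 0; I0[j] = NEG_INF; D0[j] = NEG_INF; }

  int best = 0, best_i = 0, best_j = 0;
  unsigned char best_st = ST_START;
  // trailing-gap-free end at (0, n): empty alignment, score 0
  for (int i = 1; i <= m; ++i) {
    M1[0] = 0; I1[0] = NEG_INF; D1[0] = NEG_INF; // col 0 boundary
    unsigned char* tbr = &tb[(size_t)i * row];
    for (int j = 1; j <= n; ++j) {
      unsigned char pack = 0;
      // M: consume a[i-1], b[j-1]
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int vm = M0[j - 1], vi = I0[j - 1], vd = D0[j - 1];
      int v = vm; unsigned char st = ST_M;
      if (vi > v) { v = vi; st = ST_I; }
      if (vd > v) { v = vd; st = ST_D; }
      M1[j] = v + s; pack |= st;
      // I: consume a[i-1] only (gap in b)
      int oi = M0[j] + gap_open + gap_extend;
      int ei = I0[j] + gap_extend;
      int di = D0[j] + gap_open + gap_extend;
      if (oi >= ei && oi >= di) { I1[j] = oi; pack |= (ST_M << 2); }
      else if (ei >= di)        { I1[j] = ei; pack |= (ST_I << 2); }
      else                      { I1[j] = di; pack |= (ST_D << 2); }
      // D: consume b[j-1] only (gap in a)
      int od = M1[j - 1] + gap_open + gap_extend;
      int ed = D1[j - 1] + gap_extend;
      int id = I1[j - 1] + gap_open + gap_extend;
      if (od >= ed && od >= id) { D1[j] = od; pack |= (ST_M << 4); }
      else if (ed >= id)        { D1[j] = ed; pack |= (ST_D << 4); }
      else                      { D1[j] = id; pack |= (ST_I << 4); }
      tbr[j] = pack;
      // candidate terminals: last row or last column
      if (i == m || j == n) {
        int vbest = M1[j]; unsigned char sbest = ST_M;
        if (I1[j] > vbest) { vbest = I1[j]; sbest = ST_I; }
        if (D1[j] > vbest) { vbest = D1[j]; sbest = ST_D; }
        if (vbest > best) { best = vbest; best_i = i; best_j = j; best_st = sbest; }
      }
    }
    std::swap(M0, M1); std::swap(I0, I1); std::swap(D0, D1);
  }

  AlnResult r; r.score = best; r.found = best > 0;
  r.matches = 0; r.columns = 0;
  if (!r.found) { r.a_start = r.a_end = r.b_start = r.b_end = 0; r.cigar = ""; return r; }
  // traceback
  int i = best_i, j = best_j; unsigned char st = best_st;
  std::vector<std::pair<char, int> > ops;
  while (st != ST_START && i > 0 && j >= 0) {
    const unsigned char pk = tb[(size_t)i * row + j];
    if (st == ST_M) {
      if (j == 0) break;
      if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
      else ops.push_back(std::make_pair('M', 1));
      if (a[i - 1] == b[j - 1]) r.matches++;
      r.columns++;
      st = pk & 3; --i; --j;
      if (i == 0 || j == 0) break; // reached boundary after consuming
    } else if (st == ST_I) {
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back(std::make_pair('I', 1));
      r.columns++;
      st = (pk >> 2) & 3; --i;
      if (i == 0) break;
    } else { // ST_D
      if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
      else ops.push_back(std::make_pair('D', 1));
      r.columns++;
      st = (pk >> 4) & 3; --j;
      if (j == 0) break;
    }
  }
  r.a_start = i; r.a_end = best_i;
  r.b_start = j; r.b_end = best_j;
  std::string cig;
  for (int k = (int)ops.size() - 1; k >= 0; --k) append_cigar(cig, ops[k].first, ops[k].second);
  r.cigar = cig;
  return r;
}

// Banded DP restricted to diagonals d = j - i in [dlo, dhi].
static AlnResult semiglobal_banded(const std::string& a, const std::string& b,
                                   int match, int mismatch,
                                   int gap_open, int gap_extend,
                                   int dlo, int dhi) {
  const int m = (int)a.size(), n = (int)b.size();
  dlo = std::max(dlo, -m); dhi = std::min(dhi, n);
  if (dlo > dhi) { AlnResult r; r.score = 0; r.found = false;
    r.a_start = r.a_end = r.b_start = r.b_end = r.matches = r.columns = 0; return r; }
  const int W = dhi - dlo + 1;
  // rolling score rows; one packed traceback byte per cell
  // (bits 0-1: M-pred, 2-3: I-pred, 4-5: D-pred)
  std::vector<int> M0(W, NEG_INF), I0(W, NEG_INF), D0(W, NEG_INF);
  std::vector<int> M1(W, NEG_INF), I1(W, NEG_INF), D1(W, NEG_INF);
  std::vector<unsigned char> tb((size_t)(m + 1) * W,
                                (unsigned char)(ST_START | (ST_START << 2) | (ST_START << 4)));
  #define INBAND(i, j) ((j) - (i) >= dlo && (j) - (i) <= dhi)

  // row 0 boundary: M = 0 (free leading gap in a)
  for (int j = 0; j <= n; ++j) if (INBAND(0, j)) M0[j - dlo] = 0;

  const int go = gap_open + gap_extend, ge = gap_extend;
  int best = 0, best_i = 0, best_j = 0; unsigned char best_st = ST_START;
  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(1, i + dlo), jhi = std::min(n, i + dhi);
    const char ai = a[i - 1];
    int* Mr = M1.data(); int* Ir = I1.data(); int* Dr = D1.data();
    const int* Mp = M0.data(); const int* Ip = I0.data(); const int* Dp = D0.data();
    unsigned char* tbr = &tb[(size_t)i * W];
    const int wlo = jlo - i - dlo, whi = jhi - i - dlo;
    if (jlo > jhi) {  // corridor misses [1, n] on this row
      std::fill(M1.begin(), M1.end(), NEG_INF);
      std::fill(I1.begin(), I1.end(), NEG_INF);
      std::fill(D1.begin(), D1.end(), NEG_INF);
      if (INBAND(i, 0)) M1[-i - dlo] = 0;
      std::swap(M0, M1); std::swap(I0, I1); std::swap(D0, D1);
      continue;
    }
    if (wlo > 0) { Mr[wlo - 1] = NEG_INF; Ir[wlo - 1] = NEG_INF; Dr[wlo - 1] = NEG_INF; }
    if (whi + 1 < W) { Mr[whi + 1] = NEG_INF; Ir[whi + 1] = NEG_INF; Dr[whi + 1] = NEG_INF; }
    // col 0 boundary for this row (free leading gap in b); after the edge
    // guards, which may target the same cell
    if (INBAND(i, 0)) { Mr[-i - dlo] = 0; Ir[-i - dlo] = NEG_INF; Dr[-i - dlo] = NEG_INF; }
    for (int w = wlo; w <= whi; ++w) {
      const int j = i + dlo + w;
      unsigned char pack = 0;
      // M from (i-1, j-1): previous row, same w
      {
        int vm = Mp[w], vi = Ip[w], vd = Dp[w];
        int v = vm; unsigned char st = ST_M;
        if (vi > v) { v = vi; st = ST_I; }
        if (vd > v) { v = vd; st = ST_D; }
        Mr[w] = v + ((ai == b[j - 1]) ? match : mismatch);
        pack |= st;
      }
      // I from (i-1, j): previous row, w+1
      {
        int oi = NEG_INF, ei = NEG_INF, di = NEG_INF;
        if (w + 1 < W) {  // NEG_INF has headroom; no overflow guards needed
          oi = Mp[w + 1] + go;
          ei = Ip[w + 1] + ge;
          di = Dp[w + 1] + go;
        }
        if (oi >= ei && oi >= di) { Ir[w] = oi; pack |= (ST_M << 2); }
        else if (ei >= di)        { Ir[w] = ei; pack |= (ST_I << 2); }
        else                      { Ir[w] = di; pack |= (ST_D << 2); }
      }
      // D from (i, j-1): same row, w-1
      {
        int od = NEG_INF, ed = NEG_INF, id = NEG_INF;
        if (w - 1 >= 0) {
          od = Mr[w - 1] + go;
          ed = Dr[w - 1] + ge;
          id = Ir[w - 1] + go;
        }
        if (od >= ed && od >= id) { Dr[w] = od; pack |= (ST_M << 4); }
        else if (ed >= id)        { Dr[w] = ed; pack |= (ST_D << 4); }
        else                      { Dr[w] = id; pack |= (ST_I << 4); }
      }
      tbr[w] = pack;
      if (i == m || j == n) {
        int vb = Mr[w]; unsigned char sb = ST_M;
        if (Ir[w] > vb) { vb = Ir[w]; sb = ST_I; }
        if (Dr[w] > vb) { vb = Dr[w]; sb = ST_D; }
        if (vb > best) { best = vb; best_i = i; best_j = j; best_st = sb; }
      }
    }
    std::swap(M0, M1); std::swap(I0, I1); std::swap(D0, D1);
  }

  AlnResult r; r.score = best; r.found = best > 0; r.matches = 0; r.columns = 0;
  if (!r.found) { r.a_start = r.a_end = r.b_start = r.b_end = 0; r.cigar = ""; return r; }
  int i = best_i, j = best_j; unsigned char st = best_st;
  std::vector<std::pair<char, int> > ops;
  while (st != ST_START && i > 0 && j >= 0) {
    const unsigned char pk = tb[(size_t)i * W + (j - i - dlo)];
    if (st == ST_M) {
      if (j == 0) break;
      if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
      else ops.push_back(std::make_pair('M', 1));
      if (a[i - 1] == b[j - 1]) r.matches++;
      r.columns++;
      st = pk & 3; --i; --j;
      if (i == 0 || j == 0) break;
    } else if (st == ST_I) {
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back(std::make_pair('I', 1));
      r.columns++;
      st = (pk >> 2) & 3; --i;
      if (i == 0) break;
    } else {
      if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
      else ops.push_back(std::make_pair('D', 1));
      r.columns++;
      st = (pk >> 4) & 3; --j;
      if (j == 0) break;
    }
  }
  r.a_start = i; r.a_end = best_i;
  r.b_start = j; r.b_end = best_j;
  std::string cig;
  for (int k = (int)ops.size() - 1; k >= 0; --k) append_cigar(cig, ops[k].first, ops[k].second);
  r.cigar = cig;
  #undef IDX
  #undef INBAND
  return r;
}

// [[Rcpp::export(name = ".semiglobal_full_cpp")]]
List semiglobal_full_cpp(std::string a, std::string b,
                         int match, int mismatch, int gap_open, int gap_extend) {
  return result_to_list(semiglobal_full(a, b, match, mismatch, gap_open, gap_extend));
}

// [[Rcpp::export(name = ".semiglobal_banded_cpp")]]
List semiglobal_banded_cpp(std::string a, std::string b,
                           int match, int mismatch, int gap_open, int gap_extend,
                           int dlo, int dhi) {
  return result_to_list(semiglobal_banded(a, b, match, mismatch, gap_open, gap_extend, dlo, dhi));
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    std::string s = as<std::string>(x[k]);
    std::string r(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i) {
      char c = s[s.size() - 1 - i], o;
      switch (c) {
        case 'A': o = 'T'; break; case 'C': o = 'G'; break;
        case 'G': o = 'C'; break; case 'T': o = 'A'; break;
        case 'a': o = 't'; break; case 'c': o = 'g'; break;
        case 'g': o = 'c'; break; case 't': o = 'a'; break;
        default: o = 'N';
      }
      r[i] = o;
    }
    out[k] = r;
  }
  return out;
}
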