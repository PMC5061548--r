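#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh, all X<->Y transitions allowed).
// Gap of length L costs gap_open + (L - 1) * gap_extend (both supplied as
// penalties, i.e. positive numbers subtracted from the score).
// Tie-breaking: among equally scoring alignments prefer the one with the
// smaller start on `a`, then on `b`, then the smaller end on `a`, then `b`.
// 'N' (either sequence) scores as a mismatch against everything.

namespace {

struct Cell {
  double m, x, y;       // best score ending in match / gap-in-b / gap-in-a
  int msa, msb, xsa, xsb, ysa, ysb;   // start coordinates of those paths
  signed char mtb, xtb, ytb;          // traceback: 0=fresh,1=M,2=X,3=Y
};

inline bool start_lt(int sa1, int sb1, int sa2, int sb2) {
  return sa1 < sa2 || (sa1 == sa2 && sb1 < sb2);
}

}  // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend, bool traceback = true) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18;
  // rolling rows of Cell; keep full traceback matrices only when requested
  std::vector<Cell> prev(m + 1), cur(m + 1);
  std::vector<signed char> tbM, tbX, tbY;
  if (traceback) {
    tbM.assign((size_t)(n + 1) * (m + 1), 0);
    tbX.assign((size_t)(n + 1) * (m + 1), 0);
    tbY.assign((size_t)(n + 1) * (m + 1), 0);
  }
  for (int j = 0; j <= m; ++j) {
    prev[j].m = NEG; prev[j].x = NEG; prev[j].y = NEG;
    prev[j].msa = prev[j].msb = prev[j].xsa = prev[j].xsb = INT_MAX;
    prev[j].ysa = prev[j].ysb = INT_MAX;
  }
  double best = 0.0;
  int bsa = 0, bsb = 0, bea = 0, beb = 0;  // best start/end (1-based, 0 = empty)
  bool have = false;

  for (int i = 1; i <= n; ++i) {
    cur[0].m = NEG; cur[0].x = NEG; cur[0].y = NEG;
    cur[0].msa = cur[0].msb = cur[0].xsa = cur[0].xsb = INT_MAX;
    cur[0].ysa = cur[0].ysb = INT_MAX;
    const char ai = a[(size_t)i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj = b[(size_t)j - 1];
      // mismatch / gap penalties are supplied as magnitudes
      const double sub = (ai == bj && ai != 'N') ? match : -mismatch;

      // ---- M: diagonal moves -------------------------------------------
      double mval = sub;           // fresh start at (i, j)
      int msa = i, msb = j; signed char mtb = 0;
      const Cell &d = prev[j - 1];
      double cand;
      cand = d.m + sub;
      if (cand > mval || (cand == mval && start_lt(d.msa, d.msb, msa, msb))) {
        mval = cand; msa = d.msa; msb = d.msb; mtb = 1;
      }
      cand = d.x + sub;
      if (cand > mval || (cand == mval && start_lt(d.xsa, d.xsb, msa, msb))) {
        mval = cand; msa = d.xsa; msb = d.xsb; mtb = 2;
      }
      cand = d.y + sub;
      if (cand > mval || (cand == mval && start_lt(d.ysa, d.ysb, msa, msb))) {
        mval = cand; msa = d.ysa; msb = d.ysb; mtb = 3;
      }
      cur[j].m = mval; cur[j].msa = msa; cur[j].msb = msb;
      if (traceback) tbM[(size_t)i * (m + 1) + j] = mtb;
      if (mval > best ||
          (have && mval == best && (start_lt(msa, msb, bsa, bsb) ||
            (msa == bsa && msb == bsb && (i < bea || (i == bea && j < beb)))))) {
        best = mval; bsa = msa; bsb = msb; bea = i; beb = j; have = true;
      }

      // ---- X: gap in b (consume a_i) -----------------------------------
      const Cell &u = prev[j];
      double xval = u.m - gap_open;
      int xsa = u.msa, xsb = u.msb; signed char xtb = 1;
      cand = u.x - gap_extend;
      if (cand > xval || (cand == xval && start_lt(u.xsa, u.xsb, xsa, xsb))) {
        xval = cand; xsa = u.xsa; xsb = u.xsb; xtb = 2;
      }
      cand = u.y - gap_open;
      if (cand > xval || (cand == xval && start_lt(u.ysa, u.ysb, xsa, xsb))) {
        xval = cand; xsa = u.ysa; xsb = u.ysb; xtb = 3;
      }
      cur[j].x = xval; cur[j].xsa = xsa; cur[j].xsb = xsb;
      if (traceback) tbX[(size_t)i * (m + 1) + j] = xtb;

      // ---- Y: gap in a (consume b_j) -----------------------------------
      const Cell &l = cur[j - 1];
      double yval = l.m - gap_open;
      int ysa = l.msa, ysb = l.msb; signed char ytb = 1;
      cand = l.x - gap_open;
      if (cand > yval || (cand == yval && start_lt(l.xsa, l.xsb, ysa, ysb))) {
        yval = cand; ysa = l.xsa; ysb = l.xsb; ytb = 2;
      }
      cand = l.y - gap_extend;
      if (cand > yval || (cand == yval && start_lt(l.ysa, l.ysb, ysa, ysb))) {
        yval = cand; ysa = l.ysa; ysb = l.ysb; ytb = 3;
      }
      cur[j].y = yval; cur[j].ysa = ysa; cur[j].ysb = ysb;
      if (traceback) tbY[(size_t)i * (m + 1) + j] = ytb;
    }
    std::swap(prev, cur);
  }

  if (!have || best <= 0.0) {
    return List::create(
        _["score"] = 0.0, _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER,
        _["matches"] = 0L, _["columns"] = 0L, _["identity"] = NA_REAL,
        _["a_aligned"] = "", _["b_aligned"] = "");
  }

  std::string aa, bb;
  int matches = 0, columns = 0;
  if (traceback) {
    int i = bea, j = beb, state = 1;  // end in M by construction
    while (true) {
      if (state == 1) {
        signed char t = tbM[(size_t)i * (m + 1) + j];
        aa.push_back(a[(size_t)i - 1]);
        bb.push_back(b[(size_t)j - 1]);
        if (a[(size_t)i - 1] == b[(size_t)j - 1] && a[(size_t)i - 1] != 'N') ++matches;
        ++columns;
        --i; --j;
        if (t == 0) break;
        state = t;
      } else if (state == 2) {
        signed char t = tbX[(size_t)i * (m + 1) + j];
        aa.push_back(a[(size_t)i - 1]);
        bb.push_back('-');
        ++columns;
        --i;
        state = t;
      } else {
        signed char t = tbY[(size_t)i * (m + 1) + j];
        aa.push_back('-');
        bb.push_back(b[(size_t)j - 1]);
        ++columns;
        --j;
        state = t;
      }
    }
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
  } else {
    columns = NA_INTEGER; matches = NA_INTEGER;
  }

  double ident = (traceback && columns > 0)
                     ? 100.0 * (double)matches / (double)columns : NA_REAL;
  return List::create(
      _["score"] = best, _["a_start"] = bsa, _["a_end"] = bea,
      _["b_start"] = bsb, _["b_end"] = beb,
      _["matches"] = matches, _["columns"] = columns, _["identity"] = ident,
      _["a_aligned"] = aa, _["b_aligned"] = bb);
}

// score-only Gotoh pass: no start tracking, no traceback
static double sw_score_only(const std::string &a, const std::string &b,
                            double match, double mismatch, double gap_open,
                            double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> Mp(m + 1, NEG), Xp(m + 1, NEG), Yp(m + 1, NEG);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Xc[0] = NEG; Yc[0] = NEG;
    const char ai = a[(size_t)i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj = b[(size_t)j - 1];
      const double sub = (ai == bj && ai != 'N') ? match : -mismatch;
      double diag = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      double mv = std::max(sub, diag + sub);
      double xv = std::max(Mp[j] - gap_open,
                           std::max(Xp[j] - gap_extend, Yp[j] - gap_open));
      double yv = std::max(Mc[j - 1] - gap_open,
                           std::max(Xc[j - 1] - gap_open, Yc[j - 1] - gap_extend));
      Mc[j] = mv; Xc[j] = xv; Yc[j] = yv;
      if (mv > best) best = mv;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
NumericVector sw_score_cpp(std::string query, CharacterVector refs,
                           double match, double mismatch, double gap_open,
                           double gap_extend) {
  NumericVector out(refs.size());
  for (int r = 0; r < refs.size(); ++r) {
    out[r] = sw_score_only(query, as<std::string>(refs[r]), match, mismatch,
                           gap_open, gap_extend);
  }
  return out;
}

// Align one query against many references; returns per-reference summary
// (with traceback, since identity and subject span are needed downstream).
// [[Rcpp::export(name = ".sw_align_batch_cpp")]]
DataFrame sw_align_batch_cpp(std::string query, CharacterVector refs,
                             double match, double mismatch, double gap_open,
                             double gap_extend) {
  const int k = refs.size();
  NumericVector score(k), identity(k);
  IntegerVector a_start(k), a_end(k), b_start(k), b_end(k), columns(k);
  for (int r = 0; r < k; ++r) {
    List res = sw_align_cpp(query, as<std::string>(refs[r]), match, mismatch,
                            gap_open, gap_extend, true);
    score[r] = as<double>(res["score"]);
    a_start[r] = as<int>(res["a_start"]);
    a_end[r] = as<int>(res["a_end"]);
    b_start[r] = as<int>(res["b_start"]);
    b_end[r] = as<int>(res["b_end"]);
    columns[r] = as<int>(res["columns"]);
    identity[r] = as<double>(res["identity"]);
  }
  return DataFrame::create(
      _["score"] = score, _["identity"] = identity, _["columns"] = columns,
      _["a_start"] = a_start, _["a_end"] = a_end, _["b_start"] = b_start,
      _["b_end"] = b_end, _["stringsAsFactors"] = false);
}
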