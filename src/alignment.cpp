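#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Sequences arrive as 0-based integer
// codes into the rows/cols of the substitution matrix. A gap of length L
// costs gap_open + L * gap_ext. Ties between equal-scoring end cells are
// resolved by lowest subject start, then lowest query start (alignment
// start positions after traceback); traceback itself prefers diagonal,
// then vertical (gap in query), then horizontal.
//
// Returns 0-based half-open intervals plus the aligned column index
// vectors (1-based positions, 0 marks a gap).

struct TB { int qs, ss; std::vector<int> qcol, scol; };

static TB traceback(const std::vector<double>& H, const std::vector<double>& E,
                    const std::vector<double>& F, const IntegerVector& q,
                    const IntegerVector& s, const NumericMatrix& m,
                    double go, double ge, int nq, int i, int j) {
  // i over subject (rows), j over query (cols); row-major width nq+1
  TB tb;
  int state = 0; // 0 = H, 1 = E (gap in subject / horizontal), 2 = F (vertical)
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (nq + 1) + j;
    if (state == 0) {
      double h = H[idx];
      if (h == 0) break;
      double diag = H[idx - (nq + 1) - 1] + m(s[i - 1], q[j - 1]);
      if (h == diag) {
        tb.qcol.push_back(j); tb.scol.push_back(i);
        --i; --j;
      } else if (h == F[idx]) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 2) { // vertical: consume subject residue, gap in query
      size_t up = idx - (nq + 1);
      tb.qcol.push_back(0); tb.scol.push_back(i);
      double f = F[idx];
      if (f == H[up] - go - ge) state = 0;
      --i;
      (void)f;
    } else { // horizontal: consume query residue, gap in subject
      size_t left = idx - 1;
      tb.qcol.push_back(j); tb.scol.push_back(0);
      double e = E[idx];
      if (e == H[left] - go - ge) state = 0;
      --j;
      (void)e;
    }
  }
  tb.qs = j; tb.ss = i; // 0-based start of alignment
  std::reverse(tb.qcol.begin(), tb.qcol.end());
  std::reverse(tb.scol.begin(), tb.scol.end());
  return tb;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix m,
                  double gap_open, double gap_ext) {
  const int nq = q.size(), ns = s.size();
  const double NEG = -1e30;
  std::vector<double> H((size_t)(ns + 1) * (nq + 1), 0.0);
  std::vector<double> E((size_t)(ns + 1) * (nq + 1), NEG);
  std::vector<double> F((size_t)(ns + 1) * (nq + 1), NEG);
  double best = 0.0;
  std::vector<std::pair<int,int> > ends; // (i subject, j query)
  for (int i = 1; i <= ns; ++i) {
    size_t row = (size_t)i * (nq + 1), prow = row - (nq + 1);
    for (int j = 1; j <= nq; ++j) {
      double e = std::max(H[row + j - 1] - gap_open - gap_ext,
                          E[row + j - 1] - gap_ext);
      double f = std::max(H[prow + j] - gap_open - gap_ext,
                          F[prow + j] - gap_ext);
      double h = H[prow + j - 1] + m(s[i - 1], q[j - 1]);
      h = std::max(std::max(h, e), std::max(f, 0.0));
      E[row + j] = e; F[row + j] = f; H[row + j] = h;
      if (h > best) { best = h; ends.clear(); ends.push_back(std::make_pair(i, j)); }
      else if (h == best && best > 0 && ends.size() < 32)
        ends.push_back(std::make_pair(i, j));
    }
  }
  if (best <= 0.0 || ends.empty()) {
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0,
                        _["q_col"] = IntegerVector(0),
                        _["s_col"] = IntegerVector(0));
  }
  TB chosen; int ce_i = -1, ce_j = -1; bool have = false;
  for (size_t k = 0; k < ends.size(); ++k) {
    TB tb = traceback(H, E, F, q, s, m, gap_open, gap_ext, nq,
                      ends[k].first, ends[k].second);
    if (!have || tb.ss < chosen.ss || (tb.ss == chosen.ss && tb.qs < chosen.qs)) {
      chosen = tb; ce_i = ends[k].first; ce_j = ends[k].second; have = true;
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = chosen.qs, _["q_end"] = ce_j,
                      _["s_start"] = chosen.ss, _["s_end"] = ce_i,
                      _["q_col"] = wrap(chosen.qcol),
                      _["s_col"] = wrap(chosen.scol));
}

// Matched positions in an optimal end-gap-free ("semi-global") pairwise
// alignment under unit scoring (match +1, mismatch -1, internal gap -1,
// terminal gaps free); among equal-scoring alignments the one with the
// most matches is counted. Terminal-gap freedom makes the measure
// behave like cd-hit's containment identity when lengths differ.
// [[Rcpp::export(name = ".nw_matches_cpp")]]
int nw_matches_cpp(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  std::vector<int> sprev(m + 1, 0), scur(m + 1);
  std::vector<int> mprev(m + 1, 0), mcur(m + 1);
  int best_s = 0, best_m = 0; // empty alignment allowed (score 0)
  for (int i = 1; i <= n; ++i) {
    scur[0] = 0; mcur[0] = 0; // free leading gaps
    for (int j = 1; j <= m; ++j) {
      bool eq = a[i - 1] == b[j - 1];
      int sd = sprev[j - 1] + (eq ? 1 : -1), md = mprev[j - 1] + (eq ? 1 : 0);
      int su = sprev[j] - 1, mu = mprev[j];
      int sl = scur[j - 1] - 1, ml = mcur[j - 1];
      int s = sd, mm = md;
      if (su > s || (su == s && mu > mm)) { s = su; mm = mu; }
      if (sl > s || (sl == s && ml > mm)) { s = sl; mm = ml; }
      scur[j] = s; mcur[j] = mm;
      if (j == m || i == n) { // free trailing gaps: ends on last row/col
        if (s > best_s || (s == best_s && mm > best_m)) {
          best_s = s; best_m = mm;
        }
      }
    }
    std::swap(sprev, scur);
    std::swap(mprev, mcur);
  }
  return best_m;
}
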