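// Global pairwise alignment (Gotoh, affine gaps) with percent-identity
// extraction. Identity = 100 * matching columns / alignment columns, where
// terminal gap columns are excluded from the column count (the usual
// usearch/vsearch convention for end-gapped global alignments).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

// traceback states
enum { TB_M = 0, TB_X = 1, TB_Y = 2 };

// [[Rcpp::export]]
List align_identity_cpp(std::string a, std::string b,
                        double match = 2.0, double mismatch = -4.0,
                        double gap_open = 20.0, double gap_extend = 2.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  const int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG), X((n + 1) * w, NEG),
      Y((n + 1) * w, NEG);
  // traceback: which state each cell came from
  std::vector<unsigned char> tM((n + 1) * w), tX((n + 1) * w), tY((n + 1) * w);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * w] = -(gap_open + gap_extend * i);
    tX[i * w] = TB_X;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + gap_extend * j);
    tY[j] = TB_Y;
  }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int c = i * w + j, d = (i - 1) * w + (j - 1),
                u = (i - 1) * w + j, l = i * w + (j - 1);
      const double s = (ai == b[j - 1]) ? match : mismatch;
      // M: diagonal; prefer diagonal-from-M on ties (favors matches)
      double best = M[d];
      unsigned char tb = TB_M;
      if (X[d] > best) { best = X[d]; tb = TB_X; }
      if (Y[d] > best) { best = Y[d]; tb = TB_Y; }
      M[c] = best + s;
      tM[c] = tb;
      // X: gap in b, consume a (vertical)
      double xo = M[u] - (gap_open + gap_extend);
      double xe = X[u] - gap_extend;
      double xy = Y[u] - (gap_open + gap_extend);
      if (xo >= xe && xo >= xy)      { X[c] = xo; tX[c] = TB_M; }
      else if (xe >= xy)             { X[c] = xe; tX[c] = TB_X; }
      else                           { X[c] = xy; tX[c] = TB_Y; }
      // Y: gap in a, consume b (horizontal)
      double yo = M[l] - (gap_open + gap_extend);
      double ye = Y[l] - gap_extend;
      double yx = X[l] - (gap_open + gap_extend);
      if (yo >= ye && yo >= yx)      { Y[c] = yo; tY[c] = TB_M; }
      else if (ye >= yx)             { Y[c] = ye; tY[c] = TB_Y; }
      else                           { Y[c] = yx; tY[c] = TB_X; }
    }
  }

  const int end = n * w + m;
  int state = TB_M;
  double score = M[end];
  if (X[end] > score) { score = X[end]; state = TB_X; }
  if (Y[end] > score) { score = Y[end]; state = TB_Y; }

  // traceback, recording per-column events from the end
  int i = n, j = m;
  int matches = 0, columns = 0;
  std::vector<unsigned char> ops;  // 0 = diag, 1 = up (gap in b), 2 = left
  ops.reserve(n + m);
  while (i > 0 || j > 0) {
    const int c = i * w + j;
    if (state == TB_M) {
      ops.push_back(0);
      state = tM[c];
      --i; --j;
    } else if (state == TB_X) {
      ops.push_back(1);
      state = tX[c];
      --i;
    } else {
      ops.push_back(2);
      state = tY[c];
      --j;
    }
  }
  // trim terminal gap runs at both ends of the alignment
  int lo = 0, hi = (int)ops.size() - 1;
  // ops is end-to-start; terminal gaps are leading/trailing non-diagonal runs
  while (lo <= hi && ops[lo] != 0) ++lo;
  while (hi >= lo && ops[hi] != 0) --hi;
  i = 0; j = 0;
  // replay from the start (ops reversed): positions hi..lo are interior
  int ai_pos = 0, bj_pos = 0;
  for (int k = (int)ops.size() - 1; k >= 0; --k) {
    const bool interior = (k >= lo && k <= hi);
    if (ops[k] == 0) {
      if (interior) {
        ++columns;
        if (a[ai_pos] == b[bj_pos]) ++matches;
      }
      ++ai_pos; ++bj_pos;
    } else if (ops[k] == 1) {
      if (interior) ++columns;
      ++ai_pos;
    } else {
      if (interior) ++columns;
      ++bj_pos;
    }
  }

  const double identity = columns > 0 ? 100.0 * matches / columns : 0.0;
  return List::create(_["identity"] = identity, _["matches"] = matches,
                      _["columns"] = columns, _["score"] = score);
}

// Best hit of one query against many references: returns the 1-based index
// of the best reference (ties -> lowest index) and its identity, or index 0
// when no reference reaches min_identity (percent).
// [[Rcpp::export]]
List best_hit_cpp(std::string query, CharacterVector refs,
                  double min_identity,
                  double match = 2.0, double mismatch = -4.0,
                  double gap_open = 20.0, double gap_extend = 2.0) {
  int best = 0;
  double best_id = -1.0;
  for (int r = 0; r < refs.size(); ++r) {
    List al = align_identity_cpp(query, as<std::string>(refs[r]), match,
                                 mismatch, gap_open, gap_extend);
    const double id = as<double>(al["identity"]);
    if (id >= min_identity && id > best_id) {
      best_id = id;
      best = r + 1;
    }
  }
  return List::create(_["index"] = best,
                      _["identity"] = best > 0 ? best_id : NA_REAL);
}
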