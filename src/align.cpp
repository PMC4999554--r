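#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh three-state global / overlap alignment.
//
// States: M = residue-residue column, X = gap in b (consumes a, "up"),
// Y = gap in a (consumes b, "left").  A gap run of length L costs
// gap_open + (L - 1) * gap_extend (both penalties are <= 0).
// Overlap ("glocal") mode frees terminal gaps in b only: a is consumed
// end to end while b's unaligned prefix/suffix costs nothing, which is
// the read-mapping semantics (a = read, b = reference window).
// Tie-breaking is fixed everywhere: prefer M, then X (up), then Y (left),
// so tracebacks are bit-reproducible.
//
// Scores are kept in rolling rows; traceback pointers are full byte
// matrices (state of the predecessor cell).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

enum State : unsigned char { SM = 0, SX = 1, SY = 2, SNONE = 3 };

// pick best of (m, x, y) with M > X > Y preference
static inline void best3(double m, double x, double y,
                         double &val, unsigned char &st) {
  val = m; st = SM;
  if (x > val) { val = x; st = SX; }
  if (y > val) { val = y; st = SY; }
}

// [[Rcpp::export(name = ".align_core")]]
List align_core(IntegerVector a, IntegerVector b, NumericMatrix submat,
                double gap_open, double gap_extend, bool ends_free) {
  const int la = a.size(), lb = b.size();
  const int ncol = lb + 1;

  // flat copies: Rcpp element access is too slow for the inner loop
  const int ns = submat.nrow();
  std::vector<double> sub(ns * ns);
  for (int r = 0; r < ns; ++r)
    for (int c = 0; c < ns; ++c) sub[r * ns + c] = submat(r, c);
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());

  // traceback: predecessor state for arriving in each state at (i,j)
  std::vector<unsigned char> tbM((la + 1) * (size_t)ncol, SNONE);
  std::vector<unsigned char> tbX((la + 1) * (size_t)ncol, SNONE);
  std::vector<unsigned char> tbY((la + 1) * (size_t)ncol, SNONE);

  std::vector<double> Mprev(ncol), Xprev(ncol), Yprev(ncol);
  std::vector<double> Mcur(ncol), Xcur(ncol), Ycur(ncol);

  // row 0: in overlap mode skipping a prefix of b is free
  Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= lb; ++j) {
    Mprev[j] = NEG_INF; Xprev[j] = NEG_INF;
    Yprev[j] = ends_free ? 0.0 : gap_open + (j - 1) * gap_extend;
    tbY[j] = (j == 1) ? SM : SY;
  }

  for (int i = 1; i <= la; ++i) {
    Mcur[0] = NEG_INF; Ycur[0] = NEG_INF;
    Xcur[0] = gap_open + (i - 1) * gap_extend;
    tbX[(size_t)i * ncol] = (i == 1) ? SM : SX;

    const double *subrow = &sub[(size_t)av[i - 1] * ns];
    for (int j = 1; j <= lb; ++j) {
      const size_t idx = (size_t)i * ncol + j;
      double v; unsigned char st;

      // M: diagonal move from any state
      best3(Mprev[j - 1], Xprev[j - 1], Yprev[j - 1], v, st);
      Mcur[j] = (v == NEG_INF) ? NEG_INF : v + subrow[bv[j - 1]];
      tbM[idx] = st;

      // X: vertical move (gap in b); extending X is cheap
      best3(Mprev[j] + gap_open, Xprev[j] + gap_extend, Yprev[j] + gap_open,
            v, st);
      Xcur[j] = v;
      tbX[idx] = st;

      // Y: horizontal move (gap in a)
      best3(Mcur[j - 1] + gap_open, Xcur[j - 1] + gap_open,
            Ycur[j - 1] + gap_extend, v, st);
      Ycur[j] = v;
      tbY[idx] = st;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // choose traceback start
  int ti = la, tj = lb;
  double score; unsigned char state;
  {
    double v; unsigned char st;
    best3(Mprev[lb], Xprev[lb], Yprev[lb], v, st);
    score = v; state = st;
  }
  if (ends_free) {
    // a may stop anywhere inside b: skipping b's suffix is free.
    // Scanned descending so the endpoint closest to the corner wins ties.
    for (int j = lb; j >= 0; --j) {
      double v; unsigned char st;
      best3(Mprev[j], Xprev[j], Yprev[j], v, st);
      if (v > score) { score = v; state = st; ti = la; tj = j; }
    }
  }

  // rebuild the path; ends-free: unconsumed suffixes become terminal gaps
  std::vector<int> opsRev;  // 0 = diag, 1 = up, 2 = left
  for (int i = la; i > ti; --i) opsRev.push_back(1);
  for (int j = lb; j > tj; --j) opsRev.push_back(2);
  int i = ti, j = tj;
  unsigned char st = state;
  while (i > 0 || j > 0) {
    const size_t idx = (size_t)i * ncol + j;
    unsigned char pred;
    if (st == SM)      { pred = tbM[idx]; opsRev.push_back(0); --i; --j; }
    else if (st == SX) { pred = tbX[idx]; opsRev.push_back(1); --i; }
    else               { pred = tbY[idx]; opsRev.push_back(2); --j; }
    st = pred;
  }

  const int n = opsRev.size();
  IntegerVector ia(n), ib(n);  // 1-based index into a/b, NA for gap
  int pa = 1, pb = 1;
  for (int k = 0; k < n; ++k) {
    const int op = opsRev[n - 1 - k];
    if (op == 0)      { ia[k] = pa++; ib[k] = pb++; }
    else if (op == 1) { ia[k] = pa++; ib[k] = NA_INTEGER; }
    else              { ia[k] = NA_INTEGER; ib[k] = pb++; }
  }
  return List::create(_["ia"] = ia, _["ib"] = ib, _["score"] = score);
}
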