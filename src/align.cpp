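#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment (Gotoh three-state DP). A gap run of length L costs
// gap_open + L * gap_extend, BLAST-style. States: M (diagonal), X (gap in b,
// consumes a, "up"), Y (gap in a, consumes b, "left"). Tie-breaks everywhere
// prefer M, then X, then Y, giving a deterministic traceback.

static const double NEG_INF = -1e30;

struct TB {
  // predecessor state per cell per state: 0=M, 1=X, 2=Y, 3=START
  std::vector<unsigned char> m, x, y;
  int cols;
  TB(int n, int mm) : m((n + 1) * (mm + 1)), x((n + 1) * (mm + 1)),
                      y((n + 1) * (mm + 1)), cols(mm + 1) {}
  inline int at(int i, int j) const { return i * cols + j; }
};

static inline int best3(double vm, double vx, double vy) {
  if (vm >= vx && vm >= vy) return 0;
  if (vx >= vy) return 1;
  return 2;
}

// ops codes: 1 = diagonal, 2 = up (consume a), 3 = left (consume b)
static List traceback(const TB &tb, int i, int j, int state, bool local) {
  std::vector<int> ops;
  while (i > 0 || j > 0) {
    unsigned char prev;
    if (state == 0) prev = tb.m[tb.at(i, j)];
    else if (state == 1) prev = tb.x[tb.at(i, j)];
    else prev = tb.y[tb.at(i, j)];
    if (prev == 3) break; // local alignment start
    if (state == 0) { ops.push_back(1); --i; --j; }
    else if (state == 1) { ops.push_back(2); --i; }
    else { ops.push_back(3); --j; }
    state = prev;
    if (local && i == 0 && j == 0) break;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = wrap(ops), _["a_start"] = i, _["b_start"] = j);
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_ext, bool local) {
  int n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  TB tb(n, m);
  int C = m + 1;
  double go = gap_open + gap_ext; // cost of the first position of a gap

  M[0] = 0.0;
  if (local) { X[0] = NEG_INF; Y[0] = NEG_INF; }
  for (int i = 1; i <= n; ++i) {
    if (local) {
      M[i * C] = 0.0; tb.m[tb.at(i, 0)] = 3;
    } else {
      X[i * C] = -go - gap_ext * (i - 1);
      tb.x[tb.at(i, 0)] = (i == 1) ? 0 : 1;
    }
  }
  for (int j = 1; j <= m; ++j) {
    if (local) {
      M[j] = 0.0; tb.m[tb.at(0, j)] = 3;
    } else {
      Y[j] = -go - gap_ext * (j - 1);
      tb.y[tb.at(0, j)] = (j == 1) ? 0 : 2;
    }
  }

  double best = 0.0; int bi = 0, bj = 0, bstate = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int ij = i * C + j, up = (i - 1) * C + j, lf = i * C + (j - 1),
          dg = (i - 1) * C + (j - 1);
      double s = S(a[i - 1], b[j - 1]);
      // M
      int pm = best3(M[dg], X[dg], Y[dg]);
      double vm = (pm == 0 ? M[dg] : pm == 1 ? X[dg] : Y[dg]) + s;
      tb.m[ij] = (unsigned char)pm;
      // local: diagonal predecessors are floored at 0, so a fresh start is
      // never better than extending; flooring M at 0 marks the start cell
      if (local && vm < 0.0) { vm = 0.0; tb.m[ij] = 3; }
      M[ij] = vm;
      // X: gap in b (consume a)
      double cm = M[up] - go, cx = X[up] - gap_ext, cy = Y[up] - go;
      int px = best3(cm, cx, cy);
      X[ij] = (px == 0 ? cm : px == 1 ? cx : cy);
      tb.x[ij] = (unsigned char)px;
      // Y: gap in a (consume b)
      cm = M[lf] - go; cx = X[lf] - go; cy = Y[lf] - gap_ext;
      int py = best3(cm, cx, cy);
      Y[ij] = (py == 0 ? cm : py == 1 ? cx : cy);
      tb.y[ij] = (unsigned char)py;
      if (local && M[ij] > best) { best = M[ij]; bi = i; bj = j; bstate = 0; }
    }
  }

  if (!local) {
    int ij = n * C + m;
    bstate = best3(M[ij], X[ij], Y[ij]);
    best = (bstate == 0 ? M[ij] : bstate == 1 ? X[ij] : Y[ij]);
    bi = n; bj = m;
  }
  List path = (local && best <= 0.0)
                  ? List::create(_["ops"] = IntegerVector(0), _["a_start"] = 0,
                                 _["b_start"] = 0)
                  : traceback(tb, bi, bj, bstate, local);
  return List::create(_["score"] = best, _["ops"] = path["ops"],
                      _["a_start"] = path["a_start"],
                      _["b_start"] = path["b_start"], _["a_end"] = bi,
                      _["b_end"] = bj);
}

// Profile-profile global alignment with the same scoring. PA, PB are
// nsym x L matrices of residue frequencies per column (gap mass excluded, so
// columns may sum to < 1). Column-pair score = PA[,i]' S PB[,j].
// [[Rcpp::export(name = ".align_profiles_cpp")]]
List align_profiles_cpp(NumericMatrix PA, NumericMatrix PB, NumericMatrix S,
                        double gap_open, double gap_ext) {
  int nsym = PA.nrow();
  int n = PA.ncol(), m = PB.ncol();
  // TA[b, i] = sum_a S(b, a) * PA(a, i)
  NumericMatrix TA(nsym, n);
  for (int i = 0; i < n; ++i)
    for (int bsym = 0; bsym < nsym; ++bsym) {
      double acc = 0.0;
      for (int asym = 0; asym < nsym; ++asym)
        acc += S(bsym, asym) * PA(asym, i);
      TA(bsym, i) = acc;
    }
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  TB tb(n, m);
  int C = m + 1;
  double go = gap_open + gap_ext;
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * C] = -go - gap_ext * (i - 1);
    tb.x[tb.at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -go - gap_ext * (j - 1);
    tb.y[tb.at(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int ij = i * C + j, up = (i - 1) * C + j, lf = i * C + (j - 1),
          dg = (i - 1) * C + (j - 1);
      double s = 0.0;
      for (int bsym = 0; bsym < nsym; ++bsym)
        s += PB(bsym, j - 1) * TA(bsym, i - 1);
      int pm = best3(M[dg], X[dg], Y[dg]);
      M[ij] = (pm == 0 ? M[dg] : pm == 1 ? X[dg] : Y[dg]) + s;
      tb.m[ij] = (unsigned char)pm;
      double cm = M[up] - go, cx = X[up] - gap_ext, cy = Y[up] - go;
      int px = best3(cm, cx, cy);
      X[ij] = (px == 0 ? cm : px == 1 ? cx : cy);
      tb.x[ij] = (unsigned char)px;
      cm = M[lf] - go; cx = X[lf] - go; cy = Y[lf] - gap_ext;
      int py = best3(cm, cx, cy);
      Y[ij] = (py == 0 ? cm : py == 1 ? cx : cy);
      tb.y[ij] = (unsigned char)py;
    }
  }
  int ij = n * C + m;
  int bstate = best3(M[ij], X[ij], Y[ij]);
  double best = (bstate == 0 ? M[ij] : bstate == 1 ? X[ij] : Y[ij]);
  List path = traceback(tb, n, m, bstate, false);
  return List::create(_["score"] = best, _["ops"] = path["ops"]);
}
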