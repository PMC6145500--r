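// Nearest-neighbor RNA secondary-structure engine.
//
// Energies are handled internally as integer hundredths of kcal/mol so that
// ties are exact and tracebacks are bit-reproducible across platforms.
// The model: Watson-Crick + GU wobble pairs, stacking energies, size-dependent
// hairpin/bulge/internal-loop penalties (with a linear asymmetry term for
// internal loops), and an affine multiloop term. No dangles, no coaxial
// stacking. Minimum hairpin loop size is 3 nt.

#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

static const int INF = 1000000000;

// base codes: A=1, C=2, G=3, U=4 ; pair types AU=0 UA=1 CG=2 GC=3 GU=4 UG=5
static inline int pairType(int a, int b) {
  if (a == 1 && b == 4) return 0;
  if (a == 4 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 3 && b == 4) return 4;
  if (a == 4 && b == 3) return 5;
  return -1;
}

struct Model {
  int stack[6][6];
  std::vector<int> hairpin;   // 1-based by loop size
  std::vector<int> bulge;
  std::vector<int> internal;
  int asymPerNt, asymMax;
  int mlOffset, mlBranch, mlUnpaired;
  int duplexInit;
  int maxLoop;

  int hairpinPen(int sz) const {
    if (sz < 3 || sz >= (int)hairpin.size()) return INF;
    return hairpin[sz];
  }
  int loopPen(int n1, int n2) const {
    int tot = n1 + n2;
    if (tot <= 0 || tot > maxLoop) return INF;
    if (n1 == 0 || n2 == 0) {
      if (tot >= (int)bulge.size()) return INF;
      return bulge[tot];
    }
    if (tot >= (int)internal.size()) return INF;
    int asym = asymPerNt * std::abs(n1 - n2);
    if (asym > asymMax) asym = asymMax;
    return internal[tot] + asym;
  }
};

static Model buildModel(const NumericMatrix& stack,
                        const NumericVector& hairpinPen,
                        const NumericVector& bulgePen,
                        const NumericVector& internalPen,
                        double asymPerNt, double asymMax,
                        double mlOffset, double mlBranch, double mlUnpaired,
                        double duplexInit, int maxLoop) {
  Model m;
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      m.stack[a][b] = (int)std::lround(stack(a, b) * 100.0);
  m.hairpin.assign(hairpinPen.size() + 1, INF);
  for (int i = 0; i < hairpinPen.size(); ++i)
    m.hairpin[i + 1] = R_finite(hairpinPen[i]) ?
      (int)std::lround(hairpinPen[i] * 100.0) : INF;
  m.bulge.assign(bulgePen.size() + 1, INF);
  for (int i = 0; i < bulgePen.size(); ++i)
    m.bulge[i + 1] = R_finite(bulgePen[i]) ?
      (int)std::lround(bulgePen[i] * 100.0) : INF;
  m.internal.assign(internalPen.size() + 1, INF);
  for (int i = 0; i < internalPen.size(); ++i)
    m.internal[i + 1] = R_finite(internalPen[i]) ?
      (int)std::lround(internalPen[i] * 100.0) : INF;
  m.asymPerNt = (int)std::lround(asymPerNt * 100.0);
  m.asymMax = (int)std::lround(asymMax * 100.0);
  m.mlOffset = (int)std::lround(mlOffset * 100.0);
  m.mlBranch = (int)std::lround(mlBranch * 100.0);
  m.mlUnpaired = (int)std::lround(mlUnpaired * 100.0);
  m.duplexInit = (int)std::lround(duplexInit * 100.0);
  m.maxLoop = maxLoop;
  return m;
}

static inline int addE(int a, int b) {
  if (a >= INF || b >= INF) return INF;
  return a + b;
}

class Folder {
public:
  Folder(const std::vector<int>& seq, const Model& m,
         const std::vector<bool>& blocked)
    : s(seq), mod(m), blk(blocked), n((int)seq.size()) {
    V.assign((size_t)n * n, INF);
    WM.assign((size_t)n * n, INF);
    F.assign(n + 1, 0);
    run();
  }

  int mfe() const { return F[n]; }

  // 0-based pair table, -1 = unpaired
  std::vector<int> traceback() {
    pt.assign(n, -1);
    traceF(n);
    return pt;
  }

private:
  const std::vector<int>& s;
  const Model& mod;
  const std::vector<bool>& blk;
  int n;
  std::vector<int> V, WM, F;
  std::vector<int> pt;

  inline int idx(int i, int j) const { return i * n + j; }
  inline bool canPair(int i, int j) const {
    if (blk[i] || blk[j]) return false;
    if (j - i - 1 < 3) return false;
    return pairType(s[i], s[j]) >= 0;
  }

  int interiorBest(int i, int j) {
    int best = INF;
    int lim = mod.maxLoop;
    for (int k = i + 1; k <= i + 1 + lim && k < j; ++k) {
      int n1 = k - i - 1;
      for (int l = j - 1; l >= k + 4 && (n1 + (j - l - 1)) <= lim; --l) {
        int n2 = j - l - 1;
        if (n1 == 0 && n2 == 0) continue; // stack handled separately
        if (V[idx(k, l)] >= INF) continue;
        int e = addE(mod.loopPen(n1, n2), V[idx(k, l)]);
        if (e < best) best = e;
      }
    }
    return best;
  }

  int multiBest(int i, int j) {
    // closed by pair (i,j); >= 2 branches inside
    int best = INF;
    for (int k = i + 2; k <= j - 2; ++k) {
      int a = WM[idx(i + 1, k - 1)];
      int b = WM[idx(k, j - 1)];
      if (a >= INF || b >= INF) continue;
      int e = a + b;
      if (e < best) best = e;
    }
    if (best >= INF) return INF;
    return addE(best, mod.mlOffset + mod.mlBranch);
  }

  void run() {
    for (int j = 0; j < n; ++j) {
      for (int i = j - 4; i >= 0; --i) {
        // V
        if (canPair(i, j)) {
          int best = mod.hairpinPen(j - i - 1);
          if (canPair(i + 1, j - 1) && V[idx(i + 1, j - 1)] < INF) {
            int e = addE(mod.stack[pairType(s[i], s[j])]
                                  [pairType(s[i + 1], s[j - 1])],
                         V[idx(i + 1, j - 1)]);
            if (e < best) best = e;
          }
          int e = interiorBest(i, j);
          if (e < best) best = e;
          e = multiBest(i, j);
          if (e < best) best = e;
          V[idx(i, j)] = best;
        }
        // WM: segment inside a multiloop with >= 1 branch
        int best = INF;
        if (V[idx(i, j)] < INF) best = V[idx(i, j)] + mod.mlBranch;
        if (i + 1 <= j && WM[idx(i + 1, j)] < INF)
          best = std::min(best, WM[idx(i + 1, j)] + mod.mlUnpaired);
        if (i <= j - 1 && WM[idx(i, j - 1)] < INF)
          best = std::min(best, WM[idx(i, j - 1)] + mod.mlUnpaired);
        for (int k = i + 1; k <= j; ++k) {
          int a = WM[idx(i, k - 1)], b = WM[idx(k, j)];
          if (a < INF && b < INF && a + b < best) best = a + b;
        }
        WM[idx(i, j)] = best;
      }
    }
    // exterior
    for (int j = 1; j <= n; ++j) {
      int best = F[j - 1];
      for (int i = 1; i <= j; ++i) {
        int v = V[idx(i - 1, j - 1)];
        if (v < INF && F[i - 1] + v < best) best = F[i - 1] + v;
      }
      F[j] = best;
    }
  }

  void traceF(int j) { // 1-based end
    while (j > 0) {
      bool done = false;
      for (int i = 1; i <= j; ++i) {
        int v = V[idx(i - 1, j - 1)];
        if (v < INF && F[i - 1] + v == F[j]) {
          traceV(i - 1, j - 1);
          j = i - 1;
          done = true;
          break;
        }
      }
      if (!done) --j; // j unpaired
    }
  }

  void traceV(int i, int j) {
    pt[i] = j; pt[j] = i;
    int target = V[idx(i, j)];
    // preference order: stack, interior, multiloop, hairpin
    if (canPair(i + 1, j - 1) && V[idx(i + 1, j - 1)] < INF) {
      int e = addE(mod.stack[pairType(s[i], s[j])]
                            [pairType(s[i + 1], s[j - 1])],
                   V[idx(i + 1, j - 1)]);
      if (e == target) { traceV(i + 1, j - 1); return; }
    }
    int lim = mod.maxLoop;
    for (int k = i + 1; k <= i + 1 + lim && k < j; ++k) {
      int n1 = k - i - 1;
      for (int l = j - 1; l >= k + 4 && (n1 + (j - l - 1)) <= lim; --l) {
        int n2 = j - l - 1;
        if (n1 == 0 && n2 == 0) continue;
        if (V[idx(k, l)] >= INF) continue;
        if (addE(mod.loopPen(n1, n2), V[idx(k, l)]) == target) {
          traceV(k, l);
          return;
        }
      }
    }
    for (int k = i + 2; k <= j - 2; ++k) {
      int a = WM[idx(i + 1, k - 1)], b = WM[idx(k, j - 1)];
      if (a < INF && b < INF &&
          addE(a + b, mod.mlOffset + mod.mlBranch) == target) {
        traceWM(i + 1, k - 1);
        traceWM(k, j - 1);
        return;
      }
    }
    // hairpin: nothing more to trace
  }

  void traceWM(int i, int j) {
    int target = WM[idx(i, j)];
    if (V[idx(i, j)] < INF && V[idx(i, j)] + mod.mlBranch == target) {
      traceV(i, j);
      return;
    }
    if (i + 1 <= j && WM[idx(i + 1, j)] < INF &&
        WM[idx(i + 1, j)] + mod.mlUnpaired == target) {
      traceWM(i + 1, j);
      return;
    }
    if (i <= j - 1 && WM[idx(i, j - 1)] < INF &&
        WM[idx(i, j - 1)] + mod.mlUnpaired == target) {
      traceWM(i, j - 1);
      return;
    }
    for (int k = i + 1; k <= j; ++k) {
      int a = WM[idx(i, k - 1)], b = WM[idx(k, j)];
      if (a < INF && b < INF && a + b == target) {
        traceWM(i, k - 1);
        traceWM(k, j);
        return;
      }
    }
  }
};

// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector seq, NumericMatrix stack,
                  NumericVector hairpinPen, NumericVector bulgePen,
                  NumericVector internalPen, double asymPerNt, double asymMax,
                  double mlOffset, double mlBranch, double mlUnpaired,
                  LogicalVector forceUnpaired, int maxLoop = 30) {
  int n = seq.size();
  Model mod = buildModel(stack, hairpinPen, bulgePen, internalPen, asymPerNt,
                         asymMax, mlOffset, mlBranch, mlUnpaired, 0.0, maxLoop);
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = seq[i];
  std::vector<bool> blk(n, false);
  for (int i = 0; i < forceUnpaired.size() && i < n; ++i)
    blk[i] = forceUnpaired[i];
  Folder f(s, mod, blk);
  int e = f.mfe();
  IntegerVector pt(n, 0);
  double mfe = 0.0;
  if (e < 0) {
    std::vector<int> tb = f.traceback();
    for (int i = 0; i < n; ++i) pt[i] = tb[i] + 1; // 1-based, 0 = unpaired
    mfe = e / 100.0;
  }
  return List::create(_["mfe"] = mfe, _["pair_table"] = pt);
}

// Batched MFE evaluation (no traceback); used by the randomization test
// where only the energies of many shuffled sequences are needed.
// [[Rcpp::export]]
NumericVector fold_mfe_batch_cpp(List seqs, NumericMatrix stack,
                                 NumericVector hairpinPen,
                                 NumericVector bulgePen,
                                 NumericVector internalPen,
                                 double asymPerNt, double asymMax,
                                 double mlOffset, double mlBranch,
                                 double mlUnpaired, int maxLoop = 30) {
  Model mod = buildModel(stack, hairpinPen, bulgePen, internalPen, asymPerNt,
                         asymMax, mlOffset, mlBranch, mlUnpaired, 0.0,
                         maxLoop);
  int nSeq = seqs.size();
  NumericVector out(nSeq);
  for (int q = 0; q < nSeq; ++q) {
    IntegerVector sv = seqs[q];
    std::vector<int> s(sv.begin(), sv.end());
    std::vector<bool> blk(s.size(), false);
    Folder f(s, mod, blk);
    int e = f.mfe();
    out[q] = e < 0 ? e / 100.0 : 0.0;
  }
  return out;
}

// Best intermolecular duplex energy between x (5'->3') and y (5'->3'),
// antiparallel, no intramolecular pairs.  Chain DP over candidate pairs:
// successive pairs advance along x and retreat along y.
static int duplexBest(const std::vector<int>& x, int ybeg, int yend,
                      const std::vector<int>& y, const Model& mod,
                      std::vector<int>* D = NULL,
                      std::vector<int>* pred = NULL) {
  int m = (int)x.size();
  int sLen = yend - ybeg;
  std::vector<int> localD((size_t)m * sLen, INF);
  std::vector<int> localP((size_t)m * sLen, -1);
  int best = INF;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < sLen; ++j) {
      int pt2 = pairType(x[i], y[ybeg + j]);
      if (pt2 < 0) continue;
      int cur = 0; // chain starts here
      int bp = -1;
      int iLo = i - 1 - mod.maxLoop; if (iLo < 0) iLo = 0;
      for (int ip = i - 1; ip >= iLo; --ip) {
        int n1 = i - ip - 1;
        for (int jp = j + 1; jp < sLen && (n1 + (jp - j - 1)) <= mod.maxLoop;
             ++jp) {
          int prev = localD[(size_t)ip * sLen + jp];
          if (prev >= INF) continue;
          int n2 = jp - j - 1;
          int cost;
          if (n1 == 0 && n2 == 0) {
            int pt1 = pairType(x[ip], y[ybeg + jp]);
            cost = mod.stack[pt1][pt2];
          } else {
            cost = mod.loopPen(n1, n2);
            if (cost >= INF) continue;
          }
          if (prev + cost < cur) { cur = prev + cost; bp = ip * sLen + jp; }
        }
      }
      localD[(size_t)i * sLen + j] = cur;
      localP[(size_t)i * sLen + j] = bp;
      if (cur < best) best = cur;
    }
  }
  if (D) *D = localD;
  if (pred) *pred = localP;
  if (best >= INF) return INF;
  return best + mod.duplexInit;
}

// [[Rcpp::export]]
List duplex_cpp(IntegerVector x, IntegerVector y, NumericMatrix stack,
                NumericVector bulgePen, NumericVector internalPen,
                double asymPerNt, double asymMax, double duplexInit,
                int maxLoop = 30) {
  Model mod = buildModel(stack, NumericVector(0), bulgePen, internalPen,
                         asymPerNt, asymMax, 0, 0, 0, duplexInit, maxLoop);
  std::vector<int> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  std::vector<int> D, P;
  int best = duplexBest(xs, 0, (int)ys.size(), ys, mod, &D, &P);
  if (best >= INF || best >= 0)
    return List::create(_["energy"] = 0.0,
                        _["x_pairs"] = IntegerVector(0),
                        _["y_pairs"] = IntegerVector(0));
  // locate best endpoint and walk predecessors
  int m = (int)xs.size(), sLen = (int)ys.size();
  int argmin = -1, val = INF;
  for (int c = 0; c < m * sLen; ++c)
    if (D[c] < val) { val = D[c]; argmin = c; }
  std::vector<int> xi, yj;
  int c = argmin;
  while (c >= 0) {
    xi.push_back(c / sLen + 1);
    yj.push_back(c % sLen + 1);
    c = P[c];
  }
  return List::create(_["energy"] = best / 100.0,
                      _["x_pairs"] = wrap(xi), _["y_pairs"] = wrap(yj));
}

// Per-window duplex minimum over sliding windows of length L (step 1).
// [[Rcpp::export]]
NumericVector duplex_window_scan_cpp(IntegerVector x, IntegerVector y, int L,
                                     NumericMatrix stack,
                                     NumericVector bulgePen,
                                     NumericVector internalPen,
                                     double asymPerNt, double asymMax,
                                     double duplexInit, int maxLoop = 30) {
  Model mod = buildModel(stack, NumericVector(0), bulgePen, internalPen,
                         asymPerNt, asymMax, 0, 0, 0, duplexInit, maxLoop);
  std::vector<int> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  int sLen = (int)ys.size();
  int nWin = sLen - L + 1;
  if (nWin < 1) return NumericVector(0);
  NumericVector out(nWin);
  for (int w = 0; w < nWin; ++w) {
    int best = duplexBest(xs, w, w + L, ys, mod);
    out[w] = (best >= INF || best >= 0) ? 0.0 : best / 100.0;
  }
  return out;
}
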