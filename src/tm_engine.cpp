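// Exact transfer-matrix evaluation of WSME partition functions restricted by
// one or two order parameters, with zero, one or two virtual linkers.
//
// The generating-function product <0| prod Q |0> over the stretch transfer
// matrices is evaluated as a dynamic program over decompositions of the chain
// into maximal native stretches separated by unfolded residues: a stretch
// i..j carries the Boltzmann weight
//   w_{i,j} = exp[-(sum_{i<=k<l<=j} eps_{k,l} - T sum_k S_k)/k_B T] * lambda^len
// and the lambda bookkeeping is a polynomial over integer native counts
// (an index pair for 2D order parameters). All coefficients are positive, so
// they are stored as log-magnitudes with log-sum-exp accumulation; this keeps
// disulfide-scale Boltzmann factors (e.g. exp(+40 kcal/mol / k_B T)) exact in
// the log domain where plain doubles overflow.
//
// Linkers: the insertion of a unit matrix at the linker end v expands the
// product into a sum over the stretch (gamma, delta) containing v; every
// stretch (alpha, beta) containing the other end u is multiplied by the
// additional weight w_L = exp(-sum_{k in [alpha,beta], l in [gamma,delta]}
// eps_{k,l}/k_B T), which is exactly the Boltzmann factor of all cross
// contacts between the two stretches joined by the linker. With two linkers
// the sum runs over the joint placement of both v-stretches; a bridge shared
// by both linkers is counted once.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + log1p(std::exp(-std::fabs(a - b)));
}

typedef std::vector<double> Poly; // log magnitudes, length (K1+1)*(K2+1)

struct Hook {
  // extra log-factor applied to a stretch (a, b):
  //   mode_or: rect(a,b; d1) once when the stretch contains u1 or u2
  //   else:    rect(a,b; d1) if it contains u1, times rect(a,b; d2) if u2
  bool any = false;
  bool mode_or = false;
  bool act1 = false, act2 = false;
  int u1 = -1, d1lo = 0, d1hi = -1;
  int u2 = -1, d2lo = 0, d2hi = -1;
};

struct Engine {
  int N, K1, K2, W, SZ;
  double beta, invR;
  std::vector<double> P;     // (N+1)*(N+1) prefix sums of E (1-based)
  std::vector<double> cumS;  // cumS[i] = S_1 + ... + S_i (cal/(mol K))
  std::vector<int> c1, c2;   // prefix axis counts
  std::vector<double> lwTab; // log stretch weights, (N+2)*(N+2)

  Engine(const NumericMatrix& E, const NumericVector& S, double T,
         const IntegerVector& axis, double Rcal, double Rkcal) {
    N = E.nrow();
    beta = 1.0 / (Rkcal * T);
    invR = 1.0 / Rcal;
    c1.assign(N + 1, 0); c2.assign(N + 1, 0); cumS.assign(N + 1, 0.0);
    K1 = 0; K2 = 0;
    for (int i = 1; i <= N; ++i) {
      c1[i] = c1[i - 1] + (axis[i - 1] == 1);
      c2[i] = c2[i - 1] + (axis[i - 1] == 2);
      cumS[i] = cumS[i - 1] + S[i - 1];
    }
    K1 = c1[N]; K2 = c2[N];
    W = K2 + 1; SZ = (K1 + 1) * W;
    P.assign((N + 1) * (N + 1), 0.0);
    for (int i = 1; i <= N; ++i)
      for (int j = 1; j <= N; ++j)
        P[i * (N + 1) + j] = E(i - 1, j - 1) + P[(i - 1) * (N + 1) + j] +
          P[i * (N + 1) + j - 1] - P[(i - 1) * (N + 1) + j - 1];
    lwTab.assign((N + 2) * (N + 2), 0.0);
    for (int i = 1; i <= N; ++i)
      for (int j = i; j <= N; ++j)
        lwTab[i * (N + 2) + j] =
          -beta * 0.5 * rect(i, j, i, j) +
          (cumS[j] - cumS[i - 1]) * invR;
  }

  double rect(int a, int b, int c, int d) const {
    if (a > b || c > d) return 0.0;
    return P[b * (N + 1) + d] - P[(a - 1) * (N + 1) + d] -
           P[b * (N + 1) + c - 1] + P[(a - 1) * (N + 1) + c - 1];
  }
  double lw(int i, int j) const { return lwTab[i * (N + 2) + j]; }
  int s1(int i, int j) const { return c1[j] - c1[i - 1]; }
  int s2(int i, int j) const { return c2[j] - c2[i - 1]; }

  double hook_extra(const Hook& h, int a, int b) const {
    if (!h.any) return 0.0;
    if (h.mode_or) {
      bool in1 = (h.u1 >= a && h.u1 <= b);
      bool in2 = (h.u2 >= a && h.u2 <= b);
      return (in1 || in2) ? -beta * rect(a, b, h.d1lo, h.d1hi) : 0.0;
    }
    double x = 0.0;
    if (h.act1 && h.u1 >= a && h.u1 <= b) x += -beta * rect(a, b, h.d1lo, h.d1hi);
    if (h.act2 && h.u2 >= a && h.u2 <= b) x += -beta * rect(a, b, h.d2lo, h.d2hi);
    return x;
  }

  bool hook_relevant(const Hook& h, int lo, int hi) const {
    if (!h.any || lo > hi) return false;
    bool r = false;
    if (h.mode_or || h.act1) r = r || (h.u1 >= lo && h.u1 <= hi);
    if (h.mode_or || h.act2) r = r || (h.u2 >= lo && h.u2 <= hi);
    return r;
  }

  Poly unit() const {
    Poly p(SZ, R_NegInf);
    p[0] = 0.0;
    return p;
  }

  // dest += src * exp(lc) * shift(sh1, sh2)
  void axpy(Poly& dest, const Poly& src, double lc, int sh1, int sh2) const {
    for (int a = 0; a + sh1 <= K1; ++a)
      for (int b = 0; b + sh2 <= K2; ++b) {
        double v = src[a * W + b];
        if (v == R_NegInf) continue;
        double& d = dest[(a + sh1) * W + b + sh2];
        d = logadd(d, v + lc);
      }
  }

  // partition polynomial of the isolated segment lo..hi (unit when lo > hi)
  Poly seg_partition(int lo, int hi, const Hook& h) const {
    if (lo > hi) return unit();
    int len = hi - lo + 2; // DP positions lo..hi+1 (index 1..len)
    std::vector<Poly> F(len + 1, Poly(SZ, R_NegInf));
    F[0][0] = 0.0;
    for (int j = lo; j <= hi + 1; ++j) {
      int idx = j - lo + 1;
      for (int i = lo - 1; i <= j - 1; ++i) {
        int a = i + 1, b = j - 1; // stretch a..b, empty when a > b
        double lc = 0.0; int sh1 = 0, sh2 = 0;
        if (a <= b) {
          lc = lw(a, b) + hook_extra(h, a, b);
          sh1 = s1(a, b); sh2 = s2(a, b);
        }
        axpy(F[idx], F[i - lo + 1], lc, sh1, sh2);
      }
    }
    return F[len];
  }

  Poly conv(const Poly& A, const Poly& B) const {
    Poly C(SZ, R_NegInf);
    for (int a1 = 0; a1 <= K1; ++a1)
      for (int a2 = 0; a2 <= K2; ++a2) {
        double va = A[a1 * W + a2];
        if (va == R_NegInf) continue;
        for (int b1 = 0; a1 + b1 <= K1; ++b1)
          for (int b2 = 0; a2 + b2 <= K2; ++b2) {
            double vb = B[b1 * W + b2];
            if (vb == R_NegInf) continue;
            double& d = C[(a1 + b1) * W + a2 + b2];
            d = logadd(d, va + vb);
          }
      }
    return C;
  }

  // A * w(a,b) * B * exp(lc_extra), accumulated into G
  void add_stretch_term(Poly& G, const Poly& A, int a, int b, const Poly& B,
                        double lc_extra) const {
    double lc = lw(a, b) + lc_extra;
    int sh1 = s1(a, b), sh2 = s2(a, b);
    for (int a1 = 0; a1 <= K1; ++a1)
      for (int a2 = 0; a2 <= K2; ++a2) {
        double va = A[a1 * W + a2];
        if (va == R_NegInf) continue;
        for (int b1 = 0; a1 + b1 + sh1 <= K1; ++b1)
          for (int b2 = 0; a2 + b2 + sh2 <= K2; ++b2) {
            double vb = B[b1 * W + b2];
            if (vb == R_NegInf) continue;
            double& d = G[(a1 + b1 + sh1) * W + a2 + b2 + sh2];
            d = logadd(d, va + vb + lc);
          }
      }
  }

  void add_poly(Poly& G, const Poly& A) const {
    for (int i = 0; i < SZ; ++i) G[i] = logadd(G[i], A[i]);
  }

  // ---- top-level evaluations -------------------------------------------

  Poly tm0() const {
    Hook none;
    return seg_partition(1, N, none);
  }

  Poly tm1(int u, int v) const {
    Hook none;
    // cached unhooked prefixes/suffixes
    std::vector<Poly> Mleft(N + 1), Mright(N + 2);
    Mleft[0] = unit();
    for (int x = 1; x <= N; ++x) Mleft[x] = seg_partition(1, x, none);
    Mright[N + 1] = unit();
    for (int x = N; x >= 1; --x) Mright[x] = seg_partition(x, N, none);

    Poly G(SZ, R_NegInf);
    // v unfolded: no linker connectivity possible
    add_poly(G, conv(Mleft[v - 1], v + 1 <= N ? Mright[v + 1] : unit()));
    // stretch (gamma, delta) contains v
    for (int g = 1; g <= v; ++g) {
      for (int d = v; d <= N; ++d) {
        Poly pre;
        if (u <= g - 2) {
          Hook h; h.any = true; h.act1 = true;
          h.u1 = u; h.d1lo = g; h.d1hi = d;
          pre = seg_partition(1, g - 2, h);
        } else {
          pre = Mleft[g >= 2 ? g - 2 : 0];
        }
        const Poly& suf = (d + 2 <= N + 1) ? Mright[d + 2] : Mright[N + 1];
        add_stretch_term(G, pre, g, d, suf, 0.0);
      }
    }
    return G;
  }

  // helper: segment partition with caching of the unhooked full-prefix /
  // full-suffix cases
  Poly seg2(int lo, int hi, const Hook& h, const std::vector<Poly>& Mleft,
            const std::vector<Poly>& Mright) const {
    if (lo > hi) return unit();
    if (!hook_relevant(h, lo, hi)) {
      if (lo == 1) return Mleft[hi];
      if (hi == N) return Mright[lo];
      Hook none;
      return seg_partition(lo, hi, none);
    }
    return seg_partition(lo, hi, h);
  }

  Poly tm2(int ua, int va, int ub, int vb) const {
    // order so that va <= vb (the OR Hamiltonian is symmetric in the linkers)
    if (va > vb) { std::swap(ua, ub); std::swap(va, vb); }
    Hook none;
    std::vector<Poly> Mleft(N + 1), Mright(N + 2);
    Mleft[0] = unit();
    for (int x = 1; x <= N; ++x) Mleft[x] = seg_partition(1, x, none);
    Mright[N + 1] = unit();
    for (int x = N; x >= 1; --x) Mright[x] = seg_partition(x, N, none);

    Poly G(SZ, R_NegInf);

    if (va == vb) {
      int v = va;
      // both linker ends unfolded together
      add_poly(G, conv(Mleft[v - 1], v + 1 <= N ? Mright[v + 1] : unit()));
      // stretch (g, d) contains the shared end v
      for (int g = 1; g <= v; ++g)
        for (int d = v; d <= N; ++d) {
          Hook h; h.any = true; h.mode_or = true;
          h.u1 = ua; h.u2 = ub; h.d1lo = g; h.d1hi = d;
          Poly left = seg2(1, g - 2, h, Mleft, Mright);
          const Poly& right = (d + 2 <= N + 1) ? Mright[std::min(d + 2, N + 1)]
                                               : Mright[N + 1];
          add_stretch_term(G, left, g, d, right, 0.0);
        }
      return G;
    }

    // case A: va and vb both unfolded
    {
      Poly left = Mleft[va - 1];
      Poly mid = seg_partition(va + 1, vb - 1, none);
      Poly right = vb + 1 <= N ? Mright[vb + 1] : unit();
      add_poly(G, conv(conv(left, mid), right));
    }
    // case B: va in stretch (g, d) with d < vb; vb unfolded
    for (int g = 1; g <= va; ++g)
      for (int d = va; d <= vb - 1; ++d) {
        Hook h; h.any = true; h.act1 = true;
        h.u1 = ua; h.d1lo = g; h.d1hi = d;
        Poly left = seg2(1, g - 2, h, Mleft, Mright);
        Poly right;
        if (vb >= d + 2) {
          Poly r1 = seg_partition(d + 2, vb - 1, none);
          Poly r2 = vb + 1 <= N ? Mright[vb + 1] : unit();
          right = conv(r1, r2);
        } else { // vb == d + 1: the boundary gap is vb itself
          right = vb + 1 <= N ? Mright[vb + 1] : unit();
        }
        add_stretch_term(G, left, g, d, right, 0.0);
      }
    // case C: vb in stretch (g2, d2) with g2 > va; va unfolded
    for (int g2 = va + 1; g2 <= vb; ++g2)
      for (int d2 = vb; d2 <= N; ++d2) {
        Hook h; h.any = true; h.act2 = true;
        h.u2 = ub; h.d2lo = g2; h.d2hi = d2;
        Poly left;
        if (va <= g2 - 2) {
          Poly l1 = seg2(1, va - 1, h, Mleft, Mright);
          Poly l2 = seg_partition(va + 1, g2 - 2, h);
          left = conv(l1, l2);
        } else { // va == g2 - 1: boundary gap is va itself
          left = seg2(1, g2 - 2, h, Mleft, Mright);
        }
        const Poly& right = (d2 + 2 <= N + 1) ? Mright[std::min(d2 + 2, N + 1)]
                                              : Mright[N + 1];
        add_stretch_term(G, left, g2, d2, right, 0.0);
      }
    // case D: one stretch (g, d) contains both va and vb
    for (int g = 1; g <= va; ++g)
      for (int d = vb; d <= N; ++d) {
        Hook h; h.any = true; h.mode_or = true;
        h.u1 = ua; h.u2 = ub; h.d1lo = g; h.d1hi = d;
        Poly left = seg2(1, g - 2, h, Mleft, Mright);
        const Poly& right = (d + 2 <= N + 1) ? Mright[std::min(d + 2, N + 1)]
                                             : Mright[N + 1];
        add_stretch_term(G, left, g, d, right, 0.0);
      }
    // case E: va in (g1, d1), vb in (g2, d2), disjoint stretches
    for (int g1 = 1; g1 <= va; ++g1)
      for (int d1 = va; d1 <= vb - 2; ++d1)
        for (int g2 = d1 + 2; g2 <= vb; ++g2)
          for (int d2 = vb; d2 <= N; ++d2) {
            Hook h; h.any = true; h.act1 = true; h.act2 = true;
            h.u1 = ua; h.d1lo = g1; h.d1hi = d1;
            h.u2 = ub; h.d2lo = g2; h.d2hi = d2;
            Poly left = seg2(1, g1 - 2, h, Mleft, Mright);
            Poly mid = seg_partition(d1 + 2, g2 - 2, h);
            // stretch (g1, d1) itself bridges to (g2, d2) when it holds ub
            double glog = (ub >= g1 && ub <= d1)
              ? -beta * rect(g1, d1, g2, d2) : 0.0;
            // assemble left * w(g1,d1) * mid -> then * w(g2,d2) * right
            Poly lm(SZ, R_NegInf);
            add_stretch_term(lm, left, g1, d1, mid, glog);
            const Poly& right = (d2 + 2 <= N + 1)
              ? Mright[std::min(d2 + 2, N + 1)] : Mright[N + 1];
            add_stretch_term(G, lm, g2, d2, right, 0.0);
          }
    return G;
  }
};

// [[Rcpp::export]]
NumericMatrix tm_engine_cpp(NumericMatrix E, NumericVector S,
                            double temperature, IntegerVector axis,
                            IntegerMatrix linkers, double R_cal,
                            double R_kcal) {
  int n = E.nrow();
  if (E.ncol() != n) stop("E must be square");
  if (S.size() != n || axis.size() != n) stop("S/axis length mismatch");
  if (temperature <= 0) stop("temperature must be positive");
  Engine eng(E, S, temperature, axis, R_cal, R_kcal);
  Poly res;
  int L = linkers.nrow();
  if (L == 0) {
    res = eng.tm0();
  } else if (L == 1) {
    int u = linkers(0, 0), v = linkers(0, 1);
    if (v <= u) stop("linker requires u < v");
    res = eng.tm1(u, v);
  } else if (L == 2) {
    int ua = linkers(0, 0), va = linkers(0, 1);
    int ub = linkers(1, 0), vb = linkers(1, 1);
    if (va <= ua || vb <= ub) stop("linker requires u < v");
    if (ua == ub && va == vb)
      stop("identical linkers: use the single-linker path");
    res = eng.tm2(ua, va, ub, vb);
  } else {
    stop("transfer-matrix route supports at most 2 linkers; ",
         "use the enumeration oracle for more");
  }
  NumericMatrix out(eng.K1 + 1, eng.K2 + 1);
  for (int a = 0; a <= eng.K1; ++a)
    for (int b = 0; b <= eng.K2; ++b)
      out(a, b) = res[a * eng.W + b];
  return out;
}
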