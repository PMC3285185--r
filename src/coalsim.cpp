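// Structured-coalescent simulator with recombination and infinite-sites
// mutation, in ms unit conventions: time in units of 4*N0 generations
// (N0 = present size of deme 1), theta = 4*N0*mu per locus,
// M[i][j] = 4*N0*m_ij = backward per-lineage migration rate from deme i
// to deme j, rho = 4*N0*r per locus.  Lineages carry ancestral material as
// interval sets over [0,1); material that has reached its MRCA is dropped.
// Mutations are laid down as the process runs: during an interval of
// length dt each lineage receives Poisson(theta * measure * dt) mutations
// placed uniformly on its ancestral material, each recording the set of
// sampled alleles that inherit the derived state.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<uint64_t> Bits;

struct Seg {
  double l, r;
  Bits d;
};

struct Lin {
  int deme;
  std::vector<Seg> segs;
  double spanL, spanR, meas;
};

struct Mut {
  double pos;
  Bits d;
};

static inline void refresh(Lin &L) {
  if (L.segs.empty()) { L.spanL = L.spanR = 0.0; L.meas = 0.0; return; }
  L.spanL = L.segs.front().l;
  L.spanR = L.segs.back().r;
  double m = 0.0;
  for (size_t i = 0; i < L.segs.size(); ++i) m += L.segs[i].r - L.segs[i].l;
  L.meas = m;
}

// Union of two sorted interval sets; chunks whose descendant set reaches
// the full sample are ancestral-MRCA material and are dropped.
static std::vector<Seg> merge_segs(const std::vector<Seg> &A,
                                   const std::vector<Seg> &B,
                                   const Bits &full) {
  std::vector<double> bp;
  bp.reserve(2 * (A.size() + B.size()));
  for (size_t i = 0; i < A.size(); ++i) { bp.push_back(A[i].l); bp.push_back(A[i].r); }
  for (size_t i = 0; i < B.size(); ++i) { bp.push_back(B[i].l); bp.push_back(B[i].r); }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

  std::vector<Seg> out;
  size_t ia = 0, ib = 0;
  const size_t nw = full.size();
  for (size_t k = 0; k + 1 < bp.size(); ++k) {
    double l = bp[k], r = bp[k + 1];
    while (ia < A.size() && A[ia].r <= l) ++ia;
    while (ib < B.size() && B[ib].r <= l) ++ib;
    bool ca = ia < A.size() && A[ia].l <= l;
    bool cb = ib < B.size() && B[ib].l <= l;
    if (!ca && !cb) continue;
    Bits u(nw, 0);
    if (ca) u = A[ia].d;
    if (cb) { for (size_t w = 0; w < nw; ++w) u[w] |= B[ib].d[w]; }
    if (u == full) continue;  // this chunk found its MRCA here
    if (!out.empty() && out.back().r == l && out.back().d == u) {
      out.back().r = r;
    } else {
      Seg s; s.l = l; s.r = r; s.d = u;
      out.push_back(s);
    }
  }
  return out;
}

// Waiting time to the next coalescence in a deme with k lineages, current
// (backward-time) size x_now and exponential growth rate alpha:
// hazard(s) = k(k-1)/x_now * exp(alpha * s).
static double coal_wait(int k, double x_now, double alpha) {
  double rate0 = (double)k * (k - 1) / x_now;
  double E = exp_rand();
  if (alpha == 0.0) return E / rate0;
  double arg = 1.0 + alpha * E / rate0;
  if (arg <= 0.0) return R_PosInf;
  return std::log(arg) / alpha;
}

// [[Rcpp::export]]
List sim_locus_cpp(IntegerVector nPerDeme, NumericVector size0,
                   NumericVector growth0, NumericMatrix mig0,
                   NumericVector evTime, IntegerVector evKind,
                   IntegerVector evI, IntegerVector evJ, NumericVector evVal,
                   double theta, double rho, bool returnMatrix) {
  const int nd = size0.size();
  if (nPerDeme.size() != nd || growth0.size() != nd ||
      mig0.nrow() != nd || mig0.ncol() != nd)
    stop("inconsistent deme dimensions");
  int n = 0;
  for (int d = 0; d < nd; ++d) {
    if (nPerDeme[d] < 0) stop("negative sample size");
    n += nPerDeme[d];
  }
  if (n < 2) stop("need at least 2 sampled alleles in total");
  if (theta < 0 || rho < 0) stop("theta and rho must be non-negative");

  const size_t nw = (size_t)((n + 63) / 64);
  Bits full(nw, 0);
  for (int i = 0; i < n; ++i) full[i / 64] |= (uint64_t)1 << (i % 64);

  // deme state
  std::vector<double> xb(size0.begin(), size0.end());
  std::vector<double> al(growth0.begin(), growth0.end());
  std::vector<double> tb(nd, 0.0);
  std::vector<std::vector<double> > M(nd, std::vector<double>(nd, 0.0));
  for (int i = 0; i < nd; ++i)
    for (int j = 0; j < nd; ++j)
      if (i != j) M[i][j] = mig0(i, j);
  for (int d = 0; d < nd; ++d)
    if (xb[d] <= 0) stop("deme sizes must be positive");

  std::vector<int> sampleDeme(n);
  std::vector<Lin> lins;
  lins.reserve(2 * n);
  int idx = 0;
  for (int d = 0; d < nd; ++d) {
    for (int s = 0; s < nPerDeme[d]; ++s, ++idx) {
      sampleDeme[idx] = d;
      Lin L;
      L.deme = d;
      Seg sg; sg.l = 0.0; sg.r = 1.0; sg.d = Bits(nw, 0);
      sg.d[idx / 64] |= (uint64_t)1 << (idx % 64);
      L.segs.push_back(sg);
      refresh(L);
      lins.push_back(L);
    }
  }

  std::vector<Mut> muts;
  double t = 0.0;
  double tmrca = R_NaReal;
  int evIdx = 0;
  const int nev = evTime.size();
  const double BIG = R_PosInf;
  long iter = 0;

  while (!lins.empty()) {
    if (++iter > 100000000L) stop("event budget exceeded; model may be degenerate");

    std::vector<int> kd(nd, 0);
    for (size_t i = 0; i < lins.size(); ++i) kd[lins[i].deme]++;

    // candidate waiting times
    double sCoal = BIG; int coalDeme = -1;
    for (int d = 0; d < nd; ++d) {
      if (kd[d] >= 2) {
        double x_now = xb[d] * std::exp(-al[d] * (t - tb[d]));
        double s = coal_wait(kd[d], x_now, al[d]);
        if (s < sCoal) { sCoal = s; coalDeme = d; }
      }
    }
    double migRate = 0.0;
    std::vector<double> rowsum(nd, 0.0);
    for (int d = 0; d < nd; ++d) {
      for (int j = 0; j < nd; ++j) rowsum[d] += M[d][j];
      migRate += kd[d] * rowsum[d];
    }
    double sMig = migRate > 0 ? exp_rand() / migRate : BIG;
    double spanSum = 0.0;
    if (rho > 0) {
      for (size_t i = 0; i < lins.size(); ++i)
        spanSum += lins[i].spanR - lins[i].spanL;
    }
    double recRate = rho * spanSum;
    double sRec = recRate > 0 ? exp_rand() / recRate : BIG;

    double sMin = std::min(sCoal, std::min(sMig, sRec));
    double tDem = evIdx < nev ? evTime[evIdx] : BIG;

    if (sMin == BIG && tDem == BIG)
      stop("lineages cannot reach a common ancestor under this model");

    double tNext = (t + sMin < tDem) ? t + sMin : tDem;
    double dt = tNext - t;

    // mutations over (t, t + dt) on the current lineages
    if (theta > 0 && dt > 0) {
      for (size_t i = 0; i < lins.size(); ++i) {
        const Lin &L = lins[i];
        if (L.meas <= 0) continue;
        int nm = (int)R::rpois(theta * L.meas * dt);
        for (int m = 0; m < nm; ++m) {
          double u = unif_rand() * L.meas, acc = 0.0;
          for (size_t s = 0; s < L.segs.size(); ++s) {
            double len = L.segs[s].r - L.segs[s].l;
            if (u <= acc + len || s + 1 == L.segs.size()) {
              Mut mu; mu.pos = L.segs[s].l + std::min(u - acc, len);
              mu.d = L.segs[s].d;
              muts.push_back(mu);
              break;
            }
            acc += len;
          }
        }
      }
    }
    t = tNext;

    if (evIdx < nev && evTime[evIdx] <= t) {
      // apply every demographic event scheduled at this time
      while (evIdx < nev && evTime[evIdx] <= t) {
        int kind = evKind[evIdx];
        int i = evI[evIdx] - 1;
        int j = evJ[evIdx] - 1;
        double v = evVal[evIdx];
        if (kind == 1) {            // size_change: new size, growth reset
          xb[i] = v; al[i] = 0.0; tb[i] = t;
        } else if (kind == 2) {     // growth_change
          double x_now = xb[i] * std::exp(-al[i] * (t - tb[i]));
          xb[i] = x_now; al[i] = v; tb[i] = t;
        } else if (kind == 3) {     // split_join: lineages in i move to j
          for (size_t q = 0; q < lins.size(); ++q)
            if (lins[q].deme == i) lins[q].deme = j;
          for (int q = 0; q < nd; ++q) { M[i][q] = 0.0; M[q][i] = 0.0; }
        } else if (kind == 4) {     // migration_change
          if (i != j) M[i][j] = v;
        } else stop("unknown event kind");
        ++evIdx;
      }
      continue;
    }

    if (sMin == sCoal) {
      // coalescence: choose an unordered pair in coalDeme
      int k = kd[coalDeme];
      int a = (int)(unif_rand() * k); if (a >= k) a = k - 1;
      int b = (int)(unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      int ia = -1, ib = -1, seen = 0;
      for (size_t q = 0; q < lins.size(); ++q) {
        if (lins[q].deme == coalDeme) {
          if (seen == a) ia = (int)q;
          if (seen == b) ib = (int)q;
          ++seen;
        }
      }
      Lin merged;
      merged.deme = coalDeme;
      merged.segs = merge_segs(lins[ia].segs, lins[ib].segs, full);
      refresh(merged);
      if (ia < ib) std::swap(ia, ib);
      lins.erase(lins.begin() + ia);
      lins.erase(lins.begin() + ib);
      if (!merged.segs.empty()) lins.push_back(merged);
      if (lins.empty()) tmrca = t;
    } else if (sMin == sMig) {
      double u = unif_rand() * migRate;
      int pick = -1, dest = -1;
      for (size_t q = 0; q < lins.size() && pick < 0; ++q) {
        double w = rowsum[lins[q].deme];
        if (u < w) {
          pick = (int)q;
          for (int j = 0; j < nd; ++j) {
            if (u < M[lins[q].deme][j]) { dest = j; break; }
            u -= M[lins[q].deme][j];
          }
          if (dest < 0) dest = nd - 1;
        } else u -= w;
      }
      if (pick < 0) pick = (int)lins.size() - 1;
      if (dest < 0) dest = lins[pick].deme;
      lins[pick].deme = dest;
    } else {
      // recombination: pick lineage weighted by span, split at breakpoint
      double u = unif_rand() * spanSum;
      int pick = -1;
      for (size_t q = 0; q < lins.size(); ++q) {
        double w = lins[q].spanR - lins[q].spanL;
        if (u < w) { pick = (int)q; break; }
        u -= w;
      }
      if (pick < 0) pick = (int)lins.size() - 1;
      Lin &L = lins[pick];
      double bp = L.spanL + unif_rand() * (L.spanR - L.spanL);
      std::vector<Seg> left, right;
      for (size_t s = 0; s < L.segs.size(); ++s) {
        const Seg &sg = L.segs[s];
        if (sg.r <= bp) left.push_back(sg);
        else if (sg.l >= bp) right.push_back(sg);
        else {
          Seg sl = sg; sl.r = bp;
          Seg sr = sg; sr.l = bp;
          left.push_back(sl); right.push_back(sr);
        }
      }
      if (!left.empty() && !right.empty()) {
        Lin Lr; Lr.deme = L.deme; Lr.segs = right; refresh(Lr);
        L.segs = left; refresh(L);
        lins.push_back(Lr);
      }
    }
  }

  // assemble output
  std::sort(muts.begin(), muts.end(),
            [](const Mut &a, const Mut &b) { return a.pos < b.pos; });
  const int S = (int)muts.size();
  NumericVector positions(S);
  IntegerMatrix counts(S, nd);
  for (int s = 0; s < S; ++s) {
    positions[s] = muts[s].pos;
    for (int i = 0; i < n; ++i)
      if (muts[s].d[i / 64] & ((uint64_t)1 << (i % 64)))
        counts(s, sampleDeme[i])++;
  }
  List out = List::create(
    _["positions"] = positions,
    _["counts"] = counts,
    _["sampleDeme"] = IntegerVector(sampleDeme.begin(), sampleDeme.end()),
    _["tmrca"] = tmrca);
  if (returnMatrix) {
    IntegerMatrix mat(n, S);
    for (int s = 0; s < S; ++s)
      for (int i = 0; i < n; ++i)
        mat(i, s) = (muts[s].d[i / 64] >> (i % 64)) & 1;
    out["matrix"] = mat;
  }
  return out;
}

// Fast path for the posterior predictive machinery: per-site nucleotide
// diversity, Phi-ST (AMOVA on pairwise-difference distances), per-deme
// Tajima's D averaged over demes, and S, from per-deme derived-allele
// counts.  Mirrors the R reference implementation used on alignments.
// [[Rcpp::export]]
NumericVector counts_stats_cpp(IntegerMatrix counts, IntegerVector nPer,
                               double L) {
  const int S = counts.nrow();
  const int P = counts.ncol();
  int n = 0;
  for (int d = 0; d < P; ++d) n += nPer[d];
  const double pairsTot = (double)n * (n - 1) / 2.0;
  double sumXT = 0.0;                  // sum x (n - x) over columns
  std::vector<double> sumXD(P, 0.0);   // per-deme sum x_d (n_d - x_d)
  std::vector<int> Sd(P, 0);
  for (int s = 0; s < S; ++s) {
    int x = 0;
    for (int d = 0; d < P; ++d) x += counts(s, d);
    sumXT += (double)x * (n - x);
    for (int d = 0; d < P; ++d) {
      int xd = counts(s, d);
      if (xd > 0 && xd < nPer[d]) Sd[d]++;
      sumXD[d] += (double)xd * (nPer[d] - xd);
    }
  }
  double piLocus = S ? sumXT / pairsTot : 0.0;
  double pi = piLocus / L;
  // Tajima's D per deme
  double dSum = 0.0; int dCnt = 0;
  for (int d = 0; d < P; ++d) {
    int nd = nPer[d];
    if (nd < 4 || Sd[d] == 0) continue;
    double a1 = 0, a2 = 0;
    for (int i = 1; i < nd; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
    double b1 = (nd + 1.0) / (3.0 * (nd - 1));
    double b2 = 2.0 * (nd * (double)nd + nd + 3) / (9.0 * nd * (nd - 1));
    double c1 = b1 - 1.0 / a1;
    double c2 = b2 - (nd + 2.0) / (a1 * nd) + a2 / (a1 * a1);
    double e1 = c1 / a1, e2 = c2 / (a1 * a1 + a2);
    double piD = sumXD[d] / ((double)nd * (nd - 1) / 2.0);
    double Sdd = Sd[d];
    double D = (piD - Sdd / a1) / std::sqrt(e1 * Sdd + e2 * Sdd * (Sdd - 1));
    dSum += D; dCnt++;
  }
  double tajd = dCnt ? dSum / dCnt : NA_REAL;
  // Phi-ST
  double phi = NA_REAL;
  bool ok = S > 0 && P >= 2;
  for (int d = 0; d < P; ++d) if (nPer[d] < 2) ok = false;
  if (ok) {
    double ssTotal = sumXT / 2.0 / n;
    double ssWithin = 0.0, sumSq = 0.0;
    for (int d = 0; d < P; ++d) {
      ssWithin += sumXD[d] / 2.0 / nPer[d];
      sumSq += (double)nPer[d] * nPer[d];
    }
    double sigmaW = ssWithin / (n - P);
    double nprime = (n - sumSq / n) / (P - 1);
    double sigmaA = ((ssTotal - ssWithin) / (P - 1) - sigmaW) / nprime;
    double denom = sigmaA + sigmaW;
    phi = denom == 0 ? NA_REAL : sigmaA / denom;
  }
  return NumericVector::create(pi, phi, tajd, (double)S);
}
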