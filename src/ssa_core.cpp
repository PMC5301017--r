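// Stochastic simulation cores: exact spatial SSA (direct-method and
// composition-rejection event selection with dependency-driven propensity
// updates), the operator-splitting reaction window with occupancy tracking,
// and the occupancy-based multinomial diffusion operator.
//
// Event layout: per tet, locals 0..nR-1 are reaction instances (model
// order), locals nR..nR+nD-1 are diffusion instances (one per diffusive
// species; the destination neighbour is drawn at fire time proportional to
// the per-face geometry factor). Global event id = tet * (nR + nD) + local.
// All indices crossing the R/C++ boundary are 0-based.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

struct Tables {
  int T, S, nR, nD, nLoc;
  IntegerVector rOrder, rS1, rS2;      // per reaction
  std::vector<std::vector<int> > dSp;  // per reaction: species with net change
  std::vector<std::vector<int> > dVal; // matching net deltas
  NumericMatrix cPerTet;               // T x nR per-event rate constants
  IntegerVector diffSp;                // nD species ids
  NumericMatrix dTot;                  // T x nD total diffusion rates
  IntegerMatrix neighTet;              // T x 4, -1 boundary
  NumericMatrix G;                     // T x 4 geometry factor A/(h V)
  std::vector<double> Grow;            // per-tet row sum of G
  std::vector<std::vector<int> > deps; // per event: events to refresh
};

Tables unpack(const List& tbl, int T, int S) {
  Tables x;
  x.T = T;
  x.S = S;
  x.rOrder = tbl["rOrder"];
  x.rS1 = tbl["rS1"];
  x.rS2 = tbl["rS2"];
  x.nR = x.rOrder.size();
  x.cPerTet = as<NumericMatrix>(tbl["cPerTet"]);
  x.diffSp = tbl["diffSp"];
  x.nD = x.diffSp.size();
  x.nLoc = x.nR + x.nD;
  x.dTot = as<NumericMatrix>(tbl["dTot"]);
  x.neighTet = as<IntegerMatrix>(tbl["neighTet"]);
  x.G = as<NumericMatrix>(tbl["G"]);
  List dsp = tbl["rDeltaSp"], dvl = tbl["rDeltaVal"];
  for (int r = 0; r < x.nR; r++) {
    x.dSp.push_back(as<std::vector<int> >(dsp[r]));
    x.dVal.push_back(as<std::vector<int> >(dvl[r]));
  }
  x.Grow.assign(T, 0.0);
  for (int t = 0; t < T; t++)
    for (int f = 0; f < 4; f++)
      if (x.neighTet(t, f) >= 0) x.Grow[t] += x.G(t, f);
  if (tbl.containsElementNamed("deps")) {
    List dl = tbl["deps"];
    for (int e = 0; e < dl.size(); e++)
      x.deps.push_back(as<std::vector<int> >(dl[e]));
  }
  return x;
}

inline double reacProp(const Tables& x, const IntegerMatrix& n, int t, int r) {
  double c = x.cPerTet(t, r);
  if (x.rOrder[r] == 1) return c * n(t, x.rS1[r]);
  int s1 = x.rS1[r], s2 = x.rS2[r];
  if (s1 == s2) {
    double m = n(t, s1);
    return c * m * (m - 1) / 2.0;
  }
  return c * n(t, s1) * n(t, s2);
}

inline double eventProp(const Tables& x, const IntegerMatrix& n, int e) {
  int t = e / x.nLoc, l = e % x.nLoc;
  if (l < x.nR) return reacProp(x, n, t, l);
  return n(t, x.diffSp[l - x.nR]) * x.dTot(t, l - x.nR);
}

// Pick a face of tet t proportional to its geometry factor.
inline int pickFace(const Tables& x, int t) {
  double u = unif_rand() * x.Grow[t];
  int last = -1;
  for (int f = 0; f < 4; f++) {
    double g = (x.neighTet(t, f) >= 0) ? x.G(t, f) : 0.0;
    if (g <= 0) continue;
    last = f;
    if (u <= g) return f;
    u -= g;
  }
  return last;  // round-off fell off the end; weights are fixed, last is valid
}

// Apply the stoichiometric footprint of event e; returns false if the event
// is a diffusion with no valid face (cannot happen when propensity > 0).
inline void applyEvent(const Tables& x, IntegerMatrix& n, int e) {
  int t = e / x.nLoc, l = e % x.nLoc;
  if (l < x.nR) {
    const std::vector<int>& sp = x.dSp[l];
    const std::vector<int>& dv = x.dVal[l];
    for (size_t i = 0; i < sp.size(); i++) n(t, sp[i]) += dv[i];
  } else {
    int s = x.diffSp[l - x.nR];
    int f = pickFace(x, t);
    if (f < 0) stop("internal error: diffusion fired in isolated tet");
    n(t, s) -= 1;
    n(x.neighTet(t, f), s) += 1;
  }
}

// ---- composition-rejection group structure ---------------------------------
// Power-of-two propensity groups: an event with propensity a in
// [2^(g-1), 2^g) lives in group g. Groups span 2^GMIN_EXP .. 2^GMAX_EXP;
// propensities below the floor are clamped into the lowest group (rejection
// sampling stays exact because the group bound is still an upper bound).
// Zero-propensity events leave the structure entirely.

struct CRGroups {
  static const int GMIN_EXP = -40, GMAX_EXP = 80;
  int ng;
  std::vector<std::vector<int> > members;
  std::vector<double> gsum, bound;
  std::vector<int> egroup, epos;

  void init(int nEvents) {
    ng = GMAX_EXP - GMIN_EXP + 1;
    members.assign(ng, std::vector<int>());
    gsum.assign(ng, 0.0);
    bound.resize(ng);
    for (int i = 0; i < ng; i++) bound[i] = std::ldexp(1.0, GMIN_EXP + i);
    egroup.assign(nEvents, -1);
    epos.assign(nEvents, -1);
  }
  int groupOf(double a) const {
    int e;
    std::frexp(a, &e);  // a = m * 2^e, m in [0.5, 1)
    int gi = e - GMIN_EXP;
    if (gi < 0) gi = 0;
    if (gi >= ng) gi = ng - 1;
    return gi;
  }
  void set(std::vector<double>& a, int e, double na) {
    double oa = a[e];
    int og = egroup[e];
    int ngi = (na > 0) ? groupOf(na) : -1;
    a[e] = na;
    if (og == ngi) {
      if (og >= 0) gsum[og] += na - oa;
      return;
    }
    if (og >= 0) {
      gsum[og] -= oa;
      std::vector<int>& v = members[og];
      int p = epos[e], last = v.back();
      v[p] = last;
      epos[last] = p;
      v.pop_back();
      egroup[e] = -1;
      epos[e] = -1;
    }
    if (ngi >= 0) {
      members[ngi].push_back(e);
      epos[e] = (int)members[ngi].size() - 1;
      egroup[e] = ngi;
      gsum[ngi] += na;
    }
  }
  void rebuild(const std::vector<double>& a) {
    for (int i = 0; i < ng; i++) {
      gsum[i] = 0.0;
      for (size_t j = 0; j < members[i].size(); j++) gsum[i] += a[members[i][j]];
    }
  }
  double total() const {
    double s = 0;
    for (int i = 0; i < ng; i++) s += gsum[i];
    return s;
  }
  int select(const std::vector<double>& a, double a0) {
    double u = unif_rand() * a0;
    int gi = -1;
    for (int i = 0; i < ng; i++) {
      if (gsum[i] <= 0) continue;
      gi = i;
      if (u <= gsum[i]) break;
      u -= gsum[i];
    }
    if (gi < 0) return -1;
    const std::vector<int>& v = members[gi];
    if (v.empty()) return -1;
    for (int guard = 0; guard < 1000000; guard++) {
      int idx = (int)(unif_rand() * v.size());
      if (idx >= (int)v.size()) idx = (int)v.size() - 1;
      int e = v[idx];
      if (a[e] > bound[gi])
        stop("binning-integrity error: propensity above its group bound");
      if (unif_rand() * bound[gi] <= a[e]) return e;
    }
    return -1;
  }
};

}  // namespace

// Exact spatial SSA. `counts` is modified in place and also returned.
// method: 0 = direct (hierarchical tet-then-event search), 1 =
// composition-rejection. Records snapshots of the full count matrix at the
// given times. Returns the maintained propensity table so dependency-driven
// updates can be audited against full recomputation.
// [[Rcpp::export]]
List cpp_run_exact(IntegerMatrix counts, List tables, double t0, double tEnd,
                   NumericVector recordTimes, int method, double maxSteps,
                   int rebuildEvery) {
  int T = counts.nrow(), S = counts.ncol();
  Tables x = unpack(tables, T, S);
  if ((int)x.deps.size() != T * x.nLoc) stop("deps table size mismatch");
  int nEvents = T * x.nLoc;
  std::vector<double> a(nEvents);
  std::vector<double> tetSum(T, 0.0);
  CRGroups cr;
  if (method == 1) cr.init(nEvents);
  double a0 = 0.0;

  // full (re)build of the propensity state
  int sinceRebuild = 0;
  #define REBUILD_ALL                                             \
    do {                                                          \
      a0 = 0.0;                                                   \
      std::fill(tetSum.begin(), tetSum.end(), 0.0);               \
      for (int e = 0; e < nEvents; e++) {                         \
        double na = eventProp(x, counts, e);                      \
        if (method == 1) cr.set(a, e, na);                        \
        else a[e] = na;                                           \
        tetSum[e / x.nLoc] += na;                                 \
      }                                                           \
      if (method == 1) { cr.rebuild(a); a0 = cr.total(); }        \
      else for (int t = 0; t < T; t++) a0 += tetSum[t];           \
      sinceRebuild = 0;                                           \
    } while (0)

  REBUILD_ALL;

  IntegerVector evCount(nEvents);  // fired-event frequency table
  int nrec = recordTimes.size();
  IntegerVector records(nrec > 0 ? (R_xlen_t)nrec * T * S : 0);
  int recIdx = 0;
  double t = t0;
  double steps = 0;

  // snapshot current counts for every record time < upto
  #define FLUSH_RECORDS(upto)                                     \
    while (recIdx < nrec && recordTimes[recIdx] < (upto)) {       \
      for (int tt = 0; tt < T; tt++)                              \
        for (int ss = 0; ss < S; ss++)                            \
          records[recIdx + (R_xlen_t)nrec * (tt + (R_xlen_t)T * ss)] = \
              counts(tt, ss);                                     \
      recIdx++;                                                   \
    }

  while (t < tEnd && steps < maxSteps) {
    if (method == 1) a0 = cr.total();
    if (a0 <= 1e-300) {  // depleted system: jump to the horizon, no event
      t = tEnd;
      break;
    }
    double tNew = t + exp_rand() / a0;
    if (tNew >= tEnd) {
      t = tEnd;
      break;
    }
    FLUSH_RECORDS(tNew);
    int ev = -1;
    if (method == 0) {
      for (int attempt = 0; attempt < 2 && ev < 0; attempt++) {
        double u = unif_rand() * a0;
        int tet = -1;
        double acc = 0;
        for (int tt = 0; tt < T; tt++) {
          if (tetSum[tt] > 0 && acc + tetSum[tt] >= u) {
            tet = tt;
            break;
          }
          acc += tetSum[tt];
        }
        if (tet >= 0) {
          double u2 = u - acc;
          double acc2 = 0;
          for (int l = 0; l < x.nLoc; l++) {
            int e = tet * x.nLoc + l;
            if (a[e] <= 0) continue;
            acc2 += a[e];
            if (acc2 >= u2) {
              ev = e;
              break;
            }
          }
          if (ev < 0) {  // fell off within the tet: take last positive
            for (int l = x.nLoc - 1; l >= 0; l--)
              if (a[tet * x.nLoc + l] > 0) {
                ev = tet * x.nLoc + l;
                break;
              }
          }
        }
        if (ev < 0) REBUILD_ALL;  // cumulative drift: rebuild once, retry
      }
      if (ev < 0)
        stop("internal-consistency error: direct-method selection fell off the cumulative table");
    } else {
      ev = cr.select(a, a0);
      if (ev < 0) {
        REBUILD_ALL;
        a0 = cr.total();
        if (a0 <= 1e-300) {
          t = tEnd;
          break;
        }
        ev = cr.select(a, a0);
        if (ev < 0)
          stop("internal-consistency error: composition-rejection selection failed");
      }
    }
    applyEvent(x, counts, ev);
    evCount[ev]++;
    const std::vector<int>& dep = x.deps[ev];
    for (size_t i = 0; i < dep.size(); i++) {
      int e2 = dep[i];
      double na = eventProp(x, counts, e2);
      if (method == 1) {
        cr.set(a, e2, na);
      } else {
        double d = na - a[e2];
        a[e2] = na;
        tetSum[e2 / x.nLoc] += d;
        a0 += d;
      }
    }
    t = tNew;
    steps += 1;
    if (++sinceRebuild >= rebuildEvery) REBUILD_ALL;
  }
  if (t >= tEnd) {
    // reached the horizon: remaining record times (<= tEnd) get final state
    while (recIdx < nrec) {
      for (int tt = 0; tt < T; tt++)
        for (int ss = 0; ss < S; ss++)
          records[recIdx + (R_xlen_t)nrec * (tt + (R_xlen_t)T * ss)] =
              counts(tt, ss);
      recIdx++;
    }
  } else {
    FLUSH_RECORDS(t);  // stopped early via maxSteps
  }
  if (nrec > 0) records.attr("dim") = Dimension(nrec, T, S);
  NumericVector aOut(a.begin(), a.end());
  return List::create(_["t"] = t, _["nSteps"] = steps, _["counts"] = counts,
                      _["records"] = records, _["propensities"] = aOut,
                      _["eventCounts"] = evCount);
}

// Reaction-only SSA for one operator-splitting window of length `window`
// over the hosted tets, accruing per-(tet, species) occupancy integrals
// (molecule * s). `counts` is modified in place. Occupancy of products
// created mid-window accrues from their creation time.
// [[Rcpp::export]]
NumericMatrix cpp_reaction_window(IntegerMatrix counts, List tables,
                                  IntegerVector hosted, double window) {
  int T = counts.nrow(), S = counts.ncol();
  Tables x = unpack(tables, T, S);
  int nH = hosted.size();
  NumericMatrix occ(T, S);
  if (window <= 0) return occ;
  NumericMatrix lastT(T, S);  // last occupancy update time, window-relative

  if (x.nR > 0) {
    std::vector<double> a((size_t)nH * x.nR);
    std::vector<double> tetSum(nH, 0.0);
    double a0 = 0.0;
    for (int h = 0; h < nH; h++) {
      int t = hosted[h];
      for (int r = 0; r < x.nR; r++) {
        double p = reacProp(x, counts, t, r);
        a[(size_t)h * x.nR + r] = p;
        tetSum[h] += p;
      }
      a0 += tetSum[h];
    }
    double tnow = 0.0;
    long steps = 0;
    while (a0 > 1e-300) {
      double tNew = tnow + exp_rand() / a0;
      if (tNew >= window) break;
      // select hosted tet then reaction
      int hSel = -1, rSel = -1;
      for (int attempt = 0; attempt < 2 && rSel < 0; attempt++) {
        double u = unif_rand() * a0;
        double acc = 0;
        for (int h = 0; h < nH; h++) {
          if (tetSum[h] > 0 && acc + tetSum[h] >= u) {
            hSel = h;
            double u2 = u - acc, acc2 = 0;
            for (int r = 0; r < x.nR; r++) {
              double p = a[(size_t)h * x.nR + r];
              if (p <= 0) continue;
              acc2 += p;
              if (acc2 >= u2) {
                rSel = r;
                break;
              }
            }
            if (rSel < 0)
              for (int r = x.nR - 1; r >= 0; r--)
                if (a[(size_t)h * x.nR + r] > 0) {
                  rSel = r;
                  break;
                }
            break;
          }
          acc += tetSum[h];
        }
        if (rSel < 0) {  // drift: full rebuild, retry once
          a0 = 0;
          for (int h = 0; h < nH; h++) {
            tetSum[h] = 0;
            int t = hosted[h];
            for (int r = 0; r < x.nR; r++) {
              double p = reacProp(x, counts, t, r);
              a[(size_t)h * x.nR + r] = p;
              tetSum[h] += p;
            }
            a0 += tetSum[h];
          }
          if (a0 <= 1e-300) break;
        }
      }
      if (rSel < 0) break;
      int t = hosted[hSel];
      // occupancy accrual for species touched by this reaction, then apply
      const std::vector<int>& sp = x.dSp[rSel];
      const std::vector<int>& dv = x.dVal[rSel];
      for (size_t i = 0; i < sp.size(); i++) {
        int s = sp[i];
        occ(t, s) += (double)counts(t, s) * (tNew - lastT(t, s));
        lastT(t, s) = tNew;
        counts(t, s) += dv[i];
      }
      // refresh propensities of reactions in this tet touching these species
      for (int r = 0; r < x.nR; r++) {
        double np = reacProp(x, counts, t, r);
        double d = np - a[(size_t)hSel * x.nR + r];
        if (d != 0) {
          a[(size_t)hSel * x.nR + r] = np;
          tetSum[hSel] += d;
          a0 += d;
        }
      }
      tnow = tNew;
      if (++steps % 1000000 == 0) {  // periodic drift control
        a0 = 0;
        for (int h = 0; h < nH; h++) a0 += tetSum[h];
      }
    }
  }
  // finalize integrals to the window boundary
  for (int h = 0; h < nH; h++) {
    int t = hosted[h];
    for (int s = 0; s < S; s++)
      occ(t, s) += (double)counts(t, s) * (window - lastT(t, s));
  }
  return occ;
}

// Stochastic-rounding leaver sampler: mu = meanOcc * dTotal * tau clamped to
// nNow; N = floor(mu) + Bernoulli(frac(mu)).
// [[Rcpp::export]]
IntegerVector cpp_sample_leavers(double meanOcc, double nNow, double dTotal,
                                 double tau, int nDraws) {
  if (meanOcc < 0 || nNow < 0 || dTotal < 0 || tau < 0)
    stop("inputs must be nonnegative");
  IntegerVector out(nDraws);
  double mu = meanOcc * dTotal * tau;
  if (mu > nNow) mu = nNow;
  int base = (int)std::floor(mu);
  double fr = mu - base;
  for (int i = 0; i < nDraws; i++) {
    int N = base;
    if (fr > 0 && unif_rand() < fr) N++;
    if (N > nNow) N = (int)nNow;
    out[i] = N;
  }
  return out;
}

// Occupancy-based diffusion operator for one window. For each hosted
// (tet, diffusive species): expected leavers mu = occupancy-integral * d_tot
// (equivalently mean-occupancy * d_tot * window), stochastic rounding,
// clamped to the available count; leavers are split among the neighbours
// jointly multinomially with probabilities d_k / d_tot. Moves within
// `myRank` are applied in place (two-phase, so molecules arriving this
// window are not moved again); moves to tets on other ranks are returned as
// accumulated (tet, species, m) rows for the remote change buffers.
// `rankOf` may be empty, meaning everything is local.
// [[Rcpp::export]]
IntegerMatrix cpp_diffusion_step(IntegerMatrix counts, NumericMatrix occ,
                                 List tables, IntegerVector hosted,
                                 IntegerVector rankOf, int myRank) {
  int T = counts.nrow(), S = counts.ncol();
  Tables x = unpack(tables, T, S);
  int nH = hosted.size();
  bool partitioned = rankOf.size() > 0;
  IntegerMatrix arrivals(T, S);
  std::map<std::pair<int, int>, int> remote;  // (destTet, species) -> m
  for (int h = 0; h < nH; h++) {
    int t = hosted[h];
    if (x.Grow[t] <= 0) continue;  // isolated tet: nothing can leave
    for (int j = 0; j < x.nD; j++) {
      double dT = x.dTot(t, j);
      if (dT <= 0) continue;
      int s = x.diffSp[j];
      int n = counts(t, s);
      double mu = occ(t, s) * dT;
      if (mu > n) mu = n;
      if (mu <= 0) continue;
      int N = (int)std::floor(mu);
      double fr = mu - N;
      if (fr > 0 && unif_rand() < fr) N++;
      if (N > n) N = n;
      if (N <= 0) continue;
      // conditional-binomial multinomial split over the faces
      double rem = x.Grow[t];
      int left = N;
      for (int f = 0; f < 4 && left > 0; f++) {
        if (x.neighTet(t, f) < 0) continue;
        double g = x.G(t, f);
        if (g <= 0) continue;
        int k;
        if (g >= rem) {
          k = left;
        } else {
          k = (int)R::rbinom((double)left, g / rem);
        }
        rem -= g;
        if (k > 0) {
          int dest = x.neighTet(t, f);
          left -= k;
          if (!partitioned || rankOf[dest] == myRank)
            arrivals(dest, s) += k;
          else
            remote[std::make_pair(dest, s)] += k;
        }
      }
      counts(t, s) -= N;
    }
  }
  for (int t = 0; t < T; t++)
    for (int s = 0; s < S; s++)
      if (arrivals(t, s)) counts(t, s) += arrivals(t, s);
  IntegerMatrix out((int)remote.size(), 3);
  int i = 0;
  for (std::map<std::pair<int, int>, int>::const_iterator it = remote.begin();
       it != remote.end(); ++it, ++i) {
    out(i, 0) = it->first.first;
    out(i, 1) = it->first.second;
    out(i, 2) = it->second;
  }
  return out;
}
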