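// REVO resampling and the weighted-ensemble run loop.
//
// Conventions mirror the R level: states are 0-based, transition matrices
// are column-stochastic [to, from], snapshots are taken after dynamics and
// before resampling. All randomness comes from R's RNG so set.seed()
// governs reproducibility.
//
// The resampling step follows the variation-optimization reference scheme:
// walkers keep their positions during the decide loop; cloning increments a
// copy multiplicity (amp) so an n-fold cloned walker yields n copies of
// weight w/n; merging is only between walkers with amp == 1, moving the
// squashed walker's weight onto its nearest eligible partner; the kept
// conformation of each merge group is drawn at the end by the weight
// lottery. A coupled clone/merge proposal is executed only if the
// trajectory variation V = sum_{i != j} amp_i amp_j (d_ij/d0)^alpha
// phi_i phi_j strictly increases.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

struct SquashRec {
  int walker;   // 1-based input-walker index of the terminated lineage
  double frac;  // clone-division fraction at termination (always 1 here)
  int into;     // 1-based index of the lottery-winning absorber
};

struct StepResult {
  std::vector<int> st;        // slot states (0-based)
  std::vector<double> wt;     // slot weights
  std::vector<int> origin;    // 1-based input-walker index per slot
  std::vector<double> frac;   // clone-division fraction per slot
  std::vector<SquashRec> squashes;
  int nAccepted = 0;
  long long blocked = 0;
  double deltaV = 0.0;
};

void identityResult(StepResult& out, const std::vector<int>& st,
                    const std::vector<double>& wt) {
  const int n = static_cast<int>(st.size());
  out.st = st; out.wt = wt;
  out.origin.resize(n); out.frac.assign(n, 1.0);
  for (int i = 0; i < n; ++i) out.origin[i] = i + 1;
  out.squashes.clear();
  out.nAccepted = 0; out.blocked = 0; out.deltaV = 0.0;
}

void revoStepImpl(StepResult& out, const std::vector<int>& states,
                  const std::vector<double>& weights,
                  const NumericMatrix& distLookup, double d0, double alpha,
                  double pMin, double pMax, double Cnov, double mergeDist,
                  double epsilon, int maxOps) {
  const int n = static_cast<int>(states.size());
  identityResult(out, states, weights);
  if (n < 3) return;
  const double logPminC = std::log(pMin / Cnov);
  const double eps64 = 64.0 * std::numeric_limits<double>::epsilon();
  const double inf = std::numeric_limits<double>::infinity();

  // pairwise scaled distances (positions are fixed for the whole step)
  std::vector<double> dmat(n * n), D(n * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      double d = distLookup(states[i], states[j]);
      dmat[i + n * j] = d;
      D[i + n * j] = (i == j) ? 0.0 : std::pow(d / d0, alpha);
    }

  std::vector<double> w0(weights);   // recorded (pre-resampling) weights
  std::vector<double> cur(weights);  // current weights (absorbers grow)
  std::vector<int> amp(n, 1);        // copy multiplicities (0 = squashed)
  std::vector<int> absorbedInto(n, -1);
  std::vector<double> phi(n), r(n);

  auto variation = [&](const std::vector<int>& a,
                       const std::vector<double>& w) {
    double Vv = 0.0;
    std::vector<double> ph(n, 0.0);
    for (int i = 0; i < n; ++i)
      if (a[i] > 0) ph[i] = std::log(w[i] / a[i]) - logPminC;
    for (int i = 0; i < n; ++i) {
      if (a[i] == 0) continue;
      double s = 0.0;
      for (int j = 0; j < n; ++j)
        if (j != i && a[j] > 0) s += a[j] * D[i + n * j] * ph[j];
      Vv += a[i] * ph[i] * s;
    }
    return Vv;
  };

  for (;;) {
    double V = 0.0;
    for (int i = 0; i < n; ++i)
      phi[i] = (amp[i] > 0) ? std::log(cur[i] / amp[i]) - logPminC : 0.0;
    for (int i = 0; i < n; ++i) {
      if (amp[i] == 0) { r[i] = 0.0; continue; }
      double s = 0.0;
      for (int j = 0; j < n; ++j)
        if (j != i && amp[j] > 0) s += amp[j] * D[i + n * j] * phi[j];
      r[i] = s;
      V += amp[i] * phi[i] * s;
    }

    // clone candidate: largest variation contribution whose copies would
    // stay above the minimum weight
    int maxwind = -1;
    double best = -inf;
    for (int i = 0; i < n; ++i) {
      if (amp[i] != 1) continue;   // one clone per walker per step
      if (cur[i] / (amp[i] + 1) < pMin) continue;
      double v = amp[i] * phi[i] * r[i];
      if (v > best) { best = v; maxwind = i; }
    }
    if (maxwind < 0) break;

    // squash candidate: lowest variation contribution among unsplit
    // (amp == 1) walkers that have an eligible partner; merges into its
    // nearest such partner
    int minwind = -1, closewalk = -1;
    double minv = inf;
    for (int i = 0; i < n; ++i) {
      if (amp[i] != 1 || i == maxwind) continue;
      int partner = -1;
      double pd = inf;
      for (int j = 0; j < n; ++j) {
        if (j == i || j == maxwind || amp[j] != 1) continue;
        double d = dmat[i + n * j];
        if (d > mergeDist) continue;
        if (cur[i] + cur[j] > pMax) {
          if (j > i) ++out.blocked;
          continue;
        }
        if (d < pd) { pd = d; partner = j; }
      }
      if (partner < 0) continue;
      double v = amp[i] * phi[i] * r[i];
      if (v < minv) { minv = v; minwind = i; closewalk = partner; }
    }
    if (minwind < 0) break;

    // tentative coupled operation
    std::vector<int> ampT(amp);
    std::vector<double> curT(cur);
    ampT[maxwind] += 1;
    ampT[minwind] = 0;
    curT[closewalk] += curT[minwind];
    double Vnew = variation(ampT, curT);
    // relative guard: round-off on variation-neutral proposals must not
    // read as a gain, or the loop would never terminate
    double gainFloor = std::max(epsilon, eps64 * std::fabs(V));
    if (!(Vnew > V + gainFloor)) break;

    amp.swap(ampT);
    cur.swap(curT);
    absorbedInto[minwind] = closewalk;
    ++out.nAccepted;
    out.deltaV += Vnew - V;
    if (maxOps > 0 && out.nAccepted >= maxOps) break;
  }

  if (out.nAccepted == 0) return;

  // resolve merge groups: every squashed walker chains to an alive
  // terminal absorber
  std::vector<int> terminal(n, -1);
  for (int i = 0; i < n; ++i) {
    if (amp[i] > 0) { terminal[i] = i; continue; }
    int t = i;
    while (amp[t] == 0) t = absorbedInto[t];
    terminal[i] = t;
  }
  // the kept conformation of each group is drawn by the weight lottery
  // over the members' recorded weights
  std::vector<int> lineage(n, -1);  // alive walker -> lottery winner
  for (int t = 0; t < n; ++t) {
    if (amp[t] == 0) continue;
    std::vector<int> group;
    for (int i = 0; i < n; ++i)
      if (terminal[i] == t) group.push_back(i);
    if (group.size() == 1) { lineage[t] = t; continue; }
    double tot = 0.0;
    for (int m : group) tot += w0[m];
    double u = unif_rand() * tot;
    int winner = group.back();
    double acc = 0.0;
    for (int m : group) {
      acc += w0[m];
      if (u < acc) { winner = m; break; }
    }
    lineage[t] = winner;
    for (int m : group)
      if (m != winner)
        out.squashes.push_back({m + 1, 1.0, winner + 1});
  }

  // emit slots: an alive walker with multiplicity k yields k copies of
  // weight cur/k, all carrying its group's winning lineage
  out.st.clear(); out.wt.clear(); out.origin.clear(); out.frac.clear();
  for (int a = 0; a < n; ++a) {
    if (amp[a] == 0) continue;
    int own = lineage[a];
    for (int k = 0; k < amp[a]; ++k) {
      out.st.push_back(states[own]);
      out.wt.push_back(cur[a] / amp[a]);
      out.origin.push_back(own + 1);
      out.frac.push_back(1.0 / amp[a]);
    }
  }
}

List resultToList(const StepResult& rs) {
  int nSq = static_cast<int>(rs.squashes.size());
  IntegerVector sw(nSq), si(nSq);
  NumericVector sf(nSq);
  for (int q = 0; q < nSq; ++q) {
    sw[q] = rs.squashes[q].walker;
    sf[q] = rs.squashes[q].frac;
    si[q] = rs.squashes[q].into;
  }
  return List::create(
    _["states"] = IntegerVector(rs.st.begin(), rs.st.end()),
    _["weights"] = NumericVector(rs.wt.begin(), rs.wt.end()),
    _["origin"] = IntegerVector(rs.origin.begin(), rs.origin.end()),
    _["frac"] = NumericVector(rs.frac.begin(), rs.frac.end()),
    _["squashes"] = List::create(_["walker"] = sw, _["frac"] = sf,
                                 _["into"] = si),
    _["nAccepted"] = rs.nAccepted,
    _["blockedByPmax"] = static_cast<double>(rs.blocked),
    _["deltaV"] = rs.deltaV);
}

} // namespace

// [[Rcpp::export(name = ".revoResampleCpp")]]
List revoResampleCpp(IntegerVector states, NumericVector weights,
                     NumericMatrix distLookup, double d0, double alpha,
                     double pMin, double pMax, double Cnov,
                     double mergeDist, double epsilon, int maxOps) {
  std::vector<int> st(states.begin(), states.end());
  std::vector<double> wt(weights.begin(), weights.end());
  StepResult rs;
  revoStepImpl(rs, st, wt, distLookup, d0, alpha, pMin, pMax, Cnov,
               mergeDist, epsilon, maxOps);
  return resultToList(rs);
}

// [[Rcpp::export(name = ".weRunCpp")]]
List weRunCpp(NumericMatrix cumT, int nWalkers, int nCycles, int initState,
              NumericMatrix distLookup, double d0, double alpha,
              double pMin, double pMax, double Cnov, double mergeDist,
              double epsilon, bool resample, int maxOps) {
  const int nS = cumT.nrow();
  IntegerMatrix S(nCycles, nWalkers);
  NumericMatrix W(nCycles, nWalkers);
  IntegerMatrix Pm(nCycles, nWalkers);
  NumericMatrix Fr(nCycles, nWalkers);
  std::vector<int> sqCycle, sqWalker, sqInto;
  std::vector<double> sqFrac;
  long long blocked = 0;

  std::vector<int> st(nWalkers, initState);
  std::vector<double> wt(nWalkers, 1.0 / nWalkers);
  std::vector<int> par(nWalkers, 0);
  std::vector<double> fr(nWalkers, 1.0);
  StepResult rs;

  for (int cyc = 0; cyc < nCycles; ++cyc) {
    // one dynamics step per walker
    for (int w = 0; w < nWalkers; ++w) {
      double u = unif_rand();
      int col = st[w];
      int k = 0;
      while (k < nS - 1 && cumT(k, col) < u) ++k;
      st[w] = k;
    }
    double wsum = 0.0;
    for (int w = 0; w < nWalkers; ++w) {
      S(cyc, w) = st[w];
      W(cyc, w) = wt[w];
      Pm(cyc, w) = par[w];
      Fr(cyc, w) = fr[w];
      wsum += wt[w];
    }
    if (std::fabs(wsum - 1.0) > 1e-9)
      stop("weight conservation violated at cycle %d (sum = %.15g)",
           cyc + 1, wsum);
    if (cyc + 1 < nCycles) {
      if (resample) {
        revoStepImpl(rs, st, wt, distLookup, d0, alpha, pMin, pMax, Cnov,
                     mergeDist, epsilon, maxOps);
        st = rs.st; wt = rs.wt;
        par = rs.origin; fr = rs.frac;
        blocked += rs.blocked;
        for (size_t q = 0; q < rs.squashes.size(); ++q) {
          sqCycle.push_back(cyc + 1);
          sqWalker.push_back(rs.squashes[q].walker);
          sqFrac.push_back(rs.squashes[q].frac);
          sqInto.push_back(rs.squashes[q].into);
        }
      } else {
        for (int i = 0; i < nWalkers; ++i) { par[i] = i + 1; fr[i] = 1.0; }
      }
    }
  }

  return List::create(
    _["states"] = S, _["weights"] = W, _["parents"] = Pm,
    _["cloneFrac"] = Fr,
    _["squashes"] = List::create(
      _["cycle"] = IntegerVector(sqCycle.begin(), sqCycle.end()),
      _["walker"] = IntegerVector(sqWalker.begin(), sqWalker.end()),
      _["frac"] = NumericVector(sqFrac.begin(), sqFrac.end()),
      _["into"] = IntegerVector(sqInto.begin(), sqInto.end())),
    _["blockedByPmax"] = static_cast<double>(blocked));
}
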