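// Pruned dynamic programming (functional pruning) sweep for segment-
// neighbourhood change-point detection under a convex one-parameter loss.
//
// For each segment count k the sweep maintains a list of last-change-point
// candidates tau. Each candidate carries the constant C_{k-1,tau}, the
// coefficient pair of its running segment cost, and the interval set of
// parameter values for which it is currently optimal (its live set). A new
// data point is folded into every candidate in O(1); candidates whose live
// set empties are discarded forever, which is what keeps the sweep fast.
//
// Numerical policy: level-set intervals are found by bisection to an
// absolute tolerance in theta, then enlarged by a safety margin before
// intersecting a candidate's live set and shrunk by the same margin before
// computing the complement handed to the newborn candidate. Both directions
// can only make pruning more conservative; reported costs are always exact
// function evaluations at closed-form minimizers.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double EPS_PARAM = 1e-12;
static const int MAX_BISECT = 200;

struct Model {
  int family;   // 0 nbinom, 1 poisson, 2 gaussian
  double phi;
  double lo, hi;  // clipped numeric bounds of the parameter space
};

struct Interval { double l, r; };

struct Acc {
  double d1, d2, d3;
  Acc() : d1(0.0), d2(0.0), d3(0.0) {}
  inline void add(double y, double w, const Model& m) {
    switch (m.family) {
      case 0: d1 += w * m.phi; d2 += w * y; break;
      case 1: d1 += w;         d2 += w * y; break;
      default: d1 += w; d2 += w * y; d3 += w * y * y;
    }
  }
  inline double cost(double th, const Model& m) const {
    switch (m.family) {
      case 0: return -d1 * std::log(th) - d2 * std::log1p(-th);
      case 1: return d1 * th - d2 * std::log(th);
      default: return d1 * th * th - 2.0 * d2 * th + d3;
    }
  }
  // unconstrained minimizer clipped into [m.lo, m.hi]
  inline double argmin(const Model& m) const {
    double th;
    switch (m.family) {
      case 0: th = (d1 + d2 > 0.0) ? d1 / (d1 + d2) : 0.5; break;
      case 1: th = (d1 > 0.0) ? d2 / d1 : 1.0; break;
      default: th = (d1 > 0.0) ? d2 / d1 : 0.0;
    }
    return std::min(std::max(th, m.lo), m.hi);
  }
};

struct Cand {
  int tau;          // 1-based count of points before the last segment
  double constant;  // C_{k-1, tau}
  Acc acc;
  std::vector<Interval> live;
};

// minimal cost of constant + acc over the candidate's live intervals
static double cand_min(const Cand& cd, const Model& m) {
  double th0 = cd.acc.argmin(m);
  double best = R_PosInf;
  for (const Interval& iv : cd.live) {
    double th = std::min(std::max(th0, iv.l), iv.r);
    double v = cd.acc.cost(th, m);
    if (v < best) best = v;
  }
  return cd.constant + best;
}

// {theta : offset + cost(theta) <= c} as one interval; false when empty.
// Returned bounds are outer (the interval contains the exact level set).
static bool level_set(const Acc& acc, const Model& m, double offset, double c,
                      double tol, Interval& out) {
  double target = c - offset;
  if (m.family == 2) {
    if (acc.d1 <= 0.0) {
      if (acc.d3 <= target) { out.l = m.lo; out.r = m.hi; return true; }
      return false;
    }
    double disc = 4.0 * acc.d2 * acc.d2 - 4.0 * acc.d1 * (acc.d3 - target);
    if (disc < 0.0) return false;
    double sq = std::sqrt(disc);
    out.l = std::max((2.0 * acc.d2 - sq) / (2.0 * acc.d1), m.lo);
    out.r = std::min((2.0 * acc.d2 + sq) / (2.0 * acc.d1), m.hi);
    return out.l <= out.r;
  }
  double th0 = acc.argmin(m);
  if (acc.cost(th0, m) > target) return false;
  // left side
  double l;
  if (acc.cost(m.lo, m) <= target) {
    l = m.lo;
  } else {
    double a = m.lo, b = th0;
    for (int i = 0; i < MAX_BISECT && b - a > tol; ++i) {
      double mid = 0.5 * (a + b);
      if (acc.cost(mid, m) <= target) b = mid; else a = mid;
    }
    l = a;
  }
  // right side (poisson upper bound is open: expand geometrically)
  double hib = m.hi;
  if (m.family == 1) {
    double u = std::max(th0, 1.0);
    while (u < 1e290 && acc.cost(u, m) <= target) u *= 2.0;
    hib = u;
  }
  double r;
  if (acc.cost(hib, m) <= target) {
    r = hib;
  } else {
    double a = th0, b = hib;
    for (int i = 0; i < MAX_BISECT && b - a > tol; ++i) {
      double mid = 0.5 * (a + b);
      if (acc.cost(mid, m) <= target) a = mid; else b = mid;
    }
    r = b;
  }
  out.l = l; out.r = r;
  return true;
}

// intersect a sorted disjoint interval list with [l, r] in place
static void intersect_with(std::vector<Interval>& live, double l, double r) {
  std::vector<Interval> res;
  res.reserve(live.size());
  for (const Interval& iv : live) {
    double a = std::max(iv.l, l), b = std::min(iv.r, r);
    if (a < b) res.push_back({a, b});
  }
  live.swap(res);
}

// complement of a union of intervals within [lo, hi]
static std::vector<Interval> complement(std::vector<Interval> ivs,
                                        double lo, double hi) {
  std::vector<Interval> out;
  std::sort(ivs.begin(), ivs.end(),
            [](const Interval& a, const Interval& b) { return a.l < b.l; });
  double cur = lo;
  for (const Interval& iv : ivs) {
    if (iv.l > cur) out.push_back({cur, std::min(iv.l, hi)});
    cur = std::max(cur, iv.r);
    if (cur >= hi) break;
  }
  if (cur < hi) out.push_back({cur, hi});
  return out;
}

// [[Rcpp::export(name = ".pdp_pass_cpp")]]
List pdp_pass_cpp(NumericVector y, NumericVector w, std::string family,
                  double phi, int Kmax, double tol) {
  int n = y.size();
  if (n < 1) stop("empty series");
  if (Kmax < 1 || Kmax > n) stop("Kmax must be between 1 and the number of points");
  Model m;
  if (family == "nbinom") {
    m.family = 0; m.phi = phi; m.lo = EPS_PARAM; m.hi = 1.0 - EPS_PARAM;
  } else if (family == "poisson") {
    m.family = 1; m.phi = 0.0; m.lo = EPS_PARAM; m.hi = 1e300;
  } else if (family == "gaussian") {
    m.family = 2; m.phi = 0.0; m.lo = -1e300; m.hi = 1e300;
  } else {
    stop("unknown family");
  }
  double margin = 10.0 * tol;

  NumericMatrix C(Kmax, n);
  IntegerMatrix BP(Kmax, n);
  std::fill(C.begin(), C.end(), NA_REAL);
  std::fill(BP.begin(), BP.end(), NA_INTEGER);

  // k = 1: running single-segment cost
  {
    Acc a;
    for (int t = 0; t < n; ++t) {
      a.add(y[t], w[t], m);
      C(0, t) = a.cost(a.argmin(m), m);
      BP(0, t) = 0;
    }
  }

  double max_gap = 0.0;       // live-set partition diagnostic
  double cand_steps = 0.0, cand_total = 0.0;
  int cand_peak = 0;

  for (int k = 2; k <= Kmax; ++k) {
    std::vector<Cand> cands;
    bool have_pending = true;
    Cand pending;
    pending.tau = k - 1;
    pending.constant = C(k - 2, k - 2);
    pending.live.push_back({m.lo, m.hi});

    for (int ti = k - 1; ti < n; ++ti) {   // ti = t - 1 (0-based position)
      if (have_pending) { cands.push_back(pending); have_pending = false; }
      for (Cand& cd : cands) cd.acc.add(y[ti], w[ti], m);

      double best = R_PosInf;
      int btau = NA_INTEGER;
      for (const Cand& cd : cands) {       // ascending tau: ties -> smallest
        double v = cand_min(cd, m);
        if (v < best) { best = v; btau = cd.tau; }
      }
      C(k - 1, ti) = best;
      BP(k - 1, ti) = btau;
      cand_steps += 1.0;
      cand_total += (double) cands.size();
      if ((int) cands.size() > cand_peak) cand_peak = (int) cands.size();

      if (ti < n - 1) {
        double cnew = C(k - 2, ti);        // constant of candidate tau = t
        std::vector<Interval> unionI;
        unionI.reserve(cands.size());
        std::vector<Cand> kept;
        kept.reserve(cands.size());
        for (Cand& cd : cands) {
          Interval I;
          if (level_set(cd.acc, m, cd.constant, cnew, tol, I)) {
            // shrunk copy for the newborn's complement (conservative)
            double sl = I.l + margin, sr = I.r - margin;
            if (I.l <= m.lo) sl = m.lo;
            if (I.r >= m.hi) sr = m.hi;
            if (sl < sr) unionI.push_back({sl, sr});
            // enlarged copy for keeping the candidate (conservative)
            intersect_with(cd.live, std::max(I.l - margin, m.lo),
                           std::min(I.r + margin, m.hi));
            if (!cd.live.empty()) kept.push_back(std::move(cd));
          }
          // empty level set => live set empties too: candidate pruned forever
        }
        cands.swap(kept);
        std::vector<Interval> comp = complement(unionI, m.lo, m.hi);
        if (!comp.empty()) {
          pending = Cand();
          pending.tau = ti + 1;
          pending.constant = cnew;
          pending.live = comp;
          have_pending = true;
        }
        // diagnostic: kept live sets plus the newborn's region must cover
        // the parameter space (gaps bounded by the bisection tolerance)
        std::vector<Interval> all;
        for (const Cand& cd : cands)
          all.insert(all.end(), cd.live.begin(), cd.live.end());
        all.insert(all.end(), comp.begin(), comp.end());
        std::sort(all.begin(), all.end(),
                  [](const Interval& a, const Interval& b) { return a.l < b.l; });
        double cur = m.lo;
        for (const Interval& iv : all) {
          if (iv.l - cur > max_gap) max_gap = iv.l - cur;
          cur = std::max(cur, iv.r);
        }
        if (m.hi - cur > max_gap) max_gap = m.hi - cur;
      }
    }
  }

  return List::create(
    _["cost"] = C,
    _["backpointer"] = BP,
    _["diagnostics"] = List::create(
      _["max_partition_gap"] = max_gap,
      _["mean_candidates"] = cand_steps > 0 ? cand_total / cand_steps : 1.0,
      _["peak_candidates"] = cand_peak));
}
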