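#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact measure of boolean overlays of unions of simple convex polygons by
// vertical slab decomposition. Between two consecutive slab boundaries
// (polygon vertex x's plus all pairwise edge-crossing x's) no two edges
// cross, so every cross-section interval endpoint is linear in x and the
// interval structure is constant: union/intersection length is piecewise
// linear and the first moments are quadratic, hence two-point Gauss-Legendre
// per slab integrates them exactly.

struct Edge {
  double x1, y1, x2, y2; // x1 <= x2
  int poly;
};

struct Poly {
  double xmin, xmax, ymin, ymax;
  int group;
  std::vector<double> vx, vy;
};

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// cross-section [lo, hi] of convex polygon at vertical line x; returns false
// if the line misses the polygon interior
static inline bool section(const Poly &p, double x, double &lo, double &hi) {
  if (x <= p.xmin || x >= p.xmax) return false;
  lo = R_PosInf;
  hi = R_NegInf;
  size_t n = p.vx.size();
  for (size_t i = 0; i < n; i++) {
    size_t j = (i + 1 == n) ? 0 : i + 1;
    double xa = p.vx[i], ya = p.vy[i], xb = p.vx[j], yb = p.vy[j];
    if (xa == xb) continue; // vertical edge: measure zero at Gauss nodes
    if ((xa - x) * (xb - x) <= 0.0) {
      double y = ya + (yb - ya) * (x - xa) / (xb - xa);
      if (y < lo) lo = y;
      if (y > hi) hi = y;
    }
  }
  return hi >= lo;
}

typedef std::pair<double, double> Interval;

static void merge_union(std::vector<Interval> &v, std::vector<Interval> &out) {
  out.clear();
  if (v.empty()) return;
  std::sort(v.begin(), v.end());
  double lo = v[0].first, hi = v[0].second;
  for (size_t i = 1; i < v.size(); i++) {
    if (v[i].first <= hi) {
      if (v[i].second > hi) hi = v[i].second;
    } else {
      out.push_back(Interval(lo, hi));
      lo = v[i].first;
      hi = v[i].second;
    }
  }
  out.push_back(Interval(lo, hi));
}

static void intersect_lists(const std::vector<Interval> &a,
                            const std::vector<Interval> &b,
                            std::vector<Interval> &out) {
  out.clear();
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    double lo = std::max(a[i].first, b[j].first);
    double hi = std::min(a[i].second, b[j].second);
    if (hi > lo) out.push_back(Interval(lo, hi));
    if (a[i].second < b[j].second) i++; else j++;
  }
}

// polys: list of n x 2 numeric matrices (simple convex polygons, any
// orientation); group: 0-based group index per polygon; the result is the
// area (and first moments) of the intersection over groups of the union
// within each group.
// [[Rcpp::export(name = ".region_overlay_cpp")]]
List region_overlay_cpp(List polys, IntegerVector group, int ngroups) {
  int np = polys.size();
  std::vector<Poly> P(np);
  std::vector<Edge> E;
  std::vector<double> xs;
  for (int i = 0; i < np; i++) {
    NumericMatrix m = polys[i];
    int n = m.nrow();
    Poly &p = P[i];
    p.group = group[i];
    p.xmin = p.ymin = R_PosInf;
    p.xmax = p.ymax = R_NegInf;
    p.vx.resize(n);
    p.vy.resize(n);
    for (int r = 0; r < n; r++) {
      double x = m(r, 0), y = m(r, 1);
      p.vx[r] = x;
      p.vy[r] = y;
      p.xmin = std::min(p.xmin, x); p.xmax = std::max(p.xmax, x);
      p.ymin = std::min(p.ymin, y); p.ymax = std::max(p.ymax, y);
      xs.push_back(x);
      int r2 = (r + 1 == n) ? 0 : r + 1;
      Edge e;
      if (m(r, 0) <= m(r2, 0)) {
        e.x1 = m(r, 0); e.y1 = m(r, 1); e.x2 = m(r2, 0); e.y2 = m(r2, 1);
      } else {
        e.x1 = m(r2, 0); e.y1 = m(r2, 1); e.x2 = m(r, 0); e.y2 = m(r, 1);
      }
      e.poly = i;
      E.push_back(e);
    }
  }

  // pairwise edge crossings (sweep over edges sorted by xmin)
  std::vector<int> eidx(E.size());
  for (size_t i = 0; i < E.size(); i++) eidx[i] = (int)i;
  std::sort(eidx.begin(), eidx.end(), [&](int a, int b) {
    return E[a].x1 < E[b].x1;
  });
  std::vector<int> active;
  for (size_t ii = 0; ii < eidx.size(); ii++) {
    const Edge &e = E[eidx[ii]];
    // prune
    size_t w = 0;
    for (size_t k = 0; k < active.size(); k++)
      if (E[active[k]].x2 >= e.x1) active[w++] = active[k];
    active.resize(w);
    double eylo = std::min(e.y1, e.y2), eyhi = std::max(e.y1, e.y2);
    for (size_t k = 0; k < active.size(); k++) {
      const Edge &f = E[active[k]];
      if (f.poly == e.poly) continue;
      if (f.x1 > e.x2) continue;
      if (std::max(f.y1, f.y2) < eylo || std::min(f.y1, f.y2) > eyhi) continue;
      double rx = e.x2 - e.x1, ry = e.y2 - e.y1;
      double sx = f.x2 - f.x1, sy = f.y2 - f.y1;
      double den = rx * sy - ry * sx;
      if (den == 0.0) continue; // parallel: no ordering change
      double qpx = f.x1 - e.x1, qpy = f.y1 - e.y1;
      double t = (qpx * sy - qpy * sx) / den;
      double u = (qpx * ry - qpy * rx) / den;
      if (t >= 0.0 && t <= 1.0 && u >= 0.0 && u <= 1.0)
        xs.push_back(e.x1 + t * rx);
    }
    active.push_back(eidx[ii]);
  }

  std::sort(xs.begin(), xs.end());
  xs.erase(std::unique(xs.begin(), xs.end()), xs.end());

  // polygons sorted by xmin for the slab sweep
  std::vector<int> pidx(np);
  for (int i = 0; i < np; i++) pidx[i] = i;
  std::sort(pidx.begin(), pidx.end(), [&](int a, int b) {
    return P[a].xmin < P[b].xmin;
  });

  const double g = 1.0 / (2.0 * std::sqrt(3.0));
  double area = 0.0, mx = 0.0, my = 0.0;
  std::vector<std::vector<Interval> > bucket(ngroups), merged(ngroups);
  std::vector<Interval> cur, nxt, tmp;
  std::vector<int> act;
  size_t nextp = 0;

  for (size_t si = 0; si + 1 < xs.size(); si++) {
    double xa = xs[si], xb = xs[si + 1];
    double w = xb - xa;
    if (!(w > 0.0)) continue;
    double xm = 0.5 * (xa + xb);
    while (nextp < pidx.size() && P[pidx[nextp]].xmin <= xm)
      act.push_back(pidx[nextp++]);
    size_t wr = 0;
    for (size_t k = 0; k < act.size(); k++)
      if (P[act[k]].xmax >= xm) act[wr++] = act[k];
    act.resize(wr);
    if (act.empty()) continue;

    double node[2] = { xm - g * w, xm + g * w };
    for (int q = 0; q < 2; q++) {
      double x = node[q], wt = 0.5 * w;
      for (int gg = 0; gg < ngroups; gg++) bucket[gg].clear();
      for (size_t k = 0; k < act.size(); k++) {
        const Poly &p = P[act[k]];
        double lo, hi;
        if (section(p, x, lo, hi))
          bucket[p.group].push_back(Interval(lo, hi));
      }
      bool empty = false;
      for (int gg = 0; gg < ngroups; gg++) {
        merge_union(bucket[gg], merged[gg]);
        if (merged[gg].empty()) { empty = true; break; }
      }
      if (empty) continue;
      cur = merged[0];
      for (int gg = 1; gg < ngroups; gg++) {
        intersect_lists(cur, merged[gg], tmp);
        cur.swap(tmp);
        if (cur.empty()) break;
      }
      double L = 0.0, M = 0.0;
      for (size_t k = 0; k < cur.size(); k++) {
        L += cur[k].second - cur[k].first;
        M += 0.5 * (cur[k].second * cur[k].second -
                    cur[k].first * cur[k].first);
      }
      area += wt * L;
      mx += wt * x * L;
      my += wt * M;
    }
  }

  return List::create(_["area"] = area, _["mx"] = mx, _["my"] = my);
}

// point-in-convex-polygon membership against a set of polygons
// (boundary-inclusive, tolerance scaled to polygon extent)
// [[Rcpp::export(name = ".points_in_region_cpp")]]
LogicalVector points_in_region_cpp(NumericMatrix pts, List polys) {
  int npt = pts.nrow(), np = polys.size();
  LogicalVector out(npt, false);
  std::vector<Poly> P(np);
  for (int i = 0; i < np; i++) {
    NumericMatrix m = polys[i];
    int n = m.nrow();
    Poly &p = P[i];
    p.xmin = p.ymin = R_PosInf;
    p.xmax = p.ymax = R_NegInf;
    p.vx.resize(n); p.vy.resize(n);
    for (int r = 0; r < n; r++) {
      p.vx[r] = m(r, 0); p.vy[r] = m(r, 1);
      p.xmin = std::min(p.xmin, p.vx[r]); p.xmax = std::max(p.xmax, p.vx[r]);
      p.ymin = std::min(p.ymin, p.vy[r]); p.ymax = std::max(p.ymax, p.vy[r]);
    }
  }
  for (int j = 0; j < npt; j++) {
    double x = pts(j, 0), y = pts(j, 1);
    for (int i = 0; i < np && !out[j]; i++) {
      const Poly &p = P[i];
      double scale = std::max(p.xmax - p.xmin, p.ymax - p.ymin);
      double eps = 1e-9 * (scale + 1.0) * (scale + 1.0);
      if (x < p.xmin - eps || x > p.xmax + eps ||
          y < p.ymin - eps || y > p.ymax + eps) continue;
      size_t n = p.vx.size();
      bool pos = false, neg = false, in = true;
      for (size_t r = 0; r < n; r++) {
        size_t r2 = (r + 1 == n) ? 0 : r + 1;
        double c = cross3(p.vx[r], p.vy[r], p.vx[r2], p.vy[r2], x, y);
        if (c > eps) pos = true;
        if (c < -eps) neg = true;
        if (pos && neg) { in = false; break; }
      }
      if (in) out[j] = true;
    }
  }
  return out;
}

// cumulative count of points covered by the union of the first j hulls,
// hulls supplied in the (area-sorted) order of the LoCoH construction
// [[Rcpp::export(name = ".locoh_cover_counts_cpp")]]
IntegerVector locoh_cover_counts_cpp(NumericMatrix pts, List hulls) {
  int npt = pts.nrow(), nh = hulls.size();
  std::vector<bool> covered(npt, false);
  IntegerVector out(nh);
  int total = 0;
  for (int h = 0; h < nh; h++) {
    NumericMatrix m = hulls[h];
    int n = m.nrow();
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int r = 0; r < n; r++) {
      xmin = std::min(xmin, m(r, 0)); xmax = std::max(xmax, m(r, 0));
      ymin = std::min(ymin, m(r, 1)); ymax = std::max(ymax, m(r, 1));
    }
    double scale = std::max(xmax - xmin, ymax - ymin);
    double eps = 1e-9 * (scale + 1.0) * (scale + 1.0);
    for (int j = 0; j < npt; j++) {
      if (covered[j]) continue;
      double x = pts(j, 0), y = pts(j, 1);
      if (x < xmin - eps || x > xmax + eps || y < ymin - eps || y > ymax + eps)
        continue;
      bool pos = false, neg = false, in = true;
      for (int r = 0; r < n; r++) {
        int r2 = (r + 1 == n) ? 0 : r + 1;
        double c = cross3(m(r, 0), m(r, 1), m(r2, 0), m(r2, 1), x, y);
        if (c > eps) pos = true;
        if (c < -eps) neg = true;
        if (pos && neg) { in = false; break; }
      }
      if (in) { covered[j] = true; total++; }
    }
    out[h] = total;
  }
  return out;
}
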