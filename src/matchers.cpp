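// Compiled geometry core for the constellation matchers.
//
// Everything here operates on plain coordinate vectors / index matrices so the
// R surface stays thin: triangle enumeration and invariants, a k-d tree with
// mutual nearest-neighbour search over triangle feature space, least-squares
// similarity transforms, and the RANSAC consensus loop.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <limits>
#include <set>
#include <utility>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// k-d tree (arbitrary fixed dimension, cycling split axis)

class KDTree {
  // median-split k-d tree with max-spread axis selection and bucketed
  // leaves; nearest-neighbour queries prune on the splitting coordinate
public:
  KDTree(const NumericMatrix &pts)
      : n_(pts.nrow()), d_(pts.ncol()), x_(n_ * d_), order_(n_) {
    for (int i = 0; i < n_; ++i) {
      order_[i] = i;
      for (int k = 0; k < d_; ++k) x_[i * d_ + k] = pts(i, k);
    }
    if (n_ > 0) {
      nodes_.reserve(2 * n_ / LEAF + 4);
      root_ = build(0, n_);
    }
  }

  // index (0-based) of the nearest point to q; -1 when the tree is empty
  int nearest(const double *q, double *d2out = nullptr) const {
    best_ = -1;
    bestD2_ = std::numeric_limits<double>::infinity();
    if (n_ > 0) search(root_, q);
    if (d2out) *d2out = bestD2_;
    return best_;
  }

private:
  static const int LEAF = 16;
  struct Node {
    int lo, hi;       // leaf: range in order_; internal: hi = -1
    int dim;          // split dimension
    double split;     // split coordinate
    int left, right;  // child node ids
  };
  int n_, d_;
  std::vector<double> x_;
  std::vector<int> order_;
  std::vector<Node> nodes_;
  int root_ = -1;
  mutable int best_;
  mutable double bestD2_;

  int build(int lo, int hi) {
    Node nd;
    if (hi - lo <= LEAF) {
      nd.lo = lo; nd.hi = hi; nd.dim = -1; nd.split = 0;
      nd.left = nd.right = -1;
      nodes_.push_back(nd);
      return (int)nodes_.size() - 1;
    }
    // split on the dimension with the largest spread
    int dim = 0;
    double spread = -1;
    for (int k = 0; k < d_; ++k) {
      double mn = std::numeric_limits<double>::infinity(), mx = -mn;
      for (int i = lo; i < hi; ++i) {
        double v = x_[order_[i] * d_ + k];
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx - mn > spread) { spread = mx - mn; dim = k; }
    }
    int mid = (lo + hi) / 2;
    std::nth_element(order_.begin() + lo, order_.begin() + mid,
                     order_.begin() + hi, [&](int a, int b) {
                       return x_[a * d_ + dim] < x_[b * d_ + dim];
                     });
    nd.lo = lo; nd.hi = -1; nd.dim = dim;
    nd.split = x_[order_[mid] * d_ + dim];
    nodes_.push_back(nd);
    int id = (int)nodes_.size() - 1;
    int l = build(lo, mid);
    int r = build(mid, hi);
    nodes_[id].left = l;
    nodes_[id].right = r;
    return id;
  }

  void search(int id, const double *q) const {
    const Node &nd = nodes_[id];
    if (nd.hi >= 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int p = order_[i];
        double s = 0;
        const double *xp = &x_[p * d_];
        for (int k = 0; k < d_; ++k) {
          double t = xp[k] - q[k];
          s += t * t;
          if (s >= bestD2_) break;
        }
        if (s < bestD2_) { bestD2_ = s; best_ = p; }
      }
      return;
    }
    double diff = q[nd.dim] - nd.split;
    int first = diff < 0 ? nd.left : nd.right;
    int second = diff < 0 ? nd.right : nd.left;
    search(first, q);
    if (diff * diff < bestD2_) search(second, q);
  }
};

// Mutual nearest-neighbour pairs between two point sets (rows = points).
// Returns an m x 3 matrix: 1-based row index in A, in B, squared distance.
// [[Rcpp::export]]
NumericMatrix mutual_nn_cpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("feature dimension mismatch");
  if (na == 0 || nb == 0) return NumericMatrix(0, 3);
  KDTree ta(A), tb(B);
  std::vector<int> nnAB(na), nnBA(nb);
  std::vector<double> dAB(na);
  std::vector<double> q(d);
  for (int i = 0; i < na; ++i) {
    for (int k = 0; k < d; ++k) q[k] = A(i, k);
    nnAB[i] = tb.nearest(q.data(), &dAB[i]);
  }
  for (int j = 0; j < nb; ++j) {
    for (int k = 0; k < d; ++k) q[k] = B(j, k);
    nnBA[j] = ta.nearest(q.data());
  }
  std::vector<std::array<double, 3>> out;
  for (int i = 0; i < na; ++i) {
    int j = nnAB[i];
    if (j >= 0 && nnBA[j] == i)
      out.push_back({(double)(i + 1), (double)(j + 1), dAB[i]});
  }
  NumericMatrix res(out.size(), 3);
  for (size_t r = 0; r < out.size(); ++r)
    for (int c = 0; c < 3; ++c) res(r, c) = out[r][c];
  return res;
}

// ---------------------------------------------------------------------------
// Triangle enumeration: all triples {i, a, b} where a and b are among the k
// nearest neighbours of i, deduplicated over the vertex set.
// [[Rcpp::export]]
IntegerMatrix local_triples_cpp(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (n < 3) return IntegerMatrix(0, 3);
  std::set<std::array<int, 3>> seen;
  std::vector<std::pair<double, int>> d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      d[j] = {dx * dx + dy * dy, j};
    }
    d[i].first = std::numeric_limits<double>::infinity();
    int kk = std::min(k, n - 1);
    std::partial_sort(d.begin(), d.begin() + kk, d.end());
    for (int a = 0; a < kk; ++a) {
      for (int b = a + 1; b < kk; ++b) {
        std::array<int, 3> t = {i, d[a].second, d[b].second};
        std::sort(t.begin(), t.end());
        seen.insert(t);
      }
    }
  }
  IntegerMatrix out(seen.size(), 3);
  int r = 0;
  for (const auto &t : seen) {
    out(r, 0) = t[0] + 1;
    out(r, 1) = t[1] + 1;
    out(r, 2) = t[2] + 1;
    ++r;
  }
  return out;
}

namespace {

struct TriGeom {
  // vertex coordinates and the three edge lengths
  double px[3], py[3]; // vertices in input order i, j, k
  double len[3];       // edge 0 = (0,1), edge 1 = (1,2), edge 2 = (0,2)
  bool degenerate;
};

TriGeom tri_geom(const NumericVector &x, const NumericVector &y, int i, int j,
                 int k) {
  TriGeom g;
  int v[3] = {i, j, k};
  for (int a = 0; a < 3; ++a) {
    g.px[a] = x[v[a]];
    g.py[a] = y[v[a]];
  }
  int e0[3] = {0, 1, 0}, e1[3] = {1, 2, 2};
  for (int e = 0; e < 3; ++e) {
    double dx = g.px[e1[e]] - g.px[e0[e]];
    double dy = g.py[e1[e]] - g.py[e0[e]];
    g.len[e] = std::sqrt(dx * dx + dy * dy);
  }
  g.degenerate = (g.len[0] < 1e-12 || g.len[1] < 1e-12 || g.len[2] < 1e-12);
  return g;
}

// local vertex indices (0..2) of edge e
inline void edge_verts(int e, int &a, int &b) {
  if (e == 0) { a = 0; b = 1; }
  else if (e == 1) { a = 1; b = 2; }
  else { a = 0; b = 2; }
}

inline int shared_vertex(int e1, int e2) {
  int a1, b1, a2, b2;
  edge_verts(e1, a1, b1);
  edge_verts(e2, a2, b2);
  if (a1 == a2 || a1 == b2) return a1;
  return b1;
}

inline int other_vertex(int e, int v) {
  int a, b;
  edge_verts(e, a, b);
  return (a == v) ? b : a;
}

} // namespace

// Groth-style triangle invariants.
//
// Vertices are reordered so that v1 sits at the junction of the shortest and
// longest side, v2 closes the shortest side and v3 the longest side
// (traversal from shortest to longest side). Features: side ratio
// R = longest/shortest, cosine C of the angle at v1, log perimeter,
// handedness (+/-1), angle (degrees) of v1 seen from the centroid against the
// horizontal, plus first-order tolerances in R and C propagated from the
// positional tolerance epsilon (Groth's error model: each vertex is known to
// within epsilon, so dR^2 and dC^2 follow by differentiating R and C in the
// side lengths; the second-order epsilon^4 term in the cosine tolerance keeps
// it positive for near-degenerate triangles).
//
// Columns: v1, v2, v3 (1-based spot indices), R, C, logP, handed, angle_deg,
// tolR2, tolC2.
// [[Rcpp::export]]
NumericMatrix groth_features_cpp(NumericVector x, NumericVector y,
                                 IntegerMatrix triples, double epsilon) {
  int m = triples.nrow();
  NumericMatrix out(m, 10);
  LogicalVector ok(m);
  int kept = 0;
  for (int r = 0; r < m; ++r) {
    int i = triples(r, 0) - 1, j = triples(r, 1) - 1, k = triples(r, 2) - 1;
    TriGeom g = tri_geom(x, y, i, j, k);
    if (g.degenerate) { ok[r] = false; continue; }
    int vid[3] = {i, j, k};
    // shortest edge (ties: lowest edge id), longest among the others
    int sm = 0;
    for (int e = 1; e < 3; ++e)
      if (g.len[e] < g.len[sm]) sm = e;
    int lg = -1;
    for (int e = 0; e < 3; ++e) {
      if (e == sm) continue;
      if (lg < 0 || g.len[e] >= g.len[lg]) lg = e;
    }
    int v1 = shared_vertex(sm, lg);
    int v2 = other_vertex(sm, v1);
    int v3 = other_vertex(lg, v1);
    double ax = g.px[v2] - g.px[v1], ay = g.py[v2] - g.py[v1];
    double bx = g.px[v3] - g.px[v1], by = g.py[v3] - g.py[v1];
    double ls = g.len[sm], ll = g.len[lg];
    double R = ll / ls;
    double C = (ax * bx + ay * by) / (ls * ll);
    double cross = ax * by - ay * bx;
    double handed = (cross >= 0) ? 1.0 : -1.0;
    double perim = g.len[0] + g.len[1] + g.len[2];
    double cx = (g.px[0] + g.px[1] + g.px[2]) / 3.0;
    double cy = (g.py[0] + g.py[1] + g.py[2]) / 3.0;
    double ang = std::atan2(g.py[v1] - cy, g.px[v1] - cx) * 180.0 / M_PI;
    double F = 1.0 / (ll * ll) - C / (ll * ls) + 1.0 / (ls * ls);
    double tolR2 = 2.0 * R * R * epsilon * epsilon * F;
    double S2 = 1.0 - C * C;
    double gdiff = 1.0 / (ll * ll) - 1.0 / (ls * ls);
    double tolC2 = 2.0 * S2 * epsilon * epsilon * F +
                   3.0 * C * C * std::pow(epsilon, 4) * gdiff * gdiff;
    out(r, 0) = vid[v1] + 1;
    out(r, 1) = vid[v2] + 1;
    out(r, 2) = vid[v3] + 1;
    out(r, 3) = R;
    out(r, 4) = C;
    out(r, 5) = std::log(perim);
    out(r, 6) = handed;
    out(r, 7) = ang;
    out(r, 8) = tolR2;
    out(r, 9) = tolC2;
    ok[r] = true;
    ++kept;
  }
  if (kept == m) return out;
  NumericMatrix res(kept, 10);
  int rr = 0;
  for (int r = 0; r < m; ++r) {
    if (!ok[r]) continue;
    for (int c = 0; c < 10; ++c) res(rr, c) = out(r, c);
    ++rr;
  }
  return res;
}

// Astroalign-style triangle invariants with side lengths L2 >= L1 >= L0.
// Vertices reordered: v1 = junction of L0 and L1, v2 = junction of L0 and L2,
// v3 = junction of L1 and L2. Feature vector (columns 4..12):
// L2/L1, L1/L0, centroid angle at v1 (radians), then the three vertex
// coordinates scaled down by a factor of 5.
// Columns: v1, v2, v3, r21, r10, angle_rad, x1/5, y1/5, x2/5, y2/5, x3/5, y3/5.
// [[Rcpp::export]]
NumericMatrix aa_features_cpp(NumericVector x, NumericVector y,
                              IntegerMatrix triples) {
  int m = triples.nrow();
  NumericMatrix out(m, 12);
  LogicalVector ok(m);
  int kept = 0;
  for (int r = 0; r < m; ++r) {
    int i = triples(r, 0) - 1, j = triples(r, 1) - 1, k = triples(r, 2) - 1;
    TriGeom g = tri_geom(x, y, i, j, k);
    if (g.degenerate) { ok[r] = false; continue; }
    int vid[3] = {i, j, k};
    // order the edge ids by length: e_min (L0) <= e_mid (L1) <= e_max (L2)
    int ord[3] = {0, 1, 2};
    std::sort(ord, ord + 3, [&](int a, int b) {
      if (g.len[a] != g.len[b]) return g.len[a] < g.len[b];
      return a < b;
    });
    int eL0 = ord[0], eL1 = ord[1], eL2 = ord[2];
    int v1 = shared_vertex(eL0, eL1);
    int v2 = shared_vertex(eL0, eL2);
    int v3 = shared_vertex(eL1, eL2);
    double cx = (g.px[0] + g.px[1] + g.px[2]) / 3.0;
    double cy = (g.py[0] + g.py[1] + g.py[2]) / 3.0;
    double ang = std::atan2(g.py[v1] - cy, g.px[v1] - cx);
    out(r, 0) = vid[v1] + 1;
    out(r, 1) = vid[v2] + 1;
    out(r, 2) = vid[v3] + 1;
    out(r, 3) = g.len[eL2] / g.len[eL1];
    out(r, 4) = g.len[eL1] / g.len[eL0];
    out(r, 5) = ang;
    int vv[3] = {v1, v2, v3};
    for (int a = 0; a < 3; ++a) {
      out(r, 6 + 2 * a) = g.px[vv[a]] / 5.0;
      out(r, 7 + 2 * a) = g.py[vv[a]] / 5.0;
    }
    ok[r] = true;
    ++kept;
  }
  if (kept == m) return out;
  NumericMatrix res(kept, 12);
  int rr = 0;
  for (int r = 0; r < m; ++r) {
    if (!ok[r]) continue;
    for (int c = 0; c < 12; ++c) res(rr, c) = out(r, c);
    ++rr;
  }
  return res;
}

// ---------------------------------------------------------------------------
// Least-squares similarity transform (rotation + uniform scale + translation)
// mapping src onto dst, via the complex-regression closed form.
// Returns c(rot_rad, scale, tx, ty, ok).
// [[Rcpp::export]]
NumericVector fit_similarity_cpp(NumericMatrix src, NumericMatrix dst) {
  int n = src.nrow();
  NumericVector res(5);
  if (n < 2 || dst.nrow() != n) { res[4] = 0; return res; }
  double zx = 0, zy = 0, wx = 0, wy = 0;
  for (int i = 0; i < n; ++i) {
    zx += src(i, 0); zy += src(i, 1);
    wx += dst(i, 0); wy += dst(i, 1);
  }
  zx /= n; zy /= n; wx /= n; wy /= n;
  double num_re = 0, num_im = 0, den = 0;
  for (int i = 0; i < n; ++i) {
    double a = src(i, 0) - zx, b = src(i, 1) - zy;
    double c = dst(i, 0) - wx, d = dst(i, 1) - wy;
    // conj(z) * w = (a - bi)(c + di)
    num_re += a * c + b * d;
    num_im += a * d - b * c;
    den += a * a + b * b;
  }
  if (den < 1e-20) { res[4] = 0; return res; }
  double are = num_re / den, aim = num_im / den;
  double scale = std::sqrt(are * are + aim * aim);
  if (scale < 1e-12) { res[4] = 0; return res; }
  double rot = std::atan2(aim, are);
  res[0] = rot;
  res[1] = scale;
  res[2] = wx - (are * zx - aim * zy);
  res[3] = wy - (aim * zx + are * zy);
  res[4] = 1;
  return res;
}

namespace {

inline double tri_error(const double *sx, const double *sy, const double *dx,
                        const double *dy, double are, double aim, double tx,
                        double ty) {
  double worst = 0;
  for (int v = 0; v < 3; ++v) {
    double px = are * sx[v] - aim * sy[v] + tx;
    double py = aim * sx[v] + are * sy[v] + ty;
    double ex = px - dx[v], ey = py - dy[v];
    double e = std::sqrt(ex * ex + ey * ey);
    if (e > worst) worst = e;
  }
  return worst;
}

inline double disturbance(double rot_rad, double scale, double tx, double ty) {
  return std::fabs(rot_rad) * 180.0 / M_PI / 60.0 +
         std::fabs(scale - 1.0) / 2.0 + (std::fabs(tx) + std::fabs(ty)) / 2.0;
}

} // namespace

// RANSAC over matched triangle pairs with a similarity-transform model.
//
// srcx/srcy, dstx/dsty: spot coordinates of the two constellations;
// triA/triB: m x 3 matrices of 1-based vertex indices of matched triangles,
// columns aligned by the invariant vertex ordering; pairs: p x 2 matrix of
// the unique candidate vertex pairs derived from the matched triangles. At
// each iteration one matched triangle is drawn and a transform fitted to its
// three vertex pairs. Consensus is measured either on points (default: the
// fraction of source spots and of target spots participating in a candidate
// pair whose reprojection error is within `thresh`; the smaller of the two
// fractions must reach `consensus`) or on matched triangles (fraction of
// matched triangles whose worst vertex error is within `thresh`). A
// qualifying candidate terminates the search early when its transformation
// disturbance is within max_dist; otherwise the qualifying candidate with
// the smallest disturbance is retained. The returned transform is refitted
// by least squares on the inlier candidate pairs.
// [[Rcpp::export]]
List ransac_aa_cpp(NumericVector srcx, NumericVector srcy, NumericVector dstx,
                   NumericVector dsty, IntegerMatrix triA, IntegerMatrix triB,
                   IntegerMatrix pairs, double thresh, double consensus,
                   double max_dist, int max_iter, int seed,
                   bool points_consensus) {
  int m = triA.nrow();
  int np = pairs.nrow();
  int ns = srcx.size(), nd = dstx.size();
  List fail = List::create(_["found"] = false, _["iterations"] = 0);
  if (m == 0 || np == 0) return fail;

  // vertex coordinates per matched triangle
  std::vector<double> sx(3 * m), sy(3 * m), dx(3 * m), dy(3 * m);
  for (int t = 0; t < m; ++t) {
    for (int v = 0; v < 3; ++v) {
      sx[3 * t + v] = srcx[triA(t, v) - 1];
      sy[3 * t + v] = srcy[triA(t, v) - 1];
      dx[3 * t + v] = dstx[triB(t, v) - 1];
      dy[3 * t + v] = dsty[triB(t, v) - 1];
    }
  }
  // candidate pair coordinates
  std::vector<double> pax(np), pay(np), pbx(np), pby(np);
  for (int k = 0; k < np; ++k) {
    pax[k] = srcx[pairs(k, 0) - 1];
    pay[k] = srcy[pairs(k, 0) - 1];
    pbx[k] = dstx[pairs(k, 1) - 1];
    pby[k] = dsty[pairs(k, 1) - 1];
  }
  std::vector<char> hitS(ns), hitD(nd);

  // consensus fraction reached by a transform (are, aim, tx, ty)
  auto consensus_frac = [&](double are, double aim, double tx, double ty) {
    if (points_consensus) {
      std::fill(hitS.begin(), hitS.end(), 0);
      std::fill(hitD.begin(), hitD.end(), 0);
      for (int k = 0; k < np; ++k) {
        double px = are * pax[k] - aim * pay[k] + tx;
        double py = aim * pax[k] + are * pay[k] + ty;
        double ex = px - pbx[k], ey = py - pby[k];
        if (ex * ex + ey * ey <= thresh * thresh) {
          hitS[pairs(k, 0) - 1] = 1;
          hitD[pairs(k, 1) - 1] = 1;
        }
      }
      int cs = 0, cd = 0;
      for (int i = 0; i < ns; ++i) cs += hitS[i];
      for (int i = 0; i < nd; ++i) cd += hitD[i];
      double fs = (double)cs / ns, fd = (double)cd / nd;
      return fs < fd ? fs : fd;
    }
    int cnt = 0;
    for (int u = 0; u < m; ++u)
      if (tri_error(&sx[3 * u], &sy[3 * u], &dx[3 * u], &dy[3 * u], are, aim,
                    tx, ty) <= thresh)
        ++cnt;
    return (double)cnt / m;
  };

  // simple deterministic LCG (MINSTD) so results do not depend on the
  // platform's distribution implementations
  unsigned long long state = (unsigned long long)(seed <= 0 ? 1 : seed);
  auto next_idx = [&]() {
    state = (state * 48271ULL) % 2147483647ULL;
    return (int)(state % (unsigned long long)m);
  };

  bool have = false, capped_best = true;
  double best_rot = 0, best_scale = 1, best_tx = 0, best_ty = 0,
         best_dist = std::numeric_limits<double>::infinity();
  int iterations = 0;

  NumericMatrix s3(3, 2), d3(3, 2);
  for (int it = 0; it < max_iter; ++it) {
    iterations = it + 1;
    int t = next_idx();
    // skip collinear/degenerate sample triangles
    double area = std::fabs((sx[3 * t + 1] - sx[3 * t]) *
                                (sy[3 * t + 2] - sy[3 * t]) -
                            (sx[3 * t + 2] - sx[3 * t]) *
                                (sy[3 * t + 1] - sy[3 * t]));
    if (area < 1e-14) continue;
    for (int v = 0; v < 3; ++v) {
      s3(v, 0) = sx[3 * t + v];
      s3(v, 1) = sy[3 * t + v];
      d3(v, 0) = dx[3 * t + v];
      d3(v, 1) = dy[3 * t + v];
    }
    NumericVector f = fit_similarity_cpp(s3, d3);
    if (f[4] == 0) continue;
    double are = f[1] * std::cos(f[0]), aim = f[1] * std::sin(f[0]);
    if (consensus_frac(are, aim, f[2], f[3]) < consensus) continue;
    double dist = disturbance(f[0], f[1], f[2], f[3]);
    if (dist <= max_dist) {
      best_rot = f[0]; best_scale = f[1]; best_tx = f[2]; best_ty = f[3];
      have = true; capped_best = false;
      break;
    }
    if (dist < best_dist) {
      best_rot = f[0]; best_scale = f[1]; best_tx = f[2]; best_ty = f[3];
      best_dist = dist; have = true; capped_best = true;
    }
  }
  if (!have) {
    fail["iterations"] = iterations;
    return fail;
  }

  // inlier candidate pairs under the selected candidate, then least-squares
  // refit on them
  double are = best_scale * std::cos(best_rot),
         aim = best_scale * std::sin(best_rot);
  auto pair_inliers = [&](double are_, double aim_, double tx_, double ty_,
                          std::vector<int> &idx) {
    idx.clear();
    for (int k = 0; k < np; ++k) {
      double px = are_ * pax[k] - aim_ * pay[k] + tx_;
      double py = aim_ * pax[k] + are_ * pay[k] + ty_;
      double ex = px - pbx[k], ey = py - pby[k];
      if (ex * ex + ey * ey <= thresh * thresh) idx.push_back(k);
    }
  };
  std::vector<int> inl_idx;
  pair_inliers(are, aim, best_tx, best_ty, inl_idx);
  if (inl_idx.size() >= 2) {
    NumericMatrix ps(inl_idx.size(), 2), pd(inl_idx.size(), 2);
    for (size_t r = 0; r < inl_idx.size(); ++r) {
      ps(r, 0) = pax[inl_idx[r]];
      ps(r, 1) = pay[inl_idx[r]];
      pd(r, 0) = pbx[inl_idx[r]];
      pd(r, 1) = pby[inl_idx[r]];
    }
    NumericVector f = fit_similarity_cpp(ps, pd);
    if (f[4] == 1) {
      best_rot = f[0]; best_scale = f[1]; best_tx = f[2]; best_ty = f[3];
      are = best_scale * std::cos(best_rot);
      aim = best_scale * std::sin(best_rot);
    }
  }
  LogicalVector inl(m);
  for (int u = 0; u < m; ++u)
    inl[u] = tri_error(&sx[3 * u], &sy[3 * u], &dx[3 * u], &dy[3 * u], are,
                       aim, best_tx, best_ty) <= thresh;
  return List::create(
      _["found"] = true, _["capped"] = capped_best,
      _["rotation"] = best_rot * 180.0 / M_PI, _["scale"] = best_scale,
      _["tx"] = best_tx, _["ty"] = best_ty, _["inlier"] = inl,
      _["iterations"] = iterations,
      _["disturbance"] = disturbance(best_rot, best_scale, best_tx, best_ty));
}
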