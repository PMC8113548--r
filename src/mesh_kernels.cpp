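#include <Rcpp.h>
#include <map>
#include <array>
#include <utility>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, ch. 5.1.5. Writes barycentric coords (u,v,w) of the result.
static inline void closestPointTriangle(const double *p,
                                        const double *a, const double *b,
                                        const double *c, double *out,
                                        double *bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
  bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

static inline void faceNormalRaw(const double *a, const double *b,
                                 const double *c, double *n) {
  double ab[3], ac[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
  }
  n[0] = ab[1] * ac[2] - ab[2] * ac[1];
  n[1] = ab[2] * ac[0] - ab[0] * ac[2];
  n[2] = ab[0] * ac[1] - ab[1] * ac[0];
}

// [[Rcpp::export(name = ".cgClosestPoints")]]
List cgClosestPoints(NumericMatrix queries, NumericMatrix V, IntegerMatrix F) {
  const int nq = queries.nrow(), nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  NumericMatrix pts(nq, 3);
  NumericVector dist(nq);
  IntegerVector face(nq);

  // per-face AABB for an exact lower-bound prune (results identical to the
  // exhaustive scan: a face is skipped only when it provably cannot win)
  std::vector<double> lo(3 * nf), hi(3 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      double v0 = V(F(f, 0) - 1, k), v1 = V(F(f, 1) - 1, k), v2 = V(F(f, 2) - 1, k);
      double mn = v0 < v1 ? v0 : v1; if (v2 < mn) mn = v2;
      double mx = v0 > v1 ? v0 : v1; if (v2 > mx) mx = v2;
      lo[3 * f + k] = mn;
      hi[3 * f + k] = mx;
    }
  }

  double p[3], a[3], b[3], c[3], cp[3], bary[3], best_cp[3];
  for (int q = 0; q < nq; ++q) {
    for (int k = 0; k < 3; ++k) p[k] = queries(q, k);
    double best = std::numeric_limits<double>::infinity();
    int bestf = -1;
    for (int f = 0; f < nf; ++f) {
      // squared distance from p to the face AABB
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = 0.0;
        if (p[k] < lo[3 * f + k]) d = lo[3 * f + k] - p[k];
        else if (p[k] > hi[3 * f + k]) d = p[k] - hi[3 * f + k];
        d2 += d * d;
      }
      if (d2 >= best) continue;
      for (int k = 0; k < 3; ++k) {
        a[k] = V(F(f, 0) - 1, k);
        b[k] = V(F(f, 1) - 1, k);
        c[k] = V(F(f, 2) - 1, k);
      }
      closestPointTriangle(p, a, b, c, cp, bary);
      double dd = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = p[k] - cp[k];
        dd += d * d;
      }
      if (dd < best) {
        best = dd;
        bestf = f;
        for (int k = 0; k < 3; ++k) best_cp[k] = cp[k];
      }
    }
    dist[q] = std::sqrt(best);
    face[q] = bestf + 1;
    for (int k = 0; k < 3; ++k) pts(q, k) = best_cp[k];
  }
  return List::create(_["point"] = pts, _["distance"] = dist, _["face"] = face);
}

// Signed distance by the angle-weighted pseudonormal of the closest feature
// (Baerentzen & Aanaes 2005). Positive = outward side of the surface.
// [[Rcpp::export(name = ".cgSignedDistances")]]
List cgSignedDistances(NumericMatrix queries, NumericMatrix V, IntegerMatrix F) {
  const int nq = queries.nrow(), nf = F.nrow(), nv = V.nrow();
  if (nf == 0) stop("mesh has no faces");

  // unit face normals
  std::vector<double> fn(3 * nf);
  double a[3], b[3], c[3], n[3];
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      a[k] = V(F(f, 0) - 1, k);
      b[k] = V(F(f, 1) - 1, k);
      c[k] = V(F(f, 2) - 1, k);
    }
    faceNormalRaw(a, b, c, n);
    double len = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    if (len <= 0) len = 1.0;
    for (int k = 0; k < 3; ++k) fn[3 * f + k] = n[k] / len;
  }

  // angle-weighted vertex pseudonormals
  std::vector<double> vn(3 * nv, 0.0);
  for (int f = 0; f < nf; ++f) {
    int idx[3] = {F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1};
    for (int j = 0; j < 3; ++j) {
      double v0[3], v1[3], v2[3];
      for (int k = 0; k < 3; ++k) {
        v0[k] = V(idx[j], k);
        v1[k] = V(idx[(j + 1) % 3], k);
        v2[k] = V(idx[(j + 2) % 3], k);
      }
      double e1[3], e2[3];
      double l1 = 0, l2 = 0, dot = 0;
      for (int k = 0; k < 3; ++k) {
        e1[k] = v1[k] - v0[k];
        e2[k] = v2[k] - v0[k];
        l1 += e1[k] * e1[k];
        l2 += e2[k] * e2[k];
        dot += e1[k] * e2[k];
      }
      double denom = std::sqrt(l1 * l2);
      double cosang = denom > 0 ? dot / denom : 1.0;
      if (cosang > 1.0) cosang = 1.0;
      if (cosang < -1.0) cosang = -1.0;
      double ang = std::acos(cosang);
      for (int k = 0; k < 3; ++k) vn[3 * idx[j] + k] += ang * fn[3 * f + k];
    }
  }

  // edge pseudonormals: sum of unit normals of adjacent faces
  std::map<std::pair<int, int>, std::array<double, 3> > en;
  for (int f = 0; f < nf; ++f) {
    int idx[3] = {F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1};
    for (int j = 0; j < 3; ++j) {
      int u = idx[j], v = idx[(j + 1) % 3];
      std::pair<int, int> key(std::min(u, v), std::max(u, v));
      auto it = en.find(key);
      if (it == en.end()) {
        std::array<double, 3> acc = {fn[3 * f], fn[3 * f + 1], fn[3 * f + 2]};
        en[key] = acc;
      } else {
        for (int k = 0; k < 3; ++k) it->second[k] += fn[3 * f + k];
      }
    }
  }

  List cp = cgClosestPoints(queries, V, F);
  NumericMatrix pts = cp["point"];
  NumericVector dist = cp["distance"];
  IntegerVector face = cp["face"];
  NumericVector sdist(nq);

  for (int q = 0; q < nq; ++q) {
    int f = face[q] - 1;
    int idx[3] = {F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1};
    for (int k = 0; k < 3; ++k) {
      a[k] = V(idx[0], k);
      b[k] = V(idx[1], k);
      c[k] = V(idx[2], k);
    }
    double p[3], cpt[3], bary[3];
    for (int k = 0; k < 3; ++k) {
      p[k] = queries(q, k);
      cpt[k] = pts(q, k);
    }
    closestPointTriangle(p, a, b, c, cpt, bary);
    const double eps = 1e-9;
    int nzero = (bary[0] < eps) + (bary[1] < eps) + (bary[2] < eps);
    double pn[3];
    if (nzero == 0) {
      for (int k = 0; k < 3; ++k) pn[k] = fn[3 * f + k];
    } else if (nzero == 1) {
      int j = bary[0] < eps ? 0 : (bary[1] < eps ? 1 : 2); // opposite edge
      int u = idx[(j + 1) % 3], v = idx[(j + 2) % 3];
      std::pair<int, int> key(std::min(u, v), std::max(u, v));
      const std::array<double, 3> &e = en[key];
      for (int k = 0; k < 3; ++k) pn[k] = e[k];
    } else {
      int j = bary[0] >= eps ? 0 : (bary[1] >= eps ? 1 : 2); // the live vertex
      for (int k = 0; k < 3; ++k) pn[k] = vn[3 * idx[j] + k];
    }
    double dotv = 0.0;
    for (int k = 0; k < 3; ++k) dotv += (p[k] - cpt[k]) * pn[k];
    sdist[q] = dotv >= 0 ? dist[q] : -dist[q];
  }
  return List::create(_["signed"] = sdist, _["distance"] = dist,
                      _["point"] = pts, _["face"] = face);
}

// Nearest intersection of the (two-sided) line p + t*d with the mesh,
// by |t|, restricted to |t| <= maxAbsT. Moeller-Trumbore per face.
// [[Rcpp::export(name = ".cgLineMeshNearest")]]
List cgLineMeshNearest(NumericMatrix origins, NumericMatrix dirs,
                       NumericMatrix V, IntegerMatrix F, double maxAbsT) {
  const int nq = origins.nrow(), nf = F.nrow();
  NumericVector tout(nq);
  LogicalVector hit(nq);
  IntegerVector face(nq);
  const double eps = 1e-12;
  for (int q = 0; q < nq; ++q) {
    double o[3], d[3];
    for (int k = 0; k < 3; ++k) {
      o[k] = origins(q, k);
      d[k] = dirs(q, k);
    }
    double bestAbs = maxAbsT;
    double bestT = NA_REAL;
    int bestF = NA_INTEGER;
    bool found = false;
    for (int f = 0; f < nf; ++f) {
      double a[3], e1[3], e2[3];
      for (int k = 0; k < 3; ++k) {
        a[k] = V(F(f, 0) - 1, k);
        e1[k] = V(F(f, 1) - 1, k) - a[k];
        e2[k] = V(F(f, 2) - 1, k) - a[k];
      }
      double pv[3] = {d[1] * e2[2] - d[2] * e2[1],
                      d[2] * e2[0] - d[0] * e2[2],
                      d[0] * e2[1] - d[1] * e2[0]};
      double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double tv[3] = {o[0] - a[0], o[1] - a[1], o[2] - a[2]};
      double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
      if (u < -1e-10 || u > 1.0 + 1e-10) continue;
      double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                      tv[2] * e1[0] - tv[0] * e1[2],
                      tv[0] * e1[1] - tv[1] * e1[0]};
      double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
      if (v < -1e-10 || u + v > 1.0 + 1e-10) continue;
      double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
      if (std::fabs(t) <= bestAbs) {
        bestAbs = std::fabs(t);
        bestT = t;
        bestF = f + 1;
        found = true;
      }
    }
    tout[q] = bestT;
    hit[q] = found;
    face[q] = bestF;
  }
  return List::create(_["t"] = tout, _["hit"] = hit, _["face"] = face);
}
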