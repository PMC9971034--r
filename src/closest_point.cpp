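#include <Rcpp.h>
using namespace Rcpp;

// Closest point on triangle (Ericson, Real-Time Collision Detection)
static inline void closestOnTri(const double *p, const double *a,
                                const double *b, const double *c,
                                double *out, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    bary[0] = 1; bary[1] = 0; bary[2] = 0;
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    bary[0] = 0; bary[1] = 1; bary[2] = 0;
    return;
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v*ab[i];
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    bary[0] = 0; bary[1] = 0; bary[2] = 1;
    return;
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w*ac[i];
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w*(c[i] - b[i]);
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
}

// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector dist(np);
  NumericMatrix pts(np, 3), bary(np, 3);
  IntegerVector face(np);
  // precompute triangle vertex pointers via copies for cache locality
  std::vector<double> tv(nf * 9);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      tv[f*9 + k*3 + 0] = V(vi, 0);
      tv[f*9 + k*3 + 1] = V(vi, 1);
      tv[f*9 + k*3 + 2] = V(vi, 2);
    }
  }
  double q[3], b3[3], best[3], bestb[3];
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    double bestd = R_PosInf;
    int bestf = 0;
    for (int f = 0; f < nf; ++f) {
      const double *a = &tv[f*9], *bb = &tv[f*9+3], *cc = &tv[f*9+6];
      // quick reject using vertex distance lower bound
      closestOnTri(p, a, bb, cc, q, b3);
      double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < bestd) {
        bestd = d2; bestf = f;
        best[0]=q[0]; best[1]=q[1]; best[2]=q[2];
        bestb[0]=b3[0]; bestb[1]=b3[1]; bestb[2]=b3[2];
      }
    }
    dist[i] = std::sqrt(bestd);
    face[i] = bestf + 1;
    for (int k = 0; k < 3; ++k) { pts(i,k) = best[k]; bary(i,k) = bestb[k]; }
  }
  return List::create(_["distance"] = dist, _["point"] = pts,
                      _["face"] = face, _["bary"] = bary);
}

// Directed Hausdorff distance max_{a in A} min_{b in B} |a-b|,
// for point sets of arbitrary (shared) dimension.
// [[Rcpp::export]]
double cpp_hausdorff_directed(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  double h = 0.0;
  for (int i = 0; i < na; ++i) {
    double mind = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = A(i,k) - B(j,k);
        s += diff * diff;
      }
      if (s < mind) mind = s;
      if (mind <= h) break; // cannot raise the max
    }
    if (mind > h) h = mind;
  }
  return std::sqrt(h);
}

// Minimum distance from each point to a closed polyline (2-D or 3-D rows).
// [[Rcpp::export]]
NumericVector cpp_dist_to_polyline(NumericMatrix P, NumericMatrix L,
                                   bool closed) {
  int np = P.nrow(), nl = L.nrow(), d = P.ncol();
  int nseg = closed ? nl : nl - 1;
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    for (int s = 0; s < nseg; ++s) {
      int a = s, b = (s + 1) % nl;
      double ab2 = 0.0, t = 0.0;
      for (int k = 0; k < d; ++k) {
        double e = L(b,k) - L(a,k);
        ab2 += e * e;
        t += (P(i,k) - L(a,k)) * e;
      }
      t = (ab2 > 0.0) ? t / ab2 : 0.0;
      if (t < 0.0) t = 0.0;
      if (t > 1.0) t = 1.0;
      double dd = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = P(i,k) - (L(a,k) + t * (L(b,k) - L(a,k)));
        dd += diff * diff;
      }
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
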