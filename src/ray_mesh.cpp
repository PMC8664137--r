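#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Ray casting against a triangle soup from a single origin (the X-ray focus).
// All rays share one origin, so triangles can be binned on a 2D angular grid
// in the (u, v) detector frame: a ray with angular coordinates (du/dd, dv/dd)
// can only hit triangles whose projected angular bounding box covers its cell.
// Intersection itself is Moller-Trumbore.

struct Frame {
  double d[3], u[3], v[3];
};

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// [[Rcpp::export(name = ".cpp_ray_first_hits")]]
List cpp_ray_first_hits(NumericMatrix V, IntegerMatrix F,
                        NumericVector source,
                        NumericVector axis_d, NumericVector axis_u, NumericVector axis_v,
                        NumericMatrix dirs, double t_min) {
  const int nv = V.nrow(), nf = F.nrow(), nr = dirs.nrow();
  Frame fr;
  for (int k = 0; k < 3; ++k) {
    fr.d[k] = axis_d[k]; fr.u[k] = axis_u[k]; fr.v[k] = axis_v[k];
  }
  const double src[3] = { source[0], source[1], source[2] };

  // Per-vertex angular coordinates (vertices behind the source get flagged).
  std::vector<double> au(nv), av(nv);
  std::vector<char> vbad(nv, 0);
  for (int i = 0; i < nv; ++i) {
    double p[3] = { V(i, 0) - src[0], V(i, 1) - src[1], V(i, 2) - src[2] };
    double td = dot3(p, fr.d);
    if (td < 1e-9) { vbad[i] = 1; au[i] = 0; av[i] = 0; continue; }
    au[i] = dot3(p, fr.u) / td;
    av[i] = dot3(p, fr.v) / td;
  }

  // Angular bbox per face; faces touching a bad vertex are tested for every ray.
  std::vector<double> fu0(nf), fu1(nf), fv0(nf), fv1(nf);
  std::vector<int> global_faces;
  double gu0 = std::numeric_limits<double>::infinity(), gu1 = -gu0;
  double gv0 = gu0, gv1 = gu1;
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    if (vbad[a] || vbad[b] || vbad[c]) {
      global_faces.push_back(f);
      fu0[f] = 1; fu1[f] = 0; // empty box
      continue;
    }
    double u0 = std::min(au[a], std::min(au[b], au[c]));
    double u1 = std::max(au[a], std::max(au[b], au[c]));
    double v0 = std::min(av[a], std::min(av[b], av[c]));
    double v1 = std::max(av[a], std::max(av[b], av[c]));
    fu0[f] = u0; fu1[f] = u1; fv0[f] = v0; fv1[f] = v1;
    gu0 = std::min(gu0, u0); gu1 = std::max(gu1, u1);
    gv0 = std::min(gv0, v0); gv1 = std::max(gv1, v1);
  }
  if (!std::isfinite(gu0)) { gu0 = -1; gu1 = 1; gv0 = -1; gv1 = 1; }
  const double pad = 1e-9 + 1e-6 * std::max(gu1 - gu0, gv1 - gv0);
  gu0 -= pad; gu1 += pad; gv0 -= pad; gv1 += pad;

  int ncell = std::max(1, (int)std::floor(std::sqrt((double)nf / 4.0)));
  if (ncell > 256) ncell = 256;
  const double cu = (gu1 - gu0) / ncell, cv = (gv1 - gv0) / ncell;

  // CSR binning of faces into cells.
  std::vector<int> count(ncell * ncell + 1, 0);
  auto cell_range = [&](int f, int& i0, int& i1, int& j0, int& j1) {
    i0 = (int)std::floor((fu0[f] - gu0) / cu);
    i1 = (int)std::floor((fu1[f] - gu0) / cu);
    j0 = (int)std::floor((fv0[f] - gv0) / cv);
    j1 = (int)std::floor((fv1[f] - gv0) / cv);
    i0 = std::max(0, std::min(ncell - 1, i0));
    i1 = std::max(0, std::min(ncell - 1, i1));
    j0 = std::max(0, std::min(ncell - 1, j0));
    j1 = std::max(0, std::min(ncell - 1, j1));
  };
  for (int f = 0; f < nf; ++f) {
    if (fu0[f] > fu1[f]) continue;
    int i0, i1, j0, j1; cell_range(f, i0, i1, j0, j1);
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        count[i * ncell + j + 1]++;
  }
  for (size_t i = 1; i < count.size(); ++i) count[i] += count[i - 1];
  std::vector<int> bins(count.back());
  std::vector<int> cursor(count.begin(), count.end() - 1);
  for (int f = 0; f < nf; ++f) {
    if (fu0[f] > fu1[f]) continue;
    int i0, i1, j0, j1; cell_range(f, i0, i1, j0, j1);
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        bins[cursor[i * ncell + j]++] = f;
  }

  NumericVector t_hit(nr, NA_REAL), cos_inc(nr, NA_REAL);
  IntegerVector face_hit(nr, NA_INTEGER);

  std::vector<int> cand;
  for (int r = 0; r < nr; ++r) {
    double dir[3] = { dirs(r, 0), dirs(r, 1), dirs(r, 2) };
    double best_t = std::numeric_limits<double>::infinity();
    int best_f = -1;
    double best_cos = NA_REAL;

    cand.clear();
    double td = dot3(dir, fr.d);
    if (td > 1e-12) {
      double ru = dot3(dir, fr.u) / td, rv = dot3(dir, fr.v) / td;
      if (ru >= gu0 && ru <= gu1 && rv >= gv0 && rv <= gv1) {
        int ci = std::max(0, std::min(ncell - 1, (int)std::floor((ru - gu0) / cu)));
        int cj = std::max(0, std::min(ncell - 1, (int)std::floor((rv - gv0) / cv)));
        int k0 = count[ci * ncell + cj], k1 = count[ci * ncell + cj + 1];
        for (int k = k0; k < k1; ++k) cand.push_back(bins[k]);
      }
    }
    for (size_t k = 0; k < global_faces.size(); ++k) cand.push_back(global_faces[k]);

    for (size_t k = 0; k < cand.size(); ++k) {
      int f = cand[k];
      int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      double A[3] = { V(ia, 0), V(ia, 1), V(ia, 2) };
      double e1[3] = { V(ib, 0) - A[0], V(ib, 1) - A[1], V(ib, 2) - A[2] };
      double e2[3] = { V(ic, 0) - A[0], V(ic, 1) - A[1], V(ic, 2) - A[2] };
      double pv[3] = { dir[1] * e2[2] - dir[2] * e2[1],
                       dir[2] * e2[0] - dir[0] * e2[2],
                       dir[0] * e2[1] - dir[1] * e2[0] };
      double det = dot3(e1, pv);
      if (std::fabs(det) < 1e-12) continue;
      double inv = 1.0 / det;
      double tv[3] = { src[0] - A[0], src[1] - A[1], src[2] - A[2] };
      double uu = dot3(tv, pv) * inv;
      if (uu < -1e-9 || uu > 1 + 1e-9) continue;
      double qv[3] = { tv[1] * e1[2] - tv[2] * e1[1],
                       tv[2] * e1[0] - tv[0] * e1[2],
                       tv[0] * e1[1] - tv[1] * e1[0] };
      double vv = dot3(dir, qv) * inv;
      if (vv < -1e-9 || uu + vv > 1 + 1e-9) continue;
      double t = dot3(e2, qv) * inv;
      if (t <= t_min || t >= best_t) continue;
      double nrm[3] = { e1[1] * e2[2] - e1[2] * e2[1],
                        e1[2] * e2[0] - e1[0] * e2[2],
                        e1[0] * e2[1] - e1[1] * e2[0] };
      double nlen = std::sqrt(dot3(nrm, nrm));
      double dlen = std::sqrt(dot3(dir, dir));
      if (nlen < 1e-300) continue;
      best_t = t; best_f = f;
      best_cos = std::fabs(dot3(nrm, dir)) / (nlen * dlen);
    }
    if (best_f >= 0) {
      t_hit[r] = best_t;
      face_hit[r] = best_f + 1;
      cos_inc[r] = best_cos;
    }
  }

  return List::create(_["t"] = t_hit, _["face"] = face_hit, _["cos_inc"] = cos_inc);
}
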