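#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Matched forward/back projector pair: exact ray-voxel intersection lengths
// (Siddon-style incremental traversal).  The same traversal drives
// forward projection, back projection and the SART weight sums, so the
// discrete operators A and A^T are exact adjoints by construction.

namespace {

struct Grid {
  int n[3];       // voxels per axis
  double d[3];    // voxel size (mm)
  double lo[3];   // lower world coordinate of the grid per axis
};

struct Geom {
  int mode;                    // 0 parallel2d, 1 fan2d, 2 cone3d
  double dso, dsd;             // source-origin / source-detector (mm)
  int ndu, ndv;                // detector pixels per axis (ndv = 1 in 2D)
  double du, dv;               // detector pitch (mm)
  std::vector<double> angles;  // view angles (radians, CCW from +x)
  Grid g;
};

Geom parse_geom(const List& gm) {
  Geom G;
  G.mode = as<int>(gm["mode"]);
  G.dso = as<double>(gm["dso"]);
  G.dsd = as<double>(gm["dsd"]);
  IntegerVector nd = gm["ndet"];
  NumericVector dp = gm["dpitch"];
  G.ndu = nd[0];
  G.ndv = (nd.size() > 1) ? nd[1] : 1;
  G.du = dp[0];
  G.dv = (dp.size() > 1) ? dp[1] : dp[0];
  NumericVector an = gm["angles_rad"];
  G.angles.assign(an.begin(), an.end());
  IntegerVector vs = gm["vshape"];
  NumericVector vz = gm["vsize"];
  for (int a = 0; a < 3; ++a) {
    G.g.n[a] = (a < vs.size()) ? vs[a] : 1;
    G.g.d[a] = (a < vz.size()) ? vz[a] : 1.0;
    G.g.lo[a] = -0.5 * G.g.n[a] * G.g.d[a];
  }
  return G;
}

// Walk one ray through the grid.  Appends (linear voxel index, length mm)
// pairs to idx/len and returns the count.  Voxel membership is decided at
// segment midpoints; an axis the ray is parallel to uses the half-open
// convention [lo, hi) so boundary-riding rays land in exactly one voxel.
int trace_ray(const Grid& g, const double p0[3], const double dir[3],
              std::vector<int>& idx, std::vector<double>& len) {
  const double eps = 1e-12;
  idx.clear();
  len.clear();
  double tmin = -1e300, tmax = 1e300;
  for (int a = 0; a < 3; ++a) {
    double lo = g.lo[a], hi = g.lo[a] + g.n[a] * g.d[a];
    if (std::fabs(dir[a]) > eps) {
      double t1 = (lo - p0[a]) / dir[a];
      double t2 = (hi - p0[a]) / dir[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    } else if (p0[a] < lo || p0[a] >= hi) {
      return 0;
    }
  }
  if (!(tmax - tmin > eps)) return 0;

  double t = tmin;
  int guard = 3 * (g.n[0] + g.n[1] + g.n[2]) + 6;
  while (t < tmax - eps && guard-- > 0) {
    double tnext = tmax;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(dir[a]) <= eps) continue;
      double pos = p0[a] + t * dir[a];
      double cell = (pos - g.lo[a]) / g.d[a];
      double plane;
      if (dir[a] > 0) plane = g.lo[a] + (std::floor(cell + 1e-9) + 1.0) * g.d[a];
      else            plane = g.lo[a] + (std::ceil(cell - 1e-9) - 1.0) * g.d[a];
      double tc = (plane - p0[a]) / dir[a];
      if (tc > t + eps && tc < tnext) tnext = tc;
    }
    double mid = 0.5 * (t + tnext);
    int v[3];
    bool in = true;
    for (int a = 0; a < 3; ++a) {
      v[a] = (int)std::floor((p0[a] + mid * dir[a] - g.lo[a]) / g.d[a]);
      if (v[a] < 0 || v[a] >= g.n[a]) { in = false; break; }
    }
    if (in) {
      idx.push_back(v[0] + g.n[0] * (v[1] + g.n[1] * v[2]));
      len.push_back(tnext - t);
    }
    t = tnext;
  }
  return (int)idx.size();
}

// Source point and unit direction for ray (angle ia, detector pixel iu, iv).
void make_ray(const Geom& G, int ia, int iu, int iv,
              double p0[3], double dir[3]) {
  double th = G.angles[ia];
  double c = std::cos(th), s = std::sin(th);
  double tu = (iu + 0.5 - 0.5 * G.ndu) * G.du;
  double tv = (iv + 0.5 - 0.5 * G.ndv) * G.dv;
  if (G.mode == 0) {  // parallel beam, in-plane
    p0[0] = -tu * s; p0[1] = tu * c; p0[2] = 0.0;
    dir[0] = c; dir[1] = s; dir[2] = 0.0;
  } else {            // fan (tv = 0) or cone beam, flat detector
    double sx = G.dso * c, sy = G.dso * s;
    double dcx = (G.dso - G.dsd) * c, dcy = (G.dso - G.dsd) * s;
    double px = dcx - tu * s, py = dcy + tu * c, pz = tv;
    double dx = px - sx, dy = py - sy, dz = pz;
    double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
    p0[0] = sx; p0[1] = sy; p0[2] = 0.0;
    dir[0] = dx / nrm; dir[1] = dy / nrm; dir[2] = dz / nrm;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_forward(NumericVector vol, List gm, IntegerVector angle_idx) {
  Geom G = parse_geom(gm);
  int ndet = G.ndu * G.ndv, nsel = angle_idx.size();
  NumericMatrix out(nsel, ndet);
  std::vector<int> idx; std::vector<double> len;
  double p0[3], dir[3];
  for (int k = 0; k < nsel; ++k) {
    int ia = angle_idx[k];
    for (int iv = 0; iv < G.ndv; ++iv)
      for (int iu = 0; iu < G.ndu; ++iu) {
        make_ray(G, ia, iu, iv, p0, dir);
        int m = trace_ray(G.g, p0, dir, idx, len);
        double acc = 0.0;
        for (int j = 0; j < m; ++j) acc += len[j] * vol[idx[j]];
        out(k, iu + G.ndu * iv) = acc;
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_back(NumericMatrix proj, List gm, IntegerVector angle_idx) {
  Geom G = parse_geom(gm);
  int nsel = angle_idx.size();
  int nvox = G.g.n[0] * G.g.n[1] * G.g.n[2];
  NumericVector out(nvox);
  std::vector<int> idx; std::vector<double> len;
  double p0[3], dir[3];
  for (int k = 0; k < nsel; ++k) {
    int ia = angle_idx[k];
    for (int iv = 0; iv < G.ndv; ++iv)
      for (int iu = 0; iu < G.ndu; ++iu) {
        double val = proj(k, iu + G.ndu * iv);
        if (val == 0.0) continue;
        make_ray(G, ia, iu, iv, p0, dir);
        int m = trace_ray(G.g, p0, dir, idx, len);
        for (int j = 0; j < m; ++j) out[idx[j]] += len[j] * val;
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_weights(List gm, IntegerVector angle_idx) {
  Geom G = parse_geom(gm);
  int ndet = G.ndu * G.ndv, nsel = angle_idx.size();
  int nvox = G.g.n[0] * G.g.n[1] * G.g.n[2];
  NumericMatrix rows(nsel, ndet);
  NumericVector cols(nvox);
  std::vector<int> idx; std::vector<double> len;
  double p0[3], dir[3];
  for (int k = 0; k < nsel; ++k) {
    int ia = angle_idx[k];
    for (int iv = 0; iv < G.ndv; ++iv)
      for (int iu = 0; iu < G.ndu; ++iu) {
        make_ray(G, ia, iu, iv, p0, dir);
        int m = trace_ray(G.g, p0, dir, idx, len);
        double acc = 0.0;
        for (int j = 0; j < m; ++j) { acc += len[j]; cols[idx[j]] += len[j]; }
        rows(k, iu + G.ndu * iv) = acc;
      }
  }
  return List::create(_["row_sums"] = rows, _["col_sums"] = cols);
}
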