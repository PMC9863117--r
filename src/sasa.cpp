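// Shrake-Rupley solvent-accessible surface area with a deterministic
// golden-section spiral point lattice on each expanded sphere.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static void spiral_points(int n, std::vector<double>& pts) {
  // golden-angle spiral on the unit sphere; no RNG, reproducible
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  pts.resize(3 * n);
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    pts[3*k]     = r * std::cos(phi);
    pts[3*k + 1] = r * std::sin(phi);
    pts[3*k + 2] = z;
  }
}

// Per-atom accessible areas for one conformation. `keep` excludes flagged
// duplicate atoms from the computation entirely (their area reports 0).
// [[Rcpp::export]]
NumericVector sasa_atoms_cpp(NumericMatrix xyz, NumericVector radii,
                             double probe, int npoints, LogicalVector keep) {
  const int n = xyz.nrow();
  std::vector<double> pts;
  spiral_points(npoints, pts);
  NumericVector area(n);
  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    if (!keep[i]) { area[i] = 0.0; continue; }
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i || !keep[j]) continue;
      double dx = xyz(j,0)-xyz(i,0), dy = xyz(j,1)-xyz(i,1),
             dz = xyz(j,2)-xyz(i,2);
      if (dx*dx + dy*dy + dz*dz < (er[i]+er[j])*(er[i]+er[j]))
        nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double px = xyz(i,0) + er[i]*pts[3*k];
      double py = xyz(i,1) + er[i]*pts[3*k+1];
      double pz = xyz(i,2) + er[i]*pts[3*k+2];
      bool free_pt = true;
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = nb[q];
        double dx = px-xyz(j,0), dy = py-xyz(j,1), dz = pz-xyz(j,2);
        if (dx*dx + dy*dy + dz*dz < er[j]*er[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * er[i] * er[i] * acc / npoints;
  }
  return area;
}

// Total and polar area for a subset of frames of a trajectory array
// (natoms x 3 x nframes); `frames` is 0-based.
// [[Rcpp::export]]
NumericMatrix sasa_frames_cpp(NumericVector coords, IntegerVector frames,
                              NumericVector radii, LogicalVector polar,
                              double probe, int npoints) {
  IntegerVector dim = coords.attr("dim");
  const int natoms = dim[0];
  std::vector<double> pts;
  spiral_points(npoints, pts);
  std::vector<double> er(natoms);
  for (int i = 0; i < natoms; ++i) er[i] = radii[i] + probe;
  NumericMatrix out(frames.size(), 2);
  std::vector<double> fr(3 * natoms);
  std::vector<int> nb;
  for (int fi = 0; fi < frames.size(); ++fi) {
    const double* slab = REAL(coords) + (R_xlen_t)frames[fi] * natoms * 3;
    for (int a = 0; a < natoms; ++a)
      for (int k = 0; k < 3; ++k) fr[3*a + k] = slab[a + k*natoms];
    double tot = 0.0, pol = 0.0;
    for (int i = 0; i < natoms; ++i) {
      nb.clear();
      for (int j = 0; j < natoms; ++j) {
        if (j == i) continue;
        double dx = fr[3*j]-fr[3*i], dy = fr[3*j+1]-fr[3*i+1],
               dz = fr[3*j+2]-fr[3*i+2];
        if (dx*dx + dy*dy + dz*dz < (er[i]+er[j])*(er[i]+er[j]))
          nb.push_back(j);
      }
      int acc = 0;
      for (int k = 0; k < npoints; ++k) {
        double px = fr[3*i] + er[i]*pts[3*k];
        double py = fr[3*i+1] + er[i]*pts[3*k+1];
        double pz = fr[3*i+2] + er[i]*pts[3*k+2];
        bool free_pt = true;
        for (size_t q = 0; q < nb.size(); ++q) {
          int j = nb[q];
          double dx = px-fr[3*j], dy = py-fr[3*j+1], dz = pz-fr[3*j+2];
          if (dx*dx + dy*dy + dz*dz < er[j]*er[j]) { free_pt = false; break; }
        }
        if (free_pt) ++acc;
      }
      double a_i = 4.0 * M_PI * er[i] * er[i] * acc / npoints;
      tot += a_i;
      if (polar[i]) pol += a_i;
    }
    out(fi, 0) = tot;
    out(fi, 1) = pol;
  }
  return out;
}
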