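// Internal-coordinate chain construction (NeRF) and least-squares rigid
// superposition. Hot loops for trajectory-scale work; the R wrappers own all
// validation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Place atom D from A-B-C with bond |CD|, angle B-C-D (rad) and dihedral
// A-B-C-D (rad, IUPAC sign convention).
static inline void nerf_place(const double* A, const double* B, const double* C,
                              double bond, double theta, double chi, double* D) {
  double bc[3], ab[3], n[3], m[3];
  for (int k = 0; k < 3; ++k) { bc[k] = C[k] - B[k]; ab[k] = B[k] - A[k]; }
  double nb = std::sqrt(bc[0]*bc[0] + bc[1]*bc[1] + bc[2]*bc[2]);
  for (int k = 0; k < 3; ++k) bc[k] /= nb;
  n[0] = ab[1]*bc[2] - ab[2]*bc[1];
  n[1] = ab[2]*bc[0] - ab[0]*bc[2];
  n[2] = ab[0]*bc[1] - ab[1]*bc[0];
  double nn = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
  for (int k = 0; k < 3; ++k) n[k] /= nn;
  m[0] = n[1]*bc[2] - n[2]*bc[1];
  m[1] = n[2]*bc[0] - n[0]*bc[2];
  m[2] = n[0]*bc[1] - n[1]*bc[0];
  double d1 = -bond * std::cos(theta);
  double d2 = bond * std::sin(theta) * std::cos(chi);
  double d3 = bond * std::sin(theta) * std::sin(chi);
  for (int k = 0; k < 3; ++k) D[k] = C[k] + d1*bc[k] + d2*m[k] + d3*n[k];
}

// Build program opcodes (column `special` of prog_i)
//  0: NeRF placement with refs ref1, ref2, ref3
//  1: seed N of residue 1 at the origin
//  2: seed CA of residue 1 on the +x axis
//  3: seed C of residue 1 in the xy plane (angle N-CA-C)
//  4: backbone amide H: N + 1.01 * unit(Cprev - Oprev); refs = (N, Cprev, Oprev)
// torsion types (column `ttype`): 0 fixed, 1 phi(res), 2 psi(res), 3 psi(res-1)

// [[Rcpp::export]]
NumericVector build_frames_cpp(IntegerMatrix prog_i, NumericMatrix prog_d,
                               NumericMatrix phi, NumericMatrix psi,
                               int natoms) {
  const int nentry = prog_i.nrow();
  const int nframes = phi.nrow();
  NumericVector out(Dimension(natoms, 3, nframes));
  std::vector<double> xyz(3 * natoms);  // atom-major: xyz[3*a + k]
  for (int f = 0; f < nframes; ++f) {
    for (int e = 0; e < nentry; ++e) {
      const int tgt = prog_i(e, 0), r1 = prog_i(e, 1), r2 = prog_i(e, 2),
                r3 = prog_i(e, 3), ttype = prog_i(e, 4), res = prog_i(e, 5),
                special = prog_i(e, 6);
      const double bond = prog_d(e, 0), ang = prog_d(e, 1), off = prog_d(e, 2);
      double* D = &xyz[3 * tgt];
      if (special == 1) { D[0] = D[1] = D[2] = 0.0; continue; }
      if (special == 2) { D[0] = bond; D[1] = D[2] = 0.0; continue; }
      if (special == 3) {
        // ref3 = CA, ref2 = N; place C in the xy plane
        const double* CAp = &xyz[3 * r3];
        const double* Np = &xyz[3 * r2];
        double ux = Np[0] - CAp[0], uy = Np[1] - CAp[1];
        double nu = std::sqrt(ux*ux + uy*uy);
        ux /= nu; uy /= nu;
        double ca = std::cos(ang), sa = std::sin(ang);
        D[0] = CAp[0] + bond * (ca * ux - sa * uy);
        D[1] = CAp[1] + bond * (ca * uy + sa * ux);
        D[2] = 0.0;
        continue;
      }
      if (special == 4) {
        const double* Np = &xyz[3 * r1];
        const double* Cp = &xyz[3 * r2];
        const double* Op = &xyz[3 * r3];
        double v[3];
        for (int k = 0; k < 3; ++k) v[k] = Cp[k] - Op[k];
        double nv = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
        for (int k = 0; k < 3; ++k) D[k] = Np[k] + bond * v[k] / nv;
        continue;
      }
      double tor = off;
      if (ttype == 1) tor += phi(f, res - 1) * DEG;
      else if (ttype == 2) tor += psi(f, res - 1) * DEG;
      else if (ttype == 3) tor += psi(f, res - 2) * DEG;
      nerf_place(&xyz[3 * r1], &xyz[3 * r2], &xyz[3 * r3], bond, ang, tor, D);
    }
    double* slab = REAL(out) + (R_xlen_t)f * natoms * 3;
    for (int a = 0; a < natoms; ++a)
      for (int k = 0; k < 3; ++k) slab[a + k * natoms] = xyz[3 * a + k];
  }
  return out;
}

// Optimal proper rotation mapping centred `mob` onto centred `ref`
// (row = point). Returns rotation R (apply as mob_c * R), translation and the
// minimized RMSD.
static void kabsch_core(const arma::mat& ref, const arma::mat& mob,
                        arma::mat& R, arma::rowvec& tvec, double& rmsd) {
  arma::rowvec mr = arma::mean(ref, 0), mm = arma::mean(mob, 0);
  arma::mat X = mob.each_row() - mm;   // mobile, centred
  arma::mat Y = ref.each_row() - mr;   // reference, centred
  arma::mat C = X.t() * Y;             // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, C);
  double d = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::mat Dm = arma::eye(3, 3);
  Dm(2, 2) = d;
  R = U * Dm * V.t();                  // X * R approximates Y
  tvec = mr - mm * R;
  arma::mat diff = X * R - Y;
  rmsd = std::sqrt(arma::accu(arma::square(diff)) / ref.n_rows);
}

// [[Rcpp::export]]
List kabsch_cpp(NumericMatrix ref, NumericMatrix mob) {
  arma::mat R(3, 3);
  arma::rowvec tv(3);
  double rmsd;
  kabsch_core(as<arma::mat>(ref), as<arma::mat>(mob), R, tv, rmsd);
  return List::create(_["rotation"] = wrap(R),
                      _["translation"] = NumericVector(tv.begin(), tv.end()),
                      _["rmsd"] = rmsd);
}

// Superpose every frame of `coords` (natoms x 3 x nframes) onto `ref`;
// returns the aligned array plus per-frame RMSDs.
// [[Rcpp::export]]
List superpose_frames_cpp(NumericVector coords, NumericMatrix ref) {
  IntegerVector dim = coords.attr("dim");
  const int natoms = dim[0], nframes = dim[2];
  NumericVector out(Dimension(natoms, 3, nframes));
  NumericVector rmsds(nframes);
  arma::mat refm = as<arma::mat>(ref);
  for (int f = 0; f < nframes; ++f) {
    const double* slab = REAL(coords) + (R_xlen_t)f * natoms * 3;
    arma::mat mob(natoms, 3);
    for (int a = 0; a < natoms; ++a)
      for (int k = 0; k < 3; ++k) mob(a, k) = slab[a + k * natoms];
    arma::mat R(3, 3);
    arma::rowvec tv(3);
    double rmsd;
    kabsch_core(refm, mob, R, tv, rmsd);
    arma::mat aligned = mob * R;
    aligned.each_row() += tv;
    double* oslab = REAL(out) + (R_xlen_t)f * natoms * 3;
    for (int a = 0; a < natoms; ++a)
      for (int k = 0; k < 3; ++k) oslab[a + k * natoms] = aligned(a, k);
    rmsds[f] = rmsd;
  }
  return List::create(_["coords"] = out, _["rmsd"] = rmsds);
}
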