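// Kabsch-Sander secondary-structure assignment over trajectory frames.
// Backbone H-bonds from the electrostatic proxy energy
//   E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)  [kcal/mol]
// with a bond declared at E < -0.5; pattern rules give n-turns, minimal
// helices, bridges/ladders (with single-bulge linking), turns and bends.
// Label codes: 0 '-', 1 'H', 2 'G', 3 'I', 4 'E', 5 'B', 6 'T', 7 'S'.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KS_Q = 0.084 * 332.0;  // kcal*A/mol
static const double KS_CUTOFF = -0.5;      // kcal/mol
static const double KS_EMIN = -9.9;

static inline double dist3(const double* a, const double* b) {
  double dx = a[0]-b[0], dy = a[1]-b[1], dz = a[2]-b[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// donor d (uses N, H), acceptor a (uses C, O); coordinates atom-major
static double ks_energy(const double* N, const double* H,
                        const double* C, const double* O) {
  double rON = dist3(O, N), rCH = dist3(C, H), rOH = dist3(O, H),
         rCN = dist3(C, N);
  if (rON < 0.5 || rCH < 0.5 || rOH < 0.5 || rCN < 0.5) return KS_EMIN;
  double e = KS_Q * (1.0/rON + 1.0/rCH - 1.0/rOH - 1.0/rCN);
  if (e < KS_EMIN) e = KS_EMIN;
  return e;
}

struct Bridge { int i, j; bool parallel; };
struct Ladder { int ilo, ihi, jlo, jhi; bool parallel; int nbridge; bool bulge; };

// [[Rcpp::export]]
IntegerMatrix dssp_cpp(NumericVector coords, IntegerVector nIdx,
                       IntegerVector caIdx, IntegerVector cIdx,
                       IntegerVector oIdx, IntegerVector hIdx) {
  IntegerVector dim = coords.attr("dim");
  const int natoms = dim[0], nframes = dim[2];
  const int nres = nIdx.size();
  IntegerMatrix labels(nframes, nres);
  if (nres < 3) return labels;

  std::vector<char> HB(nres * nres);          // HB[d*nres+a]
  std::vector<int> bestA(2 * nres);
  std::vector<double> bestE(2 * nres);
  std::vector<char> turn3(nres), turn4(nres), turn5(nres);
  std::vector<int> lab(nres);
  std::vector<double> fr(3 * natoms);

  for (int f = 0; f < nframes; ++f) {
    const double* slab = REAL(coords) + (R_xlen_t)f * natoms * 3;
    for (int a = 0; a < natoms; ++a)
      for (int k = 0; k < 3; ++k) fr[3*a + k] = slab[a + k*natoms];

    // two lowest-energy acceptors per donor, bonds at E < cutoff
    std::fill(HB.begin(), HB.end(), 0);
    for (int d = 0; d < nres; ++d) {
      bestA[2*d] = bestA[2*d+1] = -1;
      bestE[2*d] = bestE[2*d+1] = 0.0;
      if (hIdx[d] < 0) continue;  // chain-start residue: no amide H
      const double* Nd = &fr[3*nIdx[d]];
      const double* Hd = &fr[3*hIdx[d]];
      for (int a = 0; a < nres; ++a) {
        if (std::abs(d - a) < 2) continue;
        double e = ks_energy(Nd, Hd, &fr[3*cIdx[a]], &fr[3*oIdx[a]]);
        if (e < bestE[2*d]) {
          bestE[2*d+1] = bestE[2*d]; bestA[2*d+1] = bestA[2*d];
          bestE[2*d] = e; bestA[2*d] = a;
        } else if (e < bestE[2*d+1]) {
          bestE[2*d+1] = e; bestA[2*d+1] = a;
        }
      }
      for (int s = 0; s < 2; ++s)
        if (bestA[2*d+s] >= 0 && bestE[2*d+s] < KS_CUTOFF)
          HB[d*nres + bestA[2*d+s]] = 1;
    }

    // n-turns: HB from NH(i+n) to CO(i)
    for (int i = 0; i < nres; ++i) {
      turn3[i] = (i + 3 < nres) && HB[(i+3)*nres + i];
      turn4[i] = (i + 4 < nres) && HB[(i+4)*nres + i];
      turn5[i] = (i + 5 < nres) && HB[(i+5)*nres + i];
    }

    std::fill(lab.begin(), lab.end(), 0);

    // alpha helix: two consecutive 4-turns
    for (int i = 1; i + 4 < nres; ++i)
      if (turn4[i-1] && turn4[i])
        for (int k = i; k <= i + 3; ++k) lab[k] = 1;

    // bridges
    std::vector<Bridge> bridges;
    for (int i = 1; i + 1 < nres; ++i) {
      for (int j = i + 3; j + 1 < nres; ++j) {
        bool par = (HB[j*nres + (i-1)] && HB[(i+1)*nres + j]) ||
                   (HB[i*nres + (j-1)] && HB[(j+1)*nres + i]);
        bool anti = (HB[j*nres + i] && HB[i*nres + j]) ||
                    (HB[(j+1)*nres + (i-1)] && HB[(i+1)*nres + (j-1)]);
        if (par) bridges.push_back({i, j, true});
        else if (anti) bridges.push_back({i, j, false});
      }
    }

    // ladders: runs of consecutive bridges of one type
    std::vector<Ladder> ladders;
    std::vector<char> used(bridges.size(), 0);
    for (size_t b = 0; b < bridges.size(); ++b) {
      if (used[b]) continue;
      Ladder L{bridges[b].i, bridges[b].i, bridges[b].j, bridges[b].j,
               bridges[b].parallel, 1, false};
      used[b] = 1;
      bool grew = true;
      while (grew) {
        grew = false;
        for (size_t c = 0; c < bridges.size(); ++c) {
          if (used[c] || bridges[c].parallel != L.parallel) continue;
          int ei = L.ihi + 1;
          int ej = L.parallel ? L.jhi + 1 : L.jlo - 1;
          if (bridges[c].i == ei && bridges[c].j == ej) {
            L.ihi = ei;
            if (L.parallel) L.jhi = ej; else L.jlo = ej;
            ++L.nbridge; used[c] = 1; grew = true;
          }
        }
      }
      ladders.push_back(L);
    }

    // bulges: same-type ladders separated by <=1 residue on one strand and
    // <=4 on the other are treated as one sheet region
    for (size_t p = 0; p < ladders.size(); ++p) {
      for (size_t q = 0; q < ladders.size(); ++q) {
        if (p == q || ladders[p].parallel != ladders[q].parallel) continue;
        const Ladder& A = ladders[p];
        const Ladder& B = ladders[q];
        if (B.ilo <= A.ihi) continue;
        int gi = B.ilo - A.ihi - 1;
        int gj = A.parallel ? (B.jlo - A.jhi - 1) : (A.jlo - B.jhi - 1);
        if (gi < 0 || gj < 0) continue;
        if ((gi <= 1 && gj <= 4) || (gi <= 4 && gj <= 1)) {
          for (int k = A.ilo; k <= B.ihi; ++k) if (lab[k] == 0) lab[k] = 4;
          int jl = std::min(A.jlo, B.jlo), jh = std::max(A.jhi, B.jhi);
          for (int k = jl; k <= jh; ++k) if (lab[k] == 0) lab[k] = 4;
          ladders[p].bulge = ladders[q].bulge = true;
        }
      }
    }

    for (const Ladder& L : ladders) {
      if (L.nbridge >= 2 || L.bulge) {
        for (int k = L.ilo; k <= L.ihi; ++k) if (lab[k] == 0) lab[k] = 4;
        for (int k = L.jlo; k <= L.jhi; ++k) if (lab[k] == 0) lab[k] = 4;
      } else {
        if (lab[L.ilo] == 0) lab[L.ilo] = 5;
        if (lab[L.jlo] == 0) lab[L.jlo] = 5;
      }
    }

    // 3-10 helix: accepted blockwise where nothing of higher priority sits
    for (int i = 1; i + 3 < nres; ++i) {
      if (!(turn3[i-1] && turn3[i])) continue;
      bool ok = true;
      for (int k = i; k <= i + 2; ++k)
        if (!(lab[k] == 0 || lab[k] == 2)) ok = false;
      if (ok) for (int k = i; k <= i + 2; ++k) lab[k] = 2;
    }
    // pi helix (lower priority than alpha)
    for (int i = 1; i + 5 < nres; ++i) {
      if (!(turn5[i-1] && turn5[i])) continue;
      bool ok = true;
      for (int k = i; k <= i + 4; ++k)
        if (!(lab[k] == 0 || lab[k] == 3)) ok = false;
      if (ok) for (int k = i; k <= i + 4; ++k) lab[k] = 3;
    }

    // turns: interior residues of any single n-turn
    for (int i = 0; i < nres; ++i) {
      if (turn3[i]) for (int k = i+1; k <= i+2; ++k) if (lab[k] == 0) lab[k] = 6;
      if (turn4[i]) for (int k = i+1; k <= i+3; ++k) if (lab[k] == 0) lab[k] = 6;
      if (turn5[i]) for (int k = i+1; k <= i+4; ++k) if (lab[k] == 0) lab[k] = 6;
    }

    // bends: CA-chain curvature above 70 degrees
    for (int i = 2; i + 2 < nres; ++i) {
      if (lab[i] != 0) continue;
      const double* a = &fr[3*caIdx[i-2]];
      const double* b = &fr[3*caIdx[i]];
      const double* c = &fr[3*caIdx[i+2]];
      double u[3], v[3];
      for (int k = 0; k < 3; ++k) { u[k] = b[k]-a[k]; v[k] = c[k]-b[k]; }
      double du = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
      double dv = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
      double ct = (u[0]*v[0]+u[1]*v[1]+u[2]*v[2]) / (du*dv);
      if (ct < std::cos(70.0 * M_PI / 180.0)) lab[i] = 7;
    }

    for (int r = 0; r < nres; ++r) labels(f, r) = lab[r];
  }
  return labels;
}

// Raw Kabsch-Sander energy for one donor/acceptor residue pair in one frame
// (exposed for the R-level formula surface).
// [[Rcpp::export]]
double ks_energy_cpp(NumericVector nD, NumericVector hD,
                     NumericVector cA, NumericVector oA) {
  return ks_energy(REAL(nD), REAL(hD), REAL(cA), REAL(oA));
}
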