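#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy Monte-Carlo grid-deformation registration.
//
// Maintains a per-node displacement field D (km, forward displacement of the
// initial pattern). A proposal perturbs one node's D by an isotropic Gaussian
// step and is accepted iff the objective strictly decreases:
//   E(D) = sum_nodes (f0(x - D) - f1(x))^2 / msd0
//        + lambda * sum_{4-neighbour pairs} |D_i - D_j|^2 / L_ij^2
// msd0 is the D=0 mean squared field difference and L_ij the local cell size
// in km, so both terms are dimensionless and lambda = 1 is meaningful.
// Backward warp: f0 is bilinearly interpolated at the node position minus D
// (degree space, clamped to the grid so outside pre-images take the nearest
// edge value). Uses R's RNG, so set.seed() in R governs reproducibility.

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static double interp_clamped(const NumericMatrix &f, const NumericVector &lat,
                             const NumericVector &lon, double qlat, double qlon) {
  const int nr = f.nrow(), nc = f.ncol();
  const double la = clampd(qlat, lat[0], lat[nr - 1]);
  const double lo = clampd(qlon, lon[0], lon[nc - 1]);
  const double dlat = (lat[nr - 1] - lat[0]) / (nr - 1);
  const double dlon = (lon[nc - 1] - lon[0]) / (nc - 1);
  double fi = (la - lat[0]) / dlat;
  double fj = (lo - lon[0]) / dlon;
  int i0 = (int)std::floor(fi); if (i0 > nr - 2) i0 = nr - 2; if (i0 < 0) i0 = 0;
  int j0 = (int)std::floor(fj); if (j0 > nc - 2) j0 = nc - 2; if (j0 < 0) j0 = 0;
  const double wi = fi - i0, wj = fj - j0;
  return (1 - wi) * (1 - wj) * f(i0, j0) + (1 - wi) * wj * f(i0, j0 + 1) +
         wi * (1 - wj) * f(i0 + 1, j0) + wi * wj * f(i0 + 1, j0 + 1);
}

// [[Rcpp::export(name = ".match_core")]]
List match_core(NumericMatrix f0, NumericMatrix f1, NumericVector lat,
                NumericVector lon, double lambda, double prop_scale,
                int budget, int stall_limit, double msd0, double K) {
  const int nr = f0.nrow(), nc = f0.ncol(), n = nr * nc;
  const double dlat = (lat[nr - 1] - lat[0]) / (nr - 1);
  const double dlon = (lon[nc - 1] - lon[0]) / (nc - 1);
  const double pi = 3.14159265358979323846;

  std::vector<double> kmlon(nr), cell(nr);
  for (int i = 0; i < nr; ++i) {
    kmlon[i] = K * std::cos(lat[i] * pi / 180.0);
    cell[i] = 0.5 * (K * dlat + kmlon[i] * dlon);
  }

  NumericMatrix De(nr, nc), Dn(nr, nc), mis(nr, nc);
  double mis_total = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double r = f0(i, j) - f1(i, j);
      mis(i, j) = r * r;
      mis_total += mis(i, j);
    }
  const double mis_init = mis_total;
  double E = mis_total / msd0; // shear(0) = 0

  std::vector<double> trace;
  trace.reserve(1024);
  long accepted = 0;
  int stall = 0;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  for (int it = 0; it < budget; ++it) {
    int k = (int)(unif_rand() * n);
    if (k >= n) k = n - 1;
    const int i = k % nr, j = k / nr;
    const double sd = prop_scale * cell[i];
    const double ne = De(i, j) + norm_rand() * sd;
    const double nn = Dn(i, j) + norm_rand() * sd;

    const double qlat = lat[i] - nn / K;
    const double qlon = lon[j] - ne / kmlon[i];
    const double r = interp_clamped(f0, lat, lon, qlat, qlon) - f1(i, j);
    const double m_new = r * r;

    double dshear = 0.0;
    for (int q = 0; q < 4; ++q) {
      const int ii = i + di[q], jj = j + dj[q];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      const double L = 0.5 * (cell[i] + cell[ii]);
      const double oe = De(i, j) - De(ii, jj), on = Dn(i, j) - Dn(ii, jj);
      const double qe = ne - De(ii, jj), qn = nn - Dn(ii, jj);
      dshear += (qe * qe + qn * qn - oe * oe - on * on) / (L * L);
    }

    const double dE = (m_new - mis(i, j)) / msd0 + lambda * dshear;
    if (dE < 0) {
      De(i, j) = ne;
      Dn(i, j) = nn;
      mis_total += m_new - mis(i, j);
      mis(i, j) = m_new;
      E += dE;
      trace.push_back(E);
      ++accepted;
      stall = 0;
    } else if (++stall >= stall_limit) {
      break;
    }
  }

  return List::create(_["De"] = De, _["Dn"] = Dn,
                      _["objective_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_accepted"] = (double)accepted,
                      _["misfit_initial"] = mis_init,
                      _["misfit_final"] = mis_total);
}
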