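#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Iterative pairwise projection onto distance bounds (shake-like sweeps).
// Bound order is shuffled each sweep with a private mt19937 stream so a given
// (coords, bounds, seed) triple is bitwise reproducible.
// Indices are 0-based.
// [[Rcpp::export]]
List cpp_solve_bounds(NumericMatrix coords, IntegerVector bi, IntegerVector bj,
                      NumericVector lo, NumericVector hi, double stop_tol,
                      int max_sweeps, int seed) {
  const int n = coords.nrow();
  const int m = bi.size();
  std::vector<double> X(coords.begin(), coords.end()); // column-major, n x 3
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<int> order(m);
  for (int k = 0; k < m; ++k) order[k] = k;

  double maxviol = 0.0;
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int t = 0; t < m; ++t) {
      const int k = order[t];
      const int i = bi[k], j = bj[k];
      double dx = X[i] - X[j];
      double dy = X[i + n] - X[j + n];
      double dz = X[i + 2 * n] - X[j + 2 * n];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double target;
      if (d < lo[k]) target = lo[k];
      else if (d > hi[k]) target = hi[k];
      else continue;
      if (d < 1e-9) { dx = 1e-4; dy = 0.0; dz = 0.0; d = 1e-4; }
      const double f = 0.5 * (target - d) / d;
      X[i] += f * dx; X[i + n] += f * dy; X[i + 2 * n] += f * dz;
      X[j] -= f * dx; X[j + n] -= f * dy; X[j + 2 * n] -= f * dz;
    }
    maxviol = 0.0;
    for (int k = 0; k < m; ++k) {
      const int i = bi[k], j = bj[k];
      const double dx = X[i] - X[j];
      const double dy = X[i + n] - X[j + n];
      const double dz = X[i + 2 * n] - X[j + 2 * n];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double v = 0.0;
      if (d < lo[k]) v = lo[k] - d;
      else if (d > hi[k]) v = d - hi[k];
      if (v > maxviol) maxviol = v;
    }
    if (maxviol <= stop_tol) { ++sweep; break; }
  }
  NumericMatrix out(n, 3);
  std::copy(X.begin(), X.end(), out.begin());
  return List::create(_["coords"] = out, _["max_violation"] = maxviol,
                      _["sweeps"] = sweep);
}

// Pairwise molecular-mechanics energy and analytic gradient.
// Nonbonded pairs carry precomputed q_i*q_j, combined LJ well depth and rmin;
// bonded terms (covalent bonds, 1-3 Urey-Bradley distances, the tetrahedral
// intermediate restraint) are harmonic in the pair distance.
// diel_mode: 0 = constant dielectric eps_const, 1 = distance-dependent 4r.
// [[Rcpp::export]]
List cpp_energy_gradient(NumericMatrix coords,
                         IntegerVector nbi, IntegerVector nbj,
                         NumericVector qq, NumericVector eps,
                         NumericVector rmin,
                         IntegerVector hbi, IntegerVector hbj,
                         NumericVector r0, NumericVector kh,
                         double coulomb_k, int diel_mode, double eps_const,
                         bool want_grad) {
  const int n = coords.nrow();
  NumericMatrix grad(n, 3);
  double energy = 0.0;
  double min_dist = R_PosInf;

  const int mn = nbi.size();
  for (int k = 0; k < mn; ++k) {
    const int i = nbi[k], j = nbj[k];
    const double dx = coords(i, 0) - coords(j, 0);
    const double dy = coords(i, 1) - coords(j, 1);
    const double dz = coords(i, 2) - coords(j, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    const double r = std::sqrt(r2);
    if (r < min_dist) min_dist = r;
    if (r < 1e-6) continue; // flagged via min_dist
    double dEdr = 0.0;
    if (eps[k] != 0.0) {
      const double s = rmin[k] / r;
      const double s6 = s * s * s * s * s * s;
      energy += eps[k] * (s6 * s6 - 2.0 * s6);
      dEdr += 12.0 * eps[k] * (s6 - s6 * s6) / r;
    }
    if (qq[k] != 0.0) {
      if (diel_mode == 1) { // eps(r) = 4r -> E = k qq / (4 r^2)
        const double e = coulomb_k * qq[k] / (4.0 * r2);
        energy += e;
        dEdr += -2.0 * e / r;
      } else {
        const double e = coulomb_k * qq[k] / (eps_const * r);
        energy += e;
        dEdr += -e / r;
      }
    }
    if (want_grad && dEdr != 0.0) {
      const double f = dEdr / r;
      grad(i, 0) += f * dx; grad(i, 1) += f * dy; grad(i, 2) += f * dz;
      grad(j, 0) -= f * dx; grad(j, 1) -= f * dy; grad(j, 2) -= f * dz;
    }
  }

  const int mh = hbi.size();
  for (int k = 0; k < mh; ++k) {
    const int i = hbi[k], j = hbj[k];
    const double dx = coords(i, 0) - coords(j, 0);
    const double dy = coords(i, 1) - coords(j, 1);
    const double dz = coords(i, 2) - coords(j, 2);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < min_dist) min_dist = r;
    const double dr = r - r0[k];
    energy += kh[k] * dr * dr;
    if (want_grad && r > 1e-9) {
      const double f = 2.0 * kh[k] * dr / r;
      grad(i, 0) += f * dx; grad(i, 1) += f * dy; grad(i, 2) += f * dz;
      grad(j, 0) -= f * dx; grad(j, 1) -= f * dy; grad(j, 2) -= f * dz;
    }
  }

  return List::create(_["energy"] = energy, _["gradient"] = grad,
                      _["min_dist"] = min_dist);
}

// Brute-force rigid superposition oracle: exhaustive ZYZ Euler-angle grid at
// `step_deg` resolution, optimal translation by centroid matching. Used as an
// independent check of the analytic least-squares fit.
// [[Rcpp::export]]
double cpp_grid_rmsd(NumericMatrix P, NumericMatrix Q, double step_deg) {
  const int n = P.nrow();
  std::vector<double> px(n), py(n), pz(n), qx(n), qy(n), qz(n);
  double cpx = 0, cpy = 0, cpz = 0, cqx = 0, cqy = 0, cqz = 0;
  for (int i = 0; i < n; ++i) {
    cpx += P(i, 0); cpy += P(i, 1); cpz += P(i, 2);
    cqx += Q(i, 0); cqy += Q(i, 1); cqz += Q(i, 2);
  }
  cpx /= n; cpy /= n; cpz /= n; cqx /= n; cqy /= n; cqz /= n;
  for (int i = 0; i < n; ++i) {
    px[i] = P(i, 0) - cpx; py[i] = P(i, 1) - cpy; pz[i] = P(i, 2) - cpz;
    qx[i] = Q(i, 0) - cqx; qy[i] = Q(i, 1) - cqy; qz[i] = Q(i, 2) - cqz;
  }
  const double step = step_deg * M_PI / 180.0;
  double best = R_PosInf;
  for (double a = 0; a < 2 * M_PI; a += step) {
    const double ca = std::cos(a), sa = std::sin(a);
    for (double b = 0; b <= M_PI + 1e-12; b += step) {
      const double cb = std::cos(b), sb = std::sin(b);
      for (double g = 0; g < 2 * M_PI; g += step) {
        const double cg = std::cos(g), sg = std::sin(g);
        // R = Rz(a) Ry(b) Rz(g)
        const double r11 = ca * cb * cg - sa * sg;
        const double r12 = -ca * cb * sg - sa * cg;
        const double r13 = ca * sb;
        const double r21 = sa * cb * cg + ca * sg;
        const double r22 = -sa * cb * sg + ca * cg;
        const double r23 = sa * sb;
        const double r31 = -sb * cg;
        const double r32 = sb * sg;
        const double r33 = cb;
        double ss = 0;
        for (int i = 0; i < n; ++i) {
          const double x = r11 * px[i] + r12 * py[i] + r13 * pz[i] - qx[i];
          const double y = r21 * px[i] + r22 * py[i] + r23 * pz[i] - qy[i];
          const double z = r31 * px[i] + r32 * py[i] + r33 * pz[i] - qz[i];
          ss += x * x + y * y + z * z;
        }
        if (ss < best) best = ss;
      }
    }
  }
  return std::sqrt(best / n);
}
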