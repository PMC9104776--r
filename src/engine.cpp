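// Coarse-grained NVT molecular dynamics core: tabulated non-bonded, bond
// and angle forces under orthorhombic periodic boundaries, leapfrog
// integration, canonical stochastic velocity-rescaling (CSVR) or
// Berendsen temperature coupling. Units: nm, ps, amu, kJ/mol, K.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Tab {
  double x0, dx;
  std::vector<double> U, F;
  int n;
};

Tab makeTab(const List& t) {
  Tab tb;
  tb.x0 = as<double>(t["x0"]);
  tb.dx = as<double>(t["dx"]);
  tb.U  = as<std::vector<double>>(t["U"]);
  tb.F  = as<std::vector<double>>(t["F"]);
  tb.n  = (int)tb.U.size();
  return tb;
}

std::vector<Tab> makeTabs(const List& l) {
  std::vector<Tab> v;
  for (int i = 0; i < l.size(); ++i) v.push_back(makeTab(l[i]));
  return v;
}

// Force is interpolated linearly between nodes; the energy is the exact
// segment anti-derivative of that interpolated force anchored at the
// left node value, so -dU/dr equals the returned force everywhere (the
// O(dx^3) node mismatch this leaves in U is far below the interpolation
// error of the tables themselves). Outside the grid the table continues
// linearly with the edge force (repulsive wall below, constant slope
// above).
inline void tabEval(const Tab& t, double x, double& U, double& F,
                    long& clamped) {
  double s = (x - t.x0) / t.dx;
  if (s <= 0.0) {
    U = t.U[0] + t.F[0] * (t.x0 - x);
    F = t.F[0];
    ++clamped;
    return;
  }
  int i = (int)s;
  if (i >= t.n - 1) {
    double xe = t.x0 + (t.n - 1) * t.dx;
    U = t.U[t.n - 1] - t.F[t.n - 1] * (x - xe);
    F = t.F[t.n - 1];
    ++clamped;
    return;
  }
  double f = s - i;
  double dt = f * t.dx;
  double dF = t.F[i + 1] - t.F[i];
  F = t.F[i] + dF * f;
  U = t.U[i] - (t.F[i] * dt + 0.5 * dF * f * dt);
}

inline double mimg(double d, double L) { return d - L * std::nearbyint(d / L); }

struct System {
  int N;
  std::vector<double> x, v, m, f;  // length 3N, layout [3*i + d]
  double box[3];
  std::vector<int> type;
  std::vector<int> pairTab;  // ntypes x ntypes, -1 = no interaction
  int ntypes;
  std::vector<Tab> nb, bt, at;
  double rcut;
  std::vector<char> excl;              // N x N
  std::vector<int> bonds;              // 2 per bond
  std::vector<int> bondIdx;
  std::vector<int> angles;             // 3 per angle (angle at middle)
  std::vector<int> angleIdx;
  std::vector<char> frozen;
  long clamped = 0;
};

System buildSystem(const NumericMatrix& pos, const NumericVector& box,
                   const IntegerVector& typeIdx, const IntegerMatrix& pairTab,
                   const List& nbList, double rcut,
                   const IntegerMatrix& exclPairs, const IntegerMatrix& bonds,
                   const IntegerVector& bondTabIdx, const List& bondList,
                   const IntegerMatrix& angles,
                   const IntegerVector& angleTabIdx, const List& angleList,
                   const LogicalVector& frozen) {
  System s;
  s.N = pos.nrow();
  s.x.resize(3 * s.N);
  s.v.assign(3 * s.N, 0.0);
  s.f.assign(3 * s.N, 0.0);
  s.m.resize(s.N);
  for (int i = 0; i < s.N; ++i)
    for (int d = 0; d < 3; ++d) s.x[3 * i + d] = pos(i, d);
  for (int d = 0; d < 3; ++d) s.box[d] = box[d];
  s.type = as<std::vector<int>>(typeIdx);
  s.ntypes = pairTab.nrow();
  s.pairTab.resize(s.ntypes * s.ntypes);
  for (int a = 0; a < s.ntypes; ++a)
    for (int b = 0; b < s.ntypes; ++b)
      s.pairTab[a * s.ntypes + b] = pairTab(a, b);
  s.nb = makeTabs(nbList);
  s.rcut = rcut;
  s.excl.assign((size_t)s.N * s.N, 0);
  for (int e = 0; e < exclPairs.nrow(); ++e) {
    int i = exclPairs(e, 0), j = exclPairs(e, 1);
    s.excl[(size_t)i * s.N + j] = 1;
    s.excl[(size_t)j * s.N + i] = 1;
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    s.bonds.push_back(bonds(b, 0));
    s.bonds.push_back(bonds(b, 1));
    s.bondIdx.push_back(bondTabIdx[b]);
  }
  s.bt = makeTabs(bondList);
  for (int a = 0; a < angles.nrow(); ++a) {
    s.angles.push_back(angles(a, 0));
    s.angles.push_back(angles(a, 1));
    s.angles.push_back(angles(a, 2));
    s.angleIdx.push_back(angleTabIdx[a]);
  }
  s.at = makeTabs(angleList);
  s.frozen.resize(s.N);
  for (int i = 0; i < s.N; ++i) s.frozen[i] = frozen[i] ? 1 : 0;
  return s;
}

double computeForces(System& s) {
  std::fill(s.f.begin(), s.f.end(), 0.0);
  double epot = 0.0;
  const double rc2 = s.rcut * s.rcut;
  // non-bonded, all pairs with cutoff
  for (int i = 0; i < s.N - 1; ++i) {
    for (int j = i + 1; j < s.N; ++j) {
      if (s.excl[(size_t)i * s.N + j]) continue;
      int ti = s.pairTab[s.type[i] * s.ntypes + s.type[j]];
      if (ti < 0) continue;
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        d[k] = mimg(s.x[3 * i + k] - s.x[3 * j + k], s.box[k]);
        r2 += d[k] * d[k];
      }
      if (r2 > rc2) continue;
      double r = std::sqrt(r2);
      if (r < 1e-8)
        stop("beads %d and %d overlap (r < 1e-8 nm)", i + 1, j + 1);
      double U, F;
      tabEval(s.nb[ti], r, U, F, s.clamped);
      epot += U;
      double c = F / r;
      for (int k = 0; k < 3; ++k) {
        s.f[3 * i + k] += c * d[k];
        s.f[3 * j + k] -= c * d[k];
      }
    }
  }
  // bonds
  for (size_t b = 0; b < s.bondIdx.size(); ++b) {
    int i = s.bonds[2 * b], j = s.bonds[2 * b + 1];
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      d[k] = mimg(s.x[3 * i + k] - s.x[3 * j + k], s.box[k]);
      r2 += d[k] * d[k];
    }
    double r = std::sqrt(r2);
    if (r < 1e-8) stop("bonded beads %d and %d overlap", i + 1, j + 1);
    double U, F;
    tabEval(s.bt[s.bondIdx[b]], r, U, F, s.clamped);
    epot += U;
    double c = F / r;
    for (int k = 0; k < 3; ++k) {
      s.f[3 * i + k] += c * d[k];
      s.f[3 * j + k] -= c * d[k];
    }
  }
  // angles (at middle bead j); table x in degrees, F = -dU/d(theta_deg)
  const double RAD2DEG = 180.0 / M_PI;
  for (size_t a = 0; a < s.angleIdx.size(); ++a) {
    int i = s.angles[3 * a], j = s.angles[3 * a + 1], k = s.angles[3 * a + 2];
    double u[3], w[3], nu2 = 0.0, nw2 = 0.0, dot = 0.0;
    for (int d = 0; d < 3; ++d) {
      u[d] = mimg(s.x[3 * i + d] - s.x[3 * j + d], s.box[d]);
      w[d] = mimg(s.x[3 * k + d] - s.x[3 * j + d], s.box[d]);
      nu2 += u[d] * u[d];
      nw2 += w[d] * w[d];
      dot += u[d] * w[d];
    }
    double nu = std::sqrt(nu2), nw = std::sqrt(nw2);
    if (nu < 1e-8 || nw < 1e-8) continue;  // degenerate arm
    double ct = dot / (nu * nw);
    ct = std::max(-1.0, std::min(1.0, ct));
    double st = std::sqrt(std::max(1e-16, 1.0 - ct * ct));
    double theta = std::acos(ct) * RAD2DEG;
    double U, Fdeg;
    tabEval(s.at[s.angleIdx[a]], theta, U, Fdeg, s.clamped);
    epot += U;
    // generalized force per radian; A = -dU/dtheta_rad = Fdeg * RAD2DEG
    double A = Fdeg * RAD2DEG;
    for (int d = 0; d < 3; ++d) {
      double dthi = (ct * u[d] / nu - w[d] / nw) / (nu * st);
      double dthk = (ct * w[d] / nw - u[d] / nu) / (nw * st);
      double fi = A * dthi, fk = A * dthk;
      s.f[3 * i + d] += fi;
      s.f[3 * k + d] += fk;
      s.f[3 * j + d] -= fi + fk;
    }
  }
  return epot;
}

}  // namespace

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericVector box,
                        IntegerVector typeIdx, IntegerMatrix pairTab,
                        List nbList, double rcut, IntegerMatrix exclPairs,
                        IntegerMatrix bonds, IntegerVector bondTabIdx,
                        List bondList, IntegerMatrix angles,
                        IntegerVector angleTabIdx, List angleList,
                        LogicalVector frozen) {
  System s = buildSystem(pos, box, typeIdx, pairTab, nbList, rcut, exclPairs,
                         bonds, bondTabIdx, bondList, angles, angleTabIdx,
                         angleList, frozen);
  double epot = computeForces(s);
  NumericMatrix F(s.N, 3);
  for (int i = 0; i < s.N; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = s.f[3 * i + d];
  return List::create(_["forces"] = F, _["epot"] = epot,
                      _["clamped"] = (double)s.clamped);
}

// [[Rcpp::export]]
List cpp_run_nvt(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                 NumericVector box, IntegerVector typeIdx,
                 IntegerMatrix pairTab, List nbList, double rcut,
                 IntegerMatrix exclPairs, IntegerMatrix bonds,
                 IntegerVector bondTabIdx, List bondList,
                 IntegerMatrix angles, IntegerVector angleTabIdx,
                 List angleList, LogicalVector frozen, double dt, int nsteps,
                 double Tref, int thermostat, double tauT,
                 int sampleInterval, bool removeCom, double kB) {
  System s = buildSystem(pos, box, typeIdx, pairTab, nbList, rcut, exclPairs,
                         bonds, bondTabIdx, bondList, angles, angleTabIdx,
                         angleList, frozen);
  for (int i = 0; i < s.N; ++i) {
    s.m[i] = mass[i];
    for (int d = 0; d < 3; ++d) s.v[3 * i + d] = vel(i, d);
  }
  std::vector<int> mobile;
  for (int i = 0; i < s.N; ++i)
    if (!s.frozen[i]) mobile.push_back(i);
  int nmob = (int)mobile.size();
  if (nmob == 0 && thermostat != 0)
    stop("thermostatting a fully frozen system");
  int ndf = (nmob >= 2 && removeCom) ? 3 * nmob - 3 : 3 * nmob;
  double mtot = 0.0;
  for (int idx : mobile) mtot += s.m[idx];

  int nsamp = nsteps / sampleInterval;
  NumericVector frames(Dimension(nsamp, s.N, 3));
  NumericVector Tser(nsteps), Eser(nsteps), Kon(nsteps);
  int isamp = 0;
  std::vector<double> vold(3 * s.N);

  for (int step = 0; step < nsteps; ++step) {
    double epot = computeForces(s);
    vold = s.v;
    // leapfrog velocity update (mobile beads only)
    for (int idx : mobile)
      for (int d = 0; d < 3; ++d)
        s.v[3 * idx + d] += s.f[3 * idx + d] / s.m[idx] * dt;
    // on-step kinetic energy from time-centered velocities (pure leapfrog)
    double kon = 0.0;
    for (int idx : mobile)
      for (int d = 0; d < 3; ++d) {
        double vc = 0.5 * (vold[3 * idx + d] + s.v[3 * idx + d]);
        kon += 0.5 * s.m[idx] * vc * vc;
      }
    double K = 0.0;
    for (int idx : mobile)
      for (int d = 0; d < 3; ++d)
        K += 0.5 * s.m[idx] * s.v[3 * idx + d] * s.v[3 * idx + d];
    // temperature coupling
    if (thermostat != 0 && K > 0.0 && ndf > 0) {
      double scale = 1.0;
      if (thermostat == 1) {  // CSVR stochastic velocity rescaling
        double c = std::exp(-dt / tauT);
        double Kbar = 0.5 * ndf * kB * Tref;
        double R1 = norm_rand();
        double sumR2 = (ndf > 1) ? R::rchisq((double)(ndf - 1)) : 0.0;
        double a2 = c + (1.0 - c) * Kbar * (R1 * R1 + sumR2) / (ndf * K) +
                    2.0 * R1 * std::sqrt(c * (1.0 - c) * Kbar / (ndf * K));
        scale = std::sqrt(std::max(0.0, a2));
      } else if (thermostat == 2) {  // Berendsen
        double T = 2.0 * K / (ndf * kB);
        scale = std::sqrt(std::max(0.0, 1.0 + dt / tauT * (Tref / T - 1.0)));
      }
      for (int idx : mobile)
        for (int d = 0; d < 3; ++d) s.v[3 * idx + d] *= scale;
      K *= scale * scale;
    }
    // remove center-of-mass motion of the mobile subsystem
    if (removeCom && nmob >= 2) {
      double p[3] = {0, 0, 0};
      for (int idx : mobile)
        for (int d = 0; d < 3; ++d) p[d] += s.m[idx] * s.v[3 * idx + d];
      double dK = 0.0;
      for (int idx : mobile)
        for (int d = 0; d < 3; ++d) {
          double vv = s.v[3 * idx + d];
          s.v[3 * idx + d] -= p[d] / mtot;
          dK += 0.5 * s.m[idx] *
                (s.v[3 * idx + d] * s.v[3 * idx + d] - vv * vv);
        }
      K += dK;
    }
    // position update and wrapping
    for (int idx : mobile)
      for (int d = 0; d < 3; ++d) {
        double& xx = s.x[3 * idx + d];
        xx += s.v[3 * idx + d] * dt;
        xx -= s.box[d] * std::floor(xx / s.box[d]);
        if (!std::isfinite(xx))
          stop("integration blow-up at step %d (bead %d)", step + 1, idx + 1);
      }
    Tser[step] = (ndf > 0) ? 2.0 * K / (ndf * kB) : 0.0;
    Eser[step] = epot;
    Kon[step] = kon;
    if ((step + 1) % sampleInterval == 0 && isamp < nsamp) {
      for (int i = 0; i < s.N; ++i)
        for (int d = 0; d < 3; ++d)
          frames[isamp + nsamp * (i + s.N * d)] = s.x[3 * i + d];
      ++isamp;
    }
  }
  frames.attr("dim") = Dimension(nsamp, s.N, 3);
  NumericMatrix xout(s.N, 3), vout(s.N, 3);
  for (int i = 0; i < s.N; ++i)
    for (int d = 0; d < 3; ++d) {
      xout(i, d) = s.x[3 * i + d];
      vout(i, d) = s.v[3 * i + d];
    }
  return List::create(
      _["frames"] = frames, _["T"] = Tser, _["epot"] = Eser,
      _["kin_onstep"] = Kon, _["positions"] = xout, _["velocities"] = vout,
      _["clamped"] = (double)s.clamped, _["ndf"] = ndf);
}

// [[Rcpp::export]]
NumericVector cpp_pair_histogram(NumericVector coords, NumericVector box,
                                 IntegerVector ia, IntegerVector ib,
                                 bool same, IntegerMatrix excl, int nbins,
                                 double dx) {
  IntegerVector dim = coords.attr("dim");
  int nf = dim[0], N = dim[1];
  std::vector<char> ex((size_t)N * N, 0);
  for (int e = 0; e < excl.nrow(); ++e) {
    ex[(size_t)excl(e, 0) * N + excl(e, 1)] = 1;
    ex[(size_t)excl(e, 1) * N + excl(e, 0)] = 1;
  }
  NumericVector counts(nbins);
  double rmax = nbins * dx;
  double rmax2 = rmax * rmax;
  const double* c = coords.begin();
  for (int f = 0; f < nf; ++f) {
    int na = ia.size(), nb = ib.size();
    for (int p = 0; p < na; ++p) {
      int i = ia[p];
      int qstart = same ? p + 1 : 0;
      for (int q = qstart; q < nb; ++q) {
        int j = ib[q];
        if (i == j || ex[(size_t)i * N + j]) continue;
        double r2 = 0.0;
        for (int d = 0; d < 3; ++d) {
          double dd = c[f + nf * (i + N * d)] - c[f + nf * (j + N * d)];
          dd = mimg(dd, box[d]);
          r2 += dd * dd;
        }
        if (r2 >= rmax2) continue;
        int bin = (int)(std::sqrt(r2) / dx);
        if (bin >= 0 && bin < nbins) counts[bin] += 1.0;
      }
    }
  }
  return counts;
}
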