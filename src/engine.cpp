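// Desk-scale Langevin engine for coarse-grained bead-spring chains.
// Units at the interface: nm, ps, amu, kcal/mol. Internally forces are
// converted with 1 kcal/mol = 4.184 amu nm^2/ps^2 for the integrator.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const double KCAL2INT = 4.184; // kcal/mol -> amu nm^2/ps^2

struct PairTables {
  int nt;
  std::vector<double> eps, sigma, R, mu, nu, alpha, rstar, cutoff;
};

static PairTables unpackPair(const List &pair) {
  PairTables p;
  NumericMatrix eps = pair["eps"];
  p.nt = eps.nrow();
  auto grab = [&](const char *nm, std::vector<double> &v) {
    NumericMatrix m = pair[nm];
    v.assign(m.begin(), m.end());
  };
  grab("eps", p.eps); grab("sigma", p.sigma); grab("R", p.R);
  grab("mu", p.mu); grab("nu", p.nu); grab("alpha", p.alpha);
  grab("rstar", p.rstar); grab("cutoff", p.cutoff);
  return p;
}

// Wang-Frenkel energy and radial derivative, branch chosen by sign of eps.
static inline void wfEval(double r, double eps, double sigma, double R,
                          double mu, double nu, double alpha, double rstar,
                          double &e, double &dedr) {
  if (eps >= 0.0) {
    if (r >= R) return;
    double u = std::pow(sigma / r, 2.0 * mu);
    double w = std::pow(R / r, 2.0 * mu);
    double wm = w - 1.0;
    double pw = std::pow(wm, 2.0 * nu - 1.0);
    e += eps * alpha * (u - 1.0) * pw * wm;
    dedr += -(2.0 * mu * eps * alpha / r) * pw *
            (u * wm + 2.0 * nu * w * (u - 1.0));
  } else {
    if (r >= rstar) return;
    double u = std::pow(sigma / r, 2.0 * mu);
    double w = std::pow(R / r, 2.0 * mu);
    double wm = w - 1.0;
    double pw = std::pow(wm, 2.0 * nu - 1.0);
    e += -(eps * alpha * (u - 1.0) * pw * wm) - eps;
    dedr += (2.0 * mu * eps * alpha / r) * pw *
            (u * wm + 2.0 * nu * w * (u - 1.0));
  }
}

static inline void minImage(double *d, const double *box) {
  for (int k = 0; k < 3; ++k) d[k] -= box[k] * std::nearbyint(d[k] / box[k]);
}

class ForceField {
public:
  int n;
  double box[3];
  std::vector<int> type;
  std::vector<double> charge, mass;
  std::vector<int> bi, bj;
  std::vector<double> bk, br0;
  PairTables pair;
  double coulPref, kappa, elecCutoff;
  bool useList;
  double skin, rList, maxCut;
  std::unordered_set<long long> excl;
  // neighbour list state
  std::vector<std::pair<int, int>> nlist;
  std::vector<double> refPos;
  bool listValid = false;

  ForceField(const NumericMatrix &pos0, const NumericVector &boxv,
             const IntegerVector &typev, const NumericVector &chargev,
             const NumericVector &massv, const IntegerVector &bondi,
             const IntegerVector &bondj, const NumericVector &bondk,
             const NumericVector &bondr0, const List &pairList,
             double coulPref_, double kappa_, double elecCutoff_,
             bool useList_, double skin_)
      : n(pos0.nrow()), coulPref(coulPref_), kappa(kappa_),
        elecCutoff(elecCutoff_), useList(useList_), skin(skin_) {
    for (int k = 0; k < 3; ++k) box[k] = boxv[k];
    type.assign(typev.begin(), typev.end()); // 0-based
    charge.assign(chargev.begin(), chargev.end());
    mass.assign(massv.begin(), massv.end());
    bi.assign(bondi.begin(), bondi.end()); // 0-based
    bj.assign(bondj.begin(), bondj.end());
    bk.assign(bondk.begin(), bondk.end());
    br0.assign(bondr0.begin(), bondr0.end());
    pair = unpackPair(pairList);
    for (size_t b = 0; b < bi.size(); ++b) {
      int i = bi[b], j = bj[b];
      if (i > j) std::swap(i, j);
      excl.insert((long long)i * n + j);
    }
    maxCut = 0.0;
    for (double c : pair.cutoff) maxCut = std::max(maxCut, c);
    bool anyCharge = false;
    for (double q : charge) if (q != 0.0) anyCharge = true;
    if (anyCharge && coulPref != 0.0) maxCut = std::max(maxCut, elecCutoff);
    rList = maxCut + skin;
  }

  bool excluded(int i, int j) const {
    if (i > j) std::swap(i, j);
    return excl.count((long long)i * n + j) > 0;
  }

  void buildList(const std::vector<double> &x) {
    nlist.clear();
    if (maxCut <= 0.0) { listValid = true; refPos = x; return; }
    double r2 = rList * rList;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (excluded(i, j)) continue;
        double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                       x[3 * i + 2] - x[3 * j + 2]};
        minImage(d, box);
        if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < r2)
          nlist.emplace_back(i, j);
      }
    }
    refPos = x;
    listValid = true;
  }

  void maybeRebuild(const std::vector<double> &x) {
    if (!listValid) { buildList(x); return; }
    double lim2 = 0.25 * skin * skin, maxd2 = 0.0;
    for (int i = 0; i < 3 * n; i += 3) {
      double dx = x[i] - refPos[i], dy = x[i + 1] - refPos[i + 1],
             dz = x[i + 2] - refPos[i + 2];
      maxd2 = std::max(maxd2, dx * dx + dy * dy + dz * dz);
      if (maxd2 > lim2) break;
    }
    if (maxd2 > lim2) buildList(x);
  }

  // energy in kcal/mol, forces (kcal/mol/nm) accumulated into f
  double compute(const std::vector<double> &x, std::vector<double> &f) {
    std::fill(f.begin(), f.end(), 0.0);
    double energy = 0.0;
    // bonds
    for (size_t b = 0; b < bi.size(); ++b) {
      int i = bi[b], j = bj[b];
      double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      minImage(d, box);
      double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      double dr = r - br0[b];
      energy += bk[b] * dr * dr; // k (r - r0)^2 convention
      double dedr = 2.0 * bk[b] * dr;
      if (r > 1e-12) {
        for (int k = 0; k < 3; ++k) {
          double fk = -dedr * d[k] / r;
          f[3 * i + k] += fk;
          f[3 * j + k] -= fk;
        }
      }
    }
    // nonbonded
    auto pairTerm = [&](int i, int j) {
      double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      minImage(d, box);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 >= maxCut * maxCut || r2 < 1e-20) return;
      double r = std::sqrt(r2);
      int ti = type[i], tj = type[j];
      int idx = ti + pair.nt * tj;
      double e = 0.0, dedr = 0.0;
      if (pair.eps[idx] != 0.0 && r < pair.cutoff[idx])
        wfEval(r, pair.eps[idx], pair.sigma[idx], pair.R[idx], pair.mu[idx],
               pair.nu[idx], pair.alpha[idx], pair.rstar[idx], e, dedr);
      double qq = charge[i] * charge[j];
      if (qq != 0.0 && coulPref != 0.0 && r < elecCutoff) {
        double ey = coulPref * qq * std::exp(-kappa * r) / r;
        e += ey;
        dedr += -ey * (kappa + 1.0 / r);
      }
      energy += e;
      for (int k = 0; k < 3; ++k) {
        double fk = -dedr * d[k] / r;
        f[3 * i + k] += fk;
        f[3 * j + k] -= fk;
      }
    };
    if (maxCut > 0.0) {
      if (useList) {
        maybeRebuild(x);
        for (auto &p : nlist) pairTerm(p.first, p.second);
      } else {
        for (int i = 0; i < n - 1; ++i)
          for (int j = i + 1; j < n; ++j)
            if (!excluded(i, j)) pairTerm(i, j);
      }
    }
    return energy;
  }
};

static void checkForces(const std::vector<double> &f, int n) {
  for (int i = 0; i < n; ++i) {
    double m = std::abs(f[3 * i]) + std::abs(f[3 * i + 1]) +
               std::abs(f[3 * i + 2]);
    if (!std::isfinite(m) || m > 1e10)
      stop("force overflow (likely bead overlap) at bead %d", i + 1);
  }
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericVector box,
                        IntegerVector type, NumericVector charge,
                        NumericVector mass, IntegerVector bond_i,
                        IntegerVector bond_j, NumericVector bond_k,
                        NumericVector bond_r0, List pair, double coulPref,
                        double kappa, double elecCutoff, bool useList,
                        double skin) {
  ForceField ff(pos, box, type, charge, mass, bond_i, bond_j, bond_k,
                bond_r0, pair, coulPref, kappa, elecCutoff, useList, skin);
  int n = pos.nrow();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  double e = ff.compute(x, f);
  NumericMatrix fout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) fout(i, k) = f[3 * i + k];
  return List::create(_["energy"] = e, _["forces"] = fout);
}

// [[Rcpp::export]]
NumericMatrix cpp_minimize(NumericMatrix pos, NumericVector box,
                           IntegerVector type, NumericVector charge,
                           NumericVector mass, IntegerVector bond_i,
                           IntegerVector bond_j, NumericVector bond_k,
                           NumericVector bond_r0, List pair, double coulPref,
                           double kappa, double elecCutoff, int maxIter,
                           double maxDisp) {
  ForceField ff(pos, box, type, charge, mass, bond_i, bond_j, bond_k,
                bond_r0, pair, coulPref, kappa, elecCutoff, true, 0.3);
  int n = pos.nrow();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  double ePrev = ff.compute(x, f);
  for (int it = 0; it < maxIter; ++it) {
    double fmax = 1e-30;
    for (double v : f) fmax = std::max(fmax, std::abs(v));
    double scale = maxDisp / fmax;
    std::vector<double> xn(x);
    for (int i = 0; i < 3 * n; ++i) xn[i] += scale * f[i];
    ff.listValid = false;
    double eNew = ff.compute(xn, f);
    if (!std::isfinite(eNew)) break;
    x = xn;
    if (std::abs(ePrev - eNew) < 1e-8 * (std::abs(ePrev) + 1e-8)) break;
    ePrev = eNew;
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  return out;
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericVector box,
                      IntegerVector type, NumericVector charge,
                      NumericVector mass, IntegerVector bond_i,
                      IntegerVector bond_j, NumericVector bond_k,
                      NumericVector bond_r0, List pair, double coulPref,
                      double kappa, double elecCutoff, int nSteps, double dt,
                      double friction, double kBT, int seed, int sampleEvery,
                      bool useList, double skin) {
  ForceField ff(pos, box, type, charge, mass, bond_i, bond_j, bond_k,
                bond_r0, pair, coulPref, kappa, elecCutoff, useList, skin);
  int n = pos.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  double kBTint = kBT * KCAL2INT; // amu nm^2/ps^2

  std::vector<double> nscale(n);
  for (int i = 0; i < n; ++i) nscale[i] = std::sqrt(kBTint / mass[i]);

  // Maxwell-Boltzmann initial velocities
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) v[3 * i + k] = nscale[i] * gauss(rng);

  bool thermostat = friction > 0.0;
  double c1 = thermostat ? std::exp(-friction * dt) : 1.0;
  double c2 = thermostat ? std::sqrt(1.0 - c1 * c1) : 0.0;

  int nSamples = nSteps / std::max(sampleEvery, 1) + 1;
  std::vector<double> frames((size_t)nSamples * n * 3);
  std::vector<double> times(nSamples), pe(nSamples), ke(nSamples);

  double ePot = ff.compute(x, f);
  checkForces(f, n);

  auto record = [&](int s, double t, double epot) {
    double ekin = 0.0;
    for (int i = 0; i < n; ++i)
      ekin += 0.5 * mass[i] *
              (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
               v[3 * i + 2] * v[3 * i + 2]);
    times[s] = t;
    pe[s] = epot;
    ke[s] = ekin / KCAL2INT; // back to kcal/mol
    // frames are stored unwrapped; analysis wraps when needed
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        frames[(size_t)s * n * 3 + (size_t)i * 3 + k] = x[3 * i + k];
  };
  record(0, 0.0, ePot);

  int sample = 1;
  for (int step = 1; step <= nSteps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double fm = 0.5 * dt * KCAL2INT / mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += fm * f[3 * i + k];
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O: Ornstein-Uhlenbeck
    if (thermostat) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          v[3 * i + k] = c1 * v[3 * i + k] + c2 * nscale[i] * gauss(rng);
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // recompute forces, B: half kick
    ePot = ff.compute(x, f);
    checkForces(f, n);
    for (int i = 0; i < n; ++i) {
      double fm = 0.5 * dt * KCAL2INT / mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += fm * f[3 * i + k];
    }
    if (sampleEvery > 0 && step % sampleEvery == 0 && sample < nSamples) {
      record(sample, step * dt, ePot);
      ++sample;
    }
    if (step % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector dim = IntegerVector::create(nSamples, n, 3);
  NumericVector framesOut(frames.begin(), frames.end());
  // stored as [sample][bead][xyz] row-major; R side reshapes
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["frames"] = framesOut, _["dim"] = dim,
                      _["pe"] = NumericVector(pe.begin(), pe.end()),
                      _["ke"] = NumericVector(ke.begin(), ke.end()));
}
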