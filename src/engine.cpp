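// Compiled core of the nucleus model: energy/force evaluation with a
// Verlet neighbour list, BAOAB Langevin and Euler-Maruyama Brownian
// integrators, the semi-grand Monte Carlo speckle-chemistry sweep, and a
// steepest-descent relaxer.  All quantities are in reduced units
// (sigma = 385 nm, tau = 0.65 s, T = 1).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <sstream>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static const int CAT_CHR = 0, CAT_NUC = 1, CAT_SPK = 2, CAT_LAM = 3;
// energy component slots
static const int C_BOND = 0, C_EV = 1, C_CONTACT = 2, C_LANDMARK = 3,
                 C_LJ = 4, C_CONFINE = 5, C_DEFORM = 6, NCOMP = 7;

// Mersenne-twister RNG with Box-Muller normals (no cached partner, so the
// full generator state is a single serializable mt19937_64 stream).
struct RNG {
  std::mt19937_64 gen;
  explicit RNG(uint64_t seed) : gen(seed) {}
  double unif() {
    // 53-bit uniform in [0,1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  int unif_int(int n) { return (int)(gen() % (uint64_t)n); }
  double normal() {
    double u1 = unif();
    while (u1 <= 1e-300) u1 = unif();
    double u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  std::string state() const {
    std::ostringstream os;
    os << gen;
    return os.str();
  }
  void set_state(const std::string& s) {
    std::istringstream is(s);
    is >> gen;
  }
};

struct Params {
  double rc, eta, ccut, fcut;           // contact function (fcut = f(ccut))
  double ev_strength;
  double diam[4];
  std::vector<double> alpha_ideal;      // s = 1..S, clamped beyond S
  double comp[9];                       // 3x3 compartment couplings
  std::vector<double> chrom;            // nhap x nhap chromosome-pair
  int nhap;
  std::vector<double> chi_lam, chi_spk, chi_nuc;  // per haploid bin
  double lj_sigma, lj_cut, lj_rcap, eps_nuc, eps_spk, eps_rep;
  double conf_k, conf_R;
  double defo_k;
  bool couplings_active, lam_active, spk_active, nuc_active;
};

struct System {
  int n;
  std::vector<double> x, y, z;          // positions
  std::vector<int> cat, chain, hapbin, hapchrom, label;
  std::vector<int> spk_state;           // per particle: 1 = dP, 0 = P, -1 n/a
  std::vector<char> frozen;
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> br0, bk;
  std::unordered_set<uint64_t> bonded;
  Params p;
  // neighbour list
  double skin = 0.3;
  double rmax_pair[4][4];
  double rmax_global;
  std::vector<int> ni, nj;
  std::vector<double> x0, y0, z0;       // positions at last build
  bool skip_frozen_pairs = false;
  // forces / energy
  std::vector<double> fx, fy, fz;
  double ecomp[NCOMP];

  uint64_t key(int i, int j) const {
    return (uint64_t)std::min(i, j) * (uint64_t)n + (uint64_t)std::max(i, j);
  }

  void init_pair_cutoffs() {
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        rmax_pair[a][b] = 0.5 * (p.diam[a] + p.diam[b]);
    double wca_cut = std::pow(2.0, 1.0 / 6.0) * p.lj_sigma;
    auto up = [&](int a, int b, double v) {
      if (v > rmax_pair[a][b]) rmax_pair[a][b] = rmax_pair[b][a] = v;
    };
    if (p.couplings_active) up(CAT_CHR, CAT_CHR, p.ccut);
    if (p.lam_active) up(CAT_CHR, CAT_LAM, p.ccut);
    if (p.spk_active) up(CAT_CHR, CAT_SPK, p.ccut);
    if (p.nuc_active) up(CAT_CHR, CAT_NUC, p.ccut);
    up(CAT_NUC, CAT_NUC, p.lj_cut);
    up(CAT_SPK, CAT_SPK, p.lj_cut);
    up(CAT_NUC, CAT_SPK, wca_cut);
    rmax_global = 0.0;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        if (rmax_pair[a][b] > rmax_global) rmax_global = rmax_pair[a][b];
  }

  void build_neighbors() {
    ni.clear();
    nj.clear();
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i])) {
        Rcpp::stop("non-finite coordinate for particle %d", i + 1);
      }
    }
    double cell = rmax_global + skin;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0], zmin = z[0],
           zmax = z[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    int nx = std::max(1, (int)((xmax - xmin) / cell) + 1);
    int ny = std::max(1, (int)((ymax - ymin) / cell) + 1);
    int nz = std::max(1, (int)((zmax - zmin) / cell) + 1);
    std::vector<std::vector<int>> cells((size_t)nx * ny * nz);
    auto cidx = [&](int i) {
      int cx = std::min(nx - 1, (int)((x[i] - xmin) / cell));
      int cy = std::min(ny - 1, (int)((y[i] - ymin) / cell));
      int cz = std::min(nz - 1, (int)((z[i] - zmin) / cell));
      return (cz * ny + cy) * nx + cx;
    };
    for (int i = 0; i < n; ++i) cells[cidx(i)].push_back(i);
    for (int cz = 0; cz < nz; ++cz)
      for (int cy = 0; cy < ny; ++cy)
        for (int cx = 0; cx < nx; ++cx) {
          const std::vector<int>& A = cells[(cz * ny + cy) * nx + cx];
          if (A.empty()) continue;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int ox = cx + dx, oy = cy + dy, oz = cz + dz;
                if (ox < 0 || oy < 0 || oz < 0 || ox >= nx || oy >= ny ||
                    oz >= nz)
                  continue;
                int oc = (oz * ny + oy) * nx + ox;
                int sc = (cz * ny + cy) * nx + cx;
                if (oc < sc) continue;
                const std::vector<int>& B = cells[oc];
                for (size_t a = 0; a < A.size(); ++a) {
                  int i = A[a];
                  size_t b0 = (oc == sc) ? a + 1 : 0;
                  for (size_t b = b0; b < B.size(); ++b) {
                    int j = B[b];
                    if (skip_frozen_pairs && frozen[i] && frozen[j]) continue;
                    double rm = rmax_pair[cat[i]][cat[j]] + skin;
                    double ddx = x[i] - x[j], ddy = y[i] - y[j],
                           ddz = z[i] - z[j];
                    if (ddx * ddx + ddy * ddy + ddz * ddz < rm * rm) {
                      ni.push_back(i);
                      nj.push_back(j);
                    }
                  }
                }
              }
        }
    x0 = x; y0 = y; z0 = z;
  }

  bool needs_rebuild() const {
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - x0[i], dy = y[i] - y0[i], dz = z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  // shifted contact weight and its radial derivative
  inline double fs(double r, double* d) const {
    double t = std::tanh(p.eta * (p.rc - r));
    *d = -0.5 * p.eta * (1.0 - t * t);
    return 0.5 * (1.0 + t) - p.fcut;
  }

  inline double alpha_pair(int i, int j) const {
    double a;
    if (chain[i] == chain[j]) {
      int s = std::abs(hapbin[i] - hapbin[j]);  // same chain => same chrom
      int S = (int)p.alpha_ideal.size();
      if (s < 1) s = 1;
      if (s > S) s = S;
      a = p.alpha_ideal[s - 1] + p.comp[label[i] * 3 + label[j]];
    } else {
      a = p.comp[label[i] * 3 + label[j]] +
          p.chrom[hapchrom[i] * p.nhap + hapchrom[j]];
    }
    return a;
  }

  // capped 12-6 LJ, truncated-shifted at rcut; attractive (full) form
  inline double lj_full(double r, double eps, double rcut, double* dudr) const {
    double rr = std::max(r, p.lj_rcap);
    double s = p.lj_sigma / rr, s3 = s * s * s, s6 = s3 * s3, s12 = s6 * s6;
    double sc = p.lj_sigma / rcut, sc3 = sc * sc * sc, sc6 = sc3 * sc3;
    double ushift = 4.0 * eps * (sc6 * sc6 - sc6);
    double u = 4.0 * eps * (s12 - s6) - ushift;
    double du = -4.0 * eps * (12.0 * s12 - 6.0 * s6) / rr;
    if (r < p.lj_rcap) {  // linear continuation: finite force at overlap
      u += du * (r - p.lj_rcap);
    }
    *dudr = du;
    return u;
  }

  // purely repulsive branch (WCA): truncated-shifted at the LJ minimum
  inline double lj_wca(double r, double eps, double* dudr) const {
    double rmin = std::pow(2.0, 1.0 / 6.0) * p.lj_sigma;
    if (r >= rmin) { *dudr = 0.0; return 0.0; }
    double u = lj_full(r, eps, rmin, dudr);
    return u;
  }

  // soft-core excluded volume: bounded height, finite force at r = 0
  inline double softcore(double r, double d, double* dudr) const {
    if (r >= d) { *dudr = 0.0; return 0.0; }
    double q = 1.0 - r / d;
    *dudr = -2.0 * p.ev_strength * q / d;
    return p.ev_strength * q * q;
  }

  // energy and dU/dr of the non-bonded pair (i, j) at distance r
  double pair_energy(int i, int j, double r, double* dudr, double* comps) {
    int a = cat[i], b = cat[j];
    if (a > b) { std::swap(i, j); std::swap(a, b); }
    double u = 0.0, du = 0.0, d1;
    bool isbonded = bonded.count(key(i, j)) > 0;
    if (a == CAT_CHR && b == CAT_CHR) {
      if (!isbonded) {
        double uev = softcore(r, 0.5 * (p.diam[a] + p.diam[b]), &d1);
        u += uev; du += d1;
        if (comps) comps[C_EV] += uev;
      }
      if (p.couplings_active && r < p.ccut) {
        double al = alpha_pair(i, j);
        if (al != 0.0) {
          double f = fs(r, &d1);
          u += al * f; du += al * d1;
          if (comps) comps[C_CONTACT] += al * f;
        }
      }
      *dudr = du;
      return u;
    }
    if (a == CAT_CHR) {  // chromatin - landmark
      if (!isbonded) {
        double uev = softcore(r, 0.5 * (p.diam[a] + p.diam[b]), &d1);
        u += uev; du += d1;
        if (comps) comps[C_EV] += uev;
      }
      double chi = 0.0;
      if (b == CAT_LAM && p.lam_active) chi = p.chi_lam[hapbin[i]];
      else if (b == CAT_NUC && p.nuc_active) chi = p.chi_nuc[hapbin[i]];
      else if (b == CAT_SPK && p.spk_active && spk_state[j] == 1)
        chi = p.chi_spk[hapbin[i]];
      if (chi != 0.0 && r < p.ccut) {
        double f = fs(r, &d1);
        u += chi * f; du += chi * d1;
        if (comps) comps[C_LANDMARK] += chi * f;
      }
      *dudr = du;
      return u;
    }
    // body-body and lamina pairs
    if ((a == CAT_NUC && b == CAT_NUC)) {
      double ulj = (r < p.lj_cut) ? lj_full(r, p.eps_nuc, p.lj_cut, &d1)
                                  : (d1 = 0.0, 0.0);
      u += ulj; du += d1;
      if (comps) comps[C_LJ] += ulj;
    } else if (a == CAT_SPK && b == CAT_SPK) {
      if (spk_state[i] == 1 && spk_state[j] == 1) {
        double ulj = (r < p.lj_cut) ? lj_full(r, p.eps_spk, p.lj_cut, &d1)
                                    : (d1 = 0.0, 0.0);
        u += ulj; du += d1;
        if (comps) comps[C_LJ] += ulj;
      } else {
        double ulj = lj_wca(r, p.eps_rep, &d1);
        u += ulj; du += d1;
        if (comps) comps[C_LJ] += ulj;
      }
    } else if (a == CAT_NUC && b == CAT_SPK) {
      double ulj = lj_wca(r, p.eps_rep, &d1);
      u += ulj; du += d1;
      if (comps) comps[C_LJ] += ulj;
    } else {  // any pair involving lamina (non-chromatin): excluded volume
      if (!isbonded) {
        double uev = softcore(r, 0.5 * (p.diam[a] + p.diam[b]), &d1);
        u += uev; du += d1;
        if (comps) comps[C_EV] += uev;
      }
    }
    *dudr = du;
    return u;
  }

  // full force/energy evaluation over the neighbour list + bonds + one-body
  double compute_forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int c = 0; c < NCOMP; ++c) ecomp[c] = 0.0;
    double e = 0.0;
    // bonds
    for (size_t b = 0; b < bi.size(); ++b) {
      int i = bi[b], j = bj[b];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double u = 0.5 * bk[b] * (r - br0[b]) * (r - br0[b]);
      double dudr = bk[b] * (r - br0[b]);
      e += u;
      ecomp[C_BOND] += u;
      if (r > 1e-12) {
        double g = -dudr / r;
        fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
        fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
      }
    }
    // non-bonded
    for (size_t k = 0; k < ni.size(); ++k) {
      int i = ni[k], j = nj[k];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      double rm = rmax_pair[cat[i]][cat[j]];
      if (r2 >= rm * rm) continue;
      double r = std::sqrt(r2);
      double dudr;
      double u = pair_energy(i, j, r, &dudr, ecomp);
      e += u;
      if (r > 1e-12 && dudr != 0.0) {
        double g = -dudr / r;
        fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
        fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
      }
    }
    // confinement (non-lamina) and z-compression (lamina)
    for (int i = 0; i < n; ++i) {
      if (p.conf_k > 0.0 && cat[i] != CAT_LAM) {
        double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
        if (r > p.conf_R) {
          double d = r - p.conf_R;
          double u = p.conf_k * d * d;
          e += u;
          ecomp[C_CONFINE] += u;
          double g = -2.0 * p.conf_k * d / r;
          fx[i] += g * x[i]; fy[i] += g * y[i]; fz[i] += g * z[i];
        }
      }
      if (p.defo_k > 0.0 && cat[i] == CAT_LAM) {
        double u = 0.5 * p.defo_k * z[i] * z[i];
        e += u;
        ecomp[C_DEFORM] += u;
        fz[i] -= p.defo_k * z[i];
      }
    }
    return e;
  }

  // energy change of flipping the state of speckle particle idx
  double flip_delta(int idx) {
    int old_s = spk_state[idx], new_s = 1 - old_s;
    double de = 0.0, d1;
    for (int j = 0; j < n; ++j) {
      if (j == idx) continue;
      int cj = cat[j];
      if (cj != CAT_SPK && !(cj == CAT_CHR && p.spk_active)) continue;
      double dx = x[idx] - x[j], dy = y[idx] - y[j], dz = z[idx] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (cj == CAT_SPK) {
        if (r2 >= p.lj_cut * p.lj_cut) continue;
        double r = std::sqrt(r2);
        double uold, unew;
        if (old_s == 1 && spk_state[j] == 1)
          uold = (r < p.lj_cut) ? lj_full(r, p.eps_spk, p.lj_cut, &d1) : 0.0;
        else
          uold = lj_wca(r, p.eps_rep, &d1);
        if (new_s == 1 && spk_state[j] == 1)
          unew = (r < p.lj_cut) ? lj_full(r, p.eps_spk, p.lj_cut, &d1) : 0.0;
        else
          unew = lj_wca(r, p.eps_rep, &d1);
        de += unew - uold;
      } else {  // chromatin bead with speckle coupling (dP only)
        if (r2 >= p.ccut * p.ccut) continue;
        double chi = p.chi_spk[hapbin[j]];
        if (chi == 0.0) continue;
        double r = std::sqrt(r2);
        double f = fs(r, &d1);
        de += chi * f * ((new_s == 1 ? 1.0 : 0.0) - (old_s == 1 ? 1.0 : 0.0));
      }
    }
    return de;
  }

  // one semi-grand sweep: n_attempts attempts, proposal probability prob,
  // optional Metropolis acceptance at temperature T
  int sweep(RNG& rng, int n_attempts, double prob, bool metropolis, double T,
            const std::vector<int>& spk_idx) {
    int flips = 0;
    int nspk = (int)spk_idx.size();
    if (nspk == 0) return 0;
    for (int a = 0; a < n_attempts; ++a) {
      int idx = spk_idx[rng.unif_int(nspk)];
      if (rng.unif() >= prob) continue;
      bool accept = true;
      if (metropolis) {
        double de = flip_delta(idx);
        if (de > 0.0 && rng.unif() >= std::exp(-de / T)) accept = false;
      }
      if (accept) {
        spk_state[idx] = 1 - spk_state[idx];
        ++flips;
      }
    }
    return flips;
  }
};

static Params parse_params(List pl) {
  Params p;
  p.rc = as<double>(pl["r_c"]);
  p.eta = as<double>(pl["eta"]);
  p.ccut = as<double>(pl["cutoff"]);
  p.fcut = 0.5 * (1.0 + std::tanh(p.eta * (p.rc - p.ccut)));
  p.ev_strength = as<double>(pl["ev_strength"]);
  NumericVector dm = pl["diameters"];
  for (int i = 0; i < 4; ++i) p.diam[i] = dm[i];
  NumericVector ai = pl["alpha_ideal"];
  p.alpha_ideal.assign(ai.begin(), ai.end());
  NumericMatrix cm = pl["compartment"];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) p.comp[i * 3 + j] = cm(i, j);
  NumericMatrix ch = pl["chrom_pair"];
  p.nhap = ch.nrow();
  p.chrom.resize((size_t)p.nhap * p.nhap);
  for (int i = 0; i < p.nhap; ++i)
    for (int j = 0; j < p.nhap; ++j) p.chrom[i * p.nhap + j] = ch(i, j);
  NumericVector cl = pl["chi_lamina"], cs = pl["chi_speckle"],
                cn = pl["chi_nucleolus"];
  p.chi_lam.assign(cl.begin(), cl.end());
  p.chi_spk.assign(cs.begin(), cs.end());
  p.chi_nuc.assign(cn.begin(), cn.end());
  p.lj_sigma = as<double>(pl["lj_sigma"]);
  p.lj_cut = as<double>(pl["lj_cutoff"]);
  p.lj_rcap = as<double>(pl["lj_rcap"]);
  p.eps_nuc = as<double>(pl["eps_nucleolus"]);
  p.eps_spk = as<double>(pl["eps_speckle"]);
  p.eps_rep = as<double>(pl["eps_repulsive"]);
  p.conf_k = as<double>(pl["confinement_k"]);
  p.conf_R = as<double>(pl["confinement_radius"]);
  p.defo_k = as<double>(pl["deformation_k"]);
  auto any_nz = [](const std::vector<double>& v) {
    for (double u : v)
      if (u != 0.0) return true;
    return false;
  };
  bool comp_nz = false;
  for (int i = 0; i < 9; ++i)
    if (p.comp[i] != 0.0) comp_nz = true;
  p.couplings_active = any_nz(p.alpha_ideal) || comp_nz || any_nz(p.chrom);
  p.lam_active = any_nz(p.chi_lam);
  p.spk_active = any_nz(p.chi_spk);
  p.nuc_active = any_nz(p.chi_nuc);
  return p;
}

static System make_system(NumericMatrix pos, IntegerVector cat,
                          IntegerVector chain, IntegerVector hapbin,
                          IntegerVector hapchrom, IntegerVector label,
                          IntegerVector spk_state, LogicalVector frozen,
                          IntegerMatrix bonds, NumericVector bond_r0,
                          NumericVector bond_k, List params) {
  System s;
  s.n = pos.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  s.cat.assign(cat.begin(), cat.end());
  s.chain.assign(chain.begin(), chain.end());
  s.hapbin.assign(hapbin.begin(), hapbin.end());
  s.hapchrom.assign(hapchrom.begin(), hapchrom.end());
  s.label.assign(label.begin(), label.end());
  s.spk_state.assign(spk_state.begin(), spk_state.end());
  s.frozen.resize(s.n);
  for (int i = 0; i < s.n; ++i) s.frozen[i] = frozen[i] ? 1 : 0;
  int nb = bonds.nrow();
  s.bi.resize(nb); s.bj.resize(nb);
  for (int b = 0; b < nb; ++b) {
    s.bi[b] = bonds(b, 0) - 1;
    s.bj[b] = bonds(b, 1) - 1;
    s.bonded.insert(s.key(s.bi[b], s.bj[b]));
  }
  s.br0.assign(bond_r0.begin(), bond_r0.end());
  s.bk.assign(bond_k.begin(), bond_k.end());
  s.p = parse_params(params);
  s.fx.resize(s.n); s.fy.resize(s.n); s.fz.resize(s.n);
  s.init_pair_cutoffs();
  return s;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, IntegerVector cat,
                       IntegerVector chain, IntegerVector hapbin,
                       IntegerVector hapchrom, IntegerVector label,
                       IntegerVector spk_state, LogicalVector frozen,
                       IntegerMatrix bonds, NumericVector bond_r0,
                       NumericVector bond_k, List params) {
  System s = make_system(pos, cat, chain, hapbin, hapchrom, label, spk_state,
                         frozen, bonds, bond_r0, bond_k, params);
  s.build_neighbors();
  double e = s.compute_forces();
  NumericMatrix forces(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    forces(i, 0) = s.fx[i]; forces(i, 1) = s.fy[i]; forces(i, 2) = s.fz[i];
  }
  NumericVector comps(NCOMP);
  comps.attr("names") = CharacterVector::create(
      "bond", "excluded_volume", "contact", "landmark", "lennard_jones",
      "confinement", "deformation");
  for (int c = 0; c < NCOMP; ++c) comps[c] = s.ecomp[c];
  return List::create(_["energy"] = e, _["components"] = comps,
                      _["forces"] = forces);
}

// [[Rcpp::export]]
List cpp_run_simulation(NumericMatrix pos, IntegerVector cat,
                        IntegerVector chain, IntegerVector hapbin,
                        IntegerVector hapchrom, IntegerVector label,
                        IntegerVector spk_state, LogicalVector frozen,
                        IntegerMatrix bonds, NumericVector bond_r0,
                        NumericVector bond_k, List params, int scheme,
                        double dt, double gamma_inv, double temperature,
                        int n_steps, int record_interval,
                        int reaction_interval, double reaction_prob,
                        bool do_reactions, bool metropolis, uint64_t seed,
                        std::string rng_state, NumericMatrix vel0,
                        bool have_vel, int step_offset, int rebuild_every) {
  System s = make_system(pos, cat, chain, hapbin, hapchrom, label, spk_state,
                         frozen, bonds, bond_r0, bond_k, params);
  s.skip_frozen_pairs = true;
  RNG rng(seed);
  if (rng_state.size() > 0) rng.set_state(rng_state);

  std::vector<int> spk_idx;
  for (int i = 0; i < s.n; ++i)
    if (s.cat[i] == CAT_SPK) spk_idx.push_back(i);
  int n_spk = (int)spk_idx.size();

  // velocities (Langevin only)
  std::vector<double> vx(s.n, 0.0), vy(s.n, 0.0), vz(s.n, 0.0);
  if (scheme == 0) {
    if (have_vel) {
      for (int i = 0; i < s.n; ++i) {
        vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
      }
    } else {
      double sdv = std::sqrt(temperature);
      for (int i = 0; i < s.n; ++i) {
        if (s.frozen[i]) continue;
        vx[i] = sdv * rng.normal();
        vy[i] = sdv * rng.normal();
        vz[i] = sdv * rng.normal();
      }
    }
  }
  double gamma = 1.0 / gamma_inv;
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(temperature * (1.0 - c1 * c1));
  double mob = gamma_inv;  // Brownian mobility (m = 1)
  double bsd = std::sqrt(2.0 * temperature * mob * dt);

  int n_frames = n_steps / record_interval + 1;
  NumericVector frames((size_t)n_frames * s.n * 3);
  frames.attr("dim") = IntegerVector::create(s.n, 3, n_frames);
  IntegerMatrix state_frames(n_frames, std::max(n_spk, 1));
  NumericVector frame_steps(n_frames), frame_energy(n_frames),
      frame_ktemp(n_frames);
  int n_unfrozen = 0;
  for (int i = 0; i < s.n; ++i)
    if (!s.frozen[i]) ++n_unfrozen;

  s.build_neighbors();
  double energy = s.compute_forces();
  int total_flips = 0, total_sweeps = 0;
  int rec = 0;
  std::string abort_msg = "";

  auto record = [&](int step) {
    size_t off = (size_t)rec * s.n * 3;
    for (int i = 0; i < s.n; ++i) {
      frames[off + i] = s.x[i];
      frames[off + s.n + i] = s.y[i];
      frames[off + 2 * (size_t)s.n + i] = s.z[i];
    }
    for (int k = 0; k < n_spk; ++k) state_frames(rec, k) = s.spk_state[spk_idx[k]];
    frame_steps[rec] = step;
    frame_energy[rec] = energy;
    double ke = 0.0;
    if (scheme == 0) {
      for (int i = 0; i < s.n; ++i)
        if (!s.frozen[i])
          ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      frame_ktemp[rec] = (n_unfrozen > 0) ? ke / (1.5 * n_unfrozen) : 0.0;
    } else {
      frame_ktemp[rec] = NA_REAL;
    }
    ++rec;
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    if (scheme == 0) {  // BAOAB Langevin
      for (int i = 0; i < s.n; ++i) {
        if (s.frozen[i]) continue;
        vx[i] += 0.5 * dt * s.fx[i];
        vy[i] += 0.5 * dt * s.fy[i];
        vz[i] += 0.5 * dt * s.fz[i];
        s.x[i] += 0.5 * dt * vx[i];
        s.y[i] += 0.5 * dt * vy[i];
        s.z[i] += 0.5 * dt * vz[i];
      }
      for (int i = 0; i < s.n; ++i) {
        if (s.frozen[i]) continue;
        vx[i] = c1 * vx[i] + c2 * rng.normal();
        vy[i] = c1 * vy[i] + c2 * rng.normal();
        vz[i] = c1 * vz[i] + c2 * rng.normal();
        s.x[i] += 0.5 * dt * vx[i];
        s.y[i] += 0.5 * dt * vy[i];
        s.z[i] += 0.5 * dt * vz[i];
      }
      if ((step_offset + step) % rebuild_every == 0 || s.needs_rebuild())
        s.build_neighbors();
      energy = s.compute_forces();
      for (int i = 0; i < s.n; ++i) {
        if (s.frozen[i]) continue;
        vx[i] += 0.5 * dt * s.fx[i];
        vy[i] += 0.5 * dt * s.fy[i];
        vz[i] += 0.5 * dt * s.fz[i];
      }
    } else {  // Euler-Maruyama Brownian
      for (int i = 0; i < s.n; ++i) {
        if (s.frozen[i]) continue;
        s.x[i] += mob * dt * s.fx[i] + bsd * rng.normal();
        s.y[i] += mob * dt * s.fy[i] + bsd * rng.normal();
        s.z[i] += mob * dt * s.fz[i] + bsd * rng.normal();
      }
      if ((step_offset + step) % rebuild_every == 0 || s.needs_rebuild())
        s.build_neighbors();
      energy = s.compute_forces();
    }

    if (do_reactions && reaction_interval > 0 && step % reaction_interval == 0 &&
        n_spk > 0) {
      total_flips += s.sweep(rng, n_spk, reaction_prob, metropolis,
                             temperature, spk_idx);
      ++total_sweeps;
      energy = s.compute_forces();  // states changed
    }

    if (step % record_interval == 0) {
      if (!std::isfinite(energy)) {
        int worst = 0;
        double wmax = -1.0;
        for (int i = 0; i < s.n; ++i) {
          double f2 = s.fx[i] * s.fx[i] + s.fy[i] * s.fy[i] + s.fz[i] * s.fz[i];
          if (!std::isfinite(f2) || f2 > wmax) {
            wmax = f2;
            worst = i;
          }
        }
        std::ostringstream os;
        os << "non-finite energy at step " << step << " (particle "
           << (worst + 1) << ")";
        abort_msg = os.str();
        break;
      }
      record(step);
    }
  }

  NumericMatrix final_pos(s.n, 3), final_vel(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    final_pos(i, 0) = s.x[i]; final_pos(i, 1) = s.y[i]; final_pos(i, 2) = s.z[i];
    final_vel(i, 0) = vx[i]; final_vel(i, 1) = vy[i]; final_vel(i, 2) = vz[i];
  }
  IntegerVector final_state(std::max(n_spk, 1));
  for (int k = 0; k < n_spk; ++k) final_state[k] = s.spk_state[spk_idx[k]];

  if (rec < n_frames) {  // aborted early: trim
    frame_steps = head(frame_steps, rec);
    frame_energy = head(frame_energy, rec);
    frame_ktemp = head(frame_ktemp, rec);
  }
  return List::create(
      _["frames"] = frames, _["n_recorded"] = rec,
      _["state_frames"] = state_frames, _["frame_steps"] = frame_steps,
      _["frame_energy"] = frame_energy, _["frame_ktemp"] = frame_ktemp,
      _["final_positions"] = final_pos, _["final_velocities"] = final_vel,
      _["final_state"] = final_state, _["rng_state"] = rng.state(),
      _["total_flips"] = total_flips, _["total_sweeps"] = total_sweeps,
      _["abort"] = abort_msg);
}

// [[Rcpp::export]]
List cpp_speckle_sweep(NumericMatrix pos, IntegerVector cat,
                       IntegerVector chain, IntegerVector hapbin,
                       IntegerVector hapchrom, IntegerVector label,
                       IntegerVector spk_state, LogicalVector frozen,
                       IntegerMatrix bonds, NumericVector bond_r0,
                       NumericVector bond_k, List params, int n_attempts,
                       double prob, bool metropolis, double temperature,
                       uint64_t seed, std::string rng_state) {
  System s = make_system(pos, cat, chain, hapbin, hapchrom, label, spk_state,
                         frozen, bonds, bond_r0, bond_k, params);
  RNG rng(seed);
  if (rng_state.size() > 0) rng.set_state(rng_state);
  std::vector<int> spk_idx;
  for (int i = 0; i < s.n; ++i)
    if (s.cat[i] == CAT_SPK) spk_idx.push_back(i);
  int flips = s.sweep(rng, n_attempts, prob, metropolis, temperature, spk_idx);
  IntegerVector out_state(s.n);
  for (int i = 0; i < s.n; ++i) out_state[i] = s.spk_state[i];
  return List::create(_["spk_state"] = out_state, _["n_flips"] = flips,
                      _["rng_state"] = rng.state());
}

// [[Rcpp::export]]
NumericMatrix cpp_minimize(NumericMatrix pos, IntegerVector cat,
                           IntegerVector chain, IntegerVector hapbin,
                           IntegerVector hapchrom, IntegerVector label,
                           IntegerVector spk_state, LogicalVector frozen,
                           IntegerMatrix bonds, NumericVector bond_r0,
                           NumericVector bond_k, List params, int n_steps,
                           double max_disp) {
  System s = make_system(pos, cat, chain, hapbin, hapchrom, label, spk_state,
                         frozen, bonds, bond_r0, bond_k, params);
  s.skip_frozen_pairs = true;
  s.build_neighbors();
  for (int it = 0; it < n_steps; ++it) {
    s.compute_forces();
    double fmax = 0.0;
    for (int i = 0; i < s.n; ++i) {
      if (s.frozen[i]) continue;
      double f2 = s.fx[i] * s.fx[i] + s.fy[i] * s.fy[i] + s.fz[i] * s.fz[i];
      if (f2 > fmax) fmax = f2;
    }
    fmax = std::sqrt(fmax);
    if (fmax < 1e-10) break;
    double h = std::min(1e-3, max_disp / fmax);
    for (int i = 0; i < s.n; ++i) {
      if (s.frozen[i]) continue;
      s.x[i] += h * s.fx[i];
      s.y[i] += h * s.fy[i];
      s.z[i] += h * s.fz[i];
    }
    if (s.needs_rebuild()) s.build_neighbors();
  }
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    out(i, 0) = s.x[i]; out(i, 1) = s.y[i]; out(i, 2) = s.z[i];
  }
  return out;
}
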