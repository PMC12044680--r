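// Desk-scale MD kernels: pair + bonded energies/forces, velocity-Verlet
// with Nose-Hoover chain thermostat and Berendsen pressure coupling,
// SHAKE/RATTLE constraints, Metropolis Monte Carlo, Widom insertion.
// Units: A, fs, amu, kcal/mol, e, K (LAMMPS "real" style).

#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static const double MVSQ2E = 2390.0573;    // amu*(A/fs)^2 -> kcal/mol
static const double KB     = 0.0019872041; // kcal/mol/K
static const double P2ATM  = 68568.415;    // kcal/mol/A^3 -> atm
static const double SQRTPI = 1.7724538509055160;

struct PairParams {
  int nkind;
  std::vector<double> eps, sig;            // nkind x nkind, row-major
  double cutoff;
  int elec;                                // 0 direct, 1 dsf, 2 rf
  double alpha;                            // dsf damping
  int ljtail;                              // 0 none, 1 shift, 2 force-shift
  double kc;                               // coulomb constant
};

struct Excl {
  std::unordered_map<long long, std::pair<double,double> > map; // (lj,coul) scales
  long long key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * 2000000LL + j;
  }
  bool get(int i, int j, double &lj, double &cl) const {
    auto it = map.find(key(i, j));
    if (it == map.end()) return false;
    lj = it->second.first; cl = it->second.second;
    return true;
  }
};

static inline void min_image(double *d, const double *box, const int *per) {
  for (int k = 0; k < 3; ++k)
    if (per[k]) d[k] -= box[k] * std::round(d[k] / box[k]);
}

// LJ energy and -dU/dr / r ("force over r") with tail handling
static inline void lj_eval(double r2, double eps, double sig, double rc,
                           int tail, double &e, double &f) {
  double sr2 = sig * sig / r2;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  e = 4.0 * eps * (sr12 - sr6);
  double r = std::sqrt(r2);
  f = 24.0 * eps * (2.0 * sr12 - sr6) / r;  // -dU/dr
  if (tail >= 1) {
    double src2 = sig * sig / (rc * rc);
    double src6 = src2 * src2 * src2;
    double src12 = src6 * src6;
    e -= 4.0 * eps * (src12 - src6);
    if (tail == 2) {
      // U_fs(r) = U(r) - U(rc) - (r - rc) U'(rc), with U'(rc) = -frc
      double frc = 24.0 * eps * (2.0 * src12 - src6) / rc;
      e += frc * (r - rc);
      f -= frc;
    }
  }
}

// coulomb energy and -dU/dr given qq = kc*qi*qj
static inline void coul_eval(double r, double qq, double rc, int elec,
                             double alpha, double &e, double &f) {
  if (elec == 0) {            // direct
    e = qq / r;
    f = qq / (r * r);
  } else if (elec == 1) {     // damped shifted force (Wolf/Fennell)
    double g_r  = std::erfc(alpha * r) / r;
    double d_r  = std::erfc(alpha * r) / (r * r) +
                  2.0 * alpha / SQRTPI * std::exp(-alpha * alpha * r * r) / r;
    double g_rc = std::erfc(alpha * rc) / rc;
    double d_rc = std::erfc(alpha * rc) / (rc * rc) +
                  2.0 * alpha / SQRTPI * std::exp(-alpha * alpha * rc * rc) / rc;
    e = qq * (g_r - g_rc + d_rc * (r - rc));
    f = qq * (d_r - d_rc);
  } else {                    // reaction field, conducting boundary
    double krf = 1.0 / (2.0 * rc * rc * rc);
    double crf = 1.0 / rc + krf * rc * rc;
    e = qq * (1.0 / r + krf * r * r - crf);
    f = qq * (1.0 / (r * r) - 2.0 * krf * r);
  }
}

struct Walls {
  std::vector<double> x0, eps, sig;
  std::vector<int> side;                   // +1: wall at low x, pushes +x
  std::vector< std::vector<int> > mask;    // per-wall 0/1 per site
};

struct Bonded {
  IntegerMatrix bonds;    NumericVector bk, br0;
  IntegerMatrix angles;   NumericVector ak, ath0;     // th0 radians
  IntegerMatrix diheds;   NumericMatrix dv;           // D x 4
  double kpref;                                       // 1.0 or 0.5
};

// full energy/force evaluation; forces accumulated into f, virial into W
static double eval_all(const NumericMatrix &pos, const NumericVector &charge,
                       const IntegerVector &kind, const PairParams &pp,
                       const Excl &excl, const double *box, const int *per,
                       const Bonded &bd, const Walls &wl,
                       NumericMatrix &f, double &W, NumericVector &brk) {
  int n = pos.nrow();
  double e_lj = 0, e_coul = 0, e_bond = 0, e_ang = 0, e_dih = 0, e_wall = 0;
  double rc = pp.cutoff, rc2 = rc * rc;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) f(i, k) = 0.0;
  W = 0.0;

  // nonbonded
  for (int i = 0; i < n - 1; ++i) {
    double qi = charge[i];
    int ki = kind[i];
    for (int j = i + 1; j < n; ++j) {
      double sl = 1.0, sc = 1.0;
      if (excl.get(i, j, sl, sc) && sl == 0.0 && sc == 0.0) continue;
      double d[3];
      for (int k = 0; k < 3; ++k) d[k] = pos(i, k) - pos(j, k);
      min_image(d, box, per);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 >= rc2) continue;
      if (r2 < 1e-12) stop("overlapping sites (pair %d,%d)", i + 1, j + 1);
      int kj = kind[j];
      double eps = pp.eps[ki * pp.nkind + kj];
      double sig = pp.sig[ki * pp.nkind + kj];
      double r = std::sqrt(r2);
      double e = 0, fr = 0;
      if (eps > 0.0) {
        double el, fl;
        lj_eval(r2, eps, sig, rc, pp.ljtail, el, fl);
        e += sl * el; fr += sl * fl;
        e_lj += sl * el;
      }
      double qq = pp.kc * qi * charge[j];
      if (qq != 0.0) {
        double ec, fc;
        coul_eval(r, qq, rc, pp.elec, pp.alpha, ec, fc);
        e += sc * ec; fr += sc * fc;
        e_coul += sc * ec;
      }
      double fror = fr / r;
      for (int k = 0; k < 3; ++k) {
        double fk = fror * d[k];
        f(i, k) += fk;
        f(j, k) -= fk;
      }
      W += fr * r;
    }
  }

  // bonds: E = kpref * k * (r - r0)^2
  for (int b = 0; b < bd.bonds.nrow(); ++b) {
    int i = bd.bonds(b, 0), j = bd.bonds(b, 1);
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = pos(i, k) - pos(j, k);
    min_image(d, box, per);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    double dr = r - bd.br0[b];
    e_bond += bd.kpref * bd.bk[b] * dr * dr;
    double fmag = -2.0 * bd.kpref * bd.bk[b] * dr;   // -dU/dr
    for (int k = 0; k < 3; ++k) {
      double fk = fmag * d[k] / r;
      f(i, k) += fk;
      f(j, k) -= fk;
    }
    W += fmag * r;
  }

  // angles: E = kpref * k * (theta - th0)^2
  for (int a = 0; a < bd.angles.nrow(); ++a) {
    int i = bd.angles(a, 0), j = bd.angles(a, 1), k3 = bd.angles(a, 2);
    double d1[3], d2[3];
    for (int k = 0; k < 3; ++k) { d1[k] = pos(i, k) - pos(j, k); d2[k] = pos(k3, k) - pos(j, k); }
    min_image(d1, box, per); min_image(d2, box, per);
    double r1 = std::sqrt(d1[0]*d1[0]+d1[1]*d1[1]+d1[2]*d1[2]);
    double r2n = std::sqrt(d2[0]*d2[0]+d2[1]*d2[1]+d2[2]*d2[2]);
    double c = (d1[0]*d2[0]+d1[1]*d2[1]+d1[2]*d2[2]) / (r1 * r2n);
    if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;
    double dth = th - bd.ath0[a];
    e_ang += bd.kpref * bd.ak[a] * dth * dth;
    double dEdth = 2.0 * bd.kpref * bd.ak[a] * dth;
    double coef = dEdth / s;   // dE/d(cos theta) * (-1) handled below
    for (int k = 0; k < 3; ++k) {
      double fi = coef * (d2[k] / (r1 * r2n) - c * d1[k] / (r1 * r1));
      double fk = coef * (d1[k] / (r1 * r2n) - c * d2[k] / (r2n * r2n));
      f(i, k) += fi;
      f(k3, k) += fk;
      f(j, k) -= (fi + fk);
      W += fi * d1[k] + fk * d2[k];
    }
  }

  // dihedrals, OPLS series
  for (int d0 = 0; d0 < bd.diheds.nrow(); ++d0) {
    int i = bd.diheds(d0, 0), j = bd.diheds(d0, 1), k3 = bd.diheds(d0, 2), l = bd.diheds(d0, 3);
    double b1[3], b2[3], b3[3];
    for (int k = 0; k < 3; ++k) {
      b1[k] = pos(j, k) - pos(i, k);
      b2[k] = pos(k3, k) - pos(j, k);
      b3[k] = pos(l, k) - pos(k3, k);
    }
    min_image(b1, box, per); min_image(b2, box, per); min_image(b3, box, per);
    double m[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2], b1[0]*b2[1]-b1[1]*b2[0] };
    double nn[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2], b2[0]*b3[1]-b2[1]*b3[0] };
    double m2 = m[0]*m[0]+m[1]*m[1]+m[2]*m[2];
    double n2 = nn[0]*nn[0]+nn[1]*nn[1]+nn[2]*nn[2];
    double b2n = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (m2 < 1e-12 || n2 < 1e-12) continue;   // collinear, torsion undefined
    double x = m[0]*nn[0]+m[1]*nn[1]+m[2]*nn[2];
    double y = (m[1]*nn[2]-m[2]*nn[1])*b2[0]/b2n +
               (m[2]*nn[0]-m[0]*nn[2])*b2[1]/b2n +
               (m[0]*nn[1]-m[1]*nn[0])*b2[2]/b2n;
    double phi = std::atan2(y, x);
    double v1 = bd.dv(d0, 0), v2 = bd.dv(d0, 1), v3 = bd.dv(d0, 2), v4 = bd.dv(d0, 3);
    e_dih += 0.5 * (v1 * (1 + std::cos(phi)) + v2 * (1 - std::cos(2*phi)) +
                    v3 * (1 + std::cos(3*phi)) + v4 * (1 - std::cos(4*phi)));
    double dEdphi = 0.5 * (-v1 * std::sin(phi) + 2*v2 * std::sin(2*phi)
                           - 3*v3 * std::sin(3*phi) + 4*v4 * std::sin(4*phi));
    // dphi/dr_i = -|b2|/|m|^2 m, dphi/dr_l = +|b2|/|n|^2 n; F = -dE/dphi * dphi/dr
    double fi[3], fl[3];
    for (int k = 0; k < 3; ++k) {
      fi[k] =  dEdphi * b2n / m2 * m[k];
      fl[k] = -dEdphi * b2n / n2 * nn[k];
    }
    double p = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (b2n * b2n);
    double q = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (b2n * b2n);
    for (int k = 0; k < 3; ++k) {
      double sv = p * fi[k] - q * fl[k];
      double fj = -fi[k] - sv, fk = -fl[k] + sv;
      f(i, k)  += fi[k];
      f(j, k)  += fj;
      f(k3, k) += fk;
      f(l, k)  += fl[k];
      // atomic virial (term is translation-invariant)
      W += fi[k]*pos(i,k) + fj*pos(j,k) + fk*pos(k3,k) + fl[k]*pos(l,k);
    }
  }

  // walls: WCA repulsion on |x - x0|, masked by species
  for (size_t w = 0; w < wl.x0.size(); ++w) {
    double wc = std::pow(2.0, 1.0/6.0) * wl.sig[w];
    for (int i = 0; i < n; ++i) {
      if (!wl.mask[w][i]) continue;
      double dx = (pos(i, 0) - wl.x0[w]) * wl.side[w];  // distance into box
      if (dx >= wc || dx <= 0) {
        if (dx <= 0) { // site beyond the wall plane: strong push back
          double fmag = 500.0 * (1.0 - dx);
          e_wall += 500.0 * (0.5 - dx);
          f(i, 0) += fmag * wl.side[w];
        }
        continue;
      }
      double sr2 = wl.sig[w]*wl.sig[w]/(dx*dx);
      double sr6 = sr2*sr2*sr2;
      e_wall += 4.0 * wl.eps[w] * (sr6*sr6 - sr6) + wl.eps[w];
      double fmag = 24.0 * wl.eps[w] * (2.0*sr6*sr6 - sr6) / dx;  // -dU/d(dx) > 0
      f(i, 0) += fmag * wl.side[w];
    }
  }

  brk[0] = e_bond; brk[1] = e_ang; brk[2] = e_dih;
  brk[3] = e_lj;   brk[4] = e_coul; brk[5] = e_wall;
  return e_bond + e_ang + e_dih + e_lj + e_coul + e_wall;
}

static PairParams unpack_pp(List ffd) {
  PairParams pp;
  NumericMatrix em = ffd["epsmat"], sm = ffd["sigmat"];
  pp.nkind = em.nrow();
  pp.eps.assign(pp.nkind * pp.nkind, 0.0);
  pp.sig.assign(pp.nkind * pp.nkind, 0.0);
  for (int i = 0; i < pp.nkind; ++i)
    for (int j = 0; j < pp.nkind; ++j) {
      pp.eps[i * pp.nkind + j] = em(i, j);
      pp.sig[i * pp.nkind + j] = sm(i, j);
    }
  pp.cutoff = as<double>(ffd["cutoff"]);
  pp.elec = as<int>(ffd["elec"]);
  pp.alpha = as<double>(ffd["alpha"]);
  pp.ljtail = as<int>(ffd["ljtail"]);
  pp.kc = as<double>(ffd["kc"]);
  return pp;
}

static Excl unpack_excl(List ffd) {
  Excl ex;
  IntegerMatrix em = ffd["excl_pairs"];
  NumericVector ls = ffd["excl_lj"], cs = ffd["excl_coul"];
  for (int p = 0; p < em.nrow(); ++p)
    ex.map[ex.key(em(p, 0), em(p, 1))] = std::make_pair(ls[p], cs[p]);
  return ex;
}

static Bonded unpack_bonded(List ffd) {
  Bonded bd;
  bd.bonds = as<IntegerMatrix>(ffd["bonds"]);
  bd.bk = as<NumericVector>(ffd["bond_k"]);
  bd.br0 = as<NumericVector>(ffd["bond_r0"]);
  bd.angles = as<IntegerMatrix>(ffd["angles"]);
  bd.ak = as<NumericVector>(ffd["angle_k"]);
  bd.ath0 = as<NumericVector>(ffd["angle_th0"]);
  bd.diheds = as<IntegerMatrix>(ffd["diheds"]);
  bd.dv = as<NumericMatrix>(ffd["dihed_v"]);
  bd.kpref = as<double>(ffd["kpref"]);
  return bd;
}

static Walls unpack_walls(List ffd, int n) {
  Walls wl;
  List walls = ffd["walls"];
  for (int w = 0; w < walls.size(); ++w) {
    List one = walls[w];
    wl.x0.push_back(as<double>(one["x0"]));
    wl.eps.push_back(as<double>(one["epsilon"]));
    wl.sig.push_back(as<double>(one["sigma"]));
    wl.side.push_back(as<int>(one["side"]));
    IntegerVector m = one["mask"];
    std::vector<int> mv(n);
    for (int i = 0; i < n; ++i) mv[i] = m[i];
    wl.mask.push_back(mv);
  }
  return wl;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector charge,
                       IntegerVector kind, List ffd,
                       NumericVector box, IntegerVector periodic) {
  PairParams pp = unpack_pp(ffd);
  Excl ex = unpack_excl(ffd);
  Bonded bd = unpack_bonded(ffd);
  Walls wl = unpack_walls(ffd, pos.nrow());
  double bx[3] = { box[0], box[1], box[2] };
  int per[3] = { periodic[0], periodic[1], periodic[2] };
  NumericMatrix f(pos.nrow(), 3);
  NumericVector brk(6);
  double W = 0;
  double e = eval_all(pos, charge, kind, pp, ex, bx, per, bd, wl, f, W, brk);
  brk.names() = CharacterVector::create("bond", "angle", "dihedral",
                                        "lj", "coulomb", "wall");
  return List::create(_["energy"] = e, _["forces"] = f,
                      _["breakdown"] = brk, _["virial"] = W);
}

// ---- SHAKE / RATTLE ---------------------------------------------------

static void shake_pos(NumericMatrix &pos, const NumericMatrix &pos_ref,
                      const NumericVector &mass, const IntegerMatrix &cons,
                      const NumericVector &cd, double tol, int maxit,
                      const double *box, const int *per) {
  int nc = cons.nrow();
  if (!nc) return;
  for (int it = 0; it < maxit; ++it) {
    double maxdev = 0.0;
    for (int c = 0; c < nc; ++c) {
      int i = cons(c, 0), j = cons(c, 1);
      double d[3], dref[3];
      for (int k = 0; k < 3; ++k) {
        d[k] = pos(i, k) - pos(j, k);
        dref[k] = pos_ref(i, k) - pos_ref(j, k);
      }
      min_image(d, box, per); min_image(dref, box, per);
      double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
      double d2 = cd[c] * cd[c];
      double diff = r2 - d2;
      double dev = std::fabs(diff) / d2;
      if (dev > maxdev) maxdev = dev;
      if (dev <= tol) continue;
      double rr = d[0]*dref[0]+d[1]*dref[1]+d[2]*dref[2];
      double mi = 1.0 / mass[i], mj = 1.0 / mass[j];
      double g = diff / (2.0 * rr * (mi + mj));
      for (int k = 0; k < 3; ++k) {
        pos(i, k) -= g * mi * dref[k];
        pos(j, k) += g * mj * dref[k];
      }
    }
    if (maxdev <= tol) return;
  }
  stop("SHAKE failed to converge within max iterations");
}

static void rattle_vel(const NumericMatrix &pos, NumericMatrix &vel,
                       const NumericVector &mass, const IntegerMatrix &cons,
                       double tol, int maxit, const double *box, const int *per) {
  int nc = cons.nrow();
  if (!nc) return;
  for (int it = 0; it < maxit; ++it) {
    double maxdev = 0.0;
    for (int c = 0; c < nc; ++c) {
      int i = cons(c, 0), j = cons(c, 1);
      double d[3], dv[3];
      for (int k = 0; k < 3; ++k) {
        d[k] = pos(i, k) - pos(j, k);
        dv[k] = vel(i, k) - vel(j, k);
      }
      min_image(d, box, per);
      double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
      double rv = d[0]*dv[0]+d[1]*dv[1]+d[2]*dv[2];
      double mi = 1.0 / mass[i], mj = 1.0 / mass[j];
      double kfac = rv / (r2 * (mi + mj));
      double dev = std::fabs(rv) / r2;   // 1/fs scale
      if (dev > maxdev) maxdev = dev;
      if (dev <= tol) continue;
      for (int k = 0; k < 3; ++k) {
        vel(i, k) -= kfac * mi * d[k];
        vel(j, k) += kfac * mj * d[k];
      }
    }
    if (maxdev <= tol) return;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_shake(NumericMatrix pos, NumericMatrix pos_ref,
                        NumericVector mass, IntegerMatrix cons,
                        NumericVector cd, double tol, int maxit,
                        NumericVector box, IntegerVector periodic) {
  NumericMatrix p = clone(pos);
  double bx[3] = { box[0], box[1], box[2] };
  int per[3] = { periodic[0], periodic[1], periodic[2] };
  shake_pos(p, pos_ref, mass, cons, cd, tol, maxit, bx, per);
  return p;
}

// ---- Nose-Hoover chain ------------------------------------------------

struct NHC {
  static const int M = 3;
  double xi[3], vxi[3], Q[3];
  double kT, Nf;
  void init(double T, double tau, double Nf_) {
    kT = KB * T; Nf = Nf_;
    Q[0] = Nf * kT * tau * tau;
    for (int i = 1; i < M; ++i) Q[i] = kT * tau * tau;
    for (int i = 0; i < M; ++i) { xi[i] = 0; vxi[i] = 0; }
  }
  double step(double ke2, double dt) {   // ke2 = sum m v^2 in kcal/mol
    double dt2 = dt / 2, dt4 = dt / 4, dt8 = dt / 8;
    double G[3];
    G[0] = (ke2 - Nf * kT) / Q[0];
    for (int i = 1; i < M; ++i) G[i] = (Q[i-1]*vxi[i-1]*vxi[i-1] - kT) / Q[i];
    vxi[M-1] += G[M-1] * dt4;
    for (int i = M - 2; i >= 0; --i) {
      double e = std::exp(-dt8 * vxi[i+1]);
      vxi[i] = (vxi[i] * e + G[i] * dt4) * e;
    }
    double s = std::exp(-dt2 * vxi[0]);
    ke2 *= s * s;
    for (int i = 0; i < M; ++i) xi[i] += dt2 * vxi[i];
    G[0] = (ke2 - Nf * kT) / Q[0];
    for (int i = 0; i < M - 1; ++i) {
      double e = std::exp(-dt8 * vxi[i+1]);
      vxi[i] = (vxi[i] * e + G[i] * dt4) * e;
      G[i+1] = (Q[i]*vxi[i]*vxi[i] - kT) / Q[i+1];
    }
    vxi[M-1] += G[M-1] * dt4;
    return s;
  }
};

// ---- MD driver --------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                NumericVector charge, IntegerVector kind, List ffd,
                NumericVector box0, IntegerVector periodic,
                IntegerMatrix cons, NumericVector consd,
                List cfg) {
  int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  NumericVector box = clone(box0);
  PairParams pp = unpack_pp(ffd);
  Excl ex = unpack_excl(ffd);
  Bonded bd = unpack_bonded(ffd);
  Walls wl = unpack_walls(ffd, n);
  int per[3] = { periodic[0], periodic[1], periodic[2] };
  double bx[3] = { box[0], box[1], box[2] };

  double dt = as<double>(cfg["dt"]);
  int n_steps = as<int>(cfg["n_steps"]);
  int stride = as<int>(cfg["stride"]);
  int ensemble = as<int>(cfg["ensemble"]);   // 0 NVE, 1 NVT, 2 NPT
  int thermo = as<int>(cfg["thermostat"]);   // 0 NH chain, 1 Langevin
  double T0 = as<double>(cfg["T_target"]);
  double tauT = as<double>(cfg["tau_t"]);
  double P0 = as<double>(cfg["P_target"]);
  double tauP = as<double>(cfg["tau_p"]);
  double Nf = as<double>(cfg["dof"]);
  double shake_tol = as<double>(cfg["shake_tol"]);
  int shake_maxit = as<int>(cfg["shake_maxit"]);
  double gamma = as<double>(cfg["langevin_gamma"]); // 1/fs
  double compr = 4.57e-5; // 1/atm, weak-coupling compressibility
  IntegerVector frozen = cfg["frozen"];

  NHC nhc;
  if (ensemble >= 1 && thermo == 0) nhc.init(T0, tauT, Nf);

  NumericMatrix f(n, 3);
  NumericVector brk(6);
  double W = 0;
  double epot = eval_all(pos, charge, kind, pp, ex, bx, per, bd, wl, f, W, brk);

  int nrec = n_steps / stride + 1;
  List frames(nrec);
  NumericVector rec_t(nrec), rec_T(nrec), rec_E(nrec), rec_K(nrec),
                rec_step(nrec), rec_P(nrec);
  NumericMatrix rec_box(nrec, 3);
  int irec = 0;

  auto ke2_of = [&]() {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int k = 0; k < 3; ++k) s += mass[i] * vel(i, k) * vel(i, k);
    }
    return s * MVSQ2E;
  };
  auto record = [&](int step) {
    double ke2 = ke2_of();
    rec_step[irec] = step;
    rec_t[irec] = step * dt;
    rec_T[irec] = ke2 / (Nf * KB);
    rec_E[irec] = epot;
    rec_K[irec] = 0.5 * ke2;
    double V = bx[0] * bx[1] * bx[2];
    rec_P[irec] = (ke2 + W) / (3.0 * V) * P2ATM;
    for (int k = 0; k < 3; ++k) rec_box(irec, k) = bx[k];
    frames[irec] = clone(pos);
    ++irec;
  };
  record(0);

  NumericMatrix pos_ref(n, 3);
  for (int step = 1; step <= n_steps; ++step) {
    if (ensemble >= 1 && thermo == 0) {
      double s = nhc.step(ke2_of(), dt);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) vel(i, k) *= s;
    }
    // half kick
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      double im = dt * 0.5 / (mass[i] * MVSQ2E);
      for (int k = 0; k < 3; ++k) {
        if (!std::isfinite(f(i, k)))
          stop("non-finite force on site %d at step %d", i + 1, step);
        vel(i, k) += im * f(i, k);
      }
    }
    // drift (+ SHAKE)
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 3; ++k) pos_ref(i, k) = pos(i, k);
      if (frozen[i]) continue;
      for (int k = 0; k < 3; ++k) pos(i, k) += dt * vel(i, k);
    }
    if (cons.nrow()) {
      shake_pos(pos, pos_ref, mass, cons, consd, shake_tol, shake_maxit, bx, per);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          vel(i, k) = (pos(i, k) - pos_ref(i, k)) / dt;
    }
    // Langevin O-step
    if (ensemble >= 1 && thermo == 1) {
      double c1 = std::exp(-gamma * dt);
      for (int i = 0; i < n; ++i) {
        if (frozen[i]) continue;
        double sd = std::sqrt(KB * T0 * (1.0 - c1 * c1) / (mass[i] * MVSQ2E));
        for (int k = 0; k < 3; ++k)
          vel(i, k) = c1 * vel(i, k) + sd * R::norm_rand();
      }
      if (cons.nrow()) rattle_vel(pos, vel, mass, cons, 1e-10, 100, bx, per);
    }
    // new forces
    epot = eval_all(pos, charge, kind, pp, ex, bx, per, bd, wl, f, W, brk);
    // half kick
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      double im = dt * 0.5 / (mass[i] * MVSQ2E);
      for (int k = 0; k < 3; ++k) vel(i, k) += im * f(i, k);
    }
    if (cons.nrow()) rattle_vel(pos, vel, mass, cons, 1e-10, 100, bx, per);
    if (ensemble >= 1 && thermo == 0) {
      double s = nhc.step(ke2_of(), dt);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) vel(i, k) *= s;
    }
    // weak-coupling barostat on periodic axes
    if (ensemble == 2) {
      double V = bx[0] * bx[1] * bx[2];
      double Pinst = (ke2_of() + W) / (3.0 * V) * P2ATM;
      double mu = std::cbrt(1.0 + compr * dt / tauP * (Pinst - P0));
      if (mu < 0.95) mu = 0.95;
      if (mu > 1.05) mu = 1.05;
      for (int k = 0; k < 3; ++k) {
        if (!per[k]) continue;
        bx[k] *= mu;
        for (int i = 0; i < n; ++i) pos(i, k) *= mu;
      }
      box[0] = bx[0]; box[1] = bx[1]; box[2] = bx[2];
    }
    double Tinst = ke2_of() / (Nf * KB);
    if (ensemble >= 1 && Tinst > 10.0 * T0)
      stop("thermostat divergence: T = %.1f K at step %d", Tinst, step);
    if (step % stride == 0) record(step);
  }

  return List::create(_["frames"] = frames, _["step"] = rec_step,
                      _["time"] = rec_t, _["T"] = rec_T,
                      _["epot"] = rec_E, _["ekin"] = rec_K,
                      _["P"] = rec_P, _["box"] = rec_box,
                      _["pos"] = pos, _["vel"] = vel,
                      _["box_final"] = box);
}

// ---- Monte Carlo (monatomic toy systems) ------------------------------

static double one_particle_energy(const NumericMatrix &pos, int i,
                                  const double *xi, const IntegerVector &kind,
                                  const PairParams &pp, const double *box,
                                  const int *per, const IntegerVector &inert) {
  int n = pos.nrow();
  double rc2 = pp.cutoff * pp.cutoff;
  double e = 0;
  int ki = kind[i];
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    if (inert[i] && inert[j]) continue;  // e.g. solute-solute ideal
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = xi[k] - pos(j, k);
    min_image(d, box, per);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    if (r2 >= rc2) continue;
    if (r2 < 1e-12) return 1e30;
    double eps = pp.eps[ki * pp.nkind + kind[j]];
    if (eps <= 0) continue;
    double el, fl;
    lj_eval(r2, eps, pp.sig[ki * pp.nkind + kind[j]], pp.cutoff, pp.ljtail, el, fl);
    e += el;
  }
  return e;
}

// Metropolis single-particle translations; movable mask; returns frames
// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix pos0, IntegerVector kind, List ffd,
                NumericVector box, IntegerVector periodic,
                IntegerVector movable, IntegerVector inert,
                double kT, double disp, int n_sweeps, int stride,
                double jump_prob) {
  NumericMatrix pos = clone(pos0);
  PairParams pp = unpack_pp(ffd);
  double bx[3] = { box[0], box[1], box[2] };
  int per[3] = { periodic[0], periodic[1], periodic[2] };
  int n = pos.nrow();
  std::vector<int> mov;
  for (int i = 0; i < n; ++i) if (movable[i]) mov.push_back(i);
  int nm = (int)mov.size();
  if (!nm) stop("no movable particles");
  long acc = 0, tot = 0;
  int nrec = n_sweeps / stride;
  List frames(nrec);
  int irec = 0;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int m = 0; m < nm; ++m) {
      int i = mov[(int)(unif_rand() * nm) % nm];
      double xold[3] = { pos(i, 0), pos(i, 1), pos(i, 2) };
      double xnew[3];
      if (jump_prob > 0.0 && unif_rand() < jump_prob) {
        // symmetric teleport move: uniform anywhere in the box
        for (int k = 0; k < 3; ++k) xnew[k] = unif_rand() * bx[k];
      } else {
        for (int k = 0; k < 3; ++k)
          xnew[k] = xold[k] + disp * (unif_rand() - 0.5) * 2.0;
      }
      // wrap periodic axes; reflect at non-periodic boundaries
      for (int k = 0; k < 3; ++k) {
        if (per[k]) {
          if (xnew[k] < 0) xnew[k] += bx[k];
          if (xnew[k] >= bx[k]) xnew[k] -= bx[k];
        } else {
          if (xnew[k] < 0) xnew[k] = -xnew[k];
          if (xnew[k] > bx[k]) xnew[k] = 2.0 * bx[k] - xnew[k];
          if (xnew[k] < 0 || xnew[k] > bx[k]) xnew[k] = xold[k];
        }
      }
      double eold = one_particle_energy(pos, i, xold, kind, pp, bx, per, inert);
      double enew = one_particle_energy(pos, i, xnew, kind, pp, bx, per, inert);
      ++tot;
      if (enew <= eold || unif_rand() < std::exp(-(enew - eold) / kT)) {
        for (int k = 0; k < 3; ++k) pos(i, k) = xnew[k];
        ++acc;
      }
    }
    if (sweep % stride == 0 && irec < nrec) frames[irec++] = clone(pos);
  }
  return List::create(_["frames"] = frames, _["pos"] = pos,
                      _["acceptance"] = (double)acc / (double)tot);
}

// Widom insertion: Boltzmann factors of ghost single-site insertions;
// insertion x is drawn uniformly in [xlo, xhi] (a phase interior)
// [[Rcpp::export]]
NumericVector cpp_widom(List frames, IntegerVector kind, List ffd,
                        NumericVector box, IntegerVector periodic,
                        int solute_kind, double kT, int n_insert_per_frame,
                        double xlo, double xhi) {
  PairParams pp = unpack_pp(ffd);
  double bx[3] = { box[0], box[1], box[2] };
  int per[3] = { periodic[0], periodic[1], periodic[2] };
  int nf = frames.size();
  NumericVector bf(nf * n_insert_per_frame);
  double rc2 = pp.cutoff * pp.cutoff;
  int idx = 0;
  for (int fidx = 0; fidx < nf; ++fidx) {
    NumericMatrix pos = frames[fidx];
    int n = pos.nrow();
    for (int ins = 0; ins < n_insert_per_frame; ++ins) {
      double x[3];
      x[0] = xlo + unif_rand() * (xhi - xlo);
      for (int k = 1; k < 3; ++k) x[k] = unif_rand() * bx[k];
      double e = 0;
      for (int j = 0; j < n; ++j) {
        double d[3];
        for (int k = 0; k < 3; ++k) d[k] = x[k] - pos(j, k);
        min_image(d, bx, per);
        double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
        if (r2 >= rc2) continue;
        double eps = pp.eps[solute_kind * pp.nkind + kind[j]];
        if (eps <= 0) continue;
        if (r2 < 1e-10) { e = 1e30; break; }
        double el, fl;
        lj_eval(r2, eps, pp.sig[solute_kind * pp.nkind + kind[j]],
                pp.cutoff, pp.ljtail, el, fl);
        e += el;
        if (e > 700.0 * kT) { e = 1e30; break; }
      }
      bf[idx++] = (e >= 1e29) ? 0.0 : std::exp(-e / kT);
    }
  }
  return bf;
}
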