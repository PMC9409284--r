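#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Reduced molecular-mechanics energy:
//   vdw      12-6 Lennard-Jones, Lorentz-Berthelot combining
//   coulomb  distance-dependent dielectric eps(r) = 4r  ->  kq1q2 / (4 r^2)
//   hbond    10-12 well between donor/acceptor heavy atoms (replaces LJ)
//   xbond    directional 10-12 well for C-X...A sigma-hole interactions
//   torsion  (V/2)(1 + cos(n phi - gamma))
//   angle    k (theta - theta0)^2     (elastic bond angles, e.g. proline)
//   restraint k |x - x0|^2            (positional, Cartesian)
// All energies kcal/mol, distances Angstrom.

static inline double dist2(const NumericMatrix &x, int i, int j) {
  double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
  return dx*dx + dy*dy + dz*dz;
}

static inline double lj(double r2, double eps, double sig) {
  double s2 = sig*sig/r2, s6 = s2*s2*s2;
  return 4.0*eps*(s6*s6 - s6);
}

static inline double well1012(double r, double r0, double d) {
  double t = r0/r, t2 = t*t, t10 = t2*t2*t2*t2*t2;
  return d*(5.0*t10*t2 - 6.0*t10);
}

static double dihedral(const NumericMatrix &x, int i, int j, int k, int l) {
  double b1[3], b2[3], b3[3];
  for (int c = 0; c < 3; ++c) {
    b1[c] = x(j,c)-x(i,c); b2[c] = x(k,c)-x(j,c); b3[c] = x(l,c)-x(k,c);
  }
  double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2], b1[0]*b2[1]-b1[1]*b2[0]};
  double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2], b2[0]*b3[1]-b2[1]*b3[0]};
  double m1[3];
  double b2n = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
  for (int c = 0; c < 3; ++c) m1[c] = (n1[(c+1)%3]*b2[(c+2)%3]-n1[(c+2)%3]*b2[(c+1)%3])/b2n;
  double xx = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
  double yy = m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2];
  return std::atan2(yy, xx);
}

struct PairParams {
  double cutoff2, kcoul, hb_r0, hb_d, xb_d, xb_cosmin, xb_pad;
};

struct HBCand { int i, j; double hb_e, lj_e; };

// energy of one nonbonded pair.  Donor/acceptor pairs are collected as
// hydrogen-bond candidates; greedy saturation (one bond per donor, one per
// acceptor, best-energy first) decides later which use the 10-12 well, the
// rest falling back to Lennard-Jones.
static inline void pair_energy(const NumericMatrix &xyz,
                               const NumericVector &eps, const NumericVector &sig,
                               const NumericVector &q, const LogicalVector &hbd,
                               const LogicalVector &hba, const PairParams &pp,
                               int i, int j, double &evdw, double &ecoul,
                               std::vector<HBCand> &cand) {
  double r2 = dist2(xyz, i, j);
  if (r2 > pp.cutoff2 || r2 < 1e-12) return;
  bool hb = (hbd[i] && hba[j]) || (hbd[j] && hba[i]);
  double e = std::sqrt(eps[i]*eps[j]);
  double lj_e = (e > 0) ? lj(r2, e, 0.5*(sig[i]+sig[j])) : 0.0;
  if (hb) {
    double hb_e = well1012(std::sqrt(r2), pp.hb_r0, pp.hb_d);
    HBCand c = {i, j, hb_e, lj_e};
    cand.push_back(c);
  } else evdw += lj_e;
  if (q[i] != 0 && q[j] != 0) ecoul += pp.kcoul*q[i]*q[j]/(4.0*r2);
}

// greedy donor/acceptor matching over the candidate list
static void settle_hbonds(std::vector<HBCand> &cand, const LogicalVector &hbd,
                          const LogicalVector &hba, int n, double &evdw,
                          double &ehb) {
  std::sort(cand.begin(), cand.end(),
            [](const HBCand &a, const HBCand &b) { return a.hb_e < b.hb_e; });
  std::vector<char> dused(n, 0), aused(n, 0);
  for (size_t c = 0; c < cand.size(); ++c) {
    int i = cand[c].i, j = cand[c].j;
    bool take = false;
    if (cand[c].hb_e < cand[c].lj_e) {
      if (hbd[i] && hba[j] && !dused[i] && !aused[j]) {
        dused[i] = 1; aused[j] = 1; take = true;
      } else if (hbd[j] && hba[i] && !dused[j] && !aused[i]) {
        dused[j] = 1; aused[i] = 1; take = true;
      }
    }
    if (take) ehb += cand[c].hb_e;
    else evdw += cand[c].lj_e;
  }
}

static inline double xbond_energy(const NumericMatrix &xyz, int ci, int xi, int ai,
                                  const NumericVector &rvdw, const PairParams &pp) {
  double r2 = dist2(xyz, xi, ai);
  if (r2 > pp.cutoff2) return 0.0;
  double r = std::sqrt(r2);
  // angle C-X...A at the halogen
  double vx[3], va[3];
  for (int c = 0; c < 3; ++c) {
    vx[c] = xyz(ci,c)-xyz(xi,c); va[c] = xyz(ai,c)-xyz(xi,c);
  }
  double nx = std::sqrt(vx[0]*vx[0]+vx[1]*vx[1]+vx[2]*vx[2]);
  double na = std::sqrt(va[0]*va[0]+va[1]*va[1]+va[2]*va[2]);
  double cth = (vx[0]*va[0]+vx[1]*va[1]+vx[2]*va[2])/(nx*na);
  if (cth > pp.xb_cosmin) return 0.0;  // sigma-hole directionality gate
  double u = (pp.xb_cosmin - cth)/(pp.xb_cosmin + 1.0);
  if (u > 1.0) u = 1.0;
  double r0 = rvdw[xi] + rvdw[ai] - pp.xb_pad;
  return u*u*well1012(r, r0, pp.xb_d);
}

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix xyz, NumericVector eps, NumericVector sig,
                         NumericVector q, LogicalVector hbd, LogicalVector hba,
                         IntegerMatrix excl, IntegerMatrix tor, NumericVector tor_n,
                         NumericVector tor_V, NumericVector tor_g, IntegerMatrix ang,
                         NumericVector ang_t0, NumericVector ang_k,
                         IntegerVector rst_idx, NumericMatrix rst_xyz, NumericVector rst_k,
                         IntegerMatrix xb, LogicalVector xacc, NumericVector rvdw,
                         double cutoff, double kcoul, double hb_r0, double hb_d,
                         double xb_d, double xb_cosmin, double xb_pad,
                         IntegerVector subset, int mode) {
  int n = xyz.nrow();
  PairParams pp = {cutoff*cutoff, kcoul, hb_r0, hb_d, xb_d, xb_cosmin, xb_pad};
  std::unordered_set<long long> ex;
  for (int p = 0; p < excl.nrow(); ++p) {
    long long i = excl(p,0)-1, j = excl(p,1)-1;
    if (i > j) std::swap(i, j);
    ex.insert(i*(long long)n + j);
  }
  std::vector<char> insub(n, 0);
  for (int p = 0; p < subset.size(); ++p) insub[subset[p]-1] = 1;
  auto excluded = [&](int i, int j) {
    long long a = i, b = j; if (a > b) std::swap(a, b);
    return ex.count(a*(long long)n + b) > 0;
  };
  double evdw = 0, ecoul = 0, ehb = 0, exbond = 0, etor = 0, eang = 0, erst = 0;
  std::vector<HBCand> cand;
  if (mode == 0) {
    for (int i = 0; i < n-1; ++i)
      for (int j = i+1; j < n; ++j) {
        if (excluded(i, j)) continue;
        pair_energy(xyz, eps, sig, q, hbd, hba, pp, i, j, evdw, ecoul, cand);
      }
  } else if (mode == 1) {  // terms touching the subset (subset-subset counted once)
    for (int i = 0; i < n; ++i) {
      if (!insub[i]) continue;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (insub[j] && j < i) continue;
        if (excluded(i, j)) continue;
        pair_energy(xyz, eps, sig, q, hbd, hba, pp, i, j, evdw, ecoul, cand);
      }
    }
  } else if (mode == 2) {  // strictly cross subset / non-subset
    for (int i = 0; i < n; ++i) {
      if (!insub[i]) continue;
      for (int j = 0; j < n; ++j) {
        if (insub[j]) continue;
        if (excluded(i, j)) continue;
        pair_energy(xyz, eps, sig, q, hbd, hba, pp, i, j, evdw, ecoul, cand);
      }
    }
  } else {  // mode 3: terms strictly within the subset (an isolated part)
    for (int i = 0; i < n-1; ++i) {
      if (!insub[i]) continue;
      for (int j = i+1; j < n; ++j) {
        if (!insub[j]) continue;
        if (excluded(i, j)) continue;
        pair_energy(xyz, eps, sig, q, hbd, hba, pp, i, j, evdw, ecoul, cand);
      }
    }
  }
  settle_hbonds(cand, hbd, hba, n, evdw, ehb);
  // halogen bonds: declared C-X donors against acceptor-flagged atoms
  for (int p = 0; p < xb.nrow(); ++p) {
    int ci = xb(p,0)-1, xi = xb(p,1)-1;
    for (int a = 0; a < n; ++a) {
      if (!xacc[a] || a == ci || a == xi) continue;
      if (excluded(xi, a)) continue;
      bool touch = insub[xi] || insub[a] || insub[ci];
      if (mode == 1 && !touch) continue;
      if (mode == 2 && !(insub[xi] != (bool)insub[a])) continue;
      if (mode == 3 && !(insub[xi] && insub[a] && insub[ci])) continue;
      exbond += xbond_energy(xyz, ci, xi, a, rvdw, pp);
    }
  }
  auto touches = [&](const int *at, int cnt) {
    if (mode == 0) return true;
    if (mode == 2) return false;
    if (mode == 3) {
      for (int c = 0; c < cnt; ++c) if (!insub[at[c]]) return false;
      return true;
    }
    for (int c = 0; c < cnt; ++c) if (insub[at[c]]) return true;
    return false;
  };
  for (int t = 0; t < tor.nrow(); ++t) {
    int at[4] = {tor(t,0)-1, tor(t,1)-1, tor(t,2)-1, tor(t,3)-1};
    if (!touches(at, 4)) continue;
    double phi = dihedral(xyz, at[0], at[1], at[2], at[3]);
    etor += 0.5*tor_V[t]*(1.0 + std::cos(tor_n[t]*phi - tor_g[t]));
  }
  for (int t = 0; t < ang.nrow(); ++t) {
    int at[3] = {ang(t,0)-1, ang(t,1)-1, ang(t,2)-1};
    if (!touches(at, 3)) continue;
    double v1[3], v2[3];
    for (int c = 0; c < 3; ++c) {
      v1[c] = xyz(at[0],c)-xyz(at[1],c); v2[c] = xyz(at[2],c)-xyz(at[1],c);
    }
    double n1 = std::sqrt(v1[0]*v1[0]+v1[1]*v1[1]+v1[2]*v1[2]);
    double n2 = std::sqrt(v2[0]*v2[0]+v2[1]*v2[1]+v2[2]*v2[2]);
    double th = std::acos(std::max(-1.0, std::min(1.0,
      (v1[0]*v2[0]+v1[1]*v2[1]+v1[2]*v2[2])/(n1*n2))));
    eang += ang_k[t]*(th - ang_t0[t])*(th - ang_t0[t]);
  }
  for (int p = 0; p < rst_idx.size(); ++p) {
    int i = rst_idx[p]-1;
    if ((mode == 1 || mode == 3) && !insub[i]) continue;
    if (mode == 2) continue;
    double dx = xyz(i,0)-rst_xyz(p,0), dy = xyz(i,1)-rst_xyz(p,1), dz = xyz(i,2)-rst_xyz(p,2);
    erst += rst_k[p]*(dx*dx + dy*dy + dz*dz);
  }
  NumericVector out = NumericVector::create(
    _["vdw"] = evdw, _["coulomb"] = ecoul, _["torsion"] = etor,
    _["hbond"] = ehb, _["xbond"] = exbond, _["angle"] = eang,
    _["restraint"] = erst,
    _["total"] = evdw + ecoul + etor + ehb + exbond + eang + erst);
  return out;
}

// ---------------------------------------------------------------------------
// Fast ligand pose refiner: cyclic line searches over rigid-body + torsion
// DOF with a small greedy Monte Carlo restart loop, all against a fixed
// receptor.  Uses R's RNG so results are reproducible under set.seed().

struct LigSystem {
  NumericMatrix lig;            // mutable ligand coords
  const NumericMatrix &rec;
  const NumericVector &leps, &lsig, &lq, &reps, &rsig, &rq, &lrv, &rrv;
  const LogicalVector &lhbd, &lhba, &rhbd, &rhba, &racc;
  const IntegerMatrix &lexcl, &ltor, &lxb;
  const NumericVector &ltn, &ltV, &ltg;
  PairParams pp;
  std::unordered_set<long long> ex;
  int m;

  LigSystem(NumericMatrix lig_, const NumericMatrix &rec_,
            const NumericVector &leps_, const NumericVector &lsig_, const NumericVector &lq_,
            const LogicalVector &lhbd_, const LogicalVector &lhba_,
            const IntegerMatrix &lexcl_, const IntegerMatrix &ltor_,
            const NumericVector &ltn_, const NumericVector &ltV_, const NumericVector &ltg_,
            const IntegerMatrix &lxb_, const NumericVector &lrv_,
            const NumericVector &reps_, const NumericVector &rsig_, const NumericVector &rq_,
            const LogicalVector &rhbd_, const LogicalVector &rhba_,
            const LogicalVector &racc_, const NumericVector &rrv_, PairParams pp_)
    : lig(lig_), rec(rec_), leps(leps_), lsig(lsig_), lq(lq_), reps(reps_),
      rsig(rsig_), rq(rq_), lrv(lrv_), rrv(rrv_), lhbd(lhbd_), lhba(lhba_),
      rhbd(rhbd_), rhba(rhba_), racc(racc_), lexcl(lexcl_), ltor(ltor_),
      lxb(lxb_), ltn(ltn_), ltV(ltV_), ltg(ltg_), pp(pp_) {
    m = lig.nrow();
    for (int p = 0; p < lexcl.nrow(); ++p) {
      long long i = lexcl(p,0)-1, j = lexcl(p,1)-1;
      if (i > j) std::swap(i, j);
      ex.insert(i*(long long)m + j);
    }
  }

  double cross() const {
    double e = 0;
    int nr = rec.nrow();
    // hydrogen-bond candidates with donor/acceptor saturation: slot ids are
    // ligand atoms [0,m) and receptor atoms [m, m+nr)
    std::vector<HBCand> cand;
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < nr; ++j) {
        double dx = lig(i,0)-rec(j,0), dy = lig(i,1)-rec(j,1), dz = lig(i,2)-rec(j,2);
        double r2 = dx*dx+dy*dy+dz*dz;
        if (r2 > pp.cutoff2 || r2 < 1e-12) continue;
        bool hb = (lhbd[i] && rhba[j]) || (rhbd[j] && lhba[i]);
        double ep = std::sqrt(leps[i]*reps[j]);
        double lj_e = (ep > 0) ? lj(r2, ep, 0.5*(lsig[i]+rsig[j])) : 0.0;
        if (hb) {
          HBCand c = {i, m + j, well1012(std::sqrt(r2), pp.hb_r0, pp.hb_d), lj_e};
          cand.push_back(c);
        } else e += lj_e;
        if (lq[i] != 0 && rq[j] != 0) e += pp.kcoul*lq[i]*rq[j]/(4.0*r2);
      }
    std::sort(cand.begin(), cand.end(),
              [](const HBCand &a, const HBCand &b) { return a.hb_e < b.hb_e; });
    std::vector<char> dused(m + rec.nrow(), 0), aused(m + rec.nrow(), 0);
    for (size_t c = 0; c < cand.size(); ++c) {
      int i = cand[c].i, j = cand[c].j - m;
      bool take = false;
      if (cand[c].hb_e < cand[c].lj_e) {
        if (lhbd[i] && rhba[j] && !dused[i] && !aused[m + j]) {
          dused[i] = 1; aused[m + j] = 1; take = true;
        } else if (rhbd[j] && lhba[i] && !dused[m + j] && !aused[i]) {
          dused[m + j] = 1; aused[i] = 1; take = true;
        }
      }
      e += take ? cand[c].hb_e : cand[c].lj_e;
    }
    // halogen bonds: ligand C-X donors vs receptor acceptors
    for (int p = 0; p < lxb.nrow(); ++p) {
      int ci = lxb(p,0)-1, xi = lxb(p,1)-1;
      for (int j = 0; j < rec.nrow(); ++j) {
        if (!racc[j]) continue;
        double dx = lig(xi,0)-rec(j,0), dy = lig(xi,1)-rec(j,1), dz = lig(xi,2)-rec(j,2);
        double r2 = dx*dx+dy*dy+dz*dz;
        if (r2 > pp.cutoff2) continue;
        double r = std::sqrt(r2);
        double vx[3] = {lig(ci,0)-lig(xi,0), lig(ci,1)-lig(xi,1), lig(ci,2)-lig(xi,2)};
        double va[3] = {rec(j,0)-lig(xi,0), rec(j,1)-lig(xi,1), rec(j,2)-lig(xi,2)};
        double nx = std::sqrt(vx[0]*vx[0]+vx[1]*vx[1]+vx[2]*vx[2]);
        double na = std::sqrt(va[0]*va[0]+va[1]*va[1]+va[2]*va[2]);
        double cth = (vx[0]*va[0]+vx[1]*va[1]+vx[2]*va[2])/(nx*na);
        if (cth > pp.xb_cosmin) continue;
        double u = (pp.xb_cosmin - cth)/(pp.xb_cosmin + 1.0);
        if (u > 1.0) u = 1.0;
        double r0 = lrv[xi] + rrv[j] - pp.xb_pad;
        e += u*u*well1012(r, r0, pp.xb_d);
      }
    }
    return e;
  }

  double intra() const {
    double e = 0;
    std::vector<HBCand> cand;
    for (int i = 0; i < m-1; ++i)
      for (int j = i+1; j < m; ++j) {
        long long a = i, b = j;
        if (ex.count(a*(long long)m + b)) continue;
        double dx = lig(i,0)-lig(j,0), dy = lig(i,1)-lig(j,1), dz = lig(i,2)-lig(j,2);
        double r2 = dx*dx+dy*dy+dz*dz;
        if (r2 > pp.cutoff2 || r2 < 1e-12) continue;
        bool hb = (lhbd[i] && lhba[j]) || (lhbd[j] && lhba[i]);
        double ep = std::sqrt(leps[i]*leps[j]);
        double lj_e = (ep > 0) ? lj(r2, ep, 0.5*(lsig[i]+lsig[j])) : 0.0;
        if (hb) {
          HBCand c = {i, j, well1012(std::sqrt(r2), pp.hb_r0, pp.hb_d), lj_e};
          cand.push_back(c);
        } else e += lj_e;
        if (lq[i] != 0 && lq[j] != 0) e += pp.kcoul*lq[i]*lq[j]/(4.0*r2);
      }
    {
      double evdw2 = 0, ehb2 = 0;
      settle_hbonds(cand, lhbd, lhba, m, evdw2, ehb2);
      e += evdw2 + ehb2;
    }
    for (int t = 0; t < ltor.nrow(); ++t) {
      double phi = dihedral(lig, ltor(t,0)-1, ltor(t,1)-1, ltor(t,2)-1, ltor(t,3)-1);
      e += 0.5*ltV[t]*(1.0 + std::cos(ltn[t]*phi - ltg[t]));
    }
    return e;
  }

  double total() const { return cross() + intra(); }

  void translate(int axis, double d) { for (int i = 0; i < m; ++i) lig(i,axis) += d; }

  void rotate_about(const double c[3], const double u[3], double ang,
                    const std::vector<int> *atoms) {
    double ca = std::cos(ang), sa = std::sin(ang);
    int cnt = atoms ? (int)atoms->size() : m;
    for (int t = 0; t < cnt; ++t) {
      int i = atoms ? (*atoms)[t] : t;
      double p[3] = {lig(i,0)-c[0], lig(i,1)-c[1], lig(i,2)-c[2]};
      double du = u[0]*p[0]+u[1]*p[1]+u[2]*p[2];
      double cr[3] = {u[1]*p[2]-u[2]*p[1], u[2]*p[0]-u[0]*p[2], u[0]*p[1]-u[1]*p[0]};
      for (int cc = 0; cc < 3; ++cc)
        lig(i,cc) = c[cc] + p[cc]*ca + cr[cc]*sa + u[cc]*du*(1.0-ca);
    }
  }

  void centroid(double c[3]) const {
    c[0] = c[1] = c[2] = 0;
    for (int i = 0; i < m; ++i) for (int cc = 0; cc < 3; ++cc) c[cc] += lig(i,cc);
    for (int cc = 0; cc < 3; ++cc) c[cc] /= m;
  }
};

// golden-section line search over one DOF move; applies the best move
template <typename MoveFn>
static double line_search(LigSystem &S, MoveFn apply, double range, double e0) {
  const double gr = 0.6180339887498949;
  double a = -range, b = range;
  double cur = 0;  // current applied displacement
  double x1 = b - gr*(b-a), x2 = a + gr*(b-a);
  apply(x1 - cur); cur = x1; double f1 = S.total();
  apply(x2 - cur); cur = x2; double f2 = S.total();
  for (int it = 0; it < 14; ++it) {
    if (f1 < f2) { b = x2; x2 = x1; f2 = f1; x1 = b - gr*(b-a);
      apply(x1 - cur); cur = x1; f1 = S.total(); }
    else { a = x1; x1 = x2; f1 = f2; x2 = a + gr*(b-a);
      apply(x2 - cur); cur = x2; f2 = S.total(); }
  }
  double xb_ = (f1 < f2) ? x1 : x2, fb = std::min(f1, f2);
  if (fb < e0) { apply(xb_ - cur); return fb; }
  apply(0.0 - cur);  // revert
  return e0;
}

// [[Rcpp::export]]
List cpp_refine_pose(NumericMatrix lig_xyz, IntegerVector tor_a, IntegerVector tor_b,
                     List tor_moving, NumericVector leps, NumericVector lsig,
                     NumericVector lq, LogicalVector lhbd, LogicalVector lhba,
                     IntegerMatrix lexcl, IntegerMatrix ltor, NumericVector ltn,
                     NumericVector ltV, NumericVector ltg, IntegerMatrix lxb,
                     NumericVector lrv, NumericMatrix rec_xyz, NumericVector reps,
                     NumericVector rsig, NumericVector rq, LogicalVector rhbd,
                     LogicalVector rhba, LogicalVector racc, NumericVector rrv,
                     double cutoff, double kcoul, double hb_r0, double hb_d,
                     double xb_d, double xb_cosmin, double xb_pad,
                     int n_sweeps, int n_mc, double trans_mag, double rot_mag,
                     double tor_mag) {
  PairParams pp = {cutoff*cutoff, kcoul, hb_r0, hb_d, xb_d, xb_cosmin, xb_pad};
  NumericMatrix work = clone(lig_xyz);
  LigSystem S(work, rec_xyz, leps, lsig, lq, lhbd, lhba, lexcl, ltor, ltn, ltV,
              ltg, lxb, lrv, reps, rsig, rq, rhbd, rhba, racc, rrv, pp);
  int nt = tor_a.size();
  std::vector<std::vector<int> > mov(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerVector mv = tor_moving[t];
    for (int p = 0; p < mv.size(); ++p) mov[t].push_back(mv[p]-1);
  }
  double e_int_start = S.cross();
  NumericMatrix best = clone(work);
  double best_eint = e_int_start;
  auto note_best = [&]() {
    double ei = S.cross();
    if (ei < best_eint) { best_eint = ei; best = clone(work); }
  };
  auto sweeps = [&](int ns) {
    double e = S.total();
    for (int s = 0; s < ns; ++s) {
      double shrink = std::pow(0.55, s);
      for (int axis = 0; axis < 3; ++axis)
        e = line_search(S, [&](double d){ S.translate(axis, d); }, trans_mag*shrink, e);
      double c[3]; S.centroid(c);
      for (int axis = 0; axis < 3; ++axis) {
        double u[3] = {0,0,0}; u[axis] = 1;
        e = line_search(S, [&](double d){ S.rotate_about(c, u, d, NULL); },
                        rot_mag*shrink, e);
      }
      for (int t = 0; t < nt; ++t) {
        int ia = tor_a[t]-1, ib = tor_b[t]-1;
        e = line_search(S, [&](double d){
          double cc[3] = {S.lig(ib,0), S.lig(ib,1), S.lig(ib,2)};
          double u[3] = {S.lig(ib,0)-S.lig(ia,0), S.lig(ib,1)-S.lig(ia,1),
                         S.lig(ib,2)-S.lig(ia,2)};
          double nu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
          for (int c2 = 0; c2 < 3; ++c2) u[c2] /= nu;
          S.rotate_about(cc, u, d, &mov[t]);
        }, tor_mag*shrink, e);
      }
    }
    return e;
  };
  double e_cur = sweeps(n_sweeps);
  note_best();
  NumericMatrix keep = clone(work);
  for (int mc = 0; mc < n_mc; ++mc) {
    // random perturbation in internal coordinates, then re-minimize (greedy)
    double c[3]; S.centroid(c);
    for (int axis = 0; axis < 3; ++axis)
      S.translate(axis, R::runif(-trans_mag, trans_mag));
    double u[3] = {R::norm_rand(), R::norm_rand(), R::norm_rand()};
    double nu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
    for (int cc = 0; cc < 3; ++cc) u[cc] /= nu;
    S.rotate_about(c, u, R::runif(-rot_mag, rot_mag), NULL);
    for (int t = 0; t < nt; ++t) {
      if (R::unif_rand() < 0.5) continue;
      int ia = tor_a[t]-1, ib = tor_b[t]-1;
      double cc[3] = {S.lig(ib,0), S.lig(ib,1), S.lig(ib,2)};
      double uu[3] = {S.lig(ib,0)-S.lig(ia,0), S.lig(ib,1)-S.lig(ia,1),
                      S.lig(ib,2)-S.lig(ia,2)};
      double nn = std::sqrt(uu[0]*uu[0]+uu[1]*uu[1]+uu[2]*uu[2]);
      for (int c2 = 0; c2 < 3; ++c2) uu[c2] /= nn;
      S.rotate_about(cc, uu, R::runif(-tor_mag, tor_mag), &mov[t]);
    }
    double e_try = sweeps(std::max(2, n_sweeps-2));
    note_best();
    if (e_try < e_cur) { e_cur = e_try; keep = clone(work); }
    else { for (int i = 0; i < S.m; ++i) for (int cc = 0; cc < 3; ++cc)
             work(i,cc) = keep(i,cc); }
  }
  // report on the best-by-interaction-energy candidate
  for (int i = 0; i < S.m; ++i) for (int cc = 0; cc < 3; ++cc) work(i,cc) = best(i,cc);
  double e_int = S.cross(), e_tot = S.total();
  return List::create(_["xyz"] = best, _["e_int"] = e_int, _["e_total"] = e_tot,
                      _["e_int_start"] = e_int_start);
}
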