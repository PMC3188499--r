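// Compiled numerical core: pairwise nonbonded energy with decomposition,
// Shrake-Rupley solvent-accessible surface area, torsion-space DOF
// application, finite-difference objective gradients and rotamer packing.
// All energies are in dimensionless model units; distances in Angstrom.

#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

static const double R_ON = 5.5;   // switching starts
static const double R_OFF = 8.0;  // pair cutoff

struct EnergyModel {
  const double *x, *y, *z;
  int n;
  const double *radius, *eps, *charge, *dgfree, *vol;
  const int *donor, *acceptor, *baseidx; // baseidx 1-based, 0 = none
  const int *group;                      // 1 peptide, 2 receptor, 3 ligand
  std::unordered_set<long long> excl;
  // weights: 0 lj_attr, 1 lj_rep, 2 hbond, 3 solv, 4 elec
  double w[5];

  bool excluded(int i, int j) const {
    long long a = i < j ? i : j, b = i < j ? j : i;
    return excl.count(a * (long long)n + b) > 0;
  }
};

static double switchFn(double r) {
  if (r <= R_ON) return 1.0;
  if (r >= R_OFF) return 0.0;
  double r2 = r * r, on2 = R_ON * R_ON, off2 = R_OFF * R_OFF;
  double num = (off2 - r2) * (off2 - r2) * (off2 + 2.0 * r2 - 3.0 * on2);
  double den = (off2 - on2) * (off2 - on2) * (off2 - on2);
  return num / den;
}

// angular modulation for a donor->acceptor contact: 1 when the acceptor
// lies opposite the donor's bonded base (linear base-D...A), 0 at cis.
static double hbAngular(const EnergyModel &m, int d, int a) {
  int b = m.baseidx[d];
  if (b == 0) return 1.0;
  b -= 1;
  double ux = m.x[d] - m.x[b], uy = m.y[d] - m.y[b], uz = m.z[d] - m.z[b];
  double vx = m.x[a] - m.x[d], vy = m.y[a] - m.y[d], vz = m.z[a] - m.z[d];
  double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
  double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
  if (nu < 1e-9 || nv < 1e-9) return 1.0;
  double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
  double f = 0.5 * (1.0 + c);
  return f * f;
}

// weighted pair energy; accumulates weighted per-term sums into terms[5].
static double pairEnergy(const EnergyModel &m, int i, int j, double *terms) {
  double dx = m.x[i] - m.x[j], dy = m.y[i] - m.y[j], dz = m.z[i] - m.z[j];
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= R_OFF * R_OFF) return 0.0;
  if (m.excluded(i, j)) return 0.0;
  double r = std::sqrt(r2);
  if (r < 1e-6) r = 1e-6;
  double sw = switchFn(r);

  double sig = m.radius[i] + m.radius[j];
  double e = std::sqrt(m.eps[i] * m.eps[j]);
  double atr = 0.0, rep = 0.0;
  {
    double rl = 0.6 * sig;
    if (r >= sig) {
      double x6 = sig / r; x6 = x6 * x6 * x6; x6 = x6 * x6;
      atr = e * (x6 * x6 - 2.0 * x6);
    } else {
      atr = -e;
      double rr = r < rl ? rl : r;
      double x6 = sig / rr; x6 = x6 * x6 * x6; x6 = x6 * x6;
      rep = e * (x6 * x6 - 2.0 * x6) + e;
      if (r < rl) {
        // linearised repulsion below 0.6*sigma (minimisation stability)
        double x6l = sig / rl; x6l = x6l * x6l * x6l; x6l = x6l * x6l;
        double slope = 12.0 * e * (x6l * x6l - x6l) / rl; // -dE/dr at rl
        rep += slope * (rl - r);
      }
    }
  }

  double elec = 332.0 * m.charge[i] * m.charge[j] / (4.0 * r2);

  // Gaussian-exclusion implicit solvation
  const double lambda = 1.8;
  double dd = (r - sig) / lambda;
  double gx = std::exp(-dd * dd) / r2;
  const double knorm = 0.05;
  double solv = -knorm * gx *
    (m.dgfree[i] * m.vol[j] + m.dgfree[j] * m.vol[i]);

  double hb = 0.0;
  if (r > 2.0 && r < 3.8) {
    double g = std::exp(-(r - 2.9) * (r - 2.9) / (2.0 * 0.35 * 0.35));
    if (m.donor[i] && m.acceptor[j]) hb -= g * hbAngular(m, i, j);
    if (m.donor[j] && m.acceptor[i]) hb -= g * hbAngular(m, j, i);
  }

  double t0 = m.w[0] * atr * sw, t1 = m.w[1] * rep * sw,
         t2 = m.w[2] * hb * sw, t3 = m.w[3] * solv * sw,
         t4 = m.w[4] * elec * sw;
  if (terms) {
    terms[0] += t0; terms[1] += t1; terms[2] += t2; terms[3] += t3;
    terms[4] += t4;
  }
  return t0 + t1 + t2 + t3 + t4;
}

static EnergyModel makeModel(const NumericMatrix &xyz,
                             const NumericVector &radius,
                             const NumericVector &eps,
                             const NumericVector &charge,
                             const NumericVector &dgfree,
                             const NumericVector &vol,
                             const IntegerVector &donor,
                             const IntegerVector &acceptor,
                             const IntegerVector &baseidx,
                             const IntegerVector &group,
                             const IntegerMatrix &excl,
                             const NumericVector &weights) {
  EnergyModel m;
  m.n = xyz.nrow();
  m.x = &xyz(0, 0); m.y = &xyz(0, 1); m.z = &xyz(0, 2);
  m.radius = radius.begin(); m.eps = eps.begin(); m.charge = charge.begin();
  m.dgfree = dgfree.begin(); m.vol = vol.begin();
  m.donor = donor.begin(); m.acceptor = acceptor.begin();
  m.baseidx = baseidx.begin(); m.group = group.begin();
  for (int k = 0; k < excl.nrow(); ++k) {
    long long a = excl(k, 0) - 1, b = excl(k, 1) - 1;
    if (a > b) std::swap(a, b);
    m.excl.insert(a * (long long)m.n + b);
  }
  for (int k = 0; k < 5; ++k) m.w[k] = weights[k];
  return m;
}

// [[Rcpp::export(name = ".cppEnergy")]]
List cppEnergy(NumericMatrix xyz, NumericVector radius, NumericVector eps,
               NumericVector charge, NumericVector dgfree, NumericVector vol,
               IntegerVector donor, IntegerVector acceptor,
               IntegerVector baseidx, IntegerVector group,
               IntegerMatrix excl, NumericVector weights) {
  EnergyModel m = makeModel(xyz, radius, eps, charge, dgfree, vol, donor,
                            acceptor, baseidx, group, excl, weights);
  int n = m.n;
  NumericVector perAtom(n);
  double cross = 0.0, total = 0.0;
  NumericVector terms(5);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double e = pairEnergy(m, i, j, terms.begin());
      if (e == 0.0) continue;
      total += e;
      perAtom[i] += 0.5 * e;
      perAtom[j] += 0.5 * e;
      bool ip = m.group[i] == 1, jp = m.group[j] == 1;
      if (ip != jp) cross += e;
    }
  }
  return List::create(_["total"] = total, _["per_atom"] = perAtom,
                      _["cross_interface"] = cross, _["terms"] = terms);
}

static double constraintE(const NumericMatrix &xyz, const IntegerVector &ci,
                          const IntegerVector &cj, const NumericVector &d0,
                          const NumericVector &sd) {
  double e = 0.0;
  for (int k = 0; k < ci.size(); ++k) {
    int i = ci[k] - 1, j = cj[k] - 1;
    double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
           dz = xyz(i, 2) - xyz(j, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double u = (d - d0[k]) / sd[k];
    e += u * u;
  }
  return e;
}

// [[Rcpp::export(name = ".cppConstraintEnergy")]]
double cppConstraintEnergy(NumericMatrix xyz, IntegerVector ci,
                           IntegerVector cj, NumericVector d0,
                           NumericVector sd) {
  return constraintE(xyz, ci, cj, d0, sd);
}

static double totalEnergy(const EnergyModel &m) {
  double total = 0.0;
  for (int i = 0; i < m.n - 1; ++i)
    for (int j = i + 1; j < m.n; ++j)
      total += pairEnergy(m, i, j, nullptr);
  return total;
}

// [[Rcpp::export(name = ".cppObjective")]]
double cppObjective(NumericMatrix xyz, NumericVector radius,
                    NumericVector eps, NumericVector charge,
                    NumericVector dgfree, NumericVector vol,
                    IntegerVector donor, IntegerVector acceptor,
                    IntegerVector baseidx, IntegerVector group,
                    IntegerMatrix excl, NumericVector weights,
                    IntegerVector ci, IntegerVector cj, NumericVector d0,
                    NumericVector sd, double wcst) {
  EnergyModel m = makeModel(xyz, radius, eps, charge, dgfree, vol, donor,
                            acceptor, baseidx, group, excl, weights);
  return totalEnergy(m) + wcst * constraintE(xyz, ci, cj, d0, sd);
}

// ---- DOF application -------------------------------------------------------

static void rotateSet(NumericMatrix &xyz, const IntegerVector &idx,
                      double ox, double oy, double oz, double ax, double ay,
                      double az, double deg) {
  double th = deg * M_PI / 180.0;
  double n = std::sqrt(ax * ax + ay * ay + az * az);
  if (n < 1e-12) return;
  ax /= n; ay /= n; az /= n;
  double ct = std::cos(th), st = std::sin(th), omc = 1.0 - ct;
  double R[3][3] = {
    {ct + ax * ax * omc, ax * ay * omc - az * st, ax * az * omc + ay * st},
    {ay * ax * omc + az * st, ct + ay * ay * omc, ay * az * omc - ax * st},
    {az * ax * omc - ay * st, az * ay * omc + ax * st, ct + az * az * omc}};
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    double px = xyz(i, 0) - ox, py = xyz(i, 1) - oy, pz = xyz(i, 2) - oz;
    xyz(i, 0) = ox + R[0][0] * px + R[0][1] * py + R[0][2] * pz;
    xyz(i, 1) = oy + R[1][0] * px + R[1][1] * py + R[1][2] * pz;
    xyz(i, 2) = oz + R[2][0] * px + R[2][1] * py + R[2][2] * pz;
  }
}

// Apply one DOF displacement in place.
// type 1: torsion about axis atom a -> atom b (delta in degrees)
// type 2: translation of the moving set along global axis a (1..3), delta A
// type 3: rotation about global axis a through the moving set's centroid
static void applyOneDof(NumericMatrix &xyz, int type, int a, int b,
                        const IntegerVector &moving, double delta) {
  if (delta == 0.0 || moving.size() == 0) return;
  if (type == 1) {
    int ia = a - 1, ib = b - 1;
    rotateSet(xyz, moving, xyz(ib, 0), xyz(ib, 1), xyz(ib, 2),
              xyz(ib, 0) - xyz(ia, 0), xyz(ib, 1) - xyz(ia, 1),
              xyz(ib, 2) - xyz(ia, 2), delta);
  } else if (type == 2) {
    int ax = a - 1;
    for (int k = 0; k < moving.size(); ++k) xyz(moving[k] - 1, ax) += delta;
  } else if (type == 3) {
    double cx = 0, cy = 0, cz = 0;
    for (int k = 0; k < moving.size(); ++k) {
      cx += xyz(moving[k] - 1, 0);
      cy += xyz(moving[k] - 1, 1);
      cz += xyz(moving[k] - 1, 2);
    }
    int nm = moving.size();
    cx /= nm; cy /= nm; cz /= nm;
    double ux = a == 1, uy = a == 2, uz = a == 3;
    rotateSet(xyz, moving, cx, cy, cz, ux, uy, uz, delta);
  }
}

// [[Rcpp::export(name = ".cppApplyDofs")]]
NumericMatrix cppApplyDofs(NumericMatrix xyz, IntegerVector type,
                           IntegerVector a, IntegerVector b, List moving,
                           NumericVector deltas) {
  NumericMatrix W = clone(xyz);
  for (int k = 0; k < type.size(); ++k)
    applyOneDof(W, type[k], a[k], b[k], moving[k], deltas[k]);
  return W;
}

// Central finite-difference gradient of the constrained objective with
// respect to the DOF displacement vector `deltas`, differentiating the full
// sequential-application map coords(deltas) so the gradient is exact for
// the objective the line search evaluates.
// [[Rcpp::export(name = ".cppDofGradient")]]
NumericVector cppDofGradient(NumericMatrix xyz, IntegerVector type,
                             IntegerVector a, IntegerVector b, List moving,
                             NumericVector deltas, double hRot,
                             double hTrans, NumericVector radius,
                             NumericVector eps, NumericVector charge,
                             NumericVector dgfree, NumericVector vol,
                             IntegerVector donor, IntegerVector acceptor,
                             IntegerVector baseidx, IntegerVector group,
                             IntegerMatrix excl, NumericVector weights,
                             IntegerVector ci, IntegerVector cj,
                             NumericVector d0, NumericVector sd,
                             double wcst) {
  int m = type.size();
  int n = xyz.nrow();
  NumericVector grad(m);
  NumericMatrix W(n, 3);
  EnergyModel em = makeModel(W, radius, eps, charge, dgfree, vol, donor,
                             acceptor, baseidx, group, excl, weights);
  std::vector<double> d(deltas.begin(), deltas.end());
  auto evalAt = [&]() {
    for (int i = 0; i < n; ++i) {
      W(i, 0) = xyz(i, 0); W(i, 1) = xyz(i, 1); W(i, 2) = xyz(i, 2);
    }
    for (int k = 0; k < m; ++k)
      applyOneDof(W, type[k], a[k], b[k], moving[k], d[k]);
    return totalEnergy(em) + wcst * constraintE(W, ci, cj, d0, sd);
  };
  for (int k = 0; k < m; ++k) {
    double h = type[k] == 2 ? hTrans : hRot;
    double keep = d[k];
    d[k] = keep + h;
    double ep = evalAt();
    d[k] = keep - h;
    double en = evalAt();
    d[k] = keep;
    grad[k] = (ep - en) / (2.0 * h);
  }
  return grad;
}

// ---- Shrake-Rupley SASA ----------------------------------------------------

// [[Rcpp::export(name = ".cppSasa")]]
NumericVector cppSasa(NumericMatrix xyz, NumericVector radius, double probe,
                      int npoints) {
  int n = xyz.nrow();
  NumericVector area(n);
  // golden-spiral unit sphere points
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / npoints;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    px[k] = rk * std::cos(th); py[k] = rk * std::sin(th); pz[k] = zk;
  }
  for (int i = 0; i < n; ++i) {
    double ri = radius[i] + probe;
    // neighbour list
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radius[j] + probe;
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      if (dx * dx + dy * dy + dz * dz < (ri + rj) * (ri + rj)) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double sx = xyz(i, 0) + ri * px[k], sy = xyz(i, 1) + ri * py[k],
             sz = xyz(i, 2) + ri * pz[k];
      bool buried = false;
      for (size_t t = 0; t < nb.size(); ++t) {
        int j = nb[t];
        double rj = radius[j] + probe;
        double dx = sx - xyz(j, 0), dy = sy - xyz(j, 1), dz = sz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / npoints;
  }
  return area;
}

// ---- rotamer packing -------------------------------------------------------

static double subsetEnergy(const EnergyModel &m, const IntegerVector &A,
                           const IntegerVector &B, bool sameSet) {
  double e = 0.0;
  for (int p = 0; p < A.size(); ++p) {
    int i = A[p] - 1;
    int qstart = sameSet ? p + 1 : 0;
    for (int q = qstart; q < B.size(); ++q) {
      int j = B[q] - 1;
      if (i == j) continue;
      e += pairEnergy(m, i, j, nullptr);
    }
  }
  return e;
}

static void setCandidate(NumericMatrix &W, const IntegerVector &idx,
                         const NumericMatrix &cand) {
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    W(i, 0) = cand(k, 0); W(i, 1) = cand(k, 1); W(i, 2) = cand(k, 2);
  }
}

// Self + environment + constraint energy tables for combinatorial packing.
// posAtoms: per flexible position, 1-based indices of its moving atoms.
// cands: per position, list of nAtoms x 3 candidate coordinate matrices
// (candidate 1 must be the current coordinates).
// [[Rcpp::export(name = ".cppPack")]]
List cppPack(NumericMatrix xyz, List posAtoms, List cands,
             NumericVector radius, NumericVector eps, NumericVector charge,
             NumericVector dgfree, NumericVector vol, IntegerVector donor,
             IntegerVector acceptor, IntegerVector baseidx,
             IntegerVector group, IntegerMatrix excl, NumericVector weights,
             IntegerVector ci, IntegerVector cj, NumericVector d0,
             NumericVector sd, double wcst, double limit, int sweeps,
             double t0, double tfac) {
  int P = posAtoms.size();
  NumericMatrix W = clone(xyz);
  EnergyModel m = makeModel(W, radius, eps, charge, dgfree, vol, donor,
                            acceptor, baseidx, group, excl, weights);
  int n = m.n;

  // environment = atoms in no flexible position
  std::vector<bool> flex(n, false);
  for (int p = 0; p < P; ++p) {
    IntegerVector idx = posAtoms[p];
    for (int k = 0; k < idx.size(); ++k) flex[idx[k] - 1] = true;
  }
  IntegerVector env;
  {
    std::vector<int> e;
    for (int i = 0; i < n; ++i) if (!flex[i]) e.push_back(i + 1);
    env = wrap(e);
  }

  // constraint bookkeeping: constraints touching a flexible position are
  // charged to that position's singleton table (flexible-flexible pairs to
  // the pair table).
  std::vector<int> cstPosI(ci.size(), -1), cstPosJ(ci.size(), -1);
  for (int c = 0; c < ci.size(); ++c) {
    for (int p = 0; p < P; ++p) {
      IntegerVector idx = posAtoms[p];
      for (int k = 0; k < idx.size(); ++k) {
        if (idx[k] == ci[c]) cstPosI[c] = p;
        if (idx[k] == cj[c]) cstPosJ[c] = p;
      }
    }
  }
  IntegerVector c1(1), c2(1);
  NumericVector cd0(1), csd(1);
  auto cstOne = [&](int c) {
    c1[0] = ci[c]; c2[0] = cj[c]; cd0[0] = d0[c]; csd[0] = sd[c];
    return wcst * constraintE(W, c1, c2, cd0, csd);
  };

  std::vector<int> nr(P);
  for (int p = 0; p < P; ++p) nr[p] = ((List)cands[p]).size();

  // singleton tables: candidate vs environment + internal + constraints
  std::vector<std::vector<double>> e1(P);
  for (int p = 0; p < P; ++p) {
    IntegerVector idx = posAtoms[p];
    List cl = cands[p];
    e1[p].resize(nr[p]);
    for (int r = 0; r < nr[p]; ++r) {
      setCandidate(W, idx, cl[r]);
      double e = subsetEnergy(m, idx, env, false) +
                 subsetEnergy(m, idx, idx, true);
      for (int c = 0; c < ci.size(); ++c) {
        bool pi = cstPosI[c] == p, pj = cstPosJ[c] == p;
        if ((pi && (cstPosJ[c] < 0)) || (pj && (cstPosI[c] < 0)) ||
            (pi && pj))
          e += cstOne(c);
      }
      e1[p][r] = e;
    }
    setCandidate(W, idx, cl[0]);
  }

  // pair tables
  std::vector<std::vector<std::vector<std::vector<double>>>> e2(P);
  for (int p = 0; p < P; ++p) {
    e2[p].resize(P);
    for (int q = p + 1; q < P; ++q) {
      e2[p][q].assign(nr[p], std::vector<double>(nr[q], 0.0));
      IntegerVector ip = posAtoms[p], iq = posAtoms[q];
      List cp = cands[p], cq = cands[q];
      for (int r = 0; r < nr[p]; ++r) {
        setCandidate(W, ip, cp[r]);
        for (int s = 0; s < nr[q]; ++s) {
          setCandidate(W, iq, cq[s]);
          double e = subsetEnergy(m, ip, iq, false);
          for (int c = 0; c < ci.size(); ++c) {
            if ((cstPosI[c] == p && cstPosJ[c] == q) ||
                (cstPosI[c] == q && cstPosJ[c] == p))
              e += cstOne(c);
          }
          e2[p][q][r][s] = e;
        }
        setCandidate(W, iq, cq[0]);
      }
      setCandidate(W, ip, cp[0]);
    }
  }

  auto comboEnergy = [&](const std::vector<int> &ch) {
    double e = 0.0;
    for (int p = 0; p < P; ++p) {
      e += e1[p][ch[p]];
      for (int q = p + 1; q < P; ++q) e += e2[p][q][ch[p]][ch[q]];
    }
    return e;
  };

  double total = 1.0;
  for (int p = 0; p < P; ++p) total *= nr[p];
  std::vector<int> best(P, 0), cur(P, 0);
  double bestE = comboEnergy(best);
  bool exhaustive = total <= limit;

  if (exhaustive) {
    // odometer over the full product space
    std::vector<int> ch(P, 0);
    bool done = false;
    while (!done) {
      double e = comboEnergy(ch);
      if (e < bestE - 1e-12) { bestE = e; best = ch; }
      int p = P - 1;
      while (p >= 0) {
        if (++ch[p] < nr[p]) break;
        ch[p] = 0; --p;
      }
      if (p < 0) done = true;
    }
  } else {
    // seeded simulated annealing (geometric cooling, Gibbs-style moves);
    // uses R's RNG so set.seed() in R controls it
    double curE = comboEnergy(cur);
    double T = t0;
    for (int s = 0; s < sweeps; ++s) {
      for (int p = 0; p < P; ++p) {
        int prop = (int)std::floor(unif_rand() * nr[p]);
        if (prop >= nr[p]) prop = nr[p] - 1;
        if (prop == cur[p]) continue;
        double dE = e1[p][prop] - e1[p][cur[p]];
        for (int q = 0; q < P; ++q) {
          if (q == p) continue;
          int lo = std::min(p, q), hi = std::max(p, q);
          double nw = lo == p ? e2[lo][hi][prop][cur[q]]
                              : e2[lo][hi][cur[q]][prop];
          double od = lo == p ? e2[lo][hi][cur[p]][cur[q]]
                              : e2[lo][hi][cur[q]][cur[p]];
          dE += nw - od;
        }
        if (dE <= 0 || unif_rand() < std::exp(-dE / T)) {
          cur[p] = prop;
          curE += dE;
          if (curE < bestE - 1e-12) { bestE = curE; best = cur; }
        }
      }
      T *= tfac;
    }
  }

  IntegerVector choice(P);
  for (int p = 0; p < P; ++p) choice[p] = best[p] + 1;
  return List::create(_["choice"] = choice, _["energy"] = bestE,
                      _["exhaustive"] = exhaustive,
                      _["n_combinations"] = total);
}
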