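// Compiled kernels: neighbor-list pair enumeration, analytic force-field
// gradients (bond, angle, dihedral, LJ, Coulomb), per-frame virial stress
// assembly with central pairwise decomposition of the many-body terms, and
// a velocity-Verlet NVE integrator. Internal units: nm, ps, amu, kJ/mol, e.
// Atom indices arriving from R are 1-based and converted here.

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double COULOMB_K = 138.935458;

struct Topology {
  int n;
  arma::vec mass, charge, sigma, epsilon;
  arma::imat bonds;      // m x 2 (0-based)
  arma::vec kb, b0;
  arma::imat angles;     // m x 3
  arma::vec ktheta, theta0;
  arma::imat dihedrals;  // m x 4
  arma::vec kphi, phase;
  arma::ivec mult;
  arma::imat pairs14;    // m x 2
  arma::vec qscale, ljscale;
  std::vector<double> skip_keys; // sorted keys i*n+j (i<j): exclusions + 1-4
};

static double pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (double)i * (double)n + (double)j;
}

static Topology parse_topology(const List& top) {
  Topology t;
  t.mass = as<arma::vec>(top["mass"]);
  t.charge = as<arma::vec>(top["charge"]);
  t.sigma = as<arma::vec>(top["sigma"]);
  t.epsilon = as<arma::vec>(top["epsilon"]);
  t.n = (int)t.mass.n_elem;
  t.bonds = as<arma::imat>(top["bonds"]) - 1;
  t.kb = as<arma::vec>(top["kb"]);
  t.b0 = as<arma::vec>(top["b0"]);
  t.angles = as<arma::imat>(top["angles"]) - 1;
  t.ktheta = as<arma::vec>(top["ktheta"]);
  t.theta0 = as<arma::vec>(top["theta0"]);
  t.dihedrals = as<arma::imat>(top["dihedrals"]) - 1;
  t.kphi = as<arma::vec>(top["kphi"]);
  t.mult = as<arma::ivec>(top["mult"]);
  t.phase = as<arma::vec>(top["phase"]);
  t.pairs14 = as<arma::imat>(top["pairs14"]) - 1;
  t.qscale = as<arma::vec>(top["qscale"]);
  t.ljscale = as<arma::vec>(top["ljscale"]);
  NumericVector ek = top["skip_keys"]; // already includes 1-4 pairs
  t.skip_keys.assign(ek.begin(), ek.end());
  std::sort(t.skip_keys.begin(), t.skip_keys.end());
  return t;
}

static bool skip_pair(const Topology& t, int i, int j) {
  return std::binary_search(t.skip_keys.begin(), t.skip_keys.end(),
                            pair_key(i, j, t.n));
}

static inline arma::vec3 min_image(arma::vec3 d, const arma::vec& box) {
  if (box.n_elem == 3)
    for (int k = 0; k < 3; ++k) d[k] -= box[k] * std::round(d[k] / box[k]);
  return d;
}

// ---------------------------------------------------------------------------
// Neighbor enumeration: cell list for n >= brute_limit, brute force below.

static void enumerate_nb_pairs(const arma::mat& x, double cutoff,
                               const arma::vec& box, const Topology* t,
                               std::vector<std::pair<int,int> >& out,
                               int brute_limit = 200) {
  const int n = (int)x.n_rows;
  const double c2 = cutoff * cutoff;
  out.clear();
  bool periodic = box.n_elem == 3;
  if (n < brute_limit) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        arma::vec3 d = x.row(i).t() - x.row(j).t();
        d = min_image(d, box);
        if (arma::dot(d, d) <= c2) {
          if (t && skip_pair(*t, i, j)) continue;
          out.push_back(std::make_pair(i, j));
        }
      }
    return;
  }
  // cell list
  arma::vec3 lo, span;
  arma::ivec3 dims;
  if (periodic) {
    lo.zeros();
    span = box.subvec(0, 2);
  } else {
    for (int k = 0; k < 3; ++k) {
      lo[k] = x.col(k).min();
      span[k] = std::max(x.col(k).max() - lo[k], 1e-9);
    }
  }
  for (int k = 0; k < 3; ++k) {
    dims[k] = std::max(1, (int)std::floor(span[k] / cutoff));
    if (periodic && dims[k] < 3) dims[k] = 1; // avoid double-count over wrap
  }
  arma::vec3 cell;
  for (int k = 0; k < 3; ++k) cell[k] = span[k] / dims[k];
  int ncell = dims[0] * dims[1] * dims[2];
  std::vector<std::vector<int> > cells(ncell);
  std::vector<arma::ivec3> cidx(n);
  for (int i = 0; i < n; ++i) {
    arma::ivec3 c;
    for (int k = 0; k < 3; ++k) {
      double u = (x(i, k) - lo[k]) / cell[k];
      int ci = (int)std::floor(u);
      if (periodic) {
        ci %= dims[k]; if (ci < 0) ci += dims[k];
      } else {
        ci = std::min(std::max(ci, 0), dims[k] - 1);
      }
      c[k] = ci;
    }
    cidx[i] = c;
    cells[(c[0] * dims[1] + c[1]) * dims[2] + c[2]].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    const arma::ivec3& c = cidx[i];
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int cx = c[0] + dx, cy = c[1] + dy, cz = c[2] + dz;
          if (periodic) {
            cx = (cx + dims[0]) % dims[0];
            cy = (cy + dims[1]) % dims[1];
            cz = (cz + dims[2]) % dims[2];
          } else if (cx < 0 || cy < 0 || cz < 0 ||
                     cx >= dims[0] || cy >= dims[1] || cz >= dims[2]) {
            continue;
          }
          const std::vector<int>& neigh = cells[(cx * dims[1] + cy) * dims[2] + cz];
          for (size_t q = 0; q < neigh.size(); ++q) {
            int j = neigh[q];
            if (j <= i) continue;
            arma::vec3 d = x.row(i).t() - x.row(j).t();
            d = min_image(d, box);
            if (arma::dot(d, d) <= c2) {
              if (t && skip_pair(*t, i, j)) continue;
              out.push_back(std::make_pair(i, j));
            }
          }
        }
  }
}

// [[Rcpp::export(name = ".cpp_nb_pairs")]]
IntegerMatrix cpp_nb_pairs(const arma::mat& x, double cutoff,
                           const arma::vec& box, int brute_limit) {
  std::vector<std::pair<int,int> > pr;
  enumerate_nb_pairs(x, cutoff, box, nullptr, pr, brute_limit);
  IntegerMatrix out((int)pr.size(), 2);
  for (size_t q = 0; q < pr.size(); ++q) {
    out(q, 0) = pr[q].first + 1;
    out(q, 1) = pr[q].second + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Analytic gradients. add_virial: when vs != nullptr, accumulate the
// tension-positive pair virial (r_b - r_a) . f_ab onto both endpoints in
// the given term column.

struct VirialSink {
  arma::mat* vs;   // n x nterm
  int col;
};

static inline void add_pair(arma::mat& F, VirialSink* sink,
                            int a, int b, const arma::vec3& d, double r,
                            double g /* repulsive-positive magnitude */) {
  // force on a = g * d / r (d = r_a - r_b, possibly min-imaged)
  arma::vec3 f = (g / r) * d;
  F.row(a) += f.t();
  F.row(b) -= f.t();
  if (sink && sink->vs) {
    double val = -g * r; // (r_b - r_a) . f_ab
    (*sink->vs)(a, sink->col) += val;
    (*sink->vs)(b, sink->col) += val;
  }
}

static double bond_forces(const Topology& t, const arma::mat& x,
                          const arma::vec& box, arma::mat& F, arma::mat* vs) {
  double e = 0;
  VirialSink sink = { vs, 0 };
  for (size_t m = 0; m < t.bonds.n_rows; ++m) {
    int a = t.bonds(m, 0), b = t.bonds(m, 1);
    arma::vec3 d = min_image(x.row(a).t() - x.row(b).t(), box);
    double r = arma::norm(d);
    if (r <= 0) stop("degenerate geometry in bond term: coincident atoms");
    double dev = r - t.b0[m];
    e += 0.5 * t.kb[m] * dev * dev;
    add_pair(F, &sink, a, b, d, r, -t.kb[m] * dev);
  }
  return e;
}

// angle geometry: theta and dtheta/dr
static bool angle_grad(const arma::vec3& ri, const arma::vec3& rj,
                       const arma::vec3& rk, double& theta,
                       arma::vec3& di, arma::vec3& dj, arma::vec3& dk) {
  arma::vec3 u = ri - rj, v = rk - rj;
  double nu = arma::norm(u), nv = arma::norm(v);
  if (nu <= 0 || nv <= 0) return false;
  double ct = arma::dot(u, v) / (nu * nv);
  ct = std::min(1.0, std::max(-1.0, ct));
  double st = std::sqrt(std::max(0.0, 1 - ct * ct));
  if (st < 1e-12) return false;
  theta = std::acos(ct);
  di = (ct * u / (nu * nu) - v / (nu * nv)) / st;
  dk = (ct * v / (nv * nv) - u / (nu * nv)) / st;
  dj = -(di + dk);
  return true;
}

// solve central decomposition for a small term instance; returns pair scalars
static arma::vec central_scalars(const arma::mat& coords, const arma::imat& pairs,
                                 const arma::mat& forces, const char* term) {
  const int m = (int)coords.n_rows, p = (int)pairs.n_rows;
  arma::mat A(3 * m, p, arma::fill::zeros);
  for (int q = 0; q < p; ++q) {
    int a = pairs(q, 0), b = pairs(q, 1);
    arma::vec3 d = coords.row(a).t() - coords.row(b).t();
    double r = arma::norm(d);
    if (r <= 0) stop("degenerate geometry in %s term: coincident atoms", term);
    A.submat(3 * a, q, 3 * a + 2, q) = d / r;
    A.submat(3 * b, q, 3 * b + 2, q) = -d / r;
  }
  arma::vec fvec(3 * m);
  for (int a = 0; a < m; ++a) fvec.subvec(3 * a, 3 * a + 2) = forces.row(a).t();
  double fn = arma::norm(fvec);
  arma::vec s(p, arma::fill::zeros);
  if (fn == 0) return s;
  s = arma::pinv(A) * fvec;
  if (arma::norm(A * s - fvec) > 1e-8 * std::max(1.0, fn))
    stop("degenerate geometry in %s term: force set not representable by central pair forces", term);
  return s;
}

static double angle_forces(const Topology& t, const arma::mat& x,
                           arma::mat& F, arma::mat* vs) {
  double e = 0;
  arma::imat pairs(3, 2);
  pairs(0,0)=0; pairs(0,1)=1; pairs(1,0)=2; pairs(1,1)=1; pairs(2,0)=0; pairs(2,1)=2;
  for (size_t m = 0; m < t.angles.n_rows; ++m) {
    int ia = t.angles(m, 0), ja = t.angles(m, 1), ka = t.angles(m, 2);
    double theta;
    arma::vec3 di, dj, dk;
    if (!angle_grad(x.row(ia).t(), x.row(ja).t(), x.row(ka).t(), theta, di, dj, dk))
      stop("degenerate geometry in angle term %d: collinear or zero-length arms", (int)m + 1);
    double dev = theta - t.theta0[m];
    e += 0.5 * t.ktheta[m] * dev * dev;
    double dV = t.ktheta[m] * dev;
    arma::mat fl(3, 3);
    fl.row(0) = (-dV * di).t();
    fl.row(1) = (-dV * dj).t();
    fl.row(2) = (-dV * dk).t();
    F.row(ia) += fl.row(0); F.row(ja) += fl.row(1); F.row(ka) += fl.row(2);
    if (vs && dV != 0) {
      arma::mat coords(3, 3);
      coords.row(0) = x.row(ia); coords.row(1) = x.row(ja); coords.row(2) = x.row(ka);
      arma::vec s = central_scalars(coords, pairs, fl, "angle");
      int gidx[3] = { ia, ja, ka };
      for (int q = 0; q < 3; ++q) {
        double r = arma::norm(coords.row(pairs(q,0)) - coords.row(pairs(q,1)));
        double val = -s[q] * r;
        (*vs)(gidx[pairs(q, 0)], 1) += val;
        (*vs)(gidx[pairs(q, 1)], 1) += val;
      }
    }
  }
  return e;
}

static bool dihedral_grad(const arma::vec3& ri, const arma::vec3& rj,
                          const arma::vec3& rk, const arma::vec3& rl,
                          double& phi, arma::vec3& di, arma::vec3& dj,
                          arma::vec3& dk, arma::vec3& dl) {
  arma::vec3 b1 = rj - ri, b2 = rk - rj, b3 = rl - rk;
  arma::vec3 n1 = arma::cross(b1, b2), n2 = arma::cross(b2, b3);
  double n1sq = arma::dot(n1, n1), n2sq = arma::dot(n2, n2);
  double nb2 = arma::norm(b2);
  if (nb2 <= 0 || n1sq < 1e-20 || n2sq < 1e-20) return false;
  phi = std::atan2(arma::dot(arma::cross(n1, n2), b2) / nb2, arma::dot(n1, n2));
  di = -(nb2 / n1sq) * n1;
  dl = (nb2 / n2sq) * n2;
  double s = arma::dot(b1, b2) / (nb2 * nb2);
  double tt = arma::dot(b3, b2) / (nb2 * nb2);
  dj = -(1 + s) * di + tt * dl;
  dk = s * di - (1 + tt) * dl;
  return true;
}

static double dihedral_forces(const Topology& t, const arma::mat& x,
                              arma::mat& F, arma::mat* vs) {
  double e = 0;
  arma::imat pairs(6, 2);
  int pr[6][2] = { {0,1},{0,2},{0,3},{1,2},{1,3},{2,3} };
  for (int q = 0; q < 6; ++q) { pairs(q,0)=pr[q][0]; pairs(q,1)=pr[q][1]; }
  for (size_t m = 0; m < t.dihedrals.n_rows; ++m) {
    int ia = t.dihedrals(m,0), ja = t.dihedrals(m,1),
        ka = t.dihedrals(m,2), la = t.dihedrals(m,3);
    double phi;
    arma::vec3 di, dj, dk, dl;
    if (!dihedral_grad(x.row(ia).t(), x.row(ja).t(), x.row(ka).t(), x.row(la).t(),
                       phi, di, dj, dk, dl))
      stop("degenerate geometry in dihedral term %d: three collinear consecutive atoms", (int)m + 1);
    double arg = t.mult[m] * phi - t.phase[m];
    e += t.kphi[m] * (1 + std::cos(arg));
    double dV = -t.kphi[m] * t.mult[m] * std::sin(arg);
    arma::mat fl(4, 3);
    fl.row(0) = (-dV * di).t(); fl.row(1) = (-dV * dj).t();
    fl.row(2) = (-dV * dk).t(); fl.row(3) = (-dV * dl).t();
    F.row(ia) += fl.row(0); F.row(ja) += fl.row(1);
    F.row(ka) += fl.row(2); F.row(la) += fl.row(3);
    if (vs && dV != 0) {
      arma::mat coords(4, 3);
      coords.row(0) = x.row(ia); coords.row(1) = x.row(ja);
      coords.row(2) = x.row(ka); coords.row(3) = x.row(la);
      arma::vec s = central_scalars(coords, pairs, fl, "dihedral");
      int gidx[4] = { ia, ja, ka, la };
      for (int q = 0; q < 6; ++q) {
        double r = arma::norm(coords.row(pairs(q,0)) - coords.row(pairs(q,1)));
        double val = -s[q] * r;
        (*vs)(gidx[pairs(q, 0)], 2) += val;
        (*vs)(gidx[pairs(q, 1)], 2) += val;
      }
    }
  }
  return e;
}

// LJ + Coulomb over a precomputed nonbonded pair list plus the 1-4 pairs.
// Returns (coulomb, vdw) energies.
static arma::vec2 nonbonded_forces(const Topology& t, const arma::mat& x,
                                   const arma::vec& box, double cutoff,
                                   const std::vector<std::pair<int,int> >& nb,
                                   arma::mat& F, arma::mat* vs) {
  double ec = 0, ev = 0;
  VirialSink sc = { vs, 3 }, sv = { vs, 4 };
  const double c2 = cutoff * cutoff;
  for (size_t q = 0; q < nb.size() + t.pairs14.n_rows; ++q) {
    int a, b;
    double qs = 1, ls = 1;
    if (q < nb.size()) {
      a = nb[q].first; b = nb[q].second;
    } else {
      size_t m = q - nb.size();
      a = t.pairs14(m, 0); b = t.pairs14(m, 1);
      qs = t.qscale[m]; ls = t.ljscale[m];
    }
    arma::vec3 d = min_image(x.row(a).t() - x.row(b).t(), box);
    double r2 = arma::dot(d, d);
    if (r2 > c2) continue;
    double r = std::sqrt(r2);
    if (r <= 0) stop("degenerate geometry in nonbonded term: coincident atoms");
    if (t.charge[a] != 0 && t.charge[b] != 0) {
      double g = qs * COULOMB_K * t.charge[a] * t.charge[b] / r2;
      ec += qs * COULOMB_K * t.charge[a] * t.charge[b] / r;
      add_pair(F, &sc, a, b, d, r, g);
    }
    double eps = std::sqrt(t.epsilon[a] * t.epsilon[b]);
    if (eps > 0) {
      double sig = 0.5 * (t.sigma[a] + t.sigma[b]);
      double sr6 = std::pow(sig / r, 6), sr12 = sr6 * sr6;
      ev += ls * 4 * eps * (sr12 - sr6);
      add_pair(F, &sv, a, b, d, r, ls * (24 * eps / r) * (2 * sr12 - sr6));
    }
  }
  arma::vec2 out; out[0] = ec; out[1] = ev;
  return out;
}

// [[Rcpp::export(name = ".cpp_forces")]]
List cpp_forces(const arma::mat& x, const List& top, double cutoff,
                const arma::vec& box, int brute_limit) {
  Topology t = parse_topology(top);
  arma::mat F(t.n, 3, arma::fill::zeros);
  std::vector<std::pair<int,int> > nb;
  enumerate_nb_pairs(x, cutoff, box, &t, nb, brute_limit);
  double eb = bond_forces(t, x, box, F, nullptr);
  double ea = angle_forces(t, x, F, nullptr);
  double ed = dihedral_forces(t, x, F, nullptr);
  arma::vec2 enb = nonbonded_forces(t, x, box, cutoff, nb, F, nullptr);
  return List::create(_["forces"] = F,
                      _["energies"] = NumericVector::create(
                        _["bond"] = eb, _["angle"] = ea, _["dihedral"] = ed,
                        _["coulomb"] = enb[0], _["vdw"] = enb[1]));
}

// Per-atom, per-term virial sums S_i = sum over pairs of (r_b - r_a).f_ab
// (tension positive). Columns: bond, angle, dihedral, coulomb, vdw.
// [[Rcpp::export(name = ".cpp_frame_virials")]]
List cpp_frame_virials(const arma::mat& x, const List& top, double cutoff,
                       const arma::vec& box, int brute_limit) {
  Topology t = parse_topology(top);
  arma::mat F(t.n, 3, arma::fill::zeros);
  arma::mat vs(t.n, 5, arma::fill::zeros);
  std::vector<std::pair<int,int> > nb;
  enumerate_nb_pairs(x, cutoff, box, &t, nb, brute_limit);
  bond_forces(t, x, box, F, &vs);
  angle_forces(t, x, F, &vs);
  dihedral_forces(t, x, F, &vs);
  nonbonded_forces(t, x, box, cutoff, nb, F, &vs);
  return List::create(_["virials"] = vs, _["forces"] = F);
}

// ---------------------------------------------------------------------------
// FIRE energy minimization (fast inertial relaxation engine): used to relax
// built lattices to a force minimum before dynamics, as one would with any
// MD engine's minimizer.

// [[Rcpp::export(name = ".cpp_minimize")]]
List cpp_minimize(const arma::mat& x0, const List& top, double cutoff,
                  const arma::vec& box, int max_steps, double ftol,
                  int brute_limit) {
  Topology t = parse_topology(top);
  arma::mat x = x0;
  std::vector<std::pair<int,int> > nb;
  double skin = 0.2;
  arma::mat xref = x;
  enumerate_nb_pairs(x, cutoff + skin, box, &t, nb, brute_limit);
  arma::mat F(t.n, 3);
  double epot = 0;
  auto eval_forces = [&]() {
    F.zeros();
    epot = bond_forces(t, x, box, F, nullptr);
    epot += angle_forces(t, x, F, nullptr);
    epot += dihedral_forces(t, x, F, nullptr);
    arma::vec2 enb = nonbonded_forces(t, x, box, cutoff, nb, F, nullptr);
    epot += enb[0] + enb[1];
  };
  eval_forces();
  arma::mat v(t.n, 3, arma::fill::zeros);
  double dt = 1e-4, dt_max = 2e-3, alpha = 0.1;
  int n_pos = 0;
  double fmax = 0;
  int step = 0;
  for (step = 0; step < max_steps; ++step) {
    fmax = arma::abs(F).max();
    if (fmax < ftol) break;
    double P = arma::accu(v % F);
    if (P > 0) {
      double vn = arma::norm(v, "fro"), fn = arma::norm(F, "fro");
      if (fn > 0) v = (1 - alpha) * v + alpha * vn * (F / fn);
      if (++n_pos > 5) { dt = std::min(dt * 1.1, dt_max); alpha *= 0.99; }
    } else {
      v.zeros(); alpha = 0.1; dt *= 0.5; n_pos = 0;
    }
    v += dt * (F.each_col() / t.mass);
    x += dt * v;
    double maxd2 = 0;
    for (int i = 0; i < t.n; ++i) {
      arma::rowvec3 d = x.row(i) - xref.row(i);
      maxd2 = std::max(maxd2, (double)arma::dot(d, d));
    }
    if (maxd2 > 0.25 * skin * skin) {
      enumerate_nb_pairs(x, cutoff + skin, box, &t, nb, brute_limit);
      xref = x;
    }
    eval_forces();
  }
  return List::create(_["coords"] = x, _["epot"] = epot,
                      _["fmax"] = arma::abs(F).max(), _["steps"] = step);
}

// ---------------------------------------------------------------------------
// Velocity-Verlet NVE integrator with optional harmonic position restraint
// (restraint forces act on the dynamics but are never part of the stress).

// [[Rcpp::export(name = ".cpp_nve")]]
List cpp_nve(const arma::mat& x0, const arma::mat& v0, const List& top,
             double dt, int nsteps, int stride, double cutoff, double skin,
             double restraint_k, const arma::mat& restraint_ref,
             const arma::vec& box, int brute_limit) {
  Topology t = parse_topology(top);
  arma::mat x = x0, v = v0;
  arma::mat xref = x; // neighbor-list reference positions
  std::vector<std::pair<int,int> > nb;
  enumerate_nb_pairs(x, cutoff + skin, box, &t, nb, brute_limit);

  arma::vec invm = 1.0 / t.mass;
  bool restrained = restraint_k > 0;

  // force evaluation
  arma::mat F(t.n, 3);
  double epot = 0;
  auto eval_forces = [&]() {
    F.zeros();
    epot = bond_forces(t, x, box, F, nullptr);
    epot += angle_forces(t, x, F, nullptr);
    epot += dihedral_forces(t, x, F, nullptr);
    arma::vec2 enb = nonbonded_forces(t, x, box, cutoff, nb, F, nullptr);
    epot += enb[0] + enb[1];
    if (restrained) {
      arma::mat dx = x - restraint_ref;
      F -= restraint_k * dx;
      epot += 0.5 * restraint_k * arma::accu(dx % dx);
    }
  };

  eval_forces();
  int nsnap = nsteps / stride;
  arma::cube xs(t.n, 3, nsnap + 1);
  arma::cube vsave(t.n, 3, nsnap + 1);
  arma::vec times(nsnap + 1), epots(nsnap + 1), ekins(nsnap + 1);
  auto kinetic = [&]() {
    double ek = 0;
    for (int i = 0; i < t.n; ++i) ek += 0.5 * t.mass[i] * arma::dot(v.row(i), v.row(i));
    return ek;
  };
  int isnap = 0;
  xs.slice(0) = x; vsave.slice(0) = v;
  times[0] = 0; epots[0] = epot; ekins[0] = kinetic();

  const double half_skin2 = 0.25 * skin * skin;
  for (int step = 1; step <= nsteps; ++step) {
    v += (0.5 * dt) * (F.each_col() % invm);
    x += dt * v;
    if (!x.is_finite())
      stop("integration blow-up: non-finite coordinates at step %d", step);
    // rebuild neighbor list when any atom moved more than skin/2
    double maxd2 = 0;
    for (int i = 0; i < t.n; ++i) {
      arma::rowvec3 d = x.row(i) - xref.row(i);
      double dd = arma::dot(d, d);
      if (dd > maxd2) maxd2 = dd;
    }
    if (maxd2 > half_skin2) {
      enumerate_nb_pairs(x, cutoff + skin, box, &t, nb, brute_limit);
      xref = x;
    }
    eval_forces();
    v += (0.5 * dt) * (F.each_col() % invm);
    if (step % stride == 0) {
      ++isnap;
      xs.slice(isnap) = x;
      vsave.slice(isnap) = v;
      times[isnap] = step * dt;
      epots[isnap] = epot;
      ekins[isnap] = kinetic();
    }
  }
  return List::create(_["coords"] = xs, _["velocities"] = vsave,
                      _["times"] = times, _["epot"] = epots,
                      _["ekin"] = ekins);
}
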