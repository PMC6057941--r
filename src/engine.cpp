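#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Ideal backbone geometry (Engh-Huber style values), Angstrom / degrees.
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329, B_CA_CB = 1.522;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.2, A_C_N_CA = 121.7;
// CB from the (C, N, CA) frame: bond 1.522 A, angle N-CA-CB 110.4 deg,
// improper dihedral C-N-CA-CB -122.8 deg gives L-chirality.
static const double A_N_CA_CB = 110.4, D_C_N_CA_CB = -122.8;

static inline double deg2rad(double x) { return x * M_PI / 180.0; }

struct Vec3 { double x, y, z; };
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(a.x * a.x + a.y * a.y + a.z * a.z); }
static inline Vec3 vunit(const Vec3 &a) {
  double n = vnorm(a);
  return {a.x / n, a.y / n, a.z / n};
}
static inline double dist2(const Vec3 &a, const Vec3 &b) {
  double dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
  return dx * dx + dy * dy + dz * dz;
}

// Natural extension reference frame: place D from (A, B, C) with bond |CD|,
// angle B-C-D and dihedral A-B-C-D.
static Vec3 nerf(const Vec3 &A, const Vec3 &B, const Vec3 &C,
                 double r, double theta_deg, double phi_deg) {
  double th = deg2rad(theta_deg), ph = deg2rad(phi_deg);
  Vec3 bc = vunit(vsub(C, B));
  Vec3 n = vunit(vcross(vsub(B, A), bc));
  Vec3 m = vcross(n, bc);
  double d1 = -r * std::cos(th), d2 = r * std::sin(th) * std::cos(ph), d3 = r * std::sin(th) * std::sin(ph);
  return {C.x + bc.x * d1 + m.x * d2 + n.x * d3,
          C.y + bc.y * d1 + m.y * d2 + n.y * d3,
          C.z + bc.z * d1 + m.z * d2 + n.z * d3};
}

struct Coords {
  std::vector<Vec3> N, CA, C, CB;
  void resize(int n) { N.resize(n); CA.resize(n); C.resize(n); CB.resize(n); }
};

// Sequential internal-to-Cartesian build. phi[0], psi[n-1], omega[n-1] unused.
// omega[i] is the peptide dihedral CA(i)-C(i)-N(i+1)-CA(i+1).
// For Gly, CB is stored equal to CA (side-chain proxy falls back to CA).
static void build_chain(const std::vector<double> &phi, const std::vector<double> &psi,
                        const std::vector<double> &omega, const std::vector<int> &gly,
                        Coords &xyz) {
  int n = (int)phi.size();
  xyz.resize(n);
  xyz.N[0] = {0.0, 0.0, 0.0};
  xyz.CA[0] = {B_N_CA, 0.0, 0.0};
  double a = deg2rad(A_N_CA_C);
  xyz.C[0] = {xyz.CA[0].x - B_CA_C * std::cos(a), B_CA_C * std::sin(a), 0.0};
  for (int i = 1; i < n; ++i) {
    xyz.N[i] = nerf(xyz.N[i - 1], xyz.CA[i - 1], xyz.C[i - 1], B_C_N, A_CA_C_N, psi[i - 1]);
    xyz.CA[i] = nerf(xyz.CA[i - 1], xyz.C[i - 1], xyz.N[i], B_N_CA, A_C_N_CA, omega[i - 1]);
    xyz.C[i] = nerf(xyz.C[i - 1], xyz.N[i], xyz.CA[i], B_CA_C, A_N_CA_C, phi[i]);
  }
  for (int i = 0; i < n; ++i)
    xyz.CB[i] = gly[i] ? xyz.CA[i] : nerf(xyz.C[i], xyz.N[i], xyz.CA[i],
                                          B_CA_CB, A_N_CA_CB, D_C_N_CA_CB);
}

// Soft-core repulsion: k (r_min - r)^2 for r < r_min over N/CA/C/CB pairs,
// excluding pairs within the same or adjacent residues; CB skipped for Gly.
// A residue-level bound (CA-CA distance) prunes far pairs.
static double clash_energy_c(const Coords &xyz, const std::vector<int> &gly,
                             double r_min, double k) {
  int n = (int)xyz.N.size();
  double e = 0.0, rm2 = r_min * r_min;
  double bound = r_min + 2.0 * 1.6;  // max atom offset from its CA is < 1.6 A
  double bound2 = bound * bound;
  for (int i = 0; i < n; ++i) {
    const Vec3 *ai[4] = {&xyz.N[i], &xyz.CA[i], &xyz.C[i], &xyz.CB[i]};
    int na = gly[i] ? 3 : 4;
    for (int j = i + 2; j < n; ++j) {
      if (dist2(xyz.CA[i], xyz.CA[j]) > bound2) continue;
      const Vec3 *aj[4] = {&xyz.N[j], &xyz.CA[j], &xyz.C[j], &xyz.CB[j]};
      int nb = gly[j] ? 3 : 4;
      for (int a2 = 0; a2 < na; ++a2)
        for (int b2 = 0; b2 < nb; ++b2) {
          double d2 = dist2(*ai[a2], *aj[b2]);
          if (d2 < rm2) {
            double d = std::sqrt(d2);
            e += k * (r_min - d) * (r_min - d);
          }
        }
    }
  }
  return e;
}

// Restraint energy: lambda (d - d0)^2 + D^2 (1 - lambda^2) for d > d0, else 0.
static double restraint_energy_c(const Coords &xyz,
                                 const std::vector<int> &ci, const std::vector<int> &cj,
                                 const std::vector<double> &lam, double d0, double D) {
  double e = 0.0, D2 = D * D;
  for (size_t t = 0; t < ci.size(); ++t) {
    double d = std::sqrt(dist2(xyz.CB[ci[t]], xyz.CB[cj[t]]));
    if (d > d0) e += lam[t] * (d - d0) * (d - d0) + D2 * (1.0 - lam[t] * lam[t]);
  }
  return e;
}

static NumericMatrix to_matrix(const std::vector<Vec3> &v) {
  NumericMatrix m((int)v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i) {
    m(i, 0) = v[i].x; m(i, 1) = v[i].y; m(i, 2) = v[i].z;
  }
  return m;
}

static Coords coords_from_matrices(NumericMatrix N, NumericMatrix CA,
                                   NumericMatrix C, NumericMatrix CB) {
  Coords xyz;
  int n = N.nrow();
  xyz.resize(n);
  for (int i = 0; i < n; ++i) {
    xyz.N[i] = {N(i, 0), N(i, 1), N(i, 2)};
    xyz.CA[i] = {CA(i, 0), CA(i, 1), CA(i, 2)};
    xyz.C[i] = {C(i, 0), C(i, 1), C(i, 2)};
    xyz.CB[i] = {CB(i, 0), CB(i, 1), CB(i, 2)};
  }
  return xyz;
}

// [[Rcpp::export]]
List cf_build_coords(NumericVector phi, NumericVector psi, NumericVector omega,
                     LogicalVector is_gly) {
  int n = phi.size();
  std::vector<double> p(phi.begin(), phi.end()), s(psi.begin(), psi.end()),
      o(omega.begin(), omega.end());
  std::vector<int> g(is_gly.begin(), is_gly.end());
  Coords xyz;
  (void)n;
  build_chain(p, s, o, g, xyz);
  return List::create(_["N"] = to_matrix(xyz.N), _["CA"] = to_matrix(xyz.CA),
                      _["C"] = to_matrix(xyz.C), _["CB"] = to_matrix(xyz.CB));
}

// [[Rcpp::export]]
double cf_clash_energy(NumericMatrix N, NumericMatrix CA, NumericMatrix C,
                       NumericMatrix CB, LogicalVector is_gly,
                       double r_min, double k) {
  std::vector<int> g(is_gly.begin(), is_gly.end());
  Coords xyz = coords_from_matrices(N, CA, C, CB);
  return clash_energy_c(xyz, g, r_min, k);
}

static inline double wrap_angle(double x) {
  while (x > 180.0) x -= 360.0;
  while (x <= -180.0) x += 360.0;
  return x;
}

// Simulated-annealing engine: Metropolis Monte Carlo on free phi/psi dihedrals
// under E = E_clash + E_rest, with one stochastic lambda update per schedule
// step (drift -gamma * dE/dlambda * dt plus noise delta * sqrt(T dt) * z,
// clamped to [0,1]). Uses R's RNG stream.
// [[Rcpp::export]]
List cf_anneal(NumericVector phi, NumericVector psi, NumericVector omega,
               LogicalVector fixed, LogicalVector is_gly,
               IntegerVector ci, IntegerVector cj, NumericVector lambda0,
               double d0, NumericVector D_sched, NumericVector T_sched,
               int moves_per_step, double max_step,
               double gamma, double delta, double dt,
               bool sample_lambda, double r_min, double k_clash, bool trace) {
  int n = phi.size();
  std::vector<double> p(phi.begin(), phi.end()), s(psi.begin(), psi.end()),
      o(omega.begin(), omega.end());
  std::vector<int> g(is_gly.begin(), is_gly.end());
  std::vector<int> cii(ci.begin(), ci.end()), cjj(cj.begin(), cj.end());
  std::vector<double> lam(lambda0.begin(), lambda0.end());
  int n_steps = D_sched.size();

  // free dihedrals: (residue, 0=phi/1=psi); phi of first and psi of last
  // residue do not affect the coordinates and are excluded
  std::vector<int> fres, fkind;
  for (int i = 0; i < n; ++i) {
    if (!fixed[i]) {
      if (i > 0) { fres.push_back(i); fkind.push_back(0); }
      if (i < n - 1) { fres.push_back(i); fkind.push_back(1); }
    }
  }
  int nfree = (int)fres.size();

  Coords cur, prop;
  build_chain(p, s, o, g, cur);
  double E = clash_energy_c(cur, g, r_min, k_clash) +
             restraint_energy_c(cur, cii, cjj, lam, d0, D_sched[0]);
  long accepted = 0, attempted = 0;
  NumericVector etrace(trace ? n_steps : 0);

  for (int step = 0; step < n_steps; ++step) {
    double D = D_sched[step], T = T_sched[step];
    // D (and lambda, below) change the restraint term: refresh cached energy
    E = clash_energy_c(cur, g, r_min, k_clash) +
        restraint_energy_c(cur, cii, cjj, lam, d0, D);
    for (int m = 0; m < moves_per_step && nfree > 0; ++m) {
      int pick = (int)(R::unif_rand() * nfree);
      if (pick >= nfree) pick = nfree - 1;
      int r = fres[pick], kind = fkind[pick];
      double old = kind == 0 ? p[r] : s[r];
      double cand = wrap_angle(old + (R::unif_rand() * 2.0 - 1.0) * max_step);
      if (kind == 0) p[r] = cand; else s[r] = cand;
      build_chain(p, s, o, g, prop);
      double Enew = clash_energy_c(prop, g, r_min, k_clash) +
                    restraint_energy_c(prop, cii, cjj, lam, d0, D);
      double dE = Enew - E;
      bool acc = dE <= 0.0 || (T > 0.0 && R::unif_rand() < std::exp(-dE / T));
      ++attempted;
      if (acc) {
        std::swap(cur.N, prop.N); std::swap(cur.CA, prop.CA);
        std::swap(cur.C, prop.C); std::swap(cur.CB, prop.CB);
        E = Enew;
        ++accepted;
      } else {
        if (kind == 0) p[r] = old; else s[r] = old;
      }
    }
    if (sample_lambda && !cii.empty()) {
      double noise_scale = delta * std::sqrt(T * dt);
      for (size_t t = 0; t < cii.size(); ++t) {
        double d = std::sqrt(dist2(cur.CB[cii[t]], cur.CB[cjj[t]]));
        double grad = d > d0 ? (d - d0) * (d - d0) - 2.0 * D * D * lam[t] : 0.0;
        double nl = lam[t] - gamma * grad * dt + noise_scale * R::norm_rand();
        if (nl < 0.0) nl = 0.0;
        if (nl > 1.0) nl = 1.0;
        lam[t] = nl;
      }
      E = clash_energy_c(cur, g, r_min, k_clash) +
          restraint_energy_c(cur, cii, cjj, lam, d0, D);
    }
    if (trace) etrace[step] = E;
  }

  return List::create(
      _["phi"] = NumericVector(p.begin(), p.end()),
      _["psi"] = NumericVector(s.begin(), s.end()),
      _["lambda"] = NumericVector(lam.begin(), lam.end()),
      _["N"] = to_matrix(cur.N), _["CA"] = to_matrix(cur.CA),
      _["C"] = to_matrix(cur.C), _["CB"] = to_matrix(cur.CB),
      _["energy"] = E, _["accepted"] = (double)accepted,
      _["attempted"] = (double)attempted,
      _["trace"] = etrace);
}
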