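// Molecular-mechanics engine: energy terms, analytic gradient, and a
// limited-memory quasi-Newton minimiser with backtracking line search.
//
// The R side prepares a "system" list of numeric matrices with 1-based
// atom indices:
//   bonds          n x 4  (i, j, ks, r0)         E = ks * (r - r0)^2
//   angles         n x 5  (i, j, k, kb, theta0)  E = kb * (theta - theta0)^2,
//                                                theta0 in radians
//   torsions       n x 7  (i, j, k, l, V1, V2, V3)
//                  E = 0.5*(V1*(1+cos p) + V2*(1-cos 2p) + V3*(1+cos 3p))
//   vdw            n x 4  (i, j, eps, rstar)     E = eps*((r*/r)^12 - 2 (r*/r)^6)
//   dist_restraints n x 4 (i, j, k, r0)          E = k * (r - r0)^2
//   tors_restraints n x 6 (i, j, k, l, k, phi0)  E = k * (1 - cos(p - phi0)),
//                                                phi0 in radians
// Energies kcal/mol, lengths Angstrom.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 scale(const Vec3& a, double s) {
  return Vec3{a.x * s, a.y * s, a.z * s};
}

class System {
 public:
  NumericMatrix bonds, angles, torsions, vdw, drestr, trestr;
  explicit System(List sys)
      : bonds(as<NumericMatrix>(sys["bonds"])),
        angles(as<NumericMatrix>(sys["angles"])),
        torsions(as<NumericMatrix>(sys["torsions"])),
        vdw(as<NumericMatrix>(sys["vdw"])),
        drestr(as<NumericMatrix>(sys["dist_restraints"])),
        trestr(as<NumericMatrix>(sys["tors_restraints"])) {}
};

static inline Vec3 get(const std::vector<double>& xyz, int i) {
  return Vec3{xyz[3 * i], xyz[3 * i + 1], xyz[3 * i + 2]};
}
static inline void add_to(std::vector<double>& g, int i, const Vec3& v) {
  g[3 * i] += v.x;
  g[3 * i + 1] += v.y;
  g[3 * i + 2] += v.z;
}

// signed dihedral (radians) and, optionally, its gradient wrt the four atoms
static double dihedral(const Vec3& p1, const Vec3& p2, const Vec3& p3,
                       const Vec3& p4, Vec3* g1 = nullptr, Vec3* g2 = nullptr,
                       Vec3* g3 = nullptr, Vec3* g4 = nullptr) {
  Vec3 b1 = sub(p2, p1), b2 = sub(p3, p2), b3 = sub(p4, p3);
  Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  double lb2 = norm(b2);
  double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
  double x = dot(n1, n2);
  double y = dot(cross(n1, n2), scale(b2, 1.0 / lb2));
  double phi = std::atan2(y, x);
  if (g1 != nullptr) {
    // standard translation/rotation-invariant dihedral derivative
    Vec3 dp1 = scale(n1, -lb2 / n1sq);
    Vec3 dp4 = scale(n2, lb2 / n2sq);
    double S = -dot(b1, b2) / (lb2 * lb2);
    double T = -dot(b3, b2) / (lb2 * lb2);
    Vec3 dp2 = Vec3{(S - 1.0) * dp1.x - T * dp4.x, (S - 1.0) * dp1.y - T * dp4.y,
                    (S - 1.0) * dp1.z - T * dp4.z};
    Vec3 dp3 = Vec3{-S * dp1.x + (T - 1.0) * dp4.x,
                    -S * dp1.y + (T - 1.0) * dp4.y,
                    -S * dp1.z + (T - 1.0) * dp4.z};
    *g1 = dp1;
    *g2 = dp2;
    *g3 = dp3;
    *g4 = dp4;
  }
  return phi;
}

// Evaluates energy components; if grad is non-null, accumulates dE/dx.
static void eval(const System& S, const std::vector<double>& xyz,
                 double comps[5], std::vector<double>* grad) {
  for (int c = 0; c < 5; ++c) comps[c] = 0.0;

  // stretch
  for (int r = 0; r < S.bonds.nrow(); ++r) {
    int i = (int)S.bonds(r, 0) - 1, j = (int)S.bonds(r, 1) - 1;
    double ks = S.bonds(r, 2), r0 = S.bonds(r, 3);
    Vec3 d = sub(get(xyz, i), get(xyz, j));
    double rij = norm(d);
    double dr = rij - r0;
    comps[0] += ks * dr * dr;
    if (grad) {
      double f = 2.0 * ks * dr / rij;
      add_to(*grad, i, scale(d, f));
      add_to(*grad, j, scale(d, -f));
    }
  }

  // bend
  for (int r = 0; r < S.angles.nrow(); ++r) {
    int i = (int)S.angles(r, 0) - 1, j = (int)S.angles(r, 1) - 1,
        k = (int)S.angles(r, 2) - 1;
    double kb = S.angles(r, 3), th0 = S.angles(r, 4);
    Vec3 rij = sub(get(xyz, i), get(xyz, j));
    Vec3 rkj = sub(get(xyz, k), get(xyz, j));
    double lij = norm(rij), lkj = norm(rkj);
    double c = dot(rij, rkj) / (lij * lkj);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double dth = th - th0;
    comps[1] += kb * dth * dth;
    if (grad) {
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      double pref = 2.0 * kb * dth;
      // d(theta)/d(pi), d(theta)/d(pk)
      Vec3 gi = scale(sub(scale(rij, c / lij), scale(rkj, 1.0 / lkj)),
                      1.0 / (lij * s));
      Vec3 gk = scale(sub(scale(rkj, c / lkj), scale(rij, 1.0 / lij)),
                      1.0 / (lkj * s));
      add_to(*grad, i, scale(gi, pref));
      add_to(*grad, k, scale(gk, pref));
      add_to(*grad, j, Vec3{-pref * (gi.x + gk.x), -pref * (gi.y + gk.y),
                            -pref * (gi.z + gk.z)});
    }
  }

  // torsion
  for (int r = 0; r < S.torsions.nrow(); ++r) {
    int i = (int)S.torsions(r, 0) - 1, j = (int)S.torsions(r, 1) - 1,
        k = (int)S.torsions(r, 2) - 1, l = (int)S.torsions(r, 3) - 1;
    double V1 = S.torsions(r, 4), V2 = S.torsions(r, 5), V3 = S.torsions(r, 6);
    Vec3 g1, g2, g3, g4;
    double phi = dihedral(get(xyz, i), get(xyz, j), get(xyz, k), get(xyz, l),
                          grad ? &g1 : nullptr, grad ? &g2 : nullptr,
                          grad ? &g3 : nullptr, grad ? &g4 : nullptr);
    comps[2] += 0.5 * (V1 * (1.0 + std::cos(phi)) + V2 * (1.0 - std::cos(2 * phi)) +
                       V3 * (1.0 + std::cos(3 * phi)));
    if (grad) {
      double dE = 0.5 * (-V1 * std::sin(phi) + 2.0 * V2 * std::sin(2 * phi) -
                         3.0 * V3 * std::sin(3 * phi));
      add_to(*grad, i, scale(g1, dE));
      add_to(*grad, j, scale(g2, dE));
      add_to(*grad, k, scale(g3, dE));
      add_to(*grad, l, scale(g4, dE));
    }
  }

  // van der Waals (Lennard-Jones 6-12, minimum -eps at r = rstar)
  for (int r = 0; r < S.vdw.nrow(); ++r) {
    int i = (int)S.vdw(r, 0) - 1, j = (int)S.vdw(r, 1) - 1;
    double eps = S.vdw(r, 2), rstar = S.vdw(r, 3);
    Vec3 d = sub(get(xyz, i), get(xyz, j));
    double r2 = dot(d, d);
    double s2 = rstar * rstar / r2;
    double s6 = s2 * s2 * s2;
    comps[3] += eps * (s6 * s6 - 2.0 * s6);
    if (grad) {
      double f = eps * 12.0 * (s6 - s6 * s6) / r2;  // dE/dr * (1/r)
      add_to(*grad, i, scale(d, f));
      add_to(*grad, j, scale(d, -f));
    }
  }

  // distance restraints
  for (int r = 0; r < S.drestr.nrow(); ++r) {
    int i = (int)S.drestr(r, 0) - 1, j = (int)S.drestr(r, 1) - 1;
    double kr = S.drestr(r, 2), r0 = S.drestr(r, 3);
    Vec3 d = sub(get(xyz, i), get(xyz, j));
    double rij = norm(d);
    double dr = rij - r0;
    comps[4] += kr * dr * dr;
    if (grad) {
      double f = 2.0 * kr * dr / rij;
      add_to(*grad, i, scale(d, f));
      add_to(*grad, j, scale(d, -f));
    }
  }

  // torsion restraints
  for (int r = 0; r < S.trestr.nrow(); ++r) {
    int i = (int)S.trestr(r, 0) - 1, j = (int)S.trestr(r, 1) - 1,
        k = (int)S.trestr(r, 2) - 1, l = (int)S.trestr(r, 3) - 1;
    double kr = S.trestr(r, 4), phi0 = S.trestr(r, 5);
    Vec3 g1, g2, g3, g4;
    double phi = dihedral(get(xyz, i), get(xyz, j), get(xyz, k), get(xyz, l),
                          grad ? &g1 : nullptr, grad ? &g2 : nullptr,
                          grad ? &g3 : nullptr, grad ? &g4 : nullptr);
    comps[4] += kr * (1.0 - std::cos(phi - phi0));
    if (grad) {
      double dE = kr * std::sin(phi - phi0);
      add_to(*grad, i, scale(g1, dE));
      add_to(*grad, j, scale(g2, dE));
      add_to(*grad, k, scale(g3, dE));
      add_to(*grad, l, scale(g4, dE));
    }
  }
}

static std::vector<double> flatten(const NumericMatrix& coords) {
  int n = coords.nrow();
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i) {
    xyz[3 * i] = coords(i, 0);
    xyz[3 * i + 1] = coords(i, 1);
    xyz[3 * i + 2] = coords(i, 2);
  }
  return xyz;
}

// [[Rcpp::export]]
List mm_energy_cpp(NumericMatrix coords, List sys) {
  System S(sys);
  std::vector<double> xyz = flatten(coords);
  double comps[5];
  eval(S, xyz, comps, nullptr);
  double total = comps[0] + comps[1] + comps[2] + comps[3] + comps[4];
  return List::create(_["stretch"] = comps[0], _["bend"] = comps[1],
                      _["torsion"] = comps[2], _["vdw"] = comps[3],
                      _["restraint"] = comps[4], _["total"] = total);
}

// [[Rcpp::export]]
List mm_gradient_cpp(NumericMatrix coords, List sys) {
  System S(sys);
  std::vector<double> xyz = flatten(coords);
  int n = coords.nrow();
  std::vector<double> g(3 * n, 0.0);
  double comps[5];
  eval(S, xyz, comps, &g);
  double total = comps[0] + comps[1] + comps[2] + comps[3] + comps[4];
  NumericMatrix gm(n, 3);
  for (int i = 0; i < n; ++i) {
    gm(i, 0) = g[3 * i];
    gm(i, 1) = g[3 * i + 1];
    gm(i, 2) = g[3 * i + 2];
  }
  return List::create(_["energy"] = total, _["gradient"] = gm);
}

static double total_energy(const System& S, const std::vector<double>& xyz,
                           std::vector<double>* grad) {
  double comps[5];
  if (grad) std::fill(grad->begin(), grad->end(), 0.0);
  eval(S, xyz, comps, grad);
  return comps[0] + comps[1] + comps[2] + comps[3] + comps[4];
}

// L-BFGS (two-loop recursion, history m) with Armijo backtracking.
// The recorded energy trace is monotone non-increasing by construction.
// [[Rcpp::export]]
List mm_minimize_cpp(NumericMatrix coords, List sys, double tol = 0.01,
                     int maxit = 2000, int history = 6) {
  System S(sys);
  int n = coords.nrow();
  int dim = 3 * n;
  std::vector<double> x = flatten(coords);
  std::vector<double> g(dim, 0.0), gnew(dim, 0.0), xnew(dim, 0.0);
  double E = total_energy(S, x, &g);
  std::vector<double> trace;
  trace.push_back(E);

  std::vector<std::vector<double> > s_hist, y_hist;
  std::vector<double> rho_hist;
  bool converged = false;
  int it = 0;

  for (it = 0; it < maxit; ++it) {
    double gsq = 0.0;
    for (int d = 0; d < dim; ++d) gsq += g[d] * g[d];
    double grms = std::sqrt(gsq / dim);
    if (grms < tol) {
      converged = true;
      break;
    }

    // two-loop recursion for direction p = -H g
    std::vector<double> q(g);
    int m = (int)s_hist.size();
    std::vector<double> alpha(m);
    for (int h = m - 1; h >= 0; --h) {
      double a = 0.0;
      for (int d = 0; d < dim; ++d) a += s_hist[h][d] * q[d];
      a *= rho_hist[h];
      alpha[h] = a;
      for (int d = 0; d < dim; ++d) q[d] -= a * y_hist[h][d];
    }
    double gamma = 1.0;
    if (m > 0) {
      double sy = 0.0, yy = 0.0;
      for (int d = 0; d < dim; ++d) {
        sy += s_hist[m - 1][d] * y_hist[m - 1][d];
        yy += y_hist[m - 1][d] * y_hist[m - 1][d];
      }
      if (yy > 0) gamma = sy / yy;
    } else {
      // conservative first step for a stiff surface
      double gmax = 0.0;
      for (int d = 0; d < dim; ++d) gmax = std::max(gmax, std::fabs(g[d]));
      if (gmax > 0) gamma = std::min(1.0, 0.05 / gmax);
    }
    for (int d = 0; d < dim; ++d) q[d] *= gamma;
    for (int h = 0; h < m; ++h) {
      double b = 0.0;
      for (int d = 0; d < dim; ++d) b += y_hist[h][d] * q[d];
      b *= rho_hist[h];
      for (int d = 0; d < dim; ++d) q[d] += s_hist[h][d] * (alpha[h] - b);
    }
    // descent direction
    double gp = 0.0;
    for (int d = 0; d < dim; ++d) gp += -q[d] * g[d];
    if (gp >= 0) {  // not a descent direction: reset to steepest descent
      s_hist.clear();
      y_hist.clear();
      rho_hist.clear();
      double gmax = 0.0;
      for (int d = 0; d < dim; ++d) gmax = std::max(gmax, std::fabs(g[d]));
      double sc = (gmax > 0) ? std::min(1.0, 0.05 / gmax) : 1.0;
      for (int d = 0; d < dim; ++d) q[d] = g[d] * sc;
      gp = 0.0;
      for (int d = 0; d < dim; ++d) gp += -q[d] * g[d];
    }

    // Armijo backtracking
    double step = 1.0;
    double Enew = E;
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      for (int d = 0; d < dim; ++d) xnew[d] = x[d] - step * q[d];
      Enew = total_energy(S, xnew, nullptr);
      if (std::isfinite(Enew) && Enew <= E + 1e-4 * step * gp) {
        ok = true;
        break;
      }
      step *= 0.5;
    }
    if (!ok) break;  // cannot make progress

    total_energy(S, xnew, &gnew);
    // update history
    std::vector<double> sv(dim), yv(dim);
    double sy = 0.0;
    for (int d = 0; d < dim; ++d) {
      sv[d] = xnew[d] - x[d];
      yv[d] = gnew[d] - g[d];
      sy += sv[d] * yv[d];
    }
    if (sy > 1e-12) {
      s_hist.push_back(sv);
      y_hist.push_back(yv);
      rho_hist.push_back(1.0 / sy);
      if ((int)s_hist.size() > history) {
        s_hist.erase(s_hist.begin());
        y_hist.erase(y_hist.begin());
        rho_hist.erase(rho_hist.begin());
      }
    }
    x = xnew;
    g = gnew;
    E = Enew;
    trace.push_back(E);
    // the line search is monotone, so E above both the cap and the
    // starting energy means a genuinely diverging input
    if (E > 1e6 && E > trace[0]) {
      return List::create(_["diverged"] = true, _["energy"] = E);
    }
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[3 * i];
    out(i, 1) = x[3 * i + 1];
    out(i, 2) = x[3 * i + 2];
  }
  return List::create(_["coords"] = out, _["energy"] = E,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged, _["niter"] = it,
                      _["diverged"] = false);
}
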