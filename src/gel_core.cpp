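// Core kernels: two-body + three-body force field with Lees-Edwards periodic
// boundaries, velocity-Verlet integrators (conservative / Nose-Hoover /
// zero-T damped), per-interaction virial stress, and pore-size kernels.
//
// Conventions fixed package-wide: flow = x, gradient = z, vorticity = y.
// Reduced units d = eps = m = 1; the drag coefficient zeta multiplies -v.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Model {
  int nsp;
  std::vector<double> A;   // nsp x nsp pair strengths
  std::vector<double> B;   // nsp^3 triplet strengths, keyed by species set
  std::vector<double> cb;  // nsp^3 preferred bond-angle cosines
  double d2, d3, rcut, w, skin;
};

Model model_from_list(const List& ml) {
  Model m;
  NumericMatrix A = ml["A"];
  NumericVector B = ml["B"], cb = ml["cb"];
  m.nsp = A.nrow();
  m.A.assign(A.begin(), A.end());
  m.B.assign(B.begin(), B.end());
  m.cb.assign(cb.begin(), cb.end());
  m.d2 = as<double>(ml["d2"]);
  m.d3 = as<double>(ml["d3"]);
  m.rcut = as<double>(ml["rcut"]);
  m.w = as<double>(ml["w"]);
  m.skin = ml.containsElementNamed("skin") ? as<double>(ml["skin"]) : 0.3;
  return m;
}

// Lees-Edwards minimum image: wrap gradient (z) first, shifting the flow (x)
// component by the image offset, then wrap x and y conventionally.
inline void min_image(double& dx, double& dy, double& dz, double L, double le) {
  double nz = std::nearbyint(dz / L);
  dz -= nz * L;
  dx -= nz * le;
  dx -= L * std::nearbyint(dx / L);
  dy -= L * std::nearbyint(dy / L);
}

struct System {
  int N;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<int> sp;           // 0-based species index
  double L, le, gamma;           // box, Lees-Edwards offset, accumulated strain
  // tethers (empty = none); anchors are fixed points in the lab frame
  std::vector<double> ax, ay, az, tk;  // per-particle stiffness, 0 = free
  // neighbour bookkeeping
  std::vector<std::vector<int>> nb;  // full adjacency within rcut + skin
  double travel = 1e30;              // displacement bound since last build
  double pe = 0.0, sxz = 0.0;        // set by compute_forces
};

void build_neighbours(System& s, const Model& m) {
  const double rv = m.rcut + m.skin, rv2 = rv * rv;
  s.nb.assign(s.N, std::vector<int>());
  for (int i = 0; i < s.N; ++i) s.nb[i].clear();
  for (int i = 0; i < s.N; ++i) {
    for (int j = i + 1; j < s.N; ++j) {
      double dx = s.x[j] - s.x[i], dy = s.y[j] - s.y[i], dz = s.z[j] - s.z[i];
      min_image(dx, dy, dz, s.L, s.le);
      if (dx * dx + dy * dy + dz * dz < rv2) {
        s.nb[i].push_back(j);
        s.nb[j].push_back(i);
      }
    }
  }
  s.travel = 0.0;
}

inline double pow10i(double v) {  // v^10 by squaring
  double v2 = v * v, v4 = v2 * v2;
  return v4 * v4 * v2;
}

// stress[9] in row-major alpha*3+beta, sigma_ab = -(1/V) sum r_ij,a f_j,b
// (equal to dE/dgamma/V for the zx component under affine shear).
void compute_forces(System& s, const Model& m, double* stress) {
  const double V = s.L * s.L * s.L;
  const double rc2 = m.rcut * m.rcut;
  std::fill(s.fx.begin(), s.fx.end(), 0.0);
  std::fill(s.fy.begin(), s.fy.end(), 0.0);
  std::fill(s.fz.begin(), s.fz.end(), 0.0);
  if (stress) for (int q = 0; q < 9; ++q) stress[q] = 0.0;
  double pe = 0.0, sxz = 0.0;

  // pair term
  for (int i = 0; i < s.N; ++i) {
    for (int jn : s.nb[i]) {
      if (jn <= i) continue;
      double dx = s.x[jn] - s.x[i], dy = s.y[jn] - s.y[i], dz = s.z[jn] - s.z[i];
      min_image(dx, dy, dz, s.L, s.le);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      double A = m.A[s.sp[i] + m.nsp * s.sp[jn]];
      double q2 = (m.d2 / r) * (m.d2 / r);
      double q4 = q2 * q2, q8 = q4 * q4, q16 = q8 * q8, q18 = q16 * q2;
      pe += A * (q18 - q16);
      double dEdr = -(A / r) * (18.0 * q18 - 16.0 * q16);
      // force on j: f_j = -dEdr * rhat
      double c = -dEdr / r;
      double fjx = c * dx, fjy = c * dy, fjz = c * dz;
      s.fx[jn] += fjx; s.fy[jn] += fjy; s.fz[jn] += fjz;
      s.fx[i] -= fjx; s.fy[i] -= fjy; s.fz[i] -= fjz;
      sxz += -dz * fjx / V;
      if (stress) {
        double rv[3] = {dx, dy, dz}, fv[3] = {fjx, fjy, fjz};
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) stress[a * 3 + b] -= rv[a] * fv[b] / V;
      }
    }
  }

  // triplet term: central particle i, unordered neighbour pairs (j,k)
  const double inv_w2 = 1.0 / (m.w * m.w);
  for (int i = 0; i < s.N; ++i) {
    const std::vector<int>& ni = s.nb[i];
    const int nn = (int)ni.size();
    if (nn < 2) continue;
    // cache bond vectors within true cutoff
    std::vector<double> bx(nn), by(nn), bz(nn), br(nn);
    std::vector<char> ok(nn);
    for (int a = 0; a < nn; ++a) {
      double dx = s.x[ni[a]] - s.x[i], dy = s.y[ni[a]] - s.y[i], dz = s.z[ni[a]] - s.z[i];
      min_image(dx, dy, dz, s.L, s.le);
      double r2 = dx * dx + dy * dy + dz * dz;
      ok[a] = r2 < rc2;
      bx[a] = dx; by[a] = dy; bz[a] = dz; br[a] = std::sqrt(r2);
    }
    for (int a = 0; a < nn; ++a) {
      if (!ok[a]) continue;
      int j = ni[a];
      double r1 = br[a];
      double u1 = pow10i(r1 / m.rcut), t1 = pow10i(m.d3 / r1);
      double lam1 = t1 * (1.0 - u1) * (1.0 - u1);
      double dlam1 = -(10.0 / r1) * t1 * (1.0 - u1 * u1);
      for (int b = a + 1; b < nn; ++b) {
        if (!ok[b]) continue;
        int k = ni[b];
        double Bv = m.B[s.sp[i] + m.nsp * (s.sp[j] + m.nsp * s.sp[k])];
        if (Bv == 0.0) continue;
        double cbv = m.cb[s.sp[i] + m.nsp * (s.sp[j] + m.nsp * s.sp[k])];
        double r2n = br[b];
        double u2 = pow10i(r2n / m.rcut), t2 = pow10i(m.d3 / r2n);
        double lam2 = t2 * (1.0 - u2) * (1.0 - u2);
        double dlam2 = -(10.0 / r2n) * t2 * (1.0 - u2 * u2);
        double dot = bx[a] * bx[b] + by[a] * by[b] + bz[a] * bz[b];
        double cth = dot / (r1 * r2n);
        double qq = (cth - cbv);
        double G = std::exp(-qq * qq * inv_w2);
        double E = Bv * lam1 * lam2 * G;
        pe += E;
        double dGdc = -2.0 * qq * inv_w2 * G;
        // gradients wrt bond vectors r_ij (=g1) and r_ik (=g2)
        double radial1 = Bv * dlam1 * lam2 * G / r1;     // times r_ij
        double radial2 = Bv * lam1 * dlam2 * G / r2n;    // times r_ik
        double ang = Bv * lam1 * lam2 * dGdc;
        // dc/dr_ij = r_ik/(r1 r2) - c r_ij / r1^2
        double c1a = ang / (r1 * r2n), c1b = -ang * cth / (r1 * r1);
        double c2a = ang / (r1 * r2n), c2b = -ang * cth / (r2n * r2n);
        double g1x = radial1 * bx[a] + c1a * bx[b] + c1b * bx[a];
        double g1y = radial1 * by[a] + c1a * by[b] + c1b * by[a];
        double g1z = radial1 * bz[a] + c1a * bz[b] + c1b * bz[a];
        double g2x = radial2 * bx[b] + c2a * bx[a] + c2b * bx[b];
        double g2y = radial2 * by[b] + c2a * by[a] + c2b * by[b];
        double g2z = radial2 * bz[b] + c2a * bz[a] + c2b * bz[b];
        // forces: f_j = -g1, f_k = -g2, f_i = g1 + g2
        s.fx[j] -= g1x; s.fy[j] -= g1y; s.fz[j] -= g1z;
        s.fx[k] -= g2x; s.fy[k] -= g2y; s.fz[k] -= g2z;
        s.fx[i] += g1x + g2x; s.fy[i] += g1y + g2y; s.fz[i] += g1z + g2z;
        sxz += (bz[a] * g1x + bz[b] * g2x) / V;
        if (stress) {
          double rv1[3] = {bx[a], by[a], bz[a]}, rv2[3] = {bx[b], by[b], bz[b]};
          double f1[3] = {-g1x, -g1y, -g1z}, f2[3] = {-g2x, -g2y, -g2z};
          for (int p = 0; p < 3; ++p)
            for (int q = 0; q < 3; ++q)
              stress[p * 3 + q] -= (rv1[p] * f1[q] + rv2[p] * f2[q]) / V;
        }
      }
    }
  }

  // harmonic tethers; single-sum virial with the fixed anchor as reference
  if (!s.ax.empty()) {
    for (int i = 0; i < s.N; ++i) {
      double k = s.tk[i];
      if (k == 0.0) continue;
      double ux = s.x[i] - s.ax[i], uy = s.y[i] - s.ay[i], uz = s.z[i] - s.az[i];
      min_image(ux, uy, uz, s.L, s.le);
      pe += 0.5 * k * (ux * ux + uy * uy + uz * uz);
      s.fx[i] -= k * ux; s.fy[i] -= k * uy; s.fz[i] -= k * uz;
      sxz += k * ux * s.az[i] / V;
    }
  }

  s.pe = pe;
  s.sxz = sxz;
}

void wrap_positions(System& s) {
  for (int i = 0; i < s.N; ++i) {
    double nz = std::floor(s.z[i] / s.L);
    if (nz != 0.0) { s.z[i] -= nz * s.L; s.x[i] -= nz * s.le; }
    s.x[i] -= s.L * std::floor(s.x[i] / s.L);
    s.y[i] -= s.L * std::floor(s.y[i] / s.L);
  }
}

System system_from_args(NumericMatrix pos, NumericMatrix vel, IntegerVector sp,
                        double L, double le, double gamma) {
  System s;
  s.N = pos.nrow();
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  s.vx.assign(s.N, 0.0); s.vy.assign(s.N, 0.0); s.vz.assign(s.N, 0.0);
  s.fx.assign(s.N, 0.0); s.fy.assign(s.N, 0.0); s.fz.assign(s.N, 0.0);
  s.sp.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.sp[i] = sp[i];
  }
  if (vel.nrow() == s.N && s.N > 0)
    for (int i = 0; i < s.N; ++i) {
      s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
    }
  s.L = L; s.le = le; s.gamma = gamma;
  return s;
}

}  // namespace

// [[Rcpp::export]]
List cpp_forces_stress(NumericMatrix pos, IntegerVector sp, double L,
                       double le, List model) {
  Model m = model_from_list(model);
  if (L < 2.0 * m.rcut)
    stop("box length %f smaller than twice the interaction cutoff %f", L, m.rcut);
  System s = system_from_args(pos, NumericMatrix(0, 3), sp, L, le, 0.0);
  double stress[9];
  s.travel = 1e30;
  Model m0 = m; m0.skin = 0.0;
  build_neighbours(s, m0);
  compute_forces(s, m, stress);
  NumericMatrix F(s.N, 3), S(3, 3);
  for (int i = 0; i < s.N; ++i) { F(i,0)=s.fx[i]; F(i,1)=s.fy[i]; F(i,2)=s.fz[i]; }
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) S(a,b) = stress[a*3+b];
  return List::create(_["forces"] = F, _["potential_energy"] = s.pe,
                      _["stress"] = S);
}

// mode: 0 conservative, 1 Nose-Hoover, 2 damped zero-T
// strain_inc: per-step affine strain increments (length nsteps) or length 0.
// Returns evolved state plus a log sampled every log_stride steps.
// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos, NumericMatrix vel, IntegerVector sp,
                double L, double le, double gamma, List model,
                int mode, double dt, int nsteps,
                double targetT, double nh_tau, double zeta, double xi0,
                NumericVector strain_inc, int log_stride,
                NumericMatrix anchors, NumericVector tether_k,
                double stopT, int check_stride) {
  Model m = model_from_list(model);
  if (L < 2.0 * m.rcut)
    stop("box length %f smaller than twice the interaction cutoff %f", L, m.rcut);
  System s = system_from_args(pos, vel, sp, L, le, gamma);
  if (anchors.nrow() == s.N && s.N > 0 && tether_k.size() == s.N) {
    s.ax.resize(s.N); s.ay.resize(s.N); s.az.resize(s.N);
    s.tk.resize(s.N);
    for (int i = 0; i < s.N; ++i) {
      s.ax[i] = anchors(i, 0); s.ay[i] = anchors(i, 1); s.az[i] = anchors(i, 2);
      s.tk[i] = tether_k[i];
    }
  }
  const bool has_strain = strain_inc.size() == nsteps;
  const int N = s.N;
  const double gdof = 3.0 * std::max(N, 1);
  double xi = (mode == 1) ? xi0 : 0.0;

  build_neighbours(s, m);
  compute_forces(s, m, nullptr);

  int nlog = (log_stride > 0) ? (nsteps / log_stride + 1) : 0;
  NumericMatrix log(nlog, 4);  // time, Tkin, PE, sigma_zx
  int ilog = 0;
  int steps_done = 0;
  bool converged = (mode != 2);
  double Tk = 0.0;
  {
    double ke = 0.0;
    for (int i = 0; i < N; ++i)
      ke += 0.5 * (s.vx[i]*s.vx[i] + s.vy[i]*s.vy[i] + s.vz[i]*s.vz[i]);
    Tk = 2.0 * ke / gdof;
  }
  if (nlog > 0) { log(0,0)=0.0; log(0,1)=Tk; log(0,2)=s.pe; log(0,3)=s.sxz; ilog=1; }

  for (int step = 0; step < nsteps; ++step) {
    if (has_strain && strain_inc[step] != 0.0) {
      double dg = strain_inc[step];
      for (int i = 0; i < N; ++i) s.x[i] += dg * s.z[i];
      s.le += dg * L;
      s.le -= L * std::nearbyint(s.le / L);
      s.gamma += dg;
      s.travel += std::fabs(dg) * L * 0.5;
    }
    double damp = (mode == 1) ? xi : ((mode == 2) ? zeta : 0.0);
    double vmax2 = 0.0;
    for (int i = 0; i < N; ++i) {
      s.vx[i] += 0.5 * dt * (s.fx[i] - damp * s.vx[i]);
      s.vy[i] += 0.5 * dt * (s.fy[i] - damp * s.vy[i]);
      s.vz[i] += 0.5 * dt * (s.fz[i] - damp * s.vz[i]);
      s.x[i] += dt * s.vx[i]; s.y[i] += dt * s.vy[i]; s.z[i] += dt * s.vz[i];
      double v2 = s.vx[i]*s.vx[i] + s.vy[i]*s.vy[i] + s.vz[i]*s.vz[i];
      if (v2 > vmax2) vmax2 = v2;
    }
    wrap_positions(s);
    s.travel += dt * std::sqrt(vmax2);
    if (s.travel > 0.5 * m.skin) build_neighbours(s, m);
    compute_forces(s, m, nullptr);
    if (!std::isfinite(s.pe))
      stop("non-finite potential energy at step %d (particle overlap?)", step + 1);
    double denom = 1.0 + 0.5 * dt * damp;
    double ke = 0.0;
    for (int i = 0; i < N; ++i) {
      s.vx[i] = (s.vx[i] + 0.5 * dt * s.fx[i]) / denom;
      s.vy[i] = (s.vy[i] + 0.5 * dt * s.fy[i]) / denom;
      s.vz[i] = (s.vz[i] + 0.5 * dt * s.fz[i]) / denom;
      ke += 0.5 * (s.vx[i]*s.vx[i] + s.vy[i]*s.vy[i] + s.vz[i]*s.vz[i]);
    }
    Tk = 2.0 * ke / gdof;
    if (mode == 1) xi += dt * (Tk / targetT - 1.0) / (nh_tau * nh_tau);
    ++steps_done;
    if (log_stride > 0 && steps_done % log_stride == 0 && ilog < nlog) {
      log(ilog,0) = steps_done * dt; log(ilog,1) = Tk;
      log(ilog,2) = s.pe; log(ilog,3) = s.sxz; ++ilog;
    }
    if (mode == 2 && stopT > 0.0 && steps_done % check_stride == 0 && Tk < stopT)
      break;
  }
  if (mode == 2 && stopT > 0.0) converged = Tk < stopT;

  NumericMatrix P(N, 3), Vl(N, 3);
  for (int i = 0; i < N; ++i) {
    P(i,0)=s.x[i]; P(i,1)=s.y[i]; P(i,2)=s.z[i];
    Vl(i,0)=s.vx[i]; Vl(i,1)=s.vy[i]; Vl(i,2)=s.vz[i];
  }
  NumericMatrix logout = (ilog > 0) ? NumericMatrix(log(Range(0, ilog - 1), _))
                                    : NumericMatrix(0, 4);
  return List::create(_["positions"] = P, _["velocities"] = Vl,
                      _["le_offset"] = s.le, _["accumulated_strain"] = s.gamma,
                      _["xi"] = xi, _["log"] = logout,
                      _["steps_done"] = steps_done, _["Tkin"] = Tk,
                      _["potential_energy"] = s.pe, _["sigma_zx"] = s.sxz,
                      _["converged"] = converged);
}

// Clearance field: for each node of an Ng^3 grid at coords (L/Ng)*(i,j,k),
// largest probe sphere radius that fits without clashing with any particle:
// max(min_l |r_l - r_grid| - r_colloid, 0), periodic distances.
// Returned flat with index i + Ng*(j + Ng*k).
// [[Rcpp::export]]
NumericVector cpp_pore_clearance(NumericMatrix pos, double L, int Ng,
                                 double r_colloid) {
  const int N = pos.nrow();
  if (N == 0) stop("clearance field undefined for an empty configuration");
  const double h = L / Ng;
  NumericVector out((R_xlen_t)Ng * Ng * Ng);
  for (int k = 0; k < Ng; ++k)
    for (int j = 0; j < Ng; ++j)
      for (int i = 0; i < Ng; ++i) {
        double gx = h * i, gy = h * j, gz = h * k;
        double best = 1e300;
        for (int l = 0; l < N; ++l) {
          double dx = pos(l,0) - gx, dy = pos(l,1) - gy, dz = pos(l,2) - gz;
          dx -= L * std::nearbyint(dx / L);
          dy -= L * std::nearbyint(dy / L);
          dz -= L * std::nearbyint(dz / L);
          double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 < best) best = d2;
        }
        double c = std::sqrt(best) - r_colloid;
        out[i + (R_xlen_t)Ng * (j + (R_xlen_t)Ng * k)] = c > 0 ? c : 0.0;
      }
  return out;
}

// Assign each probe the largest clearance sphere containing it.
// status: 0 accepted, 1 overlaps a particle, 2 not covered by any node sphere.
// node is the 1-based flat index of the assigned node (pore identity).
// [[Rcpp::export]]
List cpp_pore_assign(NumericVector clearance, int Ng, double L,
                     NumericMatrix probes, NumericMatrix pos, double r_colloid) {
  const int Np = probes.nrow(), N = pos.nrow();
  const double h = L / Ng;
  NumericVector R(Np);
  IntegerVector node(Np), status(Np);
  for (int p = 0; p < Np; ++p) {
    double px = probes(p,0), py = probes(p,1), pz = probes(p,2);
    // overlap rejection
    bool overlap = false;
    const double rc2 = r_colloid * r_colloid;
    for (int l = 0; l < N; ++l) {
      double dx = pos(l,0) - px, dy = pos(l,1) - py, dz = pos(l,2) - pz;
      dx -= L * std::nearbyint(dx / L);
      dy -= L * std::nearbyint(dy / L);
      dz -= L * std::nearbyint(dz / L);
      if (dx*dx + dy*dy + dz*dz < rc2) { overlap = true; break; }
    }
    if (overlap) { status[p] = 1; R[p] = 0.0; node[p] = NA_INTEGER; continue; }
    double best = -1.0;
    int besti = -1;
    for (int k = 0; k < Ng; ++k) {
      double dz = h * k - pz; dz -= L * std::nearbyint(dz / L);
      double dz2 = dz * dz;
      for (int j = 0; j < Ng; ++j) {
        double dy = h * j - py; dy -= L * std::nearbyint(dy / L);
        double dyz2 = dz2 + dy * dy;
        for (int i = 0; i < Ng; ++i) {
          R_xlen_t idx = i + (R_xlen_t)Ng * (j + (R_xlen_t)Ng * k);
          double c = clearance[idx];
          if (c <= best || c * c <= dyz2) continue;
          double dx = h * i - px; dx -= L * std::nearbyint(dx / L);
          if (dyz2 + dx * dx < c * c) { best = c; besti = (int)idx; }
        }
      }
    }
    if (besti < 0) { status[p] = 2; R[p] = 0.0; node[p] = NA_INTEGER; }
    else { status[p] = 0; R[p] = best; node[p] = besti + 1; }
  }
  return List::create(_["R"] = R, _["node"] = node, _["status"] = status);
}
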