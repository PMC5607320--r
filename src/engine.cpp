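// Coarse-grained Go-model engine: potential energy terms, analytic forces,
// and Langevin dynamics (BBK velocity-Verlet) with optional constant-velocity
// pulling along z. Positions in Angstrom, energies in eps, mass = 1; time is
// handled in reduced units tau with user-supplied fs_per_tau calibration.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding and polar-method normals: fast and
// bit-reproducible across platforms (trace reproducibility is part of the
// package contract).
struct FastRng {
  uint64_t s[4];
  explicit FastRng(uint64_t seed) {
    build_tables();
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int32_t rand32() { return (int32_t)(next() >> 32); }
  // Marsaglia-Tsang ziggurat tables (classic 128-layer, 32-bit form)
  static uint32_t kn[128];
  static double wn[128], fn[128];
  static bool tables_ready;
  static void build_tables() {
    if (tables_ready) return;
    const double m1 = 2147483648.0;
    const double vn = 9.91256303526217e-3;
    double dn = 3.442619855899, tn = dn;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
    tables_ready = true;
  }
  inline double normal() {
    int32_t hz = rand32();
    for (;;) {
      const int iz = hz & 127;
      const uint32_t az = (uint32_t)(hz < 0 ? -(int64_t)hz : hz);
      if (az < kn[iz]) return hz * wn[iz];
      // nfix
      const double r = 3.442619855899;
      double x = hz * wn[iz];
      if (iz == 0) {
        double y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      hz = rand32();
    }
  }
};
uint32_t FastRng::kn[128];
double FastRng::wn[128], FastRng::fn[128];
bool FastRng::tables_ready = false;

struct Topo {
  int n;
  std::vector<double> x, y, z;           // workspace positions
  std::vector<int> ci, cj;               // native contacts, 0-based
  std::vector<double> sig, sig2;         // native sigma_ij (and squared)
  std::vector<double> cnat;              // native chirality, index i = 1..n-3
  std::vector<int> hphob, mcont;         // per-bead flags
  double zmin, zmax;
  double kbb, d0, sig0, dcut, kchir, emembr;
  bool theta_literal;
  std::vector<unsigned char> is_native;  // n*n lookup (n small enough)
};

struct EnergyTerms {
  double bb = 0, nat = 0, non = 0, chir = 0, membr = 0;
};

Topo build_topo(const NumericMatrix& pos, const List& topo, const List& par) {
  Topo t;
  t.n = pos.nrow();
  t.x.resize(t.n); t.y.resize(t.n); t.z.resize(t.n);
  for (int i = 0; i < t.n; ++i) {
    t.x[i] = pos(i, 0); t.y[i] = pos(i, 1); t.z[i] = pos(i, 2);
  }
  IntegerVector ci = topo["contact_i"], cj = topo["contact_j"];
  NumericVector sig = topo["contact_sigma"];
  for (int k = 0; k < ci.size(); ++k) {
    t.ci.push_back(ci[k] - 1); t.cj.push_back(cj[k] - 1);
    t.sig.push_back(sig[k]);
    t.sig2.push_back(sig[k] * sig[k]);
  }
  NumericVector cn = topo["chirality_native"];  // length n, NA outside 2..n-2
  t.cnat.assign(cn.begin(), cn.end());
  IntegerVector hp = topo["hydrophobic"], mc = topo["membrane_contact"];
  t.hphob.assign(hp.begin(), hp.end());
  t.mcont.assign(mc.begin(), mc.end());
  t.zmin = as<double>(topo["z_min"]); t.zmax = as<double>(topo["z_max"]);
  t.kbb = as<double>(par["k_bb"]); t.d0 = as<double>(par["d0"]);
  t.sig0 = as<double>(par["sigma0"]); t.dcut = as<double>(par["d_cut"]);
  t.kchir = as<double>(par["k_chir"]); t.emembr = as<double>(par["eps_membr"]);
  t.theta_literal = as<bool>(par["theta_literal"]);
  t.is_native.assign((size_t)t.n * t.n, 0);
  for (size_t k = 0; k < t.ci.size(); ++k) {
    t.is_native[(size_t)t.ci[k] * t.n + t.cj[k]] = 1;
    t.is_native[(size_t)t.cj[k] * t.n + t.ci[k]] = 1;
  }
  return t;
}

// Non-native neighbour list with skin; rebuilt on demand by caller.
void build_pairs(const Topo& t, double rlist,
                 std::vector<std::pair<int, int>>& pairs) {
  pairs.clear();
  const double r2 = rlist * rlist;
  for (int i = 0; i < t.n; ++i) {
    for (int j = i + 2; j < t.n; ++j) {
      if (t.is_native[(size_t)i * t.n + j]) continue;
      const double dx = t.x[i] - t.x[j], dy = t.y[i] - t.y[j],
                   dz = t.z[i] - t.z[j];
      if (dx * dx + dy * dy + dz * dz < r2) pairs.emplace_back(i, j);
    }
  }
}

// Accumulate forces (fx,fy,fz) and energy terms for the current positions.
void eval_ff(const Topo& t, const std::vector<std::pair<int, int>>& pairs,
             std::vector<double>& fx, std::vector<double>& fy,
             std::vector<double>& fz, EnergyTerms& e) {
  const int n = t.n;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  e = EnergyTerms();

  // backbone: V = k_BB (r - d0)^2 over consecutive beads
  for (int i = 0; i + 1 < n; ++i) {
    const double dx = t.x[i] - t.x[i + 1], dy = t.y[i] - t.y[i + 1],
                 dz = t.z[i] - t.z[i + 1];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double dr = r - t.d0;
    e.bb += t.kbb * dr * dr;
    const double fs = -2.0 * t.kbb * dr / r;   // force on i along (ri - rj)
    fx[i] += fs * dx; fy[i] += fs * dy; fz[i] += fs * dz;
    fx[i + 1] -= fs * dx; fy[i + 1] -= fs * dy; fz[i + 1] -= fs * dz;
  }

  // native contacts: 4 eps [ (s/r)^12 - (s/r)^6 ]
  for (size_t k = 0; k < t.ci.size(); ++k) {
    const int i = t.ci[k], j = t.cj[k];
    const double dx = t.x[i] - t.x[j], dy = t.y[i] - t.y[j],
                 dz = t.z[i] - t.z[j];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 <= 0) stop("native contact with zero distance");
    const double inv_r2 = 1.0 / r2;
    const double s2 = t.sig2[k] * inv_r2;
    const double s6 = s2 * s2 * s2, s12 = s6 * s6;
    e.nat += 4.0 * (s12 - s6);
    const double fs = 24.0 * (2.0 * s12 - s6) * inv_r2;  // -dV/dr / r
    fx[i] += fs * dx; fy[i] += fs * dy; fz[i] += fs * dz;
    fx[j] -= fs * dx; fy[j] -= fs * dy; fz[j] -= fs * dz;
  }

  // non-native repulsion: shifted LJ below d_cut
  const double dcut2 = t.dcut * t.dcut;
  for (const auto& p : pairs) {
    const int i = p.first, j = p.second;
    const double dx = t.x[i] - t.x[j], dy = t.y[i] - t.y[j],
                 dz = t.z[i] - t.z[j];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= dcut2) continue;
    const double inv_r2 = 1.0 / r2;
    const double s2 = t.sig0 * t.sig0 * inv_r2;
    const double s6 = s2 * s2 * s2, s12 = s6 * s6;
    e.non += 4.0 * (s12 - s6) + 1.0;
    const double fs = 24.0 * (2.0 * s12 - s6) * inv_r2;
    fx[i] += fs * dx; fy[i] += fs * dy; fz[i] += fs * dz;
    fx[j] -= fs * dx; fy[j] -= fs * dy; fz[j] -= fs * dz;
  }

  // chirality: k_CHIR C_i^2 when sign(C_i) opposes sign(C_i^NAT)
  const double d03 = t.d0 * t.d0 * t.d0;
  for (int i = 1; i + 2 < n; ++i) {
    const double cn = t.cnat[i];
    if (!R_finite(cn)) continue;
    // v_{i-1} = r_i - r_{i-1}; v_i = r_{i+1} - r_i; v_{i+1} = r_{i+2} - r_{i+1}
    const double ax = t.x[i] - t.x[i - 1], ay = t.y[i] - t.y[i - 1],
                 az = t.z[i] - t.z[i - 1];
    const double bx = t.x[i + 1] - t.x[i], by = t.y[i + 1] - t.y[i],
                 bz = t.z[i + 1] - t.z[i];
    const double cx = t.x[i + 2] - t.x[i + 1], cy = t.y[i + 2] - t.y[i + 1],
                 cz = t.z[i + 2] - t.z[i + 1];
    const double px = ay * bz - az * by, py = az * bx - ax * bz,
                 pz = ax * by - ay * bx;               // a x b
    const double trip = px * cx + py * cy + pz * cz;   // (a x b) . c
    const double C = trip / d03;
    double w;
    if (C * cn < 0) w = 1.0;
    else w = t.theta_literal ? -1.0 : 0.0;
    if (w == 0.0) continue;
    e.chir += w * t.kchir * C * C;
    // dE/dtrip = w * 2 k C / d0^3 ; grads of triple product:
    const double g = w * 2.0 * t.kchir * C / d03;
    // dtrip/da = b x c, dtrip/db = c x a, dtrip/dc = a x b
    const double bax = by * cz - bz * cy, bay = bz * cx - bx * cz,
                 baz = bx * cy - by * cx;              // b x c
    const double cax = cy * az - cz * ay, cay = cz * ax - cx * az,
                 caz = cx * ay - cy * ax;              // c x a
    // a = r_i - r_{i-1}: dE/dr_{i-1} -= g*(b x c); dE/dr_i += g*(b x c); etc.
    // Force = -dE/dr
    fx[i - 1] += g * bax; fy[i - 1] += g * bay; fz[i - 1] += g * baz;
    fx[i]     -= g * bax; fy[i]     -= g * bay; fz[i]     -= g * baz;
    fx[i]     += g * cax; fy[i]     += g * cay; fz[i]     += g * caz;
    fx[i + 1] -= g * cax; fy[i + 1] -= g * cay; fz[i + 1] -= g * caz;
    fx[i + 1] += g * px;  fy[i + 1] += g * py;  fz[i + 1] += g * pz;
    fx[i + 2] -= g * px;  fy[i + 2] -= g * py;  fz[i + 2] -= g * pz;
  }

  // membrane slab: penalty eps_membr outside, linear 3 A ramps at the borders;
  // sign +1 for hydrophobic beads, -1 for hydrophilic; native-contact beads only
  if (t.emembr != 0.0) {
    for (int i = 0; i < n; ++i) {
      if (!t.mcont[i]) continue;
      const double s = t.hphob[i] ? 1.0 : -1.0;
      const double zi = t.z[i];
      double ev = 0, dEdz = 0;
      if (zi > t.zmin && zi < t.zmax) {
        ev = 0;
      } else if (zi >= t.zmin - 3.0 && zi <= t.zmin) {
        ev = t.emembr * (t.zmin - zi) / 3.0; dEdz = -t.emembr / 3.0;
      } else if (zi >= t.zmax && zi <= t.zmax + 3.0) {
        ev = t.emembr * (zi - t.zmax) / 3.0; dEdz = t.emembr / 3.0;
      } else {
        ev = t.emembr;
      }
      e.membr += s * ev;
      fz[i] -= s * dEdz;
    }
  }
}

NumericVector terms_vector(const EnergyTerms& e) {
  NumericVector out = NumericVector::create(
      _["v_bb"] = e.bb, _["v_nat"] = e.nat, _["v_non"] = e.non,
      _["v_chir"] = e.chir, _["v_membr"] = e.membr,
      _["total"] = e.bb + e.nat + e.non + e.chir + e.membr);
  return out;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix pos, List topo, List par) {
  Topo t = build_topo(pos, topo, par);
  std::vector<std::pair<int, int>> pairs;
  build_pairs(t, t.dcut, pairs);
  std::vector<double> fx(t.n), fy(t.n), fz(t.n);
  EnergyTerms e;
  eval_ff(t, pairs, fx, fy, fz, e);
  return terms_vector(e);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, List topo, List par) {
  Topo t = build_topo(pos, topo, par);
  std::vector<std::pair<int, int>> pairs;
  build_pairs(t, t.dcut, pairs);
  std::vector<double> fx(t.n), fy(t.n), fz(t.n);
  EnergyTerms e;
  eval_ff(t, pairs, fx, fy, fz, e);
  NumericMatrix out(t.n, 3);
  for (int i = 0; i < t.n; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return out;
}

// Langevin dynamics (BBK discretisation of m r" = -gamma r' + F + noise).
// integ: dt_fs, gamma_fs, k_bt, fs_per_tau, seed
// pull (optional): pulled (1-based bead), k_pull, v_pull_fs, plus the spring
// anchor starting at the pulled bead's initial z (pulling axis = z).
// anchor: 1-based bead held fixed (0 = none).
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, List topo, List par,
                List integ, int n_steps, int stride, int anchor,
                Nullable<List> pull_, bool stop_when_detached = false) {
  Topo t = build_topo(pos, topo, par);
  const int n = t.n;
  const double fs_per_tau = as<double>(integ["fs_per_tau"]);
  const double dt = as<double>(integ["dt_fs"]) / fs_per_tau;
  const double gam = as<double>(integ["gamma_fs"]) * fs_per_tau;
  const double kbt = as<double>(integ["k_bt"]);
  const unsigned int seed = (unsigned int)as<double>(integ["seed"]);
  const double dt_fs = as<double>(integ["dt_fs"]);

  bool pulling = pull_.isNotNull();
  int pulled = -1;
  double k_pull = 0, v_pull = 0, anchor_z0 = 0, z_pull0 = 0;
  if (pulling) {
    List pull(pull_);
    pulled = as<int>(pull["pulled"]) - 1;
    k_pull = as<double>(pull["k_pull"]);
    v_pull = as<double>(pull["v_pull_fs"]) * fs_per_tau;  // A per tau
    z_pull0 = t.z[pulled];
    anchor_z0 = z_pull0;
  }
  const int anch = anchor - 1;  // -1 = none

  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  FastRng rng(seed);
  const double noise_amp = (gam > 0 && kbt > 0)
                               ? std::sqrt(2.0 * gam * kbt / dt) : 0.0;
  // BBK shares one random force per time label between the second half-kick
  // of a step and the first half-kick of the next (full-step impulse
  // variance 2 gamma kBT dt)
  std::vector<double> rxc(n, 0.0), ryc(n, 0.0), rzc(n, 0.0);
  if (noise_amp > 0)
    for (int i = 0; i < n; ++i) {
      rxc[i] = noise_amp * rng.normal();
      ryc[i] = noise_amp * rng.normal();
      rzc[i] = noise_amp * rng.normal();
    }

  const double skin = 2.0;
  std::vector<std::pair<int, int>> pairs;
  std::vector<double> x0 = t.x, y0 = t.y, z0 = t.z;  // since last rebuild
  build_pairs(t, t.dcut + skin, pairs);
  std::vector<double> fx(n), fy(n), fz(n);
  EnergyTerms e;
  eval_ff(t, pairs, fx, fy, fz, e);

  auto add_spring = [&](double tnow) {
    if (!pulling) return;
    const double za = anchor_z0 + v_pull * tnow;
    const double f = k_pull * (za - t.z[pulled]);
    fz[pulled] += f;
  };
  add_spring(0.0);
  if (anch >= 0) { fx[anch] = fy[anch] = fz[anch] = 0; vx[anch] = vy[anch] = vz[anch] = 0; }

  const int n_rec = n_steps / stride + 1;
  NumericVector r_step(n_rec), r_disp(n_rec), r_ext(n_rec), r_force(n_rec),
      r_ke(n_rec), r_q(n_rec), r_nunf(n_rec), r_vbb(n_rec), r_vnat(n_rec),
      r_vnon(n_rec), r_vchir(n_rec), r_vmembr(n_rec);
  int rec = 0;
  const int n_contacts = (int)t.ci.size();
  std::vector<unsigned char> has_intact(n);

  auto record = [&](int step) {
    double ke = 0;
    int ndof = 0;
    for (int i = 0; i < n; ++i) {
      if (i == anch) continue;
      ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      ndof += 3;
    }
    std::fill(has_intact.begin(), has_intact.end(), 0);
    int intact = 0;
    for (int k = 0; k < n_contacts; ++k) {
      const int i = t.ci[k], j = t.cj[k];
      const double dx = t.x[i] - t.x[j], dy = t.y[i] - t.y[j],
                   dz = t.z[i] - t.z[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double lim = 1.5 * t.sig[k];
      if (r2 < lim * lim) { ++intact; has_intact[i] = has_intact[j] = 1; }
    }
    int nunf = 0;
    if (pulling) {
      if (pulled >= n / 2) {
        for (int i = n - 1; i >= 0 && !has_intact[i]; --i) ++nunf;
      } else {
        for (int i = 0; i < n && !has_intact[i]; ++i) ++nunf;
      }
    }
    const double tnow = step * dt;
    r_step[rec] = step;
    r_disp[rec] = pulling ? v_pull * tnow : 0.0;
    r_ext[rec] = pulling ? (t.z[pulled] - z_pull0) : 0.0;
    r_force[rec] = pulling
        ? k_pull * (anchor_z0 + v_pull * tnow - t.z[pulled]) : 0.0;
    r_ke[rec] = ke;
    r_q[rec] = n_contacts > 0 ? (double)intact / n_contacts : NA_REAL;
    r_nunf[rec] = nunf;
    r_vbb[rec] = e.bb; r_vnat[rec] = e.nat; r_vnon[rec] = e.non;
    r_vchir[rec] = e.chir; r_vmembr[rec] = e.membr;
    ++rec;
    // "detached" tolerates a residual 1% of contacts: pairs whose native
    // separation is wide enough that 1.5*sigma exceeds the stretched-chain
    // spacing can never register as broken
    return n_contacts > 0 && intact <= n_contacts / 100;
  };
  record(0);

  const double half = 0.5 * dt;
  bool detached = false;
  int step_done = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // half kick (friction + noise applied as explicit forces, BBK)
    for (int i = 0; i < n; ++i) {
      if (i == anch) continue;
      vx[i] += half * (fx[i] - gam * vx[i] + rxc[i]);
      vy[i] += half * (fy[i] - gam * vy[i] + ryc[i]);
      vz[i] += half * (fz[i] - gam * vz[i] + rzc[i]);
      t.x[i] += dt * vx[i]; t.y[i] += dt * vy[i]; t.z[i] += dt * vz[i];
    }
    // neighbour-list refresh on displacement
    double max2 = 0;
    for (int i = 0; i < n; ++i) {
      const double dx = t.x[i] - x0[i], dy = t.y[i] - y0[i],
                   dz = t.z[i] - z0[i];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > max2) max2 = d2;
    }
    if (max2 > 0.25 * skin * skin) {
      build_pairs(t, t.dcut + skin, pairs);
      x0 = t.x; y0 = t.y; z0 = t.z;
    }
    eval_ff(t, pairs, fx, fy, fz, e);
    add_spring(step * dt);
    if (anch >= 0) { fx[anch] = fy[anch] = fz[anch] = 0; }
    const double denom = 1.0 + half * gam;
    for (int i = 0; i < n; ++i) {
      if (i == anch) continue;
      if (noise_amp > 0) {
        rxc[i] = noise_amp * rng.normal();
        ryc[i] = noise_amp * rng.normal();
        rzc[i] = noise_amp * rng.normal();
      }
      vx[i] = (vx[i] + half * (fx[i] + rxc[i])) / denom;
      vy[i] = (vy[i] + half * (fy[i] + ryc[i])) / denom;
      vz[i] = (vz[i] + half * (fz[i] + rzc[i])) / denom;
    }
    if (!R_finite(t.x[0]) || !R_finite(fx[0]))
      stop("non-finite coordinate at step %d: integration diverged", step);
    step_done = step;
    if (step % stride == 0) {
      const bool all_broken = record(step);
      if (stop_when_detached && all_broken) { detached = true; break; }
      if (step % (stride * 64) == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = t.x[i]; pos_out(i, 1) = t.y[i]; pos_out(i, 2) = t.z[i];
    vel_out(i, 0) = vx[i]; vel_out(i, 1) = vy[i]; vel_out(i, 2) = vz[i];
  }
  auto head = [&](NumericVector v) { return NumericVector(v.begin(), v.begin() + rec); };
  DataFrame trace = DataFrame::create(
      _["step"] = head(r_step),
      _["time_fs"] = head(r_step) * dt_fs,
      _["displacement_A"] = head(r_disp),
      _["extension_A"] = head(r_ext),
      _["force"] = head(r_force),
      _["kinetic"] = head(r_ke),
      _["q"] = head(r_q),
      _["n_unfolded"] = head(r_nunf),
      _["v_bb"] = head(r_vbb), _["v_nat"] = head(r_vnat),
      _["v_non"] = head(r_vnon), _["v_chir"] = head(r_vchir),
      _["v_membr"] = head(r_vmembr));
  return List::create(_["trace"] = trace, _["positions"] = pos_out,
                      _["velocities"] = vel_out, _["detached"] = detached,
                      _["steps_run"] = step_done);
}

// Pairwise similarity between rows of a histogram matrix: maximum overlap
// sum(min(a_i, b_{i+s})) over integer bin shifts |s| <= max_shift, after
// normalising each row to unit mass.
// [[Rcpp::export]]
NumericMatrix cpp_shift_overlap(NumericMatrix h, int max_shift) {
  const int n = h.nrow(), m = h.ncol();
  NumericMatrix hn(n, m);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int j = 0; j < m; ++j) s += h(i, j);
    for (int j = 0; j < m; ++j) hn(i, j) = s > 0 ? h(i, j) / s : 0.0;
  }
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    out(a, a) = 1.0;
    for (int b = a + 1; b < n; ++b) {
      double best = 0;
      for (int s = -max_shift; s <= max_shift; ++s) {
        double ov = 0;
        for (int j = 0; j < m; ++j) {
          const int jb = j + s;
          if (jb < 0 || jb >= m) continue;
          ov += std::min(hn(a, j), hn(b, jb));
        }
        if (ov > best) best = ov;
      }
      out(a, b) = out(b, a) = best;
    }
  }
  return out;
}

// Best alignment shift (in bins) of row `b` against reference row `a`.
// [[Rcpp::export]]
int cpp_best_shift(NumericVector a, NumericVector b, int max_shift) {
  const int m = a.size();
  double sa = 0, sb = 0;
  for (int j = 0; j < m; ++j) { sa += a[j]; sb += b[j]; }
  double best = -1; int best_s = 0;
  for (int s = -max_shift; s <= max_shift; ++s) {
    double ov = 0;
    for (int j = 0; j < m; ++j) {
      const int jb = j + s;
      if (jb < 0 || jb >= m) continue;
      ov += std::min(sa > 0 ? a[j] / sa : 0.0, sb > 0 ? b[jb] / sb : 0.0);
    }
    if (ov > best) { best = ov; best_s = s; }
  }
  return best_s;
}
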