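// Kinetic Monte Carlo engine for myosin-S1 binding to regulated actin
// strands under control of a continuous flexible tropomyosin-troponin chain.
//
// The chain is a discretized beam on an elastic foundation (energy
// kappa/2 phi''^2 + alpha/2 phi^2 per unit length) pinned at bound-TnI and
// strong-myosin sites. Mean angles come from a banded constrained solve of
// the pentadiagonal stiffness operator; per-site variances from the
// Takahashi recurrences on the band LDL' factor (exact on the band). After
// each pin change only a window around the change is re-solved: clamping two
// adjacent nodes at a window edge block-separates the pentadiagonal operator,
// so the windowed mean is exact given the clamped values, whose staleness
// decays as exp(-xi * window).
#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(sd);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// pentadiagonal stiffness stencil of the discretized chain energy with
// natural free ends; c4 = kappa/h^3, c0 = alpha*h
struct ChainOp {
  int n;
  double c4, c0;
  inline double K0(int i) const {
    if (i == 0 || i == n - 1) return c4 + c0;
    if (i == 1 || i == n - 2) return 5 * c4 + c0;
    return 6 * c4 + c0;
  }
  inline double K1(int i) const {  // (i, i+1)
    if (i == 0 || i == n - 2) return -2 * c4;
    return -4 * c4;
  }
  inline double K2(int) const { return c4; }  // (i, i+2)
  inline double K(int i, int j) const {
    const int lo = i < j ? i : j;
    const int d = i < j ? j - i : i - j;
    if (d == 0) return K0(lo);
    if (d == 1) return K1(lo);
    if (d == 2) return K2(lo);
    return 0.0;
  }
};

enum SiteState { FREE = 0, WEAK = 1, STRONG = 2 };
enum PinKind { NOPIN = 0, PIN_TNI = 1, PIN_MYO = 2 };

struct Engine {
  // geometry / parameters
  int N, m, n_nodes, n_strands, n_tni;
  double h, kappa, alpha, kBT, phiMinus, phiPlus, sigO, rIo, rM2o;
  bool useChain;
  int Wwin, Wmargin;  // window and sigma-margin, in sites
  ChainOp op;
  std::vector<int> tniSite;       // 0-based site of each regulatory unit
  std::vector<int> tniIdxOfSite;  // site -> regulatory index or -1

  // per-strand state, flat [strand * dim + i]
  std::vector<uint8_t> state, tniB, pin;
  std::vector<double> phiN;        // node mean angle (rad)
  std::vector<double> sigS;        // site SD (rad)
  std::vector<double> rM1, rM2;    // site weights
  std::vector<double> rI;          // regulatory-site weights
  long long nW = 0, nS = 0, nTni = 0;

  // scratch for band solves
  std::vector<double> A0, A1, A2, rhs, ld, l1, l2, y, z0, z1, z2;

  Xoshiro rng;

  void init_geometry(int N_, int m_, int n_strands_, double ds) {
    N = N_; m = m_; n_strands = n_strands_;
    n_nodes = (N - 1) * m + 1;
    h = ds / m;
    op.n = n_nodes;
    op.c4 = kappa / (h * h * h);
    op.c0 = alpha * h;
    tniSite.clear();
    tniIdxOfSite.assign(N, -1);
    for (int s = 2; s < N; s += 7) {  // monomers 3, 10, 17, ... (1-based)
      tniIdxOfSite[s] = (int)tniSite.size();
      tniSite.push_back(s);
    }
    n_tni = (int)tniSite.size();
    size_t nn = (size_t)n_nodes + 4;
    A0.resize(nn); A1.resize(nn); A2.resize(nn); rhs.resize(nn);
    ld.resize(nn); l1.resize(nn); l2.resize(nn); y.resize(nn);
    z0.resize(nn); z1.resize(nn); z2.resize(nn);
  }

  inline double pin_angle(uint8_t kind) const {
    return kind == PIN_TNI ? phiMinus : phiPlus;
  }

  // Constrained banded solve on node window [lo, hi]; updates phiN on the
  // unknown range and (optionally) sigS for sites at least Wmargin sites
  // inside any clamped window edge.
  void solve_window(int st, int lo, int hi, bool want_sigma) {
    const uint8_t* pk = &pin[(size_t)st * N];
    double* phi = &phiN[(size_t)st * n_nodes];
    double* sg = &sigS[(size_t)st * N];

    const int ulo = (lo == 0) ? 0 : lo + 2;
    const int uhi = (hi == n_nodes - 1) ? n_nodes - 1 : hi - 2;
    const int W = uhi - ulo + 1;
    if (W <= 0) return;

    for (int k = 0; k < W; ++k) {
      const int i = ulo + k;
      A0[k] = op.K0(i);
      A1[k] = (k < W - 1) ? op.K1(i) : 0.0;
      A2[k] = (k < W - 2) ? op.K2(i) : 0.0;
      rhs[k] = 0.0;
    }
    // clamped boundary values feed the right-hand side
    if (ulo > 0) {
      rhs[0] -= op.K(ulo, ulo - 1) * phi[ulo - 1] + op.K(ulo, ulo - 2) * phi[ulo - 2];
      if (W > 1) rhs[1] -= op.K(ulo + 1, ulo - 1) * phi[ulo - 1];
    }
    if (uhi < n_nodes - 1) {
      rhs[W - 1] -= op.K(uhi, uhi + 1) * phi[uhi + 1] + op.K(uhi, uhi + 2) * phi[uhi + 2];
      if (W > 1) rhs[W - 2] -= op.K(uhi - 1, uhi + 1) * phi[uhi + 1];
    }
    // pins inside the window: move couplings to rhs, then identity rows
    const int ps_lo = (ulo + m - 1) / m, ps_hi = uhi / m;
    for (int ps = ps_lo; ps <= ps_hi; ++ps) {
      if (pk[ps] == NOPIN) continue;
      const int p = ps * m, k = p - ulo;
      const double ang = pin_angle(pk[ps]);
      for (int d = -2; d <= 2; ++d) {
        if (d == 0) continue;
        const int j = p + d;
        if (j < ulo || j > uhi) continue;
        rhs[j - ulo] -= op.K(j, p) * ang;
      }
      if (k >= 1) A1[k - 1] = 0.0;
      if (k >= 2) A2[k - 2] = 0.0;
      A1[k] = 0.0; A2[k] = 0.0;
    }
    for (int ps = ps_lo; ps <= ps_hi; ++ps) {
      if (pk[ps] == NOPIN) continue;
      const int k = ps * m - ulo;
      A0[k] = 1.0;
      rhs[k] = pin_angle(pk[ps]);
    }

    // band LDL' factorization
    for (int k = 0; k < W; ++k) {
      double d = A0[k];
      if (k > 0) d -= ld[k - 1] * l1[k - 1] * l1[k - 1];
      if (k > 1) d -= ld[k - 2] * l2[k - 2] * l2[k - 2];
      ld[k] = d;
      if (k < W - 1) {
        double x = A1[k];
        if (k > 0) x -= ld[k - 1] * l2[k - 1] * l1[k - 1];
        l1[k] = x / d;
      } else l1[k] = 0.0;
      l2[k] = (k < W - 2) ? A2[k] / d : 0.0;
    }
    // solve L y = rhs, D L' x = y
    for (int k = 0; k < W; ++k) {
      double v = rhs[k];
      if (k > 0) v -= l1[k - 1] * y[k - 1];
      if (k > 1) v -= l2[k - 2] * y[k - 2];
      y[k] = v;
    }
    for (int k = W - 1; k >= 0; --k) {
      double v = y[k] / ld[k];
      if (k < W - 1) v -= l1[k] * phi[ulo + k + 1];
      if (k < W - 2) v -= l2[k] * phi[ulo + k + 2];
      phi[ulo + k] = v;
    }

    if (want_sigma) {
      // Takahashi recurrences for the band of the inverse
      z0[W - 1] = 1.0 / ld[W - 1];
      if (W > 1) {
        z1[W - 2] = -l1[W - 2] * z0[W - 1];
        z0[W - 2] = 1.0 / ld[W - 2] - l1[W - 2] * z1[W - 2];
      }
      for (int k = W - 3; k >= 0; --k) {
        z2[k] = -(l1[k] * z1[k + 1] + l2[k] * z0[k + 2]);
        z1[k] = -(l1[k] * z0[k + 1] + l2[k] * z1[k + 1]);
        z0[k] = 1.0 / ld[k] - l1[k] * z1[k] - l2[k] * z2[k];
      }
      int alo = (lo == 0) ? 0 : lo + Wmargin * m;
      int ahi = (hi == n_nodes - 1) ? n_nodes - 1 : hi - Wmargin * m;
      int s_lo = (alo + m - 1) / m, s_hi = ahi / m;
      for (int ps = s_lo; ps <= s_hi; ++ps) {
        const int p = ps * m;
        if (p < ulo || p > uhi) continue;
        sg[ps] = (pk[ps] != NOPIN) ? 0.0 : std::sqrt(kBT * z0[p - ulo]);
      }
    }
  }

  inline void refresh_r(int st, int s_lo, int s_hi) {
    const double* phi = &phiN[(size_t)st * n_nodes];
    const double* sg = &sigS[(size_t)st * N];
    double* r1 = &rM1[(size_t)st * N];
    double* r2 = &rM2[(size_t)st * N];
    double* ri = &rI[(size_t)st * n_tni];
    const double inv_sqrt2 = 0.7071067811865476;
    if (s_lo < 0) s_lo = 0;
    if (s_hi > N - 1) s_hi = N - 1;
    for (int i = s_lo; i <= s_hi; ++i) {
      const double ph = phi[i * m], s = sg[i];
      if (s > 0) {
        r1[i] = 0.5 * std::erfc(-ph / s * inv_sqrt2);
        r2[i] = 0.5 * std::erfc((phiPlus - ph) / s * inv_sqrt2);
      } else {
        r1[i] = ph > 0 ? 1.0 : (ph == 0 ? 0.5 : 0.0);
        r2[i] = ph > phiPlus ? 1.0 : (ph == phiPlus ? 0.5 : 0.0);
      }
      const int j = tniIdxOfSite[i];
      if (j >= 0) {
        ri[j] = (s > 0) ? 0.5 * std::erfc((ph - phiMinus) / s * inv_sqrt2)
                        : (ph < phiMinus ? 1.0 : (ph == phiMinus ? 0.5 : 0.0));
      }
    }
  }

  void full_solve(int st) {
    solve_window(st, 0, n_nodes - 1, true);
    refresh_r(st, 0, N - 1);
  }

  inline void on_pin_change(int st, int site) {
    if (!useChain) return;
    int lo = (site - Wwin) * m, hi = (site + Wwin) * m;
    if (lo < 0) lo = 0;
    if (hi > n_nodes - 1) hi = n_nodes - 1;
    solve_window(st, lo, hi, true);
    const int ulo = (lo == 0) ? 0 : lo + 2, uhi = (hi == n_nodes - 1) ? n_nodes - 1 : hi - 2;
    refresh_r(st, ulo / m, uhi / m);
  }
};

Engine make_engine(List chain, List config) {
  Engine e;
  e.kappa = as<double>(chain["kappa"]);
  e.alpha = as<double>(chain["alpha"]);
  e.kBT = as<double>(chain["kBT"]);
  e.phiMinus = as<double>(chain["phi_minus_rad"]);
  e.phiPlus = as<double>(chain["phi_plus_rad"]);
  e.sigO = as<double>(chain["sigma_o_rad"]);
  e.rIo = as<double>(chain["r_i_o"]);
  e.rM2o = as<double>(chain["r_m2_o"]);
  e.useChain = as<bool>(config["use_chain"]);
  e.Wwin = as<int>(config["window_sites"]);
  e.Wmargin = as<int>(config["margin_sites"]);
  e.init_geometry(as<int>(config["n_sites"]), as<int>(config["refine"]),
                  as<int>(config["n_strands"]), as<double>(chain["monomer_spacing"]));
  return e;
}

void alloc_state(Engine& e) {
  e.state.assign((size_t)e.n_strands * e.N, FREE);
  e.tniB.assign((size_t)e.n_strands * e.n_tni, 0);
  e.pin.assign((size_t)e.n_strands * e.N, NOPIN);
  e.sigS.assign((size_t)e.n_strands * e.N, 0.0);
  e.rM1.assign((size_t)e.n_strands * e.N, 0.5);
  e.rM2.assign((size_t)e.n_strands * e.N, e.rM2o);
  e.rI.assign((size_t)e.n_strands * e.n_tni, e.rIo);
  if (e.useChain) e.phiN.assign((size_t)e.n_strands * e.n_nodes, 0.0);
}

void load_state(Engine& e, List st) {
  IntegerMatrix sm = st["site_state"];
  IntegerMatrix tm = st["tni_bound"];
  if (sm.nrow() != e.N || sm.ncol() != e.n_strands ||
      tm.nrow() != e.n_tni || tm.ncol() != e.n_strands)
    stop("ensemble state dimensions do not match the configuration");
  alloc_state(e);
  e.nW = e.nS = e.nTni = 0;
  for (int s = 0; s < e.n_strands; ++s) {
    for (int i = 0; i < e.N; ++i) {
      uint8_t v = (uint8_t)sm(i, s);
      e.state[(size_t)s * e.N + i] = v;
      if (v == WEAK) ++e.nW;
      if (v == STRONG) { ++e.nS; e.pin[(size_t)s * e.N + i] = PIN_MYO; }
    }
    for (int j = 0; j < e.n_tni; ++j) {
      uint8_t b = (uint8_t)tm(j, s);
      e.tniB[(size_t)s * e.n_tni + j] = b;
      if (b) { ++e.nTni; e.pin[(size_t)s * e.N + e.tniSite[j]] = PIN_TNI; }
    }
    if (e.useChain) e.full_solve(s);
  }
  NumericVector rs = st["rng_state"];
  std::memcpy(e.rng.s, &rs[0], 4 * sizeof(uint64_t));
}

List dump_state(const Engine& e, double time) {
  IntegerMatrix sm(e.N, e.n_strands), tm(e.n_tni, e.n_strands);
  for (int s = 0; s < e.n_strands; ++s) {
    for (int i = 0; i < e.N; ++i) sm(i, s) = e.state[(size_t)s * e.N + i];
    for (int j = 0; j < e.n_tni; ++j) tm(j, s) = e.tniB[(size_t)s * e.n_tni + j];
  }
  NumericVector rs(4);
  std::memcpy(&rs[0], e.rng.s, 4 * sizeof(uint64_t));
  return List::create(_["site_state"] = sm, _["tni_bound"] = tm,
                      _["time"] = time, _["rng_state"] = rs);
}

List take_snapshot(const Engine& e, double time) {
  IntegerMatrix sm(e.N, e.n_strands), tm(e.n_tni, e.n_strands);
  NumericMatrix ph(e.N, e.n_strands), sg(e.N, e.n_strands);
  const double r2d = 180.0 / M_PI;
  for (int s = 0; s < e.n_strands; ++s) {
    for (int i = 0; i < e.N; ++i) {
      sm(i, s) = e.state[(size_t)s * e.N + i];
      if (e.useChain) {
        ph(i, s) = e.phiN[(size_t)s * e.n_nodes + (size_t)i * e.m] * r2d;
        sg(i, s) = e.sigS[(size_t)s * e.N + i] * r2d;
      }
    }
    for (int j = 0; j < e.n_tni; ++j) tm(j, s) = e.tniB[(size_t)s * e.n_tni + j];
  }
  return List::create(_["time"] = time, _["site_state"] = sm,
                      _["tni_bound"] = tm, _["phi_bar_deg"] = ph,
                      _["sigma_deg"] = sg);
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(List st, List chain, List rates, List config,
             int n_steps, int record_every, IntegerVector snapshot_steps,
             bool tni_only) {
  Engine e = make_engine(chain, config);
  load_state(e, st);
  const double dt = as<double>(config["dt"]);
  const double A_tot = as<double>(config["a_tot"]);
  const double M_tot = as<double>(config["m_tot"]);
  const double kM1 = as<double>(rates["k_on_weak_2nd"]);
  const double kmM1 = as<double>(rates["k_off_weak"]);
  const double kM2 = as<double>(rates["k_iso_fwd"]);
  const double kmM2 = as<double>(rates["k_iso_rev"]);
  const double kIon = as<double>(rates["k_tni_on"]);
  const double kmI = as<double>(rates["k_tni_off"]);
  double t0 = as<double>(st["time"]);

  const long long nA = (long long)e.n_strands * e.N;
  const long long nTniTot = (long long)e.n_strands * e.n_tni;
  const double p_mI = kmI * dt, p_mM1 = kmM1 * dt, p_mM2 = kmM2 * dt;

  const int n_rec = record_every > 0 ? 1 + n_steps / record_every : 0;
  NumericMatrix trace(n_rec, 6);
  int rec = 0;
  std::vector<int> snaps(snapshot_steps.begin(), snapshot_steps.end());
  List snap_out(snaps.size());
  size_t snap_i = 0;

  std::vector<int> changes;
  changes.reserve(64);

  // local copies: uint8 state stores may alias Engine members through
  // type-punning rules, forcing reloads of the RNG and counters every draw
  Xoshiro rng = e.rng;
  long long nWl = e.nW, nSl = e.nS, nTnil = e.nTni;

  for (int step = 0; step <= n_steps; ++step) {
    e.nW = nWl; e.nS = nSl; e.nTni = nTnil;
    const double f = (double)(e.nW + e.nS) / (double)nA;
    double Mfree = M_tot - f * A_tot;
    if (Mfree < 0) Mfree = 0;
    const double delta = 1.0 - 0.82 * f;

    if (record_every > 0 && step % record_every == 0 && rec < n_rec) {
      trace(rec, 0) = t0 + step * dt;
      trace(rec, 1) = 1.0 - (double)e.nS / nA;
      trace(rec, 2) = (double)e.nW / nA;
      trace(rec, 3) = (double)e.nS / nA;
      trace(rec, 4) = nTniTot > 0 ? (double)e.nTni / nTniTot : 0.0;
      trace(rec, 5) = Mfree;
      ++rec;
    }
    while (snap_i < snaps.size() && snaps[snap_i] == step) {
      snap_out[snap_i] = take_snapshot(e, t0 + step * dt);
      ++snap_i;
    }
    if (step == n_steps) break;

    const double cM1 = delta * kM1 * Mfree * dt;       // closed-state bin
    const double cM1w = e.useChain ? cM1 / 0.5 : cM1;  // x r_M1
    const double cM2w = e.useChain ? kM2 * dt / e.rM2o : kM2 * dt;

    for (int s = 0; s < e.n_strands; ++s) {
      uint8_t* stv = &e.state[(size_t)s * e.N];
      uint8_t* tb = &e.tniB[(size_t)s * e.n_tni];
      uint8_t* pk = &e.pin[(size_t)s * e.N];
      const double* r1 = &e.rM1[(size_t)s * e.N];
      const double* r2 = &e.rM2[(size_t)s * e.N];
      const double* ri = &e.rI[(size_t)s * e.n_tni];

      // drawing 1: TnI detachment / rebinding at regulatory sites
      changes.clear();
      const int nT = e.n_tni;
      const bool useChain = e.useChain;
      const double rIo = e.rIo;
      const int* tsite = e.tniSite.data();
      for (int j = 0; j < nT; ++j) {
        const double u = rng.unif();
        const int p = tsite[j];
        if (tb[j]) {
          if (u < p_mI) {
            tb[j] = 0; --nTnil;
            if (useChain) { pk[p] = NOPIN; changes.push_back(p); }
          }
        } else if (stv[p] == FREE) {
          const double pI = (useChain ? ri[j] / rIo : 1.0) * kIon * dt;
          if (u < pI) {
            tb[j] = 1; ++nTnil;
            if (useChain) { pk[p] = PIN_TNI; changes.push_back(p); }
          }
        }
      }
      for (size_t c = 0; c < changes.size(); ++c) e.on_pin_change(s, changes[c]);

      if (tni_only) continue;

      // drawing 2: myosin transitions at every actin site
      changes.clear();
      const int Nl = e.N;
      for (int i = 0; i < Nl; ++i) {
        const double u = rng.unif();
        const uint8_t v = stv[i];
        if (v == FREE) {
          const double p1 = useChain ? cM1w * r1[i] : cM1w;
          if (u < p1) { stv[i] = WEAK; ++nWl; }
        } else if (v == WEAK) {
          const double p2 = useChain ? cM2w * r2[i] : cM2w;
          if (u < p2) {
            stv[i] = STRONG; --nWl; ++nSl;
            if (useChain) { pk[i] = PIN_MYO; changes.push_back(i); }
          } else if (u < p2 + p_mM1) {
            stv[i] = FREE; --nWl;
          }
        } else {  // STRONG
          if (u < p_mM2) {
            stv[i] = WEAK; --nSl; ++nWl;
            if (useChain) { pk[i] = NOPIN; changes.push_back(i); }
          }
        }
      }
      for (size_t c = 0; c < changes.size(); ++c) e.on_pin_change(s, changes[c]);
    }
  }
  e.rng = rng;
  e.nW = nWl; e.nS = nSl; e.nTni = nTnil;

  colnames(trace) = CharacterVector::create("time", "frac_not_R", "frac_weak",
                                            "frac_strong", "frac_tni", "M_free");
  return List::create(_["trace"] = trace,
                      _["state"] = dump_state(e, t0 + n_steps * dt),
                      _["snapshots"] = snap_out);
}

// Full-strand chain solve for one pin configuration, through the same code
// path the engine uses (for cross-validation against the R solver).
// [[Rcpp::export]]
List cpp_chain_sites(IntegerVector pin_kind, List chain, int refine) {
  List config = List::create(
      _["use_chain"] = true, _["window_sites"] = 32, _["margin_sites"] = 14,
      _["n_sites"] = (int)pin_kind.size(), _["refine"] = refine,
      _["n_strands"] = 1);
  Engine e = make_engine(chain, config);
  alloc_state(e);
  for (int i = 0; i < e.N; ++i) e.pin[i] = (uint8_t)pin_kind[i];
  e.full_solve(0);
  const double r2d = 180.0 / M_PI;
  NumericVector ph(e.N), sg(e.N), r1(e.N), r2(e.N);
  for (int i = 0; i < e.N; ++i) {
    ph[i] = e.phiN[(size_t)i * e.m] * r2d;
    sg[i] = e.sigS[i] * r2d;
    r1[i] = e.rM1[i];
    r2[i] = e.rM2[i];
  }
  return List::create(_["phi_bar"] = ph, _["sigma"] = sg,
                      _["r_m1"] = r1, _["r_m2"] = r2);
}

// [[Rcpp::export]]
NumericVector cpp_rng_state(double seed) {
  Xoshiro r;
  r.seed((uint64_t)seed);
  NumericVector out(4);
  std::memcpy(&out[0], r.s, 4 * sizeof(uint64_t));
  return out;
}
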