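// Event-driven (discontinuous) molecular dynamics core.
//
// Motion is ballistic between events; every interaction is a set of
// spherical discontinuity surfaces per pair. The engine advances all
// positions synchronously to each event time, applies the impulse along the
// line of centres (exact momentum and energy bookkeeping), invalidates the
// affected spheres' scheduled events via per-sphere counters and re-predicts
// them by a direct scan. Periodic boundaries use the minimum-image
// convention; every pair prediction is capped at the time its minimum image
// would change, when a no-op refresh event re-predicts it.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

const int KIND_PAIR = 0, KIND_REFRESH = 1, KIND_GHOST = 2,
          KIND_SAMPLE = 3, KIND_ENERGY = 4, KIND_RESCAN = 5;

const int S_CORE = 0, S_BOND_MAX = 1,
          S_OUT_ENTER = 2, S_OUT_EXIT = 3, S_IN_ENTER = 4, S_IN_EXIT = 5,
          S_HB_FORM = 6, S_HB_BREAK = 7, S_HB_EXIT = 8, S_AUX = 9,
          S_NONE = -1;

const double DEAD = 1e-12;     // relative dead band at a surface
const double REPROJ = 1e-9;    // reprojection threshold (Angstrom)

struct Ev {
  double t;
  int kind, i, j, surf;
  unsigned ci, cj;
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.kind != b.kind) return a.kind > b.kind;
    if (a.i != b.i) return a.i > b.i;
    return a.j > b.j;
  }
};

struct Engine {
  int n;
  double L;
  std::vector<double> x, v, mass, radius;
  IntegerMatrix type;
  NumericMatrix d1, d2, din, dout, ein, eout;
  IntegerVector role;        // 1 NH, 2 CA, 3 CO, 4 R
  IntegerVector res_of;      // global residue per sphere (1-based)
  IntegerMatrix rsi;         // residue -> sphere ids (1-based, 0 = none)
  IntegerVector res_chain;
  NumericVector hb_cut;      // n_ca, n_n, c_ca, c_c
  double hb_well;

  std::vector<uint8_t> region;     // side-well shell per pair (0/1/2)
  std::vector<uint8_t> auxcnt;     // active auxiliary-wall count per pair
  std::vector<int> hb_partner;     // sphere id of bonded partner, -1 if free
  std::vector<double> hb_t0;       // formation time per donor sphere
  std::vector<unsigned> cnt;

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> q;

  double now = 0, U = 0, KE = 0;
  double tstar, t_start, t_final, cool_events;
  double n_pair = 0;
  double budget, max_time;
  bool thermostat;
  double ghost_rate, next_ghost;
  double sample_interval, energy_interval;
  double next_sample, next_energy;

  // counters
  double c_core = 0, c_bond = 0, c_well = 0, c_hb_form = 0, c_hb_break = 0,
         c_hb_bounce = 0, c_hb_transparent = 0, c_aux = 0, c_ghost = 0,
         c_refresh = 0, c_stale = 0;

  bool record_events;
  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_surf, ev_i, ev_j;
  bool record_event_vel;
  std::vector<std::vector<double>> ev_vel;

  // frames
  std::vector<double> fr_t, fr_T, fr_U, fr_KE;
  std::vector<NumericMatrix> fr_pos;
  std::vector<std::vector<int>> fr_bonds;
  std::vector<double> en_t, en_U, en_KE, en_T;

  inline int pk(int i, int j) const { return i * n + j; }
  inline double mimg(double d) const { return d - L * std::nearbyint(d / L); }

  void pair_geom(int i, int j, double* dr, double* dv,
                 double& r2, double& b, double& v2) const {
    r2 = b = v2 = 0;
    for (int k = 0; k < 3; ++k) {
      dr[k] = mimg(x[3 * i + k] - x[3 * j + k]);
      dv[k] = v[3 * i + k] - v[3 * j + k];
      r2 += dr[k] * dr[k];
      b += dr[k] * dv[k];
      v2 += dv[k] * dv[k];
    }
  }

  double kinetic() const {
    double ke = 0;
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += v[3 * i + k] * v[3 * i + k];
      ke += 0.5 * mass[i] * s;
    }
    return ke;
  }

  // earliest inward crossing of surface d (from outside), -1 if none
  static double t_in(double r2, double b, double v2, double d) {
    if (b >= 0) return -1;
    double disc = b * b - v2 * (r2 - d * d);
    if (disc <= 0) return -1;
    return (-b - std::sqrt(disc)) / v2;
  }
  // outward crossing of surface d (from inside); always exists for v2 > 0
  static double t_out(double r2, double b, double v2, double d) {
    double disc = b * b - v2 * (r2 - d * d);
    if (disc < 0) disc = 0;
    return (-b + std::sqrt(disc)) / v2;
  }

  double image_horizon(const double* dr, const double* dv) const {
    double t = R_PosInf;
    for (int k = 0; k < 3; ++k) {
      if (dv[k] > 1e-300) t = std::min(t, (L / 2 - dr[k]) / dv[k]);
      else if (dv[k] < -1e-300) t = std::min(t, (-L / 2 - dr[k]) / dv[k]);
    }
    // step strictly past the boundary so the refreshed minimum image flips
    return t + 1e-9;
  }

  int aux_cut_index(int i, int j) const {
    int ri = role[i], rj = role[j];
    if (ri > rj) std::swap(ri, rj);
    if (ri == 1 && rj == 1) return 1;            // N-N
    if (ri == 1 && rj == 2) return 0;            // N-Ca
    if (ri == 2 && rj == 3) return 2;            // C-Ca
    if (ri == 3 && rj == 3) return 3;            // C-C
    return -1;
  }

  void push(double t, int kind, int i, int j, int surf) {
    Ev e;
    e.t = t; e.kind = kind; e.i = i; e.j = j; e.surf = surf;
    e.ci = (i >= 0) ? cnt[i] : 0;
    e.cj = (j >= 0) ? cnt[j] : 0;
    q.push(e);
  }

  void predict_pair(int i, int j) {
    int tt = type(i, j);
    if (tt == 0) return;
    double dr[3], dv[3], r2, b, v2;
    pair_geom(i, j, dr, dv, r2, b, v2);
    if (v2 < 1e-300) return;
    double best = R_PosInf;
    int surf = S_NONE;
    auto consider = [&](double t, int s) {
      if (t >= 0 && t < best) { best = t; surf = s; }
    };
    if (tt == 1) {                               // bonded window
      double lo = d1(i, j), hi = d2(i, j);
      if (r2 <= lo * lo * (1 + DEAD) && b < 0) consider(0, S_CORE);
      else if (r2 >= hi * hi * (1 - DEAD) && b > 0) consider(0, S_BOND_MAX);
      else {
        consider(t_in(r2, b, v2, lo), S_CORE);
        consider(t_out(r2, b, v2, hi), S_BOND_MAX);
      }
    } else if (tt == 2) {                        // hard core (+ aux wall)
      double lo = d1(i, j);
      if (r2 <= lo * lo * (1 + DEAD) && b < 0) consider(0, S_CORE);
      else consider(t_in(r2, b, v2, lo), S_CORE);
      if (auxcnt[pk(i, j)] > 0) {
        int ic = aux_cut_index(i, j);
        if (ic >= 0) {
          double c = hb_cut[ic];
          if (r2 >= c * c * (1 - DEAD) && b > 0) consider(0, S_AUX);
          else consider(t_out(r2, b, v2, c), S_AUX);
        }
      }
    } else if (tt == 3) {                        // side-chain double well
      int reg = region[pk(i, j)];
      double lo = d1(i, j), di = din(i, j), dd = dout(i, j);
      if (reg == 0) {
        if (r2 <= dd * dd * (1 - DEAD) && b < 0) consider(0, S_OUT_ENTER);
        else consider(t_in(r2, b, v2, dd), S_OUT_ENTER);
      } else if (reg == 1) {
        if (r2 <= di * di * (1 + DEAD) && b < 0) consider(0, S_IN_ENTER);
        else consider(t_in(r2, b, v2, di), S_IN_ENTER);
        if (r2 >= dd * dd * (1 - DEAD) && b > 0) consider(0, S_OUT_EXIT);
        else consider(t_out(r2, b, v2, dd), S_OUT_EXIT);
      } else {
        if (r2 <= lo * lo * (1 + DEAD) && b < 0) consider(0, S_CORE);
        else consider(t_in(r2, b, v2, lo), S_CORE);
        if (r2 >= di * di * (1 - DEAD) && b > 0) consider(0, S_IN_EXIT);
        else consider(t_out(r2, b, v2, di), S_IN_EXIT);
      }
    } else if (tt == 4) {                        // hydrogen-bond capable
      double lo = d1(i, j), w = hb_well;
      bool bonded = hb_partner[i] == j;
      if (bonded) {
        if (r2 <= lo * lo * (1 + DEAD) && b < 0) consider(0, S_CORE);
        else if (r2 >= w * w * (1 - DEAD) && b > 0) consider(0, S_HB_BREAK);
        else {
          consider(t_in(r2, b, v2, lo), S_CORE);
          consider(t_out(r2, b, v2, w), S_HB_BREAK);
        }
      } else {
        // a pair exactly at the surface counts as inside when moving
        // inward (post-transparent-crossing) and outside when moving
        // outward (post-exit); this kills zero-time event loops
        bool inside = (r2 < w * w * (1 - DEAD)) ||
                      (r2 <= w * w * (1 + DEAD) && b < 0);
        if (!inside) {
          consider(t_in(r2, b, v2, w), S_HB_FORM);
        } else {
          if (r2 <= lo * lo * (1 + DEAD) && b < 0) consider(0, S_CORE);
          else consider(t_in(r2, b, v2, lo), S_CORE);
          if (r2 < w * w * (1 - DEAD) || b < 0)
            consider(t_out(r2, b, v2, w), S_HB_EXIT);
        }
      }
    }
    double th = image_horizon(dr, dv);
    if (surf != S_NONE && best <= th) {
      push(now + best, KIND_PAIR, i, j, surf);
    } else if (R_finite(th)) {
      push(now + th, KIND_REFRESH, i, j, S_NONE);
    }
  }

  double pair_range(int i, int j, int tt) const {
    switch (tt) {
    case 1: return d2(i, j);
    case 3: return dout(i, j);
    case 4: return hb_well;
    default: {
      double r = d1(i, j);
      if (auxcnt[pk(i, j)] > 0) {
        int ic = aux_cut_index(i, j);
        if (ic >= 0 && hb_cut[ic] > r) r = hb_cut[ic];
      }
      return r;
    }
    }
  }

  // Re-predict sphere i against all partners. Pairs beyond interaction
  // range contribute only a lower bound on their time of first possible
  // contact (minimum-image distance is 1-Lipschitz in the relative
  // displacement), consolidated into a single per-sphere rescan event.
  void repredict_sphere(int i) {
    ++cnt[i];
    double t_rescan = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      int a = std::min(i, j), b_ = std::max(i, j);
      int tt = type(a, b_);
      if (tt == 0) continue;
      double dr[3], dv[3], r2, b, v2;
      pair_geom(a, b_, dr, dv, r2, b, v2);
      double gap = std::sqrt(r2) - pair_range(a, b_, tt);
      if (gap <= 1e-9) {
        predict_pair(a, b_);
      } else {
        if (v2 < 1e-300) continue;
        double reach = gap / std::sqrt(v2);
        if (reach < t_rescan) t_rescan = reach;
      }
    }
    if (R_finite(t_rescan))
      push(now + std::max(t_rescan, 1e-12), KIND_RESCAN, i, -1, S_NONE);
  }

  void advance_all(double t) {
    double dt = t - now;
    if (dt != 0) {
      for (int i = 0; i < 3 * n; ++i) x[i] += v[i] * dt;
      now = t;
    } else {
      now = t;
    }
  }

  // impulse along the line of centres; deltaU is the potential-energy step
  // on crossing. Returns true if the crossing happened, false on reflection.
  bool impulse(int i, int j, double deltaU, bool reflect_only) {
    double dr[3], dv[3], r2, b, v2;
    pair_geom(i, j, dr, dv, r2, b, v2);
    double r = std::sqrt(r2);
    double nh[3] = { dr[0] / r, dr[1] / r, dr[2] / r };
    double vr = (dv[0] * nh[0] + dv[1] * nh[1] + dv[2] * nh[2]);
    double mu = mass[i] * mass[j] / (mass[i] + mass[j]);
    double vr_new;
    bool crossed;
    if (reflect_only || 0.5 * mu * vr * vr <= deltaU) {
      vr_new = -vr;
      crossed = false;
    } else {
      double s = (vr >= 0) ? 1.0 : -1.0;
      vr_new = s * std::sqrt(vr * vr - 2 * deltaU / mu);
      crossed = true;
      U += deltaU;
      KE -= deltaU;
    }
    double dp = mu * (vr_new - vr);
    for (int k = 0; k < 3; ++k) {
      v[3 * i + k] += dp * nh[k] / mass[i];
      v[3 * j + k] -= dp * nh[k] / mass[j];
    }
    return crossed;
  }

  double c_reproj = 0, worst_reproj = 0;

  void reproject(int i, int j, double d) {
    double dr[3], dv[3], r2, b, v2;
    pair_geom(i, j, dr, dv, r2, b, v2);
    double r = std::sqrt(r2);
    if (std::fabs(r - d) <= REPROJ || r < 1e-12) return;
    ++c_reproj;
    if (std::fabs(r - d) > worst_reproj) worst_reproj = std::fabs(r - d);
    if (audit_every > 0 && std::fabs(r - d) > 1e-6)
      Rcpp::Rcout << "REPROJECT t=" << now << " events=" << n_pair
                  << " pair=(" << i + 1 << "," << j + 1 << ") r=" << r
                  << " d=" << d << "\n";
    double corr = 0.5 * (d - r) / r;
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] += corr * dr[k];
      x[3 * j + k] -= corr * dr[k];
    }
  }

  // formation log: time, donor, acceptor, orientation (+1 parallel,
  // -1 antiparallel, 0 unclassifiable at a terminus)
  std::vector<double> hb_log_t;
  std::vector<int> hb_log_d, hb_log_a, hb_log_o, hb_log_f;
  std::vector<double> hb_log_aux[4];

  void log_hb_attempt(int donor, int acceptor, bool formed) {
    hb_log_t.push_back(now);
    hb_log_d.push_back(donor + 1);
    hb_log_a.push_back(acceptor + 1);
    hb_log_o.push_back(formation_orientation(donor, acceptor));
    hb_log_f.push_back(formed ? 1 : 0);
    int aux[4][2];
    hb_aux_spheres(donor, acceptor, aux);
    for (int a = 0; a < 4; ++a) {
      double dr[3], dv[3], r2, b2, v2;
      pair_geom(aux[a][0], aux[a][1], dr, dv, r2, b2, v2);
      hb_log_aux[a].push_back(std::sqrt(r2));
    }
  }

  int formation_orientation(int donor, int acceptor) const {
    int gi = res_of[donor] - 1, gj = res_of[acceptor] - 1;
    int nres = rsi.nrow();
    if (gi - 1 < 0 || gi + 1 >= nres || gj - 1 < 0 || gj + 1 >= nres)
      return 0;
    if (res_chain[gi - 1] != res_chain[gi] ||
        res_chain[gi + 1] != res_chain[gi] ||
        res_chain[gj - 1] != res_chain[gj] ||
        res_chain[gj + 1] != res_chain[gj]) return 0;
    int a1 = rsi(gi - 1, 1) - 1, a2 = rsi(gi + 1, 1) - 1;
    int b1 = rsi(gj - 1, 1) - 1, b2 = rsi(gj + 1, 1) - 1;
    double dot = 0;
    for (int k = 0; k < 3; ++k)
      dot += (x[3 * a2 + k] - x[3 * a1 + k]) * (x[3 * b2 + k] - x[3 * b1 + k]);
    return dot > 0 ? 1 : -1;
  }

  void hb_aux_spheres(int donor, int acceptor, int aux[4][2]) const {
    int gi = res_of[donor] - 1, gj = res_of[acceptor] - 1;
    aux[0][0] = donor;             aux[0][1] = rsi(gj, 1) - 1;      // N_i - Ca_j
    aux[1][0] = donor;             aux[1][1] = rsi(gj + 1, 0) - 1;  // N_i - N_(j+1)
    aux[2][0] = acceptor;          aux[2][1] = rsi(gi, 1) - 1;      // C_j - Ca_i
    aux[3][0] = acceptor;          aux[3][1] = rsi(gi - 1, 2) - 1;  // C_j - C_(i-1)
  }

  bool hb_eligible(int donor, int acceptor) {
    if (hb_partner[donor] >= 0 || hb_partner[acceptor] >= 0) return false;
    int aux[4][2];
    hb_aux_spheres(donor, acceptor, aux);
    for (int a = 0; a < 4; ++a) {
      double dr[3], dv[3], r2, b, v2;
      pair_geom(aux[a][0], aux[a][1], dr, dv, r2, b, v2);
      if (r2 >= hb_cut[a] * hb_cut[a]) return false;
    }
    return true;
  }

  void set_aux_walls(int donor, int acceptor, int delta,
                     std::vector<int>& touched) {
    int aux[4][2];
    hb_aux_spheres(donor, acceptor, aux);
    for (int a = 0; a < 4; ++a) {
      int i = std::min(aux[a][0], aux[a][1]);
      int j = std::max(aux[a][0], aux[a][1]);
      auxcnt[pk(i, j)] += delta;
      auxcnt[pk(j, i)] += delta;
      touched.push_back(aux[a][0]);
      touched.push_back(aux[a][1]);
    }
  }

  void record_event(double t, int kind, int surf, int i, int j) {
    if (!record_events) return;
    ev_t.push_back(t);
    ev_kind.push_back(kind);
    ev_surf.push_back(surf);
    ev_i.push_back(i + 1);
    ev_j.push_back(j + 1);
    if (record_event_vel) ev_vel.push_back(v);
  }

  void take_frame() {
    fr_t.push_back(now);
    fr_T.push_back(tstar);
    fr_U.push_back(U);
    fr_KE.push_back(KE);
    NumericMatrix p(n, 3);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) p(i, k) = x[3 * i + k];
    fr_pos.push_back(p);
    std::vector<int> bonds;
    for (int i = 0; i < n; ++i)
      if (role[i] == 1 && hb_partner[i] >= 0) {
        bonds.push_back(i + 1);
        bonds.push_back(hb_partner[i] + 1);
      }
    fr_bonds.push_back(bonds);
  }

  void take_energy() {
    en_t.push_back(now);
    en_U.push_back(U);
    en_KE.push_back(KE);
    en_T.push_back(tstar);
  }

  void update_temperature() {
    if (cool_events <= 0) { tstar = t_final; return; }
    double f = n_pair / cool_events;
    if (f > 1) f = 1;
    tstar = t_start - (t_start - t_final) * f;
  }

  void ghost_collision() {
    int u = (int)std::floor(unif_rand() * n);
    if (u >= n) u = n - 1;
    double old_ke = 0, new_ke = 0;
    for (int k = 0; k < 3; ++k) {
      old_ke += 0.5 * mass[u] * v[3 * u + k] * v[3 * u + k];
      v[3 * u + k] = std::sqrt(tstar / mass[u]) * norm_rand();
      new_ke += 0.5 * mass[u] * v[3 * u + k] * v[3 * u + k];
    }
    KE += new_ke - old_ke;
    ++c_ghost;
    repredict_sphere(u);
  }

  void execute_pair(const Ev& e) {
    int i = e.i, j = e.j;
    bool counted = true;
    switch (e.surf) {
    case S_CORE:
      reproject(i, j, d1(i, j));
      impulse(i, j, 0, true);
      ++c_core;
      break;
    case S_BOND_MAX:
      reproject(i, j, d2(i, j));
      impulse(i, j, 0, true);
      ++c_bond;
      break;
    case S_OUT_ENTER:
      reproject(i, j, dout(i, j));
      if (impulse(i, j, eout(i, j), false)) {
        region[pk(i, j)] = region[pk(j, i)] = 1;
      }
      ++c_well;
      break;
    case S_OUT_EXIT:
      reproject(i, j, dout(i, j));
      if (impulse(i, j, -eout(i, j), false)) {
        region[pk(i, j)] = region[pk(j, i)] = 0;
      }
      ++c_well;
      break;
    case S_IN_ENTER:
      reproject(i, j, din(i, j));
      if (impulse(i, j, ein(i, j) - eout(i, j), false)) {
        region[pk(i, j)] = region[pk(j, i)] = 2;
      }
      ++c_well;
      break;
    case S_IN_EXIT:
      reproject(i, j, din(i, j));
      if (impulse(i, j, eout(i, j) - ein(i, j), false)) {
        region[pk(i, j)] = region[pk(j, i)] = 1;
      }
      ++c_well;
      break;
    case S_HB_FORM: {
      reproject(i, j, hb_well);
      int donor = (role[i] == 1) ? i : j;
      int acceptor = (role[i] == 1) ? j : i;
      if (hb_eligible(donor, acceptor)) {
        impulse(i, j, -1.0, false);
        hb_partner[donor] = acceptor;
        hb_partner[acceptor] = donor;
        hb_t0[donor] = now;
        log_hb_attempt(donor, acceptor, true);
        std::vector<int> touched;
        set_aux_walls(donor, acceptor, +1, touched);
        ++c_hb_form;
        ++n_pair;
        update_temperature();
        record_event(now, KIND_PAIR, e.surf, i, j);
        repredict_sphere(i);
        repredict_sphere(j);
        for (int s : touched)
          if (s != i && s != j) repredict_sphere(s);
        return;
      } else {
        ++c_hb_transparent;      // ineligible: surface is transparent
        log_hb_attempt(donor, acceptor, false);
      }
      break;
    }
    case S_HB_BREAK: {
      reproject(i, j, hb_well);
      int donor = (role[i] == 1) ? i : j;
      int acceptor = (role[i] == 1) ? j : i;
      if (impulse(i, j, 1.0, false)) {
        hb_partner[donor] = -1;
        hb_partner[acceptor] = -1;
        std::vector<int> touched;
        set_aux_walls(donor, acceptor, -1, touched);
        ++c_hb_break;
        ++n_pair;
        update_temperature();
        record_event(now, KIND_PAIR, e.surf, i, j);
        repredict_sphere(i);
        repredict_sphere(j);
        for (int s : touched)
          if (s != i && s != j) repredict_sphere(s);
        return;
      }
      ++c_hb_bounce;
      break;
    }
    case S_HB_EXIT:
      counted = false;           // bookkeeping only: unbonded pair left well
      break;
    case S_AUX:
      reproject(i, j, hb_cut[aux_cut_index(i, j)]);
      impulse(i, j, 0, true);
      ++c_aux;
      break;
    }
    if (counted) {
      ++n_pair;
      update_temperature();
    }
    record_event(now, KIND_PAIR, e.surf, i, j);
    repredict_sphere(i);
    repredict_sphere(j);
  }

  double audit_every = 0;     // executed-event interval for self-checks
  double audit_last = 0;

  void audit() {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        int tt = type(i, j);
        if (tt == 0) continue;
        double dr[3], dv[3], r2, b, v2;
        pair_geom(i, j, dr, dv, r2, b, v2);
        double r = std::sqrt(r2);
        double lo = d1(i, j), hi = (tt == 1) ? d2(i, j) : R_PosInf;
        if (tt == 3 && region[pk(i, j)] == 2) hi = din(i, j);
        if (tt == 4 && hb_partner[i] == j) hi = hb_well;
        if (r < lo - 1e-7 || r > hi + 1e-7) {
          Rcpp::Rcout << "AUDIT violation at t=" << now
                      << " events=" << n_pair << " pair=(" << i + 1 << ","
                      << j + 1 << ") type=" << tt << " r=" << r
                      << " window=[" << lo << "," << hi << "]\n";
        }
      }
  }

  void init_regions_and_energy(IntegerMatrix hb_init) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (type(i, j) != 3) continue;
        double dr[3], dv[3], r2, b, v2;
        pair_geom(i, j, dr, dv, r2, b, v2);
        double r = std::sqrt(r2);
        int reg = (r < din(i, j)) ? 2 : (r < dout(i, j)) ? 1 : 0;
        region[pk(i, j)] = region[pk(j, i)] = (uint8_t)reg;
        if (reg == 2) U += ein(i, j);
        else if (reg == 1) U += eout(i, j);
      }
    for (int r = 0; r < hb_init.nrow(); ++r) {
      int donor = hb_init(r, 0) - 1, acceptor = hb_init(r, 1) - 1;
      hb_partner[donor] = acceptor;
      hb_partner[acceptor] = donor;
      hb_t0[donor] = now;
      std::vector<int> touched;
      set_aux_walls(donor, acceptor, +1, touched);
      U += -1.0;
    }
  }

  void run() {
    for (int i = 0; i < n; ++i) repredict_sphere(i);
    if (thermostat && next_ghost < now)
      next_ghost = now + exp_rand() / (ghost_rate * n);
    if (thermostat) push(next_ghost, KIND_GHOST, -1, -1, S_NONE);
    if (sample_interval > 0) {
      next_sample = now + sample_interval;
      push(next_sample, KIND_SAMPLE, -1, -1, S_NONE);
    }
    if (energy_interval > 0) {
      next_energy = now + energy_interval;
      push(next_energy, KIND_ENERGY, -1, -1, S_NONE);
    }

    while (n_pair < budget) {
      if (q.empty()) break;
      Ev e = q.top();
      q.pop();
      if (max_time > 0 && e.t > max_time) {
        advance_all(max_time);
        break;
      }
      if (e.kind == KIND_PAIR || e.kind == KIND_REFRESH) {
        if (cnt[e.i] != e.ci || cnt[e.j] != e.cj) { ++c_stale; continue; }
      } else if (e.kind == KIND_RESCAN) {
        if (cnt[e.i] != e.ci) { ++c_stale; continue; }
      }
      advance_all(e.t);
      switch (e.kind) {
      case KIND_PAIR:
        execute_pair(e);
        if (audit_every > 0 && n_pair >= audit_last + audit_every) {
          audit_last = n_pair;
          audit();
        }
        break;
      case KIND_REFRESH:
        ++c_refresh;
        predict_pair(e.i, e.j);
        break;
      case KIND_RESCAN:
        ++c_refresh;
        repredict_sphere(e.i);
        break;
      case KIND_GHOST:
        ghost_collision();
        next_ghost = now + exp_rand() / (ghost_rate * n);
        push(next_ghost, KIND_GHOST, -1, -1, S_NONE);
        break;
      case KIND_SAMPLE:
        take_frame();
        next_sample = now + sample_interval;
        push(next_sample, KIND_SAMPLE, -1, -1, S_NONE);
        break;
      case KIND_ENERGY:
        take_energy();
        next_energy = now + energy_interval;
        push(next_energy, KIND_ENERGY, -1, -1, S_NONE);
        break;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List dmd_run_cpp(NumericMatrix pos, NumericMatrix vel, double boxL, double t0,
                 IntegerMatrix type, NumericMatrix d1, NumericMatrix d2,
                 NumericMatrix din, NumericMatrix dout,
                 NumericMatrix ein, NumericMatrix eout,
                 NumericVector mass, IntegerVector role,
                 IntegerVector res_of, IntegerMatrix rsi,
                 IntegerVector res_chain,
                 NumericVector hb_cut, double hb_well,
                 IntegerMatrix hb_init,
                 double t_start, double t_final, double cool_events,
                 double pair_events_done,
                 double budget, double max_time,
                 bool thermostat, double ghost_rate, double next_ghost,
                 double sample_interval, double energy_interval,
                 bool record_events, bool record_event_vel,
                 double audit_every = 0) {
  Engine en;
  en.n = pos.nrow();
  en.L = boxL;
  en.now = t0;
  en.x.resize(3 * en.n);
  en.v.resize(3 * en.n);
  for (int i = 0; i < en.n; ++i)
    for (int k = 0; k < 3; ++k) {
      en.x[3 * i + k] = pos(i, k);
      en.v[3 * i + k] = vel(i, k);
    }
  en.mass.assign(mass.begin(), mass.end());
  en.type = type; en.d1 = d1; en.d2 = d2;
  en.din = din; en.dout = dout; en.ein = ein; en.eout = eout;
  en.role = role; en.res_of = res_of; en.rsi = rsi; en.res_chain = res_chain;
  en.hb_cut = hb_cut; en.hb_well = hb_well;
  en.region.assign((size_t)en.n * en.n, 0);
  en.auxcnt.assign((size_t)en.n * en.n, 0);
  en.hb_partner.assign(en.n, -1);
  en.hb_t0.assign(en.n, 0.0);
  en.cnt.assign(en.n, 0u);
  en.t_start = t_start; en.t_final = t_final; en.cool_events = cool_events;
  en.n_pair = pair_events_done;
  en.update_temperature();
  en.budget = pair_events_done + budget;
  en.max_time = max_time;
  en.thermostat = thermostat;
  en.ghost_rate = ghost_rate;
  en.next_ghost = next_ghost;
  en.sample_interval = sample_interval;
  en.energy_interval = energy_interval;
  en.record_events = record_events;
  en.record_event_vel = record_event_vel;
  en.audit_every = audit_every;

  en.init_regions_and_energy(hb_init);
  en.KE = en.kinetic();

  en.run();

  NumericMatrix pos_out(en.n, 3), vel_out(en.n, 3);
  for (int i = 0; i < en.n; ++i)
    for (int k = 0; k < 3; ++k) {
      pos_out(i, k) = en.x[3 * i + k];
      vel_out(i, k) = en.v[3 * i + k];
    }

  int nb = 0;
  for (int i = 0; i < en.n; ++i)
    if (en.role[i] == 1 && en.hb_partner[i] >= 0) ++nb;
  NumericMatrix reg(nb, 3);
  int rrow = 0;
  for (int i = 0; i < en.n; ++i)
    if (en.role[i] == 1 && en.hb_partner[i] >= 0) {
      reg(rrow, 0) = i + 1;
      reg(rrow, 1) = en.hb_partner[i] + 1;
      reg(rrow, 2) = en.hb_t0[i];
      ++rrow;
    }

  List frames(en.fr_t.size());
  for (size_t f = 0; f < en.fr_t.size(); ++f) {
    std::vector<int>& bv = en.fr_bonds[f];
    IntegerMatrix bm(bv.size() / 2, 2);
    for (size_t r = 0; r < bv.size() / 2; ++r) {
      bm(r, 0) = bv[2 * r];
      bm(r, 1) = bv[2 * r + 1];
    }
    frames[f] = List::create(_["time"] = en.fr_t[f], _["tstar"] = en.fr_T[f],
                             _["pe"] = en.fr_U[f], _["ke"] = en.fr_KE[f],
                             _["pos"] = en.fr_pos[f], _["bonds"] = bm);
  }

  List events = R_NilValue;
  if (record_events) {
    size_t m = en.ev_t.size();
    NumericVector t(m); IntegerVector ki(m), su(m), ii(m), jj(m);
    for (size_t r = 0; r < m; ++r) {
      t[r] = en.ev_t[r]; ki[r] = en.ev_kind[r]; su[r] = en.ev_surf[r];
      ii[r] = en.ev_i[r]; jj[r] = en.ev_j[r];
    }
    List vl = R_NilValue;
    if (record_event_vel) {
      List vsnap(m);
      for (size_t r = 0; r < m; ++r) {
        NumericMatrix vm(en.n, 3);
        for (int i = 0; i < en.n; ++i)
          for (int k = 0; k < 3; ++k) vm(i, k) = en.ev_vel[r][3 * i + k];
        vsnap[r] = vm;
      }
      vl = vsnap;
    }
    events = List::create(_["time"] = t, _["kind"] = ki, _["surface"] = su,
                          _["i"] = ii, _["j"] = jj, _["velocities"] = vl);
  }

  NumericVector counters = NumericVector::create(
      _["pair_events"] = en.n_pair - pair_events_done,
      _["core"] = en.c_core, _["bond_wall"] = en.c_bond,
      _["well"] = en.c_well, _["hb_formed"] = en.c_hb_form,
      _["hb_broken"] = en.c_hb_break, _["hb_bounce"] = en.c_hb_bounce,
      _["hb_transparent"] = en.c_hb_transparent, _["aux_wall"] = en.c_aux,
      _["ghost"] = en.c_ghost, _["refresh"] = en.c_refresh,
      _["stale"] = en.c_stale, _["reprojected"] = en.c_reproj,
      _["worst_reproject"] = en.worst_reproj);

  DataFrame hb_log = DataFrame::create(
      _["time"] = NumericVector(en.hb_log_t.begin(), en.hb_log_t.end()),
      _["donor"] = IntegerVector(en.hb_log_d.begin(), en.hb_log_d.end()),
      _["acceptor"] = IntegerVector(en.hb_log_a.begin(), en.hb_log_a.end()),
      _["orientation"] = IntegerVector(en.hb_log_o.begin(), en.hb_log_o.end()),
      _["formed"] = IntegerVector(en.hb_log_f.begin(), en.hb_log_f.end()),
      _["d_n_ca"] = NumericVector(en.hb_log_aux[0].begin(), en.hb_log_aux[0].end()),
      _["d_n_n"] = NumericVector(en.hb_log_aux[1].begin(), en.hb_log_aux[1].end()),
      _["d_c_ca"] = NumericVector(en.hb_log_aux[2].begin(), en.hb_log_aux[2].end()),
      _["d_c_c"] = NumericVector(en.hb_log_aux[3].begin(), en.hb_log_aux[3].end()));

  return List::create(
      _["pos"] = pos_out, _["vel"] = vel_out, _["time"] = en.now,
      _["hb_formations"] = hb_log,
      _["tstar"] = en.tstar, _["pe"] = en.U, _["ke"] = en.KE,
      _["pair_events_total"] = en.n_pair,
      _["registry"] = reg, _["frames"] = frames,
      _["energy"] = DataFrame::create(_["time"] = en.en_t, _["pe"] = en.en_U,
                                      _["ke"] = en.en_KE, _["tstar"] = en.en_T),
      _["events"] = events, _["counters"] = counters,
      _["next_ghost_time"] = en.next_ghost);
}
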