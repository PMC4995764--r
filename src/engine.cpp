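// Event-driven core of the forager simulation.
//
// All foragers sit in a priority queue keyed by the completion time of
// their current action; the forager with the least time remaining acts
// next. Fixed-cadence clocks (per-minute metabolism/mortality and
// environmental change, 100-min digestion, yearly regrowth) interleave
// with action events; at equal times the clock ticks run first, then
// action completions ordered by (time, slot, insertion order).
//
// Time is in minutes, space in meters on a torus (minimum-image
// distances). Randomness comes exclusively from R's RNG so that runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

enum Action { ACT_NONE = 0, ACT_MOVE = 1, ACT_SEARCH = 2, ACT_MOVETOFOOD = 3,
              ACT_EAT = 4, ACT_MOVETOGROUP = 5, ACT_OBSERVE = 6,
              ACT_NOTHING = 7 };

struct Ev {
  double t;
  int slot;
  long long seq;
  int epoch;
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.slot != b.slot) return a.slot > b.slot;
    return a.seq > b.seq;
  }
};

struct Engine {
  // --- world ---
  std::vector<double> type_q, type_h;
  std::vector<int> type_s;
  std::vector<char> type_alive;
  std::vector<int> live_types;
  std::vector<std::vector<int> > type_items;
  std::vector<double> item_x, item_y;
  std::vector<int> item_type;          // 0-based
  std::vector<char> item_avail;
  double side;
  int n_types0;

  // spatial grid over items (static positions, CSR layout)
  int ncx;
  double cellw;
  std::vector<int> cell_start, cell_items;

  // --- parameters ---
  int N, G, max_assessed, stomach_cap, safe_neighbors, sat_thresh;
  int S_min, S_max;
  double copy_space, safe_space, align_space, view_radius, reach;
  double digestion_time, K, Z, W, repro_cost, metab, mut_prob;
  double max_age_min, year_min, se_window, M, EC, Q_mean, Q_sd, H_global;
  double speed_mpm, search_time, mtg_step, turn_sd, aie_init, birth_energy;
  double sdr;
  bool neg_q_redraw, repro_gate, small_group_safe, grouping, quality_mode;

  // --- foragers (fixed slot array of size N) ---
  std::vector<double> fx, fy, fh, fen, f_aie, birth_t, energy0, credit, debit;
  std::vector<int> fid, fparent, fgroup;
  std::vector<char> alive;
  std::vector<int> epoch;
  std::vector<double> tr; // N x 8, row-major
  std::vector<std::vector<double> > mem_a, mem_c, mem_t, diet_n, diet_e;
  std::vector<std::vector<int> > stom_type;
  std::vector<std::vector<double> > stom_e;
  std::vector<std::vector<std::pair<int, int> > > cyc_cnt;    // type, count
  std::vector<std::vector<std::pair<int, double> > > avers;   // type, expiry
  std::vector<int> se_type;
  std::vector<double> se_time;
  std::vector<int> act, last_act, food_target, pend_type;
  std::vector<double> act_end, mv_dx, mv_dy, pend_dt, move_rem;
  std::vector<double> icnt, ie_sum, iq_sum, isk_sum; // interval diet stats

  std::vector<std::vector<int> > groups;

  // --- scheduling ---
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> pq;
  long long seq;
  double now;

  // --- control ---
  double until, diet_from, switch_time;
  long long record_every;
  bool mutate_on, log_events, want_memory, want_diet_matrix;
  std::vector<char> frozen;
  std::vector<double> tmin, tmax, tsd, switch_vals;
  int next_id;
  long long max_log;

  // --- outputs ---
  std::vector<double> tr_t, tr_energy, tr_aie, tr_iitems, tr_iquality,
      tr_iskill, tr_iintake, tr_spread_mean, tr_spread_max;
  std::vector<int> tr_pop, tr_groups;
  std::vector<double> tr_traits[8];
  std::vector<int> anc_id, anc_parent;
  std::vector<double> anc_birth;
  std::vector<double> anc_tr[8];
  std::vector<double> de_t;
  std::vector<int> de_id, de_cause;
  std::vector<double> ev_t, ev_dur;
  std::vector<int> ev_id, ev_slot, ev_act;
  std::vector<double> el_t, el_reward;
  std::vector<int> el_id, el_type;
  std::vector<double> repl_t;
  long long n_checks, n_bad;
  int pop_min, pop_max;
  bool extinct;
  double extinct_t;

  std::vector<int> cand; // scratch for SEARCH

  // Fast internal RNG (xoshiro256++), seeded from R's RNG stream at run
  // start so runs stay fully reproducible under set.seed().
  uint64_t rs[4];
  bool have_spare;
  double spare;
  void seed_rng() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(R::unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(R::unif_rand() * 4294967296.0);
      rs[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    have_spare = false;
    for (int i = 0; i < 16; ++i) next_u64();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next_u64() {
    uint64_t result = rotl(rs[0] + rs[3], 23) + rs[0];
    uint64_t t = rs[1] << 17;
    rs[2] ^= rs[0];
    rs[3] ^= rs[1];
    rs[1] ^= rs[2];
    rs[0] ^= rs[3];
    rs[2] ^= t;
    rs[3] = rotl(rs[3], 45);
    return result;
  }
  inline double unif() {
    return (next_u64() >> 11) * 1.1102230246251565e-16; // 2^-53
  }
  double norm() { // Box-Muller with cached spare
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }

  int n_types() const { return (int)type_q.size(); }

  double wrap(double v) const {
    // displacements are small relative to the side, so loop rather than fmod
    while (v >= side) v -= side;
    while (v < 0) v += side;
    return v;
  }
  double mindiff(double a, double b) const {
    double d = a - b;
    if (d > 0.5 * side) d -= side;
    else if (d < -0.5 * side) d += side;
    return d;
  }
  double dist2(double x1, double y1, double x2, double y2) const {
    double dx = mindiff(x1, x2), dy = mindiff(y1, y2);
    return dx * dx + dy * dy;
  }

  double draw_q() {
    double q = Q_mean + Q_sd * norm();
    if (neg_q_redraw) {
      while (q < 0) q = Q_mean + Q_sd * norm();
    } else if (q < 0) q = 0;
    return q;
  }

  double skill_of(int slot, int r) const {
    double t = mem_t[slot][r];
    if (t <= 0) return 0.0;
    double ts = std::pow(t, (double)type_s[r]);
    return ts / (std::pow(type_h[r], (double)type_s[r]) + ts);
  }

  // --- grid ---
  void build_grid() {
    ncx = std::max(1, (int)std::floor(side / std::max(view_radius, 1.0)));
    cellw = side / ncx;
    size_t ncell = (size_t)ncx * ncx;
    cell_start.assign(ncell + 1, 0);
    std::vector<int> cix(item_x.size());
    for (size_t i = 0; i < item_x.size(); ++i) {
      int cx = std::min(ncx - 1, (int)(item_x[i] / cellw));
      int cy = std::min(ncx - 1, (int)(item_y[i] / cellw));
      cix[i] = cy * ncx + cx;
      ++cell_start[cix[i] + 1];
    }
    for (size_t c = 1; c <= ncell; ++c) cell_start[c] += cell_start[c - 1];
    cell_items.resize(item_x.size());
    std::vector<int> fill(cell_start.begin(), cell_start.end() - 1);
    for (size_t i = 0; i < item_x.size(); ++i) {
      cell_items[fill[cix[i]]++] = (int)i;
    }
  }

  template <class F>
  void items_within(double x, double y, double rad, F fun) {
    int c0x = (int)std::floor((x - rad) / cellw);
    int c1x = (int)std::floor((x + rad) / cellw);
    int c0y = (int)std::floor((y - rad) / cellw);
    int c1y = (int)std::floor((y + rad) / cellw);
    double r2 = rad * rad;
    for (int cy = c0y; cy <= c1y; ++cy) {
      int wy = ((cy % ncx) + ncx) % ncx;
      for (int cx = c0x; cx <= c1x; ++cx) {
        int wx = ((cx % ncx) + ncx) % ncx;
        size_t c = (size_t)wy * ncx + wx;
        for (int j = cell_start[c]; j < cell_start[c + 1]; ++j) {
          int i = cell_items[j];
          if (dist2(x, y, item_x[i], item_y[i]) <= r2) fun(i);
        }
      }
    }
  }

  // --- satiation bookkeeping ---
  bool is_averted(int slot, int r) const {
    const std::vector<std::pair<int, double> >& av = avers[slot];
    for (size_t i = 0; i < av.size(); ++i) {
      if (av[i].first == r && av[i].second > now) return true;
    }
    return false;
  }
  void bump_cycle_count(int slot, int r) {
    std::vector<std::pair<int, int> >& cc = cyc_cnt[slot];
    for (size_t i = 0; i < cc.size(); ++i) {
      if (cc[i].first == r) {
        if (++cc[i].second >= sat_thresh && !is_averted(slot, r)) {
          avers[slot].push_back(std::make_pair(r, now + digestion_time));
        }
        return;
      }
    }
    cc.push_back(std::make_pair(r, 1));
    if (sat_thresh <= 1 && !is_averted(slot, r)) {
      avers[slot].push_back(std::make_pair(r, now + digestion_time));
    }
  }

  // --- scheduling helpers ---
  void schedule(int slot, int a, double dur) {
    act[slot] = a;
    act_end[slot] = now + dur;
    Ev e;
    e.t = act_end[slot];
    e.slot = slot;
    e.seq = seq++;
    e.epoch = epoch[slot];
    pq.push(e);
    if (log_events && (long long)ev_t.size() < max_log) {
      ev_t.push_back(now);
      ev_slot.push_back(slot + 1);
      ev_id.push_back(fid[slot]);
      ev_act.push_back(a);
      ev_dur.push_back(dur);
    }
  }

  // --- decision cascade (Fig-style: SAFE? -> OBSERVE? -> HUNGRY? ->
  //     FOODTARGET? -> MOVE/SEARCH) ---
  void decide(int slot) {
    bool safe = true;
    int demo = -1;
    if (grouping && fgroup[slot] >= 0) {
      const std::vector<int>& mem = groups[fgroup[slot]];
      int nm = (int)mem.size();
      int cnt = 0, kdemo = 0;
      double ss2 = safe_space * safe_space, cs2 = copy_space * copy_space;
      for (int j = 0; j < nm; ++j) {
        int m = mem[j];
        if (m == slot) continue;
        double d2 = dist2(fx[slot], fy[slot], fx[m], fy[m]);
        if (d2 <= ss2) ++cnt;
        if (d2 <= cs2 && act[m] == ACT_EAT && food_target[m] >= 0) {
          ++kdemo; // reservoir-sample a uniform demonstrator
          if (unif() * kdemo < 1.0) demo = m;
        }
      }
      if (nm - 1 >= safe_neighbors) safe = cnt >= safe_neighbors;
      else safe = small_group_safe ? (cnt == nm - 1) : false;
      if (demo >= 0) { // stimulus-enhancement short-term memory
        se_type[slot] = item_type[food_target[demo]];
        se_time[slot] = now;
      }
      if (safe && nm > 1) { // align heading with group mates in range
        double sx = 0, sy = 0;
        double as2 = align_space * align_space;
        for (int j = 0; j < nm; ++j) {
          int m = mem[j];
          if (m == slot) continue;
          if (dist2(fx[slot], fy[slot], fx[m], fy[m]) <= as2) {
            sx += std::cos(fh[m]);
            sy += std::sin(fh[m]);
          }
        }
        if (sx != 0 || sy != 0) fh[slot] = std::atan2(sy, sx);
      }
      if (!safe) { // MOVETOGROUP: one short step towards the centroid
        move_rem[slot] = 0;  // an interrupted relocation is abandoned
        food_target[slot] = -1; // and so is any pending food goal
        double sx = 0, sy = 0;
        for (int j = 0; j < nm; ++j) {
          int m = mem[j];
          if (m == slot) continue;
          sx += mindiff(fx[m], fx[slot]);
          sy += mindiff(fy[m], fy[slot]);
        }
        sx /= (nm - 1); sy /= (nm - 1);
        double d = std::sqrt(sx * sx + sy * sy);
        double step = std::min(mtg_step, d);
        if (d > 1e-12) { mv_dx[slot] = step * sx / d; mv_dy[slot] = step * sy / d; }
        else { mv_dx[slot] = 0; mv_dy[slot] = 0; }
        schedule(slot, ACT_MOVETOGROUP, mtg_step / speed_mpm);
        return;
      }
    }
    if (move_rem[slot] > 1e-9) {
      // mid-relocation: safety has been re-checked; continue the next
      // 1-m step without re-running the other decision gates
      step_move(slot);
      return;
    }
    double omega = tr[slot * 8 + 6];
    if (omega > 0 && unif() < omega) { // OBSERVE
      double tau = tr[slot * 8 + 7];
      double o = tau;
      pend_type[slot] = -1;
      pend_dt[slot] = 0;
      if (demo >= 0) {
        double pk = act_end[demo] - now;
        if (pk < 0) pk = 0;
        o = std::min(tau, pk);
        int r = item_type[food_target[demo]];
        double gain = K * (o / M) * (mem_t[demo][r] - mem_t[slot][r]);
        pend_type[slot] = r;
        pend_dt[slot] = gain > 0 ? gain : 0;
      }
      schedule(slot, ACT_OBSERVE, std::max(o, 1e-4));
      return;
    }
    if ((int)stom_type[slot].size() >= stomach_cap) { // not HUNGRY
      schedule(slot, ACT_NOTHING, 1.0);
      return;
    }
    int ft = food_target[slot];
    if (ft >= 0 && !item_avail[ft]) { food_target[slot] = ft = -1; }
    if (ft >= 0) {
      double d = std::sqrt(dist2(fx[slot], fy[slot], item_x[ft], item_y[ft]));
      if (d > view_radius + 1) { // drifted away from the chosen item
        food_target[slot] = ft = -1;
      }
    }
    if (ft >= 0) {
      double d = std::sqrt(dist2(fx[slot], fy[slot], item_x[ft], item_y[ft]));
      if (d <= reach) {
        schedule(slot, ACT_EAT, M);
      } else { // MOVETOFOOD onto the item, then EAT
        mv_dx[slot] = mindiff(item_x[ft], fx[slot]);
        mv_dy[slot] = mindiff(item_y[ft], fy[slot]);
        schedule(slot, ACT_MOVETOFOOD, std::max(d, 0.01) / speed_mpm);
      }
      return;
    }
    if (last_act[slot] == ACT_SEARCH) {
      // nothing attractive: MOVE delta meters as 1-m steps, turning once
      fh[slot] += turn_sd * norm();
      move_rem[slot] = tr[slot * 8 + 0];
      step_move(slot);
      return;
    }
    do_search(slot);
  }

  void step_move(int slot) {
    // the 1-m granularity exists so that grouping foragers re-check
    // safety between steps; solitary foragers have nothing to re-check
    // and no decision gate runs mid-move, so their steps coalesce into
    // one event with identical state and RNG trajectories
    double step = grouping ? std::min(1.0, move_rem[slot])
                           : move_rem[slot];
    mv_dx[slot] = step * std::cos(fh[slot]);
    mv_dy[slot] = step * std::sin(fh[slot]);
    move_rem[slot] -= step;
    schedule(slot, ACT_MOVE, step / speed_mpm);
  }

  void do_search(int slot) {
    cand.clear();
    std::vector<int>* cp = &cand;
    Engine* self = this;
    int me = slot;
    if (avers[slot].empty()) {
      items_within(fx[slot], fy[slot], view_radius, [cp, self](int i) {
        if (self->item_avail[i]) cp->push_back(i);
      });
    } else {
      items_within(fx[slot], fy[slot], view_radius, [cp, self, me](int i) {
        if (self->item_avail[i] && !self->is_averted(me, self->item_type[i]))
          cp->push_back(i);
      });
    }
    int k = (int)cand.size();
    int n_assess = std::min(k, max_assessed);
    int chosen = -1;
    double aie = f_aie[slot];
    double sigma = tr[slot * 8 + 2], eps = tr[slot * 8 + 3],
           gamma = tr[slot * 8 + 5];
    // below ratio_floor the power term is < ~2e-9 and treated as 0
    double ratio_floor =
        sigma > 1e-12 ? aie * std::exp(-20.0 / sigma) : 0.0;
    bool se_live = se_type[slot] >= 0 && (now - se_time[slot]) <= se_window;
    int assessed = 0;
    for (int j = 0; j < n_assess; ++j) {
      // uniform sample without replacement (partial Fisher-Yates)
      int pick = j + (int)(unif() * (k - j));
      if (pick >= k) pick = k - 1;
      std::swap(cand[j], cand[pick]);
      int it = cand[j];
      int r = item_type[it];
      ++assessed;
      double a = mem_a[slot][r];
      double pf;
      if (a >= aie) {
        pf = 1.0;
      } else {
        double base; // unknown types (a <= 0) need P_E or P_S
        if (a <= 0) base = 0.0;
        else if (a < ratio_floor) base = 0.0;
        else base = std::pow(a / aie, sigma);
        double pe = eps > 0 ? eps * (1.0 - mem_c[slot][r]) : 0.0;
        double ps = (se_live && gamma > 0 && se_type[slot] == r) ? gamma : 0.0;
        pf = base + pe + ps;
        if (pf > 1) pf = 1;
      }
      if (pf >= 1.0) { chosen = it; break; }
      if (pf > 0 && unif() < pf) { chosen = it; break; }
    }
    food_target[slot] = chosen;
    schedule(slot, ACT_SEARCH, std::max(assessed, 1) * search_time);
  }

  void do_eat(int slot) {
    int it = food_target[slot];
    food_target[slot] = -1;
    if (it < 0 || !item_avail[it]) return; // beaten to it: no state change
    item_avail[it] = 0;
    int r = item_type[it];
    double s = skill_of(slot, r);
    double e = type_q[r] * s + (Z > 0 ? Z * norm() : 0.0);
    stom_type[slot].push_back(r);
    stom_e[slot].push_back(e);
    double lam = tr[slot * 8 + 4];
    double a0 = mem_a[slot][r];
    double disc = (e == 0.0) ? 1.0
                             : std::min(1.0, std::fabs((e - a0) / e));
    mem_c[slot][r] = (1 - lam) * mem_c[slot][r] + lam * (1 - disc);
    mem_a[slot][r] = a0 + lam * (e - a0);
    mem_t[slot][r] += M; // processing-time increment per item
    if (now >= diet_from) {
      diet_n[slot][r] += 1;
      diet_e[slot][r] += e;
    }
    icnt[slot] += 1;
    ie_sum[slot] += e;
    iq_sum[slot] += type_q[r];
    isk_sum[slot] += s;
    bump_cycle_count(slot, r);
    if (log_events && (long long)el_t.size() < max_log) {
      el_t.push_back(now);
      el_id.push_back(fid[slot]);
      el_type.push_back(r + 1);
      el_reward.push_back(e);
    }
  }

  void complete(int slot) {
    int a = act[slot];
    switch (a) {
      case ACT_MOVE:
      case ACT_MOVETOGROUP:
      case ACT_MOVETOFOOD:
        fx[slot] = wrap(fx[slot] + mv_dx[slot]);
        fy[slot] = wrap(fy[slot] + mv_dy[slot]);
        break;
      case ACT_EAT:
        do_eat(slot);
        break;
      case ACT_OBSERVE:
        if (pend_type[slot] >= 0 && pend_dt[slot] > 0) {
          mem_t[slot][pend_type[slot]] += pend_dt[slot];
        }
        pend_type[slot] = -1;
        break;
      default:
        break;
    }
    last_act[slot] = a;
    decide(slot);
  }

  // --- demographics ---
  void remove_from_group(int slot) {
    int g = fgroup[slot];
    if (g < 0) return;
    std::vector<int>& mem = groups[g];
    for (size_t i = 0; i < mem.size(); ++i) {
      if (mem[i] == slot) { mem[i] = mem.back(); mem.pop_back(); break; }
    }
    fgroup[slot] = -1;
  }

  void split_if_needed(int g) {
    if (g < 0) return;
    std::vector<int>& mem = groups[g];
    int n = (int)mem.size();
    if (n <= G) return;
    for (int i = n - 1; i > 0; --i) { // shuffle
      int j = (int)(unif() * (i + 1));
      if (j > i) j = i;
      std::swap(mem[i], mem[j]);
    }
    int k = n / 2; // the two daughters differ by at most one member
    std::vector<int> daughter(mem.begin() + (n - k), mem.end());
    mem.resize(n - k);
    groups.push_back(daughter);
    int ng = (int)groups.size() - 1;
    for (size_t i = 0; i < daughter.size(); ++i) fgroup[daughter[i]] = ng;
  }

  int pick_parent() {
    // energy-weighted (h^W, negatives clamped to 0); optionally gated on
    // reserves covering the reproduction cost with richest-survivor
    // fallback
    std::vector<int> pool;
    pool.reserve(N);
    bool gated = false;
    if (repro_gate) {
      for (int s = 0; s < N; ++s) {
        if (alive[s] && fen[s] >= repro_cost) pool.push_back(s);
      }
      gated = !pool.empty();
    }
    if (!gated) {
      for (int s = 0; s < N; ++s) if (alive[s]) pool.push_back(s);
    }
    if (pool.empty()) return -1;
    if (repro_gate && !gated) { // richest-survivor fallback
      int best = pool[0];
      for (size_t i = 1; i < pool.size(); ++i) {
        if (fen[pool[i]] > fen[best]) best = pool[i];
      }
      return best;
    }
    double tot = 0;
    std::vector<double> w(pool.size());
    for (size_t i = 0; i < pool.size(); ++i) {
      double h = fen[pool[i]] > 0 ? fen[pool[i]] : 0;
      w[i] = std::pow(h, W);
      tot += w[i];
    }
    if (tot <= 0) {
      return pool[(int)(unif() * pool.size()) % pool.size()];
    }
    double u = unif() * tot, acc = 0;
    for (size_t i = 0; i < pool.size(); ++i) {
      acc += w[i];
      if (u <= acc) return pool[i];
    }
    return pool.back();
  }

  void give_birth(int slot) {
    int p = pick_parent();
    if (p < 0) { extinct = true; extinct_t = now; return; }
    fen[p] -= repro_cost;
    debit[p] += repro_cost;
    int nt = n_types();
    alive[slot] = 1;
    fid[slot] = next_id++;
    fparent[slot] = fid[p];
    fx[slot] = fx[p];
    fy[slot] = fy[p];
    fh[slot] = 2 * M_PI * unif();
    fen[slot] = birth_energy;
    energy0[slot] = birth_energy;
    credit[slot] = 0;
    debit[slot] = 0;
    f_aie[slot] = aie_init;
    birth_t[slot] = now;
    mem_a[slot].assign(nt, 0.0);
    mem_c[slot].assign(nt, 0.0);
    mem_t[slot].assign(nt, 0.0);
    diet_n[slot].assign(nt, 0.0);
    diet_e[slot].assign(nt, 0.0);
    stom_type[slot].clear();
    stom_e[slot].clear();
    cyc_cnt[slot].clear();
    avers[slot].clear();
    se_type[slot] = -1;
    se_time[slot] = -1e18;
    food_target[slot] = -1;
    pend_type[slot] = -1;
    last_act[slot] = ACT_NONE;
    move_rem[slot] = 0;
    icnt[slot] = ie_sum[slot] = iq_sum[slot] = isk_sum[slot] = 0;
    // inheritance with mutation
    for (int k = 0; k < 8; ++k) {
      double v = tr[p * 8 + k];
      if (mutate_on && !frozen[k] && unif() < mut_prob) {
        v += tsd[k] * norm();
        if (v < tmin[k]) v = tmin[k];
        if (v > tmax[k]) v = tmax[k];
      }
      tr[slot * 8 + k] = v;
    }
    // born into the parent's group
    int g = fgroup[p];
    fgroup[slot] = g;
    if (g >= 0) {
      groups[g].push_back(slot);
      split_if_needed(g);
    }
    anc_id.push_back(fid[slot]);
    anc_parent.push_back(fparent[slot]);
    anc_birth.push_back(now);
    for (int k = 0; k < 8; ++k) anc_tr[k].push_back(tr[slot * 8 + k]);
    decide(slot);
  }

  void kill(int slot, int cause) {
    de_t.push_back(now);
    de_id.push_back(fid[slot]);
    de_cause.push_back(cause);
    alive[slot] = 0;
    ++epoch[slot]; // pending queue event becomes stale
    remove_from_group(slot);
    give_birth(slot); // immediate replacement keeps the population at N
  }

  // --- fixed-cadence clocks ---
  void minute_tick() {
    for (int s = 0; s < N && !extinct; ++s) {
      if (!alive[s]) continue;
      fen[s] -= metab;
      debit[s] += metab;
      int cause = 0;
      if (now - birth_t[s] >= max_age_min) cause = 1;
      else if (fen[s] <= 0) cause = 2;
      else if (sdr > 0 && unif() < sdr) cause = 3;
      if (cause) kill(s, cause);
    }
    if (extinct) return;
    int cnt = 0;
    for (int s = 0; s < N; ++s) cnt += alive[s] ? 1 : 0;
    ++n_checks;
    if (cnt != N) ++n_bad;
    if (cnt < pop_min) pop_min = cnt;
    if (cnt > pop_max) pop_max = cnt;
    if (EC > 0 && unif() < EC / year_min) environmental_change();
  }

  void environmental_change() {
    if (live_types.empty()) return;
    int li = (int)(unif() * live_types.size());
    if (li >= (int)live_types.size()) li = (int)live_types.size() - 1;
    int old = live_types[li];
    if (quality_mode) {
      type_q[old] = draw_q();
    } else {
      int nw = n_types();
      type_q.push_back(draw_q());
      type_h.push_back(H_global);
      type_s.push_back(S_min + (int)(unif() * (S_max - S_min + 1)));
      type_alive.push_back(1);
      type_alive[old] = 0;
      live_types[li] = nw;
      type_items.push_back(std::vector<int>());
      type_items[nw].swap(type_items[old]);
      for (size_t i = 0; i < type_items[nw].size(); ++i) {
        item_type[type_items[nw][i]] = nw;
      }
      for (int s = 0; s < N; ++s) {
        if (!alive[s]) continue;
        // retired species are forgotten; the new one starts unknown
        mem_a[s][old] = 0; mem_c[s][old] = 0; mem_t[s][old] = 0;
        mem_a[s].push_back(0.0);
        mem_c[s].push_back(0.0);
        mem_t[s].push_back(0.0);
        diet_n[s].push_back(0.0);
        diet_e[s].push_back(0.0);
      }
    }
    repl_t.push_back(now);
  }

  void digestion_tick() {
    for (int s = 0; s < N; ++s) {
      if (!alive[s]) continue;
      double gain = 0;
      for (size_t i = 0; i < stom_e[s].size(); ++i) gain += stom_e[s][i];
      fen[s] += gain;
      credit[s] += gain;
      bool full = (int)stom_type[s].size() >= stomach_cap;
      double phi = tr[s * 8 + 1];
      f_aie[s] *= full ? (1 + phi) : (1 - phi);
      // numerical guards: the expectation must stay positive (it divides
      // the food-choice rule) and finite (transient overshoot while
      // exploration alone fills the stomach is geometric)
      if (f_aie[s] < 1e-12) f_aie[s] = 1e-12;
      if (f_aie[s] > 1e6) f_aie[s] = 1e6;
      stom_type[s].clear();
      stom_e[s].clear();
      cyc_cnt[s].clear();
      std::vector<std::pair<int, double> >& av = avers[s];
      size_t w = 0;
      for (size_t i = 0; i < av.size(); ++i) {
        if (av[i].second > now) av[w++] = av[i];
      }
      av.resize(w);
    }
  }

  void regrow_tick() {
    std::fill(item_avail.begin(), item_avail.end(), 1);
  }

  void apply_switch() {
    for (int k = 0; k < 8; ++k) {
      if (ISNAN(switch_vals[k])) continue;
      for (int s = 0; s < N; ++s) {
        if (alive[s]) tr[s * 8 + k] = switch_vals[k];
      }
    }
  }

  void record() {
    int pop = 0, ng = 0;
    double esum = 0, aiesum = 0, trs[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    for (int s = 0; s < N; ++s) {
      if (!alive[s]) continue;
      ++pop;
      esum += fen[s];
      aiesum += f_aie[s];
      for (int k = 0; k < 8; ++k) trs[k] += tr[s * 8 + k];
    }
    double items = 0, qn = 0, qsum = 0, sksum = 0, intake = 0;
    for (int s = 0; s < N; ++s) {
      if (!alive[s]) continue;
      items += icnt[s];
      intake += ie_sum[s];
      if (icnt[s] > 0) {
        ++qn;
        qsum += iq_sum[s] / icnt[s];
        sksum += isk_sum[s] / icnt[s];
      }
      icnt[s] = ie_sum[s] = iq_sum[s] = isk_sum[s] = 0;
    }
    double spr_mean = R_NaN, spr_max = R_NaN;
    if (grouping) {
      double smax = 0, ssum = 0;
      int gcount = 0;
      for (size_t g = 0; g < groups.size(); ++g) {
        const std::vector<int>& mem = groups[g];
        if (mem.empty()) continue;
        ++gcount;
        double mx = 0;
        for (size_t i = 0; i < mem.size(); ++i) {
          for (size_t j = i + 1; j < mem.size(); ++j) {
            double d2 = dist2(fx[mem[i]], fy[mem[i]], fx[mem[j]], fy[mem[j]]);
            if (d2 > mx) mx = d2;
          }
        }
        mx = std::sqrt(mx);
        ssum += mx;
        if (mx > smax) smax = mx;
      }
      ng = gcount;
      if (gcount > 0) { spr_mean = ssum / gcount; spr_max = smax; }
    }
    tr_t.push_back(now);
    tr_pop.push_back(pop);
    tr_groups.push_back(ng);
    tr_energy.push_back(pop ? esum / pop : R_NaN);
    tr_aie.push_back(pop ? aiesum / pop : R_NaN);
    for (int k = 0; k < 8; ++k) {
      tr_traits[k].push_back(pop ? trs[k] / pop : R_NaN);
    }
    tr_iitems.push_back(items);
    tr_iintake.push_back(pop ? intake / pop : R_NaN);
    tr_iquality.push_back(qn > 0 ? qsum / qn : R_NaN);
    tr_iskill.push_back(qn > 0 ? sksum / qn : R_NaN);
    tr_spread_mean.push_back(spr_mean);
    tr_spread_max.push_back(spr_max);
  }

  void run() {
    record();
    if (until <= 0) return;
    for (int s = 0; s < N; ++s) {
      if (alive[s] && act[s] == ACT_NONE) { now = 0; decide(s); }
    }
    long long digestion_every = (long long)digestion_time;
    long long year_every = (long long)year_min;
    long long until_min = (long long)until;
    for (long long tick = 1; tick <= until_min; ++tick) {
      double tickt = (double)tick;
      while (!pq.empty() && pq.top().t < tickt) {
        Ev e = pq.top();
        pq.pop();
        if (!alive[e.slot] || e.epoch != epoch[e.slot]) continue;
        now = e.t;
        complete(e.slot);
      }
      now = tickt;
      minute_tick();
      if (extinct) break;
      if (tick % digestion_every == 0) digestion_tick();
      if (tick % year_every == 0) regrow_tick();
      if (switch_time >= 0 && tick == (long long)switch_time) apply_switch();
      if (tick % record_every == 0) record();
    }
  }
};

} // namespace

// [[Rcpp::export]]
List sim_run_cpp(List world, List pop, List par, List ctrl) {
  Engine E;
  // world
  E.type_q = as<std::vector<double> >(world["type_q"]);
  E.type_h = as<std::vector<double> >(world["type_h"]);
  E.type_s = as<std::vector<int> >(world["type_s"]);
  {
    LogicalVector ta = world["type_alive"];
    E.type_alive.assign(ta.size(), 1);
    for (int i = 0; i < ta.size(); ++i) E.type_alive[i] = ta[i] ? 1 : 0;
    for (int i = 0; i < (int)E.type_alive.size(); ++i) {
      if (E.type_alive[i]) E.live_types.push_back(i);
    }
  }
  E.n_types0 = (int)E.type_q.size();
  E.item_x = as<std::vector<double> >(world["item_x"]);
  E.item_y = as<std::vector<double> >(world["item_y"]);
  {
    IntegerVector it = world["item_type"];
    E.item_type.resize(it.size());
    for (int i = 0; i < it.size(); ++i) E.item_type[i] = it[i] - 1;
    LogicalVector av = world["item_avail"];
    E.item_avail.resize(av.size());
    for (int i = 0; i < av.size(); ++i) E.item_avail[i] = av[i] ? 1 : 0;
  }
  E.side = as<double>(world["side"]);
  E.type_items.assign(E.type_q.size(), std::vector<int>());
  for (size_t i = 0; i < E.item_type.size(); ++i) {
    E.type_items[E.item_type[i]].push_back((int)i);
  }

  // parameters
  E.N = as<int>(par["N"]);
  E.G = as<int>(par["G"]);
  E.copy_space = as<double>(par["copy_space"]);
  E.safe_space = as<double>(par["safe_space"]);
  E.safe_neighbors = as<int>(par["safe_neighbors"]);
  E.align_space = as<double>(par["align_space"]);
  E.view_radius = as<double>(par["view_radius"]);
  E.reach = as<double>(par["reach"]);
  E.max_assessed = as<int>(par["max_assessed_items"]);
  E.stomach_cap = as<int>(par["stomach_capacity"]);
  E.digestion_time = as<double>(par["digestion_time"]);
  E.K = as<double>(par["K"]);
  E.Z = as<double>(par["Z"]);
  E.W = as<double>(par["W"]);
  E.repro_cost = as<double>(par["reproduction_cost"]);
  E.metab = as<double>(par["metabolism_rate"]);
  E.mut_prob = as<double>(par["mutation_prob"]);
  E.max_age_min = as<double>(par["max_age_min"]);
  E.year_min = as<double>(par["year_min"]);
  E.se_window = as<double>(par["se_memory_window"]);
  E.M = as<double>(par["M"]);
  E.EC = as<double>(par["EC"]);
  E.Q_mean = as<double>(par["Q_mean"]);
  E.Q_sd = as<double>(par["Q_sd"]);
  E.H_global = as<double>(par["H"]);
  E.S_min = as<int>(par["S_min"]);
  E.S_max = as<int>(par["S_max"]);
  E.speed_mpm = as<double>(par["speed_mpm"]);
  E.search_time = as<double>(par["search_item_time"]);
  E.mtg_step = as<double>(par["movetogroup_step"]);
  E.turn_sd = as<double>(par["turn_sd"]);
  E.sat_thresh = as<int>(par["satiation_threshold"]);
  E.aie_init = as<double>(par["a_ie_init"]);
  E.birth_energy = as<double>(par["birth_energy"]);
  E.sdr = as<double>(par["stochastic_death_rate"]);
  E.neg_q_redraw = as<bool>(par["neg_q_redraw"]);
  E.repro_gate = as<bool>(par["repro_gate"]);
  E.small_group_safe = as<bool>(par["small_group_safe"]);
  E.grouping = as<bool>(par["grouping"]);
  E.quality_mode = as<bool>(par["quality_mode"]);

  // control
  E.until = as<double>(ctrl["until"]);
  E.record_every = (long long)as<double>(ctrl["record_every"]);
  E.mutate_on = as<bool>(ctrl["mutate"]);
  {
    LogicalVector fr = ctrl["frozen"];
    E.frozen.resize(8);
    for (int k = 0; k < 8; ++k) E.frozen[k] = fr[k] ? 1 : 0;
  }
  E.tmin = as<std::vector<double> >(ctrl["tmin"]);
  E.tmax = as<std::vector<double> >(ctrl["tmax"]);
  E.tsd = as<std::vector<double> >(ctrl["tsd"]);
  E.switch_time = as<double>(ctrl["switch_time"]);
  E.switch_vals = as<std::vector<double> >(ctrl["switch_vals"]);
  E.log_events = as<bool>(ctrl["log_events"]);
  E.max_log = (long long)as<double>(ctrl["max_log"]);
  E.diet_from = as<double>(ctrl["diet_from"]);
  E.want_memory = as<bool>(ctrl["return_memory"]);
  E.want_diet_matrix = as<bool>(ctrl["return_diet_matrix"]);

  // foragers
  int N = E.N;
  E.fx = as<std::vector<double> >(pop["x"]);
  E.fy = as<std::vector<double> >(pop["y"]);
  E.fh = as<std::vector<double> >(pop["heading"]);
  E.fen = as<std::vector<double> >(pop["energy"]);
  if ((int)E.fx.size() != N) stop("population size must equal N");
  {
    NumericVector age = pop["age"];
    E.birth_t.resize(N);
    for (int s = 0; s < N; ++s) E.birth_t[s] = -age[s];
  }
  E.energy0 = E.fen;
  E.credit.assign(N, 0.0);
  E.debit.assign(N, 0.0);
  E.fid.resize(N);
  E.fparent.assign(N, 0);
  E.alive.assign(N, 1);
  E.epoch.assign(N, 0);
  {
    NumericMatrix tm = pop["traits"];
    E.tr.resize((size_t)N * 8);
    for (int s = 0; s < N; ++s) {
      for (int k = 0; k < 8; ++k) E.tr[s * 8 + k] = tm(s, k);
    }
  }
  {
    IntegerVector gr = pop["group"]; // 0 = solitary, else 1-based
    int maxg = 0;
    for (int s = 0; s < N; ++s) maxg = std::max(maxg, (int)gr[s]);
    E.groups.assign(maxg, std::vector<int>());
    E.fgroup.resize(N);
    for (int s = 0; s < N; ++s) {
      if (gr[s] > 0) {
        E.fgroup[s] = gr[s] - 1;
        E.groups[gr[s] - 1].push_back(s);
      } else {
        E.fgroup[s] = -1;
      }
    }
  }
  int nt = E.n_types();
  E.mem_a.assign(N, std::vector<double>(nt, 0.0));
  E.mem_c.assign(N, std::vector<double>(nt, 0.0));
  E.mem_t.assign(N, std::vector<double>(nt, 0.0));
  E.diet_n.assign(N, std::vector<double>(nt, 0.0));
  E.diet_e.assign(N, std::vector<double>(nt, 0.0));
  E.stom_type.assign(N, std::vector<int>());
  E.stom_e.assign(N, std::vector<double>());
  E.cyc_cnt.assign(N, std::vector<std::pair<int, int> >());
  E.avers.assign(N, std::vector<std::pair<int, double> >());
  E.se_type.assign(N, -1);
  E.se_time.assign(N, -1e18);
  E.act.assign(N, ACT_NONE);
  E.last_act.assign(N, ACT_NONE);
  E.food_target.assign(N, -1);
  E.pend_type.assign(N, -1);
  E.pend_dt.assign(N, 0.0);
  E.act_end.assign(N, 0.0);
  E.mv_dx.assign(N, 0.0);
  E.mv_dy.assign(N, 0.0);
  E.move_rem.assign(N, 0.0);
  E.f_aie.assign(N, E.aie_init);
  E.icnt.assign(N, 0.0);
  E.ie_sum.assign(N, 0.0);
  E.iq_sum.assign(N, 0.0);
  E.isk_sum.assign(N, 0.0);
  for (int s = 0; s < N; ++s) E.fid[s] = s + 1;
  E.next_id = N + 1;
  E.seq = 0;
  E.now = 0;
  E.n_checks = E.n_bad = 0;
  E.pop_min = E.pop_max = N;
  E.extinct = false;
  E.extinct_t = -1;

  // optional pinned memory (scripted scenarios)
  if (ctrl.containsElementNamed("init_memory") &&
      !Rf_isNull(ctrl["init_memory"])) {
    List im = ctrl["init_memory"];
    NumericMatrix a = im["a"], c = im["c"], t = im["t"];
    for (int s = 0; s < N; ++s) {
      for (int r = 0; r < nt; ++r) {
        E.mem_a[s][r] = a(s, r);
        E.mem_c[s][r] = c(s, r);
        E.mem_t[s][r] = t(s, r);
      }
    }
  }
  if (ctrl.containsElementNamed("init_aie") && !Rf_isNull(ctrl["init_aie"])) {
    NumericVector ia = ctrl["init_aie"];
    for (int s = 0; s < N; ++s) E.f_aie[s] = ia[s];
  }

  E.seed_rng();
  E.build_grid();

  // founders enter the ancestor trace with parent id 0
  for (int s = 0; s < N; ++s) {
    E.anc_id.push_back(E.fid[s]);
    E.anc_parent.push_back(0);
    E.anc_birth.push_back(E.birth_t[s]);
    for (int k = 0; k < 8; ++k) E.anc_tr[k].push_back(E.tr[s * 8 + k]);
  }

  // optional pinned initial actions (scripted scenarios)
  if (ctrl.containsElementNamed("init_action") &&
      !Rf_isNull(ctrl["init_action"])) {
    List ia = ctrl["init_action"];
    IntegerVector code = ia["code"], item = ia["item"];
    NumericVector endt = ia["end"];
    for (int s = 0; s < N; ++s) {
      if (code[s] <= 0) continue;
      E.act[s] = code[s];
      if (item[s] > 0) E.food_target[s] = item[s] - 1;
      Ev e;
      e.t = endt[s];
      e.slot = s;
      e.seq = E.seq++;
      e.epoch = E.epoch[s];
      E.act_end[s] = endt[s];
      E.pq.push(e);
    }
  }

  E.run();

  // assemble outputs
  List trace = List::create(
      _["t"] = wrap(E.tr_t), _["pop"] = wrap(E.tr_pop),
      _["n_groups"] = wrap(E.tr_groups),
      _["mean_energy"] = wrap(E.tr_energy), _["mean_a_ie"] = wrap(E.tr_aie),
      _["delta"] = wrap(E.tr_traits[0]), _["phi"] = wrap(E.tr_traits[1]),
      _["sigma"] = wrap(E.tr_traits[2]), _["epsilon"] = wrap(E.tr_traits[3]),
      _["lambda"] = wrap(E.tr_traits[4]), _["gamma"] = wrap(E.tr_traits[5]),
      _["omega"] = wrap(E.tr_traits[6]), _["tau"] = wrap(E.tr_traits[7]),
      _["items_consumed"] = wrap(E.tr_iitems),
      _["mean_intake"] = wrap(E.tr_iintake),
      _["diet_quality"] = wrap(E.tr_iquality),
      _["diet_skill"] = wrap(E.tr_iskill));
  trace["group_spread_mean"] = wrap(E.tr_spread_mean);
  trace["group_spread_max"] = wrap(E.tr_spread_max);

  List ancestors = List::create(
      _["id"] = wrap(E.anc_id), _["parent"] = wrap(E.anc_parent),
      _["birth"] = wrap(E.anc_birth),
      _["delta"] = wrap(E.anc_tr[0]), _["phi"] = wrap(E.anc_tr[1]),
      _["sigma"] = wrap(E.anc_tr[2]), _["epsilon"] = wrap(E.anc_tr[3]),
      _["lambda"] = wrap(E.anc_tr[4]), _["gamma"] = wrap(E.anc_tr[5]),
      _["omega"] = wrap(E.anc_tr[6]), _["tau"] = wrap(E.anc_tr[7]));

  List deaths = List::create(_["t"] = wrap(E.de_t), _["id"] = wrap(E.de_id),
                             _["cause"] = wrap(E.de_cause));

  int n_alive = 0;
  for (int s = 0; s < N; ++s) n_alive += E.alive[s];
  NumericMatrix ftraits(n_alive, 8);
  IntegerVector p_id(n_alive), p_parent(n_alive), p_group(n_alive),
      p_slot(n_alive);
  NumericVector p_x(n_alive), p_y(n_alive), p_heading(n_alive),
      p_energy(n_alive), p_birth(n_alive), p_aie(n_alive),
      p_energy0(n_alive), p_credit(n_alive), p_debit(n_alive);
  IntegerVector p_stomach(n_alive);
  {
    int j = 0;
    for (int s = 0; s < N; ++s) {
      if (!E.alive[s]) continue;
      p_slot[j] = s + 1;
      p_id[j] = E.fid[s];
      p_parent[j] = E.fparent[s];
      p_group[j] = E.fgroup[s] + 1; // 0 = solitary
      p_x[j] = E.fx[s];
      p_y[j] = E.fy[s];
      p_heading[j] = E.fh[s];
      p_energy[j] = E.fen[s];
      p_birth[j] = E.birth_t[s];
      p_aie[j] = E.f_aie[s];
      p_energy0[j] = E.energy0[s];
      p_credit[j] = E.credit[s];
      p_debit[j] = E.debit[s];
      p_stomach[j] = (int)E.stom_type[s].size();
      for (int k = 0; k < 8; ++k) ftraits(j, k) = E.tr[s * 8 + k];
      ++j;
    }
  }
  List population = List::create(
      _["slot"] = p_slot, _["id"] = p_id, _["parent"] = p_parent,
      _["group"] = p_group, _["x"] = p_x, _["y"] = p_y,
      _["heading"] = p_heading, _["energy"] = p_energy,
      _["birth"] = p_birth, _["a_ie"] = p_aie, _["stomach_n"] = p_stomach,
      _["energy0"] = p_energy0, _["credit"] = p_credit,
      _["debit"] = p_debit, _["traits"] = ftraits);

  // per-forager diet summary (counts weighted over all types ever known)
  NumericVector d_items(n_alive), d_intake(n_alive), d_quality(n_alive),
      d_skill(n_alive);
  IntegerVector d_id(n_alive);
  {
    int j = 0;
    for (int s = 0; s < N; ++s) {
      if (!E.alive[s]) continue;
      double tot = 0, esum = 0, qsum = 0, sksum = 0;
      int ntn = E.n_types();
      for (int r = 0; r < (int)E.diet_n[s].size() && r < ntn; ++r) {
        double d = E.diet_n[s][r];
        if (d <= 0) continue;
        tot += d;
        esum += E.diet_e[s][r];
        qsum += d * E.type_q[r];
        sksum += d * E.skill_of(s, r);
      }
      d_id[j] = E.fid[s];
      d_items[j] = tot;
      d_intake[j] = esum;
      d_quality[j] = tot > 0 ? qsum / tot : R_NaN;
      d_skill[j] = tot > 0 ? sksum / tot : R_NaN;
      ++j;
    }
  }
  List diet = List::create(_["id"] = d_id, _["n_items"] = d_items,
                           _["total_intake"] = d_intake,
                           _["repertoire_quality"] = d_quality,
                           _["average_skill"] = d_skill);

  List out = List::create(
      _["trace"] = trace, _["ancestors"] = ancestors, _["deaths"] = deaths,
      _["population"] = population, _["diet"] = diet,
      _["checks"] = List::create(
          _["n_checks"] = (double)E.n_checks, _["n_bad"] = (double)E.n_bad,
          _["pop_min"] = E.pop_min, _["pop_max"] = E.pop_max),
      _["extinct"] = E.extinct, _["extinct_t"] = E.extinct_t,
      _["n_replacements"] = (int)E.repl_t.size(),
      _["replacement_times"] = wrap(E.repl_t));

  {
    LogicalVector av(E.item_avail.size());
    for (size_t i = 0; i < E.item_avail.size(); ++i) av[i] = E.item_avail[i];
    IntegerVector it(E.item_type.size());
    for (size_t i = 0; i < E.item_type.size(); ++i) it[i] = E.item_type[i] + 1;
    LogicalVector ta(E.type_alive.size());
    for (size_t i = 0; i < E.type_alive.size(); ++i) ta[i] = E.type_alive[i];
    out["world"] = List::create(
        _["item_avail"] = av, _["item_type"] = it,
        _["type_q"] = wrap(E.type_q), _["type_h"] = wrap(E.type_h),
        _["type_s"] = wrap(E.type_s), _["type_alive"] = ta);
  }

  if (E.log_events) {
    out["events"] = List::create(
        _["t"] = wrap(E.ev_t), _["slot"] = wrap(E.ev_slot),
        _["id"] = wrap(E.ev_id), _["action"] = wrap(E.ev_act),
        _["duration"] = wrap(E.ev_dur));
    out["meals"] = List::create(
        _["t"] = wrap(E.el_t), _["id"] = wrap(E.el_id),
        _["type"] = wrap(E.el_type), _["reward"] = wrap(E.el_reward));
  }

  if (E.want_memory) {
    int ntn = E.n_types();
    NumericMatrix ma(n_alive, ntn), mc(n_alive, ntn), mt(n_alive, ntn);
    int j = 0;
    for (int s = 0; s < N; ++s) {
      if (!E.alive[s]) continue;
      for (int r = 0; r < ntn; ++r) {
        ma(j, r) = E.mem_a[s][r];
        mc(j, r) = E.mem_c[s][r];
        mt(j, r) = E.mem_t[s][r];
      }
      ++j;
    }
    out["memory"] = List::create(_["a"] = ma, _["c"] = mc, _["t"] = mt);
  }
  if (E.want_diet_matrix) {
    int ntn = E.n_types();
    NumericMatrix dn(n_alive, ntn), de(n_alive, ntn);
    int j = 0;
    for (int s = 0; s < N; ++s) {
      if (!E.alive[s]) continue;
      for (int r = 0; r < ntn; ++r) {
        dn(j, r) = E.diet_n[s][r];
        de(j, r) = E.diet_e[s][r];
      }
      ++j;
    }
    out["diet_matrix"] = List::create(_["counts"] = dn, _["rewards"] = de);
  }
  return out;
}
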