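// Discrete-event semi-MDP engine for two-tiered EMS dispatch/redeployment.
//
// The simulator advances event-to-event (call arrival, scene arrival,
// hospital arrival, handover completion, base arrival), invokes a policy at
// each decision point, and logs per-patient outcomes and per-decision
// candidate sets. The ADP value table (aggregated state -> value, visits)
// lives here as an external pointer so that harmonic updates during a
// learning episode are applied online, decision by decision.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <unordered_map>
#include <string>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- scenario

struct Scn {
  double x0, y0, x1, y1;                 // bounding box (km)
  std::vector<double> bx, by;            // bases
  std::vector<int> bcap;
  std::vector<double> hx, hy;            // hospitals
  std::vector<double> speed;             // 24 hourly speeds (km/h)
  std::vector<int> is_als;               // fleet
  double c_high, c_low, penalty, rtt;    // RLI parameters
  double pHH, pLL;                       // triage posteriors
  double mean_scene;                     // expected on-scene service (min)
};

static Scn parse_scn(const List& s) {
  Scn z;
  NumericVector bbox = s["bbox"];
  z.x0 = bbox[0]; z.y0 = bbox[1]; z.x1 = bbox[2]; z.y1 = bbox[3];
  z.bx = as<std::vector<double>>(s["base_x"]);
  z.by = as<std::vector<double>>(s["base_y"]);
  z.bcap = as<std::vector<int>>(s["base_cap"]);
  z.hx = as<std::vector<double>>(s["hosp_x"]);
  z.hy = as<std::vector<double>>(s["hosp_y"]);
  z.speed = as<std::vector<double>>(s["speed"]);
  z.is_als = as<std::vector<int>>(s["is_als"]);
  z.c_high = s["c_high"]; z.c_low = s["c_low"];
  z.penalty = s["penalty"]; z.rtt = s["rtt"];
  z.pHH = s["p_high_given_hc"]; z.pLL = s["p_low_given_lc"];
  z.mean_scene = s["mean_scene"];
  return z;
}

static inline double speed_at(const Scn& s, double clock) {
  double m = std::fmod(clock, 1440.0);
  if (m < 0) m += 1440.0;
  int hr = (int)std::floor(m / 60.0);
  if (hr > 23) hr = 23;
  return s.speed[hr];
}

static inline double travel_min(const Scn& s, double ox, double oy,
                                double dx, double dy, double clock) {
  double d = std::hypot(ox - dx, oy - dy);
  if (d == 0.0) return 0.0;
  return d / speed_at(s, clock) * 60.0;
}

static inline int cell_of(const Scn& s, double x, double y) {
  int cx = (int)std::floor(3.0 * (x - s.x0) / (s.x1 - s.x0));
  int cy = (int)std::floor(3.0 * (y - s.y0) / (s.y1 - s.y0));
  if (cx < 0) cx = 0; if (cx > 2) cx = 2;
  if (cy < 0) cy = 0; if (cy > 2) cy = 2;
  return 3 * cy + cx;                    // 0..8, row-major from south-west
}

// Time zones: 1 = [01:00, 08:00), 2 = [08:00, 11:00), 3 = rest of day.
static inline int zone_of(double clock) {
  double m = std::fmod(clock, 1440.0);
  if (m < 0) m += 1440.0;
  if (m >= 60.0 && m < 480.0) return 1;
  if (m >= 480.0 && m < 660.0) return 2;
  return 3;
}

// ------------------------------------------------------------- value table

// Aggregated state key: 9 idle-or-relocating counts, 9 pending counts, zone.
// Encoded as a 19-char string (count + 33, clamped) for hashing.
typedef std::array<int, 19> AggKey;

static std::string enc_key(const AggKey& k) {
  std::string s(19, ' ');
  for (int i = 0; i < 19; ++i) {
    int v = k[i]; if (v > 90) v = 90; if (v < 0) v = 0;
    s[i] = (char)(v + 33);
  }
  return s;
}

static AggKey dec_key(const std::string& s) {
  AggKey k;
  for (int i = 0; i < 19; ++i) k[i] = (int)s[i] - 33;
  return k;
}

struct VTEntry { double value; long count; };

struct VT {
  std::unordered_map<std::string, VTEntry> m;
  double get(const std::string& k) const {
    auto it = m.find(k);
    return it == m.end() ? 0.0 : it->second.value;
  }
  void update(const std::string& k, double v) {
    VTEntry& e = m[k];                   // inserts {0, 0} if absent
    e.count += 1;
    double d = 1.0 / (double)e.count;    // harmonic step 1/n
    e.value += d * (v - e.value);
  }
};

// s dominates r iff same zone, idle(s) >= idle(r) per cell and
// pending(s) <= pending(r) per cell.
static inline bool dominates_key(const AggKey& s, const AggKey& r) {
  if (s[18] != r[18]) return false;
  for (int i = 0; i < 9; ++i) if (s[i] < r[i]) return false;
  for (int i = 9; i < 18; ++i) if (s[i] > r[i]) return false;
  return true;
}

// Monotone projection with reference (r, z): V(r) <- z; for s dominating r,
// V(s) <- min(z, V(s)); for s dominated by r, V(s) <- max(z, V(s)).
static void project_vt(VT& vt, const std::string& rkey, double z) {
  AggKey r = dec_key(rkey);
  for (auto& kv : vt.m) {
    if (kv.first == rkey) { kv.second.value = z; continue; }
    AggKey s = dec_key(kv.first);
    if (dominates_key(s, r)) {
      if (kv.second.value > z) kv.second.value = z;
    } else if (dominates_key(r, s)) {
      if (kv.second.value < z) kv.second.value = z;
    }
  }
  VTEntry& e = vt.m[rkey];
  e.value = z;
}

// [[Rcpp::export]]
SEXP cpp_vt_new() {
  XPtr<VT> p(new VT(), true);
  return p;
}

// [[Rcpp::export]]
List cpp_vt_export(SEXP ptr) {
  XPtr<VT> p(ptr);
  int n = p->m.size();
  std::vector<std::string> keys;
  keys.reserve(n);
  for (auto& kv : p->m) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  IntegerMatrix K(n, 19);
  NumericVector val(n);
  IntegerVector cnt(n);
  for (int i = 0; i < n; ++i) {
    AggKey k = dec_key(keys[i]);
    for (int j = 0; j < 19; ++j) K(i, j) = k[j];
    VTEntry& e = p->m[keys[i]];
    val[i] = e.value;
    cnt[i] = (int)e.count;
  }
  return List::create(_["keys"] = K, _["value"] = val, _["count"] = cnt);
}

// [[Rcpp::export]]
void cpp_vt_import(SEXP ptr, IntegerMatrix keys, NumericVector value,
                   IntegerVector count) {
  XPtr<VT> p(ptr);
  p->m.clear();
  for (int i = 0; i < keys.nrow(); ++i) {
    AggKey k;
    for (int j = 0; j < 19; ++j) k[j] = keys(i, j);
    p->m[enc_key(k)] = VTEntry{value[i], (long)count[i]};
  }
}

// [[Rcpp::export]]
void cpp_vt_update(SEXP ptr, IntegerVector key, double v) {
  XPtr<VT> p(ptr);
  AggKey k;
  for (int j = 0; j < 19; ++j) k[j] = key[j];
  p->update(enc_key(k), v);
}

// [[Rcpp::export]]
void cpp_vt_project(SEXP ptr, IntegerVector key, double z) {
  XPtr<VT> p(ptr);
  AggKey k;
  for (int j = 0; j < 19; ++j) k[j] = key[j];
  project_vt(*p, enc_key(k), z);
}

// Visit-weighted mini-batch monotone projection: per time zone, sample up to
// n_per_zone distinct visited states with probability proportional to visit
// count (without replacement, via R's RNG), then apply the projection
// operator sequentially with each sampled state's current value as the
// reference value (re-read after each projection).
// [[Rcpp::export]]
int cpp_vt_minibatch(SEXP ptr, int n_per_zone) {
  XPtr<VT> p(ptr);
  RNGScope rng;
  // Decode the whole table once; work on (key, entry) views afterwards.
  size_t n = p->m.size();
  std::vector<const std::string*> skeys;
  skeys.reserve(n);
  for (auto& kv : p->m) skeys.push_back(&kv.first);
  std::sort(skeys.begin(), skeys.end(),
            [](const std::string* a, const std::string* b) { return *a < *b; });
  std::vector<AggKey> keys(n);
  std::vector<VTEntry*> ent(n);
  for (size_t i = 0; i < n; ++i) {
    keys[i] = dec_key(*skeys[i]);
    ent[i] = &p->m[*skeys[i]];
  }

  std::vector<size_t> refs;
  for (int zone = 1; zone <= 3; ++zone) {
    std::vector<size_t> idx;
    for (size_t i = 0; i < n; ++i) {
      if (keys[i][18] == zone && ent[i]->count > 0) idx.push_back(i);
    }
    int take = std::min((int)idx.size(), n_per_zone);
    std::vector<bool> used(idx.size(), false);
    for (int t = 0; t < take; ++t) {
      double tot = 0.0;
      for (size_t j = 0; j < idx.size(); ++j)
        if (!used[j]) tot += (double)ent[idx[j]]->count;
      double u = unif_rand() * tot, acc = 0.0;
      size_t pick = 0;
      for (size_t j = 0; j < idx.size(); ++j) {
        if (used[j]) continue;
        acc += (double)ent[idx[j]]->count;
        pick = j;
        if (u <= acc) break;
      }
      used[pick] = true;
      refs.push_back(idx[pick]);
    }
  }
  // Sequential projections, re-reading the reference value each time.
  for (size_t r : refs) {
    double z = ent[r]->value;
    const AggKey& rk = keys[r];
    for (size_t i = 0; i < n; ++i) {
      if (i == r) continue;
      if (dominates_key(keys[i], rk)) {
        if (ent[i]->value > z) ent[i]->value = z;
      } else if (dominates_key(rk, keys[i])) {
        if (ent[i]->value < z) ent[i]->value = z;
      }
    }
  }
  return (int)refs.size();
}

// ---------------------------------------------------------------- entities

struct Amb {
  int type;                 // 1 = ALS, 0 = BLS
  int status;               // 0 idle, 1 to-patient, 2 on-scene, 3 to-hospital,
                            // 4 at-hospital, 5 to-base
  double x, y;              // origin of current leg / resting position
  double lx, ly;            // leg destination
  double t0, t1;            // leg departure / arrival times
  int patient, dest_base, at_base;
  int seq;                  // bumped at every assignment; guards stale events
  void pos(double clock, double& px, double& py) const {
    if ((status == 1 || status == 3 || status == 5) && t1 > t0) {
      double f = (clock - t0) / (t1 - t0);
      if (f < 0) f = 0; if (f > 1) f = 1;
      px = x + (lx - x) * f; py = y + (ly - y) * f;
    } else { px = x; py = y; }
  }
};

struct Pat {
  double rx, ry, report, scene_serv, hosp_serv;
  int district, sevA, sevC;              // 1 = high
  int status;                            // 0 waiting, 1 in-service, 2 done
  int amb, hospital;
  double dispatch_t, scene_t, hosp_t, handover_t, rt, rt_pc, rli;
};

struct Ev {
  double t; int kind; int id; int seq;
  // kinds: 0 call, 1 scene-arrival, 2 hospital-arrival, 3 handover, 4 base
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.kind != b.kind) return a.kind > b.kind;
    return a.id > b.id;
  }
};

// ------------------------------------------------------------- simulation

struct DispatchRow {
  double t; int patient, sevC, n_cand, n_als;
  int chosen, chosen_als; double chosen_tt;
  int nearest, nearest_als_flag; double nearest_tt;
  int nearest_als; double nearest_als_tt;  // -1 / NA when no ALS candidate
};
struct RelocRow {
  double t; int amb, base, n_feasible; double travel;
};

struct Sim {
  Scn s;
  std::vector<Amb> ambs;
  std::vector<Pat> pats;
  std::deque<int> qH, qL;
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> evq;
  double clock;
  int mode;                 // 0 greedy, 1 myopic, 2 adp-eval, 3 adp-learn
  VT* vt;
  double gamma;
  bool has_prev;
  std::string prev_key;
  std::vector<DispatchRow> dlog;
  std::vector<RelocRow> rlog;

  double rli_f(double rt_pc, int high) const {
    if (high) return s.c_high * rt_pc + (rt_pc > s.rtt ? s.penalty : 0.0);
    return s.c_low * rt_pc;
  }

  int nearest_hospital(double px, double py, double t) const {
    int best = 0; double bt = travel_min(s, px, py, s.hx[0], s.hy[0], t);
    for (size_t h = 1; h < s.hx.size(); ++h) {
      double tt = travel_min(s, px, py, s.hx[h], s.hy[h], t);
      if (tt < bt) { bt = tt; best = (int)h; }
    }
    return best;
  }

  // Expected immediate RLI of dispatching ambulance a to patient p now.
  double contribution(int a, int p, double tt_ap) const {
    const Pat& q = pats[p];
    double rt_hat = (clock - q.report) + tt_ap;
    double wH = q.sevC ? s.pHH : (1.0 - s.pLL);
    double fL = s.c_low * rt_hat;
    double rt_high = rt_hat;
    if (!ambs[a].type) {                 // BLS: high-risk branch runs to hospital
      int h = nearest_hospital(q.rx, q.ry, clock);
      rt_high = rt_hat + s.mean_scene +
        travel_min(s, q.rx, q.ry, s.hx[h], s.hy[h], clock);
    }
    double fH = s.c_high * rt_high + (rt_high > s.rtt ? s.penalty : 0.0);
    return wH * fH + (1.0 - wH) * fL;
  }

  // Aggregated counts of the current state: idle ambulances at their
  // position, relocating ambulances at their destination base, waiting
  // patients at their location.
  void base_agg(AggKey& k) const {
    k.fill(0);
    for (const Amb& a : ambs) {
      if (a.status == 0) k[cell_of(s, a.x, a.y)] += 1;
      else if (a.status == 5) k[cell_of(s, s.bx[a.dest_base], s.by[a.dest_base])] += 1;
    }
    for (int p : qH) k[9 + cell_of(s, pats[p].rx, pats[p].ry)] += 1;
    for (int p : qL) k[9 + cell_of(s, pats[p].rx, pats[p].ry)] += 1;
    k[18] = zone_of(clock);
  }

  int base_occupancy(int b) const {
    int n = 0;
    for (const Amb& a : ambs) {
      if (a.status == 0 && a.at_base == b) ++n;
      else if (a.status == 5 && a.dest_base == b) ++n;
    }
    return n;
  }

  void learn_step(const std::vector<std::string>& keys,
                  const std::vector<double>& qv, int chosen_idx) {
    double vhat = qv[0];
    for (double q : qv) if (q < vhat) vhat = q;
    if (has_prev) vt->update(prev_key, vhat);
    prev_key = keys[chosen_idx];
    has_prev = true;
  }

  void apply_dispatch(int a, int p, double tt_ap) {
    Amb& am = ambs[a];
    double px, py;
    am.pos(clock, px, py);
    am.x = px; am.y = py;
    am.lx = pats[p].rx; am.ly = pats[p].ry;
    am.t0 = clock; am.t1 = clock + tt_ap;
    am.status = 1; am.patient = p;
    am.at_base = -1; am.dest_base = -1;  // frees any reserved slot
    am.seq += 1;                         // invalidates any pending base arrival
    pats[p].status = 1; pats[p].amb = a; pats[p].dispatch_t = clock;
    evq.push(Ev{am.t1, 1, a, am.seq});
  }

  // Decide which ambulance serves patient p among candidates; logs the
  // decision and (in learning mode) performs the value update.
  void dispatch_decision(int p, const std::vector<int>& cand) {
    int n = (int)cand.size();
    std::vector<double> tt(n), qv(n);
    std::vector<std::string> keys(n);
    AggKey base;
    if (mode >= 2) {
      base_agg(base);
      base[9 + cell_of(s, pats[p].rx, pats[p].ry)] += 1;  // p pending pre-decision
    }
    for (int i = 0; i < n; ++i) {
      const Amb& am = ambs[cand[i]];
      double px, py;
      am.pos(clock, px, py);
      tt[i] = travel_min(s, px, py, pats[p].rx, pats[p].ry, clock);
      if (mode == 1) {
        qv[i] = tt[i];
      } else {
        qv[i] = contribution(cand[i], p, tt[i]);
      }
      if (mode >= 2) {
        AggKey k = base;
        if (am.status == 0 || am.status == 5) {
          // ambulance leaves the idle-or-relocating pool
          int c = (am.status == 5)
            ? cell_of(s, s.bx[am.dest_base], s.by[am.dest_base])
            : cell_of(s, px, py);
          k[c] -= 1;
        }
        k[9 + cell_of(s, pats[p].rx, pats[p].ry)] -= 1;  // p assigned
        keys[i] = enc_key(k);
        qv[i] += gamma * vt->get(keys[i]);
      }
    }
    int best = 0;
    for (int i = 1; i < n; ++i) {
      if (qv[i] < qv[best] ||
          (qv[i] == qv[best] && (tt[i] < tt[best] ||
            (tt[i] == tt[best] && cand[i] < cand[best])))) best = i;
    }
    if (mode == 3) learn_step(keys, qv, best);

    // decision log
    int near = 0;
    for (int i = 1; i < n; ++i)
      if (tt[i] < tt[near] || (tt[i] == tt[near] && cand[i] < cand[near]))
        near = i;
    int nals = -1; int n_als = 0;
    for (int i = 0; i < n; ++i) {
      if (ambs[cand[i]].type) {
        ++n_als;
        if (nals < 0 || tt[i] < tt[nals] ||
            (tt[i] == tt[nals] && cand[i] < cand[nals])) nals = i;
      }
    }
    DispatchRow r;
    r.t = clock; r.patient = p + 1; r.sevC = pats[p].sevC;
    r.n_cand = n; r.n_als = n_als;
    r.chosen = cand[best] + 1; r.chosen_als = ambs[cand[best]].type;
    r.chosen_tt = tt[best];
    r.nearest = cand[near] + 1; r.nearest_als_flag = ambs[cand[near]].type;
    r.nearest_tt = tt[near];
    r.nearest_als = nals >= 0 ? cand[nals] + 1 : -1;
    r.nearest_als_tt = nals >= 0 ? tt[nals] : -1.0;
    dlog.push_back(r);

    apply_dispatch(cand[best], p, tt[best]);
  }

  void redeploy_decision(int a) {
    Amb& am = ambs[a];
    std::vector<int> feas;
    for (size_t b = 0; b < s.bx.size(); ++b) {
      if (base_occupancy((int)b) < s.bcap[b]) feas.push_back((int)b);
    }
    if (feas.empty()) stop("no feasible redeployment base (capacity exhausted)");
    int n = (int)feas.size();
    std::vector<double> tt(n), qv(n);
    std::vector<std::string> keys(n);
    AggKey base;
    if (mode >= 2) base_agg(base);
    for (int i = 0; i < n; ++i) {
      tt[i] = travel_min(s, am.x, am.y, s.bx[feas[i]], s.by[feas[i]], clock);
      if (mode >= 2) {
        AggKey k = base;
        k[cell_of(s, s.bx[feas[i]], s.by[feas[i]])] += 1;  // relocating counts
        keys[i] = enc_key(k);
        qv[i] = gamma * vt->get(keys[i]);   // redeployments contribute 0
      } else {
        qv[i] = tt[i];                       // greedy/myopic: nearest base
      }
    }
    int best = 0;
    for (int i = 1; i < n; ++i) {
      if (qv[i] < qv[best] ||
          (qv[i] == qv[best] && (tt[i] < tt[best] ||
            (tt[i] == tt[best] && feas[i] < feas[best])))) best = i;
    }
    if (mode == 3) learn_step(keys, qv, best);

    int b = feas[best];
    am.lx = s.bx[b]; am.ly = s.by[b];
    am.t0 = clock; am.t1 = clock + tt[best];
    am.status = 5; am.dest_base = b; am.patient = -1;
    am.seq += 1;
    evq.push(Ev{am.t1, 4, a, am.seq});
    RelocRow r;
    r.t = clock; r.amb = a + 1; r.base = b + 1;
    r.n_feasible = n; r.travel = tt[best];
    rlog.push_back(r);
  }

  void run() {
    while (!evq.empty()) {
      Ev e = evq.top(); evq.pop();
      clock = e.t;
      switch (e.kind) {
      case 0: {                          // call arrival
        int p = e.id;
        std::vector<int> cand;
        for (size_t i = 0; i < ambs.size(); ++i)
          if (ambs[i].status == 0 || ambs[i].status == 5) cand.push_back((int)i);
        if (cand.empty()) {
          if (pats[p].sevC) qH.push_back(p); else qL.push_back(p);
        } else {
          dispatch_decision(p, cand);
        }
        break;
      }
      case 1: {                          // scene arrival
        int a = e.id;
        Amb& am = ambs[a];
        int p = am.patient;
        am.x = am.lx; am.y = am.ly; am.status = 2;
        pats[p].scene_t = clock;
        pats[p].rt = clock - pats[p].report;
        double depart = clock + pats[p].scene_serv;
        int h = nearest_hospital(pats[p].rx, pats[p].ry, depart);
        pats[p].hospital = h;
        double tt = travel_min(s, pats[p].rx, pats[p].ry, s.hx[h], s.hy[h], depart);
        am.lx = s.hx[h]; am.ly = s.hy[h];
        am.t0 = depart; am.t1 = depart + tt;
        am.status = 3;
        evq.push(Ev{am.t1, 2, a, am.seq});
        break;
      }
      case 2: {                          // hospital arrival
        int a = e.id;
        Amb& am = ambs[a];
        int p = am.patient;
        am.x = am.lx; am.y = am.ly; am.status = 4;
        Pat& q = pats[p];
        q.hosp_t = clock;
        q.rt_pc = (!am.type && q.sevA) ? (q.hosp_t - q.report) : q.rt;
        q.rli = rli_f(q.rt_pc, q.sevA);
        evq.push(Ev{clock + q.hosp_serv, 3, a, am.seq});
        break;
      }
      case 3: {                          // handover complete
        int a = e.id;
        Amb& am = ambs[a];
        pats[am.patient].handover_t = clock;
        pats[am.patient].status = 2;
        am.patient = -1;
        if (!qH.empty() || !qL.empty()) {
          int p;
          if (!qH.empty()) { p = qH.front(); qH.pop_front(); }
          else { p = qL.front(); qL.pop_front(); }
          std::vector<int> cand(1, a);
          dispatch_decision(p, cand);
        } else {
          redeploy_decision(a);
        }
        break;
      }
      case 4: {                          // base arrival
        int a = e.id;
        Amb& am = ambs[a];
        if (e.seq != am.seq || am.status != 5) break;  // superseded by a dispatch
        am.x = am.lx; am.y = am.ly;
        am.status = 0; am.at_base = am.dest_base; am.dest_base = -1;
        break;
      }
      }
    }
  }
};

static void init_sim(Sim& sim, const List& scn, const DataFrame& calls,
                     int mode, double gamma) {
  sim.s = parse_scn(scn);
  sim.mode = mode;
  sim.gamma = gamma;
  sim.has_prev = false;
  sim.clock = 0.0;
  int nA = (int)sim.s.is_als.size();
  int nB = (int)sim.s.bx.size();
  sim.ambs.resize(nA);
  for (int i = 0; i < nA; ++i) {
    Amb& a = sim.ambs[i];
    int b = i % nB;                      // round-robin initial placement
    a.type = sim.s.is_als[i];
    a.status = 0; a.x = sim.s.bx[b]; a.y = sim.s.by[b];
    a.lx = a.x; a.ly = a.y; a.t0 = 0; a.t1 = 0;
    a.patient = -1; a.dest_base = -1; a.at_base = b; a.seq = 0;
  }
  NumericVector time = calls["time"], x = calls["x"], y = calls["y"],
    ss = calls["scene_service"], hs = calls["hospital_service"];
  IntegerVector district = calls["district"];
  CharacterVector sa = calls["severity_actual"], sc = calls["severity_classified"];
  int n = time.size();
  sim.pats.resize(n);
  for (int i = 0; i < n; ++i) {
    Pat& p = sim.pats[i];
    p.rx = x[i]; p.ry = y[i]; p.report = time[i];
    p.scene_serv = ss[i]; p.hosp_serv = hs[i];
    p.district = district[i];
    p.sevA = (sa[i] == "H") ? 1 : 0;
    p.sevC = (sc[i] == "H") ? 1 : 0;
    p.status = 0; p.amb = -1; p.hospital = -1;
    p.dispatch_t = NA_REAL; p.scene_t = NA_REAL; p.hosp_t = NA_REAL;
    p.handover_t = NA_REAL; p.rt = NA_REAL; p.rt_pc = NA_REAL; p.rli = NA_REAL;
    sim.evq.push(Ev{p.report, 0, i, 0});
  }
}

static List logs_to_r(const Sim& sim, double warmup, double horizon) {
  int n = (int)sim.pats.size();
  NumericVector report(n), xx(n), yy(n), dispatch_t(n), scene_t(n), hosp_t(n),
    handover_t(n), rt(n), rt_pc(n), rli(n);
  IntegerVector id(n), district(n), amb(n), hospital(n);
  CharacterVector sa(n), sc(n), at(n);
  LogicalVector inh(n), queued(n);
  for (int i = 0; i < n; ++i) {
    const Pat& p = sim.pats[i];
    id[i] = i + 1; report[i] = p.report; xx[i] = p.rx; yy[i] = p.ry;
    district[i] = p.district;
    sa[i] = p.sevA ? "H" : "L"; sc[i] = p.sevC ? "H" : "L";
    amb[i] = p.amb + 1;
    if (p.amb >= 0) at[i] = sim.ambs[p.amb].type ? "ALS" : "BLS";
    else at[i] = NA_STRING;
    hospital[i] = p.hospital + 1;
    dispatch_t[i] = p.dispatch_t; scene_t[i] = p.scene_t;
    hosp_t[i] = p.hosp_t; handover_t[i] = p.handover_t;
    rt[i] = p.rt; rt_pc[i] = p.rt_pc; rli[i] = p.rli;
    queued[i] = !NumericVector::is_na(p.dispatch_t) && p.dispatch_t > p.report;
    inh[i] = p.report >= warmup && p.report < warmup + horizon;
  }
  DataFrame patients = DataFrame::create(
    _["id"] = id, _["report"] = report, _["x"] = xx, _["y"] = yy,
    _["district"] = district, _["severity_actual"] = sa,
    _["severity_classified"] = sc, _["amb"] = amb, _["amb_type"] = at,
    _["hospital"] = hospital, _["dispatch_time"] = dispatch_t,
    _["scene_time"] = scene_t, _["hospital_time"] = hosp_t,
    _["handover_time"] = handover_t, _["rt"] = rt, _["rt_pc"] = rt_pc,
    _["rli"] = rli, _["queued"] = queued, _["in_horizon"] = inh,
    _["stringsAsFactors"] = false);

  int nd = (int)sim.dlog.size();
  NumericVector dt(nd), ctt(nd), ntt(nd), natt(nd);
  IntegerVector dpat(nd), ncand(nd), nals(nd), chosen(nd), nearest(nd), nearest_als(nd);
  LogicalVector chals(nd), high(nd), nalsf(nd), dinh(nd);
  for (int i = 0; i < nd; ++i) {
    const DispatchRow& r = sim.dlog[i];
    dt[i] = r.t; dpat[i] = r.patient; high[i] = r.sevC == 1;
    ncand[i] = r.n_cand; nals[i] = r.n_als;
    chosen[i] = r.chosen; chals[i] = r.chosen_als == 1; ctt[i] = r.chosen_tt;
    nearest[i] = r.nearest; nalsf[i] = r.nearest_als_flag == 1; ntt[i] = r.nearest_tt;
    nearest_als[i] = r.nearest_als > 0 ? r.nearest_als : NA_INTEGER;
    natt[i] = r.nearest_als > 0 ? r.nearest_als_tt : NA_REAL;
    dinh[i] = r.t >= warmup && r.t < warmup + horizon;
  }
  DataFrame dispatches = DataFrame::create(
    _["time"] = dt, _["patient"] = dpat, _["classified_high"] = high,
    _["n_candidates"] = ncand, _["n_als_candidates"] = nals,
    _["chosen"] = chosen, _["chosen_als"] = chals, _["chosen_travel"] = ctt,
    _["nearest"] = nearest, _["nearest_is_als"] = nalsf,
    _["nearest_travel"] = ntt, _["nearest_als"] = nearest_als,
    _["nearest_als_travel"] = natt, _["in_horizon"] = dinh,
    _["stringsAsFactors"] = false);

  int nr = (int)sim.rlog.size();
  NumericVector rt2(nr), rtrav(nr);
  IntegerVector ramb(nr), rbase(nr), rfeas(nr);
  LogicalVector rinh(nr);
  for (int i = 0; i < nr; ++i) {
    const RelocRow& r = sim.rlog[i];
    rt2[i] = r.t; ramb[i] = r.amb; rbase[i] = r.base;
    rfeas[i] = r.n_feasible; rtrav[i] = r.travel;
    rinh[i] = r.t >= warmup && r.t < warmup + horizon;
  }
  DataFrame relocations = DataFrame::create(
    _["time"] = rt2, _["amb"] = ramb, _["base"] = rbase,
    _["n_feasible"] = rfeas, _["travel_min"] = rtrav, _["in_horizon"] = rinh,
    _["stringsAsFactors"] = false);

  return List::create(_["patients"] = patients, _["dispatches"] = dispatches,
                      _["relocations"] = relocations);
}

// Run one episode under a fixed policy.
// mode: 0 greedy, 1 myopic, 2 adp (value table passed as keys/value).
// [[Rcpp::export]]
List cpp_run_episode(List scn, DataFrame calls, int mode,
                     Nullable<IntegerMatrix> vt_keys,
                     Nullable<NumericVector> vt_value,
                     double gamma, double warmup_min, double horizon_min) {
  Sim sim;
  VT vt;
  if (mode == 2) {
    if (vt_keys.isNull() || vt_value.isNull())
      stop("ADP policy requires a value table");
    IntegerMatrix K(vt_keys);
    NumericVector V(vt_value);
    for (int i = 0; i < K.nrow(); ++i) {
      AggKey k;
      for (int j = 0; j < 19; ++j) k[j] = K(i, j);
      vt.m[enc_key(k)] = VTEntry{V[i], 1};
    }
  }
  init_sim(sim, scn, calls, mode, gamma);
  sim.vt = &vt;
  sim.run();
  return logs_to_r(sim, warmup_min, horizon_min);
}

// Run one learning episode: act by the Bellman argmin against the shared
// value table, updating the previous decision's post-decision aggregate with
// each new sample estimate (online, harmonic step).
// [[Rcpp::export]]
List cpp_learn_episode(List scn, DataFrame calls, SEXP ptr, double gamma,
                       double warmup_min, double horizon_min,
                       bool full_logs) {
  XPtr<VT> p(ptr);
  Sim sim;
  init_sim(sim, scn, calls, 3, gamma);
  sim.vt = p.get();
  sim.run();
  double tot = 0.0; int n = 0;
  for (const Pat& q : sim.pats) {
    if (q.report >= warmup_min && q.report < warmup_min + horizon_min &&
        !NumericVector::is_na(q.rli)) {
      tot += q.rli; ++n;
    }
  }
  List out = List::create(
    _["mean_rli"] = n > 0 ? tot / n : NA_REAL,
    _["n_patients"] = n,
    _["n_decisions"] = (int)(sim.dlog.size() + sim.rlog.size()),
    _["table_size"] = (int)p->m.size());
  if (full_logs) out["logs"] = logs_to_r(sim, warmup_min, horizon_min);
  return out;
}
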