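// Discrete-event core of the ED patient-flow simulator.
//
// All randomness is pre-drawn in R (service times, checkup needs,
// persuasion/admission uniforms, room permutations) so the engine is a
// deterministic function of its inputs. Stations: registration desks,
// physician exam (strict triage 1-3 priority; factor-D ordering among
// triage 4/5), three checkup rooms (factor-B routing), bed admission with
// boarding and hourly factor-C bed releases. EDWIN-C is sampled hourly;
// its previous-day aggregate drives the factor-A persuasion of arriving
// triage-4/5 patients. After the arrival horizon the system drains so
// every patient has a disposition.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
using namespace Rcpp;

namespace {

enum EvType { EV_ARRIVAL = 0, EV_END_REG, EV_END_PHYS, EV_END_EXAM, EV_TICK };

struct Ev {
  double t;
  long seq;
  int type;
  int i;     // patient index (or -1)
  int room;  // exam room (or -1)
};

struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_engine_cpp")]]
List sim_engine_cpp(NumericVector arr, IntegerVector triage,
                    NumericVector t_reg, NumericVector t_phys,
                    NumericMatrix t_exam, LogicalMatrix need_exam,
                    NumericVector u_divert, NumericVector u_admit,
                    IntegerMatrix perm, List params) {
  const int n = arr.size();
  const int M = as<int>(params["signal_M"]);
  const int n_reg = as<int>(params["registration_servers"]);
  const IntegerVector rooms = params["exam_rooms"];  // urine, ct, xray
  const int Bt = as<int>(params["beds_Bt"]);
  const double fA = as<double>(params["factor_A"]);
  const int fB = as<int>(params["factor_B"]);
  const int fC = as<int>(params["factor_C"]);
  const int fD = as<int>(params["factor_D"]);
  const double p_divert = as<double>(params["p_divert"]);
  const NumericVector admit_probs = params["admit_probs"];
  const double horizon = as<double>(params["horizon_min"]);
  const int agg = as<int>(params["edwinc_agg_code"]);  // 0 mean, 1 max, 2 last
  const double tick_min = 60.0;
  const double divert_thr = 1.5 + (fA - 1.0) * 0.5;

  if (M < 1 || n_reg < 1 || Bt < 1) stop("resource counts must be positive");

  // per-patient state / outputs
  std::vector<double> wait_reg(n, 0), wait_phys(n, 0), wait_bed(n, 0);
  std::vector<double> serv_reg(n, 0), serv_phys(n, 0);
  std::vector<double> phys_start(n, NA_REAL), departure(n, NA_REAL);
  NumericMatrix wait_exam(n, 3), serv_exam(n, 3);
  std::vector<int> disposition(n, -1);  // 0 divert, 1 discharge, 2 admit
  std::vector<double> ready_t(n, 0), entry_t(n, 0), board_start(n, 0);
  std::vector<int> exam_order(3 * n, -1), exam_pos(n, 0), exam_len(n, 0);
  std::vector<int> rem_mask(n, 0);  // factor-B level 2: rooms still needed

  // resources and queues
  int reg_busy = 0, phys_busy = 0;
  int room_busy[3] = {0, 0, 0};
  std::deque<int> regq;
  std::deque<int> q123[3];
  std::vector<int> q45;
  std::deque<int> roomq[3];   // factor B levels 1 and 3
  std::deque<int> flexpool;   // factor B level 2
  std::deque<int> boarding;

  // census
  int n_by_triage[5] = {0, 0, 0, 0, 0};
  int total_in_ed = 0, BA = 0;

  // EDWIN-C tracking
  double prev_day_edwinc = 0.0, last_valid_edwinc = 0.0;
  std::vector<double> day_vals;
  std::vector<double> hourly_t, hourly_edwinc;

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> evq;
  long seq = 0;
  for (int i = 0; i < n; ++i) evq.push({arr[i], seq++, EV_ARRIVAL, i, -1});
  evq.push({tick_min, seq++, EV_TICK, -1, -1});

  auto schedule = [&](double t, int type, int i, int room) {
    evq.push({t, seq++, type, i, room});
  };

  auto depart = [&](int i, double t, int dispo) {
    departure[i] = t;
    disposition[i] = dispo;
    n_by_triage[triage[i] - 1]--;
    total_in_ed--;
  };

  auto start_reg = [&](double now) {
    while (reg_busy < n_reg && !regq.empty()) {
      int i = regq.front(); regq.pop_front();
      wait_reg[i] = now - ready_t[i];
      serv_reg[i] = t_reg[i];
      reg_busy++;
      schedule(now + t_reg[i], EV_END_REG, i, -1);
    }
  };

  // factor-D selection among waiting triage-4/5 patients
  auto pick_q45 = [&]() -> int {
    int best = -1;
    size_t best_pos = 0;
    for (size_t k = 0; k < q45.size(); ++k) {
      int i = q45[k];
      if (best < 0) { best = i; best_pos = k; continue; }
      bool better = false;
      if (fD == 1) {
        if (t_phys[i] < t_phys[best] ||
            (t_phys[i] == t_phys[best] && entry_t[i] < entry_t[best]))
          better = true;
      } else if (fD == 2) {
        if (entry_t[i] < entry_t[best]) better = true;
      } else {
        if (triage[i] < triage[best] ||
            (triage[i] == triage[best] && entry_t[i] < entry_t[best]))
          better = true;
      }
      if (better) { best = i; best_pos = k; }
    }
    if (best >= 0) q45.erase(q45.begin() + best_pos);
    return best;
  };

  auto start_phys = [&](double now) {
    while (phys_busy < M) {
      int i = -1;
      for (int tr = 0; tr < 3 && i < 0; ++tr)
        if (!q123[tr].empty()) { i = q123[tr].front(); q123[tr].pop_front(); }
      if (i < 0 && !q45.empty()) i = pick_q45();
      if (i < 0) break;
      wait_phys[i] = now - ready_t[i];
      serv_phys[i] = t_phys[i];
      phys_start[i] = now;
      phys_busy++;
      schedule(now + t_phys[i], EV_END_PHYS, i, -1);
    }
  };

  auto start_exam = [&](int i, int r, double now) {
    wait_exam(i, r) += now - ready_t[i];
    serv_exam(i, r) = t_exam(i, r);
    room_busy[r]++;
    schedule(now + t_exam(i, r), EV_END_EXAM, i, r);
  };

  auto fill_room = [&](int r, double now) {
    while (room_busy[r] < rooms[r]) {
      int i = -1;
      if (fB == 2) {
        for (size_t k = 0; k < flexpool.size(); ++k)
          if (rem_mask[flexpool[k]] & (1 << r)) {
            i = flexpool[k];
            flexpool.erase(flexpool.begin() + k);
            break;
          }
      } else if (!roomq[r].empty()) {
        i = roomq[r].front(); roomq[r].pop_front();
      }
      if (i < 0) break;
      start_exam(i, r, now);
    }
  };

  auto disposition_of = [&](int i, double now) {
    if (u_admit[i] < admit_probs[triage[i] - 1]) {
      BA++;
      board_start[i] = now;
      boarding.push_back(i);
    } else {
      depart(i, now, 1);
    }
  };

  // route a patient whose checkups begin or continue (factor B level 2)
  auto flex_route = [&](int i, double now) {
    ready_t[i] = now;
    for (int r = 0; r < 3; ++r)
      if ((rem_mask[i] & (1 << r)) && room_busy[r] < rooms[r]) {
        start_exam(i, r, now);
        return;
      }
    flexpool.push_back(i);
  };

  auto begin_checkups = [&](int i, double now) {
    int cnt = 0;
    for (int r = 0; r < 3; ++r) if (need_exam(i, r)) cnt++;
    if (cnt == 0) { disposition_of(i, now); return; }
    if (fB == 2) {
      rem_mask[i] = 0;
      for (int r = 0; r < 3; ++r) if (need_exam(i, r)) rem_mask[i] |= (1 << r);
      flex_route(i, now);
    } else {
      int len = 0;
      if (fB == 1) {
        for (int r = 0; r < 3; ++r)
          if (need_exam(i, r)) exam_order[3 * i + len++] = r;
      } else {  // level 3: pre-drawn random permutation
        for (int k = 0; k < 3; ++k) {
          int r = perm(i, k) - 1;
          if (need_exam(i, r)) exam_order[3 * i + len++] = r;
        }
      }
      exam_len[i] = len;
      exam_pos[i] = 0;
      int r = exam_order[3 * i];
      ready_t[i] = now;
      roomq[r].push_back(i);
      fill_room(r, now);
    }
  };

  const long max_events = 400L * (n + 10L) + 4000000L;
  long n_events = 0;

  while (!evq.empty()) {
    if (++n_events > max_events) stop("event budget exceeded (engine stuck?)");
    Ev ev = evq.top(); evq.pop();
    const double now = ev.t;

    switch (ev.type) {
    case EV_ARRIVAL: {
      int i = ev.i;
      if (triage[i] >= 4 && prev_day_edwinc >= divert_thr &&
          u_divert[i] < p_divert) {
        departure[i] = now;
        disposition[i] = 0;
        break;
      }
      n_by_triage[triage[i] - 1]++;
      total_in_ed++;
      ready_t[i] = now;
      regq.push_back(i);
      start_reg(now);
      break;
    }
    case EV_END_REG: {
      int i = ev.i;
      reg_busy--;
      ready_t[i] = now;
      entry_t[i] = now;
      if (triage[i] <= 3) q123[triage[i] - 1].push_back(i);
      else q45.push_back(i);
      start_phys(now);
      start_reg(now);
      break;
    }
    case EV_END_PHYS: {
      int i = ev.i;
      phys_busy--;
      begin_checkups(i, now);
      start_phys(now);
      break;
    }
    case EV_END_EXAM: {
      int i = ev.i, r = ev.room;
      room_busy[r]--;
      if (fB == 2) {
        rem_mask[i] &= ~(1 << r);
        if (rem_mask[i] == 0) disposition_of(i, now);
        else flex_route(i, now);
      } else {
        exam_pos[i]++;
        if (exam_pos[i] >= exam_len[i]) {
          disposition_of(i, now);
        } else {
          int r2 = exam_order[3 * i + exam_pos[i]];
          ready_t[i] = now;
          roomq[r2].push_back(i);
          fill_room(r2, now);
        }
      }
      fill_room(r, now);
      break;
    }
    case EV_TICK: {
      if (now <= horizon + 1e-9) {
        int free = Bt - BA;
        double val;
        if (free > 0) {
          double num = 0;
          for (int k = 0; k < 5; ++k)
            num += n_by_triage[k] * (6.0 - (k + 1));
          val = num / (static_cast<double>(M) * free);
          last_valid_edwinc = val;
        } else {
          val = last_valid_edwinc;  // fully boarded ED: carry forward
        }
        hourly_t.push_back(now);
        hourly_edwinc.push_back(val);
        day_vals.push_back(val);
        double day_frac = now - 1440.0 * std::floor(now / 1440.0 + 1e-12);
        if (day_frac < 1e-6 && !day_vals.empty()) {
          double a;
          if (agg == 1) a = *std::max_element(day_vals.begin(), day_vals.end());
          else if (agg == 2) a = day_vals.back();
          else {
            a = 0;
            for (double v : day_vals) a += v;
            a /= day_vals.size();
          }
          prev_day_edwinc = a;
          day_vals.clear();
        }
      }
      // factor-C bed release: quota of internal-medicine beds per check
      if (BA > 0) {
        double wf = total_in_ed > 0 ?
          static_cast<double>(BA) / total_in_ed : 0.0;
        double thr = (fC == 1) ? 0.15 : (fC == 2) ? 0.20 : 0.25;
        int quota = (fC == 1) ? 5 : (fC == 2) ? 10 : 15;
        if (wf > thr) {
          int k = std::min(quota, BA);
          for (int j = 0; j < k; ++j) {
            int i = boarding.front(); boarding.pop_front();
            wait_bed[i] = now - board_start[i];
            BA--;
            depart(i, now, 2);
          }
        }
      }
      if (now < horizon - 1e-9 || total_in_ed > 0)
        schedule(now + tick_min, EV_TICK, -1, -1);
      break;
    }
    }
  }

  return List::create(
    _["wait_reg"] = wait_reg, _["wait_phys"] = wait_phys,
    _["wait_exam"] = wait_exam, _["wait_bed"] = wait_bed,
    _["serv_reg"] = serv_reg, _["serv_phys"] = serv_phys,
    _["serv_exam"] = serv_exam,
    _["phys_start"] = phys_start, _["departure"] = departure,
    _["disposition"] = disposition,
    _["hourly_time"] = hourly_t, _["hourly_edwinc"] = hourly_edwinc);
}
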