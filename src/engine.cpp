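#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One night of the chorus: a 1-second cycle loop of
//   retarget -> move -> resolve matings
// over fixed males and searching females. Positions are continuous cm in
// [0,width] x [0,length]. All randomness comes from R's RNG stream
// (unif_rand), so set.seed() in R makes a run bit-reproducible.
//
// strategy codes: 0 random, 1 best_of_n, 2 best_of_n_no_switch,
//                 3 min_threshold
// retarget reasons: 0 initial, 1 previous target mated, 2 better male
//                   entered the n-closest set (best_of_n only)

static inline double sqdist(double ax, double ay, double bx, double by) {
  const double dx = ax - bx, dy = ay - by;
  return dx * dx + dy * dy;
}

// index of the best male among the n closest alive ones: max pulse number,
// ties by smaller distance, then lower id; -1 if none alive
static int pick_best_of_n(const std::vector<int> &alive_idx,
                          double px, double py, int n,
                          const NumericVector &mx, const NumericVector &my,
                          const IntegerVector &mpn) {
  const int m = (int)alive_idx.size();
  if (m == 0) return -1;
  std::vector<std::pair<double, int> > d(m);
  for (int j = 0; j < m; ++j) {
    const int i = alive_idx[j];
    d[j] = std::make_pair(sqdist(px, py, mx[i], my[i]), i);
  }
  const int k = std::min(n, m);
  std::partial_sort(d.begin(), d.begin() + k, d.end());
  int best = d[0].second;
  double best_d = d[0].first;
  for (int j = 1; j < k; ++j) {
    const int i = d[j].second;
    if (mpn[i] > mpn[best] ||
        (mpn[i] == mpn[best] &&
         (d[j].first < best_d || (d[j].first == best_d && i < best)))) {
      best = i;
      best_d = d[j].first;
    }
  }
  return best;
}

// closest alive male with pulse number >= theta; ties by lower id; -1 if none
static int pick_min_threshold(const std::vector<int> &alive_idx,
                              double px, double py, double theta,
                              const NumericVector &mx, const NumericVector &my,
                              const IntegerVector &mpn) {
  int best = -1;
  double best_d = 0.0;
  for (size_t j = 0; j < alive_idx.size(); ++j) {
    const int i = alive_idx[j];
    if (mpn[i] < theta) continue;
    const double dd = sqdist(px, py, mx[i], my[i]);
    if (best < 0 || dd < best_d || (dd == best_d && i < best)) {
      best = i;
      best_d = dd;
    }
  }
  return best;
}

static int pick_random(const std::vector<int> &alive_idx) {
  const int m = (int)alive_idx.size();
  if (m == 0) return -1;
  int j = (int)(unif_rand() * m);
  if (j >= m) j = m - 1;
  return alive_idx[j];
}

// [[Rcpp::export]]
List run_night_cpp(NumericVector male_x, NumericVector male_y,
                   IntegerVector male_pn,
                   NumericVector female_x, NumericVector female_y,
                   int strategy, double param,
                   double speed, double contact_radius, int max_cycles,
                   double width, double length, bool keep_log) {
  const int M = male_x.size();
  const int F = female_x.size();
  const double cr2 = contact_radius * contact_radius;
  const int n_param = (int)param;

  std::vector<bool> alive(M, true);
  std::vector<double> fx(F), fy(F);
  // status: 0 searching, 1 mated, 2 removed unmated
  std::vector<int> status(F, 0), tgt(F, -1), ntarg(F, 0), cycles(F, 0);
  std::vector<double> dist(F, 0.0);
  IntegerVector mate_pn(F, NA_INTEGER);
  IntegerVector mate_id(F, NA_INTEGER);
  for (int f = 0; f < F; ++f) {
    fx[f] = female_x[f];
    fy[f] = female_y[f];
  }

  std::vector<int> alive_idx(M);
  for (int i = 0; i < M; ++i) alive_idx[i] = i;

  std::vector<int> log_f, log_m, log_reason, log_cycle;

  int cycle = 0;
  bool timed_out = false;
  while (true) {
    if (cycle >= max_cycles) {
      timed_out = true;
      break;
    }
    ++cycle;

    // phase 1: every searching female (re)selects a target
    for (int f = 0; f < F; ++f) {
      if (status[f] != 0) continue;
      const int cur = tgt[f];
      const bool cur_valid = cur >= 0 && alive[cur];
      int reason = cur < 0 ? 0 : 1;
      int newt = cur_valid ? cur : -1;

      if (strategy == 0) {          // random: keep target until it mates
        if (!cur_valid) newt = pick_random(alive_idx);
      } else if (strategy == 3) {   // min threshold: keep until it mates
        if (!cur_valid)
          newt = pick_min_threshold(alive_idx, fx[f], fy[f], param,
                                    male_x, male_y, male_pn);
      } else {                      // best-of-n kinds
        if (strategy == 1 || !cur_valid) {
          const int cand = pick_best_of_n(alive_idx, fx[f], fy[f], n_param,
                                          male_x, male_y, male_pn);
          if (cur_valid) {
            // only leave a living target for a strictly better male
            if (cand >= 0 && male_pn[cand] > male_pn[cur]) {
              newt = cand;
              reason = 2;
            }
          } else {
            newt = cand;
          }
        }
      }

      if (newt < 0) {
        // no acceptable (min_threshold) or no alive (chorus empty) male:
        // one random-walk step of length `speed`, then removal
        if (strategy == 3) {
          const double ang = 2.0 * M_PI * unif_rand();
          fx[f] = std::min(width, std::max(0.0, fx[f] + speed * std::cos(ang)));
          fy[f] = std::min(length, std::max(0.0, fy[f] + speed * std::sin(ang)));
          dist[f] += speed;
        }
        status[f] = 2;
        cycles[f] = cycle;
        tgt[f] = -1;
        continue;
      }

      if (newt != cur) {
        tgt[f] = newt;
        ntarg[f] += 1;
        if (keep_log) {
          log_f.push_back(f + 1);
          log_m.push_back(newt + 1);
          log_reason.push_back(reason);
          log_cycle.push_back(cycle);
        }
      }
    }

    // phase 2: all remaining searching females move toward their targets
    for (int f = 0; f < F; ++f) {
      if (status[f] != 0 || tgt[f] < 0) continue;
      const int m = tgt[f];
      const double dx = male_x[m] - fx[f], dy = male_y[m] - fy[f];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d <= 0.0) continue;
      const double step = std::min(speed, d);
      fx[f] += dx / d * step;
      fy[f] += dy / d * step;
      dist[f] += step;
    }

    // phase 3: mating resolution; for each male the nearest searching
    // female within contact radius mates (exact ties broken at random);
    // both leave the pool and are not replaced. Proximity, not targeting,
    // decides: a female passing within reach of a calling male mates him.
    for (int m = 0; m < M; ++m) {
      if (!alive[m]) continue;
      int winner = -1;
      double win_d = 0.0;
      int n_tied = 0;
      for (int f = 0; f < F; ++f) {
        if (status[f] != 0) continue;
        const double dd = sqdist(fx[f], fy[f], male_x[m], male_y[m]);
        if (dd > cr2) continue;
        if (winner < 0 || dd < win_d) {
          winner = f;
          win_d = dd;
          n_tied = 1;
        } else if (dd == win_d) {
          // reservoir choice among exact ties
          ++n_tied;
          if (unif_rand() * n_tied < 1.0) winner = f;
        }
      }
      if (winner >= 0) {
        status[winner] = 1;
        mate_pn[winner] = male_pn[m];
        mate_id[winner] = m + 1;
        cycles[winner] = cycle;
        alive[m] = false;
      }
    }
    // compact the alive index once per cycle
    alive_idx.clear();
    for (int i = 0; i < M; ++i)
      if (alive[i]) alive_idx.push_back(i);

    bool any_searching = false;
    for (int f = 0; f < F; ++f)
      if (status[f] == 0) {
        any_searching = true;
        break;
      }
    if (!any_searching) break;
  }

  LogicalVector mated(F);
  IntegerVector n_targets(F), cycles_active(F), status_out(F);
  NumericVector distance(F);
  for (int f = 0; f < F; ++f) {
    mated[f] = status[f] == 1;
    n_targets[f] = ntarg[f];
    cycles_active[f] = status[f] == 0 ? max_cycles : cycles[f];
    distance[f] = dist[f];
    status_out[f] = status[f];
  }

  List out = List::create(
      _["mated"] = mated, _["mate_pn"] = mate_pn, _["mate_id"] = mate_id,
      _["distance"] = distance,
      _["n_targets"] = n_targets, _["cycles_active"] = cycles_active,
      _["status"] = status_out, _["n_cycles"] = cycle,
      _["timed_out"] = timed_out);
  if (keep_log) {
    out["log"] = DataFrame::create(
        _["female_id"] = wrap(log_f), _["male_id"] = wrap(log_m),
        _["reason"] = wrap(log_reason), _["cycle"] = wrap(log_cycle));
  }
  return out;
}
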