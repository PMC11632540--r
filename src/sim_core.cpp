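#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Daily-tick engine: warm-up + horizon loop over the synthetic population.
//
// All within-loop randomness is counter-based: each decision consumes a
// uniform that is a deterministic hash of (run seed, person id, day,
// purpose).  Runs of different intervention scenarios with the same seed
// therefore share every random decision that the intervention does not
// causally touch (common random numbers), and the R and compiled engines
// are bit-identical.  Purpose codes:
//   1 booking count (pid = 0)      7 overdose occurrence
//   2 booking candidate (pid = j)  8 bystander presence
//   3 stay duration                9 naloxone administration
//   4 community channel           10 EMS call
//   5 jail-release channel        11 fatality
//   6 peer-network channel
//
// Conventions: release_day / days_since_release use -1 for "absent";
// person indices are 0-based internally, pids in hashes are 1-based.

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double keyed_u(uint64_t seed, int64_t pid, int64_t day,
                             int purpose) {
  uint64_t z = seed;
  z = mix64(z ^ ((uint64_t) pid * 0x5851F42D4C957F2DULL));
  z = mix64(z ^ ((uint64_t) day * 0xD1342543DE82EF95ULL) ^
            ((uint64_t) purpose << 56));
  return (double) (z >> 11) * (1.0 / 9007199254740992.0);  // [0, 1)
}

// [[Rcpp::export(name = ".keyed_uniform", rng = false)]]
NumericVector keyed_uniform(double seed, IntegerVector pid, int day,
                            int purpose) {
  const uint64_t s = (uint64_t) (int64_t) seed;
  const int n = pid.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = keyed_u(s, (int64_t) pid[i], (int64_t) day, purpose);
  return out;
}

// [[Rcpp::export(name = ".sim_core", rng = false)]]
List sim_core(IntegerVector use_type,
              LogicalVector cli,
              LogicalVector in_jail0,
              IntegerVector release_day0,
              IntegerVector dsr0,
              LogicalVector has_kit0,
              LogicalVector peer_kit0,
              LogicalVector alive0,
              NumericVector rr_demo,
              List pars,
              NumericVector scenario,
              int warmup,
              int horizon,
              double seed,
              bool log_events) {
  const int n = use_type.size();
  const uint64_t sd = (uint64_t) (int64_t) seed;
  const double p0      = pars["p0_daily_od"];
  const double f_fatal = pars["f_fatal"];
  const double rr_wk02 = pars["rr_release_wk0_2"];
  const double rr_wk34 = pars["rr_release_wk3_4"];
  const double rr_wk5  = pars["rr_release_wk5plus"];
  const double p_by    = pars["p_bystander"];
  const double p_adm   = pars["p_administer"];
  const double p_ems   = pars["p_ems"];
  const double eff_nx  = pars["eff_naloxone"];
  const double eff_ems = pars["eff_ems"];
  const double rate    = pars["booking_rate"];
  const double meanlog = pars["meanlog"];
  const double sdlog   = pars["sdlog"];
  const double cov_comm = scenario[0];
  const double cov_jail = scenario[1];
  const double cov_net  = scenario[2];

  std::vector<char> in_jail(n), has_kit(n), peer_kit(n), alive(n);
  std::vector<int> release_day(n), dsr(n), od_count(n, 0);
  std::vector<char> released_flag(n, 0), died_h(n, 0);
  for (int i = 0; i < n; ++i) {
    in_jail[i] = in_jail0[i];
    has_kit[i] = has_kit0[i];
    peer_kit[i] = peer_kit0[i];
    alive[i] = alive0[i];
    release_day[i] = (release_day0[i] == NA_INTEGER) ? -1 : release_day0[i];
    dsr[i] = (dsr0[i] == NA_INTEGER) ? -1 : dsr0[i];
  }

  std::vector<int> cli_ids, user_ids;
  cli_ids.reserve(n); user_ids.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (cli[i]) cli_ids.push_back(i);
    if (use_type[i] != 0) user_ids.push_back(i);
  }
  const int n_cli_pool = (int) cli_ids.size();

  int census_cnt = 0, n_free = 0;
  for (int i = 0; i < n; ++i) {
    if (in_jail[i]) ++census_cnt;
    if (cli[i] && alive[i] && !in_jail[i]) ++n_free;
  }
  const int census0 = census_cnt;

  const int ndays = warmup + horizon;
  // release schedule bucketed by day (entries re-validated when processed)
  std::vector< std::vector<int> > schedule(ndays);
  for (int i = 0; i < n; ++i)
    if (in_jail[i] && release_day[i] >= -warmup && release_day[i] < horizon)
      schedule[release_day[i] + warmup].push_back(i);
  IntegerVector census_hist(ndays), bookings_hist(ndays), releases_hist(ndays);
  int pool_shortfalls = 0;
  double led_comm = 0, led_jail = 0, led_net = 0, led_repl = 0, led_used = 0;
  double ov_total = 0, deaths_total = 0;

  std::vector<int> ev_day, ev_pid;
  std::vector<char> ev_by, ev_avail, ev_adm, ev_ems, ev_fatal, ev_rel;
  std::vector<int> rel_today, events;
  rel_today.reserve(1024); events.reserve(1024);

  for (int day = -warmup; day < horizon; ++day) {
    const int idx = day + warmup;

    // 1. one-time community distribution at horizon start
    if (day == 0 && cov_comm > 0) {
      for (size_t k = 0; k < user_ids.size(); ++k) {
        const int i = user_ids[k];
        if (!alive[i]) continue;
        if (keyed_u(sd, i + 1, day, 4) < cov_comm && !has_kit[i]) {
          has_kit[i] = 1; led_comm += 1;
        }
      }
    }

    // 2. bookings: K ~ Poisson(rate) via inverse CDF of a keyed uniform,
    //    then uniform-without-replacement selection from the free CLI pool
    //    by keyed rejection sampling (attempt index j keys the draw)
    int booked = 0;
    if (n_cli_pool > 0 && rate > 0) {
      const int K = (int) R::qpois(keyed_u(sd, 0, day, 1), rate, 1, 0);
      if (K >= n_free) {
        if (K > n_free) ++pool_shortfalls;
        for (int k = 0; k < n_cli_pool; ++k) {
          const int i = cli_ids[k];
          if (alive[i] && !in_jail[i]) {
            const double us = keyed_u(sd, i + 1, day, 3);
            const int stay = std::max(1, (int) std::ceil(
              R::qlnorm(us, meanlog, sdlog, 1, 0)));
            in_jail[i] = 1; release_day[i] = day + stay; dsr[i] = -1;
            if (day + stay < horizon) schedule[day + stay + warmup].push_back(i);
            --n_free; ++census_cnt; ++booked;
          }
        }
      } else if (K > 0) {
        int64_t j = 0;
        while (booked < K) {
          ++j;
          const double u = keyed_u(sd, j, day, 2);
          const int i = cli_ids[(int) (u * n_cli_pool)];
          if (alive[i] && !in_jail[i]) {
            const double us = keyed_u(sd, i + 1, day, 3);
            const int stay = std::max(1, (int) std::ceil(
              R::qlnorm(us, meanlog, sdlog, 1, 0)));
            in_jail[i] = 1; release_day[i] = day + stay; dsr[i] = -1;
            if (day + stay < horizon) schedule[day + stay + warmup].push_back(i);
            --n_free; ++census_cnt; ++booked;
          }
        }
      }
    }

    // 3. releases
    rel_today.clear();
    {
      std::vector<int> &bucket = schedule[idx];
      for (size_t k = 0; k < bucket.size(); ++k) {
        const int i = bucket[k];
        if (!(in_jail[i] && release_day[i] == day)) continue;
        in_jail[i] = 0; release_day[i] = -1; dsr[i] = 0;
        --census_cnt; ++n_free;
        rel_today.push_back(i);
        if (day >= 0) released_flag[i] = 1;
      }
      bucket.clear();
    }

    // 4. jail-release and peer-network channels (horizon only)
    if (day >= 0 && !rel_today.empty()) {
      for (size_t k = 0; k < rel_today.size(); ++k) {
        const int i = rel_today[k];
        if (use_type[i] == 0 || !alive[i]) continue;
        if (keyed_u(sd, i + 1, day, 5) < cov_jail && !has_kit[i]) {
          has_kit[i] = 1; led_jail += 1;
        }
        if (keyed_u(sd, i + 1, day, 6) < cov_net && !peer_kit[i]) {
          peer_kit[i] = 1; led_net += 1;
        }
      }
    }

    // 5. overdose draws: Bernoulli per alive, out-of-custody opioid user
    events.clear();
    for (size_t k = 0; k < user_ids.size(); ++k) {
      const int i = user_ids[k];
      if (!alive[i] || in_jail[i]) continue;
      double relm = 1.0;
      if (dsr[i] >= 0)
        relm = dsr[i] < 14 ? rr_wk02 : (dsr[i] < 28 ? rr_wk34 : rr_wk5);
      double p = p0 * rr_demo[i] * relm;
      if (p > 1.0) p = 1.0;
      if (keyed_u(sd, i + 1, day, 7) < p) events.push_back(i);
    }

    // 6. resolution through the bystander tree
    for (size_t e = 0; e < events.size(); ++e) {
      const int i = events[e];
      const bool avail = has_kit[i] || peer_kit[i];
      const bool by = keyed_u(sd, i + 1, day, 8) < p_by;
      const bool adm = by && avail && (keyed_u(sd, i + 1, day, 9) < p_adm);
      const bool ems = by && (keyed_u(sd, i + 1, day, 10) < p_ems);
      const double mult = adm ? (1 - eff_nx) : (ems ? (1 - eff_ems) : 1.0);
      const bool fatal = keyed_u(sd, i + 1, day, 11) < f_fatal * mult;
      if (adm) { led_used += 1; led_repl += 1; }
      if (fatal) {
        alive[i] = 0;
        if (cli[i]) --n_free;
      }
      if (day >= 0) {
        ov_total += 1; ++od_count[i];
        if (fatal) { deaths_total += 1; died_h[i] = 1; }
        if (log_events) {
          ev_day.push_back(day); ev_pid.push_back(i + 1);
          ev_by.push_back(by); ev_avail.push_back(avail);
          ev_adm.push_back(adm); ev_ems.push_back(ems);
          ev_fatal.push_back(fatal); ev_rel.push_back(released_flag[i]);
        }
      }
    }

    // 7. post-release clocks advance at day end (only CLI members can have
    //    been released)
    for (int k = 0; k < n_cli_pool; ++k) {
      const int i = cli_ids[k];
      if (alive[i] && !in_jail[i] && dsr[i] >= 0) ++dsr[i];
    }

    census_hist[idx] = census_cnt;
    bookings_hist[idx] = booked;
    releases_hist[idx] = (int) rel_today.size();
  }

  double ov_rel = 0, deaths_rel = 0;
  for (int i = 0; i < n; ++i) {
    if (released_flag[i]) {
      ov_rel += od_count[i];
      if (died_h[i]) deaths_rel += 1;
    }
  }

  List out = List::create(
    _["overdoses_total"] = ov_total,
    _["deaths_total"] = deaths_total,
    _["overdoses_released"] = ov_rel,
    _["deaths_released"] = deaths_rel,
    _["ledger"] = NumericVector::create(
      _["community"] = led_comm, _["jail"] = led_jail, _["network"] = led_net,
      _["replacements"] = led_repl, _["used"] = led_used),
    _["census"] = census_hist,
    _["bookings"] = bookings_hist,
    _["releases"] = releases_hist,
    _["census0"] = census0,
    _["pool_shortfalls"] = pool_shortfalls);
  if (log_events) {
    out["events"] = DataFrame::create(
      _["day"] = ev_day, _["pid"] = ev_pid,
      _["bystander_present"] = LogicalVector(ev_by.begin(), ev_by.end()),
      _["naloxone_available"] = LogicalVector(ev_avail.begin(), ev_avail.end()),
      _["naloxone_administered"] = LogicalVector(ev_adm.begin(), ev_adm.end()),
      _["ems_called"] = LogicalVector(ev_ems.begin(), ev_ems.end()),
      _["fatal"] = LogicalVector(ev_fatal.begin(), ev_fatal.end()),
      _["victim_released_ever"] = LogicalVector(ev_rel.begin(), ev_rel.end()));
  }
  return out;
}
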