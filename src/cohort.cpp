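#include <Rcpp.h>
using namespace Rcpp;

// Deterministic cohort state-transition recursion.
//
// States: healthy (alive, event-free), diagnosed[k] (k cycles since
// diagnosis, k < cure_cycles, carrying excess mortality), cured (alive,
// past the excess-mortality horizon), dead_other, dead_event (cancer),
// dead_complication (fatal procedure complication).
//
// Per cycle, competing exponential hazards split exits from each alive
// state; exams are applied instantaneously at the start of their cycle to
// the healthy state only. Person-time uses a half-cycle correction
// (average of start- and end-of-cycle occupancy).
//
// Terminal-phase bookkeeping: a cancer death after time-since-diagnosis
// tau contributes min(tau, 1) person-years of terminal phase; that time is
// deducted from the initial/continuing phase person-time it overlaps, so
// the three phases partition diagnosed person-time in expectation.

// [[Rcpp::export(name = ".cohort_run_cpp")]]
List cohort_run_cpp(NumericVector mu,        // other-cause hazard per cycle (midpoint), /yr
                    NumericVector haz_event, // event (diagnosis) hazard per cycle, /yr
                    double dt,               // cycle length, years
                    IntegerVector exam_cycle,   // 0-based cycles with an exam
                    double fatal_exam_risk,     // death probability per exam
                    double excess,              // excess mortality while diagnosed, /yr
                    int cure_cycles,            // cycles of excess mortality after dx
                    int cycles_per_year) {
  const int T = mu.size();
  const int K = cure_cycles > 0 ? cure_cycles : 1;
  const double ex = cure_cycles > 0 ? excess : 0.0;

  LogicalVector is_exam(T, false);
  for (int i = 0; i < exam_cycle.size(); ++i) {
    int c = exam_cycle[i];
    if (c >= 0 && c < T) is_exam[c] = true;
  }

  // start-of-cycle state occupancy (pre-exam)
  NumericVector s_healthy(T), s_dx_initial(T), s_dx_continuing(T), s_cured(T);
  NumericVector s_dead_other(T), s_dead_event(T), s_dead_compl(T);
  // per-cycle flows and person-time
  NumericVector exams(T), compl_deaths(T), new_dx(T), event_deaths(T);
  NumericVector py_healthy(T), py_initial(T), py_continuing(T), py_cured(T);
  NumericVector py_terminal(T), ded_initial(T), ded_continuing(T);

  double H = 1.0, C = 0.0;
  double dead_other = 0.0, dead_event = 0.0, dead_compl = 0.0;
  std::vector<double> D(K, 0.0);

  for (int t = 0; t < T; ++t) {
    // record start-of-cycle states
    double d_init = 0.0, d_cont = 0.0;
    for (int k = 0; k < K; ++k) {
      if (k < cycles_per_year) d_init += D[k]; else d_cont += D[k];
    }
    s_healthy[t] = H;
    s_dx_initial[t] = d_init;
    s_dx_continuing[t] = d_cont;
    s_cured[t] = C;
    s_dead_other[t] = dead_other;
    s_dead_event[t] = dead_event;
    s_dead_compl[t] = dead_compl;

    // exam at start of cycle: healthy only
    if (is_exam[t]) {
      exams[t] = H;
      double dc = H * fatal_exam_risk;
      compl_deaths[t] = dc;
      dead_compl += dc;
      H -= dc;
    }

    const double m = mu[t];
    const double lam = haz_event[t];

    // healthy transitions
    const double tot = lam + m;
    const double ps = std::exp(-tot * dt);
    double nd = 0.0, doth = 0.0;
    if (tot > 0.0) {
      const double pe = 1.0 - ps;
      nd = H * pe * (lam / tot);
      doth = H * pe * (m / tot);
    }
    new_dx[t] = nd;
    dead_other += doth;
    py_healthy[t] = H * 0.5 * (1.0 + ps) * dt;
    // the newly diagnosed leave the healthy state mid-cycle on average and
    // enter the diagnosed compartment at the next cycle start; credit the
    // intervening half cycle to the initial diagnosed phase
    py_initial[t] += nd * 0.5 * dt;

    // diagnosed compartments (descending k so the shift is in place)
    const double totd = m + ex;
    const double psd = std::exp(-totd * dt);
    const double fr_ev = totd > 0.0 ? ex / totd : 0.0;
    const double fr_ot = totd > 0.0 ? m / totd : 0.0;
    double cured_in = 0.0;
    double ev_deaths_t = 0.0;
    for (int k = K - 1; k >= 0; --k) {
      const double d = D[k];
      const double exit = d * (1.0 - psd);
      const double dcrc = exit * fr_ev;
      const double doth_k = exit * fr_ot;
      dead_event += dcrc;
      dead_other += doth_k;
      ev_deaths_t += dcrc;
      const double py = d * 0.5 * (1.0 + psd) * dt;
      if (k < cycles_per_year) py_initial[t] += py; else py_continuing[t] += py;
      if (dcrc > 0.0) {
        const double tau = (k + 0.5) * dt;           // time since dx at death
        const double term = tau < 1.0 ? tau : 1.0;   // terminal window length
        const double lo = tau > 1.0 ? tau - 1.0 : 0.0;
        double ov_init = (tau < 1.0 ? tau : 1.0) - lo; // overlap with [0, 1)
        if (ov_init < 0.0) ov_init = 0.0;
        py_terminal[t] += dcrc * term;
        ded_initial[t] += dcrc * ov_init;
        ded_continuing[t] += dcrc * (term - ov_init);
      }
      const double stay = d * psd;
      if (k == K - 1) cured_in += stay; else D[k + 1] = stay;
    }
    event_deaths[t] = ev_deaths_t;
    D[0] = nd;

    // cured state: background mortality only
    const double psc = std::exp(-m * dt);
    py_cured[t] = C * 0.5 * (1.0 + psc) * dt;
    dead_other += C * (1.0 - psc);
    C = C * psc + cured_in;

    H = H * ps;
  }

  return List::create(
    _["s_healthy"] = s_healthy,
    _["s_dx_initial"] = s_dx_initial,
    _["s_dx_continuing"] = s_dx_continuing,
    _["s_cured"] = s_cured,
    _["s_dead_other"] = s_dead_other,
    _["s_dead_event"] = s_dead_event,
    _["s_dead_compl"] = s_dead_compl,
    _["exams"] = exams,
    _["compl_deaths"] = compl_deaths,
    _["new_dx"] = new_dx,
    _["event_deaths"] = event_deaths,
    _["py_healthy"] = py_healthy,
    _["py_initial"] = py_initial,
    _["py_continuing"] = py_continuing,
    _["py_cured"] = py_cured,
    _["py_terminal"] = py_terminal,
    _["ded_initial"] = ded_initial,
    _["ded_continuing"] = ded_continuing);
}
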