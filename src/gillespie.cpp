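#include <Rcpp.h>
using namespace Rcpp;

// Exact next-reaction sampling over the eight elementary channels:
// births (r_i n_i), pairwise competition deaths (a_ij n_i n_j / Omega) and
// directional gene-conversion events (g_ab n_A n_B / Omega, B->A and A->B).
// Competition and conversion scale with 1/Omega so the large-Omega drift of
// the scaled counts n/Omega is exactly the deterministic count-space system.
// Uses R's RNG so set.seed() on the R side fixes the event sequence.
//
// record_times (sorted, >= 0): states are reported piecewise-constant at these
// times. If keep_events is true the full event log is returned as well.
// [[Rcpp::export]]
List gillespie_core(double rA, double rB,
                    double aAA, double aAB, double aBA, double aBB,
                    double gAB, double gBA, double Omega,
                    double nA0, double nB0, double t_end,
                    NumericVector record_times, bool keep_events,
                    double max_events) {
  RNGScope scope;
  double nA = nA0, nB = nB0, t = 0.0;
  R_xlen_t nrec = record_times.size();
  NumericVector rec_nA(nrec), rec_nB(nrec);
  R_xlen_t irec = 0;

  std::vector<double> ev_t, ev_nA, ev_nB;
  if (keep_events) {
    ev_t.push_back(0.0); ev_nA.push_back(nA); ev_nB.push_back(nB);
  }

  double n_events = 0.0;
  bool overflow = false;

  while (t < t_end) {
    double w[8];
    w[0] = rA * nA;                  // birth A
    w[1] = rB * nB;                  // birth B
    w[2] = aAA * nA * nA / Omega;    // death A by A
    w[3] = aAB * nA * nB / Omega;    // death A by B
    w[4] = aBA * nA * nB / Omega;    // death B by A
    w[5] = aBB * nB * nB / Omega;    // death B by B
    w[6] = gAB * nA * nB / Omega;    // conversion B -> A
    w[7] = gBA * nA * nB / Omega;    // conversion A -> B
    double total = 0.0;
    for (int i = 0; i < 8; ++i) total += w[i];
    if (!R_finite(total)) { overflow = true; break; }
    if (total <= 0.0) { t = t_end; break; }  // absorbing (e.g. (0, 0))

    double dt = ::Rf_rexp(1.0) / total;
    double t_next = t + dt;
    while (irec < nrec && record_times[irec] < t_next &&
           record_times[irec] <= t_end) {
      rec_nA[irec] = nA; rec_nB[irec] = nB; ++irec;
    }
    t = t_next;
    if (t >= t_end) break;

    double u = ::unif_rand() * total, acc = 0.0;
    int ch = 7;
    for (int i = 0; i < 8; ++i) { acc += w[i]; if (u <= acc) { ch = i; break; } }
    switch (ch) {
      case 0: nA += 1; break;
      case 1: nB += 1; break;
      case 2: case 3: nA -= 1; break;
      case 4: case 5: nB -= 1; break;
      case 6: nA += 1; nB -= 1; break;
      case 7: nA -= 1; nB += 1; break;
    }
    if (nA < 0) nA = 0;
    if (nB < 0) nB = 0;

    if (keep_events) {
      ev_t.push_back(t); ev_nA.push_back(nA); ev_nB.push_back(nB);
    }
    if (++n_events >= max_events) {
      List out = List::create(_["error"] = "event budget exceeded",
                              _["t"] = t, _["n_A"] = nA, _["n_B"] = nB);
      return out;
    }
  }

  if (overflow) {
    return List::create(_["error"] = "propensity overflow",
                        _["t"] = t, _["n_A"] = nA, _["n_B"] = nB);
  }
  while (irec < nrec) { rec_nA[irec] = nA; rec_nB[irec] = nB; ++irec; }

  List out = List::create(_["rec_nA"] = rec_nA, _["rec_nB"] = rec_nB,
                          _["final_t"] = t, _["n_events"] = n_events);
  if (keep_events) {
    out["ev_t"] = NumericVector(ev_t.begin(), ev_t.end());
    out["ev_nA"] = NumericVector(ev_nA.begin(), ev_nA.end());
    out["ev_nB"] = NumericVector(ev_nB.begin(), ev_nB.end());
  }
  return out;
}
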