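#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Continuous-time Gillespie simulation of the spatial branching process with
// mutation influx on an L x L torus.
//
// Events and rates:
//   * de novo mutation: rate Lambda; a new allele (infinite-sites: fresh
//     allele id) appears as a single carrier at a uniform random position.
//   * birth: each carrier reproduces at rate 1 - s; the offspring carrier
//     appears at the parent's (current) position with the parent's allele id.
//   * death: each carrier dies at rate 1.
//
// Positions are updated lazily: Brownian increments are exact for any
// elapsed time, so a carrier's position is advanced (with per-axis variance
// sigma^2/2 per generation, wrapped mod L) only when the carrier is touched
// by an event or when a snapshot is recorded. Work is O(events + records*C),
// not O(events * carriers).
//
// Uses R's RNG (RNGScope via Rcpp attributes), so set.seed() in R gives
// fully deterministic runs.

static inline double wrap(double v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v = 0.0;  // guard the v/L rounding edge
  return v;
}

// [[Rcpp::export]]
List gillespie_branching_cpp(double Lambda, double s, double sigma, double L,
                             double total_time, double burn_in,
                             double record_every, int max_carriers,
                             int init_carriers) {
  if (Lambda < 0 || s <= 0 || s >= 1 || sigma <= 0 || L <= 0)
    stop("invalid rate or habitat parameters");
  if (record_every <= 0 || burn_in >= total_time)
    stop("need record_every > 0 and burn_in < total_time");

  std::vector<double> px, py, last;
  std::vector<int> allele;
  px.reserve(1024); py.reserve(1024); last.reserve(1024); allele.reserve(1024);

  int next_allele = 0;
  for (int i = 0; i < init_carriers; ++i) {
    px.push_back(R::runif(0.0, L));
    py.push_back(R::runif(0.0, L));
    last.push_back(0.0);
    allele.push_back(next_allele++);
  }

  double t = 0.0;
  double next_rec = burn_in + record_every;
  long long n_events = 0;

  int n_recs = (int)std::floor((total_time - burn_in) / record_every + 1e-9);
  if (n_recs < 0) n_recs = 0;
  NumericVector rec_times(n_recs);
  List snaps(n_recs);
  int rec_idx = 0;

  auto advance = [&](size_t i, double now) {
    double dt = now - last[i];
    if (dt > 0) {
      double sd = sigma * std::sqrt(dt / 2.0);
      px[i] = wrap(px[i] + R::rnorm(0.0, sd), L);
      py[i] = wrap(py[i] + R::rnorm(0.0, sd), L);
      last[i] = now;
    }
  };

  while (true) {
    double C = (double)px.size();
    double total_rate = Lambda + C * (2.0 - s);
    double dt = (total_rate > 0.0) ? R::rexp(1.0 / total_rate) : R_PosInf;
    double t_next = t + dt;

    // emit any snapshots scheduled before the next event
    while (rec_idx < n_recs && next_rec <= t_next && next_rec <= total_time) {
      size_t n = px.size();
      IntegerVector aid(n);
      NumericVector sx(n), sy(n);
      for (size_t i = 0; i < n; ++i) {
        advance(i, next_rec);
        aid[i] = allele[i];
        sx[i] = px[i];
        sy[i] = py[i];
      }
      rec_times[rec_idx] = next_rec;
      snaps[rec_idx] = List::create(_["allele"] = aid, _["x"] = sx,
                                    _["y"] = sy);
      ++rec_idx;
      next_rec += record_every;
    }
    if (t_next > total_time || !R_FINITE(t_next)) {
      t = total_time;
      break;
    }
    t = t_next;
    ++n_events;

    double u = R::runif(0.0, total_rate);
    if (u < Lambda) {
      // mutation: new allele, uniform position
      px.push_back(R::runif(0.0, L));
      py.push_back(R::runif(0.0, L));
      last.push_back(t);
      allele.push_back(next_allele++);
    } else {
      size_t i = (size_t)((u - Lambda) / (2.0 - s));
      if (i >= px.size()) i = px.size() - 1;  // guard float edge
      double v = (u - Lambda) - (double)i * (2.0 - s);
      if (v < 1.0 - s) {
        // birth: offspring at parent's current position
        advance(i, t);
        px.push_back(px[i]);
        py.push_back(py[i]);
        last.push_back(t);
        allele.push_back(allele[i]);
      } else {
        // death: swap-remove
        size_t m = px.size() - 1;
        px[i] = px[m]; py[i] = py[m]; last[i] = last[m]; allele[i] = allele[m];
        px.pop_back(); py.pop_back(); last.pop_back(); allele.pop_back();
      }
    }
    if ((int)px.size() > max_carriers)
      stop("carrier count exceeded max_carriers (%d): parameter regime "
           "violates the rarity assumption (cf. neighborhood size 4*pi*sigma^2*rho)",
           max_carriers);
  }

  // final state advanced to total_time
  size_t n = px.size();
  IntegerVector faid(n);
  NumericVector fx(n), fy(n);
  for (size_t i = 0; i < n; ++i) {
    advance(i, total_time);
    faid[i] = allele[i];
    fx[i] = px[i];
    fy[i] = py[i];
  }

  return List::create(
    _["times"] = rec_times,
    _["snapshots"] = snaps,
    _["final"] = List::create(_["allele"] = faid, _["x"] = fx, _["y"] = fy),
    _["n_events"] = (double)n_events,
    _["n_alleles_total"] = next_allele);
}
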