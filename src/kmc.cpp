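#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Continuous-time kinetic Monte Carlo for open TASEP with Langmuir kinetics.
//
// Events and rates (continuous-time, unit hop rate):
//   injection at site 0 (rate alpha, if empty), hop i -> i+1 (rate 1, if
//   occupied/empty pair), withdrawal at site N-1 (rate beta, if occupied),
//   adsorption (rate omega_a per empty site), evaporation (rate omega_d per
//   occupied site).
// Rejection-free category selection with O(1) bookkeeping of the number of
// occupied sites and hoppable bonds; the site/bond within a category is
// drawn by rejection sampling (expected O(N / n_category) per draw, with a
// linear-scan fallback guard).
//
// Site occupancies are time-average accumulated exactly between events via
// per-site "occupied since" stamps; the bond current <tau_i (1 - tau_{i+1})>
// is accumulated the same way. Sampling starts at t_burn.
//
// Uses R's RNG so that set.seed() in R controls reproducibility.

namespace {

struct Accum {
  std::vector<double> occ_time, occ_since;
  std::vector<double> bond_time, bond_since;
  bool on;
  Accum(int N) : occ_time(N, 0.0), occ_since(N, 0.0),
                 bond_time(N > 1 ? N - 1 : 0, 0.0),
                 bond_since(N > 1 ? N - 1 : 0, 0.0), on(false) {}
};

inline bool bond_active(const std::vector<int>& tau, int b) {
  return tau[b] == 1 && tau[b + 1] == 0;
}

} // namespace

// [[Rcpp::export]]
List kmc_run(int N, double alpha, double beta, double omega_a, double omega_d,
             double t_burn, double t_sample, IntegerVector init) {
  if (N < 2) stop("N must be >= 2");
  if (init.size() != N) stop("init must have length N");
  std::vector<int> tau(N);
  int n_occ = 0, n_bonds = 0;
  for (int i = 0; i < N; ++i) {
    tau[i] = init[i] ? 1 : 0;
    n_occ += tau[i];
  }
  for (int b = 0; b < N - 1; ++b) n_bonds += bond_active(tau, b);

  const double t_end = t_burn + t_sample;
  double t = 0.0;
  Accum acc(N);
  long long n_events = 0;

  auto start_sampling = [&](double ts) {
    for (int i = 0; i < N; ++i) if (tau[i]) acc.occ_since[i] = ts;
    for (int b = 0; b < N - 1; ++b) if (bond_active(tau, b)) acc.bond_since[b] = ts;
    acc.on = true;
  };
  if (t_burn <= 0.0) start_sampling(0.0);

  // flip site i at time tf; updates occupancy accumulators and bond state
  auto flip = [&](int i, double tf) {
    // bonds i-1 and i change status with site i
    for (int b = i - 1; b <= i; ++b) {
      if (b < 0 || b >= N - 1) continue;
      if (bond_active(tau, b)) {           // was active, will deactivate
        if (acc.on) acc.bond_time[b] += tf - acc.bond_since[b];
        --n_bonds;
      }
    }
    if (tau[i]) {                          // occupied -> empty
      if (acc.on) acc.occ_time[i] += tf - acc.occ_since[i];
      tau[i] = 0; --n_occ;
    } else {                               // empty -> occupied
      if (acc.on) acc.occ_since[i] = tf;
      tau[i] = 1; ++n_occ;
    }
    for (int b = i - 1; b <= i; ++b) {
      if (b < 0 || b >= N - 1) continue;
      if (bond_active(tau, b)) {           // newly active
        if (acc.on) acc.bond_since[b] = tf;
        ++n_bonds;
      }
    }
  };

  // rejection draw of a site with tau == want, fallback to scan
  auto draw_site = [&](int want) -> int {
    for (int k = 0; k < 64; ++k) {
      int i = (int)std::floor(unif_rand() * N);
      if (i >= N) i = N - 1;
      if (tau[i] == want) return i;
    }
    int m = 0;                             // scan fallback: count then index
    for (int i = 0; i < N; ++i) m += (tau[i] == want);
    int j = (int)std::floor(unif_rand() * m);
    for (int i = 0; i < N; ++i)
      if (tau[i] == want && j-- == 0) return i;
    return -1; // unreachable: caller guarantees m > 0
  };
  auto draw_bond = [&]() -> int {
    for (int k = 0; k < 64; ++k) {
      int b = (int)std::floor(unif_rand() * (N - 1));
      if (b >= N - 1) b = N - 2;
      if (bond_active(tau, b)) return b;
    }
    int j = (int)std::floor(unif_rand() * n_bonds);
    for (int b = 0; b < N - 1; ++b)
      if (bond_active(tau, b) && j-- == 0) return b;
    return -1;
  };

  while (t < t_end) {
    const double r_inj = alpha * (tau[0] == 0);
    const double r_out = beta * (tau[N - 1] == 1);
    const double r_ads = omega_a * (N - n_occ);
    const double r_eva = omega_d * n_occ;
    const double r_hop = (double)n_bonds;
    const double r_tot = r_inj + r_out + r_ads + r_eva + r_hop;
    if (r_tot <= 0.0) break;               // frozen configuration

    double dt = -std::log(unif_rand()) / r_tot;
    double t_new = t + dt;
    if (!acc.on && t_new >= t_burn) start_sampling(t_burn);
    if (t_new >= t_end) { t = t_end; break; }
    t = t_new;

    double u = unif_rand() * r_tot;
    if (u < r_inj) {
      flip(0, t);
    } else if (u < r_inj + r_out) {
      flip(N - 1, t);
    } else if (u < r_inj + r_out + r_ads) {
      flip(draw_site(0), t);
    } else if (u < r_inj + r_out + r_ads + r_eva) {
      flip(draw_site(1), t);
    } else {
      int b = draw_bond();
      flip(b, t);                          // particle leaves site b
      flip(b + 1, t);                      // and lands on b+1
    }
    ++n_events;
    if ((n_events & 0xFFFFF) == 0) checkUserInterrupt();
  }

  if (!acc.on) start_sampling(t_burn);     // frozen before burn-in ended
  // close open intervals at t_end
  for (int i = 0; i < N; ++i)
    if (tau[i]) acc.occ_time[i] += t_end - acc.occ_since[i];
  for (int b = 0; b < N - 1; ++b)
    if (bond_active(tau, b)) acc.bond_time[b] += t_end - acc.bond_since[b];

  NumericVector rho(N), J(N - 1);
  for (int i = 0; i < N; ++i) rho[i] = acc.occ_time[i] / t_sample;
  for (int b = 0; b < N - 1; ++b) J[b] = acc.bond_time[b] / t_sample;
  return List::create(_["rho"] = rho, _["current"] = J,
                      _["n_events"] = (double)n_events);
}
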