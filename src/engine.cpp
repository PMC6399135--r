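// Compiled simulation engine.
//
// Implements the same per-step semantics as the pure-R reference kernels
// (see R/trafficking.R), with binomial batching of the per-site
// nucleation Bernoulli draws and per-step bucketing of the vesicle
// queues. Phase order within a step:
//   1 Rab5 expiry
//   2 vesicle fusion (endocytic then exocytic)
//   3 pit scission, bud release
//   4 nucleation (pits then buds)
//   5 diffusion (surface then EE)
//   6 switch update and sorting draw
//   7 recording + conservation audit
// All times are seconds; rates arrive in min^-1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Ves {
  double arr;
  int cargo;
};

inline int rand_site(int L2) {
  int s = (int)(unif_rand() * L2);
  if (s >= L2) s = L2 - 1;
  return s;
}

inline double runif_ab(double lo, double hi) {
  return lo + unif_rand() * (hi - lo);
}

inline double rtnorm_floor(double mean, double sd, double floor_) {
  double x = norm_rand() * sd + mean;
  return (x < floor_) ? floor_ : x;
}

inline double tau_rab5_unit(double D, double a, double b, double C, double K) {
  return K * D * (C - D) / (1.0 + std::exp(-(D - a) / b));
}

// synchronous unbounded random walk; nbr is L2 x 4 (0-based)
void diffuse_grid(std::vector<int> &occ, std::vector<int> &buf,
                  const std::vector<int> &nbr, double q) {
  const int L2 = (int)occ.size();
  if (q <= 0.0) return;
  std::fill(buf.begin(), buf.end(), 0);
  for (int s = 0; s < L2; ++s) {
    int n = occ[s];
    if (n == 0) continue;
    for (int r = 0; r < n; ++r) {
      double u = unif_rand();
      if (u < 4.0 * q) {
        int dir = (int)(u / q);
        if (dir > 3) dir = 3;
        ++buf[nbr[4 * s + dir]];
      } else {
        ++buf[s];
      }
    }
  }
  occ.swap(buf);
}

} // namespace

// [[Rcpp::export]]
List sim_engine_cpp(List state, List sw, NumericVector k_endo_min,
                    List pars, int n_steps, int record_every,
                    bool enable_switch, bool audit) {
  RNGScope rng;

  const int L = as<int>(pars["lattice_side"]);
  const int L2 = L * L;
  const int S_im = as<int>(pars["S_im"]);
  const double dt = as<double>(pars["dt"]);
  const double spacing = as<double>(pars["lattice_spacing"]);
  const double q_s = as<double>(pars["d_s"]) * dt / (spacing * spacing);
  const double q_ee = as<double>(pars["d_EE"]) * dt / (spacing * spacing);
  const double k_exo = as<double>(pars["k_exo"]);
  const NumericVector pit_rng = pars["tau_pit_range"];     // seconds
  const NumericVector bud_rng = pars["tau_bud_range"];     // seconds
  const double endo_mean = as<double>(pars["tau_endo_mean"]) * 60.0;
  const double endo_sd = as<double>(pars["tau_endo_sd"]) * 60.0;
  const double exo_mean = as<double>(pars["tau_exo_mean"]) * 60.0;
  const double exo_sd = as<double>(pars["tau_exo_sd"]) * 60.0;
  const double a = as<double>(pars["a"]);
  const double b = as<double>(pars["b"]);
  const double C = as<double>(pars["C"]);
  const double K = as<double>(pars["K"]);
  const double tau_s_sec = as<double>(pars["tau_s"]) * 60.0;
  const double rab5_scale = as<double>(pars["tau_rab5_scale"]); // unit -> s
  const double p_exo_step = 1.0 - std::exp(-k_exo / 60.0 * dt);

  if (k_endo_min.size() != n_steps)
    stop("k_endo_min must have one entry per step");

  // --- unpack state -------------------------------------------------------
  std::vector<int> surf = as<std::vector<int>>(state["surf"]);
  std::vector<int> ee = as<std::vector<int>>(state["ee"]);
  std::vector<double> pit_t = as<std::vector<double>>(state["pit_t"]);
  std::vector<double> bud_t = as<std::vector<double>>(state["bud_t"]);
  std::vector<double> rab5 = as<std::vector<double>>(state["rab5_exp"]);
  if ((int)surf.size() != L2 || (int)ee.size() != L2)
    stop("lattice size mismatch between state and parameters");
  const double t0 = as<double>(state["t"]);
  int tally = as<int>(state["sorted_tally"]);

  // switch
  double h = as<double>(sw["h"]);
  double t_exc = as<double>(sw["t_exc"]); // NA if unset
  bool have_exc = !NumericVector::is_na(t_exc);
  double T_above = as<double>(sw["T_above"]);
  bool sorted = as<bool>(sw["sorted"]);
  double t_sort = as<double>(sw["t_sort"]);
  int n_sorted_event = 0;

  // neighbour table (toroidal, column-major)
  std::vector<int> nbr(4 * L2);
  for (int s = 0; s < L2; ++s) {
    int row = s % L, col = s / L;
    nbr[4 * s + 0] = ((row + L - 1) % L) + col * L;
    nbr[4 * s + 1] = ((row + 1) % L) + col * L;
    nbr[4 * s + 2] = row + ((col + L - 1) % L) * L;
    nbr[4 * s + 3] = row + ((col + 1) % L) * L;
  }
  std::vector<int> buf(L2, 0);

  // vesicle buckets by due step (1-based steps; step i is time t0 + i*dt)
  std::vector<std::vector<Ves>> endoB(n_steps + 1), exoB(n_steps + 1);
  std::vector<Ves> endo_over, exo_over; // arrivals beyond the horizon
  long endo_cargo_tot = 0, exo_cargo_tot = 0;
  long endo_n = 0, exo_n = 0; // vesicle counts in flight
  auto push_ves = [&](std::vector<std::vector<Ves>> &B, std::vector<Ves> &over,
                      double arr, int cargo) {
    double k = std::ceil((arr - t0) / dt - 1e-9);
    int idx = (k < 1.0) ? 1 : (int)k;
    if (idx > n_steps)
      over.push_back({arr, cargo});
    else
      B[idx].push_back({arr, cargo});
  };
  {
    NumericVector ea = state["endo_arr"];
    IntegerVector ec = state["endo_cargo"];
    for (int i = 0; i < ea.size(); ++i) {
      push_ves(endoB, endo_over, ea[i], ec[i]);
      endo_cargo_tot += ec[i];
      ++endo_n;
    }
    NumericVector xa = state["exo_arr"];
    IntegerVector xc = state["exo_cargo"];
    for (int i = 0; i < xa.size(); ++i) {
      push_ves(exoB, exo_over, xa[i], xc[i]);
      exo_cargo_tot += xc[i];
      ++exo_n;
    }
  }

  long surf_tot = 0, ee_tot = 0;
  for (int s = 0; s < L2; ++s) {
    surf_tot += surf[s];
    ee_tot += ee[s];
  }
  int n_rab5 = 0;
  for (int s = 0; s < L2; ++s)
    if (std::isfinite(rab5[s])) ++n_rab5;
  const long total0 = surf_tot + ee_tot + endo_cargo_tot + exo_cargo_tot + tally;

  // per-step site-event buckets replace full-lattice scans; events due
  // beyond the horizon stay in the per-site arrays and are re-bucketed
  // by the next engine call
  auto bucket_step = [&](double tt) {
    double k = std::ceil((tt - t0) / dt - 1e-9);
    return (k < 1.0) ? 1 : (int)k;
  };
  std::vector<std::vector<int>> pitB(n_steps + 1), budB(n_steps + 1),
      rabB(n_steps + 1);
  // pit-free surface sites kept in a swap-remove list so that a uniform
  // random free site is O(1) even when pits saturate the lattice
  std::vector<int> pitFree;
  std::vector<int> pitPos(L2, -1);
  pitFree.reserve(L2);
  auto pit_free_add = [&](int s) {
    pitPos[s] = (int)pitFree.size();
    pitFree.push_back(s);
  };
  auto pit_free_remove = [&](int s) {
    int idx = pitPos[s];
    int last = pitFree.back();
    pitFree[idx] = last;
    pitPos[last] = idx;
    pitFree.pop_back();
    pitPos[s] = -1;
  };
  int n_buds = 0;    // EE sites with a pending bud
  int n_both = 0;    // Rab5-positive sites with a pending bud
  for (int s = 0; s < L2; ++s) {
    if (std::isfinite(pit_t[s])) {
      int j = bucket_step(pit_t[s]);
      if (j <= n_steps) pitB[j].push_back(s);
    } else {
      pit_free_add(s);
    }
    if (std::isfinite(bud_t[s])) {
      ++n_buds;
      int j = bucket_step(bud_t[s]);
      if (j <= n_steps) budB[j].push_back(s);
      if (std::isfinite(rab5[s])) ++n_both;
    }
    if (std::isfinite(rab5[s])) {
      int j = bucket_step(rab5[s]);
      if (j <= n_steps) rabB[j].push_back(s);
    }
  }

  // records
  const int n_rec = n_steps / record_every;
  NumericMatrix rec(n_rec, 9);
  colnames(rec) = CharacterVector::create(
      "t", "postsyn", "ee_total", "n_rab5", "n_ee_rab5",
      "endo_transit", "exo_transit", "sorted_tally", "p_sort");
  int rec_i = 0;

  long n_endo_events = 0, n_exo_events = 0; // scissions / releases

  for (int i = 1; i <= n_steps; ++i) {
    const double t = t0 + i * dt;

    // 1 expire Rab5 (bucketed; entries may be stale after sorting)
    for (int s : rabB[i]) {
      if (std::isfinite(rab5[s]) && rab5[s] <= t) {
        rab5[s] = R_NegInf;
        --n_rab5;
        if (std::isfinite(bud_t[s])) --n_both;
      }
    }
    rabB[i].clear();

    // 2 fuse arrivals: endocytic (recruit Rab5), then exocytic
    for (const Ves &v : endoB[i]) {
      int s = rand_site(L2);
      ee[s] += v.cargo;
      ee_tot += v.cargo;
      endo_cargo_tot -= v.cargo;
      --endo_n;
      if (!std::isfinite(rab5[s])) {
        double D = (double)n_rab5 / L2; // pre-placement fraction
        rab5[s] = t + tau_rab5_unit(D, a, b, C, K) * rab5_scale;
        ++n_rab5;
        if (std::isfinite(bud_t[s])) ++n_both;
        int j = bucket_step(rab5[s]);
        if (j <= i) j = i + 1; // same-step expiry clears next step
        if (j <= n_steps) rabB[j].push_back(s);
      }
    }
    endoB[i].clear();
    for (const Ves &v : exoB[i]) {
      int s = rand_site(L2);
      surf[s] += v.cargo;
      surf_tot += v.cargo;
      exo_cargo_tot -= v.cargo;
      --exo_n;
    }
    exoB[i].clear();

    // 3 scission of due pits / release of due buds (bucketed)
    for (int s : pitB[i]) {
      int cargo = surf[s];
      surf[s] = 0;
      surf_tot -= cargo;
      pit_t[s] = R_PosInf;
      pit_free_add(s); // site is pit-free again, eligible this step
      double tau = rtnorm_floor(endo_mean, endo_sd, dt);
      push_ves(endoB, endo_over, t + tau, cargo);
      endo_cargo_tot += cargo;
      ++endo_n;
      ++n_endo_events;
    }
    pitB[i].clear();
    for (int s : budB[i]) {
      int cargo = ee[s];
      ee[s] = 0;
      ee_tot -= cargo;
      bud_t[s] = R_PosInf;
      --n_buds;
      if (std::isfinite(rab5[s])) --n_both;
      double tau = rtnorm_floor(exo_mean, exo_sd, dt);
      push_ves(exoB, exo_over, t + tau, cargo);
      exo_cargo_tot += cargo;
      ++exo_n;
      ++n_exo_events;
    }
    budB[i].clear();
    // Rab5-free, bud-free EE sites eligible for budding
    int free_buds = L2 - n_buds - n_rab5 + n_both;

    // 4 nucleation with binomial batching over eligible sites
    double k_now = k_endo_min[i - 1];
    if (k_now > 0.0 && !pitFree.empty()) {
      double pr = 1.0 - std::exp(-k_now / 60.0 * dt);
      int n_new = (int)R::rbinom((double)pitFree.size(), pr);
      for (int m = 0; m < n_new; ++m) {
        int idx = (int)(unif_rand() * pitFree.size());
        if (idx >= (int)pitFree.size()) idx = (int)pitFree.size() - 1;
        int s = pitFree[idx];
        pit_t[s] = t + runif_ab(pit_rng[0], pit_rng[1]);
        pit_free_remove(s);
        int j = bucket_step(pit_t[s]);
        if (j <= n_steps) pitB[j].push_back(s);
      }
    }
    if (free_buds > 0) {
      int n_new = (int)R::rbinom((double)free_buds, p_exo_step);
      int placed = 0, guard = 0;
      while (placed < n_new && guard < 100000) {
        int s = rand_site(L2);
        if (bud_t[s] == R_PosInf && !std::isfinite(rab5[s])) {
          bud_t[s] = t + runif_ab(bud_rng[0], bud_rng[1]);
          ++n_buds;
          int j = bucket_step(bud_t[s]);
          if (j <= n_steps) budB[j].push_back(s);
          ++placed;
        }
        ++guard;
      }
    }

    // 5 diffusion
    diffuse_grid(surf, buf, nbr, q_s);
    diffuse_grid(ee, buf, nbr, q_ee);

    // 6 sorting switch
    double ps = 0.0;
    if (enable_switch && !sorted) {
      double D = (double)n_rab5 / L2;
      if (D >= h) {
        if (!have_exc) {
          t_exc = t;
          have_exc = true;
        } else {
          T_above += dt;
        }
      }
      if (have_exc) {
        ps = 1.0 - std::exp(-T_above / tau_s_sec);
        if (ps > 0.0 && unif_rand() < ps) {
          int n_sorted = 0;
          for (int s = 0; s < L2; ++s) {
            if (std::isfinite(rab5[s])) {
              n_sorted += ee[s];
              ee[s] = 0;
              rab5[s] = R_NegInf;
            }
          }
          n_rab5 = 0;
          ee_tot -= n_sorted;
          tally += n_sorted;
          sorted = true;
          t_sort = t;
          n_sorted_event = n_sorted;
          n_both = 0; // no Rab5-positive sites remain
        }
      }
    }

    // 7 record + audit
    if (i % record_every == 0) {
      long co = 0;
      for (int s = 0; s < L2; ++s)
        if (std::isfinite(rab5[s])) co += ee[s];
      rec(rec_i, 0) = t;
      rec(rec_i, 1) = (double)(surf_tot + S_im);
      rec(rec_i, 2) = (double)ee_tot;
      rec(rec_i, 3) = (double)n_rab5;
      rec(rec_i, 4) = (double)co;
      rec(rec_i, 5) = (double)endo_cargo_tot;
      rec(rec_i, 6) = (double)exo_cargo_tot;
      rec(rec_i, 7) = (double)tally;
      rec(rec_i, 8) = ps;
      ++rec_i;
      if (audit) {
        long tot = surf_tot + ee_tot + endo_cargo_tot + exo_cargo_tot + tally;
        if (tot != total0)
          stop("receptor conservation violated: %ld != %ld at t = %.1f s",
               tot, total0, t);
      }
    }
  }

  // --- repack state -------------------------------------------------------
  // remaining vesicles: overflow plus any unprocessed buckets (none, since
  // every bucket index <= n_steps was drained; overflow holds the rest)
  int n_e = (int)endo_over.size(), n_x = (int)exo_over.size();
  NumericVector ea(n_e), xa(n_x);
  IntegerVector ec(n_e), xc(n_x);
  for (int i = 0; i < n_e; ++i) {
    ea[i] = endo_over[i].arr;
    ec[i] = endo_over[i].cargo;
  }
  for (int i = 0; i < n_x; ++i) {
    xa[i] = exo_over[i].arr;
    xc[i] = exo_over[i].cargo;
  }
  List out_state = List::create(
      _["surf"] = wrap(surf), _["ee"] = wrap(ee),
      _["pit_t"] = wrap(pit_t), _["bud_t"] = wrap(bud_t),
      _["rab5_exp"] = wrap(rab5),
      _["endo_arr"] = ea, _["endo_cargo"] = ec,
      _["exo_arr"] = xa, _["exo_cargo"] = xc,
      _["sorted_tally"] = tally,
      _["t"] = t0 + n_steps * dt);
  out_state.attr("class") = "endosim_state";
  List out_sw = List::create(
      _["h"] = h,
      _["t_exc"] = have_exc ? t_exc : NA_REAL,
      _["T_above"] = T_above,
      _["sorted"] = sorted,
      _["t_sort"] = sorted ? t_sort : NA_REAL);
  out_sw.attr("class") = "endosim_switch";
  return List::create(
      _["state"] = out_state, _["sw"] = out_sw, _["records"] = rec,
      _["n_sorted"] = n_sorted_event,
      _["n_endo_events"] = (double)n_endo_events,
      _["n_exo_events"] = (double)n_exo_events);
}
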