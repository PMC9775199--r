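// Metropolis protonation Monte Carlo and the stochastic-titration
// overdamped Langevin integrator. All randomness comes from R's RNG
// (unif_rand / norm_rand) so set.seed() in R gives bit-identical runs.
//
// State convention: per site, state 0 is deprotonated and states
// 1..n_tautomers are protonated tautomers. Energies arrive in kT;
// couplings arrive as matrices in pK units (multiplied by ln 10 here).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double LN10 = M_LN10;

struct CouplingSet {
  std::vector<int> ci, cj;                 // 0-based site indices
  std::vector<NumericMatrix> mat;          // pK units
};

// Energy change (kT) for moving site i from its current state to b.
double delta_site(const CouplingSet& C,
                  const std::vector<std::vector<double> >& e,
                  const std::vector<int>& s, int i, int b) {
  double de = e[i][b] - e[i][s[i]];
  for (size_t k = 0; k < C.ci.size(); ++k) {
    if (C.ci[k] == i)
      de += LN10 * (C.mat[k](b, s[C.cj[k]]) - C.mat[k](s[i], s[C.cj[k]]));
    else if (C.cj[k] == i)
      de += LN10 * (C.mat[k](s[C.ci[k]], b) - C.mat[k](s[C.ci[k]], s[i]));
  }
  return de;
}

double delta_pair(const CouplingSet& C,
                  const std::vector<std::vector<double> >& e,
                  std::vector<int>& s, int i, int j, int bi, int bj) {
  double de = delta_site(C, e, s, i, bi);
  int ai = s[i];
  s[i] = bi;
  de += delta_site(C, e, s, j, bj);
  s[i] = ai;
  return de;
}

struct MCCounts {
  long single_attempts = 0, single_accepts = 0;
  long pair_attempts = 0, pair_accepts = 0;
};

// One MC cycle: n_sites + n_pairs elementary moves, each drawn uniformly
// from the combined move set (single-site changes plus eligible pair
// moves). The resulting per-cycle kernel is a power of one reversible
// mixture kernel, so detailed balance holds between recorded cycles.
void mc_cycle(const CouplingSet& C,
              const std::vector<std::vector<double> >& e,
              const std::vector<int>& nstates,
              const IntegerMatrix& pairs,
              std::vector<int>& s, MCCounts& cnt) {
  const int n_sites = (int)s.size();
  const int n_pairs = pairs.nrow();
  const int n_moves = n_sites + n_pairs;
  for (int m = 0; m < n_moves; ++m) {
    int pick = (int)(unif_rand() * n_moves);
    if (pick >= n_moves) pick = n_moves - 1;
    if (pick < n_sites) {
      int i = pick;
      int ns = nstates[i];
      if (ns < 2) continue;
      // uniform over all states (incl. the current one): symmetric, and
      // avoids a deterministic flip-flop when a move is energy-neutral
      int b = (int)(unif_rand() * ns);
      if (b >= ns) b = ns - 1;
      double de = delta_site(C, e, s, i, b);
      ++cnt.single_attempts;
      if (de <= 0.0 || unif_rand() < std::exp(-de)) {
        s[i] = b;
        ++cnt.single_accepts;
      }
    } else {
      int p = pick - n_sites;
      int i = pairs(p, 0), j = pairs(p, 1);
      int bi = (int)(unif_rand() * nstates[i]);
      int bj = (int)(unif_rand() * nstates[j]);
      if (bi >= nstates[i]) bi = nstates[i] - 1;
      if (bj >= nstates[j]) bj = nstates[j] - 1;
      double de = delta_pair(C, e, s, i, j, bi, bj);
      ++cnt.pair_attempts;
      if (de <= 0.0 || unif_rand() < std::exp(-de)) {
        s[i] = bi;
        s[j] = bj;
        ++cnt.pair_accepts;
      }
    }
  }
}

CouplingSet build_couplings(const IntegerVector& ci, const IntegerVector& cj,
                            const List& cmat) {
  CouplingSet C;
  for (int k = 0; k < ci.size(); ++k) {
    C.ci.push_back(ci[k]);
    C.cj.push_back(cj[k]);
    C.mat.push_back(as<NumericMatrix>(cmat[k]));
  }
  return C;
}

std::vector<std::vector<double> > as_energy_vectors(const List& site_e) {
  std::vector<std::vector<double> > e;
  for (int i = 0; i < site_e.size(); ++i) {
    NumericVector v = site_e[i];
    e.push_back(std::vector<double>(v.begin(), v.end()));
  }
  return e;
}

}  // namespace

// [[Rcpp::export]]
List mc_kernel_cpp(List site_e, IntegerVector nstates_in,
                   IntegerVector ci, IntegerVector cj, List cmat,
                   IntegerMatrix pairs, int n_cycles, int n_burn,
                   IntegerVector init_state) {
  const int n_sites = site_e.size();
  std::vector<std::vector<double> > e = as_energy_vectors(site_e);
  std::vector<int> nstates(nstates_in.begin(), nstates_in.end());
  CouplingSet C = build_couplings(ci, cj, cmat);
  std::vector<int> s(init_state.begin(), init_state.end());
  MCCounts cnt;
  const int n_rec = n_cycles - n_burn;
  IntegerMatrix states(n_rec, n_sites);
  for (int c = 0; c < n_cycles; ++c) {
    mc_cycle(C, e, nstates, pairs, s, cnt);
    if (c >= n_burn)
      for (int i = 0; i < n_sites; ++i) states(c - n_burn, i) = s[i];
  }
  return List::create(
      _["states"] = states,
      _["single_attempts"] = (double)cnt.single_attempts,
      _["single_accepts"] = (double)cnt.single_accepts,
      _["pair_attempts"] = (double)cnt.pair_attempts,
      _["pair_accepts"] = (double)cnt.pair_accepts);
}

namespace {

struct Gaussian {
  double height, center, width;
  double value(double z) const {
    double u = (z - center) / width;
    return height * std::exp(-0.5 * u * u);
  }
  double deriv(double z) const {
    return -(z - center) / (width * width) * value(z);
  }
};

}  // namespace

// [[Rcpp::export]]
List cphmd_kernel_cpp(NumericVector grid_z, NumericVector grid_U,
                      NumericVector fieldp, List site_e0, List site_q,
                      IntegerVector nstates_in, IntegerVector ci,
                      IntegerVector cj, List cmat, IntegerMatrix pairs,
                      double bias_center, double bias_rate_step,
                      double bias_k_kT, double bias_k_kJ, double dt,
                      double D, int n_steps, int prot_period, int mc_cycles,
                      double z0, double box_lo, double box_hi,
                      IntegerVector init_state) {
  const int n_sites = site_e0.size();
  std::vector<std::vector<double> > e0 = as_energy_vectors(site_e0);
  std::vector<std::vector<double> > q = as_energy_vectors(site_q);
  std::vector<std::vector<double> > e = e0;  // field-adjusted workspace
  std::vector<int> nstates(nstates_in.begin(), nstates_in.end());
  CouplingSet C = build_couplings(ci, cj, cmat);
  std::vector<int> s(init_state.begin(), init_state.end());
  MCCounts cnt;

  const Gaussian well = {fieldp[0], fieldp[1], fieldp[2]};
  const Gaussian des = {fieldp[3], fieldp[4], fieldp[5]};

  const int ng = grid_z.size();
  const double gz0 = grid_z[0];
  const double gh = (grid_z[ng - 1] - grid_z[0]) / (ng - 1);

  const int n_rec = n_steps / prot_period;
  NumericMatrix out(n_rec, 4 + n_sites);

  double z = z0;
  double zc = bias_center;
  const double noise = std::sqrt(2.0 * D * dt);
  int rec = 0;

  // current microstate charge sums (for the field force)
  double q_tot = 0.0, q_abs = 0.0;
  for (int i = 0; i < n_sites; ++i) {
    q_tot += q[i][s[i]];
    q_abs += std::fabs(q[i][s[i]]);
  }

  for (int step = 1; step <= n_steps; ++step) {
    // external force from the gridded potential (piecewise-linear U)
    int k = (int)((z - gz0) / gh);
    if (k < 0) k = 0;
    if (k > ng - 2) k = ng - 2;
    double f_ext = -(grid_U[k + 1] - grid_U[k]) / gh;
    // field force on the current charge state
    double f_field =
        -LN10 * (q_abs * des.deriv(z) + q_tot * well.deriv(z));
    double f_bias = -bias_k_kT * (z - zc);
    z += D * (f_ext + f_field + f_bias) * dt + noise * norm_rand();
    zc += bias_rate_step;
    if (z < box_lo || z > box_hi)
      stop("trajectory diverged beyond the simulation box at step %d "
           "(z = %.3f nm)", step, z);

    if (step % prot_period == 0) {
      // protonation update at the instantaneous conformation
      for (int i = 0; i < n_sites; ++i) {
        for (int st = 0; st < nstates[i]; ++st) {
          double qi = q[i][st];
          e[i][st] = e0[i][st] +
                     LN10 * (std::fabs(qi) * des.value(z) +
                             qi * well.value(z));
        }
      }
      for (int c = 0; c < mc_cycles; ++c)
        mc_cycle(C, e, nstates, pairs, s, cnt);
      q_tot = q_abs = 0.0;
      for (int i = 0; i < n_sites; ++i) {
        q_tot += q[i][s[i]];
        q_abs += std::fabs(q[i][s[i]]);
      }
      out(rec, 0) = step * dt;
      out(rec, 1) = z;
      for (int i = 0; i < n_sites; ++i) out(rec, 2 + i) = s[i];
      out(rec, 2 + n_sites) = q_tot;
      out(rec, 3 + n_sites) = 0.5 * bias_k_kJ * (z - zc) * (z - zc);
      ++rec;
      if (rec == n_rec) break;
    }
  }
  return List::create(_["samples"] = out,
                      _["pair_attempts"] = (double)cnt.pair_attempts,
                      _["pair_accepts"] = (double)cnt.pair_accepts);
}
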