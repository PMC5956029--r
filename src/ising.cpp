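// [[Rcpp::depends(RcppArmadillo)]]
#include "glauber.h"
using namespace Rcpp;

// [[Rcpp::export]]
arma::vec cpp_sweep(const arma::vec& h, const arma::mat& J, double beta,
                    arma::vec state, int n_sweeps) {
  std::vector<int> perm(state.n_elem);
  for (int t = 0; t < n_sweeps; ++t) glauber_one_sweep(h, J, beta, state, perm);
  return state;
}

// Time-averaged first and second moments over post-burn-in sweeps; one sample
// per `thin` sweeps. Pair products are accumulated in blocks through BLAS
// (S^T S) to keep the cost dominated by the Glauber updates themselves.
// [[Rcpp::export]]
List cpp_sample_moments(const arma::vec& h, const arma::mat& J, double beta,
                        arma::vec state, int n_sweeps, int burn_in, int thin) {
  const int n = (int)h.n_elem;
  std::vector<int> perm(n);
  for (int t = 0; t < burn_in; ++t) glauber_one_sweep(h, J, beta, state, perm);

  const int B = 256;
  arma::mat block(B, n);
  arma::vec msum(n, arma::fill::zeros);
  arma::mat csum(n, n, arma::fill::zeros);
  int filled = 0;
  double nrec = 0.0;
  for (int t = 0; t < n_sweeps; ++t) {
    glauber_one_sweep(h, J, beta, state, perm);
    if ((t + 1) % thin != 0) continue;
    block.row(filled++) = state.t();
    nrec += 1.0;
    if (filled == B) {
      csum += block.t() * block;
      msum += arma::sum(block, 0).t();
      filled = 0;
    }
  }
  if (filled > 0) {
    arma::mat part = block.rows(0, filled - 1);
    csum += part.t() * part;
    msum += arma::sum(part, 0).t();
  }
  if (nrec < 1.0) stop("no samples recorded; increase n_sweeps or lower thin");
  arma::vec m = msum / nrec;
  arma::mat c = csum / nrec;
  c.diag().ones();
  return List::create(_["m"] = m, _["c"] = c, _["state"] = state,
                      _["n_samples"] = nrec);
}

// Exact enumeration of all 2^N states by a Gray-code walk with incremental
// energy updates. State index: bit (i-1) of the index set <=> s_i = +1.
// [[Rcpp::export]]
List cpp_enumerate(const arma::vec& h, const arma::mat& J, double beta) {
  const int n = (int)h.n_elem;
  if (n > 30) stop("enumeration limited to N <= 30 internally");
  const size_t M = ((size_t)1) << n;
  arma::vec energies(M);
  arma::vec s(n);
  s.fill(-1.0);
  double E = ising_energy_cpp(h, J, s);
  energies[0] = E;
  unsigned int prev = 0;
  for (size_t k = 1; k < M; ++k) {
    const unsigned int gray = (unsigned int)(k ^ (k >> 1));
    const unsigned int diff = gray ^ prev;
    int i = 0;
    while (!((diff >> i) & 1u)) ++i;
    const double Hi = h[i] + arma::dot(J.unsafe_col(i), s);
    E += 2.0 * s[i] * Hi;   // flip of spin i from s_i to -s_i
    s[i] = -s[i];
    energies[gray] = E;
    prev = gray;
  }
  const double Emin = energies.min();
  arma::vec w = arma::exp(-beta * (energies - Emin));
  const double Z = arma::accu(w);
  return List::create(_["prob"] = w / Z, _["energy"] = energies);
}

// Exact moments under the Boltzmann distribution (same Gray-code walk).
// [[Rcpp::export]]
List cpp_exact_moments(const arma::vec& h, const arma::mat& J, double beta) {
  List en = cpp_enumerate(h, J, beta);
  arma::vec p = en["prob"];
  const int n = (int)h.n_elem;
  const size_t M = ((size_t)1) << n;
  arma::vec s(n);
  s.fill(-1.0);
  arma::vec m(n, arma::fill::zeros);
  arma::mat c(n, n, arma::fill::zeros);
  m += p[0] * s;
  c += p[0] * (s * s.t());
  unsigned int prev = 0;
  for (size_t k = 1; k < M; ++k) {
    const unsigned int gray = (unsigned int)(k ^ (k >> 1));
    const unsigned int diff = gray ^ prev;
    int i = 0;
    while (!((diff >> i) & 1u)) ++i;
    s[i] = -s[i];
    m += p[gray] * s;
    c += p[gray] * (s * s.t());
    prev = gray;
  }
  c.diag().ones();
  return List::create(_["m"] = m, _["c"] = c);
}

// Sample energies and (optionally) a state histogram over a unit subset.
// subset0: 0-based unit indices; bit j of the histogram cell index is set
// iff the j-th subset unit is +1.
// [[Rcpp::export]]
List cpp_sample_stats(const arma::vec& h, const arma::mat& J, double beta,
                      arma::vec state, int n_sweeps, int burn_in,
                      const IntegerVector& subset0, int thin) {
  const int n = (int)h.n_elem;
  const int k = subset0.size();
  if (k > 24) stop("state histogram limited to subsets of <= 24 units");
  std::vector<int> perm(n);
  for (int t = 0; t < burn_in; ++t) glauber_one_sweep(h, J, beta, state, perm);

  NumericVector counts(k > 0 ? (R_xlen_t)1 << k : 0);
  double sE = 0.0, sE2 = 0.0, nrec = 0.0;
  for (int t = 0; t < n_sweeps; ++t) {
    glauber_one_sweep(h, J, beta, state, perm);
    if ((t + 1) % thin != 0) continue;
    const double E = ising_energy_cpp(h, J, state);
    sE += E;
    sE2 += E * E;
    nrec += 1.0;
    if (k > 0) {
      size_t code = 0;
      for (int j = 0; j < k; ++j)
        if (state[subset0[j]] > 0) code |= ((size_t)1 << j);
      counts[code] += 1.0;
    }
  }
  const double meanE = sE / nrec;
  const double varE = sE2 / nrec - meanE * meanE;
  return List::create(_["counts"] = counts, _["mean_energy"] = meanE,
                      _["var_energy"] = varE, _["n_samples"] = nrec,
                      _["state"] = state);
}

// Beta sweep for an isolated network: at each beta, restart from a random
// state, burn in, then sample energy statistics (and optionally a subset
// state histogram). Heat capacity is beta^2 * Var(E).
// [[Rcpp::export]]
List cpp_beta_sweep_isolated(const arma::vec& h, const arma::mat& J,
                             const arma::vec& betas, int n_sweeps, int burn_in,
                             const IntegerVector& subset0, int thin) {
  const int nb = (int)betas.n_elem;
  const int k = subset0.size();
  NumericVector meanE(nb), varE(nb), heatcap(nb);
  NumericMatrix counts(k > 0 ? (R_xlen_t)1 << k : 0, k > 0 ? nb : 0);
  arma::vec state(h.n_elem);
  for (int b = 0; b < nb; ++b) {
    random_state(state);
    List st = cpp_sample_stats(h, J, betas[b], state, n_sweeps, burn_in,
                               subset0, thin);
    meanE[b] = as<double>(st["mean_energy"]);
    varE[b] = as<double>(st["var_energy"]);
    heatcap[b] = betas[b] * betas[b] * varE[b];
    if (k > 0) {
      NumericVector cb = st["counts"];
      for (R_xlen_t i = 0; i < cb.size(); ++i) counts(i, b) = cb[i];
    }
  }
  return List::create(_["mean_energy"] = meanE, _["var_energy"] = varE,
                      _["heat_capacity"] = heatcap, _["counts"] = counts);
}
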