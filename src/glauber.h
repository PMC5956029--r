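#ifndef ISINGADAPT_GLAUBER_H
#define ISINGADAPT_GLAUBER_H

#include <RcppArmadillo.h>

// One full sequential Glauber sweep: every unit updated exactly once, in a
// freshly drawn random permutation, using the instantaneous state of the
// others. Uses R's RNG (caller must hold an RNGScope, which Rcpp attribute
// wrappers provide).
inline void glauber_one_sweep(const arma::vec& h, const arma::mat& J,
                              double beta, arma::vec& s,
                              std::vector<int>& perm) {
  const int n = (int)s.n_elem;
  for (int k = 0; k < n; ++k) perm[k] = k;
  for (int k = n - 1; k > 0; --k) {
    int j = (int)(unif_rand() * (k + 1));
    if (j > k) j = k;
    std::swap(perm[k], perm[j]);
  }
  for (int k = 0; k < n; ++k) {
    const int i = perm[k];
    const double H = h[i] + arma::dot(J.unsafe_col(i), s);
    const double p = 1.0 / (1.0 + std::exp(-2.0 * beta * H));
    s[i] = (unif_rand() < p) ? 1.0 : -1.0;
  }
}

// E(s) = -sum_i h_i s_i - sum_{i<j} J_ij s_i s_j  (J symmetric, zero diagonal)
inline double ising_energy_cpp(const arma::vec& h, const arma::mat& J,
                               const arma::vec& s) {
  return -arma::dot(h, s) - 0.5 * arma::dot(s, J * s);
}

inline void random_state(arma::vec& s) {
  for (arma::uword i = 0; i < s.n_elem; ++i)
    s[i] = (unif_rand() < 0.5) ? -1.0 : 1.0;
}

#endif
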