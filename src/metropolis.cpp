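#include <Rcpp.h>
using namespace Rcpp;

// Single-site Metropolis dynamics for the 2D Ising model on an L x L torus,
// J = 1, k_B = 1, zero field. One sweep = N = L*L update attempts at
// uniformly random sites. Uses R's RNG so runs are reproducible via set.seed().

static inline void one_sweep(std::vector<int> &s, int L, double p4, double p8,
                             long long *dE_acc) {
  const int N = L * L;
  for (int a = 0; a < N; ++a) {
    int i = (int)(unif_rand() * N);
    if (i >= N) i = N - 1;
    const int r = i / L, c = i % L;
    const int up    = ((r + L - 1) % L) * L + c;
    const int down  = ((r + 1) % L) * L + c;
    const int left  = r * L + (c + L - 1) % L;
    const int right = r * L + (c + 1) % L;
    const int nn = s[up] + s[down] + s[left] + s[right];
    const int dE = 2 * s[i] * nn;  // energy change of flipping spin i
    bool accept;
    if (dE <= 0) {
      accept = true;
    } else {
      const double p = (dE == 4) ? p4 : p8;
      accept = (unif_rand() < p);
    }
    if (accept) {
      s[i] = -s[i];
      if (dE_acc) *dE_acc += dE;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix ising_run_cpp(IntegerVector spins, int L, double T,
                            int n_therm, int n_record) {
  const int N = L * L;
  if (spins.size() != N) stop("spins must have length L*L");
  std::vector<int> s(spins.begin(), spins.end());
  const double p4 = std::exp(-4.0 / T), p8 = std::exp(-8.0 / T);
  RNGScope scope;
  for (int t = 0; t < n_therm; ++t) one_sweep(s, L, p4, p8, nullptr);
  IntegerMatrix rec(n_record, N);
  for (int k = 0; k < n_record; ++k) {
    one_sweep(s, L, p4, p8, nullptr);
    for (int j = 0; j < N; ++j) rec(k, j) = s[j];
  }
  rec.attr("final_spins") = IntegerVector(s.begin(), s.end());
  return rec;
}

// [[Rcpp::export]]
List ising_sweep_cpp(IntegerVector spins, int L, double T, int n_sweeps) {
  const int N = L * L;
  if (spins.size() != N) stop("spins must have length L*L");
  std::vector<int> s(spins.begin(), spins.end());
  const double p4 = std::exp(-4.0 / T), p8 = std::exp(-8.0 / T);
  long long dE = 0;
  RNGScope scope;
  for (int t = 0; t < n_sweeps; ++t) one_sweep(s, L, p4, p8, &dE);
  return List::create(_["spins"] = IntegerVector(s.begin(), s.end()),
                      _["delta_energy"] = (double)dE);
}

// State-code sampler for exhaustive Boltzmann checks on tiny lattices
// (N <= 30): records sum_j 2^j * (s_j+1)/2 after every sweep.
// [[Rcpp::export]]
NumericVector ising_state_codes_cpp(IntegerVector spins, int L, double T,
                                    int n_therm, int n_sweeps) {
  const int N = L * L;
  if (spins.size() != N) stop("spins must have length L*L");
  if (N > 30) stop("state codes only supported for N <= 30");
  std::vector<int> s(spins.begin(), spins.end());
  const double p4 = std::exp(-4.0 / T), p8 = std::exp(-8.0 / T);
  RNGScope scope;
  for (int t = 0; t < n_therm; ++t) one_sweep(s, L, p4, p8, nullptr);
  NumericVector codes(n_sweeps);
  for (int t = 0; t < n_sweeps; ++t) {
    one_sweep(s, L, p4, p8, nullptr);
    double code = 0, bit = 1;
    for (int j = 0; j < N; ++j) {
      if (s[j] > 0) code += bit;
      bit *= 2;
    }
    codes[t] = code;
  }
  return codes;
}
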