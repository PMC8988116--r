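#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Single-bit-flip Metropolis simulated annealing on a QUBO.
//
// Q is symmetric with linear terms on the diagonal and HALVED pairwise
// coefficients off it, so that E(x) = x' Q x (the model offset is added on
// the R side). The local field g[i] = sum_{j != i} Q(i,j) x_j is maintained
// incrementally; a flip of bit i changes the energy by
//   (1 - 2 x_i) * (Q(i,i) + 2 g[i]).
//
// The best state *ever visited* across all restarts is returned, not the
// final frozen state: with a large constraint penalty the chain passes
// through many feasible basins while still warm, and tracking the running
// minimum is what lets the sampler recover the ground state reliably.
//
// Uses R's RNG (unif_rand), so results are reproducible under set.seed().
// [[Rcpp::export]]
List sa_anneal_cpp(NumericMatrix Q, int n_sweeps, int n_restarts,
                   double T0, double Tend) {
  const int n = Q.nrow();
  if (n_sweeps < 1 || n_restarts < 1)
    stop("n_sweeps and n_restarts must be >= 1");
  if (T0 <= 0 || Tend <= 0 || Tend > T0)
    stop("need 0 < Tend <= T0");

  std::vector<int> x(n), best(n, 0);
  std::vector<double> g(n);
  double best_e = R_PosInf;
  const double cool = (n_sweeps > 1)
    ? std::pow(Tend / T0, 1.0 / (double)(n_sweeps - 1)) : 1.0;

  for (int r = 0; r < n_restarts; ++r) {
    for (int i = 0; i < n; ++i) x[i] = (unif_rand() < 0.5) ? 1 : 0;
    std::fill(g.begin(), g.end(), 0.0);
    for (int j = 0; j < n; ++j)
      if (x[j])
        for (int i = 0; i < n; ++i)
          if (i != j) g[i] += Q(i, j);
    double e = 0.0;
    for (int i = 0; i < n; ++i)
      if (x[i]) e += Q(i, i) + g[i];
    if (e < best_e) { best_e = e; best.assign(x.begin(), x.end()); }

    double T = T0;
    for (int s = 0; s < n_sweeps; ++s) {
      for (int i = 0; i < n; ++i) {
        const double delta = (1 - 2 * x[i]) * (Q(i, i) + 2.0 * g[i]);
        if (delta <= 0.0 || unif_rand() < std::exp(-delta / T)) {
          const int d = 1 - 2 * x[i];
          x[i] += d;
          e += delta;
          for (int j = 0; j < n; ++j)
            if (j != i) g[j] += d * Q(j, i);
          if (e < best_e) {
            best_e = e;
            best.assign(x.begin(), x.end());
          }
        }
      }
      T *= cool;
    }
  }

  // recompute the best energy exactly to shed accumulated float drift
  double e_exact = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!best[i]) continue;
    e_exact += Q(i, i);
    for (int j = i + 1; j < n; ++j)
      if (best[j]) e_exact += 2.0 * Q(i, j);
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best[i];
  return List::create(_["x"] = out, _["energy"] = e_exact);
}
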