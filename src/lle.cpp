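#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Rosenstein-style mean log-divergence of a delay-embedded scalar series.
//
// x        : scalar time series
// m        : embedding dimension
// tau      : embedding delay (samples)
// theiler  : temporal exclusion window for nearest-neighbour candidates
// max_steps: number of expansion steps followed
//
// Embedded point i (0-based) is (x[i], x[i+tau], ..., x[i+(m-1)tau]),
// i = 0..M-1 with M = n - (m-1)*tau. For every reference point the exact
// nearest neighbour outside the Theiler window is found by brute force
// (Euclidean norm in embedding space); the pair is then followed for
// max_steps steps and ln of the pair distance is averaged at each step.
// Only pairs that can be followed for the whole expansion range enter the
// average: keeping the pair cohort constant across steps avoids the
// censoring bias that arises when the most-evolved pairs drop out first.
// Zero distances (exactly repeating segments) carry no divergence
// information and are skipped.
// [[Rcpp::export(name = ".rosenstein_divergence")]]
List rosenstein_divergence(NumericVector x, int m, int tau, int theiler,
                           int max_steps) {
  const int n = x.size();
  const int M = n - (m - 1) * tau;
  if (M < 2) stop("series too short for this embedding");

  std::vector<int> nn(M, -1);
  const double *xp = REAL(x);

  for (int i = 0; i < M; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bestj = -1;
    for (int j = 0; j < M; ++j) {
      int sep = j - i;
      if (sep < 0) sep = -sep;
      if (sep <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = xp[i + k * tau] - xp[j + k * tau];
        d2 += diff * diff;
        if (d2 >= best) break;
      }
      if (d2 < best) {
        best = d2;
        bestj = j;
      }
    }
    nn[i] = bestj;
  }

  NumericVector mean_log(max_steps + 1, NA_REAL);
  IntegerVector n_pairs(max_steps + 1);

  for (int s = 0; s <= max_steps; ++s) {
    double acc = 0.0;
    int cnt = 0;
    for (int i = 0; i < M; ++i) {
      const int j = nn[i];
      if (j < 0) continue;
      if (i + max_steps >= M || j + max_steps >= M) continue; // not followable
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = xp[i + s + k * tau] - xp[j + s + k * tau];
        d2 += diff * diff;
      }
      if (d2 <= 0.0) continue; // exactly repeating segment
      acc += 0.5 * std::log(d2);
      ++cnt;
    }
    if (cnt > 0) {
      mean_log[s] = acc / cnt;
      n_pairs[s] = cnt;
    }
  }

  return List::create(_["mean_log"] = mean_log, _["n_pairs"] = n_pairs);
}
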