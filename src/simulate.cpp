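#include <Rcpp.h>
using namespace Rcpp;

// Simulate one trajectory of the delta-dB Moran process until absorption.
//
// W is the dense N x N weight matrix (W(u,v) = weight of arc u -> v, 0 if
// absent). Uses R's RNG (unif_rand), so results are reproducible with
// set.seed() from R. Returns (fixated 0/1, steps taken); errors if the
// step cap is exceeded (absorption is a.s. certain on valid inputs, so a
// cap breach signals a bug or an absurdly low cap).
//
// dB step: v dies uniformly; in-neighbors u compete with weight f(u)*W(u,v).
// Bd step: u reproduces with prob f(u)/F; offspring lands on v with prob
//          W(u,v) / rowsum_u.
// [[Rcpp::export]]
IntegerVector cpp_simulate_trajectory(NumericMatrix W, double r, double delta,
                                      int start, double step_cap) {
  const int N = W.nrow();
  std::vector<int> mut(N, 0);
  mut[start - 1] = 1;
  int k = 1;
  // row sums for Bd placement
  std::vector<double> wout(N, 0.0);
  for (int u = 0; u < N; ++u)
    for (int v = 0; v < N; ++v) wout[u] += W(u, v);
  double steps = 0;
  while (k > 0 && k < N) {
    if (++steps > step_cap)
      stop("trajectory did not absorb within step cap");
    bool db = (delta >= 1.0) || (delta > 0.0 && unif_rand() < delta);
    if (db) {
      int v = (int)(unif_rand() * N);
      if (v >= N) v = N - 1;
      double tot = 0.0;
      for (int u = 0; u < N; ++u)
        if (W(u, v) > 0.0) tot += (mut[u] ? r : 1.0) * W(u, v);
      double x = unif_rand() * tot;
      int filler = -1;
      for (int u = 0; u < N; ++u) {
        if (W(u, v) > 0.0) {
          x -= (mut[u] ? r : 1.0) * W(u, v);
          if (x <= 0.0) { filler = u; break; }
        }
      }
      if (filler < 0) continue; // numerical edge: retry step
      if (mut[v] != mut[filler]) { k += mut[filler] ? 1 : -1; mut[v] = mut[filler]; }
    } else {
      double F = N + (r - 1.0) * k;
      double x = unif_rand() * F;
      int u = -1;
      for (int w = 0; w < N; ++w) {
        x -= mut[w] ? r : 1.0;
        if (x <= 0.0) { u = w; break; }
      }
      if (u < 0) u = N - 1;
      double y = unif_rand() * wout[u];
      int v = -1;
      for (int t = 0; t < N; ++t) {
        if (W(u, t) > 0.0) {
          y -= W(u, t);
          if (y <= 0.0) { v = t; break; }
        }
      }
      if (v < 0) continue;
      if (mut[v] != mut[u]) { k += mut[u] ? 1 : -1; mut[v] = mut[u]; }
    }
  }
  return IntegerVector::create(k == N ? 1 : 0, (int)std::min(steps, 2e9));
}

// Run `reps` independent trajectories with given start vertices (1-based);
// returns (fixation count, total steps, extinct-at-step-1 count).
// [[Rcpp::export]]
NumericVector cpp_simulate_batch(NumericMatrix W, double r, double delta,
                                 IntegerVector starts, double step_cap) {
  double fix = 0, steps = 0, early = 0;
  for (int i = 0; i < starts.size(); ++i) {
    IntegerVector out = cpp_simulate_trajectory(W, r, delta, starts[i], step_cap);
    fix += out[0];
    steps += out[1];
    if (out[0] == 0 && out[1] == 1) early += 1;
  }
  return NumericVector::create(fix, steps, early);
}
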