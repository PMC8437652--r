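#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Index draws mirror the R helper sample_int1(): floor(unif * n), clamped.
// Keeping the draw protocol identical on both sides lets the pure-R
// reference loop replay a C++ run draw-for-draw.
static inline int sample_int0(int n) {
  int v = static_cast<int>(unif_rand() * n);
  if (v >= n) v = n - 1;
  return v;
}

static inline void draw_distinct(int np, const int *taken, int ntaken,
                                 int *out, int count) {
  int got = 0;
  while (got < count) {
    int r = sample_int0(np);
    bool clash = false;
    for (int t = 0; t < ntaken && !clash; ++t) clash = (r == taken[t]);
    for (int t = 0; t < got && !clash; ++t) clash = (r == out[t]);
    if (!clash) out[got++] = r;
  }
}

// WCD fitness of one center-encoded individual. Accumulation in long
// double matches R's rowSums()/sum() extended-precision accumulators.
static double wcd_fitness(const NumericMatrix &X, const double *genes,
                          int k, int d) {
  const int n = X.nrow();
  long double tot = 0.0L;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int t = 0; t < k; ++t) {
      const double *c = genes + (size_t)t * d;
      long double s = 0.0L;
      for (int j = 0; j < d; ++j) {
        double diff = X(i, j) - c[j];
        s += (long double)diff * diff;
      }
      double dist = std::sqrt((double)s);
      if (dist < best) best = dist;
    }
    tot += best;
  }
  return (double)tot;
}

// One full DE run. strategy: 0 = rand/1, 1 = best/1, 2 = current-to-best/1,
// 3 = double mutation (rand/1 when lambda < threshold, else best/1).
// [[Rcpp::export]]
List de_run_cpp(NumericMatrix X, int k, NumericMatrix pop0,
                NumericVector lo, NumericVector hi,
                double F, double CR,
                int max_generations, int stagnation_limit,
                double lambda_threshold, int strategy,
                bool diversity_rms) {
  const int d = X.ncol();
  const int NP = pop0.nrow();
  const int D = pop0.ncol();
  if (D != k * d) stop("population dimension must equal k * d");
  if (NP < 4) stop("NP must be >= 4");

  std::vector<double> pop((size_t)NP * D), next((size_t)NP * D);
  for (int i = 0; i < NP; ++i)
    for (int j = 0; j < D; ++j)
      pop[(size_t)i * D + j] = pop0(i, j);

  std::vector<double> fit(NP);
  for (int i = 0; i < NP; ++i)
    fit[i] = wcd_fitness(X, &pop[(size_t)i * D], k, d);

  std::vector<double> mu(D), mutant(D), trial(D);
  std::vector<double> history, lambda_hist;
  std::vector<int> branch_hist;
  history.reserve(max_generations);

  double best_fit = R_PosInf;
  for (int i = 0; i < NP; ++i) if (fit[i] < best_fit) best_fit = fit[i];
  int stag = 0;

  for (int g = 1; g <= max_generations; ++g) {
    // diversity indicator lambda(g), computed once per generation
    for (int j = 0; j < D; ++j) {
      long double s = 0.0L;
      for (int i = 0; i < NP; ++i) s += pop[(size_t)i * D + j];
      mu[j] = (double)(s / NP);
    }
    long double acc = 0.0L;
    for (int i = 0; i < NP; ++i) {
      long double s = 0.0L;
      for (int j = 0; j < D; ++j) {
        double diff = pop[(size_t)i * D + j] - mu[j];
        s += (long double)diff * diff;
      }
      double dist = std::sqrt((double)s);
      acc += diversity_rms ? (long double)dist * dist : (long double)dist;
    }
    double sigma = (double)(acc / NP);
    if (diversity_rms) sigma = std::sqrt(sigma);
    long double nm = 0.0L;
    for (int j = 0; j < D; ++j) nm += (long double)mu[j] * mu[j];
    double norm_mu = std::sqrt((double)nm);
    double lam = (norm_mu > 0.0) ? sigma / norm_mu : R_PosInf;

    int branch = strategy;
    if (strategy == 3) branch = (lam < lambda_threshold) ? 0 : 1;

    int best_idx = 0;
    for (int i = 1; i < NP; ++i) if (fit[i] < fit[best_idx]) best_idx = i;
    const double *xbest = &pop[(size_t)best_idx * D];

    for (int i = 0; i < NP; ++i) {
      const double *xi = &pop[(size_t)i * D];
      int excl[1] = { i };
      int r[3];
      if (branch == 0) {
        draw_distinct(NP, excl, 1, r, 3);
        const double *x1 = &pop[(size_t)r[0] * D];
        const double *x2 = &pop[(size_t)r[1] * D];
        const double *x3 = &pop[(size_t)r[2] * D];
        for (int j = 0; j < D; ++j)
          mutant[j] = x1[j] + F * (x2[j] - x3[j]);
      } else if (branch == 1) {
        draw_distinct(NP, excl, 1, r, 2);
        const double *x1 = &pop[(size_t)r[0] * D];
        const double *x2 = &pop[(size_t)r[1] * D];
        for (int j = 0; j < D; ++j)
          mutant[j] = xbest[j] + F * (x1[j] - x2[j]);
      } else {
        draw_distinct(NP, excl, 1, r, 2);
        const double *x1 = &pop[(size_t)r[0] * D];
        const double *x2 = &pop[(size_t)r[1] * D];
        for (int j = 0; j < D; ++j)
          mutant[j] = xi[j] + F * (xbest[j] - xi[j]) + F * (x1[j] - x2[j]);
      }
      for (int j = 0; j < D; ++j) {
        if (mutant[j] < lo[j]) mutant[j] = lo[j];
        else if (mutant[j] > hi[j]) mutant[j] = hi[j];
      }
      int j_rand = sample_int0(D);
      for (int j = 0; j < D; ++j) {
        double u = unif_rand();
        trial[j] = (u <= CR || j == j_rand) ? mutant[j] : xi[j];
      }
      double ft = wcd_fitness(X, trial.data(), k, d);
      double *dst = &next[(size_t)i * D];
      if (ft < fit[i]) {
        for (int j = 0; j < D; ++j) dst[j] = trial[j];
        fit[i] = ft;
      } else {
        for (int j = 0; j < D; ++j) dst[j] = xi[j];
      }
    }
    pop.swap(next);

    double nb = fit[0];
    for (int i = 1; i < NP; ++i) if (fit[i] < nb) nb = fit[i];
    stag = (nb == best_fit) ? stag + 1 : 0;
    best_fit = nb;
    history.push_back(nb);
    lambda_hist.push_back(lam);
    branch_hist.push_back(branch);
    if (stag >= stagnation_limit) break;
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }

  int best_idx = 0;
  for (int i = 1; i < NP; ++i) if (fit[i] < fit[best_idx]) best_idx = i;
  NumericVector genes(D);
  for (int j = 0; j < D; ++j) genes[j] = pop[(size_t)best_idx * D + j];

  return List::create(
    _["genes"] = genes,
    _["fitness"] = fit[best_idx],
    _["history"] = wrap(history),
    _["lambda_history"] = wrap(lambda_hist),
    _["branch_history"] = wrap(branch_hist),
    _["iterations"] = (int)history.size());
}
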