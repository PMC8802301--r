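#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Model-potential parameter layout (shared with R/.modelParams):
// [0] wallPos  [1] wallScale  [2] cmPos  [3] cmWidth  [4] cmAmp
// [5] dmPos    [6] dmHeight   [7] dmWidth
// [8] ssmPos   [9] ssmDepth  [10] ssmWidth
static inline double potEval(const double *p, double xi) {
  double r = p[1] / (xi - p[0]);
  double r3 = r * r * r;
  double r6 = r3 * r3;
  double u = r6 * r6; // (wallScale/(xi-wallPos))^12
  double d = xi - p[2];
  u += p[4] * std::exp(-d * d / (2.0 * p[3] * p[3]));
  if (p[6] != 0.0) {
    d = xi - p[5];
    u += p[6] * std::exp(-d * d / (2.0 * p[7] * p[7]));
  }
  if (p[9] != 0.0) {
    d = xi - p[8];
    u += p[9] * std::exp(-d * d / (2.0 * p[10] * p[10]));
  }
  return u;
}

// Gaussian random-walk Metropolis on the 1-D coordinate, stationary density
// proportional to exp(-(U_model + kbias*(xi-d0)^2)/kBT) on (wallPos, xMax].
// Step size is adapted toward 30-50% acceptance during burn-in only, then
// frozen. Uses R's RNG: set.seed on the R side gives bitwise-identical
// output. kbias already carries the restraint convention prefactor.
// [[Rcpp::export(name = ".metropolisChain")]]
NumericVector metropolisChain(NumericVector modelParams, double d0,
                              double kbias, double kBT, int nSamples,
                              int thin, int nBurn, double xiInit,
                              double stepInit, double xMax) {
  const double *p = modelParams.begin();
  const double wallPos = p[0];
  RNGScope scope;

  double xi = xiInit;
  double e = potEval(p, xi) + kbias * (xi - d0) * (xi - d0);
  double step = stepInit;

  int accepted = 0, window = 0;
  for (int it = 0; it < nBurn; ++it) {
    double prop = xi + step * ::norm_rand();
    if (prop > wallPos && prop <= xMax) {
      double ep = potEval(p, prop) + kbias * (prop - d0) * (prop - d0);
      double dE = ep - e;
      if (dE <= 0.0 || ::unif_rand() < std::exp(-dE / kBT)) {
        xi = prop;
        e = ep;
        ++accepted;
      }
    }
    if (++window == 50) { // adapt toward the 30-50% acceptance band
      double acc = accepted / 50.0;
      if (acc < 0.30)
        step *= 0.8;
      else if (acc > 0.50)
        step *= 1.25;
      accepted = 0;
      window = 0;
    }
  }

  NumericVector out(nSamples);
  long nIter = (long)nSamples * thin;
  int kept = 0;
  for (long it = 0; it < nIter; ++it) {
    double prop = xi + step * ::norm_rand();
    if (prop > wallPos && prop <= xMax) {
      double ep = potEval(p, prop) + kbias * (prop - d0) * (prop - d0);
      double dE = ep - e;
      if (dE <= 0.0 || ::unif_rand() < std::exp(-dE / kBT)) {
        xi = prop;
        e = ep;
      }
    }
    if ((it + 1) % thin == 0)
      out[kept++] = xi;
  }
  return out;
}
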