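#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kelly-Lochbaum reflection-line vocal tract filter.
//
// The tract is a chain of `N` equal-length digital sections (one sample of
// travel per section per direction); `areas` holds the per-frame section
// areas (N x nFrames, glottis -> lips). Pressure-wave scattering is used:
// at the junction between sections j and j+1,
//   k_j = (A_j - A_{j+1}) / (A_j + A_{j+1}),
// a right-going wave is transmitted with gain (1 + k_j) and reflected with
// k_j; a left-going wave is transmitted with (1 - k_j) and reflected with
// -k_j. Reflection coefficients are linearly interpolated sample-by-sample
// between frames. A closed section (area ~ 0) gives |k| ~ 1 and blocks
// transmission. Turbulence noise (generated and amplitude-shaped in R so all
// randomness stays under R's RNG) is injected into the forward wave at a
// per-frame section index. A fraction of the forward wave at the velar
// junction can be diverted into a fixed one-way nasal delay line radiating
// at the nostrils, which lets closed-lip (nasal) configurations produce
// output.
// [[Rcpp::export(name = ".kl_filter")]]
NumericVector kl_filter(NumericVector source,
                        NumericVector noise,
                        IntegerVector noiseSection,   // per frame, 0-based, -1 = none
                        NumericMatrix areas,          // N x nFrames
                        NumericVector nasalFrac,      // per frame in [0, 1]
                        int velarSection,
                        int samplesPerFrame,
                        double glottalReflect,
                        double lipReflect,
                        int nasalDelay,
                        double nostrilReflect) {
  const int N = areas.nrow();
  const int nFrames = areas.ncol();
  const int nSamples = nFrames * samplesPerFrame;
  if (source.size() < nSamples || noise.size() < nSamples)
    stop("source/noise shorter than nFrames * samplesPerFrame");
  if (N < 2) stop("need at least 2 tube sections");

  // per-frame junction reflection coefficients
  const int nJ = N - 1;
  NumericMatrix kf(nJ, nFrames);
  for (int t = 0; t < nFrames; ++t) {
    for (int j = 0; j < nJ; ++j) {
      double a0 = std::max(areas(j, t), 1e-6);
      double a1 = std::max(areas(j + 1, t), 1e-6);
      kf(j, t) = (a0 - a1) / (a0 + a1);
    }
  }

  std::vector<double> f(N, 0.0), b(N, 0.0), fn(N, 0.0), bn(N, 0.0);
  std::vector<double> k(nJ, 0.0);
  std::vector<double> nasal(std::max(nasalDelay, 1), 0.0);
  int nasalPos = 0;

  NumericVector out(nSamples);
  for (int s = 0; s < nSamples; ++s) {
    int t = s / samplesPerFrame;
    double frac = (double)(s - t * samplesPerFrame) / (double)samplesPerFrame;
    int t2 = (t + 1 < nFrames) ? t + 1 : t;
    for (int j = 0; j < nJ; ++j)
      k[j] = (1.0 - frac) * kf(j, t) + frac * kf(j, t2);

    fn[0] = source[s] + glottalReflect * b[0];
    for (int j = 0; j < nJ; ++j) {
      fn[j + 1] = (1.0 + k[j]) * f[j] - k[j] * b[j + 1];
      bn[j]     = k[j] * f[j] + (1.0 - k[j]) * b[j + 1];
    }
    bn[N - 1] = lipReflect * f[N - 1];
    double lipOut = (1.0 + lipReflect) * f[N - 1];

    // turbulence injection
    int ns = noiseSection[t];
    if (ns >= 0 && ns < N) fn[ns] += noise[s];

    // nasal branch: one-way diversion at the velar junction
    double nOut = 0.0;
    double cfr = nasalFrac[t];
    if (nasalDelay > 0) {
      nOut = (1.0 + nostrilReflect) * nasal[nasalPos];
      double div = 0.0;
      if (cfr > 0.0 && velarSection >= 0 && velarSection < N) {
        div = cfr * fn[velarSection];
        fn[velarSection] -= div;
      }
      nasal[nasalPos] = div;
      nasalPos = (nasalPos + 1) % nasalDelay;
    }

    out[s] = lipOut + nOut;
    std::swap(f, fn);
    std::swap(b, bn);
  }
  return out;
}
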