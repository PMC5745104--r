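// Fixed-step explicit Euler integrator for the 1-D osmotic de-swelling
// model (power-law swelling pressure). Mirrors the R reference stepper
// (.deswellRates / stepDeswell) arithmetic exactly; the R side remains the
// oracle for single steps and custom pressure laws.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List deswell_integrate_cpp(NumericVector H0, double C, double gamma_,
                           double kmu, double Lendo, double Lepi,
                           double piExt, double delta, double dt,
                           NumericVector sampleTimes, int anteriorCode) {
  const int N = H0.size();
  const int nt = sampleTimes.size();
  std::vector<double> H(H0.begin(), H0.end());
  std::vector<double> dH(N), Pi(N);
  NumericMatrix out(N, nt);
  NumericMatrix outflux(2, nt); // cumulative posterior / anterior outflow
  double cumPost = 0.0, cumAnt = 0.0;
  double t = 0.0;
  for (int s = 0; s < nt; ++s) {
    const double target = sampleTimes[s];
    const double span = target - t;
    int nSteps = (span <= 0.0) ? 0 : (int)std::ceil(span / dt - 1e-12);
    const double dts = (nSteps > 0) ? span / nSteps : 0.0;
    const bool gammaIsTwo = (gamma_ == 2.0);
    for (int step = 0; step < nSteps; ++step) {
      if (gammaIsTwo)
        for (int i = 0; i < N; ++i) Pi[i] = C / (H[i] * H[i]);
      else
        for (int i = 0; i < N; ++i) Pi[i] = C * std::pow(H[i], -gamma_);
      // internal Darcy fluxes between element centres
      double qPrev = 0.0; // flux into element 0 from above (anterior)
      double jAnt = 0.0;
      if (anteriorCode == 1) jAnt = Lepi * (piExt - Pi[0]);
      else if (anteriorCode == 2)
        jAnt = kmu * (piExt - Pi[0]) / (delta * (1.0 + H[0]) / 2.0);
      for (int i = 0; i < N; ++i) {
        double qNext;
        if (i < N - 1) {
          const double dx = delta * (2.0 + H[i] + H[i + 1]) / 2.0;
          qNext = kmu * (Pi[i + 1] - Pi[i]) / dx; // P = -Pi
        } else {
          qNext = Lendo * (piExt - Pi[N - 1]);
        }
        const double inflow = (i == 0) ? -jAnt : qPrev;
        dH[i] = (inflow - qNext) / delta;
        qPrev = qNext;
      }
      const double jPost = qPrev;
      for (int i = 0; i < N; ++i) H[i] += dts * dH[i];
      cumPost += dts * jPost;
      cumAnt += dts * jAnt;
      if (H[N - 1] < 0.0 || H[0] < 0.0)
        stop("negative hydration during integration: reduce dt");
    }
    t = target;
    for (int i = 0; i < N; ++i) out(i, s) = H[i];
    outflux(0, s) = cumPost;
    outflux(1, s) = cumAnt;
  }
  return List::create(_["hydration"] = out, _["outflux"] = outflux);
}
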