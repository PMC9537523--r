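#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of an adaptive leaky integrate-and-fire neuron
// with an optional slow rebound (h-current-like) conductance, driven by a
// square current step. When the membrane crosses the firing threshold a
// stereotyped spike waveform is stamped over the following samples so that
// derivative-based spike detection sees a genuine upstroke.
//
// Units: time ms, voltage mV, current pA, resistance MOhm (pA * MOhm = 1e-3 mV).
//
// [[Rcpp::export]]
List lif_integrate(int n, double dt_ms, double onset_ms, double dur_ms,
                   double amp_pA, double rest, double threshold, double reset,
                   double r_mohm, double tau_ms, double adapt_b_pA,
                   double adapt_tau_ms, double sag_strength, double sag_tau_ms,
                   double refractory_ms, NumericVector stamp) {
  NumericVector v(n);
  std::vector<int> spike_idx;
  double vm = rest;
  double w = 0.0;      // adaptation current, pA
  double isag = 0.0;   // rebound current, pA
  const double r_scaled = r_mohm * 1e-3; // mV per pA
  int stamp_left = 0;  // samples of the stamped waveform still to write
  int stamp_pos = 0;
  double refrac_left = 0.0;

  for (int i = 0; i < n; ++i) {
    double t = i * dt_ms;
    double input = (t >= onset_ms && t < onset_ms + dur_ms) ? amp_pA : 0.0;

    if (stamp_left > 0) {
      v[i] = stamp[stamp_pos];
      ++stamp_pos;
      --stamp_left;
      if (stamp_left == 0) {
        vm = reset;
        refrac_left = refractory_ms;
      }
      // adaptation and sag keep relaxing during the stamp
      w += dt_ms * (-w / adapt_tau_ms);
      if (sag_tau_ms > 0.0) {
        double target = sag_strength * (rest - reset) / r_scaled;
        isag += dt_ms * (target - isag) / sag_tau_ms;
      }
      continue;
    }

    double target = 0.0;
    if (sag_tau_ms > 0.0 && sag_strength != 0.0) {
      target = sag_strength * (rest - vm) / r_scaled;
      isag += dt_ms * (target - isag) / sag_tau_ms;
    }
    double dv = dt_ms * (-(vm - rest) + r_scaled * (input - w + isag)) / tau_ms;
    vm += dv;
    w += dt_ms * (-w / adapt_tau_ms);
    if (refrac_left > 0.0) refrac_left -= dt_ms;

    if (vm >= threshold && refrac_left <= 0.0) {
      spike_idx.push_back(i);
      w += adapt_b_pA;
      stamp_left = stamp.size();
      stamp_pos = 0;
      v[i] = stamp[stamp_pos];
      ++stamp_pos;
      --stamp_left;
      if (stamp_left == 0) {
        vm = reset;
        refrac_left = refractory_ms;
      }
    } else {
      v[i] = vm;
    }
  }

  return List::create(_["v"] = v,
                      _["spike_idx"] = wrap(spike_idx));
}
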