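#include <Rcpp.h>
using namespace Rcpp;

// Adaptive-exponential integrate-and-fire membrane, fixed-step explicit Euler.
// Units: ms, mV, nA, nF, uS. A spike is registered when V reaches v_peak; the
// sample at that step is recorded at v_peak, then V resets to v_reset, the
// adaptation current w jumps by b, and the membrane is clamped for t_ref ms.
// [[Rcpp::export]]
List adex_integrate(double c_m, double g_l, double e_l, double v_t,
                    double delta_t, double a_w, double b_w, double tau_w,
                    double v_reset, double v_peak, double t_ref,
                    double i_gain, double amplitude, double onset,
                    double duration, double total_time, double dt) {
  const int n = (int)std::floor(total_time / dt + 0.5) + 1;
  NumericVector volt(n);
  std::vector<double> spikes;
  double v = e_l, w = 0.0;
  double ref_until = -1.0;
  volt[0] = v;
  for (int i = 1; i < n; i++) {
    const double t_prev = (i - 1) * dt;
    const double i_stim =
        (t_prev >= onset && t_prev < onset + duration) ? i_gain * amplitude : 0.0;
    // w integrates through the refractory clamp; V is held at v_reset
    const double dw = (a_w * (v - e_l) - w) / tau_w * dt;
    if (t_prev < ref_until) {
      w += dw;
      v = v_reset;
      volt[i] = v;
      continue;
    }
    double ex = (v - v_t) / delta_t;
    if (ex > 40.0) ex = 40.0;  // cap the upswing; the cutoff fires this step
    const double dv =
        (-g_l * (v - e_l) + g_l * delta_t * std::exp(ex) - w + i_stim) / c_m * dt;
    v += dv;
    w += dw;
    if (!std::isfinite(v) || !std::isfinite(w))
      stop("integration failure: non-finite state at t = %f ms", i * dt);
    if (v >= v_peak) {
      volt[i] = v_peak;
      spikes.push_back(i * dt);
      v = v_reset;
      w += b_w;
      ref_until = i * dt + t_ref;
    } else {
      volt[i] = v;
    }
  }
  return List::create(_["voltage"] = volt,
                      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()));
}
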