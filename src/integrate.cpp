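#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven integration of a population of conductance-based LIF neurons.
//
// Units: mV, ms, nS, pF, pA.  Each neuron carries four alpha-conductance
// channels (0 = background excitation, 1 = cortical excitation,
// 2 = MSN inhibition, 3 = FSI inhibition), each implemented as the linear
// two-state system
//     tau * dg/dt = -g + h,   tau * dh/dt = -h,
// which is solved exactly over one step:
//     g <- exp(-dt/tau) * (g + h * dt/tau),  h <- h * exp(-dt/tau).
// A synaptic event adds `amount` to h; with amount = e * gbar the
// conductance peaks at exactly gbar one tau after arrival.
//
// The membrane is advanced with exponential Euler using the exact time
// average of each channel's conductance over the step,
//     avg = A * g0 + B * h0,
//     A = tau (1 - exp(-u)) / dt,  B = tau (1 - exp(-u)(1 + u)) / dt,
// with u = dt / tau.  Averaging matters for the excitatory channels, whose
// time constant (0.2 ms) is comparable to the step: an endpoint sample
// systematically underestimates the synaptic fluctuations.  Threshold is
// tested at step end, the spike time is the step-end time, and the voltage
// is clamped at V_reset for the refractory period while conductances keep
// evolving.
//
// Recurrent spikes are delivered through a ring buffer after an integer
// number of steps; external (cortical or precomputed) events arrive as a
// step-sorted event list.  Background drive is an independent Poisson
// event count per neuron per step drawn from R's RNG, so results are
// reproducible under set.seed().

// [[Rcpp::export]]
List cxx_simulate(NumericVector Cm, NumericVector gL, NumericVector EL,
                  NumericVector Vth, NumericVector Vreset,
                  IntegerVector tr_steps,
                  NumericVector Ee, NumericVector Ei,
                  NumericMatrix tau,
                  IntegerVector syn_ptr, IntegerVector syn_target,
                  IntegerVector syn_channel, IntegerVector syn_delay,
                  NumericVector syn_amount,
                  IntegerVector ev_step, IntegerVector ev_target,
                  IntegerVector ev_channel, NumericVector ev_amount,
                  NumericVector bkg_lambda, NumericVector bkg_amount,
                  NumericVector I_dc, NumericVector V0,
                  double dt, int n_steps) {
  const int n = Cm.size();
  if (n == 0) stop("no neurons to simulate");

  int max_delay = 1;
  for (int j = 0; j < syn_delay.size(); ++j) {
    if (syn_delay[j] < 1) stop("synaptic delay shorter than one time step");
    if (syn_delay[j] > max_delay) max_delay = syn_delay[j];
  }
  const int L = max_delay + 2;  // ring length; slot s+1+delay never catches slot s

  std::vector<double> g(n * 4, 0.0), h(n * 4, 0.0);
  std::vector<double> decay(n * 4), coef(n * 4), Erev(n * 4);
  std::vector<double> avA(n * 4), avB(n * 4);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 4; ++c) {
      double tc = tau(i, c);
      if (tc <= 0) stop("non-positive synaptic time constant");
      double u = dt / tc, eu = std::exp(-u);
      decay[i * 4 + c] = eu;
      coef[i * 4 + c]  = u;
      Erev[i * 4 + c]  = (c < 2) ? Ee[i] : Ei[i];
      avA[i * 4 + c] = tc * (1.0 - eu) / dt;
      avB[i * 4 + c] = tc * (1.0 - eu * (1.0 + u)) / dt;
    }
  }

  std::vector<double> buf((size_t)L * n * 4, 0.0);
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<int> refr_until(n, 0);

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(4096);
  sp_t.reserve(4096);

  const int n_ev = ev_step.size();
  int ev_i = 0;
  // skip any events scheduled before t = 0
  while (ev_i < n_ev && ev_step[ev_i] < 0) ++ev_i;

  GetRNGstate();
  for (int s = 0; s < n_steps; ++s) {
    double *slot = &buf[(size_t)(s % L) * n * 4];

    while (ev_i < n_ev && ev_step[ev_i] <= s) {
      h[(size_t)ev_target[ev_i] * 4 + ev_channel[ev_i]] += ev_amount[ev_i];
      ++ev_i;
    }

    for (int i = 0; i < n; ++i) {
      double *hi = &h[i * 4], *gi = &g[i * 4], *bi = &slot[i * 4];
      for (int c = 0; c < 4; ++c) { hi[c] += bi[c]; bi[c] = 0.0; }
      if (bkg_lambda[i] > 0) {
        int k = (int)R::rpois(bkg_lambda[i]);
        if (k > 0) hi[0] += k * bkg_amount[i];
      }

      double num = gL[i] * EL[i] + I_dc[i];
      double G = gL[i];
      const double *dc = &decay[i * 4], *cf = &coef[i * 4], *er = &Erev[i * 4];
      const double *aA = &avA[i * 4], *aB = &avB[i * 4];
      for (int c = 0; c < 4; ++c) {
        double gavg = aA[c] * gi[c] + aB[c] * hi[c];
        gi[c] = dc[c] * (gi[c] + hi[c] * cf[c]);
        hi[c] *= dc[c];
        G += gavg;
        num += gavg * er[c];
      }

      if (s >= refr_until[i]) {
        double Vinf = num / G;
        V[i] = Vinf + (V[i] - Vinf) * std::exp(-G * dt / Cm[i]);
        if (V[i] >= Vth[i]) {
          sp_id.push_back(i);
          sp_t.push_back((s + 1) * dt);
          V[i] = Vreset[i];
          refr_until[i] = s + 1 + tr_steps[i];
          for (int j = syn_ptr[i]; j < syn_ptr[i + 1]; ++j) {
            int dslot = (s + 1 + syn_delay[j]) % L;
            buf[((size_t)dslot * n + syn_target[j]) * 4 + syn_channel[j]] +=
              syn_amount[j];
          }
        }
      } else {
        V[i] = Vreset[i];
      }
    }

    if ((s & 1023) == 0 && !std::isfinite(V[0])) {
      PutRNGstate();
      stop("membrane potential diverged (NaN/Inf) at t = %f ms", s * dt);
    }
  }
  PutRNGstate();

  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(V[i]))
      stop("membrane potential of neuron %d is not finite at end of trial", i);
  }

  return List::create(_["neuron_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
                      _["time_ms"]   = NumericVector(sp_t.begin(), sp_t.end()),
                      _["v_end"]     = NumericVector(V.begin(), V.end()));
}
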