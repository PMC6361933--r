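#include <Rcpp.h>
using namespace Rcpp;

// Izhikevich RK-2 network integrator.
//
// Two-variable quadratic integrate-and-fire dynamics
//   dv/dt = 0.04 v^2 + 5 v + 140 - u + I + s
//   du/dt = a (b v - u)
// with after-spike reset v <- c, u <- u + d at v >= 30 mV, integrated by the
// midpoint Runge-Kutta rule with thalamic noise and the synaptic drive held
// constant within a step. Spikes detected at step t deliver +/- w to each
// outgoing neighbour's s-input at step t+1 only (single-step delivery).
//
// The thalamic input is drawn per neuron once per millisecond (every
// noise_hold steps) from the R RNG (Gaussian, sd = I_scale) and held constant
// across the sub-steps of that millisecond, so the per-millisecond drive
// matches the original 1-ms-step model at any resolution h. Draws happen in
// fixed neuron order, so results are reproducible under set.seed().
//
// Recorded traces are group means of the membrane potential with v capped at
// 30 mV at spike steps; S(t) is the mean of all capped potentials.

// [[Rcpp::export]]
List simulate_izh_cpp(int n,
                      IntegerVector out_ptr,   // CSR offsets, length n+1 (0-based)
                      IntegerVector out_idx,   // 0-based neighbour indices
                      NumericVector a, NumericVector b,
                      NumericVector c_reset, NumericVector d_jump,
                      NumericVector I_scale, NumericVector I_const,
                      LogicalVector is_exc,
                      double w, double h,
                      int transient_steps, int record_steps,
                      IntegerVector group,     // 1-based group id per neuron
                      int n_groups,
                      int noise_hold,         // steps per thalamic-noise draw
                      bool noise_impulse,     // kick v directly vs held current
                      NumericVector v_init) { // initial membrane potentials
  std::vector<double> v(n), u(n);
  for (int i = 0; i < n; ++i) {
    v[i] = v_init[i];
    u[i] = b[i] * v[i];
  }

  std::vector<double> noise(n, 0.0);
  std::vector<double> syn(n, 0.0), syn_next(n, 0.0);
  std::vector<int> spike_neuron, spike_step;
  std::vector<double> gsize(n_groups, 0.0);
  for (int i = 0; i < n; ++i) gsize[group[i] - 1] += 1.0;

  NumericMatrix traces(record_steps, n_groups);
  NumericVector S(record_steps);

  int total = transient_steps + record_steps;
  RNGScope scope;

  for (int t = 0; t < total; ++t) {
    std::fill(syn_next.begin(), syn_next.end(), 0.0);
    double ssum = 0.0;
    if (t >= transient_steps) {
      for (int gidx = 0; gidx < n_groups; ++gidx) traces(t - transient_steps, gidx) = 0.0;
    }
    if (t % noise_hold == 0) {
      for (int i = 0; i < n; ++i) {
        noise[i] = I_scale[i] > 0.0 ? R::rnorm(0.0, I_scale[i]) : 0.0;
        if (noise_impulse) v[i] += noise[i];
      }
    }
    for (int i = 0; i < n; ++i) {
      double drive = I_const[i] + syn[i] + (noise_impulse ? 0.0 : noise[i]);
      double vi = v[i], ui = u[i];
      double k1v = 0.04 * vi * vi + 5.0 * vi + 140.0 - ui + drive;
      double k1u = a[i] * (b[i] * vi - ui);
      double vm = vi + 0.5 * h * k1v;
      double um = ui + 0.5 * h * k1u;
      double k2v = 0.04 * vm * vm + 5.0 * vm + 140.0 - um + drive;
      double k2u = a[i] * (b[i] * vm - um);
      vi += h * k2v;
      ui += h * k2u;
      if (!R_finite(vi) || !R_finite(ui))
        stop("non-finite membrane state at neuron %d, step %d", i + 1, t + 1);
      bool spiked = vi >= 30.0;
      double vcap = spiked ? 30.0 : vi;
      if (t >= transient_steps) {
        traces(t - transient_steps, group[i] - 1) += vcap;
        ssum += vcap;
        if (spiked) {
          spike_neuron.push_back(i + 1);
          spike_step.push_back(t - transient_steps + 1);
        }
      }
      if (spiked) {
        double wsign = is_exc[i] ? w : -w;
        for (int e = out_ptr[i]; e < out_ptr[i + 1]; ++e)
          syn_next[out_idx[e]] += wsign;
        vi = c_reset[i];
        ui += d_jump[i];
      }
      v[i] = vi;
      u[i] = ui;
    }
    if (t >= transient_steps) {
      int tr = t - transient_steps;
      for (int gidx = 0; gidx < n_groups; ++gidx) traces(tr, gidx) /= gsize[gidx];
      S[tr] = ssum / n;
    }
    std::swap(syn, syn_next);
  }

  return List::create(
    _["spike_neuron"] = wrap(spike_neuron),
    _["spike_step"] = wrap(spike_step),
    _["traces"] = traces,
    _["S"] = S);
}
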