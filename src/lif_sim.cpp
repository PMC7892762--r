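#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Clock-driven LIF simulation of one population with delayed synaptic input.
//
// The presynaptic axis of every weight matrix is the concatenation
// [exogenous block (n_exo columns) | simulated population (n columns)],
// with the exogenous block ordered as the caller's global neuron order.
// Weight matrices arrive as dgCMatrix slots (post x pre, CSC), grouped by
// integer conduction delay in ascending delay order. Currents are
// accumulated column by column in ascending presynaptic index within each
// delay group, which makes the floating-point summation order identical
// between a monolithic run and a per-module run on the same network — the
// property behind the exact modular/monolithic equivalence.
//
// Membrane update (exponential Euler, exact for a piecewise-constant
// current): V <- v_rest + (V - v_rest) * decay + gain * I, with
// decay = exp(-dt/tau) and gain = R * (1 - decay). A neuron with
// V >= v_th emits a spike, resets to v_reset and skips its next
// `refrac_steps` update steps.
// [[Rcpp::export]]
List lif_sim_cpp(List delay_groups, IntegerMatrix exo, int n, int T,
                 IntegerVector refrac_steps, double decay, double gain,
                 double v_rest, double v_reset, double v_th, bool record_v) {
  int n_exo = exo.nrow();
  if (exo.ncol() != T) stop("exogenous raster must have T columns");

  struct Group {
    int delay;
    IntegerVector p, i;
    NumericVector x;
  };
  std::vector<Group> groups;
  for (int g = 0; g < delay_groups.size(); ++g) {
    List gl = delay_groups[g];
    Group gr;
    gr.delay = as<int>(gl["delay"]);
    gr.p = gl["p"];
    gr.i = gl["i"];
    gr.x = gl["x"];
    if (gr.delay < 1) stop("delays must be >= 1 step");
    groups.push_back(gr);
  }

  // active presynaptic columns per past step, exogenous and self separately
  std::vector<std::vector<int> > exo_active(T);
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < n_exo; ++j)
      if (exo(j, t) != 0) exo_active[t].push_back(j);
  std::vector<std::vector<int> > self_active(T);

  std::vector<double> V(n, v_rest), I(n);
  std::vector<int> ref(n, 0);
  IntegerMatrix spikes(n, T);
  NumericMatrix volt = record_v ? NumericMatrix(n, T) : NumericMatrix(0, 0);

  for (int t = 0; t < T; ++t) {
    std::fill(I.begin(), I.end(), 0.0);
    for (size_t g = 0; g < groups.size(); ++g) {
      int td = t - groups[g].delay;
      if (td < 0) continue;  // spikes before the simulation start are zero
      const IntegerVector &p = groups[g].p, &ri = groups[g].i;
      const NumericVector &x = groups[g].x;
      const std::vector<int> &ea = exo_active[td];
      for (size_t k = 0; k < ea.size(); ++k) {
        int j = ea[k];
        for (int q = p[j]; q < p[j + 1]; ++q) I[ri[q]] += x[q];
      }
      const std::vector<int> &sa = self_active[td];
      for (size_t k = 0; k < sa.size(); ++k) {
        int j = n_exo + sa[k];
        for (int q = p[j]; q < p[j + 1]; ++q) I[ri[q]] += x[q];
      }
    }
    for (int i = 0; i < n; ++i) {
      if (ref[i] > 0) {
        --ref[i];  // refractory: no integration, voltage held at reset
      } else {
        V[i] = v_rest + (V[i] - v_rest) * decay + gain * I[i];
        if (V[i] >= v_th) {
          spikes(i, t) = 1;
          self_active[t].push_back(i);
          V[i] = v_reset;
          ref[i] = refrac_steps[i];
        }
      }
      if (record_v) volt(i, t) = V[i];
    }
  }

  List out = List::create(Named("spikes") = spikes);
  if (record_v) out["voltage"] = volt;
  return out;
}
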