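#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear interpolation with constant extrapolation beyond the
// table edges. Tables are validated (sorted, >= 2 rows, tau > 0) on the R side.
static inline double interp_tab(double v, const NumericVector& tv,
                                const NumericVector& tt) {
  const int n = tv.size();
  if (v <= tv[0]) return tt[0];
  if (v >= tv[n - 1]) return tt[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (tv[mid] <= v) lo = mid; else hi = mid;
  }
  double w = (v - tv[lo]) / (tv[hi] - tv[lo]);
  return tt[lo] + w * (tt[hi] - tt[lo]);
}

static inline double boltz_up(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}
static inline double boltz_down(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp((v - vh) / k));
}

// Relax the two T-channel gates along a sampled voltage command.
// v[0] is the voltage at t = 0 where the state is (m0, h0); between sample
// k-1 and k the command is v[k] (piecewise-constant), so the exponential
// update over dt is exact when segment edges fall on the sample grid.
// [[Rcpp::export]]
List cpp_gate_trace(NumericVector v, double dt, double m0, double h0,
                    double vha, double ka, double vhi, double ki, double p,
                    NumericVector mtab_v, NumericVector mtab_tau,
                    NumericVector htab_v, NumericVector htab_tau,
                    double gmax, double erev) {
  const int n = v.size();
  NumericVector m(n), h(n), i(n);
  double mm = m0, hh = h0;
  m[0] = mm; h[0] = hh;
  i[0] = gmax * std::pow(mm, p) * hh * (v[0] - erev);
  for (int k = 1; k < n; ++k) {
    const double vk = v[k];
    const double minf = boltz_up(vk, vha, ka);
    const double hinf = boltz_down(vk, vhi, ki);
    const double tm = interp_tab(vk, mtab_v, mtab_tau);
    const double th = interp_tab(vk, htab_v, htab_tau);
    mm = minf + (mm - minf) * std::exp(-dt / tm);
    hh = hinf + (hh - hinf) * std::exp(-dt / th);
    m[k] = mm; h[k] = hh;
    i[k] = gmax * std::pow(mm, p) * hh * (vk - erev);
  }
  return List::create(_["m"] = m, _["h"] = h, _["i"] = i);
}

// Traub-lineage spike kinetics (transient Na, delayed-rectifier K) with an
// adjustable threshold shift vt.  Rate functions have removable
// singularities handled by the x/(1-exp(-x)) limit.
static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x / y)), robust near x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

struct SpikeRates {
  double am, bm, ah, bh, an, bn;
};

static inline SpikeRates spike_rates(double v, double vt) {
  SpikeRates r;
  const double u = v - vt;
  r.am = 0.32 * vtrap(u - 13.0, 4.0);
  r.bm = 0.28 * vtrap(40.0 - u, 5.0);
  r.ah = 0.128 * std::exp((17.0 - u) / 18.0);
  r.bh = 4.0 / (1.0 + std::exp((40.0 - u) / 5.0));
  r.an = 0.032 * vtrap(u - 15.0, 5.0);
  r.bn = 0.5 * std::exp((10.0 - u) / 40.0);
  return r;
}

// Single-compartment conductance-based neuron with Na, K, leak and a
// T-type conductance in density mode.  Gates use exponential (exact at
// fixed v) updates; the voltage uses a linearized implicit step,
// unconditionally stable at the default dt = 0.025 ms:
//   v' = (v + (dt/cm) * (sum g_x * E_x + i_inj)) / (1 + (dt/cm) * sum g_x)
// clamped[k] == true forces v to vclamp[k] at step k (voltage pre-steps).
// i_inj is in nA, converted to uA/cm^2 by the membrane area.
// [[Rcpp::export]]
List cpp_neuron_run(double dt, int n_steps, NumericVector i_inj,
                    LogicalVector clamped, NumericVector vclamp,
                    double cm, double area, double gna, double gk, double gl,
                    double ena, double ek, double el, double vt,
                    double gT, double erevT, double vha, double ka,
                    double vhi, double ki, double p,
                    NumericVector mtab_v, NumericVector mtab_tau,
                    NumericVector htab_v, NumericVector htab_tau,
                    double v0, int record_every) {
  const int n_rec = n_steps / record_every + 1;
  NumericVector t_out(n_rec), v_out(n_rec), i_out(n_rec);

  double v = v0;
  // gates start at steady state for v0
  SpikeRates r = spike_rates(v, vt);
  double m = r.am / (r.am + r.bm);
  double h = r.ah / (r.ah + r.bh);
  double n = r.an / (r.an + r.bn);
  double mT = boltz_up(v, vha, ka);
  double hT = boltz_down(v, vhi, ki);

  int rec = 0;
  t_out[0] = 0.0; v_out[0] = v; i_out[0] = i_inj[0];
  rec = 1;

  const double inj_scale = 1e-3 / area;  // nA -> uA/cm^2
  bool blew_up = false;

  for (int k = 0; k < n_steps; ++k) {
    // exponential gate updates at the current voltage
    r = spike_rates(v, vt);
    double tm = 1.0 / (r.am + r.bm), minf = r.am * tm;
    double th = 1.0 / (r.ah + r.bh), hinf = r.ah * th;
    double tn = 1.0 / (r.an + r.bn), ninf = r.an * tn;
    m = minf + (m - minf) * std::exp(-dt / tm);
    h = hinf + (h - hinf) * std::exp(-dt / th);
    n = ninf + (n - ninf) * std::exp(-dt / tn);
    const double mTinf = boltz_up(v, vha, ka);
    const double hTinf = boltz_down(v, vhi, ki);
    const double tmT = interp_tab(v, mtab_v, mtab_tau);
    const double thT = interp_tab(v, htab_v, htab_tau);
    mT = mTinf + (mT - mTinf) * std::exp(-dt / tmT);
    hT = hTinf + (hT - hTinf) * std::exp(-dt / thT);

    if (clamped[k]) {
      v = vclamp[k];
    } else {
      const double gNa = gna * m * m * m * h;
      const double gK = gk * n * n * n * n;
      const double gTt = gT * std::pow(mT, p) * hT;
      const double gsum = gNa + gK + gl + gTt;
      const double gE = gNa * ena + gK * ek + gl * el + gTt * erevT;
      const double a = dt / cm;
      v = (v + a * (gE + i_inj[k] * inj_scale)) / (1.0 + a * gsum);
    }
    if (!std::isfinite(v) || std::fabs(v) > 200.0) { blew_up = true; break; }
    if ((k + 1) % record_every == 0 && rec < n_rec) {
      t_out[rec] = (k + 1) * dt;
      v_out[rec] = v;
      i_out[rec] = i_inj[k];
      ++rec;
    }
  }
  if (rec < n_rec) {
    t_out = NumericVector(t_out.begin(), t_out.begin() + rec);
    v_out = NumericVector(v_out.begin(), v_out.begin() + rec);
    i_out = NumericVector(i_out.begin(), i_out.begin() + rec);
  }
  return List::create(_["time"] = t_out, _["v"] = v_out, _["i_inj"] = i_out,
                      _["blew_up"] = blew_up,
                      _["state"] = NumericVector::create(v, m, h, n, mT, hT));
}
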