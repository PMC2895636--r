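#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gating-function form codes (kept in sync with kinetics_form_code() in R):
// 0 constant(a); 1 logistic(vhalf,k); 2 logistic_ca(vhalf,k,ca_half);
// 3 sigmoid(a,b,vhalf,k); 4 biexp(a,b,vh1,k1,vh2,k2); 5 prodsig(s,vh1,k1,c,vh2,k2)
static inline double eval_form(int form, const double* p, double v, double ca) {
  switch (form) {
  case 0: return p[0];
  case 1: return 1.0 / (1.0 + std::exp((v - p[0]) / p[1]));
  case 2: return (ca / (ca + p[2])) / (1.0 + std::exp((v - p[0]) / p[1]));
  case 3: return p[0] + p[1] / (1.0 + std::exp((v - p[2]) / p[3]));
  case 4: return p[0] + p[1] / (std::exp((v - p[2]) / p[3]) + std::exp((v - p[4]) / p[5]));
  case 5: return p[0] / (1.0 + std::exp((v - p[1]) / p[2])) *
                 (p[3] + 1.0 / (1.0 + std::exp((v - p[4]) / p[5])));
  }
  return NA_REAL;
}

// Channel spec matrix layout, one row per channel:
//  0 gbar | 1 is_ca_reversal | 2 E (mV; ignored if ca-reversal) | 3 p | 4 q |
//  5 minf_form |  6..11 minf params | 12 taum_form | 13..18 taum params |
// 19 hinf_form | 20..25 hinf params | 26 tauh_form | 27..32 tauh params
// A form code of -1 means "gate absent" (q = 0 channels, leak).
static const int NCOL = 33;

static inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericMatrix chan, NumericVector membrane,
                  NumericVector calcium, NumericVector simpar) {
  const int nch = chan.nrow();
  if (chan.ncol() != NCOL) stop("channel spec matrix has wrong width");
  const double cm = membrane[0];        // uF/cm^2
  const double area = membrane[1];      // cm^2
  const double vlo = membrane[2], vhi = membrane[3];
  const double ca_tau = calcium[0], ca_f = calcium[1], ca_rest = calcium[2];
  const double ca_out = calcium[3], ca_pref = calcium[4];
  const double dt = simpar[0];
  const long nsteps = (long) std::llround(simpar[1] / dt);
  const long ntrans = (long) std::llround(simpar[2] / dt);
  const int stride = (int) simpar[3];
  const double v0 = simpar[4];
  const double i_inject = simpar[5];    // uA/cm^2, constant test current

  std::vector<double> m(nch), h(nch), gb(nch), Erev(nch);
  std::vector<int> pp(nch), qq(nch), isca(nch);
  // row-major copy of the spec (NumericMatrix is column-major)
  std::vector<double> spec(nch * NCOL);
  for (int c = 0; c < nch; ++c) {
    for (int k = 0; k < NCOL; ++k) spec[c * NCOL + k] = chan(c, k);
    gb[c] = chan(c, 0); isca[c] = (int) chan(c, 1); Erev[c] = chan(c, 2);
    pp[c] = (int) chan(c, 3); qq[c] = (int) chan(c, 4);
  }
  #define SP(c, k) (spec[(c) * NCOL + (k)])

  double ca = ca_rest;
  double v = v0;
  // initialise gates at steady state for (v0, ca_rest)
  for (int c = 0; c < nch; ++c) {
    double vc = std::min(std::max(v, vlo), vhi);
    int fm = (int) SP(c, 5);
    m[c] = (fm < 0) ? 1.0 : eval_form(fm, &SP(c, 6), vc, ca);
    int fh = (int) SP(c, 19);
    h[c] = (fh < 0) ? 1.0 : eval_form(fh, &SP(c, 20), vc, ca);
  }

  const long nrec = (nsteps - ntrans) / stride;
  NumericVector t_out(nrec), v_out(nrec), ca_out_v(nrec);
  long irec = 0;

  for (long s = 0; s < nsteps; ++s) {
    const double vc = std::min(std::max(v, vlo), vhi);
    const double eca = ca_pref * std::log(ca_out / ca);

    // gate update (exponential Euler), then conductance totals
    double gtot = 0.0, ge = 0.0, jca = 0.0;
    for (int c = 0; c < nch; ++c) {
      int fm = (int) SP(c, 5);
      if (fm >= 0) {
        double minf = eval_form(fm, &SP(c, 6), vc, ca);
        double taum = eval_form((int) SP(c, 12), &SP(c, 13), vc, ca);
        m[c] = minf + (m[c] - minf) * std::exp(-dt / taum);
      }
      int fh = (int) SP(c, 19);
      if (fh >= 0) {
        double hinf = eval_form(fh, &SP(c, 20), vc, ca);
        double tauh = eval_form((int) SP(c, 26), &SP(c, 27), vc, ca);
        h[c] = hinf + (h[c] - hinf) * std::exp(-dt / tauh);
      }
      const double g = gb[c] * ipow(m[c], pp[c]) * ipow(h[c], qq[c]);
      const double E = isca[c] ? eca : Erev[c];
      gtot += g;
      ge += g * E;
      if (isca[c]) jca += g * (v - E);   // uA/cm^2, Ca current density
    }

    // membrane update
    if (gtot > 0.0) {
      const double vinf = (ge + i_inject) / gtot;
      v = vinf + (v - vinf) * std::exp(-dt * gtot / cm);
    } else {
      v += dt * i_inject / cm;
    }

    // calcium pool: dCa/dt = (-f * I_Ca[nA] - Ca + Ca_rest) / tau
    const double ica_nA = jca * area * 1000.0;
    const double cainf = ca_rest - ca_f * ica_nA;
    ca = cainf + (ca - cainf) * std::exp(-dt / ca_tau);
    if (ca < 1e-9) ca = 1e-9;

    if (!std::isfinite(v) || !std::isfinite(ca))
      stop("non-finite state at t = %f ms", (s + 1) * dt);

    if (s >= ntrans && ((s - ntrans) % stride) == (stride - 1) && irec < nrec) {
      t_out[irec] = (s + 1) * dt;
      v_out[irec] = v;
      ca_out_v[irec] = ca;
      ++irec;
    }
  }

  return List::create(_["time"] = t_out, _["v"] = v_out, _["ca"] = ca_out_v);
}
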