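#include <Rcpp.h>
using namespace Rcpp;

// Integer power for small non-negative exponents (gating exponents p, q).
static inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

// Heun (explicit trapezoidal, "modified Euler") integration of the three
// clamped gating variables m_H, m_Ca, h_Ca followed by reconstruction of the
// clamp current decomposition.
//
// The command voltage V(t) is shared across all candidate models, so the
// voltage-dependent pieces that involve fixed constants are precomputed once
// in R and passed in as arrays:
//   minfH[i]     = 1 / (1 + exp((V[i] - Vhalf_mH) / k_mH))
//   tauHscale[i] = 1 / (1 + exp((V[i] + tauH_shift) / tauH_slope))
//   expVm[i]     = exp(V[i] / k_mCa)
//   expVh[i]     = exp(V[i] / k_hCa)
// The model-specific Ca half-activation voltages enter as the scalar factors
//   aM = exp(-Vhalf_mCa / k_mCa),  aH = exp(-Vhalf_hCa / k_hCa)
// so that m_inf_Ca[i] = 1 / (1 + expVm[i] * aM) without any exp() in the loop.
//
// Gating variables are clamped to [0, 1] after every step; time constants
// below `tiny` are treated as instantaneous (x tracks x_inf exactly).
// [[Rcpp::export]]
List simulate_clamp_cpp(NumericVector V, NumericVector dVdt, double dt,
                        double gL, double gH, double gCa,
                        double tauH_max, double aM, double tauMCa,
                        double aH, double tauHCa,
                        double EL, double ECa, double EH, double Cm,
                        int pCa, int qCa, int pH, int qH,
                        NumericVector minfH, NumericVector tauHscale,
                        NumericVector expVm, NumericVector expVh,
                        bool components) {
  const int n = V.size();
  const double tiny = 1e-9;
  (void)qH; // the H current carries no inactivation gate (q_H = 0, enforced in R)

  NumericVector Itot(n);
  NumericVector IL_v, ICm_v, ICa_v, IH_v, mH_v, mCa_v, hCa_v;
  if (components) {
    IL_v = NumericVector(n);  ICm_v = NumericVector(n);
    ICa_v = NumericVector(n); IH_v = NumericVector(n);
    mH_v = NumericVector(n);  mCa_v = NumericVector(n); hCa_v = NumericVector(n);
  }

  // steady state at the first command voltage
  double mH = minfH[0];
  double mCa = 1.0 / (1.0 + expVm[0] * aM);
  double hCa = 1.0 / (1.0 + expVh[0] * aH);

  for (int i = 0; i < n; ++i) {
    const double ICm = Cm * dVdt[i];
    const double IL  = gL * (V[i] - EL);
    const double ICa = gCa * ipow(mCa, pCa) * ipow(hCa, qCa) * (V[i] - ECa);
    const double IH  = gH * ipow(mH, pH) * (V[i] - EH); // q_H = 0: no inactivation gate
    Itot[i] = ICm + IL + ICa + IH;
    if (components) {
      ICm_v[i] = ICm; IL_v[i] = IL; ICa_v[i] = ICa; IH_v[i] = IH;
      mH_v[i] = mH; mCa_v[i] = mCa; hCa_v[i] = hCa;
    }
    if (i == n - 1) break;

    // Heun step from sample i to i+1
    // m_H: tau depends on V through the precomputed scale factor
    {
      const double tau0 = tauH_max * tauHscale[i];
      const double tau1 = tauH_max * tauHscale[i + 1];
      const double xi0 = minfH[i], xi1 = minfH[i + 1];
      if (tau0 < tiny || tau1 < tiny) {
        mH = xi1;
      } else {
        const double f0 = (xi0 - mH) / tau0;
        const double pred = mH + dt * f0;
        const double f1 = (xi1 - pred) / tau1;
        mH += 0.5 * dt * (f0 + f1);
      }
      if (mH < 0.0) mH = 0.0; else if (mH > 1.0) mH = 1.0;
    }
    // m_Ca: constant tau
    {
      const double xi0 = 1.0 / (1.0 + expVm[i] * aM);
      const double xi1 = 1.0 / (1.0 + expVm[i + 1] * aM);
      if (tauMCa < tiny) {
        mCa = xi1;
      } else {
        const double f0 = (xi0 - mCa) / tauMCa;
        const double pred = mCa + dt * f0;
        const double f1 = (xi1 - pred) / tauMCa;
        mCa += 0.5 * dt * (f0 + f1);
      }
      if (mCa < 0.0) mCa = 0.0; else if (mCa > 1.0) mCa = 1.0;
    }
    // h_Ca: constant tau
    {
      const double xi0 = 1.0 / (1.0 + expVh[i] * aH);
      const double xi1 = 1.0 / (1.0 + expVh[i + 1] * aH);
      if (tauHCa < tiny) {
        hCa = xi1;
      } else {
        const double f0 = (xi0 - hCa) / tauHCa;
        const double pred = hCa + dt * f0;
        const double f1 = (xi1 - pred) / tauHCa;
        hCa += 0.5 * dt * (f0 + f1);
      }
      if (hCa < 0.0) hCa = 0.0; else if (hCa > 1.0) hCa = 1.0;
    }
  }

  if (components) {
    return List::create(_["I_total"] = Itot, _["I_Cm"] = ICm_v, _["I_L"] = IL_v,
                        _["I_Ca"] = ICa_v, _["I_H"] = IH_v,
                        _["m_H"] = mH_v, _["m_Ca"] = mCa_v, _["h_Ca"] = hCa_v);
  }
  return List::create(_["I_total"] = Itot);
}

// Per-cycle extrema of a signal given 1-based [start, end] index ranges.
// Returns min, max, and the 1-based indices where they occur.
// [[Rcpp::export]]
List cycle_stats_cpp(NumericVector x, IntegerVector start, IntegerVector end) {
  const int m = start.size();
  NumericVector mn(m), mx(m);
  IntegerVector imn(m), imx(m);
  for (int k = 0; k < m; ++k) {
    int a = start[k] - 1, b = end[k] - 1;
    double lo = x[a], hi = x[a];
    int ilo = a, ihi = a;
    for (int i = a + 1; i <= b; ++i) {
      if (x[i] < lo) { lo = x[i]; ilo = i; }
      if (x[i] > hi) { hi = x[i]; ihi = i; }
    }
    mn[k] = lo; mx[k] = hi; imn[k] = ilo + 1; imx[k] = ihi + 1;
  }
  return List::create(_["min"] = mn, _["max"] = mx,
                      _["imin"] = imn, _["imax"] = imx);
}

// Permutation count for a Pearson correlation: number of random permutations
// of y whose |R| meets or exceeds |R_obs| (two-sided) or whose R meets or
// exceeds R_obs (one-sided). Uses R's RNG so results are reproducible under
// set.seed().
// [[Rcpp::export]]
int perm_cor_count_cpp(NumericVector x, NumericVector y, int n_perms,
                       bool two_sided) {
  const int n = x.size();
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    sx += x[i]; sy += y[i];
    sxx += x[i] * x[i]; syy += y[i] * y[i]; sxy += x[i] * y[i];
  }
  const double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
  if (vx <= 0 || vy <= 0) return NA_INTEGER;
  const double denom = std::sqrt(vx * vy);
  const double r_obs = (sxy - sx * sy / n) / denom;

  std::vector<double> yp(y.begin(), y.end());
  int count = 0;
  for (int p = 0; p < n_perms; ++p) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(yp[i], yp[j]);
    }
    double s = 0;
    for (int i = 0; i < n; ++i) s += x[i] * yp[i];
    const double r = (s - sx * sy / n) / denom;
    if (two_sided ? (std::fabs(r) >= std::fabs(r_obs)) : (r >= r_obs)) ++count;
  }
  return count;
}
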