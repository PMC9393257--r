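#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, zero initial state.
// Coefficients as returned by signal::butter (a[0] == 1 after normalization).
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nw = std::max(nb, na) - 1;
  std::vector<double> bb(nw + 1, 0.0), aa(nw + 1, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  std::vector<double> w(nw, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nw > 0 ? w[0] : 0.0);
    for (int j = 0; j < nw - 1; ++j)
      w[j] = bb[j + 1] * xi + w[j + 1] - aa[j + 1] * yi;
    if (nw > 0)
      w[nw - 1] = bb[nw] * xi - aa[nw] * yi;
    y[i] = yi;
  }
  return y;
}

// Both eardrum outputs in one call: each output mixes the delayed ipsilateral
// channel and the gain-scaled contralateral channel through the same band-pass.
// Returns c(power_left, power_right) as mean squared amplitude.
// [[Rcpp::export(name = ".eardrum_powers_cpp")]]
NumericVector eardrum_powers_cpp(NumericVector b, NumericVector a,
                                 NumericVector left, NumericVector right,
                                 double contra_gain, double contra_delay) {
  int n = left.size();
  int di = (int)std::floor(contra_delay);
  double fr = contra_delay - di;
  NumericVector dl(n), dr(n);
  for (int i = 0; i < n; ++i) {
    double l0 = (i - di >= 0) ? left[i - di] : 0.0;
    double l1 = (i - di - 1 >= 0) ? left[i - di - 1] : 0.0;
    double r0 = (i - di >= 0) ? right[i - di] : 0.0;
    double r1 = (i - di - 1 >= 0) ? right[i - di - 1] : 0.0;
    dl[i] = (1.0 - fr) * l0 + fr * l1;
    dr[i] = (1.0 - fr) * r0 + fr * r1;
  }
  NumericVector yl = iir_filter_cpp(b, a, dl);
  NumericVector ylc = iir_filter_cpp(b, a, right);
  NumericVector yr = iir_filter_cpp(b, a, dr);
  NumericVector yrc = iir_filter_cpp(b, a, left);
  double pl = 0.0, pr = 0.0;
  for (int i = 0; i < n; ++i) {
    double vl = yl[i] + contra_gain * ylc[i];
    double vr = yr[i] + contra_gain * yrc[i];
    pl += vl * vl;
    pr += vr * vr;
  }
  NumericVector out(2);
  out[0] = pl / n;
  out[1] = pr / n;
  return out;
}
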