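#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward algorithm for a discrete-time HMM.
// allprobs: n x N matrix of per-observation state emission densities.
// trans:    N x N transition probability matrix (rows sum to 1).
// delta:    initial state distribution, length N.
// Returns the log-likelihood (-Inf if the sequence has zero probability).
// [[Rcpp::export]]
double hmm_forward_loglik(const NumericMatrix& allprobs,
                          const NumericMatrix& trans,
                          const NumericVector& delta) {
  const int n = allprobs.nrow(), N = allprobs.ncol();
  std::vector<double> v(N), w(N);
  double ll = 0.0;
  for (int j = 0; j < N; ++j) v[j] = delta[j] * allprobs(0, j);
  double s = 0.0;
  for (int j = 0; j < N; ++j) s += v[j];
  if (s <= 0.0 || !R_finite(s)) return R_NegInf;
  for (int j = 0; j < N; ++j) v[j] /= s;
  ll += std::log(s);
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += v[i] * trans(i, j);
      w[j] = a * allprobs(t, j);
    }
    s = 0.0;
    for (int j = 0; j < N; ++j) s += w[j];
    if (s <= 0.0 || !R_finite(s)) return R_NegInf;
    for (int j = 0; j < N; ++j) v[j] = w[j] / s;
    ll += std::log(s);
  }
  return ll;
}

// Viterbi decoding in log space; ties broken toward the lower state index.
// Returns 1-based most-likely state sequence.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(const NumericMatrix& allprobs,
                          const NumericMatrix& trans,
                          const NumericVector& delta) {
  const int n = allprobs.nrow(), N = allprobs.ncol();
  NumericMatrix lv(n, N);
  IntegerMatrix bp(n, N);
  const double NEG = -1e300;
  auto lg = [&](double p) { return p > 0.0 ? std::log(p) : NEG; };
  for (int j = 0; j < N; ++j) lv(0, j) = lg(delta[j]) + lg(allprobs(0, j));
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < N; ++j) {
      double best = lv(t - 1, 0) + lg(trans(0, j));
      int arg = 0;
      for (int i = 1; i < N; ++i) {
        double cand = lv(t - 1, i) + lg(trans(i, j));
        if (cand > best) { best = cand; arg = i; }  // strict: ties keep lower i
      }
      lv(t, j) = best + lg(allprobs(t, j));
      bp(t, j) = arg;
    }
  }
  IntegerVector path(n);
  int arg = 0;
  for (int j = 1; j < N; ++j) if (lv(n - 1, j) > lv(n - 1, arg)) arg = j;
  path[n - 1] = arg + 1;
  for (int t = n - 1; t > 0; --t) {
    arg = bp(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}

// Full negative log-likelihood with emission densities computed inline
// (gamma step lengths with optional zero mass, von Mises angles, NA
// angles contributing 1). The caller precomputes log(steps) and
// cos/sin(angles) once per fit; this is the optimiser's inner loop.
// [[Rcpp::export]]
double hmm_nll_cpp(const NumericVector& steps, const NumericVector& lsteps,
                   const NumericVector& cosang, const NumericVector& sinang,
                   const NumericVector& step_mean,
                   const NumericVector& step_sd,
                   const NumericVector& angle_mean,
                   const NumericVector& angle_kappa,
                   const NumericMatrix& trans, const NumericVector& delta,
                   const NumericVector& zero_mass) {
  const int n = steps.size(), N = step_mean.size();
  std::vector<double> sh1(N), inv_scale(N), lnorm(N), kcos(N), ksin(N),
      vmc(N);
  for (int j = 0; j < N; ++j) {
    const double shape = (step_mean[j] / step_sd[j]) *
                         (step_mean[j] / step_sd[j]);
    const double scale = step_sd[j] * step_sd[j] / step_mean[j];
    sh1[j] = shape - 1.0;
    inv_scale[j] = 1.0 / scale;
    lnorm[j] = -shape * std::log(scale) - R::lgammafn(shape) +
               std::log1p(-zero_mass[j]);
    kcos[j] = angle_kappa[j] * std::cos(angle_mean[j]);
    ksin[j] = angle_kappa[j] * std::sin(angle_mean[j]);
    // log of 2*pi*I0(kappa), via the exponentially scaled Bessel function
    vmc[j] = std::log(2.0 * M_PI *
                      R::bessel_i(angle_kappa[j], 0.0, 2.0)) +
             angle_kappa[j];
  }
  std::vector<double> v(N), w(N), e(N);
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const double st = steps[t];
    const bool has_step = !NumericVector::is_na(st);
    const bool has_ang = !NumericVector::is_na(cosang[t]);
    for (int j = 0; j < N; ++j) {
      double lp = 0.0;
      bool zero = false;
      if (has_step) {
        if (st == 0.0) zero = true;
        else lp += sh1[j] * lsteps[t] - st * inv_scale[j] + lnorm[j];
      }
      if (has_ang)
        lp += kcos[j] * cosang[t] + ksin[j] * sinang[t] - vmc[j];
      e[j] = zero ? zero_mass[j] *
                    (has_ang ? std::exp(kcos[j] * cosang[t] +
                                        ksin[j] * sinang[t] - vmc[j]) : 1.0)
                  : std::exp(lp);
    }
    double s = 0.0;
    if (t == 0) {
      for (int j = 0; j < N; ++j) { v[j] = delta[j] * e[j]; s += v[j]; }
    } else {
      for (int j = 0; j < N; ++j) {
        double a = 0.0;
        for (int i = 0; i < N; ++i) a += v[i] * trans(i, j);
        w[j] = a * e[j];
        s += w[j];
      }
      for (int j = 0; j < N; ++j) v[j] = w[j];
    }
    if (s <= 0.0 || !R_finite(s)) return 1e10;
    for (int j = 0; j < N; ++j) v[j] /= s;
    ll += std::log(s);
  }
  return -ll;
}
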