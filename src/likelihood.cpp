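#include <Rcpp.h>
using namespace Rcpp;

// Gaussian likelihood of the 5-PL mean curve and its gradient with
// respect to the per-participant curve parameters and sigma.
// pid is 1-based; B is the effective slope (covariate-adjusted).
// [[Rcpp::export(name = ".fivepl_lik_grad")]]
List fivepl_lik_grad(NumericVector y, NumericVector lx, IntegerVector pid,
                     NumericVector a, NumericVector B, NumericVector c,
                     NumericVector d, NumericVector g, double sigma) {
  int N = y.size(), P = a.size();
  NumericVector ga(P), gd(P), gB(P), gc(P), gg(P), lc(P);
  for (int i = 0; i < P; i++) lc[i] = std::log(c[i]);
  double ss = 0.0;
  double s2 = sigma * sigma;
  for (int n = 0; n < N; n++) {
    int i = pid[n] - 1;
    double lr = lx[n] - lc[i];
    double e1 = B[i] * lr;
    if (e1 > 690.0) e1 = 690.0;
    double w = std::exp(e1);
    double lt = std::log1p(w);
    double q = std::exp(-g[i] * lt);
    double ad = a[i] - d[i];
    double mu = d[i] + ad * q;
    double r = y[n] - mu;
    ss += r * r;
    double e = r / s2;
    double t = 1.0 + w;
    double common = e * ad * q * w / t;
    ga[i] += e * q;
    gd[i] += e * (1.0 - q);
    gB[i] += -common * g[i] * lr;
    gc[i] += common * g[i] * B[i] / c[i];
    gg[i] += -e * ad * q * lt;
  }
  double lp = -ss / (2.0 * s2) - N * std::log(sigma);
  double gsigma = ss / (s2 * sigma) - N / sigma;
  return List::create(_["lp"] = lp, _["ga"] = ga, _["gd"] = gd,
                      _["gB"] = gB, _["gc"] = gc, _["gg"] = gg,
                      _["gsigma"] = gsigma);
}

// Gaussian likelihood of the linear mean b*x + a and its gradient.
// [[Rcpp::export(name = ".linear_lik_grad")]]
List linear_lik_grad(NumericVector y, NumericVector x, IntegerVector pid,
                     NumericVector a, NumericVector b, double sigma) {
  int N = y.size(), P = a.size();
  NumericVector ga(P), gb(P);
  double ss = 0.0;
  double s2 = sigma * sigma;
  for (int n = 0; n < N; n++) {
    int i = pid[n] - 1;
    double r = y[n] - (b[i] * x[n] + a[i]);
    ss += r * r;
    double e = r / s2;
    ga[i] += e;
    gb[i] += e * x[n];
  }
  double lp = -ss / (2.0 * s2) - N * std::log(sigma);
  double gsigma = ss / (s2 * sigma) - N / sigma;
  return List::create(_["lp"] = lp, _["ga"] = ga, _["gb"] = gb,
                      _["gsigma"] = gsigma);
}
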