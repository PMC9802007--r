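#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// log I0(z), stable for large |z| (I0 is even).  Abramowitz & Stegun
// 9.8.1/9.8.2 polynomial approximations, |relative error| < 2e-7 --
// far below the quadrature tolerances used here and ~50x faster than the
// library Bessel call, which dominates the sampler's inner loop.
static inline double log_i0(double z) {
  double x = std::fabs(z);
  if (x < 3.75) {
    double t = x / 3.75, t2 = t * t;
    double p = 1.0 + t2 * (3.5156229 + t2 * (3.0899424 + t2 * (1.2067492 +
               t2 * (0.2659732 + t2 * (0.0360768 + t2 * 0.0045813)))));
    return std::log(p);
  }
  double t = 3.75 / x;
  double p = 0.39894228 + t * (0.01328592 + t * (0.00225319 +
             t * (-0.00157565 + t * (0.00916281 + t * (-0.02057706 +
             t * (0.02635537 + t * (-0.01647633 + t * 0.00392377)))))));
  return x - 0.5 * std::log(x) + std::log(p);
}

// log 1F1(1/2; 3/2; diag(l1, l2, l3)) through the sphere-integral identity
//   1F1 = (1/4pi) \oint exp(x' X x) dx
// with the azimuthal integral done exactly (modified Bessel I0) and the
// polar integral by Gauss-Legendre quadrature on u = cos(theta):
//   1F1 = 1/2 \int_{-1}^{1} exp(l3 u^2 + (1-u^2)(l1+l2)/2)
//                           I0((1-u^2)(l1-l2)/2) du
// Accuracy is best when the largest eigenvalue sits on the polar axis,
// where Legendre nodes cluster; callers must pass l3 = max eigenvalue.
static double log_hyp1f1_diag(double l1, double l2, double l3,
                              const double* u, const double* w, int n) {
  double m = 0.5 * (l1 + l2), h = 0.5 * (l1 - l2);
  std::vector<double> li(n);
  double M = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double u2 = u[i] * u[i], s2 = 1.0 - u2;
    double e = l3 * u2 + s2 * m + log_i0(s2 * h);
    li[i] = e;
    if (e > M) M = e;
  }
  double acc = 0.0;
  for (int i = 0; i < n; ++i) acc += w[i] * std::exp(li[i] - M);
  return M + std::log(0.5 * acc);
}

// [[Rcpp::export]]
NumericVector logHyp1f1EigsCpp(NumericMatrix lam,
                               NumericVector nodes, NumericVector weights) {
  int V = lam.nrow(), n = nodes.size();
  NumericVector out(V);
  for (int v = 0; v < V; ++v) {
    double a = lam(v, 0), b = lam(v, 1), c = lam(v, 2);
    if (a > c) std::swap(a, c);
    if (b > c) std::swap(b, c);
    out[v] = log_hyp1f1_diag(a, b, c, nodes.begin(), weights.begin(), n);
  }
  return out;
}

// Per-volume log of the dispersed-stick attenuation ratio
//   log[ 1F1(1/2;3/2; kappa mu mu' - bd g g') / 1F1(1/2;3/2; kappa mu mu') ]
// The argument is rank-2 with eigenvalues (lp, lm, 0) where
//   lp + lm = kappa - bd,  lp * lm = -kappa * bd * (1 - t^2),  t = mu . g.
// ct2 holds t^2 per volume; bd = b * d_par per volume.
// [[Rcpp::export]]
NumericVector watsonStickLogRatioCpp(double kappa, NumericVector bd,
                                     NumericVector ct2,
                                     NumericVector nodes,
                                     NumericVector weights) {
  int V = bd.size(), n = nodes.size();
  double lognorm = log_hyp1f1_diag(0.0, 0.0, kappa,
                                   nodes.begin(), weights.begin(), n);
  NumericVector out(V);
  for (int v = 0; v < V; ++v) {
    double beta = bd[v];
    if (beta <= 0.0) { out[v] = 0.0; continue; }
    double s2 = 1.0 - ct2[v];
    if (s2 < 0.0) s2 = 0.0;
    double tr = kappa - beta;
    double disc = std::sqrt(tr * tr + 4.0 * kappa * beta * s2);
    double lp = 0.5 * (tr + disc), lm = 0.5 * (tr - disc);
    // lp >= 0 >= lm always, so lp is the polar eigenvalue
    out[v] = log_hyp1f1_diag(lm, 0.0, lp,
                             nodes.begin(), weights.begin(), n) - lognorm;
  }
  return out;
}

// Residual sum of squares of the ratio model over a parameter grid.
// ratio: V x G attenuation ratios (per unit sbar); shell: 0-based shell
// index per volume; sbar: S x C corrected shell means, one column per
// noise-parameter combination; cvals/evals: offset and Rician scale per
// combination; Y: observed signal. Returns G x C RSS.
// [[Rcpp::export]]
NumericMatrix gridRssCpp(NumericMatrix ratio, IntegerVector shell,
                         NumericMatrix sbar, NumericVector cvals,
                         NumericVector evals, NumericVector Y,
                         bool rician) {
  int V = ratio.nrow(), G = ratio.ncol(), C = cvals.size();
  NumericMatrix rss(G, C);
  for (int c = 0; c < C; ++c) {
    double cc = cvals[c], ee = evals[c];
    for (int g = 0; g < G; ++g) {
      double acc = 0.0;
      for (int v = 0; v < V; ++v) {
        double pred = sbar(shell[v], c) * ratio(v, g) + cc;
        if (rician) pred = std::sqrt(pred * pred + ee * ee);
        double r = pred - Y[v];
        acc += r * r;
      }
      rss(g, c) = acc;
    }
  }
  return rss;
}
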