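#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double softThreshold(double x, double lambda) {
  if (x > lambda) return x - lambda;
  if (x < -lambda) return x + lambda;
  return 0.0;
}

// Block coordinate-descent graphical lasso (Friedman-style): cycles over
// columns of the working covariance W, solving each column's lasso
// subproblem by inner coordinate descent with incrementally maintained
// residuals. Only off-diagonal precision entries are penalised, so
// diag(W) stays equal to diag(S) throughout.
// [[Rcpp::export(name = ".glassoCd")]]
List glassoCd(NumericMatrix S, double lambda, int maxIter, double tol,
              int innerMax = 200, double innerTol = 1e-8) {
  const int p = S.nrow();
  NumericMatrix Wm(p, p), Bm(p, p);
  double *W = Wm.begin(), *B = Bm.begin();
  const double *Sp = S.begin();
  for (int i = 0; i < p * p; ++i) W[i] = Sp[i];

  // convergence threshold on the average absolute change of w12 entries,
  // scaled by the average absolute off-diagonal of S (glasso convention)
  double sbar = 0.0;
  if (p > 1) {
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (i != j) sbar += std::fabs(Sp[i + p * j]);
    sbar /= (double)(p * (p - 1));
  }
  double thresh = tol * (sbar > 0 ? sbar : 1.0);

  std::vector<double> r(p);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= maxIter; ++iter) {
    double sweepChange = 0.0;
    for (int j = 0; j < p; ++j) {
      double *Bj = B + (size_t)p * j;
      // residual r_k = s12_k - (W11 beta)_k for k != j
      for (int k = 0; k < p; ++k) {
        if (k == j) { r[k] = 0.0; continue; }
        double acc = Sp[k + p * j];
        const double *Wk = W + k;  // row k, strided access
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          double b = Bj[l];
          if (b != 0.0) acc -= Wk[(size_t)p * l] * b;
        }
        r[k] = acc;
      }
      // inner lasso for column j: minimise over beta
      //   1/2 beta' W11 beta - beta' s12 + lambda |beta|_1
      for (int it = 0; it < innerMax; ++it) {
        double maxDelta = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double wkk = W[k + p * k];
          double num = r[k] + wkk * Bj[k];
          double bNew = softThreshold(num, lambda) / wkk;
          double d = bNew - Bj[k];
          if (d != 0.0) {
            double ad = std::fabs(d);
            if (ad > maxDelta) maxDelta = ad;
            const double *Wk = W + (size_t)p * k;  // column k
            for (int l = 0; l < p; ++l)
              if (l != j) r[l] -= Wk[l] * d;
            Bj[k] = bNew;
          }
        }
        if (maxDelta < innerTol) break;
      }
      // w12 = W11 beta
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double wkj = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          double b = Bj[l];
          if (b != 0.0) wkj += W[k + (size_t)p * l] * b;
        }
        sweepChange += std::fabs(wkj - W[k + (size_t)p * j]);
        W[k + (size_t)p * j] = wkj;
        W[j + (size_t)p * k] = wkj;
      }
    }
    if (p > 1) sweepChange /= (double)(p * (p - 1));
    if (sweepChange < thresh) { converged = true; break; }
  }
  if (iter > maxIter) iter = maxIter;

  // recover Theta from the final (W, B):
  //   theta_jj = 1 / (w_jj - w12' beta_j), theta_12 = -beta_j * theta_jj
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double denom = W[j + (size_t)p * j];
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      denom -= W[k + (size_t)p * j] * B[k + (size_t)p * j];
    }
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -B[k + (size_t)p * j] * tjj;
    }
  }
  // symmetrise (the two column solves of a pair agree at convergence)
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      double m = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = m;
      Theta(j, i) = m;
    }

  return List::create(_["precision"] = Theta, _["covariance"] = Wm,
                      _["converged"] = converged, _["iterations"] = iter);
}
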