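#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Conditional Gaussian kernel row with entropy matched to log(perplexity)
// via bisection on the precision beta. D2 is the squared-distance matrix.
// Returns the joint, symmetrized probability matrix P (sums to 1).
// [[Rcpp::export]]
NumericMatrix cpp_perplexity_probs(const NumericMatrix& D2, double perplexity,
                                   int max_iter = 50, double tol = 1e-5) {
  const int n = D2.nrow();
  NumericMatrix P(n, n);
  const double logU = std::log(perplexity);

  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = R_NegInf, betamax = R_PosInf;
    std::vector<double> pr(n);
    for (int it = 0; it < max_iter; ++it) {
      double sum = 0.0;
      for (int j = 0; j < n; ++j) {
        pr[j] = (j == i) ? 0.0 : std::exp(-D2(i, j) * beta);
        sum += pr[j];
      }
      if (sum <= 0) sum = DBL_MIN;
      // H = log(sum) + beta * <D2>_p
      double dsum = 0.0;
      for (int j = 0; j < n; ++j) dsum += D2(i, j) * pr[j];
      double H = std::log(sum) + beta * dsum / sum;
      double diff = H - logU;
      if (std::fabs(diff) < tol) {
        for (int j = 0; j < n; ++j) pr[j] /= sum;
        break;
      }
      if (diff > 0) {  // entropy too high -> increase beta
        betamin = beta;
        beta = R_finite(betamax) ? (beta + betamax) / 2.0 : beta * 2.0;
      } else {
        betamax = beta;
        beta = R_finite(betamin) ? (beta + betamin) / 2.0 : beta / 2.0;
      }
      if (it == max_iter - 1) for (int j = 0; j < n; ++j) pr[j] /= sum;
      sum = 0.0;  // recompute next round
    }
    for (int j = 0; j < n; ++j) P(i, j) = pr[j];
  }

  // symmetrize and normalize to a joint distribution
  double tot = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) tot += P(i, j);
  NumericMatrix Psym(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = (P(i, j) + P(j, i)) / (2.0 * tot);
      Psym(i, j) = std::max(v, 1e-12);
    }
  return Psym;
}

// Gradient-descent loop of exact (dense) t-SNE with early exaggeration,
// momentum switching and adaptive per-parameter gains. Y0 supplies the
// (seeded) initial configuration, so all randomness stays on the R side.
// [[Rcpp::export]]
NumericMatrix cpp_tsne_iterate(const NumericMatrix& P, const NumericMatrix& Y0,
                               int n_iter = 500, double eta = 200.0,
                               double exaggeration = 12.0, int exag_iter = 100,
                               double mom_init = 0.5, double mom_final = 0.8,
                               int mom_switch = 250, double min_gain = 0.01) {
  const int n = Y0.nrow(), d = Y0.ncol();
  std::vector<double> Y(n * d), dY(n * d, 0.0), iY(n * d, 0.0), gains(n * d, 1.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) Y[i * d + k] = Y0(i, k);

  std::vector<double> num(n * n);

  for (int iter = 0; iter < n_iter; ++iter) {
    const double exag = (iter < exag_iter) ? exaggeration : 1.0;
    const double mom = (iter < mom_switch) ? mom_init : mom_final;

    // Student-t kernel q_ij = 1 / (1 + ||y_i - y_j||^2)
    double qsum = 0.0;
    for (int i = 0; i < n; ++i) {
      num[i * n + i] = 0.0;
      for (int j = i + 1; j < n; ++j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double diff = Y[i * d + k] - Y[j * d + k];
          s += diff * diff;
        }
        double q = 1.0 / (1.0 + s);
        num[i * n + j] = q;
        num[j * n + i] = q;
        qsum += 2.0 * q;
      }
    }
    if (qsum < DBL_MIN) qsum = DBL_MIN;

    // gradient: 4 * sum_j (exag*P_ij - Q_ij) * q_ij * (y_i - y_j)
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < d; ++k) dY[i * d + k] = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double q = num[i * n + j];
        double mult = (exag * P(i, j) - q / qsum) * q;
        for (int k = 0; k < d; ++k)
          dY[i * d + k] += 4.0 * mult * (Y[i * d + k] - Y[j * d + k]);
      }
    }

    for (int m = 0; m < n * d; ++m) {
      gains[m] = ((dY[m] > 0) != (iY[m] > 0)) ? gains[m] + 0.2 : gains[m] * 0.8;
      if (gains[m] < min_gain) gains[m] = min_gain;
      iY[m] = mom * iY[m] - eta * gains[m] * dY[m];
      Y[m] += iY[m];
    }

    // recentre
    for (int k = 0; k < d; ++k) {
      double mean = 0.0;
      for (int i = 0; i < n; ++i) mean += Y[i * d + k];
      mean /= n;
      for (int i = 0; i < n; ++i) Y[i * d + k] -= mean;
    }
  }

  NumericMatrix out(n, d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) out(i, k) = Y[i * d + k];
  return out;
}
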