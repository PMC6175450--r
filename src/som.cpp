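#include <Rcpp.h>
using namespace Rcpp;

// Squared Euclidean distance between row g of X and row s of W.
static inline double row_dist2(const NumericMatrix& X, int g,
                               const NumericMatrix& W, int s) {
  double d = 0.0;
  for (int t = 0; t < X.ncol(); ++t) {
    double diff = X(g, t) - W(s, t);
    d += diff * diff;
  }
  return d;
}

static inline int best_node(const NumericMatrix& X, int g,
                            const NumericMatrix& W) {
  int best = 0;
  double bd = R_PosInf;
  for (int s = 0; s < W.nrow(); ++s) {
    double d = row_dist2(X, g, W, s);
    if (d < bd) { bd = d; best = s; }
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_assign_bmu(NumericMatrix X, NumericMatrix W) {
  IntegerVector out(X.nrow());
  for (int g = 0; g < X.nrow(); ++g) out[g] = best_node(X, g, W) + 1;
  return out;
}

// [[Rcpp::export]]
double cpp_quantization_error(NumericMatrix X, NumericMatrix W) {
  double tot = 0.0;
  for (int g = 0; g < X.nrow(); ++g) {
    tot += std::sqrt(row_dist2(X, g, W, best_node(X, g, W)));
  }
  return tot / X.nrow();
}

// Online Kohonen training on a rows x cols rectangular grid with a
// Gaussian neighbourhood. The learning rate and neighbourhood radius both
// decay linearly over the run. Samples are drawn with R's RNG so the
// result is reproducible under set.seed(). Returns the trained codebook
// with the quantization error recorded at ~10 checkpoints as attribute.
// [[Rcpp::export]]
NumericMatrix cpp_som_train(NumericMatrix X, NumericMatrix init,
                            int rows, int cols, int n_iter,
                            double alpha0, double alpha1,
                            double r0, double r1) {
  int S = rows * cols, T = X.ncol(), n = X.nrow();
  if (init.nrow() != S || init.ncol() != T)
    stop("init codebook has wrong dimensions");
  NumericMatrix W = clone(init);
  RNGScope scope;
  NumericVector qe(11);
  int n_check = 0;
  int check_every = n_iter > 10 ? n_iter / 10 : 1;
  qe[n_check++] = cpp_quantization_error(X, W);
  for (int it = 0; it < n_iter; ++it) {
    double frac = n_iter > 1 ? (double)it / (double)(n_iter - 1) : 1.0;
    double alpha = alpha0 + (alpha1 - alpha0) * frac;
    double radius = r0 + (r1 - r0) * frac;
    if (radius < 1e-9) radius = 1e-9;
    int g = (int)std::floor(unif_rand() * n);
    if (g >= n) g = n - 1;
    int bmu = best_node(X, g, W);
    int br = bmu / cols, bc = bmu % cols;
    double denom = 2.0 * radius * radius;
    for (int s = 0; s < S; ++s) {
      int sr = s / cols, sc = s % cols;
      double gd2 = (double)((sr - br) * (sr - br) + (sc - bc) * (sc - bc));
      if (gd2 > 9.0 * radius * radius) continue; // negligible update
      double h = std::exp(-gd2 / denom);
      double ah = alpha * h;
      for (int t = 0; t < T; ++t) W(s, t) += ah * (X(g, t) - W(s, t));
    }
    if ((it + 1) % check_every == 0 && n_check < 11)
      qe[n_check++] = cpp_quantization_error(X, W);
  }
  W.attr("qe") = qe[Range(0, n_check - 1)];
  return W;
}

// Resampling loop: for each gene, B Gaussian draws around its raw trace
// (per-timepoint spread from SD), each draw re-normalized to mean 0 /
// population variance 1 and assigned to its nearest codebook vector.
// Returns per-gene counts over nodes; every row sums to B. Draws that
// come out constant (unnormalizable) are re-drawn.
// [[Rcpp::export]]
IntegerMatrix cpp_resample_counts(NumericMatrix X, NumericMatrix SD,
                                  NumericMatrix W, int B) {
  int n = X.nrow(), T = X.ncol(), S = W.nrow();
  if (T == 0) stop("zero-length trace");
  if (SD.nrow() != n || SD.ncol() != T) stop("SD matrix shape mismatch");
  IntegerMatrix counts(n, S);
  RNGScope scope;
  std::vector<double> y(T);
  for (int g = 0; g < n; ++g) {
    for (int b = 0; b < B; ++b) {
      double var = 0.0;
      int tries = 0;
      do {
        double mean = 0.0;
        for (int t = 0; t < T; ++t) {
          y[t] = X(g, t) + SD(g, t) * norm_rand();
          mean += y[t];
        }
        mean /= T;
        var = 0.0;
        for (int t = 0; t < T; ++t) {
          y[t] -= mean;
          var += y[t] * y[t];
        }
        var /= T;
        if (++tries > 100) stop("constant trace cannot be resampled");
      } while (var <= 0.0);
      double sdv = std::sqrt(var);
      int best = 0;
      double bd = R_PosInf;
      for (int s = 0; s < S; ++s) {
        double d = 0.0;
        for (int t = 0; t < T; ++t) {
          double diff = y[t] / sdv - W(s, t);
          d += diff * diff;
        }
        if (d < bd) { bd = d; best = s; }
      }
      counts(g, best) += 1;
    }
  }
  return counts;
}
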