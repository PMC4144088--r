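#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for an HMM whose step-t transition matrix is
//   A_t = w_t * I + (1 - w_t) * P,   w_t = exp(-d_t / D),
// run over possibly several independent chains (chromosomes), each
// re-initialized from pi where chain_start is true.
//
// logB: T x M log emission densities; w: length T (entry at a chain start
// is ignored); P: M x M baseline transition matrix; pi: length M.
//
// Returns loglik, gamma (T x M), xi_sums (M x M expected transition
// counts), and pstar_sums (M x M expected counts attributed to the
// baseline-P draw of the stay/move mixture, used for the P update).
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logB, NumericVector w, NumericMatrix P,
            NumericVector pi, LogicalVector chain_start) {
  const int T = logB.nrow(), M = logB.ncol();
  NumericMatrix B(T, M);          // shifted emissions
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double mx = logB(t, 0);
    for (int j = 1; j < M; ++j) if (logB(t, j) > mx) mx = logB(t, j);
    shift[t] = mx;
    for (int j = 0; j < M; ++j) B(t, j) = std::exp(logB(t, j) - mx);
  }

  NumericMatrix alpha(T, M), beta(T, M), gamma(T, M);
  NumericVector c(T);
  double loglik = 0.0;

  // forward
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    if (chain_start[t]) {
      for (int j = 0; j < M; ++j) { alpha(t, j) = pi[j] * B(t, j); s += alpha(t, j); }
    } else {
      const double wt = w[t], mt = 1.0 - wt;
      for (int j = 0; j < M; ++j) {
        double a = wt * alpha(t - 1, j);
        for (int i = 0; i < M; ++i) a += mt * alpha(t - 1, i) * P(i, j);
        alpha(t, j) = a * B(t, j);
        s += alpha(t, j);
      }
    }
    if (s <= 0.0 || !R_finite(s)) stop("forward recursion underflow at position %d", t + 1);
    c[t] = s;
    for (int j = 0; j < M; ++j) alpha(t, j) /= s;
    loglik += std::log(s) + shift[t];
  }

  // backward (scaled by the forward constants)
  for (int t = T - 1; t >= 0; --t) {
    if (t == T - 1 || chain_start[t + 1]) {
      for (int j = 0; j < M; ++j) beta(t, j) = 1.0;
    } else {
      const double wt = w[t + 1], mt = 1.0 - wt;
      for (int i = 0; i < M; ++i) {
        double b = wt * B(t + 1, i) * beta(t + 1, i);
        for (int j = 0; j < M; ++j) b += mt * P(i, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, i) = b / c[t + 1];
      }
    }
  }

  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int j = 0; j < M; ++j) { gamma(t, j) = alpha(t, j) * beta(t, j); s += gamma(t, j); }
    for (int j = 0; j < M; ++j) gamma(t, j) /= s;
  }

  // expected transition statistics
  NumericMatrix xi_sums(M, M), pstar_sums(M, M);
  for (int t = 1; t < T; ++t) {
    if (chain_start[t]) continue;
    const double wt = w[t], mt = 1.0 - wt;
    for (int i = 0; i < M; ++i) {
      for (int j = 0; j < M; ++j) {
        double aij = mt * P(i, j) + (i == j ? wt : 0.0);
        double xi = alpha(t - 1, i) * aij * B(t, j) * beta(t, j) / c[t];
        xi_sums(i, j) += xi;
        double r = (aij > 0.0) ? mt * P(i, j) / aij : 0.0;
        pstar_sums(i, j) += xi * r;
      }
    }
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sums"] = xi_sums, _["pstar_sums"] = pstar_sums);
}

// Viterbi decoding for the same non-homogeneous model; log space, ties
// broken toward the lower state index, chains restart from pi.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericVector w, NumericMatrix P,
                          NumericVector pi, LogicalVector chain_start) {
  const int T = logB.nrow(), M = logB.ncol();
  NumericMatrix delta(T, M);
  IntegerMatrix psi(T, M);
  const double NEG = -std::numeric_limits<double>::infinity();

  for (int t = 0; t < T; ++t) {
    if (chain_start[t]) {
      for (int j = 0; j < M; ++j)
        delta(t, j) = (pi[j] > 0.0 ? std::log(pi[j]) : NEG) + logB(t, j);
    } else {
      const double wt = w[t], mt = 1.0 - wt;
      for (int j = 0; j < M; ++j) {
        double best = NEG; int arg = 0;
        for (int i = 0; i < M; ++i) {
          double aij = mt * P(i, j) + (i == j ? wt : 0.0);
          double cand = delta(t - 1, i) + (aij > 0.0 ? std::log(aij) : NEG);
          if (cand > best) { best = cand; arg = i; }
        }
        delta(t, j) = best + logB(t, j);
        psi(t, j) = arg;
      }
    }
  }

  IntegerVector path(T);
  for (int t = T - 1; t >= 0; --t) {
    if (t == T - 1 || chain_start[t + 1]) {
      double best = NEG; int arg = 0;
      for (int j = 0; j < M; ++j) if (delta(t, j) > best) { best = delta(t, j); arg = j; }
      path[t] = arg + 1;
    } else {
      path[t] = psi(t + 1, path[t + 1] - 1) + 1;
    }
  }
  return path;
}
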