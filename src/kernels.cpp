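#include <Rcpp.h>
using namespace Rcpp;

// Elementwise-max neighbour aggregation over a directed edge list.
// out(i, f) = max over edges e with dst[e] == i of X(src[e], f); rows with
// no incoming edge stay 0 and get argmax 0. argmax stores the 1-based source
// row index so the backward pass can scatter gradients exactly.
// [[Rcpp::export]]
List edge_max_fwd(IntegerVector src, IntegerVector dst,
                  NumericMatrix X, int n) {
  int F = X.ncol(), E = src.size();
  NumericMatrix out(n, F);
  IntegerMatrix arg(n, F);
  std::vector<char> has(n, 0);
  for (int e = 0; e < E; ++e) {
    int i = dst[e] - 1, j = src[e] - 1;
    if (!has[i]) {
      for (int f = 0; f < F; ++f) { out(i, f) = X(j, f); arg(i, f) = j + 1; }
      has[i] = 1;
    } else {
      for (int f = 0; f < F; ++f) {
        if (X(j, f) > out(i, f)) { out(i, f) = X(j, f); arg(i, f) = j + 1; }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// Backward of edge_max_fwd: route each output gradient to the source row
// that achieved the max.
// [[Rcpp::export]]
NumericMatrix edge_max_bwd(IntegerMatrix arg, NumericMatrix grad, int nsrc) {
  int n = arg.nrow(), F = arg.ncol();
  NumericMatrix dX(nsrc, F);
  for (int i = 0; i < n; ++i) {
    for (int f = 0; f < F; ++f) {
      int j = arg(i, f);
      if (j > 0) dX(j - 1, f) += grad(i, f);
    }
  }
  return dX;
}

// Per-group column-wise maximum (for numerically stable segment softmax).
// group is 1-based; empty groups give -Inf.
// [[Rcpp::export]]
NumericMatrix seg_max_mat(NumericMatrix val, IntegerVector group, int n) {
  int E = val.nrow(), H = val.ncol();
  NumericMatrix out(n, H);
  std::fill(out.begin(), out.end(), R_NegInf);
  for (int e = 0; e < E; ++e) {
    int g = group[e] - 1;
    for (int h = 0; h < H; ++h) {
      if (val(e, h) > out(g, h)) out(g, h) = val(e, h);
    }
  }
  return out;
}

// Per-group column-wise sum: out(g, h) = sum over rows e with group[e] == g.
// [[Rcpp::export]]
NumericMatrix seg_sum_mat(NumericMatrix val, IntegerVector group, int n) {
  int E = val.nrow(), H = val.ncol();
  NumericMatrix out(n, H);
  for (int e = 0; e < E; ++e) {
    int g = group[e] - 1;
    for (int h = 0; h < H; ++h) out(g, h) += val(e, h);
  }
  return out;
}

// Block of a pairwise Minkowski distance matrix:
// D(i, j) = (sum_f |Xb(i,f) - X(j,f)|^p)^(1/p). p = 1 and p = 2 use exact
// closed forms (Manhattan / Euclidean).
// [[Rcpp::export]]
NumericMatrix minkowski_block(NumericMatrix Xb, NumericMatrix X, double p) {
  int nb = Xb.nrow(), n = X.nrow(), F = X.ncol();
  NumericMatrix D(nb, n);
  for (int i = 0; i < nb; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0;
      if (p == 1.0) {
        for (int f = 0; f < F; ++f) s += std::fabs(Xb(i, f) - X(j, f));
        D(i, j) = s;
      } else if (p == 2.0) {
        for (int f = 0; f < F; ++f) {
          double d = Xb(i, f) - X(j, f);
          s += d * d;
        }
        D(i, j) = std::sqrt(s);
      } else {
        for (int f = 0; f < F; ++f) {
          s += std::pow(std::fabs(Xb(i, f) - X(j, f)), p);
        }
        D(i, j) = std::pow(s, 1.0 / p);
      }
    }
  }
  return D;
}
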