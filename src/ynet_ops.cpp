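// Low-level 1D network operations used by the Y-Net implementation.
// Tensors are arma::cube with layout (channels, length, batch); convolutions
// use same-(zero)padding and are realised as im2col + GEMM so the heavy
// lifting is done by BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col: (C_in*k, L*B); row index = tap*C_in + c, column index = b*L + l
static mat im2col1d(const cube& X, const int k) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int pad = (k - 1) / 2;
  mat out(C * k, (size_t)L * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& Xb = X.slice(b);
    for (int tap = 0; tap < k; ++tap) {
      const int off = tap - pad;
      const int l0 = std::max(0, -off), l1 = std::min(L, L - off);
      if (l1 <= l0) continue;
      // columns l0..l1-1 take input positions l+off
      out.submat(tap * C, (size_t)b * L + l0, tap * C + C - 1,
                 (size_t)b * L + l1 - 1) = Xb.cols(l0 + off, l1 - 1 + off);
    }
  }
  return out;
}

static void col2im1d(const mat& cols, cube& dX, const int k) {
  const int C = dX.n_rows, L = dX.n_cols, B = dX.n_slices;
  const int pad = (k - 1) / 2;
  for (int b = 0; b < B; ++b) {
    mat& Db = dX.slice(b);
    for (int tap = 0; tap < k; ++tap) {
      const int off = tap - pad;
      const int l0 = std::max(0, -off), l1 = std::min(L, L - off);
      if (l1 <= l0) continue;
      Db.cols(l0 + off, l1 - 1 + off) +=
        cols.submat(tap * C, (size_t)b * L + l0, tap * C + C - 1,
                    (size_t)b * L + l1 - 1);
    }
  }
}

// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::mat& W,
                      const arma::vec& b, const int k) {
  const int L = X.n_cols, B = X.n_slices, Cout = W.n_rows;
  mat cols = im2col1d(X, k);
  mat Y2 = W * cols;              // (Cout, L*B)
  Y2.each_col() += b;
  cube Y(Cout, L, B);
  for (int s = 0; s < B; ++s)
    Y.slice(s) = Y2.cols((size_t)s * L, (size_t)(s + 1) * L - 1);
  return Y;
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
Rcpp::List conv1d_bwd(const arma::cube& X, const arma::mat& W,
                      const arma::cube& dY, const int k) {
  const int L = X.n_cols, B = X.n_slices, Cout = W.n_rows;
  mat dY2(Cout, (size_t)L * B);
  for (int s = 0; s < B; ++s)
    dY2.cols((size_t)s * L, (size_t)(s + 1) * L - 1) = dY.slice(s);
  mat cols = im2col1d(X, k);
  mat dW = dY2 * cols.t();
  vec db = sum(dY2, 1);
  mat dcols = W.t() * dY2;
  cube dX(X.n_rows, L, B, fill::zeros);
  col2im1d(dcols, dX, k);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
Rcpp::List maxpool_fwd(const arma::cube& X, const int f) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Lo = L / f;
  cube Y(C, Lo, B);
  ucube idx(C, Lo, B);            // winning offset within each window
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < Lo; ++l) {
      for (int c = 0; c < C; ++c) {
        double best = X(c, l * f, b); uword bi = 0;
        for (int o = 1; o < f; ++o) {
          const double v = X(c, l * f + o, b);
          if (v > best) { best = v; bi = o; }
        }
        Y(c, l, b) = best; idx(c, l, b) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::cube maxpool_bwd(const arma::cube& dY, const arma::ucube& idx,
                       const int f, const int L) {
  const int C = dY.n_rows, Lo = dY.n_cols, B = dY.n_slices;
  cube dX(C, L, B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < Lo; ++l)
      for (int c = 0; c < C; ++c)
        dX(c, l * f + idx(c, l, b), b) += dY(c, l, b);
  return dX;
}

// linear x2 upsampling: y[2i] = x[i]; y[2i+1] = (x[i]+x[i+1])/2, last repeated
// [[Rcpp::export(name = ".upsample_fwd")]]
arma::cube upsample_fwd(const arma::cube& X) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  cube Y(C, 2 * L, B);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      Y.slice(b).col(2 * l) = X.slice(b).col(l);
      if (l < L - 1)
        Y.slice(b).col(2 * l + 1) =
          0.5 * (X.slice(b).col(l) + X.slice(b).col(l + 1));
      else
        Y.slice(b).col(2 * l + 1) = X.slice(b).col(l);
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".upsample_bwd")]]
arma::cube upsample_bwd(const arma::cube& dY) {
  const int C = dY.n_rows, L2 = dY.n_cols, B = dY.n_slices;
  const int L = L2 / 2;
  cube dX(C, L, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      dX.slice(b).col(l) += dY.slice(b).col(2 * l);
      if (l < L - 1) {
        dX.slice(b).col(l) += 0.5 * dY.slice(b).col(2 * l + 1);
        dX.slice(b).col(l + 1) += 0.5 * dY.slice(b).col(2 * l + 1);
      } else {
        dX.slice(b).col(l) += dY.slice(b).col(2 * l + 1);
      }
    }
  }
  return dX;
}

// PReLU with one slope per channel
// [[Rcpp::export(name = ".prelu_fwd")]]
arma::cube prelu_fwd(const arma::cube& X, const arma::vec& a) {
  cube Y = X;
  const int C = X.n_rows;
  for (uword b = 0; b < X.n_slices; ++b)
    for (uword l = 0; l < X.n_cols; ++l)
      for (int c = 0; c < C; ++c)
        if (X(c, l, b) < 0) Y(c, l, b) = a(c) * X(c, l, b);
  return Y;
}

// [[Rcpp::export(name = ".prelu_bwd")]]
Rcpp::List prelu_bwd(const arma::cube& X, const arma::vec& a,
                     const arma::cube& dY) {
  cube dX = dY;
  vec da(a.n_elem, fill::zeros);
  const int C = X.n_rows;
  for (uword b = 0; b < X.n_slices; ++b)
    for (uword l = 0; l < X.n_cols; ++l)
      for (int c = 0; c < C; ++c)
        if (X(c, l, b) < 0) {
          da(c) += dY(c, l, b) * X(c, l, b);
          dX(c, l, b) = a(c) * dY(c, l, b);
        }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("da") = da);
}
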