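// Minimal CNN primitives for the T-Net: zero-padded "same" 3x3 convolution
// (arbitrary dilation), 3x3 stride-2 transposed convolution, and 2x2 max
// pooling, each with its backward pass. Tensors are H x W x C arma::cubes;
// convolution weights are (9*Cin) x Cout matrices with row index
// t*Cin + ci, where t = 3*a + b enumerates the kernel taps (a = row tap,
// b = col tap, both 0..2, centred offsets (a-1)*dilation etc.).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline void tap_bounds(int H, int off, int& i0, int& i1) {
  // output rows i with 0 <= i + off <= H-1
  i0 = std::max(0, -off);
  i1 = std::min(H - 1, H - 1 - off);
}

// [[Rcpp::export(name = "cpp_conv3_fwd")]]
arma::cube conv3_fwd(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, int dilation) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  cube y(H, Wd, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  for (int t = 0; t < 9; ++t) {
    const int a = (t / 3 - 1) * dilation, bo = (t % 3 - 1) * dilation;
    int i0, i1, j0, j1;
    tap_bounds(H, a, i0, i1);
    tap_bounds(Wd, bo, j0, j1);
    if (i1 < i0 || j1 < j0) continue;
    const int nr = i1 - i0 + 1, nc = j1 - j0 + 1, np = nr * nc;
    mat Xs(np, Cin);
    for (int ci = 0; ci < Cin; ++ci)
      Xs.col(ci) = vectorise(x.slice(ci).submat(i0 + a, j0 + bo, i1 + a, j1 + bo));
    mat Ys = Xs * W.rows(t * Cin, t * Cin + Cin - 1);
    for (int co = 0; co < Cout; ++co)
      y.slice(co).submat(i0, j0, i1, j1) += reshape(Ys.col(co), nr, nc);
  }
  return y;
}

// [[Rcpp::export(name = "cpp_conv3_bwd")]]
Rcpp::List conv3_bwd(const arma::cube& x, const arma::mat& W, int dilation,
                     const arma::cube& gy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  cube gx(H, Wd, Cin, fill::zeros);
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(Cout);
  for (int co = 0; co < Cout; ++co) gb(co) = accu(gy.slice(co));
  for (int t = 0; t < 9; ++t) {
    const int a = (t / 3 - 1) * dilation, bo = (t % 3 - 1) * dilation;
    int i0, i1, j0, j1;
    tap_bounds(H, a, i0, i1);
    tap_bounds(Wd, bo, j0, j1);
    if (i1 < i0 || j1 < j0) continue;
    const int nr = i1 - i0 + 1, nc = j1 - j0 + 1, np = nr * nc;
    mat Xs(np, Cin), Gs(np, Cout);
    for (int ci = 0; ci < Cin; ++ci)
      Xs.col(ci) = vectorise(x.slice(ci).submat(i0 + a, j0 + bo, i1 + a, j1 + bo));
    for (int co = 0; co < Cout; ++co)
      Gs.col(co) = vectorise(gy.slice(co).submat(i0, j0, i1, j1));
    gW.rows(t * Cin, t * Cin + Cin - 1) += Xs.t() * Gs;
    mat Gx = Gs * W.rows(t * Cin, t * Cin + Cin - 1).t();  // np x Cin
    for (int ci = 0; ci < Cin; ++ci)
      gx.slice(ci).submat(i0 + a, j0 + bo, i1 + a, j1 + bo) += reshape(Gx.col(ci), nr, nc);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Transposed 3x3 convolution, stride 2, "same" padding: output is
// (2H) x (2W); out(2i+a-1, 2j+b-1) += sum_ci x(i,j,ci) * W[t*Cin+ci, co].
// [[Rcpp::export(name = "cpp_convt3_fwd")]]
arma::cube convt3_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  const int Ho = 2 * H, Wo = 2 * Wd;
  cube y(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  mat Xf(H * Wd, Cin);
  for (int ci = 0; ci < Cin; ++ci) Xf.col(ci) = vectorise(x.slice(ci));
  for (int t = 0; t < 9; ++t) {
    const int a = t / 3, bo = t % 3;
    const int i0 = (a == 0) ? 1 : 0, j0 = (bo == 0) ? 1 : 0;
    mat Ys = Xf * W.rows(t * Cin, t * Cin + Cin - 1);  // (H*Wd) x Cout
    for (int co = 0; co < Cout; ++co) {
      mat& ys = y.slice(co);
      for (int j = j0; j < Wd; ++j) {
        const int oj = 2 * j + bo - 1;
        for (int i = i0; i < H; ++i)
          ys(2 * i + a - 1, oj) += Ys(i + j * H, co);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = "cpp_convt3_bwd")]]
Rcpp::List convt3_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  cube gx(H, Wd, Cin, fill::zeros);
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(Cout);
  for (int co = 0; co < Cout; ++co) gb(co) = accu(gy.slice(co));
  mat Xf(H * Wd, Cin);
  for (int ci = 0; ci < Cin; ++ci) Xf.col(ci) = vectorise(x.slice(ci));
  for (int t = 0; t < 9; ++t) {
    const int a = t / 3, bo = t % 3;
    const int i0 = (a == 0) ? 1 : 0, j0 = (bo == 0) ? 1 : 0;
    mat Gs(H * Wd, Cout, fill::zeros);
    for (int co = 0; co < Cout; ++co) {
      const mat& gys = gy.slice(co);
      for (int j = j0; j < Wd; ++j) {
        const int oj = 2 * j + bo - 1;
        for (int i = i0; i < H; ++i)
          Gs(i + j * H, co) = gys(2 * i + a - 1, oj);
      }
    }
    gW.rows(t * Cin, t * Cin + Cin - 1) += Xf.t() * Gs;
    mat Gx = Gs * W.rows(t * Cin, t * Cin + Cin - 1).t();
    for (int ci = 0; ci < Cin; ++ci)
      gx.slice(ci) += reshape(Gx.col(ci), H, Wd);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export(name = "cpp_maxpool2_fwd")]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = Wd / 2;
  cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);  // linear index within the input slice
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int r = 2 * i, cc = 2 * j;
        double best = xs(r, cc);
        uword bi = r + cc * H;
        if (xs(r + 1, cc) > best) { best = xs(r + 1, cc); bi = r + 1 + cc * H; }
        if (xs(r, cc + 1) > best) { best = xs(r, cc + 1); bi = r + (cc + 1) * H; }
        if (xs(r + 1, cc + 1) > best) { best = xs(r + 1, cc + 1); bi = r + 1 + (cc + 1) * H; }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = "cpp_maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::ucube& idx, const arma::cube& gy,
                        int H, int Wd) {
  const int C = gy.n_slices, Ho = gy.n_rows, Wo = gy.n_cols;
  cube gx(H, Wd, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& gs = gx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        gs(idx(i, j, c)) += gy(i, j, c);
  }
  return gx;
}
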