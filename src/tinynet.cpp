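// Minibatch forward/backward pass for the desk-scale IoU regression network:
// a stack of (3x3 conv, pad 1) -> ReLU -> 2x2 max-pool blocks, then global
// average pooling -> dense(256, ReLU) -> dropout -> dense(1, sigmoid).
// All randomness (weight init, shuffling, dropout masks) lives on the R side,
// so this code is purely deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a 3x3 kernel with padding 1: output is (9*C) x (H*W),
// column-major over output pixels (h fastest, matching R array layout).
static void im2col3(const cube& x, mat& cols) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cols.zeros(9 * C, H * W);
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        uword krow = c * 9 + (kj + 1) * 3 + (ki + 1);
        for (uword j = 0; j < W; ++j) {
          int sj = (int)j + kj;
          if (sj < 0 || sj >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            int si = (int)i + ki;
            if (si < 0 || si >= (int)H) continue;
            cols(krow, j * H + i) = xc((uword)si, (uword)sj);
          }
        }
      }
    }
  }
}

// adjoint of im2col3
static void col2im3(const mat& dcols, cube& dx) {
  const uword H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  dx.zeros();
  for (uword c = 0; c < C; ++c) {
    mat& dxc = dx.slice(c);
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        uword krow = c * 9 + (kj + 1) * 3 + (ki + 1);
        for (uword j = 0; j < W; ++j) {
          int sj = (int)j + kj;
          if (sj < 0 || sj >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            int si = (int)i + ki;
            if (si < 0 || si >= (int)H) continue;
            dxc((uword)si, (uword)sj) += dcols(krow, j * H + i);
          }
        }
      }
    }
  }
}

// 2x2 max pool, stride 2; records flat argmax indices into the input slice
static void maxpool2(const cube& x, cube& out, umat& amax) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  out.set_size(Ho, Wo, C);
  amax.set_size(Ho * Wo, C);
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        uword i0 = 2 * i, j0 = 2 * j;
        double best = xc(i0, j0);
        uword bi = i0, bj = j0;
        if (xc(i0 + 1, j0) > best) { best = xc(i0 + 1, j0); bi = i0 + 1; bj = j0; }
        if (xc(i0, j0 + 1) > best) { best = xc(i0, j0 + 1); bi = i0; bj = j0 + 1; }
        if (xc(i0 + 1, j0 + 1) > best) { best = xc(i0 + 1, j0 + 1); bi = i0 + 1; bj = j0 + 1; }
        out(i, j, c) = best;
        amax(j * Ho + i, c) = bj * H + bi;
      }
    }
  }
}

struct ConvCache {
  mat cols;     // im2col of the block input
  mat pre;      // pre-ReLU activations, F x (H*W)
  umat amax;    // pool argmax
  uword H, W;   // spatial dims before pooling
};

// [[Rcpp::export(name = ".tinyNetPass")]]
Rcpp::List tinyNetPass(Rcpp::NumericVector x4d,
                       Rcpp::List convW, Rcpp::List convB,
                       arma::mat fcW1, arma::vec fcb1,
                       arma::mat fcW2, arma::vec fcb2,
                       Rcpp::NumericMatrix dropMask,
                       Rcpp::NumericVector y,
                       std::string loss,
                       bool wantGrad) {
  Rcpp::IntegerVector dims = x4d.attr("dim");
  if (dims.size() != 4) Rcpp::stop("input must be a 4-D array H x W x C x B");
  const uword H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const uword L = convW.size();

  std::vector<mat> Wl(L);
  std::vector<vec> bl(L);
  for (uword l = 0; l < L; ++l) {
    Wl[l] = Rcpp::as<mat>(convW[l]);
    bl[l] = Rcpp::as<vec>(convB[l]);
  }
  const uword nFeat = Wl[L - 1].n_rows;      // channels after last block
  const uword nHid = fcW1.n_rows;

  const bool haveY = y.size() > 0;
  const bool haveDrop = dropMask.nrow() > 0;
  if (haveY && (uword)y.size() != B) Rcpp::stop("y length must equal batch size");

  int lossCode = (loss == "bce") ? 0 : (loss == "mse") ? 1 : (loss == "mae") ? 2 : -1;
  if (lossCode < 0) Rcpp::stop("unknown loss '%s'", loss.c_str());

  // accumulated gradients
  std::vector<mat> dWl(L);
  std::vector<vec> dbl(L);
  if (wantGrad) {
    for (uword l = 0; l < L; ++l) { dWl[l].zeros(size(Wl[l])); dbl[l].zeros(Wl[l].n_rows); }
  }
  mat dfcW1(size(fcW1), fill::zeros), dfcW2(size(fcW2), fill::zeros);
  vec dfcb1(nHid, fill::zeros), dfcb2(1, fill::zeros);

  vec preds(B);
  double totLoss = 0.0;
  std::vector<ConvCache> caches(L);

  for (uword b = 0; b < B; ++b) {
    // ---- forward ----
    cube cur(H, W, C);
    std::memcpy(cur.memptr(), x4d.begin() + (size_t)b * H * W * C,
                sizeof(double) * H * W * C);
    for (uword l = 0; l < L; ++l) {
      ConvCache& cc = caches[l];
      cc.H = cur.n_rows; cc.W = cur.n_cols;
      im2col3(cur, cc.cols);
      cc.pre = Wl[l] * cc.cols;
      cc.pre.each_col() += bl[l];
      mat act = clamp(cc.pre, 0.0, datum::inf);
      // act is F x (H*W); repack into an H x W x F cube (pixel index j*H+i)
      cube actc(cc.H, cc.W, Wl[l].n_rows);
      for (uword f = 0; f < Wl[l].n_rows; ++f) {
        actc.slice(f) = reshape(act.row(f).t(), cc.H, cc.W);
      }
      cube pooled;
      maxpool2(actc, pooled, cc.amax);
      cur = pooled;
    }
    // global average pool
    const uword Hp = cur.n_rows, Wp = cur.n_cols;
    vec feat(nFeat);
    for (uword c = 0; c < nFeat; ++c) feat(c) = accu(cur.slice(c)) / (double)(Hp * Wp);
    vec h1pre = fcW1 * feat + fcb1;
    vec h1 = clamp(h1pre, 0.0, datum::inf);
    vec h1d = h1;
    if (haveDrop) {
      for (uword u = 0; u < nHid; ++u) h1d(u) *= dropMask(u, b);
    }
    double z = dot(fcW2.row(0), h1d) + fcb2(0);
    double p = 1.0 / (1.0 + std::exp(-z));
    preds(b) = p;

    double dz = 0.0;
    if (haveY) {
      double yt = y[b];
      const double eps = 1e-12;
      double pc = std::min(std::max(p, eps), 1.0 - eps);
      if (lossCode == 0) {            // cross-entropy with soft label
        totLoss += -(yt * std::log(pc) + (1.0 - yt) * std::log(1.0 - pc));
        dz = p - yt;
      } else if (lossCode == 1) {     // mse
        totLoss += (p - yt) * (p - yt);
        dz = 2.0 * (p - yt) * p * (1.0 - p);
      } else {                        // mae
        totLoss += std::abs(p - yt);
        dz = ((p > yt) ? 1.0 : (p < yt) ? -1.0 : 0.0) * p * (1.0 - p);
      }
    }
    if (!wantGrad || !haveY) continue;

    // ---- backward ----
    vec dh1d = fcW2.row(0).t() * dz;
    dfcW2.row(0) += dz * h1d.t();
    dfcb2(0) += dz;
    vec dh1 = dh1d;
    if (haveDrop) for (uword u = 0; u < nHid; ++u) dh1(u) *= dropMask(u, b);
    vec dh1pre = dh1 % conv_to<vec>::from(h1pre > 0.0);
    dfcW1 += dh1pre * feat.t();
    dfcb1 += dh1pre;
    vec dfeat = fcW1.t() * dh1pre;

    // back through GAP into a cube of pooled activations
    cube dcur(Hp, Wp, nFeat);
    for (uword c = 0; c < nFeat; ++c) dcur.slice(c).fill(dfeat(c) / (double)(Hp * Wp));

    for (int l = (int)L - 1; l >= 0; --l) {
      ConvCache& cc = caches[l];
      const uword F = Wl[l].n_rows;
      // un-pool
      mat dact(F, cc.H * cc.W, fill::zeros);
      const uword Hoo = cc.H / 2, Woo = cc.W / 2;
      for (uword c = 0; c < F; ++c) {
        for (uword q = 0; q < Hoo * Woo; ++q) {
          dact(c, cc.amax(q, c)) += dcur(q % Hoo, q / Hoo, c);
        }
      }
      // ReLU
      dact %= conv_to<mat>::from(cc.pre > 0.0);
      dWl[l] += dact * cc.cols.t();
      dbl[l] += sum(dact, 1);
      if (l > 0) {
        mat dcols = Wl[l].t() * dact;
        uword Cin = Wl[l].n_cols / 9;
        cube dx(cc.H, cc.W, Cin);
        col2im3(dcols, dx);
        // dx feeds the previous block's pool output
        dcur = dx;
      }
    }
  }

  double invB = 1.0 / (double)B;
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("pred") = Rcpp::NumericVector(preds.begin(), preds.end()),
    Rcpp::Named("loss") = haveY ? totLoss * invB : NA_REAL);
  if (wantGrad && haveY) {
    Rcpp::List gW(L), gB(L);
    for (uword l = 0; l < L; ++l) {
      gW[l] = Rcpp::wrap(mat(dWl[l] * invB));
      gB[l] = Rcpp::wrap(vec(dbl[l] * invB));
    }
    out["gradConvW"] = gW;
    out["gradConvB"] = gB;
    out["gradFcW1"] = Rcpp::wrap(mat(dfcW1 * invB));
    out["gradFcb1"] = Rcpp::wrap(vec(dfcb1 * invB));
    out["gradFcW2"] = Rcpp::wrap(mat(dfcW2 * invB));
    out["gradFcb2"] = Rcpp::wrap(vec(dfcb2 * invB));
  }
  return out;
}
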