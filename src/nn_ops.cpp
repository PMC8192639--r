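// Low-level numerical kernels for the 2.5-D slice-submodule network and the
// voxel-wise cluster stage. Batched 2-D feature maps are arma::cube of size
// H x W x (C * N), sample-major: slice index n*C + c holds channel c of
// sample n. Convolution weights are stored as a (9*Cin) x Cout matrix whose
// rows follow the im2col column order produced here (channel-major, then the
// 3x3 offset in column-major (di, dj) order).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for one sample: (H*W) x (9*C), zero ("same") padding of 1.
static arma::mat im2col3(const arma::cube& X, int n, int C) {
  const int H = X.n_rows, W = X.n_cols;
  arma::mat out(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& S = X.slice((std::size_t)n * C + c);
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di, ++k) {
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        const int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
        if (i0 > i1 || j0 > j1) continue;
        arma::mat T(H, W, arma::fill::zeros);
        T.submat(i0, j0, i1, j1) = S.submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
        out.col(c * 9 + k) = arma::vectorise(T);
      }
    }
  }
  return out;
}

// scatter-add of an im2col-layout gradient back onto the padded input
static void col2im3(arma::cube& dX, const arma::mat& dcol, int n, int C) {
  const int H = dX.n_rows, W = dX.n_cols;
  for (int c = 0; c < C; ++c) {
    arma::mat& dS = dX.slice((std::size_t)n * C + c);
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di, ++k) {
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        const int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
        if (i0 > i1 || j0 > j1) continue;
        arma::mat T = arma::reshape(dcol.col(c * 9 + k), H, W);
        dS.submat(i0 + di, j0 + dj, i1 + di, j1 + dj) += T.submat(i0, j0, i1, j1);
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
arma::cube conv_fwd(const arma::cube& X, int N, const arma::mat& W,
                    const arma::vec& b) {
  const int H = X.n_rows, Wd = X.n_cols;
  const int Cin = X.n_slices / N;
  const int Cout = W.n_cols;
  arma::cube Y(H, Wd, (std::size_t)Cout * N);
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col3(X, n, Cin);     // (H*W) x (9*Cin)
    arma::mat O = M * W;                  // (H*W) x Cout
    O.each_row() += b.t();
    for (int c = 0; c < Cout; ++c)
      Y.slice((std::size_t)n * Cout + c) = arma::reshape(O.col(c), H, Wd);
  }
  return Y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(const arma::cube& X, int N, const arma::mat& W,
              const arma::cube& dY) {
  const int H = X.n_rows, Wd = X.n_cols;
  const int Cin = X.n_slices / N;
  const int Cout = W.n_cols;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::cube dX(H, Wd, X.n_slices, arma::fill::zeros);
  arma::mat dYm(H * Wd, Cout);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < Cout; ++c)
      dYm.col(c) = arma::vectorise(dY.slice((std::size_t)n * Cout + c));
    arma::mat M = im2col3(X, n, Cin);
    dW += M.t() * dYm;
    db += arma::sum(dYm, 0).t();
    col2im3(dX, dYm * W.t(), n, Cin);
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".pool_fwd")]]
List pool_fwd(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, S = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;  // floor: trailing odd row/col dropped
  arma::cube Y(Ho, Wo, S);
  arma::cube idx(Ho, Wo, S);  // 0-based linear index into the input slice
  for (int s = 0; s < S; ++s) {
    const arma::mat& A = X.slice(s);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i2 = 2 * i, j2 = 2 * j;
        double best = A(i2, j2);
        int bi = i2, bj = j2;
        if (A(i2 + 1, j2) > best) { best = A(i2 + 1, j2); bi = i2 + 1; bj = j2; }
        if (A(i2, j2 + 1) > best) { best = A(i2, j2 + 1); bi = i2; bj = j2 + 1; }
        if (A(i2 + 1, j2 + 1) > best) { best = A(i2 + 1, j2 + 1); bi = i2 + 1; bj = j2 + 1; }
        Y(i, j, s) = best;
        idx(i, j, s) = bi + bj * H;
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".pool_bwd")]]
arma::cube pool_bwd(const arma::cube& dY, const arma::cube& idx, int H, int W) {
  const int Ho = dY.n_rows, Wo = dY.n_cols, S = dY.n_slices;
  arma::cube dX(H, W, S, arma::fill::zeros);
  for (int s = 0; s < S; ++s) {
    arma::mat& D = dX.slice(s);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        D((std::size_t)idx(i, j, s)) += dY(i, j, s);
  }
  return dX;
}

// Batch norm over the (N, H, W) extent of each channel. Biased variance is
// used for normalization; the R side maintains running moments.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(const arma::cube& X, int N, const arma::vec& gamma,
            const arma::vec& beta, double eps, bool training,
            const arma::vec& rmean, const arma::vec& rvar) {
  const int C = X.n_slices / N;
  const double m = (double)N * X.n_rows * X.n_cols;
  arma::vec mu(C), var(C);
  if (training) {
    mu.zeros(); var.zeros();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c)
        mu(c) += arma::accu(X.slice((std::size_t)n * C + c));
    mu /= m;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        arma::mat D = X.slice((std::size_t)n * C + c) - mu(c);
        var(c) += arma::accu(D % D);
      }
    var /= m;
  } else {
    mu = rmean; var = rvar;
  }
  arma::cube Y(X.n_rows, X.n_cols, X.n_slices);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t s = (std::size_t)n * C + c;
      Y.slice(s) = gamma(c) * (X.slice(s) - mu(c)) / std::sqrt(var(c) + eps) + beta(c);
    }
  return List::create(_["Y"] = Y, _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(const arma::cube& dY, const arma::cube& X, int N,
            const arma::vec& gamma, const arma::vec& mu, const arma::vec& var,
            double eps) {
  const int C = X.n_slices / N;
  const double m = (double)N * X.n_rows * X.n_cols;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  arma::vec sum_dy(C, arma::fill::zeros), sum_dy_xhat(C, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t s = (std::size_t)n * C + c;
      const arma::mat xhat = (X.slice(s) - mu(c)) / std::sqrt(var(c) + eps);
      sum_dy(c) += arma::accu(dY.slice(s));
      sum_dy_xhat(c) += arma::accu(dY.slice(s) % xhat);
    }
  dbeta = sum_dy;
  dgamma = sum_dy_xhat;
  arma::cube dX(X.n_rows, X.n_cols, X.n_slices);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t s = (std::size_t)n * C + c;
      const double inv_sd = 1.0 / std::sqrt(var(c) + eps);
      const arma::mat xhat = (X.slice(s) - mu(c)) * inv_sd;
      dX.slice(s) = gamma(c) * inv_sd *
        (dY.slice(s) - sum_dy(c) / m - xhat * (sum_dy_xhat(c) / m));
    }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Connected components on a 3-D logical mask; connectivity 6, 18 or 26.
// Returns an integer array: 0 outside the mask, 1..K component labels.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (a == 0) continue;
        if ((connectivity == 6 && a > 1) || (connectivity == 18 && a > 2))
          continue;
        off.push_back({dx, dy, dz});
      }
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  auto at = [&](int x, int y, int z) {
    return (std::size_t)x + (std::size_t)nx * (y + (std::size_t)ny * z);
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const std::size_t v = at(x, y, z);
        if (!mask[v] || lab[v] != 0) continue;
        ++next;
        std::queue<std::array<int, 3>> q;
        lab[v] = next;
        q.push({x, y, z});
        while (!q.empty()) {
          auto p = q.front(); q.pop();
          for (const auto& o : off) {
            const int X2 = p[0] + o[0], Y2 = p[1] + o[1], Z2 = p[2] + o[2];
            if (X2 < 0 || Y2 < 0 || Z2 < 0 || X2 >= nx || Y2 >= ny || Z2 >= nz)
              continue;
            const std::size_t w = at(X2, Y2, Z2);
            if (mask[w] && lab[w] == 0) { lab[w] = next; q.push({X2, Y2, Z2}); }
          }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}
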