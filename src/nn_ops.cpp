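#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Activation layout convention (matches the R side): a batch is a numeric
// array with dim (H, W, C, N), column-major, so index = h + H*(w + W*(c + C*n)).
// im2col row index r encodes (kh, kw, c) with kh fastest, matching the
// column-major reshape of a (k, k, C, F) weight array into a (k*k*C, F) matrix.

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(rng = false)]]
arma::mat cg_im2col(const arma::vec& x, int H, int W, int C, int N,
                    int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  arma::mat cols(k * k * C, (arma::uword)OH * OW * N, arma::fill::zeros);
  const double* xp = x.memptr();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const arma::uword col = (arma::uword)oh + (arma::uword)OH * (ow + (arma::uword)OW * n);
        double* cp = cols.colptr(col);
        for (int c = 0; c < C; ++c) {
          const double* plane = xp + (arma::uword)H * W * (c + (arma::uword)C * n);
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * stride - pad + kw;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh * stride - pad + kh;
              const int r = kh + k * (kw + k * c);
              if (ih >= 0 && ih < H && iw >= 0 && iw < W)
                cp[r] = plane[ih + (arma::uword)H * iw];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Inverse scatter-add of cg_im2col: cols has k*k*C rows and OH*OW*N columns,
// result has dim (H, W, C, N).
// [[Rcpp::export(rng = false)]]
arma::vec cg_col2im(const arma::mat& cols, int H, int W, int C, int N,
                    int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  arma::vec x((arma::uword)H * W * C * N, arma::fill::zeros);
  double* xp = x.memptr();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const arma::uword col = (arma::uword)oh + (arma::uword)OH * (ow + (arma::uword)OW * n);
        const double* cp = cols.colptr(col);
        for (int c = 0; c < C; ++c) {
          double* plane = xp + (arma::uword)H * W * (c + (arma::uword)C * n);
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * stride - pad + kw;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh * stride - pad + kh;
              const int r = kh + k * (kw + k * c);
              if (ih >= 0 && ih < H && iw >= 0 && iw < W)
                plane[ih + (arma::uword)H * iw] += cp[r];
            }
          }
        }
      }
    }
  }
  return x;
}

// Max pooling. Returns the pooled values and the 1-based flat index (into the
// full (H,W,C,N) input) of each maximum; ties resolve to the first position in
// (kh, kw) scan order so the result is deterministic.
// [[Rcpp::export(rng = false)]]
List cg_maxpool_fwd(const arma::vec& x, int H, int W, int C, int N,
                    int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  arma::vec y((arma::uword)OH * OW * C * N);
  arma::uvec idx((arma::uword)OH * OW * C * N);
  const double* xp = x.memptr();
  arma::uword o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const arma::uword base = (arma::uword)H * W * (c + (arma::uword)C * n);
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword besti = base;
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) continue;
              const double v = xp[base + ih + (arma::uword)H * iw];
              if (v > best) { best = v; besti = base + ih + (arma::uword)H * iw; }
            }
          }
          // y is laid out (OH, OW, C, N) but we fill (ow, oh) inner loops in
          // (oh fastest) order per (c, n); compute the target index explicitly
          const arma::uword yi = (arma::uword)oh + (arma::uword)OH * (ow + (arma::uword)OW * (c + (arma::uword)C * n));
          y(yi) = best;
          idx(yi) = besti + 1; // 1-based for R
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(rng = false)]]
arma::vec cg_maxpool_bwd(const arma::vec& dy, const arma::uvec& idx,
                         arma::uword input_len) {
  arma::vec dx(input_len, arma::fill::zeros);
  for (arma::uword i = 0; i < dy.n_elem; ++i) dx(idx(i) - 1) += dy(i);
  return dx;
}

// Block matching between two frames (H x W matrices). For each non-overlapping
// `block` x `block` tile of `prev` whose pixel variance exceeds `var_thresh`,
// the integer displacement (dy, dx) within [-search, search] minimizing the
// sum of absolute differences against `next` is reported. Candidates are
// scanned in order of increasing |d|^2 with strict improvement, so identical
// frames yield exactly zero displacement. A nonzero displacement is only
// accepted if its SAD beats the zero-displacement SAD by the `quality`
// factor; blocks whose content cannot be matched by a translation (e.g. at
// the convergence point of a contraction field) are marked invalid rather
// than reporting an arbitrary vector. Rows: by, bx, dy, dx, valid.
// [[Rcpp::export(rng = false)]]
arma::mat cg_block_match(const arma::mat& prev, const arma::mat& nxt,
                         int block, int search, double var_thresh,
                         double quality = 0.7) {
  const int H = prev.n_rows, W = prev.n_cols;
  const int nby = H / block, nbx = W / block;
  // candidate displacements sorted by squared magnitude, then (dy, dx)
  std::vector<std::array<int, 3>> cand;
  for (int dy = -search; dy <= search; ++dy)
    for (int dx = -search; dx <= search; ++dx)
      cand.push_back({dy * dy + dx * dx, dy, dx});
  std::sort(cand.begin(), cand.end());
  arma::mat out(nby * nbx, 5);
  int row = 0;
  for (int by = 0; by < nby; ++by) {
    for (int bx = 0; bx < nbx; ++bx) {
      const int y0 = by * block, x0 = bx * block;
      const arma::mat tile = prev.submat(y0, x0, y0 + block - 1, x0 + block - 1);
      const double v = arma::accu(arma::square(tile - arma::mean(arma::mean(tile)))) / (block * block);
      double bestsad = std::numeric_limits<double>::infinity();
      double sad0 = std::numeric_limits<double>::infinity();
      int bdy = 0, bdx = 0;
      bool any = false;
      if (v >= var_thresh) {
        for (const auto& c : cand) {
          const int dy = c[1], dx = c[2];
          const int ny0 = y0 + dy, nx0 = x0 + dx;
          if (ny0 < 0 || nx0 < 0 || ny0 + block > H || nx0 + block > W) continue;
          double sad = 0.0;
          for (int j = 0; j < block; ++j)
            for (int i = 0; i < block; ++i)
              sad += std::abs(nxt(ny0 + i, nx0 + j) - tile(i, j));
          if (dy == 0 && dx == 0) sad0 = sad;
          if (sad < bestsad) { bestsad = sad; bdy = dy; bdx = dx; any = true; }
        }
      }
      bool ok = v >= var_thresh && any;
      if (ok && (bdy != 0 || bdx != 0) && !(bestsad < quality * sad0)) ok = false;
      out(row, 0) = by + 1;
      out(row, 1) = bx + 1;
      out(row, 2) = ok ? bdy : 0;
      out(row, 3) = ok ? bdx : 0;
      out(row, 4) = ok ? 1.0 : 0.0;
      ++row;
    }
  }
  return out;
}
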