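// Compact two-branch convolutional network for weakly supervised droplet
// cell counting: a shared trunk of 3x3 stride-1 same-padded conv layers, a
// counting head ending in a single-channel non-negative density map at
// input resolution, and a classification head (global average pooling +
// linear). Batches are processed in chunks with activations laid out as
// (channels x pixels) matrices so every convolution is a single dgemm over
// an im2col buffer; backward recomputes the im2col instead of storing it.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int CHUNK = 32;

// act: (C, H*W*B), pixel p = s*H*W + j*H + i. Fills out (C*9, n) where the
// block of rows [tap*C, tap*C+C) holds the channel vector of the pixel
// shifted by the kernel tap (di, dj); out-of-frame taps stay zero.
static void im2colBatch(const mat &act, uword H, uword W, uword B, mat &out) {
  const uword C = act.n_rows, HW = H * W, n = HW * B;
  out.zeros(C * 9, n);
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      const uword tap = (uword)((dj + 1) * 3 + (di + 1));
      for (uword s = 0; s < B; ++s) {
        const uword off = s * HW;
        for (uword j = 0; j < W; ++j) {
          int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          int i0 = std::max(0, -di), i1 = std::min((int)H, (int)H - di);
          const double *src = act.colptr(off + (uword)js * H + (uword)(i0 + di));
          double *dst = out.colptr(off + j * H + (uword)i0) + tap * C;
          for (int i = i0; i < i1; ++i) {
            std::memcpy(dst, src, C * sizeof(double));
            src += C;
            dst += C * 9;
          }
        }
      }
    }
  }
}

// Adjoint of im2colBatch: scatter-add column gradients back onto pixels.
static void col2imBatch(const mat &colg, uword H, uword W, uword B, mat &out) {
  const uword C = out.n_rows, HW = H * W;
  out.zeros();
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      const uword tap = (uword)((dj + 1) * 3 + (di + 1));
      for (uword s = 0; s < B; ++s) {
        const uword off = s * HW;
        for (uword j = 0; j < W; ++j) {
          int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          int i0 = std::max(0, -di), i1 = std::min((int)H, (int)H - di);
          double *dst = out.colptr(off + (uword)js * H + (uword)(i0 + di));
          const double *src = colg.colptr(off + j * H + (uword)i0) + tap * C;
          for (int i = i0; i < i1; ++i) {
            for (uword c = 0; c < C; ++c) dst[c] += src[c];
            dst += C;
            src += C * 9;
          }
        }
      }
    }
  }
}

static inline void reluInPlace(mat &x) {
  double *p = x.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i)
    if (p[i] < 0.0) p[i] = 0.0;
}

// Zero entries of g where the activation was clipped by ReLU.
static inline void reluMask(mat &g, const mat &act) {
  double *p = g.memptr();
  const double *a = act.memptr();
  const uword n = g.n_elem;
  for (uword i = 0; i < n; ++i)
    if (a[i] <= 0.0) p[i] = 0.0;
}

struct Net {
  std::vector<mat> W;  // 7 conv weights (Cout, Cin*9), tap-major rows
  std::vector<vec> b;
  mat fcW;             // (2, C_trunk)
  vec fcb;
};

static Net unpackNet(const Rcpp::List &weights) {
  Net net;
  Rcpp::List Wl = weights["convW"], bl = weights["convB"];
  for (int l = 0; l < 7; ++l) {
    net.W.push_back(Rcpp::as<mat>(Wl[l]));
    net.b.push_back(Rcpp::as<vec>(bl[l]));
  }
  net.fcW = Rcpp::as<mat>(weights["fcW"]);
  net.fcb = Rcpp::as<vec>(weights["fcb"]);
  return net;
}

// Forward a chunk; fills act[0..7] (channel x pixel mats) and per-sample
// feat (C4 x B) and logits (2 x B).
static void forwardChunk(const Net &net, const cube &X, uword s0, uword B,
                         std::vector<mat> &act, mat &feat, mat &logits,
                         mat &colBuf) {
  const uword H = X.n_rows, W = X.n_cols, HW = H * W, n = HW * B;
  act[0].set_size(1, n);
  for (uword s = 0; s < B; ++s)
    std::memcpy(act[0].colptr(s * HW), X.slice(s0 + s).memptr(),
                HW * sizeof(double));
  for (int l = 1; l <= 7; ++l) {
    im2colBatch(act[l - 1], H, W, B, colBuf);
    act[l] = net.W[l - 1] * colBuf;
    act[l].each_col() += net.b[l - 1];
    reluInPlace(act[l]);
  }
  const mat &trunk = act[4];
  feat.set_size(trunk.n_rows, B);
  for (uword s = 0; s < B; ++s)
    feat.col(s) = sum(trunk.cols(s * HW, (s + 1) * HW - 1), 1) / (double)HW;
  logits = net.fcW * feat;
  logits.each_col() += net.fcb;
}

// [[Rcpp::export]]
Rcpp::List wsc_forward_cpp(Rcpp::List weights, arma::cube X) {
  Net net = unpackNet(weights);
  const uword H = X.n_rows, W = X.n_cols, N = X.n_slices, HW = H * W;
  cube density(H, W, N);
  mat logitsAll(2, N);
  vec dsum(N), dmax(N);
  std::vector<mat> act(8);
  mat feat, logits, colBuf;
  for (uword s0 = 0; s0 < N; s0 += CHUNK) {
    uword B = std::min((uword)CHUNK, N - s0);
    forwardChunk(net, X, s0, B, act, feat, logits, colBuf);
    for (uword s = 0; s < B; ++s) {
      std::memcpy(density.slice(s0 + s).memptr(), act[7].colptr(s * HW),
                  HW * sizeof(double));
      dsum(s0 + s) = accu(density.slice(s0 + s));
      dmax(s0 + s) = density.slice(s0 + s).max();
    }
    logitsAll.cols(s0, s0 + B - 1) = logits;
  }
  return Rcpp::List::create(Rcpp::Named("density") = density,
                            Rcpp::Named("logits") = logitsAll,
                            Rcpp::Named("dsum") = dsum,
                            Rcpp::Named("dmax") = dmax);
}

static inline double fcount(double dsum, double gamma) {
  return dsum < 2.0 ? dsum : 2.0 + gamma * dsum;
}
static inline double fcount_d(double dsum, double gamma) {
  return dsum < 2.0 ? 1.0 : gamma;
}

// Mini-batch loss and mean gradients.
// cls: 0 = background, 1 = droplet; y: weak count label in {0,1,2}
// (ignored for background). Per-sample loss:
//   L = Lclass + omega * Lcount * [cls == droplet]
// with Lclass = cross-entropy and Lcount = (f(D) - y)^2 + max(Dmax - 1, 0).
// [[Rcpp::export]]
Rcpp::List wsc_grad_cpp(Rcpp::List weights, arma::cube X,
                        arma::ivec cls, arma::vec y,
                        double gamma, double omega) {
  Net net = unpackNet(weights);
  const uword H = X.n_rows, W = X.n_cols, N = X.n_slices, HW = H * W;

  std::vector<mat> gW(7);
  std::vector<vec> gb(7);
  for (int l = 0; l < 7; ++l) {
    gW[l].zeros(size(net.W[l]));
    gb[l].zeros(net.b[l].n_elem);
  }
  mat gfcW(size(net.fcW), fill::zeros);
  vec gfcb(2, fill::zeros);
  double lclass = 0.0, lcount = 0.0;

  std::vector<mat> act(8);
  mat feat, logits, colBuf, delta, dcol;

  for (uword s0 = 0; s0 < N; s0 += CHUNK) {
    uword B = std::min((uword)CHUNK, N - s0);
    const uword n = HW * B;
    forwardChunk(net, X, s0, B, act, feat, logits, colBuf);

    // classification branch
    mat dlog(2, B);
    for (uword s = 0; s < B; ++s) {
      vec lg = logits.col(s);
      vec p = exp(lg - lg.max());
      p /= accu(p);
      int lab = (int)cls(s0 + s);
      lclass += -std::log(std::max(p(lab), 1e-12));
      p(lab) -= 1.0;
      dlog.col(s) = p;
    }
    gfcW += dlog * feat.t();
    gfcb += sum(dlog, 1);
    mat dfeat = net.fcW.t() * dlog;  // (C4, B)

    // counting branch seed at the density map
    delta.zeros(1, n);
    bool anyCount = false;
    for (uword s = 0; s < B; ++s) {
      if (cls(s0 + s) != 1) continue;
      anyCount = true;
      const double *d = act[7].colptr(s * HW);
      double dsum = 0.0, dmx = -1.0;
      uword imax = 0;
      for (uword i = 0; i < HW; ++i) {
        dsum += d[i];
        if (d[i] > dmx) { dmx = d[i]; imax = i; }
      }
      double f = fcount(dsum, gamma);
      lcount += (f - y(s0 + s)) * (f - y(s0 + s)) +
                (dmx > 1.0 ? dmx - 1.0 : 0.0);
      double g = omega * 2.0 * (f - y(s0 + s)) * fcount_d(dsum, gamma);
      double *dd = delta.colptr(s * HW);
      for (uword i = 0; i < HW; ++i) dd[i] = g;
      if (dmx > 1.0) dd[imax] += omega;
    }

    // counting head backward (layers 7..5) into the trunk
    mat da4;
    if (anyCount) {
      for (int l = 7; l >= 5; --l) {
        reluMask(delta, act[l]);
        im2colBatch(act[l - 1], H, W, B, colBuf);
        gW[l - 1] += delta * colBuf.t();
        gb[l - 1] += sum(delta, 1);
        dcol = net.W[l - 1].t() * delta;
        delta.set_size(act[l - 1].n_rows, n);
        col2imBatch(dcol, H, W, B, delta);
      }
      da4 = std::move(delta);
    } else {
      da4.zeros(act[4].n_rows, n);
    }

    // classifier contribution through global average pooling
    for (uword s = 0; s < B; ++s) {
      const vec df = dfeat.col(s) / (double)HW;
      for (uword p = s * HW; p < (s + 1) * HW; ++p)
        da4.col(p) += df;
    }

    // trunk backward (layers 4..1)
    delta = std::move(da4);
    for (int l = 4; l >= 1; --l) {
      reluMask(delta, act[l]);
      im2colBatch(act[l - 1], H, W, B, colBuf);
      gW[l - 1] += delta * colBuf.t();
      gb[l - 1] += sum(delta, 1);
      if (l > 1) {
        dcol = net.W[l - 1].t() * delta;
        delta.set_size(act[l - 1].n_rows, n);
        col2imBatch(dcol, H, W, B, delta);
      }
    }
  }

  double invN = 1.0 / (double)N;
  Rcpp::List gWl(7), gbl(7);
  for (int l = 0; l < 7; ++l) {
    gWl[l] = gW[l] * invN;
    gbl[l] = gb[l] * invN;
  }
  return Rcpp::List::create(
      Rcpp::Named("convW") = gWl, Rcpp::Named("convB") = gbl,
      Rcpp::Named("fcW") = gfcW * invN, Rcpp::Named("fcb") = gfcb * invN,
      Rcpp::Named("lclass") = lclass * invN,
      Rcpp::Named("lcount") = lcount * invN,
      Rcpp::Named("loss") = (lclass + omega * lcount) * invN);
}
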