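// Compact convolutional classifier for pileup tensors.
//
// Layer stack (fixed topology, filter counts configurable from R):
//   conv3x3(same) -> ReLU -> maxpool3x3/3 (valid)   [x3 blocks]
//   conv1x1 -> ReLU -> batch-norm -> flatten
//   dense -> ReLU -> dropout -> dense(2) -> softmax
// Loss: label-smoothed binary cross-entropy on the two softmax outputs,
// optimised with Adam. Convolutions run as im2col + single-precision GEMM.
//
// All randomness (shuffling, dropout masks) is drawn from R's RNG so that
// set.seed() on the R side makes training bit-reproducible.

#include <RcppArmadillo.h>
#include <limits>
#include <cstring>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static const float BN_EPS = 1e-3f;
static const float ADAM_B1 = 0.9f;
static const float ADAM_B2 = 0.999f;
static const float ADAM_EPS = 1e-7f;
static const float PROB_CLIP = 1e-7f;

// ---------------------------------------------------------------------------
// primitives

// im2col for a 3x3 same-padded convolution. C has shape (h*w, 9*c) with
// column index ci*9 + (dx+1)*3 + (dy+1); row index is the output pixel
// i + h*j (column-major, matching R array layout).
static void im2col3(const fcube& X, fmat& C) {
  const int h = X.n_rows, w = X.n_cols, c = X.n_slices;
  C.zeros(h * (uword)w, 9 * (uword)c);
  for (int ci = 0; ci < c; ++ci) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const uword col = ci * 9 + (dx + 1) * 3 + (dy + 1);
        float* dst = C.colptr(col);
        const int i0 = std::max(0, -dy);
        const int i1 = std::min(h, h - dy);  // copy rows [i0, i1)
        if (i1 <= i0) continue;
        for (int j = 0; j < w; ++j) {
          const int jj = j + dx;
          if (jj < 0 || jj >= w) continue;
          std::memcpy(dst + (size_t)j * h + i0, &X(i0 + dy, jj, ci),
                      sizeof(float) * (size_t)(i1 - i0));
        }
      }
    }
  }
}

// transpose of im2col3: scatter-add columns of dC back onto dX (pre-zeroed)
static void col2im3(const fmat& dC, fcube& dX) {
  const int h = dX.n_rows, w = dX.n_cols, c = dX.n_slices;
  for (int ci = 0; ci < c; ++ci) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const uword col = ci * 9 + (dx + 1) * 3 + (dy + 1);
        const float* src = dC.colptr(col);
        const int i0 = std::max(0, -dy);
        const int i1 = std::min(h, h - dy);
        if (i1 <= i0) continue;
        for (int j = 0; j < w; ++j) {
          const int jj = j + dx;
          if (jj < 0 || jj >= w) continue;
          float* dst = &dX(i0 + dy, jj, ci);
          const float* s = src + (size_t)j * h + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

// 3x3 max-pooling with stride 3 and floor ("valid") size reduction;
// I records the argmax linear index into X for the backward pass
static void maxpool3(const fcube& X, fcube& P, ucube& I) {
  const int h = X.n_rows, w = X.n_cols, c = X.n_slices;
  const int hp = h / 3, wp = w / 3;
  P.set_size(hp, wp, c);
  I.set_size(hp, wp, c);
  for (int k = 0; k < c; ++k)
    for (int j = 0; j < wp; ++j)
      for (int i = 0; i < hp; ++i) {
        float best = -std::numeric_limits<float>::infinity();
        uword bidx = 0;
        for (int dj = 0; dj < 3; ++dj)
          for (int di = 0; di < 3; ++di) {
            const int ii = 3 * i + di, jj = 3 * j + dj;
            const float v = X(ii, jj, k);
            if (v > best) {
              best = v;
              bidx = (uword)ii + (uword)h * jj + (uword)h * w * k;
            }
          }
        P(i, j, k) = best;
        I(i, j, k) = bidx;
      }
}

static void unpool3(const fcube& dP, const ucube& I, fcube& dX) {
  dX.zeros();
  const uword n = dP.n_elem;
  for (uword t = 0; t < n; ++t) dX(I(t)) += dP(t);
}

static void relu_inplace(fcube& A) {
  A.for_each([](float& v) { if (v < 0) v = 0; });
}

static void relu_mask(fmat& dZ, const fcube& Z) {
  const float* z = Z.memptr();
  float* d = dZ.memptr();
  for (uword t = 0; t < dZ.n_elem; ++t)
    if (z[t] <= 0) d[t] = 0;
}

// ---------------------------------------------------------------------------
// weight container

struct Net {
  fmat W1, W2, W3, W4, W5, W6;
  fmat b1, b2, b3, b4, b5, b6;       // 1 x k rows
  fmat gamma, beta, mov_mean, mov_var;  // 1 x f4
};

static fmat as_f(SEXP x) {
  NumericMatrix m;
  if (Rf_isMatrix(x)) {
    m = as<NumericMatrix>(x);
  } else {
    NumericVector v = as<NumericVector>(x);
    m = NumericMatrix(1, v.size());
    for (int i = 0; i < v.size(); ++i) m(0, i) = v[i];
  }
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

static Net net_from_list(const List& w) {
  Net n;
  n.W1 = as_f(w["W1"]); n.b1 = as_f(w["b1"]);
  n.W2 = as_f(w["W2"]); n.b2 = as_f(w["b2"]);
  n.W3 = as_f(w["W3"]); n.b3 = as_f(w["b3"]);
  n.W4 = as_f(w["W4"]); n.b4 = as_f(w["b4"]);
  n.W5 = as_f(w["W5"]); n.b5 = as_f(w["b5"]);
  n.W6 = as_f(w["W6"]); n.b6 = as_f(w["b6"]);
  n.gamma = as_f(w["gamma"]); n.beta = as_f(w["beta"]);
  n.mov_mean = as_f(w["moving_mean"]); n.mov_var = as_f(w["moving_var"]);
  return n;
}

static SEXP f_to_r(const fmat& m, bool as_vector) {
  if (as_vector) {
    NumericVector v(m.n_elem);
    for (uword t = 0; t < m.n_elem; ++t) v[t] = m(t);
    return v;
  }
  NumericMatrix out(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}

static List net_to_list(const Net& n) {
  return List::create(
      _["W1"] = f_to_r(n.W1, false), _["b1"] = f_to_r(n.b1, true),
      _["W2"] = f_to_r(n.W2, false), _["b2"] = f_to_r(n.b2, true),
      _["W3"] = f_to_r(n.W3, false), _["b3"] = f_to_r(n.b3, true),
      _["W4"] = f_to_r(n.W4, false), _["b4"] = f_to_r(n.b4, true),
      _["gamma"] = f_to_r(n.gamma, true), _["beta"] = f_to_r(n.beta, true),
      _["moving_mean"] = f_to_r(n.mov_mean, true),
      _["moving_var"] = f_to_r(n.mov_var, true),
      _["W5"] = f_to_r(n.W5, false), _["b5"] = f_to_r(n.b5, true),
      _["W6"] = f_to_r(n.W6, false), _["b6"] = f_to_r(n.b6, true));
}

struct StageDims {
  int h0, w0, c0, f1, f2, f3, f4;
  int h1, w1, h2, w2, h3, w3, hw4, flat;
};

static StageDims stage_dims(const Net& net, int h, int w, int c) {
  StageDims d;
  d.h0 = h; d.w0 = w; d.c0 = c;
  d.f1 = net.W1.n_cols; d.f2 = net.W2.n_cols;
  d.f3 = net.W3.n_cols; d.f4 = net.W4.n_cols;
  d.h1 = h / 3;   d.w1 = w / 3;
  d.h2 = d.h1 / 3; d.w2 = d.w1 / 3;
  d.h3 = d.h2 / 3; d.w3 = d.w2 / 3;
  if (d.h3 < 1 || d.w3 < 1)
    stop("input spatial dimensions collapse under three 3x3 poolings");
  d.hw4 = d.h3 * d.w3;
  d.flat = d.hw4 * d.f4;
  if ((int)net.W5.n_rows != d.flat)
    stop("dense layer fan-in does not match the pooled feature map");
  if ((uword)(h * w * c) == 0) stop("empty input");
  return d;
}

static void softmax_cols(fmat& Z) {
  for (uword j = 0; j < Z.n_cols; ++j) {
    fvec z = Z.col(j);
    z -= z.max();
    fvec e = exp(z);
    Z.col(j) = e / accu(e);
  }
}

// ---------------------------------------------------------------------------
// training

// [[Rcpp::export]]
List cnn_train_cpp(NumericMatrix Xr, NumericMatrix Yr, List wts,
                   int h, int w, int c,
                   double lr, int batch_size, int epochs,
                   double label_smoothing, double dropout_p,
                   double bn_momentum, bool shuffle) {
  Net net = net_from_list(wts);
  StageDims dm = stage_dims(net, h, w, c);
  const int d = h * w * c;
  const int n = Xr.ncol();
  if (Xr.nrow() != d) stop("sample length does not match h*w*c");
  if (Yr.nrow() != n || Yr.ncol() != 2) stop("labels must be an n x 2 matrix");
  if (batch_size < 1) stop("batch_size must be >= 1");

  fmat X(d, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < d; ++i) X(i, j) = (float)Xr(i, j);
  fmat Y(n, 2);
  for (int i = 0; i < n; ++i) { Y(i, 0) = (float)Yr(i, 0); Y(i, 1) = (float)Yr(i, 1); }

  const float eps_s = (float)label_smoothing;
  const float keep = 1.0f - (float)dropout_p;

  // parameter/gradient registry for Adam (order fixed)
  std::vector<fmat*> params = {&net.W1, &net.b1, &net.W2, &net.b2,
                               &net.W3, &net.b3, &net.W4, &net.b4,
                               &net.gamma, &net.beta,
                               &net.W5, &net.b5, &net.W6, &net.b6};
  std::vector<fmat> grads(params.size()), adam_m(params.size()), adam_v(params.size());
  for (size_t p = 0; p < params.size(); ++p) {
    adam_m[p].zeros(params[p]->n_rows, params[p]->n_cols);
    adam_v[p].zeros(params[p]->n_rows, params[p]->n_cols);
  }
  long tstep = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector hist_loss(epochs), hist_acc(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle) {  // Fisher-Yates driven by R's RNG
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(R::unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
    }
    double ep_loss = 0.0;
    long ep_correct = 0;

    for (int off = 0; off < n; off += batch_size) {
      const int bn = std::min(batch_size, n - off);

      // ---- forward ----
      std::vector<fcube> Z1(bn), Z2(bn), Z3(bn), P1(bn), P2(bn), P3(bn);
      std::vector<ucube> I1(bn), I2(bn), I3(bn);
      std::vector<fmat> Z4(bn);
      fmat B4(bn * (uword)dm.hw4, dm.f4);

      for (int s = 0; s < bn; ++s) {
        const int ix = order[off + s];
        fcube Xs(const_cast<float*>(X.colptr(ix)), dm.h0, dm.w0, dm.c0, false, true);
        fmat C1; im2col3(Xs, C1);
        fmat Z1m = C1 * net.W1; Z1m.each_row() += net.b1.row(0);
        Z1[s] = fcube(Z1m.memptr(), dm.h0, dm.w0, dm.f1);
        fcube A1 = Z1[s]; relu_inplace(A1);
        maxpool3(A1, P1[s], I1[s]);

        fmat C2; im2col3(P1[s], C2);
        fmat Z2m = C2 * net.W2; Z2m.each_row() += net.b2.row(0);
        Z2[s] = fcube(Z2m.memptr(), dm.h1, dm.w1, dm.f2);
        fcube A2 = Z2[s]; relu_inplace(A2);
        maxpool3(A2, P2[s], I2[s]);

        fmat C3; im2col3(P2[s], C3);
        fmat Z3m = C3 * net.W3; Z3m.each_row() += net.b3.row(0);
        Z3[s] = fcube(Z3m.memptr(), dm.h2, dm.w2, dm.f3);
        fcube A3 = Z3[s]; relu_inplace(A3);
        maxpool3(A3, P3[s], I3[s]);

        fmat A3m(P3[s].memptr(), dm.hw4, dm.f3, false, true);
        Z4[s] = A3m * net.W4; Z4[s].each_row() += net.b4.row(0);
        fmat A4 = Z4[s];
        A4.for_each([](float& v) { if (v < 0) v = 0; });
        B4.rows((uword)s * dm.hw4, (uword)(s + 1) * dm.hw4 - 1) = A4;
      }

      // batch norm (training statistics)
      const float N = (float)B4.n_rows;
      frowvec mu = sum(B4, 0) / N;
      fmat centered = B4.each_row() - mu;
      frowvec var = sum(square(centered), 0) / N;
      frowvec invstd = 1.0f / sqrt(var + BN_EPS);
      fmat xhat = centered.each_row() % invstd;
      fmat B5 = xhat.each_row() % net.gamma.row(0);
      B5.each_row() += net.beta.row(0);
      net.mov_mean = net.mov_mean * (float)bn_momentum + mu * (1.0f - (float)bn_momentum);
      net.mov_var = net.mov_var * (float)bn_momentum + var * (1.0f - (float)bn_momentum);

      fmat F(dm.flat, bn);
      for (int s = 0; s < bn; ++s)
        F.col(s) = vectorise(B5.rows((uword)s * dm.hw4, (uword)(s + 1) * dm.hw4 - 1));

      fmat Z5 = net.W5.t() * F;
      Z5.each_col() += net.b5.row(0).t();
      fmat A5 = Z5;
      A5.for_each([](float& v) { if (v < 0) v = 0; });

      fmat M(A5.n_rows, A5.n_cols, fill::ones);
      if (dropout_p > 0) {
        for (uword t = 0; t < M.n_elem; ++t)
          M(t) = (R::unif_rand() < keep) ? 1.0f / keep : 0.0f;
      }
      fmat A5d = A5 % M;

      fmat Z6 = net.W6.t() * A5d;
      Z6.each_col() += net.b6.row(0).t();
      fmat P = Z6;
      softmax_cols(P);

      // loss, accuracy, output gradient
      fmat dZ6(2, bn);
      for (int s = 0; s < bn; ++s) {
        const int ix = order[off + s];
        fvec y = {Y(ix, 0), Y(ix, 1)};
        fvec ys = y * (1.0f - eps_s) + eps_s / 2.0f;
        fvec p = P.col(s);
        fvec pc = clamp(p, PROB_CLIP, 1.0f - PROB_CLIP);
        ep_loss += -0.5 * accu(ys % log(pc) + (1.0f - ys) % log(1.0f - pc));
        if ((p(0) >= p(1)) == (y(0) >= y(1))) ++ep_correct;
        fvec g = 0.5f * (-(ys / pc) + (1.0f - ys) / (1.0f - pc)) / (float)bn;
        const float gp = dot(g, p);
        dZ6.col(s) = p % (g - gp);
      }

      // ---- backward ----
      for (auto& g : grads) g.reset();
      fmat dW6 = A5d * dZ6.t();
      fmat db6 = sum(dZ6, 1).t();
      fmat dA5 = net.W6 * dZ6;
      dA5 %= M;
      fmat dZ5 = dA5;
      { const float* z = Z5.memptr(); float* dd = dZ5.memptr();
        for (uword t = 0; t < dZ5.n_elem; ++t) if (z[t] <= 0) dd[t] = 0; }
      fmat dW5 = F * dZ5.t();
      fmat db5 = sum(dZ5, 1).t();
      fmat dF = net.W5 * dZ5;

      fmat dB5(B4.n_rows, dm.f4);
      for (int s = 0; s < bn; ++s)
        dB5.rows((uword)s * dm.hw4, (uword)(s + 1) * dm.hw4 - 1) =
            reshape(dF.col(s), dm.hw4, dm.f4);

      fmat dbeta = sum(dB5, 0);
      fmat dgamma = sum(dB5 % xhat, 0);
      fmat dxhat = dB5.each_row() % net.gamma.row(0);
      frowvec sum_dxhat = sum(dxhat, 0);
      frowvec sum_dxhat_xhat = sum(dxhat % xhat, 0);
      fmat dB4 = dxhat * N;
      dB4.each_row() -= sum_dxhat;
      dB4 -= xhat.each_row() % sum_dxhat_xhat;
      dB4.each_row() %= (invstd / N);

      fmat dW1(net.W1.n_rows, net.W1.n_cols, fill::zeros), db1(1, dm.f1, fill::zeros);
      fmat dW2(net.W2.n_rows, net.W2.n_cols, fill::zeros), db2(1, dm.f2, fill::zeros);
      fmat dW3(net.W3.n_rows, net.W3.n_cols, fill::zeros), db3(1, dm.f3, fill::zeros);
      fmat dW4(net.W4.n_rows, net.W4.n_cols, fill::zeros), db4(1, dm.f4, fill::zeros);

      fcube dP3(dm.h3, dm.w3, dm.f3), dA3(dm.h2, dm.w2, dm.f3);
      fcube dP2c(dm.h2, dm.w2, dm.f2), dA2(dm.h1, dm.w1, dm.f2);
      fcube dP1c(dm.h1, dm.w1, dm.f1), dA1(dm.h0, dm.w0, dm.f1);

      for (int s = 0; s < bn; ++s) {
        const int ix = order[off + s];
        fmat dA4 = dB4.rows((uword)s * dm.hw4, (uword)(s + 1) * dm.hw4 - 1);
        { const float* z = Z4[s].memptr(); float* dd = dA4.memptr();
          for (uword t = 0; t < dA4.n_elem; ++t) if (z[t] <= 0) dd[t] = 0; }
        fmat A3m(P3[s].memptr(), dm.hw4, dm.f3, false, true);
        dW4 += A3m.t() * dA4;
        db4 += sum(dA4, 0);
        fmat dA3m = dA4 * net.W4.t();
        std::memcpy(dP3.memptr(), dA3m.memptr(), sizeof(float) * dA3m.n_elem);

        unpool3(dP3, I3[s], dA3);
        fmat dZ3m(dA3.memptr(), dm.h2 * dm.w2, dm.f3, false, true);
        relu_mask(dZ3m, Z3[s]);
        fmat C3; im2col3(P2[s], C3);
        dW3 += C3.t() * dZ3m;
        db3 += sum(dZ3m, 0);
        fmat dC3 = dZ3m * net.W3.t();
        dP2c.zeros();
        col2im3(dC3, dP2c);

        unpool3(dP2c, I2[s], dA2);
        fmat dZ2m(dA2.memptr(), dm.h1 * dm.w1, dm.f2, false, true);
        relu_mask(dZ2m, Z2[s]);
        fmat C2; im2col3(P1[s], C2);
        dW2 += C2.t() * dZ2m;
        db2 += sum(dZ2m, 0);
        fmat dC2 = dZ2m * net.W2.t();
        dP1c.zeros();
        col2im3(dC2, dP1c);

        unpool3(dP1c, I1[s], dA1);
        fmat dZ1m(dA1.memptr(), dm.h0 * dm.w0, dm.f1, false, true);
        relu_mask(dZ1m, Z1[s]);
        fcube Xs(const_cast<float*>(X.colptr(ix)), dm.h0, dm.w0, dm.c0, false, true);
        fmat C1; im2col3(Xs, C1);
        dW1 += C1.t() * dZ1m;
        db1 += sum(dZ1m, 0);
      }

      std::vector<fmat*> gptr = {&dW1, &db1, &dW2, &db2, &dW3, &db3,
                                 &dW4, &db4, &dgamma, &dbeta,
                                 &dW5, &db5, &dW6, &db6};

      // Adam update
      ++tstep;
      const float bc1 = 1.0f - std::pow(ADAM_B1, (float)tstep);
      const float bc2 = 1.0f - std::pow(ADAM_B2, (float)tstep);
      for (size_t p = 0; p < params.size(); ++p) {
        fmat& g = *gptr[p];
        adam_m[p] = ADAM_B1 * adam_m[p] + (1.0f - ADAM_B1) * g;
        adam_v[p] = ADAM_B2 * adam_v[p] + (1.0f - ADAM_B2) * square(g);
        *params[p] -= (float)lr * (adam_m[p] / bc1) / (sqrt(adam_v[p] / bc2) + ADAM_EPS);
      }
    }

    hist_loss[ep] = ep_loss / n;
    hist_acc[ep] = (double)ep_correct / n;
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["weights"] = net_to_list(net),
                      _["loss"] = hist_loss, _["accuracy"] = hist_acc);
}

// ---------------------------------------------------------------------------
// inference (batch-norm uses moving statistics; dropout disabled)

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(NumericMatrix Xr, List wts,
                              int h, int w, int c, int batch_size) {
  Net net = net_from_list(wts);
  StageDims dm = stage_dims(net, h, w, c);
  const int d = h * w * c;
  const int n = Xr.ncol();
  if (Xr.nrow() != d) stop("sample length does not match h*w*c");

  frowvec invstd = 1.0f / sqrt(net.mov_var.row(0) + BN_EPS);
  NumericMatrix out(n, 2);

  for (int off = 0; off < n; off += batch_size) {
    const int bn = std::min(batch_size, n - off);
    fmat F(dm.flat, bn);
    for (int s = 0; s < bn; ++s) {
      const int ix = off + s;
      fcube Xs(dm.h0, dm.w0, dm.c0);
      for (int t = 0; t < d; ++t) Xs(t) = (float)Xr(t, ix);
      fmat C1; im2col3(Xs, C1);
      fmat Z1m = C1 * net.W1; Z1m.each_row() += net.b1.row(0);
      fcube A1(Z1m.memptr(), dm.h0, dm.w0, dm.f1);
      relu_inplace(A1);
      fcube P1; ucube I1; maxpool3(A1, P1, I1);

      fmat C2; im2col3(P1, C2);
      fmat Z2m = C2 * net.W2; Z2m.each_row() += net.b2.row(0);
      fcube A2(Z2m.memptr(), dm.h1, dm.w1, dm.f2);
      relu_inplace(A2);
      fcube P2; ucube I2; maxpool3(A2, P2, I2);

      fmat C3; im2col3(P2, C3);
      fmat Z3m = C3 * net.W3; Z3m.each_row() += net.b3.row(0);
      fcube A3(Z3m.memptr(), dm.h2, dm.w2, dm.f3);
      relu_inplace(A3);
      fcube P3; ucube I3; maxpool3(A3, P3, I3);

      fmat A3m(P3.memptr(), dm.hw4, dm.f3, false, true);
      fmat Z4 = A3m * net.W4; Z4.each_row() += net.b4.row(0);
      Z4.for_each([](float& v) { if (v < 0) v = 0; });

      fmat xhat = Z4.each_row() - net.mov_mean.row(0);
      xhat.each_row() %= invstd;
      fmat B5 = xhat.each_row() % net.gamma.row(0);
      B5.each_row() += net.beta.row(0);
      F.col(s) = vectorise(B5);
    }
    fmat Z5 = net.W5.t() * F;
    Z5.each_col() += net.b5.row(0).t();
    Z5.for_each([](float& v) { if (v < 0) v = 0; });
    fmat Z6 = net.W6.t() * Z5;
    Z6.each_col() += net.b6.row(0).t();
    softmax_cols(Z6);
    for (int s = 0; s < bn; ++s) {
      out(off + s, 0) = Z6(0, s);
      out(off + s, 1) = Z6(1, s);
    }
  }
  return out;
}
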