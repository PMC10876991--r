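// 1-D convolutional network: batched im2col forward/backward + Adam loop.
// Layout conventions (must match the R side):
//  - activations for conv stages are (B*len) x channels, position-major
//    (row index = pos*B + sample).
//  - W2 rows are ordered (kernel offset j, input channel k) as j*c1n + k.
//  - flatten is position-major over output channels: F(b, i*c2n + m).
// Dropout and shuffling consume R's RNG stream so set.seed() on the R side
// makes training bitwise reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;

static arma::mat gelu_mat(const arma::mat& x) {
  arma::mat out = x;
  out.transform([](double v) { return v * 0.5 * (1.0 + std::erf(v * INV_SQRT2)); });
  return out;
}

// d/dx x*Phi(x) = Phi(x) + x*phi(x)
static arma::mat gelu_grad_mat(const arma::mat& x) {
  arma::mat out = x;
  out.transform([](double v) {
    return 0.5 * (1.0 + std::erf(v * INV_SQRT2)) + v * INV_SQRT2PI * std::exp(-0.5 * v * v);
  });
  return out;
}

struct Spec {
  int L, c1k, c1n, p1, c2k, c2n, p2, D;
  int L1, P1, L2, P2, flat;
};

static Spec read_spec(const List& spec) {
  Spec s;
  s.L = as<int>(spec["input_len"]);
  s.c1k = as<int>(spec["conv1_kernel"]);
  s.c1n = as<int>(spec["conv1_filters"]);
  s.p1 = as<int>(spec["pool1"]);
  s.c2k = as<int>(spec["conv2_kernel"]);
  s.c2n = as<int>(spec["conv2_filters"]);
  s.p2 = as<int>(spec["pool2"]);
  s.D = as<int>(spec["dense_units"]);
  s.L1 = s.L - s.c1k + 1;
  s.P1 = s.L1 / s.p1;
  s.L2 = s.P1 - s.c2k + 1;
  s.P2 = s.L2 / s.p2;
  s.flat = s.P2 * s.c2n;
  if (s.L1 < 1 || s.P1 < 1 || s.L2 < 1 || s.P2 < 1)
    stop("architecture infeasible for input_len");
  return s;
}

struct Cache {
  arma::mat C1, Z1, A1, P1m, C2, Z2, A2, P2m, F, Z3, H, Hd, M;
  arma::umat mask1, mask2;
  arma::vec zout, p;
};

// max-pool over non-overlapping windows of size `period` along the position
// axis of a (B*len) x ch matrix; trailing remainder positions are dropped.
static void pool_forward(const arma::mat& A, int B, int len, int period,
                         arma::mat& P, arma::umat& mask) {
  int np = len / period;
  int ch = A.n_cols;
  P.set_size(np * B, ch);
  mask.set_size(np * B, ch);
  for (int t = 0; t < np; ++t) {
    arma::mat cur = A.rows(t * period * B, (t * period + 1) * B - 1);
    arma::umat arg(B, ch, arma::fill::zeros);
    for (int o = 1; o < period; ++o) {
      const arma::mat& cand = A.rows((t * period + o) * B, (t * period + o + 1) * B - 1);
      arma::umat upd = (cand > cur);
      arg(arma::find(upd)).fill((unsigned)o);
      cur = arma::max(cur, cand);
    }
    P.rows(t * B, (t + 1) * B - 1) = cur;
    mask.rows(t * B, (t + 1) * B - 1) = arg;
  }
}

static arma::mat pool_backward(const arma::mat& dP, const arma::umat& mask,
                               int B, int len, int period, int ch) {
  int np = dP.n_rows / B;
  arma::mat dA(len * B, ch, arma::fill::zeros);
  for (int t = 0; t < np; ++t) {
    const arma::mat& g = dP.rows(t * B, (t + 1) * B - 1);
    const arma::umat& mk = mask.rows(t * B, (t + 1) * B - 1);
    for (int o = 0; o < period; ++o) {
      arma::mat sel = arma::conv_to<arma::mat>::from(mk == (unsigned)o);
      dA.rows((t * period + o) * B, (t * period + o + 1) * B - 1) += g % sel;
    }
  }
  return dA;
}

static void forward(const Spec& s, const arma::mat& W1, const arma::vec& b1,
                    const arma::mat& W2, const arma::vec& b2,
                    const arma::mat& W3, const arma::vec& b3,
                    const arma::vec& W4, double b4,
                    const arma::mat& X, bool training, double dropout_p,
                    Cache& c) {
  int B = X.n_rows;
  // conv1 im2col: column j holds X[, j : j+L1-1] stacked position-major
  c.C1.set_size(B * s.L1, s.c1k);
  for (int j = 0; j < s.c1k; ++j)
    c.C1.col(j) = arma::vectorise(X.cols(j, j + s.L1 - 1));
  c.Z1 = c.C1 * W1;
  c.Z1.each_row() += b1.t();
  c.A1 = gelu_mat(c.Z1);
  pool_forward(c.A1, B, s.L1, s.p1, c.P1m, c.mask1);
  // conv2 im2col over channels
  c.C2.set_size(B * s.L2, s.c2k * s.c1n);
  for (int j = 0; j < s.c2k; ++j)
    c.C2.cols(j * s.c1n, (j + 1) * s.c1n - 1) = c.P1m.rows(j * B, (j + s.L2) * B - 1);
  c.Z2 = c.C2 * W2;
  c.Z2.each_row() += b2.t();
  c.A2 = gelu_mat(c.Z2);
  pool_forward(c.A2, B, s.L2, s.p2, c.P2m, c.mask2);
  // flatten: F(b, i*c2n + m) = P2m(i*B + b, m)
  c.F.set_size(B, s.flat);
  for (int i = 0; i < s.P2; ++i)
    c.F.cols(i * s.c2n, (i + 1) * s.c2n - 1) = c.P2m.rows(i * B, (i + 1) * B - 1);
  c.Z3 = c.F * W3;
  c.Z3.each_row() += b3.t();
  c.H = gelu_mat(c.Z3);
  if (training && dropout_p > 0) {
    c.M.set_size(B, s.D);
    double keep = 1.0 - dropout_p;
    for (arma::uword k = 0; k < c.M.n_elem; ++k)
      c.M(k) = (R::unif_rand() < dropout_p) ? 0.0 : 1.0 / keep;
    c.Hd = c.H % c.M;
  } else {
    c.M.reset();
    c.Hd = c.H;
  }
  c.zout = c.Hd * W4 + b4;
  c.p = 1.0 / (1.0 + arma::exp(-c.zout));
}

// [[Rcpp::export]]
arma::vec cnn_score_cpp(List params, List spec, const arma::mat& X) {
  Spec s = read_spec(spec);
  arma::mat W1 = as<arma::mat>(params["W1"]);
  arma::vec b1 = as<arma::vec>(params["b1"]);
  arma::mat W2 = as<arma::mat>(params["W2"]);
  arma::vec b2 = as<arma::vec>(params["b2"]);
  arma::mat W3 = as<arma::mat>(params["W3"]);
  arma::vec b3 = as<arma::vec>(params["b3"]);
  arma::vec W4 = as<arma::vec>(params["W4"]);
  double b4 = as<double>(params["b4"]);
  if ((int)X.n_cols != s.L) stop("matrix column count does not match input_len");
  Cache c;
  forward(s, W1, b1, W2, b2, W3, b3, W4, b4, X, false, 0.0, c);
  return c.p;
}

// [[Rcpp::export]]
List cnn_train_cpp(List params, List spec, const arma::mat& X, const arma::vec& y,
                   const arma::umat& perms, double lr, int batch_size,
                   double dropout_p, double beta1, double beta2, double adam_eps,
                   double clamp_eps) {
  Spec s = read_spec(spec);
  if ((int)X.n_cols != s.L) stop("matrix column count does not match input_len");
  int n = X.n_rows;
  int epochs = perms.n_cols;
  arma::mat W1 = as<arma::mat>(params["W1"]);
  arma::vec b1 = as<arma::vec>(params["b1"]);
  arma::mat W2 = as<arma::mat>(params["W2"]);
  arma::vec b2 = as<arma::vec>(params["b2"]);
  arma::mat W3 = as<arma::mat>(params["W3"]);
  arma::vec b3 = as<arma::vec>(params["b3"]);
  arma::vec W4 = as<arma::vec>(params["W4"]);
  double b4 = as<double>(params["b4"]);

  // Adam state, one slot per tensor (b4 kept as 1x1)
  std::vector<arma::mat*> Ws = {&W1, &W2, &W3};
  arma::mat mW1(arma::size(W1), arma::fill::zeros), vW1 = mW1;
  arma::mat mW2(arma::size(W2), arma::fill::zeros), vW2 = mW2;
  arma::mat mW3(arma::size(W3), arma::fill::zeros), vW3 = mW3;
  arma::vec mb1(arma::size(b1), arma::fill::zeros), vb1 = mb1;
  arma::vec mb2(arma::size(b2), arma::fill::zeros), vb2 = mb2;
  arma::vec mb3(arma::size(b3), arma::fill::zeros), vb3 = mb3;
  arma::vec mW4(arma::size(W4), arma::fill::zeros), vW4 = mW4;
  double mb4 = 0.0, vb4 = 0.0;
  long tstep = 0;

  arma::vec history(epochs, arma::fill::zeros);
  Cache c;

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size - 1, n - 1);
      int B = end - start + 1;
      arma::uvec idx(B);
      for (int r = 0; r < B; ++r) idx(r) = perms(start + r, ep) - 1;
      arma::mat Xb = X.rows(idx);
      arma::vec yb = y.elem(idx);

      forward(s, W1, b1, W2, b2, W3, b3, W4, b4, Xb, true, dropout_p, c);

      arma::vec pc = arma::clamp(c.p, clamp_eps, 1.0 - clamp_eps);
      double loss = -arma::mean(yb % arma::log(pc) + (1.0 - yb) % arma::log(1.0 - pc));
      ep_loss += loss * B;

      // backward
      arma::vec dz = (c.p - yb) / (double)B;
      arma::vec gW4 = c.Hd.t() * dz;
      double gb4 = arma::accu(dz);
      arma::mat dHd = dz * W4.t();
      arma::mat dH = c.M.is_empty() ? dHd : arma::mat(dHd % c.M);
      arma::mat dZ3 = dH % gelu_grad_mat(c.Z3);
      arma::mat gW3 = c.F.t() * dZ3;
      arma::vec gb3 = arma::sum(dZ3, 0).t();
      arma::mat dF = dZ3 * W3.t();
      arma::mat dP2(s.P2 * B, s.c2n);
      for (int i = 0; i < s.P2; ++i)
        dP2.rows(i * B, (i + 1) * B - 1) = dF.cols(i * s.c2n, (i + 1) * s.c2n - 1);
      arma::mat dA2 = pool_backward(dP2, c.mask2, B, s.L2, s.p2, s.c2n);
      arma::mat dZ2 = dA2 % gelu_grad_mat(c.Z2);
      arma::mat gW2 = c.C2.t() * dZ2;
      arma::vec gb2 = arma::sum(dZ2, 0).t();
      arma::mat dC2 = dZ2 * W2.t();
      arma::mat dP1(s.P1 * B, s.c1n, arma::fill::zeros);
      for (int j = 0; j < s.c2k; ++j)
        dP1.rows(j * B, (j + s.L2) * B - 1) += dC2.cols(j * s.c1n, (j + 1) * s.c1n - 1);
      arma::mat dA1 = pool_backward(dP1, c.mask1, B, s.L1, s.p1, s.c1n);
      arma::mat dZ1 = dA1 % gelu_grad_mat(c.Z1);
      arma::mat gW1 = c.C1.t() * dZ1;
      arma::vec gb1 = arma::sum(dZ1, 0).t();

      // Adam
      ++tstep;
      double bc1 = 1.0 - std::pow(beta1, (double)tstep);
      double bc2 = 1.0 - std::pow(beta2, (double)tstep);
      auto adam_m = [&](arma::mat& W, arma::mat& mm, arma::mat& vv, const arma::mat& g) {
        mm = beta1 * mm + (1.0 - beta1) * g;
        vv = beta2 * vv + (1.0 - beta2) * (g % g);
        W -= lr * (mm / bc1) / (arma::sqrt(vv / bc2) + adam_eps);
      };
      auto adam_v = [&](arma::vec& W, arma::vec& mm, arma::vec& vv, const arma::vec& g) {
        mm = beta1 * mm + (1.0 - beta1) * g;
        vv = beta2 * vv + (1.0 - beta2) * (g % g);
        W -= lr * (mm / bc1) / (arma::sqrt(vv / bc2) + adam_eps);
      };
      adam_m(W1, mW1, vW1, gW1);
      adam_v(b1, mb1, vb1, gb1);
      adam_m(W2, mW2, vW2, gW2);
      adam_v(b2, mb2, vb2, gb2);
      adam_m(W3, mW3, vW3, gW3);
      adam_v(b3, mb3, vb3, gb3);
      adam_v(W4, mW4, vW4, gW4);
      mb4 = beta1 * mb4 + (1.0 - beta1) * gb4;
      vb4 = beta2 * vb4 + (1.0 - beta2) * gb4 * gb4;
      b4 -= lr * (mb4 / bc1) / (std::sqrt(vb4 / bc2) + adam_eps);
    }
    history(ep) = ep_loss / n;
  }

  return List::create(
    _["params"] = List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2,
                               _["W3"] = W3, _["b3"] = b3, _["W4"] = W4, _["b4"] = b4),
    _["history"] = history);
}
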