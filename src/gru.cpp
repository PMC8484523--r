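// Fast path for GRU training: batched forward pass, backpropagation
// through time, and the (Nesterov) momentum update loop. Mirrors the R
// reference implementation in R/grunet.R exactly; the R version is kept
// as the readable specification and as a cross-check in the tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Grads {
  mat W_u, H_u, W_r, H_r, W, U;
  double loss;
};

// X: input_dim x N x T cube (slice t = inputs at timestep t)
// Y: hidden_dim x N, targets constant over time.
// The three hidden-to-hidden products per direction are evaluated as one
// stacked GEMM ([H_u; H_r; U] etc.); each output element is the same dot
// product as in the naive formulation.
static Grads loss_grad(const mat& W_u, const mat& H_u, const mat& W_r,
                       const mat& H_r, const mat& W, const mat& U,
                       const cube& X, const mat& Y, const int loss_kind,
                       cube* H_out) {
  const uword T = X.n_slices, N = X.n_cols, D = Y.n_rows,
              I = X.n_rows;
  const double norm = double(T) * double(D) * double(N);
  const mat G = join_cols(H_u, H_r, U);     // 3D x D (backward carry)
  const mat Gf = join_cols(H_u, H_r);       // 2D x D (forward gates)
  const mat Wf = join_cols(W_u, W_r);       // 2D x I
  cube Hc(D, N, T), Uc(D, N, T), Rc(D, N, T), Cc(D, N, T), UHc(D, N, T);
  mat H_prev(D, N, fill::zeros);
  double loss = 0.0;
  cube dHd(D, N, T);
  for (uword t = 0; t < T; ++t) {
    mat A = Wf * X.slice(t) + Gf * H_prev;  // stacked gate pre-activations
    mat u = sigm(A.rows(0, D - 1));
    mat r = sigm(A.rows(D, 2 * D - 1));
    mat UH = U * H_prev;
    mat c = tanh(W * X.slice(t) + r % UH);
    mat H = u % H_prev + (1.0 - u) % c;
    Uc.slice(t) = u; Rc.slice(t) = r; UHc.slice(t) = UH; Cc.slice(t) = c;
    Hc.slice(t) = H_prev;  // store the *previous* state for the backward pass
    if (loss_kind == 0) {
      loss += accu(square(H - Y));
      dHd.slice(t) = 2.0 * (H - Y) / norm;
    } else {
      mat s = clamp((H + 1.0) / 2.0, 1e-12, 1.0 - 1e-12);
      loss += accu(-(Y % log(s) + (1.0 - Y) % log(1.0 - s)));
      dHd.slice(t) = (s - Y) / (2.0 * s % (1.0 - s)) / norm;
    }
    if (H_out) H_out->slice(t) = H;
    H_prev = H;
  }
  Grads g;
  g.loss = loss / norm;
  mat Gacc(3 * D, D, fill::zeros);   // [gH_u; gH_r; gU]
  mat Xacc(3 * D, I, fill::zeros);   // [gW_u; gW_r; gW]
  mat S(3 * D, N);
  mat dH_carry(D, N, fill::zeros);
  for (uword ti = T; ti-- > 0;) {
    const mat& u = Uc.slice(ti); const mat& r = Rc.slice(ti);
    const mat& Uh = UHc.slice(ti); const mat& c = Cc.slice(ti);
    const mat& Hp = Hc.slice(ti);
    mat dH = dHd.slice(ti) + dH_carry;
    mat du = dH % (Hp - c);
    mat dc = dH % (1.0 - u);
    mat dH_prev = dH % u;
    mat dac = dc % (1.0 - square(c));
    mat dr = dac % Uh;
    mat dUh = dac % r;
    mat dau = du % u % (1.0 - u);
    mat dar = dr % r % (1.0 - r);
    S.rows(0, D - 1) = dau;
    S.rows(D, 2 * D - 1) = dar;
    S.rows(2 * D, 3 * D - 1) = dUh;
    Gacc += S * Hp.t();
    dH_prev += G.t() * S;
    S.rows(2 * D, 3 * D - 1) = dac;
    Xacc += S * X.slice(ti).t();
    dH_carry = dH_prev;
  }
  g.H_u = Gacc.rows(0, D - 1);
  g.H_r = Gacc.rows(D, 2 * D - 1);
  g.U = Gacc.rows(2 * D, 3 * D - 1);
  g.W_u = Xacc.rows(0, D - 1);
  g.W_r = Xacc.rows(D, 2 * D - 1);
  g.W = Xacc.rows(2 * D, 3 * D - 1);
  return g;
}

// [[Rcpp::export]]
Rcpp::List gru_loss_grad_cpp(Rcpp::List params, const arma::cube& X,
                             const arma::mat& Y, int loss_kind) {
  mat W_u = params["W_u"], H_u = params["H_u"], W_r = params["W_r"],
      H_r = params["H_r"], W = params["W"], U = params["U"];
  Grads g = loss_grad(W_u, H_u, W_r, H_r, W, U, X, Y, loss_kind, nullptr);
  return Rcpp::List::create(
    Rcpp::Named("loss") = g.loss,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("W_u") = g.W_u, Rcpp::Named("H_u") = g.H_u,
      Rcpp::Named("W_r") = g.W_r, Rcpp::Named("H_r") = g.H_r,
      Rcpp::Named("W") = g.W, Rcpp::Named("U") = g.U));
}

// Run n_epochs full-batch updates in place; returns the updated weights,
// velocities, and the loss at the last epoch (before its update).
// [[Rcpp::export]]
Rcpp::List gru_train_epochs_cpp(Rcpp::List params, Rcpp::List vel,
                                const arma::cube& X, const arma::mat& Y,
                                double lr, double momentum, bool nesterov,
                                int n_epochs, int loss_kind) {
  mat W_u = params["W_u"], H_u = params["H_u"], W_r = params["W_r"],
      H_r = params["H_r"], W = params["W"], U = params["U"];
  mat vW_u = vel["W_u"], vH_u = vel["H_u"], vW_r = vel["W_r"],
      vH_r = vel["H_r"], vW = vel["W"], vU = vel["U"];
  double loss = NA_REAL;
  auto upd = [&](mat& p, mat& v, const mat& gr) {
    v = momentum * v + gr;
    p -= lr * (nesterov ? gr + momentum * v : v);
  };
  for (int e = 0; e < n_epochs; ++e) {
    Grads g = loss_grad(W_u, H_u, W_r, H_r, W, U, X, Y, loss_kind, nullptr);
    loss = g.loss;
    upd(W_u, vW_u, g.W_u); upd(H_u, vH_u, g.H_u);
    upd(W_r, vW_r, g.W_r); upd(H_r, vH_r, g.H_r);
    upd(W, vW, g.W);       upd(U, vU, g.U);
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = Rcpp::List::create(
      Rcpp::Named("W_u") = W_u, Rcpp::Named("H_u") = H_u,
      Rcpp::Named("W_r") = W_r, Rcpp::Named("H_r") = H_r,
      Rcpp::Named("W") = W, Rcpp::Named("U") = U),
    Rcpp::Named("vel") = Rcpp::List::create(
      Rcpp::Named("W_u") = vW_u, Rcpp::Named("H_u") = vH_u,
      Rcpp::Named("W_r") = vW_r, Rcpp::Named("H_r") = vH_r,
      Rcpp::Named("W") = vW, Rcpp::Named("U") = vU),
    Rcpp::Named("loss") = loss);
}

// Batched forward pass; returns the hidden states as a hidden x N x T cube.
// [[Rcpp::export]]
arma::cube gru_forward_cpp(Rcpp::List params, const arma::cube& X) {
  mat W_u = params["W_u"], H_u = params["H_u"], W_r = params["W_r"],
      H_r = params["H_r"], W = params["W"], U = params["U"];
  const uword T = X.n_slices, N = X.n_cols, D = W_u.n_rows;
  cube H(D, N, T);
  mat H_prev(D, N, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const mat& Xt = X.slice(t);
    mat u = sigm(W_u * Xt + H_u * H_prev);
    mat r = sigm(W_r * Xt + H_r * H_prev);
    mat c = tanh(W * Xt + r % (U * H_prev));
    H_prev = u % H_prev + (1.0 - u) % c;
    H.slice(t) = H_prev;
  }
  return H;
}
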