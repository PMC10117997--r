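// Dense feed-forward decoder kernels: fused forward/backward/Adam steps for
// the multilayer-perceptron families (linear MLPs on one-hot codon inputs and
// embedding MLPs on codon indices).  The recurrent families are implemented
// in R; only the MLPs are ever driven through hundreds of thousands of
// iterations, so only they need a compiled hot loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

// activation codes: 0 = none, 1 = relu, 2 = tanh
inline void apply_act(mat& a, int act) {
  if (act == 1)      a.transform([](double x) { return x > 0.0 ? x : 0.0; });
  else if (act == 2) a = tanh(a);
}

// derivative expressed through the activated output
inline mat act_grad(const mat& a, int act) {
  if (act == 0) return ones(size(a));
  if (act == 1) return conv_to<mat>::from(a > 0.0);
  return 1.0 - square(a);  // tanh
}

struct Net {
  bool embed;
  int L;                 // number of affine layers
  mat E;                 // 64 x d, only when embed
  std::vector<mat> W;
  std::vector<rowvec> b;
};

Net unpack(const Rcpp::List& params, bool embed) {
  Net net;
  net.embed = embed;
  int off = embed ? 1 : 0;
  net.L = (params.size() - off) / 2;
  if (embed) net.E = Rcpp::as<mat>(params[0]);
  net.W.resize(net.L);
  net.b.resize(net.L);
  for (int l = 0; l < net.L; ++l) {
    net.W[l] = Rcpp::as<mat>(params[off + 2 * l]);
    net.b[l] = Rcpp::as<rowvec>(params[off + 2 * l + 1]);
  }
  return net;
}

// forward through the affine stack; fills activations a[0..L] and returns
// softmax probabilities
mat forward_stack(const Net& net, const mat& x0, int act, std::vector<mat>& a) {
  a.resize(net.L + 1);
  a[0] = x0;
  for (int l = 0; l < net.L; ++l) {
    a[l + 1] = a[l] * net.W[l];
    a[l + 1].each_row() += net.b[l];
    if (l < net.L - 1) apply_act(a[l + 1], act);
  }
  mat z = a[net.L];
  z.each_col() -= max(z, 1);
  mat p = exp(z);
  p.each_col() /= sum(p, 1);
  return p;
}

template <typename T>
inline void adam_update(T& w, T& m, T& v, const T& g,
                        double lr, double b1, double b2, double eps,
                        double c1, double c2) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * square(g);
  w -= lr * (m * c1) / (sqrt(v * c2) + eps);
}

}  // namespace

// [[Rcpp::export(name = ".nn_forward_cpp")]]
arma::mat nn_forward_cpp(Rcpp::List params, arma::ivec idx, arma::mat enc,
                         bool embed, int activation) {
  Net net = unpack(params, embed);
  uvec rows = conv_to<uvec>::from(idx - 1);
  mat x0 = embed ? net.E.rows(rows) : enc.rows(rows);
  std::vector<mat> a;
  return forward_stack(net, x0, activation, a);
}

// Runs n_iter optimization steps.  idx/y are 1-based codon (1..64) and class
// (1..21) indices for the whole chunk; starts is a 0-based offset vector of
// length n_iter + 1 delimiting the batches.  Returns updated parameters and
// Adam moments together with the per-iteration loss and training accuracy.
// [[Rcpp::export(name = ".nn_train_chunk_cpp")]]
Rcpp::List nn_train_chunk_cpp(Rcpp::List params, Rcpp::List m_in, Rcpp::List v_in,
                              int t0, arma::ivec idx, arma::ivec y,
                              arma::ivec starts, arma::mat enc, bool embed,
                              int activation, arma::vec class_w, double lr,
                              double beta1, double beta2, double eps) {
  Net net = unpack(params, embed);
  Net m = unpack(m_in, embed);
  Net v = unpack(v_in, embed);
  const int n_iter = starts.n_elem - 1;
  vec losses(n_iter), accs(n_iter);
  std::vector<mat> a;

  for (int it = 0; it < n_iter; ++it) {
    const int s = starts[it], e = starts[it + 1], B = e - s;
    uvec rows(B);
    for (int i = 0; i < B; ++i) rows[i] = idx[s + i] - 1;
    mat x0 = embed ? net.E.rows(rows) : enc.rows(rows);
    mat p = forward_stack(net, x0, activation, a);

    // weighted multinomial cross-entropy and argmax training accuracy
    double loss = 0.0;
    int hits = 0;
    mat g = p;
    for (int i = 0; i < B; ++i) {
      const int c = y[s + i] - 1;
      const double w = class_w[c];
      loss += -w * std::log(p(i, c) + 1e-12);
      if ((int)p.row(i).index_max() == c) ++hits;
      g(i, c) -= 1.0;
      g.row(i) *= w;
    }
    losses[it] = loss / B;
    accs[it] = (double)hits / B;
    g /= B;

    const double t = (double)t0 + it + 1;
    const double c1 = 1.0 / (1.0 - std::pow(beta1, t));
    const double c2 = 1.0 / (1.0 - std::pow(beta2, t));

    for (int l = net.L - 1; l >= 0; --l) {
      mat dW = a[l].t() * g;
      rowvec db = sum(g, 0);
      if (l > 0) {
        g = g * net.W[l].t();
        g %= act_grad(a[l], activation);
      } else if (net.embed) {
        g = g * net.W[0].t();  // gradient w.r.t. the gathered embedding rows
      }
      adam_update(net.W[l], m.W[l], v.W[l], dW, lr, beta1, beta2, eps, c1, c2);
      adam_update(net.b[l], m.b[l], v.b[l], db, lr, beta1, beta2, eps, c1, c2);
    }
    if (net.embed) {
      mat dE(size(net.E), fill::zeros);
      for (int i = 0; i < B; ++i) dE.row(rows[i]) += g.row(i);
      adam_update(net.E, m.E, v.E, dE, lr, beta1, beta2, eps, c1, c2);
    }
  }

  Rcpp::List out_p = Rcpp::clone(params), out_m = Rcpp::clone(m_in),
             out_v = Rcpp::clone(v_in);
  const int off = net.embed ? 1 : 0;
  if (net.embed) {
    out_p[0] = net.E;
    out_m[0] = m.E;
    out_v[0] = v.E;
  }
  for (int l = 0; l < net.L; ++l) {
    out_p[off + 2 * l] = net.W[l];
    out_m[off + 2 * l] = m.W[l];
    out_v[off + 2 * l] = v.W[l];
    // biases go back as plain numeric vectors, matching the R-side layout
    out_p[off + 2 * l + 1] = Rcpp::NumericVector(net.b[l].begin(), net.b[l].end());
    out_m[off + 2 * l + 1] = Rcpp::NumericVector(m.b[l].begin(), m.b[l].end());
    out_v[off + 2 * l + 1] = Rcpp::NumericVector(v.b[l].begin(), v.b[l].end());
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = out_p, Rcpp::Named("m") = out_m,
      Rcpp::Named("v") = out_v, Rcpp::Named("loss") = losses,
      Rcpp::Named("acc") = accs);
}
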