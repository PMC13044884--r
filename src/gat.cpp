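// Compact graph-attention-network regressor: forward pass, analytic
// backward pass and an RMSprop training loop over a node-batched dataset.
// All graphs of a dataset are stacked into one block; `src`/`dst` hold
// directed edges (both bond directions plus self-loops, 0-based into the
// stacked node matrix) and `graph_id` maps nodes to molecules.
//
// Layer l:  Z = X W + b;  e_k = leakyrelu(a1.Z[src_k] + a2.Z[dst_k]);
//           alpha = softmax of e over the incoming edges of each dst node;
//           A_i = sum_k alpha_k Z[src_k];  H = tanh(A) (identity on the
//           last layer, whose single channel is the per-node output).
//
// Node matrices are held transposed (channels x nodes, arma column-major)
// so the per-edge gathers and scatters touch contiguous memory.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LEAKY_SLOPE = 0.2;

struct Layer {          // Wt is (fan_out x fan_in)
  mat Wt; vec b; vec a1; vec a2;
};

struct LayerCache {
  mat Xt, Zt, Ht;       // input, transformed, activated (all C x N)
  vec e, alpha;         // per-edge pre-activation and attention weight
};

static void gat_layer_forward(const mat& Xt, const Layer& L,
                              const uvec& src, const uvec& dst,
                              bool last, LayerCache& C) {
  const uword N = Xt.n_cols, E = src.n_elem, Co = L.Wt.n_rows;
  C.Xt = Xt;
  C.Zt = L.Wt * Xt;
  C.Zt.each_col() += L.b;
  vec ss = C.Zt.t() * L.a1;
  vec sd = C.Zt.t() * L.a2;
  C.e.set_size(E);
  vec g(E);
  for (uword k = 0; k < E; ++k) {
    double ek = ss[src[k]] + sd[dst[k]];
    C.e[k] = ek;
    g[k] = ek > 0 ? ek : LEAKY_SLOPE * ek;
  }
  vec m(N, fill::value(-datum::inf));
  for (uword k = 0; k < E; ++k) if (g[k] > m[dst[k]]) m[dst[k]] = g[k];
  vec w(E), S(N, fill::zeros);
  for (uword k = 0; k < E; ++k) { w[k] = std::exp(g[k] - m[dst[k]]); S[dst[k]] += w[k]; }
  C.alpha.set_size(E);
  for (uword k = 0; k < E; ++k) C.alpha[k] = w[k] / S[dst[k]];
  mat At(Co, N, fill::zeros);
  {
    double* A = At.memptr();
    const double* Z = C.Zt.memptr();
    for (uword k = 0; k < E; ++k) {
      double a = C.alpha[k];
      double* Ad = A + Co * dst[k];
      const double* Zs = Z + Co * src[k];
      for (uword c = 0; c < Co; ++c) Ad[c] += a * Zs[c];
    }
  }
  C.Ht = last ? At : mat(tanh(At));
}

static mat gat_layer_backward(const Layer& L, const LayerCache& C,
                              const uvec& src, const uvec& dst, bool last,
                              const mat& dHt,
                              mat& dWt, vec& db, vec& da1, vec& da2) {
  const uword N = C.Xt.n_cols, E = src.n_elem, Co = C.Zt.n_rows;
  mat dAt = last ? dHt : mat(dHt % (1.0 - C.Ht % C.Ht));
  vec dalpha(E);
  mat dZt(Co, N, fill::zeros);
  {
    const double* dA = dAt.memptr();
    const double* Z = C.Zt.memptr();
    double* dZ = dZt.memptr();
    for (uword k = 0; k < E; ++k) {
      const double* dAd = dA + Co * dst[k];
      const double* Zs = Z + Co * src[k];
      double* dZs = dZ + Co * src[k];
      double acc = 0.0, a = C.alpha[k];
      for (uword c = 0; c < Co; ++c) {
        acc += dAd[c] * Zs[c];
        dZs[c] += a * dAd[c];
      }
      dalpha[k] = acc;
    }
  }
  vec csum(N, fill::zeros);
  for (uword k = 0; k < E; ++k) csum[dst[k]] += C.alpha[k] * dalpha[k];
  vec dss(N, fill::zeros), dsd(N, fill::zeros);
  for (uword k = 0; k < E; ++k) {
    double dg = C.alpha[k] * (dalpha[k] - csum[dst[k]]);
    double de = C.e[k] > 0 ? dg : LEAKY_SLOPE * dg;
    dss[src[k]] += de;
    dsd[dst[k]] += de;
  }
  dZt += L.a1 * dss.t() + L.a2 * dsd.t();
  da1 = C.Zt * dss;
  da2 = C.Zt * dsd;
  dWt = dZt * C.Xt.t();
  db = sum(dZt, 1);
  return L.Wt.t() * dZt;
}

static std::vector<Layer> init_layers(const std::vector<uword>& dims,
                                      unsigned int seed) {
  std::mt19937 rng(seed);
  std::vector<Layer> layers;
  for (size_t l = 0; l + 1 < dims.size(); ++l) {
    uword fin = dims[l], fout = dims[l + 1];
    double lim = std::sqrt(6.0 / double(fin + fout));
    std::uniform_real_distribution<double> U(-lim, lim);
    Layer L;
    // fill in (fin x fout) order so the draw sequence matches the R-facing
    // column-major W layout regardless of the transposed storage
    mat W(fin, fout);
    for (uword j = 0; j < fout; ++j)
      for (uword i = 0; i < fin; ++i) W(i, j) = U(rng);
    L.Wt = W.t();
    L.b.zeros(fout);
    double lima = std::sqrt(6.0 / double(fout + 1));
    std::uniform_real_distribution<double> Ua(-lima, lima);
    L.a1.set_size(fout); L.a2.set_size(fout);
    for (uword i = 0; i < fout; ++i) L.a1[i] = Ua(rng);
    for (uword i = 0; i < fout; ++i) L.a2[i] = Ua(rng);
    layers.push_back(std::move(L));
  }
  return layers;
}

static vec forward_all(const mat& Xt, const std::vector<Layer>& layers,
                       const uvec& src, const uvec& dst,
                       std::vector<LayerCache>& caches) {
  mat H = Xt;
  caches.resize(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    gat_layer_forward(H, layers[l], src, dst, l + 1 == layers.size(), caches[l]);
    H = caches[l].Ht;
  }
  return H.row(0).t();
}

static Rcpp::List layers_to_R(const std::vector<Layer>& layers) {
  Rcpp::List out(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    out[l] = Rcpp::List::create(
      Rcpp::Named("W") = mat(layers[l].Wt.t()), Rcpp::Named("b") = layers[l].b,
      Rcpp::Named("a1") = layers[l].a1, Rcpp::Named("a2") = layers[l].a2);
  }
  return out;
}

static std::vector<Layer> layers_from_R(Rcpp::List L) {
  std::vector<Layer> layers(L.size());
  for (int l = 0; l < L.size(); ++l) {
    Rcpp::List li = L[l];
    layers[l].Wt = Rcpp::as<mat>(li["W"]).t();
    layers[l].b = Rcpp::as<vec>(li["b"]);
    layers[l].a1 = Rcpp::as<vec>(li["a1"]);
    layers[l].a2 = Rcpp::as<vec>(li["a2"]);
  }
  return layers;
}

// [[Rcpp::export(name = ".gat_train_cpp")]]
Rcpp::List gat_train_cpp(const arma::mat& X,
                         const arma::uvec& src, const arma::uvec& dst,
                         const arma::uvec& graph_id,
                         const arma::ivec& readout_node,
                         const arma::vec& targets,
                         int n_layers, int channels,
                         int epochs, double lr, int seed,
                         double rms_alpha = 0.99, double rms_eps = 1e-8) {
  const uword n_graphs = targets.n_elem;
  const mat Xt = X.t();
  vec graph_size(n_graphs, fill::zeros);
  for (uword i = 0; i < graph_id.n_elem; ++i) graph_size[graph_id[i]] += 1.0;

  std::vector<uword> dims;
  dims.push_back(Xt.n_rows);
  for (int l = 0; l < n_layers - 1; ++l) dims.push_back((uword)channels);
  dims.push_back(1);
  std::vector<Layer> layers = init_layers(dims, (unsigned int)seed);

  std::vector<Layer> v;   // RMSprop accumulators
  for (auto& L : layers) {
    Layer s;
    s.Wt.zeros(L.Wt.n_rows, L.Wt.n_cols); s.b.zeros(L.b.n_elem);
    s.a1.zeros(L.a1.n_elem); s.a2.zeros(L.a2.n_elem);
    v.push_back(std::move(s));
  }

  std::vector<LayerCache> caches;
  vec losses(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    vec node_out = forward_all(Xt, layers, src, dst, caches);
    vec y(n_graphs, fill::zeros);
    for (uword i = 0; i < node_out.n_elem; ++i)
      y[graph_id[i]] += node_out[i];
    for (uword g = 0; g < n_graphs; ++g) {
      if (readout_node[g] >= 0) y[g] = node_out[(uword)readout_node[g]];
      else y[g] /= graph_size[g];
    }
    vec r = y - targets;
    double loss = dot(r, r) / double(n_graphs);
    losses[ep] = loss;
    if (!std::isfinite(loss)) {
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
    }
    vec dnode(node_out.n_elem, fill::zeros);
    for (uword i = 0; i < dnode.n_elem; ++i) {
      uword g = graph_id[i];
      if (readout_node[g] < 0)
        dnode[i] = 2.0 * r[g] / double(n_graphs) / graph_size[g];
    }
    for (uword g = 0; g < n_graphs; ++g)
      if (readout_node[g] >= 0)
        dnode[(uword)readout_node[g]] += 2.0 * r[g] / double(n_graphs);
    mat dHt(1, dnode.n_elem);
    dHt.row(0) = dnode.t();
    for (int l = (int)layers.size() - 1; l >= 0; --l) {
      mat dWt; vec db, da1, da2;
      dHt = gat_layer_backward(layers[l], caches[l], src, dst,
                               l + 1 == (int)layers.size(), dHt,
                               dWt, db, da1, da2);
      v[l].Wt = rms_alpha * v[l].Wt + (1 - rms_alpha) * (dWt % dWt);
      v[l].b  = rms_alpha * v[l].b  + (1 - rms_alpha) * (db % db);
      v[l].a1 = rms_alpha * v[l].a1 + (1 - rms_alpha) * (da1 % da1);
      v[l].a2 = rms_alpha * v[l].a2 + (1 - rms_alpha) * (da2 % da2);
      layers[l].Wt -= lr * dWt / (sqrt(v[l].Wt) + rms_eps);
      layers[l].b  -= lr * db  / (sqrt(v[l].b)  + rms_eps);
      layers[l].a1 -= lr * da1 / (sqrt(v[l].a1) + rms_eps);
      layers[l].a2 -= lr * da2 / (sqrt(v[l].a2) + rms_eps);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("layers") = layers_to_R(layers),
    Rcpp::Named("loss") = losses);
}

// [[Rcpp::export(name = ".gat_forward_cpp")]]
arma::vec gat_forward_cpp(const arma::mat& X,
                          const arma::uvec& src, const arma::uvec& dst,
                          Rcpp::List layers) {
  std::vector<Layer> L = layers_from_R(layers);
  std::vector<LayerCache> caches;
  return forward_all(X.t(), L, src, dst, caches);
}
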