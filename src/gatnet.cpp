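// Graph attention / graph convolution engine.
//
// Implements the forward pass and a hand-derived reverse pass for the
// graph classifiers in this package:
//   node learner: multi-head graph attention layers (masked softmax
//                 attention over structural neighborhoods), or a GCN layer
//                 (first-order symmetric normalization, or Chebyshev
//                 polynomial filter of the scaled Laplacian),
//   head:         attention pooling (per-node sigmoid score P_i, softmax
//                 contribution weights A = softmax(W^A P), prob = A.P),
//                 average pooling (prob = mean P), or a dense softmax
//                 head on the spliced node representations.
//
// Parameters live in one flat vector; the layout is mirrored by
// gat_param_layout() on the R side and must stay in sync.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

constexpr double kEps = 1e-12;

struct GatLayerCfg {
  int heads;
  int units;
  int combine;  // 0 concat, 1 average
  int act;      // 0 leaky relu, 1 sigmoid, 2 identity
  int f_in;
  int f_out;    // width after combine
};

struct ModelCfg {
  int n_nodes = 0;
  int in_dim = 0;
  int node_learner = 0;  // 0 gat, 1 gcn first-order, 2 gcn chebyshev
  std::vector<GatLayerCfg> layers;
  int gcn_units = 24;
  int cheby_order = 3;
  int head = 0;  // 0 attention, 1 average, 2 fc
  int fc_units = 64;
  double lrelu_slope = 0.2;
  double attn_slope = 0.2;
  bool edge_weighted_attention = false;
  int f_last = 0;
};

ModelCfg parse_cfg(const List& config) {
  ModelCfg c;
  c.n_nodes = as<int>(config["n_nodes"]);
  c.in_dim = as<int>(config["in_dim"]);
  std::string nl = as<std::string>(config["node_learner"]);
  c.node_learner = (nl == "gat") ? 0 : (nl == "gcn1" ? 1 : 2);
  c.lrelu_slope = as<double>(config["lrelu_slope"]);
  c.attn_slope = as<double>(config["attn_slope"]);
  c.edge_weighted_attention = as<bool>(config["edge_weighted_attention"]);
  std::string hd = as<std::string>(config["head"]);
  c.head = (hd == "attention") ? 0 : (hd == "average" ? 1 : 2);
  c.fc_units = as<int>(config["fc_units"]);
  if (c.node_learner == 0) {
    IntegerVector heads = config["heads"], units = config["units"],
                  combine = config["combine"], act = config["activation"];
    int f_in = c.in_dim;
    for (int l = 0; l < heads.size(); ++l) {
      GatLayerCfg lc;
      lc.heads = heads[l];
      lc.units = units[l];
      lc.combine = combine[l];
      lc.act = act[l];
      lc.f_in = f_in;
      lc.f_out = lc.combine == 0 ? lc.heads * lc.units : lc.units;
      c.layers.push_back(lc);
      f_in = lc.f_out;
    }
    c.f_last = f_in;
  } else {
    c.gcn_units = as<int>(config["gcn_units"]);
    c.cheby_order = as<int>(config["cheby_order"]);
    c.f_last = c.gcn_units;
  }
  return c;
}

// Parameter slicing -------------------------------------------------------

struct ParamView {
  // gat: per layer, per head: W (units x f_in), a (2*units)
  std::vector<std::vector<arma::mat>> W;
  std::vector<std::vector<arma::vec>> a;
  // gcn: one or (order+1) weight matrices (units x in_dim)
  std::vector<arma::mat> Wg;
  // heads
  arma::vec wp;   // f_last
  arma::mat WA;   // N x N
  arma::mat W1;   // fc_units x N*f_last
  arma::vec b1;
  arma::mat W2;   // 2 x fc_units
  arma::vec b2;
};

int theta_length(const ModelCfg& c) {
  int n = 0;
  if (c.node_learner == 0) {
    for (const auto& l : c.layers) n += l.heads * (l.units * l.f_in + 2 * l.units);
  } else {
    int k = c.node_learner == 1 ? 1 : c.cheby_order + 1;
    n += k * c.gcn_units * c.in_dim;
  }
  if (c.head == 0) n += c.f_last + c.n_nodes * c.n_nodes;
  else if (c.head == 1) n += c.f_last;
  else n += c.fc_units * c.n_nodes * c.f_last + c.fc_units + 2 * c.fc_units + 2;
  return n;
}

// Map a flat parameter vector onto matrices without copying.
ParamView slice_theta(double* th, const ModelCfg& c) {
  ParamView p;
  size_t off = 0;
  if (c.node_learner == 0) {
    p.W.reserve(c.layers.size());
    p.a.reserve(c.layers.size());
    for (const auto& l : c.layers) {
      std::vector<arma::mat> Wl;
      std::vector<arma::vec> al;
      // reserve so growth never copies the aliasing views away from theta
      Wl.reserve(l.heads);
      al.reserve(l.heads);
      for (int k = 0; k < l.heads; ++k) {
        Wl.emplace_back(th + off, l.units, l.f_in, false, true);
        off += (size_t)l.units * l.f_in;
        al.emplace_back(th + off, 2 * l.units, false, true);
        off += 2 * l.units;
      }
      p.W.push_back(std::move(Wl));
      p.a.push_back(std::move(al));
    }
  } else {
    int nk = c.node_learner == 1 ? 1 : c.cheby_order + 1;
    p.Wg.reserve(nk);
    for (int k = 0; k < nk; ++k) {
      p.Wg.emplace_back(th + off, c.gcn_units, c.in_dim, false, true);
      off += (size_t)c.gcn_units * c.in_dim;
    }
  }
  if (c.head == 0 || c.head == 1) {
    p.wp = arma::vec(th + off, c.f_last, false, true);
    off += c.f_last;
    if (c.head == 0) {
      p.WA = arma::mat(th + off, c.n_nodes, c.n_nodes, false, true);
      off += (size_t)c.n_nodes * c.n_nodes;
    }
  } else {
    p.W1 = arma::mat(th + off, c.fc_units, c.n_nodes * c.f_last, false, true);
    off += (size_t)c.fc_units * c.n_nodes * c.f_last;
    p.b1 = arma::vec(th + off, c.fc_units, false, true);
    off += c.fc_units;
    p.W2 = arma::mat(th + off, 2, c.fc_units, false, true);
    off += 2 * (size_t)c.fc_units;
    p.b2 = arma::vec(th + off, 2, false, true);
    off += 2;
  }
  return p;
}

inline arma::mat lrelu(const arma::mat& x, double s) {
  arma::mat out = x;
  out.transform([s](double v) { return v > 0 ? v : s * v; });
  return out;
}

inline arma::mat lrelu_grad(const arma::mat& x, double s) {
  arma::mat g = x;
  g.transform([s](double v) { return v > 0 ? 1.0 : s; });
  return g;
}

inline arma::mat sigm(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Per-graph caches kept for the reverse pass.
struct GatHeadCache {
  arma::mat Z;      // N x units
  arma::mat A;      // N x N attention coefficients (zero off-neighborhood)
  arma::mat Eraw;   // raw scores before leaky relu (valid on mask)
  arma::mat U;      // N x units aggregated pre-activation
  arma::mat Hact;   // activated head output (concat layers)
};

struct LayerCache {
  arma::mat H_in;                 // layer input
  std::vector<GatHeadCache> hc;   // per head
  arma::mat Ubar;                 // average-combine pre-activation
  arma::mat H_out;
};

struct HeadCache {
  arma::mat H;     // node representations entering the head
  arma::vec q, P;  // pooling pre-activation and node scores
  arma::vec s, Am; // prediction scores and softmax weights
  double prob = 0.5;
  // fc head
  arma::vec x, z1, h1, z2, psm;
};

struct GraphCache {
  std::vector<LayerCache> layers;
  // gcn
  arma::mat Mnorm;             // normalized propagation matrix
  std::vector<arma::mat> Tk;   // chebyshev basis matrices
  arma::mat Ugcn;              // pre-activation
  HeadCache head;
};

// Masked row softmax of leaky-relu scores; returns attention matrix.
// Dense graphs (every entry masked in) take the vectorized path.
arma::mat masked_attention(const arma::mat& E, const arma::umat& mask,
                           bool dense) {
  int n = E.n_rows;
  if (dense) {
    arma::vec mx = arma::max(E, 1);
    if (!mx.is_finite())
      stop("non-finite attention scores (divergent parameters?)");
    arma::mat A = arma::exp(E.each_col() - mx);
    A.each_col() /= arma::sum(A, 1);
    return A;
  }
  arma::mat A(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double m = -arma::datum::inf;
    bool has_neighbor = false;
    for (int j = 0; j < n; ++j)
      if (mask(i, j)) {
        has_neighbor = true;
        if (E(i, j) > m) m = E(i, j);
      }
    if (!has_neighbor) stop("node %d has an empty neighborhood", i + 1);
    if (!std::isfinite(m))
      stop("non-finite attention scores at node %d (divergent parameters?)", i + 1);
    double s = 0;
    for (int j = 0; j < n; ++j)
      if (mask(i, j)) { A(i, j) = std::exp(E(i, j) - m); s += A(i, j); }
    A.row(i) /= s;
  }
  return A;
}

double forward_graph(const arma::mat& X, const arma::mat& Adj,
                     const ModelCfg& c, const ParamView& p, GraphCache& gc) {
  const int N = c.n_nodes;
  arma::umat mask = (Adj > 0);
  bool dense = arma::all(arma::vectorise(mask) > 0);
  arma::mat logw;
  if (c.edge_weighted_attention) {
    logw = arma::mat(N, N, arma::fill::zeros);
    arma::uvec nz = arma::find(Adj > 0);
    logw.elem(nz) = arma::log(Adj.elem(nz));
  }
  arma::mat H = X;
  if (c.node_learner == 0) {
    gc.layers.resize(c.layers.size());
    for (size_t l = 0; l < c.layers.size(); ++l) {
      const GatLayerCfg& lc = c.layers[l];
      LayerCache& Lc = gc.layers[l];
      Lc.H_in = H;
      Lc.hc.resize(lc.heads);
      arma::mat Hout;
      arma::mat Usum(N, lc.units, arma::fill::zeros);
      for (int k = 0; k < lc.heads; ++k) {
        GatHeadCache& hc = Lc.hc[k];
        hc.Z = H * p.W[l][k].t();                       // N x units
        arma::vec f = hc.Z * p.a[l][k].head(lc.units);  // source term
        arma::vec g = hc.Z * p.a[l][k].tail(lc.units);  // target term
        hc.Eraw.set_size(N, N);
        for (int j = 0; j < N; ++j)
          for (int i2 = 0; i2 < N; ++i2)
            hc.Eraw(i2, j) = f(i2) + g(j);
        arma::mat E = lrelu(hc.Eraw, c.attn_slope);
        if (c.edge_weighted_attention) E += logw;
        hc.A = masked_attention(E, mask, dense);
        hc.U = hc.A * hc.Z;
        if (lc.combine == 0) {
          hc.Hact = lc.act == 0 ? lrelu(hc.U, c.lrelu_slope)
                  : lc.act == 1 ? sigm(hc.U) : hc.U;
          Hout = k == 0 ? hc.Hact : arma::join_rows(Hout, hc.Hact);
        } else {
          Usum += hc.U;
        }
      }
      if (lc.combine == 1) {
        Lc.Ubar = Usum / lc.heads;
        Hout = lc.act == 0 ? lrelu(Lc.Ubar, c.lrelu_slope)
             : lc.act == 1 ? sigm(Lc.Ubar) : Lc.Ubar;
      }
      Lc.H_out = Hout;
      H = Hout;
    }
  } else {
    // symmetric degree normalization (self-loops assumed present in Adj)
    arma::vec d = arma::sum(Adj, 1);
    for (int i = 0; i < N; ++i) if (d(i) < kEps) d(i) = kEps;
    arma::vec dn = 1.0 / arma::sqrt(d);
    gc.Mnorm = Adj;
    gc.Mnorm.each_col() %= dn;
    gc.Mnorm.each_row() %= dn.t();
    arma::mat U;
    if (c.node_learner == 1) {
      gc.Tk = {gc.Mnorm};
      U = gc.Mnorm * X * p.Wg[0].t();
    } else {
      // scaled Laplacian with lambda_max ~ 2: Ltilde = -Mnorm
      arma::mat Lt = -gc.Mnorm;
      gc.Tk.clear();
      gc.Tk.push_back(arma::eye(N, N));
      if (c.cheby_order >= 1) gc.Tk.push_back(Lt);
      for (int k = 2; k <= c.cheby_order; ++k)
        gc.Tk.push_back(2.0 * Lt * gc.Tk[k - 1] - gc.Tk[k - 2]);
      U.zeros(N, c.gcn_units);
      for (size_t k = 0; k < gc.Tk.size(); ++k)
        U += gc.Tk[k] * X * p.Wg[k].t();
    }
    gc.Ugcn = U;
    H = lrelu(U, c.lrelu_slope);
  }

  HeadCache& h = gc.head;
  h.H = H;
  if (c.head == 0 || c.head == 1) {
    h.q = H * p.wp;
    h.P = sigm(h.q);
    if (c.head == 0) {
      h.s = p.WA * h.P;
      h.Am = arma::exp(h.s - h.s.max());
      h.Am /= arma::accu(h.Am);
      h.prob = arma::dot(h.Am, h.P);
    } else {
      // computed as a uniform-weight dot product so that the attention
      // head with zeroed prediction weights reproduces it bit for bit
      arma::vec unif(N);
      unif.fill(1.0 / N);
      h.prob = arma::dot(unif, h.P);
    }
  } else {
    h.x = arma::vectorise(H.t());  // node representations spliced row-major
    h.z1 = p.W1 * h.x + p.b1;
    h.h1 = lrelu(h.z1, c.lrelu_slope);
    h.z2 = p.W2 * h.h1 + p.b2;
    arma::vec e = arma::exp(h.z2 - h.z2.max());
    h.psm = e / arma::accu(e);
    h.prob = h.psm(1);
  }
  return h.prob;
}

// Reverse pass for one graph. dloss_dprob drives the head; returns the
// gradient w.r.t. the input features if want_xgrad.
void backward_graph(const arma::mat& X, const arma::mat& Adj, int y,
                    const ModelCfg& c, const ParamView& p, const GraphCache& gc,
                    ParamView& g, arma::mat* xgrad) {
  const int N = c.n_nodes;
  const HeadCache& h = gc.head;
  arma::mat dH;  // gradient w.r.t. node representations entering the head

  if (c.head == 2) {
    arma::vec dz2 = h.psm;
    dz2(y) -= 1.0;
    g.W2 += dz2 * h.h1.t();
    g.b2 += dz2;
    arma::vec dh1 = p.W2.t() * dz2;
    arma::vec dz1 = dh1 % arma::vectorise(lrelu_grad(h.z1, c.lrelu_slope));
    g.W1 += dz1 * h.x.t();
    g.b1 += dz1;
    arma::vec dx = p.W1.t() * dz1;
    dH = arma::reshape(dx, c.f_last, N).t();
  } else {
    double prob = std::min(std::max(h.prob, kEps), 1.0 - kEps);
    double dprob = (prob - (double)y) / std::max(prob * (1.0 - prob), kEps);
    arma::vec dP;
    if (c.head == 0) {
      arma::vec dAm = dprob * h.P;
      dP = dprob * h.Am;
      arma::vec ds = h.Am % (dAm - arma::dot(dAm, h.Am));
      g.WA += ds * h.P.t();
      dP += p.WA.t() * ds;
    } else {
      dP = arma::vec(N);
      dP.fill(dprob / N);
    }
    arma::vec dq = dP % h.P % (1.0 - h.P);
    g.wp += h.H.t() * dq;
    dH = dq * p.wp.t();
  }

  if (c.node_learner != 0) {
    arma::mat dU = dH % lrelu_grad(gc.Ugcn, c.lrelu_slope);
    arma::mat dX(N, c.in_dim, arma::fill::zeros);
    for (size_t k = 0; k < gc.Tk.size(); ++k) {
      arma::mat TH = gc.Tk[k] * X;
      g.Wg[k] += dU.t() * TH;
      if (xgrad) dX += gc.Tk[k].t() * dU * p.Wg[k];
    }
    if (xgrad) *xgrad += dX;
    return;
  }

  arma::umat mask = (Adj > 0);
  for (int l = (int)c.layers.size() - 1; l >= 0; --l) {
    const GatLayerCfg& lc = c.layers[l];
    const LayerCache& Lc = gc.layers[l];
    bool need_dHin = (l > 0) || (xgrad != nullptr);
    arma::mat dHin(N, lc.f_in, arma::fill::zeros);
    arma::mat dUbar;
    if (lc.combine == 1) {
      dUbar = lc.act == 0 ? dH % lrelu_grad(Lc.Ubar, c.lrelu_slope)
            : lc.act == 1 ? dH % (Lc.H_out % (1.0 - Lc.H_out))
            : dH;
    }
    for (int k = 0; k < lc.heads; ++k) {
      const GatHeadCache& hc = Lc.hc[k];
      arma::mat dU;
      if (lc.combine == 0) {
        arma::mat dHk = dH.cols(k * lc.units, (k + 1) * lc.units - 1);
        dU = lc.act == 0 ? dHk % lrelu_grad(hc.U, c.lrelu_slope)
           : lc.act == 1 ? dHk % (hc.Hact % (1.0 - hc.Hact))
           : dHk;
      } else {
        dU = dUbar / lc.heads;
      }
      arma::mat dA = dU * hc.Z.t();             // N x N
      arma::mat dZ = hc.A.t() * dU;             // N x units
      // softmax rows (A is zero off-neighborhood, which zeroes dE there)
      arma::vec rs = arma::sum(dA % hc.A, 1);
      arma::mat dE = hc.A % (dA.each_col() - rs);
      arma::mat dEraw = dE % lrelu_grad(hc.Eraw, c.attn_slope);
      arma::vec df = arma::sum(dEraw, 1);
      arma::vec dg = arma::sum(dEraw, 0).t();
      const arma::vec a1 = p.a[l][k].head(lc.units);
      const arma::vec a2 = p.a[l][k].tail(lc.units);
      g.a[l][k].head(lc.units) += hc.Z.t() * df;
      g.a[l][k].tail(lc.units) += hc.Z.t() * dg;
      dZ += df * a1.t() + dg * a2.t();
      g.W[l][k] += dZ.t() * Lc.H_in;
      if (need_dHin) dHin += dZ * p.W[l][k];
    }
    dH = dHin;
  }
  if (xgrad) *xgrad += dH;
}

double bce_loss(double prob, int y) {
  double p = std::min(std::max(prob, kEps), 1.0 - kEps);
  return y == 1 ? -std::log(p) : -std::log(1.0 - p);
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
int cpp_theta_length(List config) {
  ModelCfg c = parse_cfg(config);
  return theta_length(c);
}

// Forward over a batch; optionally accumulate parameter and input
// gradients of the summed cross-entropy loss.
// [[Rcpp::export]]
List cpp_batch(const arma::cube& X, const arma::cube& Adj,
               const arma::ivec& y, List config, const arma::vec& theta,
               bool grad = false, bool input_grad = false) {
  ModelCfg c = parse_cfg(config);
  if ((int)theta.n_elem != theta_length(c))
    stop("parameter vector has length %d, expected %d",
         (int)theta.n_elem, theta_length(c));
  const int B = X.n_slices;
  if ((int)Adj.n_slices != B || (int)y.n_elem != B)
    stop("batch size mismatch between features, adjacency and labels");
  ParamView p = slice_theta(const_cast<double*>(theta.memptr()), c);

  arma::vec gtheta;
  ParamView g;
  if (grad) {
    gtheta.zeros(theta.n_elem);
    g = slice_theta(gtheta.memptr(), c);
  }
  arma::cube xg;
  if (input_grad) xg.zeros(X.n_rows, X.n_cols, B);

  arma::vec probs(B);
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    GraphCache gc;
    probs(b) = forward_graph(X.slice(b), Adj.slice(b), c, p, gc);
    if (y(b) >= 0) {
      if (c.head == 2) {
        double py = std::max(gc.head.psm(y(b)), kEps);
        loss += -std::log(py);
      } else {
        loss += bce_loss(probs(b), y(b));
      }
    }
    if (grad || input_grad) {
      arma::mat xgb;
      if (input_grad) xgb.zeros(X.n_rows, X.n_cols);
      if (!grad) {
        gtheta.zeros(theta.n_elem > 0 ? theta.n_elem : 1);
        g = slice_theta(gtheta.memptr(), c);
      }
      backward_graph(X.slice(b), Adj.slice(b), y(b), c, p, gc,
                     g, input_grad ? &xgb : nullptr);
      if (input_grad) xg.slice(b) = xgb;
    }
  }
  List out = List::create(_["probs"] = probs, _["loss"] = loss);
  if (grad) out["grad"] = gtheta;
  if (input_grad) out["input_grad"] = xg;
  return out;
}

// Detailed forward for one graph: node scores, contribution weights and
// per-layer attention coefficient matrices.
// [[Rcpp::export]]
List cpp_forward_detail(const arma::mat& X, const arma::mat& Adj,
                        List config, const arma::vec& theta) {
  ModelCfg c = parse_cfg(config);
  if ((int)theta.n_elem != theta_length(c))
    stop("parameter vector has length %d, expected %d",
         (int)theta.n_elem, theta_length(c));
  ParamView p = slice_theta(const_cast<double*>(theta.memptr()), c);
  GraphCache gc;
  double prob = forward_graph(X, Adj, c, p, gc);
  List out = List::create(_["prob"] = prob);
  if (c.head == 0 || c.head == 1) {
    out["node_scores"] = gc.head.P;
    if (c.head == 0) out["contribution_weights"] = gc.head.Am;
  } else {
    out["class_probs"] = gc.head.psm;
  }
  if (c.node_learner == 0) {
    List attn(c.layers.size());
    for (size_t l = 0; l < c.layers.size(); ++l) {
      List al(c.layers[l].heads);
      for (int k = 0; k < c.layers[l].heads; ++k)
        al[k] = gc.layers[l].hc[k].A;
      attn[l] = al;
    }
    out["attention"] = attn;
  }
  out["node_repr"] = gc.head.H;
  return out;
}
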