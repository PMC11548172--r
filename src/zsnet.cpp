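// Zero-shot denoiser core: a small U-Net-style encoder-decoder with spatial
// batch normalization, trained per image by Adam on an MSE + anisotropic
// total-variation objective. Feature maps are stored as (H*W) x C matrices
// with pixels in column-major order (index = x*H + y, matching R matrices),
// so every 3x3 convolution reduces to nine shifted GEMMs.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int OFF[9][2] = {
  {-1, -1}, {-1, 0}, {-1, 1},
  { 0, -1}, { 0, 0}, { 0, 1},
  { 1, -1}, { 1, 0}, { 1, 1}
}; // (dy, dx): output pixel (y, x) reads input pixel (y + dy, x + dx)

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

// ---------------------------------------------------------------------------
// shifted copy with zero fill: out(y, x, :) = X(y + dy, x + dx, :)
static mat shift_map(const mat& X, int H, int W, int dy, int dx) {
  mat out(X.n_rows, X.n_cols, fill::zeros);
  int ys = std::max(0, -dy), ye = std::min(H, H - dy);
  int xs = std::max(0, -dx), xe = std::min(W, W - dx);
  if (ye <= ys || xe <= xs) return out;
  for (int x = xs; x < xe; ++x) {
    int sx = x + dx;
    out.rows(x * H + ys, x * H + ye - 1) =
      X.rows(sx * H + ys + dy, sx * H + ye - 1 + dy);
  }
  return out;
}

// ---------------------------------------------------------------------------
// parameters of one conv3x3 + batch-norm block
struct Layer {
  cube W;        // (Cin, Cout, 9)
  rowvec b;      // Cout
  rowvec gamma, beta, rmean, rvar;
};

struct LayerGrad {
  cube dW;
  rowvec db, dgamma, dbeta;
};

// each encoder/decoder level is a pair of conv+BN+ReLU blocks; the conv
// right after upsampling is a single block
struct Block { Layer a, b; };
struct BlockGrad { LayerGrad a, b; };

struct Net {
  int depth, base;
  std::vector<Block> enc;   // depth two-conv blocks
  Block bott;
  std::vector<Layer> up;    // decoder conv after upsampling, indexed by level
  std::vector<Block> post;  // decoder block after skip concatenation
  mat Wf;                   // final 1x1 conv (C0 x 1)
  double bf;
};

struct NetGrad {
  std::vector<BlockGrad> enc, post;
  std::vector<LayerGrad> up;
  BlockGrad bott;
  mat dWf;
  double dbf;
};

static int chan(int base, int level) { return base << level; }

// ---------------------------------------------------------------------------
// conv3x3 with "same" zero padding
static mat conv3_forward(const mat& X, int H, int W, const Layer& L) {
  mat Y(X.n_rows, L.W.n_cols);
  Y.each_row() = L.b;
  for (int k = 0; k < 9; ++k)
    Y += shift_map(X, H, W, OFF[k][0], OFF[k][1]) * L.W.slice(k);
  return Y;
}

static mat conv3_backward(const mat& X, const mat& dY, int H, int W,
                          const Layer& L, LayerGrad& G) {
  G.dW.set_size(L.W.n_rows, L.W.n_cols, 9);
  G.db = sum(dY, 0);
  mat dX(X.n_rows, X.n_cols, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    G.dW.slice(k) = shift_map(X, H, W, OFF[k][0], OFF[k][1]).t() * dY;
    dX += shift_map(dY, H, W, -OFF[k][0], -OFF[k][1]) * L.W.slice(k).t();
  }
  return dX;
}

// ---------------------------------------------------------------------------
// spatial batch norm over the H*W axis, one statistic per channel
struct BNCache { mat xhat; rowvec invstd; };

static mat bn_forward(const mat& X, Layer& L, bool training, BNCache* c) {
  rowvec mu, v;
  if (training) {
    mu = mean(X, 0);
    mat cen = X.each_row() - mu;
    v = mean(square(cen), 0);
    L.rmean = BN_MOMENTUM * L.rmean + (1.0 - BN_MOMENTUM) * mu;
    L.rvar  = BN_MOMENTUM * L.rvar  + (1.0 - BN_MOMENTUM) * v;
    rowvec invstd = 1.0 / sqrt(v + BN_EPS);
    mat xhat = cen.each_row() % invstd;
    if (c) { c->xhat = xhat; c->invstd = invstd; }
    return (xhat.each_row() % L.gamma).each_row() + L.beta;
  }
  mu = L.rmean;
  rowvec invstd = 1.0 / sqrt(L.rvar + BN_EPS);
  mat xhat = (X.each_row() - mu).each_row() % invstd;
  return (xhat.each_row() % L.gamma).each_row() + L.beta;
}

static mat bn_backward(const mat& dY, const BNCache& c, const Layer& L,
                       LayerGrad& G) {
  double N = (double)dY.n_rows;
  G.dgamma = sum(dY % c.xhat, 0);
  G.dbeta  = sum(dY, 0);
  mat dxhat = dY.each_row() % L.gamma;
  rowvec s1 = sum(dxhat, 0);
  rowvec s2 = sum(dxhat % c.xhat, 0);
  mat dX = dxhat;
  dX.each_row() -= s1 / N;
  dX -= c.xhat.each_row() % (s2 / N);
  dX.each_row() %= c.invstd;
  return dX;
}

// ---------------------------------------------------------------------------
// 2x2 max pooling (H, W even), argmax kept for the backward pass
static mat maxpool_forward(const mat& X, int H, int W, umat& idx) {
  int Ho = H / 2, Wo = W / 2, C = X.n_cols;
  mat out(Ho * Wo, C);
  idx.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        int cand[4] = {
          (2 * ox) * H + 2 * oy,      (2 * ox) * H + 2 * oy + 1,
          (2 * ox + 1) * H + 2 * oy,  (2 * ox + 1) * H + 2 * oy + 1
        };
        int best = cand[0];
        for (int j = 1; j < 4; ++j) if (xc[cand[j]] > xc[best]) best = cand[j];
        out(ox * Ho + oy, c) = xc[best];
        idx(ox * Ho + oy, c) = best;
      }
    }
  }
  return out;
}

static mat maxpool_backward(const mat& dY, const umat& idx, int Hin, int Win) {
  mat dX(Hin * Win, dY.n_cols, fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c)
    for (uword r = 0; r < dY.n_rows; ++r)
      dX(idx(r, c), c) += dY(r, c);
  return dX;
}

// ---------------------------------------------------------------------------
// nearest-neighbour 2x upsampling
static mat upsample_forward(const mat& X, int H, int W) {
  int Ho = 2 * H, Wo = 2 * W;
  mat out(Ho * Wo, X.n_cols);
  for (int ox = 0; ox < Wo; ++ox)
    for (int oy = 0; oy < Ho; ++oy)
      out.row(ox * Ho + oy) = X.row((ox / 2) * H + oy / 2);
  return out;
}

static mat upsample_backward(const mat& dY, int H, int W) {
  // H, W: input (coarse) dims
  int Ho = 2 * H;
  mat dX(H * W, dY.n_cols, fill::zeros);
  for (int ox = 0; ox < 2 * W; ++ox)
    for (int oy = 0; oy < Ho; ++oy)
      dX.row((ox / 2) * H + oy / 2) += dY.row(ox * Ho + oy);
  return dX;
}

// ---------------------------------------------------------------------------
// forward caches for one conv+BN+ReLU block
struct BlockCache {
  mat X;        // conv input
  BNCache bn;
  mat act;      // post-ReLU output (mask = act > 0)
  int H, W;
};

static mat block_forward(const mat& X, int H, int W, Layer& L, bool training,
                         BlockCache* c) {
  mat y = conv3_forward(X, H, W, L);
  y = bn_forward(y, L, training, c ? &c->bn : nullptr);
  y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  if (c) { c->X = X; c->act = y; c->H = H; c->W = W; }
  return y;
}

static mat block_backward(const mat& dOut, const BlockCache& c, const Layer& L,
                          LayerGrad& G) {
  mat d = dOut % (c.act > 0);                 // ReLU
  d = bn_backward(d, c.bn, L, G);             // batch norm
  return conv3_backward(c.X, d, c.H, c.W, L, G);
}

struct Block2Cache { BlockCache a, b; };

static mat block2_forward(const mat& X, int H, int W, Block& B, bool training,
                          Block2Cache* c) {
  mat y = block_forward(X, H, W, B.a, training, c ? &c->a : nullptr);
  return block_forward(y, H, W, B.b, training, c ? &c->b : nullptr);
}

static mat block2_backward(const mat& dOut, const Block2Cache& c,
                           const Block& B, BlockGrad& G) {
  mat d = block_backward(dOut, c.b, B.b, G.b);
  return block_backward(d, c.a, B.a, G.a);
}

// ---------------------------------------------------------------------------
struct FwdCache {
  std::vector<Block2Cache> enc, post;
  std::vector<BlockCache> up;
  std::vector<umat> poolIdx;
  std::vector<mat> skip;
  Block2Cache bott;
  mat Xf;     // input to the final 1x1 conv
  mat P;      // sigmoid output
};

static mat net_forward(Net& net, const mat& input, int H, int W,
                       bool training, FwdCache* fc) {
  int d = net.depth;
  if (fc) {
    fc->enc.resize(d); fc->up.resize(d); fc->post.resize(d);
    fc->poolIdx.resize(d); fc->skip.resize(d);
  }
  mat cur = input;
  int h = H, w = W;
  std::vector<mat> skip(d);
  for (int i = 0; i < d; ++i) {
    cur = block2_forward(cur, h, w, net.enc[i], training,
                         fc ? &fc->enc[i] : nullptr);
    skip[i] = cur;
    umat idx;
    cur = maxpool_forward(cur, h, w, idx);
    if (fc) { fc->poolIdx[i] = idx; fc->skip[i] = skip[i]; }
    h /= 2; w /= 2;
  }
  cur = block2_forward(cur, h, w, net.bott, training,
                       fc ? &fc->bott : nullptr);
  for (int i = d - 1; i >= 0; --i) {
    cur = upsample_forward(cur, h, w);
    h *= 2; w *= 2;
    cur = block_forward(cur, h, w, net.up[i], training,
                        fc ? &fc->up[i] : nullptr);
    mat cat = join_rows(cur, skip[i]);
    cur = block2_forward(cat, h, w, net.post[i], training,
                         fc ? &fc->post[i] : nullptr);
  }
  mat lin = cur * net.Wf;
  lin += net.bf;
  mat P = 1.0 / (1.0 + exp(-lin));
  if (fc) { fc->Xf = cur; fc->P = P; }
  return P;
}

static void net_backward(Net& net, FwdCache& fc, const mat& dP, NetGrad& G) {
  int d = net.depth;
  G.enc.resize(d); G.up.resize(d); G.post.resize(d);
  mat dlin = dP % fc.P % (1.0 - fc.P);
  G.dWf = fc.Xf.t() * dlin;
  G.dbf = accu(dlin);
  mat cur = dlin * net.Wf.t();
  std::vector<mat> dskip(d);
  for (int i = 0; i < d; ++i) {
    mat dcat = block2_backward(cur, fc.post[i], net.post[i], G.post[i]);
    int cs = net.up[i].W.n_cols;               // channels of the up branch
    cur = dcat.cols(0, cs - 1);
    dskip[i] = dcat.cols(cs, dcat.n_cols - 1);
    cur = block_backward(cur, fc.up[i], net.up[i], G.up[i]);
    cur = upsample_backward(cur, fc.up[i].H / 2, fc.up[i].W / 2);
  }
  cur = block2_backward(cur, fc.bott, net.bott, G.bott);
  for (int i = d - 1; i >= 0; --i) {
    cur = maxpool_backward(cur, fc.poolIdx[i], fc.enc[i].a.H, fc.enc[i].a.W);
    cur += dskip[i];
    cur = block2_backward(cur, fc.enc[i], net.enc[i], G.enc[i]);
  }
}

// ---------------------------------------------------------------------------
// loss: mean((P - T)^2) + lambda * mean(|dx P| + |dy P|), forward differences
// with edge replication (the last row/column difference is zero).
static void tv_terms(const mat& P, int H, int W, double& reg, mat& dreg) {
  reg = 0.0;
  dreg.zeros(P.n_rows, 1);
  const double* p = P.colptr(0);
  double* g = dreg.colptr(0);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int i = x * H + y;
      if (x < W - 1) {
        double ddx = p[i + H] - p[i];
        reg += std::fabs(ddx);
        double s = (ddx > 0) - (ddx < 0);
        g[i + H] += s; g[i] -= s;
      }
      if (y < H - 1) {
        double ddy = p[i + 1] - p[i];
        reg += std::fabs(ddy);
        double s = (ddy > 0) - (ddy < 0);
        g[i + 1] += s; g[i] -= s;
      }
    }
  }
  double N = (double)P.n_rows;
  reg /= N;
  dreg /= N;
}

// ---------------------------------------------------------------------------
// Adam
template <typename T>
static void adam_update(T& w, T& m, T& v, const T& g, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * square(g);
  T mh = m / (1.0 - std::pow(b1, t));
  T vh = v / (1.0 - std::pow(b2, t));
  w -= lr * (mh / (sqrt(vh) + eps));
}

struct AdamLayer { cube mW, vW; rowvec mb, vb, mg, vg, mB, vB; };
struct AdamBlock { AdamLayer a, b; };
struct AdamState {
  std::vector<AdamBlock> enc, post;
  std::vector<AdamLayer> up;
  AdamBlock bott;
  mat mWf, vWf;
  double mbf = 0.0, vbf = 0.0;
};

static AdamLayer adam_zeros(const Layer& L) {
  AdamLayer a;
  a.mW.zeros(L.W.n_rows, L.W.n_cols, 9); a.vW = a.mW;
  a.mb.zeros(L.b.n_elem); a.vb = a.mb;
  a.mg.zeros(L.gamma.n_elem); a.vg = a.mg;
  a.mB.zeros(L.beta.n_elem); a.vB = a.mB;
  return a;
}

static AdamBlock adam_zeros2(const Block& B) {
  AdamBlock a;
  a.a = adam_zeros(B.a);
  a.b = adam_zeros(B.b);
  return a;
}

static void adam_layer(Layer& L, AdamLayer& a, const LayerGrad& g,
                       double lr, double t) {
  adam_update(L.W, a.mW, a.vW, g.dW, lr, t);
  adam_update(L.b, a.mb, a.vb, g.db, lr, t);
  adam_update(L.gamma, a.mg, a.vg, g.dgamma, lr, t);
  adam_update(L.beta, a.mB, a.vB, g.dbeta, lr, t);
}

static AdamBlock adam_zeros2(const Block& B);
static void adam_block(Block& B, AdamBlock& a, const BlockGrad& g,
                       double lr, double t) {
  adam_layer(B.a, a.a, g.a, lr, t);
  adam_layer(B.b, a.b, g.b, lr, t);
}

// ---------------------------------------------------------------------------
// (de)serialization to a named R list
static void push_layer(Rcpp::List& out, const std::string& nm, const Layer& L) {
  Rcpp::NumericVector w(L.W.begin(), L.W.end());
  w.attr("dim") = Rcpp::IntegerVector::create(L.W.n_rows, L.W.n_cols, 9);
  out[nm + ".W"] = w;
  out[nm + ".b"] = Rcpp::NumericVector(L.b.begin(), L.b.end());
  out[nm + ".gamma"] = Rcpp::NumericVector(L.gamma.begin(), L.gamma.end());
  out[nm + ".beta"] = Rcpp::NumericVector(L.beta.begin(), L.beta.end());
  out[nm + ".rmean"] = Rcpp::NumericVector(L.rmean.begin(), L.rmean.end());
  out[nm + ".rvar"] = Rcpp::NumericVector(L.rvar.begin(), L.rvar.end());
}

static Layer pull_layer(const Rcpp::List& in, const std::string& nm,
                        int Cin, int Cout) {
  if (!in.containsElementNamed((nm + ".W").c_str()))
    Rcpp::stop("weight list is missing component '%s.W'", nm);
  Layer L;
  Rcpp::NumericVector w = in[nm + ".W"];
  Rcpp::IntegerVector dm = w.attr("dim");
  if (dm.size() != 3 || dm[0] != Cin || dm[1] != Cout || dm[2] != 9)
    Rcpp::stop("component '%s.W' has dimensions inconsistent with depth/baseChannels", nm);
  L.W = cube(w.begin(), Cin, Cout, 9);
  Rcpp::NumericVector b = in[nm + ".b"], g = in[nm + ".gamma"],
    be = in[nm + ".beta"], rm = in[nm + ".rmean"], rv = in[nm + ".rvar"];
  L.b = rowvec(b.begin(), b.size());
  L.gamma = rowvec(g.begin(), g.size());
  L.beta = rowvec(be.begin(), be.size());
  L.rmean = rowvec(rm.begin(), rm.size());
  L.rvar = rowvec(rv.begin(), rv.size());
  return L;
}

static void push_block(Rcpp::List& out, const std::string& nm,
                       const Block& B) {
  push_layer(out, nm + "a", B.a);
  push_layer(out, nm + "b", B.b);
}

static Block pull_block(const Rcpp::List& in, const std::string& nm,
                        int Cin, int Cout) {
  Block B;
  B.a = pull_layer(in, nm + "a", Cin, Cout);
  B.b = pull_layer(in, nm + "b", Cout, Cout);
  return B;
}

static Rcpp::List pack_net(const Net& net) {
  Rcpp::List out;
  for (int i = 0; i < net.depth; ++i)
    push_block(out, "enc" + std::to_string(i), net.enc[i]);
  push_block(out, "bott", net.bott);
  for (int i = 0; i < net.depth; ++i) {
    push_layer(out, "up" + std::to_string(i), net.up[i]);
    push_block(out, "post" + std::to_string(i), net.post[i]);
  }
  Rcpp::NumericVector wf(net.Wf.begin(), net.Wf.end());
  wf.attr("dim") = Rcpp::IntegerVector::create(net.Wf.n_rows, 1);
  out["final.W"] = wf;
  out["final.b"] = net.bf;
  return out;
}

static Net unpack_net(const Rcpp::List& in, int depth, int base) {
  Net net;
  net.depth = depth; net.base = base;
  net.enc.resize(depth); net.up.resize(depth); net.post.resize(depth);
  for (int i = 0; i < depth; ++i) {
    int cin = (i == 0) ? 1 : chan(base, i - 1);
    net.enc[i] = pull_block(in, "enc" + std::to_string(i), cin, chan(base, i));
  }
  net.bott = pull_block(in, "bott", chan(base, depth - 1), base << depth);
  for (int i = 0; i < depth; ++i) {
    int cin = (i == depth - 1) ? (base << depth) : chan(base, i + 1);
    net.up[i] = pull_layer(in, "up" + std::to_string(i), cin, chan(base, i));
    net.post[i] = pull_block(in, "post" + std::to_string(i),
                             2 * chan(base, i), chan(base, i));
  }
  Rcpp::NumericVector wf = in["final.W"];
  net.Wf = mat(wf.begin(), base, 1);
  net.bf = Rcpp::as<double>(in["final.b"]);
  return net;
}

// ---------------------------------------------------------------------------
static Layer init_layer(int Cin, int Cout, std::mt19937& rng) {
  std::normal_distribution<double> N01(0.0, 1.0);
  Layer L;
  double sd = std::sqrt(2.0 / (9.0 * Cin));   // He initialization
  L.W.set_size(Cin, Cout, 9);
  for (uword i = 0; i < L.W.n_elem; ++i) L.W(i) = sd * N01(rng);
  L.b.zeros(Cout);
  L.gamma.ones(Cout);
  L.beta.zeros(Cout);
  L.rmean.zeros(Cout);
  L.rvar.ones(Cout);
  return L;
}

static Block init_block(int Cin, int Cout, std::mt19937& rng) {
  Block B;
  B.a = init_layer(Cin, Cout, rng);
  B.b = init_layer(Cout, Cout, rng);
  return B;
}

// [[Rcpp::export(name = ".net_init")]]
Rcpp::List net_init_cpp(int depth, int base, int seed) {
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> N01(0.0, 1.0);
  Net net;
  net.depth = depth; net.base = base;
  for (int i = 0; i < depth; ++i) {
    int cin = (i == 0) ? 1 : chan(base, i - 1);
    net.enc.push_back(init_block(cin, chan(base, i), rng));
  }
  net.bott = init_block(chan(base, depth - 1), base << depth, rng);
  net.up.resize(depth); net.post.resize(depth);
  for (int i = depth - 1; i >= 0; --i) {
    int cin = (i == depth - 1) ? (base << depth) : chan(base, i + 1);
    net.up[i] = init_layer(cin, chan(base, i), rng);
    net.post[i] = init_block(2 * chan(base, i), chan(base, i), rng);
  }
  double sdf = std::sqrt(2.0 / (double)base);
  net.Wf.set_size(base, 1);
  for (uword i = 0; i < net.Wf.n_elem; ++i) net.Wf(i) = sdf * N01(rng);
  net.bf = 0.0;
  return pack_net(net);
}

// [[Rcpp::export(name = ".net_train")]]
Rcpp::List net_train_cpp(Rcpp::List weights, Rcpp::NumericMatrix A,
                         Rcpp::NumericMatrix B, int epochs, double lr,
                         double lambda, int depth, int base) {
  int H = A.nrow(), W = A.ncol();
  if (B.nrow() != H || B.ncol() != W)
    Rcpp::stop("input and target shapes differ: %d x %d vs %d x %d",
               H, W, B.nrow(), B.ncol());
  if (H % (1 << depth) != 0 || W % (1 << depth) != 0)
    Rcpp::stop("training images must be padded to a multiple of 2^depth");
  Net net = unpack_net(weights, depth, base);
  mat Am(A.begin(), H * W, 1);
  mat Bm(B.begin(), H * W, 1);
  double N = (double)(H * W);

  AdamState st;
  for (int i = 0; i < depth; ++i) {
    st.enc.push_back(adam_zeros2(net.enc[i]));
    st.up.push_back(adam_zeros(net.up[i]));
    st.post.push_back(adam_zeros2(net.post[i]));
  }
  st.bott = adam_zeros2(net.bott);
  st.mWf.zeros(net.Wf.n_rows, 1); st.vWf = st.mWf;

  std::vector<double> lossTr(epochs), mseTr(epochs), regTr(epochs);
  for (int e = 0; e < epochs; ++e) {
    FwdCache fc;
    mat P = net_forward(net, Am, H, W, true, &fc);
    mat diff = P - Bm;
    double mse = accu(square(diff)) / N;
    double reg; mat dreg;
    tv_terms(P, H, W, reg, dreg);
    lossTr[e] = mse + lambda * reg;
    mseTr[e] = mse;
    regTr[e] = reg;
    mat dP = 2.0 * diff / N + lambda * dreg;
    NetGrad G;
    net_backward(net, fc, dP, G);
    double t = (double)(e + 1);
    for (int i = 0; i < depth; ++i) {
      adam_block(net.enc[i], st.enc[i], G.enc[i], lr, t);
      adam_layer(net.up[i], st.up[i], G.up[i], lr, t);
      adam_block(net.post[i], st.post[i], G.post[i], lr, t);
    }
    adam_block(net.bott, st.bott, G.bott, lr, t);
    adam_update(net.Wf, st.mWf, st.vWf, G.dWf, lr, t);
    // scalar bias of the output conv
    {
      const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
      st.mbf = b1 * st.mbf + (1 - b1) * G.dbf;
      st.vbf = b2 * st.vbf + (1 - b2) * G.dbf * G.dbf;
      net.bf -= lr * (st.mbf / (1 - std::pow(b1, t))) /
        (std::sqrt(st.vbf / (1 - std::pow(b2, t))) + eps);
    }
    if (e % 10 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = pack_net(net),
    Rcpp::Named("loss") = lossTr,
    Rcpp::Named("mse") = mseTr,
    Rcpp::Named("reg") = regTr);
}

// [[Rcpp::export(name = ".net_predict")]]
Rcpp::NumericMatrix net_predict_cpp(Rcpp::List weights, Rcpp::NumericMatrix X,
                                    int depth, int base) {
  int H = X.nrow(), W = X.ncol();
  if (H % (1 << depth) != 0 || W % (1 << depth) != 0)
    Rcpp::stop("inference input must be padded to a multiple of 2^depth");
  Net net = unpack_net(weights, depth, base);
  mat Xm(X.begin(), H * W, 1);
  mat P = net_forward(net, Xm, H, W, false, nullptr);
  Rcpp::NumericMatrix out(H, W);
  std::copy(P.begin(), P.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// k x k median filter with edge-replicated borders; no range assumptions.
// [[Rcpp::export(name = ".median_filter")]]
Rcpp::NumericMatrix median_filter_cpp(Rcpp::NumericMatrix X, int kernel) {
  if (kernel < 3 || kernel % 2 == 0)
    Rcpp::stop("kernel must be an odd integer >= 3");
  int H = X.nrow(), W = X.ncol(), r = kernel / 2;
  Rcpp::NumericMatrix out(H, W);
  std::vector<double> buf(kernel * kernel);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int n = 0;
      for (int dx = -r; dx <= r; ++dx) {
        int sx = std::min(std::max(x + dx, 0), W - 1);
        for (int dy = -r; dy <= r; ++dy) {
          int sy = std::min(std::max(y + dy, 0), H - 1);
          buf[n++] = X(sy, sx);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(y, x) = buf[n / 2];
    }
  }
  return out;
}
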