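// Minimal CNN engine: stride-2 3x3 convolution blocks with ReLU, global
// average pooling and a linear head. Implements forward, backward (for Adam
// training from R) and feature extraction for gradient-weighted class
// activation mapping. Single-threaded, deterministic: all randomness (init,
// shuffling) lives on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Arch {
  ivec channels;   // output channels per conv block
  ivec strides;    // per-block stride
  int ksize, pad, n_out, hidden;          // hidden = 0 -> linear head
};

Arch read_arch(const Rcpp::List& arch) {
  Arch a;
  a.channels = Rcpp::as<ivec>(arch["channels"]);
  a.ksize  = Rcpp::as<int>(arch["ksize"]);
  a.strides = Rcpp::as<ivec>(arch["stride"]);
  if (a.strides.n_elem == 1) a.strides = ivec(a.channels.n_elem, fill::value(a.strides(0)));
  if (a.strides.n_elem != a.channels.n_elem) Rcpp::stop("stride/channels length mismatch");
  a.pad    = Rcpp::as<int>(arch["pad"]);
  a.n_out  = Rcpp::as<int>(arch["n_out"]);
  a.hidden = arch.containsElementNamed("hidden") ?
    Rcpp::as<int>(arch["hidden"]) : 0;
  return a;
}

inline int out_dim(int n, int k, int s, int p) { return (n + 2 * p - k) / s + 1; }

// Unfold (h, w, cin) into (cin*k*k, ho*wo); output pixels column-major.
void im2col(const cube& x, int k, int s, int p, mat& cols) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int ho = out_dim(h, k, s, p), wo = out_dim(w, k, s, p);
  cols.zeros(cin * k * k, ho * wo);
  for (int ci = 0; ci < cin; ++ci) {
    const mat& xs = x.slice(ci);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int row = ci * k * k + kx * k + ky;
        for (int jo = 0; jo < wo; ++jo) {
          const int jin = jo * s + kx - p;
          if (jin < 0 || jin >= w) continue;
          double* dst = cols.colptr(jo * ho) + row;
          for (int io = 0; io < ho; ++io) {
            const int iin = io * s + ky - p;
            if (iin >= 0 && iin < h) dst[io * cols.n_rows] = xs(iin, jin);
          }
        }
      }
    }
  }
}

// Scatter-add (cin*k*k, ho*wo) gradient columns back onto the input grid.
void col2im(const mat& cols, int h, int w, int cin, int k, int s, int p, cube& dx) {
  const int ho = out_dim(h, k, s, p), wo = out_dim(w, k, s, p);
  dx.zeros(h, w, cin);
  for (int ci = 0; ci < cin; ++ci) {
    mat& ds = dx.slice(ci);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int row = ci * k * k + kx * k + ky;
        for (int jo = 0; jo < wo; ++jo) {
          const int jin = jo * s + kx - p;
          if (jin < 0 || jin >= w) continue;
          const double* src = cols.colptr(jo * ho) + row;
          for (int io = 0; io < ho; ++io) {
            const int iin = io * s + ky - p;
            if (iin >= 0 && iin < h) ds(iin, jin) += src[io * cols.n_rows];
          }
        }
      }
    }
  }
}

// Forward pass for one image; caches per-layer inputs when training.
struct Cache {
  std::vector<cube> acts;   // acts[0] = input, acts[l+1] = post-ReLU output of block l
  std::vector<mat>  cols;   // im2col matrices per block (training only)
  vec pooled;               // GAP vector
  vec hid;                  // post-ReLU hidden head activations (if hidden > 0)
  vec out;                  // head output
};

void forward_one(const cube& x, const Rcpp::List& params, const Arch& a,
                 bool keep, Cache& cc) {
  const int L = a.channels.n_elem;
  cc.acts.clear(); cc.cols.clear();
  cc.acts.push_back(x);
  cube cur = x;
  for (int l = 0; l < L; ++l) {
    const mat W = Rcpp::as<mat>(params[2 * l]);
    const vec b = Rcpp::as<vec>(params[2 * l + 1]);
    mat cols;
    im2col(cur, a.ksize, a.strides(l), a.pad, cols);
    mat y = W * cols;
    y.each_col() += b;
    y.transform([](double v) { return v > 0.0 ? v : 0.0; });
    const int ho = out_dim(cur.n_rows, a.ksize, a.strides(l), a.pad);
    const int wo = out_dim(cur.n_cols, a.ksize, a.strides(l), a.pad);
    cube nxt(ho, wo, a.channels[l]);
    for (int c = 0; c < a.channels[l]; ++c)
      nxt.slice(c) = reshape(y.row(c), ho, wo);
    if (keep) cc.cols.push_back(cols);
    cur = nxt;
    cc.acts.push_back(cur);
  }
  const int C = cur.n_slices;
  vec f(C);
  for (int c = 0; c < C; ++c) f(c) = accu(cur.slice(c)) / (cur.n_rows * cur.n_cols);
  cc.pooled = f;
  if (a.hidden > 0) {
    const mat W1 = Rcpp::as<mat>(params[2 * L]);
    const vec b1 = Rcpp::as<vec>(params[2 * L + 1]);
    const mat W2 = Rcpp::as<mat>(params[2 * L + 2]);
    const vec b2 = Rcpp::as<vec>(params[2 * L + 3]);
    cc.hid = W1 * f + b1;
    cc.hid.transform([](double v) { return v > 0.0 ? v : 0.0; });
    cc.out = W2 * cc.hid + b2;
  } else {
    const mat Wf = Rcpp::as<mat>(params[2 * L]);
    const vec bf = Rcpp::as<vec>(params[2 * L + 1]);
    cc.out = Wf * f + bf;
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn_forward(const arma::cube& imgs, const Rcpp::List& params,
                           const Rcpp::List& arch, bool want_features) {
  const Arch a = read_arch(arch);
  const int n = imgs.n_slices;
  mat preds(a.n_out, n);
  Rcpp::List feats(want_features ? n : 0);
  Cache cc;
  for (int i = 0; i < n; ++i) {
    cube x(imgs.n_rows, imgs.n_cols, 1);
    x.slice(0) = imgs.slice(i);
    forward_one(x, params, a, false, cc);
    preds.col(i) = cc.out;
    if (want_features) feats[i] = cc.acts.back();
  }
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("pred") = preds);
  if (want_features) res["features"] = feats;
  return res;
}

// One mini-batch: forward + loss + full backward. task: 0 = L1 age
// regression (labels = years), 1 = softmax cross-entropy (labels = class
// index 0/1, where column 0 of the head is the male logit).
// [[Rcpp::export]]
Rcpp::List cpp_cnn_batch_grad(const arma::cube& imgs, const arma::vec& labels,
                              const Rcpp::List& params, const Rcpp::List& arch,
                              int task) {
  const Arch a = read_arch(arch);
  const int L = a.channels.n_elem;
  const int n = imgs.n_slices;
  if ((int)labels.n_elem != n) Rcpp::stop("labels/images length mismatch");

  // zero-grad accumulators mirroring params (L conv blocks + 1 or 2 head layers)
  const int H = params.size() / 2;
  std::vector<mat> gW(H);
  std::vector<vec> gb(H);
  for (int l = 0; l < H; ++l) {
    gW[l].zeros(Rcpp::as<mat>(params[2 * l]).n_rows, Rcpp::as<mat>(params[2 * l]).n_cols);
    gb[l].zeros(Rcpp::as<vec>(params[2 * l + 1]).n_elem);
  }
  double loss = 0.0;
  Cache cc;
  for (int i = 0; i < n; ++i) {
    cube x(imgs.n_rows, imgs.n_cols, 1);
    x.slice(0) = imgs.slice(i);
    forward_one(x, params, a, true, cc);
    vec dout(a.n_out);
    if (task == 0) {
      const double r = cc.out(0) - labels(i);
      loss += std::abs(r) / n;
      dout(0) = (r > 0 ? 1.0 : (r < 0 ? -1.0 : 0.0)) / n;
    } else {
      vec z = cc.out;
      z -= z.max();
      vec p = exp(z) / accu(exp(z));
      const int y = (int)labels(i);
      loss += -std::log(std::max(p(y), 1e-12)) / n;
      dout = p / n;
      dout(y) -= 1.0 / n;
    }
    // head
    vec df;
    if (a.hidden > 0) {
      const mat W1 = Rcpp::as<mat>(params[2 * L]);
      const mat W2 = Rcpp::as<mat>(params[2 * L + 2]);
      gW[L + 1] += dout * cc.hid.t();
      gb[L + 1] += dout;
      vec dh = (W2.t() * dout) % conv_to<vec>::from(cc.hid > 0);
      gW[L] += dh * cc.pooled.t();
      gb[L] += dh;
      df = W1.t() * dh;
    } else {
      const mat Wf = Rcpp::as<mat>(params[2 * L]);
      gW[L] += dout * cc.pooled.t();
      gb[L] += dout;
      df = Wf.t() * dout;
    }
    // GAP -> last feature maps
    const cube& F = cc.acts.back();
    const double np = F.n_rows * F.n_cols;
    cube dcur(F.n_rows, F.n_cols, F.n_slices);
    for (unsigned c = 0; c < F.n_slices; ++c) dcur.slice(c).fill(df(c) / np);
    // conv blocks, last to first
    for (int l = L - 1; l >= 0; --l) {
      const cube& act = cc.acts[l + 1];   // post-ReLU output of block l
      const cube& in  = cc.acts[l];
      const int ho = act.n_rows, wo = act.n_cols, co = act.n_slices;
      mat dy(co, ho * wo);
      for (int c = 0; c < co; ++c) {
        mat g = dcur.slice(c) % conv_to<mat>::from(act.slice(c) > 0);
        dy.row(c) = vectorise(g).t();
      }
      gW[l] += dy * cc.cols[l].t();
      gb[l] += sum(dy, 1);
      if (l > 0) {
        const mat Wl = Rcpp::as<mat>(params[2 * l]);
        mat dcols = Wl.t() * dy;
        col2im(dcols, in.n_rows, in.n_cols, in.n_slices, a.ksize,
               a.strides(l), a.pad, dcur);
      }
    }
  }
  Rcpp::List grads(2 * H);
  for (int l = 0; l < H; ++l) {
    grads[2 * l] = gW[l];
    grads[2 * l + 1] = gb[l];
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss, Rcpp::Named("grads") = grads);
}
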