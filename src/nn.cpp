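// Compact CPU convolutional-network engine backing the four segmentation
// networks (plain U-Nets and the dual-encoder attention variant).
//
// Conventions: a sample is an arma::cube (H x W x C, column-major slices);
// a batch is a std::vector of such cubes.  Convolutions are im2row + GEMM.
// All state (parameters, Adam moments, batch-norm running statistics) lives
// behind an external pointer handed to R; parameter values are initialised
// from R so that every source of randomness is under R's RNG.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
#include <memory>
#include <vector>
#include <string>
#include <chrono>
#include <map>

static std::map<std::string, double> g_timers;
struct ScopeTimer {
  std::string key; std::chrono::high_resolution_clock::time_point t0;
  ScopeTimer(const std::string& k) : key(k), t0(std::chrono::high_resolution_clock::now()) {}
  ~ScopeTimer() {
    g_timers[key] += std::chrono::duration<double>(
      std::chrono::high_resolution_clock::now() - t0).count();
  }
};

using namespace arma;

// The engine computes in single precision: convolution is memory-bandwidth
// and GEMM bound, and float halves the traffic at ample precision for SGD.
typedef float real_t;
typedef arma::Mat<real_t> rmat;
typedef arma::Col<real_t> rvec;
typedef arma::Cube<real_t> rcube;
typedef std::vector<rcube> Batch;

struct Opt {
  double lr = 1e-3, b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long t = 0;           // Adam step counter
  bool update = true;   // false: collect gradients instead of stepping
};

struct Param {
  rmat w, m, v, gacc;
  std::string name;
  int fan_in = 1;

  void init(int r, int c, int fi, const std::string& nm) {
    w.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
    fan_in = fi; name = nm;
  }
  void apply(const rmat& g, Opt& o) {
    ScopeTimer st_("adam");
    if (!o.update) { gacc = g; return; }
    const real_t b1 = (real_t)o.b1, b2 = (real_t)o.b2;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    const real_t c1 = (real_t)(1.0 - std::pow(o.b1, (double)o.t));
    const real_t c2 = (real_t)(1.0 - std::pow(o.b2, (double)o.t));
    w -= (real_t)o.lr * (m / c1) / (sqrt(v / c2) + (real_t)o.eps);
  }
};

// ---------------------------------------------------------------------------
// Convolution, kernel k x k (k = 3 pad 1, or k = 1 pad 0), optional bias.
// Weight layout: (cin*k*k) x cout; im2row X: (H*W*N) x (cin*k*k).
struct Conv {
  int cin = 0, cout = 0, k = 3;
  bool use_bias = true;
  Param W, b;
  rmat X;                 // im2row cache
  int H = 0, Wd = 0, N = 0;

  void init(int ci, int co, int kk, bool bias, const std::string& nm) {
    cin = ci; cout = co; k = kk; use_bias = bias;
    W.init(ci * kk * kk, co, ci * kk * kk, nm + ".w");
    if (bias) b.init(co, 1, ci * kk * kk, nm + ".b");
  }

  void im2row(const Batch& x, rmat& out) const {
    ScopeTimer st_("conv.im2row");
    const int HW = H * Wd, p = k / 2;
    out.zeros(HW * N, cin * k * k);
    for (int c = 0; c < cin; ++c)
      for (int dj = -p; dj <= p; ++dj)
        for (int di = -p; di <= p; ++di) {
          const int col = c * k * k + (dj + p) * k + (di + p);
          real_t* dst = out.colptr(col);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const int j0 = std::max(0, -dj), j1 = std::min(Wd, Wd - dj);
          if (i1 <= i0) continue;
          for (int n = 0; n < N; ++n) {
            const real_t* src = x[(size_t)n].slice_memptr(c);
            for (int j = j0; j < j1; ++j)
              std::memcpy(dst + (size_t)n * HW + (size_t)j * H + i0,
                          src + (size_t)(j + dj) * H + (i0 + di),
                          sizeof(real_t) * (size_t)(i1 - i0));
          }
        }
  }

  Batch forward(const Batch& x, bool /*train*/) {
    ScopeTimer st_("conv.fwd");
    N = (int)x.size(); H = x[0].n_rows; Wd = x[0].n_cols;
    const int HW = H * Wd;
    im2row(x, X);
    rmat Y = X * W.w;                      // (HW*N) x cout
    if (use_bias) Y.each_row() += b.w.t();
    Batch y((size_t)N);
    for (int n = 0; n < N; ++n) {
      y[(size_t)n].set_size(H, Wd, cout);
      for (int c = 0; c < cout; ++c)
        std::memcpy(y[(size_t)n].slice_memptr(c),
                    Y.colptr(c) + (size_t)n * HW, sizeof(real_t) * HW);
    }
    return y;
  }

  Batch backward(const Batch& dy, Opt& o) {
    ScopeTimer st_("conv.bwd");
    const int HW = H * Wd, p = k / 2;
    rmat dY(HW * N, cout);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c)
        std::memcpy(dY.colptr(c) + (size_t)n * HW,
                    dy[(size_t)n].slice_memptr(c), sizeof(real_t) * HW);
    rmat dW = X.t() * dY;
    rmat dX = dY * W.w.t();                // (HW*N) x (cin*k*k)
    Batch dx((size_t)N, rcube(H, Wd, cin, fill::zeros));
    for (int c = 0; c < cin; ++c)
      for (int dj = -p; dj <= p; ++dj)
        for (int di = -p; di <= p; ++di) {
          const int col = c * k * k + (dj + p) * k + (di + p);
          const real_t* src = dX.colptr(col);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const int j0 = std::max(0, -dj), j1 = std::min(Wd, Wd - dj);
          if (i1 <= i0) continue;
          for (int n = 0; n < N; ++n) {
            real_t* dst = dx[(size_t)n].slice_memptr(c);
            for (int j = j0; j < j1; ++j) {
              real_t* d = dst + (size_t)(j + dj) * H + (i0 + di);
              const real_t* s = src + (size_t)n * HW + (size_t)j * H + i0;
              for (int i = 0; i < i1 - i0; ++i) d[i] += s[i];
            }
          }
        }
    W.apply(dW, o);
    if (use_bias) b.apply(sum(dY, 0).t(), o);
    return dx;
  }
};

// ---------------------------------------------------------------------------
// Batch normalisation over (batch, H, W) per channel.
struct BNorm {
  int C = 0;
  Param g, bt;
  rvec rmean, rvar;      // running statistics (inference mode)
  real_t mom = 0.9f, eps = 1e-5f;
  Batch xhat;
  rvec istd;
  real_t cnt = 0;

  void init(int c, const std::string& nm) {
    C = c;
    g.init(c, 1, 1, nm + ".gamma");
    bt.init(c, 1, 1, nm + ".beta");
    rmean.zeros(c); rvar.ones(c);
  }

  Batch forward(const Batch& x, bool train) {
    ScopeTimer st_("bn.fwd");
    const int N = (int)x.size(), H = x[0].n_rows, W = x[0].n_cols;
    Batch y((size_t)N, rcube(H, W, C));
    if (train) {
      cnt = (real_t)((double)N * H * W);
      rvec mu(C), var(C);
      for (int c = 0; c < C; ++c) {
        double s = 0, s2 = 0;
        for (int n = 0; n < N; ++n) {
          s += accu(x[(size_t)n].slice(c));
          s2 += accu(square(x[(size_t)n].slice(c)));
        }
        mu(c) = (real_t)(s / cnt);
        var(c) = (real_t)std::max(s2 / cnt - (double)mu(c) * mu(c), 0.0);
      }
      istd = 1 / sqrt(var + eps);
      rmean = mom * rmean + (1 - mom) * mu;
      rvar  = mom * rvar  + (1 - mom) * var * (cnt / std::max(cnt - 1, (real_t)1));
      xhat.assign((size_t)N, rcube(H, W, C));
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c) {
          xhat[(size_t)n].slice(c) = (x[(size_t)n].slice(c) - mu(c)) * istd(c);
          y[(size_t)n].slice(c) = g.w(c, 0) * xhat[(size_t)n].slice(c) + bt.w(c, 0);
        }
    } else {
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c)
          y[(size_t)n].slice(c) =
            g.w(c, 0) * (x[(size_t)n].slice(c) - rmean(c)) / std::sqrt(rvar(c) + eps) +
            bt.w(c, 0);
    }
    return y;
  }

  Batch backward(const Batch& dy, Opt& o) {
    ScopeTimer st_("bn.bwd");
    const int N = (int)dy.size(), H = dy[0].n_rows, W = dy[0].n_cols;
    rmat dg(C, 1), db(C, 1);
    Batch dx((size_t)N, rcube(H, W, C));
    for (int c = 0; c < C; ++c) {
      double sdy = 0, sdyx = 0;
      for (int n = 0; n < N; ++n) {
        sdy += accu(dy[(size_t)n].slice(c));
        sdyx += accu(dy[(size_t)n].slice(c) % xhat[(size_t)n].slice(c));
      }
      dg(c, 0) = (real_t)sdyx; db(c, 0) = (real_t)sdy;
      const real_t gc = g.w(c, 0), ic = istd(c);
      for (int n = 0; n < N; ++n)
        dx[(size_t)n].slice(c) =
          (gc * ic / cnt) *
          (cnt * dy[(size_t)n].slice(c) - (real_t)sdy -
           xhat[(size_t)n].slice(c) * (real_t)sdyx);
    }
    g.apply(dg, o); bt.apply(db, o);
    return dx;
  }
};

// ---------------------------------------------------------------------------
// Conv -> BN -> ReLU, twice ("encoder-style" block).
struct Block {
  Conv c1, c2;
  BNorm n1, n2;
  Batch y1, y2;          // post-ReLU caches (masks)

  void init(int cin, int cout, const std::string& nm) {
    c1.init(cin, cout, 3, false, nm + ".conv1");
    n1.init(cout, nm + ".bn1");
    c2.init(cout, cout, 3, false, nm + ".conv2");
    n2.init(cout, nm + ".bn2");
  }
  static void relu_(Batch& x) {
    ScopeTimer st_("relu");
    for (auto& c : x) c.transform([](real_t v) { return v > 0 ? v : (real_t)0; });
  }
  Batch forward(const Batch& x, bool train) {
    y1 = n1.forward(c1.forward(x, train), train); relu_(y1);
    y2 = n2.forward(c2.forward(y1, train), train); relu_(y2);
    return y2;
  }
  Batch backward(Batch dy, Opt& o) {
    for (size_t n = 0; n < dy.size(); ++n)
      dy[n] %= conv_to<rcube>::from(y2[n] > 0);
    Batch d = c2.backward(n2.backward(dy, o), o);
    for (size_t n = 0; n < d.size(); ++n)
      d[n] %= conv_to<rcube>::from(y1[n] > 0);
    return c1.backward(n1.backward(d, o), o);
  }
};

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2.
struct Pool {
  std::vector<Cube<uword>> idx;   // flat index (within slice) of the max

  Batch forward(const Batch& x) {
    ScopeTimer st_("pool");
    const int N = (int)x.size(), H = x[0].n_rows, W = x[0].n_cols, C = x[0].n_slices;
    const int h = H / 2, w = W / 2;
    Batch y((size_t)N, rcube(h, w, C));
    idx.assign((size_t)N, Cube<uword>(h, w, C));
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const rmat& s = x[(size_t)n].slice(c);
        for (int j = 0; j < w; ++j)
          for (int i = 0; i < h; ++i) {
            uword bi = 2 * i, bj = 2 * j;
            real_t best = s(bi, bj);
            if (s(bi + 1, bj) > best) { best = s(bi + 1, bj); bi = 2 * i + 1; bj = 2 * j; }
            if (s(2 * i, 2 * j + 1) > best) { best = s(2 * i, 2 * j + 1); bi = 2 * i; bj = 2 * j + 1; }
            if (s(2 * i + 1, 2 * j + 1) > best) { best = s(2 * i + 1, 2 * j + 1); bi = 2 * i + 1; bj = 2 * j + 1; }
            y[(size_t)n](i, j, c) = best;
            idx[(size_t)n](i, j, c) = bj * H + bi;
          }
      }
    return y;
  }
  Batch backward(const Batch& dy) {
    const int N = (int)dy.size(), h = dy[0].n_rows, w = dy[0].n_cols, C = dy[0].n_slices;
    Batch dx((size_t)N, rcube(2 * h, 2 * w, C, fill::zeros));
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        real_t* d = dx[(size_t)n].slice_memptr(c);
        for (int j = 0; j < w; ++j)
          for (int i = 0; i < h; ++i)
            d[idx[(size_t)n](i, j, c)] += dy[(size_t)n](i, j, c);
      }
    return dx;
  }
};

// ---------------------------------------------------------------------------
// Transposed convolution 2x2, stride 2 (learned upsampling).
// Weight layout: cin x (cout*4); sub-position order (a,b) -> b*2+a.
struct UpConv {
  int cin = 0, cout = 0;
  Param W, b;
  rmat X;                // (HW*N) x cin cache
  int H = 0, Wd = 0, N = 0;

  void init(int ci, int co, const std::string& nm) {
    cin = ci; cout = co;
    W.init(ci, co * 4, ci, nm + ".w");
    b.init(co, 1, ci, nm + ".b");
  }
  Batch forward(const Batch& x, bool /*train*/) {
    N = (int)x.size(); H = x[0].n_rows; Wd = x[0].n_cols;
    const int HW = H * Wd;
    X.set_size(HW * N, cin);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cin; ++c)
        std::memcpy(X.colptr(c) + (size_t)n * HW,
                    x[(size_t)n].slice_memptr(c), sizeof(real_t) * HW);
    rmat Y = X * W.w;                      // (HW*N) x (cout*4)
    Batch y((size_t)N, rcube(2 * H, 2 * Wd, cout));
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        rmat& out = y[(size_t)n].slice(c);
        for (int bb = 0; bb < 2; ++bb)
          for (int a = 0; a < 2; ++a) {
            const real_t* src = Y.colptr(c * 4 + bb * 2 + a) + (size_t)n * HW;
            for (int j = 0; j < Wd; ++j)
              for (int i = 0; i < H; ++i)
                out(2 * i + a, 2 * j + bb) = src[(size_t)j * H + i] + b.w(c, 0);
          }
      }
    return y;
  }
  Batch backward(const Batch& dy, Opt& o) {
    const int HW = H * Wd;
    rmat dY(HW * N, cout * 4);
    rvec db(cout, fill::zeros);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        const rmat& dout = dy[(size_t)n].slice(c);
        db(c) += accu(dout);
        for (int bb = 0; bb < 2; ++bb)
          for (int a = 0; a < 2; ++a) {
            real_t* dst = dY.colptr(c * 4 + bb * 2 + a) + (size_t)n * HW;
            for (int j = 0; j < Wd; ++j)
              for (int i = 0; i < H; ++i)
                dst[(size_t)j * H + i] = dout(2 * i + a, 2 * j + bb);
          }
      }
    rmat dW = X.t() * dY;
    rmat dX = dY * W.w.t();
    Batch dx((size_t)N, rcube(H, Wd, cin));
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cin; ++c)
        std::memcpy(dx[(size_t)n].slice_memptr(c),
                    dX.colptr(c) + (size_t)n * HW, sizeof(real_t) * HW);
    W.apply(dW, o); b.apply(rmat(db), o);
    return dx;
  }
};

// ---------------------------------------------------------------------------
// Additive attention gate: alpha = sigmoid(psi(relu(Wg g + Wx x))); out = alpha * x.
struct AttGate {
  Conv wg, wx, psi;
  Batch q, alpha, xin;

  void init(int c, const std::string& nm) {
    const int fi = std::max(c / 2, 1);
    wg.init(c, fi, 1, true, nm + ".wg");
    wx.init(c, fi, 1, true, nm + ".wx");
    psi.init(fi, 1, 1, true, nm + ".psi");
  }
  Batch forward(const Batch& x, const Batch& g, bool train) {
    xin = x;
    Batch qg = wg.forward(g, train), qx = wx.forward(x, train);
    q.assign(x.size(), rcube());
    for (size_t n = 0; n < x.size(); ++n) {
      q[n] = qg[n] + qx[n];
      q[n].transform([](real_t v) { return v > 0 ? v : (real_t)0; });
    }
    alpha = psi.forward(q, train);
    for (auto& a : alpha) a.transform([](real_t v) { return (real_t)(1.0 / (1.0 + std::exp(-(double)v))); });
    Batch y(x.size());
    for (size_t n = 0; n < x.size(); ++n) {
      y[n].set_size(x[n].n_rows, x[n].n_cols, x[n].n_slices);
      for (uword c = 0; c < x[n].n_slices; ++c)
        y[n].slice(c) = x[n].slice(c) % alpha[n].slice(0);
    }
    return y;
  }
  // returns gradient w.r.t. x; *dg receives gradient w.r.t. g
  Batch backward(const Batch& dy, Batch* dg, Opt& o) {
    const size_t N = dy.size();
    Batch da(N), dx1(N);
    for (size_t n = 0; n < N; ++n) {
      const uword C = xin[n].n_slices;
      da[n].set_size(dy[n].n_rows, dy[n].n_cols, 1);
      da[n].slice(0).zeros();
      dx1[n].set_size(dy[n].n_rows, dy[n].n_cols, C);
      for (uword c = 0; c < C; ++c) {
        da[n].slice(0) += dy[n].slice(c) % xin[n].slice(c);
        dx1[n].slice(c) = dy[n].slice(c) % alpha[n].slice(0);
      }
      da[n].slice(0) %= alpha[n].slice(0) % (1 - alpha[n].slice(0));
    }
    Batch dq = psi.backward(da, o);
    for (size_t n = 0; n < N; ++n)
      dq[n] %= conv_to<rcube>::from(q[n] > 0);
    *dg = wg.backward(dq, o);
    Batch dx2 = wx.backward(dq, o);
    for (size_t n = 0; n < N; ++n) dx1[n] += dx2[n];
    return dx1;
  }
};

// ---------------------------------------------------------------------------

static Batch concat_batch(const Batch& a, const Batch& b) {
  Batch y(a.size());
  for (size_t n = 0; n < a.size(); ++n) y[n] = join_slices(a[n], b[n]);
  return y;
}
static void split_batch(const Batch& d, int c1, Batch& da, Batch& db) {
  da.assign(d.size(), rcube()); db.assign(d.size(), rcube());
  for (size_t n = 0; n < d.size(); ++n) {
    da[n] = d[n].slices(0, c1 - 1);
    db[n] = d[n].slices(c1, d[n].n_slices - 1);
  }
}

enum Variant { U_M = 0, U_P = 1, U_MP = 2, AMU_MP = 3 };

struct Net {
  int variant, depth, base;
  std::vector<int> ch;
  // single-encoder path
  std::vector<Block> enc;
  std::vector<Pool> pool;
  // dual-encoder path
  std::vector<Block> encm, encp, mcab;
  std::vector<Pool> poolm, poolp;
  Block fuse;
  std::vector<AttGate> gate;
  // shared decoder
  std::vector<UpConv> up;
  std::vector<Block> dec;
  Conv head;
  Opt opt;

  // forward caches needed for backward routing
  Batch probs;

  int in_channels() const {
    return variant == U_M ? 1 : (variant == U_P ? 3 : 4);
  }

  Net(int var, int D, int B) : variant(var), depth(D), base(B) {
    ch.resize(depth);
    for (int i = 0; i < depth; ++i) ch[i] = base << i;
    if (variant == AMU_MP) {
      encm.resize(depth); encp.resize(depth); mcab.resize(depth - 1);
      poolm.resize(depth - 1); poolp.resize(depth - 1);
      gate.resize(depth - 1);
      int cm = 1, cp = 3;
      for (int i = 0; i < depth; ++i) {
        encm[i].init(cm, ch[i], "enc_m" + std::to_string(i + 1));
        encp[i].init(cp, ch[i], "enc_p" + std::to_string(i + 1));
        cm = cp = ch[i];
      }
      for (int i = 0; i < depth - 1; ++i) {
        mcab[i].init(2 * ch[i], ch[i], "mcab" + std::to_string(i + 1));
        gate[i].init(ch[i], "gate" + std::to_string(i + 1));
      }
      fuse.init(2 * ch[depth - 1], ch[depth - 1], "fuse");
    } else {
      enc.resize(depth); pool.resize(depth - 1);
      int cin = in_channels();
      for (int i = 0; i < depth; ++i) {
        enc[i].init(cin, ch[i], "enc" + std::to_string(i + 1));
        cin = ch[i];
      }
    }
    up.resize(depth - 1); dec.resize(depth - 1);
    for (int i = 0; i < depth - 1; ++i) {
      up[i].init(ch[i + 1], ch[i], "up" + std::to_string(i + 1));
      dec[i].init(2 * ch[i], ch[i], "dec" + std::to_string(i + 1));
    }
    head.init(ch[0], 2, 1, true, "head");
  }

  std::vector<Param*> params() {
    std::vector<Param*> p;
    auto addC = [&](Conv& c) { p.push_back(&c.W); if (c.use_bias) p.push_back(&c.b); };
    auto addB = [&](BNorm& b) { p.push_back(&b.g); p.push_back(&b.bt); };
    auto addBlk = [&](Block& b) { addC(b.c1); addB(b.n1); addC(b.c2); addB(b.n2); };
    if (variant == AMU_MP) {
      for (auto& b : encm) addBlk(b);
      for (auto& b : encp) addBlk(b);
      for (auto& b : mcab) addBlk(b);
      addBlk(fuse);
      for (auto& g : gate) { addC(g.wg); addC(g.wx); addC(g.psi); }
    } else {
      for (auto& b : enc) addBlk(b);
    }
    for (auto& u : up) { p.push_back(&u.W); p.push_back(&u.b); }
    for (auto& b : dec) addBlk(b);
    addC(head);
    return p;
  }
  std::vector<BNorm*> bns() {
    std::vector<BNorm*> v;
    auto addBlk = [&](Block& b) { v.push_back(&b.n1); v.push_back(&b.n2); };
    if (variant == AMU_MP) {
      for (auto& b : encm) addBlk(b);
      for (auto& b : encp) addBlk(b);
      for (auto& b : mcab) addBlk(b);
      addBlk(fuse);
    } else {
      for (auto& b : enc) addBlk(b);
    }
    for (auto& b : dec) addBlk(b);
    return v;
  }

  // ---- forward -----------------------------------------------------------
  Batch em_top, ep_top;   // per-depth encoder outputs kept implicitly in blocks
  std::vector<Batch> skips, skips_p;  // cached encoder outputs per depth

  Batch logits(const Batch& x, bool train) {
    Batch d;
    skips.assign(depth, Batch()); skips_p.assign(depth, Batch());
    if (variant == AMU_MP) {
      Batch xm(x.size()), xp(x.size());
      for (size_t n = 0; n < x.size(); ++n) {
        xm[n] = x[n].slices(0, 0);
        xp[n] = x[n].slices(1, 3);
      }
      for (int i = 0; i < depth; ++i) {
        skips[i] = encm[i].forward(xm, train);
        skips_p[i] = encp[i].forward(xp, train);
        if (i < depth - 1) {
          xm = poolm[i].forward(skips[i]);
          xp = poolp[i].forward(skips_p[i]);
        }
      }
      d = fuse.forward(concat_batch(skips[depth - 1], skips_p[depth - 1]), train);
      for (int i = depth - 2; i >= 0; --i) {
        Batch u = up[i].forward(d, train);
        Batch s = mcab[i].forward(concat_batch(skips[i], skips_p[i]), train);
        Batch a = gate[i].forward(s, u, train);
        d = dec[i].forward(concat_batch(u, a), train);
      }
    } else {
      Batch xi = x;
      for (int i = 0; i < depth; ++i) {
        skips[i] = enc[i].forward(xi, train);
        if (i < depth - 1) xi = pool[i].forward(skips[i]);
      }
      d = skips[depth - 1];
      for (int i = depth - 2; i >= 0; --i) {
        Batch u = up[i].forward(d, train);
        d = dec[i].forward(concat_batch(u, skips[i]), train);
      }
    }
    return head.forward(d, train);
  }

  Batch forward_probs(const Batch& x, bool train) {
    Batch z = logits(x, train);
    probs.assign(z.size(), rcube());
    for (size_t n = 0; n < z.size(); ++n) {
      probs[n].set_size(z[n].n_rows, z[n].n_cols, 2);
      rmat mx = max(z[n].slice(0), z[n].slice(1));
      rmat e0 = exp(z[n].slice(0) - mx), e1 = exp(z[n].slice(1) - mx);
      rmat s = e0 + e1;
      probs[n].slice(0) = e0 / s;
      probs[n].slice(1) = e1 / s;
    }
    return probs;
  }

  // ---- backward ----------------------------------------------------------
  void backward(const Batch& dlogits) {
    Batch dd = head.backward(const_cast<Batch&>(dlogits), opt);
    if (variant == AMU_MP) {
      std::vector<Batch> gm(depth), gp(depth);
      for (int i = 0; i <= depth - 2; ++i) {
        Batch dcat = dec[i].backward(dd, opt);
        Batch du, da;
        split_batch(dcat, ch[i], du, da);
        Batch dgate_g;
        Batch ds = gate[i].backward(da, &dgate_g, opt);
        for (size_t n = 0; n < du.size(); ++n) du[n] += dgate_g[n];
        Batch dmc = mcab[i].backward(ds, opt);
        split_batch(dmc, ch[i], gm[i], gp[i]);
        dd = up[i].backward(du, opt);
      }
      Batch dfu = fuse.backward(dd, opt);
      split_batch(dfu, ch[depth - 1], gm[depth - 1], gp[depth - 1]);
      // encoder chains
      for (int i = depth - 1; i >= 0; --i) {
        Batch dxm = encm[i].backward(gm[i], opt);
        Batch dxp = encp[i].backward(gp[i], opt);
        if (i > 0) {
          Batch pm = poolm[i - 1].backward(dxm);
          Batch pp = poolp[i - 1].backward(dxp);
          for (size_t n = 0; n < pm.size(); ++n) {
            gm[i - 1][n] += pm[n];
            gp[i - 1][n] += pp[n];
          }
        }
      }
    } else {
      std::vector<Batch> ge(depth);
      for (int i = 0; i <= depth - 2; ++i) {
        Batch dcat = dec[i].backward(dd, opt);
        Batch du;
        split_batch(dcat, ch[i], du, ge[i]);
        dd = up[i].backward(du, opt);
      }
      ge[depth - 1] = dd;
      for (int i = depth - 1; i >= 0; --i) {
        Batch dx = enc[i].backward(ge[i], opt);
        if (i > 0) {
          Batch pb = pool[i - 1].backward(dx);
          for (size_t n = 0; n < pb.size(); ++n) ge[i - 1][n] += pb[n];
        }
      }
    }
  }

  double loss_and_grad(const Batch& x, const std::vector<imat>& y, bool do_backward) {
    forward_probs(x, true);
    const size_t N = x.size();
    const int H = x[0].n_rows, W = x[0].n_cols;
    const double scale = 1.0 / ((double)N * H * W);
    double loss = 0;
    Batch dz(N);
    for (size_t n = 0; n < N; ++n) {
      dz[n].set_size(H, W, 2);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const int lab = y[n](i, j);
          double p = (double)probs[n](i, j, lab);
          loss -= std::log(std::max(p, 1e-12));
          dz[n](i, j, 0) = (real_t)((probs[n](i, j, 0) - (lab == 0 ? 1 : 0)) * scale);
          dz[n](i, j, 1) = (real_t)((probs[n](i, j, 1) - (lab == 1 ? 1 : 0)) * scale);
        }
    }
    loss *= scale;
    if (do_backward) backward(dz);
    return loss;
  }
};

// ---------------------------------------------------------------------------
// Rcpp interface

static Batch r_to_batch(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) Rcpp::stop("input must be a 4-d array [H, W, C, N]");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  Batch b((size_t)N);
  const double* p = x.begin();
  const size_t per = (size_t)H * W * C;
  for (int n = 0; n < N; ++n) {
    b[(size_t)n].set_size(H, W, C);
    real_t* dst = b[(size_t)n].memptr();
    const double* src = p + (size_t)n * per;
    for (size_t i = 0; i < per; ++i) dst[i] = (real_t)src[i];
  }
  return b;
}

// [[Rcpp::export]]
SEXP nn_create(std::string variant, int depth, int base) {
  int v = variant == "u_m" ? U_M : variant == "u_p" ? U_P :
          variant == "u_mp" ? U_MP : variant == "amu_mp" ? AMU_MP : -1;
  if (v < 0) Rcpp::stop("unknown variant '%s'", variant.c_str());
  if (depth < 2) Rcpp::stop("depth must be >= 2");
  if (base < 4) Rcpp::stop("base_filters must be >= 4");
  Rcpp::XPtr<Net> p(new Net(v, depth, base), true);
  return p;
}

// [[Rcpp::export]]
Rcpp::DataFrame nn_param_info(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  auto ps = net->params();
  std::vector<std::string> nm;
  Rcpp::IntegerVector nr, nc, fi;
  for (auto* p : ps) {
    nm.push_back(p->name);
    nr.push_back(p->w.n_rows); nc.push_back(p->w.n_cols); fi.push_back(p->fan_in);
  }
  return Rcpp::DataFrame::create(
    Rcpp::Named("name") = nm, Rcpp::Named("nrow") = nr,
    Rcpp::Named("ncol") = nc, Rcpp::Named("fan_in") = fi,
    Rcpp::Named("stringsAsFactors") = false);
}

// [[Rcpp::export]]
void nn_set_params(SEXP ptr, Rcpp::NumericVector flat) {
  Rcpp::XPtr<Net> net(ptr);
  auto ps = net->params();
  size_t off = 0;
  for (auto* p : ps) {
    const size_t n = p->w.n_elem;
    if (off + n > (size_t)flat.size()) Rcpp::stop("parameter vector too short");
    for (size_t i = 0; i < n; ++i) p->w[i] = (real_t)flat[off + i];
    off += n;
  }
  if (off != (size_t)flat.size()) Rcpp::stop("parameter vector length mismatch");
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_get_params(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  auto ps = net->params();
  size_t tot = 0;
  for (auto* p : ps) tot += p->w.n_elem;
  Rcpp::NumericVector out((R_xlen_t)tot);
  size_t off = 0;
  for (auto* p : ps) {
    for (size_t i = 0; i < p->w.n_elem; ++i) out[off + i] = (double)p->w[i];
    off += p->w.n_elem;
  }
  return out;
}

// [[Rcpp::export]]
double nn_param_count(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  size_t tot = 0;
  for (auto* p : net->params()) tot += p->w.n_elem;
  return (double)tot;
}

// [[Rcpp::export]]
Rcpp::List nn_get_state(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  auto bs = net->bns();
  Rcpp::List means(bs.size()), vars(bs.size());
  for (size_t i = 0; i < bs.size(); ++i) {
    means[i] = Rcpp::NumericVector(bs[i]->rmean.begin(), bs[i]->rmean.end());
    vars[i] = Rcpp::NumericVector(bs[i]->rvar.begin(), bs[i]->rvar.end());
  }
  return Rcpp::List::create(Rcpp::Named("running_mean") = means,
                            Rcpp::Named("running_var") = vars,
                            Rcpp::Named("adam_t") = (double)net->opt.t);
}

// [[Rcpp::export]]
void nn_set_state(SEXP ptr, Rcpp::List state) {
  Rcpp::XPtr<Net> net(ptr);
  auto bs = net->bns();
  Rcpp::List means = state["running_mean"], vars = state["running_var"];
  for (size_t i = 0; i < bs.size(); ++i) {
    Rcpp::NumericVector m = means[i], v = vars[i];
    bs[i]->rmean = conv_to<rvec>::from(vec(m.begin(), m.size()));
    bs[i]->rvar = conv_to<rvec>::from(vec(v.begin(), v.size()));
  }
  net->opt.t = (long)Rcpp::as<double>(state["adam_t"]);
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_forward(SEXP ptr, Rcpp::NumericVector x, bool training) {
  Rcpp::XPtr<Net> net(ptr);
  Batch b = r_to_batch(x);
  if ((int)b[0].n_slices != net->in_channels())
    Rcpp::stop("expected %d input channels, got %d", net->in_channels(), (int)b[0].n_slices);
  Batch p = net->forward_probs(b, training);
  const int H = p[0].n_rows, W = p[0].n_cols, N = (int)p.size();
  Rcpp::NumericVector out((R_xlen_t)H * W * 2 * N);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, 2, N);
  const size_t per = (size_t)H * W * 2;
  for (int n = 0; n < N; ++n) {
    const real_t* src = p[(size_t)n].memptr();
    double* dst = out.begin() + (size_t)n * per;
    for (size_t i = 0; i < per; ++i) dst[i] = (double)src[i];
  }
  return out;
}

static std::vector<imat> r_to_labels(const Rcpp::IntegerVector& y) {
  Rcpp::IntegerVector dm = y.attr("dim");
  if (dm.size() != 3) Rcpp::stop("labels must be a 3-d array [H, W, N]");
  const int H = dm[0], W = dm[1], N = dm[2];
  std::vector<imat> out((size_t)N);
  for (int n = 0; n < N; ++n) {
    out[(size_t)n].set_size(H, W);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out[(size_t)n](i, j) = y[(size_t)n * H * W + (size_t)j * H + i];
  }
  return out;
}

// [[Rcpp::export]]
double nn_train_batch(SEXP ptr, Rcpp::NumericVector x, Rcpp::IntegerVector y,
                      double lr, double beta1, double beta2, double eps) {
  Rcpp::XPtr<Net> net(ptr);
  Batch b = r_to_batch(x);
  if ((int)b[0].n_slices != net->in_channels())
    Rcpp::stop("expected %d input channels, got %d", net->in_channels(), (int)b[0].n_slices);
  std::vector<imat> lab = r_to_labels(y);
  net->opt.lr = lr; net->opt.b1 = beta1; net->opt.b2 = beta2; net->opt.eps = eps;
  net->opt.update = true;
  net->opt.t += 1;
  return net->loss_and_grad(b, lab, true);
}

// [[Rcpp::export]]
double nn_loss(SEXP ptr, Rcpp::NumericVector x, Rcpp::IntegerVector y) {
  Rcpp::XPtr<Net> net(ptr);
  Batch b = r_to_batch(x);
  std::vector<imat> lab = r_to_labels(y);
  return net->loss_and_grad(b, lab, false);
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_grad(SEXP ptr, Rcpp::NumericVector x, Rcpp::IntegerVector y) {
  Rcpp::XPtr<Net> net(ptr);
  Batch b = r_to_batch(x);
  std::vector<imat> lab = r_to_labels(y);
  net->opt.update = false;
  net->loss_and_grad(b, lab, true);
  net->opt.update = true;
  auto ps = net->params();
  size_t tot = 0;
  for (auto* p : ps) tot += p->w.n_elem;
  Rcpp::NumericVector out((R_xlen_t)tot);
  size_t off = 0;
  for (auto* p : ps) {
    if (p->gacc.n_elem != p->w.n_elem) Rcpp::stop("gradient not collected for %s", p->name.c_str());
    for (size_t i = 0; i < p->w.n_elem; ++i) out[off + i] = (double)p->gacc[i];
    off += p->w.n_elem;
  }
  return out;
}

// Skip-connection widths per decoder depth (structural introspection).
// [[Rcpp::export]]
Rcpp::DataFrame nn_skip_widths(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  Rcpp::IntegerVector d, w;
  for (int i = 0; i < net->depth - 1; ++i) {
    d.push_back(i + 1);
    w.push_back(net->ch[i]);
  }
  return Rcpp::DataFrame::create(Rcpp::Named("depth") = d,
                                 Rcpp::Named("skip_channels") = w);
}

// [[Rcpp::export]]
Rcpp::List nn_timers(bool reset) {
  Rcpp::List out;
  for (auto& kv : g_timers) out[kv.first] = kv.second;
  if (reset) g_timers.clear();
  return out;
}
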