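// Multi-level-feature CNN: VGG-style conv blocks, per-block 1x1
// projections, transposed-convolution upsampling to a common fusion size,
// channel concatenation and an FC/dropout/softmax head. Written against
// Armadillo (im2col + GEMM); single-threaded deterministic training with
// its own mt19937 stream so identical seeds give identical models on CPU.
//
// Feature maps are arma::mat (channels x pixels), pixel index p = r + c*H
// (column-major spatial layout, H rows).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::uvec;

// the engine is templated on the real type: float for training/prediction
// speed (memory-bound GEMMs), double for the finite-difference gradient
// check, which needs small step sizes

struct Conf {
  int side, C;                 // input side length (H == W) and channels
  arma::ivec convs, widths;    // per-block conv counts and widths (5)
  int P;                       // projection channels
  int fusion;                  // fusion map side length
  int fc1, fc2, nclass;
  double drop1, drop2;
  // derived
  arma::ivec post;             // post-pool side per block
  arma::ivec stride, factor;   // 1x1 stride (down) / deconv factor (up)
};

static Conf parse_conf(const List& cfg) {
  Conf c;
  c.side = as<int>(cfg["input_side"]);
  c.C = as<int>(cfg["input_channels"]);
  c.convs = as<arma::ivec>(cfg["block_convs"]);
  c.widths = as<arma::ivec>(cfg["block_widths"]);
  c.P = as<int>(cfg["projection_channels"]);
  c.fusion = as<int>(cfg["fusion_size"]);
  c.fc1 = as<int>(cfg["fc1"]);
  c.fc2 = as<int>(cfg["fc2"]);
  c.nclass = as<int>(cfg["n_classes"]);
  c.drop1 = as<double>(cfg["dropout1"]);
  c.drop2 = as<double>(cfg["dropout2"]);
  if (c.convs.n_elem != 5 || c.widths.n_elem != 5)
    stop("block_convs and block_widths must have length 5");
  if (c.side % 32 != 0)
    stop("input spatial size must be divisible by 2^5");
  c.post.set_size(5); c.stride.set_size(5); c.factor.set_size(5);
  int s = c.side;
  for (int b = 0; b < 5; ++b) {
    s /= 2;
    c.post[b] = s;
    if (s >= c.fusion) {
      if (s % c.fusion != 0)
        stop("fusion_size must divide block ", b + 1, " output size ", s);
      c.stride[b] = s / c.fusion;
      c.factor[b] = 1;
    } else {
      if (c.fusion % s != 0)
        stop("block ", b + 1, " output size ", s,
             " must divide fusion_size");
      c.stride[b] = 1;
      c.factor[b] = c.fusion / s;
    }
  }
  return c;
}

template <typename T> struct Params {
  std::vector<arma::Mat<T>> W;
  std::vector<arma::Col<T>> b;
};

// fixed parameter order: all convs (block-major), 5 projections,
// deconvs for blocks with factor > 1 (block order), fc1, fc2, output
static std::vector<std::string> param_names(const Conf& c) {
  std::vector<std::string> nm;
  for (int b = 0; b < 5; ++b)
    for (int j = 0; j < c.convs[b]; ++j)
      nm.push_back("conv" + std::to_string(b + 1) + "_" +
                   std::to_string(j + 1));
  for (int b = 0; b < 5; ++b) nm.push_back("proj" + std::to_string(b + 1));
  for (int b = 0; b < 5; ++b)
    if (c.factor[b] > 1) nm.push_back("deconv" + std::to_string(b + 1));
  nm.push_back("fc1"); nm.push_back("fc2"); nm.push_back("out");
  return nm;
}

static void param_shapes(const Conf& c, std::vector<int>& rows,
                         std::vector<int>& cols, std::vector<int>& brows) {
  rows.clear(); cols.clear(); brows.clear();
  for (int b = 0; b < 5; ++b) {
    int in = (b == 0) ? c.C : (int)c.widths[b - 1];
    for (int j = 0; j < c.convs[b]; ++j) {
      rows.push_back((int)c.widths[b]); cols.push_back(9 * in);
      brows.push_back((int)c.widths[b]);
      in = (int)c.widths[b];
    }
  }
  for (int b = 0; b < 5; ++b) {
    rows.push_back(c.P); cols.push_back((int)c.widths[b]);
    brows.push_back(c.P);
  }
  for (int b = 0; b < 5; ++b)
    if (c.factor[b] > 1) {
      rows.push_back(c.P * c.factor[b] * c.factor[b]); cols.push_back(c.P);
      brows.push_back(c.P);      // one bias per output channel
    }
  int flat = 5 * c.P * c.fusion * c.fusion;
  rows.push_back(c.fc1); cols.push_back(flat); brows.push_back(c.fc1);
  rows.push_back(c.fc2); cols.push_back(c.fc1); brows.push_back(c.fc2);
  rows.push_back(c.nclass); cols.push_back(c.fc2); brows.push_back(c.nclass);
}

// ---------------------------------------------------------------- im2col
template <typename T>
static void im2col3(const arma::Mat<T>& X, int H, int W, arma::Mat<T>& P9) {
  int Cin = X.n_rows;
  P9.zeros(9 * Cin, H * W);
  int o = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr, ++o) {
      int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
      int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      if (c1 < c0 || r1 < r0) continue;
      for (int cc = c0; cc <= c1; ++cc) {
        int dst0 = cc * H + r0, dst1 = cc * H + r1;
        int src0 = (cc + dc) * H + r0 + dr, src1 = src0 + (r1 - r0);
        P9.submat(o * Cin, dst0, (o + 1) * Cin - 1, dst1) =
          X.cols(src0, src1);
      }
    }
}

template <typename T>
static void col2im3(const arma::Mat<T>& dP9, int H, int W, int Cin,
                    arma::Mat<T>& dX) {
  dX.zeros(Cin, H * W);
  int o = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr, ++o) {
      int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
      int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      if (c1 < c0 || r1 < r0) continue;
      for (int cc = c0; cc <= c1; ++cc) {
        int dst0 = cc * H + r0, dst1 = cc * H + r1;
        int src0 = (cc + dc) * H + r0 + dr, src1 = src0 + (r1 - r0);
        dX.cols(src0, src1) +=
          dP9.submat(o * Cin, dst0, (o + 1) * Cin - 1, dst1);
      }
    }
}

// ------------------------------------------------------------- max pool
template <typename T>
static void maxpool2(const arma::Mat<T>& X, int H, int W, arma::Mat<T>& Y,
                     arma::umat& amax) {
  int C = X.n_rows, Ho = H / 2, Wo = W / 2;
  Y.set_size(C, Ho * Wo);
  amax.set_size(C, Ho * Wo);
  for (int co = 0; co < Wo; ++co)
    for (int ro = 0; ro < Ho; ++ro) {
      int po = ro + co * Ho;
      int p00 = 2 * ro + 2 * co * H;
      int cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
      for (int ch = 0; ch < C; ++ch) {
        T best = X(ch, cand[0]); int bi = cand[0];
        for (int k = 1; k < 4; ++k)
          if (X(ch, cand[k]) > best) { best = X(ch, cand[k]); bi = cand[k]; }
        Y(ch, po) = best;
        amax(ch, po) = bi;
      }
    }
}

// strided pixel selection for the 1x1 projections
static uvec stride_idx(int Hin, int s, int Ho) {
  uvec idx(Ho * Ho);
  int k = 0;
  for (int co = 0; co < Ho; ++co)
    for (int ro = 0; ro < Ho; ++ro)
      idx[k++] = (arma::uword)(ro * s + (co * s) * Hin);
  return idx;
}

template <typename M>
static inline void relu(M& X) {
  X.for_each([](typename M::elem_type& v){ if (v < 0) v = 0; });
}

// per-image cache of everything backward needs
template <typename T> struct Cache {
  std::vector<std::vector<arma::Mat<T>>> conv_in;   // [block][conv] inputs
  std::vector<std::vector<arma::Mat<T>>> conv_out;  // post-ReLU
  std::vector<arma::Mat<T>> pool_out;               // block outputs
  std::vector<arma::umat> amax;
  std::vector<arma::Mat<T>> proj_out, fused;        // post-ReLU
  arma::Col<T> flat, a1, a1d, a2, a2d, prob;
  arma::Col<T> m1, m2;                     // dropout masks (already /keep)
};

template <typename T>
static arma::Col<T> softmax(const arma::Col<T>& z) {
  arma::Col<T> p = arma::exp(z - z.max());
  return p / arma::accu(p);
}

template <typename T>
static void forward(const Conf& c, const Params<T>& P,
                    const arma::Mat<T>& x0, Cache<T>& K, bool train,
                    std::mt19937* rng) {
  using MT = arma::Mat<T>;
  K.conv_in.assign(5, {}); K.conv_out.assign(5, {});
  K.pool_out.assign(5, MT()); K.amax.assign(5, arma::umat());
  K.proj_out.assign(5, MT()); K.fused.assign(5, MT());
  MT cur = x0;
  int H = c.side, iw = 0;
  MT P9;
  for (int b = 0; b < 5; ++b) {
    for (int j = 0; j < c.convs[b]; ++j, ++iw) {
      K.conv_in[b].push_back(cur);
      im2col3(cur, H, H, P9);
      MT Z = P.W[iw] * P9;
      Z.each_col() += P.b[iw];
      relu(Z);
      K.conv_out[b].push_back(Z);
      cur = Z;
    }
    MT pooled; arma::umat am;
    maxpool2(cur, H, H, pooled, am);
    H /= 2;
    K.pool_out[b] = pooled;
    K.amax[b] = am;
    cur = pooled;
  }
  // projections (+ optional down-stride) and upsampling to fusion size
  int ip = iw;                         // proj index base
  int idq = iw + 5;                    // deconv index base
  std::vector<int> dq(5, -1);
  { int q = idq;
    for (int b = 0; b < 5; ++b) if (c.factor[b] > 1) dq[b] = q++; }
  for (int b = 0; b < 5; ++b) {
    const MT& in = K.pool_out[b];
    MT Z;
    if (c.stride[b] > 1) {
      uvec idx = stride_idx(c.post[b], c.stride[b], c.fusion);
      Z = P.W[ip + b] * in.cols(idx);
    } else Z = P.W[ip + b] * in;
    Z.each_col() += P.b[ip + b];
    relu(Z);
    K.proj_out[b] = Z;
    if (c.factor[b] > 1) {
      int f = c.factor[b], Hin = c.post[b], Ho = Hin * f;
      const MT& Wd = P.W[dq[b]];
      MT out(c.P, Ho * Ho, arma::fill::zeros);
      for (int o = 0; o < f * f; ++o) {
        int dr = o % f, dc = o / f;
        MT Yt = Wd.rows(o * c.P, (o + 1) * c.P - 1) * Z;
        for (int ci = 0; ci < Hin; ++ci)
          for (int ri = 0; ri < Hin; ++ri)
            out.col((ri * f + dr) + (ci * f + dc) * Ho) += Yt.col(ri + ci * Hin);
      }
      out.each_col() += P.b[dq[b]];
      relu(out);
      K.fused[b] = out;
    } else K.fused[b] = Z;
  }
  // concat along channels, flatten, FC head
  MT Fcat(5 * c.P, c.fusion * c.fusion);
  for (int b = 0; b < 5; ++b)
    Fcat.rows(b * c.P, (b + 1) * c.P - 1) = K.fused[b];
  K.flat = arma::vectorise(Fcat);
  int nfc = (int)P.W.size();
  K.a1 = P.W[nfc - 3] * K.flat + P.b[nfc - 3]; relu(K.a1);
  if (train && c.drop1 > 0) {
    std::bernoulli_distribution keep(1.0 - c.drop1);
    K.m1.set_size(K.a1.n_elem);
    for (arma::uword i = 0; i < K.m1.n_elem; ++i)
      K.m1[i] = keep(*rng) ? (T)(1.0 / (1.0 - c.drop1)) : (T)0;
    K.a1d = K.a1 % K.m1;
  } else K.a1d = K.a1;
  K.a2 = P.W[nfc - 2] * K.a1d + P.b[nfc - 2]; relu(K.a2);
  if (train && c.drop2 > 0) {
    std::bernoulli_distribution keep(1.0 - c.drop2);
    K.m2.set_size(K.a2.n_elem);
    for (arma::uword i = 0; i < K.m2.n_elem; ++i)
      K.m2[i] = keep(*rng) ? (T)(1.0 / (1.0 - c.drop2)) : (T)0;
    K.a2d = K.a2 % K.m2;
  } else K.a2d = K.a2;
  K.prob = softmax<T>(P.W[nfc - 1] * K.a2d + P.b[nfc - 1]);
}

template <typename T>
static void backward(const Conf& c, const Params<T>& P, const Cache<T>& K,
                     int label, Params<T>& G) {
  using MT = arma::Mat<T>;
  int nfc = (int)P.W.size();
  bool drop = K.m1.n_elem > 0;
  arma::Col<T> dz = K.prob;
  dz[label] -= 1.0;
  G.W[nfc - 1] += dz * K.a2d.t();
  G.b[nfc - 1] += dz;
  arma::Col<T> da2 = P.W[nfc - 1].t() * dz;
  if (K.m2.n_elem) da2 %= K.m2;
  da2.elem(arma::find(K.a2 <= 0)).zeros();
  G.W[nfc - 2] += da2 * K.a1d.t();
  G.b[nfc - 2] += da2;
  arma::Col<T> da1 = P.W[nfc - 2].t() * da2;
  if (drop) da1 %= K.m1;
  da1.elem(arma::find(K.a1 <= 0)).zeros();
  G.W[nfc - 3] += da1 * K.flat.t();
  G.b[nfc - 3] += da1;
  arma::Col<T> dflat = P.W[nfc - 3].t() * da1;

  MT dFcat(dflat.memptr(), 5 * c.P, c.fusion * c.fusion);

  int iw = 0;
  for (int b = 0; b < 5; ++b) iw += c.convs[b];
  int ip = iw, idq = iw + 5;
  std::vector<int> dq(5, -1);
  { int q = idq;
    for (int b = 0; b < 5; ++b) if (c.factor[b] > 1) dq[b] = q++; }

  // gradient reaching each block output via its projection branch
  std::vector<MT> dblock(5);
  for (int b = 0; b < 5; ++b) {
    MT dfused = dFcat.rows(b * c.P, (b + 1) * c.P - 1);
    MT dproj;
    if (c.factor[b] > 1) {
      dfused.elem(arma::find(K.fused[b] <= 0)).zeros();
      int f = c.factor[b], Hin = c.post[b], Ho = Hin * f;
      const MT& Wd = P.W[dq[b]];
      dproj.zeros(c.P, Hin * Hin);
      G.b[dq[b]] += arma::sum(dfused, 1);
      for (int o = 0; o < f * f; ++o) {
        int dr = o % f, dc = o / f;
        MT dYt(c.P, Hin * Hin);
        for (int ci = 0; ci < Hin; ++ci)
          for (int ri = 0; ri < Hin; ++ri)
            dYt.col(ri + ci * Hin) =
              dfused.col((ri * f + dr) + (ci * f + dc) * Ho);
        G.W[dq[b]].rows(o * c.P, (o + 1) * c.P - 1) +=
          dYt * K.proj_out[b].t();
        dproj += Wd.rows(o * c.P, (o + 1) * c.P - 1).t() * dYt;
      }
    } else dproj = dfused;
    dproj.elem(arma::find(K.proj_out[b] <= 0)).zeros();
    G.b[ip + b] += arma::sum(dproj, 1);
    const MT& in = K.pool_out[b];
    if (c.stride[b] > 1) {
      uvec idx = stride_idx(c.post[b], c.stride[b], c.fusion);
      G.W[ip + b] += dproj * in.cols(idx).t();
      MT dsub = P.W[ip + b].t() * dproj;
      dblock[b].zeros(in.n_rows, in.n_cols);
      dblock[b].cols(idx) = dsub;
    } else {
      G.W[ip + b] += dproj * in.t();
      dblock[b] = P.W[ip + b].t() * dproj;
    }
  }

  // back through the conv blocks, rear to front
  MT dnext;                          // grad wrt block b's pooled output
  MT P9, dP9, dX;
  for (int b = 4; b >= 0; --b) {
    MT dpool = dblock[b];
    if (b < 4 && dnext.n_elem) dpool += dnext;
    // unpool
    int Hpre = c.post[b] * 2;
    const MT& last = K.conv_out[b].back();
    MT dcur(last.n_rows, Hpre * Hpre, arma::fill::zeros);
    const arma::umat& am = K.amax[b];
    for (arma::uword p = 0; p < dpool.n_cols; ++p)
      for (arma::uword ch = 0; ch < dpool.n_rows; ++ch)
        dcur(ch, am(ch, p)) += dpool(ch, p);
    // convs in reverse
    int base = 0;
    for (int bb = 0; bb < b; ++bb) base += c.convs[bb];
    for (int j = c.convs[b] - 1; j >= 0; --j) {
      int w = base + j;
      dcur.elem(arma::find(K.conv_out[b][j] <= 0)).zeros();
      im2col3(K.conv_in[b][j], Hpre, Hpre, P9);
      G.W[w] += dcur * P9.t();
      G.b[w] += arma::sum(dcur, 1);
      dP9 = P.W[w].t() * dcur;
      col2im3(dP9, Hpre, Hpre, K.conv_in[b][j].n_rows, dX);
      dcur = dX;
    }
    dnext = dcur;
  }
}

// ------------------------------------------------------------ R interface
template <typename T>
static Params<T> params_from_list(const List& wl) {
  Params<T> P;
  List Ws = wl["W"], bs = wl["b"];
  for (int i = 0; i < Ws.size(); ++i) {
    P.W.push_back(arma::conv_to<arma::Mat<T>>::from(as<arma::mat>(Ws[i])));
    P.b.push_back(arma::conv_to<arma::Col<T>>::from(as<arma::vec>(bs[i])));
  }
  return P;
}

template <typename T>
static List params_to_list(const Params<T>& P,
                           const std::vector<std::string>& nm) {
  List Ws(P.W.size()), bs(P.b.size());
  for (size_t i = 0; i < P.W.size(); ++i) {
    Ws[i] = wrap(arma::conv_to<arma::mat>::from(P.W[i]));
    bs[i] = wrap(arma::conv_to<arma::vec>::from(P.b[i]));
  }
  Ws.attr("names") = wrap(nm);
  bs.attr("names") = wrap(nm);
  return List::create(_["W"] = Ws, _["b"] = bs);
}

template <typename T>
static arma::Mat<T> image_to_mat(const Conf& c, const arma::vec& xcol) {
  int HW = c.side * c.side;
  arma::Mat<T> X(c.C, HW);
  for (int ch = 0; ch < c.C; ++ch)
    for (int p = 0; p < HW; ++p)
      X(ch, p) = (T)xcol[p + ch * HW];
  return X;
}

// [[Rcpp::export]]
List cpp_cnn_init(List cfg, int seed) {
  Conf c = parse_conf(cfg);
  std::vector<int> rows, cols, brows;
  param_shapes(c, rows, cols, brows);
  std::vector<std::string> nm = param_names(c);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  Params<double> P;                    // He-normal init, double precision
  for (size_t i = 0; i < rows.size(); ++i) {
    arma::mat Wm(rows[i], cols[i]);
    double sd = std::sqrt(2.0 / cols[i]);
    for (arma::uword k = 0; k < Wm.n_elem; ++k) Wm[k] = sd * gauss(rng);
    P.W.push_back(Wm);
    P.b.push_back(arma::vec(brows[i], arma::fill::zeros));
  }
  return params_to_list(P, nm);
}

// [[Rcpp::export]]
List cpp_cnn_train(List cfg, List weights, const arma::mat& X,
                   const arma::ivec& y, const arma::mat& Xval,
                   const arma::ivec& yval, int epochs, int batch,
                   double lr, int seed) {
  typedef float T;                     // training runs in single precision
  Conf c = parse_conf(cfg);
  Params<T> P = params_from_list<T>(weights);
  std::vector<std::string> nm = param_names(c);
  int n = (int)X.n_cols, nval = (int)Xval.n_cols;

  Params<T> G, M, V;
  for (size_t i = 0; i < P.W.size(); ++i) {
    G.W.push_back(arma::Mat<T>(arma::size(P.W[i]), arma::fill::zeros));
    G.b.push_back(arma::Col<T>(P.b[i].n_elem, arma::fill::zeros));
    M.W.push_back(arma::Mat<T>(arma::size(P.W[i]), arma::fill::zeros));
    M.b.push_back(arma::Col<T>(P.b[i].n_elem, arma::fill::zeros));
    V.W.push_back(arma::Mat<T>(arma::size(P.W[i]), arma::fill::zeros));
    V.b.push_back(arma::Col<T>(P.b[i].n_elem, arma::fill::zeros));
  }
  const T b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long tstep = 0;
  std::mt19937 rng((unsigned)seed);

  // convert images once
  std::vector<arma::Mat<T>> Xi(n), Xv(nval);
  for (int i = 0; i < n; ++i) Xi[i] = image_to_mat<T>(c, X.col(i));
  for (int i = 0; i < nval; ++i) Xv[i] = image_to_mat<T>(c, Xval.col(i));

  std::vector<double> h_tl, h_ta, h_vl, h_va;
  Cache<T> K;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0; int correct = 0;
    for (int start = 0; start < n; start += batch) {
      int end = std::min(n, start + batch);
      int bs = end - start;
      for (size_t i = 0; i < G.W.size(); ++i) { G.W[i].zeros(); G.b[i].zeros(); }
      for (int ii = start; ii < end; ++ii) {
        int img = order[ii];
        forward(c, P, Xi[img], K, true, &rng);
        double pl = std::max((double)K.prob[y[img]], 1e-12);
        loss_sum += -std::log(pl);
        int pred = (K.prob[1] > K.prob[0]) ? 1 : 0;  // tie -> class 0
        if (pred == y[img]) ++correct;
        backward(c, P, K, y[img], G);
      }
      ++tstep;
      T corr = std::sqrt(1.0 - std::pow((double)b2, (double)tstep)) /
        (1.0 - std::pow((double)b1, (double)tstep));
      T blr = (T)lr;
      for (size_t i = 0; i < P.W.size(); ++i) {
        G.W[i] /= (T)bs; G.b[i] /= (T)bs;
        M.W[i] = b1 * M.W[i] + (1 - b1) * G.W[i];
        V.W[i] = b2 * V.W[i] + (1 - b2) * arma::square(G.W[i]);
        P.W[i] -= blr * corr * M.W[i] / (arma::sqrt(V.W[i]) + eps);
        M.b[i] = b1 * M.b[i] + (1 - b1) * G.b[i];
        V.b[i] = b2 * V.b[i] + (1 - b2) * arma::square(G.b[i]);
        P.b[i] -= blr * corr * M.b[i] / (arma::sqrt(V.b[i]) + eps);
      }
    }
    double vl = NA_REAL, va = NA_REAL;
    if (nval > 0) {
      double vloss = 0; int vcorr = 0;
      for (int i = 0; i < nval; ++i) {
        forward(c, P, Xv[i], K, false, nullptr);
        vloss += -std::log(std::max((double)K.prob[yval[i]], 1e-12));
        int pred = (K.prob[1] > K.prob[0]) ? 1 : 0;
        if (pred == yval[i]) ++vcorr;
      }
      vl = vloss / nval; va = (double)vcorr / nval;
    }
    h_tl.push_back(loss_sum / n);
    h_ta.push_back((double)correct / n);
    h_vl.push_back(vl);
    h_va.push_back(va);
    Rcpp::checkUserInterrupt();
  }

  DataFrame hist = DataFrame::create(
    _["epoch"] = seq_len((int)h_tl.size()),
    _["train_loss"] = h_tl, _["train_acc"] = h_ta,
    _["val_loss"] = h_vl, _["val_acc"] = h_va);
  return List::create(_["weights"] = params_to_list(P, nm),
                      _["history"] = hist);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(List cfg, List weights, const arma::mat& X) {
  typedef float T;
  Conf c = parse_conf(cfg);
  Params<T> P = params_from_list<T>(weights);
  int n = (int)X.n_cols;
  arma::mat probs(n, c.nclass);
  Cache<T> K;
  for (int i = 0; i < n; ++i) {
    arma::Mat<T> x0 = image_to_mat<T>(c, X.col(i));
    forward(c, P, x0, K, false, nullptr);
    probs.row(i) = arma::conv_to<arma::rowvec>::from(K.prob.t());
  }
  return probs;
}

// single-image loss and gradients (no dropout); used by the
// finite-difference gradient check in the test suite
// [[Rcpp::export]]
List cpp_cnn_lossgrad(List cfg, List weights, const arma::vec& x, int y) {
  Conf c = parse_conf(cfg);
  c.drop1 = 0; c.drop2 = 0;
  Params<double> P = params_from_list<double>(weights);
  Params<double> G;
  for (size_t i = 0; i < P.W.size(); ++i) {
    G.W.push_back(arma::mat(arma::size(P.W[i]), arma::fill::zeros));
    G.b.push_back(arma::vec(P.b[i].n_elem, arma::fill::zeros));
  }
  Cache<double> K;
  arma::mat x0 = image_to_mat<double>(c, x);
  forward(c, P, x0, K, false, nullptr);
  double loss = -std::log(std::max(K.prob[y], 1e-12));
  backward(c, P, K, y, G);
  return List::create(_["loss"] = loss,
                      _["grad"] = params_to_list(G, param_names(c)));
}

// layer-by-layer parameter count, used by the arithmetic oracle test
// [[Rcpp::export]]
List cpp_cnn_shapes(List cfg) {
  Conf c = parse_conf(cfg);
  std::vector<int> rows, cols, brows;
  param_shapes(c, rows, cols, brows);
  std::vector<std::string> nm = param_names(c);
  return List::create(_["name"] = wrap(nm), _["rows"] = wrap(rows),
                      _["cols"] = wrap(cols), _["bias"] = wrap(brows),
                      _["post_sizes"] =
                        wrap(arma::conv_to<std::vector<int>>::from(c.post)),
                      _["strides"] =
                        wrap(arma::conv_to<std::vector<int>>::from(c.stride)),
                      _["factors"] =
                        wrap(arma::conv_to<std::vector<int>>::from(c.factor)));
}
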