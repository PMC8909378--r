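// Compact 2D U-Net: forward pass and analytic backprop.
//
// Feature maps are arma::cube (H, W, C). Convolutions are 3x3 same-padding
// via im2col + matrix multiply; each conv (except the 1x1 head) is followed
// by instance normalisation and ReLU. Four 2x2 max-pool reductions, nearest
// upsampling and skip concatenations form the canonical depth-4 U-Net.
// Parameters arrive from R as a list of 23 units in fixed order
// (enc0a..enc3b, bottleneck a/b, then per decoder level up/deca/decb,
// finally the 1x1 head); gradients are returned in the same structure.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

static const double IN_EPS = 1e-5;

struct ConvUnit {
  mat W;        // (k*Cin, Cout), k = 9 for 3x3 and 1 for the head
  vec b;
  vec g, be;    // instance-norm scale/shift (empty for the head)
  bool has_in;
};

struct UnitCache {
  cube x_in;    // conv input
  cube xhat;    // normalised pre-activation
  vec sd;       // per-channel sqrt(var + eps)
  cube a;       // post-ReLU output (mask source)
};

static std::vector<ConvUnit> parse_params(const List& params) {
  std::vector<ConvUnit> units;
  units.reserve(params.size());
  for (int i = 0; i < params.size(); ++i) {
    List u = params[i];
    ConvUnit cu;
    cu.W = as<mat>(u["W"]);
    cu.b = as<vec>(u["b"]);
    cu.has_in = u.containsElementNamed("g") && !Rf_isNull(u["g"]);
    if (cu.has_in) {
      cu.g = as<vec>(u["g"]);
      cu.be = as<vec>(u["be"]);
    }
    units.push_back(cu);
  }
  return units;
}

// ---- conv 3x3 (same padding) ----

static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * W, 9 * C, arma::fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        uword col = c * 9 + (dy + 1) * 3 + (dx + 1);
        mat shifted(H, W, arma::fill::zeros);
        uword r0 = std::max(0, -dy), r1 = std::min((int)H, (int)H - dy);
        uword c0 = std::max(0, -dx), c1 = std::min((int)W, (int)W - dx);
        if (r1 > r0 && c1 > c0)
          shifted.submat(r0, c0, r1 - 1, c1 - 1) =
            x.slice(c).submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx);
        out.col(col) = arma::vectorise(shifted);
      }
    }
  }
  return out;
}

static cube col2im3(const mat& D, uword H, uword W, uword C) {
  cube out(H, W, C, arma::fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        uword col = c * 9 + (dy + 1) * 3 + (dx + 1);
        mat M(H, W);
        std::memcpy(M.memptr(), D.colptr(col), sizeof(double) * H * W);
        uword r0 = std::max(0, -dy), r1 = std::min((int)H, (int)H - dy);
        uword c0 = std::max(0, -dx), c1 = std::min((int)W, (int)W - dx);
        if (r1 > r0 && c1 > c0)
          out.slice(c).submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx) +=
            M.submat(r0, c0, r1 - 1, c1 - 1);
      }
    }
  }
  return out;
}

static cube mat_to_cube(const mat& Y, uword H, uword W) {
  cube out(H, W, Y.n_cols);
  for (uword c = 0; c < Y.n_cols; ++c)
    std::memcpy(out.slice(c).memptr(), Y.colptr(c), sizeof(double) * H * W);
  return out;
}

static mat cube_to_mat(const cube& x) {
  mat out(x.n_rows * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    std::memcpy(out.colptr(c), x.slice(c).memptr(),
                sizeof(double) * x.n_rows * x.n_cols);
  return out;
}

// conv + instance norm + ReLU (or bare 1x1 conv for the head)
static cube unit_forward(const ConvUnit& u, const cube& x, UnitCache* cache) {
  const uword H = x.n_rows, W = x.n_cols;
  const bool head = !u.has_in;
  mat X = head ? cube_to_mat(x) : im2col3(x);
  mat Y = X * u.W;
  Y.each_row() += u.b.t();
  cube z = mat_to_cube(Y, H, W);
  if (head) {
    if (cache) { cache->x_in = x; }
    return z;
  }
  const double N = (double)(H * W);
  cube xhat(H, W, z.n_slices);
  vec sd(z.n_slices);
  for (uword c = 0; c < z.n_slices; ++c) {
    double mu = arma::accu(z.slice(c)) / N;
    mat d = z.slice(c) - mu;
    double var = arma::accu(arma::square(d)) / N;
    sd(c) = std::sqrt(var + IN_EPS);
    xhat.slice(c) = d / sd(c);
  }
  cube a(H, W, z.n_slices);
  for (uword c = 0; c < z.n_slices; ++c)
    a.slice(c) = arma::max(u.g(c) * xhat.slice(c) + u.be(c),
                           arma::zeros<mat>(H, W));
  if (cache) {
    cache->x_in = x; cache->xhat = xhat; cache->sd = sd; cache->a = a;
  }
  return a;
}

struct UnitGrad { mat dW; vec db; vec dg; vec dbe; };

// backward through one unit; returns dL/dx and fills grads
static cube unit_backward(const ConvUnit& u, const UnitCache& cache,
                          cube dy, UnitGrad& grad) {
  const uword H = cache.x_in.n_rows, W = cache.x_in.n_cols;
  const bool head = !u.has_in;
  if (!head) {
    const double N = (double)(H * W);
    grad.dg.set_size(cache.xhat.n_slices);
    grad.dbe.set_size(cache.xhat.n_slices);
    for (uword c = 0; c < dy.n_slices; ++c) {
      // ReLU
      dy.slice(c) %= arma::conv_to<mat>::from(cache.a.slice(c) > 0);
      // affine part of instance norm
      grad.dg(c) = arma::accu(dy.slice(c) % cache.xhat.slice(c));
      grad.dbe(c) = arma::accu(dy.slice(c));
      // normalisation part
      mat dxhat = dy.slice(c) * u.g(c);
      double m_dxhat = arma::accu(dxhat) / N;
      double m_dxhat_xhat = arma::accu(dxhat % cache.xhat.slice(c)) / N;
      dy.slice(c) = (dxhat - m_dxhat - cache.xhat.slice(c) * m_dxhat_xhat) /
        cache.sd(c);
    }
  }
  mat dY = cube_to_mat(dy);
  mat X = head ? cube_to_mat(cache.x_in) : im2col3(cache.x_in);
  grad.dW = X.t() * dY;
  grad.db = arma::sum(dY, 0).t();
  mat dX = dY * u.W.t();
  if (head) return mat_to_cube(dX, H, W);
  return col2im3(dX, H, W, cache.x_in.n_slices);
}

// ---- pooling / upsampling ----

static cube maxpool2(const cube& x, arma::ucube& argmax) {
  const uword H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube out(H, W, C);
  argmax.set_size(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        double v00 = x(2 * i, 2 * j, c), v10 = x(2 * i + 1, 2 * j, c);
        double v01 = x(2 * i, 2 * j + 1, c), v11 = x(2 * i + 1, 2 * j + 1, c);
        uword k = 0; double best = v00;
        if (v10 > best) { best = v10; k = 1; }
        if (v01 > best) { best = v01; k = 2; }
        if (v11 > best) { best = v11; k = 3; }
        out(i, j, c) = best;
        argmax(i, j, c) = k;
      }
  return out;
}

static cube maxpool2_back(const cube& dy, const arma::ucube& argmax) {
  const uword H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  cube out(2 * H, 2 * W, C, arma::fill::zeros);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        uword k = argmax(i, j, c);
        out(2 * i + (k & 1), 2 * j + (k >> 1), c) = dy(i, j, c);
      }
  return out;
}

static cube upsample2(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v; out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v; out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static cube upsample2_back(const cube& dy) {
  const uword H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube out(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        out(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
          dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return out;
}

static cube concat_c(const cube& a, const cube& b) {
  cube out(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  out.slices(0, a.n_slices - 1) = a;
  out.slices(a.n_slices, out.n_slices - 1) = b;
  return out;
}

// unit index tables (see header comment)
static const int ENC_A[5] = {0, 2, 4, 6, 8};
static const int ENC_B[5] = {1, 3, 5, 7, 9};
static const int UP_IDX[4] = {10, 13, 16, 19};   // decoder levels 3,2,1,0
static const int DEC_A[4] = {11, 14, 17, 20};
static const int DEC_B[4] = {12, 15, 18, 21};
static const int HEAD = 22;

struct ForwardState {
  std::vector<UnitCache> caches;
  std::vector<arma::ucube> pool_idx;
  cube skips[4];
};

// Full network; cache-free when st == nullptr (inference).
static cube run_net(const std::vector<ConvUnit>& units, const cube& x,
                    ForwardState* st) {
  std::vector<UnitCache>* caches = nullptr;
  if (st) { st->caches.resize(23); st->pool_idx.resize(4); caches = &st->caches; }
  cube skips[4];
  std::vector<arma::ucube> pool_idx(4);
  cube cur = x;
  for (int l = 0; l < 5; ++l) {
    cur = unit_forward(units[ENC_A[l]], cur,
                       caches ? &(*caches)[ENC_A[l]] : nullptr);
    cur = unit_forward(units[ENC_B[l]], cur,
                       caches ? &(*caches)[ENC_B[l]] : nullptr);
    if (l < 4) {
      skips[l] = cur;
      cur = maxpool2(cur, pool_idx[l]);
    }
  }
  for (int k = 0; k < 4; ++k) {       // decoder levels 3,2,1,0
    int l = 3 - k;
    cur = unit_forward(units[UP_IDX[k]], upsample2(cur),
                       caches ? &(*caches)[UP_IDX[k]] : nullptr);
    cur = concat_c(skips[l], cur);
    cur = unit_forward(units[DEC_A[k]], cur,
                       caches ? &(*caches)[DEC_A[k]] : nullptr);
    cur = unit_forward(units[DEC_B[k]], cur,
                       caches ? &(*caches)[DEC_B[k]] : nullptr);
  }
  cube logits = unit_forward(units[HEAD], cur,
                             caches ? &(*caches)[HEAD] : nullptr);
  if (st) {
    for (int l = 0; l < 4; ++l) st->skips[l] = skips[l];
    st->pool_idx = pool_idx;
  }
  return logits;
}

static List grads_to_list(const std::vector<UnitGrad>& grads) {
  List out(grads.size());
  for (size_t i = 0; i < grads.size(); ++i) {
    const UnitGrad& g = grads[i];
    if (g.dg.n_elem > 0)
      out[i] = List::create(_["W"] = g.dW, _["b"] = g.db,
                            _["g"] = g.dg, _["be"] = g.dbe);
    else
      out[i] = List::create(_["W"] = g.dW, _["b"] = g.db);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_unet_logits(List params, NumericVector x) {
  std::vector<ConvUnit> units = parse_params(params);
  IntegerVector d = x.attr("dim");
  cube xc(x.begin(), d[0], d[1], d.size() == 3 ? d[2] : 1);
  cube logits = run_net(units, xc, nullptr);
  NumericVector out(logits.begin(), logits.end());
  out.attr("dim") = IntegerVector::create(logits.n_rows, logits.n_cols,
                                          logits.n_slices);
  return out;
}

// One training step: forward with cache, call back into R for the loss and
// its gradient w.r.t. the logits, then backprop. grad_fn(logits) must
// return list(loss = scalar, grad = (H, W, 5) array).
// [[Rcpp::export]]
List cpp_unet_step(List params, NumericVector x, Function grad_fn) {
  std::vector<ConvUnit> units = parse_params(params);
  IntegerVector d = x.attr("dim");
  cube xc(x.begin(), d[0], d[1], d.size() == 3 ? d[2] : 1);
  ForwardState st;
  cube logits = run_net(units, xc, &st);
  NumericVector lg0(logits.begin(), logits.end());
  lg0.attr("dim") = IntegerVector::create(logits.n_rows, logits.n_cols,
                                          logits.n_slices);
  List lr = grad_fn(lg0);
  double loss = as<double>(lr["loss"]);
  NumericVector grad_logits = lr["grad"];
  IntegerVector gd = grad_logits.attr("dim");
  cube dlogit(grad_logits.begin(), gd[0], gd[1], gd[2]);

  std::vector<UnitGrad> grads(23);
  cube cur = unit_backward(units[HEAD], st.caches[HEAD], dlogit, grads[HEAD]);
  for (int k = 3; k >= 0; --k) {      // decoder levels 0,1,2,3 reversed
    int l = 3 - k;
    cur = unit_backward(units[DEC_B[k]], st.caches[DEC_B[k]], cur,
                        grads[DEC_B[k]]);
    cur = unit_backward(units[DEC_A[k]], st.caches[DEC_A[k]], cur,
                        grads[DEC_A[k]]);
    uword cs = st.skips[l].n_slices;
    cube d_skip = cur.slices(0, cs - 1);
    cube d_up = cur.slices(cs, cur.n_slices - 1);
    cube d_pre_up = unit_backward(units[UP_IDX[k]], st.caches[UP_IDX[k]],
                                  d_up, grads[UP_IDX[k]]);
    cur = upsample2_back(d_pre_up);
    // merge with the skip path at encoder level l on the way down
    st.skips[l] = d_skip;
  }
  // encoder backward: bottleneck first (cur), then levels 3..0 adding skips
  for (int l = 4; l >= 0; --l) {
    if (l < 4) {
      cur = maxpool2_back(cur, st.pool_idx[l]);
      cur += st.skips[l];
    }
    cur = unit_backward(units[ENC_B[l]], st.caches[ENC_B[l]], cur,
                        grads[ENC_B[l]]);
    cur = unit_backward(units[ENC_A[l]], st.caches[ENC_A[l]], cur,
                        grads[ENC_A[l]]);
  }

  return List::create(_["loss"] = loss, _["grads"] = grads_to_list(grads));
}
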