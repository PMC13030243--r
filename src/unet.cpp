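// U-Net encoder-decoder for single-channel sinogram segmentation.
//
// Feature maps are stored as single-precision matrices of size (B*H*W) x C:
// one column per channel, sample b occupying rows [b*H*W, (b+1)*H*W), spatial
// index s = y + H*x (column-major within each sample). Convolutions are
// im2col + sgemm; batch norm uses batch statistics during training and
// running estimates at inference. All parameters arrive from R as a named
// list of double arrays (conv weights with dim c(3,3,cin,cout)) and are
// returned with the same names and dim attributes.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;

static const float BN_EPS = 1e-5f;

// ---------------------------------------------------------------- param store

struct ParamStore {
  std::map<std::string, fmat> P;
  std::vector<std::string> names;

  void load(const List& lst) {
    Rcpp::CharacterVector nm = lst.names();
    for (int i = 0; i < lst.size(); ++i) {
      std::string name = Rcpp::as<std::string>(nm[i]);
      NumericVector v = lst[i];
      Rcpp::RObject dim = v.attr("dim");
      int r, c;
      if (dim.isNULL()) {
        r = v.size(); c = 1;
      } else {
        Rcpp::IntegerVector d(dim);
        if (d.size() == 4) {            // conv kernel (kh, kw, cin, cout)
          r = d[0] * d[1] * d[2]; c = d[3];
        } else if (d.size() == 2) {
          r = d[0]; c = d[1];
        } else {
          r = v.size(); c = 1;
        }
      }
      fmat m(r, c);
      std::copy(v.begin(), v.end(), m.memptr());
      P[name] = std::move(m);
      names.push_back(name);
    }
  }

  // write values back into a copy of the template list (keeps dim attrs)
  List dump(const List& tmpl) const {
    List out = Rcpp::clone(tmpl);
    Rcpp::CharacterVector nm = out.names();
    for (int i = 0; i < out.size(); ++i) {
      std::string name = Rcpp::as<std::string>(nm[i]);
      NumericVector v = out[i];
      const fmat& m = P.at(name);
      std::copy(m.begin(), m.end(), v.begin());
    }
    return out;
  }
};

// ------------------------------------------------------------------- im2col

// Single-sample column matrix (HW x 9C) for one sample's rows of X starting
// at row offset `off`: col(s, (dy+1) + 3*(dx+1) + 9*c) = X(off + shifted s, c).
// Convolutions loop over samples with one reusable buffer so the column
// matrix stays cache-resident instead of touching DRAM for every layer.
static void im2col3_one(const fmat& X, int off, int H, int W, fmat& col) {
  const int HW = H * W, C = X.n_cols;
  if ((int)col.n_rows != HW || (int)col.n_cols != 9 * C) col.set_size(HW, 9 * C);
  col.zeros();
  for (int c = 0; c < C; ++c) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int k = (dy + 1) + 3 * (dx + 1) + 9 * c;
        const int y0 = std::max(0, -dy), y1 = H - 1 - std::max(0, dy);
        const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
        if (y0 > y1 || x0 > x1) continue;
        const int len = y1 - y0 + 1;
        for (int x = x0; x <= x1; ++x) {
          const float* src = X.colptr(c) + off + (x + dx) * H + (y0 + dy);
          float* dst = col.colptr(k) + x * H + y0;
          std::memcpy(dst, src, sizeof(float) * len);
        }
      }
    }
  }
}

// scatter-add transpose of im2col3_one into sample rows of dX at `off`
static void col2im3_one(const fmat& dcol, int off, int H, int W, fmat& dX) {
  const int C = dcol.n_cols / 9;
  for (int c = 0; c < C; ++c) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int k = (dy + 1) + 3 * (dx + 1) + 9 * c;
        const int y0 = std::max(0, -dy), y1 = H - 1 - std::max(0, dy);
        const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
        if (y0 > y1 || x0 > x1) continue;
        const int len = y1 - y0 + 1;
        for (int x = x0; x <= x1; ++x) {
          const float* src = dcol.colptr(k) + x * H + y0;
          float* dst = dX.colptr(c) + off + (x + dx) * H + (y0 + dy);
          for (int i = 0; i < len; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// ------------------------------------------------- conv3x3 + BN + ReLU block

struct CBRCache {
  std::string w, b, bn;   // parameter name stems
  int B, H, W;
  fmat Xin;               // input (kept for dW)
  fmat xhat;              // normalized pre-activation
  frowvec invstd;
  frowvec gamma, beta;    // copies for relu-mask reconstruction
};

static fmat cbr_forward(ParamStore& ps, fmat&& X, int B, int H, int W,
                        const std::string& stem, const std::string& bnstem,
                        bool training, CBRCache& cc) {
  const fmat& Wm = ps.P.at(stem + "_W");
  const fmat& bm = ps.P.at(stem + "_b");
  const int HW = H * W;
  const uword Cout = Wm.n_cols;
  fmat pre(B * HW, Cout);
  {
    fmat col;
    for (int b = 0; b < B; ++b) {
      im2col3_one(X, b * HW, H, W, col);
      pre.rows(b * HW, (b + 1) * HW - 1) = col * Wm;
    }
  }
  fmat& gam = ps.P.at(bnstem + "_gamma");
  fmat& bet = ps.P.at(bnstem + "_beta");
  fmat& rm = ps.P.at(bnstem + "_rm");
  fmat& rv = ps.P.at(bnstem + "_rv");
  const uword N = pre.n_rows;
  fmat out(N, Cout);
  cc.invstd.set_size(Cout);
  cc.gamma.set_size(Cout);
  cc.beta.set_size(Cout);
  const float mom = 0.1f;
  // fused: bias add, batch statistics, normalize, affine, ReLU
  for (uword c = 0; c < Cout; ++c) {
    float* pc = pre.colptr(c);
    const float bc = bm(c, 0);
    float mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (uword i = 0; i < N; ++i) {
        const float v = pc[i] + bc;
        pc[i] = v;
        s += v;
        s2 += (double)v * v;
      }
      mu = (float)(s / N);
      var = std::max(0.0, s2 / N - (double)mu * mu);
      rm(c, 0) = (1 - mom) * rm(c, 0) + mom * mu;
      rv(c, 0) = (1 - mom) * rv(c, 0) + mom * var;
    } else {
      for (uword i = 0; i < N; ++i) pc[i] += bc;
      mu = rm(c, 0);
      var = rv(c, 0);
    }
    const float inv = 1.0f / std::sqrt(var + BN_EPS);
    const float g = gam(c, 0), be = bet(c, 0);
    float* oc = out.colptr(c);
    for (uword i = 0; i < N; ++i) {
      const float xh = (pc[i] - mu) * inv;
      pc[i] = xh;                        // pre becomes xhat in place
      const float a = g * xh + be;
      oc[i] = a > 0 ? a : 0;
    }
    cc.invstd(c) = inv;
    cc.gamma(c) = g;
    cc.beta(c) = be;
  }
  cc.w = stem + "_W"; cc.b = stem + "_b"; cc.bn = bnstem;
  cc.B = B; cc.H = H; cc.W = W;
  cc.Xin = std::move(X);
  cc.xhat = std::move(pre);
  return out;
}

static fmat cbr_backward(ParamStore& ps, const CBRCache& cc, fmat dY,
                         std::map<std::string, fmat>& G) {
  const uword N = dY.n_rows, C = dY.n_cols;
  fmat dgam(C, 1), dbet(C, 1);
  // fused: ReLU mask, gamma/beta gradients, batch-norm input gradient.
  // With dxhat = g * dY, mean(dxhat) = g * sum(dY)/N and
  // mean(dxhat .* xhat) = g * sum(dY .* xhat)/N, so two passes suffice.
  for (uword c = 0; c < C; ++c) {
    const float g = cc.gamma(c), be = cc.beta(c), inv = cc.invstd(c);
    const float* xh = cc.xhat.colptr(c);
    float* d = dY.colptr(c);
    double sb = 0, sg = 0;
    for (uword i = 0; i < N; ++i) {
      if (g * xh[i] + be <= 0) d[i] = 0;
      sb += d[i];
      sg += (double)d[i] * xh[i];
    }
    dgam(c, 0) = (float)sg;
    dbet(c, 0) = (float)sb;
    const float m1 = (float)(sb / N), m2 = (float)(sg / N), k = g * inv;
    for (uword i = 0; i < N; ++i) d[i] = k * (d[i] - m1 - xh[i] * m2);
  }
  G[cc.bn + "_gamma"] = std::move(dgam);
  G[cc.bn + "_beta"] = std::move(dbet);
  // conv backward (per-sample column buffers, dW accumulated across samples)
  G[cc.b] = sum(dY, 0).t();
  const fmat& Wm = ps.P.at(cc.w);
  const int HW = cc.H * cc.W;
  fmat dW(Wm.n_rows, Wm.n_cols, fill::zeros);
  fmat dX(cc.Xin.n_rows, cc.Xin.n_cols, fill::zeros);
  fmat col, dcol;
  for (int b = 0; b < cc.B; ++b) {
    im2col3_one(cc.Xin, b * HW, cc.H, cc.W, col);
    const fmat dpre_b = dY.rows(b * HW, (b + 1) * HW - 1);
    dW += col.t() * dpre_b;
    dcol = dpre_b * Wm.t();
    col2im3_one(dcol, b * HW, cc.H, cc.W, dX);
  }
  G[cc.w] = std::move(dW);
  return dX;
}

// --------------------------------------------------------------- pool / up

static fmat pool_forward(const fmat& X, int B, int H, int W, umat& idx) {
  const int Ho = H / 2, Wo = W / 2, HWo = Ho * Wo, HW = H * W;
  const int C = X.n_cols;
  fmat out(B * HWo, C);
  idx.set_size(B * HWo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    float* dst = out.colptr(c);
    uword* id = idx.colptr(c);
    for (int b = 0; b < B; ++b) {
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo) {
          const int base = b * HW + (2 * xo) * H + 2 * yo;
          int best = base;
          float bv = src[base];
          const int cand[3] = {base + 1, base + H, base + H + 1};
          for (int k = 0; k < 3; ++k)
            if (src[cand[k]] > bv) { bv = src[cand[k]]; best = cand[k]; }
          const int o = b * HWo + xo * Ho + yo;
          dst[o] = bv;
          id[o] = best;
        }
      }
    }
  }
  return out;
}

static fmat pool_backward(const fmat& dY, const umat& idx, int n_in) {
  fmat dX(n_in, dY.n_cols, fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    const float* d = dY.colptr(c);
    const uword* id = idx.colptr(c);
    float* o = dX.colptr(c);
    for (uword i = 0; i < dY.n_rows; ++i) o[id[i]] += d[i];
  }
  return dX;
}

struct UpPlan {
  // out = sum_k w[k] . X.rows(idx[k]); nearest uses a single term
  std::vector<uvec> idx;
  std::vector<fvec> wgt;
};

static UpPlan up_plan(int B, int H, int W, bool bilinear) {
  const int Ho = 2 * H, Wo = 2 * W, HW = H * W, HWo = Ho * Wo;
  UpPlan pl;
  const int terms = bilinear ? 4 : 1;
  pl.idx.assign(terms, uvec(B * HWo));
  pl.wgt.assign(terms, fvec(B * HWo));
  for (int b = 0; b < B; ++b) {
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        const int o = b * HWo + xo * Ho + yo;
        if (!bilinear) {
          pl.idx[0][o] = b * HW + (xo / 2) * H + (yo / 2);
          pl.wgt[0][o] = 1.0f;
        } else {
          const double yc = (yo + 0.5) / 2.0 - 0.5, xc = (xo + 0.5) / 2.0 - 0.5;
          int y0 = (int)std::floor(yc), x0 = (int)std::floor(xc);
          double fy = yc - y0, fx = xc - x0;
          int t = 0;
          for (int dy = 0; dy < 2; ++dy) {
            for (int dx = 0; dx < 2; ++dx, ++t) {
              int yy = std::min(std::max(y0 + dy, 0), H - 1);
              int xx = std::min(std::max(x0 + dx, 0), W - 1);
              pl.idx[t][o] = b * HW + xx * H + yy;
              pl.wgt[t][o] = (float)((dy ? fy : 1 - fy) * (dx ? fx : 1 - fx));
            }
          }
        }
      }
    }
  }
  return pl;
}

static fmat up_forward(const fmat& X, const UpPlan& pl) {
  fmat out(pl.idx[0].n_elem, X.n_cols, fill::zeros);
  for (size_t k = 0; k < pl.idx.size(); ++k) {
    fmat tmp = X.rows(pl.idx[k]);
    tmp.each_col() %= pl.wgt[k];
    out += tmp;
  }
  return out;
}

static fmat up_backward(const fmat& dY, const UpPlan& pl, int n_in) {
  fmat dX(n_in, dY.n_cols, fill::zeros);
  for (size_t k = 0; k < pl.idx.size(); ++k) {
    const uvec& id = pl.idx[k];
    const fvec& w = pl.wgt[k];
    for (uword c = 0; c < dY.n_cols; ++c) {
      const float* d = dY.colptr(c);
      float* o = dX.colptr(c);
      for (uword i = 0; i < dY.n_rows; ++i) o[id[i]] += w[i] * d[i];
    }
  }
  return dX;
}

// ------------------------------------------------------------------ network

struct NetCfg {
  int depth, base, cin, input_size;
  double dropout_p;
  bool bilinear_up;
};

static NetCfg read_cfg(const List& config) {
  NetCfg c;
  c.depth = Rcpp::as<int>(config["depth"]);
  c.base = Rcpp::as<int>(config["base_channels"]);
  c.cin = Rcpp::as<int>(config["in_channels"]);
  c.input_size = Rcpp::as<int>(config["input_size"]);
  c.dropout_p = Rcpp::as<double>(config["dropout_p"]);
  c.bilinear_up = Rcpp::as<std::string>(config["upsample_mode"]) == "bilinear";
  return c;
}

struct Tape {
  std::vector<CBRCache> enc1, enc2, decu, decm;
  std::vector<umat> poolidx;
  std::vector<fmat> skip, dropmask_enc, dropmask_dec;
  CBRCache bot1, bot2;
  fmat dropmask_bot;
  std::vector<UpPlan> up;
  fmat head_in;          // input to 1x1 head conv
  fmat prob;             // sigmoid output
};

// xorshift128+ -- fast per-element Bernoulli draws for dropout masks
struct FastRng {
  uint64_t s0, s1;
  explicit FastRng(uint64_t seed) {
    s0 = seed * 0x9E3779B97F4A7C15ULL + 1;
    s1 = (seed ^ 0xDEADBEEFCAFEBABEULL) * 0xBF58476D1CE4E5B9ULL + 1;
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  float unif() { return (next() >> 40) * (1.0f / 16777216.0f); }
};

static void apply_dropout(fmat& X, double p, FastRng& rng, fmat& mask,
                          bool training) {
  if (!training || p <= 0) { mask.reset(); return; }
  const float pf = (float)p;
  const float scale = 1.0f / (float)(1.0 - p);
  mask.set_size(X.n_rows, X.n_cols);
  float* m = mask.memptr();
  float* x = X.memptr();
  for (uword i = 0; i < X.n_elem; ++i) {
    m[i] = (rng.unif() < pf) ? 0.0f : scale;
    x[i] *= m[i];
  }
}

static fmat unet_forward_pass(ParamStore& ps, const NetCfg& cfg, fmat X0,
                              int B, bool training, uint32_t dropout_seed,
                              Tape& tp) {
  FastRng rng(dropout_seed);
  const int D = cfg.depth;
  tp.enc1.resize(D); tp.enc2.resize(D); tp.decu.resize(D); tp.decm.resize(D);
  tp.poolidx.resize(D); tp.skip.resize(D);
  tp.dropmask_enc.resize(D); tp.dropmask_dec.resize(D);
  tp.up.resize(D);

  fmat cur = std::move(X0);
  int H = cfg.input_size, W = cfg.input_size;
  for (int k = 0; k < D; ++k) {
    const std::string s = "enc" + std::to_string(k + 1);
    cur = cbr_forward(ps, std::move(cur), B, H, W, s + "_conv1", s + "_bn1", training, tp.enc1[k]);
    cur = cbr_forward(ps, std::move(cur), B, H, W, s + "_conv2", s + "_bn2", training, tp.enc2[k]);
    apply_dropout(cur, cfg.dropout_p, rng, tp.dropmask_enc[k], training);
    tp.skip[k] = cur;
    cur = pool_forward(cur, B, H, W, tp.poolidx[k]);
    H /= 2; W /= 2;
  }
  cur = cbr_forward(ps, std::move(cur), B, H, W, "bot_conv1", "bot_bn1", training, tp.bot1);
  cur = cbr_forward(ps, std::move(cur), B, H, W, "bot_conv2", "bot_bn2", training, tp.bot2);
  apply_dropout(cur, cfg.dropout_p, rng, tp.dropmask_bot, training);

  for (int k = D - 1; k >= 0; --k) {
    const std::string s = "dec" + std::to_string(k + 1);
    tp.up[k] = up_plan(B, H, W, cfg.bilinear_up);
    cur = up_forward(cur, tp.up[k]);
    H *= 2; W *= 2;
    cur = cbr_forward(ps, std::move(cur), B, H, W, s + "_upconv", s + "_bnu", training, tp.decu[k]);
    cur = join_rows(cur, tp.skip[k]);
    cur = cbr_forward(ps, std::move(cur), B, H, W, s + "_mergeconv", s + "_bnm", training, tp.decm[k]);
    apply_dropout(cur, cfg.dropout_p, rng, tp.dropmask_dec[k], training);
  }
  tp.head_in = std::move(cur);
  const fmat& Wh = ps.P.at("head_W");
  const fmat& bh = ps.P.at("head_b");
  fmat z = tp.head_in * Wh;
  z += bh(0, 0);
  fmat p = 1.0f / (1.0f + exp(-z));
  tp.prob = p;
  return p;
}

static void unet_backward(ParamStore& ps, const NetCfg& cfg, Tape& tp,
                          fmat dz, int B, std::map<std::string, fmat>& G) {
  const fmat& Wh = ps.P.at("head_W");
  G["head_W"] = tp.head_in.t() * dz;
  G["head_b"] = fmat(1, 1, fill::value((float)accu(dz)));
  fmat cur = dz * Wh.t();
  const int D = cfg.depth;
  int H = cfg.input_size, W = cfg.input_size;
  std::vector<fmat> dskip(D);
  for (int k = 0; k < D; ++k) {            // decoder, shallow -> deep
    if (tp.dropmask_dec[k].n_elem) cur %= tp.dropmask_dec[k];
    cur = cbr_backward(ps, tp.decm[k], cur, G);
    const int cs = tp.decu[k].xhat.n_cols;  // channels of upconv output
    dskip[k] = cur.cols(cs, cur.n_cols - 1);
    cur = fmat(cur.cols(0, cs - 1));
    cur = cbr_backward(ps, tp.decu[k], cur, G);
    H /= 2; W /= 2;
    cur = up_backward(cur, tp.up[k], B * H * W);
  }
  if (tp.dropmask_bot.n_elem) cur %= tp.dropmask_bot;
  cur = cbr_backward(ps, tp.bot2, cur, G);
  cur = cbr_backward(ps, tp.bot1, cur, G);
  for (int k = D - 1; k >= 0; --k) {        // encoder, deep -> shallow
    cur = pool_backward(cur, tp.poolidx[k], dskip[k].n_rows);
    cur += dskip[k];
    H *= 2; W *= 2;
    if (tp.dropmask_enc[k].n_elem) cur %= tp.dropmask_enc[k];
    cur = cbr_backward(ps, tp.enc2[k], cur, G);
    cur = cbr_backward(ps, tp.enc1[k], cur, G);
  }
}

// ------------------------------------------------------------------ loss

struct LossOut {
  double bce, dice_soft, total, dice_hard;
};

// gradient wrt sigmoid output p, and loss values; dice averaged per sample
static fmat loss_grad(const fmat& p, const fmat& g, int B, LossOut& lo) {
  const uword n = p.n_elem;
  const uword per = n / B;
  const float eps_bce = 1e-7f;
  const float eps_dice = 1e-5f;
  fmat dp(p.n_rows, 1, fill::zeros);
  double bce = 0.0;
  for (uword i = 0; i < n; ++i) {
    float pc = std::min(std::max(p(i, 0), eps_bce), 1.0f - eps_bce);
    const float gi = g(i, 0);
    bce += -(gi * std::log(pc) + (1.0f - gi) * std::log(1.0f - pc));
    dp(i, 0) = (-gi / pc + (1.0f - gi) / (1.0f - pc)) / (double)n;
  }
  bce /= (double)n;
  double dice_sum = 0.0, dice_hard_sum = 0.0;
  for (int b = 0; b < B; ++b) {
    const uword lo_i = b * per, hi_i = (b + 1) * per - 1;
    double sp = 0, sg = 0, spg = 0, hi_int = 0, hp = 0;
    for (uword i = lo_i; i <= hi_i; ++i) {
      const float pi = p(i, 0), gi = g(i, 0);
      sp += pi; sg += gi; spg += pi * gi;
      const double pb = pi > 0.5f ? 1.0 : 0.0;
      hp += pb; hi_int += pb * gi;
    }
    const double num = 2.0 * spg + eps_dice, den = sp + sg + eps_dice;
    dice_sum += num / den;
    dice_hard_sum += (2.0 * hi_int + eps_dice) / (hp + sg + eps_dice);
    // d(num/den)/dp_i = (2 g_i * den - num) / den^2 ; loss term is -dice/B
    const double inv_den2 = 1.0 / (den * den);
    for (uword i = lo_i; i <= hi_i; ++i) {
      const double dd = (2.0 * g(i, 0) * den - num) * inv_den2;
      dp(i, 0) += (float)(-dd / B);
    }
  }
  lo.bce = bce;
  lo.dice_soft = dice_sum / B;
  lo.dice_hard = dice_hard_sum / B;
  lo.total = bce + (1.0 - lo.dice_soft);
  return dp;
}

// ------------------------------------------------------------------ exports

static fmat input_to_fmat(const NumericVector& x, int& B, int HW) {
  Rcpp::RObject dim = x.attr("dim");
  int n = x.size();
  B = n / HW;
  fmat X(n, 1);
  std::copy(x.begin(), x.end(), X.memptr());
  (void)dim;
  return X;
}

// [[Rcpp::export]]
NumericVector cpp_unet_forward(const List& params, const List& config,
                               const NumericVector& x, const bool training = false,
                               const int dropout_seed = 0) {
  NetCfg cfg = read_cfg(config);
  ParamStore ps;
  ps.load(params);
  const int HW = cfg.input_size * cfg.input_size;
  int B;
  fmat X = input_to_fmat(x, B, HW);
  Tape tp;
  fmat p = unet_forward_pass(ps, cfg, X, B, training, (uint32_t)dropout_seed, tp);
  NumericVector out(p.n_elem);
  std::copy(p.begin(), p.end(), out.begin());
  out.attr("dim") = x.attr("dim");
  return out;
}

// Loss and analytic parameter gradients for one batch (training mode,
// dropout governed by dropout_seed). Used for gradient verification.
// [[Rcpp::export]]
List cpp_unet_grad(const List& params, const List& config,
                   const NumericVector& x, const NumericVector& y,
                   const int dropout_seed = 0) {
  NetCfg cfg = read_cfg(config);
  ParamStore ps;
  ps.load(params);
  const int HW = cfg.input_size * cfg.input_size;
  int B, B2;
  fmat X = input_to_fmat(x, B, HW);
  fmat Y = input_to_fmat(y, B2, HW);
  Tape tp;
  fmat p = unet_forward_pass(ps, cfg, X, B, true, (uint32_t)dropout_seed, tp);
  LossOut lo;
  fmat dp = loss_grad(p, Y, B, lo);
  fmat dz = dp % p % (1.0f - p);
  std::map<std::string, fmat> G;
  unet_backward(ps, cfg, tp, dz, B, G);
  List gl;
  for (auto& kv : G) {
    NumericVector v(kv.second.n_elem);
    std::copy(kv.second.begin(), kv.second.end(), v.begin());
    gl[kv.first] = v;
  }
  return List::create(Rcpp::Named("loss") = lo.total,
                      Rcpp::Named("bce") = lo.bce,
                      Rcpp::Named("dice_soft") = lo.dice_soft,
                      Rcpp::Named("grads") = gl);
}

// One optimization step: forward (training mode), BCE+Dice backward, Adam.
// Returns updated parameters, Adam state, and loss bookkeeping.
// [[Rcpp::export]]
List cpp_unet_train_batch(const List& params, const List& adam_m,
                          const List& adam_v, const int step,
                          const List& config, const NumericVector& x,
                          const NumericVector& y, const double lr,
                          const double weight_decay, const int dropout_seed) {
  NetCfg cfg = read_cfg(config);
  ParamStore ps;
  ps.load(params);
  const int HW = cfg.input_size * cfg.input_size;
  int B;
  fmat X = input_to_fmat(x, B, HW);
  int B2;
  fmat Y = input_to_fmat(y, B2, HW);
  if (B2 != B) Rcpp::stop("input and target batch sizes differ");

  Tape tp;
  fmat p = unet_forward_pass(ps, cfg, X, B, true, (uint32_t)dropout_seed, tp);
  LossOut lo;
  fmat dp = loss_grad(p, Y, B, lo);
  if (!std::isfinite(lo.total))
    Rcpp::stop("non-finite training loss (bce=%f, dice=%f)", lo.bce, lo.dice_soft);
  fmat dz = dp % p % (1.0f - p);   // through sigmoid
  std::map<std::string, fmat> G;
  unet_backward(ps, cfg, tp, dz, B, G);

  // Adam with L2 weight decay folded into the gradient
  ParamStore ms, vs;
  ms.load(adam_m);
  vs.load(adam_v);
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  const float bc1 = 1.0f - std::pow(b1, (float)step);
  const float bc2 = 1.0f - std::pow(b2, (float)step);
  for (auto& kv : G) {
    const std::string& nm = kv.first;
    fmat& w = ps.P.at(nm);
    fmat g = kv.second;
    if (weight_decay > 0) g += (float)weight_decay * w;
    fmat& m = ms.P.at(nm);
    fmat& v = vs.P.at(nm);
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    w -= (float)lr * (m / bc1) / (sqrt(v / bc2) + eps);
  }

  return List::create(
      Rcpp::Named("params") = ps.dump(params),
      Rcpp::Named("m") = ms.dump(adam_m),
      Rcpp::Named("v") = vs.dump(adam_v),
      Rcpp::Named("bce") = lo.bce,
      Rcpp::Named("dice_soft") = lo.dice_soft,
      Rcpp::Named("dice_hard") = lo.dice_hard,
      Rcpp::Named("loss") = lo.total);
}
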