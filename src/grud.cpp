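// Gated recurrent cells with trainable decay-based imputation.
//
// Variants (integer codes used throughout):
//   0  plain GRU        : both decay gates pinned to 1; intended for dense
//                         (pre-filled) inputs, reduces exactly to a standard
//                         GRU with the mask vector as an extra gate input.
//   1  GRU-D            : input decay pulls the last observation toward the
//                         channel's global mean; hidden state decays toward 0.
//                         Channels with no prior observation fall back to the
//                         global mean (the decay blend then collapses to it).
//   2  GRU-D++          : as GRU-D, but a trainable per-channel default x0
//                         stands in for the missing history, blended by the
//                         same decay gate with delta counted from stay start.
//
// Recurrence, per day t (D channels, H hidden units):
//   gx_t  = exp(-max(0, w_gx * delta_t + b_gx))            (per channel)
//   gh_t  = exp(-max(0, W_gh' delta_t + b_gh))             (to hidden size)
//   xl    = last observed value, or x0 / xbar without history
//   xhat  = m * x + (1 - m) * (gx * xl + (1 - gx) * xbar)
//   hh    = gh * h_{t-1}
//   z     = sigmoid(Wz' xhat + Uz' hh + Vz' m + bz)
//   r     = sigmoid(Wr' xhat + Ur' hh + Vr' m + br)
//   c     = tanh(Wc' xhat + Uc' (r * hh) + Vc' m + bc)
//   h_t   = (1 - z) * hh + z * c
//   logit_t = w_out . [h_t ; static] + b_out
//
// Missing entries of X are sanitized to 0 before use; the mask M is the only
// source of missingness information (NaN sentinels are never read as data).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uvec;

namespace {

struct Params {
  mat Wz, Uz, Vz, Wr, Ur, Vr, Wc, Uc, Vc; // D x H, H x H, D x H
  vec bz, br, bc;                          // H
  vec w_gx, b_gx;                          // D (diagonal input decay)
  mat W_gh;                                // D x H
  vec b_gh;                                // H
  vec x0;                                  // D (GRU-D++ no-history default)
  vec w_out;                               // H + S
  double b_out;
};

Params unpack(const List& p) {
  Params q;
  q.Wz = as<mat>(p["Wz"]); q.Uz = as<mat>(p["Uz"]); q.Vz = as<mat>(p["Vz"]);
  q.Wr = as<mat>(p["Wr"]); q.Ur = as<mat>(p["Ur"]); q.Vr = as<mat>(p["Vr"]);
  q.Wc = as<mat>(p["Wc"]); q.Uc = as<mat>(p["Uc"]); q.Vc = as<mat>(p["Vc"]);
  q.bz = as<vec>(p["bz"]); q.br = as<vec>(p["br"]); q.bc = as<vec>(p["bc"]);
  q.w_gx = as<vec>(p["w_gx"]); q.b_gx = as<vec>(p["b_gx"]);
  q.W_gh = as<mat>(p["W_gh"]); q.b_gh = as<vec>(p["b_gh"]);
  q.x0 = as<vec>(p["x0"]);
  q.w_out = as<vec>(p["w_out"]); q.b_out = as<double>(p["b_out"]);
  return q;
}

inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Per-stay caches for backprop.
struct Caches {
  mat gx, gxu, gh, ghu, xhat, hh, z, r, c, h, xl_eff, hist0, m, x, dl;
  // all T x D or T x H, row t = step t; hist0 = has-history state BEFORE step t
};

// Forward pass over one stay; fills caches if keep != nullptr.
// Returns the full hidden trajectory (T x H).
mat forward_stay(const Params& q, const mat& Xraw, const mat& M, const mat& DL,
                 const vec& xbar, int variant, Caches* keep) {
  const arma::uword T = Xraw.n_rows, D = Xraw.n_cols, H = q.bz.n_elem;
  mat X = Xraw;
  // sanitize: never read X where M == 0
  for (arma::uword i = 0; i < X.n_elem; ++i)
    if (M(i) == 0.0 || !std::isfinite(X(i))) X(i) = M(i) == 0.0 ? 0.0 : X(i);
  X.elem(arma::find_nonfinite(X)).zeros();

  vec h(H, arma::fill::zeros);
  vec last_val(D, arma::fill::zeros);
  vec hist(D, arma::fill::zeros);
  mat traj(T, H);
  if (keep) {
    keep->gx.set_size(T, D);  keep->gxu.set_size(T, D);
    keep->gh.set_size(T, H);  keep->ghu.set_size(T, H);
    keep->xhat.set_size(T, D); keep->hh.set_size(T, H);
    keep->z.set_size(T, H); keep->r.set_size(T, H); keep->c.set_size(T, H);
    keep->h.set_size(T, H); keep->xl_eff.set_size(T, D);
    keep->hist0.set_size(T, D); keep->m = M; keep->x = X; keep->dl = DL;
  }
  for (arma::uword t = 0; t < T; ++t) {
    vec x = X.row(t).t(), m = M.row(t).t(), dl = DL.row(t).t();
    vec gxu = q.w_gx % dl + q.b_gx;
    vec ghu = q.W_gh.t() * dl + q.b_gh;
    vec gx = arma::exp(-arma::clamp(gxu, 0.0, arma::datum::inf));
    vec gh = arma::exp(-arma::clamp(ghu, 0.0, arma::datum::inf));
    if (variant == 0) { gx.ones(); gh.ones(); }
    vec fallback = (variant == 2) ? q.x0 : xbar;
    vec xl = hist % last_val + (1.0 - hist) % fallback;
    vec xhat = m % x + (1.0 - m) % (gx % xl + (1.0 - gx) % xbar);
    vec hh = gh % h;
    vec z = sigmoid(q.Wz.t() * xhat + q.Uz.t() * hh + q.Vz.t() * m + q.bz);
    vec r = sigmoid(q.Wr.t() * xhat + q.Ur.t() * hh + q.Vr.t() * m + q.br);
    vec c = arma::tanh(q.Wc.t() * xhat + q.Uc.t() * (r % hh) + q.Vc.t() * m + q.bc);
    vec hnew = (1.0 - z) % hh + z % c;
    if (keep) {
      keep->gx.row(t) = gx.t(); keep->gxu.row(t) = gxu.t();
      keep->gh.row(t) = gh.t(); keep->ghu.row(t) = ghu.t();
      keep->xhat.row(t) = xhat.t(); keep->hh.row(t) = hh.t();
      keep->z.row(t) = z.t(); keep->r.row(t) = r.t(); keep->c.row(t) = c.t();
      keep->h.row(t) = hnew.t(); keep->xl_eff.row(t) = xl.t();
      keep->hist0.row(t) = hist.t();
    }
    h = hnew;
    traj.row(t) = h.t();
    last_val = m % x + (1.0 - m) % last_val;
    hist = arma::max(hist, m);
  }
  return traj;
}

struct Grads {
  mat Wz, Uz, Vz, Wr, Ur, Vr, Wc, Uc, Vc, W_gh;
  vec bz, br, bc, w_gx, b_gx, b_gh, x0, w_out;
  double b_out;
  void init(arma::uword D, arma::uword H, arma::uword P) {
    Wz.zeros(D, H); Uz.zeros(H, H); Vz.zeros(D, H);
    Wr.zeros(D, H); Ur.zeros(H, H); Vr.zeros(D, H);
    Wc.zeros(D, H); Uc.zeros(H, H); Vc.zeros(D, H);
    W_gh.zeros(D, H);
    bz.zeros(H); br.zeros(H); bc.zeros(H);
    w_gx.zeros(D); b_gx.zeros(D); b_gh.zeros(H);
    x0.zeros(D); w_out.zeros(P); b_out = 0.0;
  }
};

// Backprop through one stay given d(loss)/d(logit).
void backward_stay(const Params& q, const Caches& K, const vec& stat,
                   const vec& xbar, int variant, double dlogit, Grads& g) {
  const arma::uword T = K.m.n_rows, H = q.bz.n_elem;
  const arma::uword S = stat.n_elem;
  vec hT = K.h.row(T - 1).t();
  // readout
  for (arma::uword j = 0; j < H; ++j) g.w_out(j) += dlogit * hT(j);
  for (arma::uword s = 0; s < S; ++s) g.w_out(H + s) += dlogit * stat(s);
  g.b_out += dlogit;
  vec dh = dlogit * q.w_out.subvec(0, H - 1);

  for (arma::uword ti = T; ti-- > 0;) {
    vec z = K.z.row(ti).t(), r = K.r.row(ti).t(), c = K.c.row(ti).t();
    vec hh = K.hh.row(ti).t(), xhat = K.xhat.row(ti).t(), m = K.m.row(ti).t();
    vec gx = K.gx.row(ti).t(), gh = K.gh.row(ti).t();
    vec gxu = K.gxu.row(ti).t(), ghu = K.ghu.row(ti).t();
    vec xl = K.xl_eff.row(ti).t(), hist0 = K.hist0.row(ti).t();
    vec dl = K.dl.row(ti).t();
    vec h_prev = (ti == 0) ? vec(H, arma::fill::zeros) : vec(K.h.row(ti - 1).t());

    vec dz = dh % (c - hh);
    vec dc = dh % z;
    vec dhh = dh % (1.0 - z);
    vec dac = dc % (1.0 - c % c);
    vec daz = dz % z % (1.0 - z);
    vec d_rhh = q.Uc * dac;
    vec dr = d_rhh % hh;
    dhh += d_rhh % r;
    vec dar = dr % r % (1.0 - r);
    dhh += q.Uz * daz + q.Ur * dar;
    vec dxhat = q.Wz * daz + q.Wr * dar + q.Wc * dac;

    g.Wz += xhat * daz.t(); g.Uz += hh * daz.t(); g.Vz += m * daz.t(); g.bz += daz;
    g.Wr += xhat * dar.t(); g.Ur += hh * dar.t(); g.Vr += m * dar.t(); g.br += dar;
    g.Wc += xhat * dac.t(); g.Uc += (r % hh) * dac.t(); g.Vc += m * dac.t(); g.bc += dac;

    vec dgh = dhh % h_prev;
    vec dh_prev = dhh % gh;
    if (variant != 0) {
      vec dghu = -gh % dgh % arma::conv_to<vec>::from(ghu > 0.0);
      g.W_gh += dl * dghu.t();
      g.b_gh += dghu;
      vec dgx = (1.0 - m) % dxhat % (xl - xbar);
      vec dxl = (1.0 - m) % dxhat % gx;
      if (variant == 2) g.x0 += dxl % (1.0 - hist0);
      vec dgxu = -gx % dgx % arma::conv_to<vec>::from(gxu > 0.0);
      g.w_gx += dgxu % dl;
      g.b_gx += dgxu;
    }
    dh = dh_prev;
  }
}

} // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_grud_batch(List params, List Xs, List Ms, List Ds, arma::mat statics,
                    arma::vec y, arma::vec xbar, int variant, bool want_grad) {
  Params q = unpack(params);
  const int B = Xs.size();
  const arma::uword D = q.w_gx.n_elem, H = q.bz.n_elem, P = q.w_out.n_elem;
  Grads g;
  if (want_grad) g.init(D, H, P);
  vec probs(B), logits(B);
  double loss = 0.0;
  for (int i = 0; i < B; ++i) {
    mat X = as<mat>(Xs[i]), M = as<mat>(Ms[i]), DL = as<mat>(Ds[i]);
    vec stat = statics.row(i).t();
    Caches K;
    mat traj = forward_stay(q, X, M, DL, xbar, variant, want_grad ? &K : nullptr);
    vec hT = traj.row(traj.n_rows - 1).t();
    double logit = q.b_out + arma::dot(q.w_out.subvec(0, H - 1), hT);
    for (arma::uword s = 0; s < stat.n_elem; ++s) logit += q.w_out(H + s) * stat(s);
    double p = 1.0 / (1.0 + std::exp(-logit));
    logits(i) = logit; probs(i) = p;
    // numerically stable BCE on the logit
    double li = std::max(logit, 0.0) - logit * y(i) + std::log1p(std::exp(-std::fabs(logit)));
    loss += li / B;
    if (want_grad) backward_stay(q, K, stat, xbar, variant, (p - y(i)) / B, g);
  }
  List out = List::create(_["loss"] = loss, _["probs"] = probs, _["logits"] = logits);
  if (want_grad) {
    out["grads"] = List::create(
      _["Wz"] = g.Wz, _["Uz"] = g.Uz, _["Vz"] = g.Vz, _["bz"] = g.bz,
      _["Wr"] = g.Wr, _["Ur"] = g.Ur, _["Vr"] = g.Vr, _["br"] = g.br,
      _["Wc"] = g.Wc, _["Uc"] = g.Uc, _["Vc"] = g.Vc, _["bc"] = g.bc,
      _["w_gx"] = g.w_gx, _["b_gx"] = g.b_gx,
      _["W_gh"] = g.W_gh, _["b_gh"] = g.b_gh,
      _["x0"] = g.x0, _["w_out"] = g.w_out, _["b_out"] = g.b_out);
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
List cpp_grud_forward(List params, arma::mat X, arma::mat M, arma::mat DL,
                      arma::vec stat, arma::vec xbar, int variant) {
  Params q = unpack(params);
  const arma::uword H = q.bz.n_elem;
  mat traj = forward_stay(q, X, M, DL, xbar, variant, nullptr);
  vec traj_logit(traj.n_rows);
  for (arma::uword t = 0; t < traj.n_rows; ++t) {
    double logit = q.b_out + arma::dot(q.w_out.subvec(0, H - 1), traj.row(t).t());
    for (arma::uword s = 0; s < stat.n_elem; ++s) logit += q.w_out(H + s) * stat(s);
    traj_logit(t) = logit;
  }
  return List::create(_["traj_logit"] = traj_logit, _["hidden"] = traj);
}
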