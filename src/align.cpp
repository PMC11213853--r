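// Core numerical routines for penalized linear temporal alignment.
//
// Conventions (shared with the R wrappers):
//  * sequences are D x L matrices: one row per feature, one column per frame;
//  * the warp maps normalized time t in [0,1) onto the query's frame axis:
//      pos(t) = (tau + t * s) * domain_length, clamped to [0, L-1];
//  * the frame weights are 1 + hamming(minlen) over the first minlen frames
//    and exactly 1 over the padded tail (hamming: 0.54 - 0.46 cos(2 pi n/(N-1)));
//  * the warp penalty is r = atan(|tau|) + 1.5 * atan(|s - 1|).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PAD_EPS = 1e-6;

// 1 + symmetric Hamming window of length minlen, baseline 1 up to maxlen
static std::vector<double> raised_hamming(int minlen, int maxlen) {
  std::vector<double> w(maxlen, 1.0);
  if (minlen == 1) {
    w[0] = 2.0;  // degenerate window: single point gets full raise
    return w;
  }
  for (int i = 0; i < minlen; ++i)
    w[i] = 1.0 + 0.54 - 0.46 * std::cos(2.0 * M_PI * i / (minlen - 1));
  return w;
}

// [[Rcpp::export]]
NumericVector cpp_raised_hamming(int minlen, int maxlen) {
  std::vector<double> w = raised_hamming(minlen, maxlen);
  return NumericVector(w.begin(), w.end());
}

static double column_median(const double* col0, int D, int len, int d,
                            std::vector<double>& buf) {
  buf.clear();
  for (int t = 0; t < len; ++t) buf.push_back(col0[(size_t)t * D + d]);
  std::sort(buf.begin(), buf.end());
  int n = len;
  if (n % 2 == 1) return buf[n / 2];
  return 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
}

// weighted Euclidean distance between D x lx and D x ly; the shorter input is
// tail-padded with its own per-feature median + eps up to the longer length
// [[Rcpp::export]]
double cpp_weighted_euclidean(NumericMatrix x, NumericMatrix y) {
  int D = x.nrow();
  if (y.nrow() != D) stop("feature count mismatch: %d vs %d", D, y.nrow());
  int lx = x.ncol(), ly = y.ncol();
  int minlen = std::min(lx, ly), maxlen = std::max(lx, ly);
  std::vector<double> w = raised_hamming(minlen, maxlen);
  const double* px = x.begin();
  const double* py = y.begin();
  // pad values per feature for the shorter sequence
  std::vector<double> padx(D), pady(D), buf;
  buf.reserve(maxlen);
  if (lx < maxlen)
    for (int d = 0; d < D; ++d) padx[d] = column_median(px, D, lx, d, buf) + PAD_EPS;
  if (ly < maxlen)
    for (int d = 0; d < D; ++d) pady[d] = column_median(py, D, ly, d, buf) + PAD_EPS;
  double acc = 0.0;
  for (int t = 0; t < maxlen; ++t) {
    double wt = w[t];
    const double* cx = (t < lx) ? px + (size_t)t * D : padx.data();
    const double* cy = (t < ly) ? py + (size_t)t * D : pady.data();
    for (int d = 0; d < D; ++d) {
      double diff = cx[d] - cy[d];
      acc += wt * diff * diff;
    }
  }
  return std::sqrt(acc);
}

// linear warp of x (D x lx) onto out_len samples of normalized time
static void warp_into(const double* px, int D, int lx, double tau, double s,
                      int out_len, double domain_len, double* out) {
  for (int j = 0; j < out_len; ++j) {
    double t = (double)j / out_len;
    double pos = (tau + t * s) * domain_len;
    if (pos < 0.0) pos = 0.0;
    if (pos > lx - 1.0) pos = lx - 1.0;
    int lo = (int)std::floor(pos);
    if (lo > lx - 2) lo = lx - 2;
    if (lo < 0) lo = 0;
    double frac = pos - lo;
    const double* c0 = px + (size_t)lo * D;
    const double* c1 = px + (size_t)(lo + 1) * D;
    double* co = out + (size_t)j * D;
    for (int d = 0; d < D; ++d) co[d] = c0[d] + frac * (c1[d] - c0[d]);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_sequence(NumericMatrix x, double tau, double s,
                                int out_len, double domain_len) {
  int D = x.nrow(), lx = x.ncol();
  if (lx < 2) stop("sequence must have at least 2 frames");
  if (out_len < 2) stop("out_length must be >= 2");
  if (s <= 0) stop("slope s_w must be positive");
  NumericMatrix out(D, out_len);
  warp_into(x.begin(), D, lx, tau, s, out_len, domain_len, out.begin());
  return out;
}

// [[Rcpp::export]]
double cpp_penalty(double tau, double s) {
  return std::atan(std::fabs(tau)) + 1.5 * std::atan(std::fabs(s - 1.0));
}

// alignment problem: warp query to the template length, weighted distance,
// plus alpha * penalty; buffers preallocated once per problem.
// penalty_ratio scales (tau, s) before the penalty: 1 penalizes the raw
// normalized-domain parameters, lq/lt penalizes the effective real-time
// shift and dilation (so stretching a long query onto a short template is
// a warp, not a free squeeze).
struct AlignProblem {
  const double* q;
  const double* tmpl;
  int D, lq, lt;
  double alpha, ratio;
  std::vector<double> w;       // raised hamming, length lt (equal lengths: no pad)
  std::vector<double> warped;  // D * lt scratch
  AlignProblem(const double* q_, int D_, int lq_, const double* tmpl_, int lt_,
               double alpha_, bool effective)
      : q(q_), tmpl(tmpl_), D(D_), lq(lq_), lt(lt_), alpha(alpha_),
        ratio(effective ? (double)lq_ / lt_ : 1.0),
        w(raised_hamming(lt_, lt_)), warped((size_t)D_ * lt_) {}
  double loss(double tau, double s) {
    warp_into(q, D, lq, tau, s, lt, (double)lq, warped.data());
    double acc = 0.0;
    for (int t = 0; t < lt; ++t) {
      double wt = w[t];
      const double* ca = warped.data() + (size_t)t * D;
      const double* cb = tmpl + (size_t)t * D;
      for (int d = 0; d < D; ++d) {
        double diff = ca[d] - cb[d];
        acc += wt * diff * diff;
      }
    }
    return std::sqrt(acc) + alpha * cpp_penalty(tau * ratio, s * ratio);
  }
};

// [[Rcpp::export]]
double cpp_alignment_loss(NumericMatrix query, NumericMatrix tmpl, double tau,
                          double s, double alpha, bool effective) {
  if (query.nrow() != tmpl.nrow()) stop("feature count mismatch");
  AlignProblem prob(query.begin(), query.nrow(), query.ncol(), tmpl.begin(),
                    tmpl.ncol(), alpha, effective);
  return prob.loss(tau, s);
}

struct Box {
  double tlo, thi, slo, shi;
  void clamp(double& tau, double& s) const {
    tau = std::min(std::max(tau, tlo), thi);
    s = std::min(std::max(s, slo), shi);
  }
};

// Nelder-Mead in 2-D with box projection; deterministic
static void nelder_mead(AlignProblem& prob, const Box& box, double tau0,
                        double s0, double step_t, double step_s, int maxit,
                        double tol, double& best_t, double& best_s,
                        double& best_f) {
  double px[3] = {tau0, tau0 + step_t, tau0};
  double py[3] = {s0, s0, s0 + step_s};
  double pf[3];
  for (int i = 0; i < 3; ++i) {
    box.clamp(px[i], py[i]);
    pf[i] = prob.loss(px[i], py[i]);
  }
  for (int it = 0; it < maxit; ++it) {
    // order: 0 best, 2 worst
    int idx[3] = {0, 1, 2};
    std::sort(idx, idx + 3, [&](int a, int b) { return pf[a] < pf[b]; });
    double qx[3] = {px[idx[0]], px[idx[1]], px[idx[2]]};
    double qy[3] = {py[idx[0]], py[idx[1]], py[idx[2]]};
    double qf[3] = {pf[idx[0]], pf[idx[1]], pf[idx[2]]};
    std::copy(qx, qx + 3, px);
    std::copy(qy, qy + 3, py);
    std::copy(qf, qf + 3, pf);
    double size = std::fabs(px[1] - px[0]) + std::fabs(px[2] - px[0]) +
                  std::fabs(py[1] - py[0]) + std::fabs(py[2] - py[0]);
    if (size < tol && pf[2] - pf[0] < tol) break;
    double cx = 0.5 * (px[0] + px[1]), cy = 0.5 * (py[0] + py[1]);
    double rx = cx + (cx - px[2]), ry = cy + (cy - py[2]);
    box.clamp(rx, ry);
    double rf = prob.loss(rx, ry);
    if (rf < pf[0]) {
      double ex = cx + 2.0 * (cx - px[2]), ey = cy + 2.0 * (cy - py[2]);
      box.clamp(ex, ey);
      double ef = prob.loss(ex, ey);
      if (ef < rf) { px[2] = ex; py[2] = ey; pf[2] = ef; }
      else { px[2] = rx; py[2] = ry; pf[2] = rf; }
    } else if (rf < pf[1]) {
      px[2] = rx; py[2] = ry; pf[2] = rf;
    } else {
      double kx = cx + 0.5 * (px[2] - cx), ky = cy + 0.5 * (py[2] - cy);
      box.clamp(kx, ky);
      double kf = prob.loss(kx, ky);
      if (kf < pf[2]) { px[2] = kx; py[2] = ky; pf[2] = kf; }
      else {  // shrink toward best
        for (int i = 1; i < 3; ++i) {
          px[i] = px[0] + 0.5 * (px[i] - px[0]);
          py[i] = py[0] + 0.5 * (py[i] - py[0]);
          box.clamp(px[i], py[i]);
          pf[i] = prob.loss(px[i], py[i]);
        }
      }
    }
  }
  int ib = 0;
  if (pf[1] < pf[ib]) ib = 1;
  if (pf[2] < pf[ib]) ib = 2;
  best_t = px[ib]; best_s = py[ib]; best_f = pf[ib];
}

static void align_one(AlignProblem& prob, const Box& box, int n_tau, int n_s,
                      int n_refine, int maxit, double tol, double& out_t,
                      double& out_s, double& out_f) {
  // coarse deterministic sampling of the box
  int n = n_tau * n_s;
  std::vector<double> gt(n), gs(n), gf(n);
  std::vector<int> ord(n);
  double dt = (n_tau > 1) ? (box.thi - box.tlo) / (n_tau - 1) : 0.0;
  double ds = (n_s > 1) ? (box.shi - box.slo) / (n_s - 1) : 0.0;
  int k = 0;
  for (int i = 0; i < n_tau; ++i)
    for (int j = 0; j < n_s; ++j, ++k) {
      gt[k] = box.tlo + i * dt;
      gs[k] = box.slo + j * ds;
      gf[k] = prob.loss(gt[k], gs[k]);
      ord[k] = k;
    }
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return gf[a] < gf[b]; });
  double bt = gt[ord[0]], bs = gs[ord[0]], bf = gf[ord[0]];
  // local refinement from the best starts (always include the identity warp)
  double step_t = std::max(dt * 0.5, 1e-3), step_s = std::max(ds * 0.5, 1e-3);
  int nref = std::min(n_refine, n);
  for (int r = 0; r < nref; ++r) {
    double t1, s1, f1;
    nelder_mead(prob, box, gt[ord[r]], gs[ord[r]], step_t, step_s, maxit, tol,
                t1, s1, f1);
    if (f1 < bf) { bt = t1; bs = s1; bf = f1; }
  }
  // always try the identity transform (raw and, when it differs, the
  // effective-dilation identity s = lt/lq)
  double ids[2] = {1.0, 1.0 / prob.ratio};
  for (int k = 0; k < (prob.ratio == 1.0 ? 1 : 2); ++k) {
    double s0 = ids[k];
    if (box.tlo > 0.0 || box.thi < 0.0 || box.slo > s0 || box.shi < s0)
      continue;
    double t1, s1, f1;
    nelder_mead(prob, box, 0.0, s0, step_t, step_s, maxit, tol, t1, s1, f1);
    if (f1 < bf) { bt = t1; bs = s1; bf = f1; }
    double f_id = prob.loss(0.0, s0);
    if (f_id < bf) { bt = 0.0; bs = s0; bf = f_id; }
  }
  out_t = bt; out_s = bs; out_f = bf;
}

// [[Rcpp::export]]
NumericVector cpp_linear_align(NumericMatrix query, NumericMatrix tmpl,
                               double alpha, double tau_lo, double tau_hi,
                               double s_lo, double s_hi, int n_tau, int n_s,
                               int n_refine, int maxit, double tol,
                               bool effective) {
  if (query.nrow() != tmpl.nrow()) stop("feature count mismatch");
  AlignProblem prob(query.begin(), query.nrow(), query.ncol(), tmpl.begin(),
                    tmpl.ncol(), alpha, effective);
  Box box{tau_lo, tau_hi, s_lo, s_hi};
  double t, s, f;
  align_one(prob, box, n_tau, n_s, n_refine, maxit, tol, t, s, f);
  return NumericVector::create(_["tau_w"] = t, _["s_w"] = s, _["cost"] = f);
}

// exhaustive search over explicit parameter grids (oracle / fallback)
// [[Rcpp::export]]
NumericVector cpp_grid_align(NumericMatrix query, NumericMatrix tmpl,
                             double alpha, NumericVector tau_grid,
                             NumericVector s_grid, bool effective) {
  if (query.nrow() != tmpl.nrow()) stop("feature count mismatch");
  AlignProblem prob(query.begin(), query.nrow(), query.ncol(), tmpl.begin(),
                    tmpl.ncol(), alpha, effective);
  double bf = R_PosInf, bt = NA_REAL, bs = NA_REAL;
  for (int i = 0; i < tau_grid.size(); ++i)
    for (int j = 0; j < s_grid.size(); ++j) {
      double f = prob.loss(tau_grid[i], s_grid[j]);
      if (f < bf) { bf = f; bt = tau_grid[i]; bs = s_grid[j]; }
    }
  return NumericVector::create(_["tau_w"] = bt, _["s_w"] = bs, _["cost"] = bf);
}

// batch alignment of signal slices [starts[i], ends[i]) against one template;
// starts/ends are 0-based half-open frame indices into signal (D x T)
// [[Rcpp::export]]
NumericMatrix cpp_align_slices(NumericMatrix sig, IntegerVector starts,
                               IntegerVector ends, NumericMatrix tmpl,
                               double alpha, double tau_lo, double tau_hi,
                               double s_lo, double s_hi, int n_tau, int n_s,
                               int n_refine, int maxit, double tol,
                               bool effective) {
  int D = sig.nrow(), T = sig.ncol(), n = starts.size();
  if (tmpl.nrow() != D) stop("feature count mismatch");
  Box box{tau_lo, tau_hi, s_lo, s_hi};
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("tau_w", "s_w", "cost");
  std::vector<double> slice;
  for (int i = 0; i < n; ++i) {
    int a = starts[i], b = ends[i];
    if (a < 0 || b > T || b - a < 2) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
      continue;
    }
    int len = b - a;
    slice.assign(sig.begin() + (size_t)a * D, sig.begin() + (size_t)b * D);
    AlignProblem prob(slice.data(), D, len, tmpl.begin(), tmpl.ncol(), alpha,
                      effective);
    double t, s, f;
    align_one(prob, box, n_tau, n_s, n_refine, maxit, tol, t, s, f);
    out(i, 0) = t; out(i, 1) = s; out(i, 2) = f;
  }
  return out;
}

// pairwise weighted Euclidean distances between a list of D x L_i matrices
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_wdist(List seqs) {
  int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<NumericMatrix> mats;
  mats.reserve(n);
  for (int i = 0; i < n; ++i) mats.push_back(as<NumericMatrix>(seqs[i]));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = cpp_weighted_euclidean(mats[i], mats[j]);
      out(i, j) = d;
      out(j, i) = d;
    }
  return out;
}
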