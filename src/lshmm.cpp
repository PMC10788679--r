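#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Li-Stephens haplotype-copying HMM, scaled forward-backward.
//
// State space: which panel haplotype the target is copying at each marker.
// Transition between adjacent markers m and m+1 (switch rate theta[m]):
//   stay:            (1 - theta) + theta / H
//   move to k != h:  theta / H
// i.e. a "jump" event of probability theta lands uniformly on all H
// templates, including the current one.
// Emission at an observed marker (target allele t >= 0):
//   match -> 1 - eps[m], mismatch -> eps[m].
// Unobserved markers (t < 0) emit nothing.
//
// All recursions are rescaled per marker so the likelihood never underflows;
// posteriors are renormalized per marker.

struct FBWork {
  std::vector<double> fpre;  // M x H pre-emission forward (each row sums to 1)
  std::vector<double> fhat;  // M x H normalized forward
  std::vector<double> b;     // H   backward (current marker, sums to 1)
  std::vector<double> w;     // H   scratch
  void resize(int M, int H) {
    fpre.assign((size_t)M * H, 0.0);
    fhat.assign((size_t)M * H, 0.0);
    b.assign(H, 0.0);
    w.assign(H, 0.0);
  }
};

// One forward-backward sweep for a single target haplotype.
//  A        : M x Hfull panel allele matrix (0/1), column-major
//  exclude  : column to drop from the panel (-1 = none)
//  target   : length-M alleles, -1 = unobserved at that marker
// Outputs (any may be NULL):
//  hds, loo_hds : length-M posterior-weighted dosages; loo removes the
//                 marker's own emission (leave-one-out)
//  post, loo    : M x H posterior matrices over the *included* columns
//  exp_jump     : length M-1 posterior jump probabilities per interval
//  exp_mis      : length M  posterior mismatch probabilities (observed only)
// Returns the log-likelihood of the observed alleles.
static double fb_sweep(const int* A, int M, int Hfull, int exclude,
                       const int* target, const double* theta,
                       const double* eps, FBWork& wk,
                       double* hds, double* loo_hds,
                       double* post, double* loo,
                       double* exp_jump, double* exp_mis) {
  std::vector<int> cols;
  cols.reserve(Hfull);
  for (int h = 0; h < Hfull; ++h)
    if (h != exclude) cols.push_back(h);
  const int H = (int)cols.size();
  if (H < 1) stop("panel has no haplotypes");
  wk.resize(M, H);
  // compact, marker-major copy of the included panel columns: the inner
  // loops below run over haplotypes, so keep them contiguous in memory
  std::vector<int> At((size_t)M * H);
  for (int h = 0; h < H; ++h) {
    const int* col = A + (size_t)cols[h] * M;
    for (int m = 0; m < M; ++m) At[(size_t)m * H + h] = col[m];
  }

  double loglik = 0.0;
  const double invH = 1.0 / H;

  // forward
  for (int m = 0; m < M; ++m) {
    double* fp = &wk.fpre[(size_t)m * H];
    double* fh = &wk.fhat[(size_t)m * H];
    if (m == 0) {
      for (int h = 0; h < H; ++h) fp[h] = invH;
    } else {
      const double th = theta[m - 1];
      const double stay = 1.0 - th;
      const double* prev = &wk.fhat[(size_t)(m - 1) * H];
      const double jump = th * invH;  // sum(prev) == 1
      for (int h = 0; h < H; ++h) fp[h] = stay * prev[h] + jump;
    }
    const int t = target[m];
    double s = 0.0;
    if (t >= 0) {
      const double e1 = 1.0 - eps[m], e0 = eps[m];
      const int* Am = &At[(size_t)m * H];
      for (int h = 0; h < H; ++h) {
        const double f = fp[h] * (Am[h] == t ? e1 : e0);
        fh[h] = f;
        s += f;
      }
    } else {
      for (int h = 0; h < H; ++h) { fh[h] = fp[h]; s += fp[h]; }
    }
    if (s <= 0.0) stop("forward pass underflow at marker %d", m + 1);
    const double inv = 1.0 / s;
    for (int h = 0; h < H; ++h) fh[h] *= inv;
    loglik += std::log(s);
  }

  // backward, streaming posterior/dosage/count accumulation
  for (int h = 0; h < H; ++h) wk.b[h] = invH;
  for (int m = M - 1; m >= 0; --m) {
    if (m < M - 1) {
      // wk.w holds e_{m+1} * b_{m+1}; pull it back through the transition
      const double th = theta[m];
      double sw = 0.0;
      for (int h = 0; h < H; ++h) sw += wk.w[h];
      if (exp_jump) {
        const double* fh = &wk.fhat[(size_t)m * H];
        double nojump = 0.0;
        for (int h = 0; h < H; ++h) nojump += fh[h] * wk.w[h];
        nojump *= (1.0 - th);
        const double jmp = th * invH * sw;
        exp_jump[m] = (jmp + nojump > 0.0) ? jmp / (jmp + nojump) : 0.0;
      }
      const double stay = 1.0 - th, jump = th * invH;
      double sb = 0.0;
      for (int h = 0; h < H; ++h) {
        const double v = stay * wk.w[h] + jump * sw;
        wk.b[h] = v;
        sb += v;
      }
      const double inv = 1.0 / sb;
      for (int h = 0; h < H; ++h) wk.b[h] *= inv;
    }
    // posterior at m: fhat * b ; leave-one-out: fpre * b
    const double* fh = &wk.fhat[(size_t)m * H];
    const double* fp = &wk.fpre[(size_t)m * H];
    double sp = 0.0, sl = 0.0;
    for (int h = 0; h < H; ++h) {
      sp += fh[h] * wk.b[h];
      sl += fp[h] * wk.b[h];
    }
    const double ip = 1.0 / sp, il = 1.0 / sl;
    const int t = target[m];
    const int* Am = &At[(size_t)m * H];
    double dos = 0.0, dosl = 0.0, mis = 0.0;
    for (int h = 0; h < H; ++h) {
      const double pp = fh[h] * wk.b[h] * ip;
      const double pl = fp[h] * wk.b[h] * il;
      if (Am[h] == 1) { dos += pp; dosl += pl; }
      if (t >= 0 && Am[h] != t) mis += pp;
      if (post) post[(size_t)h * M + m] = pp;
      if (loo) loo[(size_t)h * M + m] = pl;
    }
    if (hds) hds[m] = std::min(std::max(dos, 0.0), 1.0);
    if (loo_hds) loo_hds[m] = std::min(std::max(dosl, 0.0), 1.0);
    if (exp_mis) exp_mis[m] = (t >= 0) ? mis : NA_REAL;
    // prepare wk.w = e_m * b_m for the next (leftward) step
    if (m > 0) {
      if (t >= 0) {
        const double e1 = 1.0 - eps[m], e0 = eps[m];
        for (int h = 0; h < H; ++h) {
          wk.w[h] = wk.b[h] * (Am[h] == t ? e1 : e0);
        }
      } else {
        for (int h = 0; h < H; ++h) wk.w[h] = wk.b[h];
      }
    }
  }
  return loglik;
}

// [[Rcpp::export]]
List ls_fb_cpp(IntegerMatrix A, IntegerVector target, NumericVector theta,
               NumericVector eps, bool return_posterior) {
  const int M = A.nrow(), H = A.ncol();
  if (target.size() != M) stop("target length must equal the marker count");
  if (theta.size() != std::max(M - 1, 0)) stop("theta must have length markers - 1");
  if (eps.size() != M) stop("epsilon must have length markers");
  FBWork wk;
  NumericVector hds(M), loo_hds(M), exp_mis(M);
  NumericVector exp_jump(std::max(M - 1, 0));
  NumericMatrix post, loo;
  double *pp = NULL, *pl = NULL;
  if (return_posterior) {
    post = NumericMatrix(M, H);
    loo = NumericMatrix(M, H);
    pp = REAL(post);
    pl = REAL(loo);
  }
  std::vector<int> tg(target.begin(), target.end());
  for (int m = 0; m < M; ++m)
    if (tg[m] == NA_INTEGER) tg[m] = -1;
  const double ll = fb_sweep(INTEGER(A), M, H, -1, tg.data(), REAL(theta),
                             REAL(eps), wk, REAL(hds), REAL(loo_hds), pp, pl,
                             M > 1 ? REAL(exp_jump) : NULL, REAL(exp_mis));
  List out = List::create(_["hds"] = hds, _["loo_hds"] = loo_hds,
                          _["loglik"] = ll, _["exp_jump"] = exp_jump,
                          _["exp_mis"] = exp_mis);
  if (return_posterior) {
    out["posterior"] = post;
    out["loo_posterior"] = loo;
  }
  return out;
}

// Leave-one-haplotype-out Baum-Welch over a panel: each haplotype in turn is
// treated as a fully observed target against the remaining panel; expected
// jump and mismatch counts are pooled across the held-out sweeps, and the
// M-step divides by the number of sweeps.
// [[Rcpp::export]]
List ls_em_cpp(IntegerMatrix A, NumericVector theta0, NumericVector eps0,
               int max_iter, double tol, bool pooled,
               double theta_floor, double theta_ceil,
               double eps_floor, double eps_ceil) {
  const int M = A.nrow(), H = A.ncol();
  if (H < 3) stop("parameter estimation needs at least 3 haplotypes");
  if (M < 2) stop("parameter estimation needs at least 2 markers");
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> eps(eps0.begin(), eps0.end());
  std::vector<double> jump(M - 1), mis(M), misn(M);
  std::vector<double> ej(M - 1), em(M);
  std::vector<int> tg(M);
  FBWork wk;
  NumericVector llTrace(max_iter);
  int iters = 0;
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    std::fill(jump.begin(), jump.end(), 0.0);
    std::fill(mis.begin(), mis.end(), 0.0);
    std::fill(misn.begin(), misn.end(), 0.0);
    double ll = 0.0;
    for (int j = 0; j < H; ++j) {
      for (int m = 0; m < M; ++m) tg[m] = A[(size_t)j * M + m];
      ll += fb_sweep(INTEGER(A), M, H, j, tg.data(), theta.data(), eps.data(),
                     wk, NULL, NULL, NULL, NULL, ej.data(), em.data());
      for (int m = 0; m < M - 1; ++m) jump[m] += ej[m];
      for (int m = 0; m < M; ++m)
        if (!ISNA(em[m])) { mis[m] += em[m]; misn[m] += 1.0; }
    }
    llTrace[it] = ll;
    iters = it + 1;
    // M-step
    double maxrel = 0.0;
    if (pooled) {
      double tot = 0.0;
      for (int m = 0; m < M - 1; ++m) tot += jump[m];
      double th = tot / ((double)H * (M - 1));
      th = std::min(std::max(th, theta_floor), theta_ceil);
      for (int m = 0; m < M - 1; ++m) {
        maxrel = std::max(maxrel, std::fabs(th - theta[m]) /
                                      std::max(theta[m], 1e-12));
        theta[m] = th;
      }
    } else {
      for (int m = 0; m < M - 1; ++m) {
        double th = jump[m] / (double)H;
        th = std::min(std::max(th, theta_floor), theta_ceil);
        maxrel = std::max(maxrel, std::fabs(th - theta[m]) /
                                      std::max(theta[m], 1e-12));
        theta[m] = th;
      }
    }
    for (int m = 0; m < M; ++m) {
      double e = (misn[m] > 0.0) ? mis[m] / misn[m] : eps[m];
      e = std::min(std::max(e, eps_floor), eps_ceil);
      maxrel = std::max(maxrel, std::fabs(e - eps[m]) / std::max(eps[m], 1e-12));
      eps[m] = e;
    }
    if (maxrel < tol) { converged = true; break; }
  }
  return List::create(
      _["theta"] = NumericVector(theta.begin(), theta.end()),
      _["eps"] = NumericVector(eps.begin(), eps.end()),
      _["loglik"] = llTrace[Range(0, iters - 1)],
      _["iterations"] = iters, _["converged"] = converged);
}

// Held-out total log-likelihood of a panel under given parameters (used to
// check EM monotonicity).
// [[Rcpp::export]]
double ls_panel_loglik_cpp(IntegerMatrix A, NumericVector theta,
                           NumericVector eps) {
  const int M = A.nrow(), H = A.ncol();
  std::vector<int> tg(M);
  FBWork wk;
  double ll = 0.0;
  for (int j = 0; j < H; ++j) {
    for (int m = 0; m < M; ++m) tg[m] = A[(size_t)j * M + m];
    ll += fb_sweep(INTEGER(A), M, H, j, tg.data(), REAL(theta), REAL(eps), wk,
                   NULL, NULL, NULL, NULL, NULL, NULL);
  }
  return ll;
}
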